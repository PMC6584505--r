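#' Particle bounding boxes
#'
#' Boxes are stored as a data frame with one row per particle and columns
#' `cx`, `cy` (continuous center coordinates, 0-based pixels, origin at the
#' top-left of the stored array, x = column, y = row), `w`, `h` (side lengths
#' in pixels) and `confidence` in \[0, 1\] (1 for ground truth).
#'
#' @param cx,cy Box centers in pixels.
#' @param w,h Box side lengths in pixels (positive).
#' @param confidence Detection confidence in \[0, 1\].
#' @return A data frame of class `boxes` with the five columns above.
#' @export
boxes_df <- function(cx = numeric(), cy = numeric(), w = numeric(),
                     h = numeric(), confidence = 1) {
  n <- max(length(cx), length(cy))
  if (n > 0) {
    w <- rep_len(w, n); h <- rep_len(h, n)
    confidence <- rep_len(confidence, n)
  } else {
    w <- h <- confidence <- numeric()
  }
  if (any(w <= 0) || any(h <= 0)) stop_cfg("box sides must be positive")
  if (any(confidence < 0 | confidence > 1))
    stop_cfg("confidence must lie in [0, 1]")
  out <- data.frame(cx = as.numeric(cx), cy = as.numeric(cy), w = w, h = h,
                    confidence = confidence)
  class(out) <- c("boxes", "data.frame")
  out
}

#' Detection grid specification
#'
#' The detector downsamples its input by a factor of 32, so a square input of
#' `input_size` pixels is predicted on an S-by-S grid with S = input_size/32.
#' Box sizes are regressed relative to a single reference ("anchor") box whose
#' side lengths are the expected particle box size in network-input pixels.
#'
#' @param input_size Network input side length in pixels; must be divisible
#'   by 32.
#' @param anchor_w,anchor_h Reference box side lengths in input pixels.
#' @return A list of class `grid_spec` with fields `input_size`, `S`,
#'   `cell` (= 32) and the anchors.
#' @export
grid_spec <- function(input_size, anchor_w, anchor_h = anchor_w) {
  if (input_size %% 32 != 0) stop_cfg("input_size must be divisible by 32")
  if (anchor_w <= 0 || anchor_h <= 0) stop_cfg("anchors must be positive")
  structure(list(input_size = as.integer(input_size),
                 S = as.integer(input_size / 32), cell = 32L,
                 anchor_w = anchor_w, anchor_h = anchor_h),
            class = "grid_spec")
}

#' Intersection over union of axis-aligned boxes
#'
#' Computed analytically on the continuous box extents. Vectorized
#' elementwise over the rows of `a` and `b` (recycled).
#'
#' @param a,b Boxes as produced by [boxes_df()] (data frames with `cx`, `cy`,
#'   `w`, `h`).
#' @return Numeric vector of IOU values in \[0, 1\].
#' @export
iou <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  if (n == 0) return(numeric())
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  ix <- pmax(0, pmin(a$cx[ai] + a$w[ai] / 2, b$cx[bi] + b$w[bi] / 2) -
                pmax(a$cx[ai] - a$w[ai] / 2, b$cx[bi] - b$w[bi] / 2))
  iy <- pmax(0, pmin(a$cy[ai] + a$h[ai] / 2, b$cy[bi] + b$h[bi] / 2) -
                pmax(a$cy[ai] - a$h[ai] / 2, b$cy[bi] - b$h[bi] / 2))
  inter <- ix * iy
  union <- a$w[ai] * a$h[ai] + b$w[bi] * b$h[bi] - inter
  inter / union
}

# IOU between every row of a and every row of b: |a| x |b| matrix
iou_matrix <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0)
    return(matrix(0, nrow(a), nrow(b)))
  ix <- pmax(0, outer(a$cx + a$w / 2, b$cx + b$w / 2, pmin) -
                outer(a$cx - a$w / 2, b$cx - b$w / 2, pmax))
  iy <- pmax(0, outer(a$cy + a$h / 2, b$cy + b$h / 2, pmin) -
                outer(a$cy - a$h / 2, b$cy - b$h / 2, pmax))
  inter <- ix * iy
  inter / (outer(a$w * a$h, b$w * b$h, "+") - inter)
}

#' Encode boxes onto the detection grid
#'
#' Each box center selects the grid cell containing it (index
#' `floor(center/32)`); the cell stores the fractional offset of the center
#' within the cell, the box size as a ratio to the anchor, and objectness and
#' confidence targets of 1. At most one box can live in a cell: on conflict
#' the largest box wins (ties broken by lowest `cy`, then lowest `cx`) and
#' the number of dropped boxes is recorded in the `n_dropped` field.
#'
#' @param boxes Boxes in network-input pixel coordinates; centers must lie in
#'   `[0, input_size)`.
#' @param grid A [grid_spec()].
#' @return A list of class `target_tensor` with S-by-S matrices `obj`, `x`,
#'   `y`, `w`, `h`, `C`, the `grid`, and `n_dropped`.
#' @export
encode_boxes <- function(boxes, grid) {
  S <- grid$S; cell <- grid$cell
  t0 <- matrix(0, S, S)
  out <- structure(list(obj = t0, x = t0, y = t0, w = t0, h = t0, C = t0,
                        grid = grid, n_dropped = 0L),
                   class = "target_tensor")
  if (nrow(boxes) == 0) return(out)
  if (any(boxes$cx < 0 | boxes$cx >= grid$input_size |
          boxes$cy < 0 | boxes$cy >= grid$input_size))
    stop_cfg("box centers must lie inside [0, input_size)")
  ci <- floor(boxes$cx / cell)  # 0-based column
  ri <- floor(boxes$cy / cell)  # 0-based row
  # deterministic conflict resolution: largest area, then lowest cy, cx
  ord <- order(-(boxes$w * boxes$h), boxes$cy, boxes$cx)
  keyseen <- character()
  dropped <- 0L
  for (i in ord) {
    key <- paste(ri[i], ci[i])
    if (key %in% keyseen) { dropped <- dropped + 1L; next }
    keyseen <- c(keyseen, key)
    r <- ri[i] + 1; cc <- ci[i] + 1
    out$obj[r, cc] <- 1
    out$x[r, cc] <- (boxes$cx[i] - ci[i] * cell) / cell
    out$y[r, cc] <- (boxes$cy[i] - ri[i] * cell) / cell
    out$w[r, cc] <- boxes$w[i] / grid$anchor_w
    out$h[r, cc] <- boxes$h[i] / grid$anchor_h
    out$C[r, cc] <- 1
  }
  out$n_dropped <- dropped
  if (dropped > 0)
    warning(sprintf("%d box(es) dropped: grid cell already occupied", dropped))
  out
}

#' Decode a grid tensor into boxes
#'
#' The inverse of [encode_boxes()]: every cell whose confidence meets
#' `threshold` yields one box with center `(cell_index + offset) * 32` and
#' size `ratio * anchor`.
#'
#' @param x A `target_tensor` or a prediction array of shape S-by-S-by-6 with
#'   channels (x, y, w, h, confidence, class score); the class score channel
#'   is ignored.
#' @param grid A [grid_spec()]; defaults to the grid stored in a
#'   `target_tensor`.
#' @param threshold Confidence cutoff; cells with `C >= threshold` are kept.
#' @return Boxes in network-input pixel coordinates.
#' @export
decode_grid <- function(x, grid = NULL, threshold = 0.5) {
  if (inherits(x, "target_tensor")) {
    grid <- grid %||% x$grid
    comp <- x
  } else {
    if (is.null(grid)) stop_cfg("grid required for array input")
    stopifnot(length(dim(x)) == 3, dim(x)[3] >= 5)
    comp <- list(x = x[, , 1], y = x[, , 2], w = x[, , 3], h = x[, , 4],
                 C = x[, , 5])
  }
  keep <- which(comp$C >= threshold, arr.ind = TRUE)
  if (nrow(keep) == 0) return(boxes_df())
  r <- keep[, 1]; cc <- keep[, 2]
  idx <- cbind(r, cc)
  boxes_df(cx = (cc - 1 + comp$x[idx]) * grid$cell,
           cy = (r - 1 + comp$y[idx]) * grid$cell,
           w = comp$w[idx] * grid$anchor_w,
           h = comp$h[idx] * grid$anchor_h,
           confidence = comp$C[idx])
}
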