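#' Overlapping patch layout for a micrograph
#'
#' Splits an image into an `n x n` grid of overlapping square-ish patches.
#' Per axis of length L the patch size is
#' `p = min(L, ceiling(L * (1 + overlap_frac * (n - 1)) / n))` and patch
#' origins are evenly spaced with the last patch flush with the image edge,
#' so every pixel is covered by at least one patch. Each patch is later
#' downscaled to the network input size; `n = 1` means the whole micrograph
#' is downscaled as one patch.
#'
#' @param image_shape Integer vector `c(rows, cols)`.
#' @param n Patches per side (>= 1).
#' @param overlap_frac Fractional linear overlap between adjacent patches.
#' @return A list of class `patch_layout` with per-axis patch sizes
#'   (`py`, `px`), origin vectors and the patch table (`oy`, `ox` 0-based).
#' @export
make_layout <- function(image_shape, n = 1, overlap_frac = 0.2) {
  if (n < 1) stop_cfg("patch count n must be >= 1")
  n <- as.integer(n)
  axis_layout <- function(L) {
    if (n == 1) return(list(p = L, origins = 0L))
    p <- min(L, ceiling(L * (1 + overlap_frac * (n - 1)) / n))
    s <- (L - p) / (n - 1)
    origins <- as.integer(round(s * (0:(n - 1))))
    origins[n] <- L - p
    list(p = as.integer(p), origins = origins)
  }
  ay <- axis_layout(as.integer(image_shape[1]))
  ax <- axis_layout(as.integer(image_shape[2]))
  patches <- expand.grid(oy = ay$origins, ox = ax$origins)
  structure(list(n = n, overlap_frac = overlap_frac,
                 image_shape = as.integer(image_shape[1:2]),
                 py = ay$p, px = ax$p, patches = patches),
            class = "patch_layout")
}

# resize a patch to the square network input (block mean for integer
# downscale factors, bilinear otherwise)
resize_to_input <- function(patch, input_size) {
  if (nrow(patch) == input_size && ncol(patch) == input_size) return(patch)
  if (nrow(patch) == ncol(patch) && nrow(patch) %% input_size == 0)
    return(cpp_block_mean(patch, nrow(patch) %/% input_size))
  cpp_resize_bilinear(patch, input_size, input_size)
}

# pixel-center coordinate maps between patch frame and input frame
patch_to_input_coord <- function(u, scale) (u + 0.5) / scale - 0.5
input_to_patch_coord <- function(u, scale) (u + 0.5) * scale - 0.5

#' Greedy non-maximum suppression
#'
#' Keeps boxes in descending confidence order, discarding any box whose IOU
#' with an already kept box is at least `iou_threshold`. Idempotent.
#'
#' @param boxes A [boxes_df()] data frame.
#' @param iou_threshold Suppression IOU cutoff.
#' @return The surviving boxes, sorted by descending confidence.
#' @export
nms <- function(boxes, iou_threshold = 0.3) {
  if (nrow(boxes) <= 1) return(boxes)
  ord <- order(-boxes$confidence)
  boxes <- boxes[ord, , drop = FALSE]
  keep <- logical(nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    if (i == 1) { keep[1] <- TRUE; next }
    kept <- boxes[keep, , drop = FALSE]
    ious <- iou_matrix(boxes[i, , drop = FALSE], kept)
    keep[i] <- all(ious < iou_threshold)
  }
  out <- boxes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# clip box extents to the image rectangle (pixel area spans [-0.5, L-0.5])
clip_boxes <- function(boxes, image_shape) {
  if (nrow(boxes) == 0) return(boxes)
  x0 <- pmax(boxes$cx - boxes$w / 2, -0.5)
  x1 <- pmin(boxes$cx + boxes$w / 2, image_shape[2] - 0.5)
  y0 <- pmax(boxes$cy - boxes$h / 2, -0.5)
  y1 <- pmin(boxes$cy + boxes$h / 2, image_shape[1] - 0.5)
  ok <- x1 > x0 & y1 > y0
  boxes_df(cx = ((x0 + x1) / 2)[ok], cy = ((y0 + y1) / 2)[ok],
           w = (x1 - x0)[ok], h = (y1 - y0)[ok],
           confidence = boxes$confidence[ok])
}

#' Pick particles from a micrograph
#'
#' Each patch of the layout is normalized, downscaled to the network input,
#' passed through the detector in a single batch, and decoded at
#' `conf_threshold`; boxes are mapped back to micrograph pixels, duplicates
#' from overlapping patches are removed by greedy non-maximum suppression,
#' boxes are clipped to the micrograph bounds and returned sorted by
#' descending confidence.
#'
#' @param model A trained [build_detector()] model (with a grid/anchor).
#' @param mic Micrograph matrix.
#' @param layout A [make_layout()]; default is a single full-image patch.
#' @param conf_threshold Confidence cutoff in (0, 1\].
#' @param nms_iou IOU threshold for cross-patch duplicate suppression.
#' @param forward_fn Prediction function `(model, patches) -> S x S x 6 x B`
#'   array; defaults to [forward_detector()]. An idealized oracle (one that
#'   emits encoded ground truth) can be injected here to exercise the
#'   patching, decoding and suppression plumbing in isolation.
#' @return Picked [boxes_df()] in micrograph pixel coordinates.
#' @export
pick_particles <- function(model, mic, layout = NULL, conf_threshold = 0.3,
                           nms_iou = 0.3, forward_fn = NULL) {
  if (is.null(model$grid))
    stop_cfg("model has no grid/anchor; train it or supply box_size")
  if (is.null(forward_fn) && !isTRUE(model$trained))
    stop_cfg("model is untrained; fit it before picking")
  layout <- layout %||% make_layout(dim(mic), 1)
  insz <- model$cfg$input_size
  sy <- layout$py / insz; sx <- layout$px / insz
  # the reference box is a physical particle size: express it in input
  # pixels at this layout's patch scale, so decoded sizes are layout
  # independent (falls back to the stored grid for hand-built models)
  grid <- if (!is.null(model$box_size))
    grid_spec(insz, model$box_size / sx, model$box_size / sy)
  else model$grid
  xs <- vector("list", nrow(layout$patches))
  for (i in seq_len(nrow(layout$patches))) {
    oy <- layout$patches$oy[i]; ox <- layout$patches$ox[i]
    patch <- mic[oy + seq_len(layout$py), ox + seq_len(layout$px),
                 drop = FALSE]
    xs[[i]] <- normalize_image(resize_to_input(patch, insz))
  }
  pred <- if (is.null(forward_fn)) forward_detector(model, xs,
                                                    training = FALSE)
          else forward_fn(model, xs)
  all_boxes <- list()
  for (i in seq_len(nrow(layout$patches))) {
    b <- decode_grid(pred[, , , i], grid, threshold = conf_threshold)
    if (nrow(b) == 0) next
    oy <- layout$patches$oy[i]; ox <- layout$patches$ox[i]
    all_boxes[[length(all_boxes) + 1]] <-
      boxes_df(cx = ox + input_to_patch_coord(b$cx, sx),
               cy = oy + input_to_patch_coord(b$cy, sy),
               w = b$w * sx, h = b$h * sy, confidence = b$confidence)
  }
  if (length(all_boxes) == 0) return(boxes_df())
  merged <- do.call(rbind, all_boxes)
  class(merged) <- c("boxes", "data.frame")
  clip_boxes(nms(merged, nms_iou), dim(mic))
}

#' Pick a batch of micrograph files
#'
#' Reads each micrograph, picks particles and writes one coordinate file
#' per input. Unreadable files are skipped with a warning rather than
#' aborting the batch.
#'
#' @param model Trained detector.
#' @param paths Character vector of micrograph file paths.
#' @param out_dir Output directory for coordinate files.
#' @param format Output coordinate format.
#' @param layout_n,overlap_frac Patch layout parameters.
#' @param conf_threshold,nms_iou Picking thresholds.
#' @return Data frame summary with one row per input: `path`, `n_particles`
#'   (`NA` for skipped files), `output`.
#' @export
pick_batch <- function(model, paths, out_dir,
                       format = c("eman1_box", "star"), layout_n = 1,
                       overlap_frac = 0.2, conf_threshold = 0.3,
                       nms_iou = 0.3) {
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "star") ".star" else ".box"
  n <- length(paths)
  counts <- rep(NA_integer_, n)
  outputs <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    mic <- tryCatch(read_micrograph(paths[i]), error = function(e) {
      warning("skipping unreadable micrograph ", paths[i], ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(mic)) next
    layout <- make_layout(dim(mic), layout_n, overlap_frac)
    picks <- pick_particles(model, mic, layout, conf_threshold, nms_iou)
    out <- file.path(out_dir,
                     paste0(tools::file_path_sans_ext(basename(paths[i])),
                            ext))
    write_boxes(picks, out, format = format)
    counts[i] <- nrow(picks)
    outputs[i] <- out
  }
  data.frame(path = paths, n_particles = counts, output = outputs,
             stringsAsFactors = FALSE)
}
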