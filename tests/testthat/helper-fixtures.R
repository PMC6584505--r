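# Shared fixtures and independent oracles used across the suite.

# tiny reduced detector for fast forward/backward tests
tiny_detector <- function(input_size = 64, cap = 8, box_size = 24,
                          seed = 2) {
  build_detector(network_config(input_size = input_size, reduced = TRUE,
                                filter_cap = cap),
                 box_size = box_size, seed = seed)
}

random_boxes <- function(n, lim = 200, wmin = 4, wmax = 40, snap = NULL) {
  rnd <- function(lo, hi, grid) {
    v <- runif(n, lo, hi)
    if (!is.null(grid)) round(v / grid) * grid else v
  }
  # centers land on the snap lattice, sizes on twice the lattice, so box
  # edges never coincide with raster sampling points offset by snap/2
  boxes_df(cx = rnd(0, lim, snap), cy = rnd(0, lim, snap),
           w = pmax(rnd(wmin, wmax, if (is.null(snap)) NULL else 2 * snap),
                    wmin),
           h = pmax(rnd(wmin, wmax, if (is.null(snap)) NULL else 2 * snap),
                    wmin),
           confidence = runif(n))
}

# Fine-raster IOU oracle: counts raster cells whose centers fall inside
# each box. Exact for boxes whose edges lie on the raster; within O(step)
# otherwise. Independent of the analytic implementation.
raster_iou <- function(a, b, step = 1) {
  x0 <- min(a$cx - a$w / 2, b$cx - b$w / 2) - 1
  x1 <- max(a$cx + a$w / 2, b$cx + b$w / 2) + 1
  y0 <- min(a$cy - a$h / 2, b$cy - b$h / 2) - 1
  y1 <- max(a$cy + a$h / 2, b$cy + b$h / 2) + 1
  xs <- seq(x0 + step / 2, x1, by = step)
  ys <- seq(y0 + step / 2, y1, by = step)
  inside <- function(bx, px, py)
    outer(py >= bx$cy - bx$h / 2 & py < bx$cy + bx$h / 2,
          px >= bx$cx - bx$w / 2 & px < bx$cx + bx$w / 2, "&")
  ina <- inside(a, xs, ys)
  inb <- inside(b, xs, ys)
  sum(ina & inb) / sum(ina | inb)
}

# Literal term-by-term reference of the detection loss: explicit loops over
# every grid cell, written independently of detection_loss().
reference_loss <- function(pred, target, w) {
  S <- nrow(target$obj)
  total <- 0
  for (r in seq_len(S)) for (cc in seq_len(S)) {
    if (target$obj[r, cc] == 1) {
      total <- total + w$lambda_coord *
        ((target$x[r, cc] - pred[r, cc, 1])^2 +
         (target$y[r, cc] - pred[r, cc, 2])^2)
      total <- total + w$lambda_coord *
        ((sqrt(target$w[r, cc]) - sqrt(pred[r, cc, 3]))^2 +
         (sqrt(target$h[r, cc]) - sqrt(pred[r, cc, 4]))^2)
      total <- total + w$lambda_obj * (target$C[r, cc] - pred[r, cc, 5])^2
      total <- total + w$lambda_obj * (1 - pred[r, cc, 6])^2
    } else {
      total <- total + w$lambda_noobj * (0 - pred[r, cc, 5])^2
      total <- total + w$lambda_noobj * (0 - pred[r, cc, 6])^2
    }
  }
  total
}

# random valid (pred, target) pair on an S x S grid
random_pred_target <- function(S, n_obj = NULL, anchor = 32) {
  g <- grid_spec(S * 32, anchor)
  n_obj <- n_obj %||% sample(0:min(4, S * S), 1)
  cells <- sample(S * S, n_obj)
  b <- NULL
  if (n_obj > 0) {
    r <- (cells - 1) %% S; cc <- (cells - 1) %/% S
    b <- boxes_df(cx = (cc + runif(n_obj)) * 32,
                  cy = (r + runif(n_obj)) * 32,
                  w = runif(n_obj, 5, 60), h = runif(n_obj, 5, 60))
  } else b <- boxes_df()
  target <- encode_boxes(b, g)
  pred <- array(runif(S * S * 6), c(S, S, 6))
  pred[, , 3] <- exp(runif(S * S, -1, 1))
  pred[, , 4] <- exp(runif(S * S, -1, 1))
  list(pred = pred, target = target)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force PR oracle: for each threshold re-match the thresholded pick
# set from scratch with an independently written greedy matcher.
oracle_pr <- function(picks, truth, iou_threshold) {
  simple_match <- function(p, tr) {
    used <- logical(nrow(tr))
    tp <- 0L
    for (i in order(p$confidence, decreasing = TRUE)) {
      best <- 0; bj <- 0
      for (j in seq_len(nrow(tr))) {
        if (used[j]) next
        v <- iou(p[i, , drop = FALSE], tr[j, , drop = FALSE])
        if (v > best) { best <- v; bj <- j }
      }
      if (bj > 0 && best > iou_threshold) { used[bj] <- TRUE; tp <- tp + 1L }
    }
    tp
  }
  th <- sort(unique(picks$confidence), decreasing = TRUE)
  prec <- rec <- numeric(length(th))
  for (k in seq_along(th)) {
    sel <- picks[picks$confidence >= th[k], , drop = FALSE]
    tp <- simple_match(sel, truth)
    prec[k] <- tp / nrow(sel)
    rec[k] <- if (nrow(truth) == 0) 1 else tp / nrow(truth)
  }
  list(thresholds = th, precision = prec, recall = rec)
}

# scaled-down simulated study set shared by the training-based tests:
# 20 micrographs, 10 planted particles each, geometry chosen so that the
# 256-px reduced network sees the same particle-to-cell ratio as the
# full-scale recipe (template spans two grid cells, hard-core spacing
# exceeds the cell diagonal, so no two centers share a cell)
study_spec <- function(k, seed = 11) {
  sim_spec(k = k, n_micrographs = 20, micrograph_size = 512,
           template_size = 128, particles_per_micrograph = 10, seed = seed)
}

# cache heavyweight fixtures (simulated sets, trained models) per session
fixture_env <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, fixture_env)) assign(key, force(expr), fixture_env)
  get(key, fixture_env)
}

# tiny noise-free training fixture: 6 micrographs of 192 px with 3 planted
# blobs each, spaced so every box owns its own grid cell at network input
# 96 (downscale factor 2)
tiny_training_set <- function() {
  cached("tiny_training_set", {
    spec <- sim_spec(k = 0, n_micrographs = 6, micrograph_size = 192,
                     template_size = 36, particles_per_micrograph = 3,
                     min_center_distance = 92, seed = 52)
    sims <- simulate_dataset(spec)
    lapply(sims, function(s) list(micrograph = s$micrograph,
                                  boxes = s$boxes))
  })
}

# train the reduced detector on a simulated study set and return the
# pooled validation AUC and operating-point mean IOU
train_and_score <- function(sims, label_frac = 1, seed = 11,
                            max_epochs = 60) {
  samples <- lapply(sims[1:19], function(s)
    list(micrograph = s$micrograph, boxes = s$boxes))
  if (label_frac < 1) {
    sp0 <- split_dataset(19, 0.21, seed = seed)
    set.seed((seed * 7919 + 5) %% .Machine$integer.max)
    for (i in sp0$train) {
      n <- nrow(samples[[i]]$boxes)
      keep <- sample(n, max(1, round(label_frac * n)))
      samples[[i]]$boxes <- samples[[i]]$boxes[sort(keep), , drop = FALSE]
    }
  }
  model <- build_detector(network_config(input_size = 256, reduced = TRUE,
                                         filter_cap = 32), seed = seed + 1)
  cfg <- train_config(learning_rate = 1e-3, batch_size = 4,
                      max_epochs = max_epochs, early_stop_patience = 10,
                      validation_fraction = 0.21, seed = seed,
                      box_size = 128)
  model <- fit_detector(model, samples, cfg)
  sp <- split_dataset(19, 0.21, seed = seed)
  picks <- list(); truths <- list()
  for (i in sp$validation) {
    picks[[length(picks) + 1]] <-
      pick_particles(model, sims[[i]]$micrograph, conf_threshold = 0.05,
                     nms_iou = 0.3)
    truths[[length(truths) + 1]] <- sims[[i]]$boxes
  }
  auc <- pooled_pr_curve(picks, truths, 0.6)$auc
  ious <- unlist(lapply(seq_along(picks), function(j) {
    p <- picks[[j]][picks[[j]]$confidence >= 0.3, , drop = FALSE]
    match_picks(p, truths[[j]], 0.6)$pairs$iou
  }))
  list(model = model, auc = auc,
       mean_iou = if (length(ious)) mean(ious) else NA_real_)
}
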