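#' Per-image normalization
#'
#' Standardizes an image to zero mean and unit SD; a constant image maps to
#' all zeros. Any affine rescaling `a * img + b` (a > 0) of the input yields
#' the identical normalized output, which makes the detector indifferent to
#' camera gain and offset.
#'
#' @param img Numeric matrix.
#' @return Normalized matrix.
#' @export
normalize_image <- function(img) {
  s <- sd(img)
  if (!is.finite(s) || s == 0) return(img * 0)
  (img - mean(img)) / s
}

#' Micrograph-level train/validation split
#'
#' Holds out `round(N * fraction)` micrographs for validation (never a
#' particle-level split), deterministically under the seed.
#'
#' @param n_samples Number of labeled micrographs.
#' @param fraction Validation fraction.
#' @param seed RNG seed.
#' @return `list(train, validation)` of sample indices.
#' @export
split_dataset <- function(n_samples, fraction = 0.2, seed = 1) {
  if (fraction <= 0 || fraction >= 1)
    stop_cfg("validation fraction must be in (0, 1)")
  n_val <- round(n_samples * fraction)
  val <- with_seed(child_seed(seed, "split"),
                   sort(sample.int(n_samples, n_val)))
  list(train = setdiff(seq_len(n_samples), val), validation = val)
}

#' Training configuration
#'
#' @param learning_rate ADAM step size.
#' @param batch_size Patches per optimization step.
#' @param max_epochs Epoch budget.
#' @param early_stop_patience Stop after this many epochs without
#'   validation-loss improvement; the best-validation weights are returned.
#' @param validation_fraction Micrograph-level hold-out fraction.
#' @param seed Master seed governing the split, augmentation, dropout and
#'   batch order.
#' @param loss A [loss_weights()] object.
#' @param augmentation An [augmentation_config()], or `NULL` to train
#'   without augmentation.
#' @param patches_n,overlap_frac Patch layout used for training;
#'   `patches_n` may be a vector (e.g. `c(1, 2)`) to pool training patches
#'   from several layouts, making the detector robust to the layout chosen
#'   at prediction time.
#' @param box_size Particle box size in micrograph pixels; defaults to the
#'   median ground-truth box size.
#' @param adam_beta1,adam_beta2,adam_eps ADAM moment parameters.
#' @param verbose Print per-epoch loss lines.
#' @param log_file Optional path receiving per-epoch log lines.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 4,
                         max_epochs = 100, early_stop_patience = 10,
                         validation_fraction = 0.20, seed = 1,
                         loss = loss_weights(),
                         augmentation = augmentation_config(),
                         patches_n = 1, overlap_frac = 0.2,
                         box_size = NULL, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, adam_eps = 1e-8,
                         verbose = FALSE, log_file = NULL) {
  if (batch_size < 1) stop_cfg("batch_size must be >= 1")
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop_cfg("validation_fraction must be in (0, 1)")
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 max_epochs = max_epochs,
                 early_stop_patience = early_stop_patience,
                 validation_fraction = validation_fraction, seed = seed,
                 loss = loss, augmentation = augmentation,
                 patches_n = patches_n, overlap_frac = overlap_frac,
                 box_size = box_size, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, adam_eps = adam_eps,
                 verbose = verbose, log_file = log_file),
            class = "train_config")
}

# crop/rescale one labeled micrograph into (input, target) training patches
sample_to_patches <- function(img, boxes, layout, insz, grid) {
  sy <- layout$py / insz; sx <- layout$px / insz
  out <- vector("list", nrow(layout$patches))
  for (i in seq_len(nrow(layout$patches))) {
    oy <- layout$patches$oy[i]; ox <- layout$patches$ox[i]
    patch <- img[oy + seq_len(layout$py), ox + seq_len(layout$px),
                 drop = FALSE]
    inb <- boxes$cx >= ox - 0.5 & boxes$cx < ox + layout$px - 0.5 &
           boxes$cy >= oy - 0.5 & boxes$cy < oy + layout$py - 0.5
    b <- boxes[inb, , drop = FALSE]
    if (nrow(b) > 0) {
      cx <- patch_to_input_coord(b$cx - ox, sx)
      cy <- patch_to_input_coord(b$cy - oy, sy)
      b <- boxes_df(cx = pmin(pmax(cx, 0), insz - 1e-6),
                    cy = pmin(pmax(cy, 0), insz - 1e-6),
                    w = b$w / sx, h = b$h / sy,
                    confidence = b$confidence)
    }
    target <- suppressWarnings(encode_boxes(b, grid))
    out[[i]] <- list(x = normalize_image(resize_to_input(patch, insz)),
                     target = target)
  }
  out
}

adam_init <- function(weights, head) {
  zero_like <- function(p) lapply(p, function(v) v * 0)
  list(m = c(lapply(weights, function(l) zero_like(l[c("W", "gamma",
                                                       "beta")])),
             list(head = zero_like(head))),
       v = c(lapply(weights, function(l) zero_like(l[c("W", "gamma",
                                                       "beta")])),
             list(head = zero_like(head))),
       t = 0)
}

adam_step <- function(state, model, grads, head_grads, cfg) {
  state$t <- state$t + 1
  b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  upd <- function(p, g, m, v) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    p <- p - cfg$learning_rate * (m / corr1) /
      (sqrt(v / corr2) + cfg$adam_eps)
    list(p = p, m = m, v = v)
  }
  for (i in seq_along(model$weights)) {
    gl <- grads[[i]]
    for (nm in c("W", "gamma", "beta")) {
      gname <- paste0("d", nm)
      r <- upd(model$weights[[i]][[nm]], gl[[gname]],
               state$m[[i]][[nm]], state$v[[i]][[nm]])
      model$weights[[i]][[nm]] <- r$p
      state$m[[i]][[nm]] <- r$m
      state$v[[i]][[nm]] <- r$v
    }
  }
  hslot <- length(model$weights) + 1
  for (nm in c("W", "b")) {
    gname <- paste0("d", nm)
    r <- upd(model$head[[nm]], head_grads[[gname]],
             state$m[[hslot]][[nm]], state$v[[hslot]][[nm]])
    model$head[[nm]] <- r$p
    state$m[[hslot]][[nm]] <- r$m
    state$v[[hslot]][[nm]] <- r$v
  }
  list(state = state, model = model)
}

# gradient of the activated prediction w.r.t. the raw head output
head_activation_grad <- function(act) {
  d <- act
  d[, , c(1, 2, 5, 6)] <- act[, , c(1, 2, 5, 6)] *
    (1 - act[, , c(1, 2, 5, 6)])
  # exp channels: d act / d raw = act
  d
}

#' Train the detector on labeled micrographs
#'
#' Splits the micrographs into training and validation sets, then per epoch
#' augments every training micrograph, crops and downscales it into network
#' input patches, encodes the boxes into grid targets, and optimizes the
#' detection loss with ADAM. Validation loss is computed without
#' augmentation or dropout after every epoch; training stops at
#' `max_epochs` or once the validation loss has not improved for
#' `early_stop_patience` epochs, and the weights from the best validation
#' epoch are returned. Deterministic under the config seed (with
#' single-threaded numerics).
#'
#' @param model A [build_detector()] model.
#' @param samples List of labeled micrographs, each
#'   `list(micrograph = matrix, boxes = boxes_df)`; all micrographs must
#'   share one shape.
#' @param cfg A [train_config()].
#' @return The trained model; `model$history` holds per-epoch train and
#'   validation losses, `model$best_epoch` the selected epoch.
#' @export
fit_detector <- function(model, samples, cfg = train_config()) {
  if (length(samples) < 1 ||
      !any(vapply(samples, function(s) nrow(s$boxes) > 0, logical(1))))
    stop_cfg("need at least one training micrograph with at least one box")
  shp <- dim(samples[[1]]$micrograph)
  for (s in samples)
    if (!all(dim(s$micrograph) == shp))
      stop_cfg("all training micrographs must share one shape")
  insz <- model$cfg$input_size
  # patches_n may hold several layouts (e.g. c(1, 2)): training then pools
  # patches at every scale, which makes the detector robust to the patch
  # layout chosen at prediction time
  layouts <- lapply(cfg$patches_n, function(n)
    make_layout(shp, n, cfg$overlap_frac))
  box_size_mic <- cfg$box_size %||%
    median(unlist(lapply(samples, function(s) s$boxes$w)))
  # the reference box is physical: its size in input pixels follows each
  # layout's patch scale
  grids <- lapply(layouts, function(l)
    grid_spec(insz, box_size_mic * insz / l$px, box_size_mic * insz / l$py))
  if (is.null(model$grid)) model$grid <- grids[[1]]
  model$box_size <- box_size_mic

  sp <- split_dataset(length(samples), cfg$validation_fraction, cfg$seed)
  if (length(sp$train) == 0) stop_cfg("empty training split")
  all_patches <- function(img, boxes) {
    unlist(lapply(seq_along(layouts), function(li)
      sample_to_patches(img, boxes, layouts[[li]], insz, grids[[li]])),
      recursive = FALSE)
  }
  val_patches <- unlist(lapply(sp$validation, function(i)
    all_patches(samples[[i]]$micrograph, samples[[i]]$boxes)),
    recursive = FALSE)

  log_line <- function(...) {
    msg <- sprintf(...)
    if (cfg$verbose) message(msg)
    if (!is.null(cfg$log_file)) cat(msg, "\n", file = cfg$log_file,
                                    append = TRUE)
  }

  cpp_cfg <- net_cfg_for_cpp(model$cfg)
  c21 <- model$cfg$filters_per_layer[21]
  S <- model$grid$S
  adam <- adam_init(model$weights, model$head)
  best <- list(val = Inf, epoch = 0L, weights = NULL, head = NULL)
  wait <- 0L
  hist_train <- hist_val <- numeric()

  val_loss <- function() {
    if (length(val_patches) == 0) return(NA_real_)
    xs <- lapply(val_patches, `[[`, "x")
    pred <- forward_detector(model, xs, training = FALSE)
    mean(vapply(seq_along(val_patches), function(j)
      detection_loss(pred[, , , j, drop = TRUE], val_patches[[j]]$target,
                     cfg$loss), numeric(1)))
  }

  set.seed(child_seed(cfg$seed, "train"))
  for (epoch in seq_len(cfg$max_epochs)) {
    pool <- list()
    for (i in sample(sp$train)) {
      img <- samples[[i]]$micrograph; bx <- samples[[i]]$boxes
      if (!is.null(cfg$augmentation)) {
        a <- augment(img, bx, cfg$augmentation)
        img <- a$img; bx <- a$boxes
      }
      pool <- c(pool, all_patches(img, bx))
    }
    pool <- pool[sample(length(pool))]
    nb <- ceiling(length(pool) / cfg$batch_size)
    epoch_loss <- 0; npatch <- 0
    for (b in seq_len(nb)) {
      idx <- ((b - 1) * cfg$batch_size + 1):min(b * cfg$batch_size,
                                                length(pool))
      batch <- pool[idx]
      B <- length(batch)
      mask <- array((runif(S * S * c21 * B) >= model$cfg$dropout_rate) /
                      (1 - model$cfg$dropout_rate), c(S, S, c21, B))
      cb <- function(raw) {
        act <- apply_head_activations(raw)
        d <- array(0, dim(raw))
        total <- 0
        for (j in seq_len(B)) {
          aj <- act[, , , j, drop = TRUE]
          total <- total + detection_loss(aj, batch[[j]]$target, cfg$loss)
          d[, , , j] <- detection_loss_grad(aj, batch[[j]]$target,
                                            cfg$loss) *
            head_activation_grad(aj) / B
        }
        list(loss = total / B, d = d)
      }
      res <- cpp_net_run(cpp_cfg, model$weights, model$head,
                         lapply(batch, `[[`, "x"), TRUE, mask, cb, 0.9)
      if (!is.finite(res$loss))
        stop("training diverged: non-finite loss at epoch ", epoch)
      for (i in seq_along(model$weights)) {
        model$weights[[i]]$rmean <- res$new_running[[i]]$rmean
        model$weights[[i]]$rvar <- res$new_running[[i]]$rvar
      }
      st <- adam_step(adam, model, res$grads, res$head_grads, cfg)
      adam <- st$state; model <- st$model
      epoch_loss <- epoch_loss + res$loss * B
      npatch <- npatch + B
    }
    tr <- epoch_loss / npatch
    vl <- val_loss()
    hist_train <- c(hist_train, tr); hist_val <- c(hist_val, vl)
    log_line("epoch %d train_loss %.6f val_loss %.6f", epoch, tr,
             if (is.na(vl)) NaN else vl)
    crit <- if (is.na(vl)) tr else vl
    if (crit < best$val - 1e-9) {
      best <- list(val = crit, epoch = epoch, weights = model$weights,
                   head = model$head)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > cfg$early_stop_patience) break
    }
  }
  if (!is.null(best$weights)) {
    model$weights <- best$weights
    model$head <- best$head
  }
  model$trained <- TRUE
  model$best_epoch <- best$epoch
  model$history <- data.frame(epoch = seq_along(hist_train),
                              train_loss = hist_train, val_loss = hist_val)
  model$train_layouts <- layouts
  model
}
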