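test_that("patch layouts follow the size/stride formula and cover fully", {
  l1 <- make_layout(c(500, 500), 1)
  expect_equal(l1$py, 500L)
  expect_equal(nrow(l1$patches), 1L)
  expect_equal(l1$patches$oy, 0L)
  # L = 1000, n = 2, overlap 0.2 -> p = 600, origins 0 and 400
  l2 <- make_layout(c(1000, 1000), 2, 0.2)
  expect_equal(l2$px, 600L)
  expect_equal(sort(unique(l2$patches$ox)), c(0L, 400L))
  expect_equal(nrow(l2$patches), 4L)
  expect_error(make_layout(c(100, 100), 0), "n")
  # coverage: every pixel in at least one patch
  set.seed(61)
  for (i in 1:100) {
    L <- sample(100:1200, 1)
    n <- sample(1:4, 1)
    ov <- runif(1, 0, 0.5)
    l <- make_layout(c(L, L), n, ov)
    covered <- logical(L)
    for (o in unique(l$patches$ox)) covered[o + seq_len(l$px)] <- TRUE
    expect_true(all(covered))
    expect_equal(max(unique(l$patches$ox)) + l$px, L)
  }
})

test_that("greedy NMS keeps the highest-confidence duplicate, idempotent", {
  dup <- boxes_df(cx = c(100, 102), cy = c(100, 101), w = 40, h = 40,
                  confidence = c(0.8, 0.7))
  kept <- nms(dup, 0.3)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$confidence, 0.8)
  set.seed(62)
  many <- random_boxes(60, lim = 150)
  once <- nms(many, 0.3)
  twice <- nms(once, 0.3)
  expect_equal(once, twice)
  # survivors are mutually below the threshold
  if (nrow(once) > 1) {
    m <- iou_matrix(once, once)
    diag(m) <- 0
    expect_lt(max(m), 0.3)
  }
})

# oracle forward function: emits exactly the encoded ground truth for
# whatever patch geometry pick_particles uses
oracle_forward <- function(truth_boxes, layout, insz) {
  force(truth_boxes); force(layout); force(insz)
  function(model, xs) {
    S <- insz / 32L
    out <- array(0, c(S, S, 6, length(xs)))
    sy <- layout$py / insz; sx <- layout$px / insz
    for (i in seq_len(nrow(layout$patches))) {
      oy <- layout$patches$oy[i]; ox <- layout$patches$ox[i]
      b <- truth_boxes
      inb <- b$cx >= ox & b$cx < ox + layout$px - 1 &
             b$cy >= oy & b$cy < oy + layout$py - 1
      b <- b[inb, , drop = FALSE]
      if (nrow(b) > 0) {
        bb <- boxes_df(cx = (b$cx - ox + 0.5) / sx - 0.5,
                       cy = (b$cy - oy + 0.5) / sy - 0.5,
                       w = b$w / sx, h = b$h / sy)
        tgt <- suppressWarnings(encode_boxes(bb, model$grid))
        out[, , , i] <- cryopick:::target_to_pred(tgt)
      }
    }
    out
  }
}

test_that("an oracle detector recovers planted boxes through the patch
           plumbing", {
  set.seed(63)
  truth <- boxes_df(cx = c(60, 200, 330, 430), cy = c(80, 260, 120, 400),
                    w = 48, h = 48)
  mic <- matrix(rnorm(512 * 512), 512)
  model <- build_detector(network_config(input_size = 128, reduced = TRUE,
                                         filter_cap = 4),
                          box_size = 12, seed = 1)
  for (n in c(1, 2)) {
    layout <- make_layout(c(512, 512), n, 0.2)
    sx <- layout$px / 128
    model$grid <- grid_spec(128, 48 / sx)
    picks <- pick_particles(model, mic, layout, conf_threshold = 0.5,
                            nms_iou = 0.3,
                            forward_fn = oracle_forward(truth, layout, 128))
    expect_equal(nrow(picks), nrow(truth))
    ord <- order(picks$cx)
    expect_lt(max(abs(picks$cx[ord] - sort(truth$cx))), 2)
    mr <- match_picks(picks, truth, 0.6)
    expect_equal(mr$tp, nrow(truth))
  }
  # patching invariance of the pipeline: every planted particle is
  # recovered identically by the 1x1 and 2x2 layouts
  both <- lapply(c(1, 2), function(n) {
    layout <- make_layout(c(512, 512), n, 0.2)
    sx <- layout$px / 128
    model$grid <- grid_spec(128, 48 / sx)
    pick_particles(model, mic, layout, conf_threshold = 0.5, nms_iou = 0.3,
                   forward_fn = oracle_forward(truth, layout, 128))
  })
  agree <- match_picks(both[[1]], both[[2]], 0.6)
  expect_gte(agree$tp / nrow(truth), 0.95)
})

test_that("a trained detector recovers the planted particles it was
           fitted on", {
  # train once on the shared noise-free fixture; a detector is trained at
  # one patch scale, so picking uses the training layout (the vignette
  # documents this layout sensitivity)
  samples <- tiny_training_set()
  model <- cached("tiny_trained_model", {
    cfg <- train_config(learning_rate = 2e-3, batch_size = 2,
                        max_epochs = 100, early_stop_patience = 100,
                        validation_fraction = 0.2, seed = 5, box_size = 36,
                        augmentation = NULL)
    fit_detector(tiny_detector(input_size = 192, cap = 16, seed = 3),
                 samples, cfg)
  })
  for (i in 1:3) {
    mic <- samples[[i]]$micrograph
    truth <- samples[[i]]$boxes
    p1 <- pick_particles(model, mic, make_layout(dim(mic), 1),
                         conf_threshold = 0.3)
    mr <- match_picks(p1, truth, 0.6)
    expect_gte(mr$tp / nrow(truth), 0.95)
  }
})

test_that("picks are clipped to the micrograph and sorted by confidence", {
  set.seed(64)
  b <- boxes_df(cx = c(2, 50, 99), cy = c(50, 2, 99), w = 20, h = 20,
                confidence = c(0.5, 0.9, 0.7))
  clipped <- cryopick:::clip_boxes(b, c(100, 100))
  expect_equal(nrow(clipped), 3)
  expect_true(all(clipped$cx - clipped$w / 2 >= -0.5))
  expect_true(all(clipped$cy + clipped$h / 2 <= 99.5))
})

test_that("pick_batch skips unreadable files and counts boxes per file", {
  samples <- tiny_training_set()
  model <- cached("tiny_trained_model", stop("fixture missing"))
  dir <- file.path(tempdir(), "batch_in")
  out <- file.path(tempdir(), "batch_out")
  dir.create(dir, showWarnings = FALSE)
  for (i in 1:3)
    write_mrc(samples[[i]]$micrograph, file.path(dir,
                                                 sprintf("m%02d.mrc", i)))
  writeLines("not an mrc", file.path(dir, "corrupt.mrc"))
  paths <- list.files(dir, full.names = TRUE)
  expect_warning(summ <- pick_batch(model, paths, out,
                                    conf_threshold = 0.3),
                 "skipping")
  expect_equal(sum(is.na(summ$n_particles)), 1)
  ok <- which(!is.na(summ$n_particles))
  expect_length(ok, 3)
  for (i in ok) {
    lines <- readLines(summ$output[i])
    expect_equal(length(lines), summ$n_particles[i])
  }
  unlink(c(dir, out), recursive = TRUE)
})

test_that("impossible thresholds and untrained models are rejected", {
  model <- tiny_detector(input_size = 96, cap = 4)
  mic <- matrix(rnorm(96 * 96), 96)
  expect_error(pick_particles(model, mic), "untrained")
  samples <- tiny_training_set()
  trained <- cached("tiny_trained_model", stop("fixture missing"))
  # confidence can never reach 1.0 through the logistic output
  p <- pick_particles(trained, samples[[1]]$micrograph,
                      conf_threshold = 1.0)
  expect_equal(nrow(p), 0)
})
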