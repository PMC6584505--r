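#' Match picks against ground truth
#'
#' Greedy confidence-ordered assignment: picks are visited in descending
#' confidence; each is matched to the still-unmatched truth box with the
#' highest IOU provided that IOU exceeds `iou_threshold` (strictly), else it
#' is a false positive. Truth boxes left unmatched are false negatives, so
#' every pick is classified exactly once and `TP + FN = |truth|`.
#'
#' @param picks Picked [boxes_df()] (with confidences).
#' @param truth Ground-truth [boxes_df()].
#' @param iou_threshold IOU cutoff for a true positive (strict `>`).
#' @return A list of class `match_result`: `pairs` (data frame `pick`,
#'   `truth`, `iou` of matched index pairs), `fp_idx`, `fn_idx`, and counts
#'   `tp`, `fp`, `fn`.
#' @export
match_picks <- function(picks, truth, iou_threshold = 0.6) {
  ord <- order(-picks$confidence)
  im <- iou_matrix(picks, truth)
  matched <- logical(nrow(truth))
  pr <- integer(); tr <- integer(); pi_iou <- numeric(); fp <- integer()
  for (i in ord) {
    cand <- which(!matched)
    if (length(cand) > 0) {
      j <- cand[which.max(im[i, cand])]
      if (im[i, j] > iou_threshold) {
        matched[j] <- TRUE
        pr <- c(pr, i); tr <- c(tr, j); pi_iou <- c(pi_iou, im[i, j])
        next
      }
    }
    fp <- c(fp, i)
  }
  structure(list(pairs = data.frame(pick = pr, truth = tr, iou = pi_iou),
                 fp_idx = fp, fn_idx = which(!matched),
                 tp = length(pr), fp = length(fp),
                 fn = sum(!matched)), class = "match_result")
}

#' Precision and recall of a match result
#'
#' `precision = TP / (TP + FP)` (1 when there are no picks) and
#' `recall = TP / (TP + FN)` (1 when there are no truth boxes).
#'
#' @param mr A [match_picks()] result.
#' @return Named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(mr) {
  precision <- if (mr$tp + mr$fp == 0) 1 else mr$tp / (mr$tp + mr$fp)
  recall <- if (mr$tp + mr$fn == 0) 1 else mr$tp / (mr$tp + mr$fn)
  c(precision = precision, recall = recall)
}

#' Mean IOU of matched pairs
#'
#' @param mr A [match_picks()] result.
#' @return Mean IOU over true-positive pairs, `NA` if there are none.
#' @export
mean_iou <- function(mr) {
  if (mr$tp == 0) return(NA_real_)
  mean(mr$pairs$iou)
}

#' Precision-recall curve and AUC
#'
#' Sweeps the operating threshold over the distinct pick confidences. With
#' greedy confidence-ordered matching the assignment of a pick never depends
#' on lower-confidence picks, so the per-threshold points equal re-matching
#' the thresholded pick set from scratch at every threshold. The AUC is the
#' trapezoidal integral of precision over recall, anchored at recall 0 with
#' the precision of the highest-confidence operating point.
#'
#' @inheritParams match_picks
#' @return A list of class `pr_curve` with `thresholds`, `precision`,
#'   `recall` (one operating point per distinct confidence, decreasing
#'   threshold order) and `auc`.
#' @export
pr_curve <- function(picks, truth, iou_threshold = 0.6) {
  n_truth <- nrow(truth)
  if (nrow(picks) == 0) {
    return(structure(list(thresholds = numeric(), precision = numeric(),
                          recall = numeric(),
                          auc = if (n_truth == 0) 1 else 0),
                     class = "pr_curve"))
  }
  ord <- order(-picks$confidence)
  im <- iou_matrix(picks, truth)
  matched <- logical(n_truth)
  is_tp <- logical(length(ord))
  for (k in seq_along(ord)) {
    i <- ord[k]
    cand <- which(!matched)
    if (length(cand) > 0 && n_truth > 0) {
      j <- cand[which.max(im[i, cand])]
      if (im[i, j] > iou_threshold) {
        matched[j] <- TRUE
        is_tp[k] <- TRUE
      }
    }
  }
  conf_sorted <- picks$confidence[ord]
  cum_tp <- cumsum(is_tp)
  cum_n <- seq_along(ord)
  # one operating point per distinct confidence (include all picks >= t)
  last_of <- which(diff(c(conf_sorted, -Inf)) != 0)
  thresholds <- conf_sorted[last_of]
  precision <- cum_tp[last_of] / cum_n[last_of]
  recall <- if (n_truth == 0) rep(1, length(last_of))
            else cum_tp[last_of] / n_truth
  auc <- if (n_truth == 0) 1 else {
    r <- c(0, recall); p <- c(precision[1], precision)
    sum(diff(r) * (head(p, -1) + tail(p, -1)) / 2)
  }
  structure(list(thresholds = thresholds, precision = precision,
                 recall = recall, auc = auc), class = "pr_curve")
}

#' Pooled precision-recall curve over several micrographs
#'
#' Matches picks to truth within each micrograph (greedy, confidence
#' ordered), then pools every pick's (confidence, matched) outcome into one
#' ranked list and computes a single precision-recall curve and AUC against
#' the total truth count. This is the aggregate operating curve of a picker
#' on a micrograph set.
#'
#' @param picks_list,truth_list Parallel lists of [boxes_df()] data frames.
#' @param iou_threshold IOU cutoff for a true positive.
#' @return A `pr_curve` object (see [pr_curve()]).
#' @export
pooled_pr_curve <- function(picks_list, truth_list, iou_threshold = 0.6) {
  stopifnot(length(picks_list) == length(truth_list))
  conf <- numeric(); hit <- logical(); n_truth <- 0L
  for (i in seq_along(picks_list)) {
    p <- picks_list[[i]]; tr <- truth_list[[i]]
    n_truth <- n_truth + nrow(tr)
    if (nrow(p) == 0) next
    mr <- match_picks(p, tr, iou_threshold)
    is_tp <- logical(nrow(p))
    is_tp[mr$pairs$pick] <- TRUE
    conf <- c(conf, p$confidence)
    hit <- c(hit, is_tp)
  }
  if (length(conf) == 0) {
    return(structure(list(thresholds = numeric(), precision = numeric(),
                          recall = numeric(),
                          auc = if (n_truth == 0) 1 else 0),
                     class = "pr_curve"))
  }
  ord <- order(-conf)
  conf_sorted <- conf[ord]
  cum_tp <- cumsum(hit[ord])
  cum_n <- seq_along(ord)
  last_of <- which(diff(c(conf_sorted, -Inf)) != 0)
  precision <- cum_tp[last_of] / cum_n[last_of]
  recall <- if (n_truth == 0) rep(1, length(last_of))
            else cum_tp[last_of] / n_truth
  auc <- if (n_truth == 0) 1 else {
    r <- c(0, recall); p <- c(precision[1], precision)
    sum(diff(r) * (head(p, -1) + tail(p, -1)) / 2)
  }
  structure(list(thresholds = conf_sorted[last_of], precision = precision,
                 recall = recall, auc = auc), class = "pr_curve")
}

#' Evaluate picked coordinate files against ground truth
#'
#' Pairs pick and truth coordinate files by base name, pools the matches and
#' reports aggregate precision, recall, AUC, mean IOU and counts, plus a
#' per-micrograph table.
#'
#' @param picks_dir Directory of picked coordinate files.
#' @param truth_dir Directory of ground-truth coordinate files.
#' @param iou_threshold IOU cutoff for a true positive.
#' @param box_size Box size for STAR inputs.
#' @return A list with `summary` (precision, recall, auc, mean_iou, tp, fp,
#'   fn) and `per_micrograph` (data frame).
#' @export
evaluate_picks <- function(picks_dir, truth_dir, iou_threshold = 0.6,
                           box_size = NULL) {
  list_coords <- function(d) {
    f <- list.files(d, pattern = "\\.(box|star)$", full.names = TRUE)
    setNames(f, tools::file_path_sans_ext(basename(f)))
  }
  pf <- list_coords(picks_dir); tf <- list_coords(truth_dir)
  common <- intersect(names(pf), names(tf))
  if (length(common) == 0) stop_cfg("no matching coordinate file pairs")
  rows <- list()
  all_picks <- list(); all_truth <- list(); offset <- 0
  tp <- fp <- fn <- 0L
  ious <- numeric()
  per_auc <- numeric()
  for (nm in common) {
    p <- read_boxes(pf[[nm]], box_size = box_size)
    tr <- read_boxes(tf[[nm]], box_size = box_size)
    mr <- match_picks(p, tr, iou_threshold)
    prc <- pr_curve(p, tr, iou_threshold)
    tp <- tp + mr$tp; fp <- fp + mr$fp; fn <- fn + mr$fn
    ious <- c(ious, mr$pairs$iou)
    pr <- precision_recall(mr)
    rows[[nm]] <- data.frame(micrograph = nm, n_picks = nrow(p),
                             n_truth = nrow(tr), tp = mr$tp, fp = mr$fp,
                             fn = mr$fn, precision = pr[["precision"]],
                             recall = pr[["recall"]], auc = prc$auc)
  }
  summary <- list(
    precision = if (tp + fp == 0) 1 else tp / (tp + fp),
    recall = if (tp + fn == 0) 1 else tp / (tp + fn),
    auc = mean(vapply(rows, function(r) r$auc, numeric(1))),
    mean_iou = if (length(ious)) mean(ious) else NA_real_,
    tp = tp, fp = fp, fn = fn)
  list(summary = summary,
       per_micrograph = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
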