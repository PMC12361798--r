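# Evaluation metric suite: frame-level classification, cycle-level systole
# detection (AccSys) with ED/ES frame-error statistics, and pixel-level
# segmentation overlap.

#' Frame-level classification metrics
#'
#' Precision and recall are reported for the positive class; F1 is the
#' macro average of the per-class F1 scores; accuracy is the fraction of
#' correct predictions. When nothing is predicted positive, precision is
#' returned as 0 with a warning (recall handles the symmetric degenerate
#' case the same way).
#'
#' @param truth,pred equal-length label vectors.
#' @param positive the positive-class label (default `"systole"`).
#' @return named list `pre`, `rec`, `f1`, `acc`.
#' @export
classification_metrics <- function(truth, pred, positive = "systole") {
  if (length(truth) != length(pred))
    stop("truth and pred must have equal length")
  if (length(truth) == 0) stop("empty label vectors")
  truth <- as.character(truth); pred <- as.character(pred)
  classes <- sort(unique(c(truth, pred)))
  f1s <- vapply(classes, function(k) {
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (p + r > 0) 2 * p * r / (p + r) else 0
  }, numeric(1))
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  if (tp + fp == 0) {
    warning("no positive predictions: precision undefined, returning 0")
    pre <- 0
  } else pre <- tp / (tp + fp)
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(pre = pre, rec = rec, f1 = unname(mean(f1s)),
       acc = mean(truth == pred))
}

#' Cycle-level systole detection accuracy (AccSys)
#'
#' A ground-truth cardiac cycle counts as correctly predicted (toward T)
#' when at least one predicted-systole frame falls inside its systole
#' period. Matching is greedy in temporal order and each predicted period
#' may validate at most one ground-truth cycle, so a single long predicted
#' period cannot validate several cycles. AccSys = T / (P + N - T), with P
#' the predicted and N the true number of systole periods.
#'
#' @param gt_cycles,pred_cycles [parse_cycles()] results.
#' @return list with `summary` (`T`, `P`, `N`), `accsys`, and `matches`
#'   (data.frame of matched ground-truth/predicted period indices, for
#'   ED/ES error computation on validated cycles).
#' @export
accsys <- function(gt_cycles, pred_cycles) {
  gt <- gt_cycles$systole_periods
  pr <- pred_cycles$systole_periods
  N <- nrow(gt); P <- nrow(pr)
  if (N == 0 && P == 0) stop("AccSys undefined: no cycles in truth or prediction")
  used <- rep(FALSE, P)
  matches <- data.frame(gt = integer(0), pred = integer(0))
  T_ <- 0L
  for (i in seq_len(N)) {
    for (j in seq_len(P)) {
      if (used[j]) next
      if (pr[j, "start"] <= gt[i, "end"] && pr[j, "end"] >= gt[i, "start"]) {
        used[j] <- TRUE
        T_ <- T_ + 1L
        matches <- rbind(matches, data.frame(gt = i, pred = j))
        break
      }
    }
  }
  list(summary = list(T = T_, P = P, N = N),
       accsys = T_ / (P + N - T_),
       matches = matches)
}

#' ED/ES frame-error statistics over matched cycles
#'
#' Absolute frame errors between ground-truth and predicted ED (or ES)
#' frames of matched cycles: AE is the mean error, E1 the fraction of errors
#' of at most 1 frame, E2 the fraction of at most 2 frames.
#'
#' @param gt_frames,pred_frames equal-length integer vectors of matched
#'   frame indices.
#' @return named list `errors`, `ae`, `e1`, `e2`.
#' @export
phase_error_stats <- function(gt_frames, pred_frames) {
  if (length(gt_frames) == 0)
    stop("no matched cycles: frame-error statistics undefined")
  if (length(gt_frames) != length(pred_frames))
    stop("gt_frames and pred_frames must be matched pairs")
  err <- abs(gt_frames - pred_frames)
  list(errors = err, ae = mean(err), e1 = mean(err <= 1), e2 = mean(err <= 2))
}

#' Dice and IoU overlap of two binary masks
#'
#' `dice = 2|A∩B| / (|A| + |B|)`, `iou = |A∩B| / |A∪B|`. When both masks
#' are empty, both metrics are 1 by convention (evaluation frames are
#' guaranteed to contain prolapse in the intended protocol, so the
#' convention only matters for degenerate inputs).
#'
#' @param pred,truth binary matrices of the same shape.
#' @return named list `dice`, `iou`.
#' @export
overlap_metrics <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth masks must have the same shape")
  a <- pred != 0; b <- truth != 0
  inter <- sum(a & b); sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(list(dice = 1, iou = 1))
  list(dice = 2 * inter / (sa + sb), iou = inter / (sa + sb - inter))
}
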