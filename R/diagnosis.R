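# Segmentation-based MVP diagnosis: 4-class leaflet/prolapse segmentation,
# frame- and patient-level decision rules, connected-component region parsing
# and severe-zone localization.

# Per-pixel feature stack used by the segmenter: the raw frame plus
# Gaussian-smoothed copies at increasing scales (the coarse scales play the
# role of deep, low-resolution features; fusing them with the fine scales is
# the skip-connection idea of upsampling segmenters), a gradient-magnitude
# channel, and normalised image coordinates.
seg_feature_names <- c("I", "G1", "G2", "G4", "G8", "GRAD", "XN", "YN",
                       "XN2", "YN2", "XNYN")

seg_features <- function(frame) {
  h <- nrow(frame); w <- ncol(frame)
  g1 <- blur_gaussian(frame, 1)
  g2 <- blur_gaussian(frame, 2)
  g4 <- blur_gaussian(frame, 4)
  g8 <- blur_gaussian(frame, 8)
  gr <- gradient_magnitude(g2)
  xn <- matrix(seq_len(w) / w, h, w, byrow = TRUE) - 0.5
  yn <- matrix(seq_len(h) / h, h, w) - 0.5
  cbind(I = as.vector(frame), G1 = as.vector(g1), G2 = as.vector(g2),
        G4 = as.vector(g4), G8 = as.vector(g8), GRAD = as.vector(gr),
        XN = as.vector(xn), YN = as.vector(yn), XN2 = as.vector(xn^2),
        YN2 = as.vector(yn^2), XNYN = as.vector(xn * yn))
}

#' Training configuration for the leaflet/prolapse segmenter
#'
#' @param epochs training epochs.
#' @param lr learning rate (decoder group).
#' @param optimizer `"adam"` (default) or plain `"sgd"`.
#' @param hidden hidden units of the per-pixel classifier head (0 = linear).
#' @param class_weights length-4 loss weights for classes
#'   background/AL/PL/MVP.
#' @param lr_ratio_k learning-rate ratio K between the encoder (input-side)
#'   and decoder (output-side) parameter groups.
#' @param pixels_per_frame training pixels sampled per frame (stratified by
#'   class so the background does not swamp the leaflets).
#' @param batch_size minibatch size.
#' @param smooth_sigma Gaussian smoothing (pixels) applied to the per-class
#'   probability maps before the argmax at prediction time; gives the
#'   per-pixel head spatial context and suppresses isolated-pixel noise.
#' @param seed integer seed.
#' @return a plain list.
#' @export
seg_train_config <- function(epochs = 10L, lr = 0.01, hidden = 24L,
                             class_weights = c(1, 1, 1, 1), lr_ratio_k = 1,
                             pixels_per_frame = 1500L, batch_size = 512L,
                             optimizer = "adam", smooth_sigma = 1,
                             seed = 1L) {
  list(epochs = as.integer(epochs), lr = lr, hidden = as.integer(hidden),
       optimizer = optimizer, smooth_sigma = smooth_sigma,
       class_weights = class_weights, lr_ratio_k = lr_ratio_k,
       pixels_per_frame = as.integer(pixels_per_frame),
       batch_size = as.integer(batch_size), seed = as.integer(seed))
}

# Stratified pixel sampling: up to quota/4 pixels per class per frame,
# remainder topped up from the background.
sample_pixels <- function(mask, quota) {
  idx_by_class <- lapply(0:3, function(k) which(mask == k))
  per <- ceiling(quota / 4)
  picks <- unlist(lapply(idx_by_class, function(ix) {
    if (length(ix) == 0) return(integer(0))
    if (length(ix) <= per) ix else sample(ix, per)
  }))
  picks
}

#' Train the 4-class leaflet/prolapse segmenter
#'
#' Fits a dense per-pixel classifier over a multi-scale feature stack fused
#' from fine and coarse resolutions. Supports per-class loss weights and the
#' two-group learning-rate ratio K between the encoder (feature-side) and
#' decoder (classifier-side) parameter groups.
#'
#' @param dataset list of `list(frame =, mask =)` pairs (an `echo_case` can be
#'   expanded with [systolic_training_pairs()]).
#' @param train_config a [seg_train_config()].
#' @return object of class `seg_model` with per-epoch `$loss_log`.
#' @export
train_segmenter <- function(dataset, train_config = seg_train_config()) {
  if (length(dataset) == 0) stop("empty dataset: no (frame, mask) pairs")
  run_with_seed(train_config$seed + 1L, {
    feats <- list(); labs <- list()
    for (i in seq_along(dataset)) {
      fr <- dataset[[i]]$frame; mk <- dataset[[i]]$mask
      Fi <- seg_features(fr)
      pick <- sample_pixels(mk, train_config$pixels_per_frame)
      feats[[i]] <- Fi[pick, , drop = FALSE]
      labs[[i]] <- as.vector(mk)[pick]
    }
    X <- do.call(rbind, feats)
    y <- unlist(labs) + 1L
    if (length(unique(y)) < 2)
      stop("degenerate dataset: masks contain fewer than 2 classes")
    m <- mlp_train_engine(X, y, k = 4L, hidden = train_config$hidden,
                          epochs = train_config$epochs, lr = train_config$lr,
                          batch_size = train_config$batch_size,
                          class_weights = train_config$class_weights,
                          lr_ratio = train_config$lr_ratio_k,
                          seed = train_config$seed,
                          optimizer = if (is.null(train_config$optimizer)) "sgd"
                          else train_config$optimizer)
    structure(list(net = m, loss_log = m$loss_log, config = train_config),
              class = "seg_model")
  })
}

#' Expand cases into (frame, mask) training pairs
#' @param cases list of `echo_case` objects.
#' @param systolic_only keep only systolic frames (the diagnosis model runs
#'   on systolic frames).
#' @return list of `list(frame, mask)` pairs.
#' @export
systolic_training_pairs <- function(cases, systolic_only = TRUE) {
  out <- list()
  for (cs in cases) {
    keep <- if (systolic_only) which(cs$phases == "systole") else seq_along(cs$frames)
    for (i in keep) out[[length(out) + 1L]] <- list(frame = cs$frames[[i]],
                                                    mask = cs$masks[[i]])
  }
  out
}

#' Segment one frame into background/AL/PL/MVP
#'
#' @param model a trained `seg_model`.
#' @param frame grayscale matrix.
#' @param ... unused.
#' @return integer label matrix (argmax map) of the same size as `frame`,
#'   values in `{0, 1, 2, 3}`.
#' @export
segment_frame <- function(model, frame, ...) UseMethod("segment_frame")

#' @export
segment_frame.seg_model <- function(model, frame, ...) {
  P <- mlp_predict_prob(model$net, seg_features(frame))
  sg <- model$config$smooth_sigma
  if (!is.null(sg) && sg > 0) {
    h <- nrow(frame)
    P <- vapply(seq_len(ncol(P)), function(k)
      as.vector(blur_gaussian(matrix(P[, k], h), sg)), numeric(nrow(P)))
  }
  lab <- max.col(P, ties.method = "first") - 1L
  matrix(lab, nrow(frame), ncol(frame))
}

#' Frame-level MVP rule
#'
#' A frame is considered to show MVP when its predicted segmentation map
#' contains prolapse (class 3) area of at least `min_area` pixels. The
#' default `min_area = 1` reads "contains MVP area" literally; raise it for
#' noise robustness.
#'
#' @param mask integer label matrix.
#' @param min_area minimum class-3 pixel count.
#' @return list `(has_mvp, mvp_area)` of class `frame_diagnosis`.
#' @export
diagnose_frame <- function(mask, min_area = 1L) {
  area <- sum(mask == 3L)
  structure(list(has_mvp = area >= min_area, mvp_area = area),
            class = "frame_diagnosis")
}

#' Patient-level MVP rule
#'
#' A study is diagnosed as MVP when the proportion of systolic frames with
#' MVP is strictly greater than `threshold` ("greater than half" at the
#' default 0.5; a proportion of exactly 0.5 is negative). The index frame is
#' the systolic frame with the largest MVP area (ties broken by the lowest
#' frame position).
#'
#' @param frame_diagnoses list of [diagnose_frame()] results over the
#'   study's systolic frames.
#' @param threshold decision threshold on the MVP-frame proportion.
#' @return object of class `patient_diagnosis`: `n_systolic_frames`,
#'   `n_mvp_frames`, `proportion`, `is_mvp`, `index_frame` (1-based position
#'   within `frame_diagnoses`, `NA` when no frame shows MVP).
#' @export
diagnose_patient <- function(frame_diagnoses, threshold = 0.5) {
  if (length(frame_diagnoses) == 0)
    stop("no systolic frames: patient-level diagnosis undefined")
  areas <- vapply(frame_diagnoses, function(d) d$mvp_area, numeric(1))
  flags <- vapply(frame_diagnoses, function(d) d$has_mvp, logical(1))
  n <- length(flags); n_mvp <- sum(flags)
  prop <- n_mvp / n
  structure(list(n_systolic_frames = n, n_mvp_frames = n_mvp,
                 proportion = prop, is_mvp = prop > threshold,
                 index_frame = if (n_mvp > 0) which.max(areas) else NA_integer_),
            class = "patient_diagnosis")
}

#' Parse labelled regions from a segmentation mask
#'
#' Connected components (8-connectivity) are extracted per foreground class;
#' components smaller than `min_component_area` are discarded as noise.
#'
#' @param mask integer label matrix (values 0-3).
#' @param min_component_area minimum component pixel count to keep.
#' @return data.frame with columns `class` (1 = AL, 2 = PL, 3 = MVP), `id`,
#'   `area`, `centroid_x`, `centroid_y` (1-based pixel coordinates),
#'   `x0`, `y0`, `x1`, `y1` (bounding box, 0-based half-open).
#' @export
parse_regions <- function(mask, min_component_area = 1L) {
  rows <- list()
  for (k in 1:3) {
    lab <- label_components(mask == k)
    nlab <- max(lab)
    if (nlab == 0) next
    for (j in seq_len(nlab)) {
      idx <- which(lab == j, arr.ind = TRUE)
      if (nrow(idx) < min_component_area) next
      rows[[length(rows) + 1L]] <- data.frame(
        class = k, id = j, area = nrow(idx),
        centroid_x = mean(idx[, 2]), centroid_y = mean(idx[, 1]),
        x0 = min(idx[, 2]) - 1L, y0 = min(idx[, 1]) - 1L,
        x1 = max(idx[, 2]), y1 = max(idx[, 1]))
    }
  }
  if (length(rows) == 0)
    return(data.frame(class = integer(0), id = integer(0), area = integer(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      x0 = integer(0), y0 = integer(0), x1 = integer(0),
                      y1 = integer(0)))
  do.call(rbind, rows)
}

#' Localize the severe prolapse zone from a segmentation mask
#'
#' Logical judgment over the parsed regions: each leaflet region is dilated
#' by `dilation` pixels (Chebyshev); `mvp_in_AL`/`mvp_in_PL` record whether
#' any MVP component overlaps the dilated leaflet; the severe leaflet
#' (`ssz_apl`) is the one with the larger overlap with the largest MVP
#' component (ties to AL); the sub-zone (`ssz_ssz`) is the third of the
#' chosen leaflet's lateral extent, measured along the annulus axis, that
#' contains the largest component's centroid (A1-A3 / P1-P3, left to right).
#'
#' @param mask integer label matrix with at least one MVP (class 3) pixel.
#' @param annulus_axis optional numeric `(x_min, x_max)` lateral extent of
#'   the annulus; defaults to the column range of the leaflet pixels
#'   (AL union PL), the principal axis of the valve in this geometry.
#' @param dilation leaflet dilation radius in pixels.
#' @param min_component_area noise floor for MVP components.
#' @return object of class `severe_zone_call`: `ssz_apl` (`"AL"`/`"PL"`),
#'   `dsz_apl` (named logical pair), `ssz_ssz` (one of A1-A3/P1-P3).
#' @export
judge_severe_zone <- function(mask, annulus_axis = NULL, dilation = 3L,
                              min_component_area = 1L) {
  regions <- parse_regions(mask, min_component_area)
  mvp_regs <- regions[regions$class == 3, , drop = FALSE]
  if (nrow(mvp_regs) == 0)
    stop("no MVP component present: severe-zone judgment undefined")
  al_dil <- dilate_chebyshev(mask == 1L, dilation)
  pl_dil <- dilate_chebyshev(mask == 2L, dilation)
  mvp_lab <- label_components(mask == 3L)
  # overlap of every MVP component with each dilated leaflet
  any_in_al <- FALSE; any_in_pl <- FALSE
  for (j in seq_len(max(mvp_lab))) {
    comp <- mvp_lab == j
    if (sum(comp) < min_component_area) next
    if (any(comp & al_dil)) any_in_al <- TRUE
    if (any(comp & pl_dil)) any_in_pl <- TRUE
  }
  largest <- mvp_regs[which.max(mvp_regs$area), ]
  comp <- mvp_lab == largest$id
  ov_al <- sum(comp & al_dil); ov_pl <- sum(comp & pl_dil)
  leaflet <- if (ov_al >= ov_pl) "AL" else "PL"   # tie -> AL (anterior first)
  if (is.null(annulus_axis)) {
    cols <- which(colSums(mask == 1L | mask == 2L) > 0)
    annulus_axis <- if (length(cols) > 0) range(cols) else c(1, ncol(mask))
  }
  span <- annulus_axis[2] - annulus_axis[1]
  frac <- (largest$centroid_x - annulus_axis[1]) / max(span, 1e-9)
  third <- min(max(ceiling(frac * 3), 1L), 3L)
  structure(list(ssz_apl = leaflet,
                 dsz_apl = c(mvp_in_AL = any_in_al, mvp_in_PL = any_in_pl),
                 ssz_ssz = paste0(substring(leaflet, 1, 1), third)),
            class = "severe_zone_call")
}

#' ROC curve and AUC over the MVP-frame proportion
#'
#' Sweeps the patient decision threshold over every distinct observed
#' proportion (plus sentinels below and above the range), computing the true
#' and false positive rates of the strict `proportion > threshold` rule, and
#' integrates the curve by the trapezoid rule.
#'
#' @param proportions numeric vector of per-study MVP-frame proportions.
#' @param truth logical vector of patient-level MVP ground truth.
#' @return list with `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_over_proportion <- function(proportions, truth) {
  stopifnot(length(proportions) == length(truth))
  truth <- as.logical(truth)
  if (length(unique(truth)) < 2)
    stop("both truth classes are required to compute a ROC curve")
  thr <- sort(unique(c(-Inf, proportions, Inf)), decreasing = TRUE)
  pts <- t(vapply(thr, function(t) {
    pred <- proportions > t
    c(fpr = sum(pred & !truth) / sum(!truth),
      tpr = sum(pred & truth) / sum(truth))
  }, numeric(2)))
  df <- data.frame(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
  o <- order(df$fpr, df$tpr)
  fpr <- df$fpr[o]; tpr <- df$tpr[o]
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = df, auc = auc)
}
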