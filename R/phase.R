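#' Positive-class probability from a two-logit record
#'
#' Two-term softmax `exp(o_pos) / (exp(o_neg) + exp(o_pos))`, computed in a
#' numerically stable form (max logit subtracted before exponentiation).
#' Vectorised over pairs.
#'
#' @param o_neg,o_pos raw network outputs for the negative (diastole) and
#'   positive (systole) category.
#' @return probability of the positive category, in `[0, 1]`.
#' @export
positive_probability <- function(o_neg, o_pos) {
  if (any(!is.finite(o_neg)) || any(!is.finite(o_pos)))
    stop("logits must be finite")
  m <- pmax(o_neg, o_pos)
  en <- exp(o_neg - m); ep <- exp(o_pos - m)
  ep / (en + ep)
}

#' Confidence level of a binary prediction
#'
#' Twice the distance of the positive-class probability from 0.5: a maximally
#' uncertain prediction (p = 0.5) has confidence 0, a certain one (p = 0 or 1)
#' has confidence 1.
#'
#' @param p_pos positive-class probability in `[0, 1]`.
#' @return confidence in `[0, 1]`.
#' @export
confidence <- function(p_pos) {
  if (any(p_pos < 0 | p_pos > 1)) stop("p_pos must be in [0, 1]")
  2 * abs(p_pos - 0.5)
}

#' Active-if network selection
#'
#' The main network A is used preferentially; the secondary network B replaces
#' it only when both activation conditions hold: `conf_a < c_threshold` and
#' `conf_b > conf_a` (both strict).
#'
#' @param conf_a,conf_b confidence levels of networks A and B, in `[0, 1]`.
#' @param c_threshold the activation constant C (default 0.4).
#' @return `"A"` or `"B"` (vectorised).
#' @export
active_if_select <- function(conf_a, conf_b, c_threshold = 0.4) {
  if (any(conf_a < 0 | conf_a > 1 | conf_b < 0 | conf_b > 1))
    stop("confidences must be in [0, 1]")
  ifelse(conf_a < c_threshold & conf_b > conf_a, "B", "A")
}

phase_arch_spec <- function(arch) {
  # Two distinct compact architectures stand behind the main/secondary roles:
  # the main model is larger (finer input grid, wider hidden layer), the
  # secondary is a lightweight counterpart with an independent view of the
  # frame, so their confidences are not degenerate copies of each other.
  switch(arch,
         main = list(input = 16L, hidden = 24L),
         secondary = list(input = 12L, hidden = 8L),
         stop("arch must be 'main' or 'secondary'"))
}

phase_frame_features <- function(frame, input) {
  as.vector(resize_img(frame, input, input, "bilinear"))
}

#' Training configuration for the phase classifiers
#' @param epochs SGD epochs over the frame dataset.
#' @param lr learning rate.
#' @param batch_size minibatch size.
#' @param seed integer seed.
#' @return a plain list.
#' @export
phase_train_config <- function(epochs = 5L, lr = 0.3, batch_size = 128L,
                               seed = 1L) {
  list(epochs = as.integer(epochs), lr = lr, batch_size = as.integer(batch_size),
       seed = as.integer(seed))
}

#' Train a systole/diastole frame classifier
#'
#' Builds a frame-level dataset from the cases' frames and phase labels and
#' fits a compact feed-forward classifier (architecture per `arch`). Training
#' loss is logged per epoch in `$loss_log`; runs are reproducible for a fixed
#' seed.
#'
#' @param cases list of `echo_case` objects (or any list with `frames` and
#'   `phases` elements).
#' @param arch `"main"` or `"secondary"`.
#' @param train_config a [phase_train_config()].
#' @return object of class `phase_model`.
#' @export
train_phase_classifier <- function(cases, arch = c("main", "secondary"),
                                   train_config = phase_train_config()) {
  arch <- match.arg(arch)
  if (length(cases) == 0) stop("empty dataset: no cases supplied")
  spec <- phase_arch_spec(arch)
  X <- do.call(rbind, lapply(cases, function(cs)
    t(vapply(cs$frames, phase_frame_features, numeric(spec$input^2),
             input = spec$input))))
  y_lab <- unlist(lapply(cases, function(cs) as.character(cs$phases)))
  if (length(unique(y_lab)) < 2)
    stop("single-class dataset: both systole and diastole frames are required")
  y <- ifelse(y_lab == "systole", 2L, 1L)  # class 1 = diastole, 2 = systole
  m <- mlp_train_engine(X, y, k = 2L, hidden = spec$hidden,
                        epochs = train_config$epochs, lr = train_config$lr,
                        batch_size = train_config$batch_size,
                        seed = train_config$seed)
  structure(list(net = m, arch = arch, input = spec$input,
                 loss_log = m$loss_log),
            class = "phase_model")
}

#' Raw two-category logits of a phase model for one frame
#' @param model a `phase_model`.
#' @param frame grayscale matrix.
#' @return numeric `c(o_neg, o_pos)`.
#' @export
phase_logits <- function(model, frame) {
  UseMethod("phase_logits")
}

#' @export
phase_logits.phase_model <- function(model, frame) {
  x <- matrix(phase_frame_features(frame, model$input), 1)
  xs <- sweep(sweep(x, 2, model$net$mu, "-"), 2, model$net$sd, "/")
  z <- mlp_forward(model$net$par, xs, model$net$hidden)$Z
  c(o_neg = z[1, 1], o_pos = z[1, 2])
}

#' Constant-logit stub phase model
#'
#' Emits the same two-category logits for every frame; useful for tracing
#' the active-if decision rule and for degenerate pipeline tests.
#'
#' @param o_neg,o_pos the fixed logits.
#' @return object of class `phase_model_const` with a [phase_logits()] method.
#' @export
constant_phase_model <- function(o_neg, o_pos) {
  structure(list(o_neg = o_neg, o_pos = o_pos), class = "phase_model_const")
}

#' @export
phase_logits.phase_model_const <- function(model, frame) {
  c(o_neg = model$o_neg, o_pos = model$o_pos)
}

#' Predict the cardiac phase of one frame with the dual-network ensemble
#'
#' Both networks score the frame; their positive-class probabilities and
#' confidences are computed, the active-if rule selects the network, and the
#' frame is labelled systole when the chosen network's positive probability is
#' >= 0.5 (ties positive). The full decision record is returned for audit.
#'
#' @param frame grayscale matrix.
#' @param model_a,model_b main and secondary phase models (anything with a
#'   [phase_logits()] method).
#' @param c_threshold activation constant C.
#' @return list with `label` (`"systole"`/`"diastole"`) and `decision`
#'   (p_pos_A, p_pos_B, conf_A, conf_B, c_threshold, chosen).
#' @export
predict_phase <- function(frame, model_a, model_b, c_threshold = 0.4) {
  za <- phase_logits(model_a, frame)
  zb <- phase_logits(model_b, frame)
  p_a <- positive_probability(za[1], za[2])
  p_b <- positive_probability(zb[1], zb[2])
  conf_a <- confidence(p_a); conf_b <- confidence(p_b)
  chosen <- active_if_select(conf_a, conf_b, c_threshold)
  p <- if (chosen == "A") p_a else p_b
  list(label = if (p >= 0.5) "systole" else "diastole",
       decision = list(p_pos_A = unname(p_a), p_pos_B = unname(p_b),
                       conf_A = unname(conf_a), conf_B = unname(conf_b),
                       c_threshold = c_threshold, chosen = unname(chosen)))
}

#' Predict phases for every frame of a cine sequence
#'
#' @param case an `echo_case` (or list with a `frames` element).
#' @inheritParams predict_phase
#' @return data.frame with columns `frame_index` (0-based), `p_pos_A`,
#'   `p_pos_B`, `conf_A`, `conf_B`, `chosen`, `label` — the per-frame
#'   prediction export schema.
#' @export
predict_phases <- function(case, model_a, model_b, c_threshold = 0.4) {
  rows <- lapply(seq_along(case$frames), function(i) {
    pr <- predict_phase(case$frames[[i]], model_a, model_b, c_threshold)
    data.frame(frame_index = i - 1L,
               p_pos_A = pr$decision$p_pos_A, p_pos_B = pr$decision$p_pos_B,
               conf_A = pr$decision$conf_A, conf_B = pr$decision$conf_B,
               chosen = pr$decision$chosen, label = pr$label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Parse cardiac cycles from a per-frame phase label sequence
#'
#' Systole periods are the maximal runs of `"systole"` labels. Within each
#' run the first frame is taken as the end-diastole (ED) frame and the last
#' as the end-systole (ES) frame: systole runs from ED to ES, and the same
#' convention is applied to predictions and ground truth so frame-error
#' metrics compare like with like.
#'
#' @param labels character vector of `"systole"`/`"diastole"` labels.
#' @return object of class `cycle_prediction`: list with `systole_periods`
#'   (two-column matrix of inclusive 0-based `(start, end)` frames),
#'   `ed_frames`, `es_frames`.
#' @export
parse_cycles <- function(labels) {
  if (length(labels) == 0) stop("label sequence is empty")
  labels <- as.character(labels)
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sys <- which(r$values == "systole")
  periods <- cbind(start = starts[sys] - 1L, end = ends[sys] - 1L)
  structure(list(systole_periods = periods,
                 ed_frames = unname(periods[, "start"]),
                 es_frames = unname(periods[, "end"])),
            class = "cycle_prediction")
}

#' @export
print.cycle_prediction <- function(x, ...) {
  cat(sprintf("<cycle_prediction> %d systole period(s)\n",
              nrow(x$systole_periods)))
  invisible(x)
}
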