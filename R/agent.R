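# End-to-end agent: phase recognition -> systolic-frame segmentation ->
# patient diagnosis -> severe-zone localization -> heatmaps for systolic MVP
# frames.

#' Agent configuration
#'
#' All tunable thresholds of the pipeline plus the per-model training
#' configurations. Serialises losslessly to YAML via [write_agent_config()].
#'
#' @param c_threshold active-if activation constant C.
#' @param min_area frame-rule minimum MVP area (pixels).
#' @param patient_threshold patient-rule proportion threshold (strict).
#' @param belt_width edge-belt half-width for heatmap training.
#' @param dilation leaflet dilation (pixels) in severe-zone judgment.
#' @param min_component_area noise floor for parsed regions.
#' @param use_annotated_phases evaluate the diagnosis stages on annotated
#'   rather than predicted systolic frames.
#' @param seed pipeline seed.
#' @param phase_train,seg_train,heatmap_train per-model training configs
#'   (see [phase_train_config()], [seg_train_config()],
#'   [heatmap_train_config()]).
#' @return object of class `agent_config`.
#' @export
agent_config <- function(c_threshold = 0.4, min_area = 1L,
                         patient_threshold = 0.5, belt_width = 3L,
                         dilation = 3L, min_component_area = 1L,
                         use_annotated_phases = FALSE, seed = 1L,
                         phase_train = phase_train_config(),
                         seg_train = seg_train_config(),
                         heatmap_train = heatmap_train_config()) {
  stopifnot(c_threshold >= 0, c_threshold <= 1,
            patient_threshold >= 0, patient_threshold <= 1,
            min_area >= 0, belt_width >= 0)
  structure(list(c_threshold = c_threshold, min_area = as.integer(min_area),
                 patient_threshold = patient_threshold,
                 belt_width = as.integer(belt_width),
                 dilation = as.integer(dilation),
                 min_component_area = as.integer(min_component_area),
                 use_annotated_phases = isTRUE(use_annotated_phases),
                 seed = as.integer(seed),
                 phase_train = phase_train, seg_train = seg_train,
                 heatmap_train = heatmap_train),
            class = "agent_config")
}

#' @rdname agent_config
#' @param path YAML file path.
#' @param config an `agent_config`.
#' @export
write_agent_config <- function(config, path) {
  # named atomic vectors (e.g. loss weights) become YAML maps, so their
  # names survive the round trip
  fix <- function(x) {
    if (is.list(x)) lapply(x, fix)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(fix(unclass(config)), path)
  invisible(path)
}

#' @rdname agent_config
#' @export
read_agent_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(agent_config, raw[setdiff(names(raw),
                                           c("phase_train", "seg_train", "heatmap_train"))])
  for (nm in c("phase_train", "seg_train", "heatmap_train")) {
    if (is.null(raw[[nm]])) next
    tc <- utils::modifyList(cfg[[nm]], raw[[nm]])
    # YAML maps come back as lists; numeric vector fields (class weights,
    # loss weights) are restored to named numeric vectors
    for (f in names(tc))
      if (is.list(tc[[f]]) && all(vapply(tc[[f]], is.numeric, logical(1))))
        tc[[f]] <- unlist(tc[[f]])
    cfg[[nm]] <- tc
  }
  cfg
}

#' Run the full agent on one cine sequence
#'
#' Pipeline order is fixed: per-frame phase detection, cardiac-cycle parsing,
#' segmentation of the systolic frames, frame- and patient-level diagnosis,
#' severe-zone localization on the largest-area MVP frame (when the study is
#' diagnosed MVP), and saliency heatmaps for all systolic frames showing MVP.
#' Every stage's intermediate output is kept in the report (and persisted
#' under `out_dir` when given) for audit.
#'
#' `models` components may be `"oracle"`, which substitutes the case's own
#' ground truth for that stage (phases, masks, or binary prolapse maps);
#' this requires a synthetic case carrying ground truth and is intended for
#' rule-pipeline validation.
#'
#' @param case an `echo_case` (from [generate_case()] or [read_case()]).
#' @param models list with `phase_a`, `phase_b` (phase models) or
#'   `phase = "oracle"`; `seg` (a `seg_model` or `"oracle"`); optional
#'   `heatmap` (a `heatmap_model` or `"oracle"`).
#' @param config an [agent_config()].
#' @param out_dir optional run directory for persisted intermediates.
#' @return object of class `agent_report`.
#' @export
run_agent <- function(case, models, config = agent_config(), out_dir = NULL) {
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  # stage 1: phase recognition
  if (identical(models$phase, "oracle")) {
    if (is.null(case$phases)) stop("oracle phase source requires ground-truth labels")
    phase_df <- data.frame(frame_index = seq_along(case$frames) - 1L,
                           p_pos_A = NA_real_, p_pos_B = NA_real_,
                           conf_A = NA_real_, conf_B = NA_real_,
                           chosen = NA_character_,
                           label = as.character(case$phases),
                           stringsAsFactors = FALSE)
    note("phase: oracle labels (%d frames)", nrow(phase_df))
  } else {
    if (is.null(models$phase_a) || is.null(models$phase_b))
      stop("configuration error: phase_a and phase_b models are required")
    phase_df <- predict_phases(case, models$phase_a, models$phase_b,
                               config$c_threshold)
    note("phase: dual-network prediction (%d frames, C=%.2f)",
         nrow(phase_df), config$c_threshold)
  }
  labels <- if (config$use_annotated_phases && !is.null(case$phases))
    as.character(case$phases) else phase_df$label
  cycles <- parse_cycles(labels)
  sys_idx <- which(labels == "systole")
  if (length(sys_idx) == 0) {
    note("phase: no systolic frames detected")
    rep_ <- structure(list(phase = phase_df, cycles = cycles, diagnosis = NULL,
                           frame_diagnoses = NULL, severe_zone = NULL,
                           heatmaps = NULL, no_systole = TRUE, log = log),
                      class = "agent_report")
    if (!is.null(out_dir)) persist_report(rep_, case, out_dir)
    return(rep_)
  }
  note("cycles: %d systole period(s), %d systolic frames",
       nrow(cycles$systole_periods), length(sys_idx))

  # stage 2: segmentation + diagnosis rules
  if (is.null(models$seg)) stop("configuration error: seg model is required")
  masks <- lapply(sys_idx, function(i) {
    if (identical(models$seg, "oracle")) {
      if (is.null(case$masks)) stop("oracle segmenter requires ground-truth masks")
      case$masks[[i]]
    } else segment_frame(models$seg, case$frames[[i]])
  })
  frame_diags <- lapply(masks, diagnose_frame, min_area = config$min_area)
  patient <- diagnose_patient(frame_diags, config$patient_threshold)
  note("diagnosis: %d/%d systolic frames with MVP (proportion %.3f) -> is_mvp=%s",
       patient$n_mvp_frames, patient$n_systolic_frames, patient$proportion,
       patient$is_mvp)

  severe <- NULL
  heatmaps <- NULL
  if (patient$is_mvp) {
    index_mask <- masks[[patient$index_frame]]
    severe <- judge_severe_zone(index_mask, dilation = config$dilation,
                                min_component_area = config$min_component_area)
    note("severe zone: %s (%s), index frame %d", severe$ssz_ssz, severe$ssz_apl,
         sys_idx[patient$index_frame] - 1L)
    mvp_pos <- which(vapply(frame_diags, function(d) d$has_mvp, logical(1)))
    heatmaps <- lapply(mvp_pos, function(p) {
      i <- sys_idx[p]
      hm <- if (identical(models$heatmap, "oracle")) (case$masks[[i]] == 3L) * 1
      else if (!is.null(models$heatmap)) predict_heatmap(models$heatmap, case$frames[[i]])
      else NULL
      list(frame_index = i - 1L, heatmap = hm)
    })
    if (is.null(models$heatmap)) heatmaps <- NULL
    else note("heatmaps: %d systolic MVP frame(s)", length(heatmaps))
  }

  rep_ <- structure(list(phase = phase_df, cycles = cycles,
                         diagnosis = patient, frame_diagnoses = frame_diags,
                         systolic_frames = sys_idx - 1L,
                         severe_zone = severe, heatmaps = heatmaps,
                         no_systole = FALSE, log = log),
                    class = "agent_report")
  if (!is.null(out_dir)) persist_report(rep_, case, out_dir)
  rep_
}

persist_report <- function(rep_, case, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rep_$phase, file.path(out_dir, "phases_pred.csv"),
                   row.names = FALSE)
  diag_json <- if (is.null(rep_$diagnosis)) list(no_systole = TRUE) else list(
    n_systolic_frames = rep_$diagnosis$n_systolic_frames,
    n_mvp_frames = rep_$diagnosis$n_mvp_frames,
    proportion = rep_$diagnosis$proportion,
    is_mvp = rep_$diagnosis$is_mvp,
    index_frame = if (is.na(rep_$diagnosis$index_frame)) NULL
    else rep_$systolic_frames[rep_$diagnosis$index_frame],
    ssz_apl = if (is.null(rep_$severe_zone)) NULL else rep_$severe_zone$ssz_apl,
    dsz_apl = if (is.null(rep_$severe_zone)) NULL else as.list(rep_$severe_zone$dsz_apl),
    ssz_ssz = if (is.null(rep_$severe_zone)) NULL else rep_$severe_zone$ssz_ssz)
  jsonlite::write_json(diag_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(rep_$heatmaps)) {
    hd <- file.path(out_dir, "heatmaps")
    dir.create(hd, showWarnings = FALSE)
    for (h in rep_$heatmaps)
      if (!is.null(h$heatmap))
        write_heatmap_png(h$heatmap,
                          file.path(hd, sprintf("%04d.png", h$frame_index + 1L)),
                          frame = case$frames[[h$frame_index + 1L]])
  }
  writeLines(rep_$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.agent_report <- function(x, ...) {
  if (x$no_systole) cat("<agent_report> no systolic frames detected\n")
  else cat(sprintf("<agent_report> %d systolic frames, is_mvp=%s%s\n",
                   length(x$systolic_frames), x$diagnosis$is_mvp,
                   if (!is.null(x$severe_zone)) paste0(", zone=", x$severe_zone$ssz_ssz) else ""))
  invisible(x)
}

#' Evaluate phase predictions against ground truth
#'
#' Pools frame-level classification metrics over all cases and cycle-level
#' AccSys with ED/ES frame errors over matched cycles.
#'
#' @param cases list of `echo_case` objects with ground-truth phases.
#' @param predicted_labels list of character vectors (one per case).
#' @return named list of metrics: `pre`, `rec`, `f1`, `acc`, `accsys`,
#'   `ed_ae`, `ed_e1`, `ed_e2`, `es_ae`, `es_e1`, `es_e2`.
#' @export
evaluate_phase <- function(cases, predicted_labels) {
  stopifnot(length(cases) == length(predicted_labels))
  truth_all <- unlist(lapply(cases, function(cs) as.character(cs$phases)))
  pred_all <- unlist(predicted_labels)
  cm <- classification_metrics(truth_all, pred_all, positive = "systole")
  T_ <- 0L; P_ <- 0L; N_ <- 0L
  ed_err <- c(); es_err <- c()
  for (i in seq_along(cases)) {
    gt <- parse_cycles(as.character(cases[[i]]$phases))
    pr <- parse_cycles(predicted_labels[[i]])
    a <- accsys(gt, pr)
    T_ <- T_ + a$summary$T; P_ <- P_ + a$summary$P; N_ <- N_ + a$summary$N
    if (nrow(a$matches) > 0) {
      ed_err <- c(ed_err, abs(gt$ed_frames[a$matches$gt] - pr$ed_frames[a$matches$pred]))
      es_err <- c(es_err, abs(gt$es_frames[a$matches$gt] - pr$es_frames[a$matches$pred]))
    }
  }
  ed <- if (length(ed_err) > 0) phase_error_stats(ed_err, 0 * ed_err) else
    list(ae = NA, e1 = NA, e2 = NA)
  es <- if (length(es_err) > 0) phase_error_stats(es_err, 0 * es_err) else
    list(ae = NA, e1 = NA, e2 = NA)
  list(pre = cm$pre, rec = cm$rec, f1 = cm$f1, acc = cm$acc,
       accsys = T_ / (P_ + N_ - T_),
       ed_ae = ed$ae, ed_e1 = ed$e1, ed_e2 = ed$e2,
       es_ae = es$ae, es_e1 = es$e1, es_e2 = es$e2)
}

#' Evaluate patient-level diagnosis over a set of agent reports
#'
#' @param cases list of `echo_case` objects with `mvp_truth` (and
#'   `severe_zone_truth` for MVP cases).
#' @param reports list of [run_agent()] reports, same order.
#' @return named list: patient-level `pre`, `rec`, `f1`, `acc`, `auc`, and
#'   `ssz_acc` (severe-zone sub-zone accuracy over true-positive MVP calls
#'   with a ground-truth zone).
#' @export
evaluate_diagnosis <- function(cases, reports) {
  stopifnot(length(cases) == length(reports))
  truth <- vapply(cases, function(cs) isTRUE(cs$mvp_truth), logical(1))
  pred <- vapply(reports, function(r)
    !r$no_systole && isTRUE(r$diagnosis$is_mvp), logical(1))
  prop <- vapply(reports, function(r)
    if (r$no_systole) 0 else r$diagnosis$proportion, numeric(1))
  cm <- classification_metrics(ifelse(truth, "MVP", "control"),
                               ifelse(pred, "MVP", "control"), positive = "MVP")
  auc <- roc_over_proportion(prop, truth)$auc
  zone_ok <- c()
  for (i in seq_along(cases)) {
    if (truth[i] && pred[i] && !is.na(cases[[i]]$severe_zone_truth) &&
        !is.null(reports[[i]]$severe_zone))
      zone_ok <- c(zone_ok,
                   reports[[i]]$severe_zone$ssz_ssz == cases[[i]]$severe_zone_truth)
  }
  list(pre = cm$pre, rec = cm$rec, f1 = cm$f1, acc = cm$acc, auc = auc,
       ssz_acc = if (length(zone_ok) > 0) mean(zone_ok) else NA_real_)
}

#' Evaluate heatmaps against binary prolapse masks
#'
#' Heatmaps are binarised at 0.5 and compared to the ground-truth masks by
#' Dice and IoU, averaged over frames.
#'
#' @param heatmaps list of saliency matrices in `[0, 1]`.
#' @param truth_masks list of binary matrices, same order and shapes.
#' @return named list `dice`, `iou` (means over frames).
#' @export
evaluate_heatmaps <- function(heatmaps, truth_masks) {
  stopifnot(length(heatmaps) == length(truth_masks), length(heatmaps) > 0)
  ov <- lapply(seq_along(heatmaps), function(i)
    overlap_metrics(heatmaps[[i]] >= 0.5, truth_masks[[i]]))
  list(dice = mean(vapply(ov, `[[`, numeric(1), "dice")),
       iou = mean(vapply(ov, `[[`, numeric(1), "iou")))
}

#' Flatten a metrics list to a one-row-per-metric data frame / CSV
#'
#' @param metrics named list of scalar metrics (possibly nested one level).
#' @param path optional CSV output path.
#' @return data.frame with columns `metric`, `value`.
#' @export
metrics_to_csv <- function(metrics, path = NULL) {
  flat <- unlist(metrics)
  df <- data.frame(metric = names(flat), value = unname(flat),
                   stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
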