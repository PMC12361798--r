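oracle_models <- list(phase = "oracle", seg = "oracle", heatmap = "oracle")

test_that("oracle end-to-end run follows the construction on control and MVP cases", {
  ctl <- tiny_control_case()
  rep_c <- run_agent(ctl, oracle_models)
  expect_false(rep_c$no_systole)
  expect_false(rep_c$diagnosis$is_mvp)
  expect_null(rep_c$severe_zone)
  expect_null(rep_c$heatmaps)

  mvp <- tiny_mvp_case(zone = "P3", seed = 13)
  rep_m <- run_agent(mvp, oracle_models)
  expect_true(rep_m$diagnosis$is_mvp)
  expect_equal(rep_m$severe_zone$ssz_ssz, "P3")
  expect_length(rep_m$heatmaps, rep_m$diagnosis$n_mvp_frames)
  # severe zone and heatmaps present iff is_mvp
  expect_true(all(vapply(rep_m$heatmaps,
                         function(h) all(h$heatmap >= 0 & h$heatmap <= 1),
                         logical(1))))
})

test_that("an all-diastole phase source yields a no-systole report, not a crash", {
  ctl <- tiny_control_case()
  models <- list(phase_a = constant_phase_model(10, 0),
                 phase_b = constant_phase_model(10, 0), seg = "oracle")
  rep_ <- run_agent(ctl, models)
  expect_true(rep_$no_systole)
  expect_null(rep_$diagnosis)
})

test_that("missing model components raise configuration errors", {
  ctl <- tiny_control_case()
  expect_error(run_agent(ctl, list(seg = "oracle")), "phase_a")
  expect_error(run_agent(ctl, list(phase = "oracle")), "seg model")
})

test_that("agent runs are deterministic and persist auditable intermediates", {
  mvp <- tiny_mvp_case(zone = "P3", seed = 13)
  r1 <- run_agent(mvp, oracle_models)
  r2 <- run_agent(mvp, oracle_models)
  expect_identical(r1[names(r1) != "log"], r2[names(r2) != "log"])
  out <- withr::local_tempdir()
  run_agent(mvp, oracle_models, out_dir = out)
  expect_true(file.exists(file.path(out, "phases_pred.csv")))
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(dir.exists(file.path(out, "heatmaps")))
  rj <- jsonlite::read_json(file.path(out, "report.json"))
  expect_true(isTRUE(rj$is_mvp))
  expect_equal(rj$ssz_ssz, "P3")
})

test_that("evaluation of oracle predictions is perfect on a mixed dataset", {
  cases <- small_dataset()
  reports <- lapply(cases, run_agent, models = oracle_models)
  dm <- evaluate_diagnosis(cases, reports)
  expect_equal(dm$acc, 1.0)
  expect_equal(dm$auc, 1.0)
  expect_equal(dm$f1, 1.0)
  labs <- lapply(cases, function(cs) as.character(cs$phases))
  pm <- evaluate_phase(cases, labs)
  expect_equal(pm$acc, 1.0)
  expect_equal(pm$accsys, 1.0)
  expect_equal(pm$ed_ae, 0.0)
  hm <- evaluate_heatmaps(list((cases[[7]]$masks[[which(cases[[7]]$phases == "systole")[1]]] == 3L) * 1),
                          list(cases[[7]]$masks[[which(cases[[7]]$phases == "systole")[1]]] == 3L))
  expect_equal(hm$dice, 1.0)
})

test_that("agent config round-trips through YAML losslessly", {
  cfg <- agent_config(c_threshold = 0.35, min_area = 4,
                      patient_threshold = 0.6, belt_width = 2, seed = 77)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_agent_config(cfg, f)
  rt <- read_agent_config(f)
  expect_equal(unclass(rt), unclass(cfg))
})

test_that("the CLI generates datasets and rejects bad invocations", {
  out <- withr::local_tempdir()
  st <- suppressMessages(echomvp_cli(c("generate", "--n-control", "2",
                                       "--n-mvp", "2", "--out",
                                       file.path(out, "data"),
                                       "--seed", "3", "--image-size", "64")))
  expect_equal(st, 0L)
  case_dirs <- list.dirs(file.path(out, "data"), recursive = FALSE)
  expect_length(case_dirs, 4)
  expect_true(all(file.exists(file.path(case_dirs, "manifest.json"))))
  expect_equal(suppressMessages(echomvp_cli(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(echomvp_cli(c("generate", "--oops"))), 2L)
  expect_equal(suppressMessages(echomvp_cli(character(0))), 2L)
  # missing required flag -> error status
  expect_equal(suppressMessages(echomvp_cli(c("generate", "--n-mvp", "1"))), 1L)
})
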