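test_that("control cases contain no prolapse pixels and the expected frame count", {
  cs <- tiny_control_case()
  expect_length(cs$frames, 30)
  expect_false(cs$mvp_truth)
  expect_true(is.na(cs$severe_zone_truth))
  expect_equal(sum(vapply(cs$masks, function(m) sum(m == 3L), numeric(1))), 0)
})

test_that("MVP cases carry class-3 pixels on exactly the systolic frames", {
  cs <- tiny_mvp_case()
  has_mvp <- vapply(cs$masks, function(m) any(m == 3L), logical(1))
  expect_equal(sum(has_mvp), 10)  # 2 cycles x 10 frames x 0.5 systole
  expect_identical(has_mvp, cs$phases == "systole")
})

test_that("generation is bit-identical for a fixed config and seed", {
  cfg <- echo_phantom_config(image_size = c(64, 64), n_cycles = 2,
                             frames_per_cycle = 6, mvp_case = TRUE,
                             prolapse_amplitude = 8, prolapse_zone = "P1",
                             seed = 99)
  expect_identical(generate_case(cfg), generate_case(cfg))
})

test_that("invalid configurations are rejected with the violated invariant named", {
  expect_error(echo_phantom_config(n_cycles = 0), "n_cycles")
  expect_error(echo_phantom_config(frames_per_cycle = 1), "frames_per_cycle")
  expect_error(echo_phantom_config(systole_fraction = 1), "systole_fraction")
  expect_error(echo_phantom_config(mvp_case = TRUE, prolapse_amplitude = 0),
               "prolapse_amplitude")
  expect_error(echo_phantom_config(mvp_case = FALSE, prolapse_amplitude = 5),
               "prolapse_amplitude")
  expect_error(echo_phantom_config(mvp_case = TRUE, prolapse_amplitude = 5,
                                   prolapse_zone = "Q9"), "prolapse_zone")
})

test_that("phase labels alternate in runs with exactly n_cycles systole runs", {
  for (cs in list(tiny_control_case(), tiny_mvp_case())) {
    r <- rle(as.character(cs$phases))
    expect_true(all(r$values[seq(1, length(r$values), 2)] == r$values[1]))
    n_cycles <- if (cs$mvp_truth) 2 else 3
    expect_equal(sum(r$values == "systole"), n_cycles)
  }
})

test_that("pixel intensities stay in [0,1] and mask labels in {0,1,2,3}", {
  cs <- tiny_mvp_case()
  expect_true(all(vapply(cs$frames, function(f) all(f >= 0 & f <= 1), logical(1))))
  expect_true(all(vapply(cs$masks, function(m) all(m %in% 0:3), logical(1))))
})

test_that("dataset generation honours counts, determinism and the split ratio", {
  expect_length(generate_dataset(0, 0), 0)
  rng <- list(image_size = c(48, 48), frames_per_cycle = 4:6, n_cycles = 2:3)
  d1 <- generate_dataset(5, 5, config_ranges = rng, seed = 1)
  d2 <- generate_dataset(5, 5, config_ranges = rng, seed = 1)
  expect_identical(d1, d2)
  expect_equal(sum(vapply(d1, `[[`, logical(1), "mvp_truth")), 5)
  splits <- vapply(d1, `[[`, character(1), "split")
  expect_setequal(unique(splits), c("train", "val", "test"))
})

test_that("a clinical-scale cohort has the right composition", {
  d <- generate_dataset(87, 64, config_ranges = list(
    image_size = c(48, 48), frames_per_cycle = 4:5, n_cycles = 2:3), seed = 5)
  expect_length(d, 151)
  expect_equal(sum(vapply(d, `[[`, logical(1), "mvp_truth")), 64)
  # class-3 pixels only on systolic frames of MVP cases, dataset-wide
  for (cs in d) {
    has_mvp <- vapply(cs$masks, function(m) any(m == 3L), logical(1))
    if (cs$mvp_truth) expect_identical(has_mvp, cs$phases == "systole")
    else expect_false(any(has_mvp))
  }
})

test_that("cases round-trip through the on-disk layout", {
  cs <- tiny_mvp_case()
  dir <- withr::local_tempdir()
  write_case(cs, dir)
  expect_true(all(file.exists(file.path(dir, c("phases.csv", "manifest.json")))))
  expect_length(list.files(file.path(dir, "frames")), length(cs$frames))
  rt <- read_case(dir)
  expect_identical(rt$masks, cs$masks)
  expect_identical(as.character(rt$phases), cs$phases)
  expect_identical(rt$severe_zone_truth, cs$severe_zone_truth)
  expect_lt(max(abs(rt$frames[[1]] - cs$frames[[1]])), 1 / 255)
})
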