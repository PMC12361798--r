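test_that("positive probability is the stable two-term softmax", {
  expect_equal(positive_probability(0, 0), 0.5)
  # high-precision oracle: 1 / (1 + exp(-1))
  expect_equal(positive_probability(1.0, 2.0), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(positive_probability(1.0, 2.0), 0.7310586, tolerance = 1e-7)
  # extreme logits: no overflow, saturates to 1
  expect_equal(positive_probability(0, 1000), 1.0)
  expect_equal(positive_probability(1000, 0), 0.0)
  expect_error(positive_probability(NaN, 0), "finite")
  expect_error(positive_probability(0, Inf), "finite")
})

test_that("confidence is twice the distance from maximal uncertainty", {
  expect_equal(confidence(0.5), 0)
  expect_equal(confidence(1.0), 1)
  expect_equal(confidence(0.7310586), 0.4621172, tolerance = 1e-12)
  expect_error(confidence(1.2), "\\[0, 1\\]")
  # equal logits always give zero confidence
  for (o in c(-5, 0, 2.3, 100))
    expect_equal(confidence(positive_probability(o, o)), 0)
})

test_that("active-if selection follows the activation conditions", {
  expect_equal(active_if_select(0.5, 0.9, 0.4), "A")  # conf_A not below C
  expect_equal(active_if_select(0.3, 0.6, 0.4), "B")  # both conditions pass
  expect_equal(active_if_select(0.3, 0.3, 0.4), "A")  # strict tie fails
  expect_error(active_if_select(-0.1, 0.5), "\\[0, 1\\]")
})

test_that("active-if agrees with a truth-table oracle on a sampled grid", {
  set.seed(1)
  conf_a <- sample(seq(0, 1, by = 0.01), 500, replace = TRUE)
  conf_b <- sample(seq(0, 1, by = 0.01), 500, replace = TRUE)
  cth <- sample(c(0, 0.2, 0.4, 0.6, 1.0), 500, replace = TRUE)
  oracle <- ifelse(conf_a < cth & conf_b > conf_a, "B", "A")
  expect_identical(active_if_select(conf_a, conf_b, cth), oracle)
})

test_that("the dual-network frame prediction traces the active-if rule", {
  fr <- matrix(0.5, 16, 16)
  # confident main network: systole via A
  pr <- predict_phase(fr, constant_phase_model(0, 10), constant_phase_model(10, 0))
  expect_equal(pr$label, "systole")
  expect_equal(pr$decision$chosen, "A")
  # uncertain A (conf ~ 0.05), confident B: label comes from B
  pr <- predict_phase(fr, constant_phase_model(0.1, 0.0), constant_phase_model(0, 10))
  expect_equal(pr$decision$chosen, "B")
  expect_equal(pr$label, "systole")
  expect_lt(pr$decision$conf_A, 0.06)
  # confident A overrides confident B
  pr <- predict_phase(fr, constant_phase_model(10, 0), constant_phase_model(0, 10))
  expect_equal(pr$label, "diastole")
  expect_equal(pr$decision$chosen, "A")
})

test_that("cycle parsing finds maximal systole runs with ED/ES endpoints", {
  labs <- c("diastole", "diastole", "systole", "systole", "systole",
            "diastole", "diastole", "systole", "systole", "diastole")
  cp <- parse_cycles(labs)
  expect_equal(unname(cp$systole_periods[, "start"]), c(2, 7))
  expect_equal(unname(cp$systole_periods[, "end"]), c(4, 8))
  expect_equal(cp$ed_frames, c(2, 7))
  expect_equal(cp$es_frames, c(4, 8))

  expect_equal(nrow(parse_cycles(rep("diastole", 5))$systole_periods), 0)

  single <- parse_cycles("systole")
  expect_equal(unname(single$systole_periods[1, ]), c(0, 0))
  expect_equal(single$ed_frames, 0)
  expect_equal(single$es_frames, 0)
  expect_error(parse_cycles(character(0)), "empty")
})

test_that("cycle parsing is idempotent and symmetric under label swap", {
  set.seed(2)
  for (rep_i in 1:20) {
    labs <- random_label_seq(sample(2:6, 1))
    cp <- parse_cycles(labs)
    # reconstruct labels from periods, reparse
    rec <- rep("diastole", length(labs))
    for (r in seq_len(nrow(cp$systole_periods)))
      rec[(cp$systole_periods[r, 1]:cp$systole_periods[r, 2]) + 1] <- "systole"
    expect_identical(parse_cycles(rec)$systole_periods, cp$systole_periods)
    # swapping labels turns diastole runs into systole runs
    swapped <- ifelse(labs == "systole", "diastole", "systole")
    cps <- parse_cycles(swapped)
    expect_equal(nrow(cp$systole_periods) + nrow(cps$systole_periods),
                 length(rle(labs)$lengths))
  }
})

test_that("phase classifier training validates its dataset and is seeded", {
  expect_error(train_phase_classifier(list()), "empty")
  ctl <- tiny_control_case()
  only_dia <- list(list(frames = ctl$frames[ctl$phases == "diastole"],
                        phases = ctl$phases[ctl$phases == "diastole"]))
  expect_error(train_phase_classifier(only_dia), "single-class")
  cases <- list(tiny_control_case(), tiny_mvp_case())
  cfg <- phase_train_config(epochs = 2, seed = 9)
  m1 <- train_phase_classifier(cases, "main", cfg)
  m2 <- train_phase_classifier(cases, "main", cfg)
  expect_identical(m1$loss_log, m2$loss_log)
  expect_length(m1$loss_log, 2)
  # main and secondary expose distinct architectures
  sec <- train_phase_classifier(cases, "secondary", cfg)
  expect_gt(m1$input, sec$input)
})
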