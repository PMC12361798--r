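test_that("the frame rule counts prolapse pixels against min_area", {
  m0 <- matrix(0L, 8, 8)
  expect_false(diagnose_frame(m0)$has_mvp)
  m1 <- m0; m1[3, 3] <- 3L
  expect_true(diagnose_frame(m1, min_area = 1)$has_mvp)
  expect_equal(diagnose_frame(m1)$mvp_area, 1)
  m3 <- m0; m3[1, 1:3] <- 3L
  expect_false(diagnose_frame(m3, min_area = 5)$has_mvp)
})

test_that("the patient rule is strict 'greater than half' with argmax index frame", {
  fd <- function(area) diagnose_frame({m <- matrix(0L, 4, 4); if (area > 0) m[seq_len(area)] <- 3L; m})
  d <- diagnose_patient(lapply(c(5, 5, 5, 0, 0), fd))
  expect_equal(d$proportion, 0.6)
  expect_true(d$is_mvp)
  d <- diagnose_patient(lapply(c(5, 5, 0, 0), fd))
  expect_equal(d$proportion, 0.5)
  expect_false(d$is_mvp)  # exactly half is negative
  d <- diagnose_patient(lapply(c(10, 16, 12), fd))
  expect_equal(d$index_frame, 2)
  expect_error(diagnose_patient(list()), "no systolic frames")
})

test_that("adding an MVP frame never flips the patient call to negative", {
  set.seed(3)
  fd_pos <- diagnose_frame({m <- matrix(0L, 4, 4); m[1:4] <- 3L; m})
  fd_neg <- diagnose_frame(matrix(0L, 4, 4))
  for (i in 1:50) {
    flags <- sample(c(TRUE, FALSE), sample(1:12, 1), replace = TRUE)
    lst <- lapply(flags, function(f) if (f) fd_pos else fd_neg)
    before <- diagnose_patient(lst)$is_mvp
    after <- diagnose_patient(c(lst, list(fd_pos)))$is_mvp
    expect_false(before && !after)
  }
})

test_that("region parsing matches a flood-fill oracle and filters noise", {
  expect_equal(nrow(parse_regions(matrix(0L, 10, 10))), 0)
  m <- matrix(0L, 24, 24)
  m[3:7, 3:7] <- 3L          # 25 px blob
  m[15:16, 18:21] <- 3L      # 8 px blob
  m[1, 24] <- 3L             # isolated pixel
  regs <- parse_regions(m)
  expect_equal(sort(regs$area), c(1, 8, 25))
  oracle <- oracle_flood_fill(m == 3L)
  expect_equal(nrow(regs), max(oracle))
  expect_equal(sort(regs$area), sort(tabulate(oracle[oracle > 0])))
  # noise filtering
  expect_equal(nrow(parse_regions(m, min_component_area = 5)), 2)
  small <- matrix(0L, 10, 10); small[2:3, 2:3] <- 3L
  expect_equal(nrow(parse_regions(small, min_component_area = 5)), 0)
})

test_that("region areas sum to the per-class pixel counts", {
  set.seed(4)
  cs <- tiny_mvp_case()
  for (i in which(cs$phases == "systole")[1:3]) {
    regs <- parse_regions(cs$masks[[i]], min_component_area = 1)
    for (k in 1:3)
      expect_equal(sum(regs$area[regs$class == k]), sum(cs$masks[[i]] == k))
  }
})

test_that("severe-zone judgment localizes constructed prolapses", {
  base <- function() {
    m <- matrix(0L, 60, 90)
    m[28:30, 11:80] <- 1L  # AL band above the line (y = 31)
    m[33:35, 11:80] <- 2L  # PL band below
    m
  }
  # blob attached to PL (touching it), centroid in the middle third
  m <- base()
  m[36:44, 40:50] <- 3L
  call <- judge_severe_zone(m)
  expect_equal(call$ssz_apl, "PL")
  expect_equal(call$ssz_ssz, "P2")
  expect_false(call$dsz_apl[["mvp_in_AL"]])
  expect_true(call$dsz_apl[["mvp_in_PL"]])
  # two blobs, one on each leaflet
  m2 <- base()
  m2[36:40, 15:20] <- 3L   # near PL
  m2[23:27, 60:70] <- 3L   # near AL (larger)
  call2 <- judge_severe_zone(m2)
  expect_true(all(call2$dsz_apl))
  expect_equal(call2$ssz_apl, "AL")
  expect_equal(call2$ssz_ssz, "A3")  # centroid x ~ 65 of span 11..80
  # blob in the left third of AL
  m3 <- base()
  m3[23:27, 12:22] <- 3L
  expect_equal(judge_severe_zone(m3)$ssz_ssz, "A1")
  expect_error(judge_severe_zone(base()), "no MVP component")
})

test_that("ROC over the MVP-frame proportion matches the concordance oracle", {
  r <- roc_over_proportion(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1.0)
  r <- roc_over_proportion(rep(0.5, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(r$auc, 0.5)
  # hand-counted concordant pairs: 3 of 4 -> 0.75
  r <- roc_over_proportion(c(0.9, 0.6, 0.4, 0.7), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 0.75)
  expect_error(roc_over_proportion(c(0.1, 0.2), c(TRUE, TRUE)), "both truth classes")
  set.seed(5)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    sc <- round(runif(n), 2)
    tr <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(tr)) < 2) next
    expect_equal(roc_over_proportion(sc, tr)$auc, oracle_auc_concordance(sc, tr),
                 tolerance = 1e-12)
  }
})

test_that("ROC AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  sc <- runif(40); tr <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(tr, sc, quiet = TRUE, direction = "<")))
  expect_equal(roc_over_proportion(sc, tr)$auc, ref, tolerance = 1e-12)
})

test_that("segmenter validates inputs and honours degenerate K configuration", {
  expect_error(train_segmenter(list()), "empty")
  cs <- tiny_mvp_case()
  i <- which(cs$phases == "systole")[1]
  pair <- list(list(frame = cs$frames[[i]], mask = cs$masks[[i]]))
  cfg1 <- seg_train_config(epochs = 1, lr_ratio_k = 1, seed = 2)
  m1 <- train_segmenter(pair, cfg1)
  m2 <- train_segmenter(pair, cfg1)
  expect_identical(m1$net$par, m2$net$par)  # seeding contract
  pred <- segment_frame(m1, pair[[1]]$frame)
  expect_true(all(pred %in% 0:3))
  expect_equal(dim(pred), dim(pair[[1]]$frame))
})

test_that("segmenter memorizes a single training image", {
  cs <- generate_case(echo_phantom_config(
    image_size = c(128, 128), mvp_case = TRUE, prolapse_amplitude = 10,
    prolapse_zone = "P2", n_cycles = 2, frames_per_cycle = 10, seed = 5))
  i <- which(cs$phases == "systole")[1]
  pair <- list(list(frame = cs$frames[[i]], mask = cs$masks[[i]]))
  m <- train_segmenter(pair, seg_train_config(epochs = 200, lr = 0.02,
                                              hidden = 32,
                                              pixels_per_frame = 20000, seed = 1))
  pred <- segment_frame(m, pair[[1]]$frame)
  fg_dice <- mean(vapply(1:3, function(k)
    overlap_metrics(pred == k, pair[[1]]$mask == k)$dice, numeric(1)))
  expect_gte(fg_dice, 0.95)
})
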