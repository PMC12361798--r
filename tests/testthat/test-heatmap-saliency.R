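test_that("edge belt matches hand-counted and oracle geometry", {
  expect_false(any(make_edge_belt(matrix(0, 16, 16), 3)))
  expect_error(make_edge_belt(matrix(0, 4, 4), -1), ">= 0")
  # 20x20 filled square: w = 0 keeps exactly the 76 perimeter pixels
  m <- matrix(FALSE, 64, 64); m[20:39, 25:44] <- TRUE
  b0 <- make_edge_belt(m, 0)
  expect_equal(sum(b0), 4 * 20 - 4)
  # w = 2 equals the all-pairs Chebyshev-distance oracle pixel-for-pixel
  expect_identical(make_edge_belt(m, 2), oracle_edge_belt(m, 2))
})

test_that("belts grow monotonically and always contain the boundary", {
  set.seed(7)
  for (i in 1:10) {
    m <- random_blob_mask(32, 32)
    b_prev <- NULL
    for (w in 0:4) {
      b <- make_edge_belt(m, w)
      if (!is.null(b_prev)) expect_true(all(b[b_prev]))
      b_prev <- b
    }
    expect_true(all(make_edge_belt(m, 0)[] <= make_edge_belt(m, 3)[]))
  }
})

test_that("frequency attention satisfies the Fourier identities", {
  set.seed(8)
  x <- matrix(rnorm(16 * 16), 16, 16)
  ones <- matrix(1, 16, 16)
  expect_equal(frequency_attention(x, ones), 2 * x, tolerance = 1e-10)
  expect_equal(frequency_attention(x, matrix(0, 16, 16)), x, tolerance = 1e-12)
  expect_error(frequency_attention(x, matrix(1, 8, 8)), "shape")
})

test_that("frequency attention matches a dense DFT-matrix oracle on 8x8 maps", {
  set.seed(9)
  for (i in 1:5) {
    x <- matrix(rnorm(64), 8, 8)
    W <- matrix(rnorm(64), 8, 8)
    Wsym <- echomvp:::symmetrize_spectrum(W)
    got <- frequency_attention(x, W)
    want <- oracle_frequency_attention(x, Wsym)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-4)
  }
})

test_that("the spectral-weight gradient matches finite differences", {
  set.seed(10)
  x <- matrix(rnorm(36), 6, 6)
  W <- matrix(rnorm(36), 6, 6) * 0.1
  tgt <- matrix(runif(36) > 0.5, 6, 6) * 1
  loss_of <- function(W) {
    y <- frequency_attention(x, W)
    p <- 1 / (1 + exp(-y))
    -mean(tgt * log(p) + (1 - tgt) * log(1 - p))
  }
  y <- frequency_attention(x, W)
  p <- 1 / (1 + exp(-y))
  G <- (p - tgt) / length(p)
  ga <- echomvp:::freq_attention_grad(x, G)
  eps <- 1e-6
  for (idx in sample(36, 6)) {
    Wp <- W; Wp[idx] <- Wp[idx] + eps
    Wm <- W; Wm[idx] <- Wm[idx] - eps
    expect_equal(ga[idx], (loss_of(Wp) - loss_of(Wm)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("feature pyramid halves spatial sizes across its four layers", {
  fr <- matrix(runif(128 * 128), 128, 128)
  pyr <- feature_pyramid(fr)
  dims <- t(vapply(pyr$layers, function(l) dim(l)[1:2], numeric(2)))
  expect_equal(dims[, 1], c(32, 16, 8, 4))
  expect_equal(dims[, 2], c(32, 16, 8, 4))
})

test_that("content and edge heads honour their stride and linearity contracts", {
  fr <- matrix(runif(64 * 64), 64, 64)
  pyr <- feature_pyramid(fr)
  nch <- echomvp:::hm_n_channels
  # zero features -> bias-valued constant maps
  pyr0 <- pyr
  for (l in 1:4) pyr0$layers[[l]][] <- 0
  cm <- detect_content(pyr0, list(w = runif(3 * nch), b = 0.7))
  expect_true(all(cm == 0.7))
  expect_equal(dim(cm), c(8, 8))   # stride 8
  em <- detect_edge(pyr0, list(w = runif(nch), b = -0.2))
  expect_true(all(em == -0.2))
  expect_equal(dim(em), c(16, 16)) # stride 4
  # doubling features doubles bias-free logits
  head_c <- list(w = rnorm(3 * nch), b = 0)
  pyr2 <- pyr
  for (l in 1:4) pyr2$layers[[l]] <- pyr$layers[[l]] * 2
  expect_equal(detect_content(pyr2, head_c), 2 * detect_content(pyr, head_c),
               tolerance = 1e-12)
  head_e <- list(w = rnorm(nch), b = 0)
  expect_equal(detect_edge(pyr2, head_e), 2 * detect_edge(pyr, head_e),
               tolerance = 1e-12)
})

test_that("the full forward pass preserves size and the [0,1] codomain", {
  set.seed(11)
  for (size in c(64, 96)) {
    fr <- matrix(runif(size * size), size, size)
    pyr <- feature_pyramid(fr)
    params <- echomvp:::hm_init_params(dim(pyr$layers[[1]]), dim(pyr$layers[[2]]))
    hm <- refine_and_fuse(pyr, params)
    expect_equal(dim(hm), c(size, size))
    expect_true(all(hm >= 0 & hm <= 1))
  }
  # all-zero pyramid gives a constant heatmap
  fr <- matrix(0.5, 64, 64)
  pyr <- feature_pyramid(fr)
  for (l in 1:4) pyr$layers[[l]][] <- 0
  pyr$base[] <- 0
  params <- echomvp:::hm_init_params(dim(pyr$layers[[1]]), dim(pyr$layers[[2]]))
  hm <- refine_and_fuse(pyr, params)
  expect_equal(max(hm) - min(hm), 0, tolerance = 1e-12)
})

test_that("heatmap training validates input, is seeded, and memorizes one frame", {
  expect_error(train_heatmap(list()), "empty")
  cs <- tiny_mvp_case(size = 128)
  i <- which(cs$phases == "systole")[1]
  pair <- list(list(frame = cs$frames[[i]], mask = cs$masks[[i]] == 3L))
  cfg <- heatmap_train_config(epochs = 2, seed = 3)
  m1 <- train_heatmap(pair, cfg)
  m2 <- train_heatmap(pair, cfg)
  expect_identical(m1$loss_log$edge[1], m2$loss_log$edge[1])
  expect_identical(m1$params, m2$params)
  # 300-step memorization of a single frame
  m <- train_heatmap(pair, heatmap_train_config(epochs = 300, seed = 1))
  hm <- predict_heatmap(m, pair[[1]]$frame)
  expect_true(all(hm >= 0 & hm <= 1))
  expect_gte(overlap_metrics(hm >= 0.5, pair[[1]]$mask)$dice, 0.95)
  # inference is deterministic
  expect_identical(hm, predict_heatmap(m, pair[[1]]$frame))
})
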