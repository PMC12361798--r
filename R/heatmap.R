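# Edge-belt-guided saliency segmentation of the prolapse area.
#
# A fixed multi-filter feature pyramid (strides 4/8/16/32) plays the backbone
# role; learnable frequency-domain attention modulates layers 1-2; linear
# content/edge detection heads produce the coarse guidance maps; a gated
# progressive top-down refinement fuses layers 4 -> 3 -> 2 and a final head
# emits the full-resolution saliency heatmap. All gradients are analytic
# (every trainable op is linear or an explicit sigmoid gate), so training is
# plain SGD without an autodiff framework.

#' Edge belt of a binary mask
#'
#' The boundary is the set of mask pixels 8-adjacent to background (or to the
#' image border); the belt thickens it to all pixels within Chebyshev distance
#' `w` of any boundary pixel. A belt of nonzero width gives the edge
#' supervision a tolerance band, which both eases convergence of the edge
#' head and reduces sensitivity to annotation bias at the ill-defined
#' prolapse boundary. An empty mask yields an empty belt.
#'
#' @param mask binary (logical or 0/1) matrix.
#' @param w belt half-width in pixels, `>= 0`.
#' @return logical matrix of the same size.
#' @export
make_edge_belt <- function(mask, w = 3L) {
  if (w < 0) stop("belt width w must be >= 0")
  mask <- mask != 0
  if (!any(mask)) return(matrix(FALSE, nrow(mask), ncol(mask)))
  interior <- mask
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    interior <- interior & shift_mat(mask, dy, dx, pad = FALSE)
  }
  boundary <- mask & !interior
  dilate_chebyshev(boundary, w)
}

hm_n_channels <- 10L
hm_strides <- c(4L, 8L, 16L, 32L)
hm_final_hidden <- 16L                      # hidden width of the final head
hm_m2_channel <- hm_n_channels + 1L        # fused-map channel in the stack
hm_final_stack <- hm_n_channels + 7L       # stack depth seen by the head

# Full-resolution base feature stack: intensities at several Gaussian scales,
# a gradient-magnitude channel, and linear/quadratic coordinate channels.
hm_base_stack <- function(frame) {
  h <- nrow(frame); w <- ncol(frame)
  g1 <- blur_gaussian(frame, 1)
  g2 <- blur_gaussian(frame, 2)
  g4 <- blur_gaussian(frame, 4)
  gr <- gradient_magnitude(g1)
  xn <- matrix(seq_len(w) / w, h, w, byrow = TRUE) - 0.5
  yn <- matrix(seq_len(h) / h, h, w) - 0.5
  arr <- array(0, c(h, w, hm_n_channels))
  arr[, , 1] <- frame; arr[, , 2] <- g1; arr[, , 3] <- g2; arr[, , 4] <- g4
  arr[, , 5] <- gr; arr[, , 6] <- xn; arr[, , 7] <- yn
  arr[, , 8] <- xn^2; arr[, , 9] <- yn^2; arr[, , 10] <- xn * yn
  arr
}

#' Multi-layer feature pyramid of a frame
#'
#' Four feature maps at strides 4/8/16/32 obtained by block mean-pooling a
#' bank of fixed full-resolution filter responses (multi-scale intensity,
#' gradient magnitude, coordinate channels). Spatial sizes halve per layer.
#'
#' @param frame grayscale matrix.
#' @param stats optional per-channel standardisation `list(mu, sd)` (stored
#'   in a trained model); `NULL` leaves channels raw.
#' @return object of class `feature_pyramid`: `layers` (list of 4 arrays),
#'   `strides`, `base` (full-resolution channel stack).
#' @export
feature_pyramid <- function(frame, stats = NULL) {
  base <- hm_base_stack(frame)
  if (!is.null(stats)) {
    for (c_ in seq_len(hm_n_channels))
      base[, , c_] <- (base[, , c_] - stats$mu[c_]) / stats$sd[c_]
  }
  layers <- lapply(hm_strides, function(s) {
    oh <- ceiling(nrow(frame) / s); ow <- ceiling(ncol(frame) / s)
    arr <- array(0, c(oh, ow, hm_n_channels))
    for (c_ in seq_len(hm_n_channels)) arr[, , c_] <- downsample_block(base[, , c_], s)
    arr
  })
  structure(list(layers = layers, strides = hm_strides, base = base),
            class = "feature_pyramid")
}

flip_spectrum <- function(W) {
  h <- nrow(W); w <- ncol(W)
  W[c(1, rev(seq_len(h - 1) + 1)), c(1, rev(seq_len(w - 1) + 1)), drop = FALSE]
}

symmetrize_spectrum <- function(W) (W + flip_spectrum(W)) / 2

#' Learnable frequency-domain attention
#'
#' Per channel, the feature map's 2-D Fourier spectrum is reweighted by a
#' learnable real weight map and transformed back, with a residual
#' connection: `out = IFFT(W_sym * FFT(x)) + x`. The weights are symmetrised
#' under frequency negation so the reweighted spectrum stays conjugate
#' symmetric and the output exactly real. Unit weights therefore give
#' `out = 2 * x` and zero weights give `out = x`.
#'
#' @param fmap feature array `h x w x c` (or a single matrix).
#' @param weights real array of the same shape (per-channel spectral weights).
#' @return array of the same shape.
#' @export
frequency_attention <- function(fmap, weights) {
  single <- is.matrix(fmap)
  if (single) {
    if (!is.matrix(weights) || !all(dim(weights) == dim(fmap)))
      stop("spectral weights must match the feature map shape")
    fmap <- array(fmap, c(dim(fmap), 1))
    weights <- array(weights, dim(fmap))
  }
  if (!all(dim(fmap) == dim(weights)))
    stop("spectral weights must match the feature map shape")
  out <- fmap
  n <- dim(fmap)[1] * dim(fmap)[2]
  for (c_ in seq_len(dim(fmap)[3])) {
    x <- fmap[, , c_]
    Ws <- symmetrize_spectrum(weights[, , c_])
    y <- Re(stats::fft(Ws * stats::fft(x), inverse = TRUE)) / n
    out[, , c_] <- y + x
  }
  if (single) out[, , 1] else out
}

# Gradient of a loss wrt the raw (pre-symmetrisation) spectral weights, given
# the gradient G arriving at the transform branch output (residual excluded):
# y = Re(ifft(W_sym * fft(x)))/n  =>  dL/dW_sym = Re(fft(x) * ifft(G))/n,
# then symmetrised because W_sym averages W with its frequency-flip.
freq_attention_grad <- function(x, G) {
  n <- length(x)
  gW <- Re(stats::fft(x) * stats::fft(G, inverse = TRUE)) / n
  symmetrize_spectrum(gW)
}

lincomb <- function(arr, v, b = 0) {
  out <- matrix(b, dim(arr)[1], dim(arr)[2])
  for (c_ in seq_along(v)) out <- out + v[c_] * arr[, , c_]
  out
}

up2 <- function(m, out_h, out_w) upsample_nearest(m, 2L, out_h, out_w)

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Coarse content detection from pyramid layers 2-4
#'
#' Layers 3 and 4 are upsampled to stride 8, concatenated with layer 2 along
#' channels, and a linear head produces a single-channel logit map at
#' stride 8.
#'
#' @param pyramid a [feature_pyramid()] (layer 2 possibly already passed
#'   through [frequency_attention()]).
#' @param head `list(w, b)` with `w` of length `3 * n_channels`.
#' @return logit matrix at stride 8.
#' @export
detect_content <- function(pyramid, head) {
  F8 <- content_feature_stack(pyramid)
  lincomb(F8, head$w, head$b)
}

content_feature_stack <- function(pyramid) {
  l2 <- pyramid$layers[[2]]; l3 <- pyramid$layers[[3]]; l4 <- pyramid$layers[[4]]
  h8 <- dim(l2)[1]; w8 <- dim(l2)[2]
  F8 <- array(0, c(h8, w8, 3L * hm_n_channels))
  F8[, , seq_len(hm_n_channels)] <- l2
  for (c_ in seq_len(hm_n_channels)) {
    F8[, , hm_n_channels + c_] <- up2(l3[, , c_], h8, w8)
    F8[, , 2L * hm_n_channels + c_] <- upsample_nearest(l4[, , c_], 4L, h8, w8)
  }
  F8
}

#' Edge detection from pyramid layer 1
#'
#' The first (finest) layer carries most of the edge information; a linear
#' head over its channels produces a single-channel logit map at stride 4,
#' supervised against the edge-belt target during training.
#'
#' @param pyramid a [feature_pyramid()] (layer 1 possibly already passed
#'   through [frequency_attention()]).
#' @param head `list(w, b)` with `w` of length `n_channels`.
#' @return logit matrix at stride 4.
#' @export
detect_edge <- function(pyramid, head) {
  lincomb(pyramid$layers[[1]], head$w, head$b)
}

# Full forward pass. Returns all intermediates needed for the analytic
# gradients of the final stage.
hm_forward <- function(params, pyr) {
  l1 <- frequency_attention(pyr$layers[[1]], params$W1)
  l2 <- frequency_attention(pyr$layers[[2]], params$W2)
  pyr_att <- pyr
  pyr_att$layers[[1]] <- l1
  pyr_att$layers[[2]] <- l2
  edge_logit <- detect_edge(pyr_att, params$edge)      # stride 4
  content_logit <- detect_content(pyr_att, params$content)  # stride 8
  gc_ <- sigmoid(content_logit)
  ge <- sigmoid(edge_logit)
  l3 <- pyr$layers[[3]]; l4 <- pyr$layers[[4]]
  d2 <- dim(l2); d3 <- dim(l3); d4 <- dim(l4)
  gc3 <- downsample_block(gc_, 2)[seq_len(d3[1]), seq_len(d3[2]), drop = FALSE]
  gc4 <- downsample_block(gc_, 4)[seq_len(d4[1]), seq_len(d4[2]), drop = FALSE]
  ge8 <- downsample_block(ge, 2)[seq_len(d2[1]), seq_len(d2[2]), drop = FALSE]
  ge16 <- downsample_block(ge, 4)[seq_len(d3[1]), seq_len(d3[2]), drop = FALSE]
  ge32 <- downsample_block(ge, 8)[seq_len(d4[1]), seq_len(d4[2]), drop = FALSE]
  g2 <- array(rep(gc_, hm_n_channels), d2)
  g3 <- array(rep(gc3, hm_n_channels), d3)
  g4a <- array(rep(gc4, hm_n_channels), d4)
  gl2 <- l2 * g2; gl3 <- l3 * g3; gl4 <- l4 * g4a
  pre4 <- lincomb(gl4, params$v4, params$b4)
  m4 <- pre4 * ge32
  m4u <- up2(m4, d3[1], d3[2])
  pre3 <- lincomb(gl3, params$v3, params$b3) + m4u
  m3 <- pre3 * ge16
  m3u <- up2(m3, d2[1], d2[2])
  pre2 <- lincomb(gl2, params$v2, params$b2) + m3u
  m2 <- pre2 * ge8
  h <- dim(pyr$base)[1]; w <- dim(pyr$base)[2]
  m2_full <- upsample_nearest(m2, 8L, h, w)
  # guidance maps enter the final head bilinearly (smooth boundaries); they
  # are stop-gradient in the final stage so no adjoint is needed for them
  edge_full <- resize_img(edge_logit, h, w, "bilinear")
  content_full <- resize_img(content_logit, h, w, "bilinear")
  # per-pixel feature stack for the final head: full-resolution backbone
  # channels, the fused refinement map, both guidance logit maps, and
  # content/edge-probability gates applied to the finest intensity channel
  sc_full <- sigmoid(content_full)
  se_full <- sigmoid(edge_full)
  S <- array(0, c(h, w, hm_final_stack))
  S[, , seq_len(hm_n_channels)] <- pyr$base
  S[, , hm_m2_channel] <- m2_full
  S[, , hm_m2_channel + 1L] <- edge_full
  S[, , hm_m2_channel + 2L] <- content_full
  S[, , hm_m2_channel + 3L] <- sc_full
  S[, , hm_m2_channel + 4L] <- sc_full * pyr$base[, , 1]
  S[, , hm_m2_channel + 5L] <- se_full * pyr$base[, , 1]
  S[, , hm_m2_channel + 6L] <- sc_full * se_full
  # final head: a small per-pixel network (1x1-convolution stack) over S
  fin <- params$final
  H <- lapply(seq_along(fin$w2), function(j)
    tanh(lincomb(S, fin$U[, j], fin$ub[j])))
  logits <- matrix(fin$b0, h, w)
  for (j in seq_along(fin$w2)) logits <- logits + fin$w2[j] * H[[j]]
  list(l1 = l1, l2 = l2, edge_logit = edge_logit, content_logit = content_logit,
       ge8 = ge8, ge16 = ge16, ge32 = ge32, gl2 = gl2, gl3 = gl3, gl4 = gl4,
       pre4 = pre4, pre3 = pre3, pre2 = pre2, m4 = m4, m3 = m3, m2 = m2,
       m2_full = m2_full, edge_full = edge_full, content_full = content_full,
       S = S, H = H, logits = logits, heatmap = sigmoid(logits))
}

#' Gated progressive refinement and fusion into a saliency heatmap
#'
#' Layers 2-4 are modulated by the sigmoid of the coarse content map
#' (content refinement); a progressive top-down pass (layer 4 to 3 to 2)
#' mixes each gated layer with the upsampled coarser stage, gating every
#' stage by the sigmoid of the edge map (edge refinement); the fused map is
#' upsampled to the input resolution, combined with the guidance maps and
#' full-resolution features by the final head, and sigmoid-squashed to
#' `[0, 1]`.
#'
#' @param pyramid a [feature_pyramid()].
#' @param params a trained parameter set (element `params` of a
#'   `heatmap_model`).
#' @return saliency matrix in `[0, 1]` at the input resolution.
#' @export
refine_and_fuse <- function(pyramid, params) {
  hm_forward(params, pyramid)$heatmap
}

hm_init_params <- function(d1, d2) {
  list(W1 = array(stats::rnorm(prod(d1), sd = 0.01), d1),
       W2 = array(stats::rnorm(prod(d2), sd = 0.01), d2),
       edge = list(w = stats::rnorm(hm_n_channels, sd = 0.05), b = 0),
       content = list(w = stats::rnorm(3 * hm_n_channels, sd = 0.05), b = 0),
       v2 = stats::rnorm(hm_n_channels, sd = 0.05),
       v3 = stats::rnorm(hm_n_channels, sd = 0.05),
       v4 = stats::rnorm(hm_n_channels, sd = 0.05),
       b2 = 0, b3 = 0, b4 = 0,
       final = list(U = matrix(stats::rnorm(hm_final_stack * hm_final_hidden,
                                            sd = 0.1),
                               hm_final_stack, hm_final_hidden),
                    ub = rep(0, hm_final_hidden),
                    w2 = stats::rnorm(hm_final_hidden, sd = 0.1),
                    b0 = 0))
}

#' Training configuration for the heatmap model
#'
#' @param epochs passes over the dataset per training stage.
#' @param lr learning rate of the SGD stages (edge and content heads).
#' @param lr_final Adam step size of the final refinement/fusion stage.
#' @param belt_width edge-belt half-width `w` (pixels) for the edge target.
#' @param loss_weights named weights `(content, edge, final)` combining the
#'   three supervised losses into the reported joint loss.
#' @param seed integer seed.
#' @return a plain list.
#' @export
heatmap_train_config <- function(epochs = 15L, lr = 0.5, lr_final = 0.5,
                                 belt_width = 3L,
                                 loss_weights = c(content = 1, edge = 1, final = 2),
                                 seed = 1L) {
  list(epochs = as.integer(epochs), lr = lr, lr_final = lr_final,
       belt_width = as.integer(belt_width),
       loss_weights = loss_weights, seed = as.integer(seed))
}

# Adam update over a flat named list of numeric parameters.
adam_init <- function(par) list(m = lapply(par, function(x) x * 0),
                                v = lapply(par, function(x) x * 0), t = 0)

adam_step <- function(par, grad, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in names(grad)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grad[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, st = st)
}

bce_grad <- function(p, t) {
  n <- length(p)
  loss <- -mean(t * log(pmax(p, 1e-9)) + (1 - t) * log(pmax(1 - p, 1e-9)))
  list(loss = loss, g = (p - t) / n)  # gradient wrt logits
}

soft_iou_grad <- function(p, t) {
  I <- sum(p * t); U <- sum(p) + sum(t) - I
  loss <- 1 - I / max(U, 1e-9)
  gp <- -(t * U - I * (1 - t)) / max(U, 1e-9)^2  # wrt p
  list(loss = loss, g = gp * p * (1 - p))        # wrt logits
}

#' Train the edge-belt-guided heatmap model
#'
#' Stage-wise optimisation with analytic gradients: (1) the edge head and the
#' layer-1 spectral attention weights are fitted to the edge-belt target at
#' stride 4; (2) the content head and the layer-2 spectral weights are fitted
#' to the down-sampled content target at stride 8; (3) with the guidance maps
#' fixed (stop-gradient), the refinement mixing weights and the final head
#' are fitted to the full-resolution mask with a binary cross-entropy plus
#' soft-IoU loss. The joint weighted loss is logged per epoch in `$loss_log`.
#'
#' @param dataset list of `list(frame =, mask =)` pairs; masks are binary
#'   prolapse masks (all frames are expected to contain prolapse, mirroring
#'   an annotated-prolapse-frame training set).
#' @param config a [heatmap_train_config()].
#' @return object of class `heatmap_model`.
#' @export
train_heatmap <- function(dataset, config = heatmap_train_config()) {
  if (length(dataset) == 0) stop("empty dataset: no (frame, mask) pairs")
  h <- nrow(dataset[[1]]$frame); w <- ncol(dataset[[1]]$frame)
  # per-channel standardisation over (a subset of) the training frames
  idx <- seq_len(min(length(dataset), 32L))
  acc <- matrix(0, length(idx) * 2, hm_n_channels)
  for (j in seq_along(idx)) {
    st <- hm_base_stack(dataset[[idx[j]]]$frame)
    acc[2 * j - 1, ] <- apply(st, 3, mean)
    acc[2 * j, ] <- apply(st, 3, function(m) mean(m^2))
  }
  mu <- colMeans(acc[seq(1, nrow(acc), 2), , drop = FALSE])
  m2 <- colMeans(acc[seq(2, nrow(acc), 2), , drop = FALSE])
  sdv <- sqrt(pmax(m2 - mu^2, 1e-8))
  stats_ <- list(mu = mu, sd = sdv)

  pyrs <- lapply(dataset, function(d) feature_pyramid(d$frame, stats_))
  belts <- lapply(dataset, function(d) make_edge_belt(d$mask, config$belt_width))
  d1 <- dim(pyrs[[1]]$layers[[1]]); d2 <- dim(pyrs[[1]]$layers[[2]])
  # supervision targets at head resolutions
  t_edge <- lapply(belts, function(b)
    resize_img(b * 1, d1[1], d1[2], "nearest"))
  t_cont <- lapply(dataset, function(d)
    (downsample_block((d$mask != 0) * 1, 8)[seq_len(d2[1]), seq_len(d2[2]), drop = FALSE]) > 0.5)
  t_full <- lapply(dataset, function(d) (d$mask != 0) * 1)

  run_with_seed(config$seed, {
    params <- hm_init_params(d1, d2)
    n <- length(dataset)
    lw <- config$loss_weights
    loss_log <- data.frame(epoch = seq_len(config$epochs), edge = NA_real_,
                           content = NA_real_, final = NA_real_, joint = NA_real_)

    # ---- stage 1: edge head + layer-1 frequency attention ----
    for (ep in seq_len(config$epochs)) {
      tot <- 0
      for (i in sample.int(n)) {
        l1 <- frequency_attention(pyrs[[i]]$layers[[1]], params$W1)
        z <- lincomb(l1, params$edge$w, params$edge$b)
        gr <- bce_grad(sigmoid(z), t_edge[[i]] * 1)
        tot <- tot + gr$loss
        G <- gr$g
        gw <- vapply(seq_len(hm_n_channels), function(c_) sum(G * l1[, , c_]),
                     numeric(1))
        for (c_ in seq_len(hm_n_channels)) {
          Gc <- G * params$edge$w[c_]
          params$W1[, , c_] <- params$W1[, , c_] -
            config$lr * freq_attention_grad(pyrs[[i]]$layers[[1]][, , c_], Gc)
        }
        params$edge$w <- params$edge$w - config$lr * gw
        params$edge$b <- params$edge$b - config$lr * sum(G)
      }
      loss_log$edge[ep] <- tot / n
    }

    # ---- stage 2: content head + layer-2 frequency attention ----
    for (ep in seq_len(config$epochs)) {
      tot <- 0
      for (i in sample.int(n)) {
        pyr_att <- pyrs[[i]]
        pyr_att$layers[[2]] <- frequency_attention(pyrs[[i]]$layers[[2]], params$W2)
        F8 <- content_feature_stack(pyr_att)
        z <- lincomb(F8, params$content$w, params$content$b)
        gr <- bce_grad(sigmoid(z), t_cont[[i]] * 1)
        tot <- tot + gr$loss
        G <- gr$g
        gw <- vapply(seq_len(3 * hm_n_channels), function(c_) sum(G * F8[, , c_]),
                     numeric(1))
        for (c_ in seq_len(hm_n_channels)) {
          Gc <- G * params$content$w[c_]  # layer-2 block of the stack
          params$W2[, , c_] <- params$W2[, , c_] -
            config$lr * freq_attention_grad(pyrs[[i]]$layers[[2]][, , c_], Gc)
        }
        params$content$w <- params$content$w - config$lr * gw
        params$content$b <- params$content$b - config$lr * sum(G)
      }
      loss_log$content[ep] <- tot / n
    }

    # ---- stage 3: refinement mixing weights + final head (gates fixed) ----
    # Adam on the fusion/final parameters: the loss needs a sharp decision
    # boundary (large weights) that plain SGD approaches too slowly.
    flat <- list(v2 = params$v2, v3 = params$v3, v4 = params$v4,
                 b2 = params$b2, b3 = params$b3, b4 = params$b4,
                 U = params$final$U, ub = params$final$ub,
                 w2 = params$final$w2, b0 = params$final$b0)
    ad <- adam_init(flat)
    lr3 <- if (is.null(config$lr_final)) 0.5 else config$lr_final
    for (ep in seq_len(config$epochs)) {
      # cosine-decayed Adam step: fast early progress, sharp late boundaries
      lr_ep <- lr3 * 0.5 * (1 + cos(pi * (ep - 1) / config$epochs))
      tot <- 0
      for (i in sample.int(n)) {
        params$v2 <- flat$v2; params$v3 <- flat$v3; params$v4 <- flat$v4
        params$b2 <- flat$b2; params$b3 <- flat$b3; params$b4 <- flat$b4
        params$final <- list(U = flat$U, ub = flat$ub, w2 = flat$w2,
                             b0 = flat$b0)
        fw <- hm_forward(params, pyrs[[i]])
        t1 <- t_full[[i]]
        g_b <- bce_grad(fw$heatmap, t1)
        g_i <- soft_iou_grad(fw$heatmap, t1)
        tot <- tot + g_b$loss + g_i$loss
        G <- g_b$g + g_i$g  # gradient wrt final logits
        # back through the final head (per-pixel network)
        nh <- length(flat$w2)
        gU <- flat$U * 0; gub <- flat$ub * 0; gw2 <- flat$w2 * 0
        g_m2_full <- matrix(0, nrow(G), ncol(G))
        for (j in seq_len(nh)) {
          gw2[j] <- sum(G * fw$H[[j]])
          Gh <- G * flat$w2[j] * (1 - fw$H[[j]]^2)
          gub[j] <- sum(Gh)
          gU[, j] <- vapply(seq_len(hm_final_stack),
                            function(c_) sum(Gh * fw$S[, , c_]), numeric(1))
          g_m2_full <- g_m2_full + Gh * flat$U[hm_m2_channel, j]
        }
        d2s <- dim(fw$m2); d3s <- dim(fw$m3); d4s <- dim(fw$m4)
        g_m2 <- upsample_nearest_adjoint(g_m2_full, 8L, d2s[1], d2s[2])
        g_pre2 <- g_m2 * fw$ge8
        g_m3 <- upsample_nearest_adjoint(g_pre2, 2L, d3s[1], d3s[2])
        g_pre3 <- g_m3 * fw$ge16
        g_m4 <- upsample_nearest_adjoint(g_pre3, 2L, d4s[1], d4s[2])
        g_pre4 <- g_m4 * fw$ge32
        grad <- list(
          v2 = vapply(seq_len(hm_n_channels), function(c_) sum(g_pre2 * fw$gl2[, , c_]), numeric(1)),
          v3 = vapply(seq_len(hm_n_channels), function(c_) sum(g_pre3 * fw$gl3[, , c_]), numeric(1)),
          v4 = vapply(seq_len(hm_n_channels), function(c_) sum(g_pre4 * fw$gl4[, , c_]), numeric(1)),
          b2 = sum(g_pre2), b3 = sum(g_pre3), b4 = sum(g_pre4),
          U = gU, ub = gub, w2 = gw2, b0 = sum(G))
        upd <- adam_step(flat, grad, ad, lr_ep)
        flat <- upd$par; ad <- upd$st
      }
      loss_log$final[ep] <- tot / n
    }
    params$v2 <- flat$v2; params$v3 <- flat$v3; params$v4 <- flat$v4
    params$b2 <- flat$b2; params$b3 <- flat$b3; params$b4 <- flat$b4
    params$final <- list(U = flat$U, ub = flat$ub, w2 = flat$w2,
                         b0 = flat$b0)
    loss_log$joint <- lw["content"] * loss_log$content +
      lw["edge"] * loss_log$edge + lw["final"] * loss_log$final

    structure(list(params = params, stats = stats_, size = c(h, w),
                   loss_log = loss_log, config = config),
              class = "heatmap_model")
  })
}

#' Predict the prolapse saliency heatmap of a frame
#'
#' Deterministic inference: values in `[0, 1]`; thresholding at 0.5 yields
#' the binary map used for Dice/IoU evaluation. Frames whose size differs
#' from the training size are resized for inference and the heatmap is
#' resized back.
#'
#' @param model a trained `heatmap_model`.
#' @param frame grayscale matrix.
#' @return saliency matrix in `[0, 1]`, same size as `frame`.
#' @export
predict_heatmap <- function(model, frame) {
  h0 <- nrow(frame); w0 <- ncol(frame)
  fr <- if (h0 != model$size[1] || w0 != model$size[2])
    resize_img(frame, model$size[1], model$size[2], "bilinear") else frame
  pyr <- feature_pyramid(fr, model$stats)
  hm <- hm_forward(model$params, pyr)$heatmap
  if (h0 != model$size[1] || w0 != model$size[2])
    hm <- clamp01(resize_img(hm, h0, w0, "bilinear"))
  hm
}

#' Write a heatmap as grayscale PNG plus an RGB overlay
#'
#' The grayscale PNG stores `round(255 * saliency)`; the overlay blends a
#' blue-to-red colormap of the saliency onto the frame.
#'
#' @param heatmap saliency matrix in `[0, 1]`.
#' @param path output path of the grayscale PNG.
#' @param frame optional frame for the overlay, written next to `path` with
#'   suffix `_overlay.png`.
#' @param alpha overlay opacity of the colormap.
#' @return `path`, invisibly.
#' @export
write_heatmap_png <- function(heatmap, path, frame = NULL, alpha = 0.45) {
  png::writePNG(round(heatmap * 255) / 255, path)
  if (!is.null(frame)) {
    h <- nrow(heatmap); w <- ncol(heatmap)
    rgb <- array(0, c(h, w, 3))
    rgb[, , 1] <- clamp01(1.5 * heatmap - 0.25)        # red ramps up
    rgb[, , 2] <- clamp01(1 - 2 * abs(heatmap - 0.5))  # green mid
    rgb[, , 3] <- clamp01(1 - 1.5 * heatmap)           # blue ramps down
    base <- array(rep(frame, 3), c(h, w, 3))
    out <- (1 - alpha) * base + alpha * rgb
    png::writePNG(clamp01(out), sub("\\.png$", "_overlay.png", path))
  }
  invisible(path)
}
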