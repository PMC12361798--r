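# Internal image primitives.
#
# Frames are numeric matrices indexed [row = y, col = x] with intensities in
# [0, 1]; masks are integer matrices with small label sets. All operations are
# vectorised matrix ops; no compiled code.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Shift a matrix by (dy, dx), padding revealed cells with `pad`.
shift_mat <- function(m, dy, dx, pad = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(pad, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  if (length(ys) > 0 && length(xs) > 0)
    out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

gauss_kernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with replicated (clamped) edges.
blur_gaussian <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gauss_kernel1d(sigma)
  r <- (length(k) - 1L) / 2L
  h <- nrow(img); w <- ncol(img)
  # rows (y direction)
  tmp <- matrix(0, h, w)
  for (i in seq_along(k)) {
    d <- i - r - 1L
    idx <- pmin(pmax(seq_len(h) + d, 1L), h)
    tmp <- tmp + k[i] * img[idx, , drop = FALSE]
  }
  out <- matrix(0, h, w)
  for (i in seq_along(k)) {
    d <- i - r - 1L
    idx <- pmin(pmax(seq_len(w) + d, 1L), w)
    out <- out + k[i] * tmp[, idx, drop = FALSE]
  }
  out
}

# Central-difference gradient magnitude.
gradient_magnitude <- function(img) {
  gy <- (shift_mat(img, -1, 0, pad = NA) - shift_mat(img, 1, 0, pad = NA)) / 2
  gx <- (shift_mat(img, 0, -1, pad = NA) - shift_mat(img, 0, 1, pad = NA)) / 2
  gy[is.na(gy)] <- 0; gx[is.na(gx)] <- 0
  sqrt(gx^2 + gy^2)
}

# Resize with bilinear or nearest-neighbour sampling.
resize_img <- function(img, out_h, out_w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  h <- nrow(img); w <- ncol(img)
  if (h == out_h && w == out_w) return(img)
  # map output pixel centres to input coordinates (pixel centres at integers)
  fy <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  fx <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  if (method == "nearest") {
    iy <- pmin(pmax(ceiling(fy - 0.5), 1L), h)
    ix <- pmin(pmax(ceiling(fx - 0.5), 1L), w)
    return(img[iy, ix, drop = FALSE])
  }
  y0 <- pmin(pmax(floor(fy), 1L), h); y1 <- pmin(y0 + 1L, h)
  x0 <- pmin(pmax(floor(fx), 1L), w); x1 <- pmin(x0 + 1L, w)
  wy <- pmin(pmax(fy - y0, 0), 1); wx <- pmin(pmax(fx - x0, 0), 1)
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x1, drop = FALSE]
  c_ <- img[y1, x0, drop = FALSE]; d <- img[y1, x1, drop = FALSE]
  WY <- matrix(wy, out_h, out_w); WX <- matrix(wx, out_h, out_w, byrow = TRUE)
  (1 - WY) * ((1 - WX) * a + WX * b) + WY * ((1 - WX) * c_ + WX * d)
}

# Rotate about the image centre by `theta_deg` (counter-clockwise in standard
# x-right/y-down pixel coordinates this is a clockwise visual rotation; the
# exact sense is irrelevant to augmentation as the range is symmetric).
rotate_img <- function(img, theta_deg, method = c("bilinear", "nearest"),
                       pad = 0) {
  method <- match.arg(method)
  if (theta_deg == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  th <- theta_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  # inverse mapping: sample source at rotation by -theta
  sy <- cy + (-sin(-th)) * xx + cos(-th) * yy
  sx <- cx + cos(-th) * xx + sin(-th) * yy
  if (method == "nearest") {
    iy <- round(sy); ix <- round(sx)
    ok <- iy >= 1 & iy <= h & ix >= 1 & ix <= w
    out <- matrix(pad, h, w)
    out[ok] <- img[cbind(iy[ok], ix[ok])]
    return(out)
  }
  y0 <- floor(sy); x0 <- floor(sx)
  wy <- sy - y0; wx <- sx - x0
  out <- matrix(0, h, w); norm <- matrix(0, h, w)
  for (dy in 0:1) for (dx in 0:1) {
    iy <- y0 + dy; ix <- x0 + dx
    wgt <- (if (dy == 0) 1 - wy else wy) * (if (dx == 0) 1 - wx else wx)
    ok <- iy >= 1 & iy <= h & ix >= 1 & ix <= w
    add <- matrix(0, h, w)
    add[ok] <- img[cbind(iy[ok], ix[ok])] * wgt[ok]
    out <- out + add
    norm <- norm + wgt * ok
  }
  out[norm == 0] <- pad
  nz <- norm > 0
  out[nz] <- out[nz] / norm[nz]
  out
}

flip_horizontal <- function(img) img[, rev(seq_len(ncol(img))), drop = FALSE]

# 8-connectivity labelling of a logical/binary mask by iterative minimum-label
# propagation over the 3x3 neighbourhood. Converges in O(component diameter)
# vectorised passes.
label_components <- function(mask) {
  mask <- mask != 0
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lab[mask] <- seq_len(sum(mask))
  lab_full <- matrix(0L, h, w)
  lab_full[mask] <- lab[mask]
  big <- .Machine$integer.max
  repeat {
    cur <- lab_full
    cur[!mask] <- big
    nb <- cur
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      nb <- pmin(nb, shift_mat(cur, dy, dx, pad = big))
    }
    newlab <- pmin(cur, nb)
    newlab[!mask] <- 0L
    if (all(newlab == lab_full)) break
    lab_full <- newlab
  }
  # renumber 1..k in raster order of first occurrence
  ids <- unique(lab_full[lab_full > 0])
  if (length(ids) > 0)
    lab_full[lab_full > 0] <- match(lab_full[lab_full > 0], ids)
  lab_full
}

# Chebyshev (square-structuring-element) dilation by radius w: w iterations of
# a 3x3 maximum. Radius-w dilation of a set equals the union of Chebyshev
# balls of radius w around its pixels.
dilate_chebyshev <- function(mask, w) {
  mask <- mask != 0
  if (w <= 0) return(mask)
  for (i in seq_len(w)) {
    nb <- mask
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      nb <- nb | shift_mat(mask, dy, dx, pad = FALSE)
    }
    mask <- nb
  }
  mask
}

# Block mean-pooling by integer factor f (trailing partial blocks averaged
# over the pixels present).
downsample_block <- function(img, f) {
  h <- nrow(img); w <- ncol(img)
  oh <- ceiling(h / f); ow <- ceiling(w / f)
  gy <- rep(seq_len(oh), each = f)[seq_len(h)]
  gx <- rep(seq_len(ow), each = f)[seq_len(w)]
  sums <- rowsum(img, gy)            # oh x w
  sums <- t(rowsum(t(sums), gx))     # oh x ow
  cnt <- outer(tabulate(gy, oh), tabulate(gx, ow))
  sums / cnt
}

# Nearest-neighbour upsample by integer factor f, then crop/pad to (out_h, out_w).
upsample_nearest <- function(img, f, out_h, out_w) {
  up <- img[rep(seq_len(nrow(img)), each = f), rep(seq_len(ncol(img)), each = f),
            drop = FALSE]
  up[pmin(seq_len(out_h), nrow(up)), pmin(seq_len(out_w), ncol(up)), drop = FALSE]
}

# Adjoint of upsample_nearest: block-sum of a gradient map back to the coarse
# grid (used by the analytic gradients of the heatmap model).
upsample_nearest_adjoint <- function(grad, f, in_h, in_w) {
  h <- nrow(grad); w <- ncol(grad)
  gy <- pmin(ceiling(seq_len(h) / f), in_h)
  gx <- pmin(ceiling(seq_len(w) / f), in_w)
  s <- rowsum(grad, gy)
  s <- t(rowsum(t(s), gx))
  out <- matrix(0, in_h, in_w)
  out[seq_len(nrow(s)), seq_len(ncol(s))] <- s
  out
}

# Otsu threshold on a [0,1] grayscale image (256-bin histogram).
otsu_threshold <- function(img) {
  v <- pmin(pmax(as.vector(img), 0), 1)
  counts <- tabulate(pmin(floor(v * 256) + 1L, 256L), 256L)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(256) - 0.5))
  mu_t <- mu[256]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  (which.max(sb) - 0.5) / 256
}

run_with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
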