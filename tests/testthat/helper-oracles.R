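# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use the simplest possible algorithms
# (queue-based flood fill, all-pairs distances, dense DFT matrices, explicit
# pair counting) and share no code with the implementation paths they check.

# 8-connectivity connected components by queue-based flood fill.
oracle_flood_fill <- function(mask) {
  mask <- mask != 0
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (y0 in seq_len(h)) for (x0 in seq_len(w)) {
    if (!mask[y0, x0] || lab[y0, x0] != 0L) next
    cur <- cur + 1L
    queue <- list(c(y0, x0))
    lab[y0, x0] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dy in -1:1) for (dx in -1:1) {
        y <- p[1] + dy; x <- p[2] + dx
        if (y >= 1 && y <= h && x >= 1 && x <= w &&
            mask[y, x] && lab[y, x] == 0L) {
          lab[y, x] <- cur
          queue[[length(queue) + 1L]] <- c(y, x)
        }
      }
    }
  }
  lab
}

# Edge belt by all-pairs Chebyshev distances: boundary = mask pixels with an
# 8-neighbour outside the mask (or outside the image); belt = pixels within
# Chebyshev distance w of any boundary pixel.
oracle_edge_belt <- function(mask, w) {
  mask <- mask != 0
  h <- nrow(mask); w_img <- ncol(mask)
  bnd <- matrix(FALSE, h, w_img)
  for (y in seq_len(h)) for (x in seq_len(w_img)) {
    if (!mask[y, x]) next
    for (dy in -1:1) for (dx in -1:1) {
      yy <- y + dy; xx <- x + dx
      if (yy < 1 || yy > h || xx < 1 || xx > w_img || !mask[yy, xx]) {
        bnd[y, x] <- TRUE
      }
    }
  }
  bidx <- which(bnd, arr.ind = TRUE)
  belt <- matrix(FALSE, h, w_img)
  if (nrow(bidx) == 0) return(belt)
  yy <- matrix(seq_len(h), h, w_img)
  xx <- matrix(seq_len(w_img), h, w_img, byrow = TRUE)
  D <- matrix(Inf, h, w_img)
  for (b in seq_len(nrow(bidx)))   # distance to every boundary pixel
    D <- pmin(D, pmax(abs(yy - bidx[b, 1]), abs(xx - bidx[b, 2])))
  D <= w
}

# Dense 1-D DFT matrix (exp(-2*pi*i*j*k/n)).
dft_matrix <- function(n) {
  jk <- outer(0:(n - 1), 0:(n - 1))
  exp(-2i * pi * jk / n)
}

# Frequency attention by explicit DFT matrix multiplication:
# Y = F_h X F_w, weighted, inverse-transformed, plus residual.
oracle_frequency_attention <- function(x, Wsym) {
  h <- nrow(x); w <- ncol(x)
  Fh <- dft_matrix(h); Fw <- dft_matrix(w)
  X <- Fh %*% x %*% Fw
  Y <- Wsym * X
  y <- Re(solve(Fh) %*% Y %*% solve(Fw))
  y + x
}

# AccSys by explicit frame-membership counting: a ground-truth cycle is
# detected if any predicted systolic frame lies in its systole period;
# predicted periods are consumed greedily in temporal order.
oracle_accsys <- function(gt_labels, pred_labels) {
  runs_of <- function(lab) {
    r <- rle(lab)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1
    cbind(s, e)[r$values == "systole", , drop = FALSE]
  }
  gt <- runs_of(gt_labels); pr <- runs_of(pred_labels)
  used <- rep(FALSE, nrow(pr))
  T_ <- 0
  pairs <- NULL
  for (i in seq_len(nrow(gt))) {
    gt_frames <- gt[i, 1]:gt[i, 2]
    for (j in seq_len(nrow(pr))) {
      if (used[j]) next
      if (any(pr[j, 1]:pr[j, 2] %in% gt_frames)) {
        used[j] <- TRUE; T_ <- T_ + 1
        pairs <- rbind(pairs, c(i, j))
        break
      }
    }
  }
  list(T = T_, P = nrow(pr), N = nrow(gt),
       accsys = T_ / (nrow(pr) + nrow(gt) - T_), pairs = pairs)
}

# AUC as the concordant-pair fraction (ties counted half).
oracle_auc_concordance <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Confusion-matrix classification metrics computed entirely from explicit
# counts (macro-F1 over the observed label set).
oracle_classification <- function(truth, pred, positive) {
  classes <- sort(unique(c(truth, pred)))
  f1 <- sapply(classes, function(k) {
    tp <- sum(truth == k & pred == k); fp <- sum(pred == k) - tp
    fn <- sum(truth == k) - tp
    p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
    r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
    ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  })
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(pred == positive) - tp
  fn <- sum(truth == positive) - tp
  list(pre = ifelse(tp + fp > 0, tp / (tp + fp), 0),
       rec = ifelse(tp + fn > 0, tp / (tp + fn), 0),
       f1 = mean(f1), acc = mean(truth == pred))
}

# Random blob mask: union of a few filled discs.
random_blob_mask <- function(h, w, n_blobs = 2) {
  m <- matrix(FALSE, h, w)
  for (b in seq_len(n_blobs)) {
    cy <- runif(1, 4, h - 3); cx <- runif(1, 4, w - 3)
    r <- runif(1, 2, min(h, w) / 4)
    yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    m <- m | ((yy - cy)^2 + (xx - cx)^2 <= r^2)
  }
  m
}

# Random phase-label sequence with plausible run structure.
random_label_seq <- function(n_runs) {
  labs <- character(0)
  lab <- sample(c("systole", "diastole"), 1)
  for (r in seq_len(n_runs)) {
    labs <- c(labs, rep(lab, sample(1:6, 1)))
    lab <- setdiff(c("systole", "diastole"), lab)
  }
  labs
}
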