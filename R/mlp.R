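# Internal minibatch-SGD engine for small feed-forward softmax classifiers.
#
# Supports zero or one tanh hidden layer, per-class loss weights, and a
# two-group learning-rate ratio K between the input-side ("encoder") and
# output-side ("decoder") parameter groups. Feature standardisation
# statistics are stored with the model so prediction is self-contained.

mlp_init <- function(p, hidden, k) {
  if (hidden > 0) {
    list(W1 = matrix(stats::rnorm(p * hidden, sd = sqrt(1 / p)), p, hidden),
         b1 = rep(0, hidden),
         W2 = matrix(stats::rnorm(hidden * k, sd = sqrt(1 / hidden)), hidden, k),
         b2 = rep(0, k))
  } else {
    list(W2 = matrix(0, p, k), b2 = rep(0, k))
  }
}

mlp_forward <- function(par, X, hidden) {
  if (hidden > 0) {
    H <- tanh(sweep(X %*% par$W1, 2, par$b1, "+"))
    Z <- sweep(H %*% par$W2, 2, par$b2, "+")
    list(H = H, Z = Z)
  } else {
    list(H = NULL, Z = sweep(X %*% par$W2, 2, par$b2, "+"))
  }
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# X: n x p features; y: integer class labels 1..k.
# lr_ratio K multiplies the learning rate of the input-side group (W1, b1)
# relative to the output-side group; with hidden = 0 there is one group and
# K is inert. optimizer "adam" keeps per-parameter moment estimates (shared
# adam_step helper); "sgd" is plain minibatch gradient descent.
mlp_train_engine <- function(X, y, k, hidden = 0L, epochs = 10L, lr = 0.1,
                             batch_size = 256L, class_weights = NULL,
                             lr_ratio = 1, l2 = 1e-4, seed = 1L,
                             optimizer = c("sgd", "adam")) {
  optimizer <- match.arg(optimizer)
  stopifnot(nrow(X) == length(y), nrow(X) > 0)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd); sdv[sdv < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  if (is.null(class_weights)) class_weights <- rep(1, k)
  run_with_seed(seed, {
    par <- mlp_init(ncol(Xs), hidden, k)
    ad <- if (optimizer == "adam") adam_init(par)
    n <- nrow(Xs)
    loss_log <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      tot_loss <- 0; tot_w <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        Xb <- Xs[idx, , drop = FALSE]; yb <- y[idx]
        fw <- mlp_forward(par, Xb, hidden)
        P <- softmax_rows(fw$Z)
        wts <- class_weights[yb]
        pick <- P[cbind(seq_along(yb), yb)]
        tot_loss <- tot_loss + sum(-log(pmax(pick, 1e-12)) * wts)
        tot_w <- tot_w + sum(wts)
        G <- P
        G[cbind(seq_along(yb), yb)] <- G[cbind(seq_along(yb), yb)] - 1
        G <- G * wts / sum(wts)
        grad <- if (hidden > 0) {
          GH <- (G %*% t(par$W2)) * (1 - fw$H^2)
          list(W1 = crossprod(Xb, GH) + l2 * par$W1, b1 = colSums(GH),
               W2 = crossprod(fw$H, G) + l2 * par$W2, b2 = colSums(G))
        } else {
          list(W2 = crossprod(Xb, G) + l2 * par$W2, b2 = colSums(G))
        }
        if (optimizer == "adam") {
          upd <- adam_step(par, grad, ad, lr)
          if (lr_ratio != 1 && hidden > 0) {
            # rescale the encoder-group step to honour the K ratio
            upd$par$W1 <- par$W1 + lr_ratio * (upd$par$W1 - par$W1)
            upd$par$b1 <- par$b1 + lr_ratio * (upd$par$b1 - par$b1)
          }
          par <- upd$par; ad <- upd$st
        } else {
          par$W2 <- par$W2 - lr * grad$W2
          par$b2 <- par$b2 - lr * grad$b2
          if (hidden > 0) {
            par$W1 <- par$W1 - lr * lr_ratio * grad$W1
            par$b1 <- par$b1 - lr * lr_ratio * grad$b1
          }
        }
      }
      loss_log[ep] <- tot_loss / tot_w
    }
    structure(list(par = par, hidden = hidden, k = k, mu = mu, sd = sdv,
                   loss_log = loss_log,
                   config = list(epochs = epochs, lr = lr, batch_size = batch_size,
                                 class_weights = class_weights,
                                 lr_ratio = lr_ratio, l2 = l2, seed = seed)),
              class = "mlp_model")
  })
}

mlp_predict_prob <- function(model, X) {
  Xs <- sweep(sweep(X, 2, model$mu, "-"), 2, model$sd, "/")
  softmax_rows(mlp_forward(model$par, Xs, model$hidden)$Z)
}
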