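# NIPALS PLS1 core shared by the VIP screen and the trait imputation.
#
# X: observations x variables (already filtered/imputed by the caller);
# y: numeric response. X columns are centred; y is standardized internally
# and predictions are back-transformed. Deflation is on X only (univariate
# response); predictions use the regression-coefficient form
# B = W (P'W)^{-1} q.
pls1_nipals <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  if (ncomp > min(p, n - 1))
    stop("n_components exceeds what the data can support")
  x_means <- colMeans(X)
  Xc <- sweep(X, 2, x_means)
  y_mean <- mean(y); y_sd <- stats::sd(y)
  if (y_sd == 0) stop("constant response")
  u <- (y - y_mean) / y_sd

  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  ss_y <- numeric(ncomp)
  Xd <- Xc; yd <- u
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { W <- W[, seq_len(a - 1), drop = FALSE]
                      P <- P[, seq_len(a - 1), drop = FALSE]
                      Tm <- Tm[, seq_len(a - 1), drop = FALSE]
                      q <- q[seq_len(a - 1)]; ss_y <- ss_y[seq_len(a - 1)]
                      break }
    w <- w / nw
    t_ <- as.vector(Xd %*% w)
    tt <- sum(t_^2)
    p_ <- crossprod(Xd, t_) / tt
    q_ <- sum(yd * t_) / tt
    Xd <- Xd - tcrossprod(t_, p_)
    yd <- yd - q_ * t_
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_; q[a] <- q_
    ss_y[a] <- q_^2 * tt        # response variance captured by component a
  }
  ncomp <- length(q)
  structure(list(x_weights = W, x_loadings = P, scores = Tm, y_loadings = q,
                 ss_y = ss_y, explained_y_variance = ss_y / sum((u)^2),
                 x_means = x_means, y_mean = y_mean, y_sd = y_sd,
                 n_components = ncomp),
            class = "pls1_model")
}

# Regression-coefficient prediction on the original y scale.
predict_pls1 <- function(model, newX) {
  R <- model$x_weights %*%
    solve(crossprod(model$x_loadings, model$x_weights))
  b <- as.vector(R %*% model$y_loadings)
  sc <- sweep(newX, 2, model$x_means) %*% b
  as.vector(sc) * model$y_sd + model$y_mean
}

# VIP_j = sqrt(p * sum_a(SS_a * w_ja^2) / sum_a SS_a); weights are unit-norm
# per component, so mean(VIP^2) = 1 by construction.
pls1_vip <- function(model) {
  p <- nrow(model$x_weights)
  num <- as.vector(model$x_weights^2 %*% model$ss_y)
  sqrt(p * num / sum(model$ss_y))
}
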