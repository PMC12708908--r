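# Single-hidden-layer perceptron for regression, trained with
# Levenberg-Marquardt (damped Gauss-Newton on the residual Jacobian) or plain
# full-batch gradient descent. Small by design: the training sets here are at
# most a few hundred rows and ~10 selected features.

mlp_init <- function(p, hidden, seed) {
  set.seed(seed)
  list(W1 = matrix(rnorm(hidden * p, 0, 1 / sqrt(max(p, 1))), hidden, p),
       b1 = rnorm(hidden, 0, 0.1),
       w2 = rnorm(hidden, 0, 1 / sqrt(hidden)),
       b2 = 0)
}

mlp_forward <- function(theta, X) {
  A <- X %*% t(theta$W1)
  Z <- tanh(sweep(A, 2, theta$b1, "+"))
  list(Z = Z, yhat = as.numeric(Z %*% theta$w2 + theta$b2))
}

mlp_pack <- function(th) c(as.numeric(th$W1), th$b1, th$w2, th$b2)

mlp_unpack <- function(v, p, hidden) {
  i <- hidden * p
  list(W1 = matrix(v[seq_len(i)], hidden, p),
       b1 = v[i + seq_len(hidden)],
       w2 = v[i + hidden + seq_len(hidden)],
       b2 = v[i + 2 * hidden + 1])
}

# Jacobian of predictions wrt parameters, n x P
mlp_jacobian <- function(theta, X, Z) {
  n <- nrow(X); hidden <- length(theta$b1)
  G <- sweep((1 - Z^2), 2, theta$w2, "*")      # n x hidden: dyhat/da_h
  JW1 <- do.call(cbind, lapply(seq_len(hidden), function(h) X * G[, h]))
  # reorder h-major blocks to match mlp_pack (W1 column-major, hidden x p:
  # entry (h, j) sits at position (j-1)*hidden + h)
  p <- ncol(X)
  colidx <- as.vector(sapply(seq_len(p), function(j)
    (seq_len(hidden) - 1) * p + j))
  JW1 <- JW1[, colidx, drop = FALSE]
  cbind(JW1, G, Z, rep(1, n))
}

mlp_train <- function(X, y, hidden = 10, epochs = 1000,
                      optimizer = c("levenberg-marquardt", "gradient"),
                      learning_rate = 0.1, seed = 1L, tol = 1e-10) {
  optimizer <- match.arg(optimizer)
  p <- ncol(X)
  theta <- mlp_init(p, hidden, seed)
  fw <- mlp_forward(theta, X)
  sse <- sum((y - fw$yhat)^2)
  if (optimizer == "gradient") {
    n <- nrow(X)
    for (e in seq_len(epochs)) {
      fw <- mlp_forward(theta, X)
      r <- y - fw$yhat
      J <- mlp_jacobian(theta, X, fw$Z)
      g <- as.numeric(crossprod(J, r)) / n
      v <- mlp_pack(theta) + learning_rate * g
      theta <- mlp_unpack(v, p, hidden)
    }
    return(theta)
  }
  lambda <- 1e-2
  for (e in seq_len(epochs)) {
    fw <- mlp_forward(theta, X)
    r <- y - fw$yhat
    J <- mlp_jacobian(theta, X, fw$Z)
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    improved <- FALSE
    for (tries in 1:8) {
      H <- JtJ + diag(lambda, nrow(JtJ))
      delta <- tryCatch(solve(H, g), error = function(err) NULL)
      if (!is.null(delta)) {
        cand <- mlp_unpack(mlp_pack(theta) + as.numeric(delta), p, hidden)
        cand_sse <- sum((y - mlp_forward(cand, X)$yhat)^2)
        if (is.finite(cand_sse) && cand_sse < sse) {
          rel <- (sse - cand_sse) / max(sse, 1e-12)
          theta <- cand; sse <- cand_sse
          lambda <- max(lambda / 10, 1e-12)
          improved <- TRUE
          if (rel < tol) return(theta)
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) return(theta)
    }
    if (!improved) return(theta)
  }
  theta
}
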