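#' Single-hidden-layer neural network classifier
#'
#' A compact feed-forward network (tanh hidden layer, logistic output)
#' trained by BFGS on the penalized cross-entropy, with analytic gradients.
#' Inputs are standardised internally. Serves as the artificial-neural-network
#' member of the distribution-model roster.
#'
#' @param x data frame or matrix of predictors.
#' @param y 0/1 response.
#' @param size hidden units.
#' @param decay L2 weight-decay coefficient.
#' @param maxit BFGS iteration cap.
#' @return An `mlp_model`.
#' @export
mlp_fit <- function(x, y, size = 4, decay = 0.01, maxit = 300) {
  x <- as.matrix(as.data.frame(x)); storage.mode(x) <- "double"
  n <- nrow(x); p <- ncol(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd); scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  npar <- p * size + size + size + 1L
  unpack <- function(w) {
    W1 <- matrix(w[seq_len(p * size)], p, size)
    b1 <- w[p * size + seq_len(size)]
    w2 <- w[p * size + size + seq_len(size)]
    b2 <- w[npar]
    list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
  }
  nll <- function(w) {
    pr <- unpack(w)
    z <- tanh(sweep(xs %*% pr$W1, 2, pr$b1, "+"))
    eta <- as.numeric(z %*% pr$w2) + pr$b2
    -sum(y * eta - log1p(exp(eta))) + decay * sum(w^2)
  }
  grad <- function(w) {
    pr <- unpack(w)
    z <- tanh(sweep(xs %*% pr$W1, 2, pr$b1, "+"))
    eta <- as.numeric(z %*% pr$w2) + pr$b2
    d_eta <- stats::plogis(eta) - y
    g_w2 <- as.numeric(crossprod(z, d_eta)) + 2 * decay * pr$w2
    g_b2 <- sum(d_eta) + 2 * decay * pr$b2
    d_z <- (d_eta %*% t(pr$w2)) * (1 - z^2)
    g_W1 <- crossprod(xs, d_z) + 2 * decay * pr$W1
    g_b1 <- colSums(d_z) + 2 * decay * pr$b1
    c(as.numeric(g_W1), g_b1, g_w2, g_b2)
  }
  w0 <- stats::runif(npar, -0.5, 0.5)
  op <- stats::optim(w0, nll, grad, method = "BFGS",
                     control = list(maxit = maxit))
  structure(list(w = op$par, p = p, size = size, ctr = ctr, scl = scl,
                 vars = colnames(x), npar = npar), class = "mlp_model")
}

#' @export
predict.mlp_model <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$vars, drop = FALSE])
  xs <- scale(x, object$ctr, object$scl)
  p <- object$p; size <- object$size; w <- object$w
  W1 <- matrix(w[seq_len(p * size)], p, size)
  b1 <- w[p * size + seq_len(size)]
  w2 <- w[p * size + size + seq_len(size)]
  b2 <- w[object$npar]
  z <- tanh(sweep(xs %*% W1, 2, b1, "+"))
  stats::plogis(as.numeric(z %*% w2) + b2)
}
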