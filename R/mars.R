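#' Multivariate adaptive regression splines (additive, piecewise-linear)
#'
#' Bespoke MARS used both for the distribution models and the growth-climate
#' models. Forward pass: at each step the hinge pair
#' `max(x - c, 0), max(c - x, 0)` (over every variable and candidate knot)
#' giving the largest R-squared gain is added, stopping when the gain drops
#' below `r2_step` (default 0.001) or `max_terms` basis functions are reached.
#' Backward pass: basis functions are deleted one at a time (least harmful
#' first), and the subset along that path minimising either k-fold
#' cross-validated MSE (`prune = "cv"`, default 30 folds) or Friedman's GCV
#' criterion (`prune = "gcv"`) is kept.
#'
#' @param x data frame or matrix of predictors.
#' @param y numeric response (0/1 for classification use; fitted by least
#'   squares, predictions then clipped by the caller).
#' @param r2_step minimum R-squared gain to step forward.
#' @param max_terms maximum number of basis functions including intercept.
#' @param n_knots candidate knots per variable (interior quantiles).
#' @param prune `"cv"`, `"gcv"` or `"none"`.
#' @param nfold folds for `prune = "cv"` (capped at n).
#' @param penalty GCV cost per knot for `prune = "gcv"`.
#' @return A `mars_model` with `terms` (var, knot, dir), `coef`, `rss`, `r2`.
#' @export
mars_fit <- function(x, y, r2_step = 0.001, max_terms = 21, n_knots = 15,
                     prune = c("cv", "gcv", "none"), nfold = 30, penalty = 3) {
  prune <- match.arg(prune)
  x <- as.matrix(as.data.frame(x))
  storage.mode(x) <- "double"
  n <- nrow(x); p <- ncol(x)
  stopifnot(length(y) == n, n >= 4)
  vars <- colnames(x)
  tss <- sum((y - mean(y))^2)
  xrange <- apply(x, 2, range)
  if (tss == 0) {
    return(structure(list(vars = vars, terms = list(), coef = mean(y),
                          rss = 0, r2 = 1, xrange = xrange),
                     class = "mars_model"))
  }
  knots <- lapply(seq_len(p), function(j) {
    u <- unique(stats::quantile(x[, j], probs = seq(0.05, 0.95,
                                                    length.out = n_knots),
                                names = FALSE, type = 7))
    u[u > min(x[, j]) & u < max(x[, j])]
  })

  B <- matrix(1, n, 1)
  terms <- list()  # each: list(var = j, knot = c, dir = +1/-1)
  rss_cur <- tss
  repeat {
    if (ncol(B) + 2L > max_terms) break
    best <- list(rss = Inf)
    for (j in seq_len(p)) {
      for (c0 in knots[[j]]) {
        b1 <- pmax(x[, j] - c0, 0)
        b2 <- pmax(c0 - x[, j], 0)
        fit <- stats::lm.fit(cbind(B, b1, b2), y)
        rss <- sum(fit$residuals^2)
        if (rss < best$rss) best <- list(rss = rss, j = j, c0 = c0)
      }
    }
    if (!is.finite(best$rss)) break
    if ((rss_cur - best$rss) / tss < r2_step) break
    B <- cbind(B, pmax(x[, best$j] - best$c0, 0),
               pmax(best$c0 - x[, best$j], 0))
    terms <- c(terms, list(list(var = best$j, knot = best$c0, dir = 1L)),
               list(list(var = best$j, knot = best$c0, dir = -1L)))
    rss_cur <- best$rss
  }

  keep <- seq_along(terms)  # indices into terms; basis col = index + 1
  if (prune != "none" && length(terms) > 0L) {
    # backward deletion path
    path <- list(keep)
    cur <- keep
    while (length(cur) > 0L) {
      best_rss <- Inf; best_drop <- NULL
      for (d in cur) {
        cand <- setdiff(cur, d)
        fit <- stats::lm.fit(B[, c(1L, cand + 1L), drop = FALSE], y)
        rss <- sum(fit$residuals^2)
        if (rss < best_rss) { best_rss <- rss; best_drop <- d }
      }
      cur <- setdiff(cur, best_drop)
      path <- c(path, list(cur))
    }
    score <- vapply(path, function(s) {
      cols <- c(1L, s + 1L)
      if (prune == "gcv") {
        fit <- stats::lm.fit(B[, cols, drop = FALSE], y)
        m <- length(cols)
        cost <- m + penalty * (m - 1) / 2
        if (cost >= n) return(Inf)
        (sum(fit$residuals^2) / n) / (1 - cost / n)^2
      } else {
        k <- min(nfold, n)
        fold <- rep_len(seq_len(k), n)[order(seq_len(n) %% k)]  # deterministic
        pe <- 0
        for (f in seq_len(k)) {
          tr <- fold != f
          ft <- stats::lm.fit(B[tr, cols, drop = FALSE], y[tr])
          co <- ifelse(is.na(ft$coefficients), 0, ft$coefficients)
          pe <- pe + sum((y[!tr] - B[!tr, cols, drop = FALSE] %*% co)^2)
        }
        pe / n
      }
    }, numeric(1))
    keep <- path[[which.min(score)]]
  }

  cols <- c(1L, keep + 1L)
  fit <- stats::lm.fit(B[, cols, drop = FALSE], y)
  co <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  rss <- sum(fit$residuals^2)
  structure(
    list(vars = vars, terms = terms[keep], coef = as.numeric(co),
         rss = rss, r2 = 1 - rss / tss, xrange = xrange),
    class = "mars_model"
  )
}

#' Predict from a MARS model
#'
#' Predictors are clamped to their training range ("clamping", as in
#' climate-envelope practice): beyond the observed hull the piecewise-linear
#' surface continues as a constant rather than extrapolating a local hinge
#' slope without support.
#'
#' @param object a `mars_model`.
#' @param newdata data frame with the training variables.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.mars_model <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$vars, drop = FALSE])
  if (!is.null(object$xrange)) {
    for (j in seq_along(object$vars)) {
      x[, j] <- pmin(pmax(x[, j], object$xrange[1, j]), object$xrange[2, j])
    }
  }
  B <- matrix(1, nrow(x), 1)
  for (tm in object$terms) {
    B <- cbind(B, if (tm$dir > 0) pmax(x[, tm$var] - tm$knot, 0)
               else pmax(tm$knot - x[, tm$var], 0))
  }
  as.numeric(B %*% object$coef)
}
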