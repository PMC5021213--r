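# CART-style regression trees and the ensembles built on them (bagged random
# forests and logistic gradient boosting). Least-squares splitting on a 0/1
# response is equivalent to Gini-impurity splitting, so one tree type serves
# classification (probability output) and boosting-residual regression alike.

cart_build <- function(x, y, idx, depth, max_depth, min_split, min_bucket,
                       n_thresh, mtry) {
  node_val <- mean(y[idx])
  n_i <- length(idx)
  if (depth >= max_depth || n_i < min_split || stats::var(y[idx]) == 0) {
    return(list(leaf = TRUE, value = node_val))
  }
  p <- ncol(x)
  cand_vars <- if (is.null(mtry) || mtry >= p) seq_len(p) else
    sample.int(p, mtry)
  sse_parent <- sum((y[idx] - node_val)^2)
  best <- list(sse = sse_parent - 1e-10)
  for (j in cand_vars) {
    xv <- x[idx, j]
    th <- unique(stats::quantile(xv, probs = seq(1, n_thresh) /
                                   (n_thresh + 1), names = FALSE, type = 7))
    for (t0 in th) {
      left <- xv <= t0
      nl <- sum(left)
      if (nl < min_bucket || (n_i - nl) < min_bucket) next
      yl <- y[idx][left]; yr <- y[idx][!left]
      sse <- sum((yl - mean(yl))^2) + sum((yr - mean(yr))^2)
      if (sse < best$sse) best <- list(sse = sse, j = j, t0 = t0)
    }
  }
  if (is.null(best$j)) return(list(leaf = TRUE, value = node_val))
  left_idx <- idx[x[idx, best$j] <= best$t0]
  right_idx <- idx[x[idx, best$j] > best$t0]
  list(
    leaf = FALSE, var = best$j, thresh = best$t0,
    left = cart_build(x, y, left_idx, depth + 1L, max_depth, min_split,
                      min_bucket, n_thresh, mtry),
    right = cart_build(x, y, right_idx, depth + 1L, max_depth, min_split,
                       min_bucket, n_thresh, mtry)
  )
}

#' Fit a CART-style binary regression tree
#'
#' Greedy least-squares recursive partitioning (equivalent to Gini splitting
#' for a 0/1 response). Used directly as the classification-tree (CTA)
#' distribution model and as the base learner for the bagged-forest and
#' boosted-tree models.
#'
#' @param x data frame or matrix of predictors.
#' @param y numeric response (0/1 for probability trees).
#' @param max_depth maximum tree depth.
#' @param min_split minimum node size to attempt a split.
#' @param min_bucket minimum leaf size.
#' @param n_thresh candidate split thresholds per variable (quantiles).
#' @param mtry number of variables sampled per node (`NULL` = all; used by
#'   the random forest).
#' @return A `cart_model`.
#' @export
cart_fit <- function(x, y, max_depth = 6, min_split = 20, min_bucket = 7,
                     n_thresh = 16, mtry = NULL) {
  x <- as.matrix(as.data.frame(x)); storage.mode(x) <- "double"
  stopifnot(nrow(x) == length(y))
  structure(
    list(vars = colnames(x),
         tree = cart_build(x, y, seq_len(nrow(x)), 0L, max_depth, min_split,
                           min_bucket, n_thresh, mtry)),
    class = "cart_model"
  )
}

cart_walk <- function(node, x, idx, out) {
  if (node$leaf) { out[idx] <- node$value; return(out) }
  left <- x[idx, node$var] <= node$thresh
  out <- cart_walk(node$left, x, idx[left], out)
  cart_walk(node$right, x, idx[!left], out)
}

#' @export
predict.cart_model <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$vars, drop = FALSE])
  cart_walk(object$tree, x, seq_len(nrow(x)), numeric(nrow(x)))
}

#' Bagged random forest of CART trees
#'
#' Bootstrap-aggregated probability trees with per-node random variable
#' subsampling (`mtry`, default `floor(sqrt(p))`). The forest probability at
#' a point is the mean of the per-tree leaf means.
#'
#' @param x,y predictors and 0/1 response.
#' @param n_trees number of trees.
#' @param mtry variables sampled at each node.
#' @param max_depth,min_split,min_bucket tree-growing controls.
#' @return An `rf_model`.
#' @export
rf_fit <- function(x, y, n_trees = 50, mtry = NULL, max_depth = 6,
                   min_split = 10, min_bucket = 5) {
  x <- as.data.frame(x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  n <- nrow(x)
  trees <- lapply(seq_len(n_trees), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    cart_fit(x[idx, , drop = FALSE], y[idx], max_depth = max_depth,
             min_split = min_split, min_bucket = min_bucket, mtry = mtry)
  })
  structure(list(trees = trees, vars = colnames(x)), class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  preds <- vapply(object$trees, predict, numeric(nrow(as.data.frame(newdata))),
                  newdata = newdata)
  pmin(pmax(rowMeans(as.matrix(preds)), 0), 1)
}

#' Gradient-boosted trees with logistic loss
#'
#' Stagewise boosting of shallow CART trees on the logistic-loss gradient
#' (`y - p`), with shrinkage and bagging, probabilities via the inverse logit
#' of the accumulated score.
#'
#' @param x,y predictors and 0/1 response.
#' @param n_trees boosting iterations.
#' @param shrinkage learning rate.
#' @param max_depth depth of each tree (interaction depth).
#' @param bag_fraction row subsample per iteration.
#' @return A `brt_model`.
#' @export
brt_fit <- function(x, y, n_trees = 60, shrinkage = 0.1, max_depth = 2,
                    bag_fraction = 0.75) {
  x <- as.data.frame(x)
  n <- nrow(x)
  p0 <- min(max(mean(y), 1e-4), 1 - 1e-4)
  f0 <- stats::qlogis(p0)
  f <- rep(f0, n)
  trees <- vector("list", n_trees)
  m <- max(2L, floor(bag_fraction * n))
  for (b in seq_len(n_trees)) {
    r <- y - stats::plogis(f)
    idx <- sample.int(n, m)
    tr <- cart_fit(x[idx, , drop = FALSE], r[idx], max_depth = max_depth,
                   min_split = 10, min_bucket = 5)
    f <- f + shrinkage * predict(tr, x)
    trees[[b]] <- tr
  }
  structure(list(f0 = f0, shrinkage = shrinkage, trees = trees,
                 vars = colnames(x)), class = "brt_model")
}

#' @export
predict.brt_model <- function(object, newdata, ...) {
  f <- rep(object$f0, nrow(as.data.frame(newdata)))
  for (tr in object$trees) f <- f + object$shrinkage * predict(tr, newdata)
  stats::plogis(f)
}
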