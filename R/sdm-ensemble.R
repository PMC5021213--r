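#' Rank-based AUC
#'
#' Area under the ROC curve as the probability that a randomly drawn presence
#' outscores a randomly drawn absence, ties counted one half (the Mann-Whitney
#' form).
#'
#' @param scores numeric classifier scores.
#' @param labels 0/1 labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    stop_invalid("AUC undefined: only one class present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

merge_occurrence_climate <- function(occ, grid, variables = climate_variables(grid)) {
  stopifnot(inherits(occ, "occurrence_set"), inherits(grid, "climate_grid"))
  miss <- setdiff(variables, climate_variables(grid))
  if (length(miss)) {
    stop_invalid("grid lacks variables: ", paste(miss, collapse = ", "))
  }
  idx <- match(occ$cell_id, grid$cell_id)
  if (anyNA(idx)) stop_invalid("occurrence cells missing from the grid")
  list(x = as.data.frame(grid)[idx, variables, drop = FALSE],
       y = occ$presence)
}

#' Evaluate one distribution algorithm by repeated-split AUC
#'
#' Repeats a stratified random split (default 80:20 train:test, 50
#' repetitions), fits the algorithm on the training partition and scores AUC
#' on the held-out partition. Per-repetition RNG streams derive from `seed`,
#' so a fixed seed reproduces `auc_per_rep` exactly. A split whose test
#' partition is single-class is redrawn (bounded retries) before erroring.
#'
#' @param occ an `occurrence_set`.
#' @param grid the companion [climate_grid()].
#' @param algo_id algorithm id (see [sdm_default_roster()]).
#' @param n_reps evaluation repetitions.
#' @param train_frac training fraction.
#' @param seed integer seed.
#' @param variables climate variables to use (default: all in grid).
#' @param config per-algorithm settings list.
#' @return An `algorithm_report`: `algo_id`, `mean_auc`, `auc_per_rep`.
#' @export
evaluate_algorithm <- function(occ, grid, algo_id, n_reps = 50,
                               train_frac = 0.8, seed = 1,
                               variables = climate_variables(grid),
                               config = list()) {
  stopifnot(n_reps >= 1, train_frac > 0, train_frac < 1)
  if (length(unique(occ$presence)) < 2L) {
    stop_invalid("occurrence set must contain both classes")
  }
  d <- merge_occurrence_climate(occ, grid, variables)
  pos <- which(d$y == 1); neg <- which(d$y == 0)
  n1_tr <- min(max(1L, round(train_frac * length(pos))), length(pos) - 1L)
  n0_tr <- min(max(1L, round(train_frac * length(neg))), length(neg) - 1L)
  if (n1_tr < 1L || n0_tr < 1L) {
    stop_invalid("too few records for a stratified ", train_frac, " split")
  }
  aucs <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(derive_seed(seed, paste("eval", algo_id, r)))
    auc <- NA_real_
    for (try in 1:10) {
      tr <- c(sample(pos, n1_tr), sample(neg, n0_tr))
      te <- setdiff(seq_along(d$y), tr)
      if (length(unique(d$y[te])) < 2L || length(unique(d$y[tr])) < 2L) next
      fit <- sdm_fit_one(algo_id, d$x[tr, , drop = FALSE], d$y[tr], config)
      auc <- compute_auc(sdm_predict_one(algo_id, fit,
                                         d$x[te, , drop = FALSE]), d$y[te])
      break
    }
    if (is.na(auc)) stop_invalid("could not draw a two-class test split")
    aucs[r] <- auc
  }
  structure(
    list(algo_id = algo_id, mean_auc = mean(aucs), auc_per_rep = aucs,
         n_reps = n_reps, included = NA),
    class = "algorithm_report"
  )
}

#' Build the AUC-weighted ensemble distribution model
#'
#' Members are the algorithms whose mean evaluation AUC reaches `auc_cutoff`
#' (default 0.7); their weights are proportional to that mean AUC and sum to
#' one. Each member is refitted on the full data; evaluation AUCs are used
#' only for selection and weighting. The ensemble's own AUC is reported on
#' resubstitution (full-data predictions), alongside the weighted mean of the
#' members' held-out evaluation AUCs — the two defensible readings of an
#' "ensemble AUC".
#'
#' @param reports list of `algorithm_report`s.
#' @param occ,grid the training data.
#' @param auc_cutoff inclusion cutoff on mean AUC.
#' @param variables climate variables used by the members.
#' @param config per-algorithm settings list.
#' @param seed integer seed for the refits.
#' @return An `sdm_ensemble` with members (id, weight, mean_auc, model),
#'   `ensemble_auc_resub` and `ensemble_auc_eval_weighted`.
#' @export
build_ensemble <- function(reports, occ, grid, auc_cutoff = 0.7,
                           variables = climate_variables(grid),
                           config = list(), seed = 1) {
  stopifnot(length(reports) >= 1L)
  ids <- vapply(reports, `[[`, character(1), "algo_id")
  aucs <- vapply(reports, `[[`, numeric(1), "mean_auc")
  keep <- aucs >= auc_cutoff
  for (i in seq_along(reports)) reports[[i]]$included <- keep[i]
  if (!any(keep)) {
    stop_invalid("no algorithm reaches AUC >= ", auc_cutoff,
                 ": no skilled model to ensemble")
  }
  w <- aucs[keep] / sum(aucs[keep])
  d <- merge_occurrence_climate(occ, grid, variables)
  members <- Map(function(id, wi, ai) {
    set.seed(derive_seed(seed, paste("refit", id)))
    list(algo_id = id, weight = wi, mean_auc = ai,
         model = sdm_fit_one(id, d$x, d$y, config))
  }, ids[keep], w, aucs[keep])
  probs <- vapply(members, function(m)
    sdm_predict_one(m$algo_id, m$model, d$x), numeric(length(d$y)))
  ens_prob <- ensemble_probability(as.matrix(probs), w)
  structure(
    list(members = unname(members), auc_cutoff = auc_cutoff,
         variables = variables, species = attr(occ, "species") %||% "species",
         reports = reports,
         ensemble_auc_resub = compute_auc(ens_prob, d$y),
         ensemble_auc_eval_weighted = sum(w * aucs[keep])),
    class = "sdm_ensemble"
  )
}

#' Weighted-mean ensemble probability
#'
#' @param member_probs n-cells x n-members matrix of member probabilities.
#' @param weights nonnegative member weights summing to 1.
#' @return Numeric vector of ensemble probabilities.
#' @export
ensemble_probability <- function(member_probs, weights) {
  member_probs <- as.matrix(member_probs)
  stopifnot(ncol(member_probs) == length(weights), all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-8) {
    stop_invalid("ensemble weights must sum to 1")
  }
  as.numeric(member_probs %*% weights)
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf("<sdm_ensemble> %s: %d member(s), cutoff %.2f\n",
              x$species, length(x$members), x$auc_cutoff))
  for (m in x$members) {
    cat(sprintf("  %-4s weight %.3f (mean AUC %.3f)\n",
                m$algo_id, m$weight, m$mean_auc))
  }
  cat(sprintf("  AUC: %.3f (resubstitution), %.3f (weighted member eval)\n",
              x$ensemble_auc_resub, x$ensemble_auc_eval_weighted))
  invisible(x)
}

#' Predict presence over a climate grid and apply the threshold
#'
#' Ensemble probability per cell is the weighted mean of member
#' probabilities; cells with probability at or above `threshold` (default
#' 0.6) form the predicted climate space.
#'
#' @param ens an [build_ensemble()] result.
#' @param grid a [climate_grid()] carrying the training variables.
#' @param threshold presence threshold in `[0, 1]`.
#' @return A `presence_grid`: data frame (`cell_id`, `lon`, `lat`,
#'   `probability`, `presence`) with species/scenario/threshold attributes.
#' @export
predict_presence <- function(ens, grid, threshold = 0.6) {
  stopifnot(inherits(ens, "sdm_ensemble"), inherits(grid, "climate_grid"))
  miss <- setdiff(ens$variables, climate_variables(grid))
  if (length(miss)) {
    stop_invalid("grid lacks training variables: ", paste(miss, collapse = ", "))
  }
  x <- as.data.frame(grid)[, ens$variables, drop = FALSE]
  probs <- vapply(ens$members, function(m)
    sdm_predict_one(m$algo_id, m$model, x), numeric(nrow(x)))
  w <- vapply(ens$members, `[[`, numeric(1), "weight")
  p <- ensemble_probability(as.matrix(probs), w)
  presence_grid(
    data.frame(cell_id = grid$cell_id, lon = grid$lon, lat = grid$lat,
               probability = p, stringsAsFactors = FALSE),
    threshold = threshold, species = ens$species,
    scenario_name = attr(grid, "scenario_name") %||% "baseline"
  )
}

#' Presence grid container
#'
#' @param cells data frame with `cell_id`, `lon`, `lat`, `probability`.
#' @param threshold presence threshold; `presence = probability >= threshold`.
#' @param species,scenario_name labels.
#' @return A `presence_grid` data frame.
#' @export
presence_grid <- function(cells, threshold, species = "species",
                          scenario_name = "baseline") {
  stopifnot(is.data.frame(cells),
            all(c("cell_id", "lon", "lat", "probability") %in% names(cells)))
  if (threshold < 0 || threshold > 1) stop_invalid("threshold must be in [0, 1]")
  if (any(cells$probability < 0 | cells$probability > 1)) {
    stop_invalid("probabilities must lie in [0, 1]")
  }
  cells$presence <- as.integer(cells$probability >= threshold)
  rownames(cells) <- NULL
  attr(cells, "threshold") <- threshold
  attr(cells, "species") <- species
  attr(cells, "scenario_name") <- scenario_name
  class(cells) <- c("presence_grid", "data.frame")
  cells
}
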