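# Distribution-model roster. Each entry fits presence/absence against the
# climate variables and predicts a probability of presence; the ensemble
# machinery only sees this fit/predict contract, so the roster is freely
# configurable and never assumed to have seven members.

sdm_fit_one <- function(algo_id, x, y, config = list()) {
  switch(
    algo_id,
    GLM = {
      d <- cbind(.y = y, x)
      suppressWarnings(stats::glm(.y ~ ., data = d,
                                  family = stats::binomial()))
    },
    GAM = {
      k <- config$gam_knots %||% 4
      rhs <- paste(sprintf("s(%s, k = %d)", colnames(x), k), collapse = " + ")
      d <- cbind(.y = y, x)
      suppressWarnings(mgcv::gam(stats::as.formula(paste(".y ~", rhs)),
                                 data = d, family = stats::binomial()))
    },
    MARS = mars_fit(x, y, r2_step = config$mars_r2_step %||% 0.001,
                    prune = "gcv"),
    CTA = cart_fit(x, y, max_depth = config$cta_depth %||% 6,
                   min_split = 20, min_bucket = 7),
    BRT = brt_fit(x, y, n_trees = config$brt_trees %||% 60,
                  shrinkage = 0.1, max_depth = 2),
    RF = rf_fit(x, y, n_trees = config$rf_trees %||% 50,
                max_depth = config$rf_depth %||% 6),
    ANN = mlp_fit(x, y, size = config$ann_size %||% 4,
                  decay = 0.01, maxit = config$ann_maxit %||% 200),
    stop_invalid("unknown algorithm id: ", algo_id)
  )
}

sdm_predict_one <- function(algo_id, model, x) {
  p <- switch(
    algo_id,
    GLM = stats::predict(model, newdata = x, type = "response"),
    GAM = as.numeric(stats::predict(model, newdata = x, type = "response")),
    MARS = predict(model, x),
    CTA = predict(model, x),
    BRT = predict(model, x),
    RF = predict(model, x),
    ANN = predict(model, x),
    stop_invalid("unknown algorithm id: ", algo_id)
  )
  pmin(pmax(as.numeric(p), 0), 1)
}

#' The default distribution-model roster
#' @return Character vector of algorithm ids.
#' @export
sdm_default_roster <- function() {
  c("GLM", "GAM", "MARS", "CTA", "BRT", "RF", "ANN")
}
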