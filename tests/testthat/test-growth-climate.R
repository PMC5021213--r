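test_that("growth-climate families recover nested truths", {
  d <- linear_growth_table(n = 30, noise = 0)
  vars <- c("ann_mean_temp", "diurnal_range", "ann_precip")

  # exactly linear target: GLM reproduces it to machine precision, GCV ~ 0
  m <- fit_growth_family(d, "Linf", "GLM", variables = vars)
  expect_lt(max(abs(predict(m, d) - d$Linf)), 1e-8)
  expect_lt(m$gcv, 1e-10)

  # constant target: every family predicts the constant
  d2 <- d; d2$Linf <- 250
  for (f in c("GLM", "MARS")) {
    mf <- fit_growth_family(d2, "Linf", f, variables = vars)
    expect_lt(max(abs(predict(mf, d2) - 250)), 1e-6)
  }

  # noisy linear response: GLM temperature coefficient within 2 SE of truth
  d3 <- linear_growth_table(n = 100, seed = 12, noise = 5)
  m3 <- fit_growth_family(d3, "Linf", "GLM", variables = vars)
  sm <- coef(summary(m3$fit))
  expect_lt(abs(sm["ann_mean_temp", "Estimate"] - (-12)),
            2 * sm["ann_mean_temp", "Std. Error"])

  expect_error(fit_growth_family(d[1:8, ], "Linf", "GLM", variables = vars),
               ">= 10")
})

test_that("leave-one-out GCV equals the explicit-refit oracle", {
  # hand-checkable 4-point case... brute force with 4 explicit refits
  d4 <- data.frame(x = c(1, 2, 3, 4), y = c(1.1, 1.9, 3.2, 3.9),
                   population_id = letters[1:4])
  # (n < 10 guard bypassed by calling the internal scorer directly)
  loo <- climspace:::loo_mse_refit("GLM", d4[, "x", drop = FALSE], d4$y,
                                   list())
  err <- vapply(1:4, function(i) {
    f <- lm(y ~ x, data = d4[-i, ])
    d4$y[i] - predict(f, d4[i, ])
  }, numeric(1))
  expect_equal(loo, mean(err^2), tolerance = 1e-12)

  # closed-form hat-matrix identity equals explicit refits for the GLM
  d <- linear_growth_table(n = 25, seed = 5, noise = 8)
  vars <- c("ann_mean_temp", "diurnal_range", "ann_precip")
  m <- fit_growth_family(d, "Linf", "GLM", variables = vars)
  expect_lt(abs(compute_gcv(m, d, "closed_form") - compute_gcv(m, d, "refit")),
            1e-8)
  expect_error(compute_gcv(m, d[1:2, ], "refit"), "n < 3")
})

test_that("inverse-GCV weighting follows the stated normalisation", {
  fake <- function(gcv, family = "GLM") {
    structure(list(target = "Linf", family = family, variables = "x",
                   fit = NULL, config = list(), gcv = gcv, converged = TRUE,
                   n = 10), class = "growth_climate_model")
  }
  w_of <- function(ens) vapply(ens$members, `[[`, numeric(1), "weight")
  expect_equal(w_of(build_growth_ensemble(list(fake(2)))), 1)
  expect_equal(w_of(build_growth_ensemble(list(fake(2), fake(2, "GAM")))),
               c(0.5, 0.5))
  expect_equal(w_of(build_growth_ensemble(list(fake(1), fake(3, "GAM")))),
               c(0.75, 0.25))
  # a zero-GCV member takes all the weight; ties split it
  expect_equal(w_of(build_growth_ensemble(list(fake(0), fake(3, "GAM")))),
               c(1, 0))
  expect_equal(w_of(build_growth_ensemble(
    list(fake(0), fake(0, "GAM"), fake(2, "MARS")))), c(0.5, 0.5, 0))
  # non-converged members are dropped; none left is an error
  bad <- fake(1); bad$converged <- FALSE
  expect_error(build_growth_ensemble(list(bad)), "no valid member")
})

test_that("ensemble predictions are bounded by members and RMSE is the root mean square", {
  d <- linear_growth_table(n = 30, seed = 9, noise = 10)
  vars <- c("ann_mean_temp", "diurnal_range", "ann_precip")
  ms <- list(fit_growth_family(d, "Linf", "GLM", variables = vars),
             fit_growth_family(d, "Linf", "MARS", variables = vars))
  ens <- build_growth_ensemble(ms)
  w <- vapply(ens$members, `[[`, numeric(1), "weight")
  expect_equal(sum(w), 1, tolerance = 1e-12)
  p1 <- predict(ms[[1]], d); p2 <- predict(ms[[2]], d)
  pe <- predict(ens, d)
  expect_true(all(pe >= pmin(p1, p2) - 1e-9 & pe <= pmax(p1, p2) + 1e-9))
  expect_equal(assess_rmse(ens, d), sqrt(mean((d$Linf - pe)^2)))

  # hand values: residuals (3, 4) -> RMSE sqrt(12.5)
  expect_equal(sqrt(mean(c(3, 4)^2)), 3.5355, tolerance = 1e-4)
})

test_that("scenario projection shifts linearly under a pure GLM and flags degeneracy", {
  g <- small_grid()
  vars <- c("ann_mean_temp", "diurnal_range", "ann_precip")
  set.seed(14)
  idx <- sample(nrow(g), 25)
  d <- as.data.frame(g)[idx, vars]
  d$population_id <- sprintf("p%02d", 1:25)
  d$cell_id <- g$cell_id[idx]
  d$Linf <- 450 - 12 * d$ann_mean_temp + rnorm(25, 0, 5)
  d$K <- 0.05 + 0.025 * d$ann_mean_temp + rnorm(25, 0, 0.01)
  ens_l <- build_growth_ensemble(list(
    fit_growth_family(d, "Linf", "GLM", variables = vars)))
  ens_k <- build_growth_ensemble(list(
    fit_growth_family(d, "K", "GLM", variables = vars)))
  pops <- d[, c("population_id", "cell_id")]

  # identity scenario: projections equal baseline fitted values
  pr0 <- project_growth(ens_l, ens_k, g, pops)
  expect_equal(pr0$per_population$Linf_hat, unname(predict(ens_l, d)))

  # +2 degrees under a pure GLM: every population drops by exactly 2|slope|
  warm <- apply_scenario(g, scenario_spec("w2", 2))
  pr2 <- project_growth(ens_l, ens_k, warm, pops)
  slope <- coef(ens_l$members[[1]]$model$fit)["ann_mean_temp"]
  expect_equal(pr2$per_population$Linf_hat - pr0$per_population$Linf_hat,
               rep(unname(2 * slope), 25), tolerance = 1e-9)
  # scenario means are arithmetic means and CIs bracket them
  expect_equal(pr2$mean_Linf, mean(pr2$per_population$Linf_hat))
  expect_lt(pr2$ci_Linf[1], pr2$mean_Linf)
  expect_gt(pr2$ci_Linf[2], pr2$mean_Linf)

  # single population: SE undefined, CI degenerate, with a warning
  expect_warning(pr1 <- project_growth(ens_l, ens_k, g, pops[1, ]),
                 "single population")
  expect_true(is.na(pr1$se_Linf))
  expect_equal(pr1$ci_Linf, rep(pr1$mean_Linf, 2))
})
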