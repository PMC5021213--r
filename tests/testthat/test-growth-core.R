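test_that("von Bertalanffy closed form and its monotonicity", {
  expect_equal(vbgf_length(500, 0.3, 0), 0)
  expect_equal(vbgf_length(500, 0.3, 2), 500 * (1 - exp(-0.6)))
  expect_equal(vbgf_length(500, 0.3, 2), 225.594, tolerance = 1e-5)
  expect_lt(abs(vbgf_length(500, 0.3, 200) - 500), 1e-10)
  t <- seq(0, 20, by = 0.5)
  expect_true(all(diff(vbgf_length(500, 0.3, t)) > 0))   # increasing in t
  expect_true(all(vbgf_length(500, 0.3, t) <= 500))      # bounded by Linf
  expect_true(all(vbgf_length(500, 0.4, t[-1]) >
                    vbgf_length(500, 0.3, t[-1])))       # increasing in K
  expect_error(vbgf_length(-1, 0.3, 1), "must be > 0")
  expect_error(vbgf_length(500, 0.3, -1), ">= 0")
})

test_that("scale-body regression recovers lines and rejects degenerate designs", {
  L <- c(100, 150, 200, 250, 300)
  obs <- data.frame(capture_length = L,
                    scale_radius_capture = 0.5 + 0.01 * L)
  reg <- fit_scale_body_regression(obs)
  expect_equal(reg$intercept_u, 0.5, tolerance = 1e-10)
  expect_equal(reg$slope_v, 0.01, tolerance = 1e-10)
  expect_equal(reg$r2, 1, tolerance = 1e-10)

  dup <- data.frame(capture_length = rep(200, 5),
                    scale_radius_capture = rnorm(5, 2.5, 0.1))
  expect_error(fit_scale_body_regression(dup), "distinct lengths")

  # noisy data: estimates within 2 SE of the generating line
  set.seed(21)
  L2 <- runif(200, 80, 400)
  S2 <- 0.5 + 0.01 * L2 + rnorm(200, 0, 0.05)
  reg2 <- fit_scale_body_regression(
    data.frame(capture_length = L2, scale_radius_capture = S2))
  fit <- lm(S2 ~ L2)
  se <- coef(summary(fit))[, "Std. Error"]
  expect_lt(abs(reg2$intercept_u - 0.5), 2 * se[1])
  expect_lt(abs(reg2$slope_v - 0.01), 2 * se[2])
})

test_that("scale-proportional back-calculation follows the stated formula", {
  reg <- structure(list(intercept_u = 0, slope_v = 0.01, r2 = 1, n = 5),
                   class = "scale_body_regression")
  # S_a = S_c: length at annulus equals capture length
  o1 <- data.frame(capture_length = 200, scale_radius_capture = 2,
                   scale_radius_annulus = 2)
  expect_equal(backcalculate_length(o1, reg), 200)
  # zero intercept: direct proportionality
  o2 <- data.frame(capture_length = 200, scale_radius_capture = 2,
                   scale_radius_annulus = 1)
  expect_equal(backcalculate_length(o2, reg), 100)
  # hand arithmetic: u=10, v=0.05, Lc=300, Sa/Sc=0.5 -> -200 + 500*0.5 = 50
  reg3 <- structure(list(intercept_u = 10, slope_v = 0.05, r2 = 1, n = 5),
                    class = "scale_body_regression")
  o3 <- data.frame(capture_length = 300, scale_radius_capture = 12,
                   scale_radius_annulus = 6)
  expect_equal(backcalculate_length(o3, reg3), 50)
  # monotone increasing in S_a (over the range with positive results)
  sa <- seq(5, 12, by = 0.5)
  o4 <- data.frame(capture_length = 300, scale_radius_capture = 12,
                   scale_radius_annulus = sa)
  expect_true(all(diff(backcalculate_length(o4, reg3)) > 0))
  # non-positive result flagged NA with a warning
  o5 <- data.frame(capture_length = 300, scale_radius_capture = 12,
                   scale_radius_annulus = 0.1)
  expect_warning(la <- backcalculate_length(o5, reg3), "flagged")
  expect_true(is.na(la))
  # invariant violation is an error
  o6 <- data.frame(capture_length = 300, scale_radius_capture = 2,
                   scale_radius_annulus = 3)
  expect_error(backcalculate_length(o6, reg3), "S_a <= S_c")
})

test_that("VBGF fitting is an exact fixed point on noise-free data", {
  ages <- 1:8
  d <- data.frame(age = ages, length = vbgf_length(300, 0.4, ages))
  fit <- fit_vbgf(d)
  expect_lt(abs(fit$Linf - 300) / 300, 1e-4)
  expect_lt(abs(fit$K - 0.4) / 0.4, 1e-4)
  expect_true(fit$converged)
  expect_equal(fit$n_fish, 8L)
  expect_lt(fit$rss, 1e-10)
  # the two-parameter form forces length 0 at age 0
  expect_equal(vbgf_length(fit$Linf, fit$K, 0), 0)
})

test_that("VBGF fitting flags unidentifiable data and rejects bad input", {
  flat <- data.frame(age = 1:6, length = rep(200, 6))
  fit <- fit_vbgf(flat)
  expect_false(fit$converged)   # degenerate: no curvature to identify K
  expect_error(fit_vbgf(data.frame(age = c(1, 1, 1), length = c(1, 2, 3))),
               "distinct ages")
  expect_error(fit_vbgf(data.frame(age = 1:3, length = c(-1, 2, 3))), "> 0")
})

test_that("back-calculate-then-fit pipeline recovers generating parameters", {
  g <- small_grid()
  # noise-free end-to-end: exact recovery through the scale detour
  resp0 <- growth_response_spec(sd_Linf = 0, sd_K = 0, length_cv = 0,
                                scale_sd = 0)
  obs0 <- generate_growth_data(g, g$cell_id[c(2, 50, 100)], 40, 10, resp0,
                               seed = 13)
  p0 <- fit_population_growth(obs0)
  tp0 <- attr(obs0, "true_params")
  expect_lt(max(abs(p0$Linf - tp0$Linf_true) / tp0$Linf_true), 1e-4)
  expect_lt(max(abs(p0$K - tp0$K_true) / tp0$K_true), 1e-4)

  # small noise, 100 populations: per-population estimates track the truth
  # (the scale-edge truncation S_a <= S_c leaves a sub-1% downward bias, so
  # accuracy, not mean-unbiasedness, is the recoverable property)
  gw <- generate_climate_grid(15, 15, seed = 6)
  resp <- growth_response_spec()
  obs <- generate_growth_data(gw, gw$cell_id[seq(1, 200, by = 2)], 50, 10,
                              resp, seed = 17)
  p <- fit_population_growth(obs)
  tp <- attr(obs, "true_params")
  err <- (p$Linf - tp$Linf_true) / tp$Linf_true
  expect_lt(abs(mean(err)), 0.02)
  expect_lt(median(abs(err)), 0.05)
  expect_gte(mean(abs(err) < 0.05), 0.9)
  expect_gt(cor(p$Linf, tp$Linf_true), 0.9)
})
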