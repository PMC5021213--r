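test_that("generated grids honour the size, determinism and gradient contracts", {
  g <- generate_climate_grid(2, 2, seed = 1)
  expect_equal(nrow(g), 4L)
  expect_length(climate_variables(g), 9L)
  expect_true(all(vapply(climate_variables(g),
                         function(v) all(is.finite(g[[v]])), logical(1))))
  expect_false(anyDuplicated(g$cell_id) > 0)

  g1 <- generate_climate_grid(20, 30, seed = 7)
  g2 <- generate_climate_grid(20, 30, seed = 7)
  expect_identical(g1, g2)
  expect_false(identical(g1, generate_climate_grid(20, 30, seed = 8)))

  # temperature declines with latitude: Pearson r by its definition
  expect_lt(pearson_r(g1$ann_mean_temp, g1$lat), 0)

  # at least one auxiliary pair exceeds the reduction threshold
  cm <- abs(stats::cor(as.data.frame(g1)[, climate_variables(g1)]))
  diag(cm) <- 0
  expect_gt(max(cm), 0.70)

  # isothermality identity holds exactly for every cell
  expect_equal(g1$isothermality,
               100 * g1$diurnal_range / g1$temp_annual_range)

  expect_error(generate_climate_grid(1, 5, seed = 1), "n_lon")
})

test_that("scenario application shifts temperatures, scales precipitation, keeps identities", {
  g <- small_grid()
  id <- apply_scenario(g, scenario_spec("same", 0, 1))
  expect_equal(as.data.frame(id), as.data.frame(g), ignore_attr = TRUE)

  warm <- apply_scenario(g, scenario_spec("warm2", 2, 1))
  expect_equal(warm$ann_mean_temp, g$ann_mean_temp + 2)
  expect_equal(warm$temp_wettest_q, g$temp_wettest_q + 2)
  expect_equal(warm$diurnal_range, g$diurnal_range)  # ranges unshifted
  expect_equal(warm$isothermality,
               100 * warm$diurnal_range / warm$temp_annual_range)
  expect_equal(attr(warm, "scenario_name"), "warm2")
  expect_equal(warm$cell_id, g$cell_id)

  g2 <- as.data.frame(g); g2$ann_precip[1] <- 800
  wet <- apply_scenario(climate_grid(g2), scenario_spec("wet", 0, 1.1))
  expect_equal(wet$ann_precip[1], 880)

  expect_error(scenario_spec("bad", 2, -1), "precip_factor")
  expect_error(scenario_spec("bad", Inf, 1), "delta_temp")
})

test_that("logistic occupancy matches its stated distribution", {
  g <- generate_climate_grid(100, 100, seed = 2)  # 10 000 cells
  flat <- niche_spec(0, c(ann_mean_temp = 0))
  occ <- generate_occurrences(g, flat, seed = 4)
  expect_gte(mean(occ$presence), 0.47)
  expect_lte(mean(occ$presence), 0.53)

  sat <- niche_spec(50, c(ann_mean_temp = 0))
  expect_warning(occ1 <- generate_occurrences(small_grid(), sat, seed = 4),
                 "single-class")
  expect_true(all(occ1$presence == 1L))

  warm <- generate_occurrences(small_grid(), warm_niche(), seed = 4)
  d <- merge(warm, as.data.frame(small_grid()), by = "cell_id")
  expect_gt(mean(d$ann_mean_temp[d$presence == 1]),
            mean(d$ann_mean_temp[d$presence == 0]))

  expect_error(generate_occurrences(small_grid(),
                                    niche_spec(0, c(nope = 1)), 1),
               "unknown variables")
})

test_that("growth generator honours the noise-free limit and linear response", {
  g <- small_grid()
  resp0 <- growth_response_spec(sd_Linf = 0, sd_K = 0, length_cv = 0,
                                scale_sd = 0)
  obs <- generate_growth_data(g, g$cell_id[1], 30, 8, resp0, seed = 9)
  tp <- attr(obs, "true_params")
  expect_equal(obs$capture_length,
               vbgf_length(tp$Linf_true, tp$K_true, obs$age_t + 0.5))

  # two populations 3 degrees apart -> L-infinity differs by exactly 30 mm
  gd <- as.data.frame(g)
  i <- which.min(abs(gd$ann_mean_temp - 7))
  gd$ann_mean_temp[1] <- gd$ann_mean_temp[i] + 3
  g2 <- climate_grid(gd)
  resp10 <- growth_response_spec(Linf_temp_slope = -10, sd_Linf = 0,
                                 sd_K = 0, length_cv = 0, scale_sd = 0)
  obs2 <- generate_growth_data(g2, g2$cell_id[c(1, i)], 5, 8, resp10, seed = 2)
  tp2 <- attr(obs2, "true_params")
  expect_equal(abs(diff(tp2$Linf_true)), 30)

  # Monte-Carlo: mean of true L-infinity over 200 populations within 2 SE
  gbig <- generate_climate_grid(20, 20, seed = 5)
  resp <- growth_response_spec()
  cells <- gbig$cell_id[1:200]
  obs3 <- generate_growth_data(gbig, cells, 2, 5, resp, seed = 31)
  tp3 <- attr(obs3, "true_params")
  mu <- resp$Linf_intercept + resp$Linf_temp_slope * tp3$ann_mean_temp
  z <- mean(tp3$Linf_true - mu) / (resp$sd_Linf / sqrt(200))
  expect_lt(abs(z), 2)

  expect_error(
    generate_growth_data(g, g$cell_id[1], 5, 8,
                         growth_response_spec(Linf_intercept = 5,
                                              Linf_temp_slope = -10),
                         seed = 1),
    "non-positive")
  expect_error(generate_growth_data(g, "nope", 5, 8, resp0, 1), "not in grid")
  expect_error(generate_growth_data(g, g$cell_id[1], 5, 1, resp0, 1), "max_age")
})

test_that("growth observations satisfy the scale-radius invariants and determinism", {
  g <- small_grid()
  resp <- growth_response_spec()
  obs <- generate_growth_data(g, g$cell_id[1:5], 40, 10, resp, seed = 3)
  expect_true(all(obs$scale_radius_annulus > 0))
  expect_true(all(obs$scale_radius_annulus <= obs$scale_radius_capture))
  expect_true(all(obs$capture_length > 0))
  expect_true(all(obs$age_t >= 1 & obs$age_t <= 10))
  obs2 <- generate_growth_data(g, g$cell_id[1:5], 40, 10, resp, seed = 3)
  expect_identical(obs, obs2)
})

test_that("climate grid CSV round-trips through the long format", {
  g <- small_grid(n_lon = 4, n_lat = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_climate_grid(g, path)
  g2 <- read_climate_grid(path)
  expect_equal(sort(climate_variables(g2)), sort(climate_variables(g)))
  expect_equal(g2$ann_mean_temp[match(g$cell_id, g2$cell_id)],
               g$ann_mean_temp, tolerance = 1e-12)
})
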