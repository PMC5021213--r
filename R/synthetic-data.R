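#' Scenario specification
#'
#' A climate-change scenario is expressed as a uniform additive shift of the
#' temperature-level variables and a multiplicative factor on precipitation,
#' standing in for a (climate model, emission pathway, horizon year) triple.
#'
#' @param name unique text label for the scenario.
#' @param delta_temp warming in degrees C added to temperature-level variables.
#' @param precip_factor multiplier (> 0) applied to precipitation variables.
#' @param year_label text horizon label, e.g. `"2050"`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, delta_temp, precip_factor = 1, year_label = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.finite(delta_temp)) stop_invalid("delta_temp must be finite")
  if (!is.finite(precip_factor) || precip_factor <= 0) {
    stop_invalid("precip_factor must be > 0")
  }
  structure(
    list(name = name, delta_temp = delta_temp,
         precip_factor = precip_factor, year_label = as.character(year_label)),
    class = "scenario_spec"
  )
}

#' Niche specification for logistic occupancy
#'
#' Presence probability of the virtual species at a cell is
#' `plogis(intercept + sum(coefficients * climate values))`.
#'
#' @param intercept intercept on the logit scale.
#' @param coefficients named numeric vector, names matching grid variables,
#'   values in logit units per variable unit.
#' @param prevalence_target optional fraction in (0, 1); when a simulated draw
#'   comes out single-class the intercept is re-centred so the mean logit hits
#'   this prevalence and the draw is repeated once.
#' @return An object of class `niche_spec`.
#' @export
niche_spec <- function(intercept, coefficients, prevalence_target = NULL) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L)
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            all(nzchar(names(coefficients))))
  if (!is.null(prevalence_target)) {
    stopifnot(prevalence_target > 0, prevalence_target < 1)
  }
  structure(
    list(intercept = intercept, coefficients = coefficients,
         prevalence_target = prevalence_target),
    class = "niche_spec"
  )
}

#' Growth response specification (temperature-size rule structure)
#'
#' Per-population true growth parameters respond linearly to the cell's annual
#' mean temperature: asymptotic length L-infinity is expected to fall with
#' temperature (`Linf_temp_slope` < 0) while the growth coefficient K rises
#' (`K_temp_slope` > 0), plus Gaussian between-population noise. Individual
#' capture lengths carry multiplicative lognormal error; scale radii follow a
#' linear scale-body relationship with Gaussian noise.
#'
#' @param Linf_intercept mm, L-infinity at 0 degrees C.
#' @param Linf_temp_slope mm per degree C (expected negative).
#' @param K_intercept per year, K at 0 degrees C (> 0 over grid temperatures).
#' @param K_temp_slope per year per degree C (expected positive).
#' @param sd_Linf,sd_K between-population SDs (>= 0).
#' @param length_cv coefficient of variation of individual capture length.
#' @param scale_intercept,scale_slope,scale_sd linear scale-radius model
#'   `S = scale_intercept + scale_slope * length + noise` (radius units).
#' @return An object of class `growth_response_spec`.
#' @export
growth_response_spec <- function(Linf_intercept = 450, Linf_temp_slope = -12,
                                 K_intercept = 0.05, K_temp_slope = 0.025,
                                 sd_Linf = 20, sd_K = 0.03, length_cv = 0.05,
                                 scale_intercept = 0.3, scale_slope = 0.012,
                                 scale_sd = 0.08) {
  if (K_intercept <= 0) stop_invalid("K_intercept must be > 0")
  if (any(c(sd_Linf, sd_K, length_cv, scale_sd) < 0)) {
    stop_invalid("sd and cv terms must be >= 0")
  }
  if (scale_slope <= 0) stop_invalid("scale_slope must be > 0")
  structure(
    list(Linf_intercept = Linf_intercept, Linf_temp_slope = Linf_temp_slope,
         K_intercept = K_intercept, K_temp_slope = K_temp_slope,
         sd_Linf = sd_Linf, sd_K = sd_K, length_cv = length_cv,
         scale_intercept = scale_intercept, scale_slope = scale_slope,
         scale_sd = scale_sd),
    class = "growth_response_spec"
  )
}

# Variable roles used by apply_scenario(). Temperature *levels* shift under
# additive warming; ranges (diurnal, annual) cancel and stay put; isothermality
# is recomputed from its definition.
.temp_level_vars <- c("ann_mean_temp", "temp_wettest_q", "temp_driest_q",
                      "max_temp_warmest")
.precip_vars <- c("ann_precip", "precip_wettest_q")

#' Generate a synthetic bioclimatic grid
#'
#' Builds a regular lon/lat grid over a Great-Britain-like window with nine
#' bioclim-style variables: the six the downstream analysis retains (annual
#' mean temperature, mean diurnal range, isothermality, mean temperature of
#' the wettest and driest quarters, annual precipitation) plus three auxiliary
#' correlates (annual temperature range, maximum temperature of the warmest
#' month, precipitation of the wettest quarter) whose pairwise correlations
#' with the retained set exceed |r| = 0.70 by construction, so variable
#' reduction has something to do. Annual mean temperature declines with
#' latitude in expectation; isothermality is exactly
#' `100 * diurnal_range / temp_annual_range` for every cell.
#'
#' @param n_lon,n_lat grid dimensions (each >= 2).
#' @param seed integer RNG seed; identical seeds give identical grids.
#' @return A [climate_grid()] with scenario name `"baseline"`.
#' @export
generate_climate_grid <- function(n_lon, n_lat, seed) {
  if (!is.numeric(n_lon) || !is.numeric(n_lat) || n_lon < 2 || n_lat < 2) {
    stop_invalid("n_lon and n_lat must both be >= 2")
  }
  n_lon <- as.integer(n_lon); n_lat <- as.integer(n_lat)
  set.seed(derive_seed(seed, "climate_grid"))
  g <- expand.grid(lon = seq(-6, 2, length.out = n_lon),
                   lat = seq(50, 59, length.out = n_lat))
  n <- nrow(g)
  ann_mean_temp <- 11 - 0.45 * (g$lat - 50) - 0.15 * (g$lon + 2) +
    stats::rnorm(n, 0, 0.4)
  diurnal_range <- 8 + stats::rnorm(n, 0, 0.6)
  # annual range proportional to diurnal range at the grid centre: keeps
  # isothermality nearly orthogonal to its two parents while |r| between the
  # two ranges stays ~0.95 (a reduction casualty).
  temp_annual_range <- 2.5 * diurnal_range + stats::rnorm(n, 0, 0.5)
  isothermality <- 100 * diurnal_range / temp_annual_range
  temp_wettest_q <- 3 + 0.5 * ann_mean_temp + stats::rnorm(n, 0, 1.5)
  temp_driest_q <- 1 + 0.5 * ann_mean_temp + stats::rnorm(n, 0, 1.5)
  ann_precip <- 900 + 45 * (2 - g$lon) + 20 * (g$lat - 54) +
    stats::rnorm(n, 0, 60)
  max_temp_warmest <- ann_mean_temp + 0.5 * temp_annual_range +
    stats::rnorm(n, 0, 0.3)
  precip_wettest_q <- 0.35 * ann_precip + stats::rnorm(n, 0, 30)

  climate_grid(data.frame(
    cell_id = sprintf("c%05d", seq_len(n)),
    lon = g$lon, lat = g$lat,
    ann_mean_temp = ann_mean_temp,
    diurnal_range = diurnal_range,
    isothermality = isothermality,
    temp_wettest_q = temp_wettest_q,
    temp_driest_q = temp_driest_q,
    ann_precip = ann_precip,
    temp_annual_range = temp_annual_range,
    max_temp_warmest = max_temp_warmest,
    precip_wettest_q = precip_wettest_q,
    stringsAsFactors = FALSE
  ), scenario_name = "baseline")
}

#' Apply a climate-change scenario to a grid
#'
#' Temperature-level variables (annual mean, wettest-quarter mean,
#' driest-quarter mean, warmest-month maximum) are shifted by `delta_temp`;
#' precipitation variables are multiplied by `precip_factor`; diurnal and
#' annual temperature ranges are untouched (an additive shift cancels in a
#' range); isothermality is recomputed from its definition where both parent
#' ranges are present. Cell ids and coordinates are unchanged.
#'
#' @param grid a [climate_grid()].
#' @param scenario a [scenario_spec()].
#' @return A new `climate_grid` named after the scenario.
#' @export
apply_scenario <- function(grid, scenario) {
  stopifnot(inherits(grid, "climate_grid"), inherits(scenario, "scenario_spec"))
  vars <- climate_variables(grid)
  out <- as.data.frame(grid)
  for (v in intersect(.temp_level_vars, vars)) {
    out[[v]] <- out[[v]] + scenario$delta_temp
  }
  for (v in intersect(.precip_vars, vars)) {
    out[[v]] <- out[[v]] * scenario$precip_factor
  }
  if (all(c("isothermality", "diurnal_range", "temp_annual_range") %in% vars)) {
    out$isothermality <- 100 * out$diurnal_range / out$temp_annual_range
  }
  climate_grid(out, scenario_name = scenario$name)
}

#' Simulate presence/absence from a logistic climate niche
#'
#' Each cell's presence is Bernoulli with probability
#' `plogis(intercept + sum(coef * variable))`. If the draw is single-class and
#' the niche carries a `prevalence_target`, the intercept is re-centred so the
#' average logit equals `qlogis(prevalence_target)` and the draw is repeated;
#' a still-degenerate result is an error. Without a target a single-class draw
#' is returned with a warning (downstream model fitting will refuse it).
#'
#' @param grid a [climate_grid()].
#' @param niche a [niche_spec()]; coefficient names must match grid variables.
#' @param seed integer RNG seed.
#' @param species text label stored on the result.
#' @return An `occurrence_set`: data frame `(cell_id, presence)` with a
#'   `species` attribute.
#' @export
generate_occurrences <- function(grid, niche, seed, species = "virtual_species") {
  stopifnot(inherits(grid, "climate_grid"), inherits(niche, "niche_spec"))
  bad <- setdiff(names(niche$coefficients), climate_variables(grid))
  if (length(bad)) {
    stop_invalid("niche coefficients name unknown variables: ",
                 paste(bad, collapse = ", "))
  }
  set.seed(derive_seed(seed, "occurrences"))
  xb <- as.matrix(as.data.frame(grid)[, names(niche$coefficients), drop = FALSE]) %*%
    niche$coefficients
  eta <- as.numeric(xb) + niche$intercept
  presence <- stats::rbinom(length(eta), 1L, inv_logit(eta))
  if (length(unique(presence)) == 1L && !is.null(niche$prevalence_target)) {
    adj <- stats::qlogis(niche$prevalence_target) - mean(as.numeric(xb))
    presence <- stats::rbinom(length(eta), 1L, inv_logit(as.numeric(xb) + adj))
    if (length(unique(presence)) == 1L) {
      stop_invalid("degenerate occurrences: one class only even after ",
                   "re-centring toward prevalence_target")
    }
  } else if (length(unique(presence)) == 1L) {
    warning("occurrence draw is single-class; set prevalence_target to rescue",
            call. = FALSE)
  }
  occurrence_set(data.frame(cell_id = grid$cell_id, presence = presence,
                            stringsAsFactors = FALSE),
                 species = species, require_both_classes = FALSE)
}

#' Occurrence set container
#'
#' @param records data frame with columns `cell_id` and `presence` (0/1).
#' @param species text label.
#' @param require_both_classes refuse single-class sets (the default; model
#'   fitting needs both classes).
#' @return An `occurrence_set` data frame.
#' @export
occurrence_set <- function(records, species = "species",
                           require_both_classes = TRUE) {
  stopifnot(is.data.frame(records),
            all(c("cell_id", "presence") %in% names(records)))
  records$cell_id <- as.character(records$cell_id)
  if (!all(records$presence %in% c(0L, 1L))) {
    stop_invalid("presence must be 0/1")
  }
  if (require_both_classes && length(unique(records$presence)) < 2L) {
    stop_invalid("occurrence set must contain both presences and absences")
  }
  out <- records[, c("cell_id", "presence")]
  rownames(out) <- NULL
  attr(out, "species") <- species
  class(out) <- c("occurrence_set", "data.frame")
  out
}

#' Simulate length-at-age observations with scale radii
#'
#' One population per requested cell. True per-population parameters are drawn
#' from the linear temperature responses in `resp` (plus Gaussian noise); each
#' fish gets an integer age at its last annulus, uniform on `[1, max_age]`,
#' and a mean-one lognormal individual growth factor (cv = `length_cv`) that
#' scales its whole trajectory. Capture length is the von Bertalanffy length
#' half a growing season after the last annulus times that factor; scale radii
#' follow the linear scale-body law at capture and at the last annulus.
#' Invariants `0 < S_a <= S_c` and positive lengths are enforced.
#'
#' @param grid a [climate_grid()] (baseline climate).
#' @param population_cells cell ids hosting one population each.
#' @param n_fish_per_pop fish sampled per population.
#' @param max_age maximum age (years, >= 2).
#' @param resp a [growth_response_spec()].
#' @param seed integer RNG seed.
#' @return Data frame of observations (`fish_id`, `population_id`, `cell_id`,
#'   `age_t`, `capture_length`, `scale_radius_capture`,
#'   `scale_radius_annulus`) with attribute `true_params`: a per-population
#'   data frame of the generating temperature, L-infinity and K.
#' @export
generate_growth_data <- function(grid, population_cells, n_fish_per_pop,
                                 max_age, resp, seed) {
  stopifnot(inherits(grid, "climate_grid"),
            inherits(resp, "growth_response_spec"))
  if (max_age < 2) stop_invalid("max_age must be >= 2")
  if (n_fish_per_pop < 1) stop_invalid("n_fish_per_pop must be >= 1")
  population_cells <- as.character(population_cells)
  miss <- setdiff(population_cells, grid$cell_id)
  if (length(miss)) {
    stop_invalid("population cells not in grid: ", paste(miss, collapse = ", "))
  }
  temps <- grid$ann_mean_temp[match(population_cells, grid$cell_id)]
  mu_Linf <- resp$Linf_intercept + resp$Linf_temp_slope * temps
  mu_K <- resp$K_intercept + resp$K_temp_slope * temps
  if (any(mu_Linf <= 0) || any(mu_K <= 0)) {
    stop_invalid("growth response implies non-positive L-infinity or K at ",
                 "some population temperature")
  }
  set.seed(derive_seed(seed, "growth_data"))
  n_pop <- length(population_cells)
  Linf_true <- mu_Linf + stats::rnorm(n_pop, 0, resp$sd_Linf)
  K_true <- mu_K + stats::rnorm(n_pop, 0, resp$sd_K)
  if (any(Linf_true <= 0) || any(K_true <= 0)) {
    stop_invalid("drawn population parameters include non-positive ",
                 "L-infinity or K; reduce sd_Linf/sd_K")
  }
  pop_ids <- sprintf("pop_%03d", seq_len(n_pop))

  sdlog <- sqrt(log(1 + resp$length_cv^2))
  obs <- vector("list", n_pop)
  for (i in seq_len(n_pop)) {
    age <- sample.int(max_age, n_fish_per_pop, replace = TRUE)
    # mean-one lognormal fish effect scales the whole growth trajectory, so
    # the annulus length can never exceed the capture length
    eps <- if (sdlog > 0) {
      stats::rlnorm(n_fish_per_pop, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, n_fish_per_pop)
    l_annulus <- vbgf_length(Linf_true[i], K_true[i], age) * eps
    # capture midway through the growing season after the last annulus
    l_capture <- vbgf_length(Linf_true[i], K_true[i], age + 0.5) * eps
    s_capture <- resp$scale_intercept + resp$scale_slope * l_capture +
      stats::rnorm(n_fish_per_pop, 0, resp$scale_sd)
    s_annulus <- resp$scale_intercept + resp$scale_slope * l_annulus +
      stats::rnorm(n_fish_per_pop, 0, resp$scale_sd)
    s_capture <- pmax(s_capture, 1e-6)
    s_annulus <- pmin(pmax(s_annulus, 1e-6), s_capture)
    obs[[i]] <- data.frame(
      fish_id = sprintf("%s_f%04d", pop_ids[i], seq_len(n_fish_per_pop)),
      population_id = pop_ids[i],
      cell_id = population_cells[i],
      age_t = age,
      capture_length = l_capture,
      scale_radius_capture = s_capture,
      scale_radius_annulus = s_annulus,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, obs)
  rownames(out) <- NULL
  attr(out, "true_params") <- data.frame(
    population_id = pop_ids, cell_id = population_cells,
    ann_mean_temp = temps, Linf_true = Linf_true, K_true = K_true,
    stringsAsFactors = FALSE
  )
  out
}
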