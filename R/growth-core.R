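#' von Bertalanffy length at age (two-parameter form)
#'
#' `L_t = Linf * (1 - exp(-K * t))`; the two-parameter form pins length 0 at
#' age 0.
#'
#' @param Linf asymptotic length, mm (> 0).
#' @param K growth coefficient, per year (> 0).
#' @param t age in years (>= 0), vectorised.
#' @return Length(s) in mm.
#' @export
vbgf_length <- function(Linf, K, t) {
  if (any(Linf <= 0) || any(K <= 0)) stop_invalid("Linf and K must be > 0")
  if (any(t < 0)) stop_invalid("age must be >= 0")
  Linf * (1 - exp(-K * t))
}

#' Scale-body regression for back-calculation
#'
#' Ordinary least squares of scale radius at capture on capture length,
#' `S_c = u + v * L_c`. The slope must be positive for the scale-proportional
#' back-calculation to be defined.
#'
#' @param obs data frame of growth observations with columns
#'   `capture_length` and `scale_radius_capture`.
#' @return A `scale_body_regression`: list with `intercept_u`, `slope_v`,
#'   `r2`, `n`.
#' @export
fit_scale_body_regression <- function(obs) {
  stopifnot(is.data.frame(obs),
            all(c("capture_length", "scale_radius_capture") %in% names(obs)))
  if (nrow(obs) < 3L || length(unique(obs$capture_length)) < 2L) {
    stop_invalid("need >= 3 observations with >= 2 distinct lengths")
  }
  fit <- stats::lm(scale_radius_capture ~ capture_length, data = obs)
  v <- unname(stats::coef(fit)[2L])
  if (!is.finite(v) || v <= 0) {
    stop_invalid("scale-body slope is not positive; back-calculation undefined")
  }
  tss <- sum((obs$scale_radius_capture - mean(obs$scale_radius_capture))^2)
  structure(
    list(intercept_u = unname(stats::coef(fit)[1L]), slope_v = v,
         r2 = 1 - sum(stats::resid(fit)^2) / tss, n = nrow(obs)),
    class = "scale_body_regression"
  )
}

#' Back-calculate length at the last annulus (scale proportional method)
#'
#' Francis' scale-proportional formula with the scale-on-length regression
#' `S = u + v L`: `L_a = -(u/v) + (L_c + u/v) * (S_a / S_c)`. Observations
#' whose back-calculated length comes out non-positive are returned as `NA`
#' with a warning so callers can drop them.
#'
#' @param obs data frame with columns `capture_length`,
#'   `scale_radius_capture`, `scale_radius_annulus` (vectorised over rows).
#' @param reg a [fit_scale_body_regression()] result.
#' @return Numeric vector of back-calculated lengths (mm), `NA` where flagged.
#' @export
backcalculate_length <- function(obs, reg) {
  stopifnot(inherits(reg, "scale_body_regression"))
  need <- c("capture_length", "scale_radius_capture", "scale_radius_annulus")
  stopifnot(all(need %in% names(obs)))
  if (any(obs$scale_radius_annulus <= 0) ||
      any(obs$scale_radius_annulus > obs$scale_radius_capture + 1e-12)) {
    stop_invalid("scale radii must satisfy 0 < S_a <= S_c")
  }
  uv <- reg$intercept_u / reg$slope_v
  la <- -uv + (obs$capture_length + uv) *
    (obs$scale_radius_annulus / obs$scale_radius_capture)
  bad <- la <= 0
  if (any(bad)) {
    warning(sum(bad), " back-calculated length(s) <= 0; flagged NA",
            call. = FALSE)
    la[bad] <- NA_real_
  }
  la
}

#' Fit the two-parameter von Bertalanffy growth model
#'
#' Nonlinear least squares of `L_t = Linf (1 - exp(-K t))`. Start values:
#' `Linf0 = 1.1 * max(length)` and `K0` from regressing
#' `-log(1 - L/Linf0)` on age through the origin. Fitting uses the `port`
#' algorithm with positivity bounds (max 500 iterations, tolerance 1e-8);
#' on failure a Nelder-Mead fallback on log-parameters supplies best-found
#' values with `converged = FALSE`.
#'
#' @param lengths_at_age data frame with columns `age` (years) and
#'   `length` (mm), one point per fish.
#' @param population_id optional label carried into the result.
#' @return A `growth_params` list: `population_id`, `Linf`, `K`, `n_fish`,
#'   `rss`, `converged`.
#' @export
fit_vbgf <- function(lengths_at_age, population_id = NA_character_) {
  stopifnot(is.data.frame(lengths_at_age),
            all(c("age", "length") %in% names(lengths_at_age)))
  d <- lengths_at_age[is.finite(lengths_at_age$length) &
                        is.finite(lengths_at_age$age), , drop = FALSE]
  if (nrow(d) < 3L || length(unique(d$age)) < 2L) {
    stop_invalid("need >= 3 points over >= 2 distinct ages")
  }
  if (any(d$length <= 0)) stop_invalid("lengths must be > 0")
  Linf0 <- 1.1 * max(d$length)
  z <- -log(pmax(1 - d$length / Linf0, 1e-6))
  K0 <- sum(z * d$age) / sum(d$age^2)
  K0 <- min(max(K0, 0.01), 3)

  fit <- tryCatch(
    stats::nls(length ~ Linf * (1 - exp(-K * age)), data = d,
               start = list(Linf = Linf0, K = K0),
               algorithm = "port", lower = c(Linf = 1e-6, K = 1e-6),
               control = stats::nls.control(maxiter = 500, tol = 1e-8,
                                            warnOnly = FALSE)),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    co <- stats::coef(fit)
    res <- structure(
      list(population_id = population_id, Linf = unname(co["Linf"]),
           K = unname(co["K"]), n_fish = nrow(d),
           rss = sum(stats::resid(fit)^2), converged = TRUE),
      class = "growth_params"
    )
    return(res)
  }
  # fallback: direct RSS minimisation on log-parameters (keeps positivity)
  obj <- function(p) {
    sum((d$length - exp(p[1]) * (1 - exp(-exp(p[2]) * d$age)))^2)
  }
  op <- stats::optim(c(log(Linf0), log(K0)), obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12))
  structure(
    list(population_id = population_id, Linf = exp(op$par[1]),
         K = exp(op$par[2]), n_fish = nrow(d), rss = op$value,
         converged = FALSE),
    class = "growth_params"
  )
}

#' Per-population growth pipeline: back-calculate then fit
#'
#' Applies one scale-body regression (fitted across all observations, i.e.
#' per species) to back-calculate length at the last annulus for every fish,
#' then fits the von Bertalanffy model per population on
#' (age, back-calculated length).
#'
#' @param obs growth-observation data frame (see [generate_growth_data()]).
#' @param per_population_regression fit the scale-body regression within each
#'   population instead of across the species (default `FALSE`).
#' @return Data frame with one row per population: `population_id`, `cell_id`,
#'   `Linf`, `K`, `n_fish`, `rss`, `converged`.
#' @export
fit_population_growth <- function(obs, per_population_regression = FALSE) {
  stopifnot(is.data.frame(obs), "population_id" %in% names(obs))
  if (!per_population_regression) {
    reg <- fit_scale_body_regression(obs)
  }
  pops <- unique(obs$population_id)
  rows <- lapply(pops, function(p) {
    d <- obs[obs$population_id == p, , drop = FALSE]
    r <- if (per_population_regression) fit_scale_body_regression(d) else reg
    la <- backcalculate_length(d, r)
    keep <- is.finite(la)
    gp <- fit_vbgf(data.frame(age = d$age_t[keep], length = la[keep]),
                   population_id = p)
    data.frame(population_id = p,
               cell_id = unique(d$cell_id)[1L],
               Linf = gp$Linf, K = gp$K, n_fish = gp$n_fish, rss = gp$rss,
               converged = gp$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
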