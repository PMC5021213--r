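# Integration of the two model streams: regress scenario-mean growth
# parameters on percent climate-space change, and build per-scenario
# length-at-age curves with empirical confidence bands.

#' Regress a scenario-mean growth parameter on climate-space change
#'
#' Ordinary least squares of the scenario-mean parameter (L-infinity or K) on
#' the percent change in climate space across scenarios, with the F-test of
#' zero slope. With the canonical eight climate projections the F degrees of
#' freedom are (1, 6).
#'
#' @param points data frame with columns `pct_change` (percent) and
#'   `mean_param` (target units), one row per scenario.
#' @param target label carried into the result (e.g. `"Linf"`).
#' @return A `coupling_regression`: `slope`, `intercept`, `r2`, `F`,
#'   `df1`, `df2`, `p`, `n_scenarios`.
#' @export
fit_coupling_regression <- function(points, target = "param") {
  stopifnot(is.data.frame(points),
            all(c("pct_change", "mean_param") %in% names(points)))
  n <- nrow(points)
  if (n < 3L) stop_invalid("need >= 3 scenarios for the coupling regression")
  if (stats::sd(points$pct_change) == 0) {
    stop_invalid("all climate-space changes equal: slope undefined")
  }
  fit <- stats::lm(mean_param ~ pct_change, data = points)
  sm <- suppressWarnings(summary(fit))  # perfect fits trip summary.lm
  fstat <- sm$fstatistic
  # perfect fits leave summary() without an F statistic; rebuild from anova
  if (is.null(fstat)) {
    an <- stats::anova(fit)
    fstat <- c(value = an$`F value`[1], numdf = an$Df[1], dendf = an$Df[2])
  }
  p <- stats::pf(fstat[["value"]], fstat[["numdf"]], fstat[["dendf"]],
                 lower.tail = FALSE)
  structure(
    list(target = target,
         slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r2 = sm$r.squared,
         F = unname(fstat[["value"]]),
         df1 = unname(fstat[["numdf"]]), df2 = unname(fstat[["dendf"]]),
         p = p, n_scenarios = n),
    class = "coupling_regression"
  )
}

#' @export
print.coupling_regression <- function(x, ...) {
  cat(sprintf(
    "<coupling_regression> %s ~ pct climate-space change: slope %.4g, R2 = %.2f, F(%d,%d) = %.2f, p = %.3g\n",
    x$target, x$slope, x$r2, x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Mean length-at-age curves with empirical confidence bands
#'
#' Evaluates the two-parameter von Bertalanffy curve at integer ages
#' `0..max_age` for every population's projected (L-infinity, K), then takes
#' the per-age mean and the empirical 2.5th/97.5th percentiles across
#' populations as the 95 percent band.
#'
#' @param proj a [project_growth()] result.
#' @param max_age maximum age in years.
#' @param conf_level band coverage (default 0.95).
#' @return A `growth_curve_set`: data frame (`scenario`, `age`, `mean_mm`,
#'   `lo_mm`, `hi_mm`).
#' @export
build_growth_curves <- function(proj, max_age, conf_level = 0.95) {
  stopifnot(inherits(proj, "growth_projection"), max_age >= 1)
  pp <- proj$per_population
  pp <- pp[pp$valid, , drop = FALSE]
  if (nrow(pp) < 2L) stop_invalid("need >= 2 populations with valid parameters")
  ages <- 0:max_age
  curves <- vapply(seq_len(nrow(pp)), function(i)
    vbgf_length(pp$Linf_hat[i], pp$K_hat[i], ages), numeric(length(ages)))
  alpha <- (1 - conf_level) / 2
  qs <- apply(curves, 1, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  out <- data.frame(
    scenario = proj$scenario_name, age = ages,
    mean_mm = rowMeans(curves), lo_mm = qs[1, ], hi_mm = qs[2, ],
    stringsAsFactors = FALSE
  )
  class(out) <- c("growth_curve_set", "data.frame")
  out
}

#' Collate a full run into a machine-readable report
#'
#' Gathers the per-scenario range-shift rows, growth projections, coupling
#' regressions and growth curves of one or more species into one list with
#' the seed and configuration echo, suitable for JSON serialisation; the
#' same inputs always produce a byte-identical report.
#'
#' @param species_results named list (by species) of lists with elements
#'   `range_shifts` (data frame), `projections` (data frame),
#'   `coupling` (data frame), `curves` (data frame). May be empty.
#' @param seed,config run provenance to embed.
#' @return A `scenario_report` list with `species`, `tables`, `seed`,
#'   `config`.
#' @export
scenario_report <- function(species_results, seed = NA_integer_,
                            config = list()) {
  stopifnot(is.list(species_results))
  bind <- function(el) {
    tabs <- Filter(Negate(is.null), lapply(species_results, `[[`, el))
    if (!length(tabs)) return(data.frame())
    out <- do.call(rbind, tabs)
    rownames(out) <- NULL
    out
  }
  structure(
    list(species = names(species_results) %||% character(0),
         tables = list(range_shifts = bind("range_shifts"),
                       projections = bind("projections"),
                       coupling = bind("coupling"),
                       curves = bind("curves")),
         seed = seed, config = config),
    class = "scenario_report"
  )
}

#' Write a scenario report to disk
#'
#' @param report a [scenario_report()].
#' @param outdir output directory (created if needed); CSV per table plus a
#'   `summary.json`.
#' @return `outdir`, invisibly.
#' @export
write_scenario_report <- function(report, outdir) {
  stopifnot(inherits(report, "scenario_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$tables)) {
    utils::write.csv(report$tables[[nm]],
                     file.path(outdir, paste0(nm, ".csv")), row.names = FALSE)
  }
  jsonlite::write_json(
    list(species = report$species, seed = report$seed, config = report$config,
         tables = report$tables),
    file.path(outdir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(outdir)
}
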