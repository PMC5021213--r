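# End-to-end orchestration: one declarative config drives synthetic data,
# variable reduction, growth fitting, the SDM ensemble, growth-climate
# ensembles, range statistics and the integration stage, with one root seed.

canonical_variable_order <- function(grid) {
  pref <- c("ann_mean_temp", "diurnal_range", "isothermality",
            "temp_wettest_q", "temp_driest_q", "ann_precip")
  vars <- climate_variables(grid)
  c(intersect(pref, vars), setdiff(vars, pref))
}

#' Demo configuration: the synthetic study world
#'
#' One virtual cool-temperate river fish whose occupancy rises with annual
#' mean temperature (so warming expands its climate space) and whose growth
#' follows the temperature-size rule (L-infinity falls, K rises with
#' temperature), on a Great-Britain-like grid, under eight scenarios — two
#' synthetic climate models x two emission pathways x two horizon years —
#' spanning roughly +1.0 to +4.3 degrees C. Method settings sit at the
#' canonical values: |r| cutoff 0.70, 50 evaluation repetitions at 80:20,
#' AUC cutoff 0.7, presence threshold 0.6, 4-knot GAM smooths, MARS
#' R-squared step 0.001 with 30 CV folds, 43 populations of ~91 fish,
#' maximum age 10.
#'
#' @param seed integer root seed.
#' @param outdir optional output directory for artifacts.
#' @param ... overrides spliced into the config (top-level fields).
#' @return A config list for [run_pipeline()].
#' @export
demo_config <- function(seed, outdir = NULL, ...) {
  cfg <- list(
    seed = seed,
    outdir = outdir,
    synthetic = list(
      n_lon = 28, n_lat = 36,
      species = list(
        virtual_roach = list(
          niche = niche_spec(
            intercept = -7.0,
            coefficients = c(ann_mean_temp = 1.2, ann_precip = -0.004),
            prevalence_target = 0.35
          ),
          growth = growth_response_spec(),
          n_populations = 43, n_fish_per_pop = 91, max_age = 10
        )
      )
    ),
    scenarios = list(
      scenario_spec("gcm_a_rcp26_2050", 1.0, 1.02, "2050"),
      scenario_spec("gcm_a_rcp26_2070", 1.1, 1.02, "2070"),
      scenario_spec("gcm_a_rcp85_2050", 2.0, 1.04, "2050"),
      scenario_spec("gcm_a_rcp85_2070", 3.3, 1.06, "2070"),
      scenario_spec("gcm_b_rcp26_2050", 1.4, 1.01, "2050"),
      scenario_spec("gcm_b_rcp26_2070", 1.5, 1.03, "2070"),
      scenario_spec("gcm_b_rcp85_2050", 2.4, 1.05, "2050"),
      scenario_spec("gcm_b_rcp85_2070", 4.3, 1.08, "2070")
    )
  )
  utils::modifyList(cfg, list(...))
}

#' Validate a pipeline configuration and fill defaults
#'
#' Checks the config invariants (seed present, thresholds in (0, 1),
#' repetitions >= 1, positive precipitation factors, unique scenario names,
#' exactly one input mode) and injects the canonical defaults: correlation
#' cutoff 0.70, AUC cutoff 0.7, presence threshold 0.6, 50 repetitions at
#' 80:20, 4 GAM knots, MARS R-squared step 0.001 with 30 CV folds. Unknown
#' top-level fields draw a warning, not an error.
#'
#' @param cfg a config list (see [demo_config()]).
#' @return A validated `run_config`.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  known <- c("seed", "outdir", "synthetic", "input_paths", "scenarios",
             "climate", "sdm", "growth", "integration")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    warning("ignoring unknown config field(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  errs <- character(0)
  if (is.null(cfg$seed) || !is.numeric(cfg$seed) || !is.finite(cfg$seed)) {
    errs <- c(errs, "seed: required integer")
  }
  has_syn <- !is.null(cfg$synthetic); has_path <- !is.null(cfg$input_paths)
  if (has_syn == has_path) {
    errs <- c(errs, "input mode: exactly one of 'synthetic' or 'input_paths'")
  }
  if (is.null(cfg$scenarios) || !length(cfg$scenarios)) {
    errs <- c(errs, "scenarios: at least one required")
  } else {
    if (!all(vapply(cfg$scenarios, inherits, logical(1), "scenario_spec"))) {
      errs <- c(errs, "scenarios: entries must be scenario_spec objects")
    } else {
      nm <- vapply(cfg$scenarios, `[[`, character(1), "name")
      if (anyDuplicated(nm)) errs <- c(errs, "scenarios: names must be unique")
    }
  }
  cfg$climate <- utils::modifyList(list(cor_threshold = 0.70,
                                        candidate_order = NULL),
                                   cfg$climate %||% list())
  cfg$sdm <- utils::modifyList(
    list(roster = sdm_default_roster(), n_reps = 50, train_frac = 0.8,
         auc_cutoff = 0.7, presence_threshold = 0.6, config = list()),
    cfg$sdm %||% list()
  )
  cfg$growth <- utils::modifyList(
    list(gam_knots = 4, mars_r2_step = 0.001, mars_cv_folds = 30),
    cfg$growth %||% list()
  )
  cfg$integration <- utils::modifyList(list(max_age = NULL),
                                       cfg$integration %||% list())
  chk01 <- function(v, nm) {
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      errs <<- c(errs, paste0(nm, ": must lie in (0, 1)"))
    }
  }
  chk01(cfg$sdm$train_frac, "sdm.train_frac")
  chk01(cfg$sdm$presence_threshold, "sdm.presence_threshold")
  if (!is.numeric(cfg$sdm$auc_cutoff) || cfg$sdm$auc_cutoff < 0 ||
      cfg$sdm$auc_cutoff > 1) {
    errs <- c(errs, "sdm.auc_cutoff: must lie in [0, 1]")
  }
  if (!is.numeric(cfg$sdm$n_reps) || cfg$sdm$n_reps < 1) {
    errs <- c(errs, "sdm.n_reps: must be >= 1")
  }
  if (length(errs)) {
    stop_invalid("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("run_config", "list")
  cfg
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[climspace] %s", sprintf(fmt, ...)))
}

#' Run the coupled climate-space / growth pipeline
#'
#' Executes, in order: synthetic data generation, climate variable reduction,
#' per-population growth fitting (back-calculation + von Bertalanffy), the
#' AUC-weighted SDM ensemble with per-scenario presence grids, the
#' GCV-weighted growth-climate ensembles with per-scenario projections,
#' range-shift statistics, and the integration stage (coupling regressions
#' and length-at-age curves). Every stage's outputs are written under
#' `cfg$outdir` (when set) before the next stage starts. Fully deterministic
#' under a fixed seed.
#'
#' @param cfg a config list; validated with [validate_config()] first.
#' @param verbose emit per-stage progress messages.
#' @return Invisibly, a list with the baseline grid, scenario grids, the
#'   per-species results (ensembles, projections, summary tables) and the
#'   collated [scenario_report()].
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  cfg <- validate_config(cfg)
  if (!is.null(cfg$input_paths)) {
    stop_invalid("only the synthetic input mode is implemented")
  }
  outdir <- cfg$outdir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  save_csv <- function(x, name) {
    if (!is.null(outdir)) {
      utils::write.csv(x, file.path(outdir, name), row.names = FALSE)
    }
  }
  t0 <- proc.time()[["elapsed"]]
  tick <- function(stage) {
    el <- proc.time()[["elapsed"]] - t0
    stage_log(verbose, "%-18s done at %6.1f s", stage, el)
  }

  # --- synthetic data: climate surfaces + scenarios -------------------------
  syn <- cfg$synthetic
  grid <- generate_climate_grid(syn$n_lon, syn$n_lat, cfg$seed)
  scen_grids <- lapply(cfg$scenarios, function(s) apply_scenario(grid, s))
  names(scen_grids) <- vapply(cfg$scenarios, `[[`, character(1), "name")
  if (!is.null(outdir)) {
    write_climate_grid(grid, file.path(outdir, "climate_baseline.csv"))
  }
  tick("synthetic climate")

  # --- climate prep: variable reduction ------------------------------------
  retained <- reduce_variables(
    grid, cfg$climate$candidate_order %||% canonical_variable_order(grid),
    threshold = cfg$climate$cor_threshold
  )
  if (!is.null(outdir)) {
    jsonlite::write_json(list(retained_variables = retained,
                              cor_threshold = cfg$climate$cor_threshold),
                         file.path(outdir, "variable_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  stage_log(verbose, "retained variables: %s", paste(retained, collapse = ", "))
  tick("variable reduction")

  gcfg <- list(gam_knots = cfg$growth$gam_knots,
               mars_r2_step = cfg$growth$mars_r2_step,
               mars_cv_folds = cfg$growth$mars_cv_folds)
  deltas <- vapply(cfg$scenarios, `[[`, numeric(1), "delta_temp")

  species_results <- list()
  for (sp in names(syn$species)) {
    spec <- syn$species[[sp]]
    sp_seed <- derive_seed(cfg$seed, paste("species", sp))

    # occurrences + growth observations
    occ <- generate_occurrences(grid, spec$niche, sp_seed, species = sp)
    occ <- occurrence_set(occ, species = sp)  # both classes required here
    set.seed(derive_seed(sp_seed, "population_cells"))
    pres_cells <- occ$cell_id[occ$presence == 1L]
    pop_cells <- sample(pres_cells, min(spec$n_populations, length(pres_cells)))
    obs <- generate_growth_data(grid, pop_cells, spec$n_fish_per_pop,
                                spec$max_age, spec$growth, sp_seed)
    save_csv(occ, sprintf("occurrences_%s.csv", sp))
    save_csv(obs, sprintf("growth_observations_%s.csv", sp))
    tick(paste0("simulate ", sp))

    # growth core: back-calculate + von Bertalanffy per population
    params <- fit_population_growth(obs)
    save_csv(params, sprintf("growth_params_%s.csv", sp))
    tick(paste0("growth fits ", sp))

    # SDM ensemble
    reports <- lapply(cfg$sdm$roster, function(a)
      evaluate_algorithm(occ, grid, a, n_reps = cfg$sdm$n_reps,
                         train_frac = cfg$sdm$train_frac, seed = sp_seed,
                         variables = retained, config = cfg$sdm$config))
    rep_tab <- data.frame(
      species = sp,
      algo_id = vapply(reports, `[[`, character(1), "algo_id"),
      mean_auc = vapply(reports, `[[`, numeric(1), "mean_auc"),
      stringsAsFactors = FALSE
    )
    ens <- build_ensemble(reports, occ, grid, auc_cutoff = cfg$sdm$auc_cutoff,
                          variables = retained, config = cfg$sdm$config,
                          seed = sp_seed)
    pg0 <- predict_presence(ens, grid, cfg$sdm$presence_threshold)
    pgs <- lapply(scen_grids, predict_presence, ens = ens,
                  threshold = cfg$sdm$presence_threshold)
    save_csv(rep_tab, sprintf("algorithm_reports_%s.csv", sp))
    if (!is.null(outdir)) {
      jsonlite::write_json(
        list(species = sp,
             members = lapply(ens$members, function(m)
               list(algo_id = m$algo_id, weight = m$weight,
                    mean_auc = m$mean_auc)),
             auc_cutoff = ens$auc_cutoff,
             presence_threshold = cfg$sdm$presence_threshold,
             ensemble_auc_resub = ens$ensemble_auc_resub,
             ensemble_auc_eval_weighted = ens$ensemble_auc_eval_weighted),
        file.path(outdir, sprintf("ensemble_manifest_%s.json", sp)),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
      save_csv(as.data.frame(pg0), sprintf("presence_baseline_%s.csv", sp))
    }
    tick(paste0("sdm ensemble ", sp))

    # growth-climate ensembles
    gt <- cbind(params,
                as.data.frame(grid)[match(params$cell_id, grid$cell_id),
                                    retained, drop = FALSE])
    fit_members <- function(target) {
      ms <- lapply(c("GLM", "GAM", "MARS"), function(f)
        tryCatch(fit_growth_family(gt, target, f, variables = retained,
                                   config = gcfg),
                 error = function(e) {
                   warning(sprintf("%s %s model dropped: %s", sp, f,
                                   conditionMessage(e)), call. = FALSE)
                   NULL
                 }))
      Filter(Negate(is.null), ms)
    }
    ens_linf <- build_growth_ensemble(fit_members("Linf"))
    ens_k <- build_growth_ensemble(fit_members("K"))
    rmse <- c(Linf = assess_rmse(ens_linf, gt), K = assess_rmse(ens_k, gt))
    pops <- params[, c("population_id", "cell_id")]
    proj0 <- project_growth(ens_linf, ens_k, grid, pops)
    projs <- lapply(scen_grids, function(g)
      project_growth(ens_linf, ens_k, g, pops))
    proj_tab <- do.call(rbind, lapply(c(list(baseline = proj0), projs),
                                      function(p) data.frame(
      species = sp, scenario = p$scenario_name,
      mean_Linf = p$mean_Linf, se_Linf = p$se_Linf,
      ci_Linf_lo = p$ci_Linf[1], ci_Linf_hi = p$ci_Linf[2],
      mean_K = p$mean_K, se_K = p$se_K,
      ci_K_lo = p$ci_K[1], ci_K_hi = p$ci_K[2],
      n_valid = p$n_valid, stringsAsFactors = FALSE)))
    rownames(proj_tab) <- NULL
    save_csv(proj_tab, sprintf("growth_projections_%s.csv", sp))
    if (!is.null(outdir)) {
      jsonlite::write_json(
        list(species = sp, rmse = as.list(rmse),
             Linf = lapply(ens_linf$members, function(m)
               list(family = m$family, weight = m$weight, gcv = m$gcv)),
             K = lapply(ens_k$members, function(m)
               list(family = m$family, weight = m$weight, gcv = m$gcv))),
        file.path(outdir, sprintf("growth_ensemble_manifest_%s.json", sp)),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
    }
    tick(paste0("growth climate ", sp))

    # range statistics
    shifts <- do.call(rbind, lapply(pgs, range_shift_summary,
                                    pg_baseline = pg0))
    rownames(shifts) <- NULL
    save_csv(shifts, sprintf("range_shifts_%s.csv", sp))
    tick(paste0("range stats ", sp))

    # integration: coupling regressions + curves
    scen_names <- vapply(cfg$scenarios, `[[`, character(1), "name")
    mean_linf <- vapply(projs[scen_names], `[[`, numeric(1), "mean_Linf")
    mean_k <- vapply(projs[scen_names], `[[`, numeric(1), "mean_K")
    pct <- shifts$pct_change[match(scen_names, shifts$scenario)]
    coup <- list(
      fit_coupling_regression(data.frame(pct_change = pct,
                                         mean_param = mean_linf), "Linf"),
      fit_coupling_regression(data.frame(pct_change = pct,
                                         mean_param = mean_k), "K")
    )
    coup_tab <- do.call(rbind, lapply(coup, function(cr) data.frame(
      species = sp, target = cr$target, slope = cr$slope,
      intercept = cr$intercept, r2 = cr$r2, F = cr$F, df1 = cr$df1,
      df2 = cr$df2, p = cr$p, stringsAsFactors = FALSE)))
    max_age <- cfg$integration$max_age %||% spec$max_age
    curve_set <- c(list(proj0), projs[c(which.min(deltas), which.max(deltas))])
    curves <- do.call(rbind, lapply(curve_set, build_growth_curves,
                                    max_age = max_age))
    curves <- cbind(species = sp, curves, stringsAsFactors = FALSE)
    rownames(curves) <- NULL
    save_csv(coup_tab, sprintf("coupling_%s.csv", sp))
    save_csv(curves, sprintf("growth_curves_%s.csv", sp))
    tick(paste0("integration ", sp))

    species_results[[sp]] <- list(
      occurrences = occ, growth_params = params, ensemble = ens,
      reports = reports, presence_baseline = pg0, presence_scenarios = pgs,
      growth_ensembles = list(Linf = ens_linf, K = ens_k), rmse = rmse,
      projections = proj_tab, range_shifts = shifts, coupling = coup_tab,
      curves = curves
    )
  }

  report <- scenario_report(
    species_results, seed = cfg$seed,
    config = list(
      n_scenarios = length(cfg$scenarios),
      roster = cfg$sdm$roster, n_reps = cfg$sdm$n_reps,
      auc_cutoff = cfg$sdm$auc_cutoff,
      presence_threshold = cfg$sdm$presence_threshold,
      cor_threshold = cfg$climate$cor_threshold,
      retained_variables = retained
    )
  )
  if (!is.null(outdir)) write_scenario_report(report, outdir)
  tick("report")
  invisible(list(grid = grid, scenario_grids = scen_grids,
                 retained_variables = retained,
                 species = species_results, report = report))
}
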