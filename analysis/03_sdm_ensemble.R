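#!/usr/bin/env Rscript
# Stage 3 — distribution-climate modelling: reduce the candidate climate
# variables by pairwise correlation, evaluate the seven-algorithm roster by
# repeated-split AUC, build the AUC-weighted ensemble, and threshold
# per-scenario probability surfaces into presence grids.

source("analysis/00_common.R")

grid <- read_climate_grid(res_path("climate_baseline.csv"))
occ <- occurrence_set(read.csv(res_path("occurrences.csv"),
                               stringsAsFactors = FALSE),
                      species = SPECIES)

retained <- reduce_variables(grid, threshold = CFG$climate$cor_threshold)
say("variable reduction at |r| > %.2f: %d of %d retained (%s)",
    CFG$climate$cor_threshold, length(retained),
    length(climate_variables(grid)), paste(retained, collapse = ", "))
jsonlite::write_json(list(retained_variables = retained),
                     res_path("retained_variables.json"),
                     auto_unbox = TRUE, pretty = TRUE)

say("evaluating %d algorithms: %d repetitions of a stratified %d:%d split",
    length(CFG$sdm$roster), CFG$sdm$n_reps,
    round(100 * CFG$sdm$train_frac), round(100 * (1 - CFG$sdm$train_frac)))
reports <- lapply(CFG$sdm$roster, function(a) {
  r <- evaluate_algorithm(occ, grid, a, n_reps = CFG$sdm$n_reps,
                          train_frac = CFG$sdm$train_frac, seed = SEED,
                          variables = retained, config = CFG$sdm$config)
  say("  %-4s mean AUC %.3f (sd %.3f)", a, r$mean_auc, sd(r$auc_per_rep))
  r
})
write.csv(data.frame(
  algo_id = vapply(reports, `[[`, character(1), "algo_id"),
  mean_auc = vapply(reports, `[[`, numeric(1), "mean_auc")),
  res_path("algorithm_reports.csv"), row.names = FALSE)

ens <- build_ensemble(reports, occ, grid, auc_cutoff = CFG$sdm$auc_cutoff,
                      variables = retained, config = CFG$sdm$config,
                      seed = SEED)
print(ens)
jsonlite::write_json(
  list(members = lapply(ens$members, function(m)
    list(algo_id = m$algo_id, weight = m$weight, mean_auc = m$mean_auc)),
    auc_cutoff = ens$auc_cutoff,
    presence_threshold = CFG$sdm$presence_threshold,
    ensemble_auc_resub = ens$ensemble_auc_resub,
    ensemble_auc_eval_weighted = ens$ensemble_auc_eval_weighted),
  res_path("ensemble_manifest.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

pg0 <- predict_presence(ens, grid, CFG$sdm$presence_threshold)
write.csv(as.data.frame(pg0), res_path("presence_baseline.csv"),
          row.names = FALSE)
say("baseline climate space: %d cells at threshold %.1f",
    count_cells(pg0), CFG$sdm$presence_threshold)
for (nm in SCEN_NAMES) {
  sg <- read_climate_grid(res_path(sprintf("climate_%s.csv", nm)))
  pg <- predict_presence(ens, sg, CFG$sdm$presence_threshold)
  write.csv(as.data.frame(pg), res_path(sprintf("presence_%s.csv", nm)),
            row.names = FALSE)
  say("  %s: %d cells", nm, count_cells(pg))
}
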