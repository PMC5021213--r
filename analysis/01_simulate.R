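#!/usr/bin/env Rscript
# Stage 1 — simulate the study world: a bioclimatic grid over a
# Great-Britain-like window, eight warming scenarios, logistic climate-niche
# occurrences for the virtual species, and length-at-age samples with scale
# radii for its populations.

source("analysis/00_common.R")

grid <- generate_climate_grid(CFG$synthetic$n_lon, CFG$synthetic$n_lat, SEED)
say("baseline grid: %d cells, %d variables", nrow(grid),
    length(climate_variables(grid)))
say("annual mean temperature spans %.1f to %.1f degC; r(T, lat) = %.2f",
    min(grid$ann_mean_temp), max(grid$ann_mean_temp),
    cor(grid$ann_mean_temp, grid$lat))
write_climate_grid(grid, res_path("climate_baseline.csv"))

for (s in SCENARIOS) {
  sg <- apply_scenario(grid, s)
  write_climate_grid(sg, res_path(sprintf("climate_%s.csv", s$name)))
}
scen_tab <- data.frame(
  name = SCEN_NAMES,
  delta_temp = vapply(SCENARIOS, `[[`, numeric(1), "delta_temp"),
  precip_factor = vapply(SCENARIOS, `[[`, numeric(1), "precip_factor"),
  year = vapply(SCENARIOS, `[[`, character(1), "year_label"))
write.csv(scen_tab, res_path("scenarios.csv"), row.names = FALSE)
say("wrote %d scenario grids (warming %.1f to %.1f degC)",
    nrow(scen_tab), min(scen_tab$delta_temp), max(scen_tab$delta_temp))

occ <- occurrence_set(generate_occurrences(grid, SP$niche, SEED,
                                           species = SPECIES),
                      species = SPECIES)
say("occurrences: prevalence %.2f (%d presences / %d cells)",
    mean(occ$presence), sum(occ$presence), nrow(occ))
write.csv(occ, res_path("occurrences.csv"), row.names = FALSE)

set.seed(derive_seed(SEED, "analysis_population_cells"))
pop_cells <- sample(occ$cell_id[occ$presence == 1L], SP$n_populations)
obs <- generate_growth_data(grid, pop_cells, SP$n_fish_per_pop, SP$max_age,
                            SP$growth, SEED)
say("growth data: %d fish across %d populations (ages 1-%d)",
    nrow(obs), SP$n_populations, SP$max_age)
write.csv(obs, res_path("growth_observations.csv"), row.names = FALSE)
tp <- attr(obs, "true_params")
write.csv(tp, res_path("growth_true_params_synthetic.csv"), row.names = FALSE)
say("generating temperature-size structure: cor(T, true Linf) = %.2f, cor(T, true K) = %.2f",
    cor(tp$ann_mean_temp, tp$Linf_true), cor(tp$ann_mean_temp, tp$K_true))
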