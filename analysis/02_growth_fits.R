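#!/usr/bin/env Rscript
# Stage 2 — per-population growth: one species-wide scale-body regression,
# scale-proportional back-calculation to the last annulus, and a
# two-parameter von Bertalanffy fit per population.

source("analysis/00_common.R")

obs <- read.csv(res_path("growth_observations.csv"), stringsAsFactors = FALSE)

reg <- fit_scale_body_regression(obs)
say("scale-body regression: S = %.3f + %.5f L (r2 = %.3f, n = %d fish)",
    reg$intercept_u, reg$slope_v, reg$r2, reg$n)

params <- fit_population_growth(obs)
say("fitted %d populations; %d converged", nrow(params),
    sum(params$converged))
say("Linf range %.0f-%.0f mm (median %.0f); K range %.2f-%.2f /yr (median %.2f)",
    min(params$Linf), max(params$Linf), median(params$Linf),
    min(params$K), max(params$K), median(params$K))
write.csv(params, res_path("growth_params.csv"), row.names = FALSE)

truth <- read.csv(res_path("growth_true_params_synthetic.csv"),
                  stringsAsFactors = FALSE)
m <- merge(params, truth, by = c("population_id", "cell_id"))
say("recovery check against the generating parameters: median |rel err| Linf %.1f%%, K %.1f%%",
    100 * median(abs(m$Linf - m$Linf_true) / m$Linf_true),
    100 * median(abs(m$K - m$K_true) / m$K_true))
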