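# Shared plumbing for the numbered analysis scripts: seed handling, the
# results directory, and the scenario set of the synthetic study world.

library(climspace)

args <- commandArgs(trailingOnly = TRUE)
seed_arg <- which(args == "--seed")
SEED <- if (length(seed_arg) == 1L && seed_arg < length(args)) {
  as.integer(args[seed_arg + 1L])
} else 42L
RESULTS <- "results/analysis"
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

CFG <- validate_config(demo_config(SEED))
SCENARIOS <- CFG$scenarios
SCEN_NAMES <- vapply(SCENARIOS, `[[`, character(1), "name")
SPECIES <- names(CFG$synthetic$species)[1]
SP <- CFG$synthetic$species[[SPECIES]]

res_path <- function(...) file.path(RESULTS, ...)
say <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...))
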