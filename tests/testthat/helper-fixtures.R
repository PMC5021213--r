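# Shared fixtures, all generated in code (no files).

small_grid <- function(seed = 7, n_lon = 12, n_lat = 15) {
  generate_climate_grid(n_lon, n_lat, seed)
}

# hand-built grid for deterministic arithmetic tests
toy_grid <- function(values) {
  n <- nrow(values)
  climate_grid(cbind(
    data.frame(cell_id = sprintf("t%02d", seq_len(n)),
               lon = seq(-2, 0, length.out = n),
               lat = seq(51, 53, length.out = n)),
    values
  ))
}

warm_niche <- function() {
  niche_spec(-7, c(ann_mean_temp = 1.2, ann_precip = -0.004),
             prevalence_target = 0.35)
}

# Pearson r by its definitional sum formula (independent of stats::cor)
pearson_r <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# brute-force AUC over all positive-negative pairs, ties counted 1/2
auc_bruteforce <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# per-population growth table with a linear climate response, for the
# growth-climate module tests
linear_growth_table <- function(n = 30, seed = 3, noise = 5) {
  set.seed(seed)
  g <- small_grid(seed)
  idx <- sample(nrow(g), n)
  d <- as.data.frame(g)[idx, c("ann_mean_temp", "diurnal_range", "ann_precip")]
  d$Linf <- 450 - 12 * d$ann_mean_temp + rnorm(n, 0, noise)
  d$population_id <- sprintf("p%02d", seq_len(n))
  d
}
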