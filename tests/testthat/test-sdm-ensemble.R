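test_that("rank-based AUC matches hand values and the pair-counting oracle", {
  expect_equal(compute_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(compute_auc(rep(0.5, 8), rep(c(0, 1), 4)), 0.5)
  expect_equal(compute_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(compute_auc(1:4, rep(1, 4)), "one class")

  set.seed(31)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    lab <- c(0, 1, rbinom(n - 2, 1, 0.4))
    sc <- round(rnorm(n), sample(0:2, 1))  # rounding forces ties
    expect_equal(compute_auc(sc, lab), auc_bruteforce(sc, lab))
  }
})

test_that("repeated-split evaluation is deterministic and detects signal vs noise", {
  g <- small_grid()
  occ <- occurrence_set(generate_occurrences(g, warm_niche(), seed = 4),
                        species = "vr")

  r1 <- evaluate_algorithm(occ, g, "GLM", n_reps = 8, seed = 5)
  r2 <- evaluate_algorithm(occ, g, "GLM", n_reps = 8, seed = 5)
  expect_identical(r1$auc_per_rep, r2$auc_per_rep)
  expect_length(r1$auc_per_rep, 8L)
  expect_true(all(r1$auc_per_rep >= 0 & r1$auc_per_rep <= 1))

  # perfectly separable niche: near-ceiling AUC
  gd <- as.data.frame(g)
  sep <- occurrence_set(
    data.frame(cell_id = g$cell_id,
               presence = as.integer(gd$ann_mean_temp > median(gd$ann_mean_temp))),
    species = "sep")
  rs <- evaluate_algorithm(sep, g, "GLM", n_reps = 8, seed = 5)
  expect_gte(rs$mean_auc, 0.95)

  # permuted labels: mean AUC near 0.5
  gbig <- generate_climate_grid(25, 40, seed = 9)  # 1000 cells
  set.seed(41)
  null_occ <- occurrence_set(
    data.frame(cell_id = gbig$cell_id, presence = sample(rep(0:1, 500))),
    species = "null")
  rn <- evaluate_algorithm(null_occ, gbig, "GLM", n_reps = 10, seed = 5)
  expect_gte(rn$mean_auc, 0.4)
  expect_lte(rn$mean_auc, 0.6)
})

test_that("AUC-weighted ensembles follow the selection and weighting contract", {
  g <- small_grid()
  occ <- occurrence_set(generate_occurrences(g, warm_niche(), seed = 4),
                        species = "vr")
  fake_report <- function(id, auc) {
    structure(list(algo_id = id, mean_auc = auc,
                   auc_per_rep = rep(auc, 3), n_reps = 3, included = NA),
              class = "algorithm_report")
  }

  # one passing member takes weight 1 and the ensemble equals that member
  ens1 <- build_ensemble(list(fake_report("GLM", 0.9),
                              fake_report("CTA", 0.55)),
                         occ, g, auc_cutoff = 0.7, seed = 2)
  expect_length(ens1$members, 1L)
  expect_equal(ens1$members[[1]]$weight, 1)
  pg <- predict_presence(ens1, g, threshold = 0.6)
  m <- ens1$members[[1]]
  direct <- climspace:::sdm_predict_one(
    "GLM", m$model, as.data.frame(g)[, ens1$variables])
  expect_equal(pg$probability, direct)

  # symmetric and hand-normalized weights
  ens2 <- build_ensemble(list(fake_report("GLM", 0.8),
                              fake_report("MARS", 0.8)),
                         occ, g, seed = 2)
  expect_equal(vapply(ens2$members, `[[`, numeric(1), "weight"), c(0.5, 0.5))
  ens3 <- build_ensemble(list(fake_report("GLM", 0.9),
                              fake_report("MARS", 0.75)),
                         occ, g, seed = 2)
  expect_equal(vapply(ens3$members, `[[`, numeric(1), "weight"),
               c(0.9, 0.75) / 1.65)

  expect_error(build_ensemble(list(fake_report("GLM", 0.6)), occ, g),
               "no skilled model")
})

test_that("ensemble probabilities are weighted means with the stated bounds", {
  set.seed(51)
  probs <- matrix(runif(300), 100, 3)
  w <- c(0.5, 0.3, 0.2)
  p <- ensemble_probability(probs, w)
  expect_equal(p, as.numeric(probs %*% w))
  expect_true(all(p >= apply(probs, 1, min) - 1e-12))
  expect_true(all(p <= apply(probs, 1, max) + 1e-12))
  expect_error(ensemble_probability(probs, c(0.5, 0.3, 0.3)), "sum to 1")
})

test_that("presence thresholding counts cells as the arithmetic demands", {
  cells <- data.frame(cell_id = as.character(1:5), lon = 1:5, lat = 1:5,
                      probability = c(0.1, 0.55, 0.6, 0.7, 0.95))
  pg0 <- presence_grid(cells, threshold = 0)
  expect_equal(count_cells(pg0), 5L)
  pg1 <- presence_grid(cells, threshold = 1)
  expect_equal(count_cells(pg1), 0L)
  # hand-set weighted mean over two members on 5 cells
  mp <- cbind(c(0.2, 0.5, 0.9, 0.4, 0.8), c(0.6, 0.7, 0.3, 0.9, 0.2))
  p <- ensemble_probability(mp, c(0.75, 0.25))
  expect_equal(p, c(0.3, 0.55, 0.75, 0.525, 0.65))
  pg <- presence_grid(data.frame(cell_id = as.character(1:5), lon = 1:5,
                                 lat = 1:5, probability = p), 0.6)
  expect_equal(pg$presence, c(0L, 0L, 1L, 0L, 1L))
  # presence count non-increasing in threshold
  counts <- vapply(seq(0, 1, by = 0.1), function(th)
    count_cells(presence_grid(cells, th)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("prediction refuses grids lacking the training variables", {
  g <- small_grid()
  occ <- occurrence_set(generate_occurrences(g, warm_niche(), seed = 4))
  rep1 <- structure(list(algo_id = "GLM", mean_auc = 0.9,
                         auc_per_rep = 0.9, n_reps = 1, included = NA),
                    class = "algorithm_report")
  ens <- build_ensemble(list(rep1), occ, g,
                        variables = c("ann_mean_temp", "ann_precip"), seed = 2)
  gd <- as.data.frame(g)
  bare <- climate_grid(gd[, c("cell_id", "lon", "lat", "ann_mean_temp")])
  expect_error(predict_presence(ens, bare), "lacks training variables")
})
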