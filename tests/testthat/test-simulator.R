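test_that("true effects place the wild-type at the configured percentile", {
  cfg <- simulation_config("binding", seed = 7)
  # the distribution mean follows from the inverse-normal quantile
  expect_equal(cfg$wt_effect - qnorm(0.75) * cfg$effect_sd, 0.43255,
               tolerance = 1e-4)
  set.seed(7)
  eff <- draw_true_effects(cfg)
  expect_equal(unname(eff["_wt"]), 0.5)
  expect_true(all(eff[-1] > 0.05 & eff[-1] < 0.99))
  expect_equal(mean(eff[-1]), 0.43255, tolerance = 5e-3)
  # quantile recovery: the wild-type effect sits at the 75th percentile
  big <- simulation_config("binding", n_variants = 200000L, seed = 7)
  set.seed(7)
  eff_big <- draw_true_effects(big)
  expect_equal(unname(quantile(eff_big[-1], 0.75)), big$wt_effect,
               tolerance = 2e-3)
  # growth defaults
  g <- simulation_config("growth")
  expect_equal(g$wt_effect, 1)
  expect_equal(g$effect_bounds, c(0.05, 5))
})

test_that("initial populations have exact size and wild-type share", {
  cfg <- simulation_config("binding", seed = 3)
  set.seed(3)
  pop <- initial_population(cfg)
  expect_equal(unname(pop["_wt"]), 1e5)
  expect_equal(sum(pop), 1e7)
  expect_true(all(pop == floor(pop)))
  # mean non-wild-type count ~ (population - wt) / (n - 1) ~ 990
  expect_equal(mean(pop[-1]), (1e7 - 1e5) / 9999, tolerance = 1e-6)
})

test_that("binding rounds apply binomial selection then restore the population", {
  cfg <- small_config("binding")
  pop <- c(`_wt` = 1e5, a = 1e5, b = 1e5)
  cfg$population_size <- 3e5
  set.seed(10)
  # p = 1 for everyone: survivors equal the population, frequencies conserved
  out <- binding_round(pop, c(1, 1, 1), cfg)
  expect_equal(sum(out), 3e5)
  expect_equal(unname(out), unname(pop), tolerance = 0.02)
  # neutral selection leaves expected frequencies unchanged
  neutral <- replicate(200, binding_round(pop, c(0.5, 0.5, 0.5), cfg))
  expect_equal(rowMeans(neutral) / 3e5, rep(1 / 3, 3), tolerance = 0.005,
               ignore_attr = TRUE)
  # E[survivors] = c * p on a small toy (binomial mean, Monte Carlo)
  set.seed(11)
  k <- replicate(1000, rbinom(3, c(1000, 2000, 500), c(0.2, 0.5, 0.9)))
  expect_equal(rowMeans(k), c(200, 1000, 450), tolerance = 0.02)
  expect_error(binding_round(c(a = 10, b = 10), c(0, 0), cfg), "extinction")
})

test_that("growth rounds draw negative binomial counts with the stated mean", {
  cfg <- simulation_config("growth", seed = 5)
  expect_equal(cfg$doublings_per_round * log(2) / cfg$wt_effect, 2 * log(2))
  dt <- 2 * log(2)
  # E[g] = c * (exp(mu * dt) - 1): Monte Carlo on single variants
  set.seed(5)
  g_wt <- replicate(2000, rnbinom(1, size = 500, prob = exp(-1 * dt)))
  expect_equal(mean(g_wt) / 500, exp(dt) - 1, tolerance = 0.02)
  g_fast <- replicate(2000, rnbinom(1, size = 500, prob = exp(-1.5 * dt)))
  expect_equal(mean(g_fast) / 500, exp(1.5 * dt) - 1, tolerance = 0.02)
  # extinct lineages stay extinct instead of producing NAs
  cfg$population_size <- 1000
  out <- growth_round(c(a = 0, b = 50), c(1, 1), cfg)
  expect_equal(unname(out["a"]), 0)
  expect_equal(sum(out), 1000)
})

test_that("sequencing draws the configured total depth", {
  cfg <- small_config("binding")
  pop <- c(`_wt` = 1e5, a = 2e5)
  set.seed(12)
  reads <- sequence_population(pop, cfg)
  expect_equal(sum(reads), cfg$n_variants * cfg$reads_per_variant)
  # a single-variant population receives every read
  solo <- sequence_population(c(only = 500), cfg)
  expect_equal(unname(solo), cfg$n_variants * cfg$reads_per_variant)
  # read frequencies approach population frequencies at high depth
  cfg$reads_per_variant <- 1e4
  deep <- sequence_population(pop, cfg)
  expect_equal(deep / sum(deep), pop / sum(pop), tolerance = 0.01)
})

test_that("simulated datasets are reproducible and conserve totals", {
  cfg <- small_config("binding", seed = 21)
  sim1 <- simulate_dataset(cfg)
  sim2 <- simulate_dataset(cfg)
  expect_identical(sim1$tables, sim2$tables)
  expect_identical(sim1$truth, sim2$truth)
  # different seed, different draws
  sim3 <- simulate_dataset(small_config("binding", seed = 22))
  expect_false(identical(sim1$tables, sim3$tables))
  # every timepoint carries the full sequencing depth
  depth <- cfg$n_variants * cfg$reads_per_variant
  for (tb in sim1$tables) {
    expect_equal(unname(colSums(tb$counts)), rep(depth, cfg$rounds + 1))
  }
  expect_length(sim1$tables, cfg$replicates)
})

test_that("effect noise hits the configured share of variants per replicate", {
  cfg <- small_config("binding", effect_noise = TRUE, seed = 31)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth
  n_noisy <- round(0.1 * (cfg$n_variants - 1))
  expect_equal(sum(tr$noisy), n_noisy)
  expect_false(tr$noisy[tr$variant == "_wt"])
  # split evenly across replicates (2% of the library each)
  expect_equal(unname(table(tr$noisy_replicate)),
               rep(n_noisy / cfg$replicates, cfg$replicates),
               ignore_attr = TRUE)
  # the resampled effect differs from the original and stays in bounds
  expect_true(all(tr$noisy_effect[tr$noisy] != tr$effect[tr$noisy]))
  expect_true(all(tr$noisy_effect[tr$noisy] > cfg$effect_bounds[1] &
                    tr$noisy_effect[tr$noisy] < cfg$effect_bounds[2]))
  # disabling noise leaves the truth clean
  clean <- simulate_dataset(small_config("binding", seed = 31))
  expect_false(any(clean$truth$noisy))
})

test_that("jackpot noise amplifies or depletes one timepoint of one replicate", {
  cfg <- small_config("binding", jackpot_noise = TRUE, seed = 32)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth
  n_each <- round(0.05 * (cfg$n_variants - 1))
  expect_equal(sum(tr$jackpot == "amplified", na.rm = TRUE), n_each)
  expect_equal(sum(tr$jackpot == "depleted", na.rm = TRUE), n_each)
  expect_true(all(tr$jackpot_timepoint[!is.na(tr$jackpot)] %in% 0:cfg$rounds))
  # amplified variants are strongly over-represented at the chosen timepoint
  amp <- which(tr$jackpot == "amplified" & tr$jackpot_timepoint > 0)
  ratios <- vapply(amp, function(i) {
    r <- tr$jackpot_replicate[i]
    t <- tr$jackpot_timepoint[i]
    cts <- sim$tables[[r]]$counts[tr$variant[i], ]
    (cts[t + 1] + 0.5) / (median(cts[-(t + 1)]) + 0.5)
  }, 0)
  expect_gt(median(ratios), 10)
})

test_that("predicted scores follow the analytic formulas", {
  cfgb <- simulation_config("binding")
  expect_equal(predicted_scores(0.5, cfgb)$predicted, 0)
  expect_equal(predicted_scores(0.25, cfgb)$predicted, 5 * log(0.5))
  expect_equal(predicted_scores(0.25, cfgb)$predicted, -3.4657, tolerance = 1e-4)
  cfgg <- simulation_config("growth")
  pg <- predicted_scores(1.1, cfgg)
  expect_equal(pg$predicted_per_doubling, 5 * 2 * 0.1)
  expect_equal(pg$predicted, 5 * 2 * log(2) * 0.1)
  # the two growth conventions differ by a constant factor only
  pg2 <- predicted_scores(c(0.5, 1, 1.5, 2), cfgg)
  expect_equal(pg2$predicted, pg2$predicted_per_doubling * log(2))
  expect_equal(predicted_scores(1, cfgg)$predicted, 0)
})

test_that("simulated datasets round-trip to disk and feed the pipeline", {
  cfg <- small_config("binding", seed = 33)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_simulated_dataset(sim, dir)
  back <- read_counts_tsv(file.path(dir, "counts_rep1.tsv"))
  expect_equal(back$counts, sim$tables[[1]]$counts)
  truth <- read.table(file.path(dir, "truth.tsv"), sep = "\t", header = TRUE)
  expect_equal(nrow(truth), cfg$n_variants)
  echo <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  expect_equal(echo$seed, cfg$seed)
  expect_equal(echo$n_variants, cfg$n_variants)
})

test_that("scores recover true effects on a scaled-down simulation", {
  cfg <- small_config("binding", seed = 34)
  sim <- simulate_dataset(cfg)
  res <- score_replicates(sim$tables)
  m <- merge(res$combined, sim$truth[, c("variant", "predicted")],
             by = "variant")
  m <- m[is.finite(m$score), ]
  expect_gt(cor(m$score, m$predicted)^2, 0.9)
  # monotone in the true effect on decile averages
  dec <- cut(m$predicted, quantile(m$predicted, 0:10 / 10),
             include.lowest = TRUE)
  means <- tapply(m$score, dec, mean)
  expect_true(all(diff(means) > 0))
})
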