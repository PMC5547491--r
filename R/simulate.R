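# Selection simulator with known true effects: binomial binding rounds or
# pure-birth (negative binomial) growth, multinomial resampling of a
# fixed-size population, multinomial read sampling, replicate-effect noise,
# and amplification/depletion jackpot noise.

#' Simulation configuration
#'
#' Defines a simulated deep mutational scanning study. Defaults describe the
#' reference conditions used throughout the package's validation: a library
#' of 10,000 variants (including wild-type) whose true effects are normally
#' distributed with standard deviation 0.1 and the wild-type at the 75th
#' percentile; log-normal input counts with mean 990 (underlying normal sd
#' 0.4) in a population of 10 million with 1% wild-type; five rounds of
#' selection in each of five replicates; and sequencing at an average depth
#' of 200 reads per variant (about 2 million reads per timepoint).
#'
#' For binding assays a variant's true effect is its probability of being
#' selected in each round (wild-type 0.5, draws bounded to (0.05, 0.99)); for
#' growth assays it is the exponential growth rate (wild-type 1, bounds
#' (0.05, 5)) with each round lasting `doublings_per_round` wild-type
#' doublings.
#'
#' @param assay `"binding"` or `"growth"`.
#' @param n_variants Number of variants including wild-type.
#' @param effect_sd Standard deviation of the true-effect distribution.
#' @param wt_percentile Percentile of the effect distribution at which the
#'   wild-type effect sits.
#' @param wt_effect Wild-type true effect; defaults to 0.5 (binding
#'   probability) or 1 (growth rate).
#' @param effect_bounds Length-2 bounds for non-wild-type effects; draws
#'   outside are redrawn.
#' @param population_size Population size restored after every selection
#'   round.
#' @param wt_input_frequency Wild-type frequency in the input population.
#' @param input_count_mean Mean of the log-normal input count distribution.
#' @param input_log_sd Standard deviation of the underlying normal of the
#'   input count distribution.
#' @param rounds Number of selection rounds after the input.
#' @param replicates Number of replicate selections.
#' @param reads_per_variant Average sequencing depth per variant.
#' @param doublings_per_round Wild-type doublings per growth round (delta).
#' @param effect_noise If `TRUE`, 10% of non-wild-type variants get a
#'   resampled true effect in exactly one replicate (2% of variants per
#'   replicate).
#' @param jackpot_noise If `TRUE`, 10% of non-wild-type variants (half
#'   amplified, half depleted) have their population count multiplied or
#'   divided by `jackpot_factor` at one random timepoint (including input) of
#'   one replicate, before read sampling.
#' @param jackpot_factor Amplification/depletion factor (default 50).
#' @param seed Integer seed; every random draw in [simulate_dataset()] is
#'   reproducible from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(assay = c("binding", "growth"),
                              n_variants = 10000L,
                              effect_sd = 0.1,
                              wt_percentile = 0.75,
                              wt_effect = NULL,
                              effect_bounds = NULL,
                              population_size = 1e7,
                              wt_input_frequency = 0.01,
                              input_count_mean = 990,
                              input_log_sd = 0.4,
                              rounds = 5L,
                              replicates = 5L,
                              reads_per_variant = 200L,
                              doublings_per_round = 2,
                              effect_noise = FALSE,
                              jackpot_noise = FALSE,
                              jackpot_factor = 50,
                              seed = 1L) {
  assay <- match.arg(assay)
  if (is.null(wt_effect)) wt_effect <- if (assay == "binding") 0.5 else 1
  if (is.null(effect_bounds)) {
    effect_bounds <- if (assay == "binding") c(0.05, 0.99) else c(0.05, 5)
  }
  stopifnot(effect_bounds[1] < wt_effect, wt_effect < effect_bounds[2],
            n_variants >= 2, rounds >= 1, replicates >= 1,
            population_size > 0, reads_per_variant > 0)
  structure(
    list(assay = assay, n_variants = as.integer(n_variants),
         effect_sd = effect_sd, wt_percentile = wt_percentile,
         wt_effect = wt_effect, effect_bounds = effect_bounds,
         population_size = population_size,
         wt_input_frequency = wt_input_frequency,
         input_count_mean = input_count_mean, input_log_sd = input_log_sd,
         rounds = as.integer(rounds), replicates = as.integer(replicates),
         reads_per_variant = reads_per_variant,
         doublings_per_round = doublings_per_round,
         effect_noise = isTRUE(effect_noise),
         jackpot_noise = isTRUE(jackpot_noise),
         jackpot_factor = jackpot_factor, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

variant_names <- function(config) {
  c("_wt", sprintf("v%05d", seq_len(config$n_variants - 1L)))
}

#' Draw true variant effects
#'
#' Non-wild-type effects are drawn from a normal distribution whose mean is
#' placed so the wild-type effect sits at the configured percentile
#' (`mean = wt_effect - qnorm(wt_percentile) * effect_sd`). Draws outside the
#' configured bounds are redrawn (rejection sampling), avoiding point masses
#' at the bounds. The wild-type gets its effect exactly.
#'
#' @param config A [simulation_config()].
#' @return Named numeric vector of true effects, wild-type first.
#' @export
draw_true_effects <- function(config) {
  mu <- config$wt_effect - stats::qnorm(config$wt_percentile) * config$effect_sd
  n <- config$n_variants - 1L
  eff <- stats::rnorm(n, mu, config$effect_sd)
  bad <- which(eff <= config$effect_bounds[1] | eff >= config$effect_bounds[2])
  while (length(bad)) {
    eff[bad] <- stats::rnorm(length(bad), mu, config$effect_sd)
    bad <- bad[eff[bad] <= config$effect_bounds[1] |
                 eff[bad] >= config$effect_bounds[2]]
  }
  stats::setNames(c(config$wt_effect, eff), variant_names(config))
}

#' Initial variant population
#'
#' The wild-type receives `wt_input_frequency * population_size` individuals.
#' The remaining variants are drawn from a log-normal distribution (location
#' `log(input_count_mean) - input_log_sd^2 / 2`, so the log-normal mean equals
#' `input_count_mean`) and then rescaled to integers filling the rest of the
#' population exactly (largest-remainder rounding).
#'
#' @param config A [simulation_config()].
#' @return Named integer-valued numeric vector of population counts summing to
#'   `population_size`.
#' @export
initial_population <- function(config) {
  wt <- round(config$wt_input_frequency * config$population_size)
  n <- config$n_variants - 1L
  raw <- stats::rlnorm(n,
                       meanlog = log(config$input_count_mean) -
                         config$input_log_sd^2 / 2,
                       sdlog = config$input_log_sd)
  target <- config$population_size - wt
  scaled <- raw * target / sum(raw)
  base <- floor(scaled)
  short <- round(target - sum(base))
  if (short > 0) {
    top <- order(scaled - base, decreasing = TRUE)[seq_len(short)]
    base[top] <- base[top] + 1
  }
  stats::setNames(c(wt, base), variant_names(config))
}

resample_population <- function(weights, population_size) {
  if (sum(weights) <= 0) stop("total extinction: no individuals survived selection")
  out <- as.vector(stats::rmultinom(1, population_size, weights))
  names(out) <- names(weights)
  out
}

#' One round of binding selection
#'
#' Each variant's survivors are `k ~ Binomial(c, p_v)` where `c` is its
#' population count and `p_v` its selection probability; the population is
#' then restored to `population_size` by weighted sampling with replacement
#' (multinomial) with weights proportional to `k`.
#'
#' @param pop Named population counts.
#' @param p Selection probabilities, aligned with `pop`.
#' @param config A [simulation_config()].
#' @return Named population counts summing to `population_size`.
#' @export
binding_round <- function(pop, p, config) {
  stopifnot(length(pop) == length(p), all(p >= 0 & p <= 1))
  k <- stats::rbinom(length(pop), pop, p)
  resample_population(stats::setNames(k, names(pop)), config$population_size)
}

#' One round of growth selection
#'
#' One round lasts `dt = doublings_per_round * ln(2) / wt_effect` time units.
#' The post-growth count of a variant with `c` starting individuals and rate
#' `mu` is drawn from a negative binomial distribution with `size = c` and
#' `prob = exp(-mu * dt)`, i.e. mean `c * (exp(mu * dt) - 1)`. This is the
#' failure count of the negative binomial associated with pure-birth growth;
#' drawing it directly (rather than adding the `c` founders) makes the
#' per-round expected fold change `exp(mu * dt) - 1` and allows lineage
#' extinction, matching the behaviour recovered by validation against the
#' deterministic expected scores (see the methods vignette for the
#' alternatives considered). The population is then restored to
#' `population_size` by multinomial resampling.
#'
#' @param pop Named population counts.
#' @param mu Growth rates, aligned with `pop`.
#' @param config A [simulation_config()].
#' @return Named population counts summing to `population_size`.
#' @export
growth_round <- function(pop, mu, config) {
  stopifnot(length(pop) == length(mu), all(mu > 0))
  dt <- config$doublings_per_round * log(2) / config$wt_effect
  g <- numeric(length(pop))
  alive <- pop > 0
  g[alive] <- stats::rnbinom(sum(alive), size = pop[alive],
                             prob = exp(-mu[alive] * dt))
  resample_population(stats::setNames(g, names(pop)), config$population_size)
}

#' Sequence a population
#'
#' Read counts are a multinomial draw of `n_variants * reads_per_variant`
#' reads with probabilities proportional to the (possibly jackpot-modified)
#' population counts.
#'
#' @param pop Named population counts.
#' @param config A [simulation_config()].
#' @return Named read counts.
#' @export
sequence_population <- function(pop, config) {
  reads <- round(config$n_variants * config$reads_per_variant)
  out <- as.vector(stats::rmultinom(1, reads, pop))
  names(out) <- names(pop)
  out
}

# Pick noisy variants for replicate-effect noise: 10% of non-wild-type
# variants, split evenly so each replicate carries its share, with a
# resampled effect for the chosen replicate only.
assign_effect_noise <- function(config, effects) {
  n_noisy <- round(0.10 * (config$n_variants - 1L))
  idx <- sample(2:config$n_variants, n_noisy)
  reps <- rep(seq_len(config$replicates), length.out = n_noisy)
  reps <- sample(reps)
  mu <- config$wt_effect - stats::qnorm(config$wt_percentile) * config$effect_sd
  new_eff <- stats::rnorm(n_noisy, mu, config$effect_sd)
  bad <- which(new_eff <= config$effect_bounds[1] |
                 new_eff >= config$effect_bounds[2])
  while (length(bad)) {
    new_eff[bad] <- stats::rnorm(length(bad), mu, config$effect_sd)
    bad <- bad[new_eff[bad] <= config$effect_bounds[1] |
                 new_eff[bad] >= config$effect_bounds[2]]
  }
  data.frame(index = idx, replicate = reps, new_effect = new_eff)
}

# Pick jackpot-affected variants: 5% amplified + 5% depleted, split evenly
# over replicates, each at one uniformly chosen timepoint (including input).
assign_jackpot_noise <- function(config) {
  n_each <- round(0.05 * (config$n_variants - 1L))
  idx <- sample(2:config$n_variants, 2L * n_each)
  direction <- rep(c("amplified", "depleted"), each = n_each)
  reps <- sample(rep(seq_len(config$replicates), length.out = 2L * n_each))
  tp <- sample(0:config$rounds, 2L * n_each, replace = TRUE)
  data.frame(index = idx, direction = direction, replicate = reps,
             timepoint = tp)
}

#' Simulate a replicated deep mutational scanning dataset
#'
#' Runs the full generative model: true effects are drawn once; per replicate,
#' an independent input population is generated and carried through
#' `rounds` rounds of selection with the population restored to
#' `population_size` after each round; each timepoint (including the input) is
#' sequenced by multinomial read sampling. Optional replicate-effect noise and
#' jackpot noise are applied as configured. One master seed drives everything:
#' the same config yields byte-identical tables.
#'
#' @param config A [simulation_config()].
#' @return A list of class `simulated_dataset` with elements
#'   * `tables`: list of [variant_count_table()]s, one per replicate, with
#'     timepoints `0:rounds`;
#'   * `truth`: data frame of per-variant true effects, noise annotations,
#'     and analytic predicted scores (see [predicted_scores()]);
#'   * `config`: the configuration used.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  effects <- draw_true_effects(config)
  noise <- if (config$effect_noise) assign_effect_noise(config, effects)
  jackpot <- if (config$jackpot_noise) assign_jackpot_noise(config)
  rep_seeds <- sample.int(.Machine$integer.max, config$replicates)

  # per-replicate effect vectors (resampled effect in the noisy replicate)
  eff_by_rep <- replicate(config$replicates, effects, simplify = FALSE)
  if (!is.null(noise)) {
    for (i in seq_len(nrow(noise))) {
      eff_by_rep[[noise$replicate[i]]][noise$index[i]] <- noise$new_effect[i]
    }
  }

  tables <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    set.seed(rep_seeds[r])
    eff <- eff_by_rep[[r]]
    jp <- if (!is.null(jackpot)) jackpot[jackpot$replicate == r, ]
    pop <- initial_population(config)
    counts <- matrix(0, nrow = config$n_variants, ncol = config$rounds + 1L,
                     dimnames = list(names(pop), paste0("t", 0:config$rounds)))
    counts[, 1] <- sequence_population(jackpot_weights(pop, jp, 0L, config),
                                       config)
    for (t in seq_len(config$rounds)) {
      pop <- if (config$assay == "binding") {
        binding_round(pop, eff, config)
      } else {
        growth_round(pop, eff, config)
      }
      counts[, t + 1L] <- sequence_population(
        jackpot_weights(pop, jp, t, config), config)
    }
    tables[[r]] <- variant_count_table(counts, times = 0:config$rounds)
  }

  truth <- data.frame(
    variant = names(effects), effect = unname(effects),
    noisy = FALSE, noisy_replicate = NA_integer_, noisy_effect = NA_real_,
    jackpot = NA_character_, jackpot_replicate = NA_integer_,
    jackpot_timepoint = NA_integer_, stringsAsFactors = FALSE
  )
  if (!is.null(noise)) {
    truth$noisy[noise$index] <- TRUE
    truth$noisy_replicate[noise$index] <- noise$replicate
    truth$noisy_effect[noise$index] <- noise$new_effect
  }
  if (!is.null(jackpot)) {
    truth$jackpot[jackpot$index] <- jackpot$direction
    truth$jackpot_replicate[jackpot$index] <- jackpot$replicate
    truth$jackpot_timepoint[jackpot$index] <- jackpot$timepoint
  }
  truth <- cbind(truth, predicted_scores(truth$effect, config))
  structure(list(tables = tables, truth = truth, config = config),
            class = "simulated_dataset")
}

jackpot_weights <- function(pop, jp, t, config) {
  if (is.null(jp) || nrow(jp) == 0L) return(pop)
  here <- jp[jp$timepoint == t, ]
  if (nrow(here) == 0L) return(pop)
  amp <- here$index[here$direction == "amplified"]
  dep <- here$index[here$direction == "depleted"]
  pop[amp] <- pop[amp] * config$jackpot_factor
  pop[dep] <- pmax(floor(pop[dep] / config$jackpot_factor), 0)
  pop
}

#' Analytic predicted scores
#'
#' Expected regression scores given the true effects, for comparison with
#' scores estimated from simulated data.
#'
#' For binding, the expected log ratio at round `t` is
#' `t * ln(p_v / p_wt)` plus a constant, so on the normalized time axis the
#' expected slope is `predicted = rounds * ln(p_v / p_wt)`.
#'
#' For growth, real time per round is `doublings_per_round * ln(2) / mu_wt`,
#' so the natural-log slope on normalized time is
#' `predicted = rounds * doublings_per_round * ln(2) * (mu_v - mu_wt) /
#' mu_wt`. The same quantity expressed per wild-type doubling in log2 units,
#' `predicted_per_doubling = rounds * doublings_per_round * (mu_v - mu_wt)`,
#' is also returned; the two conventions differ only by the constant factor
#' `ln(2) / mu_wt`, so correlation-based comparisons are identical.
#'
#' @param effects Numeric vector of true effects (wild-type's value equals
#'   `config$wt_effect`).
#' @param config A [simulation_config()].
#' @return Data frame with column `predicted` (and, for growth,
#'   `predicted_per_doubling`).
#' @export
predicted_scores <- function(effects, config) {
  if (config$assay == "binding") {
    data.frame(predicted = config$rounds * log(effects / config$wt_effect))
  } else {
    m <- config$rounds
    delta <- config$doublings_per_round
    data.frame(
      predicted = m * delta * log(2) * (effects - config$wt_effect) /
        config$wt_effect,
      predicted_per_doubling = m * delta * (effects - config$wt_effect)
    )
  }
}

#' Write a simulated dataset to a directory
#'
#' Emits one count TSV per replicate (see [write_counts_tsv()]), a truth TSV,
#' and a JSON echo of the configuration.
#'
#' @param sim A `simulated_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_along(sim$tables)) {
    write_counts_tsv(sim$tables[[r]],
                     file.path(dir, sprintf("counts_rep%d.tsv", r)))
  }
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(sim$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
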