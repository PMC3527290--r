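# Replays of the validation study: simulate under the full coalescent with
# recombination and migration, fit the discretized Markov model, and
# summarize recovery, robustness and model-selection behaviour.
#
# The documented simulation scenarios use the rates of the original
# validation setting: coalescence rate 1250 (an effective population size
# of 20,000 at 1e-9 substitutions/bp/year and 20-year generations),
# recombination rate 0.4 (0.8 cM/Mb under the same scaling), and split
# times on the 250 kya - 2 Mya scale.

#' Documented validation scenarios
#'
#' @param name One of `"recovery"` (moderate gene flow, used for the
#'   parameter-recovery and mutation-rate-variation studies), `"phase"`
#'   (a very recent split with abundant shared polymorphism, for the
#'   unknown-phase study), `"geneflow"` (a long migration epoch with
#'   roughly one migration event per lineage, detectable against a clean
#'   split) and `"cleansplit"` (no migration).
#' @return An [im_parameters()] object.
#' @export
validation_scenario <- function(name = c("recovery", "phase", "geneflow",
                                         "cleansplit")) {
  switch(match.arg(name),
         recovery = im_parameters(0.00025, 0.001, 1250, 0.4, 250),
         phase = im_parameters(5e-5, 1e-4, 1250, 0.4, 250),
         geneflow = im_parameters(0.0005, 0.002, 1250, 0.4, 667),
         cleansplit = im_parameters(0.001, 0.001, 1250, 0.4, 0))
}

#' Optimizer options for the validation replays
#'
#' @param restarts Random restarts around the method-of-moments start.
#' @param maxit Maximum Nelder-Mead evaluations per start.
#' @param reltol Nelder-Mead relative convergence tolerance.
#' @return A list of options accepted by the `replay_*` functions.
#' @export
fit_options <- function(restarts = 2L, maxit = 800L, reltol = 1e-7)
  list(restarts = restarts, maxit = maxit, reltol = reltol)

#' Replay the parameter-recovery study
#'
#' Simulates replicate datasets under the full (non-Markov) coalescent with
#' recombination and migration and fits the IM model by maximum likelihood,
#' optionally with geometric-block mutation-rate variation as in the
#' robustness study.
#'
#' @param n_rep Number of replicate datasets.
#' @param L Sequence length per replicate (bp).
#' @param params Generating parameters.
#' @param seed Base seed; replicate `r` simulates with `seed + r`.
#' @param mut_block_mean If positive, mean geometric block length for
#'   mutation-rate variation.
#' @param mut_factor_range Factor range for the block multipliers.
#' @param options Optimizer options from [fit_options()].
#' @return A data frame with one row per replicate: the five IM estimates,
#'   log-likelihood and the seed used.
#' @export
replay_recovery <- function(n_rep = 10L, L = 1e6,
                            params = validation_scenario("recovery"),
                            seed = 100L, mut_block_mean = 0,
                            mut_factor_range = c(0.5, 1.5),
                            options = fit_options()) {
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    mm <- NULL
    if (mut_block_mean > 0) {
      set.seed(seed + 600L + r)
      mm <- perturb_mutation_rate(L, mut_block_mean, mut_factor_range)
    }
    cfg <- sim_config(params, L, 1L, seed = seed + r, mut_multipliers = mm)
    cols <- as_column_sequence(simulate_alignment(cfg)$alignment)
    fit <- im_fit(cols, "im", restarts = options$restarts, seed = r,
                  maxit = options$maxit, reltol = options$reltol)
    e <- fit$estimates
    rows[[r]] <- data.frame(rep = r, tau1 = e$tau1, tau2 = e$tau2,
                            coal = e$coal, rec = e$rec, mig = e$mig,
                            loglik = fit$loglik, seed = seed + r)
  }
  out <- do.call(rbind, rows)
  attr(out, "params") <- params
  out
}

#' Replay the unknown-phase (random-allele mosaic) study
#'
#' Simulates two haploid genomes per deme at a very recent split, collapses
#' each deme's pair into a random-phase mosaic haplotype, and fits the IM
#' model to the mosaic pair.
#'
#' @inheritParams replay_recovery
#' @return A data frame of IM estimates per replicate.
#' @export
replay_phase <- function(n_rep = 10L, L = 1e6,
                         params = validation_scenario("phase"),
                         seed = 300L, options = fit_options()) {
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(params, L, 2L, seed = seed + r)
    sim <- simulate_alignment(cfg)
    mos <- random_phase_mosaic(sim$alignment, seed = seed + 300L + r)
    fit <- im_fit(as_column_sequence(mos), "im", restarts = options$restarts,
                  seed = r, maxit = options$maxit, reltol = options$reltol)
    e <- fit$estimates
    rows[[r]] <- data.frame(rep = r, tau1 = e$tau1, tau2 = e$tau2,
                            coal = e$coal, rec = e$rec, mig = e$mig,
                            loglik = fit$loglik, seed = seed + r)
  }
  out <- do.call(rbind, rows)
  attr(out, "params") <- params
  out
}

#' Replay the model-selection study
#'
#' Fits both the IM and the clean-split I model to replicate simulations
#' and reports the AIC difference `delta = AIC(I) - AIC(IM)` (positive
#' prefers gene flow).
#'
#' @inheritParams replay_recovery
#' @param scenario `"geneflow"` or `"cleansplit"`.
#' @return A data frame with `delta` and both AICs per replicate.
#' @export
replay_model_selection <- function(n_rep = 10L, L = 1e6,
                                   scenario = c("geneflow", "cleansplit"),
                                   seed = NULL,
                                   options = fit_options(restarts = 1L,
                                                         maxit = 600L)) {
  scenario <- match.arg(scenario)
  if (is.null(seed)) seed <- if (scenario == "geneflow") 400L else 500L
  params <- validation_scenario(scenario)
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(params, L, 1L, seed = seed + r)
    cols <- as_column_sequence(simulate_alignment(cfg)$alignment)
    cmp <- im_compare(cols, restarts = options$restarts, seed = r,
                      maxit = options$maxit, reltol = options$reltol)
    rows[[r]] <- data.frame(rep = r, aic_im = cmp$aic_im, aic_i = cmp$aic_i,
                            delta = cmp$delta, seed = seed + r)
  }
  out <- do.call(rbind, rows)
  attr(out, "params") <- params
  out
}
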