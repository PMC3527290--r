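# Exact ARG simulator, sequence emission, perturbations and the
# two-nucleotide Gillespie oracle.

test_that("seeded simulations are bit-reproducible", {
  p <- im_parameters(0.0005, 0.002, 1000, 0.4, 300)
  a <- simulate_alignment(sim_config(p, 20000, 1, seed = 5))
  b <- simulate_alignment(sim_config(p, 20000, 1, seed = 5))
  expect_identical(a$arg$track, b$arg$track)
  expect_identical(unclass(a$alignment), unclass(b$alignment))
  d <- simulate_alignment(sim_config(p, 20000, 1, seed = 6))
  expect_false(identical(a$arg$track, d$arg$track))
})

test_that("without recombination the whole sequence shares one tree", {
  p <- im_parameters(0.0005, 0.002, 1000, 0, 300)
  arg <- simulate_arg(sim_config(p, 5000, 1, seed = 1))
  expect_identical(nrow(arg$track), 1L)
  expect_identical(arg$track$start, 1L)
  expect_identical(arg$track$end, 5000L)
  expect_identical(unname(arg$n_events["RECOMBINATION"]), 0L)
  expect_gt(arg$track$time, p$tau1)
})

test_that("clean-split TMRCAs are tau2 plus an exponential", {
  p <- im_parameters(0.001, 0.001, 1250, 0, 0)
  tm <- vapply(1:1500, function(s)
    simulate_arg(sim_config(p, 2, 1, seed = 10000 + s))$track$time[1],
    numeric(1L))
  expect_true(all(tm > p$tau2))
  z <- (mean(tm) - (p$tau2 + 1 / p$coal)) / (stats::sd(tm) / sqrt(length(tm)))
  expect_lt(abs(z), 3)
})

test_that("per-site TMRCA marginals match the model's interval masses", {
  # independent single-site replicates so binomial standard errors apply
  p <- main_params()
  disc <- discretize_time(p)
  m <- single_nuc_interval_masses(p, disc)
  reps <- 5000L
  tm <- vapply(seq_len(reps), function(r)
    simulate_arg(sim_config(p, 2, 1, seed = 30000 + r))$track$time[1],
    numeric(1L))
  idx <- pmin(pmax(findInterval(tm, disc$breakpoints), 1L), disc$n)
  freq <- tabulate(idx, disc$n) / reps
  se <- sqrt(m * (1 - m) / reps)
  expect_true(all(abs(freq - m) <= 4 * se + 2.5 / reps))
})

test_that("mutation emission matches the Jukes-Cantor mismatch curve", {
  p <- main_params()
  cfg <- sim_config(p, 1e5, 1, seed = 2)
  t_const <- rep(0.003, 1e5)
  aln <- sim_mutate(t_const, cfg, seed = 9)
  mism <- mean(aln[1, ] != aln[2, ])
  p_theory <- 0.75 * (1 - exp(-(8 / 3) * 0.003))
  se <- sqrt(p_theory * (1 - p_theory) / 1e5)
  expect_lt(abs(mism - p_theory), 3 * se)

  # zero TMRCA gives identical sequences
  aln0 <- sim_mutate(rep(0, 1e5), cfg, seed = 9)
  expect_identical(aln0[1, ], aln0[2, ])
})

test_that("geometric-block rate multipliers have the configured moments", {
  set.seed(31)
  mm <- perturb_mutation_rate(5e6, mean_block = 500, range = c(0.75, 1.25))
  expect_length(mm, 5e6)
  expect_true(all(mm >= 0.75 & mm <= 1.25))
  blocks <- rle(mm)$lengths
  z <- (mean(blocks) - 500) / (stats::sd(blocks) / sqrt(length(blocks)))
  expect_lt(abs(z), 3)

  expect_identical(unique(perturb_mutation_rate(1000, 500, c(1, 1))), 1)
})

test_that("synthetic recombination maps are positive, normalized and autocorrelated", {
  set.seed(8)
  rm <- random_rec_map(2e5, block = 1000)
  expect_length(rm, 2e5 - 1)
  expect_true(all(rm > 0))
  expect_equal(mean(rm), 1, tolerance = 1e-9)
  expect_gt(stats::cor(rm[-1], rm[-length(rm)]), 0.5)
})

test_that("random-phase mosaics pick one input allele per site", {
  base <- matrix(sample.int(4L, 4000, replace = TRUE), 1)
  # identical within-deme pairs: mosaic equals the input
  aln <- imcoalhmm:::new_alignment(rbind(base, base, base + 0L, base)[c(1, 2, 3, 4), ])
  mos <- random_phase_mosaic(aln, seed = 3)
  expect_identical(unname(mos[1, ]), unname(base[1, ]))

  # fully heterozygous pair: allele choice is fair and sites come from inputs
  a <- rep(1L, 10000); b <- rep(2L, 10000)
  aln2 <- imcoalhmm:::new_alignment(rbind(a, b, a, b))
  mos2 <- random_phase_mosaic(aln2, seed = 4)
  expect_true(all(mos2[1, ] %in% c(1L, 2L)))
  frac <- mean(mos2[1, ] == 2L)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
  mos3 <- random_phase_mosaic(aln2, seed = 4)
  expect_identical(unclass(mos2), unclass(mos3))
})

test_that("quartet simulations separate within- from between-deme divergence", {
  p <- im_parameters(5e-5, 1e-4, 1250, 0.4, 250)
  sim <- simulate_alignment(sim_config(p, 2e5, 2, seed = 21))
  aln <- sim$alignment
  expect_identical(nrow(aln), 4L)
  within <- mean(aln[1, ] != aln[2, ])
  between <- mean(aln[1, ] != aln[3, ])
  expect_gt(between, 0)
  expect_gt(within, 0)
  # recent split: divergence dominated by the shared ancestral coalescent,
  # but cross-deme pairs are still at least as diverged as within-deme pairs
  expect_gte(between, within * 0.8)
})

test_that("Gillespie paths without recombination coalesce jointly", {
  p <- im_parameters(0.0005, 0.001, 1000, 0, 250)
  disc <- discretize_time(p)
  set.seed(2)
  g <- gillespie_two_nucleotide(p, disc, n_paths = 2000)
  expect_equal(sum(g$J), 1)
  expect_equal(sum(diag(g$counts)), 2000L)
  expect_true(all(g$times[, 1] == g$times[, 2]))
  expect_true(all(g$times[, 1] > p$tau1))
})
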