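# Discretization, interval matrices, the joint coalescence matrix and the
# HMM transition matrix.

test_that("discretization places equally spaced break points with an infinite tail", {
  p <- im_parameters(0.001, 0.002, 1000, 0.4, 100)
  d <- discretize_time(p, n_mig = 10, n_anc = 10, anc_span = 0.001)
  expect_equal(d$delta, 0.0001)
  expect_equal(d$n, 20L)
  expect_equal(d$breakpoints[11], 0.002)
  expect_true(all(diff(d$breakpoints[1:20]) > 0))
  expect_identical(d$breakpoints[21], Inf)
  expect_length(d$breakpoints, 21L)

  # default ancestral span adapts to the coalescence rate
  d2 <- discretize_time(p)
  expect_equal(d2$delta_anc, (3 / p$coal_anc) / 10)

  p_eq <- im_parameters(0.001, 0.001, 1000, 0.4, 100)
  expect_error(discretize_time(p_eq), "degenerate")
})

test_that("interval matrices are row-stochastic and match an ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- main_params()
  disc <- discretize_time(p)
  im <- interval_matrices(p, disc)
  for (i in seq_along(im$P))
    expect_lt(max(abs(rowSums(im$P[[i]]) - 1)), 1e-10)
  expect_equal(sum(im$a0), 1, tolerance = 1e-12)

  st <- build_epoch_stack(p)
  P_ode <- oracle_expm_ode(st$Q_mig, disc$delta)
  expect_lt(max(abs(im$P[[1]] - P_ode)), 1e-9)
})

test_that("interval matrices approach the identity as the interval width vanishes", {
  p <- im_parameters(0.0005, 0.0005 + 1e-9, 1000, 0.4, 100)
  im <- interval_matrices(p, discretize_time(p, 2, 2))
  expect_lt(max(abs(im$P[[1]] - diag(nrow(im$P[[1]])))), 1e-5)
})

test_that("joint matrix is a symmetric probability distribution", {
  p <- main_params()
  J <- joint_matrix(interval_matrices(p, discretize_time(p)))
  expect_equal(sum(J), 1, tolerance = 1e-8)
  expect_gte(min(J), 0)
  expect_lt(max(abs(J - t(J))), 1e-10)
})

test_that("without recombination the nucleotides always coalesce together", {
  p <- im_parameters(0.00025, 0.001, 1250, 0, 250)
  J <- joint_matrix(interval_matrices(p, discretize_time(p)))
  expect_lt(sum(J) - sum(diag(J)), 1e-10)
})

test_that("prefix-accumulator dynamic program equals the naive full-product sums", {
  hm <- toy_hmm()
  J_naive <- oracle_joint_naive(hm$im)
  expect_equal(hm$J, J_naive, tolerance = 1e-12)

  # and on an asymmetric discretization
  p <- main_params()
  im <- interval_matrices(p, discretize_time(p, n_mig = 3, n_anc = 2))
  expect_equal(joint_matrix(im), oracle_joint_naive(im), tolerance = 1e-12)
})

test_that("M = 0 reduces to the clean-split closed form", {
  p <- im_parameters(0.00025, 0.001, 1250, 0.4, 0)
  disc <- discretize_time(p)
  J <- joint_matrix(interval_matrices(p, disc))
  marg <- rowSums(J)
  # no coalescence before tau2
  expect_lt(sum(marg[1:10]), 1e-12)
  # ancestral interval masses are truncated-exponential integrals
  bp <- disc$breakpoints
  C <- p$coal
  expected <- exp(-C * (bp[11:20] - p$tau2)) - exp(-C * (bp[12:21] - p$tau2))
  expect_equal(marg[11:20], expected, tolerance = 1e-8)
})

test_that("strong migration approaches the half-rate panmictic exponential", {
  C <- 1250
  p <- im_parameters(0.0005, 0.002, C, 0.4, 2e5)
  disc <- discretize_time(p)
  m <- single_nuc_interval_masses(p, disc)
  bp <- disc$breakpoints
  ref <- exp(-(C / 2) * (bp[1:10] - bp[1])) - exp(-(C / 2) * (bp[2:11] - bp[1]))
  expect_lt(max(abs(m[1:10] / ref - 1)), 0.01)
})

test_that("joint marginals equal the independently computed one-nucleotide masses", {
  for (p in list(main_params(),
                 im_parameters(0.0005, 0.002, 800, 0.6, 1000))) {
    disc <- discretize_time(p)
    J <- joint_matrix(interval_matrices(p, disc))
    expect_equal(rowSums(J), single_nuc_interval_masses(p, disc),
                 tolerance = 1e-8)
  }
})

test_that("up-to matrices compose and stay row-stochastic", {
  p <- main_params()
  im <- interval_matrices(p, discretize_time(p, 4, 4))
  U14 <- imcoalhmm:::up_to_matrix(im, 1, 4)
  U12 <- imcoalhmm:::up_to_matrix(im, 1, 2)
  U24 <- imcoalhmm:::up_to_matrix(im, 2, 4)
  expect_equal(U14, U12 %*% U24, tolerance = 1e-12)
  expect_identical(imcoalhmm:::up_to_matrix(im, 3, 3), diag(nrow(U24)))
  expect_lt(max(abs(rowSums(U14) - 1)), 1e-10)
})

test_that("HMM transition matrix is row-stochastic and in detailed balance", {
  p <- main_params()
  J <- joint_matrix(interval_matrices(p, discretize_time(p)))
  ht <- hmm_transition(J)
  expect_lt(max(abs(rowSums(ht$T) - 1)), 1e-8)
  expect_equal(sum(ht$pi), 1, tolerance = 1e-8)
  D <- ht$pi * ht$T  # pi_i T_ij
  expect_lt(max(abs(D - t(D))), 1e-10)
  # stationarity
  expect_equal(as.numeric(ht$pi %*% ht$T), ht$pi, tolerance = 1e-10)
})

test_that("no recombination gives an identity transition matrix", {
  p <- im_parameters(0.00025, 0.001, 1250, 0, 250)
  ht <- hmm_transition(joint_matrix(interval_matrices(p, discretize_time(p))))
  expect_lt(max(abs(ht$T - diag(20))), 1e-8)
})

test_that("the isolation-model discretization uses coalescent quantiles", {
  d <- discretize_isolation <- imcoalhmm:::discretize_isolation(0.001, 1000, 20)
  expect_equal(d$n_mig, 0L)
  expect_equal(d$breakpoints[1], 0.001)
  # equal conditional mass per finite interval
  mass <- exp(-1000 * (d$breakpoints[1:20] - 0.001)) -
    exp(-1000 * (d$breakpoints[2:21] - 0.001))
  expect_equal(mass, rep(1 / 20, 20), tolerance = 1e-10)
})
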