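# Generative enumeration of the structured-coalescent state spaces and the
# epoch rate matrices.

two_nuc_init <- function() list(lineage(1, 1, 0), lineage(2, 2, 1))

test_that("two-nucleotide enumeration matches an independent brute-force closure", {
  sp <- enumerate_state_space(two_nuc_init(), n_demes = 2, allow_migration = TRUE)
  oracle <- oracle_closure(c("l1r1d0", "l2r2d1"), n_demes = 2L, allow_mig = TRUE)
  keys <- sort(vapply(sp$states, oracle_key_of_state, character(1L)))
  expect_identical(keys, oracle$states)
  expect_identical(nrow(sp$edges), oracle$n_edges)
  # regression constants for the documented spaces
  expect_length(sp$states, 94L)
  expect_identical(nrow(sp$edges), 452L)
  expect_identical(as.integer(table(sp$class)[c("B", "L", "R", "E")]),
                   c(56L, 16L, 16L, 6L))
})

test_that("isolated and single-nucleotide spaces match the brute-force closure", {
  iso <- enumerate_state_space(two_nuc_init(), n_demes = 2, allow_migration = FALSE)
  o_iso <- oracle_closure(c("l1r1d0", "l2r2d1"), 2L, FALSE)
  expect_identical(sort(vapply(iso$states, oracle_key_of_state, character(1L))),
                   o_iso$states)
  expect_length(iso$states, 4L)  # each deme independently linked or split

  one <- enumerate_state_space(list(lineage(1, 0, 0), lineage(2, 0, 1)),
                               n_demes = 2, allow_migration = TRUE)
  o_one <- oracle_closure(c("l1r0d0", "l2r0d1"), 2L, TRUE)
  expect_identical(sort(vapply(one$states, oracle_key_of_state, character(1L))),
                   o_one$states)
  expect_length(one$states, 6L)
})

test_that("single-deme single-nucleotide system has exactly two configurations", {
  sp <- enumerate_state_space(list(lineage(1, 0, 0), lineage(2, 0, 0)),
                              n_demes = 1, allow_migration = FALSE)
  expect_length(sp$states, 2L)
  expect_setequal(sp$edges$kind, "COALESCENCE")
})

test_that("disabling migration produces no migration edges", {
  sp <- enumerate_state_space(two_nuc_init(), n_demes = 2, allow_migration = FALSE)
  expect_false(any(sp$edges$kind == "MIGRATION"))
})

test_that("enumeration is independent of initial-state presentation order", {
  a <- enumerate_state_space(two_nuc_init(), 2, TRUE)
  b <- enumerate_state_space(rev(two_nuc_init()), 2, TRUE)
  expect_identical(a$keys, b$keys)
  expect_identical(a$edges, b$edges)
})

test_that("malformed initial states are rejected", {
  expect_error(enumerate_state_space(list(lineage(1, 1, 0), lineage(1, 2, 1)), 2, TRUE),
               "not a partition")
  expect_error(enumerate_state_space(list(lineage(1, 1, 0)), 2, TRUE),
               "cover both samples")
  expect_error(lineage(0, 0, 0), "ancestral material")
})

test_that("rate matrices have zero row sums, absorbing E rows and additive rates", {
  sp <- enumerate_state_space(two_nuc_init(), 2, TRUE)
  Q <- build_rate_matrix(sp, epoch_rates(coal = c(1000, 2000), rec = 0.5, mig = 120))
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  off <- Q - diag(diag(Q))
  expect_gte(min(off), 0)
  expect_true(all(Q[sp$class == "E", ] == 0))
  expect_error(build_rate_matrix(sp, list(coal = -1, rec = 0, mig = 0)),
               "non-negative")
})

test_that("simple systems give the textbook rates", {
  # one-nucleotide two-lineage single-deme system: pair coalesces at rate C
  sp1 <- enumerate_state_space(list(lineage(1, 0, 0), lineage(2, 0, 0)), 1, FALSE)
  Q1 <- build_rate_matrix(sp1, epoch_rates(coal = 321))
  from <- which(vapply(sp1$states, length, integer(1L)) == 2L)
  to <- which(vapply(sp1$states, length, integer(1L)) == 1L)
  expect_equal(Q1[from, to], 321)

  # two fully linked lineages in one deme: diagonal is -(C + 2R)
  sp2 <- enumerate_state_space(list(lineage(1, 1, 0), lineage(2, 2, 0)), 1, FALSE)
  Q2 <- build_rate_matrix(sp2, epoch_rates(coal = 1000, rec = 0.4))
  i0 <- sp2$index[[imcoalhmm:::serialize_state(list(lineage(1, 1, 0), lineage(2, 2, 0)))]]
  expect_equal(Q2[i0, i0], -(1000 + 2 * 0.4))
})

test_that("epoch stack bridges behave as relabellings", {
  p <- main_params()
  st <- build_epoch_stack(p)
  sp <- st$spaces
  expect_true(all(rowSums(st$injection) == 1))
  expect_true(all(rowSums(st$projection) == 1))

  # projection is invariant under swapping the demes of a migration state
  swap <- function(state) lapply(state, function(l) c(l[1], l[2], 1L - l[3]))
  for (i in seq_along(sp$mig$states)) {
    key <- imcoalhmm:::serialize_state(swap(sp$mig$states[[i]]))
    j <- sp$mig$index[[key]]
    expect_identical(which(st$projection[i, ] == 1),
                     which(st$projection[j, ] == 1))
  }

  # with M = 0 the migration-epoch generator restricted to the injected
  # isolated states equals the isolated generator
  st0 <- build_epoch_stack(im_parameters(0.00025, 0.001, 1250, 0.4, 0))
  iso_in_mig <- apply(st0$injection, 1, which.max)
  expect_equal(st0$Q_mig[iso_in_mig, iso_in_mig], st0$Q_iso,
               tolerance = 1e-14, ignore_attr = TRUE)

  # ancestral generator equals a directly built one-deme system
  direct <- enumerate_state_space(
    lapply(sp$mig$states[[sp$mig$index[[imcoalhmm:::serialize_state(
      list(lineage(1, 1, 0), lineage(2, 2, 1)))]]]],
      function(l) c(l[1], l[2], 0L)),
    n_demes = 1, allow_migration = FALSE)
  Qd <- build_rate_matrix(direct, epoch_rates(p$coal_anc, p$rec))
  shared <- match(direct$keys, sp$anc$keys)
  expect_true(!anyNA(shared))
  expect_equal(st$Q_anc[shared, shared], Qd, tolerance = 1e-14,
               ignore_attr = TRUE)
})

test_that("left-side marginal of the two-nucleotide chain matches the one-nucleotide chain", {
  p <- main_params()
  st2 <- build_epoch_stack(p, n_nuc = 2L)
  st1 <- build_epoch_stack(p, n_nuc = 1L)
  iota2 <- numeric(length(st2$spaces$mig$states))
  iota2[which(st2$injection[st2$initial_iso, ] == 1)] <- 1
  iota1 <- numeric(length(st1$spaces$mig$states))
  iota1[which(st1$injection[st1$initial_iso, ] == 1)] <- 1
  for (t in c(1e-4, 5e-4, 2e-3)) {
    p2 <- iota2 %*% as.matrix(Matrix::expm(st2$Q_mig * t))
    p1 <- iota1 %*% as.matrix(Matrix::expm(st1$Q_mig * t))
    left_done2 <- sum(p2[st2$spaces$mig$class %in% c("L", "E")])
    done1 <- sum(p1[st1$spaces$mig$class != "B"])
    expect_equal(left_done2, done1, tolerance = 1e-8)
  }
})

test_that("state-space text export round-trips the canonical serialization", {
  sp <- enumerate_state_space(list(lineage(1, 0, 0), lineage(2, 0, 1)), 2, TRUE)
  path <- withr::local_tempfile(fileext = ".txt")
  write_state_space(sp, path)
  lines <- readLines(path)
  expect_length(lines, length(sp$states))
  expect_identical(vapply(strsplit(lines, "\t"), `[`, character(1L), 3L),
                   sp$keys)
})

test_that("Gillespie occupancy of the migration-epoch chain matches expm", {
  p <- main_params()
  disc <- discretize_time(p)
  set.seed(42)
  g <- gillespie_two_nucleotide(p, disc, n_paths = 2e4)
  # occupancy check via coalescence-time marginals: P(left coalesced by tau2)
  st <- build_epoch_stack(p)
  iota <- numeric(length(st$spaces$mig$states))
  iota[which(st$injection[st$initial_iso, ] == 1)] <- 1
  pvec <- iota %*% as.matrix(Matrix::expm(st$Q_mig * (p$tau2 - p$tau1)))
  p_theory <- sum(pvec[st$spaces$mig$class %in% c("L", "E")])
  p_emp <- mean(g$times[, 1] < p$tau2)
  se <- sqrt(p_theory * (1 - p_theory) / 2e4)
  expect_lt(abs(p_emp - p_theory), 4 * se)
})
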