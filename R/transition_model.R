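# Time discretization, per-interval CTMC probability matrices, the joint
# coalescence-interval distribution J(i, j), and the HMM transition matrix.

#' Discretize time for the isolation-with-migration model
#'
#' Break points are equally spaced: `n_mig` intervals of width
#' `delta = (tau2 - tau1) / n_mig` covering the migration epoch
#' `[tau1, tau2]`, followed by `n_anc` intervals in the ancestral epoch, the
#' last of which is unbounded.  The finite ancestral intervals span
#' `anc_span`, by default `3 / coal_anc` so that they cover about 95% of
#' the ancestral coalescence mass whatever the epoch geometry; pass
#' `anc_span = tau2 - tau1` to reuse the migration-epoch width throughout.
#'
#' @param params An [im_parameters()] object with `tau2 > tau1`.
#' @param n_mig,n_anc Number of intervals in the migration and ancestral
#'   epochs (defaults 10 and 10, i.e. 20 hidden states).
#' @param anc_span Total finite span of the ancestral intervals
#'   (default `3 / coal_anc`).
#' @return An object of class `im_discretization`: `breakpoints` (length
#'   `n + 1`, last `Inf`), `n`, `n_mig`, `n_anc`, `delta`, `delta_anc`.
#' @export
discretize_time <- function(params, n_mig = 10L, n_anc = 10L, anc_span = NULL) {
  n_mig <- as.integer(n_mig); n_anc <- as.integer(n_anc)
  stopifnot(n_mig >= 1L, n_anc >= 1L)
  if (params$tau2 <= params$tau1)
    stop("degenerate migration epoch: tau2 must exceed tau1")
  delta <- (params$tau2 - params$tau1) / n_mig
  if (is.null(anc_span)) anc_span <- 3 / params$coal_anc
  delta_anc <- anc_span / n_anc
  bp <- c(params$tau1 + delta * seq(0L, n_mig),
          params$tau2 + delta_anc * seq_len(n_anc - 1L), Inf)
  structure(list(breakpoints = bp, n = n_mig + n_anc, n_mig = n_mig,
                 n_anc = n_anc, delta = delta, delta_anc = delta_anc),
            class = "im_discretization")
}

# Discretization for the clean-split isolation (I) model: a single split at
# tau followed by n intervals whose finite break points are exponential
# coalescent quantiles under rate coal_anc (equal prior mass per interval).
discretize_isolation <- function(tau, coal_anc, n_intervals = 20L) {
  n <- as.integer(n_intervals)
  stopifnot(n >= 1L, tau > 0, coal_anc > 0)
  q <- -log(1 - seq(0L, n - 1L) / n) / coal_anc
  structure(list(breakpoints = c(tau + q, Inf), n = n, n_mig = 0L, n_anc = n,
                 delta = NA_real_, delta_anc = NA_real_),
            class = "im_discretization")
}

expm_mat <- function(Q, t) {
  P <- as.matrix(Matrix::expm(Q * t))
  if (any(!is.finite(P)))
    stop("matrix exponential produced non-finite entries (t = ", t, ")")
  P
}

#' Per-interval CTMC probability matrices
#'
#' Computes, for every finite time interval of a discretization, the CTMC
#' probability matrix across that interval, composed with the epoch bridges
#' where an interval abuts an epoch boundary: the matrix entering the first
#' interval is prefixed by the isolated-epoch factor
#' `expm(Q_iso * tau1) %*% injection`, and the matrix leaving the last
#' migration-epoch interval is suffixed by the projection onto the ancestral
#' state space.  The final (unbounded) interval has no finite matrix; its
#' absorption is handled in [joint_matrix()].
#'
#' @param params An [im_parameters()] object.
#' @param disc An `im_discretization`.
#' @param stack Optional pre-built [build_epoch_stack()] result.
#' @return A list with `a0` (state distribution at the first break point),
#'   `P` (list of `n - 1` interval matrices, entry `i` mapping the start of
#'   interval `i` to the start of interval `i + 1`), `spaces` (state-space
#'   id, `"mig"` or `"anc"`, at the start of each interval) and `classes`
#'   (per-interval B/L/R/E state classes).
#' @export
interval_matrices <- function(params, disc, stack = NULL) {
  if (is.null(stack)) stack <- build_epoch_stack(params)
  sp <- stack$spaces
  n <- disc$n; n_mig <- disc$n_mig
  bp <- disc$breakpoints

  # state distribution at the first break point (no coalescence is possible
  # while the samples sit in different isolated demes, only recombination)
  iota <- numeric(length(sp$iso$states)); iota[stack$initial_iso] <- 1
  if (n_mig > 0L) {
    a0 <- (iota %*% expm_mat(stack$Q_iso, bp[1L])) %*% stack$injection
    P_mig <- expm_mat(stack$Q_mig, disc$delta)
  } else {
    a0 <- ((iota %*% expm_mat(stack$Q_iso, bp[1L])) %*% stack$injection) %*%
      stack$projection
  }

  P <- vector("list", n - 1L)
  spaces <- character(n)
  anc_cache <- new.env(parent = emptyenv())
  P_anc <- function(w) {
    key <- sprintf("%.17g", w)
    if (is.null(anc_cache[[key]]))
      anc_cache[[key]] <- expm_mat(stack$Q_anc, w)
    anc_cache[[key]]
  }
  for (i in seq_len(n)) {
    spaces[i] <- if (i <= n_mig) "mig" else "anc"
    if (i == n) break
    P[[i]] <- if (i < n_mig) {
      P_mig
    } else if (i == n_mig) {
      P_mig %*% stack$projection
    } else {
      P_anc(bp[i + 1L] - bp[i])
    }
  }
  classes <- lapply(spaces, function(s) sp[[s]]$class)
  list(a0 = drop(a0), P = P, spaces = spaces, classes = classes, disc = disc)
}

# Transition probabilities from the start of interval i to the start of
# interval j (i <= j) by multiplying interval matrices.
up_to_matrix <- function(im, i, j) {
  stopifnot(i >= 1L, j <= length(im$P) + 1L, i <= j)
  n_states <- length(im$classes[[i]])
  U <- diag(n_states)
  if (j > i) for (k in i:(j - 1L)) U <- U %*% im$P[[k]]
  U
}

#' Joint coalescence-interval distribution
#'
#' `J[i, j]` is the probability that the left nucleotide of the pair finds
#' its MRCA in time interval `i` and the right nucleotide in interval `j`,
#' starting from two doubly linked sampled lineages in separate demes.  The
#' sum over paths (stay in class B until interval `i`, enter L within it,
#' remain in L, absorb into E within interval `j`; symmetrically through R
#' for `i > j`) is evaluated with prefix accumulators over intervals rather
#' than full interval-product sums.  In the final, unbounded interval every
#' surviving lineage pair coalesces with probability 1.
#'
#' @param im The result of [interval_matrices()].
#' @return An `n` by `n` matrix with non-negative entries summing to 1.
#' @export
joint_matrix <- function(im) {
  n <- im$disc$n
  cls <- im$classes
  J <- matrix(0, n, n)

  iB <- lapply(cls, function(x) which(x == "B"))
  iL <- lapply(cls, function(x) which(x == "L"))
  iR <- lapply(cls, function(x) which(x == "R"))
  iE <- lapply(cls, function(x) which(x == "E"))

  a <- im$a0[iB[[1L]]]
  if (abs(sum(im$a0) - 1) > 1e-9 || abs(sum(a) - 1) > 1e-9)
    stop("initial interval distribution is not concentrated on class B")

  WL <- matrix(0, 0L, length(iL[[1L]]))  # rows: w vectors of earlier intervals
  WR <- matrix(0, 0L, length(iR[[1L]]))
  for (j in seq_len(n)) {
    if (j == n) {
      if (nrow(WL)) J[seq_len(j - 1L), j] <- rowSums(WL)
      if (nrow(WR)) J[j, seq_len(j - 1L)] <- rowSums(WR)
      J[n, n] <- sum(a)
      break
    }
    Pj <- im$P[[j]]
    PBL <- Pj[iB[[j]], iL[[j + 1L]], drop = FALSE]
    PBR <- Pj[iB[[j]], iR[[j + 1L]], drop = FALSE]
    PBB <- Pj[iB[[j]], iB[[j + 1L]], drop = FALSE]
    PBE <- Pj[iB[[j]], iE[[j + 1L]], drop = FALSE]
    PLL <- Pj[iL[[j]], iL[[j + 1L]], drop = FALSE]
    PLE <- Pj[iL[[j]], iE[[j + 1L]], drop = FALSE]
    PRR <- Pj[iR[[j]], iR[[j + 1L]], drop = FALSE]
    PRE <- Pj[iR[[j]], iE[[j + 1L]], drop = FALSE]

    if (nrow(WL)) {
      J[seq_len(j - 1L), j] <- as.numeric(WL %*% rowSums(PLE))
      WL <- WL %*% PLL
    } else WL <- matrix(0, 0L, ncol(PLL))
    if (nrow(WR)) {
      J[j, seq_len(j - 1L)] <- as.numeric(WR %*% rowSums(PRE))
      WR <- WR %*% PRR
    } else WR <- matrix(0, 0L, ncol(PRR))

    J[j, j] <- sum(a %*% PBE)
    WL <- rbind(WL, a %*% PBL)
    WR <- rbind(WR, a %*% PBR)
    a <- drop(a %*% PBB)
  }
  if (any(J < -1e-12)) stop("negative entry in joint coalescence matrix")
  J[J < 0] <- 0
  J
}

#' HMM transition matrix and initial distribution from J
#'
#' The hidden Markov chain over coalescence intervals has transition
#' probabilities `T[i, j] = J[i, j] / pi[i]` with `pi[i] = sum_j J[i, j]`.
#' By the left/right symmetry of J, `pi` is also the stationary distribution
#' of `T` and the chain is in detailed balance.  Rows with vanishing
#' marginal mass (below 1e-300, visited only in pathological parameter
#' corners) fall back to a uniform row with a warning.
#'
#' @param J A joint coalescence matrix from [joint_matrix()].
#' @return A list with `T` (row-stochastic matrix) and `pi`.
#' @export
hmm_transition <- function(J) {
  pi <- rowSums(J)
  n <- length(pi)
  Tm <- J / pi
  bad <- pi < 1e-300
  if (any(bad)) {
    warning("zero-mass hidden state(s): uniform transition row substituted")
    Tm[bad, ] <- 1 / n
  }
  list(T = Tm, pi = pi)
}
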