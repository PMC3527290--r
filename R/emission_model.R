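# Emission probabilities: end-conditioned mean coalescence times per hidden
# interval, mapped to Jukes-Cantor alignment-column probabilities.
#
# The single-nucleotide-per-genome CTMC mirrors the epoch structure of the
# two-nucleotide system.  In the migration epoch the coalescence density is
# shaped by the interplay of migration and coalescence, and interval means
# are computed spectrally; ancestral intervals reduce to truncated
# exponentials with closed-form means.

# Single-nucleotide migration-epoch chain with all coalesced states lumped
# into one absorbing state (an exact lumping: the coalesced class is a trap
# and its internal structure is irrelevant).  Cached; rates applied per call.
single_nuc_lumped <- function(params) {
  sp <- epoch_state_spaces(1L)
  Q <- build_rate_matrix(sp$mig, epoch_rates(params$coal, 0, params$mig))
  coal <- which(sp$mig$class != "B")  # left side at MRCA = coalesced
  not <- which(sp$mig$class == "B")
  m <- length(not)
  Ql <- matrix(0, m + 1L, m + 1L)
  Ql[seq_len(m), seq_len(m)] <- Q[not, not, drop = FALSE]
  Ql[seq_len(m), m + 1L] <- rowSums(Q[not, coal, drop = FALSE])
  diag(Ql)[seq_len(m)] <- 0
  diag(Ql) <- -rowSums(Ql)
  # initial state: sample 1 in deme 0, sample 2 in deme 1 (the isolated
  # epoch is inert for a single nucleotide: no event can occur)
  init_key <- serialize_state(list(lineage(1, 0, 0), lineage(2, 0, 1)))
  a0 <- numeric(m + 1L)
  a0[match(unname(sp$mig$index[init_key]), not)] <- 1
  list(Q = Ql, m = m, a0 = a0)
}

#' Interval coalescence probabilities of the single-nucleotide system
#'
#' The probability that a single nucleotide pair (one per genome) coalesces
#' within each interval of the discretization, computed from the
#' single-nucleotide CTMC with the same epoch composition as the
#' two-nucleotide transition system.  These equal the row sums of the joint
#' coalescence matrix and serve as an independent cross-check of it.
#'
#' @param params An [im_parameters()] object.
#' @param disc An `im_discretization`.
#' @return Numeric vector of interval masses summing to 1.
#' @export
single_nuc_interval_masses <- function(params, disc) {
  state <- single_nuc_state_dists(params, disc)
  state$mass
}

# Distribution of the (lumped) single-nucleotide chain at each interval
# start, plus per-interval coalescence masses.  For ancestral intervals the
# chain is a plain exponential with rate coal_anc.
single_nuc_state_dists <- function(params, disc) {
  n <- disc$n; n_mig <- disc$n_mig
  bp <- disc$breakpoints
  mass <- numeric(n)
  alive <- 1  # P(not yet coalesced) at current interval start
  alpha <- NULL; mig <- NULL; Pd <- NULL
  alpha_list <- vector("list", n)
  if (n_mig > 0L) {
    mig <- single_nuc_lumped(params)
    Pd <- expm_mat(mig$Q, disc$delta)
    alpha <- mig$a0
    for (i in seq_len(n_mig)) {
      alpha_list[[i]] <- alpha
      nxt <- drop(alpha %*% Pd)
      mass[i] <- nxt[mig$m + 1L] - alpha[mig$m + 1L]
      alpha <- nxt
    }
    alive <- 1 - alpha[mig$m + 1L]
  }
  # ancestral epoch: exponential with rate coal_anc from tau2 onwards
  C <- params$coal_anc
  surv <- alive
  for (i in seq((n_mig + 1L), n)) {
    alpha_list[[i]] <- surv
    w <- bp[i + 1L] - bp[i]
    p <- if (is.finite(w)) surv * (1 - exp(-C * w)) else surv
    mass[i] <- p
    surv <- surv - p
  }
  list(mass = mass, alpha = alpha_list, mig = mig)
}

# integral of t * exp(lambda t) over [0, delta] (complex-safe)
time_weighted_exp_integral <- function(lambda, delta) {
  if (abs(lambda) < 1e-12) return(complex(real = delta^2 / 2, imaginary = 0))
  e <- exp(lambda * delta)
  (delta * e) / lambda - (e - 1) / lambda^2
}

#' End-conditioned mean coalescence times per interval
#'
#' For each hidden interval, the expected coalescence time of the
#' single-nucleotide system conditional on coalescing within that interval.
#' Migration-epoch intervals integrate `t` against the absorption density
#' via an eigendecomposition of the (lumped) rate matrix; because break
#' points are equally spaced, the spectral integrals are computed once and
#' reused across intervals.  If the eigenvector matrix is ill-conditioned
#' the integral falls back to adaptive quadrature of the same integrand.
#' Ancestral intervals use the truncated-exponential closed form
#' `a + 1/C - w * exp(-C w) / (1 - exp(-C w))`; the final unbounded interval
#' has mean `a + 1/C`.
#'
#' @param params An [im_parameters()] object.
#' @param disc An `im_discretization`.
#' @param cond_tol Condition-number threshold above which the spectral path
#'   is abandoned for quadrature.
#' @return A list with `mean` (per-interval means, increasing) and `mass`
#'   (interval coalescence probabilities).
#' @export
end_conditioned_means <- function(params, disc, cond_tol = 1e8) {
  n <- disc$n; n_mig <- disc$n_mig
  bp <- disc$breakpoints
  state <- single_nuc_state_dists(params, disc)
  means <- numeric(n)

  if (n_mig > 0L) {
    mig <- state$mig
    m <- mig$m
    Q <- mig$Q
    q_abs <- Q[seq_len(m), m + 1L]  # absorption rates from transient states
    eg <- eigen(Q)
    use_spectral <- is.finite(rcond(eg$vectors)) && rcond(eg$vectors) > 1 / cond_tol
    if (use_spectral) {
      V <- eg$vectors; Vi <- solve(V)
      lam <- eg$values
      # G[s] = E[ t * 1{absorbed within delta} | start s ], s transient
      I_lam <- vapply(lam, time_weighted_exp_integral, complex(1L), delta = disc$delta)
      w_k <- as.vector(Vi[, seq_len(m), drop = FALSE] %*% q_abs)  # per eigenmode
      G_full <- V %*% (I_lam * w_k)
      if (max(abs(Im(G_full))) > 1e-9)
        stop("spectral interval integral has non-negligible imaginary part")
      G <- Re(G_full)[seq_len(m)]
    } else {
      message("ill-conditioned eigenvectors: falling back to quadrature for interval means")
      dens <- function(u, s) {
        vapply(u, function(t1) {
          P <- expm_mat(Q, t1)
          sum(P[s, seq_len(m)] * q_abs)
        }, numeric(1L))
      }
      G <- vapply(seq_len(m), function(s)
        stats::integrate(function(u) u * dens(u, s), 0, disc$delta,
                         rel.tol = 1e-10)$value, numeric(1L))
    }
    for (i in seq_len(n_mig)) {
      alpha <- state$alpha[[i]][seq_len(m)]
      num <- sum(alpha * G)
      # the end-conditioned mean provably lies inside its interval; at
      # negligible interval mass the ratio num/mass loses all precision to
      # cancellation (and the hidden state has ~zero prior anyway), so
      # clamp into the interval with a midpoint fallback
      mi <- bp[i] + num / state$mass[i]
      if (!is.finite(mi) || mi <= bp[i] || mi >= bp[i + 1L])
        mi <- bp[i] + disc$delta / 2
      means[i] <- mi
    }
  }
  C <- params$coal_anc
  for (i in seq((n_mig + 1L), n)) {
    a <- bp[i]; w <- bp[i + 1L] - a
    means[i] <- if (is.finite(w))
      a + 1 / C - w * exp(-C * w) / (1 - exp(-C * w))
    else
      a + 1 / C
  }
  list(mean = means, mass = state$mass)
}

#' Jukes-Cantor emission matrix
#'
#' Maps per-interval mean coalescence times to alignment-column
#' probabilities under the Jukes-Cantor substitution model.  The mean is a
#' per-lineage divergence time, so the tree connecting the two sequences has
#' total length `2 * mean` and the mismatch probability is
#' `p = (3/4) * (1 - exp(-(8/3) * mean))`.  Missing data emits probability 1
#' in every state: it carries no information but preserves the positional
#' structure of the chain across assembly gaps.
#'
#' @param means Vector of per-interval mean coalescence times (or the result
#'   of [end_conditioned_means()]).
#' @return An `n` by 3 matrix with columns `IDENTICAL`, `DIFFERENT`,
#'   `MISSING`.
#' @export
jc_emissions <- function(means) {
  if (is.list(means)) means <- means$mean
  p <- 0.75 * (1 - exp(-(8 / 3) * means))
  cbind(IDENTICAL = 1 - p, DIFFERENT = p, MISSING = rep(1, length(p)))
}
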