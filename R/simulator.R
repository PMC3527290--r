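# Exact (non-Markov-approximated) backwards-in-time simulation of the
# coalescent with recombination and migration over discrete sites, plus
# Jukes-Cantor sequence emission and the robustness perturbations used in
# the validation studies.
#
# Lineages carry ancestral-material segments over sites 1..L with a bitmask
# recording which present-day samples each segment is ancestral to.
# Recombination acts on every link spanned by a lineage's material
# (including trapped non-ancestral stretches), so the simulated process is
# the full coalescent with recombination, not its sequential Markov
# approximation.

#' Simulation configuration
#'
#' @param params An [im_parameters()] object; all rates in substitution
#'   units as in the inference model.
#' @param L Sequence length in base pairs (`>= 2`).
#' @param n_per_deme Haploid samples per deme: 1 (default) or 2 (for the
#'   unknown-phase experiments).
#' @param seed Mandatory integer seed.
#' @param mut_multipliers Optional per-site mutation-rate multipliers
#'   (length `L`), e.g. from [perturb_mutation_rate()].
#' @param rec_multipliers Optional per-link recombination-rate multipliers
#'   (length `L - 1`), e.g. from [random_rec_map()].
#' @return An object of class `im_sim_config`.
#' @export
sim_config <- function(params, L, n_per_deme = 1L, seed,
                       mut_multipliers = NULL, rec_multipliers = NULL) {
  stopifnot(inherits(params, "im_parameters"), L >= 2, n_per_deme %in% 1:2)
  if (missing(seed)) stop("a seed is mandatory for reproducible simulations")
  if (!is.null(mut_multipliers)) stopifnot(length(mut_multipliers) == L,
                                           all(mut_multipliers >= 0))
  if (!is.null(rec_multipliers)) stopifnot(length(rec_multipliers) == L - 1,
                                           all(rec_multipliers >= 0))
  structure(list(params = params, L = as.integer(L),
                 n_per_deme = as.integer(n_per_deme), seed = as.integer(seed),
                 mut_multipliers = mut_multipliers,
                 rec_multipliers = rec_multipliers),
            class = "im_sim_config")
}

#' Geometric-block mutation-rate multipliers
#'
#' Splits the sequence into blocks with geometrically distributed lengths
#' and draws one uniform rate multiplier per block.
#'
#' @param L Sequence length.
#' @param mean_block Mean block length in bp (`>= 1`).
#' @param range Two-element factor range, e.g. `c(0.5, 1.5)`.
#' @return Numeric vector of length `L`.
#' @export
perturb_mutation_rate <- function(L, mean_block = 500, range = c(0.5, 1.5)) {
  stopifnot(mean_block >= 1, length(range) == 2L, all(range > 0))
  lens <- integer(0L)
  while (sum(lens) < L)
    lens <- c(lens, stats::rgeom(max(64L, ceiling(L / mean_block)),
                                 1 / mean_block) + 1L)
  lens <- lens[cumsum(lens) - lens < L]
  fac <- stats::runif(length(lens), range[1L], range[2L])
  rep(fac, lens)[seq_len(L)]
}

#' Synthetic autocorrelated recombination-map multipliers
#'
#' Generates per-link rate multipliers from an AR(1) process on the log
#' scale at a coarse block resolution, mimicking the broad-scale variation
#' of empirical recombination maps; multipliers are normalized to mean 1.
#'
#' @param L Sequence length (multipliers cover `L - 1` links).
#' @param block Block size in bp over which the rate is constant.
#' @param sd_log Marginal standard deviation of the log multiplier.
#' @param ar Autocorrelation between neighbouring blocks.
#' @return Numeric vector of length `L - 1`.
#' @export
random_rec_map <- function(L, block = 10000L, sd_log = 1, ar = 0.7) {
  n_blocks <- ceiling((L - 1) / block)
  z <- numeric(n_blocks)
  z[1L] <- stats::rnorm(1L, 0, sd_log)
  if (n_blocks > 1L) for (i in 2:n_blocks)
    z[i] <- ar * z[i - 1L] + stats::rnorm(1L, 0, sd_log * sqrt(1 - ar^2))
  m <- rep(exp(z), each = block)[seq_len(L - 1L)]
  m / mean(m)
}

## -- ARG engine -----------------------------------------------------------

# segment bookkeeping: matrix with columns (a, b, set); rows sorted by a
seg_span_weight <- function(segs, Sr) {
  if (nrow(segs) == 0L) return(0)
  a <- min(segs[, 1L]); b <- max(segs[, 2L])
  if (b <= a) return(0)
  Sr[b] - Sr[a]  # sum of link multipliers over links a..b-1
}

seg_site_weight <- function(segs, Sm) {
  if (nrow(segs) == 0L) return(0)
  sum(Sm[segs[, 2L] + 1L] - Sm[segs[, 1L]])
}

# merge two segment lists at a coalescence; returns new segments plus the
# sub-intervals where the union first covers `pair_mask` (track pair MRCA)
merge_lineage_segments <- function(A, B, full_mask, pair_mask) {
  pts <- sort(unique(c(A[, 1L], A[, 2L] + 1L, B[, 1L], B[, 2L] + 1L)))
  n_int <- length(pts) - 1L
  starts <- pts[-length(pts)]
  ends <- pts[-1L] - 1L
  cover <- function(S, q) {
    # set mask of S covering each query interval start (intervals never
    # straddle a segment boundary by construction of pts)
    idx <- findInterval(q, S[, 1L])
    m <- integer(length(q))
    ok <- idx >= 1L
    ok[ok] <- q[ok] <= S[idx[ok], 2L]
    m[ok] <- S[idx[ok], 3L]
    m
  }
  sA <- cover(A, starts); sB <- cover(B, starts)
  u <- bitwOr(sA, sB)
  keep <- u != 0L & u != full_mask
  pair_new <- bitwAnd(u, pair_mask) == pair_mask &
    bitwAnd(sA, pair_mask) != pair_mask & bitwAnd(sB, pair_mask) != pair_mask
  segs <- cbind(a = starts[keep], b = ends[keep], set = u[keep])
  # fuse adjacent rows with equal set
  if (nrow(segs) > 1L) {
    fuse <- segs[-1L, 1L] == segs[-nrow(segs), 2L] + 1L &
      segs[-1L, 3L] == segs[-nrow(segs), 3L]
    if (any(fuse)) {
      grp <- cumsum(c(TRUE, !fuse))
      first <- !duplicated(grp)
      last <- !duplicated(grp, fromLast = TRUE)
      segs <- cbind(a = segs[first, 1L], b = segs[last, 2L],
                    set = segs[first, 3L])
    }
  }
  list(segs = segs,
       pair_starts = starts[pair_new], pair_ends = ends[pair_new])
}

# binary search on a prefix-sum vector: s in [lo, hi] with S[s] < u <= S[s+1]
# (findInterval re-validates the whole prefix vector per call, which is
# O(L); this search is O(log L) per event)
prefix_search <- function(S, u, lo, hi) {
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (S[mid + 1L] >= u) hi <- mid else lo <- mid + 1L
  }
  lo
}

# weighted site pick inside a lineage via the global prefix sums
pick_site <- function(segs, Sm, uniform) {
  if (uniform) {
    w <- segs[, 2L] - segs[, 1L] + 1L
    r <- which(stats::runif(1L) * sum(w) <= cumsum(w))[1L]
    return(segs[r, 1L] + min(w[r] - 1L, floor(stats::runif(1L) * w[r])))
  }
  w <- Sm[segs[, 2L] + 1L] - Sm[segs[, 1L]]
  r <- which(stats::runif(1L) * sum(w) <= cumsum(w))[1L]
  a <- segs[r, 1L]
  u <- stats::runif(1L) * w[r] + Sm[a]
  prefix_search(Sm, u, a, segs[r, 2L])
}

pick_link <- function(segs, Sr, uniform) {
  a <- min(segs[, 1L]); b <- max(segs[, 2L])
  if (uniform)
    return(a + min(b - a - 1L, floor(stats::runif(1L) * (b - a))))
  u <- stats::runif(1L) * (Sr[b] - Sr[a]) + Sr[a]
  prefix_search(Sr, u, a, b - 1L)
}

#' Simulate an ancestral recombination graph under the two-deme IM model
#'
#' Exact event-driven backwards simulation: within-deme pairwise
#' coalescence at the coalescence rate, recombination on every spanned
#' link, symmetric migration during `[tau1, tau2]` only, and a merge of the
#' demes at `tau2` (the ancestral population uses `coal_anc`).  The
#' per-site time to most recent common ancestor of the first sample of each
#' deme is recorded, and, when requested, Jukes-Cantor mutation events are
#' placed on the graph as it is built.
#'
#' @param config An [sim_config()] object.
#' @param record_mutations Record mutation events on the graph (required to
#'   emit sequences for more than one sample per deme; implied by
#'   `n_per_deme = 2`).
#' @return An object of class `im_arg`: `track` (data frame `start`, `end`,
#'   `time`: the piecewise-constant TMRCA of the cross-deme pair),
#'   `mutations` (data frame `site`, `set`, `time`, if recorded),
#'   `n_events` (per event kind) and the configuration.
#' @export
simulate_arg <- function(config, record_mutations = config$n_per_deme > 1L) {
  stopifnot(inherits(config, "im_sim_config"))
  set.seed(config$seed)
  p <- config$params
  L <- config$L
  npd <- config$n_per_deme
  n_samples <- 2L * npd
  full_mask <- bitwShiftL(1L, n_samples) - 1L
  pair_mask <- bitwOr(1L, bitwShiftL(1L, npd))  # first sample of each deme

  mut_m <- config$mut_multipliers
  unif_mut <- is.null(mut_m)
  Sm <- c(0, cumsum(if (unif_mut) rep(1, L) else mut_m))
  rec_m <- config$rec_multipliers
  unif_rec <- is.null(rec_m)
  Sr <- c(0, cumsum(if (unif_rec) rep(1, L - 1L) else rec_m))

  lins <- list()
  for (s in seq_len(n_samples)) {
    lins[[s]] <- list(
      segs = cbind(a = 1L, b = L, set = bitwShiftL(1L, s - 1L)),
      deme = if (s <= npd) 0L else 1L)
  }
  rec_w <- vapply(lins, function(x) seg_span_weight(x$segs, Sr), numeric(1L))
  mut_w <- vapply(lins, function(x) seg_site_weight(x$segs, Sm), numeric(1L))

  tr_s <- integer(0L); tr_e <- integer(0L); tr_t <- numeric(0L)
  mu_site <- integer(0L); mu_set <- integer(0L); mu_time <- numeric(0L)
  n_ev <- c(COALESCENCE = 0L, RECOMBINATION = 0L, MIGRATION = 0L)

  t <- 0
  repeat {
    if (length(lins) == 0L) break
    demes <- vapply(lins, `[[`, integer(1L), "deme")
    k0 <- sum(demes == 0L); k1 <- sum(demes == 1L)
    in_mig <- t >= p$tau1 && t < p$tau2
    anc <- t >= p$tau2
    coal_rate <- if (anc) p$coal_anc * k0 * (k0 - 1) / 2
      else p$coal * (k0 * (k0 - 1) + k1 * (k1 - 1)) / 2
    rec_rate <- p$rec * sum(rec_w)
    mig_rate <- if (in_mig) p$mig * length(lins) else 0
    total <- coal_rate + rec_rate + mig_rate
    bound <- if (t < p$tau1) p$tau1 else if (t < p$tau2) p$tau2 else Inf
    if (total <= 0 && !is.finite(bound))
      stop("stalled simulation: no events possible in the ancestral epoch")
    dt <- if (total > 0) stats::rexp(1L) / total else Inf
    step_end <- min(t + dt, bound)

    if (record_mutations && sum(mut_w) > 0 && step_end > t) {
      n_mut <- stats::rpois(1L, (step_end - t) * sum(mut_w))
      if (n_mut > 0L) {
        who <- sample.int(length(lins), n_mut, replace = TRUE, prob = mut_w)
        for (m in seq_len(n_mut)) {
          ln <- lins[[who[m]]]
          site <- pick_site(ln$segs, Sm, unif_mut)
          row <- which(ln$segs[, 1L] <= site & ln$segs[, 2L] >= site)[1L]
          mu_site <- c(mu_site, site)
          mu_set <- c(mu_set, ln$segs[row, 3L])
          mu_time <- c(mu_time, t + stats::runif(1L) * (step_end - t))
        }
      }
    }

    if (t + dt >= bound) {
      t <- bound
      if (t >= p$tau2) for (i in seq_along(lins)) lins[[i]]$deme <- 0L
      next
    }
    t <- t + dt
    u <- stats::runif(1L) * total
    if (u <= coal_rate) {
      n_ev["COALESCENCE"] <- n_ev["COALESCENCE"] + 1L
      # choose a deme proportionally to its pair count, then a random pair
      w0 <- if (anc) k0 * (k0 - 1) / 2 else k0 * (k0 - 1) / 2
      w1 <- if (anc) 0 else k1 * (k1 - 1) / 2
      d <- if (stats::runif(1L) * (w0 + w1) <= w0) 0L else 1L
      cand <- which(demes == d)
      ij <- sample(cand, 2L)
      mg <- merge_lineage_segments(lins[[ij[1L]]]$segs, lins[[ij[2L]]]$segs,
                                   full_mask, pair_mask)
      if (length(mg$pair_starts)) {
        tr_s <- c(tr_s, mg$pair_starts)
        tr_e <- c(tr_e, mg$pair_ends)
        tr_t <- c(tr_t, rep(t, length(mg$pair_starts)))
      }
      keep <- setdiff(seq_along(lins), ij)
      lins <- lins[keep]; rec_w <- rec_w[keep]; mut_w <- mut_w[keep]
      if (nrow(mg$segs) > 0L) {
        lins[[length(lins) + 1L]] <- list(segs = mg$segs, deme = d)
        rec_w <- c(rec_w, seg_span_weight(mg$segs, Sr))
        mut_w <- c(mut_w, seg_site_weight(mg$segs, Sm))
      }
    } else if (u <= coal_rate + rec_rate) {
      n_ev["RECOMBINATION"] <- n_ev["RECOMBINATION"] + 1L
      i <- sample.int(length(lins), 1L, prob = rec_w)
      segs <- lins[[i]]$segs
      link <- pick_link(segs, Sr, unif_rec)
      left <- segs[segs[, 1L] <= link, , drop = FALSE]
      if (nrow(left) && left[nrow(left), 2L] > link) left[nrow(left), 2L] <- link
      right <- segs[segs[, 2L] > link, , drop = FALSE]
      if (nrow(right) && right[1L, 1L] <= link) right[1L, 1L] <- link + 1L
      d <- lins[[i]]$deme
      lins[[i]] <- list(segs = left, deme = d)
      rec_w[i] <- seg_span_weight(left, Sr)
      mut_w[i] <- seg_site_weight(left, Sm)
      lins[[length(lins) + 1L]] <- list(segs = right, deme = d)
      rec_w <- c(rec_w, seg_span_weight(right, Sr))
      mut_w <- c(mut_w, seg_site_weight(right, Sm))
    } else {
      n_ev["MIGRATION"] <- n_ev["MIGRATION"] + 1L
      i <- sample.int(length(lins), 1L)
      lins[[i]]$deme <- 1L - lins[[i]]$deme
    }
  }

  ord <- order(tr_s)
  track <- data.frame(start = tr_s[ord], end = tr_e[ord], time = tr_t[ord])
  muts <- if (record_mutations)
    data.frame(site = mu_site, set = mu_set, time = mu_time)
  else NULL
  structure(list(track = track, mutations = muts, n_events = n_ev,
                 config = config),
            class = "im_arg")
}

#' Per-site TMRCA vector of an ARG
#'
#' @param arg An `im_arg` from [simulate_arg()].
#' @return Numeric vector of length `L`.
#' @export
tmrca_vector <- function(arg) {
  out <- numeric(arg$config$L)
  tr <- arg$track
  for (i in seq_len(nrow(tr))) out[tr$start[i]:tr$end[i]] <- tr$time[i]
  out
}

## -- sequence emission ----------------------------------------------------

new_alignment <- function(mat, names = NULL) {
  if (is.null(names)) names <- paste0("seq", seq_len(nrow(mat)))
  rownames(mat) <- names
  structure(mat, class = "im_alignment")
}

#' @export
print.im_alignment <- function(x, ...) {
  cat(sprintf("im_alignment: %d sequences of length %d\n", nrow(x), ncol(x)))
  invisible(x)
}

# one JC branch: each site mutates away from `base` with the given
# probability, landing uniformly on one of the three other nucleotides
jc_branch <- function(base, p_change) {
  hit <- stats::runif(length(base)) < p_change
  if (any(hit)) {
    shift <- sample.int(3L, sum(hit), replace = TRUE)
    base[hit] <- ((base[hit] - 1L + shift) %% 4L) + 1L
  }
  base
}

#' Emit a two-sequence alignment from a TMRCA track
#'
#' Draws a uniform root base per site and evolves the two branches (each of
#' the per-site TMRCA length, scaled by any mutation-rate multipliers)
#' under Jukes-Cantor, so the per-site mismatch probability is
#' `(3/4) * (1 - exp(-(8/3) * t))`.
#'
#' @param arg An `im_arg` (or a numeric per-site TMRCA vector).
#' @param config The [sim_config()]; supplies length, multipliers and seed.
#' @param seed Seed for the mutation draws (defaults to `config$seed + 1`).
#' @return An `im_alignment` with two rows.
#' @export
sim_mutate <- function(arg, config = arg$config, seed = config$seed + 1L) {
  t_site <- if (inherits(arg, "im_arg")) tmrca_vector(arg) else as.numeric(arg)
  stopifnot(length(t_site) == config$L)
  if (!is.null(config$mut_multipliers)) t_site <- t_site * config$mut_multipliers
  set.seed(seed)
  root <- sample.int(4L, config$L, replace = TRUE)
  p <- 0.75 * (1 - exp(-(4 / 3) * t_site))
  new_alignment(rbind(jc_branch(root, p), jc_branch(root, p)),
                c("deme0_1", "deme1_1"))
}

# sequences for an ARG with recorded mutations (any sample count): apply
# mutation events oldest-first; all samples below a mutation share their
# pre-mutation base, so one redraw per event suffices
arg_to_alignment <- function(arg, seed = arg$config$seed + 1L) {
  stopifnot(!is.null(arg$mutations))
  set.seed(seed)
  n_samples <- 2L * arg$config$n_per_deme
  L <- arg$config$L
  base <- matrix(rep(sample.int(4L, L, replace = TRUE), each = n_samples),
                 n_samples, L)
  mu <- arg$mutations[order(-arg$mutations$time), , drop = FALSE]
  set_members <- lapply(seq_len(bitwShiftL(1L, n_samples) - 1L), function(m)
    which(bitwAnd(m, bitwShiftL(1L, seq_len(n_samples) - 1L)) != 0L))
  shifts <- sample.int(3L, nrow(mu), replace = TRUE)
  for (i in seq_len(nrow(mu))) {
    s <- mu$site[i]
    members <- set_members[[mu$set[i]]]
    base[members, s] <- ((base[members[1L], s] - 1L + shifts[i]) %% 4L) + 1L
  }
  nm <- c(paste0("deme0_", seq_len(arg$config$n_per_deme)),
          paste0("deme1_", seq_len(arg$config$n_per_deme)))
  new_alignment(base, nm)
}

#' Simulate an aligned sequence pair (or quartet) under the IM model
#'
#' For one sample per deme, simulates the ARG and emits Jukes-Cantor
#' sequences from the TMRCA track; for two samples per deme, mutations are
#' placed directly on the graph and four sequences are returned.
#'
#' @param config An [sim_config()] object.
#' @return A list with `alignment` (an `im_alignment`) and `arg`.
#' @export
simulate_alignment <- function(config) {
  if (config$n_per_deme == 1L) {
    arg <- simulate_arg(config, record_mutations = FALSE)
    list(alignment = sim_mutate(arg, config), arg = arg)
  } else {
    arg <- simulate_arg(config, record_mutations = TRUE)
    list(alignment = arg_to_alignment(arg), arg = arg)
  }
}

#' Collapse an unphased quartet to random-phase mosaic haploids
#'
#' For each deme, builds one pseudo-haploid sequence from the deme's two
#' samples by choosing either allele with probability 1/2 independently at
#' every heterozygous position, mimicking an unphased diploid genome
#' represented by a random allele.
#'
#' @param alignment An `im_alignment` with four rows (two per deme).
#' @param seed Integer seed.
#' @return An `im_alignment` with two rows.
#' @export
random_phase_mosaic <- function(alignment, seed) {
  stopifnot(nrow(alignment) == 4L)
  set.seed(seed)
  mosaic_one <- function(a, b) {
    het <- which(a != b)
    take_b <- het[stats::runif(length(het)) < 0.5]
    a[take_b] <- b[take_b]
    a
  }
  new_alignment(rbind(mosaic_one(alignment[1L, ], alignment[2L, ]),
                      mosaic_one(alignment[3L, ], alignment[4L, ])),
                c("deme0_mosaic", "deme1_mosaic"))
}

#' Column symbols of a simulated alignment
#'
#' @param alignment An `im_alignment`.
#' @param rows Which two rows to compare (default: one per deme).
#' @return A [column_sequence()].
#' @export
as_column_sequence <- function(alignment, rows = NULL) {
  if (is.null(rows))
    rows <- if (nrow(alignment) == 2L) c(1L, 2L)
      else c(1L, nrow(alignment) / 2L + 1L)
  column_sequence(ifelse(alignment[rows[1L], ] == alignment[rows[2L], ], 1L, 2L))
}

## -- Monte-Carlo oracle for the transition model --------------------------

#' Gillespie simulation of the two-nucleotide CTMC
#'
#' Direct event-driven sampling of the epoch-switching two-nucleotide chain
#' used by the transition model, recording the intervals in which the left
#' and right nucleotides find their MRCAs.  Serves as an independent
#' Monte-Carlo oracle for [joint_matrix()].
#'
#' @param params An [im_parameters()] object.
#' @param disc An `im_discretization` used to bin coalescence times.
#' @param n_paths Number of independent paths.
#' @return A list with `J` (empirical joint interval frequencies), `se`
#'   (binomial standard errors), `counts` and `times` (per-path left/right
#'   coalescence times).
#' @export
gillespie_two_nucleotide <- function(params, disc, n_paths = 1e5) {
  stack <- build_epoch_stack(params)
  sp <- stack$spaces
  done_flags <- function(space) {
    list(l = space$class %in% c("L", "E"), r = space$class %in% c("R", "E"))
  }
  f_iso <- done_flags(sp$iso); f_mig <- done_flags(sp$mig); f_anc <- done_flags(sp$anc)
  inj_idx <- apply(stack$injection, 1L, which.max)
  proj_idx <- apply(stack$projection, 1L, which.max)
  times <- .gillespie_paths_cpp(stack$Q_iso, stack$Q_mig, stack$Q_anc,
                                as.integer(inj_idx), as.integer(proj_idx),
                                stack$initial_iso,
                                f_iso$l, f_iso$r, f_mig$l, f_mig$r,
                                f_anc$l, f_anc$r,
                                params$tau1, params$tau2, as.integer(n_paths))
  bp <- disc$breakpoints
  li <- findInterval(times[, 1L], bp)
  ri <- findInterval(times[, 2L], bp)
  li <- pmin(pmax(li, 1L), disc$n); ri <- pmin(pmax(ri, 1L), disc$n)
  counts <- matrix(0L, disc$n, disc$n)
  for (k in seq_len(nrow(times)))
    counts[li[k], ri[k]] <- counts[li[k], ri[k]] + 1L
  J <- counts / n_paths
  list(J = J, se = sqrt(J * (1 - J) / n_paths), counts = counts, times = times)
}
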