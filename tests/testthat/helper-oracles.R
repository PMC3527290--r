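# Independent oracles, written separately from the implementation paths
# they check.

# -- brute-force state-space closure --------------------------------------
# Recursive DFS with its own state representation (character tokens) and a
# deliberately different transition application order (migration first,
# then recombination, then coalescence) to exercise order independence.

oracle_lineage_token <- function(l, r, d) paste0("l", l, "r", r, "d", d)

oracle_state_key <- function(lins) paste(sort(lins), collapse = "+")

oracle_parse <- function(tok) {
  m <- regmatches(tok, regexec("^l([0-9])r([0-9])d([0-9])$", tok))[[1L]]
  as.integer(m[2:4])
}

oracle_transitions <- function(lins, n_demes, allow_mig) {
  parts <- lapply(lins, oracle_parse)
  out <- character(0L)
  k <- length(lins)
  if (allow_mig && n_demes == 2L) {
    for (i in seq_len(k)) {
      p <- parts[[i]]
      nl <- lins
      nl[i] <- oracle_lineage_token(p[1], p[2], 1L - p[3])
      out <- c(out, oracle_state_key(nl))
    }
  }
  for (i in seq_len(k)) {
    p <- parts[[i]]
    if (p[1] != 0L && p[2] != 0L) {
      nl <- c(lins[-i], oracle_lineage_token(p[1], 0L, p[3]),
              oracle_lineage_token(0L, p[2], p[3]))
      out <- c(out, oracle_state_key(nl))
    }
  }
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      a <- parts[[i]]; b <- parts[[j]]
      if (a[3] != b[3]) next
      if (bitwAnd(a[1], b[1]) || bitwAnd(a[2], b[2])) next
      nl <- c(lins[-c(i, j)],
              oracle_lineage_token(bitwOr(a[1], b[1]), bitwOr(a[2], b[2]), a[3]))
      out <- c(out, oracle_state_key(nl))
    }
  }
  out
}

oracle_absorbed <- function(lins) {
  parts <- lapply(lins, oracle_parse)
  any(vapply(parts, function(p) p[1] == 3L, TRUE)) &&
    any(vapply(parts, function(p) p[2] == 3L, TRUE))
}

oracle_closure <- function(init_lins, n_demes, allow_mig) {
  seen <- new.env(parent = emptyenv())
  n_edges <- 0L
  recurse <- function(key) {
    if (exists(key, envir = seen, inherits = FALSE)) return(invisible())
    assign(key, TRUE, envir = seen)
    lins <- strsplit(key, "+", fixed = TRUE)[[1L]]
    if (oracle_absorbed(lins)) return(invisible())
    for (nxt in oracle_transitions(lins, n_demes, allow_mig)) {
      n_edges <<- n_edges + 1L
      recurse(nxt)
    }
  }
  recurse(oracle_state_key(init_lins))
  list(states = sort(ls(envir = seen)), n_edges = n_edges)
}

# package state -> oracle key, for set comparison
oracle_key_of_state <- function(state) {
  oracle_state_key(vapply(state, function(l)
    oracle_lineage_token(l[1], l[2], l[3]), character(1L)))
}

# -- naive full-product joint matrix --------------------------------------
# Recomputes every restricted interval product from scratch for each
# (i, j) pair; no prefix accumulation shared with joint_matrix().

oracle_joint_naive <- function(im) {
  n <- im$disc$n
  cls <- im$classes
  idx <- function(i, cl) which(cls[[i]] == cl)
  restrict_prod <- function(from, to, cl) {
    # product of P_k[cl, cl] for k in from..to (empty product = identity)
    M <- diag(length(idx(from, cl)))
    if (to >= from) for (k in from:to)
      M <- M %*% im$P[[k]][idx(k, cl), idx(k + 1L, cl), drop = FALSE]
    M
  }
  a0 <- im$a0[idx(1L, "B")]
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        if (i == n) {
          J[i, j] <- sum(a0 %*% restrict_prod(1L, n - 1L, "B"))
        } else {
          v <- a0 %*% restrict_prod(1L, i - 1L, "B")
          J[i, j] <- sum(v %*% im$P[[i]][idx(i, "B"), idx(i + 1L, "E"),
                                         drop = FALSE])
        }
      } else {
        first <- min(i, j); second <- max(i, j)
        cl <- if (i < j) "L" else "R"
        v <- a0 %*% restrict_prod(1L, first - 1L, "B")
        v <- v %*% im$P[[first]][idx(first, "B"), idx(first + 1L, cl),
                                 drop = FALSE]
        v <- v %*% restrict_prod(first + 1L, second - 1L, cl)
        J[i, j] <- if (second == n) sum(v)
        else sum(v %*% im$P[[second]][idx(second, cl), idx(second + 1L, "E"),
                                      drop = FALSE])
      }
    }
  }
  J
}

# -- exhaustive-path forward likelihood -----------------------------------

oracle_forward_bruteforce <- function(pi, T, E, cols) {
  n <- length(pi)
  L <- length(cols)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), L)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    pr <- pi[s[1L]] * E[s[1L], cols[1L]]
    if (L > 1L) for (t in 2:L)
      pr <- pr * T[s[t - 1L], s[t]] * E[s[t], cols[t]]
    total <- total + pr
  }
  log(as.numeric(total))
}

# -- ODE integration of dP/dt = Q P ---------------------------------------

oracle_expm_ode <- function(Q, t_end) {
  n <- nrow(Q)
  deriv <- function(t, y, parms) list(as.vector(Q %*% matrix(y, n, n)))
  out <- deSolve::ode(y = as.vector(diag(n)), times = c(0, t_end),
                      func = deriv, parms = NULL, method = "lsoda",
                      rtol = 1e-12, atol = 1e-14)
  matrix(out[2L, -1L], n, n)
}

# -- quadrature end-conditioned means -------------------------------------
# Integrates t times the absorption density of the lumped single-nucleotide
# chain with stats::integrate; shares no spectral machinery.

oracle_migration_means <- function(params, disc) {
  sys <- imcoalhmm:::single_nuc_lumped(params)
  st <- imcoalhmm:::single_nuc_state_dists(params, disc)
  m <- sys$m
  qa <- sys$Q[seq_len(m), m + 1L]
  vapply(seq_len(disc$n_mig), function(i) {
    alpha <- st$alpha[[i]][seq_len(m)]
    dens <- function(u) vapply(u, function(t1) {
      P <- as.matrix(Matrix::expm(sys$Q * t1))
      sum((alpha %*% P[seq_len(m), seq_len(m)]) * qa)
    }, numeric(1L))
    num <- stats::integrate(function(u) u * dens(u), 0, disc$delta,
                            rel.tol = 1e-10)$value
    disc$breakpoints[i] + num / st$mass[i]
  }, numeric(1L))
}

# shared fixtures
main_params <- function() im_parameters(0.00025, 0.001, 1250, 0.4, 250)

toy_hmm <- function(rec = 0.3) {
  # 4 hidden intervals: 2 migration + 2 ancestral
  p <- im_parameters(0.0005, 0.001, 1000, rec, 400)
  disc <- discretize_time(p, n_mig = 2L, n_anc = 2L)
  im <- interval_matrices(p, disc)
  J <- joint_matrix(im)
  ht <- hmm_transition(J)
  ecm <- end_conditioned_means(p, disc)
  list(params = p, disc = disc, im = im, J = J, pi = ht$pi, T = ht$T,
       E = jc_emissions(ecm), means = ecm$mean)
}
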