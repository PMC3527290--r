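# Structured-coalescent state spaces for one and two neighbouring nucleotides.
#
# A lineage is a pair of ancestral-material sets (left nucleotide, right
# nucleotide), each a subset of the sampled sequences {1, 2}, together with
# the deme the lineage currently occupies.  Sets are stored as bitmasks:
# 0 = empty (non-ancestral flank), 1 = {1}, 2 = {2}, 3 = {1,2} = MRCA found.
# A CTMC state is a canonically ordered set of such lineages.

MRCA_MASK <- 3L

#' Construct a lineage descriptor
#'
#' @param left,right Ancestral material carried at the left/right nucleotide:
#'   an integer vector of sample labels (subset of `c(1, 2)`), or an integer
#'   bitmask 0--3.  At least one side must be non-empty.
#' @param deme Deme index (0 or 1).
#' @return Integer vector `c(left_mask, right_mask, deme)`.
#' @export
lineage <- function(left, right, deme = 0L) {
  to_mask <- function(x) {
    x <- as.integer(x)
    if (length(x) == 0L || identical(x, 0L)) return(0L)
    if (identical(x, 3L)) return(3L)  # already a mask for {1,2}
    as.integer(sum(bitwShiftL(1L, unique(x) - 1L)))
  }
  l <- to_mask(left)
  r <- to_mask(right)
  stopifnot(l >= 0L, l <= 3L, r >= 0L, r <= 3L)
  if (l == 0L && r == 0L) stop("lineage must carry ancestral material on at least one side")
  c(l, r, as.integer(deme))
}

## -- canonical serialization ---------------------------------------------

serialize_lineage <- function(lin) sprintf("%d.%d.%d", lin[1L], lin[2L], lin[3L])

serialize_state <- function(state) {
  paste(sort(vapply(state, serialize_lineage, character(1L))), collapse = "|")
}

deserialize_state <- function(key) {
  lapply(strsplit(key, "|", fixed = TRUE)[[1L]], function(s) {
    as.integer(strsplit(s, ".", fixed = TRUE)[[1L]])
  })
}

## -- validation -----------------------------------------------------------

# Per side, the non-empty material sets must be pairwise disjoint and union
# to {1,2} (either still split or already merged into the MRCA set).
validate_state <- function(state, n_demes) {
  for (side in 1:2) {
    masks <- vapply(state, `[`, integer(1L), side)
    masks <- masks[masks != 0L]
    if (length(masks) == 0L) next  # side unused (single-nucleotide system)
    total <- 0L
    for (m in masks) {
      if (bitwAnd(total, m) != 0L)
        stop("ancestral material on side ", side, " is not a partition")
      total <- bitwOr(total, m)
    }
    if (total != MRCA_MASK)
      stop("ancestral material on side ", side, " does not cover both samples")
  }
  demes <- vapply(state, `[`, integer(1L), 3L)
  if (any(demes < 0L | demes >= n_demes))
    stop("deme index out of range for ", n_demes, " deme(s)")
  invisible(TRUE)
}

## -- state classification -------------------------------------------------

# B: neither nucleotide has found its MRCA; L: left only; R: right only;
# E: both (absorbing for the purposes of the model).
state_class <- function(state) {
  l_done <- any(vapply(state, function(x) x[1L] == MRCA_MASK, logical(1L)))
  r_done <- any(vapply(state, function(x) x[2L] == MRCA_MASK, logical(1L)))
  if (l_done && r_done) "E" else if (l_done) "L" else if (r_done) "R" else "B"
}

## -- transitions ----------------------------------------------------------

# All single-event successors of a state.  Coalescence merges two lineages
# in the same deme by per-side set union, permitted only when the same-side
# materials are disjoint (one may be empty).  Recombination splits a doubly
# linked lineage.  Migration moves one lineage to the other deme.
state_transitions <- function(state, n_demes, allow_migration) {
  out <- list()
  k <- length(state)
  add <- function(kind, deme, new_state) {
    out[[length(out) + 1L]] <<- list(kind = kind, deme = deme,
                                     key = serialize_state(new_state))
  }
  if (k >= 2L) {
    for (i in 1:(k - 1L)) {
      for (j in (i + 1L):k) {
        a <- state[[i]]; b <- state[[j]]
        if (a[3L] != b[3L]) next
        if (bitwAnd(a[1L], b[1L]) != 0L || bitwAnd(a[2L], b[2L]) != 0L) next
        merged <- c(bitwOr(a[1L], b[1L]), bitwOr(a[2L], b[2L]), a[3L])
        add("COALESCENCE", a[3L], c(state[-c(i, j)], list(merged)))
      }
    }
  }
  for (i in seq_len(k)) {
    a <- state[[i]]
    if (a[1L] != 0L && a[2L] != 0L) {
      split <- list(c(a[1L], 0L, a[3L]), c(0L, a[2L], a[3L]))
      add("RECOMBINATION", a[3L], c(state[-i], split))
    }
  }
  if (allow_migration && n_demes == 2L) {
    for (i in seq_len(k)) {
      a <- state[[i]]
      moved <- state
      moved[[i]] <- c(a[1L], a[2L], 1L - a[3L])
      add("MIGRATION", a[3L], moved)
    }
  }
  out
}

#' Enumerate a structured-coalescent state space
#'
#' Computes the breadth-first closure of an initial state under coalescence,
#' recombination and (optionally) migration events.  States in which both
#' nucleotides have found their MRCA are treated as absorbing and are not
#' expanded further.  States are indexed in canonical (lexicographic
#' serialization) order so that matrices built from the space are
#' reproducible across runs and platforms.
#'
#' @param initial A state: list of lineages as returned by [lineage()], or a
#'   list of such states (the closure is taken from all of them).
#' @param n_demes Number of demes, 1 or 2.
#' @param allow_migration Should migration transitions be generated?  Only
#'   meaningful with two demes.
#' @return An object of class `im_state_space` with components `states`
#'   (list of states in index order), `keys` (their canonical
#'   serializations), `edges` (data frame with columns `from`, `to`, `kind`,
#'   `deme`; indices are 1-based), and `class` (character vector giving the
#'   B/L/R/E class of each state).
#' @examples
#' sp <- enumerate_state_space(
#'   list(lineage(1, 1, 0), lineage(2, 2, 1)),
#'   n_demes = 2, allow_migration = TRUE)
#' length(sp$states)
#' @export
enumerate_state_space <- function(initial, n_demes = 2L, allow_migration = TRUE) {
  n_demes <- as.integer(n_demes)
  stopifnot(n_demes %in% 1:2)
  is_state <- function(x) is.list(x) && all(vapply(x, is.numeric, logical(1L)))
  initials <- if (is_state(initial)) list(initial) else initial
  # normalise: list of states, each a list of integer triples
  initials <- lapply(initials, function(st) lapply(st, function(l) {
    stopifnot(is.numeric(l), length(l) == 3L)
    as.integer(l)
  }))
  for (st in initials) validate_state(st, n_demes)

  seen <- new.env(parent = emptyenv())
  queue <- character(0L)
  edges_from <- character(0L); edges_to <- character(0L)
  edges_kind <- character(0L); edges_deme <- integer(0L)
  for (st in initials) {
    key <- serialize_state(st)
    if (!exists(key, envir = seen, inherits = FALSE)) {
      assign(key, TRUE, envir = seen)
      queue <- c(queue, key)
    }
  }
  head <- 1L
  while (head <= length(queue)) {
    key <- queue[[head]]; head <- head + 1L
    st <- deserialize_state(key)
    if (state_class(st) == "E") next
    for (tr in state_transitions(st, n_demes, allow_migration)) {
      if (!exists(tr$key, envir = seen, inherits = FALSE)) {
        assign(tr$key, TRUE, envir = seen)
        queue <- c(queue, tr$key)
      }
      edges_from <- c(edges_from, key)
      edges_to <- c(edges_to, tr$key)
      edges_kind <- c(edges_kind, tr$kind)
      edges_deme <- c(edges_deme, tr$deme)
    }
  }
  keys <- sort(queue)
  idx <- stats::setNames(seq_along(keys), keys)
  states <- lapply(keys, deserialize_state)
  edges <- data.frame(
    from = unname(idx[edges_from]),
    to = unname(idx[edges_to]),
    kind = edges_kind,
    deme = edges_deme,
    stringsAsFactors = FALSE)
  structure(
    list(states = states, keys = keys, index = idx, edges = edges,
         class = vapply(states, state_class, character(1L)),
         n_demes = n_demes, allow_migration = allow_migration),
    class = "im_state_space")
}

#' @export
print.im_state_space <- function(x, ...) {
  cat(sprintf("im_state_space: %d states, %d edges (%d deme%s, migration %s)\n",
              length(x$states), nrow(x$edges), x$n_demes,
              if (x$n_demes > 1L) "s" else "",
              if (x$allow_migration) "on" else "off"))
  cat("classes:", paste(sprintf("%s=%d", names(table(x$class)), table(x$class)),
                        collapse = " "), "\n")
  invisible(x)
}

#' Write a state space in a plain-text debug format
#'
#' One state per line in canonical serialization, preceded by its index and
#' B/L/R/E class, suitable for diffing against an independent enumeration.
#'
#' @param space An `im_state_space`.
#' @param path Output file path ("" for stdout).
#' @export
write_state_space <- function(space, path = "") {
  writeLines(sprintf("%d\t%s\t%s", seq_along(space$keys), space$class, space$keys),
             con = path)
  invisible(space)
}

## -- rate matrices --------------------------------------------------------

#' Epoch rate specification
#'
#' @param coal Coalescence rate(s): a single rate shared by all demes or a
#'   vector with one rate per deme, in events per unit of expected
#'   substitutions.
#' @param rec Recombination rate per adjacent-nucleotide link per lineage.
#' @param mig Migration rate per lineage (symmetric; 0 disables gene flow).
#' @return A list of validated rates.
#' @export
epoch_rates <- function(coal, rec = 0, mig = 0) {
  stopifnot(all(coal >= 0), rec >= 0, mig >= 0)
  list(coal = as.numeric(coal), rec = as.numeric(rec), mig = as.numeric(mig))
}

# Indicator matrices per event kind (and per deme for coalescence), from
# which a rate matrix is a parameter-weighted sum.  Cached per state space.
rate_templates <- function(space) {
  n <- length(space$states)
  e <- space$edges
  tmpl <- list()
  mk <- function(sel) {
    A <- matrix(0, n, n)
    if (any(sel)) {
      tab <- table(paste(e$from[sel], e$to[sel]))
      for (nm in names(tab)) {
        ij <- as.integer(strsplit(nm, " ", fixed = TRUE)[[1L]])
        A[ij[1L], ij[2L]] <- as.numeric(tab[[nm]])
      }
    }
    A
  }
  tmpl$coal <- lapply(0:(space$n_demes - 1L),
                      function(d) mk(e$kind == "COALESCENCE" & e$deme == d))
  tmpl$rec <- mk(e$kind == "RECOMBINATION")
  tmpl$mig <- mk(e$kind == "MIGRATION")
  tmpl
}

#' Build the CTMC rate matrix for a state space and epoch rates
#'
#' Off-diagonal entries accumulate the rates of all single events mapping one
#' state to another; diagonals make rows sum to zero.  States in class E
#' (both nucleotides at their MRCA) have all-zero rows.
#'
#' @param space An `im_state_space`.
#' @param rates An [epoch_rates()] specification.
#' @return A dense base-R matrix.
#' @export
build_rate_matrix <- function(space, rates) {
  if (any(unlist(rates) < 0)) stop("rates must be non-negative")
  tm <- attr(space, "templates")
  if (is.null(tm)) tm <- rate_templates(space)
  coal <- rep_len(rates$coal, space$n_demes)
  Q <- rates$rec * tm$rec + rates$mig * tm$mig
  for (d in seq_len(space$n_demes)) Q <- Q + coal[d] * tm$coal[[d]]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

## -- epoch systems and bridges -------------------------------------------

# 0/1 mapping matrix from space `a` into space `b` under a state rewrite
# function (identity for injection, deme-relabelling for projection).
mapping_matrix <- function(a, b, rewrite = identity) {
  Mmap <- matrix(0, length(a$states), length(b$states))
  for (i in seq_along(a$states)) {
    key <- serialize_state(rewrite(a$states[[i]]))
    j <- unname(b$index[key])
    if (is.na(j)) stop("state not present in target space: ", key)
    Mmap[i, j] <- 1
  }
  Mmap
}

project_to_deme0 <- function(state) lapply(state, function(l) c(l[1L], l[2L], 0L))

# Enumerate and cache the epoch state spaces for the n-nucleotide system
# (n_nuc = 1 or 2).  Parameter-free, so computed once per session.
.im_cache <- new.env(parent = emptyenv())

epoch_state_spaces <- function(n_nuc = 2L) {
  key <- paste0("spaces", n_nuc)
  if (!is.null(.im_cache[[key]])) return(.im_cache[[key]])
  init <- if (n_nuc == 2L)
    list(lineage(1, 1, 0), lineage(2, 2, 1))
  else
    list(lineage(1, 0, 0), lineage(2, 0, 1))
  iso <- enumerate_state_space(init, n_demes = 2L, allow_migration = FALSE)
  mig <- enumerate_state_space(init, n_demes = 2L, allow_migration = TRUE)
  anc_inits <- unique(vapply(lapply(mig$states, project_to_deme0),
                             serialize_state, character(1L)))
  anc <- enumerate_state_space(lapply(anc_inits, deserialize_state),
                               n_demes = 1L, allow_migration = FALSE)
  for (nm in c("iso", "mig", "anc")) {
    sp <- get(nm)
    attr(sp, "templates") <- rate_templates(sp)
    assign(nm, sp)
  }
  out <- list(
    iso = iso, mig = mig, anc = anc,
    injection = mapping_matrix(iso, mig),
    projection = mapping_matrix(mig, anc, project_to_deme0),
    initial_iso = unname(iso$index[[serialize_state(init)]]))
  .im_cache[[key]] <- out
  out
}

#' Model parameters for the isolation-with-migration model
#'
#' All rates and times are scaled in units of expected substitutions per
#' site, so that divergence times are directly comparable to sequence
#' divergence.
#'
#' @param tau1 Time at which gene flow ceased (backwards from the present).
#' @param tau2 Initial population split time; `tau2 >= tau1`.
#' @param coal Coalescence rate (inverse scaled population size).
#' @param rec Recombination rate per adjacent-nucleotide link.
#' @param mig Symmetric migration rate per lineage, active on
#'   `[tau1, tau2]` only.
#' @param coal_anc Coalescence rate in the ancestral (panmictic) population;
#'   defaults to `coal`.
#' @return An object of class `im_parameters`.
#' @export
im_parameters <- function(tau1, tau2, coal, rec, mig, coal_anc = coal) {
  stopifnot(tau1 >= 0, tau2 >= tau1, coal > 0, rec >= 0, mig >= 0, coal_anc > 0)
  structure(list(tau1 = tau1, tau2 = tau2, coal = coal, rec = rec, mig = mig,
                 coal_anc = coal_anc),
            class = "im_parameters")
}

#' @export
print.im_parameters <- function(x, ...) {
  cat(sprintf(paste0("im_parameters: tau1=%.6g tau2=%.6g coal=%.6g ",
                     "rec=%.6g mig=%.6g coal_anc=%.6g\n"),
              x$tau1, x$tau2, x$coal, x$rec, x$mig, x$coal_anc))
  invisible(x)
}

#' Build the three-epoch CTMC stack for a parameter set
#'
#' Returns the isolated-epoch, migration-epoch and ancestral-epoch state
#' spaces and rate matrices, together with the injection (isolated into
#' migration) and projection (migration onto ancestral) bridge matrices.
#' Migration is disabled in the isolated epoch and meaningless in the
#' panmictic ancestral epoch.
#'
#' @param params An [im_parameters()] object.
#' @param n_nuc Number of neighbouring nucleotides tracked (1 or 2).
#' @return A list with `spaces`, `Q_iso`, `Q_mig`, `Q_anc`, `injection`,
#'   `projection` and the index of the initial state in the isolated space.
#' @export
build_epoch_stack <- function(params, n_nuc = 2L) {
  sp <- epoch_state_spaces(n_nuc)
  list(
    spaces = sp,
    Q_iso = build_rate_matrix(sp$iso, epoch_rates(params$coal, params$rec, 0)),
    Q_mig = build_rate_matrix(sp$mig, epoch_rates(params$coal, params$rec, params$mig)),
    Q_anc = build_rate_matrix(sp$anc, epoch_rates(params$coal_anc, params$rec, 0)),
    injection = sp$injection,
    projection = sp$projection,
    initial_iso = sp$initial_iso)
}
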