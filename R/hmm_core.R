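# Numerically stable forward likelihood and posterior decoding over the
# reduced alignment-column alphabet {IDENTICAL, DIFFERENT, MISSING}.

COLUMN_SYMBOLS <- c("IDENTICAL", "DIFFERENT", "MISSING")

#' Construct a column-symbol sequence
#'
#' @param x Integer codes (1 = IDENTICAL, 2 = DIFFERENT, 3 = MISSING) or a
#'   character vector of symbol names.
#' @return Integer vector of class `im_columns`.
#' @export
column_sequence <- function(x) {
  if (is.character(x)) x <- match(toupper(x), COLUMN_SYMBOLS)
  x <- as.integer(x)
  if (length(x) < 1L || anyNA(x) || any(x < 1L | x > 3L))
    stop("column symbols must be in {IDENTICAL, DIFFERENT, MISSING}")
  structure(x, class = "im_columns")
}

#' @export
print.im_columns <- function(x, ...) {
  tab <- tabulate(unclass(x), nbins = 3L)
  cat(sprintf("im_columns: %d positions (identical %d, different %d, missing %d)\n",
              length(x), tab[1L], tab[2L], tab[3L]))
  invisible(x)
}

#' Run-length compress a column sequence
#'
#' The forward recursion advances runs of identical symbols through cached
#' matrix powers, so the per-evaluation cost scales with the number of
#' runs.  Compressing once before repeated likelihood evaluations (as in
#' [im_fit()]) removes the per-call compression overhead.
#'
#' @param columns A [column_sequence()].
#' @return An object of class `im_columns_rle`.
#' @export
compress_columns <- function(columns) {
  if (inherits(columns, "im_columns_rle")) return(columns)
  cols <- as.integer(columns)
  if (length(cols) < 1L || anyNA(cols) || any(cols < 1L | cols > 3L))
    stop("invalid column codes")
  r <- rle(cols)
  structure(list(values = r$values, lengths = as.numeric(r$lengths),
                 length = length(cols)),
            class = "im_columns_rle")
}

check_hmm_matrices <- function(pi, T, E) {
  n <- length(pi)
  stopifnot(is.matrix(T), nrow(T) == n, ncol(T) == n,
            is.matrix(E), nrow(E) == n, ncol(E) == 3L)
  if (max(abs(rowSums(T) - 1)) > 1e-6) stop("transition matrix is not row-stochastic")
  if (abs(sum(pi) - 1) > 1e-6) stop("initial distribution does not sum to 1")
  invisible(TRUE)
}

check_hmm_args <- function(pi, T, E, columns) {
  check_hmm_matrices(pi, T, E)
  cols <- as.integer(columns)
  if (length(cols) < 1L || any(cols < 1L | cols > 3L)) stop("invalid column codes")
  cols
}

#' Forward-algorithm log-likelihood
#'
#' Scaled forward recursion over the column sequence; runs of identical
#' symbols are advanced through cached binary powers of the per-symbol
#' update matrix, so runtime scales with the number of symbol runs rather
#' than the number of positions.
#'
#' @param pi Initial/stationary hidden-state distribution.
#' @param T Row-stochastic transition matrix.
#' @param E Emission matrix from [jc_emissions()].
#' @param columns A [column_sequence()] (or integer codes 1--3).
#' @return Log-likelihood (natural log).
#' @export
forward_loglik <- function(pi, T, E, columns) {
  check_hmm_matrices(pi, T, E)
  r <- compress_columns(columns)
  .forward_rle_cpp(pi, T, E, r$values - 1L, r$lengths)
}

#' Posterior decoding of hidden coalescence intervals
#'
#' Forward-backward posterior state probabilities per alignment column,
#' with an optional mapping to a per-position mean-TMRCA track.
#'
#' @inheritParams forward_loglik
#' @param means Optional per-interval mean coalescence times; when supplied
#'   the posterior mean TMRCA per position is returned as well.
#' @return A list with `gamma` (positions by states), `loglik`, `map`
#'   (maximum-posterior interval per position) and, if `means` is given,
#'   `tmrca`.
#' @export
posterior_decode <- function(pi, T, E, columns, means = NULL) {
  cols <- check_hmm_args(pi, T, E, columns)
  res <- .forward_backward_cpp(pi, T, E, cols - 1L)
  out <- list(gamma = res$gamma, loglik = res$loglik,
              map = max.col(res$gamma, ties.method = "first"))
  if (!is.null(means)) {
    if (is.list(means)) means <- means$mean
    out$tmrca <- as.numeric(res$gamma %*% means)
  }
  out
}

#' Export a posterior TMRCA track as BED-like rows
#'
#' Adjacent positions with equal MAP interval are merged into one row.
#' Coordinates are 0-based, half-open.
#'
#' @param decode Result of [posterior_decode()] (with `means` supplied).
#' @param chrom Chromosome/sequence name for the first column.
#' @param offset 0-based start coordinate of the first column.
#' @return A data frame with columns `chrom`, `start`, `end`, `mean_tmrca`,
#'   `map_interval`.
#' @export
tmrca_track <- function(decode, chrom = "seq", offset = 0L) {
  stopifnot(!is.null(decode$tmrca))
  r <- rle(decode$map)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  mean_t <- vapply(seq_along(starts), function(i)
    mean(decode$tmrca[(starts[i] + 1L):ends[i]]), numeric(1L))
  data.frame(chrom = chrom, start = offset + starts, end = offset + ends,
             mean_tmrca = mean_t, map_interval = r$values,
             stringsAsFactors = FALSE)
}
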