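# Maximum-likelihood fitting of the IM and I models, AIC model comparison,
# segment-wise analysis, and unit conversion of estimates.

#' Assemble the full HMM for a parameter set
#'
#' Builds the discretization, joint coalescence matrix, HMM transition
#' matrix, interval means and Jukes-Cantor emissions for either the
#' isolation-with-migration model (`"im"`) or the clean-split isolation
#' comparison model (`"i"`).  The I model shares all machinery: it has no
#' migration epoch and discretizes the ancestral epoch at exponential
#' coalescent quantiles of the fitted coalescence rate.
#'
#' @param params An [im_parameters()] object.  For the I model only `tau2`
#'   (the split time), `coal`/`coal_anc` and `rec` are used.
#' @param model `"im"` or `"i"`.
#' @param n_mig,n_anc Interval counts for the IM model (defaults 10/10).
#' @param n_intervals Interval count for the I model (default 20).
#' @param anc_span Optional finite ancestral span override, see
#'   [discretize_time()].
#' @return A list with `pi`, `T`, `E`, `means`, `mass`, `J`, `disc`,
#'   `params`, `model`.
#' @export
build_hmm <- function(params, model = c("im", "i"), n_mig = 10L, n_anc = 10L,
                      n_intervals = 20L, anc_span = NULL) {
  model <- match.arg(model)
  disc <- if (model == "im")
    discretize_time(params, n_mig, n_anc, anc_span)
  else
    discretize_isolation(params$tau2, params$coal_anc, n_intervals)
  im <- interval_matrices(params, disc)
  J <- joint_matrix(im)
  ht <- hmm_transition(J)
  ecm <- end_conditioned_means(params, disc)
  list(pi = ht$pi, T = ht$T, E = jc_emissions(ecm), means = ecm$mean,
       mass = ecm$mass, J = J, disc = disc, params = params, model = model)
}

#' Method-of-moments starting values
#'
#' Rough starts from the mean pairwise difference of the informative
#' columns: the Jukes-Cantor distance fixes the mean per-lineage divergence
#' `Tbar`, from which split times and the coalescence rate are apportioned.
#' The recombination-rate start assumes the typical genome-wide ratio of
#' recombination to mutation; the migration-rate start is a weakly
#' informative constant.
#'
#' @param columns A [column_sequence()].
#' @param model `"im"` or `"i"`.
#' @return An [im_parameters()] object.
#' @export
mom_init <- function(columns, model = c("im", "i")) {
  model <- match.arg(model)
  if (inherits(columns, "im_columns_rle")) {
    counts <- vapply(1:3, function(s)
      sum(columns$lengths[columns$values == s]), numeric(1L))
  } else {
    counts <- tabulate(as.integer(columns), nbins = 3L)
  }
  if (counts[1L] + counts[2L] == 0) stop("no informative columns: cannot initialize")
  p <- counts[2L] / (counts[1L] + counts[2L])
  p <- min(max(p, 1e-6), 0.74)
  tbar <- -0.75 * log(1 - 4 * p / 3) / 2
  if (model == "im") {
    tau2 <- tbar / 2
    im_parameters(tau1 = tau2 / 2, tau2 = tau2, coal = 1.6 / tbar,
                  rec = (1.6 / tbar) / 2000, mig = 100)
  } else {
    im_parameters(tau1 = tbar / 2, tau2 = tbar / 2, coal = 2 / tbar,
                  rec = (2 / tbar) / 2000, mig = 0)
  }
}

# log-transform reparameterizations keeping tau1 <= tau2 by construction
theta_from_params <- function(params, model) {
  if (model == "im")
    log(c(params$tau1, params$tau2 - params$tau1, params$coal, params$rec,
          params$mig))
  else
    log(c(params$tau2, params$coal, params$rec))
}

params_from_theta <- function(theta, model) {
  x <- exp(theta)
  if (model == "im")
    im_parameters(tau1 = x[1L], tau2 = x[1L] + x[2L], coal = x[3L],
                  rec = x[4L], mig = x[5L])
  else
    im_parameters(tau1 = x[1L], tau2 = x[1L], coal = x[2L], rec = x[3L],
                  mig = 0)
}

#' Fit the IM or I model by maximum likelihood
#'
#' Nelder-Mead optimization of the forward log-likelihood over
#' log-transformed free parameters (the gap `tau2 - tau1` is a free
#' positive parameter, keeping the split ordering by construction).  The
#' best of the method-of-moments start and `restarts` randomly perturbed
#' starts is returned.
#'
#' @param columns A [column_sequence()].
#' @param model `"im"` (5 free parameters) or `"i"` (3).
#' @param init Optional [im_parameters()] starting values; defaults to
#'   [mom_init()].
#' @param n_mig,n_anc,n_intervals,anc_span Discretization options, see
#'   [build_hmm()].
#' @param restarts Number of random restarts around the initial values.
#' @param seed Seed for the restart perturbations.
#' @param maxit,reltol Nelder-Mead control parameters.
#' @return An object of class `im_fit`: `estimates`, `loglik`, `aic`,
#'   `k`, `model`, `n_evals`, `converged`, `starts`.
#' @export
im_fit <- function(columns, model = c("im", "i"), init = NULL,
                   n_mig = 10L, n_anc = 10L, n_intervals = 20L,
                   anc_span = NULL, restarts = 2L, seed = NULL,
                   maxit = 500L, reltol = 1e-6) {
  model <- match.arg(model)
  cols <- compress_columns(columns)
  if (is.null(init)) init <- mom_init(cols, model)
  k <- if (model == "im") 5L else 3L
  n_evals <- 0L

  objective <- function(theta) {
    n_evals <<- n_evals + 1L
    val <- tryCatch({
      p <- params_from_theta(theta, model)
      hm <- build_hmm(p, model, n_mig = n_mig, n_anc = n_anc,
                      n_intervals = n_intervals, anc_span = anc_span)
      -forward_loglik(hm$pi, hm$T, hm$E, cols)
    }, error = function(e) NA_real_, warning = function(w) NA_real_)
    if (!is.finite(val)) 1e10 + sum(theta^2) else val
  }

  theta0 <- theta_from_params(init, model)
  starts <- list(theta0)
  if (restarts > 0L) {
    if (!is.null(seed)) set.seed(seed)
    for (r in seq_len(restarts))
      starts[[r + 1L]] <- theta0 + stats::rnorm(length(theta0), 0, 0.3)
  }
  best <- NULL
  for (th in starts) {
    opt <- stats::optim(th, objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (best$value >= 1e10)
    stop("all starts failed to produce a finite likelihood")
  est <- params_from_theta(best$par, model)
  loglik <- -best$value
  structure(list(model = model, estimates = est, loglik = loglik,
                 k = k, aic = 2 * k - 2 * loglik,
                 n_evals = n_evals, converged = best$convergence == 0L,
                 starts = length(starts), seed = seed,
                 init = init, n_mig = n_mig, n_anc = n_anc,
                 n_intervals = n_intervals),
            class = "im_fit")
}

#' @export
print.im_fit <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("im_fit [%s model]: loglik = %.3f, AIC = %.3f (k = %d)\n",
              toupper(x$model), x$loglik, x$aic, x$k))
  if (x$model == "im")
    cat(sprintf("  tau1=%.6g tau2=%.6g coal=%.6g rec=%.6g mig=%.6g\n",
                e$tau1, e$tau2, e$coal, e$rec, e$mig))
  else
    cat(sprintf("  tau=%.6g coal=%.6g rec=%.6g\n", e$tau2, e$coal, e$rec))
  cat(sprintf("  %d evaluations over %d start(s); converged: %s\n",
              x$n_evals, x$starts, x$converged))
  invisible(x)
}

#' Compare the IM model against the clean-split isolation model by AIC
#'
#' Fits both models to the same column sequence and reports
#' `delta = AIC(I) - AIC(IM)`.  Positive values prefer the
#' isolation-with-migration model, negative values the clean split.
#'
#' @inheritParams im_fit
#' @param ... Further arguments passed to [im_fit()].
#' @return An object of class `im_comparison` with `fit_im`, `fit_i`,
#'   `aic_im`, `aic_i`, `delta`.
#' @export
im_compare <- function(columns, ...) {
  fit_im <- im_fit(columns, model = "im", ...)
  fit_i <- im_fit(columns, model = "i", ...)
  structure(list(fit_im = fit_im, fit_i = fit_i,
                 aic_im = fit_im$aic, aic_i = fit_i$aic,
                 delta = fit_i$aic - fit_im$aic),
            class = "im_comparison")
}

#' @export
print.im_comparison <- function(x, ...) {
  cat(sprintf("AIC(I) = %.3f, AIC(IM) = %.3f, delta = AIC(I) - AIC(IM) = %.3f\n",
              x$aic_i, x$aic_im, x$delta))
  cat(if (x$delta > 0) "  -> gene-flow (IM) model preferred\n"
      else "  -> clean-split (I) model preferred\n")
  invisible(x)
}

#' Segment-wise model fits and comparisons
#'
#' Splits a column sequence into consecutive segments, runs [im_compare()]
#' on each, and reports one row per segment.  Segments with fewer
#' informative (non-missing) columns than `min_informative` are skipped
#' with a message.
#'
#' @inheritParams im_fit
#' @param segment_length Segment size in columns (default 10 Mbp).
#' @param min_informative Minimum informative columns per segment.
#' @param keep_tail Analyse the final partial segment as well?
#' @param ... Further arguments passed to [im_fit()].
#' @return A data frame with one row per analysed segment.
#' @export
segment_analysis <- function(columns, segment_length = 1e7,
                             min_informative = 1e4, keep_tail = FALSE, ...) {
  cols <- as.integer(columns)
  L <- length(cols)
  starts <- seq(1L, L, by = as.integer(segment_length))
  rows <- list()
  for (s in starts) {
    e <- min(s + segment_length - 1L, L)
    if (e - s + 1L < segment_length && !keep_tail) next
    seg <- cols[s:e]
    n_inf <- sum(seg != 3L)
    if (n_inf < min_informative) {
      message(sprintf("segment [%d, %d]: only %d informative columns, skipped",
                      s, e, n_inf))
      next
    }
    cmp <- im_compare(column_sequence(seg), ...)
    eim <- cmp$fit_im$estimates
    ei <- cmp$fit_i$estimates
    rows[[length(rows) + 1L]] <- data.frame(
      start = s - 1L, end = e, n_informative = n_inf,
      tau1 = eim$tau1, tau2 = eim$tau2, coal = eim$coal, rec = eim$rec,
      mig = eim$mig, loglik_im = cmp$fit_im$loglik, aic_im = cmp$aic_im,
      tau_i = ei$tau2, coal_i = ei$coal, rec_i = ei$rec,
      loglik_i = cmp$fit_i$loglik, aic_i = cmp$aic_i, delta = cmp$delta,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Convert substitution-scaled estimates to years and population sizes
#'
#' Times in substitutions per site divide by the yearly mutation rate;
#' the effective population size follows the convention
#' `Ne = 1 / (2 * coal * mu_per_generation)` with
#' `mu_per_generation = mu_per_year * generation_time`.  This is a pure
#' reparameterization; nothing is refitted.
#'
#' @param fit An `im_fit` (or an [im_parameters()] object).
#' @param mu_per_year Mutation rate per bp per year.
#' @param generation_time Generation time in years.
#' @return A list of class `im_scaled` with split times in years,
#'   `Ne` and `Ne_anc`, and for IM fits the migration rate per generation.
#' @export
scale_estimates <- function(fit, mu_per_year, generation_time) {
  stopifnot(mu_per_year > 0, generation_time > 0)
  p <- if (inherits(fit, "im_fit")) fit$estimates else fit
  mu_gen <- mu_per_year * generation_time
  structure(list(
    tau1_years = p$tau1 / mu_per_year,
    tau2_years = p$tau2 / mu_per_year,
    Ne = 1 / (2 * p$coal * mu_gen),
    Ne_anc = 1 / (2 * p$coal_anc * mu_gen),
    mig_per_generation = p$mig * mu_gen,
    mu_per_year = mu_per_year, generation_time = generation_time),
    class = "im_scaled")
}

#' @export
print.im_scaled <- function(x, ...) {
  cat(sprintf("split: %.0f years (gene flow until %.0f years ago)\n",
              x$tau2_years, x$tau1_years))
  cat(sprintf("Ne = %.0f (ancestral %.0f); migration %.3g per lineage per generation\n",
              x$Ne, x$Ne_anc, x$mig_per_generation))
  cat(sprintf("[mu = %.3g /bp/year, generation time = %.3g years]\n",
              x$mu_per_year, x$generation_time))
  invisible(x)
}

#' Invert [scale_estimates()] for split times
#'
#' @param years Time in years.
#' @param mu_per_year Mutation rate per bp per year.
#' @return Time in expected substitutions per site.
#' @export
years_to_substitutions <- function(years, mu_per_year) years * mu_per_year
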