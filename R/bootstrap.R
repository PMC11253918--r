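#' Bootstrap a fitter over resampled read sets
#'
#' Nonparametric bootstrap: each replicate resamples the observed reads
#' with replacement at the original size, reruns the fitter, and records
#' the estimate; confidence intervals are empirical percentile intervals.
#' Only observed reads are resampled — the censoring correction for the
#' missing-fluorophore rate runs inside each replicate's fit, exactly as in
#' the original fit.
#'
#' Replicate seeds are derived from the master seed by a counter scheme, so
#' replicates are independent and individually reproducible.
#'
#' @param reads A `read_set`.
#' @param fitter Function `(read_set) -> fit_result` (or a named numeric
#'   vector of estimates). A fitter with a `weights` argument instead
#'   receives the unique resampled reads plus their multiplicities, which
#'   is equivalent but avoids materializing duplicated reads.
#' @param n_boot Number of replicates (at least 2).
#' @param ci_level Confidence level of the percentile interval.
#' @param seed Master seed.
#' @param point Optional precomputed point estimate (a `fit_result` or
#'   named vector); when absent the fitter runs once on the original data.
#' @return A `bootstrap_result`: `replicates` (matrix, replicates x
#'   parameters), `point`, `ci` (2 x parameters), `ci_level`,
#'   `replicate_seeds`, `n_failed`.
#' @export
bootstrap_fit <- function(reads, fitter, n_boot = 100, ci_level = 0.9,
                          seed = NULL, point = NULL) {
  stopifnot(inherits(reads, "read_set"), n_boot >= 2,
            ci_level > 0, ci_level < 1)
  as_est <- function(x) {
    if (inherits(x, "fit_result")) error_model_to_vector(x$estimate) else x
  }
  with_seed(seed, {
    rep_seeds <- sample.int(.Machine$integer.max - 1L, n_boot)
    if (is.null(point)) point <- fitter(reads)
    point <- as_est(point)
    N <- reads$n_reads
    reps <- matrix(NA_real_, n_boot, length(point),
                   dimnames = list(NULL, names(point)))
    failed <- logical(n_boot)
    use_weights <- "weights" %in% names(formals(fitter))
    for (b in seq_len(n_boot)) {
      set.seed(rep_seeds[b])
      idx <- sample.int(N, N, replace = TRUE)
      call_fitter <- function() {
        if (use_weights) {
          w <- tabulate(idx, nbins = N)
          nz <- which(w > 0)
          fitter(subset_reads(reads, nz), weights = w[nz])
        } else {
          fitter(subset_reads(reads, idx))
        }
      }
      est <- tryCatch(as_est(call_fitter()),
                      error = function(e) {
                        warning("bootstrap replicate ", b, " failed: ",
                                conditionMessage(e), call. = FALSE)
                        NULL
                      })
      if (is.null(est)) failed[b] <- TRUE else reps[b, ] <- est[names(point)]
    }
    if (mean(failed) > 0.2) {
      stop("more than 20% of bootstrap replicates failed", call. = FALSE)
    }
    a <- (1 - ci_level) / 2
    ok <- reps[!failed, , drop = FALSE]
    ci <- apply(ok, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
    structure(
      list(replicates = ok, point = point, ci = ci, ci_level = ci_level,
           replicate_seeds = rep_seeds, n_failed = sum(failed)),
      class = "bootstrap_result"
    )
  })
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap: %d replicates (%d failed), %.0f%% percentile CIs\n",
              nrow(x$replicates) + x$n_failed, x$n_failed, 100 * x$ci_level))
  out <- rbind(point = x$point,
               median = apply(x$replicates, 2, stats::median), x$ci)
  print(round(t(out), 5))
  invisible(x)
}

#' Bootstrap confidence intervals for the error model
#'
#' Convenience wrapper wiring [bootstrap_fit()] to the two fitters. The
#' point estimate is fit first with default settings; replicates are then
#' warm-started from it (the Baum-Welch replicates start EM at the point
#' estimate; the RMSE replicates skip the global search stage and refine
#' from the point estimate), which leaves the estimator's fixed point
#' unchanged while avoiding a cold start on every resample.
#'
#' @param reads A `read_set`.
#' @param p The `labeled_peptide`.
#' @param cm A `channel_model`.
#' @param method `"bw"` (modified Baum-Welch) or `"dp"` (dye-track RMSE).
#' @param n_boot,ci_level,seed See [bootstrap_fit()].
#' @param replicate_tol Convergence tolerance used inside the replicate
#'   fits. EM approaches its fixed point along a slowly contracting path
#'   from the warm start, so stopping at step size `tol` leaves an estimate
#'   several multiples of `tol` short of the optimum — in the direction of
#'   the point estimate, which deflates the bootstrap spread. The default
#'   keeps that residual well below the replicate sampling spread; loosen
#'   it only if speed matters more than interval width.
#' @param replicate_n_sim Simulated molecules per objective evaluation in
#'   the RMSE replicates (default equal to the read count; the point fit
#'   keeps the fitter's own larger default — replicate medians are
#'   insensitive to the extra per-replicate simulation noise, which only
#'   widens the reported intervals slightly, in the conservative
#'   direction).
#' @param ... Passed to the underlying fitter.
#' @return A `bootstrap_result`.
#' @export
bootstrap_error_model <- function(reads, p, cm, method = c("bw", "dp"),
                                  n_boot = 100, ci_level = 0.9, seed = NULL,
                                  replicate_tol = 2e-5,
                                  replicate_n_sim = NULL, ...) {
  method <- match.arg(method)
  if (method == "bw") {
    point_fit <- fit_baum_welch(reads, p, cm, ...)
    fitter <- function(rs, weights = NULL) {
      fit_baum_welch(rs, p, cm, init = point_fit$estimate, tol = replicate_tol,
                     weights = weights, ...)
    }
  } else {
    point_fit <- fit_direct_powell(reads, p, cm, ...)
    fitter <- function(rs) {
      fit_direct_powell(rs, p, cm, start = point_fit$estimate,
                        n_sim = replicate_n_sim %||% rs$n_reads,
                        max_cycles = 2, ...)
    }
  }
  bootstrap_fit(reads, fitter, n_boot = n_boot, ci_level = ci_level,
                seed = seed, point = point_fit)
}
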