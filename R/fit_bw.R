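#' Sufficient statistics for the weighted MLE updates
#'
#' For each error parameter, the modified Baum-Welch M-step needs a weighted
#' trial count `n` and a weighted success count `x` (the posterior-expected
#' number of error events); the update is simply `x / n`. Both are linear in
#' the posterior flow totals through each transition-matrix factor, so
#' statistics are additive over reads and invariant to read order.
#'
#' * dye loss (per channel): `n` = expected fluorophore-cycles exposed to
#'   loss; `x` = expected fluorophores lost across the dye-loss factor.
#' * Edman failure: `n` = expected attempts (unblocked, attached states with
#'   labeled residues still ahead); `x` = posterior no-advance mass.
#' * detachment: `n` = expected attached-molecule cycles; `x` = posterior
#'   detach mass.
#' * cyclic block: `n` = expected unblocked attached cycles; `x` = posterior
#'   block mass.
#' * initial block: `n` = 1 per read; `x` = posterior initial-block mass.
#' * dud (per channel): `n` = labels per read; `x` = expected
#'   initially-missing fluorophores.
#'
#' @param flows Aggregated flow totals from [aggregate_flows()] or
#'   [fb_batch()].
#' @param n_reads Number of reads the flows were accumulated over.
#' @param space The `hmm_state_space`.
#' @return A `sufficient_stats` object: named list of `c(n =, x =)` pairs,
#'   with `dye_loss` and `dud` as per-channel lists.
#' @export
stats_from_flows <- function(flows, n_reads, space) {
  S <- space$n_states
  cnts <- space$counts
  blk <- space$blocked
  det <- space$detached_flag
  L <- space$label_counts

  # dye loss per channel
  dye_loss <- lapply(seq_len(space$n_channels), function(ch) {
    Fm <- flows$dyeloss[[ch]]
    n <- sum(rowSums(Fm) * ifelse(det, 0L, cnts[, ch]))
    drop <- outer(cnts[, ch], cnts[, ch], `-`)  # count_i - count_j
    x <- sum(Fm * drop)
    c(n = n, x = x)
  })

  # Edman failure: trials only where an attempt is informative
  Fe <- flows$edman
  em_rows <- !blk & !det & !is.na(space$edman) & space$edman < space$e_max
  n_e <- sum(rowSums(Fe)[em_rows])
  x_e <- sum(diag(Fe)[em_rows])

  Fd <- flows$detach
  n_d <- sum(rowSums(Fd)[!det])
  x_d <- sum(Fd[!det, space$detached])

  Fc <- flows$cyclic_block
  cb_rows <- !blk & !det
  n_c <- sum(rowSums(Fc)[cb_rows])
  x_c <- sum(Fc[cb_rows, blk])

  Fi <- flows$init_block
  x_b <- sum(Fi[!blk & !det, blk])

  Fu <- flows$dud
  dud <- lapply(seq_len(space$n_channels), function(ch) {
    x <- sum(Fu[space$intact, ] * (L[ch] - cnts[, ch]))
    c(n = n_reads * L[ch], x = x)
  })

  structure(
    list(edman_failure = c(n = n_e, x = x_e),
         dye_loss = dye_loss,
         detach = c(n = n_d, x = x_d),
         dud = dud,
         initial_block = c(n = n_reads, x = x_b),
         cyclic_block = c(n = n_c, x = x_c)),
    class = "sufficient_stats"
  )
}

#' Accumulate sufficient statistics from one read's posteriors
#'
#' @param post A `substep_posteriors` from [forward_backward()] (or a list
#'   of them).
#' @param space The `hmm_state_space`.
#' @return A `sufficient_stats` object.
#' @export
accumulate_stats <- function(post, space) {
  n_reads <- if (inherits(post, "substep_posteriors")) 1L else length(post)
  stats_from_flows(aggregate_flows(post, space), n_reads, space)
}

#' Add two sufficient-statistics objects
#'
#' @param a,b `sufficient_stats` objects.
#' @return Their elementwise sum.
#' @export
stats_add <- function(a, b) {
  out <- a
  for (nm in c("edman_failure", "detach", "initial_block", "cyclic_block")) {
    out[[nm]] <- a[[nm]] + b[[nm]]
  }
  for (nm in c("dye_loss", "dud")) {
    out[[nm]] <- Map(`+`, a[[nm]], b[[nm]])
  }
  out
}

#' Censoring correction for the missing-fluorophore statistics
#'
#' Molecules whose fluorophores are all dud never show up as reads, so the
#' naive dud-rate MLE is biased low. With current dud rates `d`, the
#' probability that a molecule is missing from the data is
#' `x = prod(d[channel of each label])`; the expected number of unobserved
#' molecules behind `N` observed reads is `m = N * x / (1 - x)`. These `m`
#' phantom molecules are added to the dud statistics only — each contributes
#' all of its labels as both trials and duds. Unobserved molecules carry no
#' cycle information, so no other parameter's statistics are touched.
#'
#' @param stats A `sufficient_stats`.
#' @param d Per-channel dud rates of the current iteration.
#' @param n_reads Number of observed reads.
#' @param p The `labeled_peptide`.
#' @return The corrected `sufficient_stats`, with the phantom-read count in
#'   attribute `"missing_reads"`.
#' @export
dud_bias_correction <- function(stats, d, n_reads, p) {
  L <- label_counts(p)
  x_miss <- prod(d[p$labels$channel + 1L])
  if (x_miss >= 1 - 1e-9) {
    stop("all-dud probability ~1: dud rates are degenerate", call. = FALSE)
  }
  m <- n_reads * x_miss / (1 - x_miss)
  for (ch in seq_along(stats$dud)) {
    stats$dud[[ch]] <- stats$dud[[ch]] + c(n = m * L[ch], x = m * L[ch])
  }
  attr(stats, "missing_reads") <- m
  stats
}

clamp_rate <- function(r) pmin(pmax(r, 1e-9), 1 - 1e-9)

#' Weighted maximum likelihood M-step
#'
#' Each free rate becomes `x / n` (clamped to `[1e-9, 1 - 1e-9]` for
#' numerical safety); parameters in the fixed mask, or with no trials, keep
#' their current value.
#'
#' @param stats A `sufficient_stats`.
#' @param m The current `error_model` (supplies the mask and fallbacks).
#' @return An updated `error_model`.
#' @export
m_step <- function(stats, m) {
  upd <- function(cur, st) if (st[["n"]] > 0) clamp_rate(st[["x"]] / st[["n"]]) else cur
  for (nm in c("edman_failure", "detach", "initial_block", "cyclic_block")) {
    if (!(nm %in% m$fixed)) m[[nm]] <- upd(m[[nm]], stats[[nm]])
  }
  for (nm in c("dye_loss", "dud")) {
    if (!(nm %in% m$fixed)) {
      m[[nm]] <- vapply(seq_along(m[[nm]]),
                        function(ch) upd(m[[nm]][ch], stats[[nm]][[ch]]), 0.0)
    }
  }
  m
}

#' Fit the error model by modified Baum-Welch
#'
#' Expectation-maximization over all reads of a known labeled peptide: the
#' E-step runs the factored forward-backward algorithm per read and pools
#' posterior flows; the M-step computes the weighted MLE of each free error
#' rate directly from those flows (rather than re-estimating every
#' transition probability independently). The censoring correction for the
#' missing-fluorophore rate is interleaved with each iteration. The channel
#' (emission) model is held fixed throughout.
#'
#' Convergence is declared when the largest absolute parameter change falls
#' below `tol`. The log-likelihood trajectory is monitored: with the
#' censoring correction active the relevant monotone quantity is the
#' conditional log-likelihood of the observed (censored) sample,
#' `sum(log P(read)) - N * log(1 - x)` with `x` the all-dud probability; a
#' decrease beyond `1e-8 * |loglik|` raises an error, as EM guarantees
#' monotonicity and a violation indicates an implementation fault.
#'
#' @param reads A `read_set`.
#' @param p The `labeled_peptide` that generated the reads.
#' @param cm A `channel_model` (held constant).
#' @param init Initial `error_model`; default starts every free rate at
#'   0.05. The identifiability mask ([fix_for_identifiability()]) is always
#'   applied.
#' @param tol Convergence tolerance on the maximum parameter change.
#' @param max_iter Iteration cap.
#' @param bias_correction Apply the missing-fluorophore censoring
#'   correction (disable only for demonstration of the bias).
#' @param weights Optional per-read multiplicities (e.g. bootstrap resample
#'   counts); fitting `reads` with weights `w` is identical to fitting the
#'   read set with each read repeated `w` times.
#' @return A `fit_result` with elements `estimate`, `loglik_trajectory`,
#'   `n_iterations`, `converged`, `fixed`, `missing_reads`, `method`.
#' @export
fit_baum_welch <- function(reads, p, cm, init = NULL, tol = 1e-5,
                           max_iter = 250, bias_correction = TRUE,
                           weights = NULL) {
  stopifnot(inherits(reads, "read_set"), reads$n_reads >= 1)
  n_cycles <- reads$n_observations - 1L
  space <- build_state_space(p, n_cycles)
  if (is.null(init)) {
    init <- error_model(0.05, 0.05, 0.05, 0.05, 0.05, 0.05,
                        n_channels = p$n_channels)
  }
  em <- fix_for_identifiability(init, p)
  # masked parameters start at their fixed values
  if (!is.null(weights)) {
    stopifnot(length(weights) == reads$n_reads, all(weights >= 0))
  }
  N <- if (is.null(weights)) reads$n_reads else sum(weights)
  L <- label_counts(p)
  traj <- numeric(0)
  missing_reads <- 0
  converged <- FALSE
  iter <- 0L

  cond_loglik <- function(res, em) {
    ll <- if (is.null(weights)) sum(res$loglik) else sum(weights * res$loglik)
    if (bias_correction && !("dud" %in% em$fixed)) {
      x_miss <- prod(em$dud[p$labels$channel + 1L])
      ll <- ll - N * log(1 - x_miss)
    }
    ll
  }

  while (iter < max_iter) {
    iter <- iter + 1L
    res <- fb_batch(reads, space, em, cm, weights = weights)
    if (any(!is.finite(res$loglik))) {
      stop("non-finite likelihood for read ", which(!is.finite(res$loglik))[1],
           call. = FALSE)
    }
    ll <- cond_loglik(res, em)
    if (length(traj) > 0 && ll < traj[length(traj)] - 1e-8 * abs(ll)) {
      stop(sprintf("log-likelihood decreased (%.10g -> %.10g): EM invariant violated",
                   traj[length(traj)], ll), call. = FALSE)
    }
    traj <- c(traj, ll)

    stats <- stats_from_flows(res$flows, N, space)
    if (bias_correction && !("dud" %in% em$fixed)) {
      stats <- dud_bias_correction(stats, em$dud, N, p)
      missing_reads <- attr(stats, "missing_reads")
    }
    new_em <- m_step(stats, em)
    delta <- max(abs(error_model_to_vector(new_em) - error_model_to_vector(em)))
    em <- new_em
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  new_fit_result(estimate = em, loglik_trajectory = traj, n_iterations = iter,
                 converged = converged, fixed = em$fixed,
                 missing_reads = missing_reads, method = "baum_welch")
}

new_fit_result <- function(estimate, loglik_trajectory = numeric(0),
                           n_iterations = NA_integer_, converged = NA,
                           fixed = character(0), missing_reads = NA_real_,
                           method = "unknown", objective = NA_real_,
                           n_evaluations = NA_integer_) {
  structure(
    list(estimate = estimate, loglik_trajectory = loglik_trajectory,
         n_iterations = n_iterations, converged = converged, fixed = fixed,
         missing_reads = missing_reads, method = method,
         objective = objective, n_evaluations = n_evaluations),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit (", x$method, "): ",
      if (isTRUE(x$converged)) "converged" else "not converged",
      " after ", x$n_iterations, " iterations\n", sep = "")
  if (length(x$loglik_trajectory) > 0) {
    cat(sprintf("  final log-likelihood: %.4f\n",
                x$loglik_trajectory[length(x$loglik_trajectory)]))
  }
  if (is.finite(x$objective)) {
    cat(sprintf("  final objective (RMSE): %.4f\n", x$objective))
  }
  if (is.finite(x$missing_reads) && x$missing_reads > 0) {
    cat(sprintf("  estimated censored (unobserved) molecules: %.1f\n",
                x$missing_reads))
  }
  print(x$estimate)
  invisible(x)
}
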