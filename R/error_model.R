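#' Sequencing error model
#'
#' The six error parameters of the fluorosequencing generative model. All are
#' probabilities in `[0, 1]`:
#'
#' * `edman_failure` — probability that an Edman cycle fails to remove the
#'   N-terminal residue (per cycle).
#' * `dye_loss` — probability that a fluorophore is destroyed in a cycle
#'   (chemical destruction and photobleaching combined), per fluorophore per
#'   cycle, per channel.
#' * `detach` — probability that the whole peptide detaches from the surface
#'   in a cycle; its signal is pure background thereafter.
#' * `dud` — probability that a label is missing or dark from the start
#'   ("missing fluorophore" rate), per fluorophore, per channel.
#' * `initial_block` — probability the N-terminus is chemically blocked
#'   before the first cycle, stopping Edman degradation.
#' * `cyclic_block` — probability the N-terminus becomes blocked during each
#'   cycle.
#'
#' `dye_loss` and `dud` are per-channel vectors; scalars are broadcast to
#' `n_channels`. The `fixed` attribute names parameters held constant during
#' fitting (see [fix_for_identifiability()]).
#'
#' @param edman_failure,detach,initial_block,cyclic_block Scalar rates.
#' @param dye_loss,dud Scalar or per-channel rates.
#' @param n_channels Number of fluorophore color channels.
#' @param fixed Character vector of parameter names excluded from fitting.
#' @return An `error_model` object.
#' @examples
#' error_model(edman_failure = 0.06, dye_loss = 0.05, detach = 0.05,
#'             dud = 0.07, initial_block = 0.04, cyclic_block = 0.02)
#' @export
error_model <- function(edman_failure = 0, dye_loss = 0, detach = 0, dud = 0,
                        initial_block = 0, cyclic_block = 0, n_channels = 1L,
                        fixed = character(0)) {
  n_channels <- as.integer(n_channels)
  stopifnot(n_channels >= 1L)
  bcast <- function(x, nm) {
    if (length(x) == 1L) x <- rep(as.numeric(x), n_channels)
    if (length(x) != n_channels) {
      stop(sprintf("`%s` must have length 1 or n_channels = %d", nm, n_channels),
           call. = FALSE)
    }
    as.numeric(x)
  }
  m <- structure(
    list(
      edman_failure = as.numeric(edman_failure),
      dye_loss = bcast(dye_loss, "dye_loss"),
      detach = as.numeric(detach),
      dud = bcast(dud, "dud"),
      initial_block = as.numeric(initial_block),
      cyclic_block = as.numeric(cyclic_block),
      n_channels = n_channels,
      fixed = unique(as.character(fixed))
    ),
    class = "error_model"
  )
  validate_error_model(m)
  m
}

validate_error_model <- function(m) {
  rates <- unlist(m[error_param_names()])
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1)) {
    stop("all error rates must lie in [0, 1]", call. = FALSE)
  }
  bad <- setdiff(m$fixed, error_param_names())
  if (length(bad) > 0) {
    stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(m)
}

error_param_names <- function() {
  c("edman_failure", "dye_loss", "detach", "dud", "initial_block", "cyclic_block")
}

#' Flatten an error model to a named numeric vector
#'
#' Per-channel parameters expand to `dye_loss.1`, `dud.1`, ... (1-based
#' channel suffix) when there is more than one channel.
#'
#' @param m An `error_model`.
#' @return Named numeric vector.
#' @export
error_model_to_vector <- function(m) {
  out <- c()
  for (nm in error_param_names()) {
    v <- m[[nm]]
    names(v) <- if (length(v) == 1L) nm else paste0(nm, ".", seq_along(v))
    out <- c(out, v)
  }
  out
}

#' Apply the low-fluorophore-count identifiability rules
#'
#' With a single label, several parameters cannot be told apart from the
#' data: dye loss and detachment are visibly equivalent (one fluorophore
#' disappearing mid-run could be either), no all-dud molecule is ever
#' observed so the dud rate carries no information, and the Edman failure,
#' initial block and cyclic block rates trade off through the
#' last-visible-cycle distribution (see [kappa_distribution()]) leaving the
#' system underdetermined. For a one-label peptide this fixes `detach`,
#' `dud`, and `cyclic_block` at zero and excludes them from fitting. The
#' initial block rate stays free. Peptides with two or more labels in total
#' are unaffected.
#'
#' @param m An `error_model`.
#' @param p A `labeled_peptide`.
#' @return The error model, possibly with parameters zeroed and added to its
#'   `fixed` mask.
#' @export
fix_for_identifiability <- function(m, p) {
  stopifnot(inherits(m, "error_model"), inherits(p, "labeled_peptide"))
  if (sum(label_counts(p)) == 1L) {
    m$detach <- 0
    m$dud <- rep(0, m$n_channels)
    m$cyclic_block <- 0
    m$fixed <- unique(c(m$fixed, "detach", "dud", "cyclic_block"))
  }
  m
}

#' Distribution of a single fluorophore's last visible cycle
#'
#' For a peptide with one fluorophore at position `r`, sequenced with Edman
#' failure rate `e`, initial block rate `b`, and cyclic block rate `c` (and
#' no dye loss, detachment, or duds), the probability that the fluorophore's
#' last cycle is cycle \eqn{r+i} is
#' \deqn{\kappa_i = (1-b)\,\binom{i+r-1}{i}\,(1-e)^r\,e^i\,(1-c)^{r+i}.}
#' Successive terms satisfy \eqn{\kappa_{i+1} = \kappa_i\, e(1-c)\,(i+r)/(i+1)},
#' so the ratios depend on `e` and `c` only through the product `e(1-c)`:
#' distinct `(e, b, c)` triples with equal `e(1-c)` and matched `\kappa_0`
#' give identical distributions, which is why the cyclic block rate is fixed
#' at zero for one-label peptides.
#'
#' @param r 1-based position of the fluorophore's residue.
#' @param b,e,c Initial block, Edman failure, and cyclic block rates.
#' @param i_max Largest number of extra cycles to tabulate.
#' @return Numeric vector `kappa[i + 1]` = \eqn{\kappa_i}, for `i` in
#'   `0:i_max`.
#' @export
kappa_distribution <- function(r, b, e, c, i_max) {
  stopifnot(r >= 1, b >= 0, b < 1, e >= 0, e < 1, c >= 0, c < 1, i_max >= 0)
  i <- 0:i_max
  # log-space for numerical range; lchoose(i + r - 1, i) = log C(i+r-1, i)
  lk <- log1p(-b) + lchoose(i + r - 1, i) + r * log1p(-e) +
    ifelse(i == 0, 0, i * log(e)) + (r + i) * log1p(-c)
  exp(lk)
}

#' @export
print.error_model <- function(x, ...) {
  cat("Fluorosequencing error model (", x$n_channels, " channel",
      if (x$n_channels > 1) "s", "):\n", sep = "")
  v <- error_model_to_vector(x)
  for (nm in names(v)) {
    fx <- if (sub("\\..*$", "", nm) %in% x$fixed) "  [fixed]" else ""
    cat(sprintf("  %-15s %.6g%s\n", nm, v[[nm]], fx))
  }
  invisible(x)
}

#' Fluorophore emission model
#'
#' Per-channel intensity distribution parameters, held fixed while the error
#' rates are fitted. A state with `k` fluorophores on a channel emits
#' `Normal(bg_mu + k * mu, sd)` where the variance is
#' `k * sigma^2 + bg_sigma^2` under the default `"linear"` variance mode
#' (independent fluorophores) or `sigma^2 + bg_sigma^2` for `k >= 1` under
#' `"constant"`. `bg_mu` defaults to 0 because signal extraction subtracts a
#' local background estimate from every peak.
#'
#' @param mu Mean one-fluorophore intensity per channel (arbitrary units).
#' @param sigma One-fluorophore intensity standard deviation per channel.
#' @param bg_sigma Zero-count (background) standard deviation per channel.
#' @param bg_mu Background mean per channel, default 0.
#' @param variance_mode `"linear"` or `"constant"`.
#' @return A `channel_model` object.
#' @export
channel_model <- function(mu, sigma, bg_sigma, bg_mu = 0,
                          variance_mode = c("linear", "constant")) {
  variance_mode <- match.arg(variance_mode)
  n <- max(length(mu), length(sigma), length(bg_sigma), length(bg_mu))
  mu <- rep_len(as.numeric(mu), n)
  sigma <- rep_len(as.numeric(sigma), n)
  bg_sigma <- rep_len(as.numeric(bg_sigma), n)
  bg_mu <- rep_len(as.numeric(bg_mu), n)
  if (any(sigma <= 0) || any(bg_sigma <= 0)) {
    stop("sigma and bg_sigma must be positive", call. = FALSE)
  }
  structure(
    list(mu = mu, sigma = sigma, bg_sigma = bg_sigma, bg_mu = bg_mu,
         n_channels = n, variance_mode = variance_mode),
    class = "channel_model"
  )
}

#' Emission standard deviation for a fluorophore count
#'
#' @param cm A `channel_model`.
#' @param counts Integer vector or matrix of fluorophore counts.
#' @param channel Zero-based channel index (scalar).
#' @return Standard deviations, same shape as `counts`.
#' @export
emission_sd <- function(cm, counts, channel = 0L) {
  j <- channel + 1L
  if (cm$variance_mode == "linear") {
    sqrt(counts * cm$sigma[j]^2 + cm$bg_sigma[j]^2)
  } else {
    sqrt(ifelse(counts > 0, cm$sigma[j]^2, 0) + cm$bg_sigma[j]^2)
  }
}

#' @export
print.channel_model <- function(x, ...) {
  cat("Channel model (", x$n_channels, " channel", if (x$n_channels > 1) "s",
      ", ", x$variance_mode, " variance):\n", sep = "")
  for (j in seq_len(x$n_channels)) {
    cat(sprintf("  ch %d: mu = %g, sigma = %g, bg_sigma = %g, bg_mu = %g\n",
                j - 1L, x$mu[j], x$sigma[j], x$bg_sigma[j], x$bg_mu[j]))
  }
  invisible(x)
}
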