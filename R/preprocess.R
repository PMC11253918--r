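#' Estimate one-fluorophore intensity distribution parameters
#'
#' Histograms the intensity values (Freedman-Diaconis bin width), locates
#' the dominant positive-intensity mode, and reads off `mu` as the mode
#' location (parabolic refinement through the mode bin and its neighbours)
#' and `sigma` as the half-width at half-maximum divided by
#' `sqrt(2 * log(2))`. Mode-based fitting is preferred over least squares
#' because real intensity distributions deviate from normality in their
#' tails; the peak position and width are robust to that.
#'
#' @param intensities Numeric vector of at least 100 values.
#' @param n_peaks How many local maxima to report in the diagnostics.
#' @return List with `mu`, `sigma`, and diagnostics `bin_edges`,
#'   `bin_counts`, `mode_index`, `peaks` (locations of the top `n_peaks`
#'   local maxima, by height).
#' @export
estimate_mu_sigma <- function(intensities, n_peaks = 2L) {
  x <- intensities[is.finite(intensities)]
  if (length(x) < 100) {
    stop("need at least 100 intensity values", call. = FALSE)
  }
  h <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  if (h <= 0) {
    stop("degenerate intensity distribution (zero spread); supply mu/sigma by expert override",
         call. = FALSE)
  }
  lo <- min(x) - h
  breaks <- lo + h * (0:(ceiling((max(x) - lo) / h) + 1L))
  hist <- graphics::hist(x, breaks = breaks, plot = FALSE)
  cnt <- hist$counts
  mid <- hist$mids

  pos <- which(mid > 0)
  if (length(pos) == 0 || all(cnt[pos] == 0)) {
    stop("no positive-intensity mode found; supply mu/sigma by expert override",
         call. = FALSE)
  }
  mode_i <- pos[which.max(cnt[pos])]

  # parabolic sub-bin refinement of the mode location
  mu <- mid[mode_i]
  if (mode_i > 1 && mode_i < length(cnt)) {
    y0 <- cnt[mode_i - 1]; y1 <- cnt[mode_i]; y2 <- cnt[mode_i + 1]
    den <- y0 - 2 * y1 + y2
    if (den < 0) mu <- mid[mode_i] + h * 0.5 * (y0 - y2) / den
  }
  half <- cnt[mode_i] / 2

  cross <- function(dir) {
    i <- mode_i
    repeat {
      nxt <- i + dir
      if (nxt < 1 || nxt > length(cnt)) return(NA_real_)
      if (cnt[nxt] < half) {
        # linear interpolation between bin centers
        frac <- (cnt[i] - half) / (cnt[i] - cnt[nxt])
        return(abs(mid[i] + dir * frac * h - mu))
      }
      i <- nxt
    }
  }
  hw <- c(cross(1L), cross(-1L))
  hw <- hw[is.finite(hw)]
  if (length(hw) == 0) {
    stop("could not bracket the mode's half maximum; supply sigma by expert override",
         call. = FALSE)
  }
  sigma <- mean(hw) / sqrt(2 * log(2))

  # local maxima for diagnostics (e.g. the two-fluorophore peak near 2*mu)
  is_peak <- which(cnt > c(-Inf, cnt[-length(cnt)]) & cnt >= c(cnt[-1], -Inf))
  is_peak <- is_peak[order(cnt[is_peak], decreasing = TRUE)]
  peaks <- mid[utils::head(is_peak, n_peaks)]

  list(mu = mu, sigma = sigma, bin_edges = hist$breaks, bin_counts = cnt,
       mode_index = mode_i, peaks = peaks)
}

#' Background standard deviation from local-background samples
#'
#' Signal extraction subtracts a local background around each peak; the
#' median of the per-peak local background dispersion values serves as the
#' background sigma. The median of an even-length list is the mean of the
#' central pair.
#'
#' @param local_backgrounds Numeric vector of per-peak background values.
#' @return Scalar median.
#' @export
background_sigma <- function(local_backgrounds) {
  x <- local_backgrounds[is.finite(local_backgrounds)]
  if (length(x) == 0) stop("no local background values supplied", call. = FALSE)
  stats::median(x)
}

#' Filter likely-contaminant reads by intensity ranges
#'
#' A read is dropped if any of its intensity values, in any cycle, falls in
#' an excluded half-open interval `[lo, hi)` for its channel. Used to
#' remove contaminant signals and bleed-over from adjacent peaks whose
#' intensities sit between the expected fluorophore-count peaks.
#'
#' @param reads A `read_set`.
#' @param excluded_ranges Data frame with columns `channel` (zero-based),
#'   `lo`, `hi`. `NULL` or zero rows means no filtering.
#' @return List with `kept` (a `read_set`), `report` (the ranges with a
#'   `n_caught` column — reads may be caught by several ranges), and
#'   `n_dropped`.
#' @export
filter_reads <- function(reads, excluded_ranges = NULL) {
  stopifnot(inherits(reads, "read_set"))
  if (is.null(excluded_ranges) || nrow(excluded_ranges) == 0) {
    return(list(kept = reads, report = data.frame(), n_dropped = 0L))
  }
  stopifnot(all(c("channel", "lo", "hi") %in% names(excluded_ranges)),
            all(excluded_ranges$lo < excluded_ranges$hi))
  chcol <- rep(seq_len(reads$n_channels), times = reads$n_observations)
  drop <- rep(FALSE, reads$n_reads)
  n_caught <- integer(nrow(excluded_ranges))
  for (z in seq_len(nrow(excluded_ranges))) {
    cols <- which(chcol == excluded_ranges$channel[z] + 1L)
    x <- reads$intensities[, cols, drop = FALSE]
    hit <- rowSums(x >= excluded_ranges$lo[z] & x < excluded_ranges$hi[z]) > 0
    n_caught[z] <- sum(hit)
    drop <- drop | hit
  }
  report <- cbind(excluded_ranges, n_caught = n_caught)
  list(kept = subset_reads(reads, which(!drop)), report = report,
       n_dropped = sum(drop))
}
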