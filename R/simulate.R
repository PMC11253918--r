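#' Construct a read set
#'
#' A read set holds `n_reads` radiometries as rows of a numeric matrix with
#' `n_observations * n_channels` columns, ordered observation-major then
#' channel (column `t * n_channels + ch + 1` is observation `t`, channel
#' `ch`). Observation 0 is imaged before the first Edman cycle, so
#' `n_observations = n_cycles + 1`.
#'
#' @param intensities Numeric matrix of radiometries (rows = reads).
#' @param n_channels Number of color channels.
#' @param meta Optional provenance list (true parameters, seed, ...).
#' @return A `read_set`.
#' @export
read_set <- function(intensities, n_channels, meta = list()) {
  stopifnot(is.matrix(intensities), ncol(intensities) %% n_channels == 0)
  structure(
    list(intensities = intensities,
         n_reads = nrow(intensities),
         n_channels = as.integer(n_channels),
         n_observations = ncol(intensities) %/% n_channels,
         meta = meta),
    class = "read_set"
  )
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("Read set: %d reads, %d channel(s), %d observations (%d Edman cycles)\n",
              x$n_reads, x$n_channels, x$n_observations, x$n_observations - 1L))
  invisible(x)
}

#' Extract one read as a channels-by-observations matrix
#'
#' @param rs A `read_set` or `dye_track_set`.
#' @param i Read index.
#' @return Matrix `n_channels x n_observations`.
#' @export
get_read <- function(rs, i) {
  matrix(rs$intensities[i, ], nrow = rs$n_channels)
}

#' Subset or resample a read set by index
#'
#' @param rs A `read_set`.
#' @param idx Integer indices (duplicates allowed, e.g. bootstrap samples).
#' @return A `read_set`.
#' @export
subset_reads <- function(rs, idx) {
  read_set(rs$intensities[idx, , drop = FALSE], rs$n_channels, rs$meta)
}

#' Construct a dye-track set
#'
#' Integer twin of [read_set()]: fluorophore counts instead of intensities,
#' same column layout.
#'
#' @param counts Integer matrix of per-observation fluorophore counts.
#' @param n_channels Number of color channels.
#' @param meta Optional provenance list.
#' @return A `dye_track_set`.
#' @export
dye_track_set <- function(counts, n_channels, meta = list()) {
  stopifnot(is.matrix(counts), ncol(counts) %% n_channels == 0)
  storage.mode(counts) <- "integer"
  structure(
    list(intensities = counts,
         n_reads = nrow(counts),
         n_channels = as.integer(n_channels),
         n_observations = ncol(counts) %/% n_channels,
         meta = meta),
    class = "dye_track_set"
  )
}

#' @export
print.dye_track_set <- function(x, ...) {
  cat(sprintf("Dye track set: %d tracks, %d channel(s), %d observations\n",
              x$n_reads, x$n_channels, x$n_observations))
  invisible(x)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate one molecule's true dye track
#'
#' Applies the generative error model to a single molecule: per-fluorophore
#' dud draws and an initial N-terminal block draw before observation 0, then
#' per cycle (in order) detachment, per-fluorophore dye loss, cyclic
#' N-terminal blocking, and an Edman attempt that succeeds with probability
#' `1 - edman_failure`, removing the current N-terminal residue and any
#' label on it. Counts at observation `t` are the surviving fluorophores
#' after cycle `t`'s events; a detached molecule counts zero from the
#' detachment cycle onward. The molecule is observed only if at least one
#' fluorophore is functioning at observation 0.
#'
#' Uses the current R random number stream.
#'
#' @param p A `labeled_peptide`.
#' @param m An `error_model`.
#' @param n_cycles Number of Edman cycles.
#' @return List with `track` (integer matrix `n_channels x (n_cycles + 1)`)
#'   and `observed` (logical).
#' @export
simulate_molecule <- function(p, m, n_cycles) {
  stopifnot(inherits(p, "labeled_peptide"), inherits(m, "error_model"),
            n_cycles >= 1)
  C <- p$n_channels
  pos <- p$labels$position
  ch <- p$labels$channel + 1L
  nl <- length(pos)

  alive <- stats::runif(nl) >= m$dud[ch]
  blocked <- stats::runif(1) < m$initial_block
  detached <- FALSE
  n_cleaved <- 0L

  track <- matrix(0L, nrow = C, ncol = n_cycles + 1L)
  observed <- any(alive)
  for (l in which(alive)) track[ch[l], 1L] <- track[ch[l], 1L] + 1L

  for (t in seq_len(n_cycles)) {
    if (stats::runif(1) < m$detach) detached <- TRUE
    u_loss <- stats::runif(nl)
    alive <- alive & (u_loss >= m$dye_loss[ch])
    if (!blocked && stats::runif(1) < m$cyclic_block) blocked <- TRUE
    if (!blocked && !detached && stats::runif(1) >= m$edman_failure) {
      n_cleaved <- n_cleaved + 1L
      alive[pos == n_cleaved] <- FALSE
    }
    if (!detached) {
      for (l in which(alive)) track[ch[l], t + 1L] <- track[ch[l], t + 1L] + 1L
    }
  }
  list(track = track, observed = observed)
}

#' Simulate observed fluorosequencing reads
#'
#' Draws molecules under the error model, discards unobserved ones (all
#' fluorophores dud — such molecules never appear as reads, which censors
#' the data), and keeps drawing until exactly `n_reads` observed reads
#' exist. Intensities are then drawn per observation and channel as
#' `Normal(bg_mu + count * mu, sd)` with the channel model's variance rule;
#' detached molecules emit pure background from their detachment cycle on.
#'
#' @param p A `labeled_peptide`.
#' @param m An `error_model`.
#' @param cm A `channel_model`.
#' @param n_reads Number of observed reads to generate.
#' @param n_cycles Number of Edman cycles.
#' @param seed Optional integer seed (restores the RNG state afterwards).
#' @param tracks If `TRUE`, also return the true dye tracks.
#' @return A `read_set`; when `tracks = TRUE`, a list with elements `reads`
#'   and `tracks`.
#' @export
simulate_reads <- function(p, m, cm, n_reads, n_cycles, seed = NULL,
                           tracks = FALSE) {
  stopifnot(inherits(p, "labeled_peptide"), inherits(m, "error_model"),
            inherits(cm, "channel_model"), n_reads >= 1)
  L <- label_counts(p)
  p_all_dud <- prod(m$dud[p$labels$channel + 1L])
  if (p_all_dud >= 1 - 1e-9) {
    stop("all-dud probability is ~1; no molecule is ever observable",
         call. = FALSE)
  }
  with_seed(seed, {
    sim <- sim_tracks_cpp(
      p$labels$position, p$labels$channel, p$n_channels,
      m$edman_failure, m$dye_loss, m$detach, m$dud, m$initial_block,
      m$cyclic_block, as.integer(n_cycles), as.integer(n_reads),
      FALSE, max_attempts = ceiling(20 * n_reads / (1 - p_all_dud)) + 1000L,
      histogram = FALSE)
    cnt <- sim$tracks
    C <- p$n_channels
    n_obs <- n_cycles + 1L
    chcol <- rep(seq_len(C), times = n_obs)  # channel of each column
    mu <- cm$bg_mu[chcol][col(cnt)] + cnt * cm$mu[chcol][col(cnt)]
    sdm <- matrix(0, nrow(cnt), ncol(cnt))
    for (ch in seq_len(C)) {
      cols <- which(chcol == ch)
      sdm[, cols] <- emission_sd(cm, cnt[, cols, drop = FALSE], ch - 1L)
    }
    ints <- matrix(stats::rnorm(length(cnt), mean = mu, sd = sdm),
                   nrow = nrow(cnt))
    meta <- list(true_error_model = m, seed = seed, attempts = sim$attempts)
    rs <- read_set(ints, C, meta)
    if (tracks) list(reads = rs, tracks = dye_track_set(cnt, C, meta)) else rs
  })
}

#' Simulate a histogram of observed dye tracks
#'
#' Simulates `n_molecules` molecules (a fixed number of attempts), keeps the
#' observed ones, and tabulates their noise-free dye tracks. The fixed
#' attempt count gives every molecule an identical random-draw layout, so
#' repeated calls at nearby parameter values under a common seed give
#' maximally correlated histograms — the common-random-numbers scheme the
#' RMSE objective relies on.
#'
#' @param p A `labeled_peptide`.
#' @param m An `error_model`.
#' @param n_molecules Number of molecules to attempt.
#' @param n_cycles Number of Edman cycles.
#' @param seed Optional integer seed (restores the RNG state afterwards).
#' @return A `track_histogram`.
#' @export
simulate_track_histogram <- function(p, m, n_molecules, n_cycles, seed = NULL) {
  with_seed(seed, {
    sim <- sim_tracks_cpp(
      p$labels$position, p$labels$channel, p$n_channels,
      m$edman_failure, m$dye_loss, m$detach, m$dud, m$initial_block,
      m$cyclic_block, as.integer(n_cycles), as.integer(n_molecules),
      TRUE, max_attempts = 0L, histogram = TRUE)
    new_track_histogram(sim$counts, sim$n_observed, p$n_channels,
                        n_cycles + 1L)
  })
}
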