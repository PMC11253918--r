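#' Reduce reads to integer dye tracks
#'
#' Every intensity value is replaced by the fluorophore count (0 up to the
#' per-channel maximum) whose emission density is highest at that value —
#' the integer approximation of the read. Ties break toward the smaller
#' count.
#'
#' @param reads A `read_set`.
#' @param cm A `channel_model`.
#' @param max_counts Per-channel maximum count to consider (normally the
#'   peptide's per-channel label counts).
#' @return A `dye_track_set`.
#' @export
reduce_to_dye_track <- function(reads, cm, max_counts) {
  stopifnot(inherits(reads, "read_set"))
  C <- reads$n_channels
  max_counts <- rep_len(as.integer(max_counts), C)
  X <- reads$intensities
  best_k <- matrix(0L, nrow(X), ncol(X))
  chcol <- rep(seq_len(C), times = reads$n_observations)
  for (ch in seq_len(C)) {
    cols <- which(chcol == ch)
    x <- X[, cols, drop = FALSE]
    bk <- matrix(0L, nrow(x), ncol(x))
    bd <- stats::dnorm(x, mean = cm$bg_mu[ch], sd = emission_sd(cm, 0L, ch - 1L),
                       log = TRUE)
    for (k in seq_len(max_counts[ch])) {
      d <- stats::dnorm(x, mean = cm$bg_mu[ch] + k * cm$mu[ch],
                        sd = emission_sd(cm, k, ch - 1L), log = TRUE)
      better <- d > bd  # strict: ties keep the smaller count
      bk[better] <- k
      bd[better] <- d[better]
    }
    best_k[, cols] <- bk
  }
  dye_track_set(best_k, C, reads$meta)
}

new_track_histogram <- function(counts, total, n_channels, n_observations) {
  structure(
    list(counts = counts, total = total, n_channels = n_channels,
         n_observations = n_observations),
    class = "track_histogram"
  )
}

#' Tabulate dye tracks into a histogram
#'
#' Track keys are the counts joined with commas in observation-major,
#' then channel, order (the same layout as the file format).
#'
#' @param tracks A `dye_track_set`.
#' @return A `track_histogram`: named counts and the total.
#' @export
track_histogram <- function(tracks) {
  stopifnot(inherits(tracks, "dye_track_set"))
  keys <- do.call(paste, c(as.data.frame(tracks$intensities), sep = ","))
  tab <- table(keys)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  new_track_histogram(counts, tracks$n_reads, tracks$n_channels,
                      tracks$n_observations)
}

#' @export
print.track_histogram <- function(x, ...) {
  cat(sprintf("Track histogram: %d reads over %d distinct tracks\n",
              x$total, length(x$counts)))
  invisible(x)
}

#' RMSE between observed and simulated dye-track histograms
#'
#' Simulates `n_sim` molecules at the candidate error model with a fixed
#' seed (common random numbers, so repeated evaluations at the same point
#' are identical and nearby points are maximally correlated), tabulates the
#' observed (censored) tracks, rescales the simulated counts to the
#' observed total, and returns the root-mean-square difference over the
#' union of track keys.
#'
#' By default (`sim_noise = TRUE`) each simulated molecule's track passes
#' through the emission channel and the same per-value density-argmax
#' reduction as the real reads, so both histograms carry identical
#' count-misassignment noise; with `sim_noise = FALSE` the simulated side
#' is the noise-free truth-level track, which leaves the reduction noise
#' unmatched and measurably biases weakly identified rates.
#'
#' @param m Candidate `error_model`.
#' @param observed A `track_histogram` of the data.
#' @param p The `labeled_peptide`.
#' @param cm The `channel_model` (used for the simulated-side emission and
#'   reduction).
#' @param n_sim Number of simulated molecules per evaluation.
#' @param sim_seed Seed reused for every evaluation.
#' @param pool Optional pre-drawn pool from [draw_sim_pool()]; supplying it
#'   (drawn once per fit) avoids regenerating the same `sim_seed` stream at
#'   every evaluation.
#' @param sim_noise Pass simulated tracks through the emission/reduction
#'   channel (default) or compare truth-level tracks.
#' @return Non-negative scalar.
#' @export
rmse_objective <- function(m, observed, p, cm, n_sim, sim_seed, pool = NULL,
                           sim_noise = TRUE) {
  stopifnot(inherits(observed, "track_histogram"))
  n_cycles <- observed$n_observations - 1L
  if (is.null(pool)) {
    pool <- draw_sim_pool(p, n_sim, n_cycles, sim_seed, noise = sim_noise)
  }
  raw <- sim_tracks_pool_cpp(pool$u, pool$z, p$labels$position,
                             p$labels$channel, p$n_channels,
                             m$edman_failure, m$dye_loss, m$detach, m$dud,
                             m$initial_block, m$cyclic_block, n_cycles,
                             cm$mu, cm$sigma, cm$bg_sigma, cm$bg_mu,
                             cm$variance_mode == "linear")
  sim <- new_track_histogram(raw$counts, raw$n_observed, p$n_channels,
                             observed$n_observations)
  if (sim$total == 0) return(sqrt(sum(as.numeric(observed$counts)^2)))
  scale <- observed$total / sim$total
  keys <- union(names(observed$counts), names(sim$counts))
  obs <- rep(0, length(keys)); names(obs) <- keys
  obs[names(observed$counts)] <- observed$counts
  simc <- rep(0, length(keys)); names(simc) <- keys
  simc[names(sim$counts)] <- sim$counts * scale
  sqrt(mean((obs - simc)^2))
}

#' Draw the random-number pool for common-random-numbers simulation
#'
#' Every simulated molecule consumes a fixed layout of uniforms (one per
#' label for duds, one for the initial block, then per cycle one for
#' detachment, one per label for dye loss, one for cyclic blocking and one
#' for the Edman attempt), plus — when emission noise is simulated — one
#' standard normal per observation and channel. Drawing the whole pool once
#' per fit and reusing it across objective evaluations makes the RMSE
#' objective a deterministic, maximally correlated function of the
#' parameters.
#'
#' @param p A `labeled_peptide`.
#' @param n_sim Number of molecules.
#' @param n_cycles Number of Edman cycles.
#' @param seed Seed (RNG state is restored afterwards).
#' @param noise Also draw the emission-noise normals.
#' @return List with `u` (uniforms) and `z` (normals; length 0 when
#'   `noise = FALSE`).
#' @export
draw_sim_pool <- function(p, n_sim, n_cycles, seed, noise = TRUE) {
  nl <- nrow(p$labels)
  per <- nl + 1L + n_cycles * (nl + 3L)
  n_obs <- n_cycles + 1L
  with_seed(seed, {
    u <- stats::runif(as.numeric(n_sim) * per)
    z <- if (noise) {
      stats::rnorm(as.numeric(n_sim) * n_obs * p$n_channels)
    } else numeric(0)
    list(u = u, z = z)
  })
}

#' Coordinate trisection global search
#'
#' Derivative-free global search over a box: starting from the box center,
#' repeatedly evaluate two test points symmetrically above and below the
#' current center along one dimension, keep the best of the three, halve
#' that dimension's step, and cycle through dimensions until the evaluation
#' budget is spent or all steps are below `step_tol`. Returns the best point
#' ever evaluated (never worse than the start).
#'
#' @param objective Function of a numeric vector.
#' @param lower,upper Box bounds.
#' @param budget Maximum number of objective evaluations.
#' @param start Optional start point (default box center).
#' @param step_tol Stop when every dimension's step is below this.
#' @return List with `par`, `value`, `n_evaluations`, and the evaluation
#'   `history` (list with matrix `par`, one row per evaluated point, and
#'   vector `value`).
#' @export
direct_search <- function(objective, lower, upper, budget = 150, start = NULL,
                          step_tol = 1e-3) {
  K <- length(lower)
  stopifnot(length(upper) == K, all(lower < upper), budget >= 3 * K)
  center <- if (is.null(start)) (lower + upper) / 2 else pmin(pmax(start, lower), upper)
  w <- (upper - lower) / 4
  hist_par <- matrix(NA_real_, budget, K)
  hist_val <- rep(NA_real_, budget)
  n_eval <- 0L
  score <- function(x) {
    v <- objective(x)
    n_eval <<- n_eval + 1L
    hist_par[n_eval, ] <<- x
    hist_val[n_eval] <<- v
    v
  }
  f_center <- score(center)
  best <- center
  f_best <- f_center
  while (n_eval + 2L <= budget && max(w) >= step_tol) {
    for (k in seq_len(K)) {
      if (n_eval + 2L > budget) break
      lo <- center; lo[k] <- max(lower[k], center[k] - w[k])
      hi <- center; hi[k] <- min(upper[k], center[k] + w[k])
      f_lo <- score(lo)
      f_hi <- score(hi)
      if (f_lo < f_center && f_lo <= f_hi) {
        center <- lo; f_center <- f_lo
      } else if (f_hi < f_center) {
        center <- hi; f_center <- f_hi
      }
      if (f_center < f_best) {
        best <- center; f_best <- f_center
      }
      w[k] <- w[k] / 2
    }
  }
  list(par = best, value = f_best, n_evaluations = n_eval,
       history = list(par = hist_par[seq_len(n_eval), , drop = FALSE],
                      value = hist_val[seq_len(n_eval)]))
}

#' Powell-style line minimization with pattern moves
#'
#' Refines a point by successive one-dimensional line minimizations
#' (golden-section / parabolic searches, box-clipped), cycling through the
#' coordinate directions; after each cycle an extra line minimization runs
#' along the cycle's net displacement (the pattern move of Powell's
#' direction-set idea). The pattern step lets the search track the narrow
#' ridges that pure coordinate descent stalls on — here, the trade-off
#' between the two blocking rates and the Edman failure rate — while the
#' coordinate set is kept intact so the search directions never degenerate.
#' The objective never increases: a line-search result is accepted only if
#' it improves on the current point.
#'
#' @param objective Function of a numeric vector.
#' @param start Start point (inside the box).
#' @param lower,upper Box bounds.
#' @param tol Stop when a full cycle improves the objective by less.
#' @param max_cycles Cycle cap.
#' @param line_tol `x`-tolerance of each one-dimensional search.
#' @param bracket Initial half-width of each line search's bracket as a
#'   fraction of the box scale; brackets re-center on the current point and
#'   shrink as it settles, keeping searches local once the basin is found.
#' @return List with `par`, `value`, `n_evaluations`, `n_cycles`.
#' @export
powell_refine <- function(objective, start, lower, upper, tol = 1e-3,
                          max_cycles = 30, line_tol = 2e-5, bracket = 1 / 8) {
  K <- length(start)
  x <- pmin(pmax(start, lower), upper)
  f_x <- objective(x)
  n_eval <- 1L
  cycles <- 0L
  scale <- max(upper - lower)
  w <- rep(max(bracket * scale, 4 * line_tol), K)

  # minimize objective along x + t * d within the box; returns new (x, f)
  line_min <- function(x, f_x, d, wk) {
    nz <- which(abs(d) > 1e-14)
    if (length(nz) == 0) return(list(x = x, f = f_x, moved = 0))
    # feasible t-range from the box, intersected with the local bracket
    t_bounds <- vapply(nz, function(k) {
      r <- sort(c((lower[k] - x[k]) / d[k], (upper[k] - x[k]) / d[k]))
      r
    }, numeric(2))
    t_lo <- max(max(t_bounds[1, ]), -wk)
    t_hi <- min(min(t_bounds[2, ]), wk)
    if (t_hi - t_lo < line_tol) return(list(x = x, f = f_x, moved = 0))
    f1d <- function(t) {
      n_eval <<- n_eval + 1L
      objective(pmin(pmax(x + t * d, lower), upper))
    }
    opt <- stats::optimize(f1d, interval = c(t_lo, t_hi), tol = line_tol)
    if (opt$objective < f_x) {
      list(x = pmin(pmax(x + opt$minimum * d, lower), upper),
           f = opt$objective, moved = abs(opt$minimum))
    } else {
      list(x = x, f = f_x, moved = 0)
    }
  }

  axes <- diag(K)
  repeat {
    cycles <- cycles + 1L
    f_start_cycle <- f_x
    x_start_cycle <- x
    for (i in seq_len(K)) {
      res <- line_min(x, f_x, axes[i, ], w[i])
      x <- res$x
      f_x <- res$f
      # widen while the minimum presses against the bracket, else shrink
      w[i] <- if (res$moved > 0.8 * w[i]) min(w[i] * 2, scale) else
        max(w[i] / 2, 8 * line_tol)
    }
    d_pat <- x - x_start_cycle
    if (sqrt(sum(d_pat^2)) > line_tol) {
      d_pat <- d_pat / max(abs(d_pat))
      res <- line_min(x, f_x, d_pat, scale)
      x <- res$x
      f_x <- res$f
    }
    if (f_start_cycle - f_x < tol || cycles >= max_cycles) break
  }
  list(par = x, value = f_x, n_evaluations = n_eval, n_cycles = cycles)
}

# greedy selection of low-objective, well-separated points from a search
# history: best point first, then the best point at least min_sep away
# (infinity norm) from all chosen ones, and so on
diverse_candidates <- function(history, n, min_sep) {
  ord <- order(history$value)
  chosen <- list()
  for (i in ord) {
    x <- history$par[i, ]
    far <- all(vapply(chosen, function(y) max(abs(x - y)) >= min_sep, TRUE))
    if (far) chosen[[length(chosen) + 1L]] <- x
    if (length(chosen) >= n) break
  }
  chosen
}

free_param_layout <- function(m) {
  # names and (list-name, index) slots of free parameters, in a fixed order
  lay <- list()
  for (nm in error_param_names()) {
    if (nm %in% m$fixed) next
    len <- length(m[[nm]])
    for (ch in seq_len(len)) {
      label <- if (len == 1L) nm else paste0(nm, ".", ch)
      lay[[label]] <- c(field = nm, index = ch)
    }
  }
  lay
}

vector_to_error_model <- function(par, template, layout) {
  m <- template
  for (z in seq_along(layout)) {
    sl <- layout[[z]]
    m[[sl[["field"]]]][as.integer(sl[["index"]])] <- par[z]
  }
  m
}

#' Fit the error model by dye-track RMSE minimization
#'
#' The general-purpose alternative fitter: reads are reduced to integer dye
#' tracks and tabulated; candidate error models are scored by the RMSE
#' between the observed histogram and a histogram simulated at the
#' candidate parameters ([rmse_objective()]); a coordinate trisection
#' global search ([direct_search()]) locates the basin and coordinate-wise
#' line minimization ([powell_refine()]) polishes the estimate. The
#' identifiability mask for low label counts is applied before fitting.
#'
#' @param reads A `read_set`.
#' @param p The `labeled_peptide`.
#' @param cm A `channel_model` (used only for the dye-track reduction).
#' @param box_lower,box_upper Per-rate search bounds; scalars are recycled
#'   over the free parameters. The default `[0, 0.5]` covers all rates
#'   normally encountered; raise `box_upper` (e.g. to 1 for the initial
#'   block rate) for intentionally blocked peptides.
#' @param n_sim Simulated molecules per objective evaluation; default 5x
#'   the read count.
#' @param seed Seed for the common-random-numbers objective.
#' @param budget Evaluation budget of the global search stage.
#' @param tol Per-cycle improvement tolerance of the refinement stage.
#' @param start Optional start point (an `error_model`); when given, the
#'   global search stage is skipped and only the line-minimization
#'   refinement runs — used for warm-started bootstrap replicates.
#' @param sim_noise See [rmse_objective()].
#' @param max_cycles Cycle cap of the refinement stage (see
#'   [powell_refine()]); warm-started bootstrap replicates use a small cap.
#' @param n_starts Number of diverse global-stage candidates to refine.
#'   The objective carries shallow local basins along the weakly identified
#'   blocking-rate ridge; refining the few best well-separated points the
#'   global stage visited and keeping the lowest final objective is cheap
#'   insurance against settling in the wrong one.
#' @return A `fit_result` with the final RMSE in `objective`.
#' @export
fit_direct_powell <- function(reads, p, cm, box_lower = 0, box_upper = 0.5,
                              n_sim = 5L * reads$n_reads, seed = 1L,
                              budget = 150, tol = 1e-3, start = NULL,
                              sim_noise = TRUE, max_cycles = 30,
                              n_starts = 3L) {
  stopifnot(inherits(reads, "read_set"), reads$n_reads >= 1)
  template <- error_model(n_channels = p$n_channels)
  template <- fix_for_identifiability(template, p)
  layout <- free_param_layout(template)
  K <- length(layout)
  lower <- rep_len(box_lower, K)
  upper <- rep_len(box_upper, K)

  tracks <- reduce_to_dye_track(reads, cm, label_counts(p))
  observed <- track_histogram(tracks)
  pool <- draw_sim_pool(p, n_sim, reads$n_observations - 1L, seed,
                        noise = sim_noise)

  objective <- function(par) {
    m <- vector_to_error_model(par, template, layout)
    rmse_objective(m, observed, p, cm, n_sim, sim_seed = seed, pool = pool,
                   sim_noise = sim_noise)
  }

  n_eval <- 0L
  if (is.null(start)) {
    gs <- direct_search(objective, lower, upper, budget = budget)
    n_eval <- gs$n_evaluations
    starts <- diverse_candidates(gs$history, n_starts,
                                 min_sep = 0.08 * max(upper - lower))
  } else {
    starts <- list(pmin(pmax(error_model_to_vector(start)[names(layout)],
                             lower), upper))
  }
  ref <- NULL
  n_cycles_total <- 0L
  for (x0 in starts) {
    cand <- powell_refine(objective, x0, lower, upper, tol = tol,
                          max_cycles = max_cycles)
    n_eval <- n_eval + cand$n_evaluations
    n_cycles_total <- n_cycles_total + cand$n_cycles
    if (is.null(ref) || cand$value < ref$value) ref <- cand
  }

  # valley-walk polish (cold starts only). The objective forms a curved
  # valley coupling the weakly identified rates: moving one coordinate
  # alone climbs the valley wall, and descending along the curved floor
  # yields per-cycle gains below any practical stopping tolerance, so the
  # refinement can halt partway along it. Walk each coordinate in small
  # steps, briefly re-optimizing the remaining parameters onto the valley
  # floor at each step, and keep going while the floor value drops.
  if (is.null(start) && K > 0) {
    h <- 0.01 * (upper - lower)
    for (k in seq_len(K)) {
      for (s in c(1, -1)) {
        for (step in 1:3) {
          y <- ref$par
          y[k] <- min(max(y[k] + s * h[k], lower[k]), upper[k])
          cand <- powell_refine(objective, y, lower, upper, tol = 5e-4,
                                max_cycles = 2)
          n_eval <- n_eval + cand$n_evaluations
          n_cycles_total <- n_cycles_total + cand$n_cycles
          if (cand$value < ref$value - 1e-6) ref <- cand else break
        }
      }
    }
  }
  est <- vector_to_error_model(ref$par, template, layout)

  new_fit_result(estimate = est, converged = TRUE,
                 n_iterations = n_cycles_total, fixed = template$fixed,
                 method = "direct_powell", objective = ref$value,
                 n_evaluations = n_eval)
}
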