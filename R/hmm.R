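#' Build the merged, factored HMM state space for a peptide
#'
#' States track the number of successful Edman cycles, the surviving
#' fluorophore count on each channel, and whether the N-terminus is blocked;
#' one extra absorbing state represents a detached peptide. Fluorophores on
#' the same channel are exchangeable, so states differing only in *which*
#' fluorophores survive are merged and only counts are kept. Successful
#' Edman cycles are capped at the last labeled residue position (beyond it
#' no fluorophore remains, so further progress is unobservable); this makes
#' every downstream likelihood invariant to unlabeled C-terminal residues.
#'
#' The transition matrix is never formed explicitly: it is the product of
#' one sparse factor per error type (detachment, per-channel dye loss,
#' cyclic N-terminal blocking, Edman degradation, plus initial dud and
#' initial-block factors before the first observation). Every factor is
#' row-stochastic and the Edman factor is the identity on blocked and
#' detached states.
#'
#' @param p A `labeled_peptide`.
#' @param n_cycles Number of Edman cycles (observations = `n_cycles + 1`;
#'   observation 0 is imaged before any Edman chemistry).
#' @param max_states Guard against state-space blowup.
#' @return An `hmm_state_space` object.
#' @export
build_state_space <- function(p, n_cycles, max_states = 1e6) {
  stopifnot(inherits(p, "labeled_peptide"), n_cycles >= 1)
  L <- label_counts(p)
  C <- p$n_channels
  e_max <- min(n_cycles, last_label_position(p))

  # maxc[e + 1, ch]: labels on channel ch at positions > e (still attached)
  maxc <- matrix(0L, nrow = e_max + 1L, ncol = C)
  for (e in 0:e_max) {
    for (ch in seq_len(C)) {
      maxc[e + 1L, ch] <- sum(p$labels$channel == ch - 1L & p$labels$position > e)
    }
  }

  edman <- integer(0)
  counts <- matrix(0L, nrow = 0, ncol = C)
  blocked <- logical(0)
  for (e in 0:e_max) {
    grid <- expand.grid(lapply(seq_len(C), function(ch) 0:maxc[e + 1L, ch]))
    grid <- as.matrix(grid)
    storage.mode(grid) <- "integer"
    for (b in c(FALSE, TRUE)) {
      edman <- c(edman, rep(e, nrow(grid)))
      counts <- rbind(counts, grid)
      blocked <- c(blocked, rep(b, nrow(grid)))
    }
    if (length(edman) + 1 > max_states) {
      stop("state space exceeds max_states = ", max_states,
           "; consider pruning or fewer cycles", call. = FALSE)
    }
  }
  S <- length(edman) + 1L  # + detached
  edman <- c(edman, NA_integer_)
  counts <- rbind(counts, rep(0L, C))
  blocked <- c(blocked, FALSE)
  detached <- c(rep(FALSE, S - 1L), TRUE)
  dimnames(counts) <- NULL

  key <- function(e, cnt, blk) paste(e, paste(cnt, collapse = "."), as.integer(blk))
  keys <- vapply(seq_len(S - 1L),
                 function(s) key(edman[s], counts[s, ], blocked[s]), "")
  index <- seq_len(S - 1L)
  names(index) <- keys

  # channel (1-based; 0 = unlabeled) of the residue removed by each Edman success
  res_channel <- integer(length(p$sequence))
  res_channel[p$labels$position] <- p$labels$channel + 1L

  intact <- unname(index[[key(0L, L, FALSE)]])

  structure(
    list(
      n_states = S, edman = edman, counts = counts, blocked = blocked,
      detached_flag = detached, detached = S, intact = intact,
      index = index, key = key, e_max = e_max, maxc = maxc,
      res_channel = res_channel, n_cycles = as.integer(n_cycles),
      n_channels = C, label_counts = L, peptide = p
    ),
    class = "hmm_state_space"
  )
}

#' @export
print.hmm_state_space <- function(x, ...) {
  cat(sprintf(
    "HMM state space: %d states (%d unblocked + %d blocked + 1 detached), %d cycles, Edman cap %d\n",
    x$n_states, (x$n_states - 1L) / 2L, (x$n_states - 1L) / 2L,
    x$n_cycles, x$e_max))
  invisible(x)
}

state_lookup <- function(space, e, cnt, blk) {
  unname(space$index[[space$key(e, cnt, blk)]])
}

#' Build the sparse transition-matrix factors for given error rates
#'
#' One factor per error type, as sparse triplet lists `(i, j, p)` with
#' `p = P(i -> j)`. Every factor is row-stochastic over the full state
#' space (identity on states it does not act on).
#'
#' @param space An `hmm_state_space`.
#' @param m An `error_model` with `n_channels` matching the peptide.
#' @return Named list with elements `dud`, `init_block`, `detach`,
#'   `cyclic_block`, `edman` (triplet lists) and `dyeloss` (list of triplet
#'   lists, one per channel).
#' @export
build_factors <- function(space, m) {
  stopifnot(inherits(space, "hmm_state_space"), inherits(m, "error_model"))
  if (m$n_channels != space$n_channels) {
    stop("error model has ", m$n_channels, " channels but peptide needs ",
         space$n_channels, call. = FALSE)
  }
  S <- space$n_states
  det_idx <- space$detached
  live <- which(!space$detached_flag)

  trip <- function(i, j, p) list(i = as.integer(i), j = as.integer(j),
                                 p = as.numeric(p))

  # --- initial dud factor: acts only on the intact state ------------------
  L <- space$label_counts
  C <- space$n_channels
  grid <- as.matrix(expand.grid(lapply(seq_len(C), function(ch) 0:L[ch])))
  storage.mode(grid) <- "integer"
  pr <- apply(grid, 1L, function(cnt) {
    prod(stats::dbinom(cnt, L, 1 - m$dud))
  })
  jj <- apply(grid, 1L, function(cnt) state_lookup(space, 0L, cnt, FALSE))
  others <- setdiff(seq_len(S), space$intact)
  dud <- trip(c(rep(space$intact, length(jj)), others), c(jj, others),
              c(pr, rep(1, length(others))))

  # --- blocking factors ----------------------------------------------------
  block_factor <- function(rate) {
    unb <- which(!space$blocked & !space$detached_flag)
    jb <- vapply(unb, function(s) {
      state_lookup(space, space$edman[s], space$counts[s, ], TRUE)
    }, 0L)
    rest <- setdiff(seq_len(S), unb)
    trip(c(unb, unb, rest), c(unb, jb, rest),
         c(rep(1 - rate, length(unb)), rep(rate, length(unb)),
           rep(1, length(rest))))
  }

  # --- detachment ----------------------------------------------------------
  detach <- trip(c(live, live, det_idx), c(live, rep(det_idx, length(live)), det_idx),
                 c(rep(1 - m$detach, length(live)), rep(m$detach, length(live)), 1))

  # --- per-channel dye loss ------------------------------------------------
  dyeloss <- lapply(seq_len(C), function(ch) {
    rate <- m$dye_loss[ch]
    ii <- integer(0); jj <- integer(0); pp <- numeric(0)
    for (s in seq_len(S)) {
      k <- space$counts[s, ch]
      if (space$detached_flag[s] || k == 0L) {
        ii <- c(ii, s); jj <- c(jj, s); pp <- c(pp, 1)
      } else {
        for (c2 in 0:k) {
          cnt <- space$counts[s, ]
          cnt[ch] <- c2
          ii <- c(ii, s)
          jj <- c(jj, state_lookup(space, space$edman[s], cnt, space$blocked[s]))
          pp <- c(pp, stats::dbinom(c2, k, 1 - rate))
        }
      }
    }
    trip(ii, jj, pp)
  })

  # --- Edman degradation ---------------------------------------------------
  ef <- m$edman_failure
  ii <- integer(0); jj <- integer(0); pp <- numeric(0)
  for (s in seq_len(S)) {
    e <- space$edman[s]
    if (space$detached_flag[s] || space$blocked[s] || e == space$e_max) {
      ii <- c(ii, s); jj <- c(jj, s); pp <- c(pp, 1)
      next
    }
    ii <- c(ii, s); jj <- c(jj, s); pp <- c(pp, ef)  # cycle failure: no advance
    pos <- e + 1L
    ch <- space$res_channel[pos]
    cnt <- space$counts[s, ]
    if (ch == 0L) {
      ii <- c(ii, s); jj <- c(jj, state_lookup(space, e + 1L, cnt, FALSE))
      pp <- c(pp, 1 - ef)
    } else {
      # exchangeability: the removed residue's fluorophore is still alive
      # with probability k / m_rem given k of m_rem survivors on its channel
      m_rem <- space$maxc[e + 1L, ch]
      k <- cnt[ch]
      if (k > 0L) {
        cdrop <- cnt; cdrop[ch] <- k - 1L
        ii <- c(ii, s); jj <- c(jj, state_lookup(space, e + 1L, cdrop, FALSE))
        pp <- c(pp, (1 - ef) * k / m_rem)
      }
      if (k < m_rem) {
        ii <- c(ii, s); jj <- c(jj, state_lookup(space, e + 1L, cnt, FALSE))
        pp <- c(pp, (1 - ef) * (1 - k / m_rem))
      }
    }
  }
  edman <- trip(ii, jj, pp)

  list(dud = dud, init_block = block_factor(m$initial_block), detach = detach,
       cyclic_block = block_factor(m$cyclic_block), edman = edman,
       dyeloss = dyeloss)
}

#' Expand a sparse factor to a dense transition matrix
#'
#' Test and inspection helper; production code applies triplets directly.
#'
#' @param trip Triplet list from [build_factors()].
#' @param n_states Number of states.
#' @return Dense `n_states x n_states` matrix with `T[i, j] = P(i -> j)`.
#' @export
factor_as_matrix <- function(trip, n_states) {
  M <- matrix(0, n_states, n_states)
  # accumulate (duplicate (i, j) pairs may arise when drop/keep targets merge)
  for (k in seq_along(trip$i)) {
    M[trip$i[k], trip$j[k]] <- M[trip$i[k], trip$j[k]] + trip$p[k]
  }
  M
}

#' Sub-step schedule of factor applications
#'
#' The within-cycle order is detachment, dye loss (per channel), cyclic
#' blocking, then Edman degradation; before observation 0 the initial dud
#' and initial block factors apply. The simulator uses the same order, so
#' simulation and inference agree by construction.
#'
#' @param space An `hmm_state_space`.
#' @return List of operations; each is a list with `kind` (`"factor"` or
#'   `"emit"`), and for factors `type`/`channel`, for emissions the
#'   observation index `t` (0-based).
#' @export
substep_schedule <- function(space) {
  ops <- list(list(kind = "factor", type = "dud"),
              list(kind = "factor", type = "init_block"),
              list(kind = "emit", t = 0L))
  for (t in seq_len(space$n_cycles)) {
    ops <- c(ops, list(list(kind = "factor", type = "detach")))
    for (ch in seq_len(space$n_channels)) {
      ops <- c(ops, list(list(kind = "factor", type = "dyeloss", channel = ch)))
    }
    ops <- c(ops, list(list(kind = "factor", type = "cyclic_block"),
                       list(kind = "factor", type = "edman"),
                       list(kind = "emit", t = t)))
  }
  ops
}

factor_for_op <- function(factors, op) {
  if (op$type == "dyeloss") factors$dyeloss[[op$channel]] else factors[[op$type]]
}

#' Per-state emission log-densities for one observation
#'
#' Channels are independent: the log-density is the sum over channels of a
#' normal log-density with mean `bg_mu + count * mu` and the variance given
#' by the channel model. The detached state emits pure background.
#'
#' @param space An `hmm_state_space`.
#' @param obs Numeric vector of per-channel intensities for one observation.
#' @param cm A `channel_model`.
#' @return Numeric vector of length `n_states`.
#' @export
emission_logdens <- function(space, obs, cm) {
  S <- space$n_states
  out <- numeric(S)
  for (ch in seq_len(space$n_channels)) {
    k <- space$counts[, ch]
    k[space$detached_flag] <- 0L
    out <- out + stats::dnorm(obs[ch], mean = cm$bg_mu[ch] + k * cm$mu[ch],
                              sd = emission_sd(cm, k, ch - 1L), log = TRUE)
  }
  out
}

#' Emission log-density of an observation given one state
#'
#' @param counts Integer vector of per-channel fluorophore counts (use all
#'   zeros for a detached state).
#' @param obs Numeric vector of per-channel intensities.
#' @param cm A `channel_model`.
#' @return Scalar log-density.
#' @export
emission_logpdf <- function(counts, obs, cm) {
  s <- 0
  for (ch in seq_along(counts)) {
    s <- s + stats::dnorm(obs[ch], mean = cm$bg_mu[ch] + counts[ch] * cm$mu[ch],
                          sd = emission_sd(cm, counts[ch], ch - 1L), log = TRUE)
  }
  s
}

apply_factor_fwd <- function(alpha, trip) {
  out <- numeric(length(alpha))
  contrib <- alpha[trip$i] * trip$p
  agg <- rowsum(contrib, trip$j)
  out[as.integer(rownames(agg))] <- agg
  out
}

apply_factor_bwd <- function(beta, trip) {
  out <- numeric(length(beta))
  contrib <- beta[trip$j] * trip$p
  agg <- rowsum(contrib, trip$i)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Forward log-likelihood of one read (reference implementation)
#'
#' Computes `log P(read | peptide, error model, channel model)` by the
#' factored forward algorithm with per-observation normalization. This pure
#' R implementation is the readable reference; batch fitting uses the
#' compiled equivalent (see [fb_batch()]).
#'
#' @param space An `hmm_state_space`.
#' @param m An `error_model`.
#' @param cm A `channel_model`.
#' @param read Numeric matrix `n_channels x n_observations`.
#' @return Scalar log-likelihood.
#' @export
forward_loglik <- function(space, m, cm, read) {
  fwd <- forward_pass(space, m, cm, read, keep = FALSE)
  if (!is.finite(fwd$loglik)) {
    stop("non-finite forward log-likelihood", call. = FALSE)
  }
  fwd$loglik
}

forward_pass <- function(space, m, cm, read, keep = FALSE,
                         factors = build_factors(space, m)) {
  stopifnot(is.matrix(read), nrow(read) == space$n_channels,
            ncol(read) == space$n_cycles + 1L)
  S <- space$n_states
  ops <- substep_schedule(space)
  alpha <- numeric(S)
  alpha[space$intact] <- 1
  loglik <- 0
  alphas <- if (keep) vector("list", length(ops))
  weights <- if (keep) vector("list", length(ops))
  for (k in seq_along(ops)) {
    op <- ops[[k]]
    if (op$kind == "factor") {
      alpha <- apply_factor_fwd(alpha, factor_for_op(factors, op))
    } else {
      lg <- emission_logdens(space, read[, op$t + 1L], cm)
      m0 <- max(lg)
      w <- exp(lg - m0)
      alpha <- alpha * w
      s <- sum(alpha)
      if (!is.finite(s) || s <= 0) {
        stop("forward pass underflow at observation ", op$t, call. = FALSE)
      }
      loglik <- loglik + log(s) + m0
      alpha <- alpha / s
      if (keep) weights[[k]] <- w
    }
    if (keep) alphas[[k]] <- alpha
  }
  list(loglik = loglik, alpha = alpha, alphas = alphas, weights = weights,
       ops = ops, factors = factors)
}

#' Forward-backward sub-step posteriors for one read
#'
#' Runs the factored forward-backward algorithm, returning state-occupancy
#' probabilities at every sub-step and the posterior flow through every
#' factor application (the sub-transition posteriors). These are the
#' quantities from which the weighted maximum likelihood updates of the
#' error rates are assembled.
#'
#' @inheritParams forward_loglik
#' @return A `substep_posteriors` object: list with `occupancy` (matrix,
#'   sub-steps x states, rows sum to 1), `flows` (list of sparse posterior
#'   flow matrices, one per factor application, each summing to 1),
#'   `ops` (the schedule), and `loglik`.
#' @export
forward_backward <- function(space, m, cm, read) {
  S <- space$n_states
  fwd <- forward_pass(space, m, cm, read, keep = TRUE)
  ops <- fwd$ops
  K <- length(ops)

  beta <- rep(1, S)
  occupancy <- matrix(NA_real_, nrow = K, ncol = S)
  flows <- vector("list", K)
  for (k in rev(seq_len(K))) {
    op <- ops[[k]]
    # occupancy at the sub-step after op k
    g <- fwd$alphas[[k]] * beta
    occupancy[k, ] <- g / sum(g)
    if (op$kind == "factor") {
      trip <- factor_for_op(fwd$factors, op)
      alpha_pre <- if (k > 1L) fwd$alphas[[k - 1L]] else {
        a0 <- numeric(S); a0[space$intact] <- 1; a0
      }
      xi <- alpha_pre[trip$i] * trip$p * beta[trip$j]
      xi <- xi / sum(xi)
      Fm <- matrix(0, S, S)
      for (z in seq_along(xi)) {
        Fm[trip$i[z], trip$j[z]] <- Fm[trip$i[z], trip$j[z]] + xi[z]
      }
      flows[[k]] <- Fm
      beta <- apply_factor_bwd(beta, trip)
    } else {
      beta <- beta * fwd$weights[[k]]
      beta <- beta / max(beta)
    }
  }
  structure(list(occupancy = occupancy, flows = flows, ops = ops,
                 loglik = fwd$loglik),
            class = "substep_posteriors")
}

#' Aggregate posterior flows by factor type
#'
#' Collapses the per-sub-step flows of a [forward_backward()] result (or a
#' list of them) into one total flow matrix per error type, summed over
#' cycles and reads. Sufficient statistics are linear in these totals.
#'
#' @param posts A `substep_posteriors` or list of them.
#' @param space The matching `hmm_state_space`.
#' @return Named list: matrices `dud`, `init_block`, `detach`,
#'   `cyclic_block`, `edman`, and list `dyeloss` (per channel).
#' @export
aggregate_flows <- function(posts, space) {
  if (inherits(posts, "substep_posteriors")) posts <- list(posts)
  S <- space$n_states
  z <- matrix(0, S, S)
  agg <- list(dud = z, init_block = z, detach = z, cyclic_block = z,
              edman = z, dyeloss = rep(list(z), space$n_channels))
  for (post in posts) {
    for (k in seq_along(post$ops)) {
      op <- post$ops[[k]]
      if (op$kind != "factor") next
      if (op$type == "dyeloss") {
        agg$dyeloss[[op$channel]] <- agg$dyeloss[[op$channel]] + post$flows[[k]]
      } else {
        agg[[op$type]] <- agg[[op$type]] + post$flows[[k]]
      }
    }
  }
  agg
}

#' Batch forward-backward over a read set (compiled)
#'
#' Equivalent to running [forward_backward()] on every read and aggregating
#' with [aggregate_flows()], but performed in compiled code. Returns the
#' per-read log-likelihoods and the flow totals per error type.
#'
#' @param reads A `read_set`.
#' @param space An `hmm_state_space`.
#' @param m An `error_model`.
#' @param cm A `channel_model`.
#' @param weights Optional per-read weights multiplying each read's flow
#'   contribution (e.g. bootstrap multiplicities); log-likelihoods are
#'   returned unweighted.
#' @return List with `loglik` (per-read vector) and `flows` (as
#'   [aggregate_flows()]).
#' @export
fb_batch <- function(reads, space, m, cm, weights = NULL) {
  stopifnot(inherits(reads, "read_set"))
  if (reads$n_observations != space$n_cycles + 1L) {
    stop("read set has ", reads$n_observations, " observations but state space expects ",
         space$n_cycles + 1L, call. = FALSE)
  }
  factors <- build_factors(space, m)
  res <- fb_batch_cpp(
    reads$intensities,
    space$counts, space$blocked, space$detached_flag,
    space$intact, space$detached,
    factors$dud, factors$init_block, factors$detach, factors$cyclic_block,
    factors$edman, factors$dyeloss,
    space$n_cycles,
    cm$mu, cm$sigma, cm$bg_sigma, cm$bg_mu,
    cm$variance_mode == "linear",
    if (is.null(weights)) numeric(0) else as.numeric(weights)
  )
  names(res$flows) <- c("dud", "init_block", "detach", "cyclic_block", "edman")
  res$flows$dyeloss <- res$dyeloss
  res["dyeloss"] <- NULL
  res
}

#' Dense-matrix forward log-likelihood (test oracle)
#'
#' Multiplies all sub-transition factors of a cycle into a single dense
#' transition matrix and runs the textbook forward algorithm. Exists only to
#' verify the factored implementation on small state spaces.
#'
#' @inheritParams forward_loglik
#' @return Scalar log-likelihood.
#' @export
forward_loglik_dense <- function(space, m, cm, read) {
  S <- space$n_states
  f <- build_factors(space, m)
  Tinit <- factor_as_matrix(f$dud, S) %*% factor_as_matrix(f$init_block, S)
  Tcyc <- factor_as_matrix(f$detach, S)
  for (ch in seq_len(space$n_channels)) {
    Tcyc <- Tcyc %*% factor_as_matrix(f$dyeloss[[ch]], S)
  }
  Tcyc <- Tcyc %*% factor_as_matrix(f$cyclic_block, S) %*% factor_as_matrix(f$edman, S)

  alpha <- numeric(S)
  alpha[space$intact] <- 1
  alpha <- as.vector(alpha %*% Tinit)
  loglik <- 0
  for (t in 0:space$n_cycles) {
    if (t > 0) alpha <- as.vector(alpha %*% Tcyc)
    lg <- emission_logdens(space, read[, t + 1L], cm)
    m0 <- max(lg)
    alpha <- alpha * exp(lg - m0)
    s <- sum(alpha)
    loglik <- loglik + log(s) + m0
    alpha <- alpha / s
  }
  loglik
}
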