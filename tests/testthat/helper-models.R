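# Shared fixtures: the study conditions used throughout the suite.
# Two-label single-channel peptide (the fully identifiable case), error
# rates of the magnitude reported for fluorosequencing chemistry, and a
# well-separated emission model (mu/sigma = 8, bg_sigma = sigma).

two_label_peptide <- function() parse_peptide("NH2-G{azK}*AG{azK}*|")

one_label_peptide <- function() parse_peptide("fmoc-APK*|")

study_error_model <- function() {
  error_model(edman_failure = 0.06, dye_loss = 0.05, detach = 0.05,
              dud = 0.07, initial_block = 0.04, cyclic_block = 0.02)
}

study_channel_model <- function() {
  channel_model(mu = 6000, sigma = 750, bg_sigma = 750)
}

# noise-free channel for deterministic staircase reads
sharp_channel_model <- function() {
  channel_model(mu = 6000, sigma = 1e-6, bg_sigma = 1e-6)
}

# exhaustive path-sum oracle: enumerates every error-event sequence of the
# generative model (dud draws, initial block, then per cycle detachment,
# per-fluorophore dye loss, cyclic block, Edman) and sums
# P(events) * N(read | resulting track). Independent of the HMM machinery.
enumerate_loglik <- function(p, m, cm, read) {
  n_cycles <- ncol(read) - 1L
  pos <- p$labels$position
  chs <- p$labels$channel + 1L
  nl <- length(pos)
  C <- p$n_channels

  emit <- function(track) {
    s <- 0
    for (t in 0:n_cycles) {
      s <- s + emission_logpdf(track[, t + 1L], read[, t + 1L], cm)
    }
    s
  }

  total <- 0
  # recursion over cycles; state: alive flags, blocked, detached, n_cleaved
  recurse <- function(t, alive, blocked, detached, n_cleaved, prob, track) {
    if (t > n_cycles) {
      total <<- total + prob * exp(emit(track))
      return(invisible())
    }
    step_counts <- function(alive, detached) {
      cnt <- integer(C)
      if (!detached) for (l in which(alive)) cnt[chs[l]] <- cnt[chs[l]] + 1L
      cnt
    }
    for (det_ev in if (detached) FALSE else c(FALSE, TRUE)) {
      p_det_ev <- if (detached) 1 else if (det_ev) m$detach else 1 - m$detach
      det2 <- detached || det_ev
      # enumerate dye-loss subsets of currently alive fluorophores
      alive_idx <- which(alive)
      subsets <- all_subsets(alive_idx)
      for (lost in subsets) {
        p_loss_ev <- prod(m$dye_loss[chs[lost]]) *
          prod(1 - m$dye_loss[chs[setdiff(alive_idx, lost)]])
        alive2 <- alive
        alive2[lost] <- FALSE
        for (blk_ev in if (blocked) FALSE else c(FALSE, TRUE)) {
          p_blk_ev <- if (blocked) 1 else if (blk_ev) m$cyclic_block else 1 - m$cyclic_block
          blk2 <- blocked || blk_ev
          edman_opts <- if (blk2 || det2) list(c(FALSE, 1)) else
            list(c(TRUE, 1 - m$edman_failure), c(FALSE, m$edman_failure))
          for (eo in edman_opts) {
            adv <- as.logical(eo[1]); p_ed <- eo[2]
            alive3 <- alive2
            ncl2 <- n_cleaved
            if (adv) {
              ncl2 <- ncl2 + 1L
              alive3[pos == ncl2] <- FALSE
            }
            track2 <- track
            track2[, t + 1L] <- step_counts(alive3, det2)
            recurse(t + 1L, alive3, blk2, det2, ncl2,
                    prob * p_det_ev * p_loss_ev * p_blk_ev * p_ed, track2)
          }
        }
      }
    }
  }

  for (duds in all_subsets(seq_len(nl))) {
    alive <- rep(TRUE, nl)
    alive[duds] <- FALSE
    p_dud <- prod(m$dud[chs[duds]]) * prod(1 - m$dud[chs[setdiff(seq_len(nl), duds)]])
    for (blk0 in c(FALSE, TRUE)) {
      p_blk0 <- if (blk0) m$initial_block else 1 - m$initial_block
      track <- matrix(0L, C, n_cycles + 1L)
      for (l in which(alive)) track[chs[l], 1L] <- track[chs[l], 1L] + 1L
      recurse(1L, alive, blk0, FALSE, 0L, p_dud * p_blk0, track)
    }
  }
  log(total)
}

# every subset of an index vector (bitmask enumeration; robust to length 1)
all_subsets <- function(idx) {
  n <- length(idx)
  if (n == 0) return(list(integer(0)))
  lapply(0:(2^n - 1), function(mask) idx[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
}

# staircase read for a peptide under error-free sequencing
staircase_read <- function(p, cm, n_cycles) {
  L <- label_counts(p)
  C <- p$n_channels
  read <- matrix(0, C, n_cycles + 1L)
  for (t in 0:n_cycles) {
    cnt <- vapply(seq_len(C), function(ch) {
      sum(p$labels$channel == ch - 1L & p$labels$position > t)
    }, 0L)
    read[, t + 1L] <- cm$bg_mu + cnt * cm$mu
  }
  read
}
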