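test_that("state enumeration matches a brute-force count", {
  # one label at position 3, 5 cycles: cap at 3 Edman successes;
  # independent enumeration of (edman, count, blocked) combinations
  p <- parse_peptide("NH2-AAK*|")
  s <- build_state_space(p, 5)
  brute <- 0L
  for (e in 0:3) {
    for (cnt in 0:(if (e < 3) 1 else 0)) {
      brute <- brute + 2L  # unblocked + blocked
    }
  }
  expect_equal(s$n_states, brute + 1L)  # + detached
  expect_equal(s$e_max, 3L)

  # two-label peptide: counts bounded by labels still attached
  p2 <- two_label_peptide()
  s2 <- build_state_space(p2, 10)
  for (i in seq_len(s2$n_states - 1L)) {
    e <- s2$edman[i]
    expect_lte(s2$counts[i, 1], sum(p2$labels$position > e))
  }
  expect_equal(s2$n_states, 27L)
})

test_that("every state is reachable from the intact molecule", {
  p <- two_label_peptide()
  s <- build_state_space(p, 10)
  f <- build_factors(s, error_model(0.1, 0.1, 0.1, 0.1, 0.1, 0.1))
  S <- s$n_states
  step <- matrix(0, S, S)
  for (trip in c(f[c("dud", "init_block", "detach", "cyclic_block", "edman")],
                 f$dyeloss)) {
    step <- step + factor_as_matrix(trip, S)
  }
  reach <- rep(FALSE, S)
  reach[s$intact] <- TRUE
  repeat {
    new <- reach | (colSums(step[reach, , drop = FALSE]) > 0)
    if (identical(new, reach)) break
    reach <- new
  }
  expect_true(all(reach))
})

test_that("state-space blowup is guarded", {
  p <- two_label_peptide()
  expect_error(build_state_space(p, 10, max_states = 10), "max_states")
})

test_that("every factor is row-stochastic for any rates; Edman fixes blocked states", {
  p <- parse_peptide("NH2-K*AK*1GK*|")
  s <- build_state_space(p, 6)
  set.seed(21)
  for (rep in 1:10) {
    m <- error_model(runif(1), runif(2), runif(1), runif(2), runif(1),
                     runif(1), n_channels = 2)
    f <- build_factors(s, m)
    for (trip in c(f[c("dud", "init_block", "detach", "cyclic_block", "edman")],
                   f$dyeloss)) {
      rs <- rowsum(trip$p, trip$i)
      expect_equal(as.vector(rs), rep(1, s$n_states), tolerance = 1e-12)
    }
    # blocked (and detached) states are invariant under the Edman factor
    Ed <- factor_as_matrix(f$edman, s$n_states)
    frozen <- which(s$blocked | s$detached_flag)
    expect_equal(Ed[frozen, , drop = FALSE],
                 diag(s$n_states)[frozen, , drop = FALSE])
  }
})

test_that("emission densities behave like independent per-channel normals", {
  cm <- channel_model(c(6000, 5000), c(600, 500), c(450, 400))
  # mode of the zero-count channel sits at bg_mu
  d0 <- emission_logpdf(0L, cm$bg_mu[1], channel_model(6000, 600, 450))
  expect_gt(d0, emission_logpdf(0L, cm$bg_mu[1] + 100, channel_model(6000, 600, 450)))
  # two-fluorophore mode sits at 2 mu
  cm1 <- channel_model(6000, 600, 450)
  expect_gt(emission_logpdf(2L, 12000, cm1), emission_logpdf(2L, 11000, cm1))
  expect_gt(emission_logpdf(2L, 12000, cm1), emission_logpdf(1L, 12000, cm1))
  # two channels: log-density sums over channels
  expect_equal(emission_logpdf(c(1L, 2L), c(6100, 9800), cm),
               emission_logpdf(1L, 6100, channel_model(6000, 600, 450)) +
                 emission_logpdf(2L, 9800, channel_model(5000, 500, 400)),
               tolerance = 1e-12)
})

test_that("factored forward equals dense-matrix forward and exhaustive path enumeration", {
  m <- error_model(edman_failure = 0.1, dye_loss = 0.07, detach = 0.06,
                   dud = 0.15, initial_block = 0.08, cyclic_block = 0.05)
  cm <- channel_model(6000, 900, 800)
  p1 <- parse_peptide("NH2-AK*|")
  s1 <- build_state_space(p1, 2)
  set.seed(31)
  rs <- simulate_reads(p1, m, cm, 8, 2)
  for (i in 1:8) {
    r <- get_read(rs, i)
    ll <- forward_loglik(s1, m, cm, r)
    expect_equal(ll, forward_loglik_dense(s1, m, cm, r), tolerance = 1e-12)
    expect_equal(ll, enumerate_loglik(p1, m, cm, r), tolerance = 1e-10)
  }
  # two-label peptide (richer state space), enumeration still tractable
  p2 <- parse_peptide("NH2-K*K*|")
  s2 <- build_state_space(p2, 2)
  rs2 <- simulate_reads(p2, m, cm, 4, 2)
  for (i in 1:4) {
    r <- get_read(rs2, i)
    ll <- forward_loglik(s2, m, cm, r)
    expect_equal(ll, forward_loglik_dense(s2, m, cm, r), tolerance = 1e-12)
    expect_equal(ll, enumerate_loglik(p2, m, cm, r), tolerance = 1e-10)
  }
})

test_that("error-free model concentrates all posterior mass on the staircase path", {
  p <- two_label_peptide()
  m <- error_model()
  cm <- sharp_channel_model()
  s <- build_state_space(p, 6)
  read <- staircase_read(p, cm, 6)
  post <- forward_backward(s, m, cm, read)
  for (k in seq_len(nrow(post$occupancy))) {
    expect_equal(max(post$occupancy[k, ]), 1, tolerance = 1e-9)
  }
})

test_that("sub-step posteriors are conserved and marginalize consistently", {
  p <- two_label_peptide()
  m <- study_error_model()
  cm <- study_channel_model()
  s <- build_state_space(p, 5)
  set.seed(41)
  rs <- simulate_reads(p, m, cm, 3, 5)
  for (i in 1:3) {
    post <- forward_backward(s, m, cm, get_read(rs, i))
    expect_equal(post$loglik, forward_loglik(s, m, cm, get_read(rs, i)),
                 tolerance = 1e-10)
    expect_equal(rowSums(post$occupancy), rep(1, nrow(post$occupancy)),
                 tolerance = 1e-10)
    for (k in seq_along(post$ops)) {
      if (post$ops[[k]]$kind != "factor") next
      Fm <- post$flows[[k]]
      expect_equal(sum(Fm), 1, tolerance = 1e-10)
      # outgoing flow mass equals source occupancy; incoming equals target
      prev <- if (k > 1) post$occupancy[k - 1, ] else
        replace(numeric(s$n_states), s$intact, 1)
      expect_equal(rowSums(Fm), prev, tolerance = 1e-9)
      expect_equal(colSums(Fm), post$occupancy[k, ], tolerance = 1e-9)
    }
  }
})

test_that("compiled batch forward-backward reproduces the R reference", {
  p <- two_label_peptide()
  m <- study_error_model()
  cm <- study_channel_model()
  s <- build_state_space(p, 5)
  set.seed(51)
  rs <- simulate_reads(p, m, cm, 30, 5)
  res <- fb_batch(rs, s, m, cm)
  posts <- lapply(seq_len(30), function(i) forward_backward(s, m, cm, get_read(rs, i)))
  expect_equal(res$loglik, vapply(posts, `[[`, 0.0, "loglik"), tolerance = 1e-9)
  agg <- aggregate_flows(posts, s)
  for (nm in c("dud", "init_block", "detach", "cyclic_block", "edman")) {
    expect_equal(unname(res$flows[[nm]]), unname(agg[[nm]]), tolerance = 1e-7,
                 ignore_attr = TRUE)
  }
  expect_equal(unname(res$flows$dyeloss[[1]]), unname(agg$dyeloss[[1]]),
               tolerance = 1e-7, ignore_attr = TRUE)

  # weighted batch equals duplicating reads
  idx <- c(1:30, 1:10)
  res_dup <- fb_batch(subset_reads(rs, idx), s, m, cm)
  w <- tabulate(match(idx, 1:30), 30)
  res_w <- fb_batch(rs, s, m, cm, weights = w)
  expect_equal(unname(res_w$flows$edman), unname(res_dup$flows$edman),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("posterior expected dye-loss events track the simulated truth", {
  p <- two_label_peptide()
  m <- error_model(edman_failure = 0.05, dye_loss = 0.08, detach = 0.02,
                   dud = 0.05, initial_block = 0.03, cyclic_block = 0.01)
  cm <- study_channel_model()
  s <- build_state_space(p, 8)
  sim <- simulate_reads(p, m, cm, 10000, 8, seed = 61, tracks = TRUE)
  res <- fb_batch(sim$reads, s, m, cm)
  stats <- stats_from_flows(res$flows, 10000, s)
  x_hat <- stats$dye_loss[[1]][["x"]]
  # truth: dye-loss events are drops not explained by Edman removal or
  # detachment; count them from the simulator's own tracks is involved, so
  # use the tighter binomial check on expected trials instead:
  n_hat <- stats$dye_loss[[1]][["n"]]
  rate_hat <- x_hat / n_hat
  se <- sqrt(m$dye_loss[1] * (1 - m$dye_loss[1]) / n_hat)
  expect_lt(abs(rate_hat - m$dye_loss[1]), 4 * se)
})
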