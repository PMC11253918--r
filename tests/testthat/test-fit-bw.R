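test_that("M-step computes clamped weighted MLEs and honors the mask", {
  m <- error_model(0.1, 0.1, 0, 0.1, 0.1, 0, fixed = c("detach", "cyclic_block"))
  stats <- structure(
    list(edman_failure = c(n = 100, x = 5),
         dye_loss = list(c(n = 200, x = 10)),
         detach = c(n = 50, x = 25),
         dud = list(c(n = 80, x = 0)),
         initial_block = c(n = 10, x = 2),
         cyclic_block = c(n = 50, x = 25)),
    class = "sufficient_stats")
  out <- m_step(stats, m)
  expect_equal(out$edman_failure, 0.05)
  expect_equal(out$dye_loss, 0.05)
  expect_equal(out$dud, 1e-9)          # x = 0 clamps at the floor
  expect_equal(out$initial_block, 0.2)
  expect_equal(out$detach, 0)          # masked: untouched by stats
  expect_equal(out$cyclic_block, 0)
  # zero trials leave the current value
  stats$edman_failure <- c(n = 0, x = 0)
  expect_equal(m_step(stats, m)$edman_failure, 0.1)
})

test_that("censoring correction adds the printed number of phantom reads", {
  p <- two_label_peptide()
  stats <- structure(
    list(edman_failure = c(n = 1, x = 0),
         dye_loss = list(c(n = 1, x = 0)),
         detach = c(n = 1, x = 0),
         dud = list(c(n = 200, x = 30)),
         initial_block = c(n = 100, x = 0),
         cyclic_block = c(n = 1, x = 0)),
    class = "sufficient_stats")
  out <- dud_bias_correction(stats, d = 0.5, n_reads = 100, p = p)
  m_phantom <- 100 * 0.25 / 0.75
  expect_equal(attr(out, "missing_reads"), m_phantom)
  expect_equal(out$dud[[1]][["n"]], 200 + 2 * m_phantom)
  expect_equal(out$dud[[1]][["x"]], 30 + 2 * m_phantom)
  # other statistics untouched
  expect_equal(out$edman_failure, stats$edman_failure)
  # d = 0: no phantoms
  out0 <- dud_bias_correction(stats, d = 0, n_reads = 100, p = p)
  expect_equal(attr(out0, "missing_reads"), 0)
  expect_equal(out0$dud, stats$dud)
  expect_error(dud_bias_correction(stats, d = 1, n_reads = 100, p = p),
               "degenerate")
})

test_that("sufficient statistics are additive over reads", {
  p <- two_label_peptide()
  m <- study_error_model()
  cm <- study_channel_model()
  s <- build_state_space(p, 4)
  set.seed(71)
  rs <- simulate_reads(p, m, cm, 6, 4)
  posts <- lapply(1:6, function(i) forward_backward(s, m, cm, get_read(rs, i)))
  s_all <- accumulate_stats(posts, s)
  s_a <- accumulate_stats(posts[1:2], s)
  s_b <- accumulate_stats(posts[3:6], s)
  s_sum <- stats_add(s_a, s_b)
  for (nm in c("edman_failure", "detach", "initial_block", "cyclic_block")) {
    expect_equal(s_sum[[nm]], s_all[[nm]], tolerance = 1e-9)
  }
  expect_equal(s_sum$dye_loss[[1]], s_all$dye_loss[[1]], tolerance = 1e-9)
  expect_equal(s_sum$dud[[1]], s_all$dud[[1]], tolerance = 1e-9)
})

test_that("an error-free read contributes trials but no error events", {
  p <- two_label_peptide()
  m <- error_model()  # truth: no errors
  cm <- sharp_channel_model()
  s <- build_state_space(p, 6)
  post <- forward_backward(s, m, cm, staircase_read(p, cm, 6))
  stats <- accumulate_stats(post, s)
  for (nm in c("edman_failure", "detach", "initial_block", "cyclic_block")) {
    expect_gt(stats[[nm]][["n"]], 0)
    expect_equal(stats[[nm]][["x"]], 0, tolerance = 1e-9)
  }
  expect_equal(stats$dye_loss[[1]][["x"]], 0, tolerance = 1e-9)
  expect_equal(stats$dud[[1]][["x"]], 0, tolerance = 1e-9)
})

test_that("a mid-run count drop with detach masked is attributed to dye loss", {
  p <- one_label_peptide()  # label at position 3; detach/dud/cyclic fixed 0
  cm <- sharp_channel_model()
  m <- fix_for_identifiability(
    error_model(edman_failure = 1e-9, dye_loss = 0.1), p)
  s <- build_state_space(p, 4)
  # drop at observation 1, two cycles before Edman could remove the label
  read <- matrix(cm$mu, 1, 5)
  read[1, 2:5] <- 0
  post <- forward_backward(s, m, cm, read)
  stats <- accumulate_stats(post, s)
  expect_equal(stats$dye_loss[[1]][["x"]], 1, tolerance = 1e-6)
})

test_that("EM recovers the simulation truth on a moderate dataset", {
  p <- two_label_peptide()
  m <- study_error_model()
  cm <- study_channel_model()
  rs <- simulate_reads(p, m, cm, 4000, 10, seed = 81)
  fit <- fit_baum_welch(rs, p, cm)
  expect_true(fit$converged)
  err <- abs(error_model_to_vector(fit$estimate) - error_model_to_vector(m))
  expect_lt(max(err), 0.02)
  # log-likelihood trajectory is monotone (EM invariant)
  expect_true(all(diff(fit$loglik_trajectory) >
                    -1e-8 * abs(fit$loglik_trajectory[-1])))
  expect_gt(fit$missing_reads, 0)
})

test_that("initializing at a near-truth point converges almost immediately", {
  p <- two_label_peptide()
  truth <- error_model(1e-4, 1e-4, 1e-4, 1e-4, 1e-4, 1e-4)
  cm <- channel_model(6000, 60, 60)  # essentially noise-free
  rs <- simulate_reads(p, truth, cm, 300, 5, seed = 91)
  fit <- fit_baum_welch(rs, p, cm, init = truth, tol = 1e-4)
  expect_lte(fit$n_iterations, 3)
  expect_lt(max(error_model_to_vector(fit$estimate)), 0.01)
})

test_that("one-label fits keep the unidentifiable rates fixed at zero", {
  p <- one_label_peptide()
  truth <- fix_for_identifiability(
    error_model(edman_failure = 0.08, dye_loss = 0.04, initial_block = 0.05), p)
  cm <- study_channel_model()
  rs <- simulate_reads(p, truth, cm, 3000, 8, seed = 92)
  fit <- fit_baum_welch(rs, p, cm)
  expect_identical(fit$estimate$detach, 0)
  expect_identical(fit$estimate$dud, 0)
  expect_identical(fit$estimate$cyclic_block, 0)
  expect_setequal(fit$fixed, c("detach", "dud", "cyclic_block"))
  err <- abs(c(fit$estimate$edman_failure - 0.08,
               fit$estimate$dye_loss - 0.04,
               fit$estimate$initial_block - 0.05))
  expect_lt(max(err), 0.025)
})

test_that("fitting weighted reads equals fitting duplicated reads", {
  p <- two_label_peptide()
  m <- study_error_model()
  cm <- study_channel_model()
  rs <- simulate_reads(p, m, cm, 400, 5, seed = 93)
  set.seed(94)
  idx <- sample.int(400, 400, replace = TRUE)
  fit_dup <- fit_baum_welch(subset_reads(rs, idx), p, cm, tol = 1e-4)
  w <- tabulate(idx, 400)
  nz <- which(w > 0)
  fit_w <- fit_baum_welch(subset_reads(rs, nz), p, cm, tol = 1e-4,
                          weights = w[nz])
  expect_equal(error_model_to_vector(fit_w$estimate),
               error_model_to_vector(fit_dup$estimate), tolerance = 1e-8)
})

test_that("read order does not change the fit", {
  p <- two_label_peptide()
  m <- study_error_model()
  cm <- study_channel_model()
  rs <- simulate_reads(p, m, cm, 300, 5, seed = 95)
  fit1 <- fit_baum_welch(rs, p, cm, tol = 1e-4)
  fit2 <- fit_baum_welch(subset_reads(rs, rev(seq_len(300))), p, cm, tol = 1e-4)
  expect_equal(error_model_to_vector(fit1$estimate),
               error_model_to_vector(fit2$estimate), tolerance = 1e-10)
})
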