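test_that("error-free sequencing yields the staircase track", {
  p <- two_label_peptide()
  m <- error_model()  # all rates zero
  set.seed(1)
  out <- simulate_molecule(p, m, n_cycles = 8)
  expect_true(out$observed)
  # labels at positions 2 and 5: counts drop at observations 2 and 5
  expect_equal(as.vector(out$track), c(2, 2, 1, 1, 1, rep(0, 4)))
})

test_that("all-dud molecules are never observed", {
  p <- two_label_peptide()
  m <- error_model(dud = 1)
  set.seed(2)
  for (i in 1:10) expect_false(simulate_molecule(p, m, 5)$observed)
  expect_error(simulate_reads(p, m, study_channel_model(), 10, 5, seed = 1),
               "observable")
})

test_that("a fully blocked peptide never loses counts to Edman", {
  p <- two_label_peptide()
  m <- error_model(initial_block = 1)
  set.seed(3)
  for (i in 1:10) {
    tr <- simulate_molecule(p, m, 8)$track
    expect_true(all(tr == 2))
  }
})

test_that("per-channel counts never increase over time", {
  p <- parse_peptide("NH2-K*AK*1GK*|")  # two channels
  m <- error_model(0.1, c(0.05, 0.1), 0.05, c(0.1, 0.05), 0.05, 0.03,
                   n_channels = 2)
  set.seed(4)
  for (i in 1:50) {
    tr <- simulate_molecule(p, m, 8)$track
    expect_true(all(apply(tr, 1, function(x) all(diff(x) <= 0))))
  }
})

test_that("simulated event frequencies match their nominal rates", {
  p <- two_label_peptide()
  cm <- study_channel_model()

  # censoring identity: observed fraction ~ 1 - d^2 (two labels, one channel)
  d <- 0.2
  sim <- simulate_reads(p, error_model(dud = d), cm, n_reads = 20000,
                        n_cycles = 3, seed = 5, tracks = TRUE)
  p_obs <- 1 - d^2
  pval <- binom.test(sim$reads$n_reads, sim$reads$meta$attempts,
                     p_obs)$p.value
  expect_gt(pval, 1e-4)

  # observation-0 count distribution among observed molecules:
  # P(k | observed) = dbinom(k, 2, 1 - d) / (1 - d^2)
  c0 <- sim$tracks$intensities[, 1]
  for (k in 1:2) {
    pk <- dbinom(k, 2, 1 - d) / (1 - d^2)
    se_k <- sqrt(pk * (1 - pk) / length(c0))
    expect_lt(abs(mean(c0 == k) - pk), 3 * se_k)
  }

  # initial block frequency via never-dropping tracks under pure blocking
  b <- 0.3
  sim_b <- simulate_reads(p, error_model(initial_block = b), cm,
                          n_reads = 20000, n_cycles = 6, seed = 6,
                          tracks = TRUE)
  flat <- rowSums(sim_b$tracks$intensities == 2) == 7L
  se_b <- sqrt(b * (1 - b) / 20000)
  expect_lt(abs(mean(flat) - b), 3 * se_b)
})

test_that("first-drop cycle under pure Edman failure follows the negative-binomial law", {
  # with only Edman failure active, the first drop is the cycle of the 2nd
  # Edman success (first label at position 2); its law is the last-cycle
  # distribution with r = 2, b = c = 0
  p <- two_label_peptide()
  e <- 0.06
  sim <- simulate_reads(p, error_model(edman_failure = e),
                        study_channel_model(), n_reads = 100000,
                        n_cycles = 10, seed = 7, tracks = TRUE)
  tr <- sim$tracks$intensities
  first_drop <- apply(tr < 2, 1, function(x) which(x)[1]) - 1L  # observation index
  k <- kappa_distribution(r = 2, b = 0, e = e, c = 0, i_max = 6)
  for (i in 0:6) {
    pk <- k[i + 1]
    se_k <- sqrt(pk * (1 - pk) / nrow(tr))
    expect_lt(abs(mean(first_drop == 2 + i, na.rm = TRUE) *
                    mean(!is.na(first_drop)) - pk), 3 * se_k + 1e-9)
  }
})

test_that("read intensities follow the count-conditional emission model", {
  p <- two_label_peptide()
  cm <- study_channel_model()
  sim <- simulate_reads(p, error_model(), cm, n_reads = 4000, n_cycles = 2,
                        seed = 8, tracks = TRUE)
  x2 <- sim$reads$intensities[, 1]  # observation 0, count always 2
  expect_lt(abs(mean(x2) - 2 * cm$mu), 4 * emission_sd(cm, 2) / sqrt(4000))
  expect_lt(abs(sd(x2) - emission_sd(cm, 2)), 0.1 * emission_sd(cm, 2))
})

test_that("simulation is reproducible and seed-sensitive", {
  p <- two_label_peptide()
  m <- study_error_model()
  cm <- study_channel_model()
  a <- simulate_reads(p, m, cm, 50, 5, seed = 123)
  b <- simulate_reads(p, m, cm, 50, 5, seed = 123)
  c <- simulate_reads(p, m, cm, 50, 5, seed = 124)
  expect_identical(a$intensities, b$intensities)
  expect_false(identical(a$intensities, c$intensities))
})

test_that("R single-molecule and compiled batch simulators agree in law", {
  p <- two_label_peptide()
  m <- study_error_model()
  n <- 4000
  set.seed(9)
  r_counts <- table(factor(replicate(n, {
    mol <- simulate_molecule(p, m, 4)
    if (mol$observed) paste(as.vector(mol$track), collapse = ",") else "censored"
  }), exclude = NULL))
  hist_cpp <- simulate_track_histogram(p, m, n, 4, seed = 10)
  # compare the shared high-mass tracks within 4 binomial SEs
  keys <- names(sort(hist_cpp$counts, decreasing = TRUE))[1:8]
  for (key in keys) {
    p_cpp <- hist_cpp$counts[[key]] / hist_cpp$total
    n_r <- sum(r_counts) - sum(r_counts[names(r_counts) == "censored"])
    p_r <- if (key %in% names(r_counts)) r_counts[[key]] / n_r else 0
    se <- sqrt(p_cpp * (1 - p_cpp) * (1 / n_r + 1 / hist_cpp$total))
    expect_lt(abs(p_r - p_cpp), 4 * se)
  }
})
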