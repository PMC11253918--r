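test_that("dye-track reduction assigns each value its most likely count", {
  cm <- channel_model(6000, 750, 750)
  reads <- read_set(matrix(c(0, 6000, 12000, 5900, 100, 11000), nrow = 1), 1)
  tr <- reduce_to_dye_track(reads, cm, max_counts = 2)
  expect_equal(as.vector(tr$intensities), c(0L, 1L, 2L, 1L, 0L, 2L))

  # crossover located against a brute-force density grid
  grid <- seq(2000, 4500, by = 0.5)
  d0 <- dnorm(grid, 0, emission_sd(cm, 0))
  d1 <- dnorm(grid, 6000, emission_sd(cm, 1))
  cross <- grid[which(d1 > d0)[1]]
  below <- read_set(matrix(cross - 1), 1)
  above <- read_set(matrix(cross + 1), 1)
  expect_equal(as.vector(reduce_to_dye_track(below, cm, 2)$intensities), 0L)
  expect_equal(as.vector(reduce_to_dye_track(above, cm, 2)$intensities), 1L)
})

test_that("track histograms tabulate and the RMSE has its closed form on tiny input", {
  tr <- dye_track_set(matrix(c(2, 1, 2, 1, 2, 0), nrow = 3, byrow = TRUE), 1)
  h <- track_histogram(tr)
  expect_equal(h$total, 3L)
  expect_equal(sort(unname(h$counts)), c(1L, 2L))
  expect_equal(h$counts[["2,1"]], 2L)

  # two histograms with disjoint keys, hand-computed RMSE
  a <- c("2,2" = 60, "2,1" = 40)
  b <- c("1,1" = 70, "1,0" = 30)
  keys <- union(names(a), names(b))
  av <- bv <- setNames(rep(0, 4), keys)
  av[names(a)] <- a; bv[names(b)] <- b
  expect_equal(sqrt(mean((av - bv)^2)), sqrt((60^2 + 40^2 + 70^2 + 30^2) / 4))
})

test_that("the RMSE objective is deterministic and near its floor at the truth", {
  p <- two_label_peptide()
  m <- study_error_model()
  cm <- study_channel_model()
  rs <- simulate_reads(p, m, cm, 4000, 6, seed = 111)
  obs <- track_histogram(reduce_to_dye_track(rs, cm, label_counts(p)))

  v1 <- rmse_objective(m, obs, p, cm, 20000, sim_seed = 5)
  v2 <- rmse_objective(m, obs, p, cm, 20000, sim_seed = 5)
  expect_identical(v1, v2)  # common random numbers: byte-identical

  # truth scores better than clearly wrong models
  for (delta in c(0.05, -0.03)) {
    wrong <- m
    wrong$edman_failure <- m$edman_failure + delta
    expect_lt(v1, rmse_objective(wrong, obs, p, cm, 20000, sim_seed = 5))
  }
  # self-consistency: the floor is set by sampling noise, quantified by the
  # spread over replicate simulation seeds
  floors <- vapply(1:5, function(s) {
    rmse_objective(m, obs, p, cm, 20000, sim_seed = s)
  }, 0.0)
  expect_lt(v1, mean(floors) + 3 * sd(floors) + 1e-9)
})

test_that("trisection search finds convex minima and the deeper of two basins", {
  # convex quadratic in 2D
  quad <- function(x) (x[1] - 0.1)^2 + 2 * (x[2] - 0.3)^2
  res <- direct_search(quad, c(0, 0), c(0.5, 0.5))
  expect_lt(max(abs(res$par - c(0.1, 0.3))), 0.02)

  # 1D double well: global minimum verified against an exhaustive grid
  f <- function(x) -0.8 * exp(-((x - 0.1) / 0.05)^2) - exp(-((x - 0.4) / 0.05)^2)
  grid <- seq(0, 0.5, by = 1e-4)
  x_star <- grid[which.min(vapply(grid, f, 0.0))]
  res2 <- direct_search(function(x) f(x[1]), 0, 0.5, budget = 60)
  expect_lt(abs(res2$par - x_star), 0.02)

  # budget exhaustion still returns the best point evaluated
  calls <- 0
  res3 <- direct_search(function(x) { calls <<- calls + 1; quad(x) },
                        c(0, 0), c(0.5, 0.5), budget = 7)
  expect_lte(calls, 7)
  expect_lte(res3$value, quad(c(0.25, 0.25)))
})

test_that("Powell refinement is monotone, solves separable quadratics, and stays local", {
  quad <- function(x) (x[1] - 0.12)^2 + 3 * (x[2] - 0.31)^2
  res <- powell_refine(quad, c(0.4, 0.05), c(0, 0), c(0.5, 0.5), tol = 1e-10)
  expect_lt(max(abs(res$par - c(0.12, 0.31))), 1e-3)
  expect_lte(res$value, quad(c(0.4, 0.05)))

  # started inside a local basin, the local searches stay there
  f <- function(x) -0.8 * exp(-((x[1] - 0.1) / 0.04)^2) -
    exp(-((x[1] - 0.4) / 0.04)^2)
  res2 <- powell_refine(f, 0.1, 0, 0.5, tol = 1e-10)
  expect_lt(abs(res2$par - 0.1), 0.02)

  # a correlated (ridged) quadratic is still solved via the pattern move
  ridge <- function(x) {
    u <- x[1] - 0.2; v <- x[2] - 0.25
    100 * (u + v)^2 + (u - v)^2
  }
  res3 <- powell_refine(ridge, c(0.05, 0.05), c(0, 0), c(0.5, 0.5), tol = 1e-12,
                        max_cycles = 60)
  expect_lt(max(abs(res3$par - c(0.2, 0.25))), 5e-3)
})

test_that("end-to-end RMSE fitting recovers rates and is fully reproducible", {
  p <- two_label_peptide()
  m <- study_error_model()
  cm <- study_channel_model()
  rs <- simulate_reads(p, m, cm, 4000, 10, seed = 121)
  fit <- fit_direct_powell(rs, p, cm, seed = 122)
  err <- abs(error_model_to_vector(fit$estimate) - error_model_to_vector(m))
  expect_lt(max(err), 0.05)
  fit2 <- fit_direct_powell(rs, p, cm, seed = 122)
  expect_identical(error_model_to_vector(fit$estimate),
                   error_model_to_vector(fit2$estimate))
})

test_that("one-label RMSE fits keep masked parameters at zero", {
  p <- one_label_peptide()
  truth <- fix_for_identifiability(
    error_model(edman_failure = 0.08, dye_loss = 0.05, initial_block = 0.06), p)
  cm <- study_channel_model()
  rs <- simulate_reads(p, truth, cm, 3000, 8, seed = 123)
  fit <- fit_direct_powell(rs, p, cm, seed = 124)
  expect_identical(fit$estimate$detach, 0)
  expect_identical(fit$estimate$dud, 0)
  expect_identical(fit$estimate$cyclic_block, 0)
  err <- abs(c(fit$estimate$edman_failure - 0.08,
               fit$estimate$dye_loss - 0.05,
               fit$estimate$initial_block - 0.06))
  expect_lt(max(err), 0.04)
})
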