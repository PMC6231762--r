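test_that("perceptron rate is threshold-linear with additive perturbation", {
  pp <- perceptron_params(p = 1L)
  w0 <- rep(0, pp$Nm)
  x <- as.integer(seq_len(pp$Nm) <= 200)
  expect_equal(perceptron_rate(w0, x, FALSE, pp), 0)
  # drive exactly at threshold: only the perturbation shows through
  w_at <- rep(0, pp$Nm)
  w_at[1:200] <- pp$theta / 200
  expect_equal(perceptron_rate(w_at, x, TRUE, pp), pp$A)
  expect_equal(perceptron_rate(w_at, x, FALSE, pp), 0)
  # saturation at Pmax
  w_hi <- rep(10, pp$Nm)
  expect_equal(perceptron_rate(w_hi, x, FALSE, pp), pp$Pmax)
})

test_that("perceptron SGDEGE trial moves the rate by dP and rectifies weights", {
  pp <- perceptron_params(p = 1L)
  set.seed(42)
  x <- as.integer(runif(pp$Nm) < pp$f)
  n_act <- sum(x)
  w <- rep(2 * pp$theta / (pp$f * pp$Nm), pp$Nm) # linear range, far from 0
  v <- rep(0.05, pp$Nm)
  p_before <- perceptron_rate(w, x, FALSE, pp)
  res <- sgdege_percep_trial(w, v, x, R = 90, perturbed = TRUE, pp)
  # error underestimated -> c = +1 -> rate decreases by exactly dP
  expect_identical(res$c, 1L)
  p_after <- perceptron_rate(res$w, x, FALSE, pp)
  expect_equal(p_before - p_after, pp$dP)
  # v moved up by dJ in drive units
  expect_equal(sum(res$v * x) - sum(v * x), pp$dJ)
  # unperturbed trials leave w untouched
  res2 <- sgdege_percep_trial(w, v, x, R = 90, perturbed = FALSE, pp)
  expect_identical(res2$w, w)
  expect_false(identical(res2$v, v))
  # clipping at zero
  res3 <- sgdege_percep_trial(rep(0, pp$Nm), rep(0, pp$Nm), x, R = 90, TRUE, pp)
  expect_true(all(res3$w >= 0) && all(res3$v >= 0))
})

test_that("delta rule decays the error geometrically in the linear range", {
  pp <- perceptron_params(p = 1L, lr = 0.1)
  set.seed(7)
  x <- as.integer(runif(pp$Nm) < pp$f)
  w <- rep(2 * pp$theta / (pp$f * pp$Nm), pp$Nm)
  R <- 55
  res <- delta_rule_trial(w, x, R, pp$lr, pp)
  errs <- abs(perceptron_rate(w, x, FALSE, pp) - R)
  for (k in 1:80) {
    res <- delta_rule_trial(res$w, x, R, pp$lr, pp)
    errs <- c(errs, abs(res$P - R))
  }
  ratio <- errs[-1] / errs[-length(errs)]
  expect_equal(stats::median(ratio), 1 - pp$lr, tolerance = 0.02)
  expect_lt(abs(perceptron_rate(res$w, x, FALSE, pp) - R), 0.5)
  expect_true(all(res$w >= 0))
  expect_equal(delta_rule_trial(res$w, x,
                                perceptron_rate(res$w, x, FALSE, pp),
                                pp$lr, pp)$w, res$w) # zero error -> no change
  expect_error(delta_rule_trial(w, x, R, lr = 0, pp), "positive")
})

test_that("compiled sweeps equal the pure-R single-trial operations", {
  for (seed in 1:20) {
    pp <- perceptron_params(Nm = 12L, p = 3L, theta = 1.2)
    set <- generate_pattern_set(pp, seed)
    # reproduce the perturbation stream run_perceptron() will draw
    set.seed(sgdege:::substream_seed(seed, "perceptron_perturbations"))
    pflags <- runif(5 * pp$p) < pp$rho
    for (alg in c("sgdege", "delta")) {
      ref <- r_perceptron_sweeps(alg, pp, set, 5, pflags)
      sim <- run_perceptron(alg, pp, 5, seed, set = set)
      expect_equal(sim$w, ref$w, tolerance = 1e-12)
      expect_equal(sim$curve$mean_error_hz, ref$curve, tolerance = 1e-12)
      if (alg == "sgdege") expect_equal(sim$v, ref$v, tolerance = 1e-12)
    }
  }
})

test_that("zero-sweep runs return the initial error and empty curve", {
  pp <- perceptron_params(p = 4L)
  sim <- run_perceptron("sgdege", pp, n_sweeps = 0, seed = 1)
  expect_equal(nrow(sim$curve), 0L)
  g <- glance(sim)
  expect_equal(g$final_error_hz, g$initial_error_hz)
})

test_that("SGDEGE fails to approach the floor when q >= 1", {
  pp_ok <- perceptron_params(p = 1L, q = 0.5)
  pp_bad <- perceptron_params(p = 1L, q = 1.5)
  g_ok <- glance(run_perceptron("sgdege", pp_ok, 20000, seed = 2))
  g_bad <- glance(run_perceptron("sgdege", pp_bad, 20000, seed = 2))
  expect_lt(g_ok$final_error_hz, 2 * g_ok$floor_hz)
  expect_gt(g_bad$final_error_hz, 3 * g_bad$floor_hz)
})

test_that("capacity scan reports the largest converging pattern count", {
  pp <- perceptron_params(p = 1L)
  cs <- capacity_scan("delta", pp, p_grid = c(1), n_sweeps = 500,
                      error_threshold = 1, seed = 1)
  expect_equal(cs$critical_p, 1)
  expect_error(capacity_scan("delta", pp, p_grid = integer(0), n_sweeps = 10),
               "empty")
  expect_error(capacity_scan("delta", pp, p_grid = c(5, 2), n_sweeps = 10),
               "ascending")
  cs2 <- capacity_scan("delta", pp, p_grid = c(10, 40, 120), n_sweeps = 4000,
                       error_threshold = 1, seed = 1)
  expect_s3_class(cs2$results, "tbl_df")
  expect_true(cs2$results$converged[1]) # far below the empirical capacity
  expect_false(cs2$results$converged[3]) # above it
})
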