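test_that("f-I curve rectifies below zero and saturates at rmax", {
  expect_equal(phi(-5, 300), 0)
  expect_equal(phi(400, 300), 300)
  expect_equal(phi(123.4, 300), 123.4)
  expect_equal(phi(c(-1, 0.5, 1e9), 1), c(0, 0.5, 1))
  expect_error(phi(1, rmax = 0), "positive")
})

test_that("fixed weights follow the rate-scale formulas", {
  pars <- network_params()
  expect_equal(pars$u_M_PN, 2.4)
  expect_equal(pars$u_PC_PN, -0.06)
  expect_equal(pars$u_PC_NO, -0.03)
})

test_that("initial weights respect the printed uniform bounds", {
  pars <- network_params() # defaults: T=10, rbar_PC=50, N=2000 -> w in [0, 2]
  conn <- build_connectivity(pars$shape, seed = 1)
  st <- init_weights(pars, conn, seed = 1)
  expect_true(all(st$w >= 0 & st$w <= 2))
  # v in [0, (15 + 0.5*30) * 4*10*40/20000] = [0, 2.4]
  expect_true(all(st$v >= 0 & st$v <= 2.4))
  # bounds are attained in distribution (not accidentally tighter)
  expect_gt(max(st$w), 2 * 0.999)
  expect_gt(max(st$v), 2.4 * 0.99)
  expect_identical(init_weights(pars, conn, seed = 1), st)
})

test_that("purkinje rates match the perturbed rate equation", {
  fx <- tiny_setup(seed = 5)
  pat <- pattern_slice(fx$patterns, 1)
  L <- fx$shape$L; TT <- fx$shape$T
  zero_state <- fx$state
  zero_state$w[] <- 0
  eta <- matrix(0, L, TT)
  expect_true(all(purkinje_rates(zero_state, pat, eta, fx$params) == 0))
  # a lone perturbation adds A to every cell of that column in that bin
  eta[2, 1] <- 1
  pc <- purkinje_rates(zero_state, pat, eta, fx$params)
  expect_equal(pc[, 2, 1], rep(fx$params$A, fx$shape$S))
  expect_equal(sum(pc), fx$shape$S * fx$params$A)
})

test_that("single-fibre mossy drive reaches the assigned projection neurone", {
  shape <- shape_params(S = 1, L = 4, T = 2, N = 16, p = 1)
  pars <- network_params(shape, rbar_D = 30) # u_M_PN = 4*2*4*30/16 = 60 < rmax
  conn <- build_connectivity(shape, seed = 3)
  st <- init_weights(pars, conn, seed = 3)
  st$w[] <- 0
  st$v[] <- 0
  pat <- list(active = 1L, bin = 1L, shape = shape)
  pc <- purkinje_rates(st, pat, matrix(0, 4, 2), pars)
  nuc <- nuclear_rates(st, pat, pc, pars)
  l_star <- conn$pn_assign[1]
  expect_equal(nuc$pn[l_star, 1], pars$u_M_PN)
  expect_equal(sum(nuc$pn), pars$u_M_PN)
  expect_true(all(nuc$no == 0))
})

test_that("error and inhibition are means over cells and bins", {
  pn <- matrix(c(10, 20), 1, 2)
  r <- matrix(c(20, 40), 1, 2)
  expect_equal(movement_error(pn, r), 15)
  expect_equal(movement_error(r, r), 0)
  perm <- c(2, 1)
  expect_equal(movement_error(pn[, perm, drop = FALSE], r[, perm, drop = FALSE]),
               movement_error(pn, r))
  expect_error(movement_error(pn, matrix(0, 2, 2)), "dimensions")
  no <- matrix(c(10, 30), 2, 1)
  expect_equal(olive_inhibition(no), 20)
  expect_equal(olive_inhibition(3 * no), 60)
  expect_equal(olive_inhibition(no * 0), 0)
})

test_that("error complex spike fires only for strictly positive olive drive", {
  expect_identical(ecs_sign(5, 3), 1L)
  expect_identical(ecs_sign(3, 5), -1L)
  expect_identical(ecs_sign(4, 4), -1L) # tie: no spike emitted
})

test_that("plasticity updates gate w by perturbation and rectify v", {
  fx <- tiny_setup(seed = 9)
  pat <- pattern_slice(fx$patterns, 1)
  eta0 <- matrix(0, fx$shape$L, fx$shape$T)
  up0 <- sgdege_update(fx$state, pat, eta0, 1L, fx$params)
  expect_identical(up0$w, fx$state$w) # no perturbation -> no w change
  expect_false(identical(up0$v, fx$state$v)) # v always moves
  expect_equal(up0$v[pat$active],
               pmax(fx$state$v[pat$active] + fx$params$alpha_v, 0))

  # perturb column 1 in the bin where the first active fibre fired
  eta <- eta0
  eta[1, pat$bin[1]] <- 1
  up <- sgdege_update(fx$state, pat, eta, 1L, fx$params)
  hit <- pat$active[pat$bin == pat$bin[1]]
  expect_equal(up$w[hit, 1], fx$state$w[hit, 1] - fx$params$alpha_w)
  expect_identical(up$w[, 2:3], fx$state$w[, 2:3])
  expect_identical(up$w[-hit, 1], fx$state$w[-hit, 1])

  # positivity bracket on v
  st <- fx$state
  st$v[] <- 5e-5
  dn <- sgdege_update(st, pat, eta0, -1L, fx$params)
  expect_equal(unique(dn$v[pat$active]), 0)
  expect_true(all(dn$v >= 0))
})

test_that("trial loop is deterministic and engines agree bit-for-bit scale", {
  fx <- tiny_setup(seed = 2)
  a <- run_network(fx$params, fx$patterns, fx$targets, 50, seed = 4)
  b <- run_network(fx$params, fx$patterns, fx$targets, 50, seed = 4)
  expect_identical(a$trajectory, b$trajectory)
  r <- run_network(fx$params, fx$patterns, fx$targets, 50, seed = 4, engine = "r")
  expect_equal(a$trajectory$error_hz, r$trajectory$error_hz, tolerance = 1e-12)
  expect_equal(a$state$w, r$state$w, tolerance = 1e-12)
  expect_equal(a$state$v, r$state$v, tolerance = 1e-12)
  expect_equal(nrow(run_network(fx$params, fx$patterns, fx$targets, 1,
                                seed = 1)$trajectory), 1L)
})

test_that("rates stay in [0, rmax] and v stays non-negative over a run", {
  fx <- tiny_setup(seed = 6)
  sim <- run_network(fx$params, fx$patterns, fx$targets, 300, seed = 6)
  expect_true(all(sim$state$v >= 0))
  expect_true(all(sim$trajectory$error_hz >= 0))
  expect_true(all(sim$trajectory$inhibition_hz >= 0))
  expect_true(all(sim$trajectory$inhibition_hz <= fx$params$rmax))
  eta0 <- matrix(0, fx$shape$L, fx$shape$T)
  for (mu in 1:2) {
    pc <- purkinje_rates(sim$state, pattern_slice(fx$patterns, mu), eta0, fx$params)
    expect_true(all(pc >= 0 & pc <= fx$params$rmax))
  }
})

test_that("without perturbations the Purkinje weights are frozen", {
  shape <- tiny_shape()
  pars <- network_params(shape, rho = 0)
  pats <- generate_patterns(shape, seed = 1)
  tg <- generate_targets(shape$L, shape$T, shape$p, pars$rbar_D, seed = 1)
  sim <- run_network(pars, pats, tg, 200, seed = 1)
  conn <- build_connectivity(shape, 1)
  st0 <- init_weights(pars, conn, 1)
  expect_identical(sim$state$w, st0$w)
  expect_false(identical(sim$state$v, st0$v)) # v drifts regardless
  expect_true(all(sim$trajectory$n_perturbations == 0L))
})

test_that("tidy/glance/autoplot expose the trajectory and summary", {
  fx <- tiny_setup(seed = 3)
  sim <- run_network(fx$params, fx$patterns, fx$targets, 60, seed = 3)
  td <- tidy(sim)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("trial", "pattern", "error_hz", "inhibition_hz",
                     "olive_drive_hz", "ecs", "n_perturbations"))
  expect_equal(td$olive_drive_hz, td$error_hz - td$inhibition_hz)
  g <- glance(sim)
  expect_equal(g$n_trials, 60L)
  expect_equal(g$fold_reduction, g$initial_error_hz / g$final_error_hz)
  expect_s3_class(ggplot2::autoplot(sim), "ggplot")
})
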