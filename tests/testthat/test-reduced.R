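test_that("single-trial updates follow the perturbed/unperturbed case rules", {
  pars <- reduced_params(R = 100, A = 10, rho = 0.2, dP = 1, dJ = 2, q = 0.5)
  # at the target with J = qR the perturbed comparison favours depression
  st <- reduced_step(list(P = 100, J = 50), pars, perturbed = TRUE)
  expect_identical(st$c, 1L)
  expect_equal(st$P, 99)
  expect_equal(st$J, 52)
  # unperturbed trials never move P
  st2 <- reduced_step(list(P = 60, J = 10), pars, perturbed = FALSE)
  expect_equal(st2$P, 60)
  expect_identical(st2$c, 1L) # error 40 > estimate
  # error overestimated -> J decreases, P (perturbed) increases
  st3 <- reduced_step(list(P = 100, J = 200), pars, perturbed = TRUE)
  expect_identical(st3$c, -1L)
  expect_equal(st3$P, 101)
  expect_equal(st3$J, 198)
})

test_that("step signs match an exhaustive case-rule oracle over the plane", {
  pars <- reduced_params(R = 100, A = 10, rho = 0.2, dP = 1, dJ = 2, q = 0.5)
  grid <- expand.grid(P = seq(60, 140, by = 2.5), J = seq(0, 160, by = 5),
                      pert = c(TRUE, FALSE))
  for (k in seq_len(nrow(grid))) {
    got <- reduced_step(list(P = grid$P[k], J = grid$J[k]), pars, grid$pert[k])
    want <- oracle_reduced_step(grid$P[k], grid$J[k], pars, grid$pert[k])
    expect_identical(got[c("P", "J", "c")], want[c("P", "J", "c")])
  }
})

test_that("corridor geometry yields the closed-form fixed point iff q < 1", {
  geo <- corridor_geometry(reduced_params(R = 100, A = 10, q = 0.5))
  expect_equal(unname(geo$fixed_point["P"]), 92.5)
  expect_equal(unname(geo$fixed_point["J"]), 53.75)
  expect_equal(unname(geo$fixed_point["offset"]), 7.5)
  expect_equal(unname(corridor_geometry(
    reduced_params(R = 100, A = 10, q = 1e-9))$fixed_point["P"]), 95,
    tolerance = 1e-6) # q -> 0 limit: P* = R - A/2
  expect_null(corridor_geometry(reduced_params(R = 100, A = 10, q = 1.2))$fixed_point)
  # the fixed point lies on both defining borders
  pars <- reduced_params(R = 80, A = 6, q = 0.25)
  fp <- corridor_geometry(pars)$fixed_point
  expect_equal(fp[["J"]] - pars$q * fp[["P"]] - pars$q * pars$A,
               abs(fp[["P"]] - pars$R + pars$A))
  expect_equal(fp[["J"]] - pars$q * fp[["P"]], abs(fp[["P"]] - pars$R))
})

test_that("convergence conditions evaluate the stated inequalities", {
  ok <- check_convergence_conditions(
    reduced_params(R = 100, A = 10, rho = 0.2, dP = 1, dJ = 2, q = 0.5))
  expect_true(ok$all_pass)
  bad_dj <- check_convergence_conditions(
    reduced_params(R = 100, A = 10, rho = 0.2, dP = 1, dJ = 6, q = 0.5))
  expect_false(bad_dj$dJ_small) # 6 >= (1 - 0.5) * 10
  expect_false(bad_dj$all_pass)
  bad_q <- check_convergence_conditions(
    reduced_params(R = 100, A = 10, rho = 0.2, dP = 1, dJ = 2, q = 1.0))
  expect_false(bad_q$q_below_1)
  expect_false(bad_q$all_pass)
})

test_that("trajectories are deterministic and engines agree", {
  pars <- reduced_params(R = 100, A = 10, rho = 0.2, dP = 1, dJ = 2, q = 0.5)
  a <- run_reduced(pars, 20, 20, 500, seed = 5)
  b <- run_reduced(pars, 20, 20, 500, seed = 5)
  r <- run_reduced(pars, 20, 20, 500, seed = 5, engine = "r")
  expect_identical(a$trajectory, b$trajectory)
  expect_equal(a$trajectory$P, r$trajectory$P, tolerance = 1e-12)
  expect_equal(a$trajectory$J, r$trajectory$J, tolerance = 1e-12)
})

test_that("convergence persists at high perturbation rates within (0,1)", {
  # near rho = 1 the J-only corrections are rare, so convergence is slow but
  # still guaranteed by the stated conditions; allow a long run
  pars <- reduced_params(R = 100, A = 10, rho = 0.999, dP = 1, dJ = 2, q = 0.5)
  g <- glance(run_reduced(pars, 30, 10, 1e6, seed = 9))
  expect_lt(abs(g$late_mean_P - 92.5), 3)
  pars2 <- reduced_params(R = 100, A = 10, rho = 0.95, dP = 1, dJ = 2, q = 0.5)
  g2 <- glance(run_reduced(pars2, 30, 10, 20000, seed = 9))
  expect_lt(abs(g2$late_mean_P - 92.5), 3)
})

test_that("rectified and literal unperturbed estimates differ only when J < qP", {
  pars <- reduced_params(R = 100, A = 10, rho = 0.2, dP = 1, dJ = 2, q = 0.9)
  # J < qP and |P - R| < qP - J: the literal (unrectified) estimate is
  # negative, flipping the comparison
  st_rect <- reduced_step(list(P = 99, J = 80), pars, FALSE, rectify_unperturbed = TRUE)
  st_lit <- reduced_step(list(P = 99, J = 80), pars, FALSE, rectify_unperturbed = FALSE)
  expect_identical(st_rect$c, 1L)
  expect_identical(st_lit$c, 1L)
  st_rect2 <- reduced_step(list(P = 100, J = 80), pars, FALSE, rectify_unperturbed = TRUE)
  st_lit2 <- reduced_step(list(P = 100, J = 80), pars, FALSE, rectify_unperturbed = FALSE)
  expect_identical(st_rect2$c, -1L) # 0 > [80-90]+ = 0 is false
  expect_identical(st_lit2$c, 1L)  # 0 > -10 is true
})

test_that("three-phase structure: drift, linear descent, bounded fluctuation", {
  pars <- reduced_params(R = 100, A = 10, rho = 0.2, dP = 1, dJ = 2, q = 0.5)
  sim <- run_reduced(pars, 20, 20, 10000, seed = 3)
  tr <- sim$trajectory
  # late fluctuations are bounded on the scale of the perturbation
  late <- tr$P[9000:10000]
  expect_lt(sd(late), 2 * max(pars$dP, pars$A))
  # mid-run descent towards the fixed point is roughly monotone in means
  m1 <- mean(abs(tr$P[1:500] - 92.5))
  m2 <- mean(abs(tr$P[3000:3500] - 92.5))
  m3 <- mean(abs(tr$P[9500:10000] - 92.5))
  expect_lt(m3, m2)
  expect_lt(m2, m1)
})
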