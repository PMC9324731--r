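test_that("success probability and sensitivity satisfy their closed forms", {
  expect_equal(success_probability(0.7, 0.7), 0.5)
  expect_equal(success_probability(log(3), 0), 0.75)
  expect_equal(success_probability(-0.58, -0.58), 0.5)
  expect_equal(sensitivity(0, 0), -0.25)
  expect_equal(round(sensitivity(2, 0), 3), -0.105)
  expect_equal(sensitivity(2, 0), sensitivity(0, 2)) # symmetry in +/- (theta-delta)
  expect_lt(abs(sensitivity(20, 0)), 1e-8)
  # algebraic identity K = -P(1-P) on random inputs
  set.seed(42)
  th <- rnorm(50, 0, 3); de <- rnorm(50, 0, 3)
  p <- success_probability(th, de)
  expect_equal(sensitivity(th, de), -p * (1 - p))
})

test_that("JMLE agrees with the coordinate grid-ascent oracle on small matrices", {
  for (X in oracle_matrices()) {
    fit <- fit_rasch(X, rasch_control(tol = 1e-6))
    orc <- grid_jmle(X)
    expect_lt(max(abs(unname(fit$delta) - orc$delta)), 1e-3)
    expect_lt(max(abs(unname(fit$theta) - orc$theta)), 1e-3)
  }
})

test_that("null simulation recovers delta = 0 within sampling error", {
  set.seed(11)
  X <- matrix(rbinom(2000 * 5, 1, 0.5), 2000, 5)
  fit <- fit_rasch(X)
  expect_true(all(abs(fit$delta) < 0.15)) # se ~ sqrt(1/(N*0.25)) ~ 0.045
})

test_that("parameter recovery at cohort scale: RMSE < 0.2, rank corr > 0.95", {
  t1 <- load_table1_fixture()
  sim <- simulate_cohort(cohort_spec(n = 500, seed = 101))
  fit <- fit_rasch(sim$responses)
  true_d <- t1$delta - mean(t1$delta)
  expect_lt(sqrt(mean((unname(fit$delta) - true_d)^2)), 0.2)
  expect_gt(cor(unname(fit$delta), true_d, method = "spearman"), 0.95)
  # recovery of person abilities (non-extreme). 15 items carry ~0.6 logits
  # of theoretical standard error per person, and uncorrected JMLE abilities
  # are overdispersed on top of it, so the achievable RMSE sits near 0.7.
  ok <- !fit$person_extreme
  expect_lt(sqrt(mean((fit$theta[ok] - sim$theta[ok])^2)), 0.75)
})

test_that("extreme and degenerate inputs are flagged or rejected", {
  X <- matrix(c(1, 1, 1,
                1, 0, 1,
                0, 1, 0,
                1, 1, 0), 4, 3, byrow = TRUE) # person 1 all-correct
  fit <- fit_rasch(X)
  expect_true(fit$person_extreme[1])
  expect_true(is.na(fit$theta[1]))
  expect_equal(sum(fit$delta), 0, tolerance = 1e-10) # exact centering
  # pseudo-score adjustment reports a finite, still-flagged estimate
  fit2 <- fit_rasch(X, rasch_control(extreme_adjust = 0.25))
  expect_true(fit2$person_extreme[1])
  expect_true(is.finite(fit2$theta[1]))
  expect_gt(fit2$theta[1], max(fit2$theta[-1]))
  expect_error(fit_rasch(matrix(1, 4, 3)), class = "cserecall_degenerate_data")
  expect_error(fit_rasch(matrix(0, 1, 3)), class = "cserecall_degenerate_data")
})

test_that("missing cells are skipped, not imputed", {
  set.seed(5)
  X <- matrix(rbinom(200 * 6, 1, 0.5), 200, 6)
  Xm <- X; Xm[sample(length(Xm), 120)] <- NA
  fit <- fit_rasch(Xm)
  okp <- !fit$person_extreme; oki <- !fit$item_extreme
  expect_true(all(is.finite(fit$delta[oki])))
  y <- standardized_residuals(Xm, fit)
  # on estimable cells, NA is exactly the missingness pattern
  expect_identical(is.na(y[okp, oki]), is.na(Xm[okp, oki]))
})

test_that("standardized residuals match closed forms and center at zero", {
  f <- forge_fit(theta = c(0, log(3)), delta = c(0, 0))
  y <- standardized_residuals(matrix(c(1, 0, 1, 0), 2, 2), f)
  expect_equal(y[1, 1], 1)                       # x=1 at P=0.5
  expect_equal(round(y[2, 2], 3), -1.732)        # x=0 at P=0.75
  # E[y] = 0 at fixed (theta, delta): Monte Carlo at n = 1e5
  set.seed(9)
  n <- 1e5; p <- success_probability(0.4, -0.3)
  x <- rbinom(n, 1, p)
  ybar <- mean((x - p) / sqrt(p * (1 - p)))
  expect_lt(abs(ybar), 3 / sqrt(n))
})

test_that("back-conversion to P_success gives asymmetric k=2 intervals", {
  ps <- to_psuccess(0, 0, U = 0.5, k = 2)
  expect_equal(ps$central, 0.5)
  expect_equal(round(c(ps$lower, ps$upper), 3), c(0.269, 0.731))
  expect_equal(ps$upper - ps$central, ps$central - ps$lower) # symmetric at 0.5
  ps2 <- to_psuccess(1, 0, U = 0.5, k = 2)
  expect_equal(round(unlist(ps2), 3),
               c(central = 0.731, lower = 0.5, upper = 0.881))
  expect_gt(ps2$central - ps2$lower, ps2$upper - ps2$central) # asymmetric
  ps3 <- to_psuccess(1.3, 0, U = 0)
  expect_equal(ps3$lower, ps3$central)
  expect_equal(ps3$upper, ps3$central)
})

test_that("bias correction shrinks difficulties by (L-1)/L", {
  X <- oracle_matrices()$m5x4
  f0 <- fit_rasch(X, rasch_control(tol = 1e-6))
  f1 <- fit_rasch(X, rasch_control(tol = 1e-6, bias_correction = TRUE))
  expect_equal(unname(f1$delta), unname(f0$delta) * 3 / 4, tolerance = 1e-4)
})
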