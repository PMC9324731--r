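t1 <- load_table1_fixture()

test_that("explanatory correlations reproduce the published structure", {
  cors <- explanatory_correlations(t1$X)
  expect_equal(round(cors["primacy", "recency"], 2), -0.94)
  expect_equal(round(cors["recency", "frequency"], 2), -0.18)
  expect_equal(diag(cors), c(primacy = 1, recency = 1, frequency = 1))
})

test_that("covariance PCA1 gives the published first component", {
  p <- pca_explanatory(t1$X)
  expect_equal(round(unname(p$loadings[, 1]), 2), c(0.77, -0.64, 0.02))
  expect_true(all(diff(p$eigenvalues) <= 0))
  m <- as.matrix(as.data.frame(t1$X)[, c("primacy", "recency", "frequency")])
  expect_equal(sum(p$eigenvalues), sum(diag(cov(m))))
  expect_equal(crossprod(p$loadings), diag(3), ignore_attr = TRUE)
  # the constant middle column is excluded, not an error
  expect_false("middle" %in% rownames(p$loadings))
})

test_that("PCA1 degenerate and closed-form cases", {
  one <- data.frame(primacy = c(1, 2, 4, 8))
  p1 <- pca_explanatory(one)
  expect_equal(unname(p1$loadings[, 1]), 1)
  expect_equal(p1$eigenvalues, var(one$primacy))
  # two variables, equal variance, correlation -1
  z <- c(-1, 0, 2, -1)
  p2 <- pca_explanatory(data.frame(primacy = z, recency = -z))
  expect_equal(unname(p2$loadings[, 1]), c(1, -1) / sqrt(2))
  expect_equal(p2$eigenvalues[2], 0, tolerance = 1e-12)
  expect_error(pca_explanatory(data.frame(primacy = rep(1, 4))),
               class = "cserecall_degenerate_pca")
})

test_that("CSE on the reference table reproduces the published equation", {
  m <- fit_cse(t1$delta, t1$X, U_delta = t1$U_delta)
  expect_equal(round(m$intercept), 5)
  expect_equal(round(unname(m$beta["primacy"]), 1), 0.7)
  expect_equal(round(unname(m$beta["recency"]), 1), 0.8)
  expect_equal(round(unname(m$beta["frequency"]), 1), 0.2)
  expect_equal(round(m$R, 2), 0.80)
  expect_equal(round(m$z_R[1], 2), -0.80)
  # published fitted column agrees to its printed precision
  expect_lt(max(abs(round(m$z_R, 2) - t1$z_R)), 0.05)
  expect_equal(mean(m$z_R), mean(t1$delta))
  # OLS identity: R^2 = var(fitted)/var(y), both ~0.64 here
  expect_equal(m$R^2, var(m$z_R) / var(t1$delta))
  expect_gt(m$R^2, 0.6); expect_lt(m$R^2, 0.7)
  expect_true(all(c(m$intercept_U, m$beta_U, m$U_zR) > 0))
})

test_that("PCR with all components is OLS; fewer components never raise R", {
  set.seed(14)
  for (rep in 1:5) {
    n <- 12
    X <- data.frame(primacy = rnorm(n), recency = rnorm(n), frequency = rnorm(n))
    y <- 1 + 0.5 * X$primacy - 0.3 * X$recency + rnorm(n, 0, 0.5)
    full <- fit_cse(y, X)
    ols <- lm(y ~ primacy + recency + frequency, data = X)
    expect_lt(max(abs(full$z_R - fitted(ols))), 1e-10)
    expect_equal(unname(c(full$intercept, full$beta)), unname(coef(ols)))
    r_prev <- full$R
    for (k in 2:1) {
      rk <- fit_cse(y, X, n_components = k)$R
      expect_lte(rk, r_prev + 1e-12)
      r_prev <- rk
    }
  }
})

test_that("exact linear relation is recovered with R = 1", {
  X <- data.frame(primacy = c(0, 1, 2, 3, 4, 6), recency = 0, frequency = 0)
  m <- fit_cse(2 - 1.5 * X$primacy,
               data.frame(primacy = X$primacy,
                          recency = c(0.1, -0.2, 0.3, 0, -0.1, -0.1),
                          frequency = rnorm(6)))
  expect_equal(unname(m$beta["primacy"]), -1.5)
  expect_equal(m$intercept, 2)
  expect_equal(m$R, 1)
})

test_that("contributions are additive and vanish on zero regressors", {
  m <- fit_cse(t1$delta, t1$X)
  ctb <- cse_contributions(m, t1$X)
  expect_equal(ctb$z_R, m$z_R)
  expect_equal(ctb$intercept + ctb$primacy_term + ctb$recency_term +
                 ctb$frequency_term, ctb$z_R)
  expect_equal(ctb$primacy_term[1], 0)   # primacy variable is 0 at item 1
  expect_equal(ctb$recency_term[15], 0)  # recency variable is 0 at item 15
})

test_that("subgroup CSEs: determinism, shift equivariance, error propagation", {
  ms <- subgroup_cse(list(a = t1$delta, b = t1$delta), t1$X)
  expect_equal(ms$a$beta, ms$b$beta)
  expect_equal(ms$a$intercept, ms$b$intercept)
  shifted <- subgroup_cse(list(base = t1$delta, up = t1$delta + 1.7), t1$X)
  expect_equal(shifted$up$intercept, shifted$base$intercept + 1.7)
  expect_equal(shifted$up$beta, shifted$base$beta)
  expect_error(fit_cse(t1$delta, t1$X, n_components = 9),
               class = "cserecall_parameter_error")
  expect_error(fit_cse(t1$delta[1:4], t1$X[1:4, ], n_components = 3),
               class = "cserecall_parameter_error")
})

test_that("intercept difference across simulated subgroups follows the overall shift", {
  # the group without the overall task-difficulty reduction keeps the larger
  # intercept (the effective-list-length reading of the subgroup equations)
  design <- word_list_design(15)
  spec_imp <- cohort_spec(n = 400, seed = 71)                 # full difficulty
  spec_hea <- cohort_spec(n = 400, shift = -2, seed = 1071)   # 2 logits easier
  d_imp <- unname(fit_rasch(simulate_cohort(spec_imp)$responses)$delta)
  d_hea <- unname(fit_rasch(simulate_cohort(spec_hea)$responses)$delta)
  # JMLE centers each group's difficulties; restore the group offsets from
  # the observed overall success levels before comparing intercepts
  off_imp <- qlogis(mean(simulate_cohort(spec_imp)$responses$x))
  off_hea <- qlogis(mean(simulate_cohort(spec_hea)$responses$x))
  ms <- subgroup_cse(list(impaired = d_imp - off_imp, healthy = d_hea - off_hea),
                     t1$X)
  expect_gt(ms$impaired$intercept, ms$healthy$intercept + 1)
})

test_that("uncertainty formatting follows the value(U) metrology style", {
  fmt <- cserecall:::format_uncertain
  expect_equal(unname(fmt(4.82, 2.7)), "+5(3)")
  expect_equal(unname(fmt(0.735, 0.5)), "+0.7(5)")
  expect_equal(unname(fmt(-1.86, 0.12)), "-1.9(1)")
})
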