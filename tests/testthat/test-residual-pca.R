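# shared simulated fixtures: one unidimensional cohort, one with a planted
# serial-position dimension (items 1-4 shifted +2 logits for half the cohort)
sim_pair <- function(seed, n = 500) {
  base <- cohort_spec(n = n, seed = seed)
  planted <- cohort_spec(n = c(n / 2, n / 2), labels = c("shifted", "ref"),
                         region_shift = list(c(Pr = 2), numeric(0)),
                         seed = seed)
  lapply(list(null = base, alt = planted), function(spec) {
    sim <- simulate_cohort(spec)
    fit <- fit_rasch(sim$responses)
    y <- standardized_residuals(sim$responses, fit)
    list(sim = sim, fit = fit, y = y,
         ctr = residual_contrasts(y, delta = fit$delta))
  })
}

test_that("contrast eigenvalues sum to the item count and loadings are unit norm", {
  pr <- sim_pair(201)
  for (s in pr) {
    expect_equal(sum(s$ctr$eigenvalues), length(s$ctr$eigenvalues),
                 tolerance = 1e-8)
    expect_equal(colSums(s$ctr$loadings^2), rep(1, 15),
                 ignore_attr = TRUE, tolerance = 1e-10)
    expect_true(all(diff(s$ctr$eigenvalues) <= 1e-12))
  }
})

test_that("unidimensional nulls stay below 2 items; planted data exceed their null", {
  exceed <- logical(10); null_ev <- numeric(10)
  for (k in 1:10) {
    pr <- sim_pair(300 + k)
    null_ev[k] <- pr$null$ctr$eigenvalues[1]
    exceed[k] <- pr$alt$ctr$eigenvalues[1] > pr$null$ctr$eigenvalues[1]
  }
  expect_true(all(null_ev < 2.0))
  expect_gte(mean(exceed), 0.8)
})

test_that("planted serial-position structure clusters primacy against recency", {
  pr <- sim_pair(411)
  l1 <- pr$alt$ctr$loadings[, 1]
  expect_true(all(sign(l1[1:4]) == sign(l1[1]))) # Pr items co-load
  expect_gt(abs(mean(l1[1:4]) - mean(l1[12:15])), 0.3)
})

test_that("duplicated item columns co-load maximally", {
  set.seed(6)
  y <- matrix(rnorm(300 * 6), 300, 6)
  y[, 2] <- y[, 1]
  ctr <- residual_contrasts(y)
  l1 <- abs(ctr$loadings[, 1])
  expect_equal(ctr$loadings[1, 1], ctr$loadings[2, 1], tolerance = 1e-6)
  expect_true(all(l1[1:2] > l1[3:6]))
  # zero-variance item is excluded with a warning
  y2 <- cbind(y[, 1:5], 0)
  expect_warning(ctr2 <- residual_contrasts(y2), "zero residual variance")
  expect_equal(length(ctr2$eigenvalues), 5)
})

test_that("variance fractions sum to one and respond to planted structure", {
  pr <- sim_pair(57)
  vd_null <- variance_decomposition(pr$null$sim$responses, pr$null$fit,
                                    pr$null$ctr)
  vd_alt <- variance_decomposition(pr$alt$sim$responses, pr$alt$fit,
                                   pr$alt$ctr)
  expect_equal(sum(vd_null$fractions), 1, tolerance = 1e-10)
  expect_gt(vd_null$items_fraction, 0); expect_lt(vd_null$items_fraction, 1)
  # under the null, no contrast dominates (the joint fit leaves the tail of
  # the spectrum depleted, so shares are ordered but the top ones are close)
  cshare <- vd_null$fractions[grep("^contrast", names(vd_null$fractions))]
  expect_lt(cshare[1] / cshare[2], 1.5)
  expect_true(all(cshare >= 0))
  # planted structure inflates the first-contrast share
  expect_gt(vd_alt$first_contrast_fraction, vd_null$first_contrast_fraction)
})

test_that("near-deterministic responses leave almost no unexplained variance", {
  th <- rep(c(-8, 8), each = 20); de <- seq(-0.5, 0.5, length.out = 6)
  x <- (outer(th, de, "-") > 0) * 1L
  x[1, 1] <- 1L; x[21, 6] <- 0L # keep margins non-extreme
  f <- forge_fit(th, de)
  set.seed(2)
  ctr <- residual_contrasts(matrix(rnorm(240), 40, 6)) # attribution only
  vd <- variance_decomposition(x, f, ctr)
  expect_lt(1 - vd$explained_fraction, 0.01)
})

test_that("disattenuated correlation follows the Spearman correction", {
  a <- c(1, 2, 3, 4, 5); b <- c(5.2, 4.1, 3.3, 1.9, 1.1)
  obs <- cor(a, b)
  d <- disattenuated_correlation(a, b, 0.5, 0.5)
  expect_equal(d$value, max(obs / 0.5, -1))
  expect_true(d$clipped) # obs ~ -0.998, correction overshoots
  d2 <- disattenuated_correlation(a, b, 1, 1)
  expect_equal(d2$value, obs); expect_false(d2$clipped)
  # the worked arithmetic case: -0.30 observed, reliabilities 0.5
  set.seed(10)
  u <- rnorm(200); v <- -0.3 * u + rnorm(200, 0, sqrt(1 - 0.09))
  d3 <- disattenuated_correlation(u, v, 0.5, 0.5)
  expect_equal(d3$raw, d3$observed / 0.5)
  expect_error(disattenuated_correlation(a, b, 0, 0.5),
               class = "cserecall_parameter_error")
})

test_that("cluster person measures carry reliabilities usable for disattenuation", {
  pr <- sim_pair(88, n = 300)
  cl <- pr$alt$ctr$clusters
  items1 <- which(cl == 1); items3 <- which(cl == max(cl))
  m1 <- cluster_person_measures(pr$alt$sim$responses, items1)
  m3 <- cluster_person_measures(pr$alt$sim$responses, items3)
  expect_true(m1$reliability >= 0 && m1$reliability <= 1)
  # few-item clusters measure worse than the full test
  full_rel <- separation_reliability(pr$alt$fit$theta, pr$alt$fit$theta_se)
  expect_lt(m1$reliability, full_rel)
  d <- disattenuated_correlation(m1$theta, m3$theta,
                                 max(m1$reliability, 0.05),
                                 max(m3$reliability, 0.05))
  expect_true(is.finite(d$value))
})

test_that("the decision checklist reports and flags coherently", {
  pr <- sim_pair(77, n = 300)
  vd <- variance_decomposition(pr$null$sim$responses, pr$null$fit, pr$null$ctr)
  rep0 <- linacre_checklist(pr$null$ctr, vd)
  expect_false(rep0$checks$eigenvalue$flag) # unidimensional null
  expect_equal(rep0$checks$eigenvalue$threshold, 2.0)
  # constructed strongly-correlated residual block trips the eigenvalue check
  set.seed(4)
  base <- rnorm(400)
  y <- cbind(sapply(1:3, function(i) base + rnorm(400, 0, 0.4)),
             matrix(rnorm(400 * 3), 400, 3))
  ctr <- residual_contrasts(y)
  expect_gte(ctr$eigenvalues[1], 2.0)
  vd2 <- variance_decomposition(
    pr$null$sim$responses, pr$null$fit, pr$null$ctr) # variance part reused
  rep1 <- linacre_checklist(ctr, vd2)
  expect_true(rep1$checks$eigenvalue$flag)
  # two-item boundary: contrasts computable, checklist notes the limit
  expect_warning(ctr2 <- residual_contrasts(y[, 1:2]), "fewer than 3")
  rep2 <- linacre_checklist(ctr2, vd2)
  expect_match(rep2$note, "too few items")
})
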