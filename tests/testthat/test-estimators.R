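test_that("Wald ratios follow the first-order arithmetic", {
  h <- harmonized_fixture(beta_exposure = c(0.5, -0.5), se_exposure = 0.01,
                          beta_outcome = c(0.1, 0.1), se_outcome = 0.02)
  r <- wald_ratios(h)
  expect_equal(r$ratio, c(0.2, -0.2))
  expect_equal(r$ratio_se, c(0.04, 0.04))
  expect_equal(r$weight, 1 / c(0.04, 0.04)^2)
})

test_that("a zero exposure beta is a degenerate-instrument error", {
  h <- harmonized_fixture(beta_exposure = c(0.5, 0), se_exposure = 0.01,
                          beta_outcome = c(0.1, 0.1), se_outcome = 0.02)
  expect_error(wald_ratios(h), "s2")
})

test_that("Wald ratios match direct arithmetic on random pairs", {
  set.seed(21)
  bx <- stats::rnorm(50, 0.3, 0.2); bx[abs(bx) < 0.01] <- 0.05
  by <- stats::rnorm(50, 0, 0.05)
  sy <- stats::runif(50, 0.001, 0.05)
  r <- wald_ratios(harmonized_fixture(bx, 0.01, by, sy))
  expect_equal(r$ratio, by / bx)
  expect_equal(r$ratio_se, sy / abs(bx))
})

test_that("IVW reproduces the weighted-mean arithmetic oracle", {
  r <- ratios_fixture(ratio = c(0.2, 0.15, 1 / 6),
                      ratio_se = c(0.1, 0.05, 1 / 30))
  fit <- mr_ivw(r, "fixed")
  # weights {100, 400, 900}
  expect_equal(fit$beta, (0.2 * 100 + 0.15 * 400 + 900 / 6) / 1400,
               tolerance = 1e-12)
  expect_equal(fit$beta, 0.16429, tolerance = 1e-4)
  expect_equal(fit$se, sqrt(1 / 1400), tolerance = 1e-12)
  expect_equal(fit$se, 0.02673, tolerance = 1e-3)
})

test_that("a single instrument returns its Wald ratio as ivw_fixed", {
  r <- ratios_fixture(0.2, 0.04)
  fit <- mr_ivw(r)
  expect_equal(fit$method, "ivw_fixed")
  expect_equal(fit$beta, 0.2)
  expect_equal(fit$se, 0.04)
})

test_that("random-effects IVW inflates the SE by sqrt(max(1, Q/(J-1)))", {
  r <- ratios_fixture(ratio = c(0.5, -0.2, 0.9, 0.1),
                      ratio_se = c(0.05, 0.04, 0.06, 0.05))
  fx <- mr_ivw(r, "fixed")
  rd <- mr_ivw(r, "random")
  q <- cochran_q(r)$q
  expect_equal(rd$beta, fx$beta)
  expect_equal(rd$se, fx$se * sqrt(max(1, q / 3)))
  # homogeneous data never deflates below the fixed SE
  r2 <- ratios_fixture(ratio = rep(0.2, 4) + c(0, 1e-6, -1e-6, 0),
                       ratio_se = rep(0.05, 4))
  expect_equal(mr_ivw(r2, "random")$se, mr_ivw(r2, "fixed")$se)
})

test_that("IVW equals weighted least squares through the origin", {
  set.seed(22)
  for (rep in 1:100) {
    J <- sample(3:15, 1)
    bx <- stats::rnorm(J, 0.3, 0.1); bx[abs(bx) < 0.01] <- 0.05
    by <- stats::rnorm(J, 0.1 * bx, 0.02)
    sy <- stats::runif(J, 0.005, 0.05)
    r <- wald_ratios(harmonized_fixture(bx, 0.01, by, sy))
    fit <- mr_ivw(r, "fixed")
    wls <- stats::lm(by ~ bx - 1, weights = 1 / sy^2)
    expect_equal(fit$beta, unname(stats::coef(wls)), tolerance = 1e-10)
  }
})

test_that("Egger recovers an exact line and matches lm on random data", {
  # exact fit: y = 0.01 + 0.2 x, equal weights
  x <- c(0.1, 0.2, 0.3, 0.4)
  r <- wald_ratios(harmonized_fixture(x, 0.01, 0.01 + 0.2 * x, 0.02))
  fit <- mr_egger(r)
  expect_equal(fit$beta, 0.2, tolerance = 1e-10)
  expect_equal(fit$extra$egger_intercept, 0.01, tolerance = 1e-10)
  # proportional effects: intercept 0, slope c, intercept p = 1
  r0 <- wald_ratios(harmonized_fixture(x, 0.01, 0.3 * x, 0.02))
  fit0 <- mr_egger(r0)
  expect_equal(fit0$extra$egger_intercept, 0, tolerance = 1e-12)
  expect_equal(fit0$beta, 0.3, tolerance = 1e-12)
  expect_equal(fit0$extra$intercept_p, 1)
  # random instances against lm with weights (the normal-equations oracle)
  set.seed(23)
  for (rep in 1:20) {
    J <- 20
    bx <- abs(stats::rnorm(J, 0.3, 0.1)) + 0.01
    by <- stats::rnorm(J, 0.05 + 0.2 * bx, 0.03)
    sy <- stats::runif(J, 0.01, 0.05)
    r <- wald_ratios(harmonized_fixture(bx, 0.01, by, sy))
    fit <- mr_egger(r)
    lmfit <- summary(stats::lm(by ~ bx, weights = 1 / sy^2))
    expect_equal(fit$beta, lmfit$coefficients["bx", "Estimate"],
                 tolerance = 1e-10)
    expect_equal(fit$se, lmfit$coefficients["bx", "Std. Error"],
                 tolerance = 1e-10)
    expect_equal(fit$extra$egger_intercept,
                 lmfit$coefficients["(Intercept)", "Estimate"],
                 tolerance = 1e-10)
    expect_equal(fit$extra$intercept_se,
                 lmfit$coefficients["(Intercept)", "Std. Error"],
                 tolerance = 1e-10)
    expect_equal(fit$pvalue,
                 lmfit$coefficients["bx", "Pr(>|t|)"], tolerance = 1e-10)
  }
})

test_that("Egger pre-orients instruments to non-negative exposure betas", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  y <- 0.01 + 0.2 * x
  r1 <- wald_ratios(harmonized_fixture(x, 0.01, y, 0.02))
  # negating some instruments' orientation must not change the fit
  s <- c(1, -1, 1, -1)
  r2 <- wald_ratios(harmonized_fixture(s * x, 0.01, s * y, 0.02))
  f1 <- mr_egger(r1); f2 <- mr_egger(r2)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-12)
  expect_equal(f2$extra$egger_intercept, f1$extra$egger_intercept,
               tolerance = 1e-12)
  expect_equal(f2$extra$n_flipped, 2)
})

test_that("weighted median interpolates cumulative weight midpoints", {
  # ordinary median with equal weights
  r <- ratios_fixture(c(1, 2, 3), rep(0.1, 3))
  expect_equal(mr_weighted_median(r, n_boot = 10)$beta, 2)
  # interpolation oracle: weights {1,1,2} -> midpoints {.125,.375,.75}
  r2 <- ratios_fixture(c(1, 2, 3), 1 / sqrt(c(1, 1, 2)))
  expect_equal(mr_weighted_median(r2, n_boot = 10)$beta, 2 + 1 / 8 / 0.375,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(r2, n_boot = 10)$beta, 2.3333,
               tolerance = 1e-4)
})

test_that("weighted median matches a stats::approx interpolation oracle", {
  set.seed(24)
  for (rep in 1:25) {
    J <- sample(3:12, 1)
    ratio <- stats::rnorm(J)
    se <- stats::runif(J, 0.1, 2)
    r <- ratios_fixture(ratio, se)
    o <- order(ratio)
    wn <- (1 / se^2)[o] / sum(1 / se^2)
    p <- cumsum(wn) - wn / 2
    oracle <- stats::approx(p, ratio[o], xout = 0.5, rule = 2)$y
    expect_equal(mr_weighted_median(r, n_boot = 5)$beta, oracle,
                 tolerance = 1e-10)
  }
})

test_that("degenerate weighted median: identical ratios give tiny SE", {
  r <- ratios_fixture(rep(0.25, 5), rep(0.001, 5))
  fit <- mr_weighted_median(r, n_boot = 200, seed = 3)
  expect_equal(fit$beta, 0.25)
  expect_lt(fit$se, 0.002)
})

test_that("weighted mode finds the dominant cluster", {
  # all equal: the common value with SE 0
  r0 <- ratios_fixture(rep(0.3, 4), rep(0.05, 4))
  fit0 <- mr_weighted_mode(r0, n_boot = 10)
  expect_equal(fit0$beta, 0.3)
  expect_equal(fit0$se, 0)
  # tight cluster with dominant weight vs a far outlier
  r1 <- ratios_fixture(c(0.1, 0.11, 0.12, 0.9),
                       c(0.01, 0.01, 0.01, 0.2))
  fit1 <- mr_weighted_mode(r1, n_boot = 10)
  expect_gte(fit1$beta, 0.1)
  expect_lte(fit1$beta, 0.12)
  # grid-search density oracle at coarse resolution agrees
  dens <- function(x, v, w, h) {
    sapply(x, function(xi) sum(w / sum(w) * stats::dnorm((xi - v) / h)) / h)
  }
  v <- r1$ratio; w <- r1$weight
  h <- 0.9 * min(stats::sd(v), stats::mad(v)) * 4^(-1 / 5)
  grid <- seq(min(v), max(v), length.out = 10000)
  expect_equal(fit1$beta, grid[which.max(dens(grid, v, w, h))],
               tolerance = 1e-3)
})

test_that("weighted mode sits in the heavier of two symmetric clusters", {
  r <- ratios_fixture(c(-0.5, -0.49, -0.51, 0.5, 0.49, 0.51),
                      c(0.05, 0.05, 0.05, 0.02, 0.02, 0.02))
  fit <- mr_weighted_mode(r, n_boot = 10)
  expect_gt(fit$beta, 0.4)  # heavier weights on the positive cluster
  # and the mirrored weighting lands in the negative cluster
  r2 <- ratios_fixture(c(-0.5, -0.49, -0.51, 0.5, 0.49, 0.51),
                       c(0.02, 0.02, 0.02, 0.05, 0.05, 0.05))
  expect_lt(mr_weighted_mode(r2, n_boot = 10)$beta, -0.4)
})

test_that("bootstrap methods are bit-reproducible given (n_boot, seed)", {
  r <- ratios_fixture(c(0.1, 0.2, 0.3, 0.15), c(0.02, 0.05, 0.04, 0.03))
  a <- mr_weighted_median(r, n_boot = 100, seed = 42)
  b <- mr_weighted_median(r, n_boot = 100, seed = 42)
  expect_identical(a$se, b$se)
  c1 <- mr_weighted_mode(r, n_boot = 50, seed = 9)
  c2 <- mr_weighted_mode(r, n_boot = 50, seed = 9)
  expect_identical(c1$se, c2$se)
  # and the caller's RNG stream is untouched
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(mr_weighted_median(r, n_boot = 10, seed = 5))
  expect_identical(stats::runif(1), before)
})

test_that("all four estimators are scale-equivariant in the outcome", {
  set.seed(25)
  J <- 8
  bx <- abs(stats::rnorm(J, 0.3, 0.1)) + 0.05
  by <- stats::rnorm(J, 0.2 * bx, 0.02)
  sy <- stats::runif(J, 0.01, 0.03)
  fit1 <- mr_fit(harmonized_fixture(bx, 0.01, by, sy),
                 n_boot = 100, seed = 2)
  cc <- 3.7
  fit2 <- mr_fit(harmonized_fixture(bx, 0.01, cc * by, cc * sy),
                 n_boot = 100, seed = 2)
  expect_equal(fit2$results$beta, cc * fit1$results$beta,
               tolerance = 1e-8)
})

test_that("with zero noise and no pleiotropy all methods return theta", {
  theta <- 0.3
  bx <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  fit <- mr_fit(harmonized_fixture(bx, 0.01, theta * bx, 0.02),
                n_boot = 20, seed = 1)
  expect_equal(unname(coef(fit)), rep(theta, 4), tolerance = 1e-8)
})

test_that("beta_to_or reproduces the published OR transforms", {
  expect_equal(round(beta_to_or(-0.006, 0.0018)$or, 3), 0.994)
  expect_equal(round(beta_to_or(0.087, 0.005)$or, 3), 1.091)
  ci <- beta_to_or(0, 0.1)
  expect_equal(ci$or, 1)
  expect_equal(ci$ci_low * ci$ci_high, 1, tolerance = 1e-12)
  # or = exp(beta) and CI ordering hold across random inputs
  set.seed(26)
  b <- stats::rnorm(20); s <- stats::runif(20, 0.001, 1)
  tr <- beta_to_or(b, s)
  expect_equal(tr$or, exp(b))
  expect_true(all(tr$ci_low < tr$or & tr$or < tr$ci_high))
})
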