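test_that("degenerate and closed-form fits behave as expected", {
  x <- matrix(seq(-2, 2, length.out = 12), ncol = 1)
  y <- 2 * x
  m <- plsr_fit(x, y, 1)
  expect_equal(unname(m$R2), 1, tolerance = 1e-10)
  expect_equal(unname(m$coefficients[1, 1]), 1, tolerance = 1e-10)
  expect_warning(v1 <- vip_vt2(m), "fewer than 2")
  expect_equal(unname(v1$VIP), 1)
  # first weight vector proportional to X'y on orthonormal predictors
  set.seed(21)
  q <- qr.Q(qr(matrix(rnorm(30 * 3), 30)))
  xo <- q * sqrt(29)                      # unit-variance orthogonal columns
  yo <- xo[, 1] + rnorm(30, sd = 0.3)
  mo <- plsr_fit(xo, yo, 1)
  cp <- drop(crossprod(scale(xo), scale(yo)))
  expect_equal(unname(mo$weights[, 1]), unname(cp / sqrt(sum(cp^2))),
               tolerance = 1e-8)
})

test_that("full-rank PLS equals ordinary least squares", {
  set.seed(22)
  x <- matrix(rnorm(20 * 4), 20)
  y <- rnorm(20)
  m <- plsr_fit(x, y, 4)
  ols <- lm(scale(y) ~ scale(x) - 1)
  expect_equal(unname(fitted(m)[, 1]),
               as.numeric(mean(y) + sd(y) * fitted(ols)), tolerance = 1e-8)
  expect_equal(unname(m$R2), summary(ols)$r.squared, tolerance = 1e-8)
})

test_that("scores are orthogonal and VIP squares average to one", {
  set.seed(23)
  x <- matrix(rnorm(25 * 6), 25)
  y <- cbind(rnorm(25), rnorm(25))
  m <- plsr_fit(x, y, 4)
  g <- crossprod(m$scores)
  expect_equal(unname(g[upper.tri(g)]), rep(0, 6), tolerance = 1e-8)
  v <- vip_vt2(m)
  expect_equal(sum(v$VIP^2), 6, tolerance = 1e-8)
  expect_true(all(v$VT2 >= 0 & v$VT2 <= 100 + 1e-8))
  # coefficients reproduce the scaled fitted values
  Xs <- scale(x); Ys <- scale(y)
  expect_equal(Xs %*% m$coefficients,
               (fitted(m) - rep(colMeans(y), each = 25)) %*%
                 diag(1 / apply(y, 2, sd)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("cross-validation separates signal from noise", {
  set.seed(24)
  x <- matrix(rnorm(10), ncol = 1)
  y <- 3 * x[, 1]
  expect_gt(press_q2(x, y, 1)$Q2, 0.99)
  q2_noise <- replicate(20, {
    xn <- matrix(rnorm(31 * 10), 31)
    yn <- rnorm(31)
    press_q2(xn, yn, 3)$Q2
  })
  expect_lt(median(q2_noise), 0.05)
})

test_that("Q2 never exceeds R2 on the study panel", {
  p <- fixture_panel(); cl <- fixture_climate()
  X <- climate_predictors(cl)[p$breeds, retained_predictors]
  Y <- fixture_responses(p)
  for (fit in c("per-response", "joint")) {
    cv <- press_q2(X, Y, 3, fit = fit)
    expect_true(all(cv$Q2 <= cv$R2 + 1e-8))
  }
})

test_that("van der Voet test: exact enumeration, MC agreement, and power", {
  ra <- rnorm(20); rb <- ra
  expect_equal(van_der_voet_test(ra, rb)$p, 1)
  rb2 <- ra * 2
  expect_lt(van_der_voet_test(ra, rb2)$p, 0.01)
  set.seed(25)
  r8a <- rnorm(8); r8b <- rnorm(8, sd = 1.2)
  exact <- van_der_voet_test(r8a, r8b, exact_max = 12)
  expect_identical(exact$method, "exact")
  mc <- van_der_voet_test(r8a, r8b, n_draws = 4000, exact_max = 0)
  se <- sqrt(exact$p * (1 - exact$p) / 4000)
  expect_lt(abs(mc$p - exact$p), 2 * se + 1e-3)
})

test_that("component selection finds a single informative dimension", {
  set.seed(26)
  x <- matrix(rnorm(40 * 5), 40)
  y <- x[, 1] + rnorm(40, sd = 1)
  sel <- select_n_components(x, y, 4)
  expect_identical(sel$ncomp, 1L)
  expect_lte(sel$ncomp, sel$ncomp_min_press)
  expect_length(sel$press, 4)
})

test_that("variable elimination drops pure noise and improves prediction", {
  set.seed(27)
  wins <- 0L; drops <- 0L
  for (k in 1:50) {
    n <- 30
    z <- rnorm(n)
    x <- cbind(s1 = z + rnorm(n, sd = 0.4), s2 = z + rnorm(n, sd = 0.4),
               s3 = z + rnorm(n, sd = 0.4), noise = rnorm(n))
    y <- z + rnorm(n, sd = 0.4)
    el <- eliminate_variables(x, y, 4)
    if ("noise" %in% el$dropped) drops <- drops + 1L
    if (el$improved) wins <- wins + 1L
  }
  expect_gte(drops, 40L)
  expect_gte(wins, 40L)
  # identical copies of the signal: none dropped
  set.seed(28)
  z <- rnorm(30)
  xc <- cbind(a = z, b = z, c = z)
  y <- z + rnorm(30, sd = 0.2)
  el2 <- suppressWarnings(eliminate_variables(xc + rnorm(90, sd = 1e-6), y, 1))
  expect_length(el2$dropped, 0)
})

test_that("the study-panel fit reproduces the published structure", {
  p <- fixture_panel(); cl <- fixture_climate()
  X14 <- climate_predictors(cl)[p$breeds, ]
  Y <- fixture_responses(p)
  el <- eliminate_variables(X14, Y, 3, fit = "joint")
  # the four predictors the published screen discarded all fail here too
  expect_true(all(c("MAXaT", "HrMx", "HrMi", "THI") %in% el$dropped))
  expect_true(el$improved)
  # root-mean-PRESS of complete and reduced models near the published pair
  expect_equal(el$root_mean_press_full, 0.9726, tolerance = 0.05 / 0.97)
  expect_equal(el$root_mean_press_reduced, 0.9589, tolerance = 0.05 / 0.96)
  # minimum-PRESS component count on the reduced predictor set
  X10 <- X14[, retained_predictors]
  sel <- select_n_components(X10, Y, 6, fit = "joint")
  expect_identical(sel$ncomp_min_press, 3L)
  # I-668 and G-660 coefficients have opposite signs except MiR
  m <- plsr_fit(X10, Y, 3)
  b <- scaled_coefficients(m)
  opp <- sign(b[, "I-668"]) != sign(b[, "G-660"])
  expect_true(all(opp[setdiff(rownames(b), "MiR")]))
})

test_that("parameter recovery: the environment-driven locus has the top Q2", {
  hits <- 0L
  for (k in 1:50) {
    cfg <- sim_config(n_breeds = 31, n_animals = 27, n_neutral_loci = 3,
                      selected = data.frame(variable = "MINaT", slope = 1.3,
                                            baseline = -0.8),
                      seed = 4000 + k)
    cli <- simulate_climate(cfg)
    sim <- simulate_breed_panel(cfg, cli)
    X <- climate_predictors(cli, c("MINaT", "MAXaT", "TAR", "HrA"))
    Y <- allele_freq(sim$panel)
    q2 <- press_q2(X, Y, 2)$Q2
    if (names(which.max(q2)) == "sel1") hits <- hits + 1L
  }
  expect_gte(hits, 45L)
})

test_that("fit agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(29)
  x <- matrix(rnorm(20 * 5), 20, dimnames = list(NULL, paste0("v", 1:5)))
  y <- cbind(x %*% rnorm(5) + rnorm(20), rnorm(20))
  m <- plsr_fit(x, y, 2)
  mo <- mixOmics::pls(x, y, ncomp = 2, mode = "regression", scale = TRUE)
  pred <- predict(mo, x)$predict[, , 2]
  expect_equal(unname(fitted(m)), unname(pred), tolerance = 1e-6)
})
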