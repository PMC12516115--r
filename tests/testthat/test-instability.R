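# a ready-made fitted model + scores for the process tests
.fit_fixture <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      spec <- spec_uni(5, 3)
      set.seed(91)
      th <- theta_random(spec)
      dat <- simulate_grm(spec, th, 2000, seed = 92)
      f <- fit_ofa(dat, spec)
      fit <<- list(fit = f, scores = approx_scores(f), n = 2000)
    }
    fit
  }
})

test_that("cumulative score process is tied down at both ends", {
  fx <- .fit_fixture()
  proc <- score_process(fx$scores, z = rnorm(fx$n), type = "metric")
  expect_equal(unname(proc$csp[1, ]), rep(0, proc$q))
  expect_lt(max(abs(proc$csp[fx$n + 1, ])), 1e-8)
  expect_equal(dim(proc$csp), c(fx$n + 1L, ncol(fx$scores)))
})

test_that("decorrelated increments have near-identity covariance", {
  fx <- .fit_fixture()
  set.seed(93)
  proc <- score_process(fx$scores, z = rnorm(fx$n), type = "metric")
  inc <- diff(proc$csp) * sqrt(fx$n)   # rescaled one-step increments
  V <- crossprod(inc) / fx$n
  offdiag <- V[upper.tri(V)]
  expect_lt(mean(abs(offdiag)), 0.05)
  expect_lt(max(abs(diag(V) - 1)), 0.1)
})

test_that("a singular score covariance is reported with the culprit", {
  fx <- .fit_fixture()
  sc <- fx$scores
  sc[, 2] <- sc[, 1]                   # perfectly collinear parameters
  expect_error(score_process(sc, rnorm(fx$n)), "singular")
})

test_that("a median threshold shift peaks the process near the middle", {
  set.seed(94)
  scn <- dif_scenario("unidimensional", k = 2, n = 5000,
                      scenario = "thresholds_subset")
  dat <- simulate_dif_study(scn)
  fit <- fit_ofa(dat, scn$spec)
  sc <- approx_scores(fit)
  proc <- score_process(sc, dat$Znum, type = "metric")
  peak <- which.max(rowSums(proc$csp^2)) - 1L
  expect_gt(peak / scn$n, 0.35)
  expect_lt(peak / scn$n, 0.65)
})

test_that("an all-zero process yields zero statistics and p-values of 1", {
  n <- 50
  q <- 3
  proc <- structure(list(csp = matrix(0, n + 1, q,
                                      dimnames = list(NULL, letters[1:q])),
                         t = (0:n) / n, z = rep(1:5, each = 10),
                         type = "metric", B = diag(q), n = n, q = q),
                    class = "ofa_csp")
  for (kind in c("DM", "CvM", "maxLM")) {
    res <- test_statistic(proc, kind, crit_reps = 2000, crit_nsteps = 200)
    expect_equal(res$value, 0)
    expect_equal(res$p_value, 1)
  }
  proc$type <- "ordinal"
  for (kind in c("WDMo", "maxLMo")) {
    res <- test_statistic(proc, kind, crit_reps = 2000)
    expect_equal(res$value, 0)
    expect_equal(res$p_value, 1)
  }
  proc$type <- "categorical"
  res <- test_statistic(proc, "LMuo")
  expect_equal(res$value, 0)
  expect_equal(res$p_value, 1)
})

test_that("DM p-value matches the Brownian-bridge sup distribution", {
  n <- 400
  q <- 1
  proc <- structure(list(csp = matrix(0, n + 1, 1), t = (0:n) / n,
                         z = seq_len(n), type = "metric", B = diag(1),
                         n = n, q = q), class = "ofa_csp")
  proc$csp[round(n / 2) + 1, 1] <- 1.358   # force the max to 1.358
  res <- test_statistic(proc, "DM")
  expect_equal(res$p_value, 0.05, tolerance = 0.002)
  # independent Monte-Carlo check of the 95% point of sup|bridge|
  set.seed(95)
  sups <- replicate(4000, {
    e <- rnorm(300) / sqrt(300)
    w <- cumsum(e)
    max(abs(w - (1:300) / 300 * w[300]))
  })
  expect_lt(abs(quantile(sups, 0.95) - 1.358), 0.05)
})

test_that("LMuo equals the chi-square tail at q(C-1) degrees of freedom", {
  fx <- .fit_fixture()
  z <- sample(1:4, fx$n, replace = TRUE)
  proc <- score_process(fx$scores, z, type = "categorical")
  res <- test_statistic(proc, "LMuo")
  df <- proc$q * (length(unique(z)) - 1)
  # independent gamma-form tail probability
  expect_equal(res$p_value,
               1 - pgamma(res$value / 2, shape = df / 2), tolerance = 1e-10)
})

test_that("covariate reversal and monotone transforms act as expected", {
  fx <- .fit_fixture()
  set.seed(96)
  z <- rnorm(fx$n)
  a <- dif_test(fx$fit, z, type = "metric", scores = fx$scores)
  b <- dif_test(fx$fit, exp(z), type = "metric", scores = fx$scores)
  expect_equal(a$value, b$value)
  expect_equal(a$p_value, b$p_value)
  zo <- sample(1:5, fx$n, replace = TRUE)
  o1 <- dif_test(fx$fit, zo, type = "ordinal", scores = fx$scores)
  o2 <- dif_test(fx$fit, -zo, type = "ordinal", scores = fx$scores)
  expect_equal(o1$value, o2$value, tolerance = 1e-8)
  c1 <- dif_test(fx$fit, zo, type = "categorical", scores = fx$scores)
  c2 <- dif_test(fx$fit, 6 - zo, type = "categorical", scores = fx$scores)
  expect_equal(c1$value, c2$value, tolerance = 1e-8)
})

test_that("statistic/covariate pairings are enforced", {
  fx <- .fit_fixture()
  proc <- score_process(fx$scores, rnorm(fx$n), type = "metric")
  expect_error(test_statistic(proc, "LMuo"), "categorical")
  expect_error(test_statistic(proc, "WDMo"), "ordinal")
  proc2 <- score_process(fx$scores, rep(1, fx$n), type = "ordinal")
  expect_error(test_statistic(proc2, "maxLMo"), "levels")
})

test_that("simulated critical values are reproducible and monotone in q", {
  t1 <- simulate_critical_values("maxLM", n_params = 2, n_reps = 2000,
                                 seed = 7, nsteps = 300)
  t2 <- simulate_critical_values("maxLM", n_params = 2, n_reps = 2000,
                                 seed = 7, nsteps = 300)
  expect_identical(t1, t2)
  t4 <- simulate_critical_values("maxLM", n_params = 4, n_reps = 2000,
                                 seed = 7, nsteps = 300)
  expect_true(all(t4$critical_value > t1$critical_value))
  b1 <- simulate_critical_values("maxLMo", n_params = 1,
                                 boundaries_or_trim = c(0.25, 0.5, 0.75),
                                 n_reps = 3000, seed = 8)
  b3 <- simulate_critical_values("maxLMo", n_params = 3,
                                 boundaries_or_trim = c(0.25, 0.5, 0.75),
                                 n_reps = 3000, seed = 8)
  expect_true(all(b3$critical_value > b1$critical_value))
})
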