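test_that("objective is the printed quadratic form", {
  spec <- spec_uni(3, 3)
  th <- theta_uni_fixed(spec)
  kappa0 <- implied_moments(spec, th)$kappa
  pstar <- length(kappa0)
  # exact fit gives zero
  expect_equal(wls_objective(spec, th, kappa0, diag(pstar)), 0)
  # identity weight: squared Euclidean distance
  set.seed(51)
  kh <- kappa0 + rnorm(pstar, sd = 0.05)
  expect_equal(wls_objective(spec, th, kh, diag(pstar)),
               sum((kh - kappa0)^2))
  # general W: brute-force elementwise triple product
  A <- matrix(rnorm(pstar^2, sd = 0.1), pstar)
  W <- crossprod(A) + diag(pstar)
  Wi <- solve(W)
  r <- kh - kappa0
  brute <- 0
  for (i in seq_len(pstar)) for (j in seq_len(pstar))
    brute <- brute + r[i] * Wi[i, j] * r[j]
  expect_equal(wls_objective(spec, th, kh, W), unname(brute))
})

test_that("analytic gradient matches finite differences and scaling law", {
  skip_if_not_installed("numDeriv")
  spec <- spec_uni(3, 3)
  set.seed(52)
  th <- theta_random(spec)
  kappa0 <- implied_moments(spec, th)$kappa
  pstar <- length(kappa0)
  expect_equal(wls_gradient(spec, th, kappa0, diag(pstar)),
               rep(0, length(th)), ignore_attr = TRUE)
  kh <- kappa0 + rnorm(pstar, sd = 0.05)
  A <- matrix(rnorm(pstar^2, sd = 0.1), pstar)
  W <- crossprod(A) + diag(pstar)
  g <- wls_gradient(spec, th, kh, W)
  gfd <- numDeriv::grad(function(x) wls_objective(spec, x, kh, W), th)
  expect_lt(max(abs(g - gfd)), 1e-5)
  expect_equal(wls_gradient(spec, th, kh, 4 * W), g / 4)
})

test_that("fit recovers exactly when moments equal the implied values", {
  spec <- spec_uni(3, 3)
  th0 <- theta_uni_fixed(spec)
  im <- implied_moments(spec, th0)
  mats <- theta_to_matrices(spec, th0)
  pstar <- length(im$kappa)
  fake <- structure(list(
    tau_hat = mats$tau, rho_hat = unname(im$sigma_star),
    kappa_hat = im$kappa, W = diag(pstar), n = 100L, items = spec$items),
    class = "ofa_saturated")
  dat <- simulate_grm(spec, th0, 50, seed = 53)
  fit <- fit_ofa(dat, spec, start = th0, moments = fake)
  expect_lt(fit$objective, 1e-12)
  expect_equal(fit$theta, th0, tolerance = 1e-6)
})

test_that("fit is invariant to row order and marks convergence", {
  spec <- spec_uni(4, 3)
  set.seed(54)
  th <- theta_random(spec)
  dat <- simulate_grm(spec, th, 800, seed = 55)
  f1 <- fit_ofa(dat, spec)
  f2 <- fit_ofa(dat[sample(nrow(dat)), ], spec)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-8)
  expect_true(f1$converged)
  expect_lt(f1$gradient_norm, 1e-4)
  expect_gte(f1$objective, 0)
})

test_that("parameters are recovered on simulated data", {
  spec <- spec_uni(5, 3)
  spec2 <- spec_uni(5, 2)
  set.seed(56)
  th0 <- theta_random(spec)
  fit <- fit_ofa(simulate_grm(spec, th0, 5000, seed = 57), spec)
  # every parameter within Monte-Carlo range of the truth at n = 5000
  expect_lt(max(abs(fit$theta - th0)), 0.08)
  expect_lt(mean(abs(fit$theta - th0)), 0.03)
  # bias shrinks with n (same generating parameters, binary items)
  th2 <- theta_random(spec2)
  err <- vapply(c(1000, 20000), function(n) {
    f <- fit_ofa(simulate_grm(spec2, th2, n, seed = n), spec2)
    mean(abs(f$theta - th2))
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("dwls option fits with a diagonal weight and full-W scores", {
  spec <- spec_uni(4, 2)
  set.seed(58)
  th <- theta_random(spec)
  dat <- simulate_grm(spec, th, 600, seed = 59)
  fit <- fit_ofa(dat, spec, estimator = "dwls")
  expect_true(fit$converged)
  expect_equal(fit$estimator, "dwls")
  # the carried W is the full matrix, not a diagonal
  expect_gt(max(abs(fit$moments$W[lower.tri(fit$moments$W)])), 0)
  sc <- approx_scores(fit)
  expect_lt(max(abs(colSums(sc))), 1e-8 * nrow(dat))
})

test_that("tidy and glance expose estimates and metadata", {
  spec <- spec_uni(3, 2)
  set.seed(60)
  dat <- simulate_grm(spec, theta_random(spec), 400, seed = 61)
  fit <- fit_ofa(dat, spec)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term[td$free], names(fit$theta))
  expect_equal(td$estimate[td$free], unname(fit$theta))
  expect_equal(td$estimate[td$term == "F1~~F1"], 1)   # fixed variance
  gl <- glance(fit)
  expect_equal(gl$n, 400L)
  expect_equal(gl$n_free, length(fit$theta))
})

test_that("fit serializes to JSON and responses round-trip through CSV", {
  spec <- spec_uni(3, 2)
  set.seed(62)
  dat <- simulate_grm(spec, theta_random(spec), 200, seed = 63)
  fit <- fit_ofa(dat, spec)
  fj <- file.path(tempdir(), "fit.json")
  write_fit_json(fit, fj)
  back <- jsonlite::fromJSON(fj)
  expect_equal(unlist(back$theta), fit$theta, tolerance = 1e-12)
  fc <- file.path(tempdir(), "dat.csv")
  utils::write.csv(dat, fc, row.names = FALSE)
  expect_equal(as.data.frame(read_ordinal_csv(fc)), as.data.frame(dat))
})
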