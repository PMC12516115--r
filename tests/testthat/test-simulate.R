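test_that("simulated marginals match the probit of the thresholds", {
  spec <- spec_uni(3, 4)
  set.seed(111)
  th <- theta_random(spec)
  mats <- theta_to_matrices(spec, th)
  Y <- simulate_grm(spec, th, 20000, seed = 112)
  for (j in 1:3) {
    emp <- cumsum(table(factor(Y[[j]], 1:4))) / 20000
    expect_lt(max(abs(emp[1:3] - pnorm(mats$tau[[j]]))), 0.015)
  }
  # degenerate case: balanced binary item without common part
  sp2 <- grm_spec(list(F1 = "y1"), n_cat = 2)
  th2 <- make_theta(sp2, list(0), matrix(0, 1, 1), 1)
  Y2 <- simulate_grm(sp2, th2, 20000, seed = 113)
  expect_lt(abs(mean(Y2$y1 == 2) - 0.5), 0.01)
})

test_that("simulation is reproducible by seed", {
  spec <- spec_uni(4, 3)
  set.seed(114)
  th <- theta_random(spec)
  expect_identical(simulate_grm(spec, th, 200, seed = 5),
                   simulate_grm(spec, th, 200, seed = 5))
  scn <- dif_scenario("unidimensional", k = 2, n = 400, seed = 6)
  expect_identical(simulate_dif_study(scn, seed = 7),
                   simulate_dif_study(scn, seed = 7))
})

test_that("null mode leaves responses independent of all covariates", {
  set.seed(115)
  pvals <- replicate(20, {
    scn <- dif_scenario("unidimensional", k = 1, n = 600,
                        scenario = "null")
    dat <- simulate_dif_study(scn)
    min(suppressWarnings(c(
      chisq.test(table(dat$y1, dat$Zcat))$p.value,
      chisq.test(table(dat$y2, dat$Zord))$p.value,
      chisq.test(table(dat$y3, dat$Znum > 100))$p.value)))
  })
  expect_gte(sum(pvals > 0.001), 19)
})

test_that("threshold-subset DIF moves only the designated item", {
  set.seed(116)
  scn <- dif_scenario("unidimensional", k = 2, n = 20000,
                      scenario = "thresholds_subset")
  dat <- simulate_dif_study(scn)
  lower <- dat$Znum <= 100
  gap <- vapply(1:5, function(j) {
    max(abs(vapply(1:2, function(k)
      mean(dat[[j + 1]][lower] > k) - mean(dat[[j + 1]][!lower] > k),
      numeric(1))))
  }, numeric(1))
  expect_gt(gap[1], 0.05)
  expect_lt(max(gap[2:5]), 0.03)
  # group labels are recoverable from the numeric covariate split
  expect_identical(dat$group == "reference", lower)
})

test_that("scenario invariants hold on the drawn parameters", {
  set.seed(117)
  scn_t <- dif_scenario("multidimensional", k = 2, n = 400,
                        scenario = "thresholds_subset")
  expect_identical(scn_t$focal$a, scn_t$ref$a)
  expect_identical(scn_t$focal$tau_irt[3:9], scn_t$ref$tau_irt[3:9])
  expect_false(identical(scn_t$focal$tau_irt[[1]], scn_t$ref$tau_irt[[1]]))
  scn_l <- dif_scenario("multidimensional", k = 1, n = 400,
                        scenario = "loadings_all")
  expect_identical(scn_l$focal$tau_irt, scn_l$ref$tau_irt)
  expect_true(all(scn_l$focal$a[scn_l$ref$a != 0] !=
                    scn_l$ref$a[scn_l$ref$a != 0]))
  scn_0 <- dif_scenario("unidimensional", k = 1, n = 400,
                        scenario = "null")
  expect_identical(scn_0$focal$theta, scn_0$ref$theta)
  expect_error(dif_scenario("unidimensional", n = 401), "even")
})

test_that("expected item score is bounded, monotone and reduces for l = 2", {
  spec <- spec_uni(2, 2)
  th <- make_theta(spec, list(0.3, 0), matrix(c(0, 0.6), 1, 2), 1)
  # lambda = 0: S constant in xi, equal to P(Y = 2) = 1 - Phi(tau)
  xi <- matrix(seq(-3, 3, length.out = 21), ncol = 1)
  s1 <- scoring_function(spec, th, xi, j = 1)
  expect_equal(s1, rep(1 - pnorm(0.3), 21))
  # loaded binary item: S = P(Y = 2 | xi), monotone increasing in xi
  s2 <- scoring_function(spec, th, xi, j = 2)
  expect_true(all(diff(s2) > 0))
  expect_true(all(s2 >= 0 & s2 <= 1))
  # multi-category: range [0, l-1], monotone on a grid
  spec4 <- spec_uni(2, 5)
  set.seed(118)
  th4 <- theta_random(spec4)
  s4 <- scoring_function(spec4, th4, xi, j = 1)
  expect_true(all(diff(s4) >= 0))
  expect_true(all(s4 >= 0 & s4 <= 4))
})

test_that("NCDIF closed form and basic properties", {
  spec <- spec_uni(2, 2)
  tauv <- 0.2
  delta <- 0.5
  thR <- make_theta(spec, list(tauv, 0), matrix(0, 1, 2), 1)
  thF <- make_theta(spec, list(tauv + delta, 0), matrix(0, 1, 2), 1)
  xi <- matrix(rnorm(500), ncol = 1)
  expect_equal(ncdif(spec, thF, thR, xi, j = 1),
               (pnorm(tauv + delta) - pnorm(tauv))^2, tolerance = 1e-12)
  expect_equal(ncdif(spec, thR, thR, xi, j = 1), 0)
  expect_error(ncdif(spec, thF, thR, xi[0, , drop = FALSE], 1), "empty")
  # Monte-Carlo stability across independent factor-score samples
  set.seed(119)
  scn <- dif_scenario("unidimensional", k = 2, n = 400,
                      scenario = "thresholds_subset")
  v1 <- scenario_ncdif(scn, n_xi = 10000, seed = 120)$ncdif[1]
  v2 <- scenario_ncdif(scn, n_xi = 10000, seed = 121)$ncdif[1]
  expect_lt(abs(v1 - v2) / max(v1, 1e-12), 0.05)
})

test_that("loading-only DIF has much smaller NCDIF than threshold DIF", {
  set.seed(122)
  r <- replicate(30, {
    thr <- dif_scenario("unidimensional", k = 2, n = 400,
                        scenario = "thresholds_subset")
    lod <- dif_scenario("unidimensional", k = 2, n = 400,
                        scenario = "loadings_all")
    c(thr = scenario_ncdif(thr, n_xi = 2000)$ncdif[1],
      lod = scenario_ncdif(lod, n_xi = 2000)$ncdif[1])
  })
  expect_lt(mean(r["lod", ]), 0.8 * mean(r["thr", ]))
})
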