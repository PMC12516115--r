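test_that("indicator block stacks category exceedances in kappa order", {
  expect_equal(indicator_block(c(1, 3), n_cat = c(3, 3)), c(0, 0, 1, 1))
  expect_equal(indicator_block(c(2, 1), n_cat = c(3, 3)), c(1, 0, 0, 0))
  expect_error(indicator_block(c(0, 2), n_cat = c(3, 3)), "invalid")
  # column means equal the empirical exceedance probabilities
  set.seed(71)
  Y <- cbind(sample(1:3, 200, TRUE), sample(1:4, 200, TRUE))
  im <- t(apply(Y, 1, indicator_block, n_cat = c(3, 4)))
  expect_equal(colMeans(im),
               c(mean(Y[, 1] > 1), mean(Y[, 1] > 2),
                 mean(Y[, 2] > 1), mean(Y[, 2] > 2), mean(Y[, 2] > 3)))
})

test_that("cross-product block uses raw categories in pair order", {
  expect_equal(crossproduct_block(c(2, 3, 1), y_bar = c(2, 3, 1)),
               c(0, 0, 0))
  y_bar <- c(1.5, 2.5, 2)
  s <- crossproduct_block(c(2, 3, 1), y_bar)
  expect_equal(s, c(0.5 * 0.5, 0.5 * (-1), 0.5 * (-1)))
  # average of s_i is the divide-by-n covariance of each pair
  set.seed(72)
  Y <- cbind(sample(1:3, 300, TRUE), sample(1:5, 300, TRUE),
             sample(1:2, 300, TRUE))
  yb <- colMeans(Y)
  S <- t(apply(Y, 1, crossproduct_block, y_bar = yb))
  cv <- cov(Y) * (nrow(Y) - 1) / nrow(Y)
  expect_equal(colMeans(S), c(cv[1, 2], cv[1, 3], cv[2, 3]),
               ignore_attr = TRUE)
})

test_that("score columns sum to zero on any data and any estimate", {
  set.seed(73)
  for (spec in list(spec_uni(5, 3), spec_multi(2))) {
    th <- theta_random(spec)
    dat <- simulate_grm(spec, th, 500, seed = 74)
    fit <- fit_ofa(dat, spec)
    sc <- approx_scores(fit)
    expect_equal(dim(sc), c(500L, length(fit$theta)), ignore_attr = TRUE)
    expect_lt(max(abs(colSums(sc))), 1e-8 * 500)
    # also away from the optimum: the identity is algebraic, not a fit
    fit2 <- fit
    fit2$theta <- th
    expect_lt(max(abs(colSums(approx_scores(fit2)))), 1e-8 * 500)
  }
})

test_that("single binary item reduces to the hand formula", {
  spec <- suppressWarnings(grm_spec(
    list(F1 = "y1"), n_cat = 2,
    fixed_loadings = list(list(factor = "F1", item = "y1", value = 0.4))))
  set.seed(75)
  y <- tibble::tibble(y1 = sample(1:2, 300, TRUE, prob = c(0.4, 0.6)))
  fit <- fit_ofa(y, spec)
  sc <- approx_scores(fit)
  # psi_i = Delta' W^-1 (1{y_i > 1} - mean); Delta = 1, W scalar
  w <- fit$moments$W[1, 1]
  hand <- ((y$y1 > 1) - mean(y$y1 > 1)) / w
  expect_equal(unname(sc[, 1]), unname(hand))
})

test_that("scores permute with persons and duplicate with observations", {
  spec <- spec_uni(3, 3)
  set.seed(76)
  dat <- simulate_grm(spec, theta_random(spec), 240, seed = 77)
  fit <- fit_ofa(dat, spec)
  sc <- approx_scores(fit)
  perm <- sample(nrow(dat))
  sc_perm <- approx_scores(fit, data = dat[perm, ])
  expect_equal(unclass(sc_perm), unclass(sc)[perm, ], ignore_attr = TRUE)
  sc_dup <- approx_scores(fit, data = dplyr::bind_rows(dat, dat))
  expect_equal(unclass(sc_dup), rbind(unclass(sc), unclass(sc)),
               ignore_attr = TRUE)
  expect_lt(max(abs(colSums(sc_dup))), 1e-8 * nrow(sc_dup))
})

test_that("a group threshold shift flips the sign of group mean scores", {
  set.seed(78)
  scn <- dif_scenario("unidimensional", k = 2, n = 5000,
                      scenario = "thresholds_subset")
  dat <- simulate_dif_study(scn)
  fit <- fit_ofa(dat, scn$spec)
  sc <- approx_scores(fit)
  ref <- dat$group == "reference"
  thr_cols <- grep("\\|t", colnames(sc), value = TRUE)
  m_ref <- colMeans(sc[ref, thr_cols, drop = FALSE])
  m_foc <- colMeans(sc[!ref, thr_cols, drop = FALSE])
  # the strongest systematic threshold-score separation sits on the item
  # whose thresholds were shifted, and its direction flips between groups
  top <- names(which.max(abs(m_ref)))
  expect_match(top, "^y1\\|")
  expect_true(sign(m_ref[top]) == -sign(m_foc[top]))
  expect_gt(abs(m_ref[top]), 0.02)
})

test_that("scores export to CSV with an identifier column", {
  spec <- spec_uni(3, 2)
  set.seed(79)
  dat <- simulate_grm(spec, theta_random(spec), 100, seed = 80)
  fit <- fit_ofa(dat, spec)
  sc <- approx_scores(fit)
  fp <- file.path(tempdir(), "scores.csv")
  write_scores_csv(sc, fp, id = seq_len(100))
  back <- utils::read.csv(fp, check.names = FALSE)
  expect_equal(back$id, 1:100)
  expect_equal(as.matrix(back[, -1]), unclass(sc), ignore_attr = TRUE,
               tolerance = 1e-6)
})
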