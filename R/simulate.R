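# Graded-response-model simulator: random admissible parameter draws,
# response generation, focal/reference DIF scenarios with aligned covariates
# and NCDIF effect sizes. Parameters are drawn on the IRT (probit) scale --
# discriminations a > 0, residual sd 1 -- and converted to the standardized
# delta scale of the fitted model via
#   lambda = a / sqrt(a' Psi a + 1),  tau* = tau_irt / sqrt(a' Psi a + 1),
# so that any positive discrimination maps to an admissible loading.

# minimum spacing between consecutive standardized thresholds so that no
# response category is squeezed to negligible mass (keeps every category
# observable at the study sample sizes)
.enforce_gap <- function(tau, gap = 0.1) {
  if (length(tau) < 2L) return(tau)
  tau[1L] + c(0, cumsum(pmax(diff(tau), gap)))
}

.irt_to_delta <- function(spec, a, tau_irt, Psi) {
  v <- colSums(a * (Psi %*% a)) + 1
  Lam <- sweep(a, 2L, sqrt(v), "/")
  tau <- lapply(seq_len(spec$p), function(j) tau_irt[[j]] / sqrt(v[j]))
  make_theta(spec, tau, Lam, Psi)
}

#' Draw random admissible parameters for an ordinal factor model
#'
#' Reference-style parameter draw: IRT-scale discriminations uniform on
#' `discrim_range` for every declared loading, thresholds centred on the
#' equal-probability grid `qnorm(k/l)` with uniform jitter, latent
#' correlations at `factor_cor` (variances from the spec's fixed values),
#' converted to the delta scale.
#'
#' @param spec A `grm_spec`.
#' @param discrim_range Range of the uniform IRT discrimination draw.
#' @param thr_jitter Half-width of the uniform jitter on the standardized
#'   threshold grid.
#' @param factor_cor Latent correlation used for free factor covariances.
#' @param seed Optional seed (RNG state is restored afterwards if set).
#' @return List of class `grm_params`: `theta` (delta scale), `a`
#'   (IRT discriminations, `m x p`), `tau_irt`, `Psi`.
#' @export
grm_params <- function(spec, discrim_range = c(0.6, 1.1), thr_jitter = 0.3,
                       factor_cor = 0.5, seed = NULL) {
  draw <- function() {
    Psi <- spec$psi_pat
    diag(Psi)[is.na(diag(Psi))] <- 1
    Psi[is.na(Psi)] <- factor_cor
    a <- matrix(0, spec$m, spec$p, dimnames = dimnames(spec$lambda_pat))
    on_f <- is.na(spec$lambda_pat) | spec$lambda_pat != 0
    a[on_f] <- stats::runif(sum(on_f), discrim_range[1], discrim_range[2])
    v <- colSums(a * (Psi %*% a)) + 1
    tau_irt <- lapply(seq_len(spec$p), function(j) {
      lj <- spec$n_cat[j]
      base <- stats::qnorm(seq_len(lj - 1L) / lj)
      tt <- sort(base + stats::runif(lj - 1L, -thr_jitter, thr_jitter))
      .enforce_gap(tt) * sqrt(v[j])
    })
    names(tau_irt) <- spec$items
    structure(list(theta = .irt_to_delta(spec, a, tau_irt, Psi),
                   a = a, tau_irt = tau_irt, Psi = Psi, spec = spec),
              class = "grm_params")
  }
  if (is.null(seed)) draw() else .with_preserved_rng({
    set.seed(seed)
    draw()
  })
}

#' Simulate graded responses from an ordinal factor model
#'
#' Latent factor scores are drawn from `N(0, Psi)`, latent responses from
#' the delta-parameterized measurement model (residual variance
#' `1 - lambda' Psi lambda`), and categories assigned by the threshold
#' relation -- equivalently, each category is drawn from its conditional
#' probability given the factor scores.
#'
#' @param spec A `grm_spec`.
#' @param params A `grm_params` object or a delta-scale `theta` vector.
#' @param n Number of persons.
#' @param seed Optional seed.
#' @param return_xi If `TRUE`, attach the simulated factor scores as
#'   attribute `"xi"`.
#' @return Tibble of integer responses with the spec's item columns.
#' @export
simulate_grm <- function(spec, params, n, seed = NULL, return_xi = FALSE) {
  theta <- if (inherits(params, "grm_params")) params$theta else params
  if (!is.null(seed)) set.seed(seed)
  mats <- theta_to_matrices(spec, theta)
  L <- mats$Lambda
  Psi <- mats$Psi
  resid_var <- 1 - colSums(L * (Psi %*% L))
  if (any(resid_var <= 0)) stop("inadmissible theta: communality >= 1")
  xi <- matrix(stats::rnorm(n * spec$m), n, spec$m) %*% chol(Psi)
  ystar <- xi %*% L +
    matrix(stats::rnorm(n * spec$p), n, spec$p) %*% diag(sqrt(resid_var),
                                                         spec$p)
  Y <- vapply(seq_len(spec$p), function(j) {
    findInterval(ystar[, j], mats$tau[[j]]) + 1L
  }, integer(n))
  colnames(Y) <- spec$items
  out <- tibble::as_tibble(as.data.frame(Y))
  if (return_xi) attr(out, "xi") <- xi
  out
}

#' Define a DIF simulation scenario
#'
#' Mirrors the simulation design of the power study: a unidimensional
#' 5-item model or a multidimensional model with 3 correlated factors and 3
#' items each; `k` thresholds per item; a focal and a reference half whose
#' IRT-scale parameters differ according to `scenario`:
#' `"all_params"` (every threshold and discrimination shifted),
#' `"thresholds_subset"` (thresholds of item 1, or items 1-2 in the
#' multidimensional shape), `"loadings_all"` (all discriminations), or
#' `"null"` (identical parameters, covariates assigned at random).
#' Shifts are uniform on `shift_range` with random sign; in the
#' multidimensional all-parameter scenario the factor correlations also
#' differ (smaller shifts, redrawn until positive definite).
#'
#' @param model `"unidimensional"` or `"multidimensional"`.
#' @param k Thresholds per item (categories minus one), e.g. 1, 2, 4 or 6.
#' @param n Total sample size (focal + reference halves); must be even.
#' @param scenario Fluctuation scenario, see above.
#' @param shift_range Range of the absolute parameter shift.
#' @param discrim_range,thr_jitter,factor_cor Passed to [grm_params()].
#' @param seed Optional seed for the parameter draw.
#' @return Object of class `dif_scenario` with the spec, reference and
#'   focal parameters (both scales) and the covariate layout.
#' @export
dif_scenario <- function(model = c("unidimensional", "multidimensional"),
                         k = 2, n = 1000,
                         scenario = c("all_params", "thresholds_subset",
                                      "loadings_all", "null"),
                         shift_range = c(0.3, 0.6),
                         discrim_range = c(0.6, 1.1), thr_jitter = 0.3,
                         factor_cor = 0.5, seed = NULL) {
  model <- match.arg(model)
  scenario <- match.arg(scenario)
  if (n %% 2L != 0L) stop("n must be even (focal and reference halves)")
  if (!is.null(seed)) set.seed(seed)
  spec <- if (model == "unidimensional") {
    grm_spec(list(F1 = paste0("y", 1:5)), n_cat = k + 1L)
  } else {
    grm_spec(list(F1 = paste0("y", 1:3), F2 = paste0("y", 4:6),
                  F3 = paste0("y", 7:9)), n_cat = k + 1L)
  }
  ref <- grm_params(spec, discrim_range, thr_jitter, factor_cor)
  shift <- function(x, lo = shift_range[1], hi = shift_range[2]) {
    x + sample(c(-1, 1), length(x), TRUE) * stats::runif(length(x), lo, hi)
  }
  # thresholds of one item shift coherently (one sign per item, magnitudes
  # per threshold): a difficulty shift, not a spread change -- this is what
  # makes threshold DIF effect sizes comparable to all-parameter DIF
  shift_item <- function(tv, lo = shift_range[1], hi = shift_range[2]) {
    tv + sample(c(-1, 1), 1L) * stats::runif(length(tv), lo, hi)
  }
  a_f <- ref$a
  tau_f <- ref$tau_irt
  Psi_f <- ref$Psi
  dif_items <- integer(0)
  if (scenario == "all_params") {
    on_f <- a_f != 0
    a_f[on_f] <- pmax(shift(a_f[on_f]), 0.1)
    tau_f <- lapply(tau_f, function(tv) .enforce_gap(sort(shift_item(tv))))
    if (spec$m > 1L) {
      for (tries in 1:100) {
        Psi_try <- ref$Psi
        off <- upper.tri(Psi_try)
        Psi_try[off] <- pmin(pmax(shift(Psi_try[off], 0.1, 0.3), -0.9), 0.9)
        Psi_try[lower.tri(Psi_try)] <- t(Psi_try)[lower.tri(Psi_try)]
        if (min(eigen(Psi_try, TRUE, TRUE)$values) > 0.05) {
          Psi_f <- Psi_try
          break
        }
      }
    }
    dif_items <- seq_len(spec$p)
  } else if (scenario == "thresholds_subset") {
    dif_items <- if (model == "unidimensional") 1L else 1:2
    for (j in dif_items) {
      tau_f[[j]] <- .enforce_gap(sort(shift_item(tau_f[[j]])))
    }
  } else if (scenario == "loadings_all") {
    on_f <- a_f != 0
    a_f[on_f] <- pmax(shift(a_f[on_f]), 0.1)
    dif_items <- seq_len(spec$p)
  }
  structure(list(
    model = model, k = k, n = n, scenario = scenario, spec = spec,
    ref = ref,
    focal = structure(list(theta = .irt_to_delta(spec, a_f, tau_f, Psi_f),
                           a = a_f, tau_irt = tau_f, Psi = Psi_f,
                           spec = spec), class = "grm_params"),
    dif_items = dif_items), class = "dif_scenario")
}

#' @export
print.dif_scenario <- function(x, ...) {
  cat("DIF scenario: ", x$model, ", k = ", x$k, ", n = ", x$n,
      ", scenario = ", x$scenario, "\n", sep = "")
  invisible(x)
}

#' Simulate a focal/reference DIF study with covariates
#'
#' Generates responses for the reference half under the reference
#' parameters and the focal half under the focal parameters, and attaches
#' three covariates aligned with the group split: `Znum` (integers, the
#' reference half uniform on 1..100, the focal half on 101..200), and
#' `Zord` / `Zcat` (five ordered resp. unordered levels; the reference half
#' draws from the lower levels 1-2, the focal half from the upper levels
#' 3-5, so the group boundary coincides with a level boundary).
#' Under the `"null"` scenario a single group of size `n` is simulated and
#' all covariates are assigned uniformly at random.
#'
#' @param scn A [dif_scenario()].
#' @param seed Optional seed.
#' @param max_tries Resample-and-log fallback: datasets with an unobserved
#'   response category are redrawn up to this many times (an error after
#'   that), so first-stage thresholds are always estimable.
#' @return Tibble with `id`, the item columns, `Znum`, `Zord`, `Zcat` and
#'   `group` (`"reference"`/`"focal"`), with `scn` attached as attribute
#'   `"scenario"`.
#' @export
simulate_dif_study <- function(scn, seed = NULL, max_tries = 20L) {
  if (!is.null(seed)) set.seed(seed)
  n <- scn$n
  spec <- scn$spec
  all_observed <- function(df) {
    all(vapply(seq_len(spec$p), function(j) {
      length(unique(df[[spec$items[j]]])) == spec$n_cat[j]
    }, logical(1)))
  }
  draw_until_complete <- function(gen) {
    for (tr in seq_len(max_tries)) {
      Y <- gen()
      if (all_observed(Y)) {
        if (tr > 1L) attr(Y, "resampled") <- tr - 1L
        return(Y)
      }
    }
    stop("unobserved response category after ", max_tries, " resamples")
  }
  if (scn$scenario == "null") {
    Y <- draw_until_complete(function() simulate_grm(spec, scn$ref, n))
    out <- dplyr::mutate(Y,
      id = dplyr::row_number(),
      Znum = sample(1:200, n, replace = TRUE),
      Zord = sample(1:5, n, replace = TRUE),
      Zcat = sample(1:5, n, replace = TRUE),
      group = "reference")
  } else {
    h <- n %/% 2L
    Yb <- draw_until_complete(function()
      dplyr::bind_rows(simulate_grm(spec, scn$ref, h),
                       simulate_grm(spec, scn$focal, h)))
    out <- dplyr::mutate(Yb,
      id = dplyr::row_number(),
      Znum = c(sample(1:100, h, replace = TRUE),
               sample(101:200, h, replace = TRUE)),
      Zord = c(sample(1:2, h, replace = TRUE),
               sample(3:5, h, replace = TRUE)),
      Zcat = c(sample(1:2, h, replace = TRUE),
               sample(3:5, h, replace = TRUE)),
      group = rep(c("reference", "focal"), each = h))
  }
  out <- dplyr::relocate(out, "id")
  attr(out, "scenario") <- scn
  out
}

#' Expected item score function of the graded response model
#'
#' `S(xi, theta) = sum_k (k - 1) P(Y_j = k | xi, theta)`, the conditional
#' mean of the zero-based item score; ranges in `[0, l - 1]` and is
#' non-decreasing in the latent composite `lambda_j' xi`.
#'
#' @param spec A `grm_spec`.
#' @param params `grm_params` or delta-scale `theta`.
#' @param xi Factor-score vector (length `m`) or matrix (`n x m`).
#' @param j Item index or name.
#' @return Numeric vector of expected scores, one per row of `xi`.
#' @export
scoring_function <- function(spec, params, xi, j) {
  theta <- if (inherits(params, "grm_params")) params$theta else params
  if (is.character(j)) j <- match(j, spec$items)
  mats <- theta_to_matrices(spec, theta)
  xi <- rbind(xi)
  if (ncol(xi) != spec$m) stop("xi must have ", spec$m, " columns")
  lam <- mats$Lambda[, j]
  v <- 1 - drop(crossprod(lam, mats$Psi %*% lam))
  if (v <= 0) stop("inadmissible theta for item ", spec$items[j])
  eta <- drop(xi %*% lam)
  # S = sum_k P(Y > k) over k = 1..l-1
  s <- 0
  for (tk in mats$tau[[j]]) {
    s <- s + stats::pnorm((tk - eta) / sqrt(v), lower.tail = FALSE)
  }
  s
}

#' Noncompensatory DIF effect size (NCDIF)
#'
#' Mean squared difference of the expected item score function between the
#' focal and reference parameterizations, averaged over a focal-group
#' factor-score sample.
#'
#' @param spec A `grm_spec`.
#' @param params_focal,params_ref `grm_params` or delta-scale thetas.
#' @param xi Factor-score sample of the focal group (`n_F x m`).
#' @param j Item index or name.
#' @return Scalar `>= 0`.
#' @export
ncdif <- function(spec, params_focal, params_ref, xi, j) {
  xi <- rbind(xi)
  if (nrow(xi) == 0L) stop("empty factor-score sample")
  d <- scoring_function(spec, params_focal, xi, j) -
    scoring_function(spec, params_ref, xi, j)
  mean(d^2)
}

#' NCDIF effect sizes of a scenario
#'
#' @param scn A [dif_scenario()].
#' @param n_xi Size of the focal factor-score sample.
#' @param seed Optional seed.
#' @return Tibble with one row per item: `item`, `ncdif`.
#' @export
scenario_ncdif <- function(scn, n_xi = 5000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xi <- matrix(stats::rnorm(n_xi * scn$spec$m), n_xi, scn$spec$m) %*%
    chol(scn$focal$Psi)
  tibble::tibble(
    item = scn$spec$items,
    ncdif = vapply(seq_len(scn$spec$p), function(j)
      ncdif(scn$spec, scn$focal, scn$ref, xi, j), numeric(1)))
}
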