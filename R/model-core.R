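#' Cumulative category response probability of the graded response model
#'
#' Probability of responding in category `<= k` of item `j` given factor
#' scores `xi`: `Phi((tau_jk - lambda_j' xi) / resid_sd)`. With
#' `resid_sd = 1` this is the normal-ogive response function on the
#' discrimination (probit) scale; for a delta-parameterized model pass
#' `resid_sd = sqrt(1 - lambda_j' Psi lambda_j)` so that conditional and
#' marginal probabilities are mutually consistent (the simulator and the
#' expected-score functions do this internally).
#'
#' @param spec A `grm_spec`.
#' @param theta Free-parameter vector.
#' @param xi Numeric vector of factor scores, length `m`.
#' @param j Item index (or name).
#' @param k Category, `1 <= k <= n_cat[j]`; `k = n_cat[j]` returns 1.
#' @param resid_sd Residual standard deviation of the latent response;
#'   `NULL` (default) derives it from the delta parameterization.
#' @return Scalar probability.
#' @export
cumulative_prob <- function(spec, theta, xi, j, k, resid_sd = NULL) {
  if (is.character(j)) j <- match(j, spec$items)
  if (is.na(j) || j < 1 || j > spec$p) stop("item index out of range")
  if (length(xi) != spec$m) stop("xi must have length ", spec$m)
  lj <- spec$n_cat[j]
  if (k < 1 || k > lj) stop("category k out of range for item ", spec$items[j])
  mats <- theta_to_matrices(spec, theta)
  if (k == lj) return(1)
  lam <- mats$Lambda[, j]
  if (is.null(resid_sd)) {
    v <- 1 - drop(crossprod(lam, mats$Psi %*% lam))
    if (v <= 0) stop("Heywood case: latent-response variance of item ",
                     spec$items[j], " exhausted by the common part")
    resid_sd <- sqrt(v)
  }
  stats::pnorm((mats$tau[[j]][k] - sum(lam * xi)) / resid_sd)
}

#' Model-implied saturated moments
#'
#' Evaluates `kappa(theta) = (tau(theta), sigma*(theta))`: the model-implied
#' thresholds and the vech of the model-implied latent-response correlation
#' matrix. Under the delta parameterization the residual variance of item `j`
#' is `1 - lambda_j' Psi lambda_j`, so every latent response has unit
#' variance and `sigma*_{js} = lambda_j' Psi lambda_s`.
#'
#' @param spec A `grm_spec`.
#' @param theta Free-parameter vector.
#' @return List of class `ofa_moments` with `tau_model` (stacked thresholds),
#'   `sigma_star` (length `p(p-1)/2`, pairs `(j,s)`, `j < s`, lexicographic),
#'   `kappa` (their concatenation) and `resid_var`.
#' @export
implied_moments <- function(spec, theta) {
  mats <- theta_to_matrices(spec, theta)
  L <- mats$Lambda
  Psi <- mats$Psi
  PL <- Psi %*% L                     # m x p
  commonal <- colSums(L * PL)         # lambda_j' Psi lambda_j
  bad <- which(commonal >= 1)
  if (length(bad))
    stop("Heywood case: item(s) ", paste(spec$items[bad], collapse = ", "),
         " have latent-response communality >= 1")
  S <- crossprod(L, PL)               # p x p, lambda_j' Psi lambda_s
  pr <- .pairs_js(spec$p)             # lexicographic (j,s), j < s
  sigma_star <- S[pr]
  tau_model <- unlist(mats$tau, use.names = FALSE)
  names(sigma_star) <- .pair_names(spec)
  names(tau_model) <- spec$param_table$name[
    spec$param_table$block == "threshold"]
  structure(list(tau_model = tau_model, sigma_star = sigma_star,
                 kappa = c(tau_model, sigma_star),
                 resid_var = 1 - commonal),
            class = "ofa_moments")
}

# kappa(theta) without admissibility checks -- the WLS objective is smooth in
# theta even where the residual variance goes negative, so the optimizer may
# evaluate it there (a barrier keeps the final estimate admissible)
.implied_kappa_raw <- function(spec, theta) {
  mats <- theta_to_matrices(spec, theta, validate = FALSE)
  L <- mats$Lambda
  PL <- mats$Psi %*% L
  S <- crossprod(L, PL)
  pr <- .pairs_js(spec$p)
  list(kappa = c(unlist(mats$tau, use.names = FALSE), S[pr]),
       commonal = colSums(L * PL), mats = mats, PL = PL)
}

.pairs_js <- function(p) {
  if (p < 2L) return(cbind(j = integer(0), s = integer(0)))
  cbind(j = rep(seq_len(p - 1), times = (p - 1):1),
        s = unlist(lapply(seq_len(p - 1), function(j) seq(j + 1, p))))
}

.pair_names <- function(spec) {
  pr <- .pairs_js(spec$p)
  if (nrow(pr) == 0L) return(character(0))
  paste0(spec$items[pr[, 1]], "~~", spec$items[pr[, 2]])
}

#' Jacobian of the implied moments with respect to the free parameters
#'
#' The `p* x |theta|` matrix with row blocks d tau / d theta (identity on the
#' threshold positions) and d sigma* / d theta by the chain rule of the delta
#' parameterization: for a pair `(j, s)`,
#' `d sigma*_{js} / d lambda_{qj} = (Psi lambda_s)_q`,
#' `d / d psi_{qq} = lambda_{qj} lambda_{qs}`, and
#' `d / d psi_{qr} = lambda_{qj} lambda_{rs} + lambda_{rj} lambda_{qs}`.
#'
#' @param spec A `grm_spec`.
#' @param theta Free-parameter vector.
#' @param validate Check `theta` admissibility first (thresholds ascending,
#'   `Psi` positive definite).
#' @return Matrix with `p(l-1) + p(p-1)/2` rows and `|theta|` columns.
#' @export
delta_matrix <- function(spec, theta, validate = TRUE) {
  mats <- theta_to_matrices(spec, theta, validate = validate)
  L <- mats$Lambda
  Psi <- mats$Psi
  PL <- Psi %*% L
  pt <- spec$param_table
  free <- which(pt$free)
  q_len <- length(free)
  n_thr <- sum(spec$n_cat - 1L)
  pr <- .pairs_js(spec$p)
  pstar <- n_thr + nrow(pr)
  D <- matrix(0, pstar, q_len,
              dimnames = list(NULL, pt$name[free]))
  thr_rows <- which(pt$block == "threshold")      # all thresholds are rows
  # threshold block: identity on free thresholds
  for (ci in seq_along(free)) {
    r <- free[ci]
    if (pt$block[r] == "threshold") {
      D[match(r, thr_rows), ci] <- 1
    }
  }
  fidx <- match(pt$factor, spec$factors)
  fidx2 <- match(pt$factor2, spec$factors)
  iidx <- match(pt$item, spec$items)
  for (rw in seq_len(nrow(pr))) {
    j <- pr[rw, 1]; s <- pr[rw, 2]
    row <- n_thr + rw
    for (ci in seq_along(free)) {
      r <- free[ci]
      blk <- pt$block[r]
      if (blk == "loading") {
        qq <- fidx[r]
        if (iidx[r] == j) D[row, ci] <- D[row, ci] + PL[qq, s]
        if (iidx[r] == s) D[row, ci] <- D[row, ci] + PL[qq, j]
      } else if (blk == "lat_var") {
        qq <- fidx[r]
        D[row, ci] <- L[qq, j] * L[qq, s]
      } else if (blk == "lat_cov") {
        qq <- fidx[r]; rr <- fidx2[r]
        D[row, ci] <- L[qq, j] * L[rr, s] + L[rr, j] * L[qq, s]
      }
    }
  }
  D
}
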