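# Stage two: minimize the weighted least squares discrepancy
#   F(theta) = [kappa_hat - kappa(theta)]' W^{-1} [kappa_hat - kappa(theta)]
# with analytic gradient -2 [kappa_hat - kappa(theta)]' W^{-1} Delta.

#' WLS discrepancy between saturated and model-implied moments
#'
#' @param spec A `grm_spec`.
#' @param theta Free-parameter vector.
#' @param kappa_hat Stacked first-stage moments (thresholds, polychorics).
#' @param W Positive-definite weight matrix (asymptotic covariance of
#'   `kappa_hat`); its inverse weights the quadratic form.
#' @return Scalar objective value, `>= 0`.
#' @export
wls_objective <- function(spec, theta, kappa_hat, W) {
  r <- kappa_hat - implied_moments(spec, theta)$kappa
  drop(crossprod(r, solve(W, r)))
}

#' Gradient of the WLS discrepancy
#'
#' @inheritParams wls_objective
#' @return Numeric vector of length `|theta|`:
#'   `-2 [kappa_hat - kappa(theta)]' W^{-1} Delta`.
#' @export
wls_gradient <- function(spec, theta, kappa_hat, W) {
  r <- kappa_hat - implied_moments(spec, theta)$kappa
  D <- delta_matrix(spec, theta)
  drop(-2 * crossprod(D, solve(W, r)))
}

# ---- internal reparameterization -------------------------------------------
# thresholds: first threshold + log-gaps (enforces strict ascent);
# free latent variances: log; loadings and latent covariances: identity.

.nu_info <- function(spec) {
  pt <- spec$param_table
  free <- pt[pt$free, ]
  blocks <- free$block
  # per item, positions (within theta) of its free thresholds
  thr_groups <- split(seq_len(nrow(free))[blocks == "threshold"],
                      free$item[blocks == "threshold"])
  list(blocks = blocks, thr_groups = thr_groups,
       latvar = which(blocks == "lat_var"))
}

.theta_to_nu <- function(info, theta) {
  nu <- theta
  for (g in info$thr_groups) {
    if (length(g) > 1L) nu[g[-1L]] <- log(diff(theta[g]))
  }
  nu[info$latvar] <- log(theta[info$latvar])
  nu
}

.nu_to_theta <- function(info, nu) {
  theta <- nu
  for (g in info$thr_groups) {
    if (length(g) > 1L) theta[g] <- cumsum(c(nu[g[1L]], exp(nu[g[-1L]])))
  }
  theta[info$latvar] <- exp(nu[info$latvar])
  theta
}

# chain rule: grad_nu = (d theta / d nu)' grad_theta
.grad_to_nu <- function(info, nu, grad_theta) {
  g <- grad_theta
  for (gi in info$thr_groups) {
    if (length(gi) > 1L) {
      rev_cum <- rev(cumsum(rev(grad_theta[gi])))
      g[gi[1L]] <- rev_cum[1L]
      g[gi[-1L]] <- rev_cum[-1L] * exp(nu[gi[-1L]])
    }
  }
  g[info$latvar] <- grad_theta[info$latvar] * exp(nu[info$latvar])
  g
}

#' Fit an ordinal factor model by weighted least squares
#'
#' Two-stage limited-information estimation of a (multidimensional) graded
#' response model: stage one estimates thresholds and polychoric
#' correlations with their asymptotic covariance `W`
#' ([polychoric_stage()]); stage two minimizes the WLS discrepancy with an
#' analytic gradient, optimizing over an unconstrained reparameterization
#' (first threshold plus log-gaps, log latent variances) so threshold order
#' is maintained by construction. A quadratic barrier keeps item
#' communalities below 1 during the search; a Heywood solution at the
#' optimum is an error.
#'
#' @param data Data frame containing at least the item columns named in
#'   `spec` (integer categories starting at 1); extra columns are ignored.
#' @param spec A `grm_spec`.
#' @param estimator `"wls"` (full weight matrix, the default) or `"dwls"`
#'   (diagonal weight matrix in the fit; the full `W` is still carried for
#'   score computation).
#' @param start Optional starting `theta`; defaults to first-stage
#'   thresholds, free loadings 0.7, free latent variances 0.5, free latent
#'   covariances 0.
#' @param max_iter Maximum BFGS iterations.
#' @param conv_tol Convergence tolerance on the max-norm of the gradient.
#' @param moments Optional precomputed [polychoric_stage()] result.
#' @return Object of class `ofa_fit`.
#' @examples
#' spec <- grm_spec(list(F1 = paste0("y", 1:5)), n_cat = 3)
#' dat <- simulate_grm(spec, grm_params(spec, seed = 1), n = 300, seed = 2)
#' fit <- fit_ofa(dat, spec)
#' glance(fit)
#' @export
fit_ofa <- function(data, spec, estimator = c("wls", "dwls"), start = NULL,
                    max_iter = 500L, conv_tol = 1e-5, moments = NULL) {
  estimator <- match.arg(estimator)
  Y <- as.matrix(as.data.frame(data)[, spec$items, drop = FALSE])
  storage.mode(Y) <- "integer"
  if (is.null(moments)) moments <- polychoric_stage(Y, n_cat = spec$n_cat)
  kappa_hat <- moments$kappa_hat
  W <- moments$W
  Wfit <- if (estimator == "dwls") diag(diag(W)) else W
  Wi <- chol2inv(chol(Wfit))

  pt <- spec$param_table
  if (is.null(start)) {
    start <- numeric(sum(pt$free))
    names(start) <- pt$name[pt$free]
    free <- pt[pt$free, ]
    start[free$block == "loading"] <- 0.7
    start[free$block == "lat_var"] <- 0.5
    start[free$block == "lat_cov"] <- 0
    thr_free <- which(free$block == "threshold")
    start[thr_free] <- unlist(moments$tau_hat, use.names = FALSE)[
      match(free$name[thr_free], names(kappa_hat))]
  }
  info <- .nu_info(spec)
  nu0 <- .theta_to_nu(info, start)

  vmax <- 0.98
  cpen <- 1e3
  free <- pt[pt$free, ]
  eval_at <- function(nu) {
    theta <- .nu_to_theta(info, nu)
    raw <- .implied_kappa_raw(spec, theta)
    r <- kappa_hat - raw$kappa
    Wir <- Wi %*% r
    val <- drop(crossprod(r, Wir))
    D <- delta_matrix(spec, theta, validate = FALSE)
    grad <- drop(-2 * crossprod(D, Wir))
    # communality barrier
    over <- raw$commonal - vmax
    hot <- which(over > 0)
    if (length(hot)) {
      val <- val + cpen * sum(over[hot]^2)
      L <- raw$mats$Lambda; PL <- raw$PL
      for (j in hot) {
        coef <- 2 * cpen * over[j]
        for (ci in seq_len(nrow(free))) {
          blk <- free$block[ci]
          if (blk == "loading" && free$item[ci] == spec$items[j]) {
            q <- match(free$factor[ci], spec$factors)
            grad[ci] <- grad[ci] + coef * 2 * PL[q, j]
          } else if (blk == "lat_var") {
            q <- match(free$factor[ci], spec$factors)
            grad[ci] <- grad[ci] + coef * L[q, j]^2
          } else if (blk == "lat_cov") {
            q <- match(free$factor[ci], spec$factors)
            rr <- match(free$factor2[ci], spec$factors)
            grad[ci] <- grad[ci] + coef * 2 * L[q, j] * L[rr, j]
          }
        }
      }
    }
    # latent correlation barrier (keeps Psi away from the unit boundary)
    Psi <- raw$mats$Psi
    for (ci in which(free$block == "lat_cov")) {
      q <- match(free$factor[ci], spec$factors)
      rr <- match(free$factor2[ci], spec$factors)
      lim <- 0.97 * sqrt(Psi[q, q] * Psi[rr, rr])
      ex <- abs(Psi[q, rr]) - lim
      if (ex > 0) {
        val <- val + cpen * ex^2
        grad[ci] <- grad[ci] + 2 * cpen * ex * sign(Psi[q, rr])
      }
    }
    list(value = val, grad = .grad_to_nu(info, nu, grad), theta = theta)
  }

  cache <- new.env(parent = emptyenv())
  fn <- function(nu) {
    e <- eval_at(nu)
    assign("last", list(nu = nu, e = e), envir = cache)
    e$value
  }
  gr <- function(nu) {
    l <- get0("last", envir = cache)
    if (!is.null(l) && identical(l$nu, nu)) return(l$e$grad)
    eval_at(nu)$grad
  }

  opt <- stats::optim(nu0, fn, gr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12))
  # one polish restart if the gradient has not flattened out yet
  final <- eval_at(opt$par)
  if (max(abs(final$grad)) > conv_tol) {
    opt2 <- stats::optim(opt$par, fn, gr, method = "BFGS",
                         control = list(maxit = max_iter, reltol = 1e-14))
    if (opt2$value <= opt$value) {
      opt <- opt2
      final <- eval_at(opt$par)
    }
  }
  theta_hat <- final$theta
  gnorm <- max(abs(final$grad))
  # admissibility at the optimum (errors on Heywood)
  implied <- implied_moments(spec, theta_hat)
  structure(list(
    spec = spec, theta = theta_hat, objective = final$value,
    converged = opt$convergence == 0 && gnorm < max(conv_tol, 1e-3),
    n_iter = unname(opt$counts["function"]), gradient_norm = gnorm,
    moments = moments, implied = implied, estimator = estimator,
    n = moments$n, Y = Y), class = "ofa_fit")
}

#' @export
print.ofa_fit <- function(x, ...) {
  cat("Ordinal factor model fit (", toupper(x$estimator), "), n = ", x$n,
      ", ", length(x$theta), " free parameters\n", sep = "")
  cat("objective ", format(x$objective, digits = 6), ", gradient max-norm ",
      format(x$gradient_norm, digits = 3),
      if (x$converged) ", converged" else ", NOT converged", "\n", sep = "")
  invisible(x)
}

#' Tidy an ordinal factor model fit
#'
#' @param x An `ofa_fit`.
#' @param ... Unused.
#' @return Tibble with one row per model parameter (free and fixed):
#'   `term`, `block`, `item`, `factor`, `estimate`, `free`.
#' @method tidy ofa_fit
#' @export
tidy.ofa_fit <- function(x, ...) {
  pt <- x$spec$param_table
  est <- pt$fixed_value
  est[pt$free] <- x$theta
  tibble::tibble(term = pt$name, block = pt$block, item = pt$item,
                 factor = pt$factor, estimate = est, free = pt$free)
}

#' Glance at an ordinal factor model fit
#'
#' @param x An `ofa_fit`.
#' @param ... Unused.
#' @return One-row tibble with the objective value, convergence metadata and
#'   problem dimensions.
#' @method glance ofa_fit
#' @export
glance.ofa_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, converged = x$converged,
                 n_iter = x$n_iter, gradient_norm = x$gradient_norm,
                 n = x$n, n_free = length(x$theta),
                 estimator = x$estimator)
}

#' Write a fit to JSON / read an ordinal response CSV
#'
#' `write_fit_json()` serializes the estimates and convergence metadata;
#' `read_ordinal_csv()` reads a header CSV of integer-coded responses (and
#' any covariate columns) as a tibble.
#'
#' @param fit An `ofa_fit`.
#' @param path Output (input) file path.
#' @return `write_fit_json()` the path, invisibly; `read_ordinal_csv()` a
#'   tibble.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(theta = as.list(fit$theta), objective = fit$objective,
         converged = fit$converged, n_iter = fit$n_iter,
         gradient_norm = fit$gradient_norm, n = fit$n,
         estimator = fit$estimator),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_ordinal_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}
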