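# Stage one of the limited-information pipeline: univariate probit
# thresholds, Olsson two-step polychoric correlations, and the asymptotic
# covariance matrix W of the stacked saturated moments kappa-hat.

#' Estimate item thresholds from ordinal data
#'
#' Univariate first step: `tau_jk = qnorm(P(Y_j <= k))` from the empirical
#' cumulative proportions, the maximum-likelihood solution of the saturated
#' univariate probit model.
#'
#' @param data Data frame or matrix of integer responses, categories coded
#'   `1..l_j`.
#' @param n_cat Optional vector of category counts; defaults to the observed
#'   maximum per item. Every category `1..n_cat` must be observed.
#' @return Named list of ascending threshold vectors, one per item, with the
#'   per-item category proportions attached as attribute `"prop"`.
#' @export
estimate_thresholds <- function(data, n_cat = NULL) {
  Y <- as.matrix(data)
  p <- ncol(Y)
  items <- colnames(Y) %||% paste0("y", seq_len(p))
  if (is.null(n_cat)) n_cat <- apply(Y, 2, max)
  n_cat <- rep_len(as.integer(n_cat), p)
  out <- vector("list", p)
  props <- vector("list", p)
  for (j in seq_len(p)) {
    lj <- n_cat[j]
    if (lj < 2L) stop("item ", items[j], " is constant (single category)")
    cnt <- tabulate(Y[, j], nbins = lj)
    if (any(cnt == 0L))
      stop("item ", items[j], ": category ", which(cnt == 0L)[1],
           " unobserved; thresholds are not estimable")
    cum <- cumsum(cnt) / sum(cnt)
    out[[j]] <- stats::qnorm(cum[-lj])
    props[[j]] <- cnt / sum(cnt)
  }
  names(out) <- items
  names(props) <- items
  attr(out, "prop") <- props
  out
}

#' Bivariate-normal cell probabilities of an ordinal item pair
#'
#' Rectangle probabilities between consecutive thresholds under a standard
#' bivariate normal with correlation `rho`.
#'
#' @param tau_j,tau_s Ascending finite threshold vectors of the two items.
#' @param rho Latent correlation.
#' @return `(l_j) x (l_s)` matrix of cell probabilities summing to 1.
#' @export
polychoric_cellprobs <- function(tau_j, tau_s, rho) {
  a <- c(-Inf, tau_j, Inf)
  b <- c(-Inf, tau_s, Inf)
  la <- length(a)
  lb <- length(b)
  Fm <- matrix(0, la, lb)
  Fm[la, ] <- stats::pnorm(b)
  Fm[, lb] <- stats::pnorm(a)
  if (la > 2L && lb > 2L) {
    A <- rep(tau_j, times = lb - 2L)
    B <- rep(tau_s, each = la - 2L)
    Fm[2:(la - 1L), 2:(lb - 1L)] <- matrix(pbvn(A, B, rho), la - 2L, lb - 2L)
  }
  Fm[1L, ] <- 0
  Fm[, 1L] <- 0
  Fm[la, lb] <- 1
  pi_ab <- Fm[-1L, -1L, drop = FALSE] - Fm[-la, -1L, drop = FALSE] -
    Fm[-1L, -lb, drop = FALSE] + Fm[-la, -lb, drop = FALSE]
  pmax(pi_ab, 0)
}

# d pi_ab / d rho: corner sums of the bivariate density (infinite corners
# contribute zero); same shape as polychoric_cellprobs()
.cellprob_drho <- function(tau_j, tau_s, rho) {
  a <- c(-Inf, tau_j, Inf)
  b <- c(-Inf, tau_s, Inf)
  la <- length(a)
  lb <- length(b)
  G <- matrix(0, la, lb)
  if (la > 2L && lb > 2L) {
    A <- rep(tau_j, times = lb - 2L)
    B <- rep(tau_s, each = la - 2L)
    G[2:(la - 1L), 2:(lb - 1L)] <- matrix(dbvn(A, B, rho), la - 2L, lb - 2L)
  }
  G[-1L, -1L, drop = FALSE] - G[-la, -1L, drop = FALSE] -
    G[-1L, -lb, drop = FALSE] + G[-la, -lb, drop = FALSE]
}

#' Two-step polychoric correlation of one item pair
#'
#' Maximizes the bivariate-normal contingency-table log-likelihood over the
#' latent correlation, holding the thresholds fixed at their univariate
#' estimates (Olsson's two-step estimator).
#'
#' @param yj,ys Integer response vectors (categories from 1).
#' @param tau_j,tau_s Fixed threshold vectors from [estimate_thresholds()].
#' @param bound Interior search boundary; estimates at the boundary are
#'   clipped with a warning.
#' @return Scalar correlation estimate in `(-bound, bound)`.
#' @export
estimate_polychoric <- function(yj, ys, tau_j, tau_s, bound = 0.999) {
  lj <- length(tau_j) + 1L
  ls <- length(tau_s) + 1L
  tab <- table(factor(yj, levels = seq_len(lj)),
               factor(ys, levels = seq_len(ls)))
  tab <- matrix(as.numeric(tab), lj, ls)
  if (lj == ls && sum(diag(tab)) == sum(tab)) {
    warning("item pair is perfectly dependent; polychoric clipped to ", bound)
    return(bound)
  }
  negll <- function(r) {
    pi_ab <- polychoric_cellprobs(tau_j, tau_s, r)
    -sum(tab * log(pmax(pi_ab, 1e-300)))
  }
  opt <- stats::optimize(negll, interval = c(-bound, bound), tol = 1e-8)
  rho <- opt$minimum
  if (abs(rho) > bound - 1e-4) {
    warning("polychoric correlation at the search boundary; clipped")
    rho <- sign(rho) * bound
  }
  rho
}

#' First-stage saturated moments with asymptotic covariance
#'
#' Runs the complete first stage on a response matrix: thresholds for every
#' item, polychoric correlations for every pair, and the weight matrix `W`
#' (an estimate of `n` times the asymptotic covariance of `kappa-hat`) built
#' from per-case influence functions of the two-stage estimator. The
#' influence function of a threshold is the scaled probit estimating
#' function; the influence function of a correlation corrects the pairwise
#' likelihood score for the sampling error of the thresholds it conditions
#' on (block-triangular two-stage construction).
#'
#' @param data Data frame or matrix of integer responses (covariate columns
#'   must be excluded by the caller; see [fit_ofa()]).
#' @param n_cat Optional category counts per item.
#' @param rho_bound Interior boundary for the polychoric search.
#' @return Object of class `ofa_saturated`: list with `tau_hat`, `rho_hat`,
#'   `kappa_hat`, `W`, `influence` (the `n x p*` per-case contributions) and
#'   `n`.
#' @export
polychoric_stage <- function(data, n_cat = NULL, rho_bound = 0.999) {
  Y <- as.matrix(data)
  storage.mode(Y) <- "integer"
  n <- nrow(Y)
  p <- ncol(Y)
  items <- colnames(Y) %||% paste0("y", seq_len(p))
  colnames(Y) <- items
  tau_hat <- estimate_thresholds(Y, n_cat)
  n_thr <- lengths(tau_hat)

  # threshold influence functions: (1{y<=k} - Phi(tau)) / phi(tau)
  IF_tau <- matrix(0, n, sum(n_thr))
  col0 <- 0L
  for (j in seq_len(p)) {
    tj <- tau_hat[[j]]
    for (k in seq_along(tj)) {
      IF_tau[, col0 + k] <-
        ((Y[, j] <= k) - stats::pnorm(tj[k])) / stats::dnorm(tj[k])
    }
    col0 <- col0 + length(tj)
  }

  pr <- .pairs_js(p)
  rho_hat <- numeric(nrow(pr))
  IF_rho <- matrix(0, n, nrow(pr))
  thr_offset <- c(0L, cumsum(n_thr))
  for (rw in seq_len(nrow(pr))) {
    j <- pr[rw, 1]; s <- pr[rw, 2]
    tj <- tau_hat[[j]]; ts <- tau_hat[[s]]
    rho <- estimate_polychoric(Y[, j], Y[, s], tj, ts, bound = rho_bound)
    rho_hat[rw] <- rho

    score_tab <- function(tj., ts., r) {
      pi_ab <- pmax(polychoric_cellprobs(tj., ts., r), 1e-300)
      .cellprob_drho(tj., ts., r) / pi_ab
    }
    sc <- score_tab(tj, ts, rho)
    cells <- cbind(Y[, j], Y[, s])
    g_rho <- sc[cells]
    phat <- matrix(0, length(tj) + 1L, length(ts) + 1L)
    cnt <- table(factor(Y[, j], seq_len(length(tj) + 1L)),
                 factor(Y[, s], seq_len(length(ts) + 1L)))
    phat[] <- as.numeric(cnt) / n

    h <- 1e-4
    # Fisher-type curvature in rho (numeric derivative of the mean score)
    A_rr <- -sum(phat * (score_tab(tj, ts, rho + h) -
                           score_tab(tj, ts, rho - h))) / (2 * h)
    # cross-derivatives wrt the conditioning thresholds
    A_rt <- numeric(length(tj) + length(ts))
    for (k in seq_along(tj)) {
      tp <- tj; tp[k] <- tj[k] + h
      tm <- tj; tm[k] <- tj[k] - h
      A_rt[k] <- -sum(phat * (score_tab(tp, ts, rho) -
                                score_tab(tm, ts, rho))) / (2 * h)
    }
    for (k in seq_along(ts)) {
      tp <- ts; tp[k] <- ts[k] + h
      tm <- ts; tm[k] <- ts[k] - h
      A_rt[length(tj) + k] <-
        -sum(phat * (score_tab(tj, tp, rho) -
                       score_tab(tj, tm, rho))) / (2 * h)
    }
    if (!is.finite(A_rr) || A_rr <= 0)
      stop("degenerate pairwise information for pair (", items[j], ", ",
           items[s], ")")
    IF_pair_tau <- cbind(
      IF_tau[, (thr_offset[j] + 1L):(thr_offset[j] + n_thr[j]), drop = FALSE],
      IF_tau[, (thr_offset[s] + 1L):(thr_offset[s] + n_thr[s]), drop = FALSE])
    IF_rho[, rw] <- (g_rho - drop(IF_pair_tau %*% A_rt)) / A_rr
  }

  IF <- cbind(IF_tau, IF_rho)
  # center: estimating functions have mean ~0 at the estimate; remove the
  # float residue so W is exactly the second moment of the deviations
  IF <- sweep(IF, 2L, colMeans(IF))
  W <- crossprod(IF) / n
  ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev))
    stop("weight matrix W numerically singular (min eigenvalue ",
         format(min(ev)), "); consider the DWLS option")

  kappa_hat <- c(unlist(tau_hat, use.names = FALSE), rho_hat)
  rho_names <- if (nrow(pr)) paste0(items[pr[, 1]], "~~", items[pr[, 2]])
    else character(0)
  kn <- c(unlist(lapply(seq_len(p), function(j)
    paste0(items[j], "|t", seq_len(n_thr[j]))), use.names = FALSE),
    rho_names)
  names(kappa_hat) <- kn
  dimnames(W) <- list(kn, kn)
  structure(list(tau_hat = tau_hat, rho_hat = rho_hat, kappa_hat = kappa_hat,
                 W = W, influence = IF, n = n, items = items),
            class = "ofa_saturated")
}

#' @export
print.ofa_saturated <- function(x, ...) {
  cat("Saturated ordinal moments: ", length(x$tau_hat), " items, ",
      length(x$rho_hat), " polychoric correlations, n = ", x$n, "\n", sep = "")
  invisible(x)
}
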