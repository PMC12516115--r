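# Decorrelated cumulative score process and the score-based parameter
# instability statistics (DM, CvM, maxLM for metric covariates; WDMo,
# maxLMo for ordinal; LMuo for categorical), with closed-form, chi-square
# or Brownian-bridge-simulated p-values.

#' Decorrelated cumulative score process along a covariate
#'
#' Persons are ordered by the covariate (stable: ties keep their original
#' order), scores are cumulated and decorrelated with the inverse symmetric
#' square root of the outer-product covariance estimate
#' `B = (1/n) sum_i psi_i psi_i'`, giving
#' `CSP(H) = B^{-1/2} n^{-1/2} sum_{h <= H} psi_(h|Z)`. Under the null of
#' parameter stability each column converges to an independent Brownian
#' bridge in `H/n`.
#'
#' @param scores An [approx_scores()] matrix (zero-sum columns).
#' @param z Covariate vector, length `n`.
#' @param type Covariate scale: `"metric"`, `"ordinal"` or `"categorical"`.
#' @return Object of class `ofa_csp`: list with `csp` (`(n+1) x q`,
#'   row `H+1` is `CSP(H)`, so the first and last rows are exactly 0), `t`
#'   (`H/n`), `z` (sorted covariate), `type`, `B`, `n`, `q`.
#' @export
score_process <- function(scores, z,
                          type = c("metric", "ordinal", "categorical")) {
  type <- match.arg(type)
  sc <- unclass(scores)
  n <- nrow(sc)
  if (length(z) != n) stop("covariate length ", length(z), " != n = ", n)
  q <- ncol(sc)
  B <- crossprod(sc) / n
  ev <- eigen(B, symmetric = TRUE)
  tol <- 1e-10 * sum(diag(B))
  if (min(ev$values) < tol) {
    worst <- which.min(ev$values)
    lead <- order(abs(ev$vectors[, worst]), decreasing = TRUE)[1:2]
    stop("score covariance (nearly) singular; deficient direction loads on ",
         paste(colnames(sc)[lead], collapse = ", "),
         " (unidentified or degenerate parameter?)")
  }
  Bis <- ev$vectors %*% (t(ev$vectors) / sqrt(ev$values))
  ord <- order(z, seq_along(z))
  cums <- apply(sc[ord, , drop = FALSE], 2L, cumsum)
  csp <- rbind(0, cums %*% Bis / sqrt(n))
  colnames(csp) <- colnames(sc)
  structure(list(csp = csp, t = (0:n) / n, z = z[ord], type = type,
                 B = B, n = n, q = q), class = "ofa_csp")
}

#' @export
print.ofa_csp <- function(x, ...) {
  cat("Cumulative score process: n = ", x$n, ", ", x$q, " parameters, ",
      x$type, " covariate\n", sep = "")
  invisible(x)
}

#' Plot a cumulative score process
#'
#' One line per decorrelated parameter process against the ordering
#' fraction `H/n`; under parameter stability each is approximately a
#' Brownian bridge, and DIF along the covariate shows as a systematic peak.
#'
#' @param object An `ofa_csp`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ofa_csp
#' @export
autoplot.ofa_csp <- function(object, ...) {
  df <- tibble::as_tibble(object$csp, .name_repair = "minimal")
  df$t <- object$t
  long <- tidyr::pivot_longer(df, -"t", names_to = "parameter",
                              values_to = "csp")
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$csp,
                                     group = .data$parameter,
                                     colour = .data$parameter)) +
    ggplot2::geom_line(show.legend = object$q <= 12) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "ordering fraction H/n",
                  y = "decorrelated cumulative score") +
    ggplot2::theme_minimal()
}

# ---- ordinal/categorical block boundaries ----------------------------------

.block_info <- function(proc) {
  lev <- unique(proc$z)          # sorted order already
  cnt <- as.numeric(table(factor(proc$z, levels = lev)))
  ends <- cumsum(cnt)            # H index at the end of each block
  list(levels = lev, counts = cnt, ends = ends,
       t = ends / proc$n)
}

# ---- statistics -------------------------------------------------------------

.stat_DM <- function(proc) max(abs(proc$csp))

.stat_CvM <- function(proc) {
  sum(rowSums(proc$csp[-1L, , drop = FALSE]^2)) / proc$n
}

.stat_maxLM <- function(proc, trim = 0.1) {
  n <- proc$n
  H <- seq(ceiling(trim * n), floor((1 - trim) * n))
  H <- H[H >= 1 & H <= n - 1]
  tt <- H / n
  ss <- rowSums(proc$csp[H + 1L, , drop = FALSE]^2)
  max(ss / (tt * (1 - tt)))
}

.stat_LMuo <- function(proc) {
  bi <- .block_info(proc)
  C <- length(bi$levels)
  if (C < 2) stop("categorical covariate needs >= 2 observed levels")
  starts <- c(0, bi$ends[-C])
  inc <- proc$csp[bi$ends + 1L, , drop = FALSE] -
    proc$csp[starts + 1L, , drop = FALSE]
  sum((proc$n / bi$counts) * rowSums(inc^2))
}

.stat_WDMo <- function(proc) {
  bi <- .block_info(proc)
  C <- length(bi$levels)
  if (C < 2) stop("ordinal covariate needs >= 2 observed levels")
  tc <- bi$t[-C]
  rows <- bi$ends[-C] + 1L
  mx <- apply(abs(proc$csp[rows, , drop = FALSE]), 1L, max)
  max(mx / sqrt(tc * (1 - tc)))
}

.stat_maxLMo <- function(proc) {
  bi <- .block_info(proc)
  C <- length(bi$levels)
  if (C < 2) stop("ordinal covariate needs >= 2 observed levels")
  tc <- bi$t[-C]
  rows <- bi$ends[-C] + 1L
  ss <- rowSums(proc$csp[rows, , drop = FALSE]^2)
  max(ss / (tc * (1 - tc)))
}

# ---- null distributions -----------------------------------------------------

# P(sup_t |B(t)| <= c) for a scalar Brownian bridge, alternating series
.kolmogorov_cdf <- function(c) {
  if (c <= 0) return(0)
  i <- seq_len(100)
  max(0, min(1, 1 + 2 * sum((-1)^i * exp(-2 * i^2 * c^2))))
}

.crit_cache <- new.env(parent = emptyenv())

.with_preserved_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# joint null sample of (CvM, maxLM) functionals of q independent bridges
.bridge_path_null <- function(q, nsteps, nrep, trim, seed) {
  key <- paste("path", q, nsteps, nrep, round(trim, 4), seed, sep = "_")
  hit <- get0(key, envir = .crit_cache)
  if (!is.null(hit)) return(hit)
  res <- .with_preserved_rng({
    set.seed(seed)
    tt <- seq_len(nsteps) / nsteps
    keep <- tt >= trim & tt <= 1 - trim & tt < 1
    denom <- (tt * (1 - tt))[keep]
    cvm <- numeric(nrep)
    mlm <- numeric(nrep)
    idx_end <- seq_len(q) * nsteps
    for (r in seq_len(nrep)) {
      e <- rnorm(nsteps * q)
      cs <- cumsum(e)                 # blockwise cumsum via offsets
      if (q > 1L) {
        offs <- c(0, cs[idx_end[-q]])
        cs <- cs - rep(offs, each = nsteps)
      }
      Wm <- matrix(cs / sqrt(nsteps), nsteps, q)
      Bm <- Wm - tcrossprod(tt, Wm[nsteps, ])
      ss <- rowSums(Bm^2)
      cvm[r] <- mean(ss)
      mlm[r] <- max(ss[keep] / denom)
    }
    list(cvm = sort(cvm), maxlm = sort(mlm))
  })
  assign(key, res, envir = .crit_cache)
  res
}

# null sample of the ordered maxLM functional at given bridge time points
.bridge_boundary_null <- function(q, tc, nrep, seed) {
  key <- paste("bnd", q, paste(round(tc, 3), collapse = "-"), nrep, seed,
               sep = "_")
  hit <- get0(key, envir = .crit_cache)
  if (!is.null(hit)) return(hit)
  res <- .with_preserved_rng({
    set.seed(seed)
    C1 <- length(tc)
    Sig <- outer(tc, tc, pmin) - outer(tc, tc)
    L <- chol(Sig + diag(1e-12, C1))
    Z <- matrix(rnorm(nrep * q * C1), nrep * q, C1) %*% L
    grp <- rep(seq_len(nrep), each = q)
    SS <- rowsum(Z^2, grp)            # nrep x C1 sums over parameters
    stat <- apply(sweep(SS, 2L, tc * (1 - tc), "/"), 1L, max)
    sort(stat)
  })
  assign(key, res, envir = .crit_cache)
  res
}

.sim_pvalue <- function(null_sorted, stat) {
  mean(null_sorted >= stat - 1e-12)
}

#' Simulate null critical values for bridge-based statistics
#'
#' Monte-Carlo null distribution of a fluctuation statistic computed on `q`
#' independent discretized Brownian bridges; used internally for the CvM,
#' maxLM and maxLMo p-values (with cached tables) and exported for
#' inspection.
#'
#' @param kind One of `"CvM"`, `"maxLM"`, `"maxLMo"`.
#' @param n_params Number of decorrelated parameter processes `q`.
#' @param boundaries_or_trim For `maxLM`, the trimming fraction (default
#'   0.1); for `maxLMo`, the vector of interior boundary fractions `t_c`.
#' @param n_reps Monte-Carlo replications.
#' @param seed RNG seed (table is reproducible by seed).
#' @param nsteps Bridge discretization for path functionals.
#' @return Tibble with columns `prob` and `critical_value` for the usual
#'   quantiles, with the full sorted null sample as attribute `"null"`.
#' @export
simulate_critical_values <- function(kind = c("CvM", "maxLM", "maxLMo"),
                                     n_params, boundaries_or_trim = 0.1,
                                     n_reps = 5000, seed = 1,
                                     nsteps = 1000) {
  kind <- match.arg(kind)
  null <- switch(kind,
    CvM = .bridge_path_null(n_params, nsteps, n_reps,
                            trim = 0.1, seed = seed)$cvm,
    maxLM = .bridge_path_null(n_params, nsteps, n_reps,
                              trim = boundaries_or_trim, seed = seed)$maxlm,
    maxLMo = .bridge_boundary_null(n_params, boundaries_or_trim,
                                   n_reps, seed = seed))
  probs <- c(0.9, 0.95, 0.99)
  out <- tibble::tibble(prob = probs,
                        critical_value = stats::quantile(null, probs,
                                                         names = FALSE))
  attr(out, "null") <- null
  out
}

#' Score-based parameter instability statistic with p-value
#'
#' Computes one of the six fluctuation statistics from a cumulative score
#' process and its p-value. Statistic/covariate pairing: DM, CvM and maxLM
#' require a metric covariate ordering; WDMo and maxLMo an ordinal one;
#' LMuo a categorical one.
#'
#' @param proc An `ofa_csp` from [score_process()].
#' @param kind `"DM"`, `"CvM"`, `"maxLM"`, `"LMuo"`, `"WDMo"` or
#'   `"maxLMo"`.
#' @param trim Trimming fraction for maxLM (interior window
#'   `H/n` in `[trim, 1 - trim]`).
#' @param crit_reps,crit_nsteps Monte-Carlo size and bridge discretization
#'   for simulated p-values (cached per configuration).
#' @return One-row tibble: `statistic`, `value`, `p_value`, `method`,
#'   `n_params`.
#' @export
test_statistic <- function(proc, kind = c("DM", "CvM", "maxLM", "LMuo",
                                          "WDMo", "maxLMo"),
                           trim = 0.1, crit_reps = 5000,
                           crit_nsteps = 1000) {
  kind <- match.arg(kind)
  ok <- switch(kind, DM = , CvM = , maxLM = "metric",
               WDMo = , maxLMo = "ordinal", LMuo = "categorical")
  if (proc$type != ok)
    stop(kind, " requires a ", ok, " covariate (process has ", proc$type, ")")
  q <- proc$q
  if (kind == "DM") {
    stat <- .stat_DM(proc)
    pv <- 1 - .kolmogorov_cdf(stat)^q
    method <- "closed_form"
  } else if (kind == "CvM") {
    stat <- .stat_CvM(proc)
    null <- .bridge_path_null(q, crit_nsteps, crit_reps, trim = 0.1,
                              seed = 42000 + q)$cvm
    pv <- .sim_pvalue(null, stat)
    method <- "simulated"
  } else if (kind == "maxLM") {
    stat <- .stat_maxLM(proc, trim = trim)
    null <- .bridge_path_null(q, crit_nsteps, crit_reps, trim = trim,
                              seed = 42000 + q)$maxlm
    pv <- .sim_pvalue(null, stat)
    method <- "simulated"
  } else if (kind == "LMuo") {
    stat <- .stat_LMuo(proc)
    C <- length(unique(proc$z))
    pv <- stats::pchisq(stat, df = q * (C - 1), lower.tail = FALSE)
    method <- "chi2"
  } else if (kind == "WDMo") {
    stat <- .stat_WDMo(proc)
    bi <- .block_info(proc)
    tc <- bi$t[-length(bi$t)]
    if (stat <= 0) {
      pv <- 1
    } else {
      Sig <- outer(tc, tc, pmin) - outer(tc, tc)
      lim <- stat * sqrt(tc * (1 - tc))
      pr1 <- mvtnorm::pmvnorm(lower = -lim, upper = lim,
                              sigma = Sig + diag(1e-12, length(tc)))
      pv <- min(1, max(0, 1 - as.numeric(pr1)^q))
    }
    method <- "closed_form"
  } else {
    stat <- .stat_maxLMo(proc)
    bi <- .block_info(proc)
    # null table at boundaries snapped to a 0.05 grid so it can be cached
    # and reused across data sets with near-identical level proportions
    tc <- unique(pmin(pmax(round(bi$t[-length(bi$t)] * 20) / 20, 0.025),
                      0.975))
    null <- .bridge_boundary_null(q, tc, max(crit_reps, 20000),
                                  seed = 43000 + q)
    pv <- .sim_pvalue(null, stat)
    method <- "simulated"
  }
  tibble::tibble(statistic = kind, value = stat, p_value = pv,
                 method = method, n_params = q)
}

#' Score-based DIF tests for a fitted ordinal factor model
#'
#' End-to-end convenience: computes approximated scores, builds the
#' cumulative score process along a covariate, and applies the fluctuation
#' statistics matched to the covariate scale.
#'
#' @param fit An [fit_ofa()] result.
#' @param z Covariate vector (length `n`).
#' @param type Covariate scale; defaults for `stats` depend on it: metric
#'   uses DM, CvM and maxLM; ordinal uses WDMo and maxLMo; categorical uses
#'   LMuo.
#' @param stats Character vector of statistics to compute (must be
#'   compatible with `type`).
#' @param scores Optional precomputed [approx_scores()] matrix.
#' @param covariate Covariate name recorded in the output.
#' @param ... Passed to [test_statistic()].
#' @return Tibble with one row per statistic: `covariate`, `type`,
#'   `statistic`, `value`, `p_value`, `method`, `n_params`.
#' @examples
#' spec <- grm_spec(list(F1 = paste0("y", 1:5)), n_cat = 3)
#' dat <- simulate_grm(spec, grm_params(spec, seed = 1), n = 400, seed = 2)
#' fit <- fit_ofa(dat, spec)
#' dif_test(fit, z = rnorm(400), type = "metric", stats = "DM")
#' @export
dif_test <- function(fit, z, type = c("metric", "ordinal", "categorical"),
                     stats = NULL, scores = NULL,
                     covariate = deparse(substitute(z)), ...) {
  type <- match.arg(type)
  if (is.null(stats))
    stats <- switch(type, metric = c("DM", "CvM", "maxLM"),
                    ordinal = c("WDMo", "maxLMo"), categorical = "LMuo")
  if (is.null(scores)) scores <- approx_scores(fit)
  proc <- score_process(scores, z, type = type)
  out <- purrr::map_dfr(stats, function(k) test_statistic(proc, k, ...))
  dplyr::bind_cols(tibble::tibble(covariate = covariate, type = type,
                                  .rows = nrow(out)), out)
}
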