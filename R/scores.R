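# Approximated per-person score contributions for a WLS-fitted ordinal
# factor model. The casewise WLS objective has no closed-form score; the
# approximation transports the GEE estimating-function logic to the WLS
# moment structure: row i is
#   Delta' W^{-1} [ (indicators_i - mean indicators) ; (s_i - s_bar) ]
# with the category-exceedance indicators in the threshold block and the raw
# observed-category cross products in the correlation block. Columns sum to
# zero by construction, the empirical M-estimator identity.

#' Category-exceedance indicator block for one response row
#'
#' Stacked indicators `1{y_ij > k}` for `j = 1..p`, `k = 1..l_j - 1`, in the
#' order of the threshold block of the saturated moment vector.
#'
#' @param y_i Integer response vector of one person.
#' @param n_cat Categories per item.
#' @return 0/1 vector of length `sum(n_cat - 1)`.
#' @export
indicator_block <- function(y_i, n_cat) {
  if (any(y_i < 1 | y_i > n_cat)) stop("invalid response category")
  unlist(lapply(seq_along(y_i), function(j) {
    as.numeric(y_i[j] > seq_len(n_cat[j] - 1L))
  }), use.names = FALSE)
}

#' Pairwise cross-product block for one response row
#'
#' `s_i` of the approximated score function: products of mean-centred raw
#' observed categories for pairs `(j, s)`, `j < s`, in the same lexicographic
#' order as the polychoric correlations.
#'
#' @param y_i Integer response vector of one person.
#' @param y_bar Per-item arithmetic means of the observed categories.
#' @return Numeric vector of length `p(p-1)/2`.
#' @export
crossproduct_block <- function(y_i, y_bar) {
  if (length(y_i) != length(y_bar)) stop("y_i and y_bar lengths differ")
  d <- y_i - y_bar
  pr <- .pairs_js(length(y_i))
  d[pr[, 1]] * d[pr[, 2]]
}

#' Approximated score matrix of a WLS ordinal factor fit
#'
#' @param fit An [fit_ofa()] result (the fitted data travels with it).
#' @param data Optional replacement response data (columns as in the spec);
#'   defaults to the data the model was fitted to.
#' @return An `n x |theta|` matrix of class `ofa_scores` with parameter
#'   names as columns; every column sums to zero (up to float accumulation).
#' @examples
#' spec <- grm_spec(list(F1 = paste0("y", 1:5)), n_cat = 3)
#' dat <- simulate_grm(spec, grm_params(spec, seed = 1), n = 300, seed = 2)
#' fit <- fit_ofa(dat, spec)
#' colSums(approx_scores(fit))   # ~ 0
#' @export
approx_scores <- function(fit, data = NULL) {
  spec <- fit$spec
  Y <- if (is.null(data)) fit$Y else {
    m <- as.matrix(as.data.frame(data)[, spec$items, drop = FALSE])
    storage.mode(m) <- "integer"
    m
  }
  n <- nrow(Y)
  n_cat <- spec$n_cat
  # indicator block, vectorized over persons: column (j,k) is 1{Y[,j] > k}
  ind <- matrix(0, n, sum(n_cat - 1L))
  col0 <- 0L
  for (j in seq_len(spec$p)) {
    for (k in seq_len(n_cat[j] - 1L)) {
      ind[, col0 + k] <- as.numeric(Y[, j] > k)
    }
    col0 <- col0 + n_cat[j] - 1L
  }
  y_bar <- colMeans(Y)
  Yc <- sweep(Y, 2L, y_bar)
  pr <- .pairs_js(spec$p)
  s_mat <- Yc[, pr[, 1], drop = FALSE] * Yc[, pr[, 2], drop = FALSE]
  dev <- cbind(sweep(ind, 2L, colMeans(ind)),
               sweep(s_mat, 2L, colMeans(s_mat)))
  D <- delta_matrix(spec, fit$theta)
  W <- fit$moments$W
  if (ncol(dev) != nrow(W) || nrow(D) != nrow(W))
    stop("dimension mismatch: deviations ", ncol(dev), ", W ", nrow(W),
         " x ", ncol(W), ", Delta ", nrow(D), " x ", ncol(D))
  sc <- dev %*% solve(W, D)
  colnames(sc) <- colnames(D)
  rownames(sc) <- rownames(Y)
  class(sc) <- c("ofa_scores", class(sc))
  sc
}

#' @export
print.ofa_scores <- function(x, ...) {
  cat("Approximated score matrix: ", nrow(x), " persons x ", ncol(x),
      " parameters\n", sep = "")
  cat("max |column sum| =", format(max(abs(colSums(x))), digits = 3), "\n")
  invisible(x)
}

#' Write scores to CSV
#'
#' @param scores An `ofa_scores` matrix.
#' @param path Output path.
#' @param id Optional row-identifier vector (kept as first column).
#' @return The path, invisibly.
#' @export
write_scores_csv <- function(scores, path, id = NULL) {
  df <- as.data.frame(unclass(scores))
  if (!is.null(id)) df <- cbind(id = id, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
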