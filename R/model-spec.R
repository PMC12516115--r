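#' Specify an ordinal factor model (multidimensional graded response model)
#'
#' Builds the model skeleton used throughout the package: which items load on
#' which factors, how many ordered categories each item has, and which
#' loadings and latent (co)variances are fixed versus free. The model follows
#' the delta parameterization: each latent response variable has total
#' variance 1, so free loadings live in the unit ball and the model-implied
#' item-pair moments are correlations.
#'
#' Identification follows the usual convention: per factor, either the latent
#' variance is fixed to 1 and all loadings are free (`std_lv = TRUE`, the
#' default), or the first loading is fixed to 1 and the variance is free.
#'
#' @param factors Named list mapping factor names to character vectors of
#'   item names, e.g. `list(F1 = c("y1","y2","y3"))`. Items may appear under
#'   several factors (within-item multidimensionality).
#' @param n_cat Number of ordered response categories per item; scalar
#'   (recycled) or named/unnamed vector of length `p`. All `n_cat >= 2`.
#' @param std_lv If `TRUE`, latent variances are fixed to 1 and loadings are
#'   free; if `FALSE`, the first loading per factor is fixed to 1 and the
#'   latent variance is free.
#' @param fixed_loadings Optional list of `list(factor=, item=, value=)`
#'   entries fixing individual loadings.
#' @param psi_fixed Optional list of `list(f1=, f2=, value=)` entries fixing
#'   latent covariances (off-diagonal); by default all covariances between
#'   factors are freely estimated.
#' @return An object of class `grm_spec`.
#' @examples
#' spec <- grm_spec(list(F1 = paste0("y", 1:5)), n_cat = 3)
#' spec$param_table
#' @export
grm_spec <- function(factors, n_cat, std_lv = TRUE, fixed_loadings = NULL,
                     psi_fixed = NULL) {
  stopifnot(is.list(factors), length(factors) >= 1, !is.null(names(factors)))
  fnames <- names(factors)
  items <- unique(unlist(factors, use.names = FALSE))
  p <- length(items)
  m <- length(fnames)
  if (length(n_cat) == 1L) n_cat <- rep(n_cat, p)
  if (!is.null(names(n_cat))) n_cat <- n_cat[items]
  n_cat <- as.integer(n_cat)
  stopifnot(length(n_cat) == p)
  if (any(n_cat < 2L)) stop("every item needs at least 2 categories")
  names(n_cat) <- items

  # loading pattern: NA = free, 0 = item not on factor, other = fixed value
  lambda_pat <- matrix(0, m, p, dimnames = list(fnames, items))
  for (q in fnames) lambda_pat[q, factors[[q]]] <- NA_real_
  for (fx in fixed_loadings %||% list()) {
    lambda_pat[fx$factor, fx$item] <- fx$value
  }

  psi_pat <- matrix(NA_real_, m, m, dimnames = list(fnames, fnames))
  diag(psi_pat) <- if (std_lv) 1 else NA_real_
  if (!std_lv) {
    for (q in seq_len(m)) {
      first <- which(lambda_pat[q, ] != 0 | is.na(lambda_pat[q, ]))[1]
      if (is.na(lambda_pat[q, first])) lambda_pat[q, first] <- 1
    }
  }
  for (fx in psi_fixed %||% list()) {
    psi_pat[fx$f1, fx$f2] <- psi_pat[fx$f2, fx$f1] <- fx$value
  }

  spec <- structure(
    list(items = items, factors = fnames, p = p, m = m, n_cat = n_cat,
         lambda_pat = lambda_pat, psi_pat = psi_pat),
    class = "grm_spec")
  .check_identification(spec)
  spec$param_table <- .build_param_table(spec)
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_identification <- function(spec) {
  lp <- spec$lambda_pat
  loads <- is.na(lp) | lp != 0
  if (any(colSums(loads) == 0))
    stop("item(s) ", paste(spec$items[colSums(loads) == 0], collapse = ", "),
         " load on no factor")
  for (q in seq_len(spec$m)) {
    var_free <- is.na(spec$psi_pat[q, q])
    first <- which(loads[q, ])[1]
    first_fixed <- !is.na(lp[q, first])
    if (var_free && !first_fixed)
      stop("factor ", spec$factors[q], " unidentified: fix Var(",
           spec$factors[q], ") to 1 or fix its first loading")
    if (!var_free && first_fixed && all(!is.na(lp[q, loads[q, ]])))
      warning("factor ", spec$factors[q],
              " has no free loadings and fixed variance")
  }
  invisible(TRUE)
}

# Frozen free-parameter ordering: thresholds (item-major, category-minor),
# loadings (factor-major, item order within factor), latent variances,
# latent covariances (pairs (q,r), q < r, lexicographic). Score columns and
# Jacobian columns use this exact ordering.
.build_param_table <- function(spec) {
  rows <- list()
  for (j in seq_len(spec$p)) {
    it <- spec$items[j]
    for (k in seq_len(spec$n_cat[j] - 1L)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        name = paste0(it, "|t", k), block = "threshold", item = it,
        cat = k, factor = NA_character_, factor2 = NA_character_,
        free = TRUE, fixed_value = NA_real_)
    }
  }
  for (q in seq_len(spec$m)) {
    fq <- spec$factors[q]
    for (j in seq_len(spec$p)) {
      v <- spec$lambda_pat[q, j]
      if (!is.na(v) && v == 0) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        name = paste0(fq, "=~", spec$items[j]), block = "loading",
        item = spec$items[j], cat = NA_integer_, factor = fq,
        factor2 = NA_character_, free = is.na(v), fixed_value = v)
    }
  }
  for (q in seq_len(spec$m)) {
    fq <- spec$factors[q]
    v <- spec$psi_pat[q, q]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      name = paste0(fq, "~~", fq), block = "lat_var", item = NA_character_,
      cat = NA_integer_, factor = fq, factor2 = fq, free = is.na(v),
      fixed_value = v)
  }
  if (spec$m > 1L) {
    for (q in seq_len(spec$m - 1L)) {
      for (r in seq(q + 1L, spec$m)) {
        v <- spec$psi_pat[q, r]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          name = paste0(spec$factors[q], "~~", spec$factors[r]),
          block = "lat_cov", item = NA_character_, cat = NA_integer_,
          factor = spec$factors[q], factor2 = spec$factors[r],
          free = is.na(v), fixed_value = v)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
print.grm_spec <- function(x, ...) {
  cat("Ordinal factor model: ", x$p, " items, ", x$m, " factor(s), ",
      sum(x$param_table$free), " free parameters\n", sep = "")
  cat("categories per item:", paste(x$n_cat, collapse = " "), "\n")
  invisible(x)
}

#' Names of the free parameters, in the frozen estimation order
#' @param spec A `grm_spec`.
#' @return Character vector of length `|theta|`.
#' @export
theta_names <- function(spec) {
  spec$param_table$name[spec$param_table$free]
}

#' Assemble a free-parameter vector from matrices
#'
#' Packs thresholds, a loading matrix and a latent covariance matrix into the
#' named free-parameter vector `theta` (the inverse of
#' [theta_to_matrices()]).
#'
#' @param spec A `grm_spec`.
#' @param tau List (or single vector) of ascending thresholds per item.
#' @param lambda `m x p` loading matrix (rows = factors).
#' @param psi `m x m` latent covariance matrix.
#' @return Named numeric vector in the frozen ordering.
#' @export
make_theta <- function(spec, tau, lambda, psi = NULL) {
  if (!is.list(tau)) tau <- list(tau)
  lambda <- rbind(lambda)
  if (is.null(psi)) psi <- diag(spec$m)
  psi <- as.matrix(psi)
  pt <- spec$param_table
  th <- numeric(sum(pt$free))
  names(th) <- pt$name[pt$free]
  idx <- 0L
  for (r in which(pt$free)) {
    idx <- idx + 1L
    row <- pt[r, ]
    th[idx] <- switch(row$block,
      threshold = tau[[match(row$item, spec$items)]][row$cat],
      loading = lambda[match(row$factor, spec$factors),
                       match(row$item, spec$items)],
      lat_var = psi[match(row$factor, spec$factors),
                    match(row$factor, spec$factors)],
      lat_cov = psi[match(row$factor, spec$factors),
                    match(row$factor2, spec$factors)])
  }
  th
}

#' Unpack a free-parameter vector into model matrices
#'
#' @param spec A `grm_spec`.
#' @param theta Numeric vector of free parameters in the frozen order.
#' @param validate If `TRUE`, check threshold monotonicity and positive
#'   definiteness of the latent covariance matrix.
#' @return List with `tau` (list of per-item threshold vectors), `Lambda`
#'   (`m x p`), `Psi` (`m x m`).
#' @export
theta_to_matrices <- function(spec, theta, validate = TRUE) {
  pt <- spec$param_table
  if (length(theta) != sum(pt$free))
    stop("theta has length ", length(theta), ", expected ", sum(pt$free))
  full <- pt$fixed_value
  full[pt$free] <- theta
  tau <- lapply(seq_len(spec$p), function(j) {
    v <- full[pt$block == "threshold" & pt$item == spec$items[j]]
    names(v) <- NULL
    v
  })
  names(tau) <- spec$items
  Lambda <- matrix(0, spec$m, spec$p,
                   dimnames = list(spec$factors, spec$items))
  lrows <- which(pt$block == "loading")
  for (r in lrows) {
    Lambda[pt$factor[r], pt$item[r]] <- full[r]
  }
  Psi <- matrix(0, spec$m, spec$m,
                dimnames = list(spec$factors, spec$factors))
  for (r in which(pt$block == "lat_var")) {
    Psi[pt$factor[r], pt$factor[r]] <- full[r]
  }
  for (r in which(pt$block == "lat_cov")) {
    Psi[pt$factor[r], pt$factor2[r]] <-
      Psi[pt$factor2[r], pt$factor[r]] <- full[r]
  }
  if (validate) {
    for (j in seq_len(spec$p)) {
      if (length(tau[[j]]) > 1 && any(diff(tau[[j]]) <= 0))
        stop("thresholds of item ", spec$items[j], " not ascending")
    }
    ev <- eigen(Psi, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("latent covariance matrix Psi not positive definite")
  }
  list(tau = tau, Lambda = Lambda, Psi = Psi)
}

#' Parse a compact model-syntax string
#'
#' Accepts a small lavaan-style syntax: `F1 =~ y1 + y2 + 0.7*y3` declares
#' loadings (a numeric premultiplier fixes a loading), `F1 ~~ F2` frees a
#' latent covariance and `F1 ~~ 0.5*F2` fixes it, `F1 ~~ 1*F1` fixes a latent
#' variance (freeing the variance with `F1 ~~ F1` switches that factor to
#' first-loading identification), and `y1 | t1 + t2` declares the number of
#' thresholds (i.e. categories minus one) for an item.
#'
#' @param text Model syntax (single string, lines separated by newlines or
#'   semicolons).
#' @param n_cat Default category count for items without a `|` line.
#' @return A `grm_spec`.
#' @examples
#' parse_model_syntax("F1 =~ y1 + y2 + y3\ny1 | t1 + t2", n_cat = 3)
#' @export
parse_model_syntax <- function(text, n_cat = NULL) {
  lines <- unlist(strsplit(text, "[\n;]"))
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  factors <- list()
  fixed_loadings <- list()
  psi_fixed <- list()
  var_free <- character()
  ncat_map <- integer()
  for (ln in lines) {
    if (grepl("=~", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "=~", fixed = TRUE)[[1]]
      f <- trimws(parts[1])
      terms <- trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
      for (tm in terms) {
        if (grepl("*", tm, fixed = TRUE)) {
          bits <- trimws(strsplit(tm, "*", fixed = TRUE)[[1]])
          it <- bits[2]
          factors[[f]] <- union(factors[[f]], it)
          fixed_loadings[[length(fixed_loadings) + 1L]] <-
            list(factor = f, item = it, value = as.numeric(bits[1]))
        } else {
          factors[[f]] <- union(factors[[f]], tm)
        }
      }
    } else if (grepl("~~", ln, fixed = TRUE)) {
      parts <- trimws(strsplit(ln, "~~", fixed = TRUE)[[1]])
      rhs <- parts[2]
      if (grepl("*", rhs, fixed = TRUE)) {
        bits <- trimws(strsplit(rhs, "*", fixed = TRUE)[[1]])
        psi_fixed[[length(psi_fixed) + 1L]] <-
          list(f1 = parts[1], f2 = bits[2], value = as.numeric(bits[1]))
      } else if (parts[1] == rhs) {
        var_free <- c(var_free, parts[1])
      } else {
        # free covariance: the default; nothing to record
      }
    } else if (grepl("|", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "|", fixed = TRUE)[[1]]
      it <- trimws(parts[1])
      kk <- length(trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]]))
      ncat_map[it] <- kk + 1L
    } else stop("cannot parse model line: ", ln)
  }
  items <- unique(unlist(factors, use.names = FALSE))
  nc <- rep(n_cat %||% 2L, length(items))
  names(nc) <- items
  nc[names(ncat_map)] <- ncat_map
  if (is.null(n_cat) && length(ncat_map) == 0)
    stop("supply n_cat or '|' threshold lines")
  spec <- grm_spec(factors, n_cat = nc, std_lv = TRUE,
                   fixed_loadings = fixed_loadings, psi_fixed = psi_fixed)
  if (length(var_free)) {
    # switch the named factors to first-loading identification
    spec <- grm_spec(factors, n_cat = nc, std_lv = FALSE,
                     fixed_loadings = fixed_loadings, psi_fixed = psi_fixed)
  }
  spec
}

#' Read a model specification from JSON
#'
#' JSON layout: `{"factors": {"F1": ["y1","y2"]}, "n_cat": 3,
#' "std_lv": true, "fixed_loadings": [{"factor":"F1","item":"y1","value":1}],
#' "psi_fixed": [{"f1":"F1","f2":"F2","value":0.5}]}`.
#'
#' @param path Path to a JSON file (or a JSON string).
#' @return A `grm_spec`.
#' @export
spec_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  grm_spec(factors = x$factors,
           n_cat = unlist(x$n_cat),
           std_lv = x$std_lv %||% TRUE,
           fixed_loadings = x$fixed_loadings,
           psi_fixed = x$psi_fixed)
}
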