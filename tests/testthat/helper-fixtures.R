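# shared fixtures: small specs and a deterministic admissible theta

spec_uni <- function(p = 5, l = 3) {
  grm_spec(stats::setNames(list(paste0("y", seq_len(p))), "F1"), n_cat = l)
}

spec_multi <- function(l = 3) {
  grm_spec(list(F1 = paste0("y", 1:3), F2 = paste0("y", 4:6),
                F3 = paste0("y", 7:9)), n_cat = l)
}

# fixed, hand-chosen admissible parameters (no RNG)
theta_uni_fixed <- function(spec) {
  p <- spec$p
  tau <- lapply(seq_len(p), function(j) {
    lj <- spec$n_cat[j]
    stats::qnorm(seq_len(lj - 1) / lj) + 0.1 * j / p
  })
  lam <- matrix(seq(0.5, 0.8, length.out = p), 1, p)
  make_theta(spec, tau, lam, psi = 1)
}

theta_multi_fixed <- function(spec) {
  tau <- lapply(seq_len(9), function(j) {
    lj <- spec$n_cat[j]
    stats::qnorm(seq_len(lj - 1) / lj) - 0.05 + 0.01 * j
  })
  lam <- matrix(0, 3, 9)
  lam[1, 1:3] <- c(0.6, 0.7, 0.5)
  lam[2, 4:6] <- c(0.65, 0.55, 0.7)
  lam[3, 7:9] <- c(0.5, 0.6, 0.75)
  psi <- matrix(0.5, 3, 3)
  diag(psi) <- 1
  make_theta(spec, tau, lam, psi)
}

# random admissible theta for property loops (uses current RNG)
theta_random <- function(spec) {
  tau <- lapply(seq_len(spec$p), function(j) {
    lj <- spec$n_cat[j]
    sort(stats::qnorm(seq_len(lj - 1) / lj) + stats::runif(lj - 1, -.2, .2))
  })
  lam <- spec$lambda_pat
  lam[is.na(lam)] <- stats::runif(sum(is.na(lam)), 0.3, 0.8)
  m <- spec$m
  psi <- diag(m)
  if (m > 1) psi[psi == 0] <- stats::runif(1, 0.2, 0.6)
  make_theta(spec, tau, lam, psi)
}
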