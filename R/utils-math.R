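# Internal numerical helpers shared across modules.

#' @keywords internal
#' @noRd
sym <- function(m) (m + t(m)) / 2

# log-determinant of a symmetric positive-definite matrix via Cholesky;
# errors propagate to callers that implement their own jitter policies
logdet_spd <- function(m) {
  2 * sum(log(diag(chol(m))))
}

# Cholesky with a deterministic 1e-8 * mean(diag) jitter retry, per the
# distance-module policy; fails if the matrix is still not SPD afterwards.
chol_jitter <- function(m, label = "covariance") {
  out <- tryCatch(chol(sym(m)), error = function(e) NULL)
  if (is.null(out)) {
    eps <- 1e-8 * mean(diag(m))
    if (!is.finite(eps) || eps <= 0) eps <- 1e-8
    out <- tryCatch(chol(sym(m) + diag(eps, nrow(m))), error = function(e) NULL)
    if (is.null(out)) {
      stop(sprintf("%s is singular even after jitter", label), call. = FALSE)
    }
  }
  out
}

# inverse of an SPD matrix through its Cholesky factor
inv_spd <- function(m, label = "covariance") {
  chol2inv(chol_jitter(m, label))
}

# symmetric-matrix functional calculus: f applied to eigenvalues
spd_matfun <- function(m, f, floor = NULL) {
  e <- eigen(sym(m), symmetric = TRUE)
  vals <- e$values
  if (!is.null(floor)) vals <- pmax(vals, floor)
  sym(e$vectors %*% (f(vals) * t(e$vectors)))
}

spd_logm <- function(m) spd_matfun(m, log, floor = 1e-12)
spd_expm <- function(m) spd_matfun(m, exp)

# half-vectorization (lower triangle incl. diagonal)
vech <- function(m) m[lower.tri(m, diag = TRUE)]

# multivariate normal sampler (zero mean), chol-based so base R suffices
rmvn0 <- function(n, sigma) {
  r <- chol_jitter(sigma, "emission covariance")
  matrix(stats::rnorm(n * ncol(sigma)), n) %*% r
}

# multivariate log-gamma
lmgamma <- function(a, p) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

# KL( Wishart(nu1, V1) || Wishart(nu0, V0) ) for precision-scale matrices,
# parametrised by the *inverse* scales (what the fitter stores)
kl_wishart <- function(nu1, V1inv, nu0, V0inv) {
  J <- nrow(V1inv)
  ldV1inv <- logdet_spd(V1inv)
  ldV0inv <- logdet_spd(V0inv)
  elogdet <- sum(digamma((nu1 + 1 - seq_len(J)) / 2)) + J * log(2) - ldV1inv
  tr01 <- sum(V0inv * chol2inv(chol_jitter(V1inv, "Wishart scale")))
  # negated log-normalizers: -logB(V, nu) expressed through the stored V^-1
  nlogB0 <- (nu0 / 2) * ldV0inv - (nu0 * J / 2) * log(2) - lmgamma(nu0 / 2, J)
  nlogB1 <- (nu1 / 2) * ldV1inv - (nu1 * J / 2) * log(2) - lmgamma(nu1 / 2, J)
  (nu1 - nu0) / 2 * elogdet + nu1 / 2 * (tr01 - J) + nlogB1 - nlogB0
}

# KL( Gamma(a1, b1) || Gamma(a0, b0) ), shape/rate
kl_gamma <- function(a1, b1, a0, b0) {
  (a1 - a0) * digamma(a1) - lgamma(a1) + lgamma(a0) +
    a0 * (log(b1) - log(b0)) + a1 * (b0 - b1) / b1
}

# column variances with population (1/n) divisor
col_pop_var <- function(m) {
  mu <- colMeans(m)
  colMeans(m * m) - mu * mu
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
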