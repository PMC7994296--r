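# Subject-by-subject distance matrices: the common currency that lets very
# different representations (a full HMM, a single FC matrix, a structural
# feature vector) be compared on equal footing downstream.

#' Symmetric Kullback-Leibler divergence between Gaussians
#'
#' `0.5 * KL(G1 || G2) + 0.5 * KL(G2 || G1)` in closed form. For the
#' zero-mean case (FC matrices of standardized time series) only covariances
#' enter; means are supported for the amplitude-variant states.
#'
#' @param S1,S2 SPD covariance matrices of equal dimension.
#' @param m1,m2 Optional mean vectors (default zero).
#' @return A nonnegative number; zero iff the two distributions coincide.
#' @export
symmetric_kl_gaussian <- function(S1, S2, m1 = NULL, m2 = NULL) {
  S1 <- as.matrix(S1)
  S2 <- as.matrix(S2)
  J <- nrow(S1)
  if (!all(dim(S1) == dim(S2))) stopf("covariances must share dimensions")
  P1 <- inv_spd(S1, "first covariance")
  P2 <- inv_spd(S2, "second covariance")
  # log-determinant terms cancel in the symmetrized sum
  d <- 0.25 * (sum(P2 * S1) + sum(P1 * S2) - 2 * J)
  if (!is.null(m1) || !is.null(m2)) {
    m1 <- m1 %||% rep(0, J)
    m2 <- m2 %||% rep(0, J)
    dm <- m1 - m2
    d <- d + 0.25 * (drop(dm %*% P2 %*% dm) + drop(dm %*% P1 %*% dm))
  }
  max(d, 0)
}

# directed Gaussian KL, used by the HMM divergence
kl_gaussian <- function(S1, S2, m1 = NULL, m2 = NULL) {
  J <- nrow(S1)
  P2 <- inv_spd(S2, "second covariance")
  d <- 0.5 * (sum(P2 * S1) - J + logdet_spd(S2) - logdet_spd(S1))
  if (!is.null(m1) || !is.null(m2)) {
    dm <- (m1 %||% rep(0, J)) - (m2 %||% rep(0, J))
    d <- d + 0.5 * drop(dm %*% P2 %*% dm)
  }
  max(d, 0)
}

#' Kullback-Leibler divergence between Dirichlet distributions
#'
#' Standard closed form via log-gamma and digamma functions. Used on the
#' posterior transition pseudo-counts of each transition-matrix row.
#'
#' @param a,b Positive parameter vectors of equal length.
#' @return `KL(Dir(a) || Dir(b))`, nonnegative, asymmetric in its arguments.
#' @export
kl_dirichlet <- function(a, b) {
  if (length(a) != length(b)) stopf("parameter vectors must have equal length")
  if (any(a <= 0) || any(b <= 0)) stopf("Dirichlet parameters must be positive")
  a0 <- sum(a)
  b0 <- sum(b)
  lgamma(a0) - sum(lgamma(a)) - lgamma(b0) + sum(lgamma(b)) +
    sum((a - b) * (digamma(a) - digamma(a0)))
}

#' Stationary distribution of a transition matrix
#'
#' The long-run state probabilities `nu` with `nu %*% P == nu`, computed from
#' the leading left eigenvector and verified against the power-iteration
#' limit of `pi %*% P^n`. For reducible or periodic chains (where that limit
#' depends on the start), falls back to `fallback` (typically the subject's
#' fractional occupancy) with a warning.
#'
#' @param P Row-stochastic `K x K` matrix.
#' @param pi Initial state probabilities (used for power-iteration
#'   validation and as the default fallback).
#' @param fallback Distribution to return for degenerate chains; defaults
#'   to `pi`.
#' @return A probability vector `nu` with `max|nu %*% P - nu| < 1e-10` on
#'   the regular path.
#' @export
stationary_weights <- function(P, pi = NULL, fallback = NULL) {
  P <- as.matrix(P)
  K <- nrow(P)
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8)) stopf("P must be row-stochastic")
  if (is.null(pi)) pi <- rep(1 / K, K)
  fallback <- fallback %||% pi
  if (K == 1L) return(1)
  e <- eigen(t(P))
  vals <- e$values
  i1 <- which.max(Re(vals))
  nu <- Re(e$vectors[, i1])
  nu <- nu / sum(nu)
  others <- Mod(vals[-i1])
  degenerate <- any(nu < -1e-8) || (length(others) && max(others) > 1 - 1e-8)
  if (!degenerate && max(abs(drop(nu %*% P) - nu)) < 1e-10) {
    # validate against the power-iteration limit from pi
    v <- pi
    ok <- FALSE
    for (i in seq_len(1e5)) {
      v2 <- drop(v %*% P)
      if (max(abs(v2 - v)) < 1e-12) {
        ok <- TRUE
        v <- v2
        break
      }
      v <- v2
    }
    if (ok && max(abs(v - nu)) < 1e-6) {
      return(pmax(nu, 0) / sum(pmax(nu, 0)))
    }
  }
  warnf("transition matrix is reducible or periodic; falling back to the supplied occupancy")
  fallback
}

#' Symmetric Kullback-Leibler divergence between two subject HMMs
#'
#' The HMM has no closed-form KL; the directed divergence is approximated as
#' a stationary-weighted sum of per-state terms,
#' `KL(M1 || M2) = sum_k nu_k (KL(P1_k, P2_k) + KL(G1_k, G2_k))`,
#' where `P_k` is the Dirichlet-distributed k-th transition-matrix row,
#' `G_k` the state Gaussian, and `nu` the stationary distribution of the
#' *first* argument's chain. The symmetric divergence averages the two
#' directions. States must be matched between models, which holds by
#' construction when both are dual-estimated from the same group model.
#'
#' @param M1,M2 Subject-level `fcdyn_hmm` models sharing `K`, `J`, variant.
#' @param dirichlet How to compare transition rows: `"posterior"` (KL of
#'   the Dirichlet posterior pseudo-counts, default) or `"point"`
#'   (categorical KL of the expected rows).
#' @return A nonnegative number, zero for identical models.
#' @export
symmetric_kl_hmm <- function(M1, M2, dirichlet = c("posterior", "point")) {
  dirichlet <- match.arg(dirichlet)
  if (M1$K != M2$K || M1$J != M2$J) stopf("models must share K and J")
  if (M1$variant != M2$variant) stopf("models must share the observation variant")
  0.5 * kl_hmm_directed(M1, M2, dirichlet) + 0.5 * kl_hmm_directed(M2, M1, dirichlet)
}

kl_hmm_directed <- function(M1, M2, dirichlet = "posterior") {
  K <- M1$K
  nu <- stationary_weights(M1$transition_matrix, M1$initial_probs,
    fallback = M1$w
  )
  total <- 0
  for (k in seq_len(K)) {
    klp <- if (K == 1L) {
      0
    } else if (dirichlet == "posterior") {
      kl_dirichlet(M1$transition_counts[k, ], M2$transition_counts[k, ])
    } else {
      p <- M1$transition_matrix[k, ]
      q <- M2$transition_matrix[k, ]
      sum(p * (log(pmax(p, 1e-300)) - log(pmax(q, 1e-300))))
    }
    klg <- switch(M1$variant,
      fc = kl_gaussian(M1$covariances[[k]], M2$covariances[[k]]),
      mean = kl_gaussian(M1$covariance, M2$covariance, M1$means[k, ], M2$means[k, ]),
      var = kl_gaussian(
        diag(M1$variances[, k], M1$J),
        diag(M2$variances[, k], M2$J)
      )
    )
    total <- total + nu[k] * (klp + klg)
  }
  total
}

#' Build a subject-by-subject distance matrix
#'
#' Reduces one representation per subject to an `N x N` dissimilarity
#' matrix: symmetric KL between dual-estimated HMMs (`"hmm"`), symmetric KL
#' between the zero-mean Gaussians defined by each subject's time-averaged
#' FC matrix (`"avfc"`; with standardized data this is a principled distance
#' between correlation matrices), or Euclidean distance between structural
#' feature rows (`"structural"`).
#'
#' @param representations For `"hmm"`, a list of subject-level `fcdyn_hmm`;
#'   for `"avfc"`, a list of `J x J` FC matrices; for `"structural"`, a
#'   numeric matrix with one row of component weights per subject.
#' @param modality One of `"hmm"`, `"avfc"`, `"structural"`.
#' @param subject_ids Subject identifiers; defaults to list/row names.
#' @param ... Passed on to the pairwise distance (e.g. `dirichlet` for
#'   `"hmm"`).
#' @return A `fcdyn_dm`: the distance matrix with `modality` and subject ids
#'   attached. Symmetric, zero diagonal, nonnegative.
#' @export
build_distance_matrix <- function(representations, modality = c("hmm", "avfc", "structural"),
                                  subject_ids = NULL, ...) {
  modality <- match.arg(modality)
  if (modality == "structural") {
    m <- as.matrix(representations)
    if (any(!is.finite(m))) stopf("structural features contain non-finite values")
    subject_ids <- subject_ids %||% rownames(m) %||% as.character(seq_len(nrow(m)))
    if (anyDuplicated(subject_ids)) stopf("duplicate subject ids")
    d <- as.matrix(stats::dist(m))
    dimnames(d) <- list(subject_ids, subject_ids)
    return(new_dm(d, modality))
  }
  n <- length(representations)
  subject_ids <- subject_ids %||% names(representations) %||% as.character(seq_len(n))
  if (anyDuplicated(subject_ids)) stopf("duplicate subject ids")
  pairfun <- if (modality == "hmm") {
    function(a, b) symmetric_kl_hmm(a, b, ...)
  } else {
    function(a, b) symmetric_kl_gaussian(a, b)
  }
  if (modality == "avfc") {
    # precompute inverses once: KL needs tr(S2^-1 S1) both ways
    invs <- lapply(representations, function(s) inv_spd(as.matrix(s), "FC matrix"))
    J <- nrow(as.matrix(representations[[1]]))
    pairfun <- function(i, j) {
      max(0.25 * (sum(invs[[j]] * representations[[i]]) +
        sum(invs[[i]] * representations[[j]]) - 2 * J), 0)
    }
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- pairfun(i, j)
      }
    }
  } else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- pairfun(representations[[i]], representations[[j]])
      }
    }
  }
  dimnames(d) <- list(subject_ids, subject_ids)
  new_dm(d, modality)
}

new_dm <- function(values, modality) {
  stopifnot(isTRUE(all.equal(values, t(values), tolerance = 1e-10)))
  values <- (values + t(values)) / 2
  diag(values) <- 0
  structure(values, modality = modality, class = c("fcdyn_dm", "matrix", "array"))
}

#' @export
print.fcdyn_dm <- function(x, ...) {
  cat(sprintf(
    "<fcdyn_dm> %s distance matrix: %d subjects, mean off-diagonal distance %.4g\n",
    attr(x, "modality"), nrow(x), mean(x[upper.tri(x)])
  ))
  invisible(x)
}

dm_subjects <- function(dm) rownames(dm)

#' Write / read a distance matrix as CSV
#'
#' CSV serialization keeps the subject ids as header row and first column.
#'
#' @param dm A `fcdyn_dm`.
#' @param path Output file.
#' @return `path` (write) or a `fcdyn_dm` (read).
#' @export
write_dm_csv <- function(dm, path) {
  df <- data.frame(subject_id = rownames(dm), unclass(dm), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dm_csv
#' @param modality Modality label to attach on read.
#' @export
read_dm_csv <- function(path, modality = "hmm") {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  new_dm(m, modality)
}
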