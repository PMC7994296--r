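# Shared fixtures, built in code and cached per test run.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# Two zero-mean states differing only in correlation sign (equal variances):
# visible to the fc variant, invisible to the var variant.
switch_states <- function(rho = 0.8) {
  list(
    matrix(c(1, rho, rho, 1), 2),
    matrix(c(1, -rho, -rho, 1), 2)
  )
}

# Markov-switching session with known state path
make_switching_session <- function(T = 2000, states = switch_states(),
                                   p_stay = 0.98, seed = 1,
                                   subject_id = "s1", session_id = 1) {
  set.seed(seed)
  K <- length(states)
  P <- matrix((1 - p_stay) / (K - 1), K, K)
  diag(P) <- p_stay
  z <- integer(T)
  z[1] <- sample.int(K, 1)
  for (t in 2:T) z[t] <- sample.int(K, 1, prob = P[z[t - 1], ])
  x <- matrix(rnorm(T * ncol(states[[1]])), T)
  chols <- lapply(states, chol)
  for (k in seq_len(K)) {
    idx <- which(z == k)
    x[idx, ] <- x[idx, , drop = FALSE] %*% chols[[k]]
  }
  list(session = standardize_session(x, subject_id, session_id), z = z)
}

# frame-wise decoding accuracy, maximized over state relabelings
decode_accuracy <- function(gamma, z) {
  K <- ncol(gamma)
  perms <- gtools_permutations(K)
  hat <- max.col(gamma)
  max(vapply(seq_len(nrow(perms)), function(i) {
    mean(perms[i, ][hat] == z)
  }, numeric(1)))
}

# all permutations of 1:K (K small), no external dependency
gtools_permutations <- function(K) {
  if (K == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(K - 1)
  out <- NULL
  for (pos in seq_len(K)) {
    out <- rbind(out, cbind(
      sub[, seq_len(pos - 1), drop = FALSE], K,
      sub[, seq(pos, K - 1)[seq_len(K - pos)], drop = FALSE]
    ))
  }
  out
}

# match states of a fitted model to reference covariances by total Frobenius
# distance over permutations; returns the best permutation
match_states <- function(fit_covs, ref_covs) {
  K <- length(ref_covs)
  perms <- gtools_permutations(K)
  costs <- vapply(seq_len(nrow(perms)), function(i) {
    sum(vapply(seq_len(K), function(k) {
      sum((fit_covs[[perms[i, k]]] - ref_covs[[k]])^2)
    }, numeric(1)))
  }, numeric(1))
  perms[which.min(costs), ]
}

# small cohort shared across tests (cheap: 12 subjects, short sessions)
small_cohort <- function() {
  cached("small_cohort", generate_cohort(cohort_spec(
    n_subjects = 12, K = 2, J = 4, T = 150, seed = 7,
    missing_rate = 0
  )))
}

# group fit on the small cohort, shared
small_group_fit <- function() {
  cached("small_group_fit", fit_group_hmm(
    small_cohort()$sessions,
    K = 2, variant = "fc", seed = 1, max_iter = 50
  ))
}

random_spd <- function(J, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(J * J), J)
  crossprod(A) / J + diag(0.5, J)
}
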