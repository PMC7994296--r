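test_that("symmetric Gaussian KL: identity, 1-D value, and block additivity", {
  S <- random_spd(4, seed = 1)
  expect_equal(symmetric_kl_gaussian(S, S), 0, tolerance = 1e-12)
  # 1-D variances (1, 2): log terms cancel, 0.25 * (1/2 + 2 - 2) = 0.125
  expect_equal(symmetric_kl_gaussian(matrix(1), matrix(2)), 0.125, tolerance = 1e-12)
  # additivity over independent blocks
  A1 <- random_spd(3, seed = 2)
  A2 <- random_spd(3, seed = 3)
  B1 <- random_spd(2, seed = 4)
  B2 <- random_spd(2, seed = 5)
  blockdiag <- function(a, b) {
    out <- matrix(0, nrow(a) + nrow(b), ncol(a) + ncol(b))
    out[seq_len(nrow(a)), seq_len(ncol(a))] <- a
    out[-seq_len(nrow(a)), -seq_len(ncol(a))] <- b
    out
  }
  expect_equal(
    symmetric_kl_gaussian(blockdiag(A1, B1), blockdiag(A2, B2)),
    symmetric_kl_gaussian(A1, A2) + symmetric_kl_gaussian(B1, B2),
    tolerance = 1e-10
  )
})

test_that("symmetric Gaussian KL agrees with a Monte-Carlo estimator", {
  set.seed(7)
  for (J in c(2, 5)) {
    S1 <- cov2cor(random_spd(J))
    S2 <- cov2cor(random_spd(J))
    n <- 2e5
    ldens <- function(X, S) {
      P <- solve(S)
      -J / 2 * log(2 * pi) - 0.5 * determinant(S)$modulus[1] -
        0.5 * rowSums((X %*% P) * X)
    }
    X1 <- matrix(rnorm(n * J), n) %*% chol(S1)
    X2 <- matrix(rnorm(n * J), n) %*% chol(S2)
    w1 <- ldens(X1, S1) - ldens(X1, S2)
    w2 <- ldens(X2, S2) - ldens(X2, S1)
    mc <- 0.5 * mean(w1) + 0.5 * mean(w2)
    se <- 0.5 * sqrt(var(w1) / n + var(w2) / n)
    expect_lt(
      abs(symmetric_kl_gaussian(S1, S2) - mc), 3 * se + 1e-8
    )
  }
})

test_that("Dirichlet KL: identity, closed-form value, and asymmetry", {
  expect_equal(kl_dirichlet(c(2, 3), c(2, 3)), 0, tolerance = 1e-12)
  # KL((1,1) || (2,2)) = -ln 6 + 2 = 0.20824...
  expect_equal(kl_dirichlet(c(1, 1), c(2, 2)), 2 - log(6), tolerance = 1e-10)
  expect_equal(kl_dirichlet(c(1, 1), c(2, 2)), 0.2082, tolerance = 1e-3)
  expect_false(isTRUE(all.equal(
    kl_dirichlet(c(1, 1), c(2, 2)), kl_dirichlet(c(2, 2), c(1, 1))
  )))
  expect_error(kl_dirichlet(c(1, -1), c(1, 1)), "positive")
})

test_that("stationary weights solve nu P = nu and fall back for reducible chains", {
  expect_equal(
    stationary_weights(matrix(c(.9, .1, .1, .9), 2, byrow = TRUE)),
    c(0.5, 0.5),
    tolerance = 1e-10
  )
  P <- matrix(c(.5, .5, .25, .75), 2, byrow = TRUE)
  nu <- stationary_weights(P)
  expect_equal(nu, c(1 / 3, 2 / 3), tolerance = 1e-10)
  expect_lt(max(abs(drop(nu %*% P) - nu)), 1e-10)
  expect_warning(
    out <- stationary_weights(diag(2), pi = c(.7, .3)),
    "reducible"
  )
  expect_equal(out, c(.7, .3))
})

test_that("HMM divergence: identity, one-state reduction, and term-by-term assembly", {
  cohort <- small_cohort()
  fit <- small_group_fit()
  duals <- dual_estimate_cohort(fit, cohort$sessions)
  M1 <- duals[[1]]
  M2 <- duals[[2]]
  expect_equal(symmetric_kl_hmm(M1, M1), 0, tolerance = 1e-10)

  # K = 1 reduces to the symmetric Gaussian KL of the single states
  fit1 <- fit_group_hmm(cohort$sessions, K = 1, variant = "fc", seed = 1, max_iter = 20)
  d1 <- dual_estimate_cohort(fit1, cohort$sessions)
  expect_equal(
    symmetric_kl_hmm(d1[[1]], d1[[2]]),
    symmetric_kl_gaussian(d1[[1]]$covariances[[1]], d1[[2]]$covariances[[1]]),
    tolerance = 1e-10
  )

  # models identical except one state's covariance, identical TPMs:
  # only that state's Gaussian term survives, weighted by its nu
  M2b <- M1
  M2b$covariances[[2]] <- M2$covariances[[2]]
  nu <- stationary_weights(M1$transition_matrix, M1$initial_probs)
  hand <- nu[2] * 0.5 * (
    fcdyn:::kl_gaussian(M1$covariances[[2]], M2b$covariances[[2]]) +
      fcdyn:::kl_gaussian(M2b$covariances[[2]], M1$covariances[[2]])
  )
  expect_equal(symmetric_kl_hmm(M1, M2b), hand, tolerance = 1e-10)

  # invariance to a common relabeling of states
  relabel <- function(M, p) {
    M$covariances <- M$covariances[p]
    M$transition_matrix <- M$transition_matrix[p, p]
    M$transition_counts <- M$transition_counts[p, p]
    M$initial_probs <- M$initial_probs[p]
    M$w <- M$w[p]
    M
  }
  p <- c(2, 1)
  expect_equal(
    symmetric_kl_hmm(M1, M2),
    symmetric_kl_hmm(relabel(M1, p), relabel(M2, p)),
    tolerance = 1e-10
  )
  expect_error(symmetric_kl_hmm(M1, d1[[1]]), "share K")
})

test_that("distance matrices satisfy their invariants for every modality", {
  cohort <- small_cohort()
  fit <- small_group_fit()
  duals <- dual_estimate_cohort(fit, cohort$sessions)
  dms <- list(
    hmm = build_distance_matrix(duals, "hmm"),
    avfc = build_distance_matrix(time_averaged_fc(cohort$sessions), "avfc"),
    structural = build_distance_matrix(cohort$structural$FA, "structural")
  )
  for (dm in dms) {
    expect_true(all(dm >= 0))
    expect_equal(unclass(dm), t(unclass(dm)), tolerance = 1e-10)
    expect_true(all(diag(dm) == 0))
    expect_equal(rownames(dm), sort(cohort$subject_ids))
  }
})

test_that("structural distances are Euclidean and homogeneous of degree one", {
  m <- rbind(a = c(0, 0), b = c(3, 4))
  dm <- build_distance_matrix(m, "structural")
  expect_equal(dm["a", "b"], 5)
  dm3 <- build_distance_matrix(3 * m, "structural")
  expect_equal(unclass(dm3), 3 * unclass(dm), tolerance = 1e-12)
  expect_error(
    build_distance_matrix(rbind(a = 1:2, a = 3:4), "structural"),
    "duplicate"
  )
})

test_that("avfc distance matrix matches pairwise symmetric KL calls", {
  mats <- lapply(1:3, function(i) cov2cor(random_spd(4, seed = i)))
  names(mats) <- c("x", "y", "z")
  dm <- build_distance_matrix(mats, "avfc")
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expect_equal(
        dm[i, j], symmetric_kl_gaussian(mats[[i]], mats[[j]]),
        tolerance = 1e-10
      )
    }
  }
  same <- build_distance_matrix(list(a = mats[[1]], b = mats[[1]]), "avfc")
  expect_lt(max(abs(same)), 1e-12)
})

test_that("distance matrix CSV round trip preserves values and ids", {
  dm <- build_distance_matrix(small_cohort()$structural$MD, "structural")
  path <- withr::local_tempfile(fileext = ".csv")
  write_dm_csv(dm, path)
  back <- read_dm_csv(path, "structural")
  expect_equal(rownames(back), rownames(dm))
  expect_lt(max(abs(unclass(back) - unclass(dm))), 1e-8)
})
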