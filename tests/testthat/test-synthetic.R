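test_that("cohorts are bit-reproducible from their seed and satisfy the type invariants", {
  spec <- cohort_spec(n_subjects = 8, K = 2, J = 4, T = 120, seed = 13)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(
    lapply(c1$sessions, unclass),
    lapply(c2$sessions, unclass)
  )
  expect_identical(c1$traits, c2$traits)
  expect_identical(c1$structural$FA, c2$structural$FA)

  # sessions pass standardization checks; true states SPD; TPM stochastic
  for (s in c1$sessions[1:4]) {
    expect_lt(max(abs(colMeans(s))), 1e-8)
    expect_lt(max(abs(apply(s, 2, var) - 1)), 1e-6)
  }
  for (i in seq_along(c1$true$subject_tpm)) {
    expect_lt(max(abs(rowSums(c1$true$subject_tpm[[i]]) - 1)), 1e-10)
  }
  ev <- unlist(lapply(c1$true$subject_states, function(by_day) {
    lapply(by_day, function(states) {
      lapply(states, function(S) min(eigen(S, only.values = TRUE)$values))
    })
  }))
  expect_true(all(ev > 0))
  # family blocks cover all subjects
  expect_setequal(c1$families$subject_id, c1$subject_ids)
})

test_that("sampled second moments approach the occupancy-weighted true state mixture", {
  cohort <- generate_cohort(cohort_spec(
    n_subjects = 3, K = 2, J = 4, T = 2500,
    sessions_per_day = 1, days = 1, state_perturb = 0.15, seed = 5,
    missing_rate = 0
  ))
  ids <- vapply(cohort$sessions, function(s) attr(s, "subject_id"), character(1))
  for (i in 1:3) {
    sid <- cohort$subject_ids[i]
    X <- do.call(rbind, lapply(cohort$sessions[ids == sid], unclass))
    emp <- crossprod(X) / nrow(X)
    z <- cohort$true$state_paths[[i]]
    w_true <- tabulate(z, nbins = 2) / length(z)
    mix <- Reduce(`+`, Map(`*`, as.list(w_true), cohort$true$subject_states[[i]][[1]]))
    # standardization rescales columns slightly; O(1/sqrt(T)) agreement
    expect_lt(max(abs(emp - mix)), 6 / sqrt(2500))
  }
})

test_that("zero perturbation collapses between-subject distances relative to a perturbed cohort", {
  base <- list(
    n_subjects = 10, K = 2, J = 4, T = 1200, sessions_per_day = 1, days = 1,
    seed = 11, missing_rate = 0
  )
  c0 <- generate_cohort(do.call(cohort_spec, c(base, list(state_perturb = 0, tpm_conc = Inf, day_drift = 0))))
  c1 <- generate_cohort(do.call(cohort_spec, c(base, list(state_perturb = 0.5))))
  d0 <- build_distance_matrix(time_averaged_fc(c0$sessions), "avfc")
  d1 <- build_distance_matrix(time_averaged_fc(c1$sessions), "avfc")
  expect_lt(
    mean(d0[upper.tri(d0)]),
    mean(d1[upper.tri(d1)]) / 5
  )
})

test_that("fitting the generating model class recovers the group states", {
  cohort <- generate_cohort(cohort_spec(
    n_subjects = 20, K = 3, J = 6, T = 500, sessions_per_day = 1, days = 1,
    state_perturb = 0.15, seed = 17, missing_rate = 0
  ))
  fit <- fit_group_hmm(cohort$sessions, K = 3, variant = "fc", seed = 2)
  perm <- match_states(fit$covariances, cohort$true$group_states)
  cors <- vapply(1:3, function(k) {
    ut <- upper.tri(fit$covariances[[perm[k]]])
    cor(fit$covariances[[perm[k]]][ut], cohort$true$group_states[[k]][ut])
  }, numeric(1))
  expect_gt(mean(cors), 0.9)
})

test_that("trait variance attribution matches the design under an oracle regression", {
  cohort <- generate_cohort(cohort_spec(
    n_subjects = 1000, K = 3, J = 6, T = 2, # traits derive from true params, not series
    trait_design = tibble::tribble(
      ~trait, ~group, ~f_static, ~f_dynamic, ~f_struct, ~f_noise,
      "t_mix", "g", 0.3, 0.3, 0.2, 0.2,
      "t_noise", "g", 0, 0, 0, 1,
      "t_static", "g", 1, 0, 0, 0
    ),
    missing_rate = 0, seed = 23
  ))
  comps <- attr(cohort$traits, "components")
  for (tn in c("t_mix", "t_noise", "t_static")) {
    y <- cohort$traits[[tn]]
    cmp <- comps[[tn]]
    fit <- lm(y ~ static + dynamic + struct, data = cmp)
    d <- cohort$spec$trait_design
    row <- d[d$trait == tn, ]
    r2_oracle <- 1 - var(residuals(fit)) / var(y)
    expect_equal(r2_oracle, 1 - row$f_noise, tolerance = 0.05)
  }
  # the dynamic component is decorrelated from structure and static FC
  cmp <- comps[["t_mix"]]
  expect_lt(abs(cor(cmp$dynamic, cmp$struct)), 0.1)
  expect_lt(abs(cor(cmp$dynamic, cmp$static)), 0.1)
})

test_that("pure-noise traits are unpredictable from any distance matrix", {
  cohort <- generate_cohort(cohort_spec(
    n_subjects = 60, K = 2, J = 4, T = 200,
    trait_design = tibble::tibble(
      trait = "null_t", group = "g",
      f_static = 0, f_dynamic = 0, f_struct = 0, f_noise = 1
    ),
    missing_rate = 0, seed = 31
  ))
  dm <- build_distance_matrix(cohort$structural$FA, "structural")
  folds <- make_family_folds(cohort$families, 5, seed = 1)
  y <- setNames(cohort$traits$null_t, cohort$traits$subject_id)
  fit <- krr_predict_cv(dm, y, folds)
  expect_lt(fit$r2, 0.08)
})

test_that("dynamic trait signal requires at least two states", {
  expect_error(
    cohort_spec(
      n_subjects = 10, K = 1, J = 3, T = 50,
      trait_design = tibble::tibble(
        trait = "t", group = "g",
        f_static = 0, f_dynamic = 1, f_struct = 0, f_noise = 0
      )
    ),
    "K >= 2"
  )
})
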