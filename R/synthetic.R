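# Synthetic cohorts with the statistical structure the analyses assume:
# shared group FC states, subject-specific deviations, multi-session/day
# acquisition with day-level drift, family blocks, low-rank structural
# features partially coupled to time-averaged FC, motion summaries, and
# traits whose variance is attributable in controlled proportions to
# time-averaged FC, time-varying FC, structure, and noise.

#' Specify a synthetic cohort
#'
#' Defaults describe a desk-scale cohort mirroring a multi-session resting
#' fMRI design: `N` subjects scanned in `sessions_per_day * days` sessions
#' (two per day over two days), `J` parcels, `K` latent connectivity states
#' differing only in their correlation structure (unit variances), sticky
#' subject-specific transition matrices, and a day-two drift of the state
#' covariances so split-half reproducibility has a day structure.
#'
#' @param n_subjects,K,J,T Cohort size, state count, parcel count, and
#'   timepoints per session.
#' @param sessions_per_day,days Session layout (default 2 sessions x 2 days).
#' @param self_transition Group-level self-transition probability
#'   (temporal stickiness of the states).
#' @param state_perturb SD of the subject-specific state deviations on the
#'   matrix-log scale (0 = all subjects share the group states).
#' @param tpm_conc Dirichlet concentration for subject transition rows
#'   (larger = subjects closer to the group transition matrix).
#' @param day_drift SD of the independent per-day state perturbation (on the
#'   matrix-log scale) around the stable subject effect; when positive, the
#'   subject transition matrix also drifts per day at half the
#'   subject-effect scale. Days decorrelate symmetrically, which is what
#'   split-half reproducibility analyses probe.
#' @param family_sizes,family_probs Family-size distribution.
#' @param struct_dim,struct_rank Structural feature count per measure and
#'   the rank of their shared latent.
#' @param struct_couple Correlation between the structural latent and the
#'   leading principal components of the subjects' time-averaged FC
#'   (structure and time-averaged FC are partially coupled, as observed
#'   empirically; the dynamic trait component is orthogonalized away from
#'   both).
#' @param struct_noise SD of feature-level structural noise.
#' @param motion_loading Loading of the motion summary onto every trait
#'   (0 = traits free of motion contamination; set positive to exercise
#'   confound handling).
#' @param missing_rate Fraction of trait values set missing at random.
#' @param trait_design Tibble with columns `trait`, `group`, `f_static`,
#'   `f_dynamic`, `f_struct`, `f_noise` (fractions summing to 1 per trait).
#' @param seed Integer seed; cohorts are bit-reproducible given the spec.
#' @return A `fcdyn_cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 100L, K = 3L, J = 10L, T = 400L,
                        sessions_per_day = 2L, days = 2L,
                        self_transition = 0.9,
                        state_perturb = 0.25, tpm_conc = 50,
                        day_drift = 0.12,
                        family_sizes = 1:3, family_probs = c(0.55, 0.3, 0.15),
                        struct_dim = 50L, struct_rank = 5L,
                        struct_couple = 0.4, struct_noise = 0.3,
                        motion_loading = 0, missing_rate = 0.02,
                        trait_design = default_trait_design(),
                        seed = 1L) {
  trait_design <- tibble::as_tibble(trait_design)
  fr <- as.matrix(trait_design[, c("f_static", "f_dynamic", "f_struct", "f_noise")])
  if (any(fr < 0) || any(fr > 1) || any(abs(rowSums(fr) - 1) > 1e-8)) {
    stopf("trait variance fractions must lie in [0,1] and sum to 1 per trait")
  }
  if (K < 2 && any(fr[, "f_dynamic"] > 0)) {
    stopf("dynamic trait signal requires K >= 2 states")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), K = as.integer(K), J = as.integer(J),
      T = as.integer(T), sessions_per_day = as.integer(sessions_per_day),
      days = as.integer(days), self_transition = self_transition,
      state_perturb = state_perturb, tpm_conc = tpm_conc, day_drift = day_drift,
      family_sizes = family_sizes, family_probs = family_probs,
      struct_dim = as.integer(struct_dim), struct_rank = as.integer(struct_rank),
      struct_couple = struct_couple, struct_noise = struct_noise,
      motion_loading = motion_loading, missing_rate = missing_rate,
      trait_design = trait_design, seed = as.integer(seed)
    ),
    class = "fcdyn_cohort_spec"
  )
}

#' Default behavioural trait design
#'
#' A small battery spanning the behavioural groups, with variance
#' attributions chosen so that some traits lean on time-averaged FC, some on
#' time-varying FC (the intelligence-like traits), some on structure, and
#' all carry substantial noise.
#'
#' @return A tibble usable as `trait_design` in [cohort_spec()].
#' @export
default_trait_design <- function() {
  tibble::tribble(
    ~trait, ~group, ~f_static, ~f_dynamic, ~f_struct, ~f_noise,
    "demo_1", "demographic", 0.30, 0.05, 0.35, 0.30,
    "demo_2", "demographic", 0.25, 0.05, 0.30, 0.40,
    "intel_1", "intelligence", 0.10, 0.35, 0.05, 0.50,
    "intel_2", "intelligence", 0.10, 0.30, 0.10, 0.50,
    "affect_1", "affective", 0.10, 0.05, 0.05, 0.80,
    "affect_2", "affective", 0.15, 0.05, 0.10, 0.70,
    "person_1", "personality", 0.20, 0.05, 0.25, 0.50,
    "person_2", "personality", 0.15, 0.10, 0.20, 0.55,
    "sleep_1", "sleep", 0.15, 0.15, 0.10, 0.60,
    "sleep_2", "sleep", 0.10, 0.10, 0.15, 0.65
  )
}

# symmetric Gaussian noise matrix for matrix-log perturbations
sym_noise <- function(J, sd) {
  a <- matrix(stats::rnorm(J * J, sd = sd), J, J)
  (a + t(a)) / 2
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}

#' Generate a synthetic cohort
#'
#' Draws group states as random correlation matrices (unit variances, so
#' states differ purely in their correlation structure), perturbs them per
#' subject on the matrix-log scale (guaranteeing positive definiteness),
#' draws subject transition matrices from row-wise Dirichlet perturbations
#' of a sticky group matrix, applies per-day drift to states and transition
#' matrices, samples each session by
#' Markov-chain state switching with zero-mean Gaussian emissions, and
#' attaches families, low-rank structural features (FA/MD/VBM-like, shared
#' latent partially coupled to time-averaged FC), motion summaries, and the
#' designed traits.
#'
#' @param spec A [cohort_spec()].
#' @return A `fcdyn_cohort`: `sessions` (standardized, subject-then-session
#'   order), `true` generating parameters (group/subject states, transition
#'   matrices, stationary weights, expected time-averaged FC, state paths),
#'   `structural` feature matrices plus their latent, `families`, `motion`,
#'   `traits`, and `trait_groups`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "fcdyn_cohort_spec"))
  set.seed(spec$seed)
  N <- spec$n_subjects
  K <- spec$K
  J <- spec$J
  ids <- sprintf("S%03d", seq_len(N))

  # group states: random correlation matrices sharing unit variances
  group_states <- lapply(seq_len(K), function(k) {
    B <- matrix(stats::rnorm(J * 2), J, 2)
    stats::cov2cor(sym(tcrossprod(B) + diag(stats::runif(J, 0.5, 1.5), J)))
  })
  off <- if (K > 1) (1 - spec$self_transition) / (K - 1) else 0
  group_tpm <- matrix(off, K, K)
  diag(group_tpm) <- if (K > 1) spec$self_transition else 1

  # families
  fam_sizes <- integer(0)
  while (sum(fam_sizes) < N) {
    fam_sizes <- c(fam_sizes, sample(spec$family_sizes, 1, prob = spec$family_probs))
  }
  fam_id <- rep(sprintf("F%03d", seq_along(fam_sizes)), fam_sizes)[seq_len(N)]
  families <- tibble::tibble(subject_id = ids, family_id = fam_id)

  # subject-level generative parameters
  log_group <- lapply(group_states, spd_logm)
  subject_states <- vector("list", N) # [[i]][[day]][[k]]
  subject_tpm <- vector("list", N)
  subject_tpm_day <- vector("list", N) # [[i]][[day]]
  stationary <- matrix(0, N, K)
  avfc_true <- vector("list", N)
  for (i in seq_len(N)) {
    subj_eff <- lapply(seq_len(K), function(k) sym_noise(J, spec$state_perturb))
    # day-level drift: an independent state perturbation per day, so days
    # decorrelate symmetrically around the stable subject effect
    day_eff <- lapply(seq_len(spec$days), function(d) {
      lapply(seq_len(K), function(k) sym_noise(J, spec$day_drift))
    })
    subject_states[[i]] <- lapply(seq_len(spec$days), function(d) {
      lapply(seq_len(K), function(k) {
        # renormalized to a correlation matrix: states differ in correlation
        # only, matching the standardized emissions
        stats::cov2cor(spd_expm(
          log_group[[k]] + subj_eff[[k]] + day_eff[[d]][[k]]
        ))
      })
    })
    subject_tpm[[i]] <- if (spec$tpm_conc > 0 && is.finite(spec$tpm_conc)) {
      t(apply(group_tpm, 1, function(r) rdirichlet1(spec$tpm_conc * pmax(r, 1e-8))))
    } else {
      group_tpm
    }
    # day-level dynamics drift around the stable subject TPM, at half the
    # subject-effect scale (Dirichlet concentration 4x), matching the
    # state-drift ratio
    subject_tpm_day[[i]] <- lapply(seq_len(spec$days), function(d) {
      if (spec$day_drift > 0 && is.finite(spec$tpm_conc)) {
        t(apply(subject_tpm[[i]], 1, function(r) {
          rdirichlet1(4 * spec$tpm_conc * pmax(r, 1e-8))
        }))
      } else {
        subject_tpm[[i]]
      }
    })
    nu <- stationary_weights(subject_tpm[[i]])
    stationary[i, ] <- nu
    avfc_true[[i]] <- Reduce(`+`, lapply(seq_len(spec$days), function(d) {
      nu_d <- stationary_weights(subject_tpm_day[[i]][[d]])
      Reduce(`+`, Map(`*`, as.list(nu_d), subject_states[[i]][[d]]))
    })) / spec$days
  }

  # sessions: Markov-chain switching, zero-mean Gaussian emissions
  sessions <- list()
  true_states <- list()
  n_sessions <- spec$sessions_per_day * spec$days
  for (i in seq_len(N)) {
    for (s in seq_len(n_sessions)) {
      d <- ceiling(s / spec$sessions_per_day)
      P <- subject_tpm_day[[i]][[d]]
      nu <- stationary_weights(P)
      chols <- lapply(subject_states[[i]][[d]], function(S) chol_jitter(S, "state covariance"))
      z <- integer(spec$T)
      z[1] <- sample.int(K, 1, prob = nu)
      if (spec$T > 1) {
        for (t in 2:spec$T) z[t] <- sample.int(K, 1, prob = P[z[t - 1], ])
      }
      E <- matrix(stats::rnorm(spec$T * J), spec$T, J)
      x <- matrix(0, spec$T, J)
      for (k in seq_len(K)) {
        idx <- which(z == k)
        if (length(idx)) x[idx, ] <- E[idx, , drop = FALSE] %*% chols[[k]]
      }
      sessions[[length(sessions) + 1]] <- standardize_session(x, ids[i], s)
      true_states[[length(true_states) + 1]] <- z
    }
  }

  # structural features: shared low-rank latent, partially coupled to the
  # leading PCs of the subjects' (true) time-averaged FC
  Fs <- t(vapply(avfc_true, vech, numeric(J * (J + 1) / 2)))
  keep <- apply(Fs, 2, stats::sd) > 1e-10
  r <- min(spec$struct_rank, N - 1)
  if (any(keep)) {
    Fs_std <- scale(Fs[, keep, drop = FALSE])
    r <- min(r, ncol(Fs_std))
    U <- scale(svd(Fs_std, nu = r, nv = 0)$u[, seq_len(r), drop = FALSE])
  } else {
    # degenerate cohort (no between-subject FC variation): latent is pure noise
    U <- matrix(stats::rnorm(N * r), N, r)
  }
  Z <- spec$struct_couple * U +
    sqrt(max(0, 1 - spec$struct_couple^2)) * matrix(stats::rnorm(N * r), N, r)
  load_fa <- matrix(stats::rnorm(spec$struct_dim * r), spec$struct_dim, r)
  load_md <- 0.75 * load_fa + sqrt(1 - 0.75^2) * matrix(stats::rnorm(spec$struct_dim * r), spec$struct_dim, r)
  load_vbm <- 0.4 * load_fa + sqrt(1 - 0.4^2) * matrix(stats::rnorm(spec$struct_dim * r), spec$struct_dim, r)
  mk_struct <- function(L) {
    m <- Z %*% t(L) / sqrt(r) +
      spec$struct_noise * matrix(stats::rnorm(N * spec$struct_dim), N, spec$struct_dim)
    rownames(m) <- ids
    m
  }
  structural <- list(
    FA = mk_struct(load_fa), MD = mk_struct(load_md), VBM = mk_struct(load_vbm),
    latent = `rownames<-`(Z, ids)
  )

  motion <- matrix(stats::rnorm(N * 2), N, 2,
    dimnames = list(ids, c("motion_mean", "motion_max"))
  )

  cohort <- structure(
    list(
      spec = spec,
      subject_ids = ids,
      sessions = sessions,
      true = list(
        group_states = group_states, group_tpm = group_tpm,
        subject_states = subject_states, subject_tpm = subject_tpm,
        subject_tpm_day = subject_tpm_day,
        stationary = stationary, avfc = avfc_true,
        state_paths = true_states
      ),
      structural = structural,
      families = families,
      motion = motion
    ),
    class = "fcdyn_cohort"
  )
  traits <- generate_traits(cohort, spec$trait_design, seed = spec$seed + 1L)
  cohort$traits <- traits
  cohort$trait_groups <- attr(traits, "groups")
  cohort
}

#' Generate traits with controlled variance attribution
#'
#' Each trait is a standardized mixture of four standardized components:
#' a projection of the subjects' time-averaged FC entries (`f_static`), a
#' projection of transition-matrix/occupancy features orthogonalized at the
#' population level against the time-averaged FC principal components
#' (`f_dynamic`; uncorrelated with both time-averaged FC and the structural
#' latent by construction), a projection of the observed structural feature
#' matrices (`f_struct`), and Gaussian noise (`f_noise`). Fractions are
#' variance shares. Motion contamination (if `motion_loading > 0` in the spec) is
#' added on top, outside the fractions.
#'
#' @param cohort A `fcdyn_cohort`.
#' @param design Trait design tibble (see [cohort_spec()]); an optional
#'   `struct_source` column (`"all"`, `"FA"`, `"MD"`, `"VBM"`) restricts
#'   the structural component to one measure's features, e.g. to probe
#'   measure-matched deconfounding.
#' @param seed Integer seed.
#' @return A tibble `subject_id` + one column per trait, with attributes
#'   `groups` (trait -> behavioural group) and `components` (the true
#'   generating components per trait, for oracle checks).
#' @export
generate_traits <- function(cohort, design = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "fcdyn_cohort"))
  design <- tibble::as_tibble(design %||% cohort$spec$trait_design)
  spec <- cohort$spec
  if (spec$K < 2 && any(design$f_dynamic > 0)) {
    stopf("dynamic trait signal requires K >= 2 states")
  }
  set.seed(seed)
  N <- length(cohort$subject_ids)
  J <- spec$J
  K <- spec$K

  Fs <- t(vapply(cohort$true$avfc, vech, numeric(J * (J + 1) / 2)))
  Fs <- Fs[, apply(Fs, 2, stats::sd) > 1e-10, drop = FALSE]
  if (ncol(Fs)) {
    Fs <- scale(Fs)
    p <- min(20, ncol(Fs), max(1, floor(N / 5)))
    Ps <- svd(Fs, nu = p, nv = 0)$u[, seq_len(p), drop = FALSE]
  } else {
    # degenerate cohort: no between-subject FC variation to project on
    Ps <- matrix(0, N, 1)
  }

  clamp <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)
  Fd_raw <- cbind(
    t(vapply(cohort$true$subject_tpm, function(P) stats::qlogis(clamp(diag(P))), numeric(K))),
    stats::qlogis(clamp(cohort$true$stationary))
  )
  Fd_raw <- Fd_raw[, apply(Fd_raw, 2, stats::sd) > 1e-10, drop = FALSE]
  # population-level orthogonalization against the time-averaged FC subspace
  Fd <- if (ncol(Fd_raw)) {
    stats::lm.fit(cbind(1, Ps), Fd_raw)$residuals
  } else {
    Fd_raw
  }
  # structural trait component projects from the observed feature matrices
  # (what a structural analysis can measure), not the generating latent;
  # a design column `struct_source` can restrict it to one measure
  struct_feats <- function(src) {
    if (identical(src, "all") || is.null(src) || is.na(src)) {
      scale(cbind(
        cohort$structural$FA, cohort$structural$MD, cohort$structural$VBM
      ))
    } else {
      scale(cohort$structural[[src]])
    }
  }

  std <- function(x) {
    s <- stats::sd(x)
    if (s < 1e-12) stats::rnorm(length(x)) else (x - mean(x)) / s
  }
  proj <- function(M) {
    if (is.null(M) || !ncol(M)) return(stats::rnorm(N))
    std(drop(M %*% stats::rnorm(ncol(M))))
  }

  traits <- tibble::tibble(subject_id = cohort$subject_ids)
  comps <- list()
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    z_static <- proj(Fs)
    z_dyn <- proj(Fd)
    src <- if ("struct_source" %in% names(d)) d$struct_source else "all"
    z_struct <- proj(struct_feats(src))
    eps <- stats::rnorm(N)
    y <- sqrt(d$f_static) * z_static + sqrt(d$f_dynamic) * z_dyn +
      sqrt(d$f_struct) * z_struct + sqrt(d$f_noise) * eps
    y <- std(y)
    if (spec$motion_loading > 0) {
      y <- y + spec$motion_loading * std(drop(cohort$motion %*% c(1, 0.5)))
    }
    if (spec$missing_rate > 0) {
      y[stats::runif(N) < spec$missing_rate] <- NA_real_
    }
    traits[[d$trait]] <- y
    comps[[d$trait]] <- tibble::tibble(
      static = z_static, dynamic = z_dyn, struct = z_struct, noise = eps
    )
  }
  attr(traits, "groups") <- stats::setNames(design$group, design$trait)
  attr(traits, "components") <- comps
  traits
}

#' @export
print.fcdyn_cohort <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<fcdyn_cohort> %d subjects, %d sessions each (T = %d, J = %d), K = %d true states, %d traits\n",
    s$n_subjects, s$sessions_per_day * s$days, s$T, s$J, s$K,
    ncol(x$traits) - 1
  ))
  invisible(x)
}
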