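# Group-level hidden Markov model with Gaussian observation variants:
#   fc   - zero-mean, full state-specific covariance (FC states; the model
#          of interest: state switches are modulations of connectivity)
#   mean - state-specific means, one covariance shared across states
#          (amplitude-only control)
#   var  - zero-mean, diagonal state-specific covariance (variance-only
#          control; blind to cross-region correlation)
# Inference is variational Bayes with conjugate priors: Wishart on state
# precisions (Gamma per element for the var variant), Dirichlet on transition
# matrix rows (with a self-transition pseudo-count boost that regularises
# state switching) and on the initial distribution. The free energy
# (negative evidence lower bound) is tracked and is non-increasing.

## ---- forward-backward ------------------------------------------------------

# Scaled forward-backward for one session.
# logB: T x K expected observation log-densities; lA: K x K (sub)probability
# transition weights (exp of expected log); lpi: K initial weights.
# Returns gamma (T x K), xi (K x K expected transition counts summed over t),
# and the log-normalizer that feeds the free energy.
forward_backward <- function(logB, lA, lpi) {
  Tn <- nrow(logB)
  K <- ncol(logB)
  shift <- apply(logB, 1, max)
  B <- exp(logB - shift)
  alpha <- matrix(0, Tn, K)
  cs <- numeric(Tn)
  a <- lpi * B[1L, ]
  cs[1L] <- sum(a)
  alpha[1L, ] <- a / cs[1L]
  if (Tn > 1L) {
    for (t in 2:Tn) {
      a <- (alpha[t - 1L, ] %*% lA) * B[t, ]
      cs[t] <- sum(a)
      alpha[t, ] <- a / cs[t]
    }
  }
  beta <- matrix(0, Tn, K)
  beta[Tn, ] <- 1
  if (Tn > 1L) {
    for (t in (Tn - 1L):1L) {
      beta[t, ] <- lA %*% (B[t + 1L, ] * beta[t + 1L, ]) / cs[t + 1L]
    }
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi <- matrix(0, K, K)
  if (Tn > 1L) {
    m <- B[-1L, , drop = FALSE] * beta[-1L, , drop = FALSE] / cs[-1L]
    xi <- lA * crossprod(alpha[-Tn, , drop = FALSE], m)
  }
  list(gamma = gamma, xi = xi, logz = sum(log(cs)) + sum(shift))
}

## ---- observation-model posteriors ------------------------------------------

# M-step: conjugate posterior updates given responsibilities.
obs_mstep <- function(X, gamma, priors, variant) {
  K <- ncol(gamma)
  J <- ncol(X)
  Nk <- colSums(gamma)
  if (variant == "fc") {
    post <- vector("list", K)
    for (k in seq_len(K)) {
      Sk <- crossprod(X, gamma[, k] * X)
      nu <- priors$nu0 + Nk[k]
      Winv <- sym(priors$W0inv + Sk)
      R <- chol_jitter(Winv, "state precision scale")
      elogdet <- sum(digamma((nu + 1 - seq_len(J)) / 2)) + J * log(2) -
        2 * sum(log(diag(R)))
      post[[k]] <- list(
        nu = nu, Winv = Winv, N = Nk[k],
        ELam = nu * chol2inv(R), Elogdet = elogdet
      )
    }
    post
  } else if (variant == "mean") {
    beta <- priors$beta0 + Nk
    m <- matrix(0, K, J)
    Winv <- sym(priors$W0inv)
    for (k in seq_len(K)) {
      sk_raw <- crossprod(X, gamma[, k] * X)
      m[k, ] <- colSums(gamma[, k] * X) / beta[k]
      Winv <- Winv + sk_raw - beta[k] * tcrossprod(m[k, ])
    }
    Winv <- sym(Winv)
    nu <- priors$nu0 + sum(Nk)
    R <- chol_jitter(Winv, "shared precision scale")
    elogdet <- sum(digamma((nu + 1 - seq_len(J)) / 2)) + J * log(2) -
      2 * sum(log(diag(R)))
    list(
      nu = nu, Winv = Winv, ELam = nu * chol2inv(R), Elogdet = elogdet,
      beta = beta, m = m, N = Nk
    )
  } else { # var
    a <- outer(rep(1, J), priors$a0 + Nk / 2) # J x K
    b <- priors$b0 + 0.5 * crossprod(X * X, gamma) # J x K
    list(a = a, b = b, N = Nk)
  }
}

# Expected observation log-densities under the variational posterior.
obs_logdens <- function(X, post, variant) {
  J <- ncol(X)
  Tn <- nrow(X)
  cst <- -J / 2 * log(2 * pi)
  if (variant == "fc") {
    K <- length(post)
    logB <- matrix(0, Tn, K)
    for (k in seq_len(K)) {
      q <- rowSums((X %*% post[[k]]$ELam) * X)
      logB[, k] <- cst + 0.5 * post[[k]]$Elogdet - 0.5 * q
    }
    logB
  } else if (variant == "mean") {
    K <- nrow(post$m)
    logB <- matrix(0, Tn, K)
    for (k in seq_len(K)) {
      Xc <- sweep(X, 2, post$m[k, ])
      q <- rowSums((Xc %*% post$ELam) * Xc) + J / post$beta[k]
      logB[, k] <- cst + 0.5 * post$Elogdet - 0.5 * q
    }
    logB
  } else {
    elog <- digamma(post$a) - log(post$b) # J x K
    erate <- post$a / post$b
    sweep((X * X) %*% (-0.5 * erate), 2, cst + 0.5 * colSums(elog), `+`)
  }
}

# KL(q || prior) for the observation model, feeding the free energy.
obs_kl <- function(post, priors, variant) {
  if (variant == "fc") {
    sum(vapply(
      post,
      function(p) kl_wishart(p$nu, p$Winv, priors$nu0, priors$W0inv),
      numeric(1)
    ))
  } else if (variant == "mean") {
    J <- ncol(post$m)
    klw <- kl_wishart(post$nu, post$Winv, priors$nu0, priors$W0inv)
    ELam <- post$ELam
    klm <- 0
    for (k in seq_len(nrow(post$m))) {
      mk <- post$m[k, ]
      klm <- klm + 0.5 * (J * priors$beta0 / post$beta[k] - J +
        priors$beta0 * drop(mk %*% ELam %*% mk) +
        J * log(post$beta[k] / priors$beta0))
    }
    klw + klm
  } else {
    sum(kl_gamma(post$a, post$b, priors$a0, matrix(priors$b0,
      nrow = nrow(post$b), ncol = ncol(post$b)
    )))
  }
}

# Point estimates of the observation model for decoding / reporting.
obs_point <- function(post, variant) {
  if (variant == "fc") {
    lapply(post, function(p) sym(p$Winv / p$nu))
  } else if (variant == "mean") {
    list(means = post$m, covariance = sym(post$Winv / post$nu))
  } else {
    post$b / post$a # J x K variances
  }
}

## ---- initialization ---------------------------------------------------------

# Responsibilities initialized from k-means on sliding-window summaries
# (window covariances for fc/var, window means for the mean variant), plus
# seed-controlled noise. Falls back to a random Dirichlet draw when the data
# are too short to support windows.
init_gamma <- function(sessions, K, variant) {
  if (K == 1L) {
    return(lapply(sessions, function(s) matrix(1, nrow(s), 1)))
  }
  Ts <- vapply(sessions, nrow, integer(1))
  win <- min(50L, max(10L, floor(min(Ts) / 2)))
  feats <- list()
  index <- list()
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    if (nrow(s) < win + 1L) next
    starts <- unique(c(seq(1L, nrow(s) - win + 1L, by = max(1L, win %/% 2L)),
      nrow(s) - win + 1L))
    for (st in starts) {
      w <- s[st:(st + win - 1L), , drop = FALSE]
      f <- if (variant == "mean") colMeans(w) else vech(crossprod(w) / win)
      feats[[length(feats) + 1L]] <- f
      index[[length(index) + 1L]] <- c(i, st, st + win - 1L)
    }
  }
  labels_for <- NULL
  if (length(feats) >= 2L * K) {
    fm <- do.call(rbind, feats)
    km <- tryCatch(
      stats::kmeans(fm, centers = K, nstart = 3, iter.max = 30),
      error = function(e) NULL
    )
    if (!is.null(km)) labels_for <- km$cluster
  }
  out <- vector("list", length(sessions))
  for (i in seq_along(sessions)) {
    Tn <- nrow(sessions[[i]])
    g <- matrix(stats::rgamma(Tn * K, shape = 1), Tn, K)
    if (!is.null(labels_for)) {
      lab <- integer(Tn)
      for (j in seq_along(index)) {
        if (index[[j]][1] == i) lab[index[[j]][2]:index[[j]][3]] <- labels_for[j]
      }
      lab[lab == 0L] <- sample.int(K, sum(lab == 0L), replace = TRUE)
      g <- 0.15 * g + 0.85 * (outer(lab, seq_len(K), `==`) * 1)
    }
    out[[i]] <- g / rowSums(g)
  }
  out
}

## ---- the fitter -------------------------------------------------------------

#' Fit a group-level state-switching connectivity model
#'
#' Fits a hidden Markov model to the concatenated sessions of a cohort by
#' variational Bayesian inference. In the default `"fc"` variant every state
#' is a zero-mean Gaussian with a full covariance matrix, so a state change is
#' a change in functional connectivity rather than in signal amplitude. The
#' `"mean"` variant (per-state means, one shared covariance) and `"var"`
#' variant (per-state diagonal variances, zero mean) are controls that carry
#' no time-varying connectivity information.
#'
#' State covariances and the transition probability matrix are estimated at
#' the group level; state time courses (posterior state probabilities) are
#' specific to each session. Because the optimisation is seed-dependent,
#' repeated fits with distinct seeds (see [fit_group_hmm_reps()]) are treated
#' as first-class replicate estimates.
#'
#' @param sessions List of [standardize_session()] outputs; all sessions must
#'   share the parcel count `J`. Sessions are concatenated in subject-then-
#'   session order.
#' @param K Number of states (default 8).
#' @param variant Observation model: `"fc"`, `"mean"`, or `"var"`.
#' @param seed Integer seed controlling initialization.
#' @param max_iter,tol Stopping rule: stop when the relative free-energy
#'   change falls below `tol`, or after `max_iter` variational cycles.
#' @param stickiness Self-transition pseudo-count added to the Dirichlet
#'   prior on transition-matrix rows; temporal regularization against
#'   spurious state switching.
#' @return A `fcdyn_hmm` object (`level = "group"`) holding the state
#'   observation models, transition matrix and Dirichlet posterior counts,
#'   initial state probabilities, per-session state time courses, and the
#'   free-energy trace (non-increasing).
#' @export
fit_group_hmm <- function(sessions, K = 8L, variant = c("fc", "mean", "var"),
                          seed = 1L, max_iter = 500L, tol = 1e-5,
                          stickiness = 10) {
  variant <- match.arg(variant)
  check_sessions(sessions)
  ord <- order(
    vapply(sessions, session_subject, character(1)),
    vapply(sessions, function(s) as.character(session_id_of(s)), character(1))
  )
  sessions <- sessions[ord]
  K <- as.integer(K)
  if (K < 1L) stopf("K must be >= 1")
  Ts <- vapply(sessions, nrow, integer(1))
  if (K > sum(Ts)) stopf("K = %d exceeds the total number of timepoints (%d)", K, sum(Ts))
  X <- do.call(rbind, lapply(sessions, unclass))
  J <- ncol(X)
  ends <- cumsum(Ts)
  starts <- c(1L, utils::head(ends, -1L) + 1L)

  set.seed(seed)
  C_pooled <- sym(crossprod(X) / nrow(X))
  nu0 <- J + 2
  priors <- list(
    nu0 = nu0, W0inv = nu0 * C_pooled,
    a0 = nu0 / 2, b0 = (nu0 / 2) * diag(C_pooled),
    beta0 = 1,
    alphaA0 = matrix(1, K, K) + diag(stickiness, K),
    alphapi0 = rep(1, K)
  )

  gammas <- init_gamma(sessions, K, variant)
  gamma <- do.call(rbind, gammas)
  xi <- matrix(0, K, K)
  firsts <- rep(0, K)
  for (i in seq_along(gammas)) {
    g <- gammas[[i]]
    if (nrow(g) > 1L) {
      xi <- xi + crossprod(g[-nrow(g), , drop = FALSE], g[-1L, , drop = FALSE])
    }
    firsts <- firsts + g[1L, ]
  }

  fe <- numeric(0)
  converged <- FALSE
  post <- NULL
  alphaA <- NULL
  alphapi <- NULL
  for (it in seq_len(max_iter)) {
    # M-step
    post <- obs_mstep(X, gamma, priors, variant)
    alphaA <- priors$alphaA0 + xi
    alphapi <- priors$alphapi0 + firsts
    lA <- exp(digamma(alphaA) - digamma(rowSums(alphaA)))
    lpi <- exp(digamma(alphapi) - digamma(sum(alphapi)))
    # E-step
    logB <- obs_logdens(X, post, variant)
    xi <- matrix(0, K, K)
    firsts <- rep(0, K)
    logz <- 0
    for (i in seq_along(starts)) {
      fbi <- forward_backward(logB[starts[i]:ends[i], , drop = FALSE], lA, lpi)
      gamma[starts[i]:ends[i], ] <- fbi$gamma
      xi <- xi + fbi$xi
      firsts <- firsts + fbi$gamma[1L, ]
      logz <- logz + fbi$logz
    }
    # free energy = KL(q(theta) || p(theta)) - log-evidence bound term
    klA <- sum(vapply(
      seq_len(K),
      function(j) kl_dirichlet(alphaA[j, ], priors$alphaA0[j, ]),
      numeric(1)
    ))
    f <- obs_kl(post, priors, variant) + klA +
      kl_dirichlet(alphapi, priors$alphapi0) - logz
    fe <- c(fe, f)
    if (it >= 2L && abs(fe[it - 1L] - fe[it]) < tol * abs(fe[it - 1L])) {
      converged <- TRUE
      break
    }
  }
  # final M-step so reported parameters match the final responsibilities
  post <- obs_mstep(X, gamma, priors, variant)
  alphaA <- priors$alphaA0 + xi
  alphapi <- priors$alphapi0 + firsts

  pt <- obs_point(post, variant)
  gl <- lapply(seq_along(starts), function(i) {
    gamma[starts[i]:ends[i], , drop = FALSE]
  })
  idx <- tibble::tibble(
    subject_id = vapply(sessions, session_subject, character(1)),
    session_id = vapply(sessions, function(s) as.character(session_id_of(s)), character(1)),
    T = Ts
  )
  structure(
    list(
      variant = variant, level = "group", K = K, J = J,
      covariances = if (variant == "fc") pt else NULL,
      means = if (variant == "mean") pt$means else NULL,
      covariance = if (variant == "mean") pt$covariance else NULL,
      variances = if (variant == "var") pt else NULL,
      transition_matrix = alphaA / rowSums(alphaA),
      transition_counts = alphaA,
      initial_probs = alphapi / sum(alphapi),
      gamma = gl,
      sessions_index = idx,
      free_energy = fe,
      posterior = post,
      priors = priors,
      seed = seed,
      converged = converged,
      n_iter = length(fe)
    ),
    class = "fcdyn_hmm"
  )
}

#' Repeated group fits with distinct seeds
#'
#' The variational optimisation can land in different local optima depending
#' on initialization, so replicate inferences are part of the analysis: each
#' repetition yields its own distance matrix and predictions downstream.
#'
#' @inheritParams fit_group_hmm
#' @param seeds Integer vector, one seed per repetition (default `1:5`).
#' @return A list of `fcdyn_hmm` fits, one per seed.
#' @export
fit_group_hmm_reps <- function(sessions, K = 8L, variant = "fc", seeds = 1:5, ...) {
  lapply(seeds, function(s) fit_group_hmm(sessions, K, variant, seed = s, ...))
}

#' @export
print.fcdyn_hmm <- function(x, ...) {
  cat(sprintf(
    "<fcdyn_hmm> %s-level %s-variant model: K = %d states, J = %d parcels\n",
    x$level, x$variant, x$K, x$J
  ))
  if (length(x$free_energy)) {
    cat(sprintf(
      "  %d variational iterations, final free energy %.2f (%s)\n",
      x$n_iter, utils::tail(x$free_energy, 1),
      if (isTRUE(x$converged)) "converged" else "max_iter reached"
    ))
  }
  invisible(x)
}

## ---- decoding and likelihood -----------------------------------------------

# log-densities under the point-estimate observation model
point_logdens <- function(model, X) {
  J <- ncol(X)
  cst <- -J / 2 * log(2 * pi)
  if (model$variant == "fc") {
    K <- model$K
    logB <- matrix(0, nrow(X), K)
    for (k in seq_len(K)) {
      S <- model$covariances[[k]]
      P <- inv_spd(S, sprintf("state %d covariance", k))
      logB[, k] <- cst - 0.5 * logdet_spd(S) - 0.5 * rowSums((X %*% P) * X)
    }
    logB
  } else if (model$variant == "mean") {
    P <- inv_spd(model$covariance, "shared covariance")
    ld <- logdet_spd(model$covariance)
    K <- model$K
    logB <- matrix(0, nrow(X), K)
    for (k in seq_len(K)) {
      Xc <- sweep(X, 2, model$means[k, ])
      logB[, k] <- cst - 0.5 * ld - 0.5 * rowSums((Xc %*% P) * Xc)
    }
    logB
  } else {
    v <- model$variances # J x K
    sweep((X * X) %*% (-0.5 / v), 2, cst - 0.5 * colSums(log(v)), `+`)
  }
}

#' Posterior state probabilities for new sessions
#'
#' Decodes sessions under a fitted model's point-estimate parameters,
#' returning the per-timepoint posterior state probabilities (state time
#' courses). Rows sum to one.
#'
#' @param model A `fcdyn_hmm`.
#' @param sessions A list of sessions (shared `J` with the model).
#' @return A list of `T x K` gamma matrices, one per session.
#' @export
decode_states <- function(model, sessions) {
  check_sessions(sessions)
  if (ncol(sessions[[1]]) != model$J) stopf("sessions and model disagree on J")
  lapply(sessions, function(s) {
    forward_backward(
      point_logdens(model, unclass(s)),
      model$transition_matrix, model$initial_probs
    )$gamma
  })
}

#' Data log-likelihood under the point-estimate model
#'
#' Exact forward-algorithm log-likelihood of the sessions under the model's
#' point-estimate states, transition matrix, and initial probabilities. With
#' `K = 1` this is the ordinary multivariate-Gaussian log-likelihood.
#'
#' @inheritParams decode_states
#' @return A single number, the summed log-likelihood.
#' @export
hmm_loglik <- function(model, sessions) {
  check_sessions(sessions)
  sum(vapply(sessions, function(s) {
    forward_backward(
      point_logdens(model, unclass(s)),
      model$transition_matrix, model$initial_probs
    )$logz
  }, numeric(1)))
}
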