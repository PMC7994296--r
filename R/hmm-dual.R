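# Dual estimation: subject-specific versions of a group model, in analogy to
# dual regression in ICA. One re-estimation cycle: the subject's state time
# courses under the group model define subject-specific states; those states
# are then used to re-decode the state time courses and the transition matrix.

#' Dual-estimate a subject-specific model from a group fit
#'
#' Given a group-level model and one subject's sessions, computes (1) the
#' subject's state time courses under the group model, (2) subject-specific
#' state observation models as gamma-weighted moments of the subject's data,
#' and (3) re-decoded state time courses plus a subject transition matrix and
#' initial probabilities under those subject states. States stay matched to
#' the group model's states by construction, which is what makes
#' between-subject model distances well defined.
#'
#' The returned fractional occupancy `w` is the time average of the
#' state-defining gamma (step 1), so that for the `"fc"` variant the exact
#' reconstruction identity holds: `sum_k w[k] * covariances[[k]]` equals the
#' subject's pooled sample second-moment matrix (see
#' [reconstruct_time_averaged_fc()]).
#'
#' @param group A `fcdyn_hmm` with `level = "group"`.
#' @param subject_sessions List of sessions belonging to one subject;
#'   concatenated in the given order and weighted by timepoint.
#' @param occupancy_floor States whose total occupancy falls below this many
#'   effective samples are retained with a prior-dominated observation model
#'   (a warning is issued) rather than dropped, so state matching across
#'   subjects stays trivial. The blending deliberately trades the exact
#'   time-averaged-FC reconstruction identity on such states for positive
#'   definiteness; set the floor to 0 to keep the raw weighted moments (the
#'   identity then holds exactly whenever every state has nonzero
#'   occupancy).
#' @return A `fcdyn_hmm` with `level = "subject"`, carrying `w` (fractional
#'   occupancy), `gamma` (re-decoded state time courses per session),
#'   `gamma_defining` (the state-defining gammas from step 1), and the
#'   subject transition matrix/counts.
#' @export
dual_estimate <- function(group, subject_sessions, occupancy_floor = 10) {
  if (!inherits(group, "fcdyn_hmm") || group$level != "group") {
    stopf("`group` must be a group-level fcdyn_hmm")
  }
  check_sessions(subject_sessions)
  if (ncol(subject_sessions[[1]]) != group$J) stopf("sessions and model disagree on J")
  K <- group$K
  J <- group$J
  subject <- session_subject(subject_sessions[[1]])
  Ts <- vapply(subject_sessions, nrow, integer(1))
  X <- do.call(rbind, lapply(subject_sessions, unclass))
  Tn <- nrow(X)

  # step 1: state time courses under the group model
  g0 <- decode_states(group, subject_sessions)
  g0c <- do.call(rbind, g0)
  Nk <- colSums(g0c)
  w <- Nk / Tn

  # step 2: subject-specific states from the defining gamma
  variant <- group$variant
  pr <- group$priors
  # truly empty states always take the prior path, whatever the floor
  low <- which(Nk < max(occupancy_floor, 1e-9))
  if (length(low)) {
    warnf(
      "subject %s: state(s) %s have occupancy below %g effective samples; prior-dominated estimates retained",
      subject, paste(low, collapse = ", "), occupancy_floor
    )
  }
  covariances <- NULL
  means <- NULL
  covariance <- NULL
  variances <- NULL
  if (variant == "fc") {
    covariances <- lapply(seq_len(K), function(k) {
      Sk <- crossprod(X, g0c[, k] * X)
      if (k %in% low) {
        sym((pr$W0inv + Sk) / (pr$nu0 + Nk[k]))
      } else {
        sym(Sk / Nk[k])
      }
    })
  } else if (variant == "mean") {
    means <- t(vapply(seq_len(K), function(k) {
      if (k %in% low) {
        colSums(g0c[, k] * X) / (pr$beta0 + Nk[k])
      } else {
        colSums(g0c[, k] * X) / Nk[k]
      }
    }, numeric(J)))
    S <- matrix(0, J, J)
    for (k in seq_len(K)) {
      Xc <- sweep(X, 2, means[k, ])
      S <- S + crossprod(Xc, g0c[, k] * Xc)
    }
    covariance <- sym(S / Tn)
  } else {
    variances <- vapply(seq_len(K), function(k) {
      sjj <- colSums(g0c[, k] * X * X)
      if (k %in% low) {
        (2 * pr$b0 + sjj) / (2 * pr$a0 + Nk[k])
      } else {
        sjj / Nk[k]
      }
    }, numeric(J))
    variances <- matrix(variances, nrow = J)
  }

  # step 3: re-decode gamma and the TPM under the subject states
  subj <- structure(
    list(
      variant = variant, level = "subject", K = K, J = J,
      covariances = covariances, means = means, covariance = covariance,
      variances = variances,
      transition_matrix = group$transition_matrix,
      initial_probs = group$initial_probs
    ),
    class = "fcdyn_hmm"
  )
  logB <- point_logdens(subj, X)
  ends <- cumsum(Ts)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  xi <- matrix(0, K, K)
  firsts <- rep(0, K)
  gl <- vector("list", length(Ts))
  for (i in seq_along(Ts)) {
    fbi <- forward_backward(
      logB[starts[i]:ends[i], , drop = FALSE],
      group$transition_matrix, group$initial_probs
    )
    gl[[i]] <- fbi$gamma
    xi <- xi + fbi$xi
    firsts <- firsts + fbi$gamma[1L, ]
  }
  alphaA <- pr$alphaA0 + xi
  alphapi <- pr$alphapi0 + firsts

  subj$transition_matrix <- alphaA / rowSums(alphaA)
  subj$transition_counts <- alphaA
  subj$initial_probs <- alphapi / sum(alphapi)
  subj$gamma <- gl
  subj$gamma_defining <- g0
  subj$w <- w
  subj$subject_id <- subject
  subj$sessions_index <- tibble::tibble(
    subject_id = subject,
    session_id = vapply(subject_sessions, function(s) as.character(session_id_of(s)), character(1)),
    T = Ts
  )
  subj
}

#' Dual-estimate every subject of a cohort
#'
#' @param group A group-level `fcdyn_hmm`.
#' @param sessions All sessions of the cohort; grouped by subject id.
#' @param ... Passed to [dual_estimate()].
#' @return A named list of subject-level `fcdyn_hmm` models, ordered by
#'   subject id.
#' @export
dual_estimate_cohort <- function(group, sessions, ...) {
  check_sessions(sessions)
  ids <- vapply(sessions, session_subject, character(1))
  split_sessions <- split(sessions, factor(ids, levels = unique(sort(ids))))
  out <- lapply(split_sessions, dual_estimate, group = group, ...)
  names(out) <- names(split_sessions)
  out
}
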