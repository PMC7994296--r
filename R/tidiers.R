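# broom-style accessors: tidy() rows are observations, glance() is a
# one-row model summary.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted state model
#'
#' One row per state: fractional occupancy (subject level), expected dwell
#' time implied by the self-transition probability, and the mean absolute
#' off-diagonal state FC.
#'
#' @param x A `fcdyn_hmm`.
#' @param ... Unused.
#' @return A tibble with one row per state.
#' @export
tidy.fcdyn_hmm <- function(x, ...) {
  self <- diag(x$transition_matrix)
  occ <- if (!is.null(x$w)) {
    x$w
  } else {
    colMeans(do.call(rbind, x$gamma))
  }
  mean_fc <- vapply(seq_len(x$K), function(k) {
    S <- switch(x$variant,
      fc = x$covariances[[k]],
      mean = x$covariance,
      var = diag(x$variances[, k], x$J)
    )
    mean(abs(S[upper.tri(S)]))
  }, numeric(1))
  tibble::tibble(
    state = seq_len(x$K),
    occupancy = occ,
    self_transition = self,
    expected_dwell = 1 / pmax(1 - self, 1e-12),
    mean_abs_off_diag_fc = mean_fc
  )
}

#' @rdname tidy.fcdyn_hmm
#' @export
glance.fcdyn_hmm <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, level = x$level, K = x$K, J = x$J,
    n_iter = x$n_iter %||% NA_integer_,
    converged = x$converged %||% NA,
    free_energy = if (length(x$free_energy)) utils::tail(x$free_energy, 1) else NA_real_
  )
}

#' Tidy a distance matrix
#'
#' Long form, one row per unordered subject pair.
#'
#' @param x A `fcdyn_dm`.
#' @param ... Unused.
#' @return A tibble `subject_a, subject_b, distance`.
#' @export
tidy.fcdyn_dm <- function(x, ...) {
  ids <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(
    subject_a = ids[idx[, 1]],
    subject_b = ids[idx[, 2]],
    distance = unclass(x)[idx]
  )
}

#' Tidy a cross-validated prediction
#'
#' @param x A `fcdyn_krr`.
#' @param ... Unused.
#' @return `tidy()`: the per-subject prediction tibble. `glance()`: one row
#'   with `r`, `r2`, `mse`, `n`, `degenerate`.
#' @export
tidy.fcdyn_krr <- function(x, ...) x$predictions

#' @rdname tidy.fcdyn_krr
#' @export
glance.fcdyn_krr <- function(x, ...) {
  tibble::tibble(r = x$r, r2 = x$r2, mse = x$mse, n = x$n, degenerate = x$degenerate)
}

#' @export
tidy.fcdyn_prediction_set <- function(x, ...) x$summary

#' @export
glance.fcdyn_prediction_set <- function(x, ...) {
  tibble::tibble(
    n_traits = nrow(x$summary),
    mean_r2 = mean(x$summary$r2),
    n_significant = sum(x$summary$p_bonferroni < 0.05)
  )
}
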