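# Time-averaged and time-varying FC summaries derived from a fitted model.

#' Reconstruct the time-averaged FC matrix from a state model
#'
#' The occupancy-weighted average of the state covariance matrices,
#' `sum_k w[k] * Sigma[[k]]`. For a dual-estimated subject model this equals
#' the subject's time-averaged FC (the pooled second-moment matrix of the
#' standardized data, i.e. its correlation matrix up to the `T` divisor)
#' exactly: the state decomposition loses no time-averaged information. For
#' a group-level model the same weighted average is only an approximation
#' (there are fewer states than subjects), and the result is flagged
#' `approximate`.
#'
#' @param model A `fcdyn_hmm` with variant `"fc"`.
#' @param w Fractional occupancies; defaults to the model's own `w` for
#'   subject-level models, must be supplied for group-level models.
#' @return A `J x J` symmetric PSD matrix with attribute `approximate`.
#' @export
reconstruct_time_averaged_fc <- function(model, w = NULL) {
  if (!inherits(model, "fcdyn_hmm")) stopf("`model` must be a fcdyn_hmm")
  if (model$variant != "fc") {
    stopf("time-averaged FC reconstruction is defined for the 'fc' variant, not '%s'", model$variant)
  }
  if (is.null(w)) {
    if (model$level != "subject" || is.null(model$w)) {
      stopf("supply fractional occupancies `w` for a group-level model")
    }
    w <- model$w
  }
  if (length(w) != model$K) stopf("`w` must have length K = %d", model$K)
  out <- Reduce(`+`, Map(`*`, as.list(w), model$covariances))
  attr(out, "approximate") <- model$level == "group"
  out
}

#' Temporal variability of instantaneous FC
#'
#' Builds an instantaneous FC estimate at every timepoint as the
#' gamma-weighted sum of the state covariance matrices, then takes the
#' elementwise variance of these instantaneous estimates across time
#' (population divisor `T`). The result is a `J x J` nonnegative symmetric
#' matrix quantifying, for each region pair, how much its connectivity
#' fluctuates within the session; it is constructed to be unrelated to the
#' time-averaged FC level itself.
#'
#' @param states A variant-`"fc"` `fcdyn_hmm` or a list of `K` state
#'   covariance matrices.
#' @param gamma A `T x K` state time course matrix (e.g. the row-bound
#'   gammas of a subject).
#' @return A `J x J` matrix of per-edge temporal variances.
#' @export
fc_temporal_variability <- function(states, gamma) {
  if (inherits(states, "fcdyn_hmm")) {
    if (states$variant != "fc") stopf("FC temporal variability requires the 'fc' variant")
    states <- states$covariances
  }
  gamma <- as.matrix(gamma)
  if (nrow(gamma) < 2) stopf("need at least 2 timepoints to measure temporal variability")
  K <- length(states)
  if (ncol(gamma) != K) stopf("gamma has %d columns but there are %d states", ncol(gamma), K)
  J <- nrow(states[[1]])
  Cflat <- vapply(states, as.numeric, numeric(J * J)) # J^2 x K
  inst <- gamma %*% t(Cflat) # T x J^2
  v <- col_pop_var(inst)
  sym(matrix(pmax(v, 0), J, J))
}
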