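#' Standardize one scanning session
#'
#' Demeans and scales every parcel (column) of a single session's time series
#' to zero mean and unit sample variance (divisor `T - 1`), the preprocessing
#' applied separately to every scan before any model fitting. Standardization
#' makes subject-level second-moment matrices directly interpretable as
#' Pearson correlation (functional connectivity) matrices.
#'
#' @param raw A numeric `T x J` matrix (timepoints by parcels/components).
#' @param subject_id,session_id Identifiers carried on the returned object.
#' @return A `fcdyn_session` object: the standardized matrix with
#'   `subject_id` and `session_id` attributes.
#' @examples
#' s <- standardize_session(matrix(rnorm(200), 50, 4), "s1", 1)
#' colMeans(s)   # ~0
#' apply(s, 2, var)  # ~1
#' @export
standardize_session <- function(raw, subject_id = "s1", session_id = 1L) {
  raw <- as.matrix(raw)
  if (!is.numeric(raw)) stopf("session data must be numeric")
  if (nrow(raw) < 2) stopf("a session needs at least 2 timepoints, got %d", nrow(raw))
  if (any(!is.finite(raw))) stopf("session data contains non-finite values")
  sds <- apply(raw, 2, stats::sd)
  bad <- which(sds < .Machine$double.eps^0.5 * pmax(1, abs(colMeans(raw))))
  if (length(bad)) {
    stopf("column %s is constant; cannot standardize a zero-variance parcel", bad[1])
  }
  out <- scale(raw, center = TRUE, scale = sds)
  attributes(out)[c("scaled:center", "scaled:scale")] <- NULL
  new_session(out, subject_id, session_id)
}

new_session <- function(data, subject_id, session_id) {
  structure(data,
    subject_id = as.character(subject_id),
    session_id = session_id,
    class = c("fcdyn_session", "matrix", "array")
  )
}

#' @export
print.fcdyn_session <- function(x, ...) {
  cat(sprintf(
    "<fcdyn_session> subject %s, session %s: %d timepoints x %d parcels\n",
    attr(x, "subject_id"), attr(x, "session_id"), nrow(x), ncol(x)
  ))
  invisible(x)
}

session_subject <- function(s) attr(s, "subject_id")
session_id_of <- function(s) attr(s, "session_id")

# validate a list of sessions shares one J and is standardized
check_sessions <- function(sessions) {
  if (!length(sessions)) stopf("no sessions supplied")
  Js <- vapply(sessions, ncol, integer(1))
  if (length(unique(Js)) != 1) stopf("sessions disagree on parcel count J")
  invisible(sessions)
}

#' Read per-session time series from delimited text
#'
#' Expects one CSV per session named `<subject>_<session>.csv` (no header,
#' `T` rows by `J` columns), the plain-text layout mirrored by
#' [write_sessions_csv()]. Sessions are standardized on read.
#'
#' @param dir Directory containing the session files.
#' @return A list of `fcdyn_session` objects, ordered by subject then session.
#' @export
read_sessions_csv <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) stopf("no session CSV files found under %s", dir)
  lapply(files, function(f) {
    nm <- sub("\\.csv$", "", basename(f))
    parts <- strsplit(nm, "_(?=[^_]+$)", perl = TRUE)[[1]]
    raw <- as.matrix(utils::read.csv(f, header = FALSE))
    standardize_session(raw, parts[1], parts[2])
  })
}

#' Write sessions as delimited text
#'
#' @param sessions List of `fcdyn_session` objects.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sessions_csv <- function(sessions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in sessions) {
    f <- file.path(dir, sprintf("%s_%s.csv", session_subject(s), session_id_of(s)))
    utils::write.table(unclass(s), f,
      sep = ",", row.names = FALSE,
      col.names = FALSE
    )
  }
  invisible(dir)
}
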