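# Representation-similarity analysis of trait predictions: how similarly do
# different brain representations explain behaviour, and how reproducible
# are the distance matrices across scanning sessions?

# predictions: long tibble with representation, trait, subject_id, y_hat
check_predictions_tbl <- function(predictions) {
  predictions <- tibble::as_tibble(predictions)
  need <- c("representation", "trait", "subject_id", "y_hat")
  if (!all(need %in% names(predictions))) {
    stopf("`predictions` needs columns %s", paste(need, collapse = ", "))
  }
  predictions
}

# mean over traits of the Pearson correlation between two representations'
# prediction vectors, on a given subset of subjects
pair_similarity <- function(wide_by_trait, rep_a, rep_b, subj_idx = NULL) {
  vals <- vapply(wide_by_trait, function(m) {
    a <- m[, rep_a]
    b <- m[, rep_b]
    if (!is.null(subj_idx)) {
      a <- a[subj_idx]
      b <- b[subj_idx]
    }
    ok <- stats::complete.cases(a, b)
    if (sum(ok) < 3 || stats::sd(a[ok]) < 1e-12 || stats::sd(b[ok]) < 1e-12) {
      return(NA_real_)
    }
    stats::cor(a[ok], b[ok])
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

# reshape the long prediction table into per-trait subject x representation
# matrices for fast resampling
predictions_by_trait <- function(predictions) {
  reps <- sort(unique(predictions$representation))
  subjects <- sort(unique(predictions$subject_id))
  by_trait <- split(predictions, predictions$trait)
  lapply(by_trait, function(df) {
    m <- matrix(NA_real_, length(subjects), length(reps),
      dimnames = list(subjects, reps)
    )
    m[cbind(
      match(df$subject_id, subjects),
      match(df$representation, reps)
    )] <- df$y_hat
    m
  })
}

#' Similarity matrices of trait predictions between representations
#'
#' For each behavioural group, computes a representation-by-representation
#' matrix whose entry (a, b) is the mean, over the group's traits, of the
#' Pearson correlation across subjects between the two representations'
#' out-of-sample predictions. Two representations that predict the traits
#' through the same information yield highly correlated predictions even if
#' their accuracy differs; dissimilar predictions mean largely
#' non-overlapping information about that aspect of behaviour.
#'
#' @param predictions Long tibble with columns `representation`, `trait`,
#'   `subject_id`, `y_hat` (e.g. row-bound from
#'   [predict_traits()]`$predictions` runs with a `representation` column
#'   added).
#' @param groups Named vector mapping trait to behavioural group.
#' @return A `fcdyn_similarity`: tidy tibble `group, rep_a, rep_b,
#'   similarity` with the per-group matrices in `attr(, "matrices")`.
#'   Degenerate (constant) prediction vectors are excluded pairwise from
#'   the mean.
#' @export
prediction_similarity_matrix <- function(predictions, groups) {
  predictions <- check_predictions_tbl(predictions)
  traits <- unique(predictions$trait)
  if (!all(traits %in% names(groups))) stopf("every trait needs a group label")
  reps <- sort(unique(predictions$representation))
  rows <- list()
  mats <- list()
  for (g in unique(unname(groups[traits]))) {
    tr_g <- traits[groups[traits] == g]
    wb <- predictions_by_trait(predictions[predictions$trait %in% tr_g, ])
    m <- matrix(1, length(reps), length(reps), dimnames = list(reps, reps))
    for (i in seq_along(reps)) {
      for (j in seq_along(reps)[-seq_len(i)]) {
        m[i, j] <- m[j, i] <- pair_similarity(wb, reps[i], reps[j])
      }
    }
    mats[[g]] <- m
    idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
    rows[[g]] <- tibble::tibble(
      group = g,
      rep_a = reps[idx[, 1]], rep_b = reps[idx[, 2]],
      similarity = m[idx]
    )
  }
  structure(dplyr::bind_rows(rows), matrices = mats, class = c("fcdyn_similarity", class(tibble::tibble())))
}

#' Bootstrap comparison of two sets of prediction similarities
#'
#' Tests whether one set of representation pairs (e.g. time-averaged FC vs
#' structural) is more similar, in terms of explaining behaviour, than
#' another set (e.g. FC-HMM vs structural). Subjects are resampled with
#' replacement; on each resample the mean prediction correlation is
#' recomputed over each set of pairs, giving a bootstrap density per set and
#' a one-sided p-value for the a-priori direction `mean(A) > mean(B)` with
#' add-one smoothing.
#'
#' @inheritParams prediction_similarity_matrix
#' @param pairs_a,pairs_b Data frames with `rep_a`, `rep_b` columns naming
#'   the representation pairs in each set.
#' @param traits Optional subset of traits (default: all in `predictions`).
#' @param n_boot Bootstrap iterations (>= 1000 recommended; fewer warns).
#' @param seed Integer seed.
#' @return A list: per-set summaries (`mean`, 2.5%/97.5% quantiles,
#'   histogram), the bootstrap draws, the point estimates, and `p`.
#' @export
bootstrap_compare_similarities <- function(predictions, pairs_a, pairs_b,
                                           traits = NULL, n_boot = 10000L,
                                           seed = 1L) {
  predictions <- check_predictions_tbl(predictions)
  if (!is.null(traits)) predictions <- predictions[predictions$trait %in% traits, ]
  if (!nrow(pairs_a) || !nrow(pairs_b)) stopf("both pair sets must be non-empty")
  if (n_boot < 1000) warnf("n_boot = %d is low; densities will be coarse", n_boot)
  wb <- predictions_by_trait(predictions)
  n_subj <- nrow(wb[[1]])
  set_mean <- function(pairs, idx = NULL) {
    mean(vapply(seq_len(nrow(pairs)), function(i) {
      pair_similarity(wb, pairs$rep_a[i], pairs$rep_b[i], idx)
    }, numeric(1)), na.rm = TRUE)
  }
  point_a <- set_mean(pairs_a)
  point_b <- set_mean(pairs_b)
  set.seed(seed)
  # each set gets its own resamples: the two densities are estimated
  # independently, and the test compares them
  draws_a <- numeric(n_boot)
  draws_b <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    draws_a[b] <- set_mean(pairs_a, sample.int(n_subj, replace = TRUE))
    draws_b[b] <- set_mean(pairs_b, sample.int(n_subj, replace = TRUE))
  }
  summarize_draws <- function(x) {
    h <- graphics::hist(x, breaks = 30, plot = FALSE)
    list(
      mean = mean(x), q025 = stats::quantile(x, 0.025, names = FALSE),
      q975 = stats::quantile(x, 0.975, names = FALSE),
      breaks = h$breaks, counts = h$counts
    )
  }
  list(
    point_a = point_a, point_b = point_b,
    summary_a = summarize_draws(draws_a),
    summary_b = summarize_draws(draws_b),
    draws_a = draws_a, draws_b = draws_b,
    p = (1 + sum(draws_a <= draws_b)) / (n_boot + 1)
  )
}

#' Split-half reproducibility of a distance matrix
#'
#' Pearson correlation between the upper-triangle entries of two distance
#' matrices estimated on different halves of the data (e.g. day 1 vs day 2
#' sessions, or first vs second session of each day). Each entry is the
#' distance between one pair of subjects; high correlation means the
#' representation ranks subject dissimilarities reproducibly.
#'
#' @param dm_split1,dm_split2 Distance matrices over the same subjects in
#'   the same order.
#' @return The Pearson correlation across the `N(N-1)/2` subject pairs.
#' @export
split_half_reproducibility <- function(dm_split1, dm_split2) {
  if (!all(dim(dm_split1) == dim(dm_split2))) stopf("distance matrices must share dimensions")
  s1 <- rownames(dm_split1)
  s2 <- rownames(dm_split2)
  if (!is.null(s1) && !is.null(s2) && !identical(s1, s2)) {
    stopf("distance matrices must cover the same subjects in the same order")
  }
  ut <- upper.tri(dm_split1)
  stats::cor(unclass(dm_split1)[ut], unclass(dm_split2)[ut])
}
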