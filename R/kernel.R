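# Trait prediction from distance matrices: Gaussian-kernel ridge regression
# with family-respecting nested cross-validation, CV-safe confound handling,
# cross-validated structural deconfounding, and the associated tests.

#' Gaussian kernel of a distance matrix
#'
#' `H = exp(-(tau * Dist)^2)`, a radial-basis kernel parametrised by the
#' radius `tau`. Whatever representation produced the distances, the kernel
#' (and hence the regression) has the same form and number of parameters,
#' which is what makes modalities comparable.
#'
#' @param dm A `fcdyn_dm` or numeric distance matrix.
#' @param tau Positive kernel radius (units: inverse distance).
#' @return A `fcdyn_kernel` matrix with unit diagonal and entries in (0, 1].
#' @export
gaussian_kernel <- function(dm, tau) {
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0) stopf("tau must be a positive scalar")
  h <- exp(-(tau * unclass(dm))^2)
  structure(sym(h), tau = tau, class = c("fcdyn_kernel", "matrix", "array"))
}

#' Assign whole families to cross-validation folds
#'
#' Greedy size-balanced assignment: families are shuffled (seed-controlled),
#' ordered by decreasing size, and each is placed into the currently
#' smallest fold. Related subjects therefore never straddle a train/test
#' boundary, so familial resemblance cannot leak into the predictions.
#'
#' @param families A data frame with `subject_id` and `family_id` columns
#'   (singleton families allowed).
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return A tibble `subject_id, family_id, fold`; the spread between the
#'   largest and smallest fold never exceeds the largest family size.
#' @export
make_family_folds <- function(families, n_folds = 10L, seed = 1L) {
  families <- tibble::as_tibble(families)
  if (!all(c("subject_id", "family_id") %in% names(families))) {
    stopf("`families` needs subject_id and family_id columns")
  }
  fams <- split(as.character(families$subject_id), as.character(families$family_id))
  if (n_folds > length(fams)) {
    stopf("cannot make %d folds from %d families", n_folds, length(fams))
  }
  set.seed(seed)
  fams <- fams[sample.int(length(fams))]
  fams <- fams[order(-lengths(fams))]
  sizes <- rep(0L, n_folds)
  fold_of <- integer(length(fams))
  for (i in seq_along(fams)) {
    f <- which.min(sizes)
    fold_of[i] <- f
    sizes[f] <- sizes[f] + length(fams[[i]])
  }
  out <- tibble::tibble(
    subject_id = unlist(fams, use.names = FALSE),
    family_id = rep(names(fams), lengths(fams)),
    fold = rep(fold_of, lengths(fams))
  )
  out[match(families$subject_id, out$subject_id), ]
}

# training-fold-only linear confound removal: fit on train, apply to all
confound_adjust <- function(y, confounds, train_idx) {
  X <- cbind(1, as.matrix(confounds))
  fit <- stats::lm.fit(X[train_idx, , drop = FALSE], y[train_idx])
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  y - drop(X %*% beta)
}

# ridge solve for several lambdas at once via one eigendecomposition
ridge_eigen <- function(K_train) {
  e <- eigen(sym(K_train), symmetric = TRUE)
  list(U = e$vectors, d = e$values)
}

ridge_alpha <- function(eg, yc, lambda) {
  denom <- eg$d + lambda
  if (min(denom) <= 1e-10) {
    lambda <- lambda + (1e-10 - min(denom)) + 1e-8
    warnf("kernel system near-singular; raising lambda floor to %.3g", lambda)
    denom <- eg$d + lambda
  }
  drop(eg$U %*% ((crossprod(eg$U, yc)) / denom))
}

#' Kernel ridge regression with family-respecting nested cross-validation
#'
#' Predicts one trait from a subject-by-subject distance matrix. For each
#' outer fold, an inner cross-validation over the training subjects (one
#' inner split per remaining outer fold) selects the ridge penalty `lambda`
#' and kernel radius `tau` jointly by minimum validation error; the model is
#' then refit on the whole training fold and applied to the held-out
#' subjects via the kernel row between test and training subjects. All
#' centering and confound statistics come from training subjects only.
#'
#' @param dm A `fcdyn_dm` (or matrix with subject-id dimnames). May instead
#'   be a named list of distance matrices, one per outer fold, when the
#'   upstream representation itself is re-estimated inside each training
#'   fold.
#' @param y Numeric trait vector, named by subject id (or aligned with the
#'   distance matrix rows); `NA` values drop those subjects for this trait.
#' @param folds Fold assignment from [make_family_folds()].
#' @param lambda_grid Ridge penalties; default 10 log-spaced values in
#'   `[1e-4, 1e3]`.
#' @param tau_grid Kernel radii; default `{0.25, .5, 1, 2, 4, 8}` divided by
#'   the median training-fold distance (distances from divergences carry no
#'   fixed units, so the grid is scale-adaptive).
#' @param confounds Optional numeric matrix of per-subject nuisance
#'   covariates (e.g. motion summaries), regressed out of the trait using
#'   training-fold coefficients only.
#' @return A `fcdyn_krr` object: `predictions` (tibble with `subject_id`,
#'   `fold`, observed `y`, confound-adjusted target `y_target`, and
#'   out-of-sample `y_hat`), `fold_params` (chosen `lambda`/`tau` per
#'   fold), and accuracy summaries (`r`, `r2`, `mse`).
#' @export
krr_predict_cv <- function(dm, y, folds, lambda_grid = NULL, tau_grid = NULL,
                           confounds = NULL) {
  per_fold <- is.list(dm) && !is.matrix(dm)
  dm0 <- if (per_fold) dm[[1]] else dm
  ids <- rownames(dm0) %||% as.character(seq_len(nrow(dm0)))
  if (is.null(names(y))) {
    if (length(y) != length(ids)) stopf("unnamed y must align with the distance matrix")
    names(y) <- ids
  }
  folds <- tibble::as_tibble(folds)
  fold_of <- stats::setNames(folds$fold, as.character(folds$subject_id))
  obs <- ids[!is.na(y[ids]) & ids %in% names(fold_of)]
  if (length(obs) < 20) stopf("need at least 20 observed trait values, got %d", length(obs))
  yv <- y[obs]
  fv <- fold_of[obs]
  lambda_grid <- lambda_grid %||% 10^seq(-4, 3, length.out = 10)
  fold_levels <- sort(unique(fold_of))
  empty <- setdiff(fold_levels, unique(fv))
  if (length(empty)) stopf("fold(s) %s contain no observed trait values", paste(empty, collapse = ", "))
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    rownames(confounds) <- rownames(confounds) %||% ids
  }

  pred <- rep(NA_real_, length(obs))
  target <- rep(NA_real_, length(obs))
  names(pred) <- names(target) <- obs
  fp <- list()
  for (f in fold_levels) {
    D <- unclass(if (per_fold) dm[[as.character(f)]] else dm)[obs, obs]
    test <- which(fv == f)
    train <- which(fv != f)
    ya <- if (is.null(confounds)) {
      yv
    } else {
      confound_adjust(yv, confounds[obs, , drop = FALSE], train)
    }
    target[test] <- ya[test]
    mu <- mean(ya[train])
    yc <- ya[train] - mu
    Dtr <- D[train, train]
    med <- stats::median(Dtr[upper.tri(Dtr)][Dtr[upper.tri(Dtr)] > 0])
    if (!is.finite(med) || med <= 0) med <- 1
    taus <- tau_grid %||% (c(0.25, 0.5, 1, 2, 4, 8) / med)
    # inner CV: leave one remaining outer fold out; with fewer than two
    # remaining folds (possible in reduced designs), chunk the training
    # subjects deterministically instead
    inner_ids <- fv[train]
    if (length(unique(inner_ids)) < 2) {
      inner_ids <- rep_len(seq_len(min(5L, length(train))), length(train))
    }
    inner_levels <- sort(unique(inner_ids))
    sse <- matrix(0, length(taus), length(lambda_grid))
    for (ti in seq_along(taus)) {
      Ktr <- exp(-(taus[ti] * Dtr)^2)
      for (g in inner_levels) {
        val <- which(inner_ids == g)
        tr2 <- which(inner_ids != g)
        mu2 <- mean(ya[train][tr2])
        yc2 <- ya[train][tr2] - mu2
        eg <- ridge_eigen(Ktr[tr2, tr2])
        proj <- crossprod(eg$U, yc2)
        Kval <- Ktr[val, tr2, drop = FALSE] %*% eg$U
        for (li in seq_along(lambda_grid)) {
          yhat <- drop(Kval %*% (proj / pmax(eg$d + lambda_grid[li], 1e-10))) + mu2
          sse[ti, li] <- sse[ti, li] + sum((ya[train][val] - yhat)^2)
        }
      }
    }
    best <- arrayInd(which.min(sse), dim(sse))
    tau <- taus[best[1]]
    lambda <- lambda_grid[best[2]]
    eg <- ridge_eigen(exp(-(tau * Dtr)^2))
    alpha <- ridge_alpha(eg, yc, lambda)
    Ktest <- exp(-(tau * D[test, train, drop = FALSE])^2)
    pred[test] <- drop(Ktest %*% alpha) + mu
    fp[[length(fp) + 1]] <- tibble::tibble(
      fold = f, lambda = lambda, tau = tau,
      n_train = length(train), n_test = length(test),
      min_kernel_eigenvalue = min(eg$d)
    )
  }
  predictions <- tibble::tibble(
    subject_id = obs, fold = unname(fv),
    y = unname(yv), y_target = unname(target), y_hat = unname(pred)
  )
  degenerate <- stats::sd(pred) < 1e-12
  r <- if (degenerate) 0 else stats::cor(pred, target)
  structure(
    list(
      predictions = predictions,
      fold_params = dplyr::bind_rows(fp),
      r = r, r2 = r^2,
      mse = mean((pred - target)^2),
      n = length(obs),
      degenerate = degenerate
    ),
    class = "fcdyn_krr"
  )
}

#' @export
print.fcdyn_krr <- function(x, ...) {
  cat(sprintf(
    "<fcdyn_krr> %d subjects, %d folds: r = %.3f, r2 = %.3f%s\n",
    x$n, nrow(x$fold_params), x$r, x$r2,
    if (x$degenerate) " (degenerate: constant predictions)" else ""
  ))
  invisible(x)
}

#' Cross-validated deconfounding of a trait
#'
#' Predicts the trait from a confound modality (typically a structural
#' distance matrix) with [krr_predict_cv()], and returns the out-of-sample
#' residuals `y - y_hat`. These residuals are the deconfounded trait: what
#' remains of the behavioural variability after discounting what the
#' confound representation can itself predict. Cross-validated residuals are
#' less aggressive and less biased than regressing the confound out in-sample.
#'
#' @inheritParams krr_predict_cv
#' @param confound_dm Distance matrix of the confound modality.
#' @return A named numeric vector of residuals (NA for subjects missing the
#'   trait), with the fitted `fcdyn_krr` attached as attribute `"fit"`.
#' @export
cv_deconfound <- function(y, confound_dm, folds, lambda_grid = NULL,
                          tau_grid = NULL, confounds = NULL) {
  fit <- krr_predict_cv(confound_dm, y, folds, lambda_grid, tau_grid, confounds)
  res <- stats::setNames(rep(NA_real_, length(y)), names(y))
  res[fit$predictions$subject_id] <-
    fit$predictions$y_target - fit$predictions$y_hat
  attr(res, "fit") <- fit
  res
}

#' Accuracy and significance of a cross-validated prediction
#'
#' Explained variance is the squared Pearson correlation between the
#' out-of-sample predictions and the (confound-adjusted) observed trait;
#' its significance is a Student's t-test of the correlation on `n - 2`
#' degrees of freedom, Bonferroni-corrected for the number of traits tested.
#' The signed correlation is reported alongside, since squaring hides
#' anti-correlated predictions.
#'
#' @param result A `fcdyn_krr`.
#' @param n_tests Number of tests for the Bonferroni correction (default 1).
#' @return A one-row tibble: `r2`, `r`, `p`, `p_bonferroni`, `mse`, `n`,
#'   `degenerate`.
#' @export
evaluate_prediction <- function(result, n_tests = 1L) {
  p <- result$predictions
  if (nrow(p) < 3) stopf("need at least 3 prediction/observation pairs")
  if (result$degenerate) {
    return(tibble::tibble(
      r2 = 0, r = 0, p = 1, p_bonferroni = 1,
      mse = result$mse, n = result$n, degenerate = TRUE
    ))
  }
  n <- result$n
  r <- result$r
  tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
  pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
  tibble::tibble(
    r2 = r^2, r = r, p = pval,
    p_bonferroni = min(1, pval * n_tests),
    mse = result$mse, n = n, degenerate = FALSE
  )
}

#' Compare two representations' explained variance across traits
#'
#' Within each behavioural group, the statistic is the mean per-trait
#' difference in explained variance between representations A and B. Its
#' null distribution comes from random sign flips of the paired differences
#' (exchangeability of A and B under the null); the two-sided p-value uses
#' add-one smoothing.
#'
#' @param r2_a,r2_b Per-trait explained variance under each representation
#'   (equal length, paired by trait).
#' @param groups Behavioural group label per trait.
#' @param n_perm Number of sign-flip permutations (default 10000).
#' @param seed Integer seed.
#' @return A tibble with one row per group: `group`, `n_traits`,
#'   `mean_diff`, `p`.
#' @export
compare_representations <- function(r2_a, r2_b, groups, n_perm = 10000L, seed = 1L) {
  if (length(r2_a) != length(r2_b) || length(r2_a) != length(groups)) {
    stopf("r2_a, r2_b and groups must have equal length")
  }
  set.seed(seed)
  purrr::map_dfr(split(seq_along(groups), groups), function(idx) {
    if (length(idx) < 2) stopf("group '%s' has fewer than 2 traits", groups[idx[1]])
    d <- r2_a[idx] - r2_b[idx]
    obs <- mean(d)
    flips <- matrix(sample(c(-1, 1), n_perm * length(d), replace = TRUE), n_perm)
    null <- drop(flips %*% d) / length(d)
    tibble::tibble(
      group = as.character(groups[idx[1]]),
      n_traits = length(idx),
      mean_diff = obs,
      p = (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
    )
  })
}

#' Predict a table of traits from one distance matrix
#'
#' Tidy wrapper around [krr_predict_cv()]: one row of results per trait
#' column. Folds are rebuilt per trait on the subjects observed for that
#' trait (families still never split); optional cross-validated structural
#' deconfounding and motion confounds are applied per trait.
#'
#' @param dm A `fcdyn_dm` (or per-fold list, see [krr_predict_cv()]).
#' @param traits Data frame with `subject_id` and one numeric column per
#'   trait (NA = missing).
#' @param families Data frame with `subject_id`, `family_id`.
#' @param n_folds,seed Fold construction parameters.
#' @param folds Optional precomputed fold assignment shared across traits
#'   (used by the pipeline so all representations and traits see the same
#'   partition); when `NULL`, folds are rebuilt per trait on the observed
#'   subjects.
#' @param deconfound_dm Optional confound distance matrix; traits are
#'   replaced by their cross-validated residuals before prediction.
#' @param confounds Optional per-subject motion covariate matrix (rownames =
#'   subject ids).
#' @param n_tests Bonferroni denominator; defaults to the number of traits.
#' @param groups Optional named vector of behavioural group labels per trait,
#'   carried into the summary.
#' @param ... Passed to [krr_predict_cv()].
#' @return A `fcdyn_prediction_set`: `summary` tibble (per trait: `r2`,
#'   `r`, `p_bonferroni`, selected parameters), `predictions` tibble in long
#'   form, and the per-trait `fcdyn_krr` fits.
#' @export
predict_traits <- function(dm, traits, families, n_folds = 10L, seed = 1L,
                           folds = NULL, deconfound_dm = NULL, confounds = NULL,
                           n_tests = NULL, groups = NULL, ...) {
  traits <- tibble::as_tibble(traits)
  trait_names <- setdiff(names(traits), "subject_id")
  n_tests <- n_tests %||% length(trait_names)
  fits <- list()
  summaries <- list()
  preds <- list()
  for (tn in trait_names) {
    y <- stats::setNames(traits[[tn]], as.character(traits$subject_id))
    if (is.null(folds)) {
      fam_obs <- families[as.character(families$subject_id) %in% names(y)[!is.na(y)], ]
      trait_folds <- make_family_folds(fam_obs, n_folds, seed)
    } else {
      trait_folds <- folds
    }
    if (!is.null(deconfound_dm)) {
      y <- cv_deconfound(y, deconfound_dm, trait_folds, confounds = confounds)
      attr(y, "fit") <- NULL
      fit <- krr_predict_cv(dm, y, trait_folds, ...)
    } else {
      fit <- krr_predict_cv(dm, y, trait_folds, confounds = confounds, ...)
    }
    ev <- evaluate_prediction(fit, n_tests)
    fits[[tn]] <- fit
    summaries[[tn]] <- dplyr::mutate(ev,
      trait = tn,
      group = if (!is.null(groups)) unname(groups[tn]) else NA_character_,
      .before = 1
    )
    preds[[tn]] <- dplyr::mutate(fit$predictions, trait = tn, .before = 1)
  }
  structure(
    list(
      summary = dplyr::bind_rows(summaries),
      predictions = dplyr::bind_rows(preds),
      fits = fits
    ),
    class = "fcdyn_prediction_set"
  )
}

#' @export
print.fcdyn_prediction_set <- function(x, ...) {
  cat(sprintf("<fcdyn_prediction_set> %d traits\n", nrow(x$summary)))
  print(x$summary, ...)
  invisible(x)
}
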