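test_that("the Gaussian kernel evaluates correctly and scales in tau as in distance", {
  d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  h <- gaussian_kernel(d, 1)
  expect_equal(diag(unclass(h)), c(a = 1, b = 1))
  expect_equal(h[1, 2], exp(-1), tolerance = 1e-12)
  expect_equal(
    unclass(gaussian_kernel(d, 2))[, ], unclass(gaussian_kernel(2 * d, 1))[, ],
    tolerance = 1e-12, ignore_attr = TRUE
  )
  expect_error(gaussian_kernel(d, 0), "positive")
})

test_that("family folds never split families, balance sizes, and are seed-deterministic", {
  fam <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:20),
    family_id = c(rep("f1", 4), sprintf("f%d", 2:17))
  )
  folds <- make_family_folds(fam, n_folds = 5, seed = 3)
  expect_equal(dplyr::n_distinct(folds$fold[folds$family_id == "f1"]), 1L)
  tab <- table(folds$fold)
  expect_lte(max(tab) - min(tab), 4)
  folds2 <- make_family_folds(fam, n_folds = 5, seed = 3)
  expect_identical(folds, folds2)
  # singleton families spread one per fold
  singles <- tibble::tibble(subject_id = letters[1:10], family_id = letters[1:10])
  f10 <- make_family_folds(singles, n_folds = 10, seed = 1)
  expect_equal(sort(unique(f10$fold)), 1:10)
  expect_equal(unname(table(f10$fold))[1], 1L)
  expect_error(make_family_folds(singles, n_folds = 11), "11 folds")
})

test_that("KRR matches the closed-form alpha = h (H + lambda I)^-1 and the large-lambda ridge limit", {
  # fixed (lambda, tau): test-fold predictions must equal the directly
  # assembled kernel ridge solution on the training fold
  set.seed(4)
  n <- 24
  ids <- sprintf("s%02d", 1:n)
  d <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  dimnames(d) <- list(ids, ids)
  y <- setNames(rnorm(n), ids)
  folds <- tibble::tibble(
    subject_id = ids, family_id = ids,
    fold = rep(1:2, each = 12)
  )
  tau <- 1.1
  lambda <- 0.5
  fit <- krr_predict_cv(d, y, folds, lambda_grid = lambda, tau_grid = tau)
  tr <- ids[folds$fold == 1]
  te <- ids[folds$fold == 2]
  mu <- mean(y[tr])
  H <- exp(-(tau * d[tr, tr])^2)
  h <- exp(-(tau * d[te, tr])^2)
  yhat <- drop(h %*% solve(H + lambda * diag(length(tr)), y[tr] - mu)) + mu
  got <- fit$predictions$y_hat[match(te, fit$predictions$subject_id)]
  expect_equal(got, unname(yhat), tolerance = 1e-8)
  # the single-training-subject closed form collapses to
  # y_hat = mu + (y1 - mu) * exp(-(tau d)^2) / (1 + lambda) = y1-independent
  # center: verified directly on the 1 x 1 algebra
  y1 <- 0.7
  d1 <- 0.4
  alpha <- (y1 - y1) / (1 + lambda) # centered target is zero
  expect_equal(alpha * exp(-(tau * d1)^2) + y1, y1)

  # ridge limit: enormous lambda pushes every prediction to the training mean
  set.seed(1)
  n <- 30
  dmat <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  dimnames(dmat) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
  yy <- setNames(rnorm(n), rownames(dmat))
  fspec <- tibble::tibble(
    subject_id = rownames(dmat), family_id = rownames(dmat),
    fold = rep(1:3, each = 10)
  )
  fit_inf <- krr_predict_cv(dmat, yy, fspec, lambda_grid = 1e8, tau_grid = 1)
  for (f in 1:3) {
    test <- fit_inf$predictions$fold == f
    mu_f <- mean(yy[fspec$subject_id[fspec$fold != f]])
    expect_lt(max(abs(fit_inf$predictions$y_hat[test] - mu_f)), 1e-4)
  }
})

test_that("nested-CV KRR recovers signal carried by the distance-generating latent", {
  set.seed(5)
  n <- 200
  latent <- sort(rnorm(n))
  ids <- sprintf("s%03d", 1:n)
  dmat <- as.matrix(dist(latent))
  dimnames(dmat) <- list(ids, ids)
  y <- setNames(tanh(latent) + rnorm(n, sd = 0.5 * sd(tanh(latent))), ids)
  fam <- tibble::tibble(subject_id = ids, family_id = ids)
  folds <- make_family_folds(fam, 10, seed = 2)
  fit <- krr_predict_cv(dmat, y, folds)
  expect_gt(fit$r2, 0.3)
  # subject-order invariance
  perm <- sample(n)
  fit_p <- krr_predict_cv(dmat[perm, perm], y[perm], folds)
  m <- match(fit$predictions$subject_id, fit_p$predictions$subject_id)
  expect_equal(fit$predictions$y_hat, fit_p$predictions$y_hat[m], tolerance = 1e-8)
})

test_that("no information leaks from test folds: poisoned test labels leave predictions unchanged", {
  set.seed(6)
  n <- 60
  ids <- sprintf("s%03d", 1:n)
  dmat <- as.matrix(dist(matrix(rnorm(n * 3), n)))
  dimnames(dmat) <- list(ids, ids)
  y <- setNames(rnorm(n), ids)
  conf <- matrix(rnorm(n * 2), n, dimnames = list(ids, c("m1", "m2")))
  fam <- tibble::tibble(subject_id = ids, family_id = ids)
  folds <- make_family_folds(fam, 5, seed = 1)
  fit <- krr_predict_cv(dmat, y, folds, confounds = conf)
  test1 <- folds$subject_id[folds$fold == 1]
  y_poison <- y
  y_poison[test1] <- y_poison[test1] + 1e6
  fit_p <- krr_predict_cv(dmat, y_poison, folds, confounds = conf)
  keep <- fit$predictions$fold == 1
  expect_equal(
    fit$predictions$y_hat[keep], fit_p$predictions$y_hat[keep],
    tolerance = 1e-8
  )
})

test_that("cross-validated deconfounding removes structural signal and preserves unrelated traits", {
  set.seed(8)
  n <- 200
  ids <- sprintf("s%03d", 1:n)
  latent <- matrix(rnorm(n * 3), n)
  struct <- cbind(latent %*% matrix(rnorm(3 * 20), 3), 0.2 * matrix(rnorm(n * 20), n))
  rownames(struct) <- ids
  sdm <- build_distance_matrix(struct, "structural", subject_ids = ids)
  fam <- tibble::tibble(subject_id = ids, family_id = ids)
  folds <- make_family_folds(fam, 10, seed = 4)

  # trait independent of structure: residuals stay close to the trait
  y_free <- setNames(rnorm(n), ids)
  res_free <- cv_deconfound(y_free, sdm, folds)
  expect_gt(cor(res_free, y_free), 0.9)

  # trait = smooth noiseless function of the structural latent: nothing left
  y_struct <- setNames(drop(tanh(latent %*% c(1, -0.5, 0.25))), ids)
  res_struct <- cv_deconfound(y_struct, sdm, folds)
  fit_after <- krr_predict_cv(sdm, res_struct, folds)
  expect_lt(fit_after$r2, 0.05)

  # all-identical subjects: constant prediction, residuals = centered target
  dm0 <- matrix(0, n, n, dimnames = list(ids, ids))
  res0 <- cv_deconfound(y_free, dm0, folds)
  fitted0 <- attr(res0, "fit")
  expect_true(fitted0$degenerate ||
    sd(fitted0$predictions$y_hat) < sd(y_free) / 20)
})

test_that("prediction evaluation reports squared Pearson with its sign caveat and calibrated t-test", {
  mk <- function(yhat, y) {
    structure(
      list(
        predictions = tibble::tibble(
          subject_id = sprintf("s%02d", seq_along(y)),
          fold = 1, y = y, y_target = y, y_hat = yhat
        ),
        r = if (sd(yhat) < 1e-12) 0 else cor(yhat, y),
        r2 = if (sd(yhat) < 1e-12) 0 else cor(yhat, y)^2,
        mse = mean((yhat - y)^2), n = length(y),
        degenerate = sd(yhat) < 1e-12
      ),
      class = "fcdyn_krr"
    )
  }
  y <- rnorm(40)
  expect_equal(evaluate_prediction(mk(y, y))$r2, 1)
  anti <- evaluate_prediction(mk(-y, y))
  expect_equal(anti$r2, 1)
  expect_equal(anti$r, -1)
  degen <- evaluate_prediction(mk(rep(1, 40), y))
  expect_true(degen$degenerate)
  expect_equal(degen$r2, 0)
  # Bonferroni: p multiplied by the number of tests, capped at one
  one <- evaluate_prediction(mk(y + rnorm(40), y), n_tests = 10)
  expect_equal(one$p_bonferroni, min(1, one$p * 10))

  # null calibration of the t-test (modest replicate count; the acceptance
  # suite runs the full calibration)
  set.seed(9)
  rej <- mean(replicate(400, {
    a <- rnorm(50)
    b <- rnorm(50)
    evaluate_prediction(mk(a, b))$p < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("sign-flip group comparison: identity, separation bound, and error on tiny groups", {
  r2a <- rep(0.2, 10)
  same <- compare_representations(r2a, r2a, rep("g", 10), n_perm = 2000, seed = 1)
  expect_equal(same$mean_diff, 0)
  expect_gt(same$p, 0.9)
  shifted <- compare_representations(r2a + 0.1, r2a, rep("g", 10), n_perm = 2000, seed = 1)
  expect_lte(shifted$p, 2 * (1 + 2000 * 2^-10) / 2001)
  expect_error(
    compare_representations(1:3 / 10, 1:3 / 10, c("g", "g", "h"), n_perm = 1000),
    "fewer than 2"
  )
})
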