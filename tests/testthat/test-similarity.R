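make_pred_tbl <- function(mat_by_rep, traits = "t1") {
  # mat_by_rep: named list of subject x trait matrices of predictions
  purrr::map_dfr(names(mat_by_rep), function(rep) {
    m <- mat_by_rep[[rep]]
    purrr::map_dfr(seq_along(traits), function(j) {
      tibble::tibble(
        representation = rep, trait = traits[j],
        subject_id = rownames(m), y_hat = m[, j]
      )
    })
  })
}

test_that("prediction similarity: self-correlation one, duplicates one, independent near zero", {
  set.seed(2)
  n <- 500
  ids <- sprintf("s%03d", 1:n)
  a <- matrix(rnorm(n), n, 1, dimnames = list(ids, NULL))
  b <- matrix(rnorm(n), n, 1, dimnames = list(ids, NULL))
  tbl <- make_pred_tbl(list(A = a, A2 = a, B = b))
  sim <- prediction_similarity_matrix(tbl, c(t1 = "g"))
  m <- attr(sim, "matrices")$g
  expect_equal(diag(m), c(A = 1, A2 = 1, B = 1))
  expect_equal(m["A", "A2"], 1, tolerance = 1e-10)
  expect_lt(abs(m["A", "B"]), 0.1)
  expect_equal(unclass(m), t(unclass(m)))
  # invariance to consistent subject reordering
  perm <- sample(n)
  tbl_p <- make_pred_tbl(list(A = a[perm, , drop = FALSE], A2 = a[perm, , drop = FALSE], B = b[perm, , drop = FALSE]))
  sim_p <- prediction_similarity_matrix(tbl_p, c(t1 = "g"))
  expect_equal(attr(sim_p, "matrices")$g, m, tolerance = 1e-10)
})

test_that("degenerate constant predictions are excluded pairwise from the group mean", {
  n <- 50
  ids <- sprintf("s%02d", 1:n)
  a <- cbind(rnorm(n), rnorm(n))
  rownames(a) <- ids
  b <- a + 0.1 * matrix(rnorm(2 * n), n)
  const <- a
  const[, 2] <- 1 # constant prediction for trait 2
  tbl <- make_pred_tbl(list(A = a, B = b, C = const), traits = c("t1", "t2"))
  sim <- prediction_similarity_matrix(tbl, c(t1 = "g", t2 = "g"))
  m <- attr(sim, "matrices")$g
  # A-C mean uses only trait 1 (trait 2 pair is dropped as degenerate)
  expect_equal(m["A", "C"], cor(a[, 1], const[, 1]), tolerance = 1e-10)
})

test_that("bootstrap comparison is symmetric under identical sets and separates shifted sets", {
  set.seed(3)
  n <- 120
  ids <- sprintf("s%03d", 1:n)
  base <- rnorm(n)
  noisy <- function(r) {
    m <- cbind(r * base + sqrt(1 - r^2) * rnorm(n))
    rownames(m) <- ids
    m
  }
  tbl <- make_pred_tbl(list(
    X1 = noisy(.9), X2 = noisy(.9), Y1 = noisy(.2), Y2 = noisy(.2)
  ))
  pairs_high <- tibble::tibble(rep_a = "X1", rep_b = "X2")
  pairs_low <- tibble::tibble(rep_a = "Y1", rep_b = "Y2")
  # identical sets: p near one half
  same <- bootstrap_compare_similarities(tbl, pairs_high, pairs_high,
    n_boot = 2000, seed = 1
  )
  expect_gt(same$p, 0.4)
  expect_lt(same$p, 0.6)
  # well-separated sets: p at the add-one floor
  sep <- bootstrap_compare_similarities(tbl, pairs_high, pairs_low,
    n_boot = 2000, seed = 1
  )
  expect_lte(sep$p, 2 / 2001)
  # bootstrap mean close to the point estimate
  expect_lt(abs(sep$summary_a$mean - sep$point_a), 2 * sd(sep$draws_a))
  expect_warning(
    bootstrap_compare_similarities(tbl, pairs_high, pairs_low, n_boot = 500, seed = 1),
    "low"
  )
})

test_that("split-half reproducibility: identity, noise attenuation, and independence", {
  set.seed(4)
  n <- 60
  ids <- sprintf("s%02d", 1:n)
  base <- as.matrix(dist(matrix(rnorm(n * 3), n)))
  dimnames(base) <- list(ids, ids)
  dm1 <- fcdyn:::new_dm(base, "avfc")
  expect_equal(split_half_reproducibility(dm1, dm1), 1)
  # additive independent noise of equal variance attenuates r to ~ 1/sqrt(2)
  ut <- upper.tri(base)
  s <- sd(base[ut])
  noise_m <- function(seed) {
    set.seed(seed)
    nm <- matrix(0, n, n)
    nm[ut] <- rnorm(sum(ut), sd = s)
    nm + t(nm)
  }
  rs <- vapply(1:20, function(i) {
    split_half_reproducibility(dm1, fcdyn:::new_dm(base + noise_m(i), "avfc"))
  }, numeric(1))
  expect_equal(mean(rs), 1 / sqrt(2), tolerance = 0.05)
  # independent matrices: near zero
  ind <- abs(split_half_reproducibility(
    fcdyn:::new_dm(noise_m(7) - min(noise_m(7)), "avfc"),
    fcdyn:::new_dm(noise_m(8) - min(noise_m(8)), "avfc")
  ))
  expect_lt(ind, 0.15)
  expect_error(
    split_half_reproducibility(dm1, fcdyn:::new_dm(base[-1, -1], "avfc")),
    "dimensions"
  )
})
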