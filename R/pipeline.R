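# End-to-end driver: simulate-or-load -> fit (x repetitions) -> dual-estimate
# -> distance matrices -> predictions (raw + deconfounded) -> comparisons ->
# representation similarity. Structural prediction feeds cross-validated
# residuals into the functional predictions.

#' Time-averaged FC matrices of a cohort
#'
#' One correlation (= second-moment, for standardized data) matrix per
#' subject, pooled over that subject's sessions with the `T` divisor.
#'
#' @param sessions List of standardized sessions.
#' @return Named list of `J x J` matrices, one per subject.
#' @export
time_averaged_fc <- function(sessions) {
  check_sessions(sessions)
  ids <- vapply(sessions, session_subject, character(1))
  lapply(split(sessions, factor(ids, levels = unique(sort(ids)))), function(ss) {
    X <- do.call(rbind, lapply(ss, unclass))
    sym(crossprod(X) / nrow(X))
  })
}

#' Per-fold group models and distance matrices
#'
#' The conservative cross-validation variant: the group-level model is refit
#' on each outer training fold's sessions only, then every subject (training
#' and test) is dual-estimated from that fold's group model, giving one
#' distance matrix per fold. Test subjects never influence the group states
#' used to embed them.
#'
#' @param sessions All sessions of the cohort.
#' @param folds Fold assignment from [make_family_folds()].
#' @param K,variant,seed,... Passed to [fit_group_hmm()].
#' @return A list with `dms` (named list of `fcdyn_dm`, one per fold, usable
#'   as the `dm` argument of [krr_predict_cv()]) and `models` (the per-fold
#'   group fits).
#' @export
fold_hmm_dms <- function(sessions, folds, K = 8L, variant = "fc", seed = 1L, ...) {
  check_sessions(sessions)
  ids <- vapply(sessions, session_subject, character(1))
  dms <- list()
  models <- list()
  for (f in sort(unique(folds$fold))) {
    train_ids <- as.character(folds$subject_id[folds$fold != f])
    fit <- fit_group_hmm(sessions[ids %in% train_ids],
      K = K, variant = variant, seed = seed, ...
    )
    duals <- dual_estimate_cohort(fit, sessions)
    dms[[as.character(f)]] <- build_distance_matrix(duals, "hmm")
    models[[as.character(f)]] <- fit
  }
  list(dms = dms, models = models)
}

#' Load a run configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A named list suitable for [run_pipeline()].
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stopf("configuration must be YAML or JSON: %s", path)
  }
}

pipeline_defaults <- function() {
  list(
    cohort = list(),
    K = 8L, variants = "fc", repetitions = 5L,
    hmm_scope = "fold", # "fold": refit group model per training fold
    n_folds = 10L,
    lambda_grid = NULL, tau_grid = NULL,
    deconfound = "none", # any of none, FA, MD, VBM
    motion = FALSE,
    n_perm = 10000L, n_boot = 2000L,
    seed = 1L, out_dir = NULL
  )
}

#' Run the full comparison pipeline
#'
#' Executes the whole analysis on a synthetic cohort (or sessions loaded
#' from disk): repeated group-model fits, dual estimation, distance matrices
#' for every representation (time-averaged FC, each state-model repetition,
#' and the three structural measures), kernel ridge regression predictions
#' of every trait — raw and structure-deconfounded — per-group permutation
#' comparisons of the state model against time-averaged FC, and the
#' representation-similarity matrices of the predictions. Every stage is
#' seeded from the configuration, so a rerun with the same configuration
#' reproduces the outputs.
#'
#' @param config A named list (missing entries take defaults), or a path to
#'   a YAML/JSON file. Main entries: `cohort` (arguments to
#'   [cohort_spec()], or `sessions_dir`/`traits_csv`/`families_csv` paths),
#'   `K`, `variants` (subset of fc/mean/var), `repetitions`, `hmm_scope`
#'   (`"fold"` refits the group model inside each training fold; `"cohort"`
#'   fits once on everyone, defensible because the fit never sees the
#'   traits), `n_folds`, `deconfound` (`"none"` or any of FA/MD/VBM),
#'   `motion`, `n_perm`, `n_boot`, `seed`, `out_dir`.
#' @return A `fcdyn_pipeline` list: the cohort, distance matrices,
#'   prediction sets (`$predictions$raw` and per-deconfound), group
#'   comparisons, similarity object, and a manifest echoing configuration,
#'   seeds and stage timings.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage, start) {
    timings[[stage]] <<- round(as.numeric(difftime(Sys.time(), start, units = "secs")), 2)
  }

  # --- data -----------------------------------------------------------------
  st <- Sys.time()
  if (!is.null(cfg$cohort$sessions_dir)) {
    sessions <- read_sessions_csv(cfg$cohort$sessions_dir)
    traits <- tibble::as_tibble(utils::read.csv(cfg$cohort$traits_csv))
    families <- tibble::as_tibble(utils::read.csv(cfg$cohort$families_csv))
    trait_groups <- NULL
    if (!is.null(cfg$cohort$groups_csv)) {
      g <- utils::read.csv(cfg$cohort$groups_csv)
      trait_groups <- stats::setNames(g$group, g$trait)
    }
    structural <- NULL
    motion <- NULL
    cohort <- NULL
  } else {
    cohort_args <- cfg$cohort
    cohort_args$seed <- cohort_args$seed %||% cfg$seed
    cohort <- generate_cohort(do.call(cohort_spec, cohort_args))
    sessions <- cohort$sessions
    traits <- cohort$traits
    families <- cohort$families
    trait_groups <- cohort$trait_groups
    structural <- cohort$structural
    motion <- cohort$motion
  }
  tick("data", st)

  folds <- make_family_folds(families, cfg$n_folds, cfg$seed)
  confounds <- if (isTRUE(cfg$motion)) motion else NULL

  # --- distance matrices ----------------------------------------------------
  st <- Sys.time()
  dms <- list()
  dms$avfc <- build_distance_matrix(time_averaged_fc(sessions), "avfc")
  if (!is.null(structural)) {
    for (m in c("FA", "MD", "VBM")) {
      dms[[m]] <- build_distance_matrix(structural[[m]], "structural")
    }
  }
  models <- list()
  for (v in cfg$variants) {
    for (r in seq_len(cfg$repetitions)) {
      label <- sprintf("%s-hmm-%d", v, r)
      seed_r <- cfg$seed + r - 1L
      if (identical(cfg$hmm_scope, "fold")) {
        fh <- fold_hmm_dms(sessions, folds, K = cfg$K, variant = v, seed = seed_r)
        dms[[label]] <- fh$dms
        models[[label]] <- fh$models
      } else {
        fit <- fit_group_hmm(sessions, K = cfg$K, variant = v, seed = seed_r)
        duals <- dual_estimate_cohort(fit, sessions)
        dms[[label]] <- build_distance_matrix(duals, "hmm")
        models[[label]] <- fit
      }
    }
  }
  tick("distance_matrices", st)

  # --- predictions ----------------------------------------------------------
  st <- Sys.time()
  run_predictions <- function(deconfound_dm) {
    out <- list()
    for (label in names(dms)) {
      out[[label]] <- predict_traits(
        dms[[label]], traits, families,
        n_folds = cfg$n_folds, seed = cfg$seed,
        folds = folds,
        deconfound_dm = deconfound_dm, confounds = confounds,
        groups = trait_groups,
        lambda_grid = cfg$lambda_grid, tau_grid = cfg$tau_grid
      )
    }
    out
  }
  predictions <- list(raw = run_predictions(NULL))
  for (m in setdiff(cfg$deconfound, "none")) {
    if (is.null(dms[[m]])) stopf("deconfounding by %s requires structural features", m)
    predictions[[paste0("deconf_", m)]] <- run_predictions(dms[[m]])
  }
  tick("predictions", st)

  # --- comparisons: state model vs time-averaged FC per behavioural group ---
  st <- Sys.time()
  comparisons <- NULL
  hmm_labels <- grep("^fc-hmm-", names(dms), value = TRUE)
  if (length(hmm_labels) && !is.null(trait_groups)) {
    comparisons <- purrr::map_dfr(names(predictions), function(layer) {
      purrr::map_dfr(hmm_labels, function(label) {
        a <- predictions[[layer]][[label]]$summary
        b <- predictions[[layer]][["avfc"]]$summary
        dplyr::mutate(
          compare_representations(
            a$r2, b$r2, unname(trait_groups[a$trait]),
            n_perm = cfg$n_perm, seed = cfg$seed
          ),
          layer = layer, representation = label, .before = 1
        )
      })
    })
  }
  tick("comparisons", st)

  # --- representation similarity --------------------------------------------
  st <- Sys.time()
  similarity <- NULL
  if (!is.null(trait_groups)) {
    long <- purrr::map_dfr(names(predictions$raw), function(label) {
      dplyr::mutate(predictions$raw[[label]]$predictions, representation = label)
    })
    similarity <- prediction_similarity_matrix(long, trait_groups)
  }
  tick("similarity", st)

  manifest <- list(
    package_version = as.character(utils::packageVersion("fcdyn")),
    config = cfg[setdiff(names(cfg), "out_dir")],
    hmm_seeds = if (cfg$repetitions > 0) cfg$seed + seq_len(cfg$repetitions) - 1L else integer(0),
    fold_seed = cfg$seed,
    timings_sec = timings,
    total_sec = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
  )

  result <- structure(
    list(
      cohort = cohort, dms = dms, models = models, folds = folds,
      predictions = predictions, comparisons = comparisons,
      similarity = similarity, manifest = manifest
    ),
    class = "fcdyn_pipeline"
  )
  if (!is.null(cfg$out_dir)) write_pipeline(result, cfg$out_dir)
  result
}

#' @export
print.fcdyn_pipeline <- function(x, ...) {
  cat(sprintf(
    "<fcdyn_pipeline> %d representations, %d prediction layers, %.1f s total\n",
    length(x$dms), length(x$predictions), x$manifest$total_sec
  ))
  invisible(x)
}

#' Write pipeline outputs to disk
#'
#' Distance matrices and prediction tables as CSV, comparisons/similarity
#' as CSV, the manifest as JSON.
#'
#' @param result A `fcdyn_pipeline`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (label in names(result$dms)) {
    dm <- result$dms[[label]]
    if (is.list(dm) && !is.matrix(dm)) dm <- dm[[1]] # fold-scope: first fold shown
    write_dm_csv(dm, file.path(dir, sprintf("dm_%s.csv", label)))
  }
  for (layer in names(result$predictions)) {
    summ <- purrr::map_dfr(names(result$predictions[[layer]]), function(label) {
      dplyr::mutate(result$predictions[[layer]][[label]]$summary, representation = label)
    })
    utils::write.csv(summ, file.path(dir, sprintf("predictions_%s.csv", layer)), row.names = FALSE)
  }
  if (!is.null(result$comparisons)) {
    utils::write.csv(result$comparisons, file.path(dir, "comparisons.csv"), row.names = FALSE)
  }
  if (!is.null(result$similarity)) {
    utils::write.csv(as.data.frame(result$similarity), file.path(dir, "similarity.csv"),
      row.names = FALSE
    )
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(dir)
}
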