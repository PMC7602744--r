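# Project learning curve: hold human projects out of training and measure
# accuracy on them as a function of how many human projects the training set
# contains. A curve that rises steeply with the number of training projects
# diagnoses study-level overfitting; its plateau height estimates how well
# the model transfers to unseen studies.

#' Learning-curve configuration
#'
#' With N human projects, training combinations of size n are drawn from the
#' first N - 1 projects (one project is always reserved for testing, so the
#' held-out set is never empty), capped at `min(cap, choose(N - 1, n))`
#' distinct combinations per n. Each combination is resampled `resamples`
#' times. Defaults are the full-scale protocol (cap 200, 5 resamples);
#' desk-scale runs use `cap = 20, resamples = 2`.
#'
#' @param n_range which n to evaluate; default `1:(N - 1)` at run time.
#' @param cap maximum combinations per n (default 200).
#' @param resamples training-set redraws per combination (default 5).
#' @param per_class training samples per class; defaults to the pet pool
#'   size at run time.
#' @param seed integer seed.
#' @return a `learning_curve_config` list.
#' @export
learning_curve_config <- function(n_range = NULL, cap = 200, resamples = 5,
                                  per_class = NULL, seed = 1) {
  if (cap < 1 || resamples < 1) {
    abort2("cap and resamples must be >= 1", "hostclass_bad_arg")
  }
  structure(
    list(n_range = n_range, cap = cap, resamples = resamples,
         per_class = per_class, seed = seed),
    class = "learning_curve_config"
  )
}

#' Enumerate training-project combinations
#'
#' All `choose(N - 1, n)` combinations when that is at most `cap`, otherwise
#' `cap` distinct combinations sampled uniformly without replacement.
#'
#' @param N number of human projects.
#' @param n combination size, `1 <= n <= N - 1`.
#' @param cap maximum number of combinations.
#' @param seed integer seed.
#' @return list of integer vectors (indices into `1:(N - 1)`).
#' @export
enumerate_combinations <- function(N, n, cap = 200, seed = 1) {
  if (n < 1 || n > N - 1) {
    abort2(sprintf("n must be in 1..%d, got %d", N - 1, n),
           "hostclass_bad_arg")
  }
  total <- choose(N - 1, n)
  if (total <= cap) {
    m <- combn(N - 1, n)
    return(lapply(seq_len(ncol(m)), function(j) m[, j]))
  }
  withr::with_seed(derive_seed(seed, paste("combos", N, n)), {
    seen <- new.env(parent = emptyenv())
    out <- vector("list", cap)
    k <- 0L
    while (k < cap) {
      combo <- sort(sample.int(N - 1, n))
      key <- paste(combo, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        k <- k + 1L
        out[[k]] <- combo
      }
    }
    out
  })
}

#' Run the project learning curve
#'
#' The pet side of every training set is the full pet pool. For each n, each
#' project combination and each resample, the human side is drawn from the
#' combination's projects with replacement, project-balanced, up to
#' `per_class` samples; a forest is trained with the supplied (frozen)
#' hyperparameters and plain accuracy is measured on every human project
#' absent from training. Hyperparameters are not re-searched per resample.
#'
#' @param table a rare-filtered [feature_table()].
#' @param metadata aligned sample metadata.
#' @param params hyperparameters (`mtry`, `depth`, `min_split`, `trees`),
#'   e.g. from [two_step_param_search()].
#' @param chao named per-sample Chao1 values; computed via [table_chao()]
#'   when `NULL`.
#' @param config a [model_config()] (feature mode / CLR for the design).
#' @param mw_set optional restricted taxon set.
#' @param lc a [learning_curve_config()].
#' @return a `learning_curve_result`: `records` data frame with one row per
#'   (n, combination, resample, held-out project) and fields `accuracy`,
#'   `n_test`; plus `human_projects` and the configs.
#' @export
run_learning_curve <- function(table, metadata, params, chao = NULL,
                               config = model_config(), mw_set = NULL,
                               lc = learning_curve_config()) {
  metadata <- align_table_metadata(table, validate_metadata(metadata))
  if (is.null(chao)) {
    chao <- table_chao(table, depth = min(rowSums(table$counts)),
                       seed = lc$seed)
  }
  design <- assemble_design(table, metadata, chao, config, mw_set = mw_set)
  x <- design$x
  y <- design$y
  ids <- rownames(x)
  human_projects <- unique(metadata$project_id[metadata$host == "human"])
  N <- length(human_projects)
  if (N < 2L) {
    abort2("need at least 2 human projects", "hostclass_bad_arg")
  }
  pet_idx <- which(metadata$host == "pet")
  per_class <- as.integer(lc$per_class %||% length(pet_idx))
  n_range <- lc$n_range %||% seq_len(N - 1L)
  hum_ids_by_project <- split(metadata$sample_id[metadata$host == "human"],
                              metadata$project_id[metadata$host == "human"])
  records <- list()
  for (n in n_range) {
    combos <- enumerate_combinations(N, n, cap = lc$cap,
                                     seed = derive_seed(lc$seed, paste0("n", n)))
    for (ci in seq_along(combos)) {
      train_projects <- human_projects[combos[[ci]]]
      test_projects <- setdiff(human_projects, train_projects)
      pools <- vapply(hum_ids_by_project[train_projects], length, integer(1))
      quotas <- project_quotas(pools, per_class, replacement = TRUE)
      for (r in seq_len(lc$resamples)) {
        stage <- paste("lc", n, ci, r)
        hum_ids <- withr::with_seed(
          derive_seed(lc$seed, stage),
          unlist(lapply(train_projects, function(p) {
            sample(hum_ids_by_project[[p]], quotas[[p]], replace = TRUE)
          }), use.names = FALSE)
        )
        stopifnot(length(hum_ids) == per_class)
        train_rows <- c(pet_idx, match(hum_ids, ids))
        fit <- fit_ranger(x[train_rows, , drop = FALSE], y[train_rows],
                          params, seed = derive_seed(lc$seed, paste0(stage, "fit")))
        for (tp in test_projects) {
          test_ids <- hum_ids_by_project[[tp]]
          pred <- stats::predict(
            fit, data = x[test_ids, , drop = FALSE],
            seed = derive_seed(lc$seed, paste(stage, tp, "pred"))
          )$predictions
          records[[length(records) + 1L]] <- data.frame(
            n = n,
            combination = paste(combos[[ci]], collapse = ","),
            resample = r,
            test_project = tp,
            accuracy = mean(pred == "human"),
            n_test = length(test_ids),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  structure(
    list(records = do.call(rbind, records), human_projects = human_projects,
         per_class = per_class, lc = lc, params = params),
    class = "learning_curve_result"
  )
}

#' Summarize a learning-curve result
#'
#' @param result a [run_learning_curve()] result.
#' @return list with `per_n` (mean and SD of accuracy per n, averaged over
#'   combinations, resamples and test projects) and `per_project` (mean
#'   accuracy per held-out project).
#' @export
summarize_curve <- function(result) {
  stopifnot(inherits(result, "learning_curve_result"))
  rec <- result$records
  if (is.null(rec) || !nrow(rec)) {
    abort2("empty learning-curve result", "hostclass_bad_arg")
  }
  per_n <- do.call(rbind, lapply(split(rec, rec$n), function(d) {
    data.frame(
      n = d$n[1L],
      mean_accuracy = mean(d$accuracy),
      sd_accuracy = if (nrow(d) > 1L) sd(d$accuracy) else 0,
      n_models = length(unique(paste(d$combination, d$resample))),
      n_records = nrow(d)
    )
  }))
  per_project <- do.call(rbind, lapply(split(rec, rec$test_project),
                                       function(d) {
    data.frame(
      test_project = d$test_project[1L],
      mean_accuracy = mean(d$accuracy),
      n_records = nrow(d)
    )
  }))
  rownames(per_n) <- rownames(per_project) <- NULL
  list(per_n = per_n[order(per_n$n), ], per_project = per_project)
}
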