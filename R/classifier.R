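# Random-forest protocol: design assembly (abundances + a Chao1 richness
# column, optional CLR, optional restriction to Mann-Whitney-selected taxa),
# two-step hyperparameter selection under stratified 5-fold CV, repeated
# final fits scored out-of-bag, and feature-importance reporting. The forest
# learner itself is ranger; the protocol around it is the package's.

HOST_LEVELS <- c("pet", "human") # "human" is class 1 throughout

#' Model configuration
#'
#' Hyperparameter search space and CV settings. The default coarse grid for
#' step 1 spans each range at low cost: candidate features per split
#' (`mtry`) in {2, round(sqrt(p)), p}, tree depth and minimum node size to
#' split in {2, 12, 32, 52}, tree count in {10, 100, 500}. Step-2 fine
#' ranges: every integer 2..52 for depth and min-split, a 25-point geometric
#' ladder over 2..p for `mtry`, and {1, 5, 10, 50, 100, 500, 1000} trees.
#' Grids are functions of p (the number of design columns) and may be
#' overridden for small problems.
#'
#' @param feature_mode `"all"`, `"mw_fdr"` or `"mw_holm"`.
#' @param clr apply the centred log-ratio transform to abundance columns.
#' @param folds stratified CV folds (default 5).
#' @param seed integer seed governing folds and tree growing.
#' @param coarse_grid optional data frame with columns `mtry`, `depth`,
#'   `min_split`, `trees` replacing the default step-1 grid.
#' @param fine_grid optional named list of candidate vectors (same four
#'   names) replacing the default step-2 sweeps.
#' @return a `model_config` list.
#' @export
model_config <- function(feature_mode = c("all", "mw_fdr", "mw_holm"),
                         clr = FALSE, folds = 5, seed = 1,
                         coarse_grid = NULL, fine_grid = NULL) {
  feature_mode <- match.arg(feature_mode)
  structure(
    list(feature_mode = feature_mode, clr = clr, folds = folds, seed = seed,
         coarse_grid = coarse_grid, fine_grid = fine_grid),
    class = "model_config"
  )
}

default_coarse_grid <- function(p) {
  expand.grid(
    mtry = unique(pmin(c(2L, as.integer(round(sqrt(p))), as.integer(p)), p)),
    depth = c(2L, 12L, 32L, 52L),
    min_split = c(2L, 12L, 32L, 52L),
    trees = c(10L, 100L, 500L)
  )
}

default_fine_grid <- function(p) {
  ladder <- unique(as.integer(round(exp(seq(log(2), log(max(p, 2)),
                                            length.out = 25)))))
  list(
    mtry = ladder,
    depth = 2:52,
    min_split = 2:52,
    trees = c(1L, 5L, 10L, 50L, 100L, 500L, 1000L)
  )
}

#' Assemble the model design matrix
#'
#' Columns are the selected taxa's relative abundances (or CLR values when
#' `config$clr` is on; CLR is computed on the full filtered table before any
#' restriction, mirroring a transform-then-subset workflow) plus one `chao`
#' column of mean rarefied Chao1 values. Labels encode "human" as class 1.
#'
#' @param table a rare-filtered [feature_table()].
#' @param metadata aligned sample metadata.
#' @param chao named per-sample Chao1 values (see [table_chao()]); must
#'   cover every sample of the table.
#' @param config a [model_config()].
#' @param mw_set taxa to restrict to when `feature_mode` is not `"all"`.
#' @param pseudocount CLR pseudocount (default 1).
#' @return list with `x` (matrix), `y` (factor, levels pet < human), `taxa`.
#' @export
assemble_design <- function(table, metadata, chao, config = model_config(),
                            mw_set = NULL, pseudocount = 1) {
  stopifnot(inherits(table, "feature_table"))
  metadata <- align_table_metadata(table, validate_metadata(metadata))
  taxa <- colnames(table$counts)
  if (config$feature_mode != "all") {
    if (is.null(mw_set)) {
      abort2(sprintf("feature mode '%s' needs a Mann-Whitney feature set",
                     config$feature_mode), "hostclass_bad_arg")
    }
    taxa <- taxa[taxa %in% mw_set] # stable input order
  }
  if (!length(taxa)) {
    abort2("empty feature set: no taxa selected", "hostclass_empty_features")
  }
  abund <- if (isTRUE(config$clr)) {
    clr_transform(table, pseudocount = pseudocount)[, taxa, drop = FALSE]
  } else {
    relative_abundance(table)[, taxa, drop = FALSE]
  }
  ids <- rownames(table$counts)
  if (!all(ids %in% names(chao))) {
    missing <- setdiff(ids, names(chao))
    abort2(sprintf("missing Chao values for: %s",
                   paste(missing, collapse = ", ")),
           "hostclass_misaligned")
  }
  x <- cbind(abund, chao = chao[ids])
  y <- factor(metadata$host, levels = HOST_LEVELS)
  list(x = x, y = y, taxa = taxa)
}

fit_ranger <- function(x, y, params, seed, probability = FALSE, ...) {
  ranger::ranger(
    x = x, y = y,
    num.trees = params$trees,
    mtry = min(params$mtry, ncol(x)),
    max.depth = params$depth,
    min.node.size = params$min_split,
    probability = probability,
    seed = seed,
    num.threads = 1L,
    ...
  )
}

#' Stratified cross-validation accuracy of one hyperparameter setting
#'
#' @param x design matrix, `y` labels, `params` list with `mtry`, `depth`,
#'   `min_split`, `trees`, `folds` a list of test-index vectors, `seed` a
#'   base seed.
#' @return mean held-out accuracy over folds.
#' @keywords internal
cv_accuracy <- function(x, y, params, folds, seed) {
  accs <- vapply(seq_along(folds), function(k) {
    test <- folds[[k]]
    fit <- fit_ranger(
      x[-test, , drop = FALSE], y[-test], params,
      seed = derive_seed(seed, paste("cv", params$mtry, params$depth,
                                     params$min_split, params$trees, k))
    )
    # predict() draws a tie-break seed from the global RNG unless given one
    pred <- stats::predict(fit, data = x[test, , drop = FALSE],
                           seed = derive_seed(seed, paste("cvpred", k))
                           )$predictions
    mean(pred == y[test])
  }, numeric(1))
  mean(accs)
}

pick_best <- function(grid, acc) {
  # ties broken toward the simpler model: fewer trees, then shallower,
  # then larger min-split, then fewer candidate features per split
  best <- which(acc == max(acc))
  ord <- order(grid$trees[best], grid$depth[best], -grid$min_split[best],
               grid$mtry[best])
  best[ord[1L]]
}

#' Two-step hyperparameter selection
#'
#' Step 1 evaluates the full Cartesian coarse grid by stratified k-fold CV
#' mean accuracy. Step 2 sweeps each hyperparameter (in order `mtry`,
#' `depth`, `min_split`, `trees`) over its fine range with the other three
#' frozen at their current optima, updating the parameter before moving on.
#' Ties always resolve toward the simpler model. Deterministic under
#' `config$seed`.
#'
#' @param x design matrix.
#' @param y two-class factor labels (levels pet < human).
#' @param config a [model_config()].
#' @return a `param_search` list: `params` (selected), `cv_accuracy`,
#'   `step1` (coarse grid with accuracies), `step2` (per-parameter sweep
#'   tables), `folds`.
#' @export
two_step_param_search <- function(x, y, config = model_config()) {
  if (nlevels(droplevels(y)) < 2L) {
    abort2("labels are degenerate: a single class", "hostclass_bad_arg")
  }
  p <- ncol(x)
  folds <- withr::with_seed(derive_seed(config$seed, "folds"),
                            caret::createFolds(y, k = config$folds))
  coarse <- config$coarse_grid %||% default_coarse_grid(p)
  coarse$mtry <- pmin(coarse$mtry, p)
  coarse <- unique(coarse)
  acc1 <- vapply(seq_len(nrow(coarse)), function(i) {
    cv_accuracy(x, y, as.list(coarse[i, ]), folds, config$seed)
  }, numeric(1))
  current <- as.list(coarse[pick_best(coarse, acc1), ])
  step1 <- cbind(coarse, cv_accuracy = acc1)

  fine <- config$fine_grid %||% default_fine_grid(p)
  step2 <- list()
  for (par in c("mtry", "depth", "min_split", "trees")) {
    cand <- unique(pmin(fine[[par]], if (par == "mtry") p else Inf))
    grid <- do.call(rbind, lapply(cand, function(v) {
      row <- current
      row[[par]] <- as.integer(v)
      as.data.frame(row)
    }))
    acc <- vapply(seq_len(nrow(grid)), function(i) {
      cv_accuracy(x, y, as.list(grid[i, ]), folds, config$seed)
    }, numeric(1))
    current <- as.list(grid[pick_best(grid, acc), ])
    step2[[par]] <- cbind(grid, cv_accuracy = acc)
  }
  structure(
    list(params = lapply(current, as.integer),
         cv_accuracy = cv_accuracy(x, y, current, folds, config$seed),
         step1 = step1, step2 = step2, folds = folds),
    class = "param_search"
  )
}

oob_metrics <- function(truth, pred, positive = "human") {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  c(accuracy = mean(pred == truth), precision = precision,
    recall = recall, f1 = f1)
}

#' Final fit with out-of-bag scoring
#'
#' Fits `refits` probability forests differing only by seed and reports
#' out-of-bag accuracy, precision, recall and F1 (positive class "human",
#' decision threshold 0.5) as mean +/- SD across refits. Errors if any
#' sample is in-bag for every tree of a refit, since its OOB prediction
#' would be undefined — use more trees.
#'
#' @param x design matrix.
#' @param y labels (factor, levels pet < human).
#' @param params list with `mtry`, `depth`, `min_split`, `trees`.
#' @param seed integer seed.
#' @param refits number of repeated fits (default 10). With `refits = 1`
#'   the SDs are 0 by convention and flagged.
#' @return a `model_report`: `params`, `metrics` (data frame metric /
#'   mean / sd), `importance` (named, non-negative, sums to 1, averaged over
#'   refits), `forest` (first refit, used for prediction), `feature_names`,
#'   `oob_scores` (per-refit), `class1_oob` (per-sample OOB probability of
#'   "human" from the first refit), `sd_degenerate`.
#' @export
fit_final <- function(x, y, params, seed = 1, refits = 10) {
  stopifnot(is.matrix(x), is.factor(y))
  scores <- matrix(NA_real_, refits, 4,
                   dimnames = list(NULL, c("accuracy", "precision",
                                           "recall", "f1")))
  imp <- matrix(0, refits, ncol(x), dimnames = list(NULL, colnames(x)))
  forest <- NULL
  class1 <- NULL
  for (r in seq_len(refits)) {
    rf <- fit_ranger(x, y, params, seed = derive_seed(seed, paste0("refit", r)),
                     probability = TRUE, importance = "impurity",
                     keep.inbag = TRUE)
    inbag <- matrix(unlist(rf$inbag.counts), nrow = nrow(x))
    never_oob <- rowSums(inbag == 0) == 0
    if (any(never_oob)) {
      abort2(sprintf(
        "%d sample(s) are in-bag for every tree; increase the tree count for a stable OOB estimate",
        sum(never_oob)
      ), "hostclass_oob_unstable")
    }
    prob <- rf$predictions[, "human"]
    pred <- factor(ifelse(prob >= 0.5, "human", "pet"), levels = HOST_LEVELS)
    scores[r, ] <- oob_metrics(y, pred)
    vi <- rf$variable.importance
    imp[r, names(vi)] <- vi / sum(vi)
    if (r == 1L) {
      forest <- rf
      class1 <- prob
    }
  }
  sd_degenerate <- refits == 1L
  if (sd_degenerate) {
    warning("refits = 1: reported SDs are 0 by convention")
  }
  metrics <- data.frame(
    metric = colnames(scores),
    mean = colMeans(scores),
    sd = if (sd_degenerate) rep(0, 4) else apply(scores, 2L, sd),
    row.names = NULL
  )
  structure(
    list(params = params, metrics = metrics,
         importance = colMeans(imp), forest = forest,
         feature_names = colnames(x), oob_scores = as.data.frame(scores),
         class1_oob = stats::setNames(class1, rownames(x)),
         refits = refits, sd_degenerate = sd_degenerate, seed = seed),
    class = "model_report"
  )
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf(
    "model_report: %d features, %d trees (mtry %d, depth %d, min-split %d)\n",
    length(x$feature_names), x$params$trees, x$params$mtry, x$params$depth,
    x$params$min_split
  ))
  for (i in seq_len(nrow(x$metrics))) {
    cat(sprintf("  OOB %-9s %.3f +/- %.3f\n", x$metrics$metric[i],
                x$metrics$mean[i], x$metrics$sd[i]))
  }
  invisible(x)
}

#' Overlap between top random-forest features and a Mann-Whitney set
#'
#' Fraction of the top-k importance-ranked features (the Chao column is
#' excluded from the ranking) that lie in `mw_set`, with `k = length(mw_set)`.
#'
#' @param report a [fit_final()] report.
#' @param mw_set non-empty character vector of taxa.
#' @return overlap fraction in `[0, 1]`.
#' @export
importance_overlap <- function(report, mw_set) {
  stopifnot(inherits(report, "model_report"))
  if (!length(mw_set)) {
    abort2("mw_set must be non-empty", "hostclass_bad_arg")
  }
  imp <- report$importance[setdiff(names(report$importance), "chao")]
  k <- min(length(mw_set), length(imp))
  top <- names(sort(imp, decreasing = TRUE))[seq_len(k)]
  mean(top %in% mw_set)
}

#' Class-1 ("human") probability scores for new samples
#'
#' @param report a [fit_final()] report.
#' @param newx matrix with exactly the training design's columns, in the
#'   same order (a permuted or mismatched design is an error, never a
#'   silent misprediction).
#' @param seed tie-break seed for the vote aggregation (default 1).
#' @return per-sample probability of class "human" in `[0, 1]`; classify as
#'   human iff the score is >= 0.5.
#' @export
predict_scores <- function(report, newx, seed = 1) {
  stopifnot(inherits(report, "model_report"))
  if (!identical(colnames(newx), report$feature_names)) {
    abort2("design columns do not match the training design",
           "hostclass_misaligned")
  }
  stats::predict(report$forest, data = newx,
                 seed = derive_seed(seed, "predict"))$predictions[, "human"]
}

#' Per-project score histograms
#'
#' Bins the class-1 scores of each project for export and plotting.
#'
#' @param scores named per-sample scores (names are sample ids).
#' @param metadata sample metadata.
#' @param breaks histogram breaks over `[0, 1]` (default 20 bins).
#' @return data frame with `project_id`, `bin_low`, `bin_high`, `count`.
#' @export
score_histograms <- function(scores, metadata, breaks = seq(0, 1, by = 0.05)) {
  metadata <- validate_metadata(metadata)
  meta <- metadata[match(names(scores), metadata$sample_id), , drop = FALSE]
  out <- do.call(rbind, lapply(split(seq_along(scores), meta$project_id),
                               function(idx) {
    h <- hist(scores[idx], breaks = breaks, plot = FALSE)
    data.frame(
      project_id = meta$project_id[idx[1L]],
      bin_low = h$breaks[-length(h$breaks)],
      bin_high = h$breaks[-1L],
      count = h$counts,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Serialize a model report as JSON
#'
#' The forest object itself is not serialized; everything the tables report
#' (parameters, metrics, importances, per-refit scores) is.
#'
#' @param report a [fit_final()] report.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_report <- function(report, path) {
  out <- report[c("params", "metrics", "importance", "oob_scores",
                  "refits", "sd_degenerate", "seed")]
  out$importance <- as.list(out$importance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
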