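# Project-median differential abundance. Each study contributes a single
# median relative-abundance value per taxon, so the Mann-Whitney test
# compares projects (not samples) between host classes; this is what makes
# the selection robust to per-study batch effects.

#' Project-median relative abundances
#'
#' @param table a [feature_table()].
#' @param metadata aligned sample metadata; every sample must belong to a
#'   project, and every project to a single host class.
#' @return a `project_median_matrix`: projects x taxa matrix of median
#'   relative abundances with a `host` attribute giving each project's class.
#' @export
project_medians <- function(table, metadata) {
  stopifnot(inherits(table, "feature_table"))
  metadata <- align_table_metadata(table, validate_metadata(metadata))
  ra <- relative_abundance(table)
  projects <- unique(metadata$project_id)
  med <- matrix(NA_real_, length(projects), ncol(ra),
                dimnames = list(projects, colnames(ra)))
  host <- character(length(projects))
  for (i in seq_along(projects)) {
    rows <- metadata$project_id == projects[i]
    if (!any(rows)) {
      abort2(sprintf("project '%s' has zero samples", projects[i]),
             "hostclass_bad_metadata")
    }
    h <- unique(metadata$host[rows])
    if (length(h) != 1L) {
      abort2(sprintf("project '%s' mixes host classes", projects[i]),
             "hostclass_bad_metadata")
    }
    host[i] <- h
    med[i, ] <- apply(ra[rows, , drop = FALSE], 2L, median)
  }
  structure(med, host = host, class = c("project_median_matrix", "matrix"))
}

#' Two-sided Mann-Whitney p-value
#'
#' Uses the exact null distribution of the rank-sum statistic when both
#' groups have at most `exact_cutoff` values and the pooled data are free of
#' ties (the cutoff covers a 12-project versus 10-project design); otherwise
#' falls back to the tie-corrected normal approximation with continuity
#' correction. Two identical constant groups carry no evidence and return 1.
#'
#' @param x,y non-empty numeric vectors.
#' @param exact_cutoff largest group size for which the exact distribution
#'   is used (default 12).
#' @return the two-sided p-value.
#' @export
mann_whitney_two_sided <- function(x, y, exact_cutoff = 12) {
  if (!length(x) || !length(y)) {
    abort2("both groups must be non-empty", "hostclass_bad_arg")
  }
  pooled <- c(x, y)
  if (all(pooled == pooled[1L])) {
    return(1)
  }
  ties <- anyDuplicated(pooled) > 0L
  exact <- !ties && length(x) <= exact_cutoff && length(y) <= exact_cutoff
  p <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value
  )
  if (is.nan(p)) 1 else min(p, 1)
}

#' Holm-Bonferroni rejection flags
#'
#' Step-down control of the family-wise error rate: with p-values sorted
#' ascending, the first k hypotheses are rejected where
#' `p(i) <= alpha / (m - i + 1)` holds for all `i <= k`.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param alpha significance level in `(0, 1)`.
#' @return logical rejection flags in input order.
#' @export
holm_correction <- function(pvals, alpha = 0.05) {
  check_pvals(pvals, alpha)
  p.adjust(pvals, method = "holm") <= alpha
}

#' Benjamini-Hochberg rejection flags
#'
#' Step-up control of the false discovery rate: the k smallest p-values are
#' rejected, where k is the largest index with `p(k) <= k * alpha / m`.
#'
#' @inheritParams holm_correction
#' @return logical rejection flags in input order.
#' @export
bh_fdr <- function(pvals, alpha = 0.05) {
  check_pvals(pvals, alpha)
  p.adjust(pvals, method = "BH") <= alpha
}

check_pvals <- function(pvals, alpha) {
  if (anyNA(pvals) || any(pvals < 0) || any(pvals > 1)) {
    abort2("p-values must lie in [0, 1]", "hostclass_bad_arg")
  }
  if (alpha <= 0 || alpha >= 1) {
    abort2("alpha must lie in (0, 1)", "hostclass_bad_arg")
  }
}

#' Project-median Mann-Whitney differential abundance
#'
#' For each taxon, the two-sided Mann-Whitney test compares the pet
#' projects' median relative abundances against the human projects', and
#' both Holm-Bonferroni and Benjamini-Hochberg decisions are recorded at
#' `alpha`.
#'
#' @param table a [feature_table()], already rare-filtered.
#' @param metadata aligned sample metadata.
#' @param alpha significance level (default 0.05).
#' @return a data frame of class `diffabund_result` with columns `taxon`,
#'   `level`, `p_value`, `holm`, `fdr`, `direction` (host with the higher
#'   median of project medians), plus an `alpha` attribute.
#' @export
diff_abundance <- function(table, metadata, alpha = 0.05) {
  pm <- project_medians(table, metadata)
  host <- attr(pm, "host")
  if (!all(c("pet", "human") %in% host)) {
    abort2("both host classes must contribute projects", "hostclass_bad_metadata")
  }
  pet <- pm[host == "pet", , drop = FALSE]
  hum <- pm[host == "human", , drop = FALSE]
  p <- vapply(seq_len(ncol(pm)), function(j) {
    mann_whitney_two_sided(pet[, j], hum[, j])
  }, numeric(1))
  med_pet <- apply(pet, 2L, median)
  med_hum <- apply(hum, 2L, median)
  direction <- ifelse(med_hum > med_pet, "human",
                      ifelse(med_hum < med_pet, "pet", "none"))
  res <- data.frame(
    taxon = colnames(pm),
    level = table$level,
    p_value = p,
    holm = holm_correction(p, alpha),
    fdr = bh_fdr(p, alpha),
    direction = direction,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(res, "alpha") <- alpha
  class(res) <- c("diffabund_result", "data.frame")
  res
}

#' Taxa selected by a multiplicity-controlled test
#'
#' @param result a [diff_abundance()] result.
#' @param mode `"fdr"` (Benjamini-Hochberg) or `"holm"`.
#' @return character vector of selected taxa in the result's (input) order.
#' @export
select_features <- function(result, mode = c("fdr", "holm")) {
  mode <- match.arg(mode)
  stopifnot(inherits(result, "diffabund_result"))
  result$taxon[result[[mode]]]
}

#' Mann-Whitney test of a per-sample statistic on project medians
#'
#' Applies the same project-median procedure to a per-sample scalar (e.g.
#' the rarefied Chao1 value): projects are reduced to their median and the
#' pet projects are compared against the human projects. Reported
#' separately; never enters the feature sets.
#'
#' @param values named numeric vector of per-sample values.
#' @param metadata sample metadata covering all names of `values`.
#' @return list with `p_value`, `medians` (per project) and `host`.
#' @export
project_median_test <- function(values, metadata) {
  metadata <- validate_metadata(metadata)
  metadata <- metadata[match(names(values), metadata$sample_id), , drop = FALSE]
  if (anyNA(metadata$sample_id)) {
    abort2("values contain samples missing from metadata", "hostclass_misaligned")
  }
  med <- tapply(values, metadata$project_id, median)
  host <- tapply(metadata$host, metadata$project_id, function(h) unique(h)[1L])
  host <- host[names(med)]
  list(
    p_value = mann_whitney_two_sided(med[host == "pet"], med[host == "human"]),
    medians = med,
    host = host
  )
}

#' Write a differential-abundance result as TSV
#'
#' @param result a [diff_abundance()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diffabund_tsv <- function(result, path) {
  write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
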