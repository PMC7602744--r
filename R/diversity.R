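# Alpha diversity: bias-corrected Chao1, and the repeated fixed-depth
# subsampling protocol that averages Chao1 over several rarefied draws to
# damp the influence of low-abundance taxa.

#' Bias-corrected Chao1 richness
#'
#' `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))`, where `S_obs` is the number of
#' observed taxa, `F1` the number of singletons and `F2` the number of
#' doubletons. The bias-corrected variant is defined even when no doubletons
#' are observed.
#'
#' @param counts vector of non-negative integer read counts, at least one
#'   positive.
#' @return the estimated richness (taxa).
#' @export
chao1 <- function(counts) {
  if (!is_count_vector(counts)) {
    abort2("counts must be non-negative integers", "hostclass_bad_arg")
  }
  if (all(counts == 0)) {
    abort2("chao1 is undefined for an all-zero sample", "hostclass_bad_arg")
  }
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Chao1 under repeated fixed-depth subsampling
#'
#' Draws `reps` independent subsamples of exactly `depth` reads without
#' replacement (multivariate hypergeometric) from the sample's reads and
#' returns the mean of the per-subsample Chao1 values. When the sample
#' totals exactly `depth`, every subsample is the full sample and the
#' replicates have zero variance.
#'
#' @param counts vector of non-negative integer read counts.
#' @param depth reads per subsample (default 5000).
#' @param reps number of subsamples (default 5).
#' @param seed integer seed; identical seeds give identical estimates.
#' @return an object of class `chao_estimate` with fields `value` (mean of
#'   replicates), `replicates`, `depth` and `reps`.
#' @export
rarefied_chao <- function(counts, depth = 5000, reps = 5, seed = 1) {
  if (!is_count_vector(counts)) {
    abort2("counts must be non-negative integers", "hostclass_bad_arg")
  }
  total <- sum(counts)
  if (total < depth) {
    abort2(
      sprintf("insufficient depth: sample has %d reads, need %d", total, depth),
      "hostclass_insufficient_depth"
    )
  }
  if (total == depth) {
    replicates <- rep(chao1(counts), reps)
  } else {
    replicates <- withr::with_seed(seed, vapply(seq_len(reps), function(i) {
      # rrarefy warns heuristically when a vector holds no low counts;
      # integer read counts are validated above, so the warning is noise
      sub <- suppressWarnings(
        vegan::rrarefy(matrix(counts, nrow = 1L), sample = depth)
      )[1L, ]
      chao1(sub)
    }, numeric(1)))
  }
  structure(
    list(value = mean(replicates), replicates = replicates,
         depth = depth, reps = reps),
    class = "chao_estimate"
  )
}

#' @export
print.chao_estimate <- function(x, ...) {
  cat(sprintf("Chao1 (mean of %d subsamples at depth %d): %.3f\n",
              x$reps, x$depth, x$value))
  invisible(x)
}

#' Per-sample rarefied Chao1 for a whole table
#'
#' Samples shallower than `depth` are dropped with a warning naming them;
#' the caller decides whether that is acceptable.
#'
#' @param table a [feature_table()].
#' @inheritParams rarefied_chao
#' @return named numeric vector of mean Chao1 values for retained samples.
#' @export
table_chao <- function(table, depth = 5000, reps = 5, seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  totals <- rowSums(table$counts)
  shallow <- rownames(table$counts)[totals < depth]
  if (length(shallow)) {
    warning(sprintf(
      "dropping %d sample(s) shallower than %d reads: %s",
      length(shallow), depth, paste(shallow, collapse = ", ")
    ))
  }
  keep <- setdiff(rownames(table$counts), shallow)
  vapply(keep, function(id) {
    rarefied_chao(table$counts[id, ], depth = depth, reps = reps,
                  seed = derive_seed(seed, paste0("chao/", id)))$value
  }, numeric(1))
}
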