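# Compositional transforms: centred log-ratio (CLR), which maps closed
# compositions to unconstrained real space, and Bray-Curtis dissimilarity.

#' Centred log-ratio transform
#'
#' Per sample: add `pseudocount` to every count, close to proportions, and
#' take the log of each proportion minus the log of the row's geometric
#' mean. Rows of the result sum to zero, and the transform is invariant to
#' positive scaling of a zero-free row.
#'
#' @param x a [feature_table()] or a samples x taxa numeric matrix with at
#'   least two taxa.
#' @param pseudocount value added to every entry before closure (default 1
#'   read). May be 0 only when `x` has no zero entries.
#' @return samples x taxa matrix of CLR values with attribute
#'   `pseudocount` recording the zero-replacement policy.
#' @export
clr_transform <- function(x, pseudocount = 1) {
  m <- if (inherits(x, "feature_table")) x$counts else as.matrix(x)
  if (ncol(m) < 2L) {
    abort2("CLR needs at least 2 taxa", "hostclass_bad_arg")
  }
  if (any(m < 0)) {
    abort2("CLR input must be non-negative", "hostclass_bad_arg")
  }
  if (pseudocount <= 0 && any(m == 0)) {
    abort2("pseudocount must be positive when zeros are present",
           "hostclass_bad_arg")
  }
  m <- m + pseudocount
  p <- m / rowSums(m)
  lp <- log(p)
  out <- lp - rowMeans(lp)
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `1 - 2 * sum(min(u_i, v_i)) / (sum(u) + sum(v))`; 0 for identical
#' vectors, 1 for disjoint supports.
#'
#' @param u,v equal-length non-negative vectors, not both all-zero.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(u, v) {
  if (length(u) != length(v)) {
    abort2("vectors must have equal length", "hostclass_bad_arg")
  }
  if (any(u < 0) || any(v < 0)) {
    abort2("abundances must be non-negative", "hostclass_bad_arg")
  }
  tot <- sum(u) + sum(v)
  if (tot == 0) {
    abort2("Bray-Curtis is undefined for two all-zero vectors",
           "hostclass_bad_arg")
  }
  1 - 2 * sum(pmin(u, v)) / tot
}

#' Pairwise Bray-Curtis distance matrix
#'
#' @param x samples x taxa abundance matrix (or [feature_table()]).
#' @return square symmetric matrix of dissimilarities.
#' @export
bray_curtis_matrix <- function(x) {
  m <- if (inherits(x, "feature_table")) x$counts else as.matrix(x)
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Write a square distance matrix as TSV
#'
#' For external ordination or plotting tools.
#'
#' @param d square distance matrix with sample ids as dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), d,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
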