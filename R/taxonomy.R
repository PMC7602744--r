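# Taxonomic lineages are semicolon-delimited rank strings, ordered
# kingdom -> genus. A table "at level k" carries lineages truncated to the
# first k ranks; grouping at a higher rank is a prefix operation.

#' Taxonomic ranks used throughout the package
#'
#' Ordered from kingdom down to genus; a lineage at a given level carries
#' exactly as many labels as the level's position in this vector.
#'
#' @return character vector of the six rank names.
#' @export
taxonomic_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus")
}

rank_index <- function(level) {
  idx <- match(level, taxonomic_ranks())
  if (is.na(idx)) {
    abort2(sprintf("unknown taxonomic level '%s'", level), "hostclass_bad_level")
  }
  idx
}

#' Split lineage strings into rank labels
#'
#' @param lineages character vector of semicolon-delimited lineages.
#' @param level the rank the lineages are truncated to; each lineage must
#'   have exactly as many labels as the level implies.
#' @return a character matrix with one row per lineage and one column per rank.
#' @export
parse_lineage <- function(lineages, level = "genus") {
  k <- rank_index(level)
  parts <- strsplit(lineages, ";", fixed = TRUE)
  n <- lengths(parts)
  if (any(n != k)) {
    bad <- lineages[n != k][1L]
    abort2(
      sprintf(
        "malformed lineage '%s': expected %d ranks at level '%s', found %d",
        bad, k, level, lengths(strsplit(bad, ";", fixed = TRUE))
      ),
      "hostclass_bad_lineage"
    )
  }
  out <- do.call(rbind, parts)
  colnames(out) <- taxonomic_ranks()[seq_len(k)]
  out
}

#' Truncate lineages to a higher rank
#'
#' @inheritParams parse_lineage
#' @param to target rank, at or above `level`.
#' @return character vector of truncated lineages.
#' @export
truncate_lineage <- function(lineages, level = "genus", to = "family") {
  k_from <- rank_index(level)
  k_to <- rank_index(to)
  if (k_to > k_from) {
    abort2(
      sprintf("cannot truncate level '%s' down to '%s'", level, to),
      "hostclass_bad_level"
    )
  }
  mat <- parse_lineage(lineages, level)
  apply(mat[, seq_len(k_to), drop = FALSE], 1L, paste, collapse = ";")
}

#' Label for a taxon unassigned at a rank
#'
#' Unassigned ranks are rendered as `"unclassified <parent label>"` so that
#' partially classified taxa group deterministically under their deepest
#' named ancestor (e.g. "unclassified Bacteria" at every rank below kingdom).
#'
#' @param parent label of the deepest classified ancestor.
#' @return character label.
#' @export
unclassified_label <- function(parent) {
  paste("unclassified", parent)
}
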