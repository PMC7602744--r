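# Feature tables are samples x taxa integer count matrices. Rows are named
# by sample id, columns by lineage truncated to the table's level. Sample
# metadata travels as a separate data frame keyed by sample_id, as the
# tables themselves are exchanged as plain TSV.

#' Construct a feature table
#'
#' @param counts samples x taxa matrix of non-negative integer read counts,
#'   with sample ids as row names and lineage strings as column names.
#' @param level taxonomic rank of the columns (see [taxonomic_ranks()]).
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(counts, level = "genus") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort2("counts must carry sample ids as rownames and lineages as colnames",
           "hostclass_bad_table")
  }
  if (!is_count_vector(as.vector(counts))) {
    abort2("counts must be non-negative integers", "hostclass_bad_table")
  }
  if (anyDuplicated(rownames(counts))) {
    abort2("duplicate sample ids in feature table", "hostclass_bad_table")
  }
  if (anyDuplicated(colnames(counts))) {
    abort2("duplicate taxa in feature table", "hostclass_bad_table")
  }
  parse_lineage(colnames(counts), level) # validates rank counts
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, level = level), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "feature_table: %d samples x %d taxa at level '%s'\n",
    nrow(x$counts), ncol(x$counts), x$level
  ))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

#' Per-sample relative abundances
#'
#' Counts are stored as integers and closed to proportions on demand, never
#' stored normalized, to avoid double normalization.
#'
#' @param table a [feature_table()].
#' @return samples x taxa matrix of fractions summing to 1 per row.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  totals <- rowSums(table$counts)
  if (any(totals == 0)) {
    abort2("sample with zero total reads", "hostclass_bad_table")
  }
  table$counts / totals
}

validate_metadata <- function(metadata) {
  need <- c("sample_id", "host", "species", "project_id")
  if (!all(need %in% names(metadata))) {
    abort2(
      paste("metadata must have columns:", paste(need, collapse = ", ")),
      "hostclass_bad_metadata"
    )
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (anyDuplicated(metadata$sample_id)) {
    abort2("duplicate sample ids in metadata", "hostclass_bad_metadata")
  }
  if (!all(metadata$host %in% c("pet", "human"))) {
    abort2("host must be 'pet' or 'human'", "hostclass_bad_metadata")
  }
  if (!all(metadata$species %in% c("cat", "dog", "human"))) {
    abort2("species must be 'cat', 'dog' or 'human'", "hostclass_bad_metadata")
  }
  expect_host <- ifelse(metadata$species == "human", "human", "pet")
  if (!all(metadata$host == expect_host)) {
    bad <- metadata$sample_id[metadata$host != expect_host][1L]
    abort2(
      sprintf("sample '%s': species/host combination is inconsistent", bad),
      "hostclass_bad_metadata"
    )
  }
  metadata
}

align_table_metadata <- function(table, metadata) {
  ids_t <- rownames(table$counts)
  ids_m <- metadata$sample_id
  only_t <- setdiff(ids_t, ids_m)
  only_m <- setdiff(ids_m, ids_t)
  if (length(only_t) || length(only_m)) {
    abort2(
      sprintf(
        "samples present in only one input: %s",
        paste(c(only_t, only_m), collapse = ", ")
      ),
      "hostclass_misaligned"
    )
  }
  metadata[match(ids_t, ids_m), , drop = FALSE]
}

#' Read a feature table and its sample metadata from TSV
#'
#' The feature table is a tab-delimited file with a `sample_id` first column
#' and one column per taxon, headed by the semicolon-delimited lineage. The
#' metadata file carries `sample_id`, `host`, `species`, `project_id`.
#' The taxonomic level is inferred from the number of ranks in the lineage
#' headers and must be consistent across columns.
#'
#' @param path path to the feature-table TSV.
#' @param metadata_path path to the metadata TSV.
#' @return a list with elements `table` ([feature_table()]) and `metadata`
#'   (data frame aligned to the table's row order).
#' @export
read_feature_table <- function(path, metadata_path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(raw)[1L] != "sample_id") {
    abort2("first column of a feature table TSV must be 'sample_id'",
           "hostclass_bad_table")
  }
  counts <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(counts) || any(counts != round(counts))) {
    abort2("feature table contains non-integer counts", "hostclass_bad_table")
  }
  rownames(counts) <- as.character(raw$sample_id)
  nranks <- lengths(strsplit(colnames(counts), ";", fixed = TRUE))
  if (length(unique(nranks)) != 1L || nranks[1L] > 6L) {
    abort2("lineage headers disagree on rank depth", "hostclass_bad_lineage")
  }
  level <- taxonomic_ranks()[nranks[1L]]
  table <- feature_table(counts, level = level)
  metadata <- validate_metadata(
    read.delim(metadata_path, check.names = FALSE, stringsAsFactors = FALSE)
  )
  metadata <- align_table_metadata(table, metadata)
  list(table = table, metadata = metadata)
}

#' Write a feature table as TSV
#'
#' @param table a [feature_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(
    sample_id = rownames(table$counts),
    table$counts,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Write sample metadata as TSV
#'
#' @param metadata metadata data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  metadata <- validate_metadata(metadata)
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a BIOM-style dense TSV export
#'
#' Read-only import of the transposed layout many QIIME exports use: taxa as
#' rows (first column `#OTU ID` or similar holding the lineage), samples as
#' columns.
#'
#' @param path path to the dense TSV.
#' @return a [feature_table()] (samples x taxa).
#' @export
read_biom_dense_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "# Constructed")]
  raw <- read.delim(text = lines, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
  lineages <- as.character(raw[[1L]])
  counts <- t(as.matrix(raw[, -1L, drop = FALSE]))
  colnames(counts) <- lineages
  nranks <- lengths(strsplit(lineages, ";", fixed = TRUE))
  if (length(unique(nranks)) != 1L || nranks[1L] > 6L) {
    abort2("lineage rows disagree on rank depth", "hostclass_bad_lineage")
  }
  feature_table(counts, level = taxonomic_ranks()[nranks[1L]])
}

#' Aggregate a feature table to a higher taxonomic rank
#'
#' Counts of taxa sharing the same lineage prefix at the target rank are
#' summed, so per-sample read totals are conserved. Output taxa appear in
#' order of first occurrence in the input.
#'
#' @param table a [feature_table()].
#' @param level target rank, at or above the table's level.
#' @return a [feature_table()] at the requested level.
#' @export
aggregate_to_level <- function(table, level) {
  stopifnot(inherits(table, "feature_table"))
  k_to <- rank_index(level)
  k_from <- rank_index(table$level)
  if (k_to > k_from) {
    abort2(
      sprintf("cannot aggregate '%s' table down to '%s'", table$level, level),
      "hostclass_bad_level"
    )
  }
  if (k_to == k_from) {
    return(table)
  }
  prefix <- truncate_lineage(colnames(table$counts), table$level, level)
  groups <- factor(prefix, levels = unique(prefix))
  agg <- t(rowsum(t(table$counts), group = groups, reorder = FALSE))
  feature_table(agg, level = level)
}

#' Remove taxa that are rare in both host classes
#'
#' A taxon is removed iff the fraction of samples with zero reads is
#' strictly greater than `zero_fraction_threshold` within the pet class AND
#' strictly greater within the human class (so a taxon at exactly the
#' threshold in either class is kept). Column order of retained taxa is
#' preserved.
#'
#' @param table a [feature_table()].
#' @param metadata aligned sample metadata.
#' @param zero_fraction_threshold proportion in `[0, 1]`; default 0.9.
#' @return a filtered [feature_table()].
#' @export
filter_rare <- function(table, metadata, zero_fraction_threshold = 0.9) {
  stopifnot(inherits(table, "feature_table"))
  if (zero_fraction_threshold < 0 || zero_fraction_threshold > 1) {
    abort2("zero_fraction_threshold must be in [0, 1]", "hostclass_bad_arg")
  }
  metadata <- align_table_metadata(table, validate_metadata(metadata))
  keep_any <- logical(ncol(table$counts))
  for (cls in c("pet", "human")) {
    rows <- metadata$host == cls
    if (!any(rows)) {
      abort2(sprintf("host class '%s' has zero samples", cls),
             "hostclass_bad_metadata")
    }
    zf <- colMeans(table$counts[rows, , drop = FALSE] == 0)
    keep_any <- keep_any | (zf <= zero_fraction_threshold)
  }
  feature_table(table$counts[, keep_any, drop = FALSE], level = table$level)
}
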