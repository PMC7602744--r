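# The multi-study design the package's presets emulate: public cat, dog and
# human gut 16S datasets, each sequenced in its own project, with a training
# partition and a set of additional held-out projects.

#' Reference multi-study design
#'
#' Per-project sample counts of the public gut 16S datasets that the
#' `"study_like"` synthetic preset and the balanced-dataset defaults are
#' modelled on. `n_total` is the project's full sample count; `n_train` is
#' its contribution to the training pool (0 for the additional, held-out
#' projects). The human training pool is larger than the pet pool, which is
#' what makes project-balanced down-sampling of the human side necessary.
#'
#' @return data frame with columns `project_id`, `host`, `species`,
#'   `n_total`, `n_train`, `partition`.
#' @export
reference_study_design <- function() {
  df <- rbind(
    data.frame(
      project_id = c("PRJNA504021", "PRJNA349988", "PRJNA248757",
                     "PRJNA338653", "PRJNA350163"),
      host = "pet", species = "cat",
      n_total = c(65L, 44L, 30L, 19L, 6L),
      n_train = c(65L, 44L, 30L, 19L, 6L),
      partition = "train", stringsAsFactors = FALSE
    ),
    data.frame(
      project_id = c("PRJNA488105", "PRJNA525542", "PRJNA358232",
                     "PRJNA391562", "PRJNA493249", "PRJDB5398",
                     "PRJNA492898"),
      host = "pet", species = "dog",
      n_total = c(34L, 32L, 30L, 23L, 19L, 13L, 6L),
      n_train = c(34L, 32L, 30L, 23L, 19L, 13L, 6L),
      partition = "train", stringsAsFactors = FALSE
    ),
    data.frame(
      project_id = c("PMID29795809", "PMID25417156", "PMID28195358",
                     "PMID28179361", "PMID31027508", "PMID26179554",
                     "PMID28429209", "qiita_10928", "PMID29404425",
                     "PMID28191884"),
      host = "human", species = "human",
      n_total = c(681L, 200L, 115L, 102L, 49L, 31L, 22L, 21L, 12L, 9L),
      n_train = c(46L, 45L, 45L, 45L, 45L, 31L, 22L, 21L, 12L, 9L),
      partition = "train", stringsAsFactors = FALSE
    ),
    data.frame(
      project_id = c("PRJNA470724", "PMID32078625_cat", "PMID32078625_dog",
                     "PRJNA401442", "PRJNA589580", "PRJNA592436"),
      host = "pet", species = c("cat", "cat", "dog", "dog", "dog", "dog"),
      n_total = c(74L, 46L, 192L, 56L, 35L, 29L),
      n_train = 0L,
      partition = "additional", stringsAsFactors = FALSE
    ),
    data.frame(
      project_id = c("PRJNA385551", "PRJNA493726"),
      host = "human", species = "human",
      n_total = c(284L, 74L),
      n_train = 0L,
      partition = "additional", stringsAsFactors = FALSE
    )
  )
  rownames(df) <- NULL
  df
}

#' Expand a per-project design into sample metadata
#'
#' One metadata row per sample, with ids `<project>_s001`, `<project>_s002`,
#' ...; useful for exercising the dataset builder on a printed design.
#'
#' @param design data frame with columns `project_id`, `host`, `species` and
#'   a count column.
#' @param count_col which column holds the per-project sample count
#'   (default `"n_train"`).
#' @return metadata data frame.
#' @export
design_metadata <- function(design, count_col = "n_train") {
  design <- design[design[[count_col]] > 0L, , drop = FALSE]
  rows <- data.frame(
    project_id = rep(design$project_id, design[[count_col]]),
    host = rep(design$host, design[[count_col]]),
    species = rep(design$species, design[[count_col]]),
    stringsAsFactors = FALSE
  )
  rows$sample_id <- paste0(
    rows$project_id, "_s",
    sprintf("%03d", unlist(lapply(design[[count_col]], seq_len),
                           use.names = FALSE))
  )
  validate_metadata(rows[, c("sample_id", "host", "species", "project_id")])
}
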