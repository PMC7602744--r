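# Synthetic multi-project generator. Emulates the statistical structure the
# pipeline assumes: a shared taxon catalogue with realistic rank structure,
# host effects on a planted subset of genera, host-exclusive taxa, per-study
# batch effects shared by all samples of a project, per-sample noise, and
# multinomial read counts at fixed depth. Ground truth (which taxa carry
# host signal, every effect size, every project shift) is returned alongside
# the data so recovery can be scored exactly.

#' Multi-project layouts
#'
#' `"study_like"` mirrors the cross-study design the package targets: 12 pet
#' projects (5 cat, 7 dog) of sizes 65, 44, 30, 19, 6, 34, 32, 30, 23, 19,
#' 13, 6 (321 samples) and 10 human projects of sizes 46, 45, 45, 45, 45,
#' 31, 22, 21, 12, 9 (321 samples). `"tiny"` is 4 + 4 projects of 10 samples
#' for fast tests.
#'
#' @param preset `"study_like"` or `"tiny"`.
#' @return list with `pet_sizes`, `pet_species`, `human_sizes`.
#' @export
make_study_layout <- function(preset = c("study_like", "tiny")) {
  preset <- match.arg(preset)
  if (preset == "study_like") {
    list(
      pet_sizes = c(65L, 44L, 30L, 19L, 6L, 34L, 32L, 30L, 23L, 19L, 13L, 6L),
      pet_species = c(rep("cat", 5L), rep("dog", 7L)),
      human_sizes = c(46L, 45L, 45L, 45L, 45L, 31L, 22L, 21L, 12L, 9L)
    )
  } else {
    list(
      pet_sizes = rep(10L, 4L),
      pet_species = c("cat", "cat", "dog", "dog"),
      human_sizes = rep(10L, 4L)
    )
  }
}

#' Expand a layout into sample metadata
#'
#' @param layout a [make_study_layout()] list (or one with custom sizes).
#' @return metadata data frame with one row per sample.
#' @export
layout_metadata <- function(layout) {
  pet_projects <- sprintf("pet%02d", seq_along(layout$pet_sizes))
  hum_projects <- sprintf("hum%02d", seq_along(layout$human_sizes))
  rows <- rbind(
    data.frame(
      project_id = rep(pet_projects, layout$pet_sizes),
      host = "pet",
      species = rep(layout$pet_species, layout$pet_sizes),
      stringsAsFactors = FALSE
    ),
    data.frame(
      project_id = rep(hum_projects, layout$human_sizes),
      host = "human",
      species = "human",
      stringsAsFactors = FALSE
    )
  )
  rows$sample_id <- paste0(
    rows$project_id, "_s",
    sprintf("%03d", unlist(lapply(c(layout$pet_sizes, layout$human_sizes),
                                  seq_len), use.names = FALSE))
  )
  validate_metadata(rows[, c("sample_id", "host", "species", "project_id")])
}

#' Generator configuration
#'
#' The taxon catalogue (60 genera in 25 families across 8 phyla by default)
#' is built deterministically from `catalogue_seed`: two genera are
#' host-exclusive — a human-only genus in its own Verrucomicrobia-like
#' phylum (an Akkermansia-like marker) and a pet-only genus in a
#' Fusobacteria-like phylum — and `n_planted` of the shared genera carry a
#' host log-fold effect of magnitude `effect_size`, alternating direction.
#' Exclusive taxa get a low baseline so they are sparsely detected rather
#' than a perfect presence/absence flag. Batch effects are per-(project,
#' taxon) normal shifts of sd `sigma_batch` in log space; per-sample noise
#' has sd `sigma_sample`; counts are multinomial at `depth` reads.
#'
#' @param layout a [make_study_layout()] list.
#' @param n_genera,n_families,n_phyla catalogue dimensions (the two
#'   exclusive genera and their families/phyla are counted in these totals).
#' @param n_planted number of shared genera with a host effect (default 8).
#' @param effect_size host log-fold shift magnitude on planted taxa
#'   (default 2, i.e. about 7.4-fold).
#' @param sigma_batch sd of per-(project, taxon) log shifts (default 0.8).
#' @param sigma_sample sd of per-sample log noise (default 0.6).
#' @param depth reads per sample (default 5000).
#' @param include_exclusive include the two host-exclusive genera
#'   (default TRUE); disable for null calibration where no taxon may carry
#'   host signal.
#' @param exclusive_baseline log-abundance of exclusive taxa (default -4,
#'   about one read per sample at the default depth, so detection is sparse
#'   and varies across projects).
#' @param catalogue_seed seed for the deterministic catalogue (baselines,
#'   planted subset).
#' @return a `generator_config` list.
#' @export
make_generator_config <- function(layout = make_study_layout("study_like"),
                                  n_genera = 60, n_families = 25, n_phyla = 8,
                                  n_planted = 8, effect_size = 2,
                                  sigma_batch = 0.8, sigma_sample = 0.6,
                                  depth = 5000, include_exclusive = TRUE,
                                  exclusive_baseline = -4,
                                  catalogue_seed = 20101) {
  if (depth < 1) abort2("depth must be >= 1", "hostclass_bad_arg")
  if (sigma_batch < 0 || sigma_sample < 0) {
    abort2("sigma values must be >= 0", "hostclass_bad_arg")
  }
  if (!length(layout$pet_sizes) || !length(layout$human_sizes)) {
    abort2("layout needs projects for both hosts", "hostclass_bad_arg")
  }
  n_shared <- n_genera - if (include_exclusive) 2L else 0L
  if (n_shared < 1L) abort2("catalogue has zero taxa", "hostclass_bad_arg")
  n_shared_fam <- n_families - if (include_exclusive) 2L else 0L
  n_shared_phy <- n_phyla - if (include_exclusive) 2L else 0L
  fam_of <- ((seq_len(n_shared) - 1L) %% n_shared_fam) + 1L
  phy_of_fam <- ((seq_len(n_shared_fam) - 1L) %% n_shared_phy) + 1L
  lineage <- sprintf(
    "Bacteria;Phylum%02d;Class%02d;Order%02d;Family%02d;Genus%03d",
    phy_of_fam[fam_of], phy_of_fam[fam_of], fam_of, fam_of, seq_len(n_shared)
  )
  exclusive_human <- exclusive_pet <- character(0)
  if (include_exclusive) {
    exclusive_human <-
      "Bacteria;Verrucomicrobia_like;ClassV;OrderV;FamilyV;Akkermansia_like"
    exclusive_pet <-
      "Bacteria;Fusobacteria_like;ClassF;OrderF;FamilyF;Fusobacterium_like"
    lineage <- c(lineage, exclusive_human, exclusive_pet)
  }
  baseline <- withr::with_seed(derive_seed(catalogue_seed, "baseline"),
                               rnorm(length(lineage), 0, 1))
  names(baseline) <- lineage
  if (include_exclusive) {
    baseline[c(exclusive_human, exclusive_pet)] <- exclusive_baseline
  }
  planted <- withr::with_seed(
    derive_seed(catalogue_seed, "planted"),
    sort(sample(seq_len(n_shared), min(n_planted, n_shared)))
  )
  delta <- stats::setNames(numeric(length(lineage)), lineage)
  if (length(planted)) {
    # Planted effects come in balanced pairs: a human-elevated taxon and a
    # pet-elevated mirror sharing the same base intensity, so the expected
    # total load is equal in both hosts and closure does not smear the host
    # signal over the null taxa (hosts "swap usage" of taxa rather than one
    # host simply carrying more of everything).
    signs <- rep(c(1, -1), length.out = length(planted))
    delta[lineage[planted]] <- signs * effect_size
    pair_mid <- rep(baseline[lineage[planted[c(TRUE, FALSE)]]],
                    each = 2)[seq_along(planted)]
    baseline[lineage[planted]] <- pair_mid - signs * effect_size / 2
  }
  structure(
    list(
      layout = layout, taxa = lineage, baseline = baseline, delta = delta,
      planted = lineage[planted], exclusive_human = exclusive_human,
      exclusive_pet = exclusive_pet, sigma_batch = sigma_batch,
      sigma_sample = sigma_sample, depth = depth,
      include_exclusive = include_exclusive, catalogue_seed = catalogue_seed
    ),
    class = "generator_config"
  )
}

#' Generate a multi-project host-labelled dataset
#'
#' Per sample, the log-intensity of each taxon is
#' `baseline + delta * [host is human] + project shift + sample noise`;
#' host-exclusive taxa are zeroed in the wrong host; intensities are
#' exponentiated and closed to a composition, and counts are drawn
#' multinomially at the configured depth. Regeneration under the same seed
#' is bit-identical.
#'
#' @param config a [make_generator_config()] object.
#' @param seed integer seed.
#' @return list with `table` ([feature_table()] at genus level), `metadata`,
#'   and `truth` (planted and exclusive taxa, all effect sizes, per-project
#'   shifts, the config and seed).
#' @export
generate_dataset <- function(config, seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  metadata <- layout_metadata(config$layout)
  taxa <- config$taxa
  n_taxa <- length(taxa)
  projects <- unique(metadata$project_id)
  counts <- matrix(0L, nrow(metadata), n_taxa,
                   dimnames = list(metadata$sample_id, taxa))
  shifts <- matrix(NA_real_, length(projects), n_taxa,
                   dimnames = list(projects, taxa))
  withr::with_seed(derive_seed(seed, "generate"), {
    for (pr in projects) {
      rows <- which(metadata$project_id == pr)
      host <- metadata$host[rows[1L]]
      shift <- rnorm(n_taxa, 0, config$sigma_batch)
      shifts[pr, ] <- shift
      eta_base <- config$baseline +
        (host == "human") * config$delta + shift
      for (i in rows) {
        eta <- eta_base + rnorm(n_taxa, 0, config$sigma_sample)
        w <- exp(eta)
        if (config$include_exclusive) {
          if (host == "pet") w[taxa == config$exclusive_human] <- 0
          if (host == "human") w[taxa == config$exclusive_pet] <- 0
        }
        counts[i, ] <- as.integer(
          stats::rmultinom(1L, size = config$depth, prob = w / sum(w))
        )
      }
    }
  })
  list(
    table = feature_table(counts, level = "genus"),
    metadata = metadata,
    truth = list(
      planted = config$planted,
      exclusive_human = config$exclusive_human,
      exclusive_pet = config$exclusive_pet,
      delta = config$delta,
      baseline = config$baseline,
      project_shifts = shifts,
      seed = seed,
      config = config
    )
  )
}

#' Write a generated dataset to disk
#'
#' Feature table and metadata as the package's standard TSVs, ground truth
#' as a JSON sidecar.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if missing).
#' @return named character vector of the three paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    table = file.path(dir, "feature_table.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_feature_table(dataset$table, paths[["table"]])
  write_metadata(dataset$metadata, paths[["metadata"]])
  truth <- dataset$truth
  truth$config <- NULL
  truth$project_shifts <- as.data.frame(truth$project_shifts)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
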