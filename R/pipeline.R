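# End-to-end orchestration: generate or ingest -> aggregate -> filter ->
# diversity -> Mann-Whitney selection -> design assembly -> hyperparameter
# search -> final fit -> learning curve, writing every intermediate as
# TSV/JSON plus a manifest of derived seeds and parameters so a run can be
# reproduced byte-for-byte.

#' Pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed global run seed; every stochastic stage derives its own seed
#'   from it and records the derivation in the manifest.
#' @param preset synthetic preset (`"tiny"` or `"study_like"`) used when no
#'   input paths are given.
#' @param table_path,metadata_path optional input TSVs; both or neither.
#' @param level taxonomic level to analyse (default `"genus"`).
#' @param feature_mode `"all"`, `"mw_fdr"` or `"mw_holm"`.
#' @param clr use CLR-transformed abundances.
#' @param alpha significance level for feature selection.
#' @param depth subsampling depth for Chao1 (defaults to the generator's).
#' @param search run the two-step hyperparameter search (else use
#'   `params`).
#' @param params hyperparameters used when `search = FALSE`.
#' @param learning_curve run the learning-curve stage.
#' @param lc_scale `"desk"` (cap 20, 2 resamples) or `"full"` (cap 200, 5).
#' @param generator optional [make_generator_config()] override.
#' @param coarse_grid,fine_grid optional search-grid overrides.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1, preset = "tiny",
                       table_path = NULL, metadata_path = NULL,
                       level = "genus", feature_mode = "all", clr = FALSE,
                       alpha = 0.05, depth = NULL, search = FALSE,
                       params = list(mtry = 8L, depth = 12L, min_split = 2L,
                                     trees = 100L),
                       learning_curve = FALSE, lc_scale = c("desk", "full"),
                       generator = NULL, coarse_grid = NULL,
                       fine_grid = NULL) {
  lc_scale <- match.arg(lc_scale)
  structure(
    list(out_dir = out_dir, seed = seed, preset = preset,
         table_path = table_path, metadata_path = metadata_path,
         level = level, feature_mode = feature_mode, clr = clr,
         alpha = alpha, depth = depth, search = search, params = params,
         learning_curve = learning_curve, lc_scale = lc_scale,
         generator = generator, coarse_grid = coarse_grid,
         fine_grid = fine_grid),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

stage <- function(name, manifest_env, expr) {
  result <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  manifest_env$stages <- c(manifest_env$stages, name)
  result
}

#' Run the full pipeline
#'
#' Validates inputs before any compute, executes the stages in order, and
#' writes every intermediate artifact plus a `manifest.json` of seeds,
#' package version and parameters. Reruns with the same configuration are
#' byte-identical for all deterministic outputs.
#'
#' @param config a [run_config()] (or path to a YAML file readable by
#'   [read_run_config()]).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (xor(is.null(config$table_path), is.null(config$metadata_path))) {
    abort2("table_path and metadata_path must be given together",
           "hostclass_bad_arg")
  }
  if (!is.null(config$table_path)) {
    for (p in c(config$table_path, config$metadata_path)) {
      if (!file.exists(p)) {
        abort2(sprintf("input file not found: %s", p), "hostclass_bad_arg")
      }
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  env <- new.env()
  env$stages <- character(0)
  seeds <- list(
    generate = derive_seed(config$seed, "generate"),
    chao = derive_seed(config$seed, "chao"),
    balance = derive_seed(config$seed, "balance"),
    model = derive_seed(config$seed, "model"),
    learning_curve = derive_seed(config$seed, "learning_curve")
  )

  ingest <- stage("ingest", env, {
    if (is.null(config$table_path)) {
      gen <- config$generator %||%
        make_generator_config(layout = make_study_layout(config$preset))
      ds <- generate_dataset(gen, seed = seeds$generate)
      write_dataset(ds, file.path(config$out_dir, "input"))
      ds[c("table", "metadata")]
    } else {
      read_feature_table(config$table_path, config$metadata_path)
    }
  })
  table <- stage("aggregate", env,
                 aggregate_to_level(ingest$table, config$level))
  filtered <- stage("filter_rare", env, filter_rare(table, ingest$metadata))
  stage("write_filtered", env, write_feature_table(
    filtered, file.path(config$out_dir, "filtered_table.tsv")
  ))
  depth <- config$depth %||% min(rowSums(ingest$table$counts))
  chao <- stage("diversity", env,
                table_chao(ingest$table, depth = depth, seed = seeds$chao))
  chao_test <- stage("diversity_test", env,
                     project_median_test(chao, ingest$metadata))
  da <- stage("diff_abundance", env,
              diff_abundance(filtered, ingest$metadata, alpha = config$alpha))
  stage("write_diffabund", env, write_diffabund_tsv(
    da, file.path(config$out_dir, "differential_abundance.tsv")
  ))
  balanced <- stage("balance", env,
                    build_balanced_dataset(ingest$metadata,
                                           seed = seeds$balance))
  stage("write_manifesttsv", env, write_manifest_tsv(
    balanced, ingest$metadata,
    file.path(config$out_dir, "balanced_dataset.tsv")
  ))
  train_ids <- unlist(balanced$sample_ids, use.names = FALSE)
  mcfg <- model_config(feature_mode = config$feature_mode, clr = config$clr,
                       seed = seeds$model, coarse_grid = config$coarse_grid,
                       fine_grid = config$fine_grid)
  mw_set <- if (config$feature_mode == "mw_fdr") {
    select_features(da, "fdr")
  } else if (config$feature_mode == "mw_holm") {
    select_features(da, "holm")
  } else NULL
  sub_table <- feature_table(
    filtered$counts[train_ids, , drop = FALSE], level = filtered$level
  )
  sub_meta <- ingest$metadata[match(train_ids, ingest$metadata$sample_id), ]
  design <- stage("assemble", env,
                  assemble_design(sub_table, sub_meta, chao, mcfg,
                                  mw_set = mw_set))
  params <- config$params
  search <- NULL
  if (isTRUE(config$search)) {
    search <- stage("param_search", env,
                    two_step_param_search(design$x, design$y, mcfg))
    params <- search$params
  }
  report <- stage("fit", env,
                  fit_final(design$x, design$y, params, seed = seeds$model))
  stage("write_report", env, write_model_report(
    report, file.path(config$out_dir, "model_report.json")
  ))
  lc_summary <- NULL
  if (isTRUE(config$learning_curve)) {
    lc <- if (config$lc_scale == "desk") {
      learning_curve_config(cap = 20, resamples = 2, seed = seeds$learning_curve)
    } else {
      learning_curve_config(cap = 200, resamples = 5,
                            seed = seeds$learning_curve)
    }
    lc_res <- stage("learning_curve", env,
                    run_learning_curve(filtered, ingest$metadata, params,
                                       chao = chao, config = mcfg,
                                       mw_set = mw_set, lc = lc))
    lc_summary <- summarize_curve(lc_res)
    write.table(lc_summary$per_n,
                file.path(config$out_dir, "learning_curve.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package_version = as.character(packageVersion("hostclass")),
    seed = config$seed,
    derived_seeds = seeds,
    level = config$level,
    feature_mode = config$feature_mode,
    clr = config$clr,
    alpha = config$alpha,
    depth = depth,
    params = params,
    chao_project_median_p = chao_test$p_value,
    n_features = length(design$taxa),
    stages = env$stages
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
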