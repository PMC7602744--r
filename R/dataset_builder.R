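# Host-balanced dataset construction. The minority host class is taken in
# full; the majority class is sampled down to the same size with per-project
# quotas so that no single study dominates the training set.

#' Per-project sampling quotas
#'
#' Water-filling: all projects share an equal quota; projects smaller than
#' the equal share contribute everything they have and the shortfall is
#' re-spread over the remaining projects; the final integer remainder is
#' assigned one sample at a time to the projects with the most remaining
#' samples, ties broken by project id. With `replacement = TRUE` pool sizes
#' do not cap the quotas (project-balanced resampling), and the remainder
#' goes to the largest pools first.
#'
#' @param pool_sizes named integer vector of available samples per project.
#' @param target total number of samples to allocate.
#' @param replacement allow quotas above pool sizes.
#' @return named integer vector of quotas summing to `target`.
#' @export
project_quotas <- function(pool_sizes, target, replacement = FALSE) {
  if (is.null(names(pool_sizes)) || anyDuplicated(names(pool_sizes))) {
    abort2("pool_sizes must have unique project names", "hostclass_bad_arg")
  }
  if (!replacement && target > sum(pool_sizes)) {
    abort2(
      sprintf("target %d exceeds the %d available samples", target,
              sum(pool_sizes)),
      "hostclass_bad_arg"
    )
  }
  ids <- names(pool_sizes)
  quota <- stats::setNames(integer(length(pool_sizes)), ids)
  active <- rep(TRUE, length(pool_sizes))
  rem <- as.integer(target)
  if (!replacement) {
    repeat {
      share <- rem %/% sum(active)
      small <- active & (pool_sizes <= share)
      if (!any(small)) break
      quota[small] <- as.integer(pool_sizes[small])
      active[small] <- FALSE
      rem <- as.integer(target - sum(quota))
      if (!any(active)) return(quota)
    }
  }
  share <- rem %/% sum(active)
  quota[active] <- quota[active] + share
  r <- rem - share * sum(active)
  if (r > 0) {
    cand <- ids[active]
    remaining <- pool_sizes[cand] - quota[cand]
    ord <- cand[order(-remaining, cand)]
    bump <- ord[seq_len(r)]
    quota[bump] <- quota[bump] + 1L
  }
  quota
}

#' Build a host-balanced, project-balanced dataset
#'
#' The per-class target defaults to the minority class total, so the
#' minority class is taken in full and the majority class is down-sampled
#' with per-project quotas (see [project_quotas()]). Sampling is without
#' replacement unless `replacement = TRUE`, the mode used by the project
#' learning curve where a few projects must supply the whole class.
#'
#' @param metadata sample metadata (see [validate_metadata] columns).
#' @param seed integer seed.
#' @param replacement sample within projects with replacement.
#' @param target_per_class samples per class; defaults to the minority
#'   class total.
#' @return an object of class `balanced_dataset`: list with `sample_ids`
#'   (named list per class), `quotas`, `target_per_class`, `replacement`,
#'   `seed`.
#' @export
build_balanced_dataset <- function(metadata, seed = 1, replacement = FALSE,
                                   target_per_class = NULL) {
  metadata <- validate_metadata(metadata)
  classes <- c("pet", "human")
  totals <- vapply(classes, function(cls) sum(metadata$host == cls), integer(1))
  if (any(totals == 0)) {
    abort2("both host classes must be non-empty", "hostclass_bad_metadata")
  }
  target <- as.integer(target_per_class %||% min(totals))
  out <- list()
  quotas <- list()
  for (cls in classes) {
    sub <- metadata[metadata$host == cls, , drop = FALSE]
    if (!replacement && target == nrow(sub)) {
      out[[cls]] <- sub$sample_id
      quotas[[cls]] <- table(factor(sub$project_id,
                                    levels = unique(sub$project_id)))
      quotas[[cls]] <- stats::setNames(as.integer(quotas[[cls]]),
                                       names(quotas[[cls]]))
      next
    }
    pools <- vapply(split(sub$sample_id, sub$project_id), length, integer(1))
    q <- project_quotas(pools, target, replacement = replacement)
    ids_by_project <- split(sub$sample_id, sub$project_id)
    picked <- withr::with_seed(
      derive_seed(seed, paste0("balance/", cls)),
      unlist(lapply(names(q), function(p) {
        pool <- ids_by_project[[p]]
        if (!replacement && q[[p]] == length(pool)) return(pool)
        sample(pool, q[[p]], replace = replacement)
      }), use.names = FALSE)
    )
    out[[cls]] <- picked
    quotas[[cls]] <- q
  }
  structure(
    list(sample_ids = out, quotas = quotas, target_per_class = target,
         replacement = replacement, seed = seed),
    class = "balanced_dataset"
  )
}

#' @export
print.balanced_dataset <- function(x, ...) {
  cat(sprintf(
    "balanced_dataset: %d pet + %d human samples (%s replacement, seed %d)\n",
    length(x$sample_ids$pet), length(x$sample_ids$human),
    if (x$replacement) "with" else "without", x$seed
  ))
  invisible(x)
}

#' Mixed-species evaluation sets
#'
#' Draws `n_sets` sets of samples with a fixed species composition (default
#' 50 cats + 50 dogs + 100 humans, a 200-sample host-balanced set); sampling
#' within a set is without replacement.
#'
#' @param metadata sample metadata.
#' @param n_sets number of sets (default 100).
#' @param composition named integer vector of per-species quotas.
#' @param seed integer seed.
#' @return list of character vectors of sample ids.
#' @export
build_mixed_sets <- function(metadata, n_sets = 100,
                             composition = c(cat = 50, dog = 50, human = 100),
                             seed = 1) {
  metadata <- validate_metadata(metadata)
  pools <- split(metadata$sample_id, metadata$species)
  for (sp in names(composition)) {
    if (composition[[sp]] > length(pools[[sp]] %||% character(0))) {
      abort2(
        sprintf("species '%s' pool (%d) smaller than quota %d", sp,
                length(pools[[sp]] %||% character(0)), composition[[sp]]),
        "hostclass_bad_arg"
      )
    }
  }
  withr::with_seed(derive_seed(seed, "mixed_sets"), {
    lapply(seq_len(n_sets), function(i) {
      unlist(lapply(names(composition), function(sp) {
        if (composition[[sp]] == 0) return(character(0))
        sample(pools[[sp]], composition[[sp]])
      }), use.names = FALSE)
    })
  })
}

#' Write a sample-id manifest as TSV
#'
#' @param dataset a [build_balanced_dataset()] result.
#' @param metadata sample metadata.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest_tsv <- function(dataset, metadata, path) {
  metadata <- validate_metadata(metadata)
  ids <- unlist(dataset$sample_ids, use.names = FALSE)
  df <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf(
    "# balanced dataset: target_per_class=%d replacement=%s seed=%d",
    dataset$target_per_class, dataset$replacement, dataset$seed
  ), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
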