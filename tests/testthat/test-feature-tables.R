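test_that("a toy table round-trips through TSV bit-identically", {
  tab <- toy_table()
  meta <- toy_metadata()
  p1 <- withr::local_tempfile(fileext = ".tsv")
  pm <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab, p1)
  write_metadata(meta, pm)
  back <- read_feature_table(p1, pm)
  expect_identical(back$table$counts, tab$counts)
  expect_identical(back$table$level, "genus")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(back$table, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("metadata validation enforces the species/host invariant", {
  meta <- toy_metadata()
  meta$host[1] <- "human" # but species is cat
  expect_error(write_metadata(meta, tempfile()), "inconsistent",
               class = "hostclass_bad_metadata")
  meta2 <- rbind(toy_metadata(), toy_metadata()[1, ])
  expect_error(hostclass:::validate_metadata(meta2), "duplicate",
               class = "hostclass_bad_metadata")
})

test_that("misaligned table and metadata raise an error naming the sample", {
  tab <- toy_table()
  meta <- toy_metadata()[1, , drop = FALSE] # s2 missing
  p1 <- withr::local_tempfile(fileext = ".tsv")
  pm <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab, p1)
  write_metadata(meta, pm)
  expect_error(read_feature_table(p1, pm), "s2",
               class = "hostclass_misaligned")
})

test_that("malformed lineages and non-integer counts are rejected", {
  expect_error(parse_lineage("Bacteria;P1;C1", level = "genus"),
               "expected 6 ranks", class = "hostclass_bad_lineage")
  p1 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tBacteria;P1", "s1\t1.5"), con = p1)
  pm <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(toy_metadata()[1, ], pm)
  expect_error(read_feature_table(p1, pm), "non-integer",
               class = "hostclass_bad_table")
})

test_that("aggregation sums counts over lineage prefixes", {
  tab <- toy_table()
  # genus -> genus is the identity
  expect_identical(aggregate_to_level(tab, "genus"), tab)
  fam <- aggregate_to_level(tab, "family")
  expect_identical(
    fam$counts,
    matrix(c(15L, 7L, 3L, 2L), nrow = 2, byrow = TRUE,
           dimnames = list(c("s1", "s2"),
                           c("Bacteria;P1;C1;O1;F1", "Bacteria;P1;C1;O2;F2")))
  )
  expect_error(aggregate_to_level(fam, "genus"), "aggregate",
               class = "hostclass_bad_level")
})

test_that("aggregation conserves per-sample totals at every rank and composes", {
  for (seed in 1:5) {
    tab <- rand_dataset(seed)$table
    for (lv in taxonomic_ranks()) {
      agg <- aggregate_to_level(tab, lv)
      expect_equal(rowSums(agg$counts), rowSums(tab$counts))
    }
    # idempotent at a fixed level, and genus->family->phylum == genus->phylum
    fam <- aggregate_to_level(tab, "family")
    expect_identical(aggregate_to_level(fam, "family"), fam)
    expect_identical(aggregate_to_level(fam, "phylum")$counts,
                     aggregate_to_level(tab, "phylum")$counts)
  }
})

test_that("filter_rare removes taxa only when rare in both classes", {
  counts <- matrix(0L, 20, 3, dimnames = list(
    sprintf("s%02d", 1:20),
    c("Bacteria;P1;C1;O1;F1;g1", "Bacteria;P1;C1;O1;F1;g2",
      "Bacteria;P1;C1;O1;F1;g3")
  ))
  counts[, 1] <- 5L                      # never zero -> retained
  counts[11, 2] <- 3L                    # zero in 10/10 pets, 9/10 humans
  counts[, 3] <- 0L                      # zero everywhere -> removed
  counts[, 1] <- counts[, 1] + 0L
  meta <- data.frame(
    sample_id = rownames(counts),
    host = rep(c("pet", "human"), each = 10),
    species = rep(c("cat", "human"), each = 10),
    project_id = rep(c("pA", "pB"), each = 10),
    stringsAsFactors = FALSE
  )
  out <- filter_rare(feature_table(counts, "genus"), meta)
  # human zero fraction for g2 is exactly 0.9, not > 0.9 -> retained
  expect_identical(colnames(out$counts), colnames(counts)[1:2])
  expect_error(filter_rare(feature_table(counts, "genus"), meta, 1.5),
               class = "hostclass_bad_arg")
})

test_that("filter_rare matches a brute-force zero-fraction oracle and is monotone", {
  for (seed in 1:8) {
    ds <- rand_dataset(seed, n_pet = 5, n_human = 7, n_taxa = 15)
    for (thr in c(0.2, 0.5, 0.9)) {
      kept <- colnames(filter_rare(ds$table, ds$metadata, thr)$counts)
      zf <- sapply(c("pet", "human"), function(cls) {
        colMeans(ds$table$counts[ds$metadata$host == cls, , drop = FALSE] == 0)
      })
      oracle <- colnames(ds$table$counts)[!(zf[, "pet"] > thr & zf[, "human"] > thr)]
      expect_identical(kept, oracle)
    }
    # raising the threshold never drops a taxon a lower threshold kept
    k1 <- colnames(filter_rare(ds$table, ds$metadata, 0.3)$counts)
    k2 <- colnames(filter_rare(ds$table, ds$metadata, 0.7)$counts)
    expect_true(all(k1 %in% k2))
  }
})

test_that("BIOM-style dense TSV imports agree with the native layout", {
  tab <- toy_table()
  p <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(`#OTU ID` = colnames(tab$counts), t(tab$counts),
                   check.names = FALSE)
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_biom_dense_tsv(p)
  expect_equal(back$counts[rownames(tab$counts), colnames(tab$counts)],
               tab$counts)
})
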