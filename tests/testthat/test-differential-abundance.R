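# definitional oracles live in helper-oracles.R

test_that("project medians reduce each study to its median relative abundance", {
  # single-sample project: its row is that sample's relative abundances
  tab <- toy_table()
  meta <- toy_metadata()
  pm <- project_medians(tab, meta)
  expect_equal(pm["pA", ], relative_abundance(tab)["s1", ])
  expect_identical(attr(pm, "host"), c("pet", "human"))

  # three samples with relative abundances 0.2, 0.4, 0.9 -> median 0.4
  counts <- matrix(c(2L, 8L, 4L, 6L, 9L, 1L), 3, 2, byrow = TRUE,
                   dimnames = list(c("a", "b", "c"),
                                   c("Bacteria;P1;C1;O1;F1;g1",
                                     "Bacteria;P1;C1;O1;F1;g2")))
  meta3 <- data.frame(sample_id = c("a", "b", "c"), host = "pet",
                      species = "dog", project_id = "pX",
                      stringsAsFactors = FALSE)
  pm3 <- project_medians(feature_table(counts, "genus"), meta3)
  expect_equal(unname(pm3["pX", 1]), 0.4)
})

test_that("the cross-study training design yields 12 pet and 10 human project rows", {
  md <- design_metadata(reference_study_design(), "n_train")
  counts <- matrix(1L, nrow(md), 2,
                   dimnames = list(md$sample_id,
                                   c("Bacteria;P1;C1;O1;F1;g1",
                                     "Bacteria;P1;C1;O1;F1;g2")))
  pm <- project_medians(feature_table(counts, "genus"), md)
  expect_equal(sum(attr(pm, "host") == "pet"), 12)
  expect_equal(sum(attr(pm, "host") == "human"), 10)
})

test_that("Mann-Whitney p is exact under complete separation and safe under ties", {
  p <- mann_whitney_two_sided(1:12, 101:110)
  expect_equal(p, 2 * 1 / choose(22, 10), tolerance = 1e-12)
  expect_equal(mann_whitney_two_sided(rep(3, 6), rep(3, 5)), 1)
  expect_error(mann_whitney_two_sided(numeric(0), 1:3),
               class = "hostclass_bad_arg")
  # rank-based: invariant to monotone transforms of the pooled values
  x <- c(0.1, 0.7, 2.3, 5); y <- c(0.4, 1.1, 3.3)
  expect_equal(mann_whitney_two_sided(x, y),
               mann_whitney_two_sided(exp(x), exp(y)))
})

test_that("Mann-Whitney p matches exhaustive permutation on all 4-vs-3 rank datasets", {
  splits <- combn(7, 4)
  for (j in seq_len(ncol(splits))) {
    x <- splits[, j]
    y <- setdiff(1:7, x)
    expect_equal(mann_whitney_two_sided(x, y),
                 mw_permutation_oracle(x, y),
                 tolerance = 1e-12,
                 info = paste("split", j))
  }
})

test_that("Holm and BH decisions match hand-worked step examples", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_identical(holm_correction(p), c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(bh_fdr(p), rep(TRUE, 4))
  expect_identical(holm_correction(rep(1, 5)), rep(FALSE, 5))
  expect_identical(bh_fdr(rep(1, 5)), rep(FALSE, 5))
  expect_identical(holm_correction(0.01), TRUE)
  expect_error(holm_correction(c(0.5, 1.2)), class = "hostclass_bad_arg")
  expect_error(bh_fdr(0.5, alpha = 0), class = "hostclass_bad_arg")
})

test_that("Holm and BH match definitional oracles and BH dominates Holm", {
  for (seed in 1:200) {
    p <- withr::with_seed(seed, runif(sample(2:50, 1))^sample(1:3, 1))
    h <- holm_correction(p, 0.05)
    b <- bh_fdr(p, 0.05)
    expect_identical(h, holm_oracle(p, 0.05))
    expect_identical(b, bh_oracle(p, 0.05))
    expect_true(all(b[h])) # every Holm rejection is a BH rejection
  }
})

test_that("feature selection returns flagged taxa in stable order", {
  res <- structure(
    data.frame(taxon = c("t1", "t2", "t3"), level = "genus",
               p_value = c(0.001, 0.5, 0.002),
               holm = c(TRUE, FALSE, FALSE),
               fdr = c(TRUE, FALSE, TRUE),
               direction = "human", stringsAsFactors = FALSE),
    class = c("diffabund_result", "data.frame")
  )
  expect_identical(select_features(res, "fdr"), c("t1", "t3"))
  expect_identical(select_features(res, "holm"), "t1")
  expect_true(all(select_features(res, "holm") %in% select_features(res, "fdr")))
})

test_that("planted host effects are recovered by the FDR set on one seeded run", {
  cfg <- make_generator_config()
  ds <- generate_dataset(cfg, seed = 5)
  ft <- filter_rare(ds$table, ds$metadata)
  da <- diff_abundance(ft, ds$metadata)
  sel <- select_features(da, "fdr")
  expect_true(all(ds$truth$planted %in% sel))
  expect_true(all(select_features(da, "holm") %in% sel))
})

test_that("the project-median test applies to per-sample scalars like Chao1", {
  ds <- rand_dataset(21, n_pet = 8, n_human = 8)
  vals <- stats::setNames(rowSums(ds$table$counts), ds$metadata$sample_id)
  res <- project_median_test(vals, ds$metadata)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_length(res$medians, 4)
})
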