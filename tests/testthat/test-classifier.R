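tiny_fit_data <- function(seed = 1) {
  cfg <- make_generator_config(layout = make_study_layout("tiny"))
  ds <- generate_dataset(cfg, seed = seed)
  ft <- filter_rare(ds$table, ds$metadata)
  chao <- table_chao(ds$table, depth = 5000, seed = seed)
  list(ds = ds, ft = ft, chao = chao)
}

test_that("the design matrix is taxa plus one Chao column with class-1 = human", {
  d <- tiny_fit_data(1)
  des <- assemble_design(d$ft, d$ds$metadata, d$chao)
  expect_equal(ncol(des$x), ncol(d$ft$counts) + 1)
  expect_identical(colnames(des$x)[ncol(des$x)], "chao")
  expect_identical(levels(des$y), c("pet", "human"))
  # restricting to a 5-taxon set gives 6 columns
  mw <- colnames(d$ft$counts)[3:7]
  des5 <- assemble_design(d$ft, d$ds$metadata, d$chao,
                          model_config(feature_mode = "mw_fdr"), mw_set = mw)
  expect_equal(ncol(des5$x), 6)
  expect_identical(des5$taxa, mw)
  # CLR applies to abundance columns only
  desc <- assemble_design(d$ft, d$ds$metadata, d$chao,
                          model_config(clr = TRUE))
  abund <- desc$x[, setdiff(colnames(desc$x), "chao")]
  expect_lt(max(abs(rowSums(clr_transform(d$ft)))), 1e-9)
  expect_false(all(abs(rowSums(desc$x)) < 1e-9)) # chao column breaks the sum
  # errors: empty set, missing chao
  expect_error(assemble_design(d$ft, d$ds$metadata, d$chao,
                               model_config(feature_mode = "mw_fdr"),
                               mw_set = character(0)),
               class = "hostclass_empty_features")
  expect_error(assemble_design(d$ft, d$ds$metadata, d$chao[-1]),
               class = "hostclass_misaligned")
})

test_that("CV folds are stratified within one sample of the global class balance", {
  d <- separable_design(2, n_per_class = 33)
  cfg <- model_config(seed = 7,
                      coarse_grid = expand.grid(mtry = 2, depth = 5,
                                                min_split = 2, trees = 10),
                      fine_grid = list(mtry = 2, depth = 5, min_split = 2,
                                       trees = 10))
  res <- two_step_param_search(d$x, d$y, cfg)
  global <- mean(d$y == "human")
  for (f in res$folds) {
    expect_lte(abs(sum(d$y[f] == "human") - global * length(f)), 1)
  }
})

test_that("the two-step search finds a perfect simple model on separable data", {
  d <- separable_design(3)
  cfg <- model_config(
    seed = 5,
    coarse_grid = expand.grid(mtry = c(2, 4), depth = c(2, 10),
                              min_split = c(2, 10), trees = c(10, 50)),
    fine_grid = list(mtry = c(2, 4), depth = c(2, 6, 10),
                     min_split = c(2, 10), trees = c(10, 50))
  )
  res <- two_step_param_search(d$x, d$y, cfg)
  expect_equal(res$cv_accuracy, 1)
  # tie-break: the simplest configuration attaining the maximum
  step_trees <- res$step2$trees
  best_acc <- max(step_trees$cv_accuracy)
  expect_equal(res$params$trees, min(step_trees$trees[
    step_trees$cv_accuracy == best_acc]))
  # deterministic under the seed
  res2 <- two_step_param_search(d$x, d$y, cfg)
  expect_identical(res$params, res2$params)
  expect_identical(res$step1, res2$step1)
  expect_error(two_step_param_search(d$x, factor(rep("pet", length(d$y)),
                                                 levels = c("pet", "human")),
                                     cfg),
               class = "hostclass_bad_arg")
})

test_that("with a single coarse combination, step 2 equals explicit 1-D sweeps", {
  d <- separable_design(4, n_per_class = 25, p = 5)
  coarse <- expand.grid(mtry = 2, depth = 4, min_split = 4, trees = 10)
  fine <- list(mtry = c(2, 3), depth = c(2, 4, 8), min_split = c(2, 4),
               trees = c(5, 10, 50))
  cfg <- model_config(seed = 11, coarse_grid = coarse, fine_grid = fine)
  res <- two_step_param_search(d$x, d$y, cfg)

  # oracle: sequential 1-D sweeps coded independently of the search routine
  folds <- withr::with_seed(derive_seed(11, "folds"),
                            caret::createFolds(d$y, k = 5))
  current <- as.list(coarse)
  for (par in c("mtry", "depth", "min_split", "trees")) {
    accs <- sapply(fine[[par]], function(v) {
      prm <- current
      prm[[par]] <- v
      hostclass:::cv_accuracy(d$x, d$y, prm, folds, 11)
    })
    grid <- do.call(rbind, lapply(fine[[par]], function(v) {
      prm <- current; prm[[par]] <- v; as.data.frame(prm)
    }))
    current <- as.list(grid[hostclass:::pick_best(grid, accs), ])
  }
  expect_identical(res$params, lapply(current, as.integer))
})

test_that("final fits report stable OOB scores with normalized importances", {
  d <- tiny_fit_data(6)
  des <- assemble_design(d$ft, d$ds$metadata, d$chao)
  params <- list(mtry = 8, depth = 12, min_split = 2, trees = 100)
  rep5 <- fit_final(des$x, des$y, params, seed = 2, refits = 5)
  expect_gte(rep5$metrics$mean[rep5$metrics$metric == "accuracy"], 0.95)
  expect_true(all(rep5$metrics$mean >= 0 & rep5$metrics$mean <= 1))
  expect_true(all(rep5$metrics$sd >= 0))
  expect_true(all(rep5$importance >= 0))
  expect_equal(sum(rep5$importance), 1)
  expect_equal(nrow(rep5$oob_scores), 5)
  # refits = 1 -> zero SDs, flagged
  expect_warning(rep1 <- fit_final(des$x, des$y, params, seed = 2, refits = 1),
                 "refits = 1")
  expect_true(rep1$sd_degenerate)
  expect_true(all(rep1$metrics$sd == 0))
  # a one-tree forest cannot give every sample an OOB vote
  expect_error(fit_final(des$x, des$y,
                         list(mtry = 8, depth = 12, min_split = 2, trees = 1),
                         seed = 2, refits = 1),
               class = "hostclass_oob_unstable")
})

test_that("OOB accuracy tracks held-out accuracy on exchangeable data", {
  lay <- list(pet_sizes = rep(75L, 4), pet_species = rep("dog", 4),
              human_sizes = rep(75L, 4))
  cfg <- make_generator_config(layout = lay, sigma_batch = 0, effect_size = 1)
  train <- generate_dataset(cfg, seed = 21)
  fresh <- generate_dataset(cfg, seed = 22)
  ft_t <- filter_rare(train$table, train$metadata)
  chao_t <- table_chao(train$table, seed = 1)
  des_t <- assemble_design(ft_t, train$metadata, chao_t)
  params <- list(mtry = 8, depth = 12, min_split = 2, trees = 200)
  report <- fit_final(des_t$x, des_t$y, params, seed = 3, refits = 3)
  oob <- report$metrics$mean[report$metrics$metric == "accuracy"]
  # fresh data, same taxa columns
  keep <- colnames(ft_t$counts)
  ft_f <- feature_table(fresh$table$counts[, keep, drop = FALSE], "genus")
  chao_f <- table_chao(fresh$table, seed = 2)
  des_f <- assemble_design(ft_f, fresh$metadata, chao_f)
  scores <- predict_scores(report, des_f$x)
  held_out <- mean((scores >= 0.5) == (des_f$y == "human"))
  expect_lte(abs(oob - held_out), 0.05)
})

test_that("an all-constant feature does not change predicted classes", {
  d <- separable_design(8)
  params <- list(mtry = 3, depth = 10, min_split = 2, trees = 100)
  base <- fit_final(d$x, d$y, params, seed = 4, refits = 1) |>
    suppressWarnings()
  xc <- cbind(d$x, constant = 1)
  withc <- fit_final(xc, d$y, params, seed = 4, refits = 1) |>
    suppressWarnings()
  pred_a <- predict_scores(base, d$x) >= 0.5
  pred_b <- predict_scores(withc, xc) >= 0.5
  expect_identical(pred_a, pred_b)
})

test_that("importance overlap scores the top-k features against a reference set", {
  d <- separable_design(9, p = 5)
  # only column 1 is informative; make a second informative column
  d$x[d$y == "human", 2] <- d$x[d$y == "human", 2] + 8
  params <- list(mtry = 2, depth = 10, min_split = 2, trees = 200)
  report <- fit_final(d$x, d$y, params, seed = 5, refits = 2)
  informative <- colnames(d$x)[1:2]
  expect_equal(importance_overlap(report, informative), 1)
  expect_equal(importance_overlap(report, colnames(d$x)[1:4]), 1)
  expect_equal(importance_overlap(report, setdiff(colnames(d$x)[3:4],
                                                  "chao")), 0)
  expect_error(importance_overlap(report, character(0)),
               class = "hostclass_bad_arg")
})

test_that("prediction refuses mismatched or permuted design columns", {
  d <- separable_design(10)
  params <- list(mtry = 2, depth = 8, min_split = 2, trees = 100)
  report <- fit_final(d$x, d$y, params, seed = 6, refits = 2)
  scores <- predict_scores(report, d$x)
  expect_true(all(scores >= 0 & scores <= 1))
  expect_true(all(scores[d$y == "human"] >= 0.5))
  expect_error(predict_scores(report, d$x[, rev(colnames(d$x))]),
               class = "hostclass_misaligned")
  hist_df <- score_histograms(
    stats::setNames(scores, rownames(d$x)),
    data.frame(sample_id = rownames(d$x),
               host = as.character(d$y),
               species = ifelse(d$y == "human", "human", "dog"),
               project_id = rep(c("pA", "hA"), each = 30),
               stringsAsFactors = FALSE)
  )
  expect_setequal(unique(hist_df$project_id), c("pA", "hA"))
  expect_equal(sum(hist_df$count), 60)
})

test_that("model reports serialize to JSON", {
  d <- separable_design(11)
  report <- fit_final(d$x, d$y,
                      list(mtry = 2, depth = 8, min_split = 2, trees = 50),
                      seed = 7, refits = 2)
  p <- withr::local_tempfile(fileext = ".json")
  write_model_report(report, p)
  back <- jsonlite::read_json(p)
  expect_equal(back$params$trees, 50)
  expect_length(back$importance, ncol(d$x))
})
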