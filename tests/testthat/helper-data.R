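# Fixtures are built in code: a tiny hand-written table for exact checks and
# a seeded random-table factory for property-style tests.

toy_counts <- function() {
  m <- matrix(
    c(10L, 5L, 7L,
      0L, 3L, 2L),
    nrow = 2, byrow = TRUE,
    dimnames = list(
      c("s1", "s2"),
      c("Bacteria;P1;C1;O1;F1;g1",
        "Bacteria;P1;C1;O1;F1;g2",
        "Bacteria;P1;C1;O2;F2;g3")
    )
  )
  m
}

toy_table <- function() feature_table(toy_counts(), level = "genus")

toy_metadata <- function() {
  data.frame(
    sample_id = c("s1", "s2"),
    host = c("pet", "human"),
    species = c("cat", "human"),
    project_id = c("pA", "pB"),
    stringsAsFactors = FALSE
  )
}

# random genus table with a two-class metadata, for property tests
rand_dataset <- function(seed, n_pet = 6, n_human = 6, n_taxa = 12,
                         max_count = 30) {
  withr::with_seed(seed, {
    n <- n_pet + n_human
    counts <- matrix(rpois(n * n_taxa, lambda = runif(n_taxa, 0, 8)),
                     nrow = n, byrow = TRUE)
    counts[sample(length(counts), length(counts) %/% 4)] <- 0L
    counts[, 1] <- counts[, 1] + 1L # keep every sample non-empty
    storage.mode(counts) <- "integer"
    fams <- sprintf("F%02d", ((seq_len(n_taxa) - 1) %% 5) + 1)
    phys <- sprintf("P%02d", ((seq_len(n_taxa) - 1) %% 3) + 1)
    colnames(counts) <- sprintf("Bacteria;%s;C_%s;O_%s;%s;g%03d",
                                phys, phys, fams, fams, seq_len(n_taxa))
    rownames(counts) <- sprintf("s%03d", seq_len(n))
    metadata <- data.frame(
      sample_id = rownames(counts),
      host = rep(c("pet", "human"), c(n_pet, n_human)),
      species = rep(c("dog", "human"), c(n_pet, n_human)),
      project_id = rep(c("p1", "p2", "h1", "h2"),
                       c(ceiling(n_pet / 2), floor(n_pet / 2),
                         ceiling(n_human / 2), floor(n_human / 2))),
      stringsAsFactors = FALSE
    )
    list(table = feature_table(counts, "genus"), metadata = metadata)
  })
}

# small separable design for classifier tests
separable_design <- function(seed = 1, n_per_class = 30, p = 6) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(2 * n_per_class * p), ncol = p)
    y <- factor(rep(c("pet", "human"), each = n_per_class),
                levels = c("pet", "human"))
    x[y == "human", 1] <- x[y == "human", 1] + 8
    colnames(x) <- c(sprintf("taxon%02d", seq_len(p - 1)), "chao")
    rownames(x) <- sprintf("s%03d", seq_len(2 * n_per_class))
    list(x = x, y = y)
  })
}
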