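# Shared builders for tests. Everything is generated in code; no stored
# fixtures. Configs are deliberately small: the statistic's validity does not
# depend on ensemble size, and the learning rate is raised as the tree count
# shrinks (rate x rounds held near 10, the analysis profile's product).

toy_config <- function(num_rounds = 20, learning_rate = 0.3, n_folds = 3,
                       ...) {
  boost_config(num_rounds = num_rounds, learning_rate = learning_rate,
               n_folds = n_folds, ...)
}

# Reduced-size profile used by the simulation-heavy acceptance checks.
smoke_config <- function(n_folds = 5) {
  boost_config(num_rounds = 50, learning_rate = 0.2, n_folds = n_folds)
}

default_pool <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synth_haplotype_pool(seed = 90L)
    cache
  }
})

# Hand-rolled tiny dataset: 2 genes x (2 + 2) SNPs, deterministic genotypes.
tiny_data <- function(n = 40, seed = 1) {
  g <- ggiboost:::with_seed(seed,
    matrix(sample(0:2, n * 4, replace = TRUE), ncol = 4))
  colnames(g) <- c("rsA1", "rsA2", "rsB1", "rsB2")
  y <- ggiboost:::with_seed(seed + 1, sample(0:1, n, replace = TRUE))
  y[1:2] <- c(0L, 1L)  # both classes guaranteed
  ggi_data(g, y, data.frame(snp_id = colnames(g),
                            gene_id = c("A", "A", "B", "B")))
}

write_tiny_tsv <- function(data, dir = withr::local_tempdir(.local_envir =
                                                              parent.frame())) {
  geno <- file.path(dir, "geno.tsv")
  map <- file.path(dir, "genes.tsv")
  write_genotypes_tsv(data, geno)
  write_gene_map(data, map)
  list(geno = geno, map = map, dir = dir)
}

# Manually constructed ensemble dump in the engine's table layout:
# trees described as lists of rows (id, feature or NA, gain, yes, no).
manual_dump <- function(trees) {
  rows <- do.call(rbind, lapply(seq_along(trees), function(t) {
    td <- trees[[t]]
    data.frame(Tree = t - 1L, ID = paste0(t - 1L, "-", td$node),
               Feature = ifelse(is.na(td$feature), "Leaf", td$feature),
               Gain = td$gain,
               Yes = ifelse(is.na(td$yes), NA, paste0(t - 1L, "-", td$yes)),
               No = ifelse(is.na(td$no), NA, paste0(t - 1L, "-", td$no)),
               stringsAsFactors = FALSE)
  }))
  rows
}
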