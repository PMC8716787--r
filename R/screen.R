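#' Enumerate unordered gene pairs
#'
#' @param genes character vector of gene names.
#' @return data frame with columns `gene1`, `gene2`, one row per unordered
#'   pair (`choose(G, 2)` rows), pairs in lexicographic order.
#' @export
enumerate_gene_pairs <- function(genes) {
  genes <- sort(unique(as.character(genes)))
  if (length(genes) < 2) stop_ggi("need at least 2 genes")
  idx <- utils::combn(length(genes), 2)
  data.frame(gene1 = genes[idx[1, ]], gene2 = genes[idx[2, ]],
             stringsAsFactors = FALSE)
}

#' Screen gene pairs for interaction
#'
#' Runs the permutation interaction test for every requested pair of genes,
#' each on the submatrix of that pair's SNPs. Per-pair seeds are derived
#' deterministically from the master seed and the sorted gene names, so the
#' result does not depend on pair order or worker count.
#'
#' @param data a [ggi_data] covering two or more genes.
#' @param pairs `"all"` for every unordered pair, or a data frame / 2-column
#'   matrix of gene name pairs.
#' @param config a [boost_config].
#' @param m permutations per pair.
#' @param alpha significance level (the real-data analyses in the field
#'   typically use 0.01 with m = 1000).
#' @param adjust `"none"` (raw permutation p-values, the default) or `"bh"`
#'   for Benjamini-Hochberg across the screened pairs; significance is then
#'   judged on the adjusted values.
#' @param seed master seed.
#' @param workers parallel workers, passed through to [ggi_test()].
#' @return a `ggi_screen` object: a data frame with columns `gene1`, `gene2`,
#'   `delta_err0`, `p_value` (and `p_adjusted` under BH), `significant`,
#'   ordered by p-value; attributes record alpha, adjust, m and seed.
#' @export
ggi_screen <- function(data, pairs = "all", config = boost_config(),
                       m = 1000, alpha = 0.01, adjust = c("none", "bh"),
                       seed = 1L, workers = 1L) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(data, "ggi_data"))
  genes <- unique(data$snps$gene_id)
  if (identical(pairs, "all")) {
    pairs <- enumerate_gene_pairs(genes)
  } else {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    names(pairs)[1:2] <- c("gene1", "gene2")
    unknown <- setdiff(unique(c(pairs$gene1, pairs$gene2)), genes)
    if (length(unknown) > 0)
      stop_ggi("unknown gene name(s): ", paste(unknown, collapse = ", "))
    key <- apply(pairs[, 1:2], 1, function(r) paste(sort(r), collapse = "\r"))
    if (anyDuplicated(key)) stop_ggi("duplicate pair in `pairs`")
    if (any(pairs$gene1 == pairs$gene2))
      stop_ggi("a gene cannot be paired with itself")
  }
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    g12 <- sort(c(pairs$gene1[i], pairs$gene2[i]))
    cols <- which(data$snps$gene_id %in% g12)
    sub <- ggi_data(data$genotypes[, cols, drop = FALSE], data$phenotype,
                    data$snps[cols, , drop = FALSE], data$sample_ids)
    fit <- ggi_test(sub, partition = gene_partition_from(sub, g12),
                    config = config, m = m,
                    seed = derive_seed(seed, "pair", g12[1], g12[2]),
                    workers = workers)
    rows[[i]] <- data.frame(gene1 = g12[1], gene2 = g12[2],
                            delta_err0 = fit$delta_err0,
                            p_value = fit$p_value,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (adjust == "bh") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjusted < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  out <- out[order(out$p_value, out$gene1, out$gene2), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, alpha = alpha, adjust = adjust, m = as.integer(m),
            seed = as.integer(seed),
            class = c("ggi_screen", "data.frame"))
}

#' @export
print.ggi_screen <- function(x, ...) {
  cat("Gene-pair interaction screen: ", nrow(x), " pairs, alpha = ",
      attr(x, "alpha"), ", m = ", attr(x, "m"), " permutations, adjust = ",
      attr(x, "adjust"), "\n", sep = "")
  cat(sum(x$significant), " significant pair(s)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("... ", nrow(x) - 10, " more rows\n", sep = "")
  invisible(x)
}

#' Write a screen result as TSV
#' @param x a `ggi_screen`.
#' @param path output file.
#' @export
write_ggi_screen <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
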