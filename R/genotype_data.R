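#' Case-control genotype container
#'
#' Bundles an n x d matrix of minor-allele counts with SNP metadata and a
#' binary phenotype. Genotypes are coded 0/1/2 (copies of the minor allele);
#' missing genotypes are `NA` — an out-of-band sentinel, never 0.
#'
#' @param genotypes integer matrix, samples in rows, SNPs in columns; entries
#'   in \{0, 1, 2, NA\}. Column names are taken as SNP ids if `snps` lacks them.
#' @param phenotype vector of 0 (control) / 1 (case), one per sample.
#' @param snps data frame with columns `snp_id`, `gene_id` and optionally
#'   `chromosome`, `position` (1-based, inclusive); one row per genotype column.
#' @param sample_ids optional character vector of unique sample identifiers.
#' @return an object of class `ggi_data`: a list with elements `genotypes`,
#'   `snps`, `phenotype`, `sample_ids`.
#' @export
ggi_data <- function(genotypes, phenotype, snps, sample_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.character(snps)) snps <- data.frame(snp_id = colnames(genotypes),
                                             gene_id = snps)
  snps <- as.data.frame(snps)
  if (!all(c("snp_id", "gene_id") %in% names(snps)))
    stop_ggi("`snps` must have columns snp_id and gene_id")
  if (nrow(snps) != ncol(genotypes))
    stop_ggi("snps table has ", nrow(snps), " rows but genotype matrix has ",
             ncol(genotypes), " columns")
  if (anyDuplicated(snps$snp_id))
    stop_ggi("duplicated snp_id in SNP table")
  bad <- !(genotypes %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad))
    stop_ggi("genotype values outside {0, 1, 2, NA} found (e.g. ",
             genotypes[which(bad)[1]], ")")
  phenotype <- as.integer(phenotype)
  if (length(phenotype) != nrow(genotypes))
    stop_ggi("phenotype length does not match number of samples")
  if (anyNA(phenotype) || !all(phenotype %in% c(0L, 1L)))
    stop_ggi("phenotype must be coded 0 (control) / 1 (case)")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(genotypes) %||% paste0("S", seq_len(nrow(genotypes)))
  }
  if (anyDuplicated(sample_ids)) stop_ggi("sample ids must be unique")
  colnames(genotypes) <- snps$snp_id
  rownames(genotypes) <- sample_ids
  structure(list(genotypes = genotypes, snps = snps,
                 phenotype = phenotype, sample_ids = as.character(sample_ids)),
            class = "ggi_data")
}

#' @export
print.ggi_data <- function(x, ...) {
  ng <- table(x$snps$gene_id)
  cat("Case-control genotype data: ", nrow(x$genotypes), " samples (",
      sum(x$phenotype == 1L), " cases / ", sum(x$phenotype == 0L),
      " controls), ", ncol(x$genotypes), " SNPs in ", length(ng),
      " gene(s)\n", sep = "")
  cat("  ", paste(names(ng), " (", as.integer(ng), " SNPs)",
                  sep = "", collapse = ", "), "\n", sep = "")
  nmiss <- sum(is.na(x$genotypes))
  if (nmiss > 0) cat("  missing genotypes: ", nmiss, "\n", sep = "")
  invisible(x)
}

#' @export
dim.ggi_data <- function(x) dim(x$genotypes)

#' Minor allele frequency per SNP
#'
#' Computed over non-missing entries as `min(f, 1 - f)` where `f` is the
#' coded-allele frequency `mean(g) / 2`.
#'
#' @param data a [ggi_data] object or a genotype matrix.
#' @return numeric vector, one MAF in `[0, 0.5]` per SNP.
#' @export
snp_maf <- function(data) {
  g <- if (inherits(data, "ggi_data")) data$genotypes else as.matrix(data)
  f <- colMeans(g, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Disjoint two-gene SNP partition
#'
#' The additivity constraint is defined by a partition of the SNP columns into
#' the two genes' index sets `s1` (p SNPs) and `s2` (q SNPs).
#'
#' @param s1,s2 integer vectors of 1-based column indices; disjoint, nonempty.
#' @param gene1,gene2 gene names.
#' @export
gene_partition <- function(s1, s2, gene1 = "gene1", gene2 = "gene2") {
  s1 <- as.integer(s1); s2 <- as.integer(s2)
  if (length(s1) < 1 || length(s2) < 1)
    stop_ggi("both genes must contribute at least one SNP")
  if (length(intersect(s1, s2)) > 0)
    stop_ggi("gene index sets overlap: ",
             paste(intersect(s1, s2), collapse = ", "))
  if (anyDuplicated(s1) || anyDuplicated(s2))
    stop_ggi("duplicated indices within a gene set")
  structure(list(gene1 = gene1, gene2 = gene2, s1 = s1, s2 = s2),
            class = "gene_partition")
}

#' @export
print.gene_partition <- function(x, ...) {
  cat("Gene partition: ", x$gene1, " (p = ", length(x$s1), " SNPs) vs ",
      x$gene2, " (q = ", length(x$s2), " SNPs)\n", sep = "")
  invisible(x)
}

#' Build the two-gene partition recorded in a dataset
#'
#' @param data a [ggi_data] object whose SNP table maps columns to exactly two
#'   genes (or more, in which case `genes` selects the pair).
#' @param genes optional length-2 character vector naming the pair.
#' @return a [gene_partition].
#' @export
gene_partition_from <- function(data, genes = NULL) {
  gid <- data$snps$gene_id
  if (is.null(genes)) {
    genes <- unique(gid)
    if (length(genes) != 2L)
      stop_ggi("expected exactly 2 genes, found ", length(genes), " (",
               paste(genes, collapse = ", "), "); pass `genes` to pick a pair")
  }
  if (length(genes) != 2L) stop_ggi("`genes` must name exactly 2 genes")
  missing_g <- setdiff(genes, gid)
  if (length(missing_g) > 0)
    stop_ggi("unknown gene(s): ", paste(missing_g, collapse = ", "))
  gene_partition(which(gid == genes[1]), which(gid == genes[2]),
                 genes[1], genes[2])
}

#' Read a SNP-to-gene map
#'
#' Tab-separated file with columns `snp_id`, `gene_id` and optionally
#' `chromosome`, `position`.
#'
#' @param path file path.
#' @export
read_gene_map <- function(path) {
  if (!file.exists(path)) stop_ggi("gene map file not found: ", path)
  gm <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("snp_id", "gene_id") %in% names(gm)))
    stop_ggi("gene map must have columns snp_id and gene_id")
  if (anyDuplicated(gm$snp_id))
    stop_ggi("gene map assigns some snp_id more than once")
  gm
}

#' Read case-control genotypes with a gene map
#'
#' Supports two plain-text layouts: PLINK `.raw` additive coding (header
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one `SNP_allele` column per
#' SNP; phenotype 1 = control, 2 = case, remapped here to 0/1; `NA` =
#' missing), and a simple TSV dialect (first column `sample_id`, one column
#' per SNP, a `label` column holding 0/1). Every SNP column must be assigned
#' to a gene by the map; two genes are expected for a pair test, and a
#' message reports any other count.
#'
#' @param geno_path genotype file path.
#' @param gene_map path to the SNP-to-gene map TSV, or a data frame as
#'   returned by [read_gene_map()].
#' @param format `"auto"` (by file extension), `"plink_raw"`, or `"tsv"`.
#' @param label_col name of the phenotype column in the TSV dialect.
#' @return a [ggi_data] object; when the map yields exactly two genes, the
#'   matching [gene_partition] is attached as attribute `"partition"`.
#' @export
read_genotypes <- function(geno_path, gene_map,
                           format = c("auto", "plink_raw", "tsv"),
                           label_col = "label") {
  format <- match.arg(format)
  if (!file.exists(geno_path)) stop_ggi("genotype file not found: ", geno_path)
  if (format == "auto")
    format <- if (grepl("\\.raw$", geno_path)) "plink_raw" else "tsv"
  gm <- if (is.data.frame(gene_map)) gene_map else read_gene_map(gene_map)

  if (format == "plink_raw") {
    raw <- utils::read.table(geno_path, header = TRUE, sep = "",
                             stringsAsFactors = FALSE, check.names = FALSE)
    meta_cols <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(meta_cols %in% names(raw)))
      stop_ggi("not a PLINK .raw file: header must contain ",
               paste(meta_cols, collapse = " "))
    snp_cols <- setdiff(names(raw), meta_cols)
    geno <- as.matrix(raw[, snp_cols, drop = FALSE])
    # PLINK appends the counted allele to each SNP column (rs123_A); strip
    # it only where the raw name is not itself a mapped SNP id, so ids that
    # legitimately contain underscores survive
    stripped <- sub("_[ACGT0-9]+$", "", snp_cols)
    colnames(geno) <- ifelse(snp_cols %in% gm$snp_id, snp_cols, stripped)
    ph <- raw$PHENOTYPE
    if (!all(ph %in% c(1, 2)))
      stop_ggi("PLINK .raw PHENOTYPE must be coded 1 (control) / 2 (case)")
    label <- as.integer(ph == 2)
    ids <- as.character(raw$IID)
  } else {
    tab <- utils::read.delim(geno_path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    if (names(tab)[1] != "sample_id")
      stop_ggi("TSV genotype file must start with a sample_id column")
    if (!label_col %in% names(tab))
      stop_ggi("phenotype column '", label_col, "' not found")
    label <- as.integer(tab[[label_col]])
    ids <- as.character(tab$sample_id)
    geno <- as.matrix(tab[, setdiff(names(tab), c("sample_id", label_col)),
                          drop = FALSE])
  }

  unmapped <- setdiff(colnames(geno), gm$snp_id)
  if (length(unmapped) > 0)
    stop_ggi("SNP(s) absent from the gene map: ",
             paste(unmapped, collapse = ", "))
  gm <- gm[match(colnames(geno), gm$snp_id), , drop = FALSE]
  genes <- unique(gm$gene_id)
  if (length(genes) < 2)
    stop_ggi("expected exactly 2 genes for a pair test, found ",
             length(genes))
  if (length(genes) != 2)
    message("gene map yields ", length(genes),
            " genes; a pair test needs exactly 2 (use ggi_screen for many)")
  out <- ggi_data(geno, label, gm, sample_ids = ids)
  if (length(genes) == 2L)
    attr(out, "partition") <- gene_partition_from(out)
  out
}

#' Write genotypes to the plain TSV dialect
#'
#' Inverse of the TSV branch of [read_genotypes()]; preserves values, SNP
#' order and labels.
#'
#' @param data a [ggi_data] object.
#' @param path output file.
#' @export
write_genotypes_tsv <- function(data, path) {
  tab <- data.frame(sample_id = data$sample_ids,
                    label = data$phenotype,
                    as.data.frame(data$genotypes), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genotypes as PLINK .raw (additive coding)
#' @inheritParams write_genotypes_tsv
#' @export
write_plink_raw <- function(data, path) {
  tab <- data.frame(FID = data$sample_ids, IID = data$sample_ids,
                    PAT = 0L, MAT = 0L, SEX = 0L,
                    PHENOTYPE = data$phenotype + 1L,
                    as.data.frame(data$genotypes), check.names = FALSE)
  utils::write.table(tab, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the SNP-to-gene map of a dataset
#' @inheritParams write_genotypes_tsv
#' @export
write_gene_map <- function(data, path) {
  utils::write.table(data$snps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Quality-control filter for SNPs
#'
#' Drops every SNP whose missing rate is at least `max_missing_rate`, whose
#' minor allele frequency (over non-missing entries) is at most `min_maf`, or
#' whose genotype counts among the CONTROL samples depart from Hardy-Weinberg
#' equilibrium at `hwe_alpha`. Boundaries are inclusive for the first two
#' rules (a SNP at exactly MAF 0.05 is dropped) and strict for HWE
#' (`p < hwe_alpha`). Each dropped SNP is reported once, with the first
#' triggering rule in the order missing_rate, maf, hwe.
#'
#' @param data a [ggi_data] object.
#' @param max_missing_rate drop when missing fraction >= this (default 0.10).
#' @param min_maf drop when MAF <= this (default 0.05).
#' @param hwe_alpha drop when the control-sample HWE p-value < this
#'   (default 1e-4).
#' @param hwe_test `"auto"` uses the chi-square (1 df) test, switching to the
#'   exact test when any HWE-expected genotype count is below 5; `"chisq"` or
#'   `"exact"` force one.
#' @return the filtered [ggi_data], with a `qc_report` data frame attached as
#'   attribute `"qc_report"` (see [qc_report()]). Errors if every SNP of a
#'   gene is removed, since that gene can no longer enter a pair test.
#' @export
qc_filter <- function(data, max_missing_rate = 0.10, min_maf = 0.05,
                      hwe_alpha = 1e-4,
                      hwe_test = c("auto", "chisq", "exact")) {
  hwe_test <- match.arg(hwe_test)
  g <- data$genotypes
  miss <- colMeans(is.na(g))
  maf <- snp_maf(g)
  ctrl <- g[data$phenotype == 0L, , drop = FALSE]
  hwe_p <- apply(ctrl, 2, function(col) {
    col <- col[!is.na(col)]
    n <- tabulate(col + 1L, nbins = 3L)
    hwe_pvalue(n[1], n[2], n[3], method = hwe_test)
  })
  reason <- rep(NA_character_, ncol(g))
  reason[hwe_p < hwe_alpha] <- "hwe"
  reason[maf <= min_maf] <- "maf"
  reason[miss >= max_missing_rate] <- "missing_rate"
  drop <- !is.na(reason)
  report <- data.frame(snp_id = data$snps$snp_id,
                       gene_id = data$snps$gene_id,
                       missing_rate = miss, maf = maf, hwe_p = hwe_p,
                       dropped = drop, reason = reason,
                       row.names = NULL, stringsAsFactors = FALSE)
  keep <- which(!drop)
  lost <- setdiff(unique(data$snps$gene_id),
                  unique(data$snps$gene_id[keep]))
  if (length(lost) > 0)
    stop_ggi("QC removed every SNP of gene(s): ",
             paste(lost, collapse = ", "), "; the pair is untestable")
  out <- ggi_data(g[, keep, drop = FALSE], data$phenotype,
                  data$snps[keep, , drop = FALSE], data$sample_ids)
  attr(out, "qc_report") <- report
  out
}

#' Retrieve the QC report attached by [qc_filter()]
#' @param data a [ggi_data] returned by [qc_filter()].
#' @export
qc_report <- function(data) attr(data, "qc_report")

#' Fill in or remove missing genotypes
#'
#' @param data a [ggi_data] object.
#' @param strategy `"mode"` replaces each missing entry with that SNP's most
#'   frequent observed genotype (smallest genotype wins ties); `"drop_sample"`
#'   removes every sample with any missing entry.
#' @return a [ggi_data] with no missing entries.
#' @export
impute_missing <- function(data, strategy = c("mode", "drop_sample")) {
  strategy <- match.arg(strategy)
  g <- data$genotypes
  if (!anyNA(g)) return(data)
  if (strategy == "mode") {
    for (j in seq_len(ncol(g))) {
      nas <- is.na(g[, j])
      if (any(nas)) {
        counts <- tabulate(g[!nas, j] + 1L, nbins = 3L)
        g[nas, j] <- which.max(counts) - 1L
      }
    }
    ggi_data(g, data$phenotype, data$snps, data$sample_ids)
  } else {
    keep <- !apply(is.na(g), 1, any)
    if (!any(keep)) stop_ggi("drop_sample would remove every sample")
    ggi_data(g[keep, , drop = FALSE], data$phenotype[keep], data$snps,
             data$sample_ids[keep])
  }
}
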