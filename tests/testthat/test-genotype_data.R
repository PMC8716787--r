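test_that("container validates genotypes, labels and SNP metadata", {
  g <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  snps <- data.frame(snp_id = c("rs1", "rs2"), gene_id = c("A", "B"))
  d <- ggi_data(g, c(0, 1), snps)
  expect_s3_class(d, "ggi_data")
  expect_identical(dim(d), c(2L, 2L))

  expect_error(ggi_data(matrix(c(0, 3), 1, 2), 1, snps), "outside")
  expect_error(ggi_data(g, c(0, 2), snps), "0 \\(control\\) / 1 \\(case\\)")
  expect_error(ggi_data(g, c(0, 1),
                        data.frame(snp_id = c("rs1", "rs1"),
                                   gene_id = c("A", "B"))),
               "duplicated snp_id")
  expect_error(ggi_data(g, c(0, 1), snps, sample_ids = c("s", "s")),
               "unique")
  # NA is the missing sentinel and is legal
  g[1, 1] <- NA_integer_
  expect_silent(ggi_data(g, c(0, 1), snps))
})

test_that("smallest valid TSV reads into a 2-gene partition", {
  dir <- withr::local_tempdir()
  writeLines(c("sample_id\tlabel\trs1\trs2",
               "s1\t0\t0\t1", "s2\t1\t1\t2", "s3\t1\t2\t0"),
             file.path(dir, "g.tsv"))
  writeLines(c("snp_id\tgene_id", "rs1\tA", "rs2\tB"),
             file.path(dir, "m.tsv"))
  d <- read_genotypes(file.path(dir, "g.tsv"), file.path(dir, "m.tsv"))
  expect_identical(dim(d), c(3L, 2L))
  expect_identical(d$phenotype, c(0L, 1L, 1L))
  part <- attr(d, "partition")
  expect_identical(part$s1, 1L)
  expect_identical(part$s2, 2L)
  expect_identical(c(part$gene1, part$gene2), c("A", "B"))
})

test_that("PLINK .raw round-trips values, order and recoded labels", {
  d <- tiny_data(n = 25, seed = 4)
  d$genotypes[3, 2] <- NA_integer_
  d <- ggi_data(d$genotypes, d$phenotype, d$snps, d$sample_ids)
  dir <- withr::local_tempdir()
  raw <- file.path(dir, "d.raw"); map <- file.path(dir, "d.map.tsv")
  write_plink_raw(d, raw)
  write_gene_map(d, map)
  # PHENOTYPE on disk is 1/2; cases are the 2s
  on_disk <- read.table(raw, header = TRUE)
  expect_true(all(on_disk$PHENOTYPE %in% c(1, 2)))
  expect_identical(sum(on_disk$PHENOTYPE == 2), sum(d$phenotype == 1L))
  back <- read_genotypes(raw, map)
  expect_identical(unname(back$genotypes), unname(d$genotypes))
  expect_identical(back$snps$snp_id, d$snps$snp_id)
  expect_identical(back$phenotype, d$phenotype)
})

test_that("TSV writer round-trips through the reader", {
  d <- tiny_data(n = 15, seed = 9)
  f <- write_tiny_tsv(d)
  back <- read_genotypes(f$geno, f$map)
  expect_identical(unname(back$genotypes), unname(d$genotypes))
  expect_identical(back$phenotype, d$phenotype)
  expect_identical(back$snps$snp_id, d$snps$snp_id)
})

test_that("reader rejects unmapped SNPs and too few genes; >2 genes kept for screening", {
  d <- tiny_data()
  f <- write_tiny_tsv(d)
  # gene map missing one SNP
  gm <- d$snps[1:3, ]
  write.table(gm, f$map, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_genotypes(f$geno, f$map), "absent from the gene map")
  # single gene
  gm <- transform(d$snps, gene_id = "A")
  write.table(gm, f$map, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_genotypes(f$geno, f$map), "exactly 2 genes")
  # three genes: readable (screening needs it), but a pair test must refuse
  gm <- transform(d$snps, gene_id = c("A", "A", "B", "C"))
  write.table(gm, f$map, sep = "\t", quote = FALSE, row.names = FALSE)
  d3 <- suppressMessages(read_genotypes(f$geno, f$map))
  expect_null(attr(d3, "partition"))
  expect_error(gene_partition_from(d3), "expected exactly 2 genes")
})

test_that("partition construction enforces disjoint nonempty gene sets", {
  p <- gene_partition(1:6, 7:13)
  expect_identical(length(p$s1), 6L)
  expect_error(gene_partition(c(1, 3), c(3, 4)), "overlap")
  expect_error(gene_partition(integer(), 1:2), "at least one SNP")
})

test_that("qc_filter applies threshold rules at the stated boundaries", {
  set.seed(42)
  n <- 200
  mk <- function(maf) rbinom(n, 2, maf)
  g <- cbind(ok = mk(0.3), low_maf = mk(0.04),
             boundary_maf = rep(c(0L, 1L), c(180, 20)),  # MAF exactly 0.05
             missing = mk(0.3), ok2 = mk(0.25))
  g[1:24, "missing"] <- NA  # 12% missing
  d <- ggi_data(g, rep(c(0, 1), n / 2),
                data.frame(snp_id = colnames(g),
                           gene_id = c("A", "A", "A", "B", "B")))
  filt <- qc_filter(d)
  rep_ <- qc_report(filt)
  expect_identical(rep_$reason[rep_$snp_id == "missing"], "missing_rate")
  expect_identical(rep_$reason[rep_$snp_id == "low_maf"], "maf")
  # <= boundary: MAF exactly 0.05 is dropped
  expect_identical(rep_$reason[rep_$snp_id == "boundary_maf"], "maf")
  expect_identical(colnames(filt$genotypes), c("ok", "ok2"))
  # reasons partition the dropped set
  expect_true(all(!is.na(rep_$reason[rep_$dropped])))
  expect_true(all(is.na(rep_$reason[!rep_$dropped])))
})

test_that("qc_filter is idempotent and never increases the SNP count", {
  pool <- default_pool()
  d <- simulate_xor_dataset(pool, n = 300, seed = 5)
  f1 <- qc_filter(d)
  f2 <- qc_filter(f1)
  expect_lte(ncol(f1$genotypes), ncol(d$genotypes))
  expect_identical(colnames(f2$genotypes), colnames(f1$genotypes))
})

test_that("qc_filter signals an untestable pair when a gene loses all SNPs", {
  set.seed(1)
  g <- cbind(a1 = rbinom(50, 2, 0.3), b1 = rbinom(50, 2, 0.02))
  d <- ggi_data(g, rep(c(0, 1), 25),
                data.frame(snp_id = colnames(g), gene_id = c("A", "B")))
  expect_error(qc_filter(d), "untestable")
})

test_that("HWE rule is computed on controls only", {
  # controls in HWE; cases wildly out of HWE -- SNP must survive
  g_ctrl <- rep(c(0L, 1L, 2L), c(49, 42, 9))    # ~HWE at f = 0.3
  g_case <- rep(c(0L, 2L), c(50, 50))           # no hets at all
  hwe_ok <- rep(c(0L, 1L, 1L, 2L), length.out = 200)  # exact HWE at f = 0.5
  d <- ggi_data(cbind(s = c(g_ctrl, g_case), o = hwe_ok, b = hwe_ok),
                rep(c(0, 1), c(100, 100)),
                data.frame(snp_id = c("s", "o", "b"),
                           gene_id = c("A", "A", "B")))
  filt <- qc_filter(d)
  expect_true("s" %in% colnames(filt$genotypes))
  # flip labels: the no-het group becomes the controls -> dropped for HWE
  d2 <- ggi_data(d$genotypes, 1L - d$phenotype, d$snps)
  rep2 <- qc_report(qc_filter(d2))
  expect_identical(rep2$reason[rep2$snp_id == "s"], "hwe")
})

test_that("impute_missing fills modes or drops incomplete samples", {
  g <- cbind(a = c(0L, 0L, NA, 2L, 1L), b = c(2L, 2L, 2L, NA, 1L))
  d <- ggi_data(g, c(0, 1, 0, 1, 0),
                data.frame(snp_id = c("a", "b"), gene_id = c("A", "B")))
  m <- impute_missing(d, "mode")
  expect_identical(m$genotypes[3, "a"], 0L)   # mode of (0,0,2,1) is 0
  expect_identical(m$genotypes[4, "b"], 2L)
  expect_false(anyNA(m$genotypes))
  s <- impute_missing(d, "drop_sample")
  expect_identical(nrow(s$genotypes), 3L)
  # complete data returned unchanged
  expect_identical(impute_missing(m, "mode"), m)
})
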