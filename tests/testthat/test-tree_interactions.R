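test_that("dump parsing round-trips stump, empty and depth-bounded ensembles", {
  stump <- parse_dump(manual_dump(list(
    data.frame(node = 0:2, feature = c("x", NA, NA), gain = c(3, 0, 0),
               yes = c(1, NA, NA), no = c(2, NA, NA)))))
  expect_identical(length(stump$trees), 1L)
  expect_identical(sum(!is.na(stump$trees[[1]]$feature)), 1L)
  expect_identical(sum(is.na(stump$trees[[1]]$feature)), 2L)

  empty <- parse_dump(data.frame(Tree = integer(), ID = character(),
                                 Feature = character(), Gain = numeric(),
                                 Yes = character(), No = character()))
  expect_identical(length(empty$trees), 0L)
  expect_error(parse_dump(data.frame(Tree = 1)), "malformed")

  pool <- default_pool()
  dat <- simulate_xor_dataset(pool, 300, seed = 2)
  x <- matrix(as.numeric(dat$genotypes), 300,
              dimnames = dimnames(dat$genotypes))
  fit <- fit_boosted(x, dat$phenotype, toy_config(num_rounds = 10))
  dump <- parse_dump(fit)
  internal <- vapply(dump$trees, function(t) sum(!is.na(t$feature)),
                     numeric(1))
  expect_true(all(internal <= 7))  # depth-3 bound: at most 2^3 - 1 splits
})

test_that("pair statistics accumulate the child node's gain per edge", {
  # root A (gain 10) -> internal child B (gain 4) + leaf
  t1 <- data.frame(node = 0:4,
                   feature = c("A", "B", NA, NA, NA),
                   gain = c(10, 4, 0, 0, 0),
                   yes = c(1, 3, NA, NA, NA),
                   no = c(2, 4, NA, NA, NA))
  st <- pair_stats(parse_dump(manual_dump(list(t1))))
  expect_identical(nrow(st), 1L)
  expect_identical(st$parent_snp, "A")
  expect_identical(st$child_snp, "B")
  expect_equal(st$sum_gain, 4)
  expect_identical(st$frequency, 1L)

  # two trees with the same edge: gains add, frequency counts edges
  t2 <- transform(t1, gain = c(12, 6, 0, 0, 0))
  st2 <- pair_stats(parse_dump(manual_dump(list(t1, t2))))
  expect_equal(st2$sum_gain, 10)
  expect_identical(st2$frequency, 2L)
})

test_that("gain conservation: pair gains + root gains = all internal gains", {
  pool <- default_pool()
  dat <- simulate_xor_dataset(pool, 500, seed = 6)
  x <- matrix(as.numeric(dat$genotypes), 500,
              dimnames = dimnames(dat$genotypes))
  fit <- fit_boosted(x, dat$phenotype, toy_config(num_rounds = 30))
  dump <- parse_dump(fit)
  st <- pair_stats(dump)
  internal_total <- sum(unlist(lapply(dump$trees, function(t)
    t$gain[!is.na(t$feature)])))
  root_total <- sum(vapply(dump$trees, function(t)
    if (is.na(t$feature[1])) 0 else t$gain[1], numeric(1)))
  expect_equal(sum(st$sum_gain) + root_total, internal_total,
               tolerance = 1e-6)
  # frequencies count exactly the internal-child edges
  edge_count <- sum(vapply(dump$trees, function(t) {
    ids <- t$id[!is.na(t$feature)]
    sum(t$yes[!is.na(t$feature)] %in% ids) +
      sum(t$no[!is.na(t$feature)] %in% ids)
  }, numeric(1)))
  expect_identical(sum(st$frequency), as.integer(edge_count))
})

test_that("strong XOR puts the causal cross-gene pair on top", {
  pool <- default_pool()
  genes <- setNames(pool$snps$gene_id, pool$snps$snp_id)
  hits <- 0L
  for (s in 1:5) {
    dat <- simulate_xor_dataset(pool, 2000, seed = 40 + s)
    truth <- attr(dat, "truth")
    x <- matrix(as.numeric(dat$genotypes), 2000,
                dimnames = dimnames(dat$genotypes))
    fit <- fit_boosted(x, dat$phenotype,
                       toy_config(num_rounds = 50, learning_rate = 0.3))
    st <- pair_stats(fit, snp_names = colnames(x), genes = genes,
                     cross_gene_only = TRUE)
    top <- sort(c(st$parent_snp[1], st$child_snp[1]))
    if (identical(top, sort(c(truth$causal_snp_1, truth$causal_snp_2))))
      hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("a constrained fit yields no cross-gene pairs", {
  pool <- default_pool()
  dat <- simulate_xor_dataset(pool, 400, seed = 3)
  x <- matrix(as.numeric(dat$genotypes), 400,
              dimnames = dimnames(dat$genotypes))
  cs <- build_constraints(pool$partition)
  fit <- fit_boosted(x, dat$phenotype, toy_config(num_rounds = 20),
                     constraints = cs)
  genes <- setNames(pool$snps$gene_id, pool$snps$snp_id)
  st <- pair_stats(fit, snp_names = colnames(x), genes = genes,
                   cross_gene_only = TRUE)
  expect_identical(nrow(st), 0L)
  expect_true(audit_constraint_compliance(fit, cs,
                                          feature_names = colnames(x)))
})

test_that("ranking and unordered folding are deterministic", {
  t1 <- data.frame(node = 0:6,
                   feature = c("A", "B", "C", NA, NA, NA, NA),
                   gain = c(10, 4, 4, 0, 0, 0, 0),
                   yes = c(1, 3, 5, NA, NA, NA, NA),
                   no = c(2, 4, 6, NA, NA, NA, NA))
  st <- pair_stats(parse_dump(manual_dump(list(t1))))
  # equal gains, equal frequency: lexicographic tie-break
  expect_identical(st$child_snp, c("B", "C"))
  ta <- data.frame(node = 0:4, feature = c("A", "B", NA, NA, NA),
                   gain = c(10, 4, 0, 0, 0), yes = c(1, 3, NA, NA, NA),
                   no = c(2, 4, NA, NA, NA))
  t2 <- data.frame(node = 0:4, feature = c("B", "A", NA, NA, NA),
                   gain = c(2, 7, 0, 0, 0), yes = c(1, 3, NA, NA, NA),
                   no = c(2, 4, NA, NA, NA))
  # one (A,B) and one (B,A) edge: unordered folding merges them
  stu <- pair_stats(parse_dump(manual_dump(list(ta, t2))),
                    ordered = FALSE)
  merged <- stu[stu$parent_snp == "A" & stu$child_snp == "B", ]
  expect_equal(merged$sum_gain, 4 + 7)
  expect_identical(merged$frequency, 2L)
})

test_that("equal-width intensity bins label the four quarters", {
  st <- data.frame(parent_snp = letters[1:4], child_snp = LETTERS[1:4],
                   sum_gain = c(387.85, 250, 90, 10), frequency = 1:4)
  b <- gain_bins(st, 4)
  # max 387.85: 387.85 -> top bin, 250 -> bin 3, 90 -> bin 1, 10 -> bin 1
  expect_identical(b$bin, c(4L, 3L, 1L, 1L))
  same <- data.frame(parent_snp = "a", child_snp = "b", sum_gain = 5,
                     frequency = 1)
  expect_identical(gain_bins(same)$bin, 4L)
  expect_identical(gain_bins(rbind(same, same))$bin, c(4L, 4L))
  expect_error(gain_bins(same[0, ]), "empty")
})

test_that("per-SNP gain totals sum the splits of each feature", {
  t1 <- data.frame(node = 0:4,
                   feature = c("A", "B", NA, NA, NA),
                   gain = c(10, 4, 0, 0, 0),
                   yes = c(1, 3, NA, NA, NA), no = c(2, 4, NA, NA, NA))
  t2 <- data.frame(node = 0:2, feature = c("A", NA, NA), gain = c(5, 0, 0),
                   yes = c(1, NA, NA), no = c(2, NA, NA))
  tot <- snp_gain_totals(parse_dump(manual_dump(list(t1, t2))))
  expect_equal(unname(tot["A"]), 15)
  expect_equal(unname(tot["B"]), 4)
})
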