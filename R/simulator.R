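#' Synthetic haplotype pool with block LD structure
#'
#' Builds a pool of phased binary haplotypes (rows) over SNPs (columns)
#' arranged in gene blocks with controllable within-block linkage
#' disequilibrium. Each block is generated from a latent Gaussian AR(1)
#' chain; the latent correlation between adjacent SNPs is calibrated
#' numerically so that the BINARY allele correlation satisfies
#' `r^2 ~ within_block_r2`. Alleles are assigned by empirical-quantile
#' thresholding of the latent values, so each SNP's realized minor-allele
#' frequency equals its target to within rounding (`1 / n_haplotypes`).
#' Blocks (genes) are mutually independent.
#'
#' The default pool mimics a two-gene template: 90 haplotypes, a 6-SNP
#' high-LD gene and a 7-SNP low-LD gene, MAFs spread over 0.2-0.4.
#'
#' @param n_haplotypes pool size H (default 90).
#' @param blocks list of `list(n_snps =, r2 =)` per gene block.
#' @param target_mafs vector of target MAFs in (0, 0.5], one per SNP
#'   (defaults to an even spread over 0.2-0.4 within each block).
#' @param gene_names one name per block.
#' @param seed RNG seed.
#' @return a `haplotype_pool`: list with `alleles` (H x L 0/1 matrix),
#'   `snps` (SNP table with gene ids and realized MAFs) and `partition`.
#' @export
synth_haplotype_pool <- function(n_haplotypes = 90,
                                 blocks = list(list(n_snps = 6, r2 = 0.7),
                                               list(n_snps = 7, r2 = 0.2)),
                                 target_mafs = NULL,
                                 gene_names = NULL, seed = 1L) {
  H <- as.integer(n_haplotypes)
  if (H < 2) stop_ggi("need at least 2 haplotypes")
  nb <- length(blocks)
  gene_names <- gene_names %||% paste0("GENE", seq_len(nb))
  sizes <- vapply(blocks, function(b) as.integer(b$n_snps), integer(1))
  if (is.null(target_mafs))
    target_mafs <- unlist(lapply(sizes, function(s)
      seq(0.2, 0.4, length.out = s)))
  if (length(target_mafs) != sum(sizes))
    stop_ggi("target_mafs must have one entry per SNP")
  if (any(target_mafs <= 0 | target_mafs > 0.5))
    stop_ggi("target MAFs must lie in (0, 0.5]")

  alleles <- matrix(0L, H, sum(sizes))
  off <- 0L
  with_seed(seed, {
    for (b in seq_len(nb)) {
      L <- sizes[b]
      r2 <- blocks[[b]]$r2
      if (r2 < 0 || r2 > 1) stop_ggi("block r2 must lie in [0, 1]")
      mafs <- target_mafs[off + seq_len(L)]
      z <- matrix(0, H, L)
      z[, 1] <- stats::rnorm(H)
      if (L > 1) for (j in 2:L) {
        rho <- latent_rho_for_r2(r2, mafs[j - 1], mafs[j])
        z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * stats::rnorm(H)
      }
      for (j in seq_len(L)) {
        k <- max(1L, round(H * mafs[j]))
        alleles[, off + j] <- as.integer(rank(z[, j], ties.method = "first") <= k)
      }
      off <- off + L
    }
  })
  snp_id <- unlist(lapply(seq_len(nb), function(b)
    paste0("G", b, "_", seq_len(sizes[b]))))
  snps <- data.frame(snp_id = snp_id,
                     gene_id = rep(gene_names, sizes),
                     maf = colMeans(alleles),
                     stringsAsFactors = FALSE)
  colnames(alleles) <- snp_id
  ends <- cumsum(sizes)
  part <- if (nb == 2) gene_partition(seq_len(ends[1]),
                                      (ends[1] + 1):ends[2],
                                      gene_names[1], gene_names[2]) else NULL
  structure(list(alleles = alleles, snps = snps, partition = part,
                 blocks = blocks, seed = as.integer(seed)),
            class = "haplotype_pool")
}

# Latent AR(1) correlation giving binary allele r^2 ~ target for a pair of
# SNPs thresholded at qnorm(maf1), qnorm(maf2). The binary (phi) correlation
# is computed from the bivariate normal orthant probability, evaluated by
# 1-D quadrature; rho is found by root search. r2 = 1 needs equal MAFs
# (complete LD duplicates the column); unequal MAFs cannot reach phi = 1.
latent_rho_for_r2 <- function(r2, maf1, maf2) {
  if (r2 == 0) return(0)
  a <- stats::qnorm(maf1); b <- stats::qnorm(maf2)
  phi_of <- function(rho) {
    if (rho >= 1) {
      p11 <- min(maf1, maf2)
    } else {
      p11 <- stats::integrate(function(z)
        stats::dnorm(z) * stats::pnorm((b - rho * z) / sqrt(1 - rho^2)),
        -Inf, a, rel.tol = 1e-10)$value
    }
    (p11 - maf1 * maf2) /
      sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
  }
  if (r2 >= 1) {
    if (abs(maf1 - maf2) > 1e-12)
      stop_ggi("r2 = 1 is infeasible for unequal MAFs (", maf1, " vs ",
               maf2, ")")
    return(1)
  }
  target_phi <- sqrt(r2)
  max_phi <- phi_of(0.999999)
  if (target_phi >= max_phi)
    stop_ggi("requested r2 = ", r2, " infeasible for MAFs ", maf1, ", ",
             maf2, " (max attainable r2 = ", round(max_phi^2, 3), ")")
  stats::uniroot(function(r) phi_of(r) - target_phi, c(0, 0.999999),
                 tol = 1e-8)$root
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat("Haplotype pool: ", nrow(x$alleles), " haplotypes x ",
      ncol(x$alleles), " SNPs\n", sep = "")
  for (g in unique(x$snps$gene_id)) {
    sel <- x$snps$gene_id == g
    cat("  ", g, ": ", sum(sel), " SNPs, MAF ",
        paste(range(round(x$snps$maf[sel], 3)), collapse = "-"), "\n",
        sep = "")
  }
  invisible(x)
}

#' Draw unphased genotypes by haplotype resampling
#'
#' Each individual is the sum of two haplotypes sampled uniformly with
#' replacement from the pool, so genotypes follow Hardy-Weinberg products of
#' the pool's haplotype frequencies and inherit its LD structure.
#'
#' @param pool a `haplotype_pool`.
#' @param n number of individuals.
#' @param seed RNG seed.
#' @return integer genotype matrix (n x L, entries 0/1/2) with SNP column
#'   names; the pool's SNP table and partition travel as attributes.
#' @export
genotypes_from_pool <- function(pool, n, seed = 1L) {
  stopifnot(inherits(pool, "haplotype_pool"), is_count(n))
  H <- nrow(pool$alleles)
  if (H < 1) stop_ggi("empty haplotype pool")
  with_seed(seed, {
    i1 <- sample.int(H, n, replace = TRUE)
    i2 <- sample.int(H, n, replace = TRUE)
  })
  g <- pool$alleles[i1, , drop = FALSE] + pool$alleles[i2, , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Case-control sampling under a two-locus disease model
#'
#' Rejection sampling: individuals are drawn from the haplotype pool and
#' assigned case status with probability equal to the penetrance of their
#' genotype at the causal SNP pair; draws continue until both the case and
#' control quotas are filled. An attempt cap guards infeasible
#' prevalence/quota combinations.
#'
#' @param pool a `haplotype_pool` with exactly two gene blocks.
#' @param model a `penetrance_model` from [build_penetrance()].
#' @param causal_pair length-2 integer vector of SNP column indices, one per
#'   gene; `NULL` picks a cross-gene pair uniformly at random.
#' @param n_cases,n_controls quotas.
#' @param seed RNG seed.
#' @param max_draws attempt cap (default 1e7).
#' @return a [ggi_data] (cases first) with attribute `"truth"` recording the
#'   model name, theta, causal SNP ids, gamma, prevalence and seed.
#' @export
sample_case_control <- function(pool, model, causal_pair = NULL,
                                n_cases, n_controls, seed = 1L,
                                max_draws = 1e7) {
  stopifnot(inherits(pool, "haplotype_pool"),
            inherits(model, "penetrance_model"),
            is_count(n_cases), is_count(n_controls))
  part <- pool$partition
  if (is.null(part)) stop_ggi("pool must have exactly two gene blocks")
  if (is.null(causal_pair)) {
    causal_pair <- with_seed(derive_seed(seed, "causal"),
                             c(sample(part$s1, 1), sample(part$s2, 1)))
  }
  causal_pair <- as.integer(causal_pair)
  in1 <- causal_pair %in% part$s1
  in2 <- causal_pair %in% part$s2
  if (!((in1[1] && in2[2]) || (in1[2] && in2[1])))
    stop_ggi("causal SNPs must come from the two different genes")

  pen <- model$penetrance_table
  case_rows <- list(); ctrl_rows <- list()
  got_case <- 0L; got_ctrl <- 0L
  drawn <- 0; batch_i <- 0L
  batch <- max(2000L, ceiling((n_cases + n_controls) / 4))
  while (got_case < n_cases || got_ctrl < n_controls) {
    if (drawn >= max_draws)
      stop_ggi("attempt cap (", format(max_draws, scientific = FALSE),
               " draws) exceeded with ", got_case, "/", n_cases, " cases and ",
               got_ctrl, "/", n_controls, " controls; the prevalence/quota ",
               "combination looks infeasible")
    batch_i <- batch_i + 1L
    g <- genotypes_from_pool(pool, batch,
                             seed = derive_seed(seed, "geno", batch_i))
    u <- with_seed(derive_seed(seed, "status", batch_i),
                   stats::runif(batch))
    p_case <- pen[cbind(g[, causal_pair[1]] + 1L, g[, causal_pair[2]] + 1L)]
    is_case <- u < p_case
    drawn <- drawn + batch
    if (got_case < n_cases && any(is_case)) {
      take <- utils::head(which(is_case), n_cases - got_case)
      case_rows[[length(case_rows) + 1L]] <- g[take, , drop = FALSE]
      got_case <- got_case + length(take)
    }
    if (got_ctrl < n_controls && any(!is_case)) {
      take <- utils::head(which(!is_case), n_controls - got_ctrl)
      ctrl_rows[[length(ctrl_rows) + 1L]] <- g[take, , drop = FALSE]
      got_ctrl <- got_ctrl + length(take)
    }
  }
  geno <- rbind(do.call(rbind, case_rows), do.call(rbind, ctrl_rows))
  pheno <- rep(c(1L, 0L), c(n_cases, n_controls))
  out <- ggi_data(geno, pheno, pool$snps,
                  sample_ids = paste0("S", seq_len(n_cases + n_controls)))
  attr(out, "partition") <- part
  attr(out, "truth") <- list(model = model$model, theta = model$theta,
                             causal_snp_1 = pool$snps$snp_id[causal_pair[1]],
                             causal_snp_2 = pool$snps$snp_id[causal_pair[2]],
                             gamma = model$gamma,
                             prevalence = model$prevalence,
                             seed = as.integer(seed))
  out
}

#' Deterministic XOR phenotype dataset
#'
#' A purely epistatic benchmark: one SNP is picked from each gene and the
#' label is 1 iff exactly one of the two carries a minor allele
#' (`(g_u >= 1) XOR (g_v >= 1)`). No additive model can represent this
#' rule, so the additivity-gap statistic should be large.
#'
#' @param pool a two-gene `haplotype_pool`.
#' @param n samples.
#' @param seed RNG seed (genotype draw; SNP choice uses a derived seed
#'   unless given).
#' @param snps optional length-2 column indices of the causal SNPs.
#' @return a [ggi_data] with attribute `"truth"`.
#' @export
simulate_xor_dataset <- function(pool, n, seed = 1L, snps = NULL) {
  part <- pool$partition
  if (is.null(snps))
    snps <- with_seed(derive_seed(seed, "xor_snps"),
                      c(sample(part$s1, 1), sample(part$s2, 1)))
  g <- genotypes_from_pool(pool, n, seed = derive_seed(seed, "geno"))
  y <- as.integer(xor(g[, snps[1]] >= 1L, g[, snps[2]] >= 1L))
  out <- ggi_data(g, y, pool$snps)
  attr(out, "partition") <- part
  attr(out, "truth") <- list(model = "xor_deterministic",
                             causal_snp_1 = pool$snps$snp_id[snps[1]],
                             causal_snp_2 = pool$snps$snp_id[snps[2]],
                             seed = as.integer(seed))
  out
}

#' Additive (no-interaction) logistic phenotype dataset
#'
#' Null-of-additivity benchmark: labels are Bernoulli with log-odds linear
#' in the two causal genotypes, `logit P(y=1) = b1 g_u + b2 g_v + c`, with
#' the intercept centering the log-odds so classes are roughly balanced.
#' Additive log-odds satisfy the no-interaction null, so the test should
#' reject at its nominal rate only.
#'
#' @inheritParams simulate_xor_dataset
#' @param beta length-2 effect sizes on the allele counts.
#' @export
simulate_additive_dataset <- function(pool, n, seed = 1L, snps = NULL,
                                      beta = c(1, 1)) {
  part <- pool$partition
  if (is.null(snps))
    snps <- with_seed(derive_seed(seed, "add_snps"),
                      c(sample(part$s1, 1), sample(part$s2, 1)))
  g <- genotypes_from_pool(pool, n, seed = derive_seed(seed, "geno"))
  eta <- beta[1] * g[, snps[1]] + beta[2] * g[, snps[2]]
  eta <- eta - mean(eta)
  y <- with_seed(derive_seed(seed, "labels"),
                 stats::rbinom(n, 1, stats::plogis(eta)))
  out <- ggi_data(g, y, pool$snps)
  attr(out, "partition") <- part
  attr(out, "truth") <- list(model = "additive_logistic",
                             causal_snp_1 = pool$snps$snp_id[snps[1]],
                             causal_snp_2 = pool$snps$snp_id[snps[2]],
                             beta = beta, seed = as.integer(seed))
  out
}
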