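#' Hardy-Weinberg equilibrium p-value from genotype counts
#'
#' Given counts of the three genotypes at a biallelic SNP, tests the null of
#' Hardy-Weinberg proportions. The default chi-square statistic compares
#' observed counts with `n * (p^2, 2pq, q^2)` on 1 degree of freedom (no
#' continuity correction). The exact test conditions on the observed allele
#' counts and sums the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed table
#' (the standard SNP exact test). With `method = "auto"` the chi-square test
#' is used unless any expected genotype count is below 5, in which case the
#' exact test takes over.
#'
#' @param n_aa,n_ab,n_bb counts of the two homozygotes and the heterozygote
#'   (`n_ab`); order of the homozygotes is immaterial.
#' @param method `"auto"`, `"chisq"` or `"exact"`.
#' @return a p-value in `[0, 1]`; degenerate inputs (no samples, monomorphic
#'   SNP) return 1.
#' @export
hwe_pvalue <- function(n_aa, n_ab, n_bb, method = c("auto", "chisq", "exact")) {
  method <- match.arg(method)
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  na <- 2 * n_aa + n_ab   # copies of allele a
  nb <- 2 * n_bb + n_ab
  if (na == 0 || nb == 0) return(1)
  p <- na / (2 * n)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  if (method == "auto") method <- if (any(expected < 5)) "exact" else "chisq"
  if (method == "chisq") {
    stat <- sum((c(n_aa, n_ab, n_bb) - expected)^2 / expected)
    return(stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
  hwe_exact_pvalue(n_aa, n_ab, n_bb)
}

# Exact test conditioning on allele counts: enumerate all feasible
# heterozygote counts (same parity as the observed minor-allele count) and
# sum probabilities <= that of the observed configuration. Probabilities are
# computed on the log scale via lchoose/lfactorial.
hwe_exact_pvalue <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  nb <- 2 * n_bb + n_ab
  rare <- min(na, nb)
  hets <- seq(rare %% 2, rare, by = 2)
  # Pr(N_ab = h | allele counts) ∝ n! / (naa! h! nbb!) * 2^h
  log_p <- vapply(hets, function(h) {
    aa <- (rare - h) / 2
    bb <- n - aa - h
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2)
  }, numeric(1))
  log_p <- log_p - max(log_p)
  pr <- exp(log_p); pr <- pr / sum(pr)
  obs <- which(hets == n_ab)
  sum(pr[pr <= pr[obs] * (1 + 1e-12)])
}
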