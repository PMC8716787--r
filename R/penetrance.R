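#' Exponent masks of the built-in two-locus disease models
#'
#' Each disease model is a 3 x 3 exponent mask `k(g1, g2)` over the genotype
#' combinations of the two causal SNPs: the disease odds are
#' `gamma * (1 + theta)^k(g1, g2)`, where `1 + theta` is the genotype odds
#' ratio and `gamma` the baseline odds of the genotype carrying no risk
#' configuration. The built-in masks follow the classical two-locus
#' taxonomy:
#'
#' * `recessive_dominant` — effect iff locus 1 is homozygous minor AND locus
#'   2 carries at least one minor allele (`g1 == 2 & g2 >= 1`);
#' * `dominant_dominant` — effect iff both loci carry at least one minor
#'   allele;
#' * `xor` — effect iff exactly one locus carries a risk genotype
#'   (`(g1 >= 1) XOR (g2 >= 1)`);
#' * `threshold` — effect once the total minor-allele count across the two
#'   loci reaches 2 (`g1 + g2 >= 2`);
#' * `multiplicative` — `k = (g1 >= 1) + (g2 >= 1)`: marginal effects at
#'   each locus with joint amplification;
#' * `recessive_recessive` — effect only for the double minor homozygote
#'   (`g1 == 2 & g2 == 2`).
#'
#' Masks are data, not code: [build_penetrance()] accepts a user-supplied
#' 3 x 3 numeric mask in place of a model name.
#'
#' @param model model name.
#' @return 3 x 3 numeric matrix, rows `g1 = 0..2`, columns `g2 = 0..2`.
#' @export
disease_model_mask <- function(model = c("recessive_dominant",
                                         "dominant_dominant", "xor",
                                         "threshold", "multiplicative",
                                         "recessive_recessive")) {
  model <- match.arg(model)
  g1 <- matrix(0:2, 3, 3)
  g2 <- t(g1)
  k <- switch(model,
    recessive_dominant  = (g1 == 2) * (g2 >= 1),
    dominant_dominant   = (g1 >= 1) * (g2 >= 1),
    xor                 = ((g1 >= 1) + (g2 >= 1)) == 1,
    threshold           = (g1 + g2) >= 2,
    multiplicative      = (g1 >= 1) + (g2 >= 1),
    recessive_recessive = (g1 == 2) * (g2 == 2))
  k <- matrix(as.numeric(k), 3, 3,
              dimnames = list(g1 = 0:2, g2 = 0:2))
  k
}

#' Two-locus penetrance model calibrated to a population prevalence
#'
#' Builds the 3 x 3 odds table `gamma * (1 + theta)^mask` and its penetrance
#' table `odds / (1 + odds)`, solving for the baseline odds `gamma` so that
#' the population prevalence constraint
#' `sum(penetrance * Pr(g)) = prevalence`
#' holds to within 1e-10. The prevalence is monotone increasing in `gamma`,
#' so bisection on the bracket `[prevalence * 1e-6, 1]` always converges.
#' With `theta = 0` every cell has odds `gamma`, giving the closed form
#' `gamma = prevalence / (1 - prevalence)`, which is used directly.
#'
#' @param model a model name (see [disease_model_mask()]) or a 3 x 3 numeric
#'   exponent mask.
#' @param theta effect size; the genotype odds ratio is `1 + theta`.
#' @param prevalence population disease prevalence in (0, 1).
#' @param genotype_probs 3 x 3 joint genotype probabilities of the two causal
#'   SNPs (must sum to 1), e.g. from [causal_genotype_probs()].
#' @return a `penetrance_model`: list with `model`, `theta`, `prevalence`,
#'   `gamma`, `mask`, `odds_table`, `penetrance_table`, `genotype_probs`.
#' @export
build_penetrance <- function(model, theta, prevalence, genotype_probs) {
  if (is.character(model)) {
    name <- match.arg(model, c("recessive_dominant", "dominant_dominant",
                               "xor", "threshold", "multiplicative",
                               "recessive_recessive"))
    mask <- disease_model_mask(name)
  } else {
    mask <- as.matrix(model)
    if (!all(dim(mask) == c(3, 3)) || any(mask < 0))
      stop_ggi("a custom mask must be a nonnegative 3 x 3 matrix")
    name <- "custom"
  }
  stopifnot(length(theta) == 1, theta >= 0,
            length(prevalence) == 1, prevalence > 0, prevalence < 1)
  genotype_probs <- as.matrix(genotype_probs)
  if (!all(dim(genotype_probs) == c(3, 3)) || any(genotype_probs < 0) ||
      abs(sum(genotype_probs) - 1) > 1e-8)
    stop_ggi("genotype_probs must be a 3 x 3 probability table summing to 1")

  or_pow <- (1 + theta)^mask
  prev_of <- function(gamma) {
    odds <- gamma * or_pow
    sum((odds / (1 + odds)) * genotype_probs)
  }
  if (theta == 0) {
    gamma <- prevalence / (1 - prevalence)
  } else {
    lo <- prevalence * 1e-6; hi <- 1
    flo <- prev_of(lo) - prevalence
    fhi <- prev_of(hi) - prevalence
    if (flo > 0 || fhi < 0)
      stop_ggi("gamma solver: prevalence ", prevalence,
               " not bracketed by odds in [", lo, ", ", hi, "] (f(lo) = ",
               signif(flo, 3), ", f(hi) = ", signif(fhi, 3), ")")
    for (it in seq_len(200)) {
      gamma <- (lo + hi) / 2
      fm <- prev_of(gamma) - prevalence
      if (abs(fm) < 1e-14 || (hi - lo) < .Machine$double.eps * gamma) break
      if (fm < 0) lo <- gamma else hi <- gamma
    }
    if (abs(prev_of(gamma) - prevalence) > 1e-10)
      stop_ggi("gamma solver did not reach 1e-10 accuracy on [",
               lo, ", ", hi, "]")
  }
  odds <- gamma * or_pow
  pen <- odds / (1 + odds)
  dimnames(odds) <- dimnames(pen) <- list(g1 = 0:2, g2 = 0:2)
  structure(list(model = name, theta = theta, prevalence = prevalence,
                 gamma = gamma, mask = mask, odds_table = odds,
                 penetrance_table = pen, genotype_probs = genotype_probs),
            class = "penetrance_model")
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat("Two-locus penetrance model '", x$model, "': OR = ", 1 + x$theta,
      ", prevalence = ", x$prevalence, ", gamma = ",
      format(x$gamma, digits = 6), "\n", sep = "")
  cat("Penetrance table (rows g1 = 0..2, cols g2 = 0..2):\n")
  print(signif(x$penetrance_table, 4))
  invisible(x)
}

#' Joint genotype probabilities of a causal SNP pair
#'
#' The two genes sit in unlinked blocks, so the joint distribution is the
#' product of the marginal genotype distributions; each marginal follows
#' Hardy-Weinberg proportions of the pool's empirical haplotype allele
#' frequency (individuals are sums of two independently drawn haplotypes).
#'
#' @param pool a `haplotype_pool`.
#' @param causal_pair length-2 SNP column indices, one per gene.
#' @return 3 x 3 probability matrix (rows: locus-1 genotype 0..2).
#' @export
causal_genotype_probs <- function(pool, causal_pair) {
  f <- colMeans(pool$alleles[, as.integer(causal_pair), drop = FALSE])
  marg <- function(fq) c((1 - fq)^2, 2 * fq * (1 - fq), fq^2)
  outer(marg(f[1]), marg(f[2]))
}
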