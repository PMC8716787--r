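#' Monte-Carlo rejection rates of the interaction test
#'
#' Shared engine behind [estimate_type1()] and [estimate_power()]. For every
#' setting (disease model x odds ratio x sample size) it simulates
#' `replicates` balanced case-control datasets from the haplotype pool,
#' runs the full permutation test on each, and reports the fraction rejected
#' at `alpha` (strict `p < alpha`) together with a Clopper-Pearson 95%
#' binomial interval. Per-replicate seeds are derived from the master seed,
#' the setting and the replicate index, so any single replicate can be
#' reproduced in isolation and reruns are resumable.
#'
#' @param pool a two-gene `haplotype_pool`.
#' @param models character vector of disease model names.
#' @param odds_ratios genotype odds ratios (OR = 1 + theta); 1 means the
#'   null is true and the rejection rate estimates type-I error.
#' @param sample_sizes total sample sizes n (split into n/2 cases and n/2
#'   controls).
#' @param prevalence population prevalence used to calibrate each model.
#' @param replicates simulated datasets per setting.
#' @param alpha significance level.
#' @param m permutations per test.
#' @param config a [boost_config] (the fidelity profile).
#' @param seed master seed.
#' @param causal_pair optional fixed causal SNP pair (column indices); by
#'   default each replicate draws its own cross-gene pair at random.
#' @param manifest optional path to a per-replicate TSV manifest; completed
#'   replicates found there are skipped and new ones appended, so an
#'   interrupted grid resumes to identical aggregates.
#' @param workers parallel workers per test.
#' @return a `power_estimates` data frame: `model`, `or`, `n`, `replicates`,
#'   `m1` (rejections), `power`, `ci_lo`, `ci_hi`.
#' @export
estimate_rejection_rate <- function(pool, models, odds_ratios, sample_sizes,
                                    prevalence = 0.01, replicates = 100,
                                    alpha = 0.05, m = 1000,
                                    config = boost_config(), seed = 1L,
                                    causal_pair = NULL, manifest = NULL,
                                    workers = 1L) {
  stopifnot(inherits(pool, "haplotype_pool"), is_count(replicates),
            alpha > 0, alpha <= 1)
  done <- NULL
  if (!is.null(manifest) && file.exists(manifest))
    done <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  grid <- expand.grid(model = models, or = odds_ratios, n = sample_sizes,
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (s in seq_len(nrow(grid))) {
    model <- grid$model[s]; or <- grid$or[s]; n <- grid$n[s]
    pvals <- numeric(replicates)
    for (r in seq_len(replicates)) {
      key <- !is.null(done) && any(done$model == model & done$or == or &
                                     done$n == n & done$replicate == r)
      if (key) {
        pvals[r] <- done$p_value[done$model == model & done$or == or &
                                   done$n == n & done$replicate == r][1]
        next
      }
      rs <- derive_seed(seed, "rep", model, or, n, r)
      cp <- causal_pair %||%
        with_seed(derive_seed(rs, "causal_pick"),
                  c(sample(pool$partition$s1, 1),
                    sample(pool$partition$s2, 1)))
      pm <- build_penetrance(model, theta = or - 1, prevalence = prevalence,
                             genotype_probs = causal_genotype_probs(pool, cp))
      dat <- sample_case_control(pool, pm, causal_pair = cp,
                                 n_cases = n %/% 2, n_controls = n - n %/% 2,
                                 seed = rs)
      fit <- ggi_test(dat, config = config, m = m,
                      seed = derive_seed(rs, "test"), workers = workers)
      pvals[r] <- fit$p_value
      if (!is.null(manifest)) {
        row <- data.frame(model = model, or = or, n = n, replicate = r,
                          p_value = pvals[r], seed = rs)
        utils::write.table(row, manifest, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = !file.exists(manifest),
                           append = file.exists(manifest))
      }
    }
    m1 <- sum(pvals < alpha)
    ci <- stats::binom.test(m1, replicates)$conf.int
    out[[s]] <- data.frame(model = model, or = or, n = n,
                           replicates = replicates, m1 = m1,
                           power = m1 / replicates,
                           ci_lo = ci[1], ci_hi = ci[2],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "alpha") <- alpha
  attr(res, "m") <- as.integer(m)
  attr(res, "seed") <- as.integer(seed)
  class(res) <- c("power_estimates", "data.frame")
  res
}

#' Empirical type-I error of the interaction test
#'
#' Runs [estimate_rejection_rate()] with the odds ratio pinned at 1, i.e.
#' every genotype combination has the same disease odds and the additivity
#' null holds; the rejection rate should match the nominal level.
#'
#' @inheritParams estimate_rejection_rate
#' @export
estimate_type1 <- function(pool, sample_sizes, prevalence = 0.01,
                           replicates = 100, alpha = 0.05, m = 1000,
                           config = boost_config(), seed = 1L,
                           manifest = NULL, workers = 1L) {
  estimate_rejection_rate(pool, models = "multiplicative", odds_ratios = 1,
                          sample_sizes = sample_sizes,
                          prevalence = prevalence, replicates = replicates,
                          alpha = alpha, m = m, config = config, seed = seed,
                          manifest = manifest, workers = workers)
}

#' Empirical power of the interaction test
#'
#' Rejection rate when the simulated datasets carry a true two-locus
#' interaction (`OR > 1`), per disease model / odds ratio / sample size.
#'
#' @inheritParams estimate_rejection_rate
#' @export
estimate_power <- function(pool, models, odds_ratios, sample_sizes,
                           prevalence = 0.01, replicates = 100,
                           alpha = 0.05, m = 1000,
                           config = boost_config(), seed = 1L,
                           causal_pair = NULL, manifest = NULL,
                           workers = 1L) {
  if (any(odds_ratios <= 1))
    stop_ggi("power estimation needs OR > 1 (use estimate_type1 for OR = 1)")
  estimate_rejection_rate(pool, models = models, odds_ratios = odds_ratios,
                          sample_sizes = sample_sizes,
                          prevalence = prevalence, replicates = replicates,
                          alpha = alpha, m = m, config = config, seed = seed,
                          causal_pair = causal_pair, manifest = manifest,
                          workers = workers)
}

#' @export
print.power_estimates <- function(x, ...) {
  cat("Monte-Carlo rejection rates (alpha = ", attr(x, "alpha"), ", m = ",
      attr(x, "m"), " permutations per test)\n", sep = "")
  print.data.frame(as.data.frame(x), digits = 3, row.names = FALSE)
  invisible(x)
}
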