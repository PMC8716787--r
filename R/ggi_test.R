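#' Gene-gene interaction test by constrained boosting and permutation
#'
#' The main fitting function. Computes the observed additivity-gap statistic
#' `delta_err0` (see [delta_err()]), then shuffles the phenotype `m` times
#' and recomputes the FULL procedure — both classifiers, freshly stratified
#' cross-validation folds — on each permuted label vector to obtain the null
#' draws `delta_err_1..m`. The p-value is the fraction of null draws at least
#' as large as the observed statistic,
#' `p = #\{i : delta_err_i >= delta_err0\} / m`,
#' so every p-value is a multiple of `1/m` and 0 is attainable. An optional
#' conservative estimator `(count + 1) / (m + 1)` avoids exact zeros for
#' downstream multiplicity adjustment.
#'
#' Permutation seeds are pre-assigned from `seed` and the permutation index,
#' so results are reproducible and independent of execution order or the
#' number of workers.
#'
#' @param data a [ggi_data] covering exactly two genes (or supply `x`, `y`,
#'   `partition` explicitly via [delta_err()]'s conventions).
#' @param partition optional [gene_partition]; defaults to the one recorded
#'   in `data`.
#' @param config a [boost_config].
#' @param m number of label permutations (the profile used for real-data
#'   analysis is m = 1000).
#' @param seed master seed driving folds and permutations.
#' @param estimator `"plain"` (default, admits p = 0) or `"add_one"` for
#'   `(count + 1) / (m + 1)`.
#' @param workers number of parallel workers for the permutation loop
#'   (socket cluster; results are worker-count invariant).
#' @return an object of class `ggi_test`: gene names, `delta_err0`,
#'   `err_orig`/`err_cons`, the `m` permutation statistics `perm_deltas`,
#'   `p_value`, `seed` and a config snapshot. Methods: `print`, `summary`,
#'   `plot`.
#' @examples
#' pool <- synth_haplotype_pool(seed = 7)
#' dat <- simulate_xor_dataset(pool, n = 300, seed = 7)
#' fit <- ggi_test(dat, config = boost_config(num_rounds = 20,
#'                 learning_rate = 0.3, n_folds = 3), m = 9, seed = 1)
#' fit
#' @export
ggi_test <- function(data, partition = NULL, config = boost_config(),
                     m = 1000, seed = 1L,
                     estimator = c("plain", "add_one"), workers = 1L) {
  estimator <- match.arg(estimator)
  if (!is_count(m)) stop_ggi("m must be a positive integer")
  if (inherits(data, "ggi_data")) {
    partition <- partition %||% attr(data, "partition") %||%
      gene_partition_from(data)
    x <- data$genotypes
    y <- data$phenotype
  } else stop_ggi("`data` must be a ggi_data object")
  if (anyNA(x)) stop_ggi("missing genotypes; run impute_missing() first")
  if (length(unique(y)) < 2L) stop_ggi("labels are single-class")

  observed <- delta_err(data, partition = partition, config = config,
                        folds_seed = derive_seed(seed, "folds", 0L))
  one_perm <- function(i) {
    perm <- with_seed(derive_seed(seed, "perm", i),
                      sample.int(length(y)))
    dperm <- ggi_data(x, y[perm], data$snps, data$sample_ids)
    delta_err(dperm, partition = partition, config = config,
              folds_seed = derive_seed(seed, "folds", i))$delta_err
  }
  perm_deltas <- if (workers > 1L) {
    # socket cluster rather than forking: xgboost's native threads do not
    # survive a fork. Per-permutation seeds are pre-assigned, so the split
    # across workers cannot change the result.
    cl <- parallel::makePSOCKcluster(workers)
    on.exit(parallel::stopCluster(cl), add = TRUE)
    unlist(parallel::parLapplyLB(cl, seq_len(m), one_perm))
  } else {
    vapply(seq_len(m), one_perm, numeric(1))
  }
  p <- perm_pvalue_from_deltas(observed$delta_err, perm_deltas, estimator)
  structure(list(gene1 = partition$gene1, gene2 = partition$gene2,
                 delta_err0 = observed$delta_err,
                 err_orig = observed$err_orig,
                 err_cons = observed$err_cons,
                 fold_errors_orig = observed$fold_errors_orig,
                 fold_errors_cons = observed$fold_errors_cons,
                 perm_deltas = perm_deltas, m = as.integer(m),
                 p_value = p, estimator = estimator,
                 seed = as.integer(seed), config = config),
            class = "ggi_test")
}

# The permutation p-value counting rule: ties (perm delta == observed) count
# toward the numerator, and Inf >= Inf is a tie. The plain estimator admits
# p = 0; add_one is the conservative (count + 1) / (m + 1) variant.
perm_pvalue_from_deltas <- function(delta0, perm_deltas,
                                    estimator = c("plain", "add_one")) {
  estimator <- match.arg(estimator)
  count <- sum(perm_deltas >= delta0)
  if (estimator == "plain") count / length(perm_deltas)
  else (count + 1) / (length(perm_deltas) + 1)
}

#' @export
print.ggi_test <- function(x, ...) {
  cat("Gene-gene interaction test (constrained boosting + permutation)\n")
  cat("  genes: ", x$gene1, " x ", x$gene2, "\n", sep = "")
  cat("  delta_err0 = ", format(x$delta_err0, digits = 4),
      "  (err_orig = ", format(x$err_orig, digits = 4),
      ", err_cons = ", format(x$err_cons, digits = 4), ")\n", sep = "")
  cat("  p-value = ", format(x$p_value, digits = 4), "  (m = ", x$m,
      " permutations)\n", sep = "")
  invisible(x)
}

#' @export
summary.ggi_test <- function(object, ...) {
  q <- stats::quantile(object$perm_deltas[is.finite(object$perm_deltas)],
                       c(0.5, 0.9, 0.95, 0.99), names = FALSE, na.rm = TRUE)
  out <- list(gene1 = object$gene1, gene2 = object$gene2,
              delta_err0 = object$delta_err0, p_value = object$p_value,
              m = object$m, err_orig = object$err_orig,
              err_cons = object$err_cons,
              null_quantiles = stats::setNames(q, c("50%", "90%", "95%", "99%")),
              n_infinite_null = sum(is.infinite(object$perm_deltas)))
  class(out) <- "summary.ggi_test"
  out
}

#' @export
print.summary.ggi_test <- function(x, ...) {
  cat("Gene pair: ", x$gene1, " x ", x$gene2, "\n", sep = "")
  cat("Observed delta_err0: ", format(x$delta_err0, digits = 4), "\n", sep = "")
  cat("CV errors: unconstrained ", format(x$err_orig, digits = 4),
      ", additive ", format(x$err_cons, digits = 4), "\n", sep = "")
  cat("Permutation null quantiles (finite draws):\n")
  print(round(x$null_quantiles, 4))
  if (x$n_infinite_null > 0)
    cat("  (", x$n_infinite_null, " degenerate null draws with zero",
        " unconstrained error)\n", sep = "")
  cat("p-value: ", format(x$p_value, digits = 4), " from ", x$m,
      " permutations\n", sep = "")
  invisible(x)
}

#' @export
plot.ggi_test <- function(x, ...) {
  finite <- x$perm_deltas[is.finite(x$perm_deltas)]
  xl <- range(c(finite, if (is.finite(x$delta_err0)) x$delta_err0))
  graphics::hist(finite, breaks = 30, xlim = xl,
                 main = paste(x$gene1, "x", x$gene2),
                 xlab = "permutation delta_err", col = "grey85", border = "white")
  graphics::abline(v = x$delta_err0, col = "firebrick", lwd = 2)
  graphics::legend("topright", legend = sprintf("observed (p = %.3g)",
                                                x$p_value),
                   col = "firebrick", lwd = 2, bty = "n")
  invisible(x)
}

#' Write an interaction test result to disk
#'
#' Writes a one-row TSV (gene pair, statistic, p-value) and a JSON file
#' carrying the permutation draws for audit.
#'
#' @param fit a `ggi_test` object.
#' @param path_prefix output path prefix; `<prefix>.tsv` and `<prefix>.json`
#'   are written.
#' @export
write_ggi_test <- function(fit, path_prefix) {
  tab <- data.frame(gene1 = fit$gene1, gene2 = fit$gene2,
                    delta_err0 = fit$delta_err0, err_orig = fit$err_orig,
                    err_cons = fit$err_cons, m = fit$m,
                    p_value = fit$p_value, seed = fit$seed)
  utils::write.table(tab, paste0(path_prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(gene1 = fit$gene1, gene2 = fit$gene2, delta_err0 = fit$delta_err0,
         perm_deltas = fit$perm_deltas, m = fit$m, p_value = fit$p_value,
         seed = fit$seed, estimator = fit$estimator,
         config = unclass(fit$config)),
    paste0(path_prefix, ".json"), auto_unbox = TRUE, digits = NA,
    na = "string")
  invisible(path_prefix)
}
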