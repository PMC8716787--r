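#' Boosting configuration
#'
#' Parameters of the gradient-boosted tree classifiers underlying the
#' interaction statistic. The objective is fixed to binary logistic loss and
#' the evaluation metric to misclassification error (predicted probability
#' thresholded at 0.5). The `"full"` profile uses 1000 trees of depth 3 at
#' learning rate 0.01 with 10-fold cross-validation; the `"desk"` profile is
#' a reduced-fidelity setting for interactive work and simulation batteries,
#' shrinking the tree count while raising the learning rate so that
#' `learning_rate * num_rounds` is preserved (0.1 x 100 = 0.01 x 1000).
#'
#' @param num_rounds number of boosting rounds (trees); no early stopping.
#' @param max_depth maximum tree depth.
#' @param learning_rate shrinkage (xgboost `eta`).
#' @param n_folds cross-validation folds (stratified by label).
#' @param nthread threads for the boosting engine; 1 guarantees bit-level
#'   reproducibility.
#' @param aggregate `"fold_mean"` averages the per-fold error rates (standard
#'   CV); `"pooled"` computes one error over all held-out predictions.
#' @param profile optional preset, `"full"` or `"desk"`; explicit arguments
#'   override preset values.
#' @export
boost_config <- function(num_rounds = 1000, max_depth = 3,
                         learning_rate = 0.01, n_folds = 10, nthread = 1,
                         aggregate = c("fold_mean", "pooled"),
                         profile = NULL) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("full", "desk"))
    if (profile == "desk") {
      if (missing(num_rounds)) num_rounds <- 100
      if (missing(learning_rate)) learning_rate <- 0.1
    }
  }
  aggregate <- match.arg(aggregate)
  stopifnot(is_count(num_rounds), is_count(max_depth), is_count(n_folds),
            n_folds >= 2, learning_rate > 0)
  structure(list(num_rounds = as.integer(num_rounds),
                 max_depth = as.integer(max_depth),
                 learning_rate = learning_rate,
                 n_folds = as.integer(n_folds),
                 nthread = as.integer(nthread),
                 aggregate = aggregate),
            class = "boost_config")
}

#' @export
print.boost_config <- function(x, ...) {
  cat("Boosting config: ", x$num_rounds, " trees, depth ", x$max_depth,
      ", learning rate ", x$learning_rate, ", ", x$n_folds,
      "-fold CV (", x$aggregate, ")\n", sep = "")
  invisible(x)
}

#' Interaction constraint groups from a gene partition
#'
#' Encodes the additivity constraint: each tree may split only on features
#' from a single group, so the fitted log-odds decompose as
#' `F1(gene-1 SNPs) + F2(gene-2 SNPs)` — no cross-gene interactions.
#'
#' @param partition a [gene_partition].
#' @return a `constraint_spec`: a list of two disjoint 0-based feature index
#'   vectors, as consumed by the boosting engine.
#' @export
build_constraints <- function(partition) {
  stopifnot(inherits(partition, "gene_partition"))
  groups <- list(as.integer(partition$s1) - 1L,
                 as.integer(partition$s2) - 1L)
  if (length(intersect(groups[[1]], groups[[2]])) > 0 ||
      any(lengths(groups) == 0))
    stop_ggi("constraint groups must be disjoint and nonempty")
  structure(groups, class = "constraint_spec")
}

# Stratified fold assignment: within each label class, samples are shuffled
# (under `seed`) and dealt out cyclically, so case/control ratios match
# across folds and no training fold can lose a class entirely (each class
# needs >= 2 members).
assign_folds <- function(y, n_folds, seed) {
  y <- as.integer(y)
  if (length(y) < n_folds) stop_ggi("fewer samples than folds")
  if (length(unique(y)) < 2L)
    stop_ggi("labels are single-class; the classifier is undefined")
  if (min(table(y)) < 2L)
    stop_ggi("each class needs at least 2 samples for stratified CV")
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

xgb_params <- function(config, constraints = NULL) {
  p <- list(objective = "binary:logistic",
            eval_metric = "error",
            max_depth = config$max_depth,
            eta = config$learning_rate,
            nthread = config$nthread,
            tree_method = "exact")
  if (!is.null(constraints))
    p$interaction_constraints <- lapply(constraints, as.integer)
  p
}

#' Fit one boosted ensemble
#'
#' Thin wrapper over the boosting engine with the package's fixed loss
#' (binary logistic) and optional additivity constraint; used for full-data
#' fits whose tree structure is mined by [pair_stats()].
#'
#' @param x numeric matrix of genotypes (no missing values).
#' @param y binary labels.
#' @param config a [boost_config].
#' @param constraints a `constraint_spec` from [build_constraints()], or NULL.
#' @return an `xgb.Booster`.
#' @export
fit_boosted <- function(x, y, config = boost_config(), constraints = NULL) {
  if (anyNA(x)) stop_ggi("missing genotypes; run impute_missing() first")
  dm <- xgboost::xgb.DMatrix(data = x, label = as.numeric(y),
                             nthread = config$nthread)
  xgboost::xgb.train(params = xgb_params(config, constraints), data = dm,
                     nrounds = config$num_rounds, verbose = 0)
}

#' Cross-validated misclassification error
#'
#' For each fold, trains a boosted ensemble on the remaining folds (with the
#' additivity constraint when given) and scores the held-out fold by
#' thresholding the predicted case probability at 0.5. Deterministic given
#' the fold assignment and config.
#'
#' @param x genotype matrix (n x d, entries 0/1/2, no missing values).
#' @param y binary labels (0/1).
#' @param config a [boost_config].
#' @param constraints optional `constraint_spec`.
#' @param folds integer fold assignment of length n, e.g. from the seed-driven
#'   stratified allocator used by [delta_err()].
#' @return list with `error` (the aggregated CV error) and `fold_errors`.
#' @export
cv_error <- function(x, y, config = boost_config(), constraints = NULL,
                     folds) {
  y <- as.numeric(y)
  if (anyNA(x)) stop_ggi("missing genotypes; run impute_missing() first")
  stopifnot(length(folds) == nrow(x), length(y) == nrow(x))
  fold_ids <- sort(unique(folds))
  fold_errors <- numeric(length(fold_ids))
  pooled_wrong <- 0
  params <- xgb_params(config, constraints)
  for (k in seq_along(fold_ids)) {
    te <- folds == fold_ids[k]
    ytr <- y[!te]
    if (length(unique(ytr)) < 2L)
      stop_ggi("training fold ", fold_ids[k], " contains a single class")
    dtr <- xgboost::xgb.DMatrix(data = x[!te, , drop = FALSE], label = ytr,
                                nthread = config$nthread)
    fit <- xgboost::xgb.train(params = params, data = dtr,
                              nrounds = config$num_rounds, verbose = 0)
    pred <- stats::predict(fit, xgboost::xgb.DMatrix(
      data = x[te, , drop = FALSE], nthread = config$nthread))
    wrong <- (pred >= 0.5) != (y[te] == 1)
    fold_errors[k] <- mean(wrong)
    pooled_wrong <- pooled_wrong + sum(wrong)
  }
  error <- if (config$aggregate == "pooled") pooled_wrong / nrow(x)
           else mean(fold_errors)
  list(error = error, fold_errors = fold_errors)
}

#' The additivity-gap statistic
#'
#' Fits the unconstrained and the constrained (additive across genes)
#' classifiers on the SAME cross-validation folds and returns the relative
#' error increase caused by forbidding cross-gene interactions:
#' `delta_err = (err_cons - err_orig) / err_orig`. A positive value means the
#' unconstrained model predicts better, i.e. evidence of interaction. When
#' `err_orig` is exactly 0 the ratio is degenerate: the statistic is defined
#' as `Inf` if `err_cons > 0` and `0` otherwise, which preserves the ordering
#' used by the permutation p-value.
#'
#' @param x genotype matrix or [ggi_data].
#' @param y binary labels (ignored when `x` is a [ggi_data]).
#' @param partition a [gene_partition] over the columns of `x`.
#' @param config a [boost_config].
#' @param folds_seed seed for the stratified fold assignment.
#' @return object of class `delta_err_result`: list with `delta_err`,
#'   `err_orig`, `err_cons`, `fold_errors_orig`, `fold_errors_cons`, `folds`.
#' @export
delta_err <- function(x, y = NULL, partition = NULL,
                      config = boost_config(), folds_seed = 1L) {
  if (inherits(x, "ggi_data")) {
    partition <- partition %||% attr(x, "partition") %||% gene_partition_from(x)
    y <- x$phenotype
    x <- x$genotypes
  }
  stopifnot(inherits(partition, "gene_partition"))
  d <- length(partition$s1) + length(partition$s2)
  if (d != ncol(x))
    stop_ggi("partition covers ", d, " SNPs but the matrix has ", ncol(x))
  x <- matrix(as.numeric(x), nrow = nrow(x),
              dimnames = dimnames(x))
  folds <- assign_folds(y, config$n_folds, folds_seed)
  orig <- cv_error(x, y, config, constraints = NULL, folds = folds)
  cons <- cv_error(x, y, config, constraints = build_constraints(partition),
                   folds = folds)
  de <- if (orig$error > 0) (cons$error - orig$error) / orig$error
        else if (cons$error > 0) Inf else 0
  structure(list(delta_err = de, err_orig = orig$error,
                 err_cons = cons$error,
                 fold_errors_orig = orig$fold_errors,
                 fold_errors_cons = cons$fold_errors,
                 folds = folds),
            class = "delta_err_result")
}

#' @export
print.delta_err_result <- function(x, ...) {
  cat("Additivity gap: delta_err = ", format(x$delta_err, digits = 4),
      "  (err_orig = ", format(x$err_orig, digits = 4),
      ", err_cons = ", format(x$err_cons, digits = 4), ")\n", sep = "")
  invisible(x)
}
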