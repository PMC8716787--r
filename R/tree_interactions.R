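#' Parse a boosted-tree ensemble dump
#'
#' Converts the boosting engine's tree table (or a fitted booster) into a
#' plain list-of-trees structure used by the mining and audit functions.
#' Each tree is a data frame of nodes with the split feature (`NA` for
#' leaves), the split gain, and child node ids; structure and node counts
#' round-trip the engine's dump losslessly.
#'
#' @param model an `xgb.Booster`, or a data frame in the engine's
#'   `xgb.model.dt.tree` layout (columns Tree, ID, Feature, Gain, Yes, No).
#' @return a `tree_ensemble`: list with `trees` (list of node data frames)
#'   and `feature_names` (NULL when the dump uses bare indices).
#' @export
parse_dump <- function(model) {
  if (inherits(model, "xgb.Booster")) {
    dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = model))
    feature_names <- tryCatch(xgboost::getinfo(model, "feature_name"),
                              error = function(e) NULL)
  } else {
    dt <- as.data.frame(model)
    feature_names <- attr(model, "feature_names")
  }
  need <- c("Tree", "ID", "Feature", "Gain", "Yes", "No")
  if (!all(need %in% names(dt)))
    stop_ggi("malformed dump: need columns ", paste(need, collapse = ", "))
  trees <- lapply(split(dt, dt$Tree), function(td) {
    data.frame(id = td$ID,
               feature = ifelse(td$Feature == "Leaf", NA_character_,
                                td$Feature),
               gain = td$Gain, yes = td$Yes, no = td$No,
               stringsAsFactors = FALSE)
  })
  structure(list(trees = unname(trees), feature_names = feature_names),
            class = "tree_ensemble")
}

#' @export
print.tree_ensemble <- function(x, ...) {
  internal <- sum(vapply(x$trees, function(t) sum(!is.na(t$feature)),
                         numeric(1)))
  cat("Tree ensemble: ", length(x$trees), " trees, ", internal,
      " internal nodes\n", sep = "")
  invisible(x)
}

# Root-to-leaf feature paths of one tree (list of character vectors).
tree_paths <- function(tree) {
  lookup <- seq_len(nrow(tree))
  names(lookup) <- tree$id
  walk <- function(i, feats) {
    if (is.na(tree$feature[i])) return(list(feats))
    f <- c(feats, tree$feature[i])
    c(walk(lookup[[tree$yes[i]]], f), walk(lookup[[tree$no[i]]], f))
  }
  walk(1L, character())
}

#' Check a constrained ensemble for cross-group splits
#'
#' TRUE iff every root-to-leaf path of every tree uses split features from a
#' single constraint group — the structural guarantee behind the additivity
#' constraint.
#'
#' @param dump a `tree_ensemble` (or a fitted booster, parsed on the fly).
#' @param constraints a `constraint_spec` (0-based feature index groups).
#' @param feature_names feature names in column order, used to resolve named
#'   split features to indices; defaults to the names recorded in the dump.
#' @export
audit_constraint_compliance <- function(dump, constraints,
                                        feature_names = NULL) {
  if (!inherits(dump, "tree_ensemble")) dump <- parse_dump(dump)
  feature_names <- feature_names %||% dump$feature_names
  to_index <- function(f) {
    if (grepl("^[0-9]+$", f[1]) && is.null(feature_names)) return(as.integer(f))
    if (is.null(feature_names))
      stop_ggi("dump uses feature names; supply feature_names")
    idx <- match(f, feature_names) - 1L
    if (anyNA(idx)) stop_ggi("unknown feature(s) in dump: ",
                             paste(f[is.na(idx)], collapse = ", "))
    idx
  }
  for (tree in dump$trees) {
    if (all(is.na(tree$feature))) next
    for (p in tree_paths(tree)) {
      idx <- to_index(p)
      ok <- any(vapply(constraints, function(g) all(idx %in% g), logical(1)))
      if (!ok) return(FALSE)
    }
  }
  TRUE
}

#' Parent-child split-pair statistics (sumGain)
#'
#' Mines marker-level interactions from a fitted (typically unconstrained)
#' ensemble: for every edge from an internal node to an internal CHILD node,
#' the child's split gain is accumulated into the ordered
#' (parent feature, child feature) pair and the pair's frequency is
#' incremented. Pairs are ranked by total gain (`sum_gain`) descending, ties
#' broken by frequency then lexicographic names. Deeper relations
#' (grandparent-grandchild) are not counted.
#'
#' @param dump a `tree_ensemble` or fitted booster.
#' @param snp_names optional feature names in column order, to resolve bare
#'   feature indices in the dump.
#' @param genes optional named character vector mapping SNP name to gene id;
#'   required for `cross_gene_only`.
#' @param cross_gene_only keep only pairs whose two SNPs belong to different
#'   genes.
#' @param ordered keep (parent, child) direction (default); `FALSE` folds
#'   each pair to unordered.
#' @return a `pair_stats` data frame: `parent_snp`, `child_snp`, `sum_gain`,
#'   `frequency`.
#' @export
pair_stats <- function(dump, snp_names = NULL, genes = NULL,
                       cross_gene_only = FALSE, ordered = TRUE) {
  if (!inherits(dump, "tree_ensemble")) dump <- parse_dump(dump)
  snp_names <- snp_names %||% dump$feature_names
  resolve <- function(f) {
    if (!is.null(snp_names) && grepl("^[0-9]+$", f))
      snp_names[as.integer(f) + 1L] else f
  }
  acc <- new.env(parent = emptyenv())
  for (tree in dump$trees) {
    lookup <- stats::setNames(seq_len(nrow(tree)), tree$id)
    for (i in which(!is.na(tree$feature))) {
      for (child_id in c(tree$yes[i], tree$no[i])) {
        j <- lookup[[child_id]]
        if (is.na(tree$feature[j])) next
        a <- resolve(tree$feature[i]); b <- resolve(tree$feature[j])
        pr <- if (ordered) c(a, b) else sort(c(a, b))
        key <- paste(pr, collapse = "\r")
        cur <- acc[[key]] %||% c(0, 0)
        acc[[key]] <- c(cur[1] + tree$gain[j], cur[2] + 1)
      }
    }
  }
  keys <- ls(acc)
  if (length(keys) == 0) {
    out <- data.frame(parent_snp = character(), child_snp = character(),
                      sum_gain = numeric(), frequency = integer(),
                      stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    out <- data.frame(
      parent_snp = vapply(parts, `[`, "", 1),
      child_snp = vapply(parts, `[`, "", 2),
      sum_gain = vapply(keys, function(k) acc[[k]][1], numeric(1)),
      frequency = as.integer(vapply(keys, function(k) acc[[k]][2],
                                    numeric(1))),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  if (cross_gene_only) {
    if (is.null(genes)) stop_ggi("cross_gene_only needs `genes`")
    keep <- genes[out$parent_snp] != genes[out$child_snp]
    out <- out[which(keep), , drop = FALSE]
  }
  out <- out[order(-out$sum_gain, -out$frequency, out$parent_snp,
                   out$child_snp), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pair_stats", "data.frame")
  out
}

#' Per-SNP total split gain
#'
#' Sum of the split gain over every internal node splitting on each feature.
#'
#' @inheritParams pair_stats
#' @export
snp_gain_totals <- function(dump, snp_names = NULL) {
  if (!inherits(dump, "tree_ensemble")) dump <- parse_dump(dump)
  snp_names <- snp_names %||% dump$feature_names
  feats <- unlist(lapply(dump$trees, function(t) t$feature[!is.na(t$feature)]))
  gains <- unlist(lapply(dump$trees, function(t) t$gain[!is.na(t$feature)]))
  tot <- tapply(gains, feats, sum)
  nm <- names(tot)
  if (!is.null(snp_names) && all(grepl("^[0-9]+$", nm)))
    nm <- snp_names[as.integer(nm) + 1L]
  sort(stats::setNames(as.numeric(tot), nm), decreasing = TRUE)
}

#' Equal-width intensity bins for pair statistics
#'
#' Divides the range `[0, max(sum_gain)]` into `n_bins` equal parts and
#' labels each pair with its bin (1 = weakest, `n_bins` = strongest), for
#' heat-style rendering of interaction intensity.
#'
#' @param stats a `pair_stats` data frame.
#' @param n_bins number of bins (default 4).
#' @return `stats` with an integer `bin` column appended.
#' @export
gain_bins <- function(stats, n_bins = 4) {
  if (nrow(stats) == 0) stop_ggi("empty pair statistics")
  mx <- max(stats$sum_gain)
  bin <- if (mx <= 0) rep(n_bins, nrow(stats))
         else pmax(1L, ceiling(stats$sum_gain / mx * n_bins))
  stats$bin <- as.integer(bin)
  stats
}

#' Write pair statistics as TSV
#' @param stats a `pair_stats` data frame.
#' @param path output file.
#' @export
write_pair_stats <- function(stats, path) {
  out <- data.frame(index = seq_len(nrow(stats)), as.data.frame(stats))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
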