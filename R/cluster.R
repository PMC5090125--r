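# Hierarchical clustering of site methylation profiles with bootstrap
# branch support (ordinary bootstrap probabilities, pvclust-style).

#' Average-linkage tree on correlation dissimilarity
#'
#' Dissimilarity between site row-vectors is `1 - Pearson correlation`
#' (range 0..2); merging is average linkage (UPGMA).
#'
#' @param values Numeric matrix, rows = site profiles across samples
#'   (rownames = site ids).
#' @return List of class `msre_tree`: `hclust`, `labels`, `bipartitions`
#'   (leaf-label sets per internal node), `bp` (`NA` until
#'   [bootstrap_branch_support()]), `n_boot`, `seed`.
#' @export
correlation_linkage_tree <- function(values) {
  if (nrow(values) < 2L) stopf("need at least 2 sites")
  if (ncol(values) < 3L) stopf("need at least 3 samples")
  sds <- apply(values, 1, stats::sd)
  if (any(sds == 0)) {
    stopf("zero-variance site(s): %s",
          paste(rownames(values)[sds == 0], collapse = ", "))
  }
  hc <- stats::hclust(stats::as.dist(1 - stats::cor(t(values))),
                      method = "average")
  structure(list(hclust = hc, labels = hc$labels,
                 bipartitions = merge_leaf_sets(hc),
                 bp = rep(NA_real_, nrow(hc$merge)),
                 n_boot = 0L, seed = NA_integer_), class = "msre_tree")
}

# canonical key per internal node: sorted leaf labels, \r-joined
merge_leaf_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    leaves <- unlist(lapply(kids, function(k) {
      if (k < 0) hc$labels[-k] else sets[[k]]
    }))
    sets[[i]] <- sort(leaves)
  }
  vapply(sets, paste, "", collapse = "\r")
}

#' Bootstrap branch support
#'
#' Resamples sample columns with replacement `n_boot` times, rebuilds the
#' tree each time, and reports for every internal branch of the original
#' tree the percentage of replicate trees containing the identical leaf
#' bipartition (BP). Correlations undefined in a replicate (zero variance
#' after resampling) are treated as 0.
#'
#' @param values Site-by-sample matrix (as in
#'   [correlation_linkage_tree()]).
#' @param n_boot Bootstrap replicates (default 1000; below 100 a warning is
#'   emitted but the run proceeds).
#' @param seed RNG seed.
#' @return An `msre_tree` with `bp` filled in (percent, 0..100).
#' @export
bootstrap_branch_support <- function(values, n_boot = 1000, seed = 1) {
  tree <- correlation_linkage_tree(values)
  if (n_boot < 100) warning("n_boot < 100: branch supports will be noisy")
  set.seed(seed)
  hits <- integer(length(tree$bipartitions))
  n <- ncol(values)
  for (b in seq_len(n_boot)) {
    cols <- sample.int(n, n, replace = TRUE)
    cm <- suppressWarnings(stats::cor(t(values[, cols, drop = FALSE])))
    cm[is.na(cm)] <- 0
    diag(cm) <- 1
    hcb <- stats::hclust(stats::as.dist(1 - cm), method = "average")
    hits <- hits + tree$bipartitions %in% merge_leaf_sets(hcb)
  }
  tree$bp <- 100 * hits / n_boot
  tree$n_boot <- as.integer(n_boot)
  tree$seed <- as.integer(seed)
  tree
}

#' @export
print.msre_tree <- function(x, ...) {
  cat(sprintf("msre_tree: %d leaves, %d internal branches%s\n",
              length(x$labels), length(x$bipartitions),
              if (x$n_boot > 0) sprintf(", BP from %d bootstraps", x$n_boot)
              else ""))
  invisible(x)
}

#' Bipartition table of a tree
#'
#' @param tree An `msre_tree`.
#' @return Data frame `branch`, `n_leaves`, `bp`, `leaves`
#'   (comma-separated).
#' @export
bipartition_table <- function(tree) {
  leaves <- strsplit(tree$bipartitions, "\r", fixed = TRUE)
  data.frame(branch = seq_along(leaves),
             n_leaves = lengths(leaves), bp = tree$bp,
             leaves = vapply(leaves, paste, "", collapse = ","),
             stringsAsFactors = FALSE)
}

#' Write a tree as Newick with BP node labels
#'
#' @param tree An `msre_tree` (with or without supports).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree$hclust)
  pp <- ape::prop.part(phy)
  keys <- vapply(pp, function(ix) paste(sort(phy$tip.label[ix]), collapse = "\r"),
                 "")
  lab <- rep("", phy$Nnode)
  hit <- match(keys, tree$bipartitions)
  ok <- !is.na(hit) & !is.na(tree$bp[pmax(hit, 1L)])
  lab[ok] <- sprintf("%.0f", tree$bp[hit[ok]])
  phy$node.label <- lab
  ape::write.tree(phy, file = path)
  invisible(path)
}
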