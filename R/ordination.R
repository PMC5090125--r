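# NMDS-based group discrimination: distances, ordination, confidence
# ellipses, permutation separation test, per-site discrimination ranking.

#' Between-sample distance matrix
#'
#' Bray-Curtis (default, the community-ecology convention) or Euclidean
#' distances between sample columns of the methylation matrix.
#'
#' @param mat A `methylation_matrix` or a numeric matrix (rows = features).
#' @param metric `"bray-curtis"` or `"euclidean"`.
#' @return A `dist` object over samples.
#' @export
distance_matrix <- function(mat, metric = c("bray-curtis", "euclidean")) {
  metric <- match.arg(metric)
  v <- if (inherits(mat, "methylation_matrix")) mat$values else mat
  if (ncol(v) < 3L) stopf("need at least 3 samples")
  if (any(v < 0)) stopf("values must be nonnegative")
  if (metric == "bray-curtis" && any(colSums(v) == 0)) {
    stopf("all-zero sample column is undefined under Bray-Curtis")
  }
  vegan::vegdist(t(v), method = if (metric == "bray-curtis") "bray" else
    "euclidean")
}

#' Kruskal stress-1 of a configuration
#'
#' Independent stress evaluation: configuration distances are isotonically
#' regressed on the dissimilarity order (stats::isoreg) and
#' `sqrt(sum((dhat - fit)^2) / sum(dhat^2))` is returned. Used as the oracle
#' for the NMDS minimizer.
#'
#' @param d Dissimilarities (`dist`).
#' @param points Configuration matrix (samples x k).
#' @return Stress-1 in `[0, 1]`.
#' @export
kruskal_stress <- function(d, points) {
  dv <- as.vector(d)
  dh <- as.vector(stats::dist(points))
  o <- order(dv, dh)
  fit <- stats::isoreg(seq_along(o), dh[o])$yf
  sqrt(sum((dh[o] - fit)^2) / sum(dh[o]^2))
}

#' Non-metric multidimensional scaling
#'
#' Minimizes Kruskal stress-1 (monotone regression of configuration
#' distances on dissimilarity ranks) via `vegan::monoMDS`, from one
#' metric-scaling start (classical MDS) plus `n_starts` seeded random
#' starts; the best solution is returned, centred and rotated to its
#' principal axes with a deterministic sign convention.
#'
#' @param d Symmetric dissimilarities (`dist` or matrix).
#' @param k Embedding dimension (default 2).
#' @param n_starts Random restarts.
#' @param max_iter Iterations per start.
#' @param tol Stress convergence tolerance.
#' @param seed RNG seed for the random starts.
#' @return List of class `msre_nmds`: `points` (n x k, centred), `stress`,
#'   `converged`, `n_starts`, `seed`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, max_iter = 300, tol = 1e-6,
                 seed = 1) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d))) stopf("distance matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  if (n <= k) stopf("need more samples than dimensions")
  set.seed(seed)
  inits <- c(list(stats::cmdscale(d, k = k)),
             lapply(seq_len(n_starts), function(i) matrix(stats::rnorm(n * k),
                                                          n, k)))
  best <- NULL
  for (y in inits) {
    fit <- vegan::monoMDS(d, y = y, k = k, model = "global",
                          maxit = max_iter, smin = 1e-7, sfgrmin = 1e-9,
                          sratmax = 1 - tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  sv <- svd(pts)
  pts <- sv$u %*% diag(sv$d, k, k)
  # sign convention: largest-magnitude coordinate positive on each axis
  for (j in seq_len(k)) {
    if (pts[which.max(abs(pts[, j])), j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- attr(d, "Labels")
  colnames(pts) <- paste0("NMDS", seq_len(k))
  structure(list(points = pts, stress = best$stress,
                 converged = best$maxits == 0 || best$stress < 1e-6,
                 n_starts = n_starts, seed = seed), class = "msre_nmds")
}

#' @export
print.msre_nmds <- function(x, ...) {
  cat(sprintf("NMDS: %d points, k=%d, stress-1 = %.4g\n", nrow(x$points),
              ncol(x$points), x$stress))
  invisible(x)
}

#' Confidence ellipse of a group mean
#'
#' Standard-error ellipse: the covariance of the group mean (sample
#' covariance / n) scaled by the chi-square(2) quantile at `level`.
#'
#' @param points Ordination coordinates (n x 2).
#' @param members Row indices or logical mask of the group.
#' @param level Confidence level in (0, 1).
#' @return List of class `group_ellipse`: `center`, `cov`, `level`,
#'   `semi_axes` (descending), `angle` (radians of the major axis).
#' @export
confidence_ellipse <- function(points, members, level = 0.95) {
  pts <- points[members, , drop = FALSE]
  if (nrow(pts) < 2L) stopf("need at least 2 points in the group")
  if (level <= 0 || level >= 1) stopf("level must be in (0, 1)")
  ctr <- colMeans(pts)
  cv <- stats::cov(pts) / nrow(pts)
  eg <- eigen(cv, symmetric = TRUE)
  r2 <- stats::qchisq(level, df = 2)
  structure(list(center = ctr, cov = cv, level = level,
                 semi_axes = sqrt(pmax(eg$values, 0) * r2),
                 angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1])),
            class = "group_ellipse")
}

#' Permutation test of group separation
#'
#' Statistic: mean between-group distance minus mean within-group distance.
#' All label relabelings are enumerated when there are at most
#' `max_exhaustive` of them (p = fraction of relabelings with a statistic at
#' least as large, identity included — exact small-sample inference);
#' otherwise Monte-Carlo with `p = (1 + #{>= obs}) / (1 + n_perm)`.
#'
#' @param d `dist` or symmetric matrix of sample distances.
#' @param groups Two-group labels in sample order.
#' @param n_perm Monte-Carlo permutations (>= 99).
#' @param seed RNG seed.
#' @param max_exhaustive Enumeration cutoff on `choose(n, n_A)`.
#' @return List: `statistic`, `p_value`, `method` (`"exhaustive"` or
#'   `"monte-carlo"`), `n_perm`.
#' @export
permutation_group_test <- function(d, groups, n_perm = 9999, seed = 1,
                                   max_exhaustive = 10000) {
  if (n_perm < 99) stopf("n_perm must be >= 99")
  dm <- as.matrix(d)
  g <- as_group_factor(groups)
  if (nlevels(g) != 2L || any(tabulate(g, 2L) < 2L)) {
    stopf("two groups with >= 2 samples each required")
  }
  n <- nrow(dm)
  stat <- function(ia) {
    inA <- seq_len(n) %in% ia
    between <- dm[inA, !inA, drop = FALSE]
    wA <- dm[inA, inA, drop = FALSE]
    wB <- dm[!inA, !inA, drop = FALSE]
    within <- c(wA[upper.tri(wA)], wB[upper.tri(wB)])
    mean(between) - mean(within)
  }
  ia0 <- which(g == levels(g)[1])
  obs <- stat(ia0)
  nA <- length(ia0)
  if (choose(n, nA) <= max_exhaustive) {
    combos <- utils::combn(n, nA)
    stats_all <- apply(combos, 2, stat)
    p <- mean(stats_all >= obs - 1e-12)
    method <- "exhaustive"
    n_used <- ncol(combos)
  } else {
    set.seed(seed)
    perm <- vapply(seq_len(n_perm), function(i) stat(sample.int(n, nA)), 0)
    p <- (1 + sum(perm >= obs - 1e-12)) / (1 + n_perm)
    method <- "monte-carlo"
    n_used <- n_perm
  }
  list(statistic = obs, p_value = p, method = method, n_perm = n_used)
}

#' Rank sites by contribution to group separation
#'
#' Samples are projected onto the axis joining the two group centroids in
#' ordination space; each site is scored by the absolute Pearson
#' correlation between its value vector and that projection. Zero-variance
#' sites score 0; ties break by site id.
#'
#' @param mat A `methylation_matrix` (rows scored individually).
#' @param coordinates Ordination coordinates for the same samples (e.g.
#'   `nmds(...)$points`).
#' @param groups Two-group labels in sample order.
#' @return Data frame `site_id`, `score`, `rank` (descending score).
#' @export
site_discrimination_ranking <- function(mat, coordinates, groups) {
  g <- as_group_factor(groups)
  if (nlevels(g) != 2L) stopf("exactly two groups required")
  axis <- colMeans(coordinates[g == levels(g)[2], , drop = FALSE]) -
    colMeans(coordinates[g == levels(g)[1], , drop = FALSE])
  proj <- as.vector(coordinates %*% axis)
  v <- mat$values
  sds <- apply(v, 1, stats::sd)
  score <- numeric(nrow(v))
  ok <- sds > 0 & stats::sd(proj) > 0
  score[ok] <- abs(stats::cor(t(v[ok, , drop = FALSE]), proj))
  out <- data.frame(site_id = rownames(v), score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$site_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
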