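#' Convert a methylation matrix to pseudo-counts
#'
#' `count = round(value * scale)` per cell. With `scale = NULL` the scale is
#' auto-calibrated by method of moments, `scale = mean(value) /
#' within-group variance`, so the resulting counts have an approximately
#' Poisson mean-variance relation and the downstream negative-binomial
#' machinery is correctly specified. `scale = 0.05` reproduces the magnitude
#' of published MSRE-seq "methylated cytosine count" libraries (mean count
#' about 3) but discards most of the measurement precision; see the vignette.
#'
#' The M and U channels are measured with different precision (spanning
#' coverage vs calibrated cut-end excess), so under auto-calibration each
#' channel receives its own scale; an explicit numeric `scale` applies
#' globally.
#'
#' @param mat A `methylation_matrix` (values on the percent scale).
#' @param scale Counts per percentage point, or `NULL` to auto-calibrate.
#' @return List of class `count_matrix`: integer `counts`, `lib_sizes`
#'   (column sums), `groups` (factor, manifest order), `scale` (possibly
#'   one value per channel).
#' @export
to_counts <- function(mat, scale = NULL) {
  v <- mat$values
  if (any(v < 0)) stopf("matrix values must be nonnegative")
  g <- as_group_factor(mat$manifest$group)
  if (is.null(scale)) {
    chan <- substr(rownames(v) %||% character(0), 1, 2)
    groups_of_rows <- if (all(chan %in% c("M.", "U."))) chan else
      rep("all", nrow(v))
    scale <- vapply(split(seq_len(nrow(v)), groups_of_rows), function(rows) {
      wv <- within_group_variance(v[rows, , drop = FALSE], g)
      if (wv > 0) mean(v[rows, ]) / wv else 1
    }, 0)
    counts <- round(v * scale[groups_of_rows])
  } else {
    counts <- round(v * scale)
  }
  storage.mode(counts) <- "integer"
  lib <- colSums(counts)
  if (any(lib <= 0)) stopf("zero library size for sample(s): %s",
                           paste(colnames(v)[lib <= 0], collapse = ", "))
  structure(list(counts = counts, lib_sizes = lib, groups = g, scale = scale),
            class = "count_matrix")
}

# mean pooled within-group variance across rows
within_group_variance <- function(v, g) {
  num <- 0
  den <- 0
  for (lv in levels(g)) {
    cols <- v[, g == lv, drop = FALSE]
    n <- ncol(cols)
    if (n >= 2L) {
      rv <- apply(cols, 1, stats::var)
      num <- num + sum(rv) * (n - 1)
      den <- den + nrow(cols) * (n - 1)
    }
  }
  if (den == 0) 0 else num / den
}

# counts rescaled to the mean library size (per-sample normalization)
normalize_counts <- function(cm) {
  sweep(cm$counts, 2, mean(cm$lib_sizes) / cm$lib_sizes, `*`)
}

#' Method-of-moments common dispersion
#'
#' On library-size-normalized counts, each site contributes
#' `max(0, (v - mu) / mu^2)` with `mu` the site mean and `v` the pooled
#' within-group variance; the common dispersion is the median over sites.
#' Deterministic; requires at least two samples per group.
#'
#' @param cm A `count_matrix` from [to_counts()].
#' @return Scalar dispersion estimate `phi >= 0`.
#' @export
estimate_common_dispersion <- function(cm) {
  phi <- tagwise_moment_estimates(cm)
  stats::median(pmax(0, phi), na.rm = TRUE)
}

# raw per-site moment estimates (can be negative); NA when mu == 0
tagwise_moment_estimates <- function(cm) {
  if (any(tabulate(cm$groups) < 2L)) stopf("need >= 2 samples per group")
  y <- normalize_counts(cm)
  g <- cm$groups
  mu <- rowMeans(y)
  v <- numeric(nrow(y))
  den <- 0
  for (lv in levels(g)) {
    cols <- y[, g == lv, drop = FALSE]
    if (ncol(cols) >= 2L) {
      v <- v + apply(cols, 1, stats::var) * (ncol(cols) - 1)
      den <- den + ncol(cols) - 1
    }
  }
  v <- v / den
  ifelse(mu > 0, (v - mu) / mu^2, NA_real_)
}

#' Shrunken tagwise dispersions
#'
#' Per-site dispersion as a weighted combination of the common value (prior
#' weight `w`) and the site's own moment estimate (data weight = residual
#' degrees of freedom), floored at `1e-3`.
#'
#' @param cm A `count_matrix`.
#' @param phi Common dispersion.
#' @param prior_w Prior weight `w >= 0`; `Inf` returns `phi` everywhere,
#'   `0` returns the floored per-site estimates.
#' @return Numeric vector of per-site dispersions.
#' @export
estimate_tagwise_dispersion <- function(cm, phi, prior_w = 10) {
  if (prior_w < 0) stopf("prior weight must be >= 0")
  raw <- tagwise_moment_estimates(cm)
  raw[is.na(raw)] <- phi
  df <- length(cm$groups) - nlevels(cm$groups)
  comb <- if (is.infinite(prior_w)) rep(phi, length(raw)) else
    (prior_w * phi + df * raw) / (prior_w + df)
  pmax(comb, 1e-3)
}

#' Exact negative-binomial two-group test
#'
#' Counts are rescaled to the geometric-mean library size (rounded
#' half-to-even) so totals are exchangeable, then summed per group. Under
#' the null the probability of each split `(k, t - k)` of the total `t` is
#' proportional to the product of negative-binomial point masses with means
#' proportional to group sample counts and dispersion `phi`; the two-sided
#' p-value is the normalized sum of split probabilities not exceeding the
#' observed one. `phi = 0` degenerates to binomial point masses.
#'
#' @param counts_a,counts_b Per-sample raw counts in each group.
#' @param lib_a,lib_b Matching library sizes (default: already equalized).
#' @param phi Dispersion for this site.
#' @return Two-sided p-value in (0, 1].
#' @export
exact_nb_test <- function(counts_a, counts_b, lib_a = NULL, lib_b = NULL,
                          phi = 0) {
  na <- length(counts_a)
  nb <- length(counts_b)
  if (!is.null(lib_a)) {
    libs <- c(lib_a, lib_b)
    ref <- exp(mean(log(libs)))
    eq <- round(c(counts_a, counts_b) * ref / libs)
    counts_a <- eq[seq_len(na)]
    counts_b <- eq[na + seq_len(nb)]
  }
  a <- sum(counts_a)
  b <- sum(counts_b)
  t <- a + b
  if (t == 0) return(1)
  k <- 0:t
  if (phi > 1e-8) {
    lp <- stats::dnbinom(k, size = na / phi, mu = t * na / (na + nb),
                         log = TRUE) +
      stats::dnbinom(t - k, size = nb / phi, mu = t * nb / (na + nb),
                     log = TRUE)
  } else {
    lp <- stats::dbinom(k, t, na / (na + nb), log = TRUE)
  }
  lp <- lp - max(lp)
  p <- exp(lp)
  pobs <- p[a + 1L]
  min(1, sum(p[p <= pobs * (1 + 1e-10)]) / sum(p))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, restored to input
#' order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return FDR-adjusted values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(m / (m:1) * p[o]))
  q[order(o)]
}

#' Per-site differential methylation table
#'
#' Full chain: pseudo-counts, common and tagwise dispersions, per-row exact
#' NB test, BH adjustment. `logMET` is `log2(mean normalized count + 0.5)`
#' (the published tables carry a signed transform whose definition is not
#' public; this analog of edgeR's logCPM is the documented definition here).
#' `logFC` is group2 minus group1 on the log2 scale; `response` is `"up"`
#' when the second manifest group has the higher normalized signal.
#'
#' @param mat A `methylation_matrix` (typically prefiltered).
#' @param alpha_fdr FDR threshold used for the `n_up`/`n_down` attribute.
#' @param scale Passed to [to_counts()].
#' @param prior_w Passed to [estimate_tagwise_dispersion()].
#' @return Data frame sorted by (`p_fdr`, `p_std`, `site_id`) with columns
#'   `site_id`, `logMET`, `logFC`, `p_std`, `p_fdr`, `response`; attributes
#'   `n_up`, `n_down` (significant at `alpha_fdr`), `common_dispersion`,
#'   `scale`.
#' @export
differential_table <- function(mat, alpha_fdr = 0.05, scale = NULL,
                               prior_w = 10) {
  cm <- to_counts(mat, scale)
  phi <- estimate_common_dispersion(cm)
  phi_i <- estimate_tagwise_dispersion(cm, phi, prior_w)
  g <- cm$groups
  ia <- which(g == levels(g)[1])
  ib <- which(g == levels(g)[2])
  ref <- exp(mean(log(cm$lib_sizes)))
  eq <- round(sweep(cm$counts, 2, ref / cm$lib_sizes, `*`))
  p <- vapply(seq_len(nrow(eq)), function(i) {
    exact_nb_test(eq[i, ia], eq[i, ib], phi = phi_i[i])
  }, 0)
  y <- normalize_counts(cm)
  ma <- rowMeans(y[, ia, drop = FALSE])
  mb <- rowMeans(y[, ib, drop = FALSE])
  out <- data.frame(site_id = rownames(cm$counts),
                    logMET = log2(rowMeans(y) + 0.5),
                    logFC = log2(mb + 0.5) - log2(ma + 0.5),
                    p_std = p, p_fdr = bh_adjust(p),
                    stringsAsFactors = FALSE)
  out$response <- ifelse(out$logFC >= 0, "up", "down")
  out <- out[order(out$p_fdr, out$p_std, out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  sig <- out$p_fdr < alpha_fdr
  attr(out, "n_up") <- sum(sig & out$response == "up")
  attr(out, "n_down") <- sum(sig & out$response == "down")
  attr(out, "common_dispersion") <- phi
  attr(out, "scale") <- cm$scale
  out
}

#' Write a differential table to TSV
#'
#' Column order matches the published report layout; a header comment
#' documents the direction convention.
#'
#' @param tab [differential_table()] output.
#' @param path Output path.
#' @param group2 Name of the second (comparison) group, for the header note.
#' @return `path`, invisibly.
#' @export
write_diff_tsv <- function(tab, path, group2 = "group2") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# response 'up' = higher methylation signal in second manifest group (%s)",
    group2), con)
  utils::write.table(format(tab, digits = 4, scientific = TRUE), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
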