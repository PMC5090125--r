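# independent enumeration oracle for the exact NB split test
oracle_exact_p <- function(a, b, na, nb, phi) {
  t <- a + b
  if (t == 0) return(1)
  pk <- numeric(t + 1)
  for (k in 0:t) {
    pk[k + 1] <- if (phi > 0) {
      dnbinom(k, size = na / phi, mu = t * na / (na + nb)) *
        dnbinom(t - k, size = nb / phi, mu = t * nb / (na + nb))
    } else {
      dbinom(k, t, na / (na + nb))
    }
  }
  sum(pk[pk <= pk[a + 1] * (1 + 1e-10)]) / sum(pk)
}

test_that("to_counts scales, records library sizes, and validates", {
  v <- rbind(c(60, 60), c(40, 20))
  mat <- toy_matrix(v, c("s1", "s2"), c("a", "b"))
  cm <- to_counts(mat, scale = 0.05)
  expect_equal(unname(cm$counts[1, ]), c(3L, 3L)) # pct 60 * 0.05
  expect_equal(unname(cm$lib_sizes), unname(colSums(cm$counts)))
  expect_error(to_counts(toy_matrix(v * 0, c("s1", "s2"), c("a", "b")),
                         scale = 0.05), "library size")
  expect_error(to_counts(toy_matrix(-v, c("s1", "s2"), c("a", "b"))),
               "nonnegative")
})

test_that("auto scale yields near-Poisson pseudo-counts per channel", {
  set.seed(4)
  n <- 400
  truep <- runif(n, 30, 90)
  v <- sapply(1:6, function(i) truep + rnorm(n, 0, sqrt(truep / 2)))
  mat <- toy_matrix(v - min(v) + 1, paste0("s", 1:6),
                    rep(c("a", "b"), each = 3))
  cm <- to_counts(mat)
  y <- msreprof:::normalize_counts(cm)
  idx <- mean(apply(y[, 1:3], 1, var) / rowMeans(y)) # dispersion index ~ 1
  expect_lt(abs(idx - 1), 0.2)
})

test_that("common dispersion: Poisson floor, NB recovery, identical columns", {
  set.seed(5)
  mkcm <- function(counts) {
    mat <- toy_matrix(counts, paste0("s", 1:6), rep(c("a", "b"), each = 3))
    to_counts(mat, scale = 1)
  }
  pois <- matrix(rpois(2000 * 6, 50), ncol = 6)
  expect_lt(estimate_common_dispersion(mkcm(pois)), 0.02)

  nb <- matrix(rnbinom(2000 * 6, mu = 50, size = 1 / 0.2), ncol = 6)
  phi_nb <- estimate_common_dispersion(mkcm(nb))
  expect_gt(phi_nb, 0.1)
  expect_lt(phi_nb, 0.3)

  same <- matrix(rep(rpois(500, 40), 6), ncol = 6)
  expect_equal(estimate_common_dispersion(mkcm(same)), 0)
  # fewer than 2 per group errors
  m1 <- toy_matrix(pois[1:10, 1:2, drop = FALSE], c("s1", "s2"), c("a", "b"))
  expect_error(estimate_common_dispersion(to_counts(m1, scale = 1)),
               "2 samples")
})

test_that("tagwise dispersion shrinkage limits", {
  set.seed(6)
  counts <- matrix(rnbinom(500 * 6, mu = 40, size = 10), ncol = 6)
  cm <- to_counts(toy_matrix(counts, paste0("s", 1:6),
                             rep(c("a", "b"), each = 3)), scale = 1)
  phi <- estimate_common_dispersion(cm)
  expect_equal(estimate_tagwise_dispersion(cm, phi, Inf),
               rep(max(phi, 1e-3), 500))
  raw <- msreprof:::tagwise_moment_estimates(cm)
  expect_equal(estimate_tagwise_dispersion(cm, phi, 0), pmax(raw, 1e-3))
  # median of shrunken values stays near the common value
  expect_lt(abs(median(estimate_tagwise_dispersion(cm, phi, 10)) - phi), 0.1)
  expect_error(estimate_tagwise_dispersion(cm, phi, -1), ">= 0")
})

test_that("exact NB test: modal split, symmetry, degenerate total", {
  expect_equal(exact_nb_test(c(5, 5, 5), c(5, 5, 5), phi = 0.1), 1)
  p1 <- exact_nb_test(c(9, 3, 2), c(1, 1, 0), phi = 0.2)
  p2 <- exact_nb_test(c(1, 1, 0), c(9, 3, 2), phi = 0.2)
  expect_equal(p1, p2)
  expect_equal(exact_nb_test(c(0, 0), c(0, 0), phi = 0.1), 1)
  # library equalization rescales to the geometric mean
  p3 <- exact_nb_test(c(10, 10), c(2, 2), lib_a = c(1000, 1000),
                      lib_b = c(200, 200), phi = 0)
  expect_equal(p3, 1) # equal rates after normalization -> modal split
})

test_that("exact NB test matches enumeration oracle over the grid", {
  for (phi in c(0, 0.1, 0.5)) {
    for (t in c(1, 2, 5, 10, 17, 30)) {
      for (a in unique(c(0, 1, floor(t / 3), t))) {
        got <- exact_nb_test(a, t - a, phi = phi)
        want <- oracle_exact_p(a, t - a, 1, 1, phi)
        expect_equal(got, want, tolerance = 1e-12)
        # unequal group sizes too
        got2 <- exact_nb_test(c(a, 0), t - a, phi = phi)
        want2 <- oracle_exact_p(a, t - a, 2, 1, phi)
        expect_equal(got2, want2, tolerance = 1e-12)
      }
    }
  }
  # a=0, b=10 against direct enumeration (spec example)
  expect_equal(exact_nb_test(0, 10, phi = 0), oracle_exact_p(0, 10, 1, 1, 0),
               tolerance = 1e-12)
})

test_that("bh_adjust is the BH step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(c(0.05, 0.05)), c(0.05, 0.05))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(7)
  for (i in 1:5) {
    p <- runif(sample(5:200, 1))
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"))
  }
  # order-preserving; re-adjustment can only increase (BH is a step-up
  # envelope, not an idempotent map — p.adjust agrees)
  p <- runif(100)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(bh_adjust(q) >= q - 1e-12))
  expect_equal(bh_adjust(q), p.adjust(q, method = "BH"))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
})

test_that("exact test p-values are honest under a simulated NB null", {
  set.seed(12)
  n <- 2000
  phi_true <- 0.05
  counts <- matrix(rnbinom(n * 6, mu = 60, size = 1 / phi_true), ncol = 6)
  cm <- to_counts(toy_matrix(counts, paste0("s", 1:6),
                             rep(c("a", "b"), each = 3)), scale = 1)
  phi <- estimate_common_dispersion(cm)
  phi_i <- estimate_tagwise_dispersion(cm, phi, 10)
  p <- vapply(seq_len(n), function(i)
    exact_nb_test(counts[i, 1:3], counts[i, 4:6], phi = phi_i[i]), 0)
  expect_lt(max(abs(sort(p) - ppoints(n, a = 0))), 0.06) # near-uniform
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.08)
})

test_that("differential_table runs the chain deterministically", {
  co <- small_cohort()
  mat <- co$matrix
  dt1 <- differential_table(mat)
  dt2 <- differential_table(mat)
  expect_identical(dt1, dt2)
  expect_equal(colnames(dt1),
               c("site_id", "logMET", "logFC", "p_std", "p_fdr", "response"))
  expect_true(all(dt1$p_fdr >= dt1$p_std - 1e-12))
  expect_true(all(diff(dt1$p_fdr) >= -1e-12)) # sorted by adjusted p
  expect_true(all(dt1$response[dt1$logFC > 0] == "up"))
  expect_true(all(dt1$response[dt1$logFC < 0] == "down"))

  # planted sites are enriched among discoveries even in the small cohort
  called <- dt1$site_id[dt1$p_fdr < 0.05]
  planted_m <- co$truth$site_id[co$truth$is_diff]
  expect_gt(mean(planted_m %in% called), 0.5)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_diff_tsv(dt1, path, group2 = "case")
  expect_match(readLines(path, n = 1), "second manifest group")
})
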