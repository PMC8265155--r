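test_that("the Welch test matches stats::t.test on random instances", {
  set.seed(21)
  for (i in 1:20) {
    a <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2), sd = runif(1, 0.1, 2))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2), sd = runif(1, 0.1, 2))
    ours <- multisep:::welch_test(a, b)
    ref <- t.test(b, a, var.equal = FALSE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-8)
  }
})

test_that("near-identical groups give a null result", {
  fit <- two_cluster_fit(10, 10)
  set.seed(5)
  # both clusters carry the same jittered score profile: no effect to find
  jitter <- rnorm(10, 0, 1e-6)
  scores <- setNames(numeric(20), names(fit$assignments))
  scores[fit$assignments == 1] <- -0.5 + jitter
  scores[fit$assignments == 2] <- -0.5 + jitter
  res <- test_pair(fit, scores, crispr_gene = "GB")
  expect_lt(abs(res$effect), 1e-3)
  expect_gt(res$p, 0.9)
})

test_that("a planted essentiality shift is detected with the right sign", {
  fit <- two_cluster_fit(10, 10)
  set.seed(6)
  # knockout damaging (CERES ~ -1) in the low-expression cluster only
  scores <- setNames(c(rnorm(10, -1, 0.05), rnorm(10, 0, 0.05)),
                     names(fit$assignments))
  res <- test_pair(fit, scores, crispr_gene = "GB")
  expect_equal(res$effect, 1, tolerance = 0.1)
  expect_lt(res$p, 1e-10)
  expect_identical(c(res$cluster_lo, res$cluster_hi), c(1L, 2L))
  # Welch oracle from first principles on the same groups
  lo <- scores[fit$assignments == 1]; hi <- scores[fit$assignments == 2]
  se2 <- var(lo) / 10 + var(hi) / 10
  tstat <- (mean(hi) - mean(lo)) / sqrt(se2)
  df <- se2^2 / ((var(lo) / 10)^2 / 9 + (var(hi) / 10)^2 / 9)
  expect_equal(res$p, 2 * pt(-abs(tstat), df), tolerance = 1e-12)
})

test_that("with three clusters the best adjacent comparison is reported", {
  set.seed(9)
  x <- c(rnorm(30, 0, 0.05), rnorm(30, 5, 0.05), rnorm(30, 10, 0.05))
  names(x) <- sprintf("L%03d", seq_along(x))
  fit <- fit_gene_mixture(x, k_min = 3, k_max = 3, seed = 2, gene = "GA")
  # only the (2,3) neighbours differ in CRISPR score
  scores <- setNames(c(rnorm(30, 0, 0.05), rnorm(30, 0, 0.05), rnorm(30, -1, 0.05)),
                     names(x))
  res <- test_pair(fit, scores, crispr_gene = "GB")
  expect_identical(res$cluster_lo, 2L)
  expect_identical(res$cluster_hi, 3L)
  # brute force: recompute every adjacent comparison and confirm minimal p
  ps <- vapply(1:2, function(i) {
    t.test(scores[fit$assignments == i + 1], scores[fit$assignments == i])$p.value
  }, numeric(1))
  expect_equal(res$p, min(ps), tolerance = 1e-9)
  # the extreme (first vs last) comparison is retained alongside
  expect_true("extreme" %in% res$comparisons$type)
})

test_that("reversing group order flips the effect sign, not the p-value", {
  set.seed(31)
  a <- rnorm(12, 0, 0.3); b <- rnorm(15, 0.8, 0.5)
  fwd <- multisep:::welch_test(a, b)
  rev <- multisep:::welch_test(b, a)
  expect_equal(fwd$p, rev$p, tolerance = 1e-12)
  expect_equal(fwd$statistic, -rev$statistic, tolerance = 1e-12)
})

test_that("clusters below the minimum group size are skipped or not testable", {
  fit <- two_cluster_fit(2, 18)
  scores <- setNames(rnorm(20), names(fit$assignments))
  expect_error(test_pair(fit, scores, crispr_gene = "GB"),
               class = "not_testable_error")
  res <- test_pair(fit, scores, min_group = 2, crispr_gene = "GB")
  expect_identical(res$n_lo, 2L)
})

test_that("BH q-values match the hand step-up formula", {
  expect_equal(compute_qvalues(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(compute_qvalues(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04), tolerance = 1e-12)
  set.seed(41)
  p <- runif(50)^2
  q <- compute_qvalues(p)
  # independent step-up computation
  o <- order(p)
  hand <- numeric(50)
  hand[o] <- rev(cummin(rev(50 * p[o] / seq_len(50))))
  expect_equal(q, pmin(hand, 1), tolerance = 1e-12)
  # order equivariance
  perm <- sample(50)
  expect_equal(compute_qvalues(p[perm]), q[perm], tolerance = 1e-12)
  expect_error(compute_qvalues(c(0.5, 1.2)), class = "value_error")
})

test_that("Storey q-values shrink toward pi0 and stay valid", {
  set.seed(43)
  p <- c(runif(300)^3, runif(700))  # enriched small p-values, pi0 ~ 0.7
  q_bh <- compute_qvalues(p, "bh")
  q_st <- compute_qvalues(p, "storey")
  expect_true(all(q_st >= 0 & q_st <= 1))
  expect_true(all(q_st <= q_bh + 1e-12))  # pi0 <= 1
  expect_gt(cor(q_st, q_bh), 0.99)
  # small inputs fall back to the conservative pi0 = 1 (BH-equivalent)
  expect_equal(compute_qvalues(c(0.01, 0.5), "storey"),
               compute_qvalues(c(0.01, 0.5), "bh"), tolerance = 1e-12)
})

test_that("the genome-wide scan applies the inclusion thresholds", {
  sim <- small_sim()
  fits <- small_fits()
  res <- scan_crispr(sim$dataset, fits = fits, seed = 501)
  expect_true(all(abs(res$log2FC) > 0.1))
  expect_true(all(res$p_value < 0.1))
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  expect_false(is.unsorted(res$q_value))
  # filter dominance: infinite effect threshold empties the table
  none <- scan_crispr(sim$dataset, fits = fits, effect_min = Inf, seed = 501)
  expect_identical(nrow(none), 0L)
  # q-values are computed over all tested pairs, before filtering
  full <- scan_crispr(sim$dataset, fits = fits, filtered = FALSE, seed = 501)
  expect_identical(attr(res, "n_tested"), nrow(full))
  key <- paste(res$mRNA_gene, res$crispr_gene)
  expect_equal(res$q_value,
               full$q_value[match(key, paste(full$mRNA_gene, full$crispr_gene))],
               tolerance = 1e-12)
})

test_that("scans fail cleanly without CRISPR data or enough tissue lines", {
  sim <- small_sim()
  d <- sim$dataset
  d_nocr <- d; d_nocr$crispr <- NULL
  expect_error(scan_crispr(d_nocr), class = "config_error")
  d2 <- d
  d2$tissues[] <- "big"
  d2$tissues[1:2] <- "tiny"
  expect_error(scan_crispr(d2, tissue = "tiny"),
               class = "tissue_too_small_error")
})
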