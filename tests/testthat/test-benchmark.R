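toy_db <- function() {
  data.frame(gene_a = c("A", "C"), gene_b = c("B", "D"),
             score = c(0.8, 0.6), stringsAsFactors = FALSE)
}

named_scores <- function(pairs_df, values) {
  setNames(values, score_key(pairs_df$gene_a, pairs_df$gene_b))
}

test_that("gold standards apply the confidence threshold and stay balanced", {
  preds <- c(setNames(c(3, 2), c(score_key("A", "B"), score_key("C", "D"))),
             setNames(runif(20), score_key(paste0("X", 1:20), paste0("Y", 1:20))))
  gold <- build_gold_standard(toy_db(), 0.7, preds, seed = 5)
  pos <- gold$pairs[gold$pairs$label == "positive", ]
  expect_identical(nrow(pos), 1L)
  expect_identical(score_key(pos$gene_a, pos$gene_b), score_key("A", "B"))
  expect_identical(sum(gold$pairs$label == "negative"), 1L)
  # negatives never come from the database at any score
  neg_keys <- score_key(gold$pairs$gene_a[gold$pairs$label == "negative"],
                        gold$pairs$gene_b[gold$pairs$label == "negative"])
  expect_false(any(neg_keys %in% score_key(toy_db()$gene_a, toy_db()$gene_b)))
  # same seed, same resample; different seed may differ
  gold2 <- build_gold_standard(toy_db(), 0.7, preds, seed = 5)
  expect_identical(gold$pairs, gold2$pairs)
  expect_error(build_gold_standard(toy_db(), 0.99, preds),
               class = "empty_gold_standard_error")
})

test_that("AROC is the Mann-Whitney concordance probability", {
  pairs <- data.frame(gene_a = paste0("a", 1:6), gene_b = paste0("b", 1:6),
                      stringsAsFactors = FALSE)
  gold <- structure(list(
    pairs = cbind(pairs, label = c("positive", "positive", "positive",
                                   "negative", "negative", "negative")),
    positive_threshold = 0.7, negative_source = "resampled", seed = 1L,
    balance = 1), class = "gold_standard")
  # perfect separation
  s_perfect <- named_scores(pairs, c(5, 4, 3, 2, 1, 0))
  expect_equal(compute_roc(s_perfect, gold)$auroc, 1)
  # hand-chosen scores with one tie, checked by exhaustive pair enumeration
  s_tie <- named_scores(pairs, c(3, 2, 1, 2, 0.5, 0))
  res <- compute_roc(s_tie, gold)
  pos <- c(3, 2, 1); neg <- c(2, 0.5, 0)
  conc <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_equal(res$auroc, conc, tolerance = 1e-12)
  expect_false(is.unsorted(res$roc_points$tpr))
  expect_false(is.unsorted(res$roc_points$fpr))
  expect_error(compute_roc(s_tie[-1], gold), "missing scores",
               class = "value_error")
})

test_that("AROC equals the exhaustive concordant-pair fraction on random instances", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(10:100, 1)
    lab <- sample(c(rep(TRUE, ceiling(n / 3)), rep(FALSE, n - ceiling(n / 3))))
    s <- round(rnorm(n), sample(0:1, 1))  # rounding forces ties
    auc <- multisep:::auroc_mw(s, lab)
    brute <- mean(outer(s[lab], s[!lab], ">") + 0.5 * outer(s[lab], s[!lab], "=="))
    expect_equal(auc, brute, tolerance = 1e-10)
  }
})

test_that("label-independent scores give chance-level AROC", {
  set.seed(59)
  n <- 2000
  pairs <- data.frame(gene_a = paste0("a", 1:n), gene_b = paste0("b", 1:n),
                      stringsAsFactors = FALSE)
  gold <- structure(list(
    pairs = cbind(pairs, label = sample(rep(c("positive", "negative"), n / 2))),
    positive_threshold = 0.7, negative_source = "resampled", seed = 1L,
    balance = 1), class = "gold_standard")
  s <- named_scores(pairs, rnorm(n))
  expect_equal(compute_roc(s, gold)$auroc, 0.5, tolerance = 0.05)
})

test_that("the paired DeLong test behaves at its boundary cases", {
  set.seed(63)
  n <- 200
  pairs <- data.frame(gene_a = paste0("a", 1:n), gene_b = paste0("b", 1:n),
                      stringsAsFactors = FALSE)
  lab <- sample(rep(c("positive", "negative"), n / 2))
  gold <- structure(list(pairs = cbind(pairs, label = lab),
                         positive_threshold = 0.7,
                         negative_source = "resampled", seed = 1L,
                         balance = 1), class = "gold_standard")
  s_a <- named_scores(pairs, rnorm(n))
  # identical score sets: zero difference, p = 1
  same <- compare_aurocs(s_a, s_a, gold)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  # a perfect separator against label-independent noise
  s_perfect <- named_scores(pairs, (lab == "positive") + rnorm(n, 0, 1e-3))
  cmp <- compare_aurocs(s_perfect, s_a, gold)
  expect_lt(cmp$p, 0.01)
  expect_gt(cmp$delta, 0.3)
})

test_that("DeLong agrees with an independent implementation and the bootstrap", {
  set.seed(67)
  n <- 150
  pairs <- data.frame(gene_a = paste0("a", 1:n), gene_b = paste0("b", 1:n),
                      stringsAsFactors = FALSE)
  lab <- sample(rep(c("positive", "negative"), n / 2))
  gold <- structure(list(pairs = cbind(pairs, label = lab),
                         positive_threshold = 0.7,
                         negative_source = "resampled", seed = 1L,
                         balance = 1), class = "gold_standard")
  y <- as.integer(lab == "positive")
  for (i in 1:5) {
    s_a <- named_scores(pairs, y * runif(1, 0.5, 1.5) + rnorm(n))
    s_b <- named_scores(pairs, y * runif(1, 0, 0.5) + rnorm(n))
    ours <- compare_aurocs(s_a, s_b, gold)
    ref <- pROC::roc.test(pROC::roc(y, unname(s_a), quiet = TRUE, direction = "<"),
                          pROC::roc(y, unname(s_b), quiet = TRUE, direction = "<"),
                          method = "delong", paired = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
    expect_equal(ours$auroc_a, as.numeric(ref$estimate[1]), tolerance = 1e-10)
  }
  # mid-effect fixture: bootstrap cross-check within 0.02
  s_a <- named_scores(pairs, y * 0.8 + rnorm(n))
  s_b <- named_scores(pairs, rnorm(n))
  p_dl <- compare_aurocs(s_a, s_b, gold)$p
  p_bs <- compare_aurocs(s_a, s_b, gold, method = "bootstrap",
                         n_boot = 2000, seed = 3)$p
  expect_lt(abs(p_dl - p_bs), 0.02)
})

test_that("FDR estimation respects prevalence and degenerates sensibly", {
  n <- 400
  pairs <- data.frame(gene_a = paste0("a", 1:n), gene_b = paste0("b", 1:n),
                      stringsAsFactors = FALSE)
  lab <- rep(c("positive", "negative"), n / 2)
  gold <- structure(list(pairs = cbind(pairs, label = lab),
                         positive_threshold = 0.7,
                         negative_source = "resampled", seed = 1L,
                         balance = 1), class = "gold_standard")
  y <- lab == "positive"
  # only true positives above the threshold
  s_clean <- named_scores(pairs, ifelse(y, 10, 0))
  expect_equal(estimate_fdr(s_clean, gold, score_threshold = 5), 0)
  # label-independent scores at the real-world prevalence
  set.seed(71)
  s_null <- named_scores(pairs, rnorm(n))
  fdr <- estimate_fdr(s_null, gold, score_threshold = 0, prevalence = 0.0375)
  expect_equal(fdr, 0.9625, tolerance = 0.02)
  # resampling route agrees with reweighting
  fdr_rs <- estimate_fdr(s_null, gold, score_threshold = 0,
                         prevalence = 0.0375, method = "resample",
                         n_resample = 50000, seed = 11)
  expect_equal(fdr_rs, fdr, tolerance = 0.02)
  expect_warning(out <- estimate_fdr(s_null, gold, score_threshold = 99),
                 "undefined")
  expect_true(is.na(out))
  expect_error(estimate_fdr(s_null, gold, 0, prevalence = 1.5),
               class = "value_error")
})
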