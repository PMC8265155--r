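# matrices with a prescribed number of copy-number-loss, low-expression lines
daisy_toy <- function(n = 100, n_loss = 10, seed = 61) {
  set.seed(seed)
  lines <- sprintf("L%03d", 1:n)
  expr <- matrix(rnorm(n * 2, 6, 1), n, 2, dimnames = list(lines, c("A", "B")))
  cn <- matrix(rnorm(n * 2, 0, 0.05), n, 2, dimnames = list(lines, c("A", "B")))
  if (n_loss > 0) {
    idx <- order(expr[, "A"])[seq_len(n_loss)]
    cn[idx, "A"] <- -1
    expr[idx, "A"] <- min(expr[, "A"]) - rev(seq_len(n_loss)) * 0.01
  }
  list(expr = expr, cn = cn,
       loss_lines = if (n_loss > 0) lines[order(expr[, "A"])[seq_len(n_loss)]]
       else character())
}

test_that("the inactivity mask needs copy-number loss in at least 2 lines", {
  toy <- daisy_toy(n_loss = 10)
  mask <- daisy_inactive_mask("A", toy$cn, toy$expr)
  expect_identical(sort(names(mask)[mask]), sort(toy$loss_lines))
  expect_error(daisy_inactive_mask("A", daisy_toy(n_loss = 1)$cn,
                                   daisy_toy(n_loss = 1)$expr),
               "at least|need >= 2|1 cell line", class = "not_predictable_error")
  expect_error(daisy_inactive_mask("A", daisy_toy(n_loss = 0)$cn,
                                   daisy_toy(n_loss = 0)$expr),
               class = "not_predictable_error")
})

test_that("self-pairs and degenerate partners are rejected", {
  sim <- small_sim()
  d <- sim$dataset
  g <- colnames(d$expression)[1]
  expect_error(daisy_pair_score(g, g, d), class = "not_predictable_error")
  expect_error(bisep_surrogate_score(g, g, d), class = "not_predictable_error")
})

test_that("DAISY component p-values match enumeration oracles on tiny inputs", {
  # rank-sum: exact p by enumerating all group assignments
  set.seed(71)
  a <- rnorm(4); b <- rnorm(4)
  w <- wilcox.test(a, b, alternative = "greater", exact = TRUE)
  pooled <- c(a, b)
  combs <- combn(8, 4)
  u_obs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_all <- apply(combs, 2, function(idx) {
    sum(outer(pooled[idx], pooled[-idx], ">"))
  })
  expect_equal(w$p.value, mean(u_all >= u_obs), tolerance = 1e-8)
  # Spearman: exact p by enumerating permutations at n = 5
  x <- c(1.2, 0.3, 2.5, 1.9, 0.1); y <- c(0.4, 0.2, 1.1, 2.0, 0.3)
  ct <- cor.test(x, y, method = "spearman", exact = TRUE)
  perms <- asplit(all_perms(5), 1)
  rho_obs <- cor(rank(x), rank(y))
  rho_all <- vapply(perms, function(p) cor(rank(x), rank(y[p])), numeric(1))
  p_exact <- mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
  expect_equal(ct$p.value, p_exact, tolerance = 1e-8)
})

test_that("a null partner scores low, a planted SoF pattern scores high", {
  set.seed(81)
  n <- 200
  lines <- sprintf("L%03d", 1:n)
  n_genes <- 120
  genes <- c("A", sprintf("N%03d", seq_len(n_genes - 1)))
  expr <- matrix(rnorm(n * n_genes, 6, 1), n, n_genes,
                 dimnames = list(lines, genes))
  cn <- matrix(rnorm(n * n_genes, 0, 0.05), n, n_genes,
               dimnames = list(lines, genes))
  # gene A lost + lowly expressed in 20 lines
  lost <- order(expr[, "A"])[1:20]
  cn[lost, "A"] <- -1
  # planted partner: amplified where A is lost, plus coexpression with A
  expr <- cbind(expr,
                P = 0.5 * scale(expr[, "A"])[, 1] + rnorm(n, 0, sqrt(0.75)))
  expr[lost, "P"] <- expr[lost, "P"] + 1.5
  cn <- cbind(cn, P = rnorm(n, 0, 0.05))
  d <- structure(list(expression = expr, crispr = NULL, mutations = NULL,
                      tissues = setNames(rep("all", n), lines),
                      annotations = NULL, protein = NULL, copy_number = cn,
                      cell_lines = lines, alignment = list()),
                 class = "multisep_dataset")
  planted <- daisy_pair_score("A", "P", d)
  null_scores <- vapply(sprintf("N%03d", 1:100), function(g) {
    daisy_pair_score("A", g, d)$score
  }, numeric(1))
  expect_lt(median(null_scores), 1)
  # planted pair outranks every null pair (top 1%)
  expect_gt(planted$score, max(null_scores))
  expect_lt(planted$components$sof_p, 0.05)
})

test_that("the bimodality gate passes multimodal genes and rejects unimodal ones", {
  sim <- small_sim()
  d <- sim$dataset
  tr <- sim$truth
  uni <- names(tr$planted_k)[tr$planted_k == 1]
  multi <- names(tr$planted_k)[tr$planted_k == 2]
  partner <- colnames(d$crispr)[1]
  expect_error(
    bisep_surrogate_score(uni[1], setdiff(colnames(d$crispr), uni[1])[1], d),
    class = "not_predictable_error")
  a <- setdiff(multi, partner)[1]
  sc <- bisep_surrogate_score(a, partner, d)
  expect_true(is.finite(sc$score))
  expect_gte(sc$components$bic_1 - sc$components$bic_2, 10)
})

test_that("a planted CRISPR shift yields a two-group fold-change near its size", {
  set.seed(91)
  n <- 120
  lines <- sprintf("L%03d", 1:n)
  expr <- cbind(A = c(rnorm(60, 2, 0.4), rnorm(60, 8, 0.4)),
                B = rnorm(n, 5, 1))
  rownames(expr) <- lines
  crispr <- cbind(A = rnorm(n, 0, 0.2),
                  B = c(rnorm(60, -1, 0.2), rnorm(60, 0, 0.2)))
  rownames(crispr) <- lines
  d <- structure(list(expression = expr, crispr = crispr, mutations = NULL,
                      tissues = setNames(rep("all", n), lines),
                      annotations = NULL, protein = NULL, copy_number = NULL,
                      cell_lines = lines, alignment = list()),
                 class = "multisep_dataset")
  sc <- bisep_surrogate_score("A", "B", d)
  expect_equal(sc$score, 1, tolerance = 0.15)
  # two-group mean-difference oracle on the true split
  oracle <- mean(crispr[61:120, "B"]) - mean(crispr[1:60, "B"])
  expect_equal(sc$score, oracle, tolerance = 0.05)
})

test_that("null partners of a bimodal gene give small fold-changes", {
  set.seed(95)
  n <- 150
  lines <- sprintf("L%03d", 1:n)
  expr <- cbind(A = c(rnorm(75, 2, 0.4), rnorm(75, 8, 0.4)))
  rownames(expr) <- lines
  crispr <- matrix(rnorm(n * 100, 0, 0.2), n, 100,
                   dimnames = list(lines, sprintf("N%03d", 1:100)))
  d <- structure(list(expression = expr, crispr = crispr, mutations = NULL,
                      tissues = setNames(rep("all", n), lines),
                      annotations = NULL, protein = NULL, copy_number = NULL,
                      cell_lines = lines, alignment = list()),
                 class = "multisep_dataset")
  scores <- vapply(colnames(crispr), function(g) {
    bisep_surrogate_score("A", g, d)$score
  }, numeric(1))
  expect_lt(median(abs(scores)), 0.1)
})

test_that("baseline batch scoring skips unpredictable pairs rather than zeroing", {
  sim <- small_sim()
  d <- sim$dataset
  genes <- colnames(d$expression)
  pairs <- data.frame(gene_a = genes[1:10], gene_b = genes[11:20],
                      stringsAsFactors = FALSE)
  res <- score_baseline_pairs(pairs, d, method = "daisy")
  expect_identical(nrow(res) + attr(res, "n_unpredictable"), nrow(pairs))
  if (nrow(res) > 0) expect_true(all(is.finite(res$score)))
})
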