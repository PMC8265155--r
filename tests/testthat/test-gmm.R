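test_that("a well-separated bimodal gene recovers two components", {
  set.seed(42)
  x <- c(rnorm(100, 0, 1), rnorm(100, 10, 1))
  names(x) <- sprintf("L%03d", seq_along(x))
  truth <- rep(1:2, each = 100)
  fit <- fit_gene_mixture(x, seed = 1)
  expect_identical(fit$k, 2L)
  expect_lt(abs(fit$means[1] - 0), 0.5)
  expect_lt(abs(fit$means[2] - 10), 0.5)
  expect_lte(sum(fit$assignments != truth), 2L)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  # independent mixture-model implementation agrees on the selection and the
  # per-k BIC values (sign convention differs: mclust maximizes)
  mb <- mclust::mclustBIC(unname(x), G = 2:5, modelNames = "V", verbose = FALSE)
  expect_identical(fit$k, (2:5)[which.max(mb[, "V"])])
  expect_equal(unname(fit$bic_by_k["2"]), -as.numeric(mb["2", "V"]),
               tolerance = 1e-4)
})

test_that("BIC equals -2 logLik + p log n for the returned parameters", {
  set.seed(3)
  x <- c(rnorm(5, 0, 0.3), rnorm(5, 4, 0.3))
  fit <- fit_gene_mixture(x, k_min = 2, k_max = 2, seed = 9)
  # independent closed-form recomputation from the reported parameters
  ll <- sum(log(rowSums(vapply(1:2, function(j) {
    fit$weights[j] * dnorm(fit$data, fit$means[j], sqrt(fit$variances[j]))
  }, numeric(length(fit$data))))))
  expect_equal(unname(fit$bic_by_k["2"]), -2 * ll + 5 * log(10),
               tolerance = 1e-6)
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
})

test_that("unimodal data still yields between 2 and 5 clusters", {
  set.seed(11)
  x <- rnorm(200, 5, 1)
  fit <- fit_gene_mixture(x, seed = 4)
  expect_gte(fit$k, 2L)
  expect_lte(fit$k, 5L)
})

test_that("degenerate and undersized inputs raise typed errors", {
  expect_error(fit_gene_mixture(rep(3.7, 50), seed = 1),
               class = "degenerate_gene_error")
  expect_error(fit_gene_mixture(c(1, 2, 3, 4, 5), seed = 1),
               class = "insufficient_data_error")
  expect_error(fit_gene_mixture(c(rnorm(3), rep(NA, 20)), seed = 1),
               class = "insufficient_data_error")
})

test_that("means are ascending and a constant shift moves means, not labels", {
  set.seed(8)
  for (rep_i in 1:5) {
    x <- c(rnorm(60, 2, 0.5), rnorm(60, 6, 0.5), rnorm(40, 12, 0.5))
    fit <- fit_gene_mixture(x, seed = rep_i)
    expect_true(all(diff(fit$means) > 0))
    shifted <- fit_gene_mixture(x + 100, seed = rep_i)
    expect_identical(shifted$k, fit$k)
    expect_equal(shifted$means, fit$means + 100, tolerance = 1e-6)
    expect_identical(unname(shifted$assignments), unname(fit$assignments))
  }
})

test_that("identical seeds give bit-identical fits", {
  set.seed(12)
  x <- c(rnorm(80, 1), rnorm(80, 6))
  f1 <- fit_gene_mixture(x, seed = 77)
  f2 <- fit_gene_mixture(x, seed = 77)
  expect_identical(f1, f2)
  f3 <- fit_gene_mixture(x, seed = 78)
  expect_false(identical(f1$loglik, f3$loglik))
})

test_that("cluster_all_genes fits every gene and reports failures", {
  sim <- small_sim()
  fits <- small_fits()
  expect_identical(length(fits), ncol(sim$dataset$expression))
  ks <- vapply(fits, function(f) f$k, integer(1))
  expect_true(all(ks >= 2 & ks <= 5))
  expect_identical(nrow(attr(fits, "failures")), 0L)
  # a constant gene is skipped with a reason, not fatal
  expr <- sim$dataset$expression
  expr <- cbind(expr, CONST = rep(1, nrow(expr)))
  fits2 <- cluster_all_genes(expr[, c("G001", "CONST")], seed = 1)
  expect_identical(names(fits2), "G001")
  expect_identical(attr(fits2, "failures")$gene, "CONST")
})

test_that("tissue-restricted clustering uses exactly that tissue's lines", {
  sim <- small_sim()
  d <- sim$dataset
  tiss <- names(sort(table(d$tissues), decreasing = TRUE))[1]
  n_tiss <- sum(d$tissues == tiss)
  fits <- cluster_all_genes(d$expression[, 1:3], tissues = d$tissues,
                            tissue_subset = tiss, seed = 2)
  for (f in fits) expect_identical(f$n_cells, n_tiss)
  expect_true(all(names(fits[[1]]$assignments) %in%
                    names(d$tissues)[d$tissues == tiss]))
  expect_error(
    cluster_all_genes(d$expression, tissues = d$tissues,
                      tissue_subset = tiss, min_lines = n_tiss + 1L),
    tiss, class = "tissue_too_small_error")
})

test_that("cluster tables export and read back losslessly", {
  fits <- small_fits()
  tab <- cluster_table(fits)
  expect_named(tab, c("gene", "cell_line", "cluster", "k", "cluster_mean"))
  expect_identical(nrow(tab),
                   sum(vapply(fits, function(f) length(f$assignments), integer(1))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_table(tab, path)
  back <- read_cluster_table(path)
  expect_equal(back$cluster, tab$cluster)
  expect_equal(back$cluster_mean, tab$cluster_mean, tolerance = 1e-9)
})

test_that("fit methods expose the usual modelling verbs", {
  fit <- two_cluster_fit()
  expect_identical(coef(fit)$means, fit$means)
  expect_s3_class(summary(fit), "summary.multisep_fit")
  expect_identical(attr(logLik(fit), "df"), 5)
  expect_identical(unname(predict(fit)), unname(fit$assignments))
  expect_identical(unname(predict(fit, newdata = c(-1, 11))), c(1L, 2L))
  post <- predict(fit, type = "posterior")
  expect_equal(unname(rowSums(post)), rep(1, fit$n_cells), tolerance = 1e-9)
  expect_equal(unname(fitted(fit) + residuals(fit)), unname(fit$data))
  draws <- simulate(fit, nsim = 50, seed = 2)
  expect_length(draws, 50)
  expect_identical(simulate(fit, nsim = 50, seed = 2), draws)
  expect_output(print(fit), "k = 2")
})
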