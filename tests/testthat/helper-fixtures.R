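# Shared fixtures, computed lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small planted-dependency panel for module tests
small_sim <- function() cached("small_sim", {
  generate_dataset(n_lines = 120L, n_genes = 30L, n_tissues = 6L,
                   n_crispr_pairs = 3L, n_mutation_pairs = 3L, seed = 501L)
})

small_fits <- function() cached("small_fits", {
  sim <- small_sim()
  cluster_all_genes(sim$dataset$expression, seed = 501L)
})

# default-scale study fixture used by the acceptance checks
default_sim <- function() cached("default_sim", generate_preset("default", seed = 2024L))

default_fits <- function() cached("default_fits", {
  cluster_all_genes(default_sim()$dataset$expression, seed = 2024L)
})

# a two-cluster mixture fit with exactly prescribed group sizes, built from
# near-separated expression values (used to exercise the dependency tests
# with known cluster memberships)
two_cluster_fit <- function(n1 = 10L, n2 = 10L, gene = "GX", seed = 7L) {
  set.seed(seed)
  x <- c(stats::rnorm(n1, 0, 0.05), stats::rnorm(n2, 10, 0.05))
  names(x) <- sprintf("L%03d", seq_along(x))
  fit <- fit_gene_mixture(x, k_min = 2L, k_max = 2L, seed = seed, gene = gene)
  stopifnot(identical(unname(tabulate(fit$assignments, 2L)),
                      as.integer(c(n1, n2))))
  fit
}

expect_no_rows_lost <- function(annotated, original) {
  expect_identical(nrow(annotated), nrow(original))
}

# all permutations of 1..n (n! x n matrix), for tiny enumeration oracles
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}
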