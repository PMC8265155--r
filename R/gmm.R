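# Per-gene univariate Gaussian mixture fitting by EM with BIC selection of
# the component count over 2..5. This is the partitioning engine every
# downstream dependency test builds on: clusters are relabelled so cluster 1
# always carries the lowest mean expression, making "low-expression cluster"
# well defined across genes.

log_row_sum_exp <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx + log(rowSums(exp(m - mx)))
}

# Component log-densities (n x k): log w_j + log N(x | mu_j, sigma2_j),
# computed as one matrix expression for speed in the EM inner loop.
log_component_density <- function(x, mu, sigma2, w) {
  dev2 <- outer(x, mu, "-")^2
  sweep(dev2, 2L, -2 * sigma2, "/") +
    rep(log(w) - 0.5 * log(2 * pi * sigma2), each = length(x))
}

mixture_loglik <- function(x, mu, sigma2, w) {
  sum(log_row_sum_exp(log_component_density(x, mu, sigma2, w)))
}

#' Fit a per-gene Gaussian mixture over cell-line expression
#'
#' Fits univariate heteroscedastic Gaussian mixtures by
#' expectation-maximization for each component count `k` in
#' `k_min:k_max` and keeps the fit minimizing the Bayesian Information
#' Criterion, `BIC = -2 logLik + p log(n)` with `p = 3k - 1` free parameters
#' (lower is better; ties go to the smaller `k`). Unimodal models (`k = 1`)
#' are never evaluated: a single cluster cannot support the downstream
#' partition-based dependency tests. Components are relabelled in ascending
#' mean order (ties broken by decreasing weight, then original index), so
#' cluster 1 is always the low-expression cluster. Cell lines receive hard
#' maximum-posterior assignments, posterior ties resolving to the lower-mean
#' cluster.
#'
#' Each `k` is fitted from `restarts` k-means++ seedings and the best final
#' log-likelihood is kept, protecting BIC comparability across `k`.
#' Component variances are floored at `1e-4` times the total variance to
#' prevent singular components. Non-finite values are excluded before
#' fitting.
#'
#' @param values Numeric vector of expression values for one gene across cell
#'   lines, ideally named by cell line.
#' @param k_min,k_max Range of component counts evaluated (defaults 2 and 5).
#' @param seed Integer seed; identical seeds give bit-identical fits.
#' @param restarts EM restarts per component count.
#' @param gene Gene symbol recorded in the fit.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per restart.
#' @return An object of class `multisep_fit` with elements `gene`, `k`,
#'   `means`, `variances`, `weights` (summing to 1), `assignments` (named
#'   integer vector over cell lines with finite values), `posterior`,
#'   `bic_by_k`, `loglik_by_k`, `loglik`, `n_cells`, `seed`.
#' @examples
#' x <- c(rnorm(60, 2, 0.5), rnorm(60, 8, 0.5))
#' fit <- fit_gene_mixture(x, seed = 1)
#' fit$k
#' coef(fit)
#' @export
fit_gene_mixture <- function(values, k_min = 2L, k_max = 5L, seed = 1L,
                             restarts = 10L, gene = NA_character_,
                             tol = 1e-8, max_iter = 500L) {
  if (is.null(names(values))) {
    names(values) <- paste0("cell", seq_along(values))
  }
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < k_max + 1L) {
    stop_insufficient(sprintf(
      "gene %s: %d finite values, need at least %d", gene, n, k_max + 1L))
  }
  vx <- stats::var(x)
  if (!is.finite(vx) || vx < 1e-10) {
    stop_degenerate(sprintf(
      "gene %s: expression variance %.3g below tolerance (constant input?)", gene, vx))
  }
  var_floor <- 1e-4 * vx
  ks <- seq.int(k_min, k_max)
  fits <- vector("list", length(ks))
  bic <- loglik <- stats::setNames(rep(NA_real_, length(ks)), ks)
  with_seed(seed, {
    for (i in seq_along(ks)) {
      k <- ks[i]
      # pre-drawn uniforms feed the k-means++ seeding of each restart; EM
      # itself is deterministic given the seeding
      u <- matrix(stats::runif(restarts * k), nrow = restarts)
      f <- .gmm_em_best(unname(x), k, u, vx, var_floor, tol, max_iter)
      fits[[i]] <- f
      loglik[i] <- f$loglik
      bic[i] <- -2 * f$loglik + (3 * k - 1) * log(n)
    }
  })
  sel <- which.min(bic)  # ties resolve to the smallest k (ascending order)
  k <- ks[sel]
  f <- fits[[sel]]
  ord <- order(f$mu, -f$w, seq_len(k))
  mu <- f$mu[ord]; sigma2 <- f$sigma2[ord]; w <- f$w[ord]
  ld <- log_component_density(x, mu, sigma2, w)
  post <- exp(ld - log_row_sum_exp(ld))
  dimnames(post) <- list(names(x), NULL)
  assign <- max.col(post, ties.method = "first")  # ties -> lower-mean cluster
  names(assign) <- names(x)
  structure(list(
    gene = gene, k = k, means = mu, variances = sigma2, weights = w,
    assignments = assign, posterior = post,
    bic_by_k = bic, loglik_by_k = loglik, loglik = f$loglik,
    n_cells = n, data = x, seed = as.integer(seed)
  ), class = "multisep_fit")
}

#' Fit mixtures for every gene of an expression matrix
#'
#' Optionally restricts to the cell lines of one tissue. Genes that fail the
#' fitting preconditions (too few finite values, near-constant expression)
#' are skipped and reported, not fatal.
#'
#' @param expr Cell-line-by-gene expression matrix (rownames = cell lines).
#' @param tissues Named character vector mapping cell line to tissue label;
#'   required when `tissue_subset` is given.
#' @param tissue_subset Optional tissue label; only its cell lines are used.
#' @param min_lines Minimum cell lines required for a tissue subset.
#' @param seed Base seed; each gene's fit uses a seed derived from it and the
#'   gene symbol, so results are independent of gene order.
#' @inheritParams fit_gene_mixture
#' @return Named list of `multisep_fit` objects (class `multisep_fits`), with
#'   attribute `failures`: data.frame (gene, reason) for skipped genes.
#' @export
cluster_all_genes <- function(expr, tissues = NULL, tissue_subset = NULL,
                              min_lines = 10L, k_min = 2L, k_max = 5L,
                              seed = 1L, restarts = 10L) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  lines <- rownames(expr)
  if (!is.null(tissue_subset)) {
    if (is.null(tissues)) stop_config("tissue_subset given but no tissue annotation supplied")
    lines <- intersect(lines, names(tissues)[tissues == tissue_subset])
    if (length(lines) < min_lines) {
      stop_tissue_too_small(sprintf(
        "tissue '%s' has %d cell line(s), below the minimum of %d",
        tissue_subset, length(lines), min_lines))
    }
  }
  sub <- expr[lines, , drop = FALSE]
  genes <- colnames(sub)
  fits <- vector("list", length(genes))
  names(fits) <- genes
  fail_gene <- character(); fail_reason <- character()
  for (g in genes) {
    fits[[g]] <- tryCatch(
      fit_gene_mixture(sub[, g], k_min = k_min, k_max = k_max,
                       seed = derive_seed(seed, g), restarts = restarts,
                       gene = g),
      multisep_error = function(e) {
        fail_gene <<- c(fail_gene, g)
        fail_reason <<- c(fail_reason, conditionMessage(e))
        NULL
      }
    )
  }
  fits <- fits[!vapply(fits, is.null, logical(1))]
  structure(fits,
            class = "multisep_fits",
            tissue = tissue_subset %||% "all",
            failures = data.frame(gene = fail_gene, reason = fail_reason,
                                  stringsAsFactors = FALSE))
}

#' @export
print.multisep_fits <- function(x, ...) {
  ks <- vapply(x, function(f) f$k, integer(1))
  cat(sprintf("multisep mixture fits: %d genes (tissue: %s)\n",
              length(x), attr(x, "tissue")))
  if (length(ks)) { cat("selected k:\n"); print(table(ks)) }
  fl <- attr(x, "failures")
  if (nrow(fl)) cat(sprintf("skipped genes: %d\n", nrow(fl)))
  invisible(x)
}

#' Export cluster assignments as a long table
#'
#' One row per (gene, cell line): columns `gene`, `cell_line`, `cluster`,
#' `k`, `cluster_mean`. Mirrors the downloadable cluster-results format.
#'
#' @param fits A `multisep_fits` list (or a single `multisep_fit`).
#' @return `data.frame` in long format.
#' @export
cluster_table <- function(fits) {
  if (inherits(fits, "multisep_fit")) fits <- list(fits)
  rows <- lapply(fits, function(f) {
    data.frame(gene = f$gene, cell_line = names(f$assignments),
               cluster = unname(f$assignments), k = f$k,
               cluster_mean = f$means[f$assignments],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read the long cluster table
#'
#' @param x Table from [cluster_table()].
#' @param path File path (tab-separated).
#' @return `path` (write) or the table (read).
#' @export
write_cluster_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cluster_table
#' @export
read_cluster_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
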