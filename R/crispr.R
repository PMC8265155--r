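# CRISPR dependency testing: Welch t-tests of CERES-like essentiality scores
# between neighbouring expression clusters of a partner gene.
#
# The "log2FC" output column keeps the field's column name but holds a
# difference of cluster mean CERES scores: CERES values are signed and centred
# near zero (essential ~ -1, non-essential ~ 0), so a ratio-based fold change
# is ill-defined. See the methods vignette.

# Welch two-sample t-test (unequal variances, Welch-Satterthwaite df),
# two-tailed. Direct formulas keep the genome-wide scan fast.
welch_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  if (se2 <= 0) {
    # both groups constant: identical means -> p = 1, else p -> 0
    return(list(statistic = if (ma == mb) 0 else sign(mb - ma) * Inf,
                df = na + nb - 2,
                p = if (ma == mb) 1 else 0))
  }
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(statistic = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

#' Test one (expression gene, CRISPR gene) pair
#'
#' Every adjacent cluster pair (i, i+1) of the expression mixture with at
#' least `min_group` finite CRISPR scores on both sides is compared with a
#' two-tailed Welch t-test. The reported comparison is the one with the
#' smallest p-value (ties resolved toward the larger absolute effect). The
#' effect is `mean(cluster i+1) - mean(cluster i)`: positive when knockout is
#' more damaging (more negative CERES) in the low-expression cluster, the
#' synthetic-lethality signature. The extreme-cluster comparison (first vs
#' last) is also computed and kept in the full comparison table.
#'
#' @param model A `multisep_fit` for the expression gene.
#' @param crispr_scores Numeric vector of CERES-like scores named by cell
#'   line (aligned by name to the model's assignments).
#' @param min_group Minimum cell lines per compared cluster (default 3).
#' @param crispr_gene,tissue Labels recorded in the result.
#' @return List of class `crispr_dependency`: `mrna_gene`, `crispr_gene`,
#'   `tissue`, `cluster_lo`, `cluster_hi`, `effect`, `p`, `n_lo`, `n_hi`, and
#'   `comparisons` (all adjacent plus the extreme comparison).
#' @export
test_pair <- function(model, crispr_scores, min_group = 3L,
                      crispr_gene = NA_character_, tissue = "all") {
  stopifnot(inherits(model, "multisep_fit"))
  cl <- model$assignments
  s <- crispr_scores[names(cl)]
  ok <- is.finite(s)
  cl <- cl[ok]; s <- s[ok]
  k <- model$k
  groups <- split(unname(s), factor(cl, levels = seq_len(k)))
  sizes <- lengths(groups)

  pairs_lo <- seq_len(k - 1L); pairs_hi <- pairs_lo + 1L
  type <- rep("adjacent", k - 1L)
  if (k > 2L) { pairs_lo <- c(pairs_lo, 1L); pairs_hi <- c(pairs_hi, k); type <- c(type, "extreme") }
  m <- length(pairs_lo)
  eff <- p <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    a <- groups[[pairs_lo[i]]]; b <- groups[[pairs_hi[i]]]
    if (length(a) < min_group || length(b) < min_group) next
    tt <- welch_test(a, b)
    eff[i] <- mean(b) - mean(a); p[i] <- tt$p
  }
  ok_cmp <- !is.na(p)
  comparisons <- data.frame(cluster_lo = pairs_lo[ok_cmp], cluster_hi = pairs_hi[ok_cmp],
                            n_lo = sizes[pairs_lo[ok_cmp]], n_hi = sizes[pairs_hi[ok_cmp]],
                            effect = eff[ok_cmp], p = p[ok_cmp], type = type[ok_cmp],
                            stringsAsFactors = FALSE, row.names = NULL)
  adj_idx <- which(ok_cmp & type == "adjacent")
  if (length(adj_idx) == 0L) {
    stop_not_testable(sprintf(
      "gene %s vs %s: no adjacent cluster pair has >= %d cell lines with finite scores on both sides",
      model$gene, crispr_gene, min_group))
  }
  sel <- adj_idx[order(p[adj_idx], -abs(eff[adj_idx]))][1L]
  best <- list(cluster_lo = pairs_lo[sel], cluster_hi = pairs_hi[sel],
               n_lo = length(groups[[pairs_lo[sel]]]),
               n_hi = length(groups[[pairs_hi[sel]]]),
               effect = eff[sel], p = p[sel])
  structure(list(
    mrna_gene = model$gene, crispr_gene = crispr_gene, tissue = tissue,
    cluster_lo = best$cluster_lo, cluster_hi = best$cluster_hi,
    effect = best$effect, p = best$p,
    n_lo = best$n_lo, n_hi = best$n_hi,
    cluster_sizes = as.integer(sizes), comparisons = comparisons
  ), class = "crispr_dependency")
}

#' @export
print.crispr_dependency <- function(x, ...) {
  cat(sprintf("%s (expression) vs %s (CRISPR), tissue %s\n",
              x$mrna_gene, x$crispr_gene, x$tissue))
  cat(sprintf("  clusters %d vs %d (n = %d, %d): effect = %.4f, p = %.3g\n",
              x$cluster_lo, x$cluster_hi, x$n_lo, x$n_hi, x$effect, x$p))
  invisible(x)
}

#' Multiple-testing adjusted q-values
#'
#' `"bh"` applies the Benjamini-Hochberg step-up adjustment. `"storey"`
#' estimates the null proportion pi0 on a lambda grid (0.05 to 0.95, step
#' 0.05) with a cubic smoothing spline evaluated at the largest lambda
#' (capped at 1), then returns `pi0 * m * p_(i) / i` with the usual step-up
#' minimum. Output preserves input order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param method `"bh"` (default) or `"storey"`.
#' @return Numeric vector of q-values, same length and order as `pvals`.
#' @export
compute_qvalues <- function(pvals, method = c("bh", "storey")) {
  method <- match.arg(method)
  if (length(pvals) == 0L) return(numeric(0))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop_value("p-values must lie in [0, 1]")
  }
  if (method == "bh") return(stats::p.adjust(pvals, method = "BH"))
  m <- length(pvals)
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0_hat <- vapply(lambda, function(l) mean(pvals > l) / (1 - l), numeric(1))
  pi0 <- if (m >= 100) {
    sp <- stats::smooth.spline(lambda, pi0_hat, df = 3)
    stats::predict(sp, x = max(lambda))$y
  } else {
    # small inputs: the spline is unstable; fall back to the conservative
    # BH-equivalent pi0 = 1
    1
  }
  pi0 <- min(max(pi0, 1e-8), 1)
  o <- order(pvals, decreasing = TRUE)
  q <- rep(NA_real_, m)
  q[o] <- pmin(1, cummin(pi0 * m * pvals[o] / rank(pvals, ties.method = "max")[o]))
  q
}

#' Genome-wide CRISPR dependency scan
#'
#' Tests every (expression gene, CRISPR gene) combination with [test_pair()],
#' adjusts p-values over all tested pairs within the scan scope, then keeps
#' rows passing the inclusion thresholds `|log2FC| > effect_min` and
#' `p < p_max` (defaults 0.1 and 0.1). Rows are sorted by q-value.
#'
#' @param dataset A `multisep_dataset` containing a CRISPR matrix.
#' @param tissue Optional tissue label restricting the scan scope.
#' @param effect_min,p_max Inclusion thresholds.
#' @param q_method Passed to [compute_qvalues()].
#' @param min_group Minimum cluster size per comparison.
#' @param fits Optional precomputed `multisep_fits`; computed on demand
#'   otherwise.
#' @param mrna_genes,crispr_genes Optional gene subsets.
#' @param seed Seed for on-demand clustering.
#' @param filtered If `FALSE`, return every tested pair (thresholds ignored).
#' @return `data.frame` with columns `mRNA_gene`, `crispr_gene`, `tissue`,
#'   `cluster_lo`, `cluster_hi`, `n_lo`, `n_hi`, `log2FC`, `p_value`,
#'   `q_value`; attribute `n_tested` gives the pre-filter test count.
#' @export
scan_crispr <- function(dataset, tissue = NULL, effect_min = 0.1, p_max = 0.1,
                        q_method = "bh", min_group = 3L, fits = NULL,
                        mrna_genes = NULL, crispr_genes = NULL, seed = 1L,
                        filtered = TRUE) {
  stopifnot(inherits(dataset, "multisep_dataset"))
  if (is.null(dataset$crispr)) stop_config("dataset has no CRISPR matrix")
  if (is.null(fits)) {
    expr <- dataset$expression
    if (!is.null(mrna_genes)) expr <- expr[, intersect(colnames(expr), mrna_genes), drop = FALSE]
    fits <- cluster_all_genes(expr, tissues = dataset$tissues,
                              tissue_subset = tissue, seed = seed)
  }
  cg <- colnames(dataset$crispr)
  if (!is.null(crispr_genes)) cg <- intersect(cg, crispr_genes)
  tissue_label <- tissue %||% "all"
  cap <- length(fits) * length(cg)
  v_mrna <- v_cg <- character(cap)
  v_lo <- v_hi <- v_nlo <- v_nhi <- integer(cap)
  v_eff <- v_p <- numeric(cap)
  idx <- 0L
  for (f in fits) {
    for (g in cg) {
      res <- tryCatch(
        test_pair(f, dataset$crispr[, g], min_group = min_group,
                  crispr_gene = g, tissue = tissue_label),
        not_testable_error = function(e) NULL)
      if (is.null(res)) next
      idx <- idx + 1L
      v_mrna[idx] <- res$mrna_gene; v_cg[idx] <- g
      v_lo[idx] <- res$cluster_lo; v_hi[idx] <- res$cluster_hi
      v_nlo[idx] <- res$n_lo; v_nhi[idx] <- res$n_hi
      v_eff[idx] <- res$effect; v_p[idx] <- res$p
    }
  }
  out <- if (idx > 0L) {
    keep <- seq_len(idx)
    data.frame(mRNA_gene = v_mrna[keep], crispr_gene = v_cg[keep],
               tissue = tissue_label, cluster_lo = v_lo[keep],
               cluster_hi = v_hi[keep], n_lo = v_nlo[keep], n_hi = v_nhi[keep],
               log2FC = v_eff[keep], p_value = v_p[keep],
               stringsAsFactors = FALSE)
  } else NULL
  if (is.null(out)) {
    out <- data.frame(mRNA_gene = character(), crispr_gene = character(),
                      tissue = character(), cluster_lo = integer(),
                      cluster_hi = integer(), n_lo = integer(), n_hi = integer(),
                      log2FC = numeric(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE)
    attr(out, "n_tested") <- 0L
    return(out)
  }
  out$q_value <- compute_qvalues(out$p_value, method = q_method)
  n_tested <- nrow(out)
  if (filtered) {
    out <- out[abs(out$log2FC) > effect_min & out$p_value < p_max, , drop = FALSE]
  }
  out <- out[order(out$q_value, out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- n_tested
  out
}
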