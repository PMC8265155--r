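# Baseline comparators.
#
# DAISY here follows the published data-mining protocol restricted to the
# data types in scope (copy number + RNA-seq): a gene is called inactive in a
# cell line when its copy number is lost AND its expression sits in the
# lowest quantile; the survival-of-the-fittest (SoF) component asks whether
# the partner gene is relatively over-active in those inactive lines, and the
# coexpression component tests rank correlation between the two genes'
# expression. The two one-procedure p-values are combined by Fisher's method
# (the shRNA-essentiality procedure has no input here and is omitted). Genes
# without copy-number losses in at least 2 cell lines yield no prediction.
#
# The BiSEp surrogate reproduces the behaviour attributed to that method:
# two clusters only, comparisons gated on statistically identified
# bimodality, and fold-change scoring. It is a surrogate, not a
# re-implementation of BiSEp's own bimodality statistics; the gate is a
# BIC margin of the two-component over the one-component Gaussian fit.

#' Cell lines where a gene is called inactive (DAISY)
#'
#' Inactive = copy-number log-ratio below `loss_threshold` AND expression in
#' the gene's lowest `loss_quantile`. Fewer than 2 inactive lines means no
#' DAISY prediction can be made for the gene.
#'
#' @param gene Gene symbol.
#' @param copy_number,expression Cell-line-by-gene matrices sharing rownames.
#' @param loss_quantile Expression quantile defining "low" (default 0.1).
#' @param loss_threshold Copy-number log-ratio call for loss (default -0.3).
#' @return Logical vector named by cell line.
#' @export
daisy_inactive_mask <- function(gene, copy_number, expression,
                                loss_quantile = 0.1, loss_threshold = -0.3) {
  if (!gene %in% colnames(copy_number) || !gene %in% colnames(expression)) {
    stop_not_predictable(sprintf("gene %s absent from copy-number or expression matrix", gene))
  }
  lines <- intersect(rownames(copy_number), rownames(expression))
  cn <- copy_number[lines, gene]
  ex <- expression[lines, gene]
  lost <- is.finite(cn) & cn < loss_threshold
  if (sum(lost) < 2L) {
    stop_not_predictable(sprintf(
      "gene %s: copy-number losses in %d cell line(s), need >= 2", gene, sum(lost)))
  }
  low <- ex <= stats::quantile(ex, loss_quantile, na.rm = TRUE)
  mask <- lost & low & is.finite(ex)
  if (sum(mask) < 2L) {
    stop_not_predictable(sprintf(
      "gene %s: only %d cell line(s) with both copy-number loss and lowest-quantile expression",
      gene, sum(mask)))
  }
  mask
}

#' DAISY pairwise dependency score
#'
#' Combines the SoF test (one-sided Wilcoxon rank-sum: is gene `b`'s
#' expression higher in `a`-inactive lines than in the rest?) with a Spearman
#' coexpression test between `a` and `b` via Fisher's method. The score is
#' `-log10` of the combined p-value (higher = more likely dependent).
#'
#' @param a,b Gene symbols (self-pairs are rejected).
#' @param dataset A `multisep_dataset` with expression and copy-number
#'   matrices.
#' @param loss_quantile,loss_threshold Passed to [daisy_inactive_mask()].
#' @return List of class `baseline_score`: `gene_a`, `gene_b`, `method`,
#'   `score`, `components` (`sof_p`, `coexpr_p`, `combined_p`, `n_inactive`).
#' @export
daisy_pair_score <- function(a, b, dataset, loss_quantile = 0.1,
                             loss_threshold = -0.3) {
  stopifnot(inherits(dataset, "multisep_dataset"))
  if (is.null(dataset$copy_number)) stop_config("dataset has no copy-number matrix")
  if (identical(a, b)) stop_not_predictable("self-pairs are not scored")
  mask <- daisy_inactive_mask(a, dataset$copy_number, dataset$expression,
                              loss_quantile, loss_threshold)
  if (!b %in% colnames(dataset$expression)) {
    stop_not_predictable(sprintf("gene %s absent from expression matrix", b))
  }
  eb <- dataset$expression[names(mask), b]
  ea <- dataset$expression[names(mask), a]
  if (!is.finite(stats::var(eb)) || stats::var(eb) < 1e-10) {
    stop_not_predictable(sprintf("gene %s: degenerate expression values", b))
  }
  sof <- suppressWarnings(stats::wilcox.test(eb[mask], eb[!mask],
                                             alternative = "greater"))
  cx <- suppressWarnings(stats::cor.test(ea, eb, method = "spearman"))
  sof_p <- max(sof$p.value, .Machine$double.xmin)
  coexpr_p <- max(cx$p.value, .Machine$double.xmin)
  stat <- -2 * (log(sof_p) + log(coexpr_p))
  combined <- stats::pchisq(stat, df = 4, lower.tail = FALSE)
  structure(list(
    gene_a = a, gene_b = b, method = "daisy",
    score = -log10(max(combined, .Machine$double.xmin)),
    components = list(sof_p = sof_p, coexpr_p = coexpr_p,
                      combined_p = combined, n_inactive = sum(mask))
  ), class = "baseline_score")
}

#' Bimodality-gated two-cluster baseline score
#'
#' Splits cell lines into exactly two groups by a two-component Gaussian fit
#' of gene `a`'s expression, but only when bimodality is statistically
#' identified: the two-component BIC must beat the single-Gaussian BIC by at
#' least `bic_margin`. The score is the CRISPR fold-change of gene `b`
#' between the two groups (mean of the high-expression group minus mean of
#' the low-expression group).
#'
#' @param a,b Gene symbols.
#' @param dataset A `multisep_dataset` with expression and CRISPR matrices.
#' @param bic_margin Required BIC improvement of 2 over 1 components.
#' @param min_group Minimum lines per group.
#' @param seed Seed for the two-component fit.
#' @return List of class `baseline_score` with `components` (`bic_1`,
#'   `bic_2`, group sizes).
#' @export
bisep_surrogate_score <- function(a, b, dataset, bic_margin = 10,
                                  min_group = 3L, seed = 1L) {
  stopifnot(inherits(dataset, "multisep_dataset"))
  if (is.null(dataset$crispr)) stop_config("dataset has no CRISPR matrix")
  if (identical(a, b)) stop_not_predictable("self-pairs are not scored")
  if (!a %in% colnames(dataset$expression)) {
    stop_not_predictable(sprintf("gene %s absent from expression matrix", a))
  }
  if (!b %in% colnames(dataset$crispr)) {
    stop_not_predictable(sprintf("gene %s absent from CRISPR matrix", b))
  }
  x <- dataset$expression[, a]
  names(x) <- rownames(dataset$expression)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 6L) stop_not_predictable(sprintf("gene %s: too few finite values", a))
  # one-component fit has a closed form
  mu <- mean(x); s2 <- stats::var(x) * (n - 1) / n
  ll1 <- sum(stats::dnorm(x, mu, sqrt(s2), log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(n)
  fit2 <- tryCatch(
    fit_gene_mixture(x, k_min = 2L, k_max = 2L, seed = seed, gene = a),
    multisep_error = function(e) NULL)
  if (is.null(fit2)) stop_not_predictable(sprintf("gene %s: two-component fit failed", a))
  bic2 <- unname(fit2$bic_by_k["2"])
  if (!(bic1 - bic2 >= bic_margin)) {
    stop_not_predictable(sprintf(
      "gene %s: bimodality gate failed (BIC margin %.2f < %.2f)",
      a, bic1 - bic2, bic_margin))
  }
  s <- dataset$crispr[names(fit2$assignments), b]
  lo <- s[fit2$assignments == 1L & is.finite(s)]
  hi <- s[fit2$assignments == 2L & is.finite(s)]
  if (length(lo) < min_group || length(hi) < min_group) {
    stop_not_predictable(sprintf(
      "pair %s/%s: a two-cluster group has fewer than %d finite CRISPR scores",
      a, b, min_group))
  }
  structure(list(
    gene_a = a, gene_b = b, method = "bisep_surrogate",
    score = mean(hi) - mean(lo),
    components = list(bic_1 = bic1, bic_2 = bic2, n_lo = length(lo),
                      n_hi = length(hi))
  ), class = "baseline_score")
}

#' @export
print.baseline_score <- function(x, ...) {
  cat(sprintf("%s score for (%s, %s): %.4f\n", x$method, x$gene_a, x$gene_b, x$score))
  invisible(x)
}

#' Score a set of gene pairs with a baseline method
#'
#' Pairs failing a method's preconditions (no copy-number losses, bimodality
#' gate, degenerate values) are absent from the output rather than
#' zero-scored, reproducing each method's coverage behaviour.
#'
#' @param pairs `data.frame` with columns `gene_a`, `gene_b`.
#' @param dataset A `multisep_dataset`.
#' @param method `"daisy"` or `"bisep"`.
#' @param seed Seed (used by the bimodality fits).
#' @param ... Passed to the per-pair scorer.
#' @return `data.frame`: `gene_a`, `gene_b`, `method`, `score`, plus
#'   component columns; attribute `n_unpredictable` counts skipped pairs.
#' @export
score_baseline_pairs <- function(pairs, dataset, method = c("daisy", "bisep"),
                                 seed = 1L, ...) {
  method <- match.arg(method)
  rows <- list(); skipped <- 0L
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    res <- tryCatch(
      if (method == "daisy") daisy_pair_score(a, b, dataset, ...)
      else bisep_surrogate_score(a, b, dataset, seed = derive_seed(seed, a), ...),
      not_predictable_error = function(e) NULL)
    if (is.null(res)) { skipped <- skipped + 1L; next }
    comp <- res$components
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = a, gene_b = b, method = res$method, score = res$score,
      as.data.frame(comp[vapply(comp, is_scalar_number, logical(1))]),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(), gene_b = character(),
               method = character(), score = numeric())
  rownames(out) <- NULL
  attr(out, "n_unpredictable") <- skipped
  out
}
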