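# Mutation dependency testing: chi-squared enrichment of mutation status (or
# mutation classes) across a partner gene's expression clusters. The classic
# signature is mutual exclusivity: mutations depleted from the partner's
# low-expression cluster.

# Severity ranking used to pick one class per (cell line, gene) when several
# records exist: truncating > splice > missense > in-frame > other.
.class_severity <- c(
  nonsense = 1, frameshift_deletion = 2, frameshift_insertion = 3,
  splice_site = 4, missense = 5, inframe_deletion = 6, inframe_insertion = 7,
  start_lost = 8, nonstop = 9
)

#' Mutation status of one gene across cell lines
#'
#' Collapses a long mutation table to one status per cell line: wild-type or
#' a single mutation class (the most deleterious recorded class when a line
#' carries several records for the gene).
#'
#' @param mutations Long mutation table (`cell_line`, `gene`,
#'   `mutation_class`).
#' @param gene Gene symbol.
#' @param cell_lines Cell-line universe for which status is reported.
#' @return Named character vector over `cell_lines`: `"wild_type"` or a
#'   mutation class.
#' @export
mutation_status <- function(mutations, gene, cell_lines) {
  status <- stats::setNames(rep("wild_type", length(cell_lines)), cell_lines)
  rec <- mutations[mutations$gene == gene & mutations$cell_line %in% cell_lines, ,
                   drop = FALSE]
  if (nrow(rec) > 0) {
    sev <- .class_severity[rec$mutation_class]
    sev[is.na(sev)] <- 100  # unknown classes rank least deleterious
    rec <- rec[order(sev), , drop = FALSE]
    rec <- rec[!duplicated(rec$cell_line), , drop = FALSE]
    status[rec$cell_line] <- rec$mutation_class
  }
  status
}

#' Chi-squared test of mutation enrichment across expression clusters
#'
#' Builds a clusters-by-status contingency table over the cell lines assigned
#' by the expression mixture and applies Pearson's chi-squared test without
#' continuity correction. In `"binary"` mode (default) the status is
#' wild-type vs mutated; `"by_class"` resolves mutation classes, pooling any
#' class whose smallest expected cell count falls below 1 into `"other"`.
#' If more than 20% of expected counts fall below 5 a message notes that the
#' chi-squared approximation is strained (the test is still performed).
#'
#' @param model A `multisep_fit` for the expression gene.
#' @param statuses Named character vector (cell line -> mutation class or
#'   `"wild_type"`), e.g. from [mutation_status()].
#' @param mode `"binary"` or `"by_class"`.
#' @param min_mutations Minimum mutated cell lines among assigned lines
#'   (default 5).
#' @param mutation_gene,tissue Labels recorded in the result.
#' @return List of class `mutation_dependency`: `mrna_gene`, `mutation_gene`,
#'   `tissue`, `chi2`, `dof`, `p`, `n_mutations`, `counts` (the contingency
#'   table used).
#' @export
test_mutation_pair <- function(model, statuses, mode = c("binary", "by_class"),
                               min_mutations = 5L,
                               mutation_gene = NA_character_, tissue = "all") {
  stopifnot(inherits(model, "multisep_fit"))
  mode <- match.arg(mode)
  cl <- model$assignments
  st <- statuses[names(cl)]
  ok <- !is.na(st)
  cl <- cl[ok]; st <- st[ok]
  n <- length(cl)
  mutated <- st != "wild_type"
  n_mut <- sum(mutated)
  if (n_mut < min_mutations) {
    stop_not_testable(sprintf(
      "gene %s vs %s: %d mutated cell line(s), need >= %d",
      model$gene, mutation_gene, n_mut, min_mutations))
  }
  if (n_mut == n) {
    stop_not_testable(sprintf(
      "gene %s vs %s: all assigned cell lines are mutated", model$gene, mutation_gene))
  }
  clf <- factor(cl, levels = seq_len(model$k))
  if (mode == "binary") {
    tab <- table(cluster = clf, status = factor(ifelse(mutated, "mutated", "wild_type"),
                                                levels = c("wild_type", "mutated")))
  } else {
    lab <- ifelse(mutated, st, "wild_type")
    tab <- table(cluster = clf, status = lab)
    # pool classes whose smallest expected cell count is below 1
    cls <- setdiff(colnames(tab), "wild_type")
    n_by_cluster <- rowSums(tab)
    min_frac <- min(n_by_cluster) / n
    pool <- cls[colSums(tab)[cls] * min_frac < 1]
    if (length(pool) > 1) {
      other <- rowSums(tab[, pool, drop = FALSE])
      tab <- cbind(tab[, setdiff(colnames(tab), pool), drop = FALSE], other = other)
    }
  }
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]  # drop empty clusters
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    # all assigned lines fall in one cluster (or one status): a one-way table
    # is a goodness-of-fit problem, not a dependency test
    stop_not_testable(sprintf(
      "gene %s vs %s: contingency table collapses to a single %s",
      model$gene, mutation_gene,
      if (nrow(tab) < 2L) "cluster" else "status"))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (mean(expected < 5) > 0.2) {
    message(sprintf(
      "test_mutation_pair: %s vs %s: %.0f%% of expected counts < 5; chi-squared approximation may be strained",
      model$gene, mutation_gene, 100 * mean(expected < 5)))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(
    mrna_gene = model$gene, mutation_gene = mutation_gene, tissue = tissue,
    chi2 = unname(ct$statistic), dof = as.integer(unname(ct$parameter)),
    p = ct$p.value, n_mutations = n_mut, counts = tab, mode = mode
  ), class = "mutation_dependency")
}

#' @export
print.mutation_dependency <- function(x, ...) {
  cat(sprintf("%s (mutation) vs %s (expression clusters), tissue %s\n",
              x$mutation_gene, x$mrna_gene, x$tissue))
  cat(sprintf("  chi2 = %.3f (dof %d), p = %.3g, mutated lines = %d\n",
              x$chi2, x$dof, x$p, x$n_mutations))
  print(x$counts)
  invisible(x)
}

#' Scan mutation genes against all expression clusterings
#'
#' For each requested mutation gene, tests mutation-status enrichment across
#' the expression clusters of every fitted gene. Retained rows satisfy
#' `p < p_max` (default 0.05) and carry at least `min_mutations` mutated
#' lines (default 5). q-values are computed over all tested pairs within the
#' scan before filtering.
#'
#' @param dataset A `multisep_dataset` with a mutation table.
#' @param mutation_genes Non-empty character vector; genes absent from the
#'   mutation table are skipped with a warning.
#' @param tissue Optional tissue label restricting the scan scope.
#' @param p_max Inclusion threshold on the unadjusted p-value.
#' @param min_mutations Minimum mutated lines per test.
#' @param mode `"binary"` or `"by_class"`.
#' @param q_method Passed to [compute_qvalues()].
#' @param fits Optional precomputed `multisep_fits`.
#' @param mrna_genes Optional expression-gene subset.
#' @param seed Seed for on-demand clustering.
#' @param filtered If `FALSE`, return every tested pair.
#' @return `data.frame` with columns `mutation_gene`, `mRNA_gene`, `tissue`,
#'   `chi2`, `dof`, `p_value`, `q_value`, `n_mutations`; attribute `n_tested`.
#' @export
scan_mutations <- function(dataset, mutation_genes, tissue = NULL,
                           p_max = 0.05, min_mutations = 5L,
                           mode = "binary", q_method = "bh", fits = NULL,
                           mrna_genes = NULL, seed = 1L, filtered = TRUE) {
  stopifnot(inherits(dataset, "multisep_dataset"))
  if (is.null(dataset$mutations)) stop_config("dataset has no mutation table")
  if (length(mutation_genes) == 0L) stop_config("mutation_genes must be non-empty")
  known <- unique(dataset$mutations$gene)
  missing <- setdiff(mutation_genes, known)
  if (length(missing) > 0) {
    warning(sprintf("mutation gene(s) absent from the mutation table, skipped: %s",
                    paste(missing, collapse = ", ")), call. = FALSE)
    mutation_genes <- setdiff(mutation_genes, missing)
  }
  if (is.null(fits)) {
    expr <- dataset$expression
    if (!is.null(mrna_genes)) expr <- expr[, intersect(colnames(expr), mrna_genes), drop = FALSE]
    fits <- cluster_all_genes(expr, tissues = dataset$tissues,
                              tissue_subset = tissue, seed = seed)
  }
  tissue_label <- tissue %||% "all"
  rows <- list()
  for (mg in mutation_genes) {
    statuses <- mutation_status(dataset$mutations, mg, dataset$cell_lines)
    for (f in fits) {
      res <- tryCatch(
        suppressMessages(test_mutation_pair(
          f, statuses, mode = mode, min_mutations = min_mutations,
          mutation_gene = mg, tissue = tissue_label)),
        not_testable_error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        mutation_gene = mg, mRNA_gene = f$gene, tissue = tissue_label,
        chi2 = res$chi2, dof = res$dof, p_value = res$p,
        n_mutations = res$n_mutations, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(mutation_gene = character(), mRNA_gene = character(),
                      tissue = character(), chi2 = numeric(), dof = integer(),
                      p_value = numeric(), q_value = numeric(),
                      n_mutations = integer(), stringsAsFactors = FALSE)
    attr(out, "n_tested") <- 0L
    return(out)
  }
  out$q_value <- compute_qvalues(out$p_value, method = q_method)
  out <- out[, c("mutation_gene", "mRNA_gene", "tissue", "chi2", "dof",
                 "p_value", "q_value", "n_mutations")]
  n_tested <- nrow(out)
  if (filtered) {
    out <- out[out$p_value < p_max & out$n_mutations >= min_mutations, , drop = FALSE]
  }
  out <- out[order(out$q_value, out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- n_tested
  out
}
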