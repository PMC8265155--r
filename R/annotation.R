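# Orthogonal functional-similarity evidence for result tables: shared GO
# terms, physical protein-protein interactions, paralogy; plus per-cluster
# protein-concentration summaries.

result_gene_columns <- function(results) {
  for (cand in list(c("mRNA_gene", "crispr_gene"),
                    c("mutation_gene", "mRNA_gene"),
                    c("gene_a", "gene_b"))) {
    if (all(cand %in% colnames(results))) return(cand)
  }
  stop_config("cannot identify the two gene columns of the results table")
}

#' Annotate result rows with functional-similarity evidence
#'
#' Adds three columns to a scan results table: `shared_go_count` (number of
#' GO terms common to both genes), `has_ppi` and `is_paralogue` (symmetric
#' pair lookups). Annotation is pure: row order, row count and statistics are
#' untouched unless one of the `require_*` filters is set. Genes absent from
#' an annotation source count as unannotated (zero shared terms, `FALSE`
#' flags); per-source missing-gene counts are attached as attribute
#' `missing_genes`, and per-filter pass counts as attribute `filter_counts`.
#'
#' @param results Scan results table (CRISPR, mutation, or generic
#'   `gene_a`/`gene_b` pairs).
#' @param ann Annotation sets: list with `go_terms` (gene -> character vector
#'   of term ids), `ppi_edges` and `paralogue_pairs` (data.frames `gene_a`,
#'   `gene_b`).
#' @param require_go,require_ppi,require_paralogue Subset rows to those with
#'   the corresponding evidence.
#' @return The annotated (and possibly filtered) table.
#' @export
annotate_pairs <- function(results, ann, require_go = FALSE,
                           require_ppi = FALSE, require_paralogue = FALSE) {
  cols <- result_gene_columns(results)
  a <- results[[cols[1L]]]; b <- results[[cols[2L]]]
  go <- ann$go_terms %||% list()
  shared_go <- mapply(function(x, y) {
    length(intersect(go[[x]], go[[y]]))
  }, a, b, USE.NAMES = FALSE)
  ppi_keys <- if (nrow(ann$ppi_edges %||% data.frame()) > 0)
    pair_key(ann$ppi_edges$gene_a, ann$ppi_edges$gene_b) else character()
  par_keys <- if (nrow(ann$paralogue_pairs %||% data.frame()) > 0)
    pair_key(ann$paralogue_pairs$gene_a, ann$paralogue_pairs$gene_b) else character()
  keys <- pair_key(a, b)
  out <- results
  out$shared_go_count <- as.integer(shared_go)
  out$has_ppi <- keys %in% ppi_keys
  out$is_paralogue <- keys %in% par_keys
  genes <- unique(c(a, b))
  missing <- c(go = sum(!genes %in% names(go)),
               ppi = sum(!genes %in% unique(c(ann$ppi_edges$gene_a, ann$ppi_edges$gene_b))),
               paralogue = sum(!genes %in% unique(c(ann$paralogue_pairs$gene_a,
                                                    ann$paralogue_pairs$gene_b))))
  counts <- c(shared_go = sum(out$shared_go_count > 0),
              ppi = sum(out$has_ppi), paralogue = sum(out$is_paralogue))
  keep <- rep(TRUE, nrow(out))
  if (require_go) keep <- keep & out$shared_go_count > 0
  if (require_ppi) keep <- keep & out$has_ppi
  if (require_paralogue) keep <- keep & out$is_paralogue
  out <- out[keep, , drop = FALSE]
  attr(out, "filter_counts") <- counts
  attr(out, "missing_genes") <- missing
  out
}

#' Per-cluster summary of protein concentrations
#'
#' Summarizes a protein-concentration vector within each expression cluster
#' of a fitted mixture: coverage, median and quartiles. Clusters without
#' protein coverage are flagged (`covered = FALSE`), never dropped.
#'
#' @param model A `multisep_fit`.
#' @param protein_values Numeric vector named by cell line (coverage may be
#'   partial).
#' @param min_n Minimum measurements for at least one cluster.
#' @return `data.frame` with one row per cluster: `cluster`, `n`, `median`,
#'   `q1`, `q3`, `covered`, `mrna_mean`.
#' @export
protein_by_cluster <- function(model, protein_values, min_n = 3L) {
  stopifnot(inherits(model, "multisep_fit"))
  cl <- model$assignments
  common <- intersect(names(cl), names(protein_values))
  common <- common[is.finite(protein_values[common])]
  if (length(common) == 0L) {
    stop_not_testable(sprintf(
      "gene %s: no overlap between protein measurements and clustered cell lines",
      model$gene))
  }
  p <- protein_values[common]
  g <- cl[common]
  out <- data.frame(cluster = seq_len(model$k), n = 0L,
                    median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                    covered = FALSE, mrna_mean = model$means)
  for (j in seq_len(model$k)) {
    v <- p[g == j]
    out$n[j] <- length(v)
    if (length(v) > 0) {
      qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      out$q1[j] <- qs[1L]; out$median[j] <- qs[2L]; out$q3[j] <- qs[3L]
      out$covered[j] <- TRUE
    }
  }
  if (max(out$n) < min_n) {
    stop_not_testable(sprintf(
      "gene %s: no cluster has >= %d protein measurements", model$gene, min_n))
  }
  out
}
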