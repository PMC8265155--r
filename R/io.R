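# Dataset model and delimited-text readers/writers for DepMap-shaped inputs.
#
# Wide matrices (expression, CRISPR, protein, copy number) follow the DepMap
# convention: first column = cell line identifier, header row = gene symbols.
# The field separator (comma or tab) is auto-detected from the header line.

#' Nine non-silent somatic mutation classes recognized by default
#'
#' MAF-style class names. Silent records are dropped on load because they do
#' not support loss-of-function semantics.
#'
#' @format Character vector of length 9.
#' @export
MUTATION_CLASSES <- c(
  "missense", "nonsense", "frameshift_insertion", "frameshift_deletion",
  "inframe_insertion", "inframe_deletion", "splice_site", "nonstop",
  "start_lost"
)

# MAF Variant_Classification -> canonical class (lower-cased keys).
.maf_class_map <- c(
  missense_mutation = "missense",
  nonsense_mutation = "nonsense",
  frame_shift_ins = "frameshift_insertion",
  frame_shift_del = "frameshift_deletion",
  in_frame_ins = "inframe_insertion",
  in_frame_del = "inframe_deletion",
  splice_site = "splice_site",
  nonstop_mutation = "nonstop",
  translation_start_site = "start_lost",
  start_lost = "start_lost",
  silent = "silent"
)

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop_config(sprintf("empty file: %s", path))
  n_tab <- lengths(regmatches(first, gregexpr("\t", first, fixed = TRUE)))
  n_comma <- lengths(regmatches(first, gregexpr(",", first, fixed = TRUE)))
  if (n_tab >= n_comma && n_tab > 0) "\t" else ","
}

check_unique <- function(ids, what, path) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop_config(sprintf(
      "duplicate %s identifier(s) in %s: %s",
      what, path, paste(dup, collapse = ", ")
    ))
  }
  invisible(ids)
}

#' Read a wide cell-line-by-gene matrix
#'
#' First column holds cell-line identifiers, remaining columns one gene each.
#' Comma or tab separation is auto-detected. Values are numeric; empty fields
#' and `NA` become missing values (flagged, never silently zero).
#'
#' @param path Path to the delimited file.
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` to all values (for raw
#'   rather than pre-transformed inputs). Default `FALSE`.
#' @return Numeric matrix with cell-line rownames and gene colnames.
#' @export
read_matrix <- function(path, log2_transform = FALSE) {
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2) stop_config(sprintf("matrix file needs >= 2 columns: %s", path))
  lines <- as.character(df[[1L]])
  genes <- colnames(df)[-1L]
  check_unique(lines, "cell-line", path)
  check_unique(genes, "gene", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- lines
  if (log2_transform) m <- log2(m + 1)
  m
}

#' Write a wide cell-line-by-gene matrix
#'
#' @param m Numeric matrix with rownames (cell lines) and colnames (genes).
#' @param path Output path; `.tsv` extension selects tab separation.
#' @param id_col Name for the identifier column header.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_col = "cell_line") {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format somatic mutation table
#'
#' Requires columns `cell_line`, `gene`, `mutation_class`; MAF-compatible
#' aliases (`Tumor_Sample_Barcode`, `Hugo_Symbol`, `Variant_Classification`)
#' are accepted, and MAF class names are normalized to the canonical
#' enumeration in [MUTATION_CLASSES]. Silent records are dropped with a
#' message giving the count.
#'
#' @param path Path to the delimited file.
#' @param classes Accepted mutation classes; records with other classes are
#'   kept (validation reports them) so no data is lost silently.
#' @return `data.frame` with columns `cell_line`, `gene`, `mutation_class`.
#' @export
read_mutations <- function(path, classes = MUTATION_CLASSES) {
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  aliases <- c(cell_line = "Tumor_Sample_Barcode", gene = "Hugo_Symbol",
               mutation_class = "Variant_Classification")
  for (want in names(aliases)) {
    if (!want %in% colnames(df)) {
      alt <- aliases[[want]]
      if (alt %in% colnames(df)) {
        colnames(df)[colnames(df) == alt] <- want
      } else {
        stop_config(sprintf("mutation table %s lacks column '%s' (or alias '%s')",
                            path, want, alt))
      }
    }
  }
  df <- df[, c("cell_line", "gene", "mutation_class")]
  df$cell_line <- as.character(df$cell_line)
  df$gene <- as.character(df$gene)
  cls <- as.character(df$mutation_class)
  mapped <- .maf_class_map[tolower(cls)]
  cls <- ifelse(is.na(mapped), cls, mapped)
  df$mutation_class <- cls
  n_silent <- sum(cls == "silent")
  if (n_silent > 0) {
    message(sprintf("read_mutations: dropped %d silent record(s)", n_silent))
    df <- df[cls != "silent", , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read a cell-line-to-tissue annotation table
#'
#' Two columns: cell line identifier and tissue label (header names flexible;
#' the first two columns are used).
#'
#' @param path Path to the delimited file.
#' @return Named character vector: tissue labels named by cell line.
#' @export
read_tissues <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_config(sprintf("tissue table needs 2 columns: %s", path))
  ids <- as.character(df[[1L]])
  check_unique(ids, "cell-line", path)
  stats::setNames(as.character(df[[2L]]), ids)
}

#' Read a symmetric gene-pair set (PPI edges or paralogue pairs)
#'
#' Two-column edge list. Pairs are stored unordered ((A,B) and (B,A) are the
#' same pair); self-pairs are dropped.
#'
#' @param path Path to the delimited file.
#' @return `data.frame` with columns `gene_a`, `gene_b` (canonical order).
#' @export
read_gene_pairs <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_config(sprintf("pair list needs 2 columns: %s", path))
  a <- as.character(df[[1L]]); b <- as.character(df[[2L]])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- unique(data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Read a gene-to-GO-term long table
#'
#' @param path Path to a two-column (gene, go_term) delimited file.
#' @return Named list: gene -> character vector of GO term identifiers.
#' @export
read_go_table <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_config(sprintf("GO table needs 2 columns: %s", path))
  split(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Read a SynLethDB-format gene-pair score table
#'
#' Three columns: `gene_a`, `gene_b`, `score` (confidence in `[0, 1]`).
#'
#' @param path Path to the delimited file.
#' @return `data.frame` with columns `gene_a`, `gene_b`, `score`.
#' @export
read_gold_standard_db <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop_config(sprintf("gold-standard table needs 3 columns: %s", path))
  out <- data.frame(gene_a = as.character(df[[1L]]),
                    gene_b = as.character(df[[2L]]),
                    score = as.numeric(df[[3L]]),
                    stringsAsFactors = FALSE)
  out
}

#' Assemble an aligned multi-omics dataset
#'
#' `config` may be (i) a directory containing the standard file names written
#' by [write_dataset()] (`expression.csv`, `tissues.csv`, and optionally
#' `crispr.csv`, `mutations.tsv`, `protein.csv`, `copy_number.csv`, `go.tsv`,
#' `ppi.tsv`, `paralogues.tsv`), (ii) a YAML file with those keys mapping to
#' paths, or (iii) a named list of paths. Expression and tissue inputs are
#' mandatory.
#'
#' All matrices are aligned to the intersection of their cell-line universes
#' (an empty intersection is fatal); mutation records outside the universe
#' are dropped; cell lines missing from the tissue table receive the
#' reserved label `"unannotated"`. Expression values are used as given
#' (assumed `log2(TPM+1)`-like); set `log2_transform = TRUE` for raw inputs.
#'
#' @param config Directory, YAML path, or named list of file paths.
#' @param log2_transform Apply `log2(x+1)` to the expression matrix.
#' @param min_variance Genes whose expression variance falls below this value
#'   are dropped from the expression matrix (0 disables filtering).
#' @return A `multisep_dataset`: list with elements `expression`, `crispr`,
#'   `mutations`, `tissues`, `annotations`, `protein`, `copy_number`,
#'   `cell_lines`, and an `alignment` report of dropped lines per source.
#' @export
load_dataset <- function(config, log2_transform = FALSE, min_variance = 0) {
  paths <- resolve_dataset_config(config)
  if (is.null(paths$expression) || is.null(paths$tissues)) {
    stop_config("config must name at least 'expression' and 'tissues' inputs")
  }
  expr <- read_matrix(paths$expression, log2_transform = log2_transform)
  if (!all(is.finite(expr))) stop_config("expression matrix contains non-finite values")
  if (min_variance > 0) {
    v <- apply(expr, 2L, stats::var)
    expr <- expr[, v >= min_variance, drop = FALSE]
  }
  crispr <- if (!is.null(paths$crispr)) read_matrix(paths$crispr) else NULL
  protein <- if (!is.null(paths$protein)) read_matrix(paths$protein) else NULL
  cn <- if (!is.null(paths$copy_number)) read_matrix(paths$copy_number) else NULL
  mutations <- if (!is.null(paths$mutations)) read_mutations(paths$mutations) else NULL
  tissues <- read_tissues(paths$tissues)

  universe <- rownames(expr)
  alignment <- list()
  for (nm in c("crispr", "copy_number")) {
    m <- switch(nm, crispr = crispr, copy_number = cn)
    if (!is.null(m)) {
      alignment[[nm]] <- setdiff(universe, rownames(m))
      universe <- intersect(universe, rownames(m))
    }
  }
  if (length(universe) == 0L) {
    stop_config("empty cell-line intersection across expression/CRISPR/copy-number inputs")
  }
  alignment$expression <- setdiff(rownames(expr), universe)
  expr <- expr[universe, , drop = FALSE]
  if (!is.null(crispr)) crispr <- crispr[universe, , drop = FALSE]
  if (!is.null(cn)) cn <- cn[universe, , drop = FALSE]
  if (!is.null(protein)) {
    # protein coverage is a subset in practice; keep covered lines only
    alignment$protein <- setdiff(rownames(protein), universe)
    protein <- protein[intersect(universe, rownames(protein)), , drop = FALSE]
  }
  if (!is.null(mutations)) {
    out <- !(mutations$cell_line %in% universe)
    alignment$mutations <- unique(mutations$cell_line[out])
    mutations <- mutations[!out, , drop = FALSE]
    rownames(mutations) <- NULL
  }
  tiss <- tissues[universe]
  names(tiss) <- universe
  tiss[is.na(tiss)] <- "unannotated"

  annotations <- NULL
  if (!is.null(paths$go) || !is.null(paths$ppi) || !is.null(paths$paralogues)) {
    annotations <- list(
      go_terms = if (!is.null(paths$go)) read_go_table(paths$go) else list(),
      ppi_edges = if (!is.null(paths$ppi)) read_gene_pairs(paths$ppi) else
        data.frame(gene_a = character(), gene_b = character()),
      paralogue_pairs = if (!is.null(paths$paralogues)) read_gene_pairs(paths$paralogues) else
        data.frame(gene_a = character(), gene_b = character())
    )
  }
  structure(list(
    expression = expr, crispr = crispr, mutations = mutations,
    tissues = tiss, annotations = annotations, protein = protein,
    copy_number = cn, cell_lines = universe, alignment = alignment,
    source = paths
  ), class = "multisep_dataset")
}

resolve_dataset_config <- function(config) {
  std <- c(expression = "expression.csv", tissues = "tissues.csv",
           crispr = "crispr.csv", mutations = "mutations.tsv",
           protein = "protein.csv", copy_number = "copy_number.csv",
           go = "go.tsv", ppi = "ppi.tsv", paralogues = "paralogues.tsv")
  if (is.list(config)) return(config)
  if (!is.character(config) || length(config) != 1L) {
    stop_config("config must be a directory, a YAML file, or a named list of paths")
  }
  if (dir.exists(config)) {
    paths <- file.path(config, std)
    names(paths) <- names(std)
    return(as.list(paths[file.exists(paths)]))
  }
  if (file.exists(config)) {
    cfg <- yaml::read_yaml(config)
    base <- dirname(normalizePath(config))
    cfg <- lapply(cfg, function(p) {
      if (is.character(p) && !file.exists(p) && file.exists(file.path(base, p)))
        file.path(base, p) else p
    })
    return(cfg)
  }
  stop_config(sprintf("config not found: %s", config))
}

#' @export
print.multisep_dataset <- function(x, ...) {
  cat("multisep dataset\n")
  cat(sprintf("  cell lines: %d (%d tissue groups)\n",
              length(x$cell_lines), length(unique(x$tissues))))
  cat(sprintf("  expression: %d genes\n", ncol(x$expression)))
  if (!is.null(x$crispr)) cat(sprintf("  CRISPR:     %d genes\n", ncol(x$crispr)))
  if (!is.null(x$mutations)) {
    cat(sprintf("  mutations:  %d records, %d genes\n",
                nrow(x$mutations), length(unique(x$mutations$gene))))
  }
  if (!is.null(x$protein)) {
    cat(sprintf("  protein:    %d genes on %d lines\n",
                ncol(x$protein), nrow(x$protein)))
  }
  if (!is.null(x$copy_number)) cat(sprintf("  copy number: %d genes\n", ncol(x$copy_number)))
  invisible(x)
}

#' Summarize a dataset without modifying it
#'
#' Reports per-source dimensions, missing-value rates, tissue group sizes and
#' the mutation-class frequency table. Unknown mutation-class labels (outside
#' [MUTATION_CLASSES]) trigger a warning naming each label.
#'
#' @param d A `multisep_dataset`.
#' @param classes Recognized mutation classes.
#' @return A list of class `multisep_validation` (counts, NaN rates, tissue
#'   sizes, class frequencies).
#' @export
validate_dataset <- function(d, classes = MUTATION_CLASSES) {
  stopifnot(inherits(d, "multisep_dataset"))
  na_rate <- function(m) if (is.null(m)) NA_real_ else mean(!is.finite(m))
  rep <- list(
    n_cell_lines = length(d$cell_lines),
    n_expression_genes = ncol(d$expression),
    n_crispr_genes = if (is.null(d$crispr)) 0L else ncol(d$crispr),
    n_mutation_records = if (is.null(d$mutations)) 0L else nrow(d$mutations),
    missing_rate = c(expression = na_rate(d$expression),
                     crispr = na_rate(d$crispr),
                     protein = na_rate(d$protein),
                     copy_number = na_rate(d$copy_number)),
    tissue_sizes = sort(table(d$tissues), decreasing = TRUE),
    mutation_class_freq = if (is.null(d$mutations)) table(character()) else
      table(d$mutations$mutation_class)
  )
  if (!is.null(d$mutations)) {
    unknown <- setdiff(unique(d$mutations$mutation_class), classes)
    if (length(unknown) > 0) {
      warning(sprintf("unknown mutation class label(s): %s",
                      paste(unknown, collapse = ", ")), call. = FALSE)
    }
    rep$unknown_classes <- unknown
  }
  structure(rep, class = "multisep_validation")
}

#' @export
print.multisep_validation <- function(x, ...) {
  cat(sprintf("cell lines: %d | expression genes: %d | CRISPR genes: %d | mutation records: %d\n",
              x$n_cell_lines, x$n_expression_genes, x$n_crispr_genes, x$n_mutation_records))
  cat("missing rates:\n"); print(round(x$missing_rate, 4))
  cat(sprintf("tissue groups: %d (sizes %s)\n", length(x$tissue_sizes),
              paste(as.integer(x$tissue_sizes), collapse = ", ")))
  if (length(x$mutation_class_freq) > 0) {
    cat("mutation classes:\n"); print(x$mutation_class_freq)
  }
  invisible(x)
}
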