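# Synthetic DepMap-shaped data with planted structure and a machine-readable
# truth ledger. The generator directly parameterizes every statistical
# assumption the analysis modules exercise: mixture-distributed expression,
# cluster-shifted CERES scores (essential baselines near -1, non-essential
# near 0), cluster-dependent mutation odds (logistic exclusivity), per-gene
# copy-number losses coupled to low expression, and a partially covered
# protein matrix correlated with mRNA.

#' Generate a synthetic cell-line panel with planted dependencies
#'
#' Expression for each gene is drawn from a Gaussian mixture with a planted
#' component count (a configurable fraction of genes is unimodal, so
#' bimodality-gated methods have something to reject). Component means are
#' spaced `separation` within-component standard deviations apart. CRISPR
#' scores sit at an essential (-1) or non-essential (0) baseline with noise;
#' for each planted CRISPR pair the partner's scores are shifted down by
#' `crispr_effect` in the lowest-expression cluster of the mRNA gene
#' (knockout more damaging where the partner is lowly expressed). Mutations
#' are Bernoulli per (line, gene) at `mutation_rate`; for each planted
#' mutation pair the rate is depleted on the logit scale by
#' `exclusivity_strength` inside the partner's lowest-expression cluster.
#' Copy-number losses target each gene's lowest-expression lines; some genes
#' get none or a single loss line so copy-number-dependent methods lose
#' coverage, as in real panels.
#'
#' @param n_lines,n_genes Panel dimensions (at least 20 and 10).
#' @param n_tissues Number of tissue groups (balanced assignment).
#' @param k_choices Planted component counts for multimodal genes.
#' @param unimodal_fraction Fraction of genes drawn from a single Gaussian.
#' @param separation Distance between neighbouring component means, in units
#'   of the within-component standard deviation.
#' @param component_sd Within-component standard deviation (log2 expression
#'   units).
#' @param essential_fraction Fraction of genes with CERES baseline
#'   `essential_baseline`.
#' @param essential_baseline,nonessential_baseline,ceres_sd CERES score
#'   baselines and noise standard deviation.
#' @param n_crispr_pairs,crispr_effect Planted CRISPR dependencies and their
#'   CERES shift.
#' @param n_mutation_pairs,exclusivity_strength Planted mutation-exclusivity
#'   dependencies and their logit-scale depletion.
#' @param n_tissue_specific Number of planted CRISPR pairs whose effect is
#'   confined to a single tissue.
#' @param mutation_rate Marginal per-(line, gene) mutation probability for
#'   background genes.
#' @param hotspot_rate Mutation probability for planted mutation genes
#'   (outside depleted clusters); recurrently mutated cancer genes are the
#'   realistic carriers of mutation dependencies.
#' @param cn_noise_sd,cn_loss_value Copy-number log-ratio noise and loss
#'   level.
#' @param protein_line_coverage,protein_gene_coverage,protein_cor Protein
#'   matrix coverage fractions and target mRNA-protein correlation.
#' @param seed Integer seed; the whole panel is deterministic given the seed.
#' @return List with `dataset` (a `multisep_dataset`) and `truth` (class
#'   `synthetic_truth`): `planted_k`, `planted_crispr_pairs`,
#'   `planted_mutation_pairs`, `null_genes`, `seed`, `params`.
#' @export
generate_dataset <- function(n_lines = 200L, n_genes = 60L, n_tissues = 10L,
                             k_choices = 2:4, unimodal_fraction = 0.3,
                             separation = 6, component_sd = 0.5,
                             essential_fraction = 0.2,
                             essential_baseline = -1,
                             nonessential_baseline = 0, ceres_sd = 0.2,
                             n_crispr_pairs = 5L, crispr_effect = 1.0,
                             n_mutation_pairs = 5L, exclusivity_strength = 4,
                             n_tissue_specific = 0L,
                             mutation_rate = 0.15, hotspot_rate = 0.3,
                             cn_noise_sd = 0.1, cn_loss_value = -1,
                             protein_line_coverage = 0.5,
                             protein_gene_coverage = 0.5, protein_cor = 0.8,
                             seed = 1L) {
  if (n_lines < 20L || n_genes < 10L || n_tissues < 1L) {
    stop_config("need n_lines >= 20, n_genes >= 10, n_tissues >= 1")
  }
  if (crispr_effect < 0 || exclusivity_strength < 0) {
    stop_config("effect sizes must be non-negative")
  }
  lines <- sprintf("CL%04d", seq_len(n_lines))
  genes <- sprintf("G%03d", seq_len(n_genes))
  with_seed(seed, {
    tissue_pool <- sprintf("tissue%02d", seq_len(n_tissues))
    tissues <- stats::setNames(sample(rep_len(tissue_pool, n_lines)), lines)

    # expression + per-gene planted component membership
    planted_k <- stats::setNames(integer(n_genes), genes)
    comp_of <- matrix(1L, n_lines, n_genes, dimnames = list(lines, genes))
    expr <- matrix(NA_real_, n_lines, n_genes, dimnames = list(lines, genes))
    n_uni <- round(unimodal_fraction * n_genes)
    uni <- if (n_uni > 0) sample(genes, n_uni) else character()
    for (g in genes) {
      if (g %in% uni) {
        planted_k[g] <- 1L
        expr[, g] <- stats::rnorm(n_lines, stats::runif(1, 2, 10), component_sd)
      } else {
        k <- if (length(k_choices) == 1L) k_choices else sample(k_choices, 1L)
        planted_k[g] <- k
        w <- stats::runif(k, 0.5, 1.5); w <- w / sum(w)
        base <- stats::runif(1, 2, 6)
        mus <- base + (seq_len(k) - 1L) * separation * component_sd
        comp <- sample.int(k, n_lines, replace = TRUE, prob = w)
        comp_of[, g] <- comp
        expr[, g] <- stats::rnorm(n_lines, mus[comp], component_sd)
      }
    }
    multimodal <- setdiff(genes, uni)

    # planted pairs: mRNA partner must be multimodal so "lowest cluster" is real
    pick_pairs <- function(n, used) {
      out <- data.frame(mrna_gene = character(), partner = character(),
                        stringsAsFactors = FALSE)
      while (nrow(out) < n) {
        a <- sample(multimodal, 1L)
        b <- sample(setdiff(genes, a), 1L)
        key <- pair_key(a, b)
        if (key %in% used) next
        used <- c(used, key)
        out <- rbind(out, data.frame(mrna_gene = a, partner = b,
                                     stringsAsFactors = FALSE))
      }
      list(pairs = out, used = used)
    }
    used <- character()
    n_cp <- n_crispr_pairs + n_tissue_specific
    cp <- if (n_cp > 0) pick_pairs(n_cp, used) else
      list(pairs = data.frame(mrna_gene = character(), partner = character()),
           used = used)
    used <- cp$used
    mp <- if (n_mutation_pairs > 0) pick_pairs(n_mutation_pairs, used) else
      list(pairs = data.frame(mrna_gene = character(), partner = character()),
           used = used)

    crispr_pairs <- cp$pairs
    crispr_pairs <- if (nrow(crispr_pairs) > 0) data.frame(
      mrna_gene = crispr_pairs$mrna_gene, crispr_gene = crispr_pairs$partner,
      effect_size = crispr_effect,
      tissue = c(rep("all", n_crispr_pairs),
                 if (n_tissue_specific > 0) sample(tissue_pool, n_tissue_specific,
                                                   replace = TRUE)),
      stringsAsFactors = FALSE) else data.frame(
      mrna_gene = character(), crispr_gene = character(),
      effect_size = numeric(), tissue = character(), stringsAsFactors = FALSE)
    mutation_pairs <- if (nrow(mp$pairs) > 0) data.frame(
      mrna_gene = mp$pairs$mrna_gene, mutation_gene = mp$pairs$partner,
      exclusivity_strength = exclusivity_strength, stringsAsFactors = FALSE
    ) else data.frame(mrna_gene = character(), mutation_gene = character(),
                      exclusivity_strength = numeric(), stringsAsFactors = FALSE)

    # CRISPR scores
    essential <- sample(genes, round(essential_fraction * n_genes))
    baseline <- ifelse(genes %in% essential, essential_baseline,
                       nonessential_baseline)
    crispr <- matrix(stats::rnorm(n_lines * n_genes, rep(baseline, each = n_lines),
                                  ceres_sd),
                     n_lines, n_genes, dimnames = list(lines, genes))
    for (i in seq_len(nrow(crispr_pairs))) {
      a <- crispr_pairs$mrna_gene[i]; b <- crispr_pairs$crispr_gene[i]
      in_low <- comp_of[, a] == 1L
      if (crispr_pairs$tissue[i] != "all") {
        in_low <- in_low & tissues[lines] == crispr_pairs$tissue[i]
      }
      crispr[in_low, b] <- crispr[in_low, b] - crispr_pairs$effect_size[i]
    }

    # mutations (logistic exclusivity for planted pairs); planted mutation
    # genes are recurrently mutated "hotspot" genes, as the canonical
    # dependency examples in this field are
    rec_line <- character(); rec_gene <- character(); rec_class <- character()
    class_probs <- c(missense = 0.55, nonsense = 0.10,
                     frameshift_deletion = 0.08, frameshift_insertion = 0.06,
                     splice_site = 0.08, inframe_deletion = 0.04,
                     inframe_insertion = 0.03, nonstop = 0.03,
                     start_lost = 0.03)
    for (g in genes) {
      base_rate <- if (g %in% mutation_pairs$mutation_gene) hotspot_rate else mutation_rate
      lp <- rep(stats::qlogis(base_rate), n_lines)
      hit <- mutation_pairs$mutation_gene == g
      for (i in which(hit)) {
        a <- mutation_pairs$mrna_gene[i]
        lp[comp_of[, a] == 1L] <- lp[comp_of[, a] == 1L] -
          mutation_pairs$exclusivity_strength[i]
      }
      mut <- stats::runif(n_lines) < stats::plogis(lp)
      if (any(mut)) {
        rec_line <- c(rec_line, lines[mut])
        rec_gene <- c(rec_gene, rep(g, sum(mut)))
        rec_class <- c(rec_class, sample(names(class_probs), sum(mut),
                                         replace = TRUE, prob = class_probs))
      }
    }
    mutations <- data.frame(cell_line = rec_line, gene = rec_gene,
                            mutation_class = rec_class, stringsAsFactors = FALSE)

    # copy number: loss lines are each gene's lowest-expression lines, so a
    # loss call co-occurs with low expression as in real deletions
    max_loss <- max(2L, floor(0.1 * n_lines))
    cn <- matrix(stats::rnorm(n_lines * n_genes, 0, cn_noise_sd),
                 n_lines, n_genes, dimnames = list(lines, genes))
    regime <- sample(c("none", "single", "common"), n_genes, replace = TRUE,
                     prob = c(0.4, 0.2, 0.4))
    for (j in seq_len(n_genes)) {
      n_loss <- switch(regime[j], none = 0L, single = 1L,
                       common = sample(5:max_loss, 1L))
      if (n_loss == 0L) next
      lowest <- order(expr[, j])[seq_len(n_loss)]
      cn[lowest, j] <- cn_loss_value + stats::rnorm(n_loss, 0, cn_noise_sd)
    }

    # protein: partial coverage, target mRNA-protein correlation
    p_lines <- sort(sample(lines, round(protein_line_coverage * n_lines)))
    p_genes <- sort(sample(genes, round(protein_gene_coverage * n_genes)))
    protein <- matrix(NA_real_, length(p_lines), length(p_genes),
                      dimnames = list(p_lines, p_genes))
    for (g in p_genes) {
      z <- scale(expr[p_lines, g])[, 1L]
      protein[, g] <- protein_cor * z +
        sqrt(1 - protein_cor^2) * stats::rnorm(length(p_lines))
    }

    # annotations: planted pairs share a GO term and a PPI edge; background
    # terms/edges are random
    terms <- sprintf("GO:%07d", seq_len(20L))
    go_terms <- lapply(stats::setNames(genes, genes), function(g) {
      sample(terms, sample(1:4, 1L))
    })
    planted_all <- rbind(
      data.frame(gene_a = crispr_pairs$mrna_gene, gene_b = crispr_pairs$crispr_gene,
                 stringsAsFactors = FALSE),
      data.frame(gene_a = mutation_pairs$mrna_gene, gene_b = mutation_pairs$mutation_gene,
                 stringsAsFactors = FALSE))
    for (i in seq_len(nrow(planted_all))) {
      shared <- sample(terms, 1L)
      go_terms[[planted_all$gene_a[i]]] <-
        union(go_terms[[planted_all$gene_a[i]]], shared)
      go_terms[[planted_all$gene_b[i]]] <-
        union(go_terms[[planted_all$gene_b[i]]], shared)
    }
    rand_pairs <- function(n) {
      a <- sample(genes, n, replace = TRUE)
      b <- sample(genes, n, replace = TRUE)
      keep <- a != b
      unique(data.frame(gene_a = pmin(a[keep], b[keep]),
                        gene_b = pmax(a[keep], b[keep]),
                        stringsAsFactors = FALSE))
    }
    ppi <- unique(rbind(planted_all[planted_all$gene_a != planted_all$gene_b, ],
                        rand_pairs(n_genes)))
    swap <- ppi$gene_a > ppi$gene_b
    tmp <- ppi$gene_a[swap]; ppi$gene_a[swap] <- ppi$gene_b[swap]; ppi$gene_b[swap] <- tmp
    ppi <- unique(ppi)
    paralogues <- rand_pairs(max(3L, n_genes %/% 20L))

    planted_genes <- unique(c(planted_all$gene_a, planted_all$gene_b))
    truth <- structure(list(
      planted_k = planted_k,
      planted_crispr_pairs = crispr_pairs,
      planted_mutation_pairs = mutation_pairs,
      null_genes = setdiff(genes, planted_genes),
      essential_genes = sort(essential),
      component_of = comp_of,
      seed = as.integer(seed),
      params = list(n_lines = n_lines, n_genes = n_genes,
                    n_tissues = n_tissues, separation = separation,
                    component_sd = component_sd, ceres_sd = ceres_sd,
                    mutation_rate = mutation_rate,
                    crispr_effect = crispr_effect,
                    exclusivity_strength = exclusivity_strength)
    ), class = "synthetic_truth")

    dataset <- structure(list(
      expression = expr, crispr = crispr, mutations = mutations,
      tissues = tissues[lines],
      annotations = list(go_terms = go_terms, ppi_edges = ppi,
                         paralogue_pairs = paralogues),
      protein = protein, copy_number = cn, cell_lines = lines,
      alignment = list(), source = list(generator = "generate_dataset")
    ), class = "multisep_dataset")
    list(dataset = dataset, truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic truth (seed %d): %d genes, k table:\n",
              x$seed, length(x$planted_k)))
  print(table(x$planted_k))
  cat(sprintf("planted CRISPR pairs: %d | planted mutation pairs: %d | null genes: %d\n",
              nrow(x$planted_crispr_pairs), nrow(x$planted_mutation_pairs),
              length(x$null_genes)))
  invisible(x)
}

#' Named generator presets
#'
#' `"default"` is the standard planted-dependency study; `"null"` plants no
#' dependencies and uses bimodal-only expression (so every tested pair has a
#' single neighbouring-cluster comparison, isolating test calibration);
#' `"tissue-specific"` adds two pairs whose CRISPR effect exists in one
#' tissue only.
#'
#' @param preset One of `"default"`, `"null"`, `"tissue-specific"`.
#' @param seed Integer seed.
#' @param ... Overrides passed to [generate_dataset()].
#' @return As [generate_dataset()].
#' @export
generate_preset <- function(preset = c("default", "null", "tissue-specific"),
                            seed = 1L, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    "default" = list(),
    "null" = list(n_genes = 50L, k_choices = 2L, unimodal_fraction = 0,
                  n_crispr_pairs = 0L, n_mutation_pairs = 0L),
    "tissue-specific" = list(n_tissue_specific = 2L))
  args <- utils::modifyList(args, list(...))
  do.call(generate_dataset, c(args, list(seed = seed)))
}

#' Write a synthetic dataset (and its truth ledger) as delimited text
#'
#' File names match what [load_dataset()] expects from a directory config:
#' `expression.csv`, `crispr.csv`, `mutations.tsv`, `tissues.csv`,
#' `protein.csv`, `copy_number.csv`, `go.tsv`, `ppi.tsv`, `paralogues.tsv`,
#' plus `truth.json`.
#'
#' @param sim List from [generate_dataset()] (or a bare `multisep_dataset`).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  d <- if (inherits(sim, "multisep_dataset")) sim else sim$dataset
  truth <- if (inherits(sim, "multisep_dataset")) NULL else sim$truth
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(d$expression, file.path(dir, "expression.csv"))
  if (!is.null(d$crispr)) write_matrix(d$crispr, file.path(dir, "crispr.csv"))
  if (!is.null(d$copy_number)) write_matrix(d$copy_number, file.path(dir, "copy_number.csv"))
  if (!is.null(d$protein)) write_matrix(d$protein, file.path(dir, "protein.csv"))
  utils::write.table(
    data.frame(cell_line = names(d$tissues), tissue = unname(d$tissues)),
    file.path(dir, "tissues.csv"), sep = ",", quote = FALSE, row.names = FALSE)
  if (!is.null(d$mutations)) {
    utils::write.table(d$mutations, file.path(dir, "mutations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(d$annotations)) {
    go <- d$annotations$go_terms
    go_df <- data.frame(gene = rep(names(go), lengths(go)),
                        go_term = unlist(go, use.names = FALSE))
    utils::write.table(go_df, file.path(dir, "go.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(d$annotations$ppi_edges, file.path(dir, "ppi.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(d$annotations$paralogue_pairs,
                       file.path(dir, "paralogues.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(truth)) {
    tr <- truth
    tr$component_of <- NULL  # large and reconstructible; keep the ledger lean
    tr$planted_k <- as.list(tr$planted_k)
    jsonlite::write_json(unclass(tr), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Turn the truth ledger into a gold standard and SynLethDB-format table
#'
#' Planted pairs become database positives with confidence scores above 0.7;
#' negatives are resampled from unplanted gene pairs until positives make up
#' `prevalence` of the emitted gold standard.
#'
#' @param truth A `synthetic_truth`.
#' @param prevalence Positive fraction of the gold standard (0.5 = balanced).
#' @param seed Integer seed.
#' @param pair_type `"all"`, `"crispr"` or `"mutation"`: which planted pairs
#'   become positives.
#' @return List: `gold` (a `gold_standard`), `db` (`gene_a`, `gene_b`,
#'   `score` — the SynLethDB-format table of positives).
#' @export
truth_to_gold_standard <- function(truth, prevalence = 0.5, seed = 1L,
                                   pair_type = c("all", "crispr", "mutation")) {
  stopifnot(inherits(truth, "synthetic_truth"))
  pair_type <- match.arg(pair_type)
  pos <- switch(pair_type,
    crispr = data.frame(gene_a = truth$planted_crispr_pairs$mrna_gene,
                        gene_b = truth$planted_crispr_pairs$crispr_gene,
                        stringsAsFactors = FALSE),
    mutation = data.frame(gene_a = truth$planted_mutation_pairs$mrna_gene,
                          gene_b = truth$planted_mutation_pairs$mutation_gene,
                          stringsAsFactors = FALSE),
    all = rbind(
      data.frame(gene_a = truth$planted_crispr_pairs$mrna_gene,
                 gene_b = truth$planted_crispr_pairs$crispr_gene,
                 stringsAsFactors = FALSE),
      data.frame(gene_a = truth$planted_mutation_pairs$mrna_gene,
                 gene_b = truth$planted_mutation_pairs$mutation_gene,
                 stringsAsFactors = FALSE)))
  pos <- pos[!duplicated(pair_key(pos$gene_a, pos$gene_b)), , drop = FALSE]
  n_pos <- nrow(pos)
  if (n_pos == 0L) stop_config("truth contains no planted pairs")
  if (!(prevalence > 0 && prevalence <= 1)) stop_config("prevalence must be in (0, 1]")
  total <- round(n_pos / prevalence)
  n_neg <- total - n_pos
  genes <- names(truth$planted_k)
  n_possible <- choose(length(genes), 2) - n_pos
  if (n_neg > n_possible) {
    stop_config(sprintf("prevalence %.4g needs %d negatives but only %d unplanted pairs exist",
                        prevalence, n_neg, n_possible))
  }
  pos_keys <- pair_key(pos$gene_a, pos$gene_b)
  with_seed(seed, {
    db <- data.frame(gene_a = pos$gene_a, gene_b = pos$gene_b,
                     score = stats::runif(n_pos, 0.75, 0.95),
                     stringsAsFactors = FALSE)
    neg_keys <- character(); guard <- 0L
    while (length(neg_keys) < n_neg && guard < 100L) {
      a <- sample(genes, n_neg * 2L, replace = TRUE)
      b <- sample(genes, n_neg * 2L, replace = TRUE)
      keep <- a != b
      ks <- unique(pair_key(a[keep], b[keep]))
      neg_keys <- unique(c(neg_keys, setdiff(ks, pos_keys)))
      guard <- guard + 1L
    }
    neg_keys <- neg_keys[seq_len(n_neg)]
    split_keys <- strsplit(neg_keys, "\r", fixed = TRUE)
    pairs <- rbind(
      data.frame(gene_a = pos$gene_a, gene_b = pos$gene_b, label = "positive",
                 stringsAsFactors = FALSE),
      data.frame(gene_a = vapply(split_keys, `[`, "", 1L),
                 gene_b = vapply(split_keys, `[`, "", 2L),
                 label = "negative", stringsAsFactors = FALSE))
    rownames(pairs) <- NULL
    gold <- structure(list(pairs = pairs, positive_threshold = 0.7,
                           negative_source = "resampled",
                           seed = as.integer(seed),
                           balance = n_pos / max(n_neg, 1L)),
                      class = "gold_standard")
    list(gold = gold, db = db)
  })
}
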