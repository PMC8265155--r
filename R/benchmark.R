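# Benchmarking: gold standards from SynLethDB-format score tables, AROC with
# a paired DeLong comparison, and FDR estimation under configurable class
# prevalence. AROC is computed in its Mann-Whitney form (probability a random
# positive outranks a random negative, ties at half weight).

#' Ranking scores from a scan results table
#'
#' Converts a (possibly unfiltered) scan table to a named score vector keyed
#' by unordered gene pair, using `-log10(p)` — the package's ranking score
#' for benchmarking. When a pair occurs several times (both orientations,
#' several tissues, or both workflows) the best score is kept.
#'
#' @param results Scan results table with a `p_value` column.
#' @return Named numeric vector; names are canonical pair keys (see
#'   [score_key()]).
#' @export
pair_scores <- function(results) {
  cols <- result_gene_columns(results)
  p <- pmax(results$p_value, .Machine$double.xmin)
  sc <- -log10(p)
  keys <- pair_key(results[[cols[1L]]], results[[cols[2L]]])
  out <- tapply(sc, keys, max)
  stats::setNames(as.numeric(out), names(out))
}

#' Canonical unordered-pair key
#'
#' @param a,b Gene symbols.
#' @return Character key, identical for (a,b) and (b,a).
#' @export
score_key <- function(a, b) pair_key(a, b)

#' Merge score vectors from several workflows
#'
#' @param ... Named score vectors (as from [pair_scores()]).
#' @return One named vector; overlapping pairs keep their maximum score.
#' @export
combine_scores <- function(...) {
  vs <- list(...)
  all <- unlist(vs)
  out <- tapply(all, names(all), max)
  stats::setNames(as.numeric(out), names(out))
}

#' Build a labelled gold standard from a SynLethDB-format table
#'
#' Positives are database pairs with `score > threshold` for which a
#' prediction exists. Negatives are resampled uniformly from the predicted
#' pairs absent from the database at any score (so negatives are evaluable by
#' construction and carry no database evidence), to an equal count
#' (`balanced = TRUE`) or `round(n_pos * neg_ratio)`.
#'
#' @param db `data.frame` with `gene_a`, `gene_b`, `score`.
#' @param threshold Positive-confidence cutoff (e.g. 0.7 high, 0.1 low).
#' @param predictions Named score vector ([pair_scores()]) or a `data.frame`
#'   with `gene_a`, `gene_b`, `score`.
#' @param balanced Equal numbers of positives and negatives.
#' @param neg_ratio Negatives per positive when `balanced = FALSE`.
#' @param seed Seed controlling the negative resample.
#' @return List of class `gold_standard`: `pairs` (`gene_a`, `gene_b`,
#'   `label`), `positive_threshold`, `negative_source`, `seed`, `balance`.
#' @export
build_gold_standard <- function(db, threshold, predictions, balanced = TRUE,
                                neg_ratio = 1, seed = 1L) {
  if (nrow(db) == 0L) stop_empty_gold("gold-standard database is empty")
  if (is.data.frame(predictions)) {
    predictions <- stats::setNames(predictions$score,
                                   pair_key(predictions$gene_a, predictions$gene_b))
  }
  if (length(predictions) == 0L) stop_empty_gold("prediction set is empty")
  db_keys <- pair_key(db$gene_a, db$gene_b)
  pos <- db[db$score > threshold & db_keys %in% names(predictions), , drop = FALSE]
  pos <- pos[!duplicated(pair_key(pos$gene_a, pos$gene_b)), , drop = FALSE]
  if (nrow(pos) == 0L) {
    stop_empty_gold(sprintf(
      "no database pair above score %.3g has a prediction", threshold))
  }
  candidates <- setdiff(names(predictions), db_keys)
  n_neg <- if (balanced) nrow(pos) else round(nrow(pos) * neg_ratio)
  if (length(candidates) < n_neg) {
    stop_empty_gold(sprintf(
      "only %d candidate negative pairs available, need %d",
      length(candidates), n_neg))
  }
  neg_keys <- with_seed(seed, sample(candidates, n_neg))
  split_keys <- strsplit(neg_keys, "\r", fixed = TRUE)
  neg <- data.frame(gene_a = vapply(split_keys, `[`, "", 1L),
                    gene_b = vapply(split_keys, `[`, "", 2L),
                    stringsAsFactors = FALSE)
  pairs <- rbind(
    data.frame(gene_a = pos$gene_a, gene_b = pos$gene_b, label = "positive",
               stringsAsFactors = FALSE),
    data.frame(gene_a = neg$gene_a, gene_b = neg$gene_b, label = "negative",
               stringsAsFactors = FALSE))
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, positive_threshold = threshold,
                 negative_source = "resampled", seed = as.integer(seed),
                 balance = nrow(pos) / n_neg),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  tab <- table(x$pairs$label)
  cat(sprintf("gold standard: %d positives (db score > %.3g), %d resampled negatives (seed %d)\n",
              tab[["positive"]], x$positive_threshold, tab[["negative"]], x$seed))
  invisible(x)
}

gold_scores <- function(scores, gold) {
  keys <- pair_key(gold$pairs$gene_a, gold$pairs$gene_b)
  missing <- keys[!keys %in% names(scores)]
  if (length(missing) > 0) {
    stop_value(sprintf("missing scores for %d gold pair(s): %s",
                       length(missing),
                       paste(gsub("\r", "/", utils::head(missing, 5)), collapse = ", ")))
  }
  list(s = unname(scores[keys]), y = gold$pairs$label == "positive")
}

# AROC in Mann-Whitney form; ties counted at half weight.
auroc_mw <- function(s, y) {
  m <- sum(y); n <- sum(!y)
  if (m == 0L || n == 0L) stop_value("need both positive and negative labels")
  r <- rank(s)
  (sum(r[y]) - m * (m + 1) / 2) / (m * n)
}

#' ROC curve and AROC for a scored gold standard
#'
#' AROC equals the normalized Mann-Whitney U statistic (ties at half weight);
#' ROC points are emitted at every distinct score threshold.
#'
#' @param scores Named score vector covering every gold pair.
#' @param gold A `gold_standard`.
#' @param method Label recorded in the result.
#' @return List of class `multisep_benchmark`: `method`, `n_pairs`, `auroc`,
#'   `roc_points` (`threshold`, `fpr`, `tpr`), `prevalence`.
#' @export
compute_roc <- function(scores, gold, method = "multisep") {
  gs <- gold_scores(scores, gold)
  s <- gs$s; y <- gs$y
  auc <- auroc_mw(s, y)
  o <- order(s, decreasing = TRUE)
  s_o <- s[o]; y_o <- y[o]
  grp <- !duplicated(s_o, fromLast = TRUE)  # last row of each tie block
  tp <- cumsum(y_o)[grp]; fp <- cumsum(!y_o)[grp]
  roc <- data.frame(threshold = c(Inf, s_o[grp]),
                    fpr = c(0, fp / sum(!y)),
                    tpr = c(0, tp / sum(y)))
  structure(list(method = method, n_pairs = length(s), auroc = auc,
                 roc_points = roc, prevalence = mean(y)),
            class = "multisep_benchmark")
}

#' @export
print.multisep_benchmark <- function(x, ...) {
  cat(sprintf("%s: AROC = %.4f over %d pairs (prevalence %.3f)\n",
              x$method, x$auroc, x$n_pairs, x$prevalence))
  invisible(x)
}

#' Plot a benchmark ROC curve
#'
#' @param x A `multisep_benchmark`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.multisep_benchmark <- function(x, ...) {
  graphics::plot(x$roc_points$fpr, x$roc_points$tpr, type = "s",
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = sprintf("%s (AROC %.3f)", x$method, x$auroc),
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

# DeLong placement components for one score vector.
delong_placements <- function(s, y) {
  pos <- s[y]; neg <- s[!y]
  m <- length(pos); n <- length(neg)
  psi <- function(x, yv) (sum(x > yv) + 0.5 * sum(x == yv))
  v10 <- vapply(pos, function(x) psi(x, neg) / n, numeric(1))
  v01 <- vapply(neg, function(yv) psi(pos, yv) / m, numeric(1))
  list(theta = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' Paired comparison of two AROCs (DeLong test)
#'
#' Two-tailed DeLong test for the difference between the AROCs of two score
#' sets over the same gold standard. A bootstrap alternative (resampling
#' pairs with replacement and comparing the AROC difference to zero) is
#' available as a cross-check.
#'
#' @param scores_a,scores_b Named score vectors covering every gold pair.
#' @param gold A `gold_standard`.
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return List: `auroc_a`, `auroc_b`, `delta`, `z` (DeLong only), `p`.
#' @export
compare_aurocs <- function(scores_a, scores_b, gold,
                           method = c("delong", "bootstrap"),
                           n_boot = 2000L, seed = 1L) {
  method <- match.arg(method)
  ga <- gold_scores(scores_a, gold)
  gb <- gold_scores(scores_b, gold)
  if (!identical(ga$y, gb$y)) stop_value("score sets cover different gold pairs")
  y <- ga$y
  if (method == "delong") {
    pa <- delong_placements(ga$s, y)
    pb <- delong_placements(gb$s, y)
    s10 <- stats::cov(cbind(pa$v10, pb$v10))
    s01 <- stats::cov(cbind(pa$v01, pb$v01))
    v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$m +
         (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n
    delta <- pa$theta - pb$theta
    if (v <= .Machine$double.eps) {
      z <- if (abs(delta) < .Machine$double.eps^0.5) 0 else sign(delta) * Inf
    } else {
      z <- delta / sqrt(v)
    }
    p <- 2 * stats::pnorm(-abs(z))
    return(list(auroc_a = pa$theta, auroc_b = pb$theta, delta = delta,
                z = z, p = p, method = "delong"))
  }
  aa <- auroc_mw(ga$s, y); ab <- auroc_mw(gb$s, y)
  delta <- aa - ab
  idx_all <- seq_along(y)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    idx <- sample(idx_all, replace = TRUE)
    yy <- y[idx]
    if (!any(yy) || all(yy)) return(NA_real_)
    auroc_mw(ga$s[idx], yy) - auroc_mw(gb$s[idx], yy)
  }, numeric(1)))
  boots <- boots[is.finite(boots)]
  # two-tailed bootstrap p for H0: delta = 0, from the resampled distribution
  p <- 2 * min(mean(boots <= 0) + 0.5 / length(boots),
               mean(boots >= 0) + 0.5 / length(boots))
  list(auroc_a = aa, auroc_b = ab, delta = delta, p = min(p, 1),
       method = "bootstrap", n_boot = length(boots))
}

#' Estimate FDR at a score threshold under a given class prevalence
#'
#' Gold standards are often balanced while the real prevalence of genetic
#' dependencies is low; this re-expresses the false discovery rate at a
#' chosen prevalence. `"reweight"` (default, deterministic) computes
#' `FDR = FPR (1 - prev) / (FPR (1 - prev) + TPR prev)` from the empirical
#' true/false positive rates at the threshold. `"resample"` reconstructs a
#' dataset at the requested prevalence by resampling labelled pairs and
#' counts false discoveries directly.
#'
#' @param scores Named score vector covering every gold pair.
#' @param gold A `gold_standard`.
#' @param score_threshold Predictions with `score > score_threshold` are
#'   called positive.
#' @param prevalence Positive-class proportion in `(0, 1)`; default 0.0375.
#' @param method `"reweight"` or `"resample"`.
#' @param n_resample Size of the resampled dataset.
#' @param seed Seed for resampling.
#' @return FDR in `[0, 1]`, or `NA` (with a warning) when nothing exceeds
#'   the threshold.
#' @export
estimate_fdr <- function(scores, gold, score_threshold, prevalence = 0.0375,
                         method = c("reweight", "resample"),
                         n_resample = 20000L, seed = 1L) {
  method <- match.arg(method)
  if (!(prevalence > 0 && prevalence < 1)) stop_value("prevalence must be in (0, 1)")
  gs <- gold_scores(scores, gold)
  s <- gs$s; y <- gs$y
  if (method == "reweight") {
    tpr <- mean(s[y] > score_threshold)
    fpr <- mean(s[!y] > score_threshold)
    denom <- fpr * (1 - prevalence) + tpr * prevalence
    if (denom == 0) {
      warning("no pairs called positive at this threshold; FDR undefined", call. = FALSE)
      return(NA_real_)
    }
    return(fpr * (1 - prevalence) / denom)
  }
  n_pos <- round(n_resample * prevalence)
  n_neg <- n_resample - n_pos
  with_seed(seed, {
    sp <- sample(s[y], n_pos, replace = TRUE)
    sn <- sample(s[!y], n_neg, replace = TRUE)
    tp <- sum(sp > score_threshold); fp <- sum(sn > score_threshold)
    if (tp + fp == 0) {
      warning("no pairs called positive at this threshold; FDR undefined", call. = FALSE)
      return(NA_real_)
    }
    fp / (tp + fp)
  })
}
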