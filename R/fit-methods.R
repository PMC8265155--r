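# S3 methods for the per-gene mixture fit.

#' @export
print.multisep_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit%s: k = %d over %d cell lines\n",
              if (is.na(x$gene)) "" else sprintf(" for %s", x$gene),
              x$k, x$n_cells))
  tab <- rbind(mean = x$means, sd = sqrt(x$variances), weight = x$weights,
               n = as.numeric(tabulate(x$assignments, x$k)))
  colnames(tab) <- paste0("cluster", seq_len(x$k))
  print(round(tab, 4))
  invisible(x)
}

#' @export
summary.multisep_fit <- function(object, ...) {
  structure(list(
    gene = object$gene, k = object$k, n_cells = object$n_cells,
    components = data.frame(
      cluster = seq_len(object$k), mean = object$means,
      sd = sqrt(object$variances), weight = object$weights,
      n = tabulate(object$assignments, object$k)),
    bic_by_k = object$bic_by_k, loglik = object$loglik
  ), class = "summary.multisep_fit")
}

#' @export
print.summary.multisep_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit%s\n",
              if (is.na(x$gene)) "" else sprintf(" for %s", x$gene)))
  cat(sprintf("  n = %d, selected k = %d, logLik = %.3f\n",
              x$n_cells, x$k, x$loglik))
  print(x$components, row.names = FALSE, digits = 4)
  cat("BIC by k (lower is better):\n")
  print(round(x$bic_by_k, 2))
  invisible(x)
}

#' @export
coef.multisep_fit <- function(object, ...) {
  list(means = object$means, variances = object$variances,
       weights = object$weights)
}

#' @export
logLik.multisep_fit <- function(object, ...) {
  structure(object$loglik, df = 3 * object$k - 1, nobs = object$n_cells,
            class = "logLik")
}

#' Cluster membership for new expression values
#'
#' @param object A `multisep_fit`.
#' @param newdata Numeric vector of expression values; defaults to the
#'   training values.
#' @param type `"cluster"` for hard assignments, `"posterior"` for the full
#'   membership probability matrix.
#' @param ... Unused.
#' @return Integer vector of cluster indices, or an n-by-k posterior matrix.
#' @export
predict.multisep_fit <- function(object, newdata = NULL,
                                 type = c("cluster", "posterior"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$data else newdata
  ld <- log_component_density(x, object$means, object$variances, object$weights)
  post <- exp(ld - log_row_sum_exp(ld))
  rownames(post) <- names(x)
  if (type == "posterior") return(post)
  stats::setNames(max.col(post, ties.method = "first"), names(x))
}

#' @export
fitted.multisep_fit <- function(object, ...) {
  stats::setNames(object$means[object$assignments], names(object$assignments))
}

#' @export
residuals.multisep_fit <- function(object, ...) {
  object$data - fitted(object)
}

#' Draw new expression values from a fitted mixture
#'
#' @param object A `multisep_fit`.
#' @param nsim Number of draws per replicate.
#' @param seed Integer seed (RNG state restored afterwards).
#' @param ... Unused.
#' @return Numeric vector of `nsim` draws with attribute `component`.
#' @export
simulate.multisep_fit <- function(object, nsim = object$n_cells, seed = 1L, ...) {
  with_seed(seed, {
    comp <- sample.int(object$k, nsim, replace = TRUE, prob = object$weights)
    x <- stats::rnorm(nsim, object$means[comp], sqrt(object$variances[comp]))
    attr(x, "component") <- comp
    x
  })
}

#' Plot a fitted expression mixture
#'
#' Histogram of the expression values overlaid with the fitted component
#' densities and the overall mixture density.
#'
#' @param x A `multisep_fit`.
#' @param breaks Histogram breaks (passed to [graphics::hist()]).
#' @param ... Further arguments passed to [graphics::hist()].
#' @export
plot.multisep_fit <- function(x, breaks = 30, ...) {
  h <- graphics::hist(x$data, breaks = breaks, freq = FALSE,
                      main = if (is.na(x$gene)) "expression mixture" else x$gene,
                      xlab = "expression", ...)
  grid <- seq(min(x$data), max(x$data), length.out = 400)
  total <- rep(0, length(grid))
  for (j in seq_len(x$k)) {
    dj <- x$weights[j] * stats::dnorm(grid, x$means[j], sqrt(x$variances[j]))
    graphics::lines(grid, dj, col = j + 1, lty = 2)
    total <- total + dj
  }
  graphics::lines(grid, total, lwd = 2)
  invisible(h)
}
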