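#' @export
print.re_fit <- function(x, digits = 4, ...) {
  cat("Random-effects meta-analysis fit (REML)\n")
  if (!x$converged) {
    cat("  did not converge (k =", x$k, ")\n")
    return(invisible(x))
  }
  cat(sprintf("  k = %d contrasts\n", x$k))
  cat(sprintf("  pooled Log2FC = %.*f  (SE %.*f, 95%% CI [%.*f, %.*f])\n",
              digits, x$mu_hat, digits, x$se_mu, digits, x$ci_low,
              digits, x$ci_high))
  cat(sprintf("  z = %.*f, p = %.3g\n", digits, x$z, x$p))
  cat(sprintf("  tau^2 = %.*f, Q = %.*f, I^2 = %.1f%%\n",
              digits, x$tau2, digits, x$Q, x$I2))
  invisible(x)
}

#' @export
coef.re_fit <- function(object, ...) c(mu = object$mu_hat)

#' @export
confint.re_fit <- function(object, parm, level = 0.95, ...) {
  crit <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(c(object$mu_hat - crit * object$se_mu,
                object$mu_hat + crit * object$se_mu), nrow = 1,
              dimnames = list("mu", sprintf("%g %%",
                                            100 * c((1 - level) / 2,
                                                    1 - (1 - level) / 2))))
  m
}

#' Forest plot of a single random-effects fit
#'
#' Per-contrast log2 fold changes with 95 percent Wald whiskers and the
#' pooled random-effects summary at the bottom.
#'
#' @param x an \code{re_fit}.
#' @param ... passed to \code{plot.default}.
#' @export
plot.re_fit <- function(x, ...) {
  crit <- 1.959964
  labs <- if (is.null(x$labels)) paste("contrast", seq_len(x$k)) else x$labels
  y <- c(x$yi, x$mu_hat)
  lo <- c(x$yi - crit * sqrt(x$vi), x$ci_low)
  hi <- c(x$yi + crit * sqrt(x$vi), x$ci_high)
  labs <- c(labs, "RE Model")
  n <- length(y)
  pos <- rev(seq_len(n))
  op <- graphics::par(mar = c(4, 9, 1, 1))
  on.exit(graphics::par(op))
  plot(y, pos, xlim = range(lo, hi, 0), ylim = c(0.5, n + 0.5),
       pch = c(rep(15, n - 1), 18), yaxt = "n", ylab = "",
       xlab = "Log2FC", cex = c(rep(1, n - 1), 1.6), ...)
  graphics::segments(lo, pos, hi, pos)
  graphics::abline(v = 0, lty = 3)
  graphics::axis(2, at = pos, labels = labs, las = 1, cex.axis = 0.8)
  invisible(x)
}

#' @export
print.gene_meta <- function(x, ...) {
  cat("Per-gene random-effects meta-analysis (REML, inverse-variance)\n")
  cat(sprintf("  genes: %d (%d converged, %d unstable)\n",
              x$n_genes, x$n_converged, x$n_unstable))
  cat(sprintf("  contrasts: %d\n", nrow(x$input$contrasts)))
  ndeg <- sum(x$results$deg_flag)
  cat(sprintf("  DEGs at FDR < %g: %d\n", x$alpha, ndeg))
  cat("  top of the results table:\n")
  print(utils::head(x$results[, c("gene", "k", "mu_hat", "se_mu", "p",
                                  "fdr_q", "tau2", "I2")], 6), digits = 4)
  invisible(x)
}

#' Summarize a fitted gene-level meta-analysis
#'
#' @param object a \code{gene_meta}.
#' @param ... unused.
#' @return list of class \code{summary.gene_meta} with gene/DEG counts
#'   (up- and downregulated split), heterogeneity quantiles and the FDR
#'   threshold used.
#' @export
summary.gene_meta <- function(object, ...) {
  r <- object$results
  deg <- r[r$deg_flag, ]
  out <- list(n_genes = object$n_genes, n_converged = object$n_converged,
              n_unstable = object$n_unstable, alpha = object$alpha,
              n_deg = nrow(deg),
              n_deg_down = sum(deg$mu_hat < 0),
              n_deg_up = sum(deg$mu_hat > 0),
              tau2_quantiles = stats::quantile(r$tau2, c(0.25, 0.5, 0.75),
                                               na.rm = TRUE),
              I2_median = stats::median(r$I2, na.rm = TRUE))
  class(out) <- "summary.gene_meta"
  out
}

#' @export
print.summary.gene_meta <- function(x, ...) {
  cat("Gene-level random-effects meta-analysis summary\n")
  cat(sprintf("  %d genes analyzed; %d stable, %d unstable\n",
              x$n_genes, x$n_converged, x$n_unstable))
  cat(sprintf("  %d DEGs at FDR < %g (%d down, %d up)\n",
              x$n_deg, x$alpha, x$n_deg_down, x$n_deg_up))
  cat(sprintf("  tau^2 quartiles: %.4g / %.4g / %.4g; median I^2 = %.1f%%\n",
              x$tau2_quantiles[1], x$tau2_quantiles[2], x$tau2_quantiles[3],
              x$I2_median))
  invisible(x)
}

#' @export
coef.gene_meta <- function(object, ...) {
  stats::setNames(object$results$mu_hat, object$results$gene)
}

#' @export
as.data.frame.gene_meta <- function(x, ...) x$results

#' Forest plot for one gene of a fitted meta-analysis
#'
#' @param x a \code{gene_meta}.
#' @param gene gene symbol to plot; defaults to the top gene by FDR.
#' @param ... passed to [plot.re_fit()].
#' @export
plot.gene_meta <- function(x, gene = NULL, ...) {
  if (is.null(gene)) gene <- x$results$gene[1]
  gi <- match(gene, x$input$genes)
  if (is.na(gi)) stop("unknown gene: ", gene)
  obs <- which(!is.na(x$input$y[gi, ]))
  fit <- fit_random_effects(x$input$y[gi, obs], x$input$v[gi, obs],
                            labels = x$input$contrasts$contrast_id[obs])
  plot(fit, main = gene, ...)
  invisible(fit)
}
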