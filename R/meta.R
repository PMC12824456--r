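#' Restricted maximum-likelihood estimate of between-contrast variance
#'
#' Estimates the heterogeneity variance tau^2 of the intercept-only
#' random-effects model y_i = mu + u_i + e_i, u_i ~ N(0, tau^2),
#' e_i ~ N(0, v_i), by maximizing the restricted log-likelihood
#' \deqn{l_R(\tau^2) = -\tfrac12 \sum \log(v_i+\tau^2)
#'   - \tfrac12 \log \sum (v_i+\tau^2)^{-1}
#'   - \tfrac12 \sum w_i (y_i - \hat\mu(\tau^2))^2}
#' with \eqn{w_i = 1/(v_i+\tau^2)} and \eqn{\hat\mu(\tau^2)} the
#' inverse-variance weighted mean. Optimization is Fisher scoring with
#' step-halving, clamped at zero; if scoring does not converge a bounded
#' one-dimensional search over \code{[0, tau2_max]} is used, and if that
#' is still unstable the fit is flagged as not converged.
#'
#' @param y numeric vector of effect sizes (log2 fold changes), length k >= 2.
#' @param v numeric vector of sampling variances (squared SEs), all > 0.
#' @param tol convergence tolerance on successive tau^2 values.
#' @param max_iter maximum Fisher-scoring iterations.
#' @param tau2_max upper bound for the fallback search; default 100 * max(v).
#' @return list with elements \code{tau2}, \code{converged}, \code{n_iter}.
#' @examples
#' reml_tau2(c(1, 2, 3), c(1, 1, 1))$tau2   # 0: dispersion fully sampling
#' @export
reml_tau2 <- function(y, v, tol = 1e-8, max_iter = 100L, tau2_max = NULL) {
  k <- length(y)
  if (k < 2L) stop("insufficient data: need at least 2 contrasts, got ", k)
  if (length(v) != k) stop("y and v must have equal length")
  if (!all(is.finite(y))) stop("all effect sizes must be finite")
  if (!all(is.finite(v)) || any(v <= 0)) stop("all sampling variances must be finite and > 0")
  if (is.null(tau2_max)) tau2_max <- 100 * max(v)

  # standardize by the mean sampling variance so the optimization is
  # invariant to the scale of the data (tau2 is rescaled on return)
  vscale <- mean(v)
  if (is.finite(vscale) && vscale > 0) {
    y <- y / sqrt(vscale)
    v <- v / vscale
    tau2_max <- tau2_max / vscale
  } else {
    vscale <- 1
  }

  ll <- function(t2) .reml_ll(t2, y, v)

  # DerSimonian-Laird start
  wf <- 1 / v
  mu_fe <- sum(wf * y) / sum(wf)
  Q <- sum(wf * (y - mu_fe)^2)
  t2 <- max(0, (Q - (k - 1)) / (sum(wf) - sum(wf^2) / sum(wf)))

  ll_cur <- ll(t2)
  converged <- FALSE
  iter <- 0L
  if (is.finite(ll_cur)) {
    while (iter < max_iter) {
      iter <- iter + 1L
      w <- 1 / (v + t2)
      sw <- sum(w)
      mu <- sum(w * y) / sw
      trP <- sw - sum(w^2) / sw
      yP2y <- sum((w * (y - mu))^2)
      score <- -0.5 * trP + 0.5 * yP2y
      info <- 0.5 * (sum(w^2) - 2 * sum(w^3) / sw + (sum(w^2) / sw)^2)
      if (!is.finite(score) || !is.finite(info) || info <= 0) break
      delta <- score / info
      t2_new <- max(0, t2 + delta)
      ll_new <- ll(t2_new)
      # step-halving stabilizes large steps; near the optimum the ascent
      # comparison is floating-point noise, so small steps pass unchecked
      halved <- 0L
      while (!is.finite(ll_new) ||
             (ll_new < ll_cur && abs(delta) > 1e-6 * (1 + t2))) {
        if (halved >= 30L) break
        delta <- delta / 2
        t2_new <- max(0, t2 + delta)
        ll_new <- ll(t2_new)
        halved <- halved + 1L
      }
      if (!is.finite(ll_new)) break
      step <- abs(t2_new - t2)
      t2 <- t2_new
      ll_cur <- ll_new
      if (step < tol) converged <- TRUE
      # polish beyond the declared tolerance so the estimate is accurate on
      # any scale of v (steps are cheap; precision feeds z and p directly)
      if (step < tol * 1e-4) break
    }
  }

  if (!converged) {
    # bounded fallback search
    opt <- tryCatch(
      stats::optimize(ll, interval = c(0, tau2_max), maximum = TRUE, tol = tol / 10),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$objective)) {
      t2 <- opt$maximum
      # the optimizer never lands exactly on a boundary; snap to 0 when the
      # likelihood there is at least as high
      ll0 <- ll(0)
      if (is.finite(ll0) && ll0 >= opt$objective) t2 <- 0
      converged <- TRUE
    } else {
      return(list(tau2 = NA_real_, converged = FALSE, n_iter = iter))
    }
  }
  list(tau2 = t2 * vscale, converged = TRUE, n_iter = iter)
}

# restricted log-likelihood of the intercept-only random-effects model
.reml_ll <- function(t2, y, v) {
  w <- 1 / (v + t2)
  sw <- sum(w)
  if (!is.finite(sw) || sw <= 0) return(NaN)
  mu <- sum(w * y) / sw
  -0.5 * sum(log(v + t2)) - 0.5 * log(sw) - 0.5 * sum(w * (y - mu)^2)
}

#' Fit the intercept-only random-effects model to one gene
#'
#' Inverse-variance pooling at the REML heterogeneity estimate:
#' weights w_i = 1/(v_i + tau2), pooled effect mu_hat = sum(w y)/sum(w),
#' SE(mu_hat) = sum(w)^(-1/2), two-sided Wald z-test, 95 percent Wald
#' interval. Cochran's Q is computed at the fixed-effect weights 1/v_i and
#' I^2 = max(0, (Q - (k-1))/Q) * 100.
#'
#' @inheritParams reml_tau2
#' @param labels optional character vector naming the contrasts.
#' @param knapp_hartung logical; if TRUE use the Knapp-Hartung adjusted
#'   standard error with a t-reference distribution (k - 1 df) instead of
#'   the Wald-normal default.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return object of class \code{re_fit}.
#' @examples
#' fit <- fit_random_effects(c(-0.5, -0.3, -0.4, -0.6, -0.2), rep(0.04, 5))
#' fit$mu_hat
#' @export
fit_random_effects <- function(y, v, tol = 1e-8, max_iter = 100L,
                               labels = NULL, knapp_hartung = FALSE,
                               conf_level = 0.95) {
  est <- reml_tau2(y, v, tol = tol, max_iter = max_iter)
  k <- length(y)
  if (!est$converged) {
    out <- list(mu_hat = NA_real_, se_mu = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, z = NA_real_, p = NA_real_,
                tau2 = NA_real_, Q = NA_real_, I2 = NA_real_, k = k,
                converged = FALSE, n_iter = est$n_iter,
                yi = y, vi = v, labels = labels)
    class(out) <- "re_fit"
    return(out)
  }
  tau2 <- est$tau2
  w <- 1 / (v + tau2)
  sw <- sum(w)
  mu_hat <- sum(w * y) / sw
  se_mu <- sqrt(1 / sw)
  if (knapp_hartung) {
    s2 <- sum(w * (y - mu_hat)^2) / ((k - 1) * sw)
    se_mu <- sqrt(max(s2, .Machine$double.eps))
    z <- mu_hat / se_mu
    p <- 2 * stats::pt(-abs(z), df = k - 1)
    crit <- stats::qt(1 - (1 - conf_level) / 2, df = k - 1)
  } else {
    z <- mu_hat / se_mu
    p <- 2 * stats::pnorm(-abs(z))
    crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  }
  wf <- 1 / v
  mu_fe <- sum(wf * y) / sum(wf)
  Q <- sum(wf * (y - mu_fe)^2)
  I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  out <- list(mu_hat = mu_hat, se_mu = se_mu,
              ci_low = mu_hat - crit * se_mu, ci_high = mu_hat + crit * se_mu,
              z = z, p = p, tau2 = tau2, Q = Q, I2 = I2, k = k,
              converged = TRUE, n_iter = est$n_iter,
              yi = y, vi = v, labels = labels)
  class(out) <- "re_fit"
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values q_(i) = min_{j >= i} (p_(j) * m / j), capped at
#' 1, mapped back to input order. Missing entries are excluded from m and
#' returned missing. Delegates the step-up computation to
#' \code{stats::p.adjust}.
#'
#' @param p numeric vector of p-values in [0, 1]; NA allowed.
#' @return numeric vector of q-values, same length and order as \code{p}.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  if (any(ok)) q[ok] <- stats::p.adjust(p[ok], method = "BH", n = sum(ok))
  q
}

#' Per-gene random-effects meta-analysis across contrasts
#'
#' The central fitting function: for every gene in an aligned gene-by-contrast
#' input it fits the intercept-only random-effects model (REML tau^2,
#' inverse-variance pooling, Wald inference) on that gene's non-missing
#' contrasts, applies Benjamini-Hochberg FDR over the genes whose fits
#' converged, and flags differentially expressed genes at \code{fdr_q <
#' alpha}. Genes whose REML fit is numerically unstable carry no p-value into
#' the FDR step and are counted separately.
#'
#' @param input a \code{gene_meta_input} object from [align_contrasts()].
#' @param alpha FDR threshold for the DEG flag (default 0.05).
#' @param knapp_hartung passed to [fit_random_effects()].
#' @param tol,max_iter REML convergence controls.
#' @return object of class \code{gene_meta}: a per-gene results table
#'   (sorted by \code{fdr_q}, then \code{p}, then symbol) plus the input and
#'   bookkeeping counts. See [summary.gene_meta()].
#' @seealso [fit_random_effects()], [align_contrasts()]
#' @export
run_meta <- function(input, alpha = 0.05, knapp_hartung = FALSE,
                     tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(input, "gene_meta_input"))
  genes <- input$genes
  n <- length(genes)
  if (n == 0L) stop("empty input: no genes to meta-analyze")
  cols <- c("mu_hat", "se_mu", "ci_low", "ci_high", "z", "p",
            "tau2", "Q", "I2")
  res <- matrix(NA_real_, nrow = n, ncol = length(cols),
                dimnames = list(genes, cols))
  kvec <- integer(n)
  conv <- logical(n)
  for (i in seq_len(n)) {
    obs <- !is.na(input$y[i, ])
    fit <- fit_random_effects(input$y[i, obs], input$v[i, obs],
                              tol = tol, max_iter = max_iter,
                              knapp_hartung = knapp_hartung)
    kvec[i] <- fit$k
    conv[i] <- fit$converged
    res[i, ] <- c(fit$mu_hat, fit$se_mu, fit$ci_low, fit$ci_high,
                  fit$z, fit$p, fit$tau2, fit$Q, fit$I2)
  }
  p_for_fdr <- ifelse(conv, res[, "p"], NA_real_)
  fdr_q <- bh_fdr(p_for_fdr)
  deg <- !is.na(fdr_q) & fdr_q < alpha
  tab <- data.frame(gene = genes, k = kvec, res, fdr_q = fdr_q,
                    deg_flag = deg, converged = conv,
                    stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(tab$fdr_q, tab$p, tab$gene, na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  out <- list(results = tab, input = input, alpha = alpha,
              n_genes = n, n_converged = sum(conv),
              n_unstable = sum(!conv), knapp_hartung = knapp_hartung)
  class(out) <- "gene_meta"
  out
}

#' Write meta-analysis results to a tab-separated file
#'
#' @param meta a \code{gene_meta} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_meta_results <- function(meta, path) {
  stopifnot(inherits(meta, "gene_meta"))
  tab <- meta$results[, c("gene", "k", "mu_hat", "se_mu", "ci_low", "ci_high",
                          "z", "p", "tau2", "Q", "I2", "fdr_q", "deg_flag",
                          "converged")]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
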