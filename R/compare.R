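#' Resolve mouse-to-human orthologs to a one-to-one map
#'
#' Applies a three-rule decision cascade per mouse symbol, in order:
#' (1) mouse symbols mapping to exactly one human symbol are kept as-is;
#' (2) among remaining conflicts, candidate rows whose mouse and human
#' symbols match case-insensitively are preferred;
#' (3) otherwise the row with the most supporting databases wins, ties
#' broken by the smallest original row index.
#'
#' @param table data.frame of candidate ortholog rows.
#' @param mouse_col,human_col,support_col column names (defaults
#'   \code{mouse_symbol}, \code{human_symbol}, \code{support}).
#' @return data.frame of class \code{ortholog_map} with columns
#'   \code{mouse_symbol}, \code{human_symbol}, \code{support},
#'   \code{row_index}, \code{rule} (which cascade rule resolved the row);
#'   at most one row per mouse symbol. Idempotent: re-resolving the output
#'   returns it unchanged.
#' @export
resolve_orthologs <- function(table, mouse_col = "mouse_symbol",
                              human_col = "human_symbol",
                              support_col = "support") {
  stopifnot(is.data.frame(table))
  for (col in c(mouse_col, human_col))
    if (!col %in% names(table)) stop("missing column: ", col)
  df <- data.frame(mouse_symbol = as.character(table[[mouse_col]]),
                   human_symbol = as.character(table[[human_col]]),
                   support = if (support_col %in% names(table))
                     as.numeric(table[[support_col]]) else NA_real_,
                   row_index = seq_len(nrow(table)),
                   stringsAsFactors = FALSE)
  pick <- function(cand) {
    if (length(unique(cand$human_symbol)) == 1L) {
      cand <- cand[1L, , drop = FALSE]
      cand$rule <- 1L
      return(cand)
    }
    match_rows <- toupper(cand$mouse_symbol) == toupper(cand$human_symbol)
    if (any(match_rows)) {
      cand <- cand[match_rows, , drop = FALSE]
      if (length(unique(cand$human_symbol)) == 1L) {
        cand <- cand[1L, , drop = FALSE]
        cand$rule <- 2L
        return(cand)
      }
    }
    if (anyNA(cand$support))
      stop("validation error: support column required to break a ",
           "multi-mapping for mouse symbol ", cand$mouse_symbol[1])
    cand <- cand[order(-cand$support, cand$row_index), , drop = FALSE]
    cand <- cand[1L, , drop = FALSE]
    cand$rule <- 3L
    cand
  }
  parts <- split(df, df$mouse_symbol)
  out <- do.call(rbind, lapply(parts, pick))
  out <- out[order(out$row_index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ortholog_map", class(out))
  out
}

#' Compare DEG effect sizes against an external study
#'
#' Joins the differentially expressed genes of a meta-analysis to an
#' external result table (optionally through a resolved ortholog map) and
#' computes parametric and nonparametric concordance statistics: Pearson
#' correlation (two-sided t-based p), Spearman correlation (average ranks
#' for ties, two-sided p), the ordinary least-squares slope and intercept of
#' external on internal log2 fold change, and the fraction of
#' sign-concordant genes.
#'
#' @param deg a \code{gene_meta} object (its \code{deg_flag} rows are used)
#'   or a data.frame with columns \code{gene} and \code{log2fc}.
#' @param external data.frame with columns \code{gene}, \code{log2fc},
#'   \code{p} (external study results, keyed by human symbol when an
#'   ortholog map is supplied).
#' @param ortholog optional \code{ortholog_map} from [resolve_orthologs()].
#' @param nominal_alpha threshold for the external nominal-significance flag
#'   (default 0.05).
#' @return object of class \code{deg_comparison}: list with
#'   \code{n_overlap}, \code{n_unmatched}, \code{n_filtered_by_ortholog},
#'   \code{pearson_r}, \code{pearson_p}, \code{spearman_rho},
#'   \code{spearman_p}, \code{slope}, \code{intercept},
#'   \code{direction_agreement}, \code{truncated} (external table appears
#'   restricted to significant genes), and the per-gene join \code{table}.
#' @export
compare_deg_effects <- function(deg, external, ortholog = NULL,
                                nominal_alpha = 0.05) {
  if (inherits(deg, "gene_meta")) {
    r <- deg$results
    deg <- data.frame(gene = r$gene[r$deg_flag],
                      log2fc = r$mu_hat[r$deg_flag],
                      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene", "log2fc") %in% names(deg)),
            all(c("gene", "log2fc", "p") %in% names(external)))
  n_deg <- nrow(deg)
  key <- deg$gene
  n_filtered <- 0L
  if (!is.null(ortholog)) {
    idx <- match(deg$gene, ortholog$mouse_symbol)
    key <- ortholog$human_symbol[idx]
    n_filtered <- sum(is.na(key))
    deg <- deg[!is.na(key), , drop = FALSE]
    key <- key[!is.na(key)]
  }
  hit <- match(key, external$gene)
  n_unmatched <- sum(is.na(hit))
  ours <- deg$log2fc[!is.na(hit)]
  gene <- deg$gene[!is.na(hit)]
  ext <- external[hit[!is.na(hit)], , drop = FALSE]
  n_overlap <- length(ours)
  if (n_overlap < 3L)
    stop("insufficient overlap: only ", n_overlap,
         " DEGs found in the external table (need >= 3)")
  truncated <- all(ext$p < nominal_alpha, na.rm = TRUE)
  if (truncated)
    warning("external table only reports nominally significant genes; ",
            "correlations on truncated results are biased")
  pe <- stats::cor.test(ours, ext$log2fc, method = "pearson")
  sp <- suppressWarnings(
    stats::cor.test(ours, ext$log2fc, method = "spearman", exact = FALSE))
  fit <- stats::lm(ext$log2fc ~ ours)
  out <- list(n_deg = n_deg, n_overlap = n_overlap,
              n_unmatched = n_unmatched, n_filtered_by_ortholog = n_filtered,
              pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
              spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
              slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              direction_agreement = mean(sign(ours) == sign(ext$log2fc)),
              truncated = truncated,
              table = data.frame(gene = gene, our_log2fc = ours,
                                 external_log2fc = ext$log2fc,
                                 external_p = ext$p,
                                 nominal = !is.na(ext$p) & ext$p < nominal_alpha,
                                 stringsAsFactors = FALSE))
  class(out) <- "deg_comparison"
  out
}

#' @export
print.deg_comparison <- function(x, ...) {
  cat("Cross-study DEG effect-size comparison\n")
  cat(sprintf("  DEGs supplied: %d; compared: %d (unmatched %d, no ortholog %d)\n",
              x$n_deg, x$n_overlap, x$n_unmatched, x$n_filtered_by_ortholog))
  cat(sprintf("  Pearson R = %.3f (p = %.3g); Spearman rho = %.3f (p = %.3g)\n",
              x$pearson_r, x$pearson_p, x$spearman_rho, x$spearman_p))
  cat(sprintf("  OLS: external = %.3f + %.3f * internal; sign agreement %.1f%%\n",
              x$intercept, x$slope, 100 * x$direction_agreement))
  if (x$truncated)
    cat("  note: external table truncated to nominally significant genes\n")
  invisible(x)
}
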