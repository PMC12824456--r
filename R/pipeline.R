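#' Forest-plot data for one gene
#'
#' One row per contrast in which the gene was measured (in manifest order),
#' each with its log2 fold change and 95 percent Wald interval
#' (y +/- 1.959964 * se), followed by a single random-effects summary row
#' with the pooled estimate and its interval. Contrasts without the gene are
#' omitted, not zero-filled.
#'
#' @param gene gene symbol.
#' @param input the \code{gene_meta_input} the model was fitted on.
#' @param meta the fitted \code{gene_meta}.
#' @return data.frame with columns \code{label}, \code{y}, \code{ci_low},
#'   \code{ci_high}, \code{is_summary}.
#' @export
forest_data <- function(gene, input, meta) {
  stopifnot(inherits(input, "gene_meta_input"), inherits(meta, "gene_meta"))
  gi <- match(gene, input$genes)
  ri <- match(gene, meta$results$gene)
  if (is.na(gi) || is.na(ri)) stop("unknown gene: ", gene)
  obs <- which(!is.na(input$y[gi, ]))
  y <- input$y[gi, obs]
  se <- sqrt(input$v[gi, obs])
  crit <- 1.959964
  res <- meta$results[ri, ]
  data.frame(label = c(input$contrasts$contrast_id[obs], "RE Model"),
             y = c(y, res$mu_hat),
             ci_low = c(y - crit * se, res$ci_low),
             ci_high = c(y + crit * se, res$ci_high),
             is_summary = c(rep(FALSE, length(obs)), TRUE),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Clustered heatmap data for the top differentially expressed genes
#'
#' Rows are the \code{top_n} genes with the smallest FDR (ties by p, then
#' symbol); columns are all contrasts reordered by agglomerative
#' hierarchical clustering of their log2 fold-change profiles
#' (pairwise-complete Euclidean distance, complete linkage by default).
#' Missing cells stay missing so a renderer can grey them out.
#'
#' @param meta fitted \code{gene_meta}.
#' @param input the matching \code{gene_meta_input}.
#' @param top_n number of genes to show (default 50); if fewer genes are
#'   available all are used, with a warning.
#' @param linkage hclust agglomeration method (default "complete").
#' @return list of class \code{heatmap_data}: \code{matrix} (genes x
#'   contrasts, columns in clustered order), \code{col_order} (permutation
#'   of the original contrast order), \code{hclust} (the column clustering).
#' @export
heatmap_data <- function(meta, input, top_n = 50L, linkage = "complete") {
  stopifnot(inherits(meta, "gene_meta"), inherits(input, "gene_meta_input"))
  tab <- meta$results
  if (nrow(tab) < top_n) {
    warning("only ", nrow(tab), " genes available; using all")
    top_n <- nrow(tab)
  }
  ord <- order(tab$fdr_q, tab$p, tab$gene, na.last = TRUE)
  top <- tab$gene[ord][seq_len(top_n)]
  m <- input$y[match(top, input$genes), , drop = FALSE]
  rownames(m) <- top
  hc <- stats::hclust(stats::dist(t(m)), method = linkage)
  out <- list(matrix = m[, hc$order, drop = FALSE], col_order = hc$order,
              hclust = hc)
  class(out) <- "heatmap_data"
  out
}

#' Run the full meta-analysis pipeline
#'
#' Orchestrates ingest -> align -> per-gene random-effects meta-analysis ->
#' preranked enrichment (-> external comparison when supplied) and writes
#' result tables, report data (heatmap matrix, forest data for the top
#' DEGs), a YAML manifest and a plain-text log (with every exclusion count)
#' to an output directory. With a \code{synthetic} configuration the input
#' tables are generated first. Re-running with the same configuration and
#' seed reproduces every output byte-identically.
#'
#' @param config either a path to a YAML file or a list with components:
#'   \describe{
#'     \item{synthetic}{logical; generate inputs with the synth module
#'       (\code{sim} holds [sim_config()] overrides).}
#'     \item{contrast_tables}{(non-synthetic runs) list of entries with
#'       \code{path}, \code{contrast_id}, \code{dataset_id}, \code{platform};
#'       optional \code{column_map}, \code{symbol_delim}.}
#'     \item{gmt}{path to a GMT file (synthetic runs supply their own).}
#'     \item{external, ortholog}{optional paths to an external results TSV
#'       and an ortholog candidate table for the comparison stage.}
#'     \item{min_contrasts, fdr_alpha, n_perm, min_size, max_size, top_n,
#'       n_forest}{thresholds; defaults 5, 0.05, 10000, 10, 1000, 50, 6.}
#'     \item{seed}{mandatory integer seed.}
#'     \item{out_dir}{output directory.}
#'   }
#' @return the output directory path, invisibly; the directory contains
#'   \code{meta_results.tsv}, \code{enrichment.tsv}, \code{heatmap.tsv},
#'   \code{forest/}, optional \code{comparison*}, \code{manifest.yaml},
#'   \code{log.txt}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(synthetic = FALSE, min_contrasts = 5L, fdr_alpha = 0.05,
                   n_perm = 10000L, min_size = 10L, max_size = 1000L,
                   top_n = 50L, n_forest = 6L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$seed)) stop("config error [setup]: seed is mandatory")
  if (is.null(config$out_dir)) stop("config error [setup]: out_dir is mandatory")
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  # -- inputs ---------------------------------------------------------------
  gmt_path <- config$gmt
  external <- ortho_raw <- NULL
  if (isTRUE(config$synthetic)) {
    sim_args <- config$sim
    sim_args$seed <- config$seed
    cfg <- stage("simulate", do.call(sim_config, sim_args))
    truth <- stage("simulate", simulate_truth(cfg))
    sim <- stage("simulate", simulate_contrast_tables(cfg, truth))
    tables <- sim$tables
    table_meta <- sim$contrasts
    sets <- truth$sets
    note("simulated ", length(tables), " contrast tables, ",
         cfg$n_genes, " genes, ", length(sets), " gene sets")
    if (!is.null(config$external_b)) {
      ext <- stage("simulate",
                   simulate_external_study(truth,
                                           attenuation_b = config$external_b,
                                           noise_sd = config$external_noise_sd,
                                           seed = config$seed + 2L))
      external <- ext$external
      ortho_raw <- ext$ortholog
    }
  } else {
    specs <- config$contrast_tables
    if (is.null(specs) || length(specs) == 0L)
      stop("config error [ingest]: no contrast tables supplied")
    if (config$min_contrasts > length(specs))
      stop("config error [setup]: min_contrasts (", config$min_contrasts,
           ") exceeds the number of contrasts (", length(specs), ")")
    tables <- NULL
    table_meta <- do.call(rbind, lapply(specs, function(s)
      data.frame(contrast_id = s$contrast_id, dataset_id = s$dataset_id,
                 platform = s$platform, path = s$path,
                 stringsAsFactors = FALSE)))
    sets <- if (!is.null(gmt_path)) stage("enrich", read_gmt(gmt_path)) else NULL
    if (!is.null(config$external))
      external <- utils::read.delim(config$external, stringsAsFactors = FALSE)
    if (!is.null(config$ortholog))
      ortho_raw <- utils::read.delim(config$ortholog, sep = "",
                                     stringsAsFactors = FALSE)
  }
  if (config$min_contrasts > nrow(table_meta))
    stop("config error [setup]: min_contrasts (", config$min_contrasts,
         ") exceeds the number of contrasts (", nrow(table_meta), ")")

  # -- ingest ---------------------------------------------------------------
  results <- vector("list", nrow(table_meta))
  for (i in seq_len(nrow(table_meta))) {
    cid <- table_meta$contrast_id[i]
    if (isTRUE(config$synthetic)) {
      tmp <- tempfile(fileext = ".tsv")
      utils::write.table(tables[[cid]], tmp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      recs <- stage("ingest", parse_contrast_table(tmp))
      unlink(tmp)
    } else {
      cm <- config$contrast_tables[[i]]$column_map
      recs <- stage("ingest", if (is.null(cm))
        parse_contrast_table(table_meta$path[i])
        else parse_contrast_table(table_meta$path[i], column_map = cm))
    }
    res <- stage("ingest", collapse_to_genes(recs, cid,
                                             table_meta$dataset_id[i],
                                             table_meta$platform[i]))
    ex <- attr(res, "exclusions")
    note("ingest ", cid, ": rows=", sum(ex), " usable=", ex[["usable"]],
         " multi_mapped=", ex[["multi_mapped"]],
         " unmapped=", ex[["unmapped"]], " unusable=", ex[["unusable"]],
         " dropped_nonfinite=", attr(recs, "n_dropped_nonfinite"))
    results[[i]] <- res
  }

  input <- stage("align", align_contrasts(results, config$min_contrasts))
  note("align: ", length(input$genes), " genes retained, ",
       input$n_dropped, " dropped below ", config$min_contrasts, " contrasts")

  # -- meta -----------------------------------------------------------------
  meta <- stage("meta", run_meta(input, alpha = config$fdr_alpha))
  deg <- meta$results[meta$results$deg_flag, ]
  note("meta: ", meta$n_converged, " converged, ", meta$n_unstable,
       " unstable; ", nrow(deg), " DEGs at FDR < ", config$fdr_alpha,
       " (", sum(deg$mu_hat < 0), " down, ", sum(deg$mu_hat > 0), " up)")
  write_meta_results(meta, file.path(config$out_dir, "meta_results.tsv"))

  # -- enrichment -----------------------------------------------------------
  enr <- NULL
  if (!is.null(sets)) {
    enr <- stage("enrich",
                 preranked_gsea(meta, sets, n_perm = config$n_perm,
                                min_size = config$min_size,
                                max_size = config$max_size,
                                seed = config$seed + 1L))
    sk <- attr(enr, "skipped")
    note("enrich: ", nrow(enr), " sets tested, ", nrow(sk), " skipped, ",
         sum(enr$fdr_q < config$fdr_alpha), " enriched at FDR < ",
         config$fdr_alpha)
    write_enrichment(enr, file.path(config$out_dir, "enrichment.tsv"))
  }

  # -- comparison -----------------------------------------------------------
  cmp <- NULL
  if (!is.null(external) && nrow(deg) >= 3L) {
    omap <- if (!is.null(ortho_raw)) stage("compare", resolve_orthologs(ortho_raw))
    cmp <- stage("compare", compare_deg_effects(meta, external, ortholog = omap))
    note("compare: n_overlap=", cmp$n_overlap, " unmatched=", cmp$n_unmatched,
         " no_ortholog=", cmp$n_filtered_by_ortholog,
         sprintf(" pearson_r=%.4f spearman_rho=%.4f slope=%.4f",
                 cmp$pearson_r, cmp$spearman_rho, cmp$slope))
    utils::write.table(cmp$table,
                       file.path(config$out_dir, "comparison_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(utils::capture.output(print(cmp)),
               file.path(config$out_dir, "comparison.txt"))
  }

  # -- report data ----------------------------------------------------------
  hm <- stage("report", suppressWarnings(
    heatmap_data(meta, input, top_n = min(config$top_n, nrow(meta$results)))))
  utils::write.table(data.frame(gene = rownames(hm$matrix), hm$matrix,
                                check.names = FALSE),
                     file.path(config$out_dir, "heatmap.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  forest_dir <- file.path(config$out_dir, "forest")
  dir.create(forest_dir, showWarnings = FALSE)
  top_genes <- utils::head(meta$results$gene[meta$results$converged],
                           config$n_forest)
  for (g in top_genes)
    utils::write.table(stage("report", forest_data(g, input, meta)),
                       file.path(forest_dir, paste0(g, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    seed = config$seed,
    synthetic = isTRUE(config$synthetic),
    parameters = config[c("min_contrasts", "fdr_alpha", "n_perm", "min_size",
                          "max_size", "top_n", "n_forest")],
    contrasts = table_meta$contrast_id,
    counts = list(genes_aligned = length(input$genes),
                  genes_converged = meta$n_converged,
                  genes_unstable = meta$n_unstable,
                  degs = nrow(deg),
                  enriched_sets = if (is.null(enr)) NULL
                                  else sum(enr$fdr_q < config$fdr_alpha)),
    outputs = c("meta_results.tsv",
                if (!is.null(enr)) "enrichment.tsv",
                if (!is.null(cmp)) c("comparison.txt", "comparison_genes.tsv"),
                "heatmap.tsv", "log.txt"))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  writeLines(log_lines, file.path(config$out_dir, "log.txt"))
  invisible(config$out_dir)
}
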