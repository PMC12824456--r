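#' Parse a per-contrast differential-expression table
#'
#' Reads a tab-separated differential-expression export (one header row; one
#' row per probe/element) and returns probe-level records: element ID, gene
#' symbol(s), log2 fold change, and a standard error. When the table carries
#' a t-statistic but no SE column, the SE is derived from the Wald
#' relationship \code{se = |log2fc / t|}; rows where that division is
#' impossible (t zero, missing, or non-finite) are flagged unusable. Rows
#' with a non-finite log2 fold change are dropped and counted.
#'
#' @param path path to a tab-separated file with a header row.
#' @param column_map named list mapping roles to column names. Mandatory
#'   roles: \code{element}, \code{symbol}, \code{log2fc}, and at least one of
#'   \code{se} / \code{t_stat}. Optional: \code{p_value}. Defaults match the
#'   synthetic tables written by [simulate_contrast_tables()].
#' @param symbol_delim delimiter separating multiple gene symbols within the
#'   symbol field (default \code{"|"}).
#' @return data.frame of class \code{probe_records} with columns
#'   \code{element_id}, \code{gene_symbols} (list column of trimmed symbol
#'   vectors), \code{log2fc}, \code{t_stat}, \code{se}, \code{p_value},
#'   \code{usable}; attribute \code{n_dropped_nonfinite} counts dropped rows.
#' @export
parse_contrast_table <- function(path,
                                 column_map = list(element = "Element",
                                                   symbol = "GeneSymbol",
                                                   log2fc = "Log2FC",
                                                   t_stat = "Tstat",
                                                   p_value = "PValue"),
                                 symbol_delim = "|") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty input: no data rows in ", path)
  need <- c("element", "symbol", "log2fc")
  for (role in need) {
    col <- column_map[[role]]
    if (is.null(col)) stop("configuration error: column_map lacks role '", role, "'")
    if (!col %in% names(tab))
      stop("configuration error: missing mandatory column '", col, "'")
  }
  has_se <- !is.null(column_map$se) && column_map$se %in% names(tab)
  has_t <- !is.null(column_map$t_stat) && column_map$t_stat %in% names(tab)
  if (!has_se && !has_t)
    stop("configuration error: need a column for at least one of 'se' / 't_stat'")

  get_num <- function(role) {
    col <- column_map[[role]]
    if (is.null(col) || !col %in% names(tab)) return(rep(NA_real_, nrow(tab)))
    suppressWarnings(as.numeric(tab[[col]]))
  }
  log2fc <- get_num("log2fc")
  keep <- is.finite(log2fc)
  n_drop <- sum(!keep)

  syms <- as.character(tab[[column_map$symbol]])[keep]
  symlist <- lapply(strsplit(syms, symbol_delim, fixed = TRUE), function(s) {
    s <- trimws(s)
    s[nzchar(s)]
  })
  se <- get_num("se")[keep]
  tstat <- get_num("t_stat")[keep]
  log2fc <- log2fc[keep]

  derive <- is.na(se) & !is.na(tstat) & is.finite(tstat) & tstat != 0
  se[derive] <- abs(log2fc[derive] / tstat[derive])
  usable <- !is.na(se) & is.finite(se) & se > 0

  out <- data.frame(element_id = as.character(tab[[column_map$element]])[keep],
                    log2fc = log2fc, t_stat = tstat, se = se,
                    p_value = get_num("p_value")[keep],
                    usable = usable, stringsAsFactors = FALSE)
  out$gene_symbols <- symlist
  attr(out, "n_dropped_nonfinite") <- n_drop
  class(out) <- c("probe_records", class(out))
  out
}

#' Collapse probe-level records to gene-level effect sizes
#'
#' Records mapping to anything other than exactly one official gene symbol
#' are excluded (multi-mapped or unmapped, counted separately), as are
#' records without a usable standard error. Remaining records are grouped by
#' symbol; the gene-level effect size is the arithmetic mean of the probe
#' log2 fold changes, the gene-level SE aggregates the probe SEs
#' (\code{se_method}), and the sampling variance is SE squared.
#'
#' @param records a \code{probe_records} data.frame from
#'   [parse_contrast_table()].
#' @param contrast_id,dataset_id identifiers recorded on the result.
#' @param platform one of \code{"rnaseq"}, \code{"microarray"}.
#' @param se_method probe-SE aggregation: \code{"mean"} (arithmetic mean,
#'   default) or \code{"rms"} (root mean square).
#' @return data.frame of class \code{contrast_result} with columns
#'   \code{gene}, \code{y}, \code{se}, \code{sv}, \code{n_probes}, one row
#'   per gene symbol; attributes \code{contrast_id}, \code{dataset_id},
#'   \code{platform} and \code{exclusions} (named counts: usable,
#'   multi_mapped, unmapped, unusable — these sum to the input row count).
#' @export
collapse_to_genes <- function(records, contrast_id, dataset_id,
                              platform = c("rnaseq", "microarray"),
                              se_method = c("mean", "rms")) {
  platform <- match.arg(platform)
  se_method <- match.arg(se_method)
  stopifnot(is.data.frame(records), "gene_symbols" %in% names(records))
  nsym <- lengths(records$gene_symbols)
  cat_multi <- nsym >= 2L
  cat_unmapped <- nsym == 0L
  cat_unusable <- nsym == 1L & !records$usable
  cat_usable <- nsym == 1L & records$usable
  excl <- c(usable = sum(cat_usable), multi_mapped = sum(cat_multi),
            unmapped = sum(cat_unmapped), unusable = sum(cat_unusable))
  if (excl[["usable"]] == 0L)
    stop("empty input: no usable single-symbol records for contrast ", contrast_id)

  sym <- vapply(records$gene_symbols[cat_usable], `[`, character(1), 1L)
  lfc <- records$log2fc[cat_usable]
  se <- records$se[cat_usable]
  y <- tapply(lfc, sym, mean)
  gse <- if (se_method == "mean") tapply(se, sym, mean)
         else sqrt(tapply(se^2, sym, mean))
  np <- tapply(sym, sym, length)
  genes <- sort(unique(sym))
  out <- data.frame(gene = genes, y = as.numeric(y[genes]),
                    se = as.numeric(gse[genes]),
                    sv = as.numeric(gse[genes])^2,
                    n_probes = as.integer(np[genes]),
                    stringsAsFactors = FALSE)
  attr(out, "contrast_id") <- contrast_id
  attr(out, "dataset_id") <- dataset_id
  attr(out, "platform") <- platform
  attr(out, "exclusions") <- excl
  class(out) <- c("contrast_result", class(out))
  out
}

#' Align gene-level results across contrasts
#'
#' Builds genes-by-contrasts effect (y) and sampling-variance (v) matrices
#' over the union of gene symbols, with a shared missingness mask, and drops
#' genes represented in fewer than \code{min_contrasts} contrasts. Five is
#' the default so that every retained gene is backed by at least three
#' studies under the two-contrasts-per-dataset design.
#'
#' @param results list of \code{contrast_result} objects.
#' @param min_contrasts minimum number of contrasts a gene must appear in.
#' @return object of class \code{gene_meta_input}: list with \code{genes},
#'   \code{contrasts} (data.frame: contrast_id, dataset_id, platform),
#'   \code{y} and \code{v} matrices, per-gene count \code{k}, and
#'   \code{n_dropped} (genes failing the filter).
#' @export
align_contrasts <- function(results, min_contrasts = 5L) {
  stopifnot(is.list(results), length(results) >= 1L)
  ids <- vapply(results, attr, character(1), "contrast_id")
  if (anyDuplicated(ids)) stop("validation error: duplicate contrast_id: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  if (min_contrasts > length(results))
    stop("configuration error: min_contrasts (", min_contrasts,
         ") exceeds number of contrasts (", length(results), ")")
  genes <- sort(unique(unlist(lapply(results, `[[`, "gene"))))
  y <- v <- matrix(NA_real_, nrow = length(genes), ncol = length(results),
                   dimnames = list(genes, ids))
  for (j in seq_along(results)) {
    r <- results[[j]]
    idx <- match(r$gene, genes)
    y[idx, j] <- r$y
    v[idx, j] <- r$sv
  }
  k <- rowSums(!is.na(y))
  keep <- k >= min_contrasts
  out <- list(genes = genes[keep],
              contrasts = data.frame(
                contrast_id = ids,
                dataset_id = vapply(results, attr, character(1), "dataset_id"),
                platform = vapply(results, attr, character(1), "platform"),
                stringsAsFactors = FALSE),
              y = y[keep, , drop = FALSE], v = v[keep, , drop = FALSE],
              k = unname(k[keep]), n_dropped = sum(!keep),
              min_contrasts = min_contrasts)
  class(out) <- "gene_meta_input"
  out
}

#' Write a gene-level contrast result to a tab-separated file
#' @param result a \code{contrast_result}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_contrast_result <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an aligned gene-by-contrast input as wide matrices plus a manifest
#'
#' Writes \code{<prefix>_y.tsv}, \code{<prefix>_v.tsv} (genes in rows,
#' contrasts in columns, empty cells for missing) and
#' \code{<prefix>_contrasts.tsv} (contrast_id, dataset_id, platform).
#'
#' @param input a \code{gene_meta_input}.
#' @param prefix output path prefix.
#' @return the three paths, invisibly.
#' @export
write_meta_input <- function(input, prefix) {
  stopifnot(inherits(input, "gene_meta_input"))
  paths <- paste0(prefix, c("_y.tsv", "_v.tsv", "_contrasts.tsv"))
  wide <- function(m) data.frame(gene = rownames(m), m, check.names = FALSE,
                                 stringsAsFactors = FALSE)
  utils::write.table(wide(input$y), paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(wide(input$v), paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(input$contrasts, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
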