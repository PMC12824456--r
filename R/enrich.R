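#' Read a GMT gene-set database
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' \code{name<TAB>description<TAB>member1<TAB>member2...}. Duplicate member
#' symbols within a line are removed and counted.
#'
#' @param path path to a GMT file.
#' @return object of class \code{gene_set_db}: named list of character
#'   vectors (the members), with attributes \code{descriptions} and
#'   \code{n_dedup} (total duplicate members removed).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("parse error: line ", which(nf < 3L)[1], " has fewer than 3 fields")
  nms <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(nms))
    stop("validation error: duplicate set name: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  n_dedup <- 0L
  sets <- lapply(fields, function(f) {
    mem <- f[-(1:2)]
    u <- unique(mem)
    n_dedup <<- n_dedup + length(mem) - length(u)
    u
  })
  names(sets) <- nms
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[`, character(1), 2L), nms)
  attr(sets, "n_dedup") <- n_dedup
  class(sets) <- "gene_set_db"
  sets
}

#' Write a gene-set collection to a GMT file
#' @param sets named list of character vectors (member symbols).
#' @param path output path.
#' @param descriptions optional character vector of descriptions.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, d, mem) paste(c(nm, d, mem), collapse = "\t"),
                  names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

# Enrichment score from sorted hit positions.
# pos: 1-based positions of the set's members in the ranked list (sorted);
# w: |stat|^p at those positions; N: length of the ranked list.
# The running sum gains w_j/sum(w) at each hit and loses 1/(N-m) at each
# miss; the ES is the extreme of maximal absolute deviation, and the
# leading edge is the run of hits at or before (positive ES) / at or after
# (negative ES) the extremum.
.es_core <- function(pos, w, N) {
  m <- length(pos)
  if (m == 0L) return(list(es = NA_real_, le_idx = integer(0)))
  if (m == N) return(list(es = 1, le_idx = seq_len(m)))
  sw <- sum(w)
  if (sw <= 0) w <- rep(1, m) else w <- w / sum(w)
  d <- 1 / (N - m)
  cw <- cumsum(w)
  top <- cw - (pos - seq_len(m)) * d          # value just after each hit
  bot <- top - w                               # value just before each hit
  maxP <- max(top)
  minP <- min(bot)
  if (maxP > -minP) {
    j <- which.max(top)
    list(es = maxP, le_idx = seq_len(j))
  } else if (maxP < -minP) {
    j <- which.min(bot)
    list(es = minP, le_idx = j:m)
  } else {
    list(es = 0, le_idx = integer(0))
  }
}

#' Weighted running-sum enrichment score for one gene set
#'
#' Computes the GSEA enrichment score of a gene set against a ranked list:
#' walking down the list, member genes ("hits") add
#' \code{|r_i|^p / sum_hits |r|^p} and non-members subtract
#' \code{1/(N - N_hits)}; the ES is the running-sum value of maximal
#' absolute deviation from zero. The leading edge is the members at or
#' before the extremum (positive ES) or at or after it (negative ES).
#'
#' @param ranked named numeric vector of ranking statistics, sorted
#'   descending; names are gene symbols.
#' @param members character vector of set members.
#' @param weight_exponent the weighting exponent p (default 1; 0 gives the
#'   unweighted Kolmogorov-Smirnov walk).
#' @return list with \code{es} (NA if no member is in the ranked list) and
#'   \code{leading_edge} (character vector, in rank order).
#' @export
enrichment_score <- function(ranked, members, weight_exponent = 1) {
  stopifnot(is.numeric(ranked), !is.null(names(ranked)))
  if (any(!is.finite(ranked))) stop("ranking statistics must be finite")
  pos <- sort(match(unique(members), names(ranked)))
  pos <- pos[!is.na(pos)]
  if (length(pos) == 0L)
    return(list(es = NA_real_, leading_edge = character(0)))
  w <- abs(ranked[pos])^weight_exponent
  core <- .es_core(pos, w, length(ranked))
  list(es = core$es, leading_edge = names(ranked)[pos[core$le_idx]])
}

# null ES distribution for one set size: n_perm random gene sets of size m
# drawn without replacement from the ranked universe
.null_es <- function(m, n_perm, absr, N) {
  vapply(seq_len(n_perm), function(i) {
    pos <- sort(sample.int(N, m))
    .es_core(pos, absr[pos], N)$es
  }, numeric(1))
}

#' Preranked gene-set enrichment on meta-analysis results
#'
#' Ranks converged genes by pooled log2 fold change (descending, ties broken
#' by ascending symbol), filters sets to those with \code{min_size} to
#' \code{max_size} members in that universe, and tests each against a null
#' distribution of enrichment scores from \code{n_perm} random gene sets of
#' equal size (the simple, non-adaptive permutation scheme). The permutation
#' p-value compares against same-sign null scores,
#' \code{p = (1 + #(|null| >= |es|)) / (1 + #same-sign nulls)}, the NES
#' divides the ES by the mean same-sign null magnitude, and q-values are
#' Benjamini-Hochberg over all tested sets. Deterministic given \code{seed}.
#'
#' @param meta a \code{gene_meta} object (or data.frame with columns
#'   \code{gene}, \code{mu_hat}, \code{converged}).
#' @param db a \code{gene_set_db} from [read_gmt()], or a named list of
#'   member vectors.
#' @param n_perm permutations per set size (default 10000; < 1000 warns).
#' @param min_size,max_size set-size bounds after intersecting with the
#'   ranked universe (defaults 10 and 1000).
#' @param weight_exponent ES weighting exponent (default 1).
#' @param seed integer seed; mandatory for reproducibility.
#' @return data.frame of class \code{enrichment_result} with columns
#'   \code{set}, \code{p}, \code{fdr_q}, \code{es}, \code{nes}, \code{size},
#'   \code{leading_edge} ("|"-joined); attribute \code{skipped} records
#'   excluded sets and reasons.
#' @export
preranked_gsea <- function(meta, db, n_perm = 10000L, min_size = 10L,
                           max_size = 1000L, weight_exponent = 1, seed) {
  if (missing(seed)) stop("seed is required for a reproducible permutation null")
  if (n_perm < 1000L)
    warning("n_perm = ", n_perm, " gives a coarse permutation floor; ",
            "1000 or more is recommended")
  tab <- if (inherits(meta, "gene_meta")) meta$results else meta
  stopifnot(all(c("gene", "mu_hat", "converged") %in% names(tab)))
  tab <- tab[tab$converged, , drop = FALSE]
  ord <- order(-tab$mu_hat, tab$gene)
  ranked <- stats::setNames(tab$mu_hat[ord], tab$gene[ord])
  N <- length(ranked)
  absr <- abs(ranked)^weight_exponent

  sets <- lapply(db, function(mem) sort(match(unique(mem), names(ranked))))
  sets <- lapply(sets, function(p) p[!is.na(p)])
  sizes <- lengths(sets)
  skip_empty <- sizes == 0L
  skip_size <- !skip_empty & (sizes < min_size | sizes > max_size)
  keep <- !(skip_empty | skip_size)
  skipped <- data.frame(set = names(db)[!keep],
                        reason = ifelse(skip_empty[!keep],
                                        "no members in ranked universe",
                                        "size outside [min_size, max_size]"),
                        stringsAsFactors = FALSE)
  sets <- sets[keep]
  sizes <- sizes[keep]
  if (length(sets) == 0L) {
    out <- data.frame(set = character(0), p = numeric(0), fdr_q = numeric(0),
                      es = numeric(0), nes = numeric(0), size = integer(0),
                      leading_edge = character(0), stringsAsFactors = FALSE)
    attr(out, "skipped") <- skipped
    class(out) <- c("enrichment_result", class(out))
    return(out)
  }

  set.seed(seed)
  nulls <- list()
  for (m in sort(unique(sizes)))
    nulls[[as.character(m)]] <- .null_es(m, n_perm, absr, N)

  es <- numeric(length(sets))
  pval <- numeric(length(sets))
  nes <- numeric(length(sets))
  le <- character(length(sets))
  for (i in seq_along(sets)) {
    pos <- sets[[i]]
    core <- .es_core(pos, absr[pos], N)
    es[i] <- core$es
    le[i] <- paste(names(ranked)[pos[core$le_idx]], collapse = "|")
    nl <- nulls[[as.character(sizes[i])]]
    same <- if (es[i] >= 0) nl[nl >= 0] else nl[nl < 0]
    if (length(same) == 0L) {
      pval[i] <- 1
      nes[i] <- NA_real_
    } else {
      pval[i] <- (1 + sum(abs(same) >= abs(es[i]))) / (1 + length(same))
      nes[i] <- es[i] / mean(abs(same))
    }
  }
  out <- data.frame(set = names(sets), p = pval, fdr_q = bh_fdr(pval),
                    es = es, nes = nes, size = as.integer(sizes),
                    leading_edge = le, stringsAsFactors = FALSE,
                    row.names = NULL)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Write enrichment results to a tab-separated file
#' @param enr an \code{enrichment_result}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_enrichment <- function(enr, path) {
  utils::write.table(enr[, c("set", "p", "fdr_q", "es", "nes", "size",
                             "leading_edge")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
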