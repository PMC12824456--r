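#' Configuration for the synthetic multi-dataset study design
#'
#' The default design mirrors a six-dataset, eight-contrast chronic-stress
#' study: two microarray and four RNA-seq datasets, two of the RNA-seq
#' datasets contributing separate susceptible and resilient contrasts that
#' conceptually share controls but are emitted as independent contrasts.
#' Platform coverage defaults (microarray 0.80, RNA-seq 0.90) leave roughly
#' 3 percent of genes observed in fewer than five contrasts, so the
#' minimum-contrast filter is exercised.
#'
#' @param n_genes number of simulated genes.
#' @param datasets data.frame with columns \code{dataset_id},
#'   \code{platform} ("microarray"/"rnaseq"), \code{n_contrasts} (1 or 2).
#' @param pi_de proportion of genes with a nonzero true pooled effect.
#' @param effect_sd sd of the true pooled log2 fold change for DE genes.
#' @param tau between-contrast heterogeneity sd (log2 units).
#' @param df_v chi-squared degrees of freedom controlling how noisy the
#'   per-gene sampling variances are around the platform base value.
#' @param base_v named vector of baseline sampling variances per platform.
#' @param coverage named vector: probability a gene is measured by a dataset
#'   of each platform.
#' @param probe_multiplicity probabilities that a microarray gene has 1, 2,
#'   or 3 probes (RNA-seq genes always have one element).
#' @param multi_mapped_fraction fraction of probe rows annotated with two
#'   gene symbols (excluded downstream as multi-mapped).
#' @param n_sets,set_size_range,n_planted_sets,plant_strength gene-set
#'   generation: total sets, size range, number of sets with planted
#'   enrichment, and the probability a planted-set member is drawn from the
#'   sign-consistent DE genes.
#' @param seed integer seed; mandatory.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 10000L,
                       datasets = data.frame(
                         dataset_id = paste0("DS", 1:6),
                         platform = c("microarray", "rnaseq", "rnaseq",
                                      "rnaseq", "rnaseq", "microarray"),
                         n_contrasts = c(1L, 2L, 2L, 1L, 1L, 1L),
                         stringsAsFactors = FALSE),
                       pi_de = 0.1, effect_sd = 0.4, tau = 0.1,
                       df_v = 10, base_v = c(microarray = 0.03, rnaseq = 0.05),
                       coverage = c(microarray = 0.80, rnaseq = 0.90),
                       probe_multiplicity = c(0.5, 0.3, 0.2),
                       multi_mapped_fraction = 0.05,
                       n_sets = 100L, set_size_range = c(10L, 100L),
                       n_planted_sets = 5L, plant_strength = 0.9,
                       seed) {
  if (missing(seed) || !is.finite(seed))
    stop("seed is mandatory: silent nondeterminism is not allowed")
  props <- c(pi_de = pi_de, multi_mapped_fraction = multi_mapped_fraction,
             plant_strength = plant_strength, coverage)
  if (any(props < 0 | props > 1))
    stop("proportions must lie in [0, 1]: ",
         paste(names(props)[props < 0 | props > 1], collapse = ", "))
  stopifnot(is.data.frame(datasets),
            all(c("dataset_id", "platform", "n_contrasts") %in% names(datasets)),
            all(datasets$platform %in% names(base_v)),
            all(datasets$platform %in% names(coverage)),
            n_genes >= 1, effect_sd > 0, tau >= 0, df_v > 0,
            abs(sum(probe_multiplicity) - 1) < 1e-8,
            set_size_range[1] <= set_size_range[2])
  cfg <- list(n_genes = as.integer(n_genes), datasets = datasets,
              pi_de = pi_de, effect_sd = effect_sd, tau = tau, df_v = df_v,
              base_v = base_v, coverage = coverage,
              probe_multiplicity = probe_multiplicity,
              multi_mapped_fraction = multi_mapped_fraction,
              n_sets = as.integer(n_sets),
              set_size_range = as.integer(set_size_range),
              n_planted_sets = as.integer(n_planted_sets),
              plant_strength = plant_strength, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Draw the ground truth for a synthetic study
#'
#' Per gene: a true pooled effect \code{mu_g} (zero with probability
#' \code{1 - pi_de}, otherwise Normal(0, effect_sd^2)) and a shared
#' between-contrast heterogeneity variance \code{tau^2}. Per dataset: a
#' coverage mask (which genes its platform measures). Gene sets are drawn
#' uniformly from all genes, except the planted sets, whose members come
#' from sign-consistent DE genes with probability \code{plant_strength}.
#'
#' @param config a \code{sim_config}.
#' @return object of class \code{sim_truth}: list with \code{genes},
#'   \code{mu}, \code{de_flag}, \code{tau2}, \code{contrasts} (data.frame
#'   with contrast_id, dataset_id, platform), \code{measured}
#'   (genes x contrasts logical matrix), \code{sets}, \code{set_planted},
#'   \code{set_sign}, and the \code{config}.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("Gene%05d", seq_len(n))
  de <- stats::rbinom(n, 1L, config$pi_de) == 1L
  mu <- numeric(n)
  mu[de] <- stats::rnorm(sum(de), 0, config$effect_sd)
  de <- mu != 0

  ds <- config$datasets
  contrasts <- do.call(rbind, lapply(seq_len(nrow(ds)), function(i) {
    lab <- if (ds$n_contrasts[i] == 2L) c("susceptible", "resilient") else "stress"
    data.frame(contrast_id = paste(ds$dataset_id[i], lab, sep = "_"),
               dataset_id = ds$dataset_id[i], platform = ds$platform[i],
               stringsAsFactors = FALSE)
  }))
  meas_ds <- sapply(seq_len(nrow(ds)), function(i)
    stats::runif(n) < config$coverage[[ds$platform[i]]])
  measured <- meas_ds[, match(contrasts$dataset_id, ds$dataset_id), drop = FALSE]
  dimnames(measured) <- list(genes, contrasts$contrast_id)

  if (config$n_planted_sets > 0 &&
      config$pi_de * n < config$set_size_range[2])
    stop("configuration error: expected DE gene count (", config$pi_de * n,
         ") smaller than the largest possible planted set (",
         config$set_size_range[2], ")")
  sizes <- sample(seq(config$set_size_range[1], config$set_size_range[2]),
                  config$n_sets, replace = TRUE)
  planted <- seq_len(config$n_sets) <= config$n_planted_sets
  signs <- ifelse(stats::runif(config$n_sets) < 0.5, 1, -1)
  signs[!planted] <- NA
  sets <- vector("list", config$n_sets)
  names(sets) <- sprintf("Set%03d", seq_len(config$n_sets))
  for (s in seq_len(config$n_sets)) {
    if (planted[s]) {
      pool_de <- genes[de & sign(mu) == signs[s]]
      pool_bg <- genes[!de]
      take_de <- stats::rbinom(1L, sizes[s], config$plant_strength)
      take_de <- min(take_de, length(pool_de))
      sets[[s]] <- c(sample(pool_de, take_de),
                     sample(pool_bg, sizes[s] - take_de))
    } else {
      sets[[s]] <- sample(genes, sizes[s])
    }
  }
  out <- list(genes = genes, mu = stats::setNames(mu, genes),
              de_flag = stats::setNames(de, genes), tau2 = config$tau^2,
              contrasts = contrasts, measured = measured,
              sets = sets, set_planted = stats::setNames(planted, names(sets)),
              set_sign = stats::setNames(signs, names(sets)),
              config = config)
  class(out) <- "sim_truth"
  out
}

#' Simulate probe-level contrast tables from a drawn truth
#'
#' For each contrast and measured gene the true contrast effect is
#' \code{theta = mu_g + u}, \code{u ~ N(0, tau^2)}; the observed effect adds
#' sampling noise \code{e ~ N(0, v)} with
#' \code{v = base_v(platform) * size_factor * chisq(df_v)/df_v}. Microarray
#' genes are expanded to 1-3 probes scattering around the gene value;
#' a configured fraction of probe rows receives a second gene symbol; the
#' t-statistic is emitted as \code{y/se} so the ingest SE-derivation path is
#' exercised (no SE column is written).
#'
#' @param config a \code{sim_config}.
#' @param truth the matching \code{sim_truth}.
#' @param dir optional directory; when given, per-contrast TSVs, a GMT file,
#'   and a truth TSV are written there.
#' @return list with \code{tables} (named list of probe-level data.frames
#'   with columns Element, GeneSymbol, Log2FC, Tstat, PValue),
#'   \code{contrasts}, \code{truth}, and (if \code{dir} given) \code{paths}.
#' @export
simulate_contrast_tables <- function(config, truth, dir = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(config$seed + 1L)
  genes <- truth$genes
  contrasts <- truth$contrasts
  nc <- nrow(contrasts)
  size_factor <- exp(stats::rnorm(nc, 0, 0.3))
  tables <- vector("list", nc)
  names(tables) <- contrasts$contrast_id
  for (i in seq_len(nc)) {
    plat <- contrasts$platform[i]
    g <- genes[truth$measured[, i]]
    ng <- length(g)
    u <- stats::rnorm(ng, 0, sqrt(truth$tau2))
    theta <- truth$mu[g] + u
    v <- config$base_v[[plat]] * size_factor[i] *
      stats::rchisq(ng, config$df_v) / config$df_v
    se <- sqrt(v)
    np <- if (plat == "microarray")
      sample(1:3, ng, replace = TRUE, prob = config$probe_multiplicity)
    else rep(1L, ng)
    gi <- rep(seq_len(ng), np)
    # each probe is an independent measurement of the contrast effect with
    # the gene's sampling SD, so the reported SE is honest per probe and the
    # mean-SE collapse policy is mildly conservative for multi-probe genes
    plfc <- theta[gi] + stats::rnorm(length(gi), 0, se[gi])
    pse <- se[gi]
    sym <- g[gi]
    multi <- stats::runif(length(gi)) < config$multi_mapped_fraction
    if (any(multi)) {
      other <- sample(genes, sum(multi), replace = TRUE)
      sym[multi] <- paste(sym[multi], other, sep = "|")
    }
    tstat <- plfc / pse
    tables[[i]] <- data.frame(
      Element = sprintf("%s_el%06d", contrasts$contrast_id[i], seq_along(gi)),
      GeneSymbol = sym, Log2FC = plfc, Tstat = tstat,
      PValue = 2 * stats::pnorm(-abs(tstat)), stringsAsFactors = FALSE)
  }
  out <- list(tables = tables, contrasts = contrasts, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- character(nc)
    for (i in seq_len(nc)) {
      paths[i] <- file.path(dir, paste0(contrasts$contrast_id[i], ".tsv"))
      utils::write.table(tables[[i]], paths[i], sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    gmt <- file.path(dir, "gene_sets.gmt")
    write_gmt(truth$sets, gmt,
              descriptions = ifelse(truth$set_planted, "planted", "background"))
    tpath <- file.path(dir, "truth.tsv")
    utils::write.table(
      data.frame(gene = genes, mu = truth$mu, de_flag = truth$de_flag,
                 stringsAsFactors = FALSE),
      tpath, sep = "\t", quote = FALSE, row.names = FALSE)
    out$paths <- c(paths, gmt = gmt, truth = tpath)
  }
  out
}

#' Simulate an external comparison study with an ortholog table
#'
#' External log2 fold changes are an attenuated, noisy copy of the true
#' pooled effects: \code{b * mu_g + N(0, noise_sd^2)}, with p-values from
#' the implied z-test. Human symbols are upper-cased mouse symbols; a
#' configurable fraction of mouse symbols receives additional conflicting
#' candidate rows (including support-count ties) so the ortholog-resolution
#' cascade is exercised.
#'
#' @param truth a \code{sim_truth}.
#' @param attenuation_b multiplicative attenuation of the true effects.
#' @param noise_sd sd of the external sampling noise (also used as the
#'   external SE for the p-value).
#' @param ortholog_noise fraction of mouse symbols given extra candidate
#'   ortholog rows.
#' @param seed integer seed.
#' @return list with \code{external} (data.frame gene/log2fc/p keyed by
#'   human symbol) and \code{ortholog} (raw candidate rows: mouse_symbol,
#'   human_symbol, support).
#' @export
simulate_external_study <- function(truth, attenuation_b = 0.5, noise_sd = 0.2,
                                    ortholog_noise = 0.1, seed) {
  stopifnot(inherits(truth, "sim_truth"))
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  genes <- truth$genes
  human <- toupper(genes)
  eps <- stats::rnorm(length(genes), 0, noise_sd)
  lfc <- attenuation_b * truth$mu + eps
  se <- max(noise_sd, 1e-12)
  p <- 2 * stats::pnorm(-abs(lfc / se))
  ortho <- data.frame(mouse_symbol = genes, human_symbol = human,
                      support = sample(6:12, length(genes), replace = TRUE),
                      stringsAsFactors = FALSE)
  extra_idx <- which(stats::runif(length(genes)) < ortholog_noise)
  if (length(extra_idx) > 0) {
    n_extra <- sample(1:2, length(extra_idx), replace = TRUE)
    rows <- rep(extra_idx, n_extra)
    # half the conflicts tie the true row's support to exercise row-index
    # tie-breaking; the rest are strictly weaker candidates
    tie <- stats::runif(length(rows)) < 0.5
    supp <- ifelse(tie, ortho$support[rows],
                   pmax(1, ortho$support[rows] -
                          sample(1:5, length(rows), replace = TRUE)))
    extra <- data.frame(mouse_symbol = genes[rows],
                        human_symbol = paste0(human[rows], "L",
                                              seq_along(rows) %% 3 + 1),
                        support = supp, stringsAsFactors = FALSE)
    ortho <- rbind(ortho, extra)
    ortho <- ortho[order(ortho$mouse_symbol,
                         -ortho$support, ortho$human_symbol), ]
    rownames(ortho) <- NULL
  }
  list(external = data.frame(gene = human, log2fc = unname(lfc), p = unname(p),
                             stringsAsFactors = FALSE),
       ortholog = ortho)
}
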