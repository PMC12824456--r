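# shared fixture builders: everything generated in code at test time

write_probe_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a small hand-made probe table exercising every ingest branch
probe_table_fixture <- function() {
  data.frame(
    Element = paste0("p", 1:8),
    GeneSymbol = c("Fos", "Fos", "Gm123|Fos", "Arc", "", "Npas4", "Bdnf",
                   "Egr1"),
    Log2FC = c(-0.5, -0.3, -0.6, 0.4, 0.2, 0.1, NA, 0.3),
    Tstat = c(-2.5, -1.5, -3.0, 2.0, 1.0, 0.0, 1.0, 1.5),
    PValue = c(0.02, 0.2, 0.01, 0.06, 0.4, 0.9, 0.5, 0.2),
    stringsAsFactors = FALSE)
}

# contrast_result built directly (bypassing parsing) for align tests
make_contrast_result <- function(genes, y, se, contrast_id,
                                 dataset_id = contrast_id,
                                 platform = "rnaseq") {
  out <- data.frame(gene = genes, y = y, se = se, sv = se^2,
                    n_probes = 1L, stringsAsFactors = FALSE)
  attr(out, "contrast_id") <- contrast_id
  attr(out, "dataset_id") <- dataset_id
  attr(out, "platform") <- platform
  attr(out, "exclusions") <- c(usable = length(genes), multi_mapped = 0L,
                               unmapped = 0L, unusable = 0L)
  class(out) <- c("contrast_result", class(out))
  out
}

# independent grid oracle for the REML heterogeneity estimate
grid_reml_tau2 <- function(y, v, upper = 5, step = 1e-4) {
  grid <- seq(0, upper, by = step)
  w <- outer(grid, v, function(t2, vv) 1 / (vv + t2))
  sw <- rowSums(w)
  mu <- rowSums(sweep(w, 2, y, `*`)) / sw
  resid2 <- (matrix(y, nrow = length(grid), ncol = length(y), byrow = TRUE) - mu)^2
  ll <- -0.5 * rowSums(log(outer(grid, v, `+`))) - 0.5 * log(sw) -
    0.5 * rowSums(w * resid2)
  grid[which.max(ll)]
}

# from-definition BH step-up oracle: q_(i) = min_{j>=i} p_(j) * m / j
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  run <- Inf
  for (j in m:1) {
    run <- min(run, ps[j] * m / j)
    q[j] <- min(run, 1)
  }
  q[order(o)]
}

# tiny deterministic sim config for pipeline-level tests
small_sim_config <- function(seed, n_genes = 600, ...) {
  sim_config(n_genes = n_genes, n_sets = 15L, set_size_range = c(5L, 20L),
             n_planted_sets = 2L, seed = seed, ...)
}
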