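test_that("simulation config validates proportions and requires a seed", {
  expect_error(sim_config(n_genes = 100), "seed")
  expect_error(sim_config(n_genes = 100, pi_de = 1.5, seed = 1), "\\[0, 1\\]")
  cfg <- small_sim_config(seed = 1)
  expect_s3_class(cfg, "sim_config")
  expect_equal(nrow(cfg$datasets), 6)
  expect_equal(sum(cfg$datasets$n_contrasts), 8)  # two datasets emit pairs
})

test_that("simulated truth honours the DE proportion and planting", {
  # null configuration: no DE genes at all
  cfg0 <- sim_config(n_genes = 500, pi_de = 0, n_planted_sets = 0L,
                     n_sets = 5L, set_size_range = c(5L, 20L), seed = 2)
  tr0 <- simulate_truth(cfg0)
  expect_true(all(tr0$mu == 0))
  expect_false(any(tr0$de_flag))

  # DE count within the binomial 99% interval
  cfg <- sim_config(n_genes = 5000, pi_de = 0.1, seed = 3,
                    n_sets = 10L, set_size_range = c(10L, 50L),
                    n_planted_sets = 2L)
  tr <- simulate_truth(cfg)
  bounds <- qbinom(c(0.005, 0.995), 5000, 0.1)
  expect_gte(sum(tr$de_flag), bounds[1])
  expect_lte(sum(tr$de_flag), bounds[2])
  expect_identical(tr$de_flag, tr$mu != 0)

  # degenerate plant: every planted member is DE with a common sign
  cfg1 <- sim_config(n_genes = 2000, pi_de = 0.2, plant_strength = 1,
                     n_sets = 6L, set_size_range = c(10L, 30L),
                     n_planted_sets = 3L, seed = 4)
  tr1 <- simulate_truth(cfg1)
  for (s in names(tr1$sets)[tr1$set_planted]) {
    mem <- tr1$sets[[s]]
    expect_true(all(tr1$de_flag[mem]))
    expect_true(all(sign(tr1$mu[mem]) == tr1$set_sign[s]))
  }
})

test_that("contrast tables reflect the variance model and seed determinism", {
  cfg <- small_sim_config(seed = 5, n_genes = 2000)
  tr <- simulate_truth(cfg)
  sim <- simulate_contrast_tables(cfg, tr)
  expect_equal(length(sim$tables), 8)
  expect_equal(names(sim$tables), tr$contrasts$contrast_id)

  # identical seed => identical outputs
  sim2 <- simulate_contrast_tables(cfg, simulate_truth(cfg))
  expect_identical(sim$tables, sim2$tables)

  # moment check: across contrasts, var(y - mu) ~ tau^2 + mean(v)
  # (single-element RNA-seq contrasts so probe scatter doesn't enter)
  rna <- which(tr$contrasts$platform == "rnaseq")
  devs <- vs <- numeric(0)
  for (i in rna) {
    t <- sim$tables[[i]]
    one <- !grepl("|", t$GeneSymbol, fixed = TRUE)
    mu <- tr$mu[t$GeneSymbol[one]]
    devs <- c(devs, t$Log2FC[one] - mu)
    vs <- c(vs, (t$Log2FC[one] / t$Tstat[one])^2)
  }
  expect_equal(var(devs), tr$tau2 + mean(vs), tolerance = 0.15)

  # noiseless limit: tau = 0, tiny base_v => observations hug mu
  cfg0 <- sim_config(n_genes = 300, tau = 0,
                     base_v = c(microarray = 1e-8, rnaseq = 1e-8),
                     n_sets = 5L, set_size_range = c(5L, 10L),
                     n_planted_sets = 0L, seed = 6)
  tr0 <- simulate_truth(cfg0)
  sim0 <- simulate_contrast_tables(cfg0, tr0)
  t1 <- sim0$tables[[2]]
  one <- !grepl("|", t1$GeneSymbol, fixed = TRUE)
  expect_lt(max(abs(t1$Log2FC[one] - tr0$mu[t1$GeneSymbol[one]])), 1e-3)
})

test_that("multi-mapped probes appear at the configured rate and are excluded downstream", {
  cfg <- sim_config(n_genes = 4000, multi_mapped_fraction = 0.05,
                    n_sets = 5L, set_size_range = c(5L, 10L),
                    n_planted_sets = 0L, seed = 7)
  tr <- simulate_truth(cfg)
  sim <- simulate_contrast_tables(cfg, tr)
  total_multi <- 0L; total_rows <- 0L
  for (cid in names(sim$tables)) {
    path <- write_probe_tsv(sim$tables[[cid]])
    recs <- parse_contrast_table(path)
    i <- match(cid, sim$contrasts$contrast_id)
    res <- collapse_to_genes(recs, cid, sim$contrasts$dataset_id[i],
                             sim$contrasts$platform[i])
    ex <- attr(res, "exclusions")
    expect_equal(sum(ex), nrow(recs))   # conservation in every contrast
    total_multi <- total_multi + ex[["multi_mapped"]]
    total_rows <- total_rows + nrow(recs)
  }
  bounds <- qbinom(c(0.005, 0.995), total_rows, 0.05)
  expect_gte(total_multi, bounds[1])
  expect_lte(total_multi, bounds[2])
})

test_that("the closed loop recovers true pooled effects and heterogeneity", {
  cfg <- small_sim_config(seed = 8, n_genes = 1500)
  tr <- simulate_truth(cfg)
  sim <- simulate_contrast_tables(cfg, tr)
  results <- lapply(names(sim$tables), function(cid) {
    path <- write_probe_tsv(sim$tables[[cid]])
    i <- match(cid, sim$contrasts$contrast_id)
    collapse_to_genes(parse_contrast_table(path), cid,
                      sim$contrasts$dataset_id[i], sim$contrasts$platform[i])
  })
  meta <- run_meta(align_contrasts(results, min_contrasts = 5))
  r <- meta$results
  mu_true <- tr$mu[r$gene]
  expect_lt(abs(mean(r$mu_hat - mu_true)), 0.01)       # negligible bias
  # estimated heterogeneity: clamping tau2 at zero biases the per-gene mean
  # upward at small k, so the contract is that the bias shrinks as k grows
  bias_for_k <- function(k, seed) {
    set.seed(seed)
    tau2 <- tr$tau2; v <- 0.05; n <- 600
    yk <- matrix(rnorm(n * k, 0, sqrt(tau2 + v)), n, k)
    t2 <- apply(yk, 1, function(y) reml_tau2(y, rep(v, k))$tau2)
    mean(t2) - tau2
  }
  b8 <- bias_for_k(8, 91)
  b20 <- bias_for_k(20, 92)
  expect_lt(abs(b20), abs(b8))
  expect_lt(abs(b20), 0.005)
  # called genes with a strong true effect have the right sign
  strong <- r$deg_flag & abs(mu_true) >= 0.5
  if (any(strong))
    expect_true(all(sign(r$mu_hat[strong]) == sign(mu_true[strong])))
})

test_that("external study simulation supports the comparison contract", {
  cfg <- small_sim_config(seed = 9, n_genes = 1000)
  tr <- simulate_truth(cfg)
  # perfect external study reproduces effects exactly
  ext0 <- simulate_external_study(tr, attenuation_b = 1, noise_sd = 0,
                                  ortholog_noise = 0, seed = 10)
  deg <- data.frame(gene = tr$genes[tr$de_flag],
                    log2fc = unname(tr$mu[tr$de_flag]),
                    stringsAsFactors = FALSE)
  omap <- resolve_orthologs(ext0$ortholog)
  cmp <- suppressWarnings(compare_deg_effects(deg, ext0$external,
                                              ortholog = omap))
  expect_equal(cmp$pearson_r, 1, tolerance = 1e-12)
  expect_equal(cmp$slope, 1, tolerance = 1e-12)

  # conflicting ortholog rows still resolve to the true human symbol
  ext1 <- simulate_external_study(tr, 0.5, 0.2, ortholog_noise = 0.3, seed = 11)
  omap1 <- resolve_orthologs(ext1$ortholog)
  expect_equal(nrow(omap1), length(tr$genes))
  expect_identical(sort(omap1$human_symbol), sort(toupper(tr$genes)))

  # b = 0: correlations centred on zero across replicates
  rs <- sapply(1:10, function(s) {
    e <- simulate_external_study(tr, 0, 0.2, ortholog_noise = 0, seed = 100 + s)
    suppressWarnings(compare_deg_effects(deg, e$external,
                                         ortholog = resolve_orthologs(e$ortholog))$pearson_r)
  })
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)) + 0.05)
})
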