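test_that("REML recovers closed forms in the equal-variance case", {
  # s^2 = 1 equals v, so no excess dispersion
  est <- reml_tau2(c(1, 2, 3), c(1, 1, 1))
  expect_equal(est$tau2, 0)
  expect_true(est$converged)
  # constant effects: zero dispersion
  expect_equal(reml_tau2(rep(0.7, 5), rep(1, 5))$tau2, 0)

  set.seed(31)
  for (i in 1:50) {
    k <- sample(4:10, 1)
    v <- runif(1, 0.02, 0.5)
    y <- rnorm(k, 0, 1)
    expected <- max(0, var(y) - v)
    expect_equal(reml_tau2(y, rep(v, k))$tau2, expected, tolerance = 1e-8)
    # mu_hat is the arithmetic mean under equal weights
    expect_equal(fit_random_effects(y, rep(v, k))$mu_hat, mean(y),
                 tolerance = 1e-10)
  }
})

test_that("REML agrees with a likelihood-grid oracle and with metafor", {
  set.seed(32)
  for (i in 1:40) {
    k <- sample(5:8, 1)
    y <- rnorm(k)
    v <- runif(k, 0.01, 1)
    ours <- reml_tau2(y, v)$tau2
    expect_lt(abs(ours - grid_reml_tau2(y, v)), 1e-4)
  }
  skip_if_not_installed("metafor")
  set.seed(33)
  for (i in 1:20) {
    k <- sample(5:8, 1)
    y <- rnorm(k)
    v <- runif(k, 0.01, 1)
    ref <- metafor::rma(yi = y, vi = v, method = "REML",
                        control = list(tol = 1e-10))
    fit <- fit_random_effects(y, v)
    # both optimizers are iterative; agreement to ~1e-3 relative is the
    # meaningful cross-check (the grid oracle above pins absolute accuracy)
    expect_equal(fit$tau2, ref$tau2, tolerance = 1e-3)
    expect_equal(fit$mu_hat, as.numeric(ref$beta), tolerance = 1e-3)
    expect_equal(fit$se_mu, ref$se, tolerance = 1e-3)
  }
})

test_that("the pooled fit satisfies its defining identities", {
  y <- c(1, 2, 3); v <- c(1, 1, 1)
  fit <- fit_random_effects(y, v)
  expect_equal(fit$mu_hat, 2)
  expect_equal(fit$se_mu, sqrt(1 / 3))
  expect_equal(c(fit$ci_low, fit$ci_high),
               2 + c(-1, 1) * 1.959964 * sqrt(1 / 3), tolerance = 1e-6)

  # zero effects -> exact null
  f0 <- fit_random_effects(rep(0, 5), runif(5, 0.1, 1))
  expect_equal(f0$mu_hat, 0)
  expect_equal(f0$z, 0)
  expect_equal(f0$p, 1)

  # weighting identity re-evaluated at the returned tau2
  set.seed(34)
  for (i in 1:20) {
    k <- sample(5:8, 1)
    y <- rnorm(k); v <- runif(k, 0.01, 1)
    fit <- fit_random_effects(y, v)
    w <- 1 / (v + fit$tau2)
    expect_equal(fit$mu_hat, sum(w * y) / sum(w), tolerance = 1e-12)
    expect_equal(fit$se_mu, 1 / sqrt(sum(w)), tolerance = 1e-12)
    expect_true(fit$ci_low <= fit$mu_hat && fit$mu_hat <= fit$ci_high)
    expect_gte(fit$tau2, 0)
    expect_gte(fit$Q, 0)
    expect_true(fit$I2 >= 0 && fit$I2 <= 100)
  }
})

test_that("the fit is scale-equivariant and ignores infinite-variance contrasts", {
  set.seed(35)
  for (i in 1:10) {
    k <- sample(5:8, 1)
    y <- rnorm(k); v <- runif(k, 0.01, 1)
    c_ <- runif(1, 0.5, 3)
    f1 <- fit_random_effects(y, v)
    f2 <- fit_random_effects(c_ * y, c_^2 * v)
    expect_equal(f2$mu_hat, c_ * f1$mu_hat, tolerance = 1e-8)
    expect_equal(f2$tau2, c_^2 * f1$tau2, tolerance = 1e-6)
    expect_equal(f2$z, f1$z, tolerance = 1e-6)
    expect_equal(f2$p, f1$p, tolerance = 1e-6)
    expect_equal(f2$Q, f1$Q, tolerance = 1e-8)
    expect_equal(f2$I2, f1$I2, tolerance = 1e-6)
  }
  # a nearly-uninformative contrast barely moves the pooled mean
  y <- c(0.5, 0.4, 0.6, 0.5, 0.45); v <- rep(0.04, 5)
  base <- fit_random_effects(y, v)$mu_hat
  padded <- fit_random_effects(c(y, 50), c(v, 1e8))$mu_hat
  expect_equal(padded, base, tolerance = 1e-4)
})

test_that("degenerate meta-analysis inputs are rejected", {
  expect_error(reml_tau2(1, 1), "at least 2")
  expect_error(reml_tau2(c(1, 2), c(1, 0)), "variances")
  expect_error(reml_tau2(c(1, 2), c(1, -1)), "variances")
  expect_error(reml_tau2(c(1, NA), c(1, 1)), "finite")
})

test_that("BH adjustment matches the step-up definition and handles NAs", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.1, 0.9)), c(0.015, 0.15, 0.9))
  expect_equal(bh_fdr(1), 1)

  # NAs excluded from m and returned missing
  q <- bh_fdr(c(0.005, NA, 0.1, 0.9))
  expect_true(is.na(q[2]))
  expect_equal(q[-2], c(0.015, 0.15, 0.9))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(36)
  for (i in 1:30) {
    n <- sample(1:200, 1)
    p <- round(runif(n), sample(1:3, 1))   # rounding forces ties
    expect_equal(bh_fdr(p), stepup_bh(p), tolerance = 1e-12)
  }
  # q >= p and monotone in the p-ordering
  p <- runif(100)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("per-gene fits are independent and unstable genes are quarantined", {
  # gene with identical (y, v) replicated across contrasts matches the
  # single-vector fit
  y <- c(-0.4, -0.5, -0.3, -0.45, -0.35)
  se <- c(0.2, 0.25, 0.15, 0.2, 0.3)
  results <- lapply(1:5, function(j)
    make_contrast_result(c("target", "other"), c(y[j], 0.1), c(se[j], 0.2),
                         paste0("c", j)))
  inp <- align_contrasts(results, min_contrasts = 5)
  meta <- run_meta(inp)
  direct <- fit_random_effects(y, se^2)
  row <- meta$results[meta$results$gene == "target", ]
  expect_equal(row$mu_hat, direct$mu_hat)
  expect_equal(row$tau2, direct$tau2)
  expect_equal(row$p, direct$p)
  expect_equal(row$k, 5)

  # effects so extreme the restricted likelihood overflows to non-finite:
  # the gene must be flagged unstable and carry no q-value
  res_bad <- lapply(1:5, function(j)
    make_contrast_result(c("ok", "patho"), c(0.1, (-1)^j * 1e200), c(0.2, 0.2),
                         paste0("c", j)))
  # overflow arithmetic inside the quarantined fit emits numeric warnings
  meta2 <- suppressWarnings(run_meta(align_contrasts(res_bad, min_contrasts = 5)))
  patho <- meta2$results[meta2$results$gene == "patho", ]
  expect_false(patho$converged)
  expect_true(is.na(patho$fdr_q))
  expect_false(patho$deg_flag)
  expect_equal(meta2$n_converged + meta2$n_unstable, meta2$n_genes)
  # BH m counts converged genes only
  ok <- meta2$results[meta2$results$gene == "ok", ]
  expect_equal(ok$fdr_q, ok$p)
})

test_that("run_meta output is ordered, flagged, and serializable", {
  set.seed(37)
  results <- lapply(1:6, function(j) {
    g <- sprintf("g%02d", 1:40)
    make_contrast_result(g, rnorm(40, ifelse(seq_along(g) <= 5, -0.8, 0), 0.2),
                         runif(40, 0.1, 0.3), paste0("c", j))
  })
  meta <- run_meta(align_contrasts(results, min_contrasts = 5))
  r <- meta$results
  expect_true(!is.unsorted(r$fdr_q[!is.na(r$fdr_q)]))
  expect_identical(r$deg_flag, !is.na(r$fdr_q) & r$fdr_q < 0.05)
  expect_true(all(r$fdr_q >= r$p, na.rm = TRUE))
  p <- tempfile(fileext = ".tsv")
  write_meta_results(meta, p)
  back <- read.delim(p, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(r))
  expect_equal(back$mu_hat, r$mu_hat, tolerance = 1e-10)
  # the strongly shifted genes are detected with the right sign
  expect_true(all(r$mu_hat[r$gene %in% sprintf("g%02d", 1:5)] < 0))
})

test_that("the Knapp-Hartung flag widens small-k inference", {
  set.seed(38)
  y <- rnorm(5, 0.5, 0.3); v <- runif(5, 0.05, 0.2)
  wald <- fit_random_effects(y, v)
  kh <- fit_random_effects(y, v, knapp_hartung = TRUE)
  expect_equal(kh$mu_hat, wald$mu_hat)      # point estimate unchanged
  expect_true(kh$ci_high - kh$ci_low > 0)
  expect_true(kh$p >= 0 && kh$p <= 1)
})
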