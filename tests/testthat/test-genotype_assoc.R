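three_clusters <- function(n = 300, sd = 0.05, seed = 1,
                           means = c(-0.66, 0, 0.40),
                           w = c(0.2, 0.6, 0.2)) {
  set.seed(seed)
  k <- sample.int(3, n, replace = TRUE, prob = w)
  rnorm(n, means[k], sd)
}

test_that("region summaries follow their closed forms", {
  pm <- toy_probe_map(10, spacing = 1000)
  region <- tibble::tibble(chrom = "chr1", start = 2999, end = 3000) # probe 3 only
  lrr <- matrix(rnorm(50), 5, 10,
                dimnames = list(sprintf("S%d", 1:5), pm$probe_id))
  s <- summarize_region(lrr, pm, region, "mean")
  expect_equal(s$score, unname(lrr[, 3]))
  expect_equal(attr(s, "n_probes"), 1)

  # constant rows: both methods monotone in the row constant
  region <- tibble::tibble(chrom = "chr1", start = 0, end = 10000)
  cvals <- c(-0.6, -0.1, 0, 0.2, 0.5)
  lrr_c <- matrix(rep(cvals, 10), 5, 10)
  expect_equal(summarize_region(lrr_c, pm, region, "mean")$score, cvals)
  p <- summarize_region(lrr_c, pm, region, "pc1")$score
  expect_true(all(diff(p[order(cvals)]) > 0) || all(diff(rank(p)) > 0))
  expect_equal(rank(p), rank(cvals))

  # rank-1 matrix u v^T: pc1 scores proportional to u
  set.seed(2)
  u <- rnorm(5); v <- abs(rnorm(10)) + 0.5
  s <- summarize_region(outer(u, v), pm, region, "pc1")$score
  uc <- u - mean(u)
  expect_equal(abs(cor(s, uc)), 1, tolerance = 1e-10)
  expect_gte(cor(s, rowMeans(outer(u, v))), 0)

  none <- tibble::tibble(chrom = "chr9", start = 0, end = 100)
  expect_error(summarize_region(lrr, pm, none), class = "cnvrisk_region_skipped")
  expect_error(summarize_region(matrix(1, 5, 10), pm, region, "pc1"),
               class = "cnvrisk_degenerate_summary")
})

test_that("K = 1 mixture fits reduce to moment estimates with closed-form BIC", {
  set.seed(3)
  x <- rnorm(100, 0.2, 0.3)
  f <- fit_mixture(x, 1, "free", "free", seed = 1)
  expect_equal(f$means, mean(x), tolerance = 1e-6)
  expect_equal(f$variances, var(x) * 99 / 100, tolerance = 1e-6)
  ll <- sum(dnorm(x, f$means, sqrt(f$variances), log = TRUE))
  expect_equal(f$loglik, ll, tolerance = 1e-8)
  expect_equal(f$bic, -2 * ll + 2 * log(100), tolerance = 1e-6)
  expect_equal(f$copy_numbers, 2L)
})

test_that("mixture posteriors are proper and EM never decreases the likelihood", {
  x <- three_clusters(seed = 4)
  for (mm in c("free", "proportional")) {
    for (vm in c("free", "proportional", "constant")) {
      f <- fit_mixture(x, 3, mm, vm, seed = 1)
      expect_s3_class(f, "cnv_mixture")
      expect_false(inherits(f, "cnv_mixture_failed"))
      expect_equal(rowSums(f$posterior), rep(1, length(x)), tolerance = 1e-9)
      expect_equal(sum(f$weights), 1, tolerance = 1e-9)
    }
  }
  # monotone likelihood trace, checked on the raw EM engine
  init <- cnvrisk:::init_mixture(x, 3)
  em <- cnvrisk:::mixture_em(x, 3, "free", "constant", init, c(1L, 2L, 3L))
  expect_false(em$collapsed)
  expect_true(all(diff(em$ll_trace) > -1e-6))
})

test_that("well-separated clusters are genotyped almost perfectly", {
  set.seed(5)
  k <- sample.int(3, 400, replace = TRUE, prob = c(0.2, 0.6, 0.2))
  x <- rnorm(400, c(-0.66, 0, 0.40)[k], 0.05)
  f <- fit_mixture(x, 3, "free", "constant", seed = 1)
  g <- assign_genotypes(f)
  expect_gte(mean(g == k), 0.99) # labels anchored: modal component is CN 2
  expect_equal(sort(unique(g)), 1:3)
})

test_that("BIC selects K = 3 for three clear clusters in most seeds", {
  hits <- vapply(1:50, function(s) {
    x <- three_clusters(n = 300, sd = 0.05, seed = 200 + s)
    fit <- select_model(x, k_grid = 1:4,
                        model_grid = data.frame(mean_model = "free",
                                                var_model = "constant"),
                        seed = 1)
    !inherits(fit, "cnv_mixture_failed") && fit$K == 3
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("model selection prefers parsimony and excludes problem loci", {
  set.seed(6)
  x <- rnorm(200, 0, 0.1) # unimodal
  fit <- select_model(x, k_grid = 1:3, seed = 1)
  expect_equal(fit$K, 1)

  # deterministic given identical inputs
  fit2 <- select_model(x, k_grid = 1:3, seed = 1)
  expect_equal(glance(fit), glance(fit2))

  # singleton locus excluded with the rare/singleton reason
  ex <- select_model(x, k_grid = 1:3, seed = 1, n_events = 1)
  expect_s3_class(ex, "cnv_mixture_excluded")
  expect_match(ex$reason, "singleton")
})

test_that("the joint LRT is near zero without effect and powered with one", {
  # beta = 0 data: statistic small, p not extreme
  x <- three_clusters(n = 400, sd = 0.05, seed = 7)
  set.seed(7)
  y <- rbinom(400, 1, 0.5)
  res <- lrt_association(x, y, 3, "free", "constant", seed = 1)
  expect_false(res$excluded)
  expect_gte(res$lrt_stat, 0)
  expect_lt(res$lrt_stat, 8)

  # strong planted per-copy effect: median LRT over seeds clears 3.84
  lrts <- vapply(1:11, function(s) {
    set.seed(300 + s)
    k <- sample.int(3, 400, replace = TRUE, prob = c(0.2, 0.6, 0.2))
    x <- rnorm(400, c(-0.66, 0, 0.40)[k], 0.05)
    y <- rbinom(400, 1, plogis(-2 + 1.0 * k))
    lrt_association(x, y, 3, "free", "constant", seed = 1)$lrt_stat
  }, numeric(1))
  expect_gt(median(lrts), qchisq(0.95, 1))
})

test_that("the per-copy logistic follow-up recovers an odds ratio", {
  set.seed(8)
  k <- sample.int(3, 1500, replace = TRUE, prob = c(0.2, 0.6, 0.2))
  x <- rnorm(1500, c(-0.66, 0, 0.40)[k], 0.05)
  y <- rbinom(1500, 1, plogis(-2 * log(2) + log(2) * k))
  f <- fit_mixture(x, 3, "free", "constant", seed = 1)
  res <- percopy_logistic(f, y)
  expect_false(res$excluded)
  expect_gt(res$or_hi, 2 * 0.99)
  expect_lt(res$or_lo, 2 * 1.01)
  expect_equal(unname(res$per_copy_or), 2, tolerance = 0.25)

  # single observed class -> excluded
  f1 <- fit_mixture(rnorm(100, 0, 0.05), 1, "free", "constant", seed = 1)
  expect_true(percopy_logistic(f1, rbinom(100, 1, 0.5))$excluded)
})

test_that("Bonferroni bookkeeping flags the documented counts", {
  res <- tibble::tibble(lrt_p = c(1e-5, 0.01, 0.04, 0.06, rep(0.5, 6)))
  out <- multiple_testing(res, alpha = 0.05)
  expect_equal(out$bonferroni_threshold[1], 0.005)
  expect_equal(sum(out$significant_bonferroni), 1)
  expect_equal(sum(out$significant_nominal), 3)
  # excluded rows are not counted as tested
  res$lrt_p[10] <- NA
  out <- multiple_testing(res, alpha = 0.05)
  expect_equal(out$bonferroni_threshold[1], 0.05 / 9)
})

test_that("the locus scan runs end to end on a cohort with a risk locus", {
  risk <- list(beta = log(2.5), cn_freqs = c(0.02, 0.18, 0.6, 0.18, 0.02))
  # the source population is 4x the study size when a risk locus is set, so
  # the probe space must hold all its private singletons without collision
  cfg <- sim_config(n_cases = 40, n_controls = 40, n_probes = 6000,
                    n_chroms = 2, n_common_cnvrs = 2, singleton_rate = 0.15,
                    duplicate_pairs = 0, n_batches = 2, n_snps = 0,
                    lrr_sd_range = c(0.08, 0.14), risk_locus = risk,
                    prop_quad_cases = 0, prop_quad_controls = 0, seed = 17)
  co <- simulate_cohort(cfg)
  calls <- call_cnvs(co, "viterbi")
  cnvrs <- cluster_cnvrs(calls)
  res <- cnvr_association(co, cnvrs, platform_filter = "duo",
                          summary_method = "mean", k_grid = 1:4, seed = 1)
  expect_equal(nrow(res), nrow(cnvrs))
  expect_true(all(c("lrt_stat", "lrt_p", "per_copy_or",
                    "significant_bonferroni") %in% names(res)))
  # singleton CNVRs are excluded as rare events
  sing <- res$cnvr_id %in% cnvrs$cnvr_id[cnvrs$singleton]
  expect_true(all(res$excluded[sing]))
  # the risk CNVR (largest multi-member locus overlapping the planted risk
  # interval) should be among the tested, low-p loci
  risk_iv <- tibble::tibble(chrom = co$risk_locus$chrom,
                            start = co$risk_locus$start,
                            end = co$risk_locus$end)
  hit <- which(cnvrs$chrom == risk_iv$chrom &
                 cnvrs$start < risk_iv$end & risk_iv$start < cnvrs$end &
                 !cnvrs$singleton)
  expect_gte(length(hit), 1)
  tested <- res[res$cnvr_id %in% cnvrs$cnvr_id[hit] & !res$excluded, ]
  expect_gte(nrow(tested), 1)
  expect_lt(min(tested$lrt_p), 0.05)
})

test_that("published locus table ships intact", {
  tab <- published_cnvr_lrt()
  expect_equal(nrow(tab), 176)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_setequal(unique(tab$type), c("deletion", "duplication", "multiallelic"))
})
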