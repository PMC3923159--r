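model <- hmm_model()

test_that("GC correction removes a GC-linear wave and preserves flat signal", {
  set.seed(1)
  pm <- toy_probe_map(500, gc = runif(500, 0.3, 0.7))
  # exactly linear in gc -> quadratic fit removes it entirely
  lrr <- 2 * (pm$gc - mean(pm$gc))
  out <- gc_correct(lrr, pm)
  expect_lt(max(abs(out - mean(lrr))), 1e-10)

  # constant signal -> intercept-only fit, output equals input
  expect_equal(gc_correct(rep(0.3, 500), pm), rep(0.3, 500))

  # signal independent of gc -> output close to input
  lrr <- rnorm(500, 0, 0.2)
  out <- gc_correct(lrr, pm)
  expect_lt(max(abs(out - lrr)), 0.1)
  expect_gt(cor(out, lrr), 0.99)

  # missing values pass through
  lrr[10] <- NA
  expect_true(is.na(gc_correct(lrr, pm)[10]))
  expect_error(gc_correct(rep(NA_real_, 500), pm), class = "cnvrisk_domain_error")
})

test_that("emission likelihood peaks at the generating state and factorizes", {
  ll <- vapply(0:4, function(s) emission_loglik(0, 0.5, 0.5, s, model),
               numeric(1))
  expect_equal(which.max(ll) - 1L, 2L)

  # missing BAF reduces to the LRR factor
  w <- model$uniform_outlier_weight
  expected <- log((1 - w) * dnorm(-0.66, model$lrr_means[2], model$lrr_sds[2]) +
                    w * dunif(-0.66, -5, 5))
  expect_equal(emission_loglik(-0.66, NA, 0.5, 1, model), expected)

  expect_error(emission_loglik(0, 0.5, 0.5, 7, model),
               class = "cnvrisk_domain_error")
})

test_that("emission densities integrate to one over (lrr, baf)", {
  lrr_grid <- seq(-6, 6, length.out = 1201)
  baf_grid <- seq(0.0005, 0.9995, length.out = 1000)
  d_lrr <- diff(lrr_grid)[1]; d_baf <- diff(baf_grid)[1]
  for (s in c(0L, 1L, 2L, 3L)) {
    ll <- outer(lrr_grid, baf_grid,
                function(l, b) emission_loglik(l, b, 0.4, s, model))
    mass <- sum(exp(ll)) * d_lrr * d_baf
    expect_equal(mass, 1, tolerance = 0.01)
  }
})

test_that("transitions are stochastic with the documented distance limits", {
  A <- transition_matrix(1, model)
  expect_lt(max(abs(A - diag(5))), 1e-6)

  for (d in c(17, 5e3, 1e5, 2e6)) {
    A <- transition_matrix(d, model)
    expect_equal(rowSums(A), rep(1, 5))
    expect_true(all(A >= 0))
  }

  A <- transition_matrix(model$distance_scale, model)
  off_mass <- 1 - diag(A)
  expect_equal(off_mass,
               rep((1 - model$stay_base) * (1 - exp(-1)), 5))
})

test_that("planted aberrations are called with exact spans (both decoders)", {
  pm <- toy_probe_map(60, pfb = runif(60, 0.2, 0.8))
  sig <- toy_signal(pm, runs = list(list(at = 21:40, cn = 1L)), seed = 2)
  for (fun in list(call_viterbi, call_posterior)) {
    calls <- fun(sig$lrr, sig$baf, pm, model, "s1", apply_gc_correct = FALSE)
    expect_equal(nrow(calls), 1)
    expect_equal(calls$copy_number, 1L)
    expect_equal(calls$type, "deletion")
    expect_equal(calls$n_probes, 20L)
    expect_equal(calls$start, pm$pos[21] - 1)
    expect_equal(calls$end, pm$pos[40])
  }

  dup <- toy_signal(pm, runs = list(list(at = 21:40, cn = 3L)), seed = 2)
  calls <- call_viterbi(dup$lrr, dup$baf, pm, model, "s1", apply_gc_correct = FALSE)
  expect_equal(calls$copy_number, 3L)
  expect_equal(calls$type, "duplication")

  null <- toy_signal(pm, seed = 3)
  expect_equal(nrow(call_viterbi(null$lrr, null$baf, pm, model, "s1",
                                 apply_gc_correct = FALSE)), 0)
  expect_equal(nrow(call_posterior(null$lrr, null$baf, pm, model, "s1",
                                   apply_gc_correct = FALSE)), 0)
})

test_that("Viterbi matches exhaustive path enumeration on random instances", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:7, 1)
    pm <- toy_probe_map(n, spacing = sample(c(2e3, 2e4, 2e5), 1),
                        pfb = runif(n))
    lrr <- rnorm(n, sample(c(-0.7, 0, 0.4), 1), 0.3)
    baf <- ifelse(runif(n) < 0.1, NA, runif(n))
    E <- oracle_emissions(lrr, baf, pm$pfb, model)
    dist <- diff(pm$pos)
    expect_equal(cnvrisk:::viterbi_path(E, dist, model),
                 brute_force_viterbi(E, dist, model))
  }
})

test_that("forward-backward posteriors are proper and dominate planted states", {
  pm <- toy_probe_map(40, pfb = runif(40, 0.2, 0.8))
  sig <- toy_signal(pm, runs = list(list(at = 11:25, cn = 3L)),
                    lrr_noise = 0.12, baf_noise = 0.02, seed = 4)
  E <- oracle_emissions(sig$lrr, sig$baf, pm$pfb, model)
  post <- cnvrisk:::forward_backward(E, diff(pm$pos), model)
  expect_equal(rowSums(post), rep(1, 40), tolerance = 1e-9)
  expect_true(all(post[15:22, 4] > 0.5))
})

test_that("logBF rewards true aberrations, penalizes diploid spans, and is additive", {
  pm <- toy_probe_map(60, pfb = runif(60, 0.2, 0.8))
  sig <- toy_signal(pm, runs = list(list(at = 21:40, cn = 1L)), seed = 2)
  call <- tibble::tibble(sample_id = "s1", chrom = "chr1",
                         start = pm$pos[21] - 1, end = pm$pos[40],
                         copy_number = 1L, type = "deletion",
                         n_probes = 20L, confidence = NA_real_, caller = "A")
  bf <- log_bf(call, sig$lrr, sig$baf, pm, model)
  expect_gt(bf, 15)

  # additivity over disjoint probe subsets
  left <- call; left$end <- pm$pos[30]
  right <- call; right$start <- pm$pos[30]
  expect_equal(log_bf(left, sig$lrr, sig$baf, pm, model) +
                 log_bf(right, sig$lrr, sig$baf, pm, model), bf)

  # claiming a deletion over diploid probes scores non-positive
  wrong <- call; wrong$start <- pm$pos[1] - 1; wrong$end <- pm$pos[15]
  expect_lte(log_bf(wrong, sig$lrr, sig$baf, pm, model), 0)
})

test_that("sample metrics follow their definitions", {
  calls0 <- random_calls(3)[0, ]
  m <- sample_metrics(rep(0.1, 100), runif(100, 0.3, 0.7), calls0)
  expect_equal(m$lrr_sd, 0)
  expect_equal(m$n_calls, 0)

  expect_warning(m2 <- sample_metrics(rnorm(100), rep(c(0, 1), 50), calls0),
                 "band")
  expect_equal(m2$baf_sd, 0)
  expect_true(m2$in_band_empty)

  set.seed(8)
  m3 <- suppressWarnings(sample_metrics(rnorm(1e4, 0, 0.2), rep(NA_real_, 1e4),
                                        calls0))
  expect_lt(abs(m3$lrr_sd - 0.2) / 0.2, 0.03)
})
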