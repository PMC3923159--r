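# Independent oracles and small fixture builders used across the suite.

# --- fixtures ----------------------------------------------------------------

# evenly spaced probe map on one chromosome
toy_probe_map <- function(n, spacing = 5000, chrom = "chr1", gc = NULL,
                          pfb = NULL) {
  tibble::tibble(
    probe_id = sprintf("P%04d", seq_len(n)),
    chrom = chrom,
    pos = as.integer(seq_len(n) * spacing),
    gc = gc %||% rep(0.5, n),
    pfb = pfb %||% rep(0.5, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# noiseless diploid signal with optional planted runs
# runs: list of list(at = probe indices, cn = copy number)
toy_signal <- function(probes, runs = list(), lrr_noise = 0, baf_noise = 0,
                       seed = 1) {
  set.seed(seed)
  n <- nrow(probes)
  cn <- rep(2L, n)
  for (r in runs) cn[r$at] <- r$cn
  lrr <- state_mean_lrr(cn) + rnorm(n, 0, lrr_noise)
  baf <- rep(NA_real_, n)
  for (c in unique(cn[cn > 0])) {
    ix <- which(cn == c)
    b <- rbinom(length(ix), c, probes$pfb[ix])
    baf[ix] <- pmin(1, pmax(0, b / c + rnorm(length(ix), 0, baf_noise)))
  }
  list(lrr = lrr, baf = baf, cn = cn)
}

# random call table for round-trip / clustering tests
random_calls <- function(n, seed = 1, chroms = c("chr1", "chr2"),
                         samples = sprintf("S%02d", 1:8)) {
  set.seed(seed)
  start <- sample.int(1e6, n)
  len <- sample.int(2e5, n) + 5000
  cn <- sample(c(0L, 1L, 3L, 4L), n, replace = TRUE)
  tibble::tibble(
    sample_id = sample(samples, n, replace = TRUE),
    chrom = sample(chroms, n, replace = TRUE),
    start = as.numeric(start),
    end = as.numeric(start + len),
    copy_number = cn,
    type = ifelse(cn < 2, "deletion", "duplication"),
    n_probes = sample(5:60, n, replace = TRUE),
    confidence = round(runif(n, 15, 60), 3),
    caller = sample(c("A", "B"), n, replace = TRUE)
  )
}

# --- oracle: exhaustive Viterbi ---------------------------------------------

# enumerate all 5^n state paths and maximize the joint log-probability,
# using the same emission/transition definitions through the public API
brute_force_viterbi <- function(E, dist, model) {
  n <- nrow(E)
  grid <- as.matrix(expand.grid(rep(list(1:5), n)))
  score <- log(model$state_prior)[grid[, 1]] + E[cbind(1L, grid[, 1])]
  if (n > 1) {
    for (t in 2:n) {
      logA <- log(transition_matrix(dist[t - 1], model))
      score <- score + logA[cbind(grid[, t - 1], grid[, t])] +
        E[cbind(t, grid[, t])]
    }
  }
  as.integer(unname(grid[which.max(score), ])) - 1L
}

# emission matrix through the exported per-state interface
oracle_emissions <- function(lrr, baf, pfb, model) {
  vapply(0:4, function(s) emission_loglik(lrr, baf, pfb, s, model),
         numeric(length(lrr)))
}

# --- oracle: quadratic connected-components clustering ------------------------

brute_force_cnvrs <- function(calls, min_overlap = 0.40) {
  n <- nrow(calls)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (calls$chrom[i] != calls$chrom[j]) next
      o <- max(0, min(calls$end[i], calls$end[j]) -
                 max(calls$start[i], calls$start[j]))
      mo <- min(o / (calls$end[i] - calls$start[i]),
                o / (calls$end[j] - calls$start[j]))
      adj[i, j] <- mo >= min_overlap
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# canonical form of a partition for comparison
partition_signature <- function(comp) {
  unname(split(seq_along(comp), comp)) |>
    lapply(sort) |>
    (\(x) x[order(vapply(x, min, integer(1)))])()
}

# --- oracle: HWE exact test from log-factorials -------------------------------

hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  if (rare == 0) return(1.0)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hr <- (rare - h) / 2
    hc <- n - h - hr
    lgamma(n + 1) - lgamma(hr + 1) - lgamma(h + 1) - lgamma(hc + 1) +
      h * log(2) + lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  obs <- probs[match(n_ab, hets)]
  sum(probs[probs <= obs * (1 + 1e-12)])
}
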