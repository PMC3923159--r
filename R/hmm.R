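# Dual-decoder HMM CNV caller over (LRR, BAF).
#
# One emission/transition family, two decoders: Viterbi MAP path ("caller A")
# and forward-backward posterior-MAP ("caller B"). Distance-dependent
# transitions, GC-wave correction by quadratic regression of LRR on probe GC,
# and a log10 Bayes-factor confidence score per call.

#' HMM model for CNV calling
#'
#' Parameters of the five-state (copy numbers 0--4) hidden Markov model.
#' LRR emissions are Gaussian around the canonical state means
#' ([state_mean_lrr()]); BAF emissions are a mixture over the canonical
#' allelic bands (band `b/c` for `b = 0..c` at copy number `c`), weighted by
#' `Binomial(c, pfb)` genotype frequencies, with truncated-Gaussian band
#' noise. A small uniform outlier component makes the emissions robust to
#' isolated artifacts.
#'
#' @param lrr_means Length-5 LRR state means (copy numbers 0..4); the diploid
#'   mean must be 0.
#' @param lrr_sds Length-5 positive LRR state SDs.
#' @param baf_band_sd SD of the truncated-Gaussian BAF band noise.
#' @param stay_base Baseline self-transition probability at large
#'   inter-probe distance (`p0`).
#' @param distance_scale Distance scale `D` in bp of the transition decay
#'   `1 - exp(-d/D)`.
#' @param uniform_outlier_weight Weight of the uniform outlier emission
#'   component, in `[0, 1)`.
#' @param state_prior Length-5 prior over states, heavily favouring the
#'   diploid state; used for the first probe and to share off-diagonal
#'   transition mass.
#' @param outlier_lrr_range LRR support of the uniform outlier component.
#' @return A list of class `hmm_model`.
#' @export
hmm_model <- function(lrr_means = state_mean_lrr(0:4),
                      lrr_sds = 0.15 * c(2.0, 1.3, 1.0, 1.1, 1.2),
                      baf_band_sd = 0.04,
                      stay_base = 0.999,
                      distance_scale = 1e5,
                      uniform_outlier_weight = 0.01,
                      state_prior = c(0.0025, 0.0025, 0.99, 0.0025, 0.0025),
                      outlier_lrr_range = c(-5, 5)) {
  if (any(lrr_sds <= 0)) stop_domain("lrr_sds must be positive")
  if (baf_band_sd <= 0) stop_domain("baf_band_sd must be positive")
  if (stay_base <= 0 || stay_base >= 1) stop_domain("stay_base must be in (0, 1)")
  if (distance_scale <= 0) stop_domain("distance_scale must be positive")
  if (uniform_outlier_weight < 0 || uniform_outlier_weight >= 1) {
    stop_domain("uniform_outlier_weight must be in [0, 1)")
  }
  if (abs(lrr_means[3]) > 1e-12) stop_domain("diploid LRR mean must be 0")
  state_prior <- state_prior / sum(state_prior)
  structure(list(states = 0:4, lrr_means = lrr_means, lrr_sds = lrr_sds,
                 baf_band_sd = baf_band_sd, stay_base = stay_base,
                 distance_scale = distance_scale,
                 uniform_outlier_weight = uniform_outlier_weight,
                 state_prior = state_prior,
                 outlier_lrr_range = outlier_lrr_range),
            class = "hmm_model")
}

#' GC-wave correction
#'
#' Removes the spatial intensity artifact correlated with local GC content
#' by subtracting the least-squares quadratic fit of LRR on probe GC
#' fraction. Missing values are excluded from the fit and passed through.
#' The output is the mean-centred residual plus the sample's global LRR
#' mean, so the genome-wide level is preserved.
#'
#' @param lrr Per-probe LRR vector aligned to `probes`.
#' @param probes Probe map with a `gc` column.
#' @return Corrected LRR vector of the same length.
#' @export
gc_correct <- function(lrr, probes) {
  ok <- !is.na(lrr)
  if (!any(ok)) stop_domain("gc_correct: all LRR values missing")
  gc <- probes$gc
  fit <- lm(lrr ~ gc + I(gc^2), data = data.frame(lrr = lrr[ok], gc = gc[ok]))
  out <- lrr
  res <- stats::residuals(fit)
  out[ok] <- res - mean(res) + mean(lrr[ok])
  out
}

# truncated-normal density on [0, 1]
dtnorm01 <- function(x, mean, sd) {
  dnorm(x, mean, sd) / (pnorm(1, mean, sd) - pnorm(0, mean, sd))
}

# BAF band-mixture density for copy number c (vectorized over probes);
# copy number 0 carries no allelic signal: uniform density 1 on [0, 1]
baf_mix_density <- function(baf, pfb, cn, band_sd) {
  if (cn == 0L) return(rep(1, length(baf)))
  dens <- rep(0, length(baf))
  for (b in 0:cn) {
    w <- dbinom(b, cn, pfb)
    dens <- dens + w * dtnorm01(baf, b / cn, band_sd)
  }
  dens
}

#' Per-probe emission log-likelihood
#'
#' Log-likelihood of one probe's `(lrr, baf)` observation under a
#' copy-number state: a `(1 - w)` mixture of the Gaussian LRR density times
#' the BAF band mixture, plus a `w`-weighted uniform outlier component.
#' Missing BAF contributes the LRR factor only.
#'
#' @param lrr,baf,pfb Numeric vectors (recycled to common length); `baf` may
#'   contain `NA`.
#' @param state A single copy-number state in 0..4.
#' @param model An [hmm_model()].
#' @return Numeric vector of log-likelihoods.
#' @export
emission_loglik <- function(lrr, baf, pfb, state, model) {
  if (!state %in% model$states) stop_domain("state must be one of the model states")
  i <- state + 1L
  n <- max(length(lrr), length(baf), length(pfb))
  lrr <- rep_len(lrr, n); baf <- rep_len(baf, n); pfb <- rep_len(pfb, n)
  lrr_d <- dnorm(lrr, model$lrr_means[i], model$lrr_sds[i])
  baf_d <- rep(1, n)
  ok <- !is.na(baf)
  if (any(ok)) {
    baf_d[ok] <- baf_mix_density(baf[ok], pfb[ok], state, model$baf_band_sd)
  }
  rng <- model$outlier_lrr_range
  out_d <- stats::dunif(lrr, rng[1], rng[2]) # baf factor of the outlier is uniform (density 1)
  w <- model$uniform_outlier_weight
  log((1 - w) * lrr_d * baf_d + w * out_d)
}

# n x 5 emission log-likelihood matrix
emission_matrix <- function(lrr, baf, pfb, model) {
  vapply(model$states,
         function(s) emission_loglik(lrr, baf, pfb, s, model),
         numeric(length(lrr)))
}

#' Distance-dependent transition matrix
#'
#' The probability of leaving the current state grows with the physical
#' distance between adjacent probes: the off-diagonal mass is
#' `(1 - p0) * (1 - exp(-distance/D))`, shared among destination states in
#' proportion to the state prior. As `distance -> 0` the matrix tends to the
#' identity.
#'
#' @param distance Inter-probe distance in bp (>= 1).
#' @param model An [hmm_model()].
#' @return A 5x5 row-stochastic matrix.
#' @export
transition_matrix <- function(distance, model) {
  if (distance < 1) stop_domain("distance must be >= 1 bp")
  m <- (1 - model$stay_base) * (1 - exp(-distance / model$distance_scale))
  p <- model$state_prior
  A <- matrix(0, 5, 5)
  for (i in 1:5) {
    A[i, -i] <- m * p[-i] / sum(p[-i])
    A[i, i] <- 1 - m
  }
  A
}

# per-chromosome decode helpers ------------------------------------------------

# off-diagonal share matrix W (diag 0) reused across steps
prior_share_matrix <- function(model) {
  p <- model$state_prior
  W <- matrix(0, 5, 5)
  for (i in 1:5) W[i, -i] <- p[-i] / sum(p[-i])
  W
}

viterbi_path <- function(E, dist, model) {
  n <- nrow(E)
  lp <- log(model$state_prior)
  W <- prior_share_matrix(model)
  I5 <- diag(5)
  delta <- lp + E[1, ]
  psi <- matrix(1L, n, 5)
  if (n > 1) {
    for (t in 2:n) {
      m <- (1 - model$stay_base) * (1 - exp(-dist[t - 1] / model$distance_scale))
      logA <- log(m * W + (1 - m) * I5)
      cand <- delta + logA # cand[i, j] = delta[i] + logA[i, j]
      # first max per column = tie broken toward the lower copy-number state
      idx <- max.col(t(cand), ties.method = "first")
      psi[t, ] <- idx
      delta <- cand[cbind(idx, 1:5)] + E[t, ]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1) for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path - 1L # copy numbers
}

forward_backward <- function(E, dist, model) {
  n <- nrow(E)
  W <- prior_share_matrix(model)
  I5 <- diag(5)
  la <- matrix(0, n, 5)
  lb <- matrix(0, n, 5)
  la[1, ] <- log(model$state_prior) + E[1, ]
  logAs <- vector("list", if (n > 1) n - 1 else 0)
  if (n > 1) {
    for (t in 2:n) {
      m <- (1 - model$stay_base) * (1 - exp(-dist[t - 1] / model$distance_scale))
      logA <- log(m * W + (1 - m) * I5)
      logAs[[t - 1]] <- logA
      for (j in 1:5) la[t, j] <- logsumexp(la[t - 1, ] + logA[, j]) + E[t, j]
    }
    for (t in (n - 1):1) {
      logA <- logAs[[t]]
      for (i in 1:5) lb[t, i] <- logsumexp(logA[i, ] + E[t + 1, ] + lb[t + 1, ])
    }
  }
  lg <- la + lb
  post <- exp(lg - row_logsumexp(lg))
  post / rowSums(post)
}

# collapse a per-probe state path into call rows (0-based half-open intervals)
runs_to_calls <- function(path, pos, chrom, keep_run = NULL) {
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 2L
  if (!is.null(keep_run)) keep <- keep & keep_run(starts, ends, r$values)
  if (!any(keep)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  copy_number = integer(), n_probes = integer(),
                  first_idx = integer(), last_idx = integer()))
  }
  tibble(chrom = chrom,
         start = pos[starts[keep]] - 1,
         end = as.numeric(pos[ends[keep]]),
         copy_number = as.integer(r$values[keep]),
         n_probes = r$lengths[keep],
         first_idx = starts[keep], last_idx = ends[keep])
}

decode_sample <- function(lrr, baf, probes, model, decoder, sample_id,
                          apply_gc_correct = TRUE) {
  if (apply_gc_correct) lrr <- gc_correct(lrr, probes)
  out <- list()
  for (ch in unique(probes$chrom)) {
    sel <- which(probes$chrom == ch)
    usable <- sel[!is.na(lrr[sel])]
    if (length(usable) < 2) {
      warn(paste0(sample_id, ": chromosome ", ch, " skipped (<2 usable probes)"))
      next
    }
    E <- emission_matrix(lrr[usable], baf[usable], probes$pfb[usable], model)
    dist <- diff(probes$pos[usable])
    if (decoder == "viterbi") {
      path <- viterbi_path(E, dist, model)
      calls <- runs_to_calls(path, probes$pos[usable], ch)
    } else {
      post <- forward_backward(E, dist, model)
      path <- max.col(post, ties.method = "first") - 1L
      mean_post_ok <- function(starts, ends, values) {
        vapply(seq_along(starts), function(k) {
          ix <- starts[k]:ends[k]
          mean(post[cbind(ix, values[k] + 1L)]) >= 0.5
        }, logical(1))
      }
      calls <- runs_to_calls(path, probes$pos[usable], ch, keep_run = mean_post_ok)
    }
    if (nrow(calls) > 0) {
      # logBF over the call's probes: called state vs diploid
      calls$confidence <- vapply(seq_len(nrow(calls)), function(k) {
        ix <- calls$first_idx[k]:calls$last_idx[k]
        sum(E[ix, calls$copy_number[k] + 1L] - E[ix, 3L]) / log(10)
      }, numeric(1))
      out[[ch]] <- calls
    }
  }
  if (length(out) == 0) {
    return(tibble(sample_id = character(), chrom = character(), start = numeric(),
                  end = numeric(), copy_number = integer(), type = character(),
                  n_probes = integer(), confidence = numeric(), caller = character()))
  }
  calls <- bind_rows(out)
  tibble(sample_id = sample_id, chrom = calls$chrom, start = calls$start,
         end = calls$end, copy_number = calls$copy_number,
         type = ifelse(calls$copy_number < 2, "deletion", "duplication"),
         n_probes = calls$n_probes, confidence = calls$confidence,
         caller = if (decoder == "viterbi") "A" else "B")
}

#' Call CNVs for one sample by Viterbi decoding ("caller A")
#'
#' Maximum a posteriori state path per chromosome; maximal runs of a
#' non-diploid state become calls spanning the first to last probe of the
#' run. Ties in the Viterbi maximization are broken toward the lower copy
#' number for determinism. Confidence is the log10 Bayes factor of the
#' called state against the diploid state over the call's probes.
#'
#' @param lrr,baf Per-probe signal vectors aligned to `probes`.
#' @param probes Probe map.
#' @param model An [hmm_model()].
#' @param sample_id Sample label carried into the calls.
#' @param apply_gc_correct Apply [gc_correct()] before decoding.
#' @return A call tibble (`sample_id`, `chrom`, `start`, `end`,
#'   `copy_number`, `type`, `n_probes`, `confidence`, `caller`).
#' @export
call_viterbi <- function(lrr, baf, probes, model = hmm_model(),
                         sample_id = "sample", apply_gc_correct = TRUE) {
  decode_sample(lrr, baf, probes, model, "viterbi", sample_id, apply_gc_correct)
}

#' Call CNVs for one sample by posterior decoding ("caller B")
#'
#' Forward-backward per-probe posteriors; runs of a non-diploid per-probe
#' MAP state whose mean posterior is at least 0.5 become calls. An
#' independent decoder of the same emission/transition family, so that
#' dual-caller consensus semantics are preserved with fully specified
#' computation.
#'
#' @inheritParams call_viterbi
#' @return A call tibble.
#' @export
call_posterior <- function(lrr, baf, probes, model = hmm_model(),
                           sample_id = "sample", apply_gc_correct = TRUE) {
  decode_sample(lrr, baf, probes, model, "posterior", sample_id, apply_gc_correct)
}

#' Call CNVs across a cohort
#'
#' Runs one decoder over every sample of a simulated or assembled cohort.
#'
#' @param cohort A `cnv_cohort` (see [simulate_cohort()]).
#' @param decoder `"viterbi"` (caller A) or `"posterior"` (caller B).
#' @param model An [hmm_model()].
#' @param apply_gc_correct Apply GC-wave correction per sample.
#' @return A call tibble over all samples.
#' @export
call_cnvs <- function(cohort, decoder = c("viterbi", "posterior"),
                      model = hmm_model(), apply_gc_correct = TRUE) {
  decoder <- match.arg(decoder)
  res <- lapply(seq_len(nrow(cohort$samples)), function(i) {
    decode_sample(cohort$lrr[i, ], cohort$baf[i, ], cohort$probes, model,
                  decoder, cohort$samples$sample_id[i], apply_gc_correct)
  })
  bind_rows(res)
}

#' Log10 Bayes-factor confidence of calls
#'
#' Recomputes, for each call, the log10 ratio of the emission likelihood of
#' the called state to the diploid state over the call's probes. Additive
#' over disjoint probe subsets.
#'
#' @param calls A call tibble.
#' @param lrr,baf Signal vectors aligned to `probes` for the calls' sample.
#' @param probes Probe map.
#' @param model An [hmm_model()].
#' @return Numeric vector of log10 Bayes factors, one per call.
#' @export
log_bf <- function(calls, lrr, baf, probes, model = hmm_model()) {
  vapply(seq_len(nrow(calls)), function(k) {
    ix <- which(probes$chrom == calls$chrom[k] &
                  probes$pos > calls$start[k] & probes$pos <= calls$end[k] &
                  !is.na(lrr))
    if (length(ix) == 0) stop_domain("log_bf: call spans no usable probes")
    num <- emission_loglik(lrr[ix], baf[ix], probes$pfb[ix],
                           calls$copy_number[k], model)
    den <- emission_loglik(lrr[ix], baf[ix], probes$pfb[ix], 2L, model)
    sum(num - den) / log(10)
  }, numeric(1))
}

#' Per-sample signal quality metrics
#'
#' `lrr_sd` is the SD of non-missing LRR; `baf_sd` is the SD of BAF values
#' restricted to the open heterozygous band `(0.25, 0.75)` (0 with an
#' `in_band_empty` flag when no BAF falls in the band); `n_calls` counts
#' this sample's calls.
#'
#' @param lrr,baf Per-probe signal vectors for one sample.
#' @param calls Call tibble for the same sample (any caller).
#' @return A one-row tibble: `lrr_sd`, `baf_sd`, `n_calls`,
#'   `missing_fraction`, `in_band_empty`.
#' @export
sample_metrics <- function(lrr, baf, calls) {
  in_band <- !is.na(baf) & baf > 0.25 & baf < 0.75
  empty <- !any(in_band)
  if (empty) {
    warn("no BAF values in the (0.25, 0.75) band; baf_sd reported as 0")
  }
  tibble(
    lrr_sd = if (all(is.na(lrr))) NA_real_ else sd(lrr, na.rm = TRUE),
    baf_sd = if (empty) 0 else sd(baf[in_band]),
    n_calls = nrow(calls),
    missing_fraction = mean(is.na(lrr)),
    in_band_empty = empty
  )
}

#' Signal quality metrics for every sample of a cohort
#'
#' @param cohort A `cnv_cohort`.
#' @param calls Call tibble (used for per-sample call counts).
#' @param apply_gc_correct Compute LRR SD on GC-corrected signal.
#' @return A tibble with one row per sample.
#' @export
cohort_metrics <- function(cohort, calls, apply_gc_correct = TRUE) {
  res <- lapply(seq_len(nrow(cohort$samples)), function(i) {
    sid <- cohort$samples$sample_id[i]
    lrr <- cohort$lrr[i, ]
    if (apply_gc_correct) lrr <- gc_correct(lrr, cohort$probes)
    m <- suppressWarnings(
      sample_metrics(lrr, cohort$baf[i, ], calls[calls$sample_id == sid, ]))
    m$sample_id <- sid
    m
  })
  bind_rows(res) |> relocate("sample_id")
}
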