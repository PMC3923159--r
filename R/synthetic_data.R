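# Synthetic SNP-array cohort generator.
#
# Emulates the statistical structure a case-control CNV analysis assumes:
# canonical LRR shifts and BAF bands per copy-number state, per-sample noise
# heterogeneity, batch GC-wave artifacts, platform noise differences, common
# CNVRs at population frequencies, private singleton CNVs, and an optional
# risk CNVR with a per-copy effect on disease odds, sampled retrospectively
# (fixed case/control counts from a larger source population).

#' Canonical LRR state mean for a copy-number state
#'
#' Fixed table of expected log R ratio by integer copy number, conventional
#' for Illumina-style arrays: deep negative for homozygous deletion, moderate
#' negative for hemizygous deletion, zero for diploid, modest positive shifts
#' for duplications. The table anchors the simulator and the HMM caller
#' jointly.
#'
#' @param copy_number Integer vector with values in `0:4`.
#' @return Numeric vector of LRR means.
#' @export
state_mean_lrr <- function(copy_number) {
  if (any(!copy_number %in% 0:4)) {
    stop_domain("copy_number must be in 0..4")
  }
  mu <- c(-3.5, -0.66, 0, 0.40, 0.68)
  mu[copy_number + 1L]
}

#' Simulation configuration
#'
#' Builds the configuration object consumed by [simulate_cohort()]. Defaults
#' describe a hospital-based case-control SNP-array study: 223 cases and 169
#' controls (plus 10 duplicate-pair re-runs), 28 genotyping batches, a
#' duo/quad platform mix that differs between cases and controls, per-sample
#' LRR noise drawn from `lrr_sd_range`, batch-specific GC-wave amplitudes and
#' roughly one private singleton CNV per sample.
#'
#' @param n_cases,n_controls Number of cases/controls drawn into the study.
#' @param n_probes Total probes across all chromosomes (>= 100).
#' @param n_chroms Number of simulated chromosomes (`"chr1"`, ...).
#' @param mean_spacing Mean inter-probe gap in bp (exponential gaps).
#' @param cnvr_freqs Common CNVR loci: a data frame with columns `chrom`,
#'   `start`, `end` (0-based half-open), `type` (`deletion`/`duplication`)
#'   and `freq` (carrier frequency in `[0, 1]`), or `NULL` to auto-place
#'   `n_common_cnvrs` loci on the simulated map.
#' @param n_common_cnvrs Number of auto-placed common CNVRs when
#'   `cnvr_freqs` is `NULL`.
#' @param singleton_rate Mean number of private rare CNVs per sample
#'   (Poisson).
#' @param risk_locus Optional list with elements `beta` (per-copy log odds
#'   ratio), `cn_freqs` (named or length-5 vector of copy-number frequencies
#'   for copy numbers 0..4) and optionally `chrom`, `start`, `end`
#'   (auto-placed when absent).
#' @param lrr_sd_range Range `(lo, hi)` of per-sample LRR noise SD.
#' @param baf_sd SD of BAF noise around the canonical band positions.
#' @param gc_wave_amplitude_by_batch Numeric vector of per-batch GC-wave
#'   amplitudes (recycled/truncated to `n_batches`), or `NULL` for the
#'   default evenly spaced `0.02..0.12`.
#' @param platform_noise_multiplier Named numeric vector with entries `duo`
#'   and `quad` multiplying the per-sample LRR SD.
#' @param n_batches Number of genotyping batches.
#' @param duplicate_pairs Number of samples re-run as technical duplicates.
#' @param prop_quad_cases,prop_quad_controls Fraction of cases/controls
#'   genotyped on the quad platform.
#' @param n_snps Number of SNPs in the auxiliary genotype matrix (for SNP QC
#'   and ancestry PCA); `0` to skip.
#' @param fst Divergence between the two simulated ancestry groups
#'   (Balding-Nichols model) in the genotype matrix.
#' @param seed Integer seed; all draws flow from this single generator.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 223, n_controls = 169,
                       n_probes = 30000, n_chroms = 4, mean_spacing = 8000,
                       cnvr_freqs = NULL, n_common_cnvrs = 12,
                       singleton_rate = 0.96,
                       risk_locus = NULL,
                       lrr_sd_range = c(0.10, 0.20),
                       baf_sd = 0.03,
                       gc_wave_amplitude_by_batch = NULL,
                       platform_noise_multiplier = c(duo = 1.0, quad = 1.25),
                       n_batches = 28,
                       duplicate_pairs = 10,
                       prop_quad_cases = 0.354, prop_quad_controls = 0.107,
                       n_snps = 2000, fst = 0.01,
                       seed = 1L) {
  if (n_probes < 100) stop_domain("n_probes must be >= 100")
  if (lrr_sd_range[1] > lrr_sd_range[2]) stop_domain("lrr_sd_range must be (lo, hi)")
  if (!is.null(cnvr_freqs)) {
    if (any(cnvr_freqs$freq < 0 | cnvr_freqs$freq > 1)) {
      stop_domain("cnvr frequencies must be in [0, 1]")
    }
  }
  if (is.null(gc_wave_amplitude_by_batch)) {
    gc_wave_amplitude_by_batch <- seq(0.02, 0.12, length.out = n_batches)
  } else {
    gc_wave_amplitude_by_batch <- rep_len(gc_wave_amplitude_by_batch, n_batches)
  }
  if (!is.null(risk_locus)) {
    if (is.null(risk_locus$beta) || is.null(risk_locus$cn_freqs)) {
      stop_usage("risk_locus needs elements beta and cn_freqs")
    }
    if (length(risk_locus$cn_freqs) != 5 || abs(sum(risk_locus$cn_freqs) - 1) > 1e-8) {
      stop_domain("risk_locus$cn_freqs must be 5 frequencies (copy numbers 0..4) summing to 1")
    }
  }
  structure(list(
    n_cases = n_cases, n_controls = n_controls,
    n_probes = n_probes, n_chroms = n_chroms, mean_spacing = mean_spacing,
    cnvr_freqs = cnvr_freqs, n_common_cnvrs = n_common_cnvrs,
    singleton_rate = singleton_rate, risk_locus = risk_locus,
    lrr_sd_range = lrr_sd_range, baf_sd = baf_sd,
    gc_wave_amplitude_by_batch = gc_wave_amplitude_by_batch,
    platform_noise_multiplier = platform_noise_multiplier,
    n_batches = n_batches, duplicate_pairs = duplicate_pairs,
    prop_quad_cases = prop_quad_cases, prop_quad_controls = prop_quad_controls,
    n_snps = n_snps, fst = fst, seed = as.integer(seed)
  ), class = "sim_config")
}

# smooth GC track in [0.3, 0.7]: sum of low-frequency sinusoids over probe index
smooth_gc <- function(n) {
  idx <- seq_len(n)
  raw <- sin(2 * pi * idx / (n / runif(1, 1.5, 3))) +
    0.6 * sin(2 * pi * idx / (n / runif(1, 4, 8)) + runif(1, 0, 2 * pi)) +
    0.3 * sin(2 * pi * idx / (n / runif(1, 10, 20)) + runif(1, 0, 2 * pi))
  lo <- min(raw); hi <- max(raw)
  if (hi - lo < 1e-12) return(rep(0.5, n))
  0.3 + 0.4 * (raw - lo) / (hi - lo)
}

simulate_probe_map <- function(config) {
  per_chrom <- diff(round(seq(0, config$n_probes, length.out = config$n_chroms + 1)))
  maps <- lapply(seq_len(config$n_chroms), function(ci) {
    n <- per_chrom[ci]
    gaps <- pmax(1, round(rexp(n, rate = 1 / config$mean_spacing)))
    tibble(
      chrom = paste0("chr", ci),
      pos = as.integer(cumsum(gaps)),
      gc = smooth_gc(n),
      pfb = runif(n)
    )
  })
  probes <- bind_rows(maps)
  probes$probe_id <- sprintf("P%06d", seq_len(nrow(probes)))
  probes[c("probe_id", "chrom", "pos", "gc", "pfb")]
}

# place an interval spanning exactly `n_span` probes, starting at probe index
# `i0` within chromosome `chrom`; returns 0-based half-open coordinates
interval_from_probes <- function(probes, chrom, i0, n_span) {
  pc <- probes[probes$chrom == chrom, ]
  i1 <- i0 + n_span - 1L
  tibble(chrom = chrom, start = pc$pos[i0] - 1, end = as.numeric(pc$pos[i1]))
}

place_random_locus <- function(probes, span_range = c(20L, 60L)) {
  chrom <- sample(unique(probes$chrom), 1L)
  nc <- sum(probes$chrom == chrom)
  n_span <- sample(seq(span_range[1], span_range[2]), 1L)
  i0 <- sample.int(nc - n_span, 1L)
  interval_from_probes(probes, chrom, i0, n_span)
}

overlaps_any <- function(iv, pool) {
  if (nrow(pool) == 0) return(FALSE)
  any(pool$chrom == iv$chrom & pool$start < iv$end & iv$start < pool$end)
}

default_common_cnvrs <- function(probes, n_loci) {
  placed <- tibble(chrom = character(), start = numeric(), end = numeric(),
                   type = character(), freq = numeric())
  for (i in seq_len(n_loci)) {
    repeat {
      iv <- place_random_locus(probes, c(20L, 60L))
      if (!overlaps_any(iv, placed)) break
    }
    iv$type <- if (i %% 2 == 0) "duplication" else "deletion"
    iv$freq <- exp(runif(1, log(0.02), log(0.30)))
    placed <- bind_rows(placed, iv)
  }
  placed
}

# BAF for one sample given per-probe copy number (vectorized)
simulate_baf <- function(cn, pfb, baf_sd) {
  n <- length(cn)
  baf <- rep(NA_real_, n)
  for (c in sort(unique(cn[cn > 0]))) {
    ix <- which(cn == c)
    b <- rbinom(length(ix), c, pfb[ix])
    baf[ix] <- pmin(1, pmax(0, b / c + rnorm(length(ix), 0, baf_sd)))
  }
  baf
}

#' Simulate a case-control SNP-array cohort with planted CNVs
#'
#' Generates a probe map, per-sample LRR/BAF signal matrices, a sample sheet,
#' a ground-truth CNV set and an auxiliary SNP genotype matrix under the
#' conditions described by a [sim_config()]. Disease status is assigned
#' retrospectively: when a risk locus is configured, a larger source
#' population is simulated, disease is drawn with probability
#' `plogis(alpha + beta * copy_number)` (with `alpha` anchored so that a
#' diploid individual has probability 0.5), and the fixed case/control
#' counts are sampled without replacement.
#'
#' With zero noise (`lrr_sd_range = c(0, 0)`, `baf_sd = 0`, zero GC-wave
#' amplitudes) every planted CNV's probes sit exactly at the canonical LRR
#' state mean and BAF band positions.
#'
#' @param config A [sim_config()].
#' @return A list of class `cnv_cohort` with elements `probes` (probe map
#'   tibble), `samples` (sample sheet tibble), `lrr` and `baf` (sample-by-probe
#'   matrices with sample-id rownames), `truth` (tibble of planted CNVs:
#'   `sample_id`, `chrom`, `start`, `end`, `copy_number`, `origin`),
#'   `genotypes` (dosage matrix or `NULL`) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)

  probes <- simulate_probe_map(config)
  n_probes <- nrow(probes)
  # probe index lookup per chromosome (global row indices, probes sorted)
  probe_rows <- function(iv) {
    which(probes$chrom == iv$chrom & probes$pos > iv$start & probes$pos <= iv$end)
  }

  common <- config$cnvr_freqs
  if (is.null(common)) {
    common <- default_common_cnvrs(probes, config$n_common_cnvrs)
  } else {
    common <- as_tibble(common)
  }
  bounds <- probes |> group_by(.data$chrom) |> summarise(maxpos = max(.data$pos))
  for (i in seq_len(nrow(common))) {
    mx <- bounds$maxpos[match(common$chrom[i], bounds$chrom)]
    if (is.na(mx) || common$start[i] < 0 || common$end[i] > mx) {
      stop_domain("common CNVR interval outside simulated chromosome bounds")
    }
  }

  risk <- config$risk_locus
  if (!is.null(risk) && is.null(risk$chrom)) {
    repeat {
      iv <- place_random_locus(probes, c(25L, 50L))
      if (!overlaps_any(iv, common)) break
    }
    risk$chrom <- iv$chrom; risk$start <- iv$start; risk$end <- iv$end
  }

  n_study <- config$n_cases + config$n_controls
  n_pop <- if (is.null(risk)) n_study else 4L * n_study

  # -- population truth ------------------------------------------------------
  carrier <- matrix(runif(n_pop * nrow(common)) < rep(common$freq, each = n_pop),
                    nrow = n_pop)
  carrier_cn <- ifelse(common$type == "deletion", 1L, 3L)
  risk_cn <- if (is.null(risk)) {
    rep(2L, n_pop)
  } else {
    sample(0:4, n_pop, replace = TRUE, prob = risk$cn_freqs)
  }

  # singleton CNVs, private by construction (collision check enforces privacy)
  singleton_pool <- tibble(chrom = character(), start = numeric(), end = numeric(),
                           copy_number = integer(), indiv = integer())
  n_sing <- rpois(n_pop, config$singleton_rate)
  risk_iv <- if (is.null(risk)) NULL else
    tibble(chrom = risk$chrom, start = risk$start, end = risk$end)
  for (i in which(n_sing > 0)) {
    for (j in seq_len(n_sing[i])) {
      attempts <- 0L
      repeat {
        attempts <- attempts + 1L
        if (attempts > 200L) {
          abort(paste0(
            "cannot place private singleton CNVs without collisions: ",
            "the simulated coordinate space is saturated (",
            nrow(singleton_pool), " placed); increase n_probes or lower ",
            "singleton_rate"), class = "cnvrisk_simulation_error")
        }
        iv <- place_random_locus(probes, c(10L, 40L))
        if (!overlaps_any(iv, common) &&
            !overlaps_any(iv, singleton_pool) &&
            (is.null(risk_iv) || !overlaps_any(iv, risk_iv))) break
      }
      iv$copy_number <- if (runif(1) < 0.5) sample(c(0L, 1L), 1, prob = c(0.1, 0.9)) else
        sample(c(3L, 4L), 1, prob = c(0.9, 0.1))
      iv$indiv <- i
      singleton_pool <- bind_rows(singleton_pool, iv)
    }
  }

  # -- retrospective case/control sampling ----------------------------------
  if (is.null(risk)) {
    status_pool <- sample(rep(c("case", "control"),
                              c(config$n_cases, config$n_controls)))
    picked <- seq_len(n_study)
    status <- status_pool
  } else {
    alpha <- -2 * risk$beta # diploid baseline probability 0.5
    p_case <- plogis(alpha + risk$beta * risk_cn)
    y <- runif(n_pop) < p_case
    if (sum(y) < config$n_cases || sum(!y) < config$n_controls) {
      abort(sprintf(
        "infeasible case/control counts: population of %d yielded %d cases, %d controls (need %d/%d)",
        n_pop, sum(y), sum(!y), config$n_cases, config$n_controls),
        class = "cnvrisk_simulation_error")
    }
    picked <- c(sample(which(y), config$n_cases),
                sample(which(!y), config$n_controls))
    status <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
  }

  # -- sample sheet ----------------------------------------------------------
  is_case <- status == "case"
  n <- n_study
  gender <- ifelse(runif(n) < ifelse(is_case, 0.578, 0.420), "male", "female")
  famhx <- ifelse(is_case & runif(n) < 24 / 223, "yes", "no")
  dna_source <- character(n)
  dna_source[is_case] <- sample(c("blood", "buccal", "saliva"), sum(is_case),
                                replace = TRUE, prob = c(0.139, 0.700, 0.161))
  dna_source[!is_case] <- sample(c("buccal", "saliva"), sum(!is_case),
                                 replace = TRUE, prob = c(0.846, 0.154))
  platform <- ifelse(runif(n) < ifelse(is_case, config$prop_quad_cases,
                                       config$prop_quad_controls),
                     "quad", "duo")
  batch <- sample(paste0("batch", seq_len(config$n_batches)), n, replace = TRUE)
  age <- round(pmin(88, pmax(30, rnorm(n, ifelse(is_case, 61, 60), 11))))
  lrr_sd_true <- runif(n, config$lrr_sd_range[1], config$lrr_sd_range[2])

  samples <- tibble(
    sample_id = sprintf("S%04d", seq_len(n)),
    status = status, age = age, gender = gender, family_history = famhx,
    dna_source = dna_source, batch = batch, platform = platform,
    duplicate_of = NA_character_,
    lrr_sd_true = lrr_sd_true,
    risk_cn = risk_cn[picked],
    indiv = picked
  )

  # technical duplicates: same underlying truth, re-noised, new batch
  if (config$duplicate_pairs > 0) {
    dup_of <- sample(seq_len(n), config$duplicate_pairs)
    dups <- samples[dup_of, ]
    dups$sample_id <- paste0(samples$sample_id[dup_of], "D")
    dups$duplicate_of <- samples$sample_id[dup_of]
    dups$batch <- sample(paste0("batch", seq_len(config$n_batches)),
                         config$duplicate_pairs, replace = TRUE)
    dups$lrr_sd_true <- runif(config$duplicate_pairs,
                              config$lrr_sd_range[1], config$lrr_sd_range[2])
    samples <- bind_rows(samples, dups)
  }

  # -- truth set for the sampled study --------------------------------------
  truth_list <- list()
  for (s in seq_len(nrow(samples))) {
    ind <- samples$indiv[s]
    rows <- list()
    hit <- which(carrier[ind, ])
    if (length(hit) > 0) {
      rows$common <- tibble(chrom = common$chrom[hit], start = common$start[hit],
                            end = common$end[hit],
                            copy_number = carrier_cn[hit], origin = "common")
    }
    sp <- singleton_pool[singleton_pool$indiv == ind, ]
    if (nrow(sp) > 0) {
      rows$sing <- tibble(chrom = sp$chrom, start = sp$start, end = sp$end,
                          copy_number = sp$copy_number, origin = "singleton")
    }
    if (!is.null(risk) && samples$risk_cn[s] != 2L) {
      rows$risk <- tibble(chrom = risk$chrom, start = risk$start, end = risk$end,
                          copy_number = samples$risk_cn[s], origin = "risk")
    }
    if (length(rows) > 0) {
      tr <- bind_rows(rows)
      tr$sample_id <- samples$sample_id[s]
      truth_list[[s]] <- tr
    }
  }
  truth <- if (length(truth_list) > 0) {
    bind_rows(truth_list)[c("sample_id", "chrom", "start", "end", "copy_number", "origin")]
  } else {
    tibble(sample_id = character(), chrom = character(), start = numeric(),
           end = numeric(), copy_number = integer(), origin = character())
  }

  # -- signals ---------------------------------------------------------------
  gc_std <- as.numeric(scale(probes$gc))
  batch_amp <- setNames(config$gc_wave_amplitude_by_batch,
                        paste0("batch", seq_len(config$n_batches)))
  mult <- config$platform_noise_multiplier

  lrr <- matrix(0, nrow(samples), n_probes,
                dimnames = list(samples$sample_id, probes$probe_id))
  baf <- matrix(NA_real_, nrow(samples), n_probes,
                dimnames = list(samples$sample_id, probes$probe_id))
  for (s in seq_len(nrow(samples))) {
    cn <- rep(2L, n_probes)
    tr <- truth[truth$sample_id == samples$sample_id[s], ]
    if (nrow(tr) > 0) {
      for (k in seq_len(nrow(tr))) cn[probe_rows(tr[k, ])] <- tr$copy_number[k]
    }
    noise_sd <- samples$lrr_sd_true[s] * mult[[samples$platform[s]]]
    eps <- if (noise_sd > 0) rnorm(n_probes, 0, noise_sd) else 0
    lrr[s, ] <- state_mean_lrr(cn) + batch_amp[[samples$batch[s]]] * gc_std + eps
    baf[s, ] <- simulate_baf(cn, probes$pfb, config$baf_sd)
  }

  # -- auxiliary SNP genotype matrix ----------------------------------------
  genotypes <- NULL
  if (config$n_snps > 0) {
    p_anc <- runif(config$n_snps, 0.1, 0.9)
    f <- config$fst
    shape <- function(p) cbind(p * (1 - f) / f, (1 - p) * (1 - f) / f)
    sh <- shape(p_anc)
    p_a <- stats::rbeta(config$n_snps, sh[, 1], sh[, 2])
    p_b <- stats::rbeta(config$n_snps, sh[, 1], sh[, 2])
    group <- sample(c("A", "B"), nrow(samples), replace = TRUE)
    genotypes <- matrix(NA_integer_, nrow(samples), config$n_snps,
                        dimnames = list(samples$sample_id,
                                        sprintf("rs%06d", seq_len(config$n_snps))))
    for (s in seq_len(nrow(samples))) {
      p <- if (group[s] == "A") p_a else p_b
      g <- rbinom(config$n_snps, 2L, p)
      g[runif(config$n_snps) < 0.01] <- NA_integer_
      genotypes[s, ] <- g
    }
    samples$ancestry_group <- group
  }

  samples$indiv <- NULL
  structure(list(probes = probes, samples = samples, lrr = lrr, baf = baf,
                 truth = truth, genotypes = genotypes, config = config,
                 risk_locus = risk),
            class = "cnv_cohort")
}

#' @export
print.cnv_cohort <- function(x, ...) {
  cat("<cnv_cohort> ", nrow(x$samples), " samples (",
      sum(x$samples$status == "case"), " cases / ",
      sum(x$samples$status == "control"), " controls), ",
      nrow(x$probes), " probes on ", length(unique(x$probes$chrom)),
      " chromosomes, ", nrow(x$truth), " planted CNVs\n", sep = "")
  invisible(x)
}
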