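# Sample- and call-level QC, duplicate resolution, dual-caller consensus.

#' Derive a QC threshold from a cohort metric
#'
#' `mean(values) + k * IQR(values)`, with quartiles by linear interpolation
#' between order statistics (the common "type 7" convention). This is how
#' cohort-specific sample-QC cutoffs (LRR SD, BAF SD, call-count caps) are
#' derived from the observed metric distribution.
#'
#' @param values Numeric vector with at least 4 finite values.
#' @param k IQR multiplier.
#' @return The threshold value.
#' @export
derive_threshold <- function(values, k) {
  values <- values[is.finite(values)]
  if (length(values) < 4) {
    abort("derive_threshold needs at least 4 finite values",
          class = "cnvrisk_insufficient_data_error")
  }
  mean(values) + k * IQR(values, type = 7)
}

#' QC threshold profiles
#'
#' Fixed default thresholds ship as two profiles: `caller_a` (LRR SD 0.28,
#' BAF SD 0.13, 124 calls; calls dropped below 5 kb or 5 probes) and
#' `caller_b` (LRR SD 0.21, BAF SD 0.102, 160 calls; calls dropped below
#' logBF 15). Use [derive_threshold()] to recompute sample-level cutoffs
#' from your own cohort.
#'
#' @param profile `"caller_a"` or `"caller_b"`.
#' @param lrr_sd_max,baf_sd_max,n_calls_max,min_length,min_probes,min_logbf
#'   Overrides for individual thresholds.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(profile = c("caller_a", "caller_b"),
                          lrr_sd_max = NULL, baf_sd_max = NULL,
                          n_calls_max = NULL, min_length = NULL,
                          min_probes = NULL, min_logbf = NULL) {
  profile <- match.arg(profile)
  def <- if (profile == "caller_a") {
    list(lrr_sd_max = 0.28, baf_sd_max = 0.13, n_calls_max = 124L,
         min_length = 5000, min_probes = 5L, min_logbf = 15)
  } else {
    list(lrr_sd_max = 0.21, baf_sd_max = 0.102, n_calls_max = 160L,
         min_length = 5000, min_probes = 5L, min_logbf = 15)
  }
  out <- list(
    profile = profile,
    lrr_sd_max = lrr_sd_max %||% def$lrr_sd_max,
    baf_sd_max = baf_sd_max %||% def$baf_sd_max,
    n_calls_max = n_calls_max %||% def$n_calls_max,
    min_length = min_length %||% def$min_length,
    min_probes = min_probes %||% def$min_probes,
    min_logbf = min_logbf %||% def$min_logbf
  )
  if (any(unlist(out[-1]) <= 0)) stop_domain("all QC thresholds must be positive")
  structure(out, class = "qc_thresholds")
}

#' Sample-level QC
#'
#' A sample fails iff `lrr_sd > lrr_sd_max` OR `baf_sd > baf_sd_max` OR
#' `n_calls > n_calls_max` (strict inequalities: metrics exactly at a
#' threshold pass). All violated criteria are listed.
#'
#' @param metrics Per-sample metrics tibble (see [cohort_metrics()]).
#' @param thresholds A [qc_thresholds()].
#' @return `metrics` with added columns `pass` (logical) and `reasons`
#'   (comma-separated violated criteria, `""` when passing).
#' @export
sample_qc <- function(metrics, thresholds) {
  v_lrr <- metrics$lrr_sd > thresholds$lrr_sd_max
  v_baf <- metrics$baf_sd > thresholds$baf_sd_max
  v_n <- metrics$n_calls > thresholds$n_calls_max
  reasons <- pmap(list(v_lrr, v_baf, v_n), function(a, b, c) {
    paste(c("lrr_sd", "baf_sd", "n_calls")[c(a, b, c)], collapse = ",")
  })
  metrics |>
    mutate(pass = !(v_lrr | v_baf | v_n),
           reasons = unlist(reasons))
}

#' Call-level QC
#'
#' With `criteria = "length_probes"` drops calls shorter than `min_length`
#' bp or spanning fewer than `min_probes` probes; with `criteria = "logbf"`
#' drops calls with confidence below `min_logbf`. Violations are strict
#' (`<`), so a call exactly at a threshold is kept. Input order is
#' preserved.
#'
#' @param calls A call tibble.
#' @param thresholds A [qc_thresholds()].
#' @param criteria `"length_probes"` or `"logbf"`.
#' @return A list with elements `calls` (kept calls) and `report`
#'   (per-call keep/drop with reason, plus before/after counts as
#'   attributes `n_before`/`n_after`).
#' @export
call_qc <- function(calls, thresholds, criteria = c("length_probes", "logbf")) {
  if (!criteria[1] %in% c("length_probes", "logbf")) {
    stop_usage("unknown call-QC criteria label")
  }
  criteria <- match.arg(criteria)
  if (criteria == "length_probes") {
    len <- calls$end - calls$start
    v_len <- len < thresholds$min_length
    v_np <- calls$n_probes < thresholds$min_probes
    drop <- v_len | v_np
    reason <- ifelse(v_len & v_np, "length,n_probes",
                     ifelse(v_len, "length", ifelse(v_np, "n_probes", "")))
  } else {
    drop <- calls$confidence < thresholds$min_logbf
    reason <- ifelse(drop, "logbf", "")
  }
  report <- calls |> mutate(keep = !drop, reason = reason)
  attr(report, "n_before") <- nrow(calls)
  attr(report, "n_after") <- sum(!drop)
  list(calls = calls[!drop, , drop = FALSE], report = report)
}

#' Resolve technical duplicate pairs
#'
#' From each declared duplicate pair keeps the member with the lower LRR SD
#' (the quality metric used throughout sample QC); exact ties keep the
#' lexicographically smaller sample id. Non-duplicates pass through.
#'
#' @param samples Sample sheet with a `duplicate_of` column.
#' @param metrics Per-sample metrics with `sample_id` and `lrr_sd`.
#' @return The retained subset of `samples`.
#' @export
resolve_duplicates <- function(samples, metrics) {
  if (!"duplicate_of" %in% names(samples)) return(samples)
  dup <- samples[!is.na(samples$duplicate_of), ]
  if (nrow(dup) == 0) return(samples)
  if (!all(dup$duplicate_of %in% samples$sample_id)) {
    stop_format("duplicate_of references a sample missing from the sheet")
  }
  sdmap <- setNames(metrics$lrr_sd, metrics$sample_id)
  drop <- character(0)
  for (i in seq_len(nrow(dup))) {
    a <- dup$sample_id[i]; b <- dup$duplicate_of[i]
    sa <- sdmap[[a]]; sb <- sdmap[[b]]
    loser <- if (sa < sb) b else if (sb < sa) a else max(a, b)
    drop <- c(drop, loser)
  }
  samples[!samples$sample_id %in% drop, , drop = FALSE]
}

#' Dual-caller consensus merge
#'
#' Retains only CNV calls made in the same individual by both callers:
#' calls of the same sample and type (deletion/deletion or
#' duplication/duplication) overlapping by at least 1 bp are pooled
#' transitively (a connected component per sample/type); each component
#' containing calls from both callers yields one merged call whose
#' boundaries are the smallest start and largest end of its members.
#' The merged copy number is the member state most extreme in the shared
#' direction, the confidence is the minimum of the members, and the probe
#' count is recomputed on the merged span. Components seen by only one
#' caller are dropped.
#'
#' @param calls_a,calls_b QC-filtered call tibbles from callers A and B.
#' @param probes Probe map used to recompute `n_probes` on merged spans.
#' @return A merged call tibble with `caller = "consensus"`.
#' @export
consensus_merge <- function(calls_a, calls_b, probes) {
  empty <- tibble(sample_id = character(), chrom = character(),
                  start = numeric(), end = numeric(), copy_number = integer(),
                  type = character(), n_probes = integer(),
                  confidence = numeric(), caller = character())
  if (nrow(calls_a) == 0 || nrow(calls_b) == 0) return(empty)
  pool <- bind_rows(mutate(calls_a, .src = "a"), mutate(calls_b, .src = "b")) |>
    arrange(.data$sample_id, .data$type, .data$chrom, .data$start)
  groups <- pool |> group_by(.data$sample_id, .data$type, .data$chrom)
  keys <- group_keys(groups)
  idx <- group_rows(groups)
  merged <- vector("list", length(idx))
  for (g in seq_along(idx)) {
    rows <- pool[idx[[g]], ]
    # sweep by ascending start: transitive pooling of >=1 bp overlaps
    comp <- integer(nrow(rows)); comp[1] <- 1L
    reach <- rows$end[1]
    for (i in seq_len(nrow(rows))[-1]) {
      if (rows$start[i] < reach) {
        comp[i] <- comp[i - 1]
        reach <- max(reach, rows$end[i])
      } else {
        comp[i] <- comp[i - 1] + 1L
        reach <- rows$end[i]
      }
    }
    both <- vapply(split(rows$.src, comp),
                   function(s) length(unique(s)) == 2L, logical(1))
    keep_comp <- as.integer(names(both)[both])
    if (length(keep_comp) == 0) next
    merged[[g]] <- bind_rows(lapply(keep_comp, function(cc) {
      r <- rows[comp == cc, ]
      tibble(sample_id = r$sample_id[1], type = r$type[1], chrom = r$chrom[1],
             start = min(r$start), end = max(r$end),
             copy_number = if (r$type[1] == "deletion") min(r$copy_number)
                           else max(r$copy_number),
             confidence = min(r$confidence))
    }))
  }
  res <- bind_rows(merged)
  if (nrow(res) == 0) return(empty)
  res$n_probes <- vapply(seq_len(nrow(res)), function(k) {
    sum(probes$chrom == res$chrom[k] &
          probes$pos > res$start[k] & probes$pos <= res$end[k])
  }, integer(1))
  res$caller <- "consensus"
  res |>
    select(all_of(call_columns)) |>
    arrange(.data$sample_id, .data$chrom, .data$start)
}

#' Full dual-caller discovery pipeline
#'
#' Runs both decoders over a cohort, resolves technical duplicates, applies
#' sample-level QC per caller profile, call-level QC (length/probes for
#' caller A, logBF for caller B), and returns the dual-caller consensus call
#' set together with the intermediate products.
#'
#' @param cohort A `cnv_cohort`.
#' @param model An [hmm_model()].
#' @param thresholds_a,thresholds_b [qc_thresholds()] for the two callers.
#' @param apply_gc_correct Apply GC-wave correction before calling.
#' @return A list: `consensus` (merged call tibble), `calls_a`, `calls_b`
#'   (post-QC per-caller calls), `metrics`, `retained_samples`, and
#'   `qc` (per-stage counts).
#' @export
discover_cnvs <- function(cohort, model = hmm_model(),
                          thresholds_a = qc_thresholds("caller_a"),
                          thresholds_b = qc_thresholds("caller_b"),
                          apply_gc_correct = TRUE) {
  calls_a <- call_cnvs(cohort, "viterbi", model, apply_gc_correct)
  calls_b <- call_cnvs(cohort, "posterior", model, apply_gc_correct)
  metrics <- cohort_metrics(cohort, calls_a, apply_gc_correct)

  kept <- resolve_duplicates(cohort$samples, metrics)
  m_kept <- metrics[metrics$sample_id %in% kept$sample_id, ]

  qc_a <- sample_qc(m_kept, thresholds_a)
  qc_b <- sample_qc(m_kept, thresholds_b)
  ok_a <- qc_a$sample_id[qc_a$pass]
  ok_b <- qc_b$sample_id[qc_b$pass]

  ca <- call_qc(calls_a[calls_a$sample_id %in% ok_a, ], thresholds_a, "length_probes")
  cb <- call_qc(calls_b[calls_b$sample_id %in% ok_b, ], thresholds_b, "logbf")

  consensus <- consensus_merge(ca$calls, cb$calls, cohort$probes)
  retained <- kept[kept$sample_id %in% intersect(ok_a, ok_b), ]

  list(consensus = consensus, calls_a = ca$calls, calls_b = cb$calls,
       metrics = metrics, retained_samples = retained,
       qc = tibble(
         stage = c("calls_a_raw", "calls_a_qc", "calls_b_raw", "calls_b_qc",
                   "consensus", "samples_raw", "samples_dedup", "samples_qc"),
         n = c(nrow(calls_a), nrow(ca$calls), nrow(calls_b), nrow(cb$calls),
               nrow(consensus), nrow(cohort$samples), nrow(kept), nrow(retained))
       ))
}
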