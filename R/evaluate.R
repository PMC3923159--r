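# Breakpoint-tolerant comparison of calls against a planted truth set.

# probe indices (within the map) of an interval's first/last probe
interval_probe_span <- function(x, probes) {
  first <- integer(nrow(x)); last <- integer(nrow(x))
  for (i in seq_len(nrow(x))) {
    ix <- which(probes$chrom == x$chrom[i] &
                  probes$pos > x$start[i] & probes$pos <= x$end[i])
    first[i] <- if (length(ix)) min(ix) else NA_integer_
    last[i] <- if (length(ix)) max(ix) else NA_integer_
  }
  tibble(first = first, last = last)
}

#' Evaluate calls against a ground-truth CNV set
#'
#' Matches calls to truth intervals of the same sample, chromosome and
#' direction (deletion vs duplication) whose breakpoint probe indices agree
#' within `tol_probes` probes on each side. Reports breakpoint-tolerant
#' sensitivity (matched truth / total truth) and precision (matched calls /
#' total calls).
#'
#' @param calls Call tibble.
#' @param truth Truth tibble (`sample_id`, `chrom`, `start`, `end`,
#'   `copy_number`), e.g. the `truth` element of [simulate_cohort()].
#' @param probes Probe map.
#' @param tol_probes Breakpoint tolerance in probes (default 2).
#' @param min_probes Only truth events spanning at least this many probes
#'   are scored (smaller events are excluded from both totals).
#' @return A one-row tibble: `sensitivity`, `precision`, `n_truth`,
#'   `n_calls`, `n_matched_truth`, `n_matched_calls`.
#' @export
evaluate_calls <- function(calls, truth, probes, tol_probes = 2L,
                           min_probes = 1L) {
  tspan <- interval_probe_span(truth, probes)
  truth <- truth |>
    mutate(first = tspan$first, last = tspan$last,
           dir = ifelse(.data$copy_number < 2, "deletion", "duplication")) |>
    filter(!is.na(.data$first), .data$last - .data$first + 1L >= min_probes)
  cspan <- interval_probe_span(calls, probes)
  calls <- calls |> mutate(first = cspan$first, last = cspan$last)

  truth_hit <- logical(nrow(truth))
  call_hit <- logical(nrow(calls))
  for (i in seq_len(nrow(truth))) {
    cand <- which(calls$sample_id == truth$sample_id[i] &
                    calls$chrom == truth$chrom[i] &
                    calls$type == truth$dir[i] &
                    abs(calls$first - truth$first[i]) <= tol_probes &
                    abs(calls$last - truth$last[i]) <= tol_probes)
    if (length(cand) > 0) {
      truth_hit[i] <- TRUE
      call_hit[cand] <- TRUE
    }
  }
  tibble(sensitivity = if (nrow(truth)) mean(truth_hit) else NA_real_,
         precision = if (nrow(calls)) mean(call_hit) else NA_real_,
         n_truth = nrow(truth), n_calls = nrow(calls),
         n_matched_truth = sum(truth_hit), n_matched_calls = sum(call_hit))
}
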