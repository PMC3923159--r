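# CNVR clustering by mutual overlap and reference-locus annotation.

#' Mutual overlap of two intervals
#'
#' `min(o/|a|, o/|b|)` where `o` is the intersection length under the
#' 0-based half-open convention; 0 for intervals on different chromosomes.
#' Vectorized over rows.
#'
#' @param a,b Data frames with columns `chrom`, `start`, `end` (recycled to
#'   a common number of rows).
#' @return Numeric vector of mutual-overlap fractions in `[0, 1]`.
#' @export
mutual_overlap <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  la <- a$end[ai] - a$start[ai]
  lb <- b$end[bi] - b$start[bi]
  if (any(la <= 0) || any(lb <= 0)) stop_domain("zero-length interval")
  o <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  o <- pmax(0, o)
  out <- pmin(o / la, o / lb)
  out[a$chrom[ai] != b$chrom[bi]] <- 0
  out
}

#' Cluster CNV calls into CNV regions (CNVRs)
#'
#' Builds the graph with an edge between calls whose mutual overlap is at
#' least `min_overlap`; CNVRs are the connected components (single linkage),
#' with "relaxed" boundaries: the smallest start and largest end of any
#' member call. Clustering ignores deletion/duplication type -- mixed
#' components are classified `multiallelic`; a CNVR with exactly one member
#' call is flagged `singleton`. Output is invariant to input order (calls
#' are canonically sorted internally) and CNVR ids are assigned in
#' `(chrom, start)` order.
#'
#' @param calls A call tibble.
#' @param min_overlap Mutual-overlap threshold in `(0, 1]` (default 0.40).
#' @return A tibble with one row per CNVR: `cnvr_id`, `chrom`, `start`,
#'   `end`, `type_class`, `n_members`, `singleton`, and `members`
#'   (list-column of member row indices into the sorted input, returned as
#'   attribute `call_order`). Each input call also receives its CNVR id in
#'   the attribute `assignment`.
#' @export
cluster_cnvrs <- function(calls, min_overlap = 0.40) {
  if (min_overlap <= 0 || min_overlap > 1) stop_usage("min_overlap must be in (0, 1]")
  if (nrow(calls) == 0) {
    return(tibble(cnvr_id = character(), chrom = character(), start = numeric(),
                  end = numeric(), type_class = character(),
                  n_members = integer(), singleton = logical(),
                  members = list()))
  }
  ord <- order(calls$chrom, calls$start, calls$end, calls$sample_id)
  calls <- calls[ord, ]
  n <- nrow(calls)

  # candidate overlapping pairs per chromosome via IRanges, then the exact
  # mutual-overlap filter
  edges <- list()
  for (ch in unique(calls$chrom)) {
    ix <- which(calls$chrom == ch)
    ir <- IRanges::IRanges(start = calls$start[ix] + 1, end = calls$end[ix])
    hits <- IRanges::findOverlaps(ir, ir)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    keep <- q < s
    q <- q[keep]; s <- s[keep]
    if (length(q) == 0) next
    mo <- mutual_overlap(calls[ix[q], ], calls[ix[s], ])
    sel <- mo >= min_overlap
    if (any(sel)) edges[[ch]] <- cbind(ix[q[sel]], ix[s[sel]])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges) > 0) {
    em <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(em))
  }
  comp <- igraph::components(g)$membership

  cnvrs <- tibble(comp = comp, chrom = calls$chrom, start = calls$start,
                  end = calls$end, type = calls$type, row = seq_len(n)) |>
    group_by(.data$comp) |>
    summarise(chrom = .data$chrom[1],
              start = min(.data$start), end = max(.data$end),
              type_class = if (all(.data$type == "deletion")) "deletion"
                           else if (all(.data$type == "duplication")) "duplication"
                           else "multiallelic",
              n_members = dplyr::n(),
              singleton = dplyr::n() == 1L,
              members = list(.data$row),
              .groups = "drop") |>
    arrange(.data$chrom, .data$start, .data$end)
  cnvrs$cnvr_id <- sprintf("CNVR%04d", seq_len(nrow(cnvrs)))
  out <- cnvrs |> select("cnvr_id", "chrom", "start", "end", "type_class",
                         "n_members", "singleton", "members")
  assignment <- character(n)
  for (k in seq_len(nrow(out))) assignment[out$members[[k]]] <- out$cnvr_id[k]
  attr(out, "call_order") <- ord
  attr(out, "assignment") <- assignment
  out
}

#' Map calls to their CNVR ids
#'
#' @param calls The call tibble that was clustered.
#' @param cnvrs The result of [cluster_cnvrs()] on those calls.
#' @return Character vector of CNVR ids aligned to the rows of `calls`.
#' @export
cnvr_assignment <- function(calls, cnvrs) {
  ord <- attr(cnvrs, "call_order")
  assignment <- attr(cnvrs, "assignment")
  if (is.null(ord) || length(assignment) != nrow(calls)) {
    stop_usage("cnvrs does not correspond to these calls")
  }
  out <- character(nrow(calls))
  out[ord] <- assignment
  out
}

#' Annotate items against a reference CNV locus list
#'
#' An item is "overlapped" iff some reference interval (of matching type
#' when `same_type`) covers at least `threshold` of the item's length.
#' Coverage is one-directional (fraction of the query covered), the
#' convention used when asking whether a discovered CNV was previously
#' reported.
#'
#' @param x Calls or CNVRs: a data frame with `chrom`, `start`, `end` and a
#'   type column (`type` or `type_class`).
#' @param reference Reference loci: data frame with `chrom`, `start`, `end`,
#'   `type` and optionally `locus_id`.
#' @param threshold Minimum covered fraction in `(0, 1]`.
#' @param same_type Require the reference type to match the item type
#'   (multiallelic items match either type).
#' @return `x` with added columns `overlapped`, `best_fraction`, `best_ref`.
#' @export
annotate_overlap <- function(x, reference, threshold = 0.40, same_type = TRUE) {
  if (threshold <= 0 || threshold > 1) stop_usage("threshold must be in (0, 1]")
  type_col <- if ("type" %in% names(x)) "type" else "type_class"
  ref_id <- reference$locus_id %||% format_region(reference)
  n <- nrow(x)
  best_fraction <- numeric(n); best_ref <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    len <- x$end[i] - x$start[i]
    if (len <= 0) stop_domain("zero-length query interval")
    cand <- reference$chrom == x$chrom[i]
    if (same_type && type_col %in% names(x)) {
      it <- x[[type_col]][i]
      if (it != "multiallelic") cand <- cand & reference$type == it
    }
    if (!any(cand)) next
    o <- pmax(0, pmin(x$end[i], reference$end[cand]) -
                pmax(x$start[i], reference$start[cand]))
    frac <- o / len
    j <- which.max(frac)
    best_fraction[i] <- frac[j]
    best_ref[i] <- ref_id[cand][j]
  }
  x |> mutate(best_fraction = best_fraction,
              best_ref = ifelse(best_fraction > 0, best_ref, NA_character_),
              overlapped = best_fraction >= threshold)
}

#' Per-reference-locus overlap counts by sample group
#'
#' For each reference locus, counts how many distinct query samples carry an
#' overlapping call of the same type, split by case/control status (and
#' cases with a family history), the orientation used when cross-checking
#' previously implicated loci.
#'
#' @param calls Call tibble.
#' @param reference Reference loci (see [annotate_overlap()]).
#' @param samples Sample sheet with `sample_id`, `status` and optionally
#'   `family_history`.
#' @param threshold Minimum covered fraction of the query call; use a tiny
#'   positive value for an any-overlap criterion.
#' @param same_type Require matching deletion/duplication type.
#' @return A tibble with one row per reference locus and count columns
#'   `n_cases`, `n_cases_famhx`, `n_controls`.
#' @export
reference_locus_counts <- function(calls, reference, samples,
                                   threshold = 0.40, same_type = TRUE) {
  ref_id <- reference$locus_id %||% format_region(reference)
  reference$locus_id <- ref_id
  out <- reference |> as_tibble()
  ann <- annotate_overlap(calls, reference, threshold, same_type)
  hits <- ann[ann$overlapped, c("sample_id", "best_ref")]
  meta <- samples[c("sample_id", "status")]
  meta$family_history <- samples$family_history %||% rep("no", nrow(samples))
  hits <- left_join(hits, meta, by = "sample_id") |> distinct()
  counts <- hits |>
    group_by(.data$best_ref) |>
    summarise(n_cases = n_distinct(.data$sample_id[.data$status == "case"]),
              n_cases_famhx = n_distinct(
                .data$sample_id[.data$status == "case" &
                                  .data$family_history == "yes"]),
              n_controls = n_distinct(.data$sample_id[.data$status == "control"]),
              .groups = "drop")
  out |>
    left_join(counts, by = c(locus_id = "best_ref")) |>
    mutate(across(c("n_cases", "n_cases_famhx", "n_controls"),
                  ~ tidyr::replace_na(.x, 0L)))
}

#' Reference CNV loci previously implicated in familial pancreatic cancer
#'
#' The seven loci (hg18) at which this pipeline's discovery calls are
#' cross-checked against earlier familial pancreatic cancer CNV reports,
#' shipped as a packaged plain-text fixture.
#'
#' @return A tibble with `locus_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `type` and `source`.
#' @export
fpc_reference_loci <- function() {
  path <- system.file("extdata", "fpc_reference_loci.tsv", package = "cnvrisk",
                      mustWork = TRUE)
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  reg <- parse_region(raw$locus)
  tibble(locus_id = raw$locus, chrom = reg$chrom, start = reg$start,
         end = reg$end, type = raw$type, source = raw$source)
}
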