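# Readers/writers and coordinate conventions.
#
# All intervals are held internally as 0-based half-open [start, end);
# every display or file coordinate that users see (region strings,
# probe positions, rawcnv lines) is 1-based inclusive. BED output is
# 0-based half-open, matching the internal convention.

#' Read a probe map
#'
#' Reads a tab-separated probe map with columns `probe_id`, `chrom`, `pos`
#' (1-based bp), `gc` (GC fraction in `[0, 1]`) and `pfb` (population
#' B-allele frequency in `[0, 1]`). Probes are returned sorted by
#' `(chrom, pos)`; chromosome names are compared as verbatim strings.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble with one row per probe, sorted by `(chrom, pos)`.
#' @export
read_probe_map <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  validate_probe_map(raw, source = path)
}

#' Validate (and sort) a probe map
#'
#' @param probes A data frame with columns `probe_id`, `chrom`, `pos`, `gc`, `pfb`.
#' @param source Label used in error messages.
#' @return The validated probe map as a sorted tibble.
#' @export
validate_probe_map <- function(probes, source = "probe map") {
  need <- c("probe_id", "chrom", "pos", "gc", "pfb")
  miss <- setdiff(need, names(probes))
  if (length(miss) > 0) {
    stop_format(paste0(source, ": missing columns: ", paste(miss, collapse = ", ")))
  }
  probes <- as_tibble(probes)[need]
  for (col in c("pos", "gc", "pfb")) {
    v <- suppressWarnings(as.numeric(probes[[col]]))
    if (anyNA(v)) stop_format(paste0(source, ": non-numeric values in column '", col, "'"))
    probes[[col]] <- v
  }
  probes$pos <- as.integer(probes$pos)
  probes$probe_id <- as.character(probes$probe_id)
  probes$chrom <- as.character(probes$chrom)
  if (anyDuplicated(probes$probe_id)) {
    stop_format(paste0(source, ": duplicate probe_id"))
  }
  if (any(probes$pos < 1)) stop_format(paste0(source, ": pos must be >= 1"))
  if (any(probes$gc < 0 | probes$gc > 1)) stop_format(paste0(source, ": gc outside [0, 1]"))
  if (any(probes$pfb < 0 | probes$pfb > 1)) stop_format(paste0(source, ": pfb outside [0, 1]"))
  probes <- arrange(probes, .data$chrom, .data$pos)
  if (any(duplicated(probes[c("chrom", "pos")]))) {
    stop_format(paste0(source, ": duplicated (chrom, pos)"))
  }
  probes
}

#' Read one sample's signal file
#'
#' Reads a tab-separated per-sample signal file with columns
#' `probe_id`, `lrr`, `baf` (the header aliases `Name`, `Log R Ratio` and
#' `B Allele Freq` are accepted). Values are aligned to the probe-map
#' order; probes absent from the file are marked missing (`NA`).
#'
#' @param path Path to the signal file.
#' @param probes A validated probe map (see [read_probe_map()]).
#' @return A tibble with columns `probe_id`, `lrr`, `baf` in probe-map
#'   order, carrying a `missing_fraction` attribute (fraction of map
#'   probes absent from the file).
#' @export
read_signal_file <- function(path, probes) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  nm <- names(raw)
  alias <- c("Name" = "probe_id", "Log R Ratio" = "lrr", "B Allele Freq" = "baf")
  hit <- nm %in% names(alias)
  nm[hit] <- alias[nm[hit]]
  names(raw) <- nm
  need <- c("probe_id", "lrr", "baf")
  if (!all(need %in% names(raw))) {
    stop_format(paste0(path, ": expected columns probe_id, lrr, baf (or PennCNV aliases)"))
  }
  lrr <- suppressWarnings(as.numeric(raw$lrr))
  baf <- suppressWarnings(as.numeric(raw$baf))
  bad_lrr <- !is.na(raw$lrr) & raw$lrr != "NA" & is.na(lrr)
  bad_baf <- !is.na(raw$baf) & raw$baf != "NA" & is.na(baf)
  if (any(bad_lrr) || any(bad_baf)) {
    stop_format(paste0(path, ": non-numeric LRR/BAF values"))
  }
  if (any(baf < 0 | baf > 1, na.rm = TRUE)) {
    stop_format(paste0(path, ": BAF outside [0, 1]"))
  }
  idx <- match(probes$probe_id, raw$probe_id)
  missing_fraction <- mean(is.na(idx))
  if (missing_fraction > 0.5) {
    abort(paste0(path, ": more than 50% of map probes missing from signal file"),
          class = "cnvrisk_malformed_sample_error")
  }
  out <- tibble(probe_id = probes$probe_id, lrr = lrr[idx], baf = baf[idx])
  attr(out, "missing_fraction") <- missing_fraction
  out
}

#' Read a sample sheet
#'
#' Reads a CSV sample sheet with at least `sample_id` and `status`
#' (`case`/`control`) columns; typical sheets also carry `age`, `gender`,
#' `family_history`, `dna_source`, `batch`, `platform` and `duplicate_of`.
#'
#' @param path Path to the CSV file.
#' @return A tibble, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("sample_id", "status") %in% names(sheet))) {
    stop_format(paste0(path, ": sample sheet needs sample_id and status columns"))
  }
  sheet$sample_id <- as.character(sheet$sample_id)
  if (anyDuplicated(sheet$sample_id)) stop_format(paste0(path, ": duplicate sample_id"))
  if (!all(sheet$status %in% c("case", "control"))) {
    stop_format(paste0(path, ": status must be 'case' or 'control'"))
  }
  if ("duplicate_of" %in% names(sheet)) {
    ref <- sheet$duplicate_of[!is.na(sheet$duplicate_of)]
    if (!all(ref %in% sheet$sample_id)) {
      stop_format(paste0(path, ": duplicate_of references a sample not in the sheet"))
    }
  }
  sheet
}

#' Parse genomic region strings
#'
#' Converts `"chrom:start-end"` strings with 1-based inclusive coordinates
#' into the internal 0-based half-open representation, so that
#' `end - start` is the region length in bp.
#'
#' @param text Character vector of region strings, e.g. `"chr4:115387397-115401739"`.
#' @return A tibble with columns `chrom`, `start` (0-based), `end` (exclusive).
#' @seealso [format_region()] for the inverse.
#' @export
parse_region <- function(text) {
  m <- regmatches(text, regexec("^([^:]+):([0-9]+)-([0-9]+)$", text))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop_format(paste0("malformed region string: ", text[bad][1]))
  }
  chrom <- vapply(m, `[`, character(1), 2L)
  start1 <- as.numeric(vapply(m, `[`, character(1), 3L))
  end1 <- as.numeric(vapply(m, `[`, character(1), 4L))
  if (any(end1 < start1)) {
    stop_format(paste0("region end before start: ", text[end1 < start1][1]))
  }
  tibble(chrom = chrom, start = start1 - 1, end = end1)
}

#' Format intervals as region strings
#'
#' @param x A data frame with columns `chrom`, `start`, `end` in the internal
#'   0-based half-open convention.
#' @return Character vector of `"chrom:start-end"` strings (1-based inclusive).
#' @export
format_region <- function(x) {
  sprintf("%s:%d-%d", x$chrom, as.integer(x$start) + 1L, as.integer(x$end))
}

call_columns <- c("sample_id", "chrom", "start", "end", "copy_number",
                  "type", "n_probes", "confidence", "caller")

validate_calls <- function(calls, source = "calls") {
  miss <- setdiff(call_columns, names(calls))
  if (length(miss) > 0) {
    stop_format(paste0(source, ": missing call columns: ", paste(miss, collapse = ", ")))
  }
  if (any(calls$copy_number == 2L)) stop_format(paste0(source, ": copy_number 2 is not a call"))
  del <- calls$copy_number < 2L
  if (any(calls$type != ifelse(del, "deletion", "duplication"))) {
    stop_format(paste0(source, ": type inconsistent with copy_number"))
  }
  if (any(calls$end <= calls$start)) stop_format(paste0(source, ": empty interval"))
  as_tibble(calls)[call_columns]
}

#' Write CNV calls
#'
#' Writes a call table either as a rawcnv-style tab-separated file (one line
#' per call: 1-based region string, probe count, length, copy number, sample,
#' confidence, caller) or as BED (0-based half-open, with the remaining call
#' fields packed into the name and score columns). Both dialects round-trip
#' through [read_calls()].
#'
#' @param calls A call tibble (see [call_cnvs()]).
#' @param path Output path.
#' @param dialect `"rawcnv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, dialect = c("rawcnv", "bed")) {
  dialect <- match.arg(dialect)
  calls <- validate_calls(calls)
  if (dialect == "rawcnv") {
    out <- tibble(
      region = format_region(calls),
      numsnp = calls$n_probes,
      length = as.integer(calls$end - calls$start),
      cn = calls$copy_number,
      sample_id = calls$sample_id,
      confidence = calls$confidence,
      caller = calls$caller
    )
    readr::write_tsv(out, path)
  } else {
    out <- tibble(
      chrom = calls$chrom,
      start = as.integer(calls$start),
      end = as.integer(calls$end),
      name = sprintf("%s|cn=%d|numsnp=%d|caller=%s",
                     calls$sample_id, calls$copy_number, calls$n_probes, calls$caller),
      score = calls$confidence
    )
    readr::write_tsv(out, path)
  }
  invisible(path)
}

#' Read CNV calls written by [write_calls()]
#'
#' @inheritParams write_calls
#' @return A call tibble.
#' @export
read_calls <- function(path, dialect = c("rawcnv", "bed")) {
  dialect <- match.arg(dialect)
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  if (nrow(raw) == 0) {
    return(tibble(sample_id = character(), chrom = character(),
                  start = numeric(), end = numeric(),
                  copy_number = integer(), type = character(),
                  n_probes = integer(), confidence = numeric(),
                  caller = character()))
  }
  if (dialect == "rawcnv") {
    reg <- parse_region(raw$region)
    calls <- tibble(
      sample_id = as.character(raw$sample_id),
      chrom = reg$chrom, start = reg$start, end = reg$end,
      copy_number = as.integer(raw$cn),
      type = ifelse(raw$cn < 2, "deletion", "duplication"),
      n_probes = as.integer(raw$numsnp),
      confidence = raw$confidence,
      caller = as.character(raw$caller)
    )
  } else {
    fields <- strsplit(raw$name, "|", fixed = TRUE)
    get <- function(i) vapply(fields, `[`, character(1), i)
    kv <- function(s) sub("^[^=]*=", "", s)
    cn <- as.integer(kv(get(2)))
    calls <- tibble(
      sample_id = get(1),
      chrom = raw$chrom, start = as.numeric(raw$start), end = as.numeric(raw$end),
      copy_number = cn,
      type = ifelse(cn < 2, "deletion", "duplication"),
      n_probes = as.integer(kv(get(3))),
      confidence = raw$score,
      caller = kv(get(4))
    )
  }
  validate_calls(calls, source = path)
}

#' Write a simulated cohort to disk in the pipeline's on-disk formats
#'
#' Emits the probe map (TSV), one PennCNV-dialect signal file per sample,
#' the sample sheet (CSV), the ground-truth CNV set (BED-like TSV with
#' sample and copy-number columns) and the SNP genotype matrix (TSV).
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(cohort$probes, file.path(dir, "probe_map.tsv"))
  readr::write_csv(cohort$samples, file.path(dir, "sample_sheet.csv"))
  sigdir <- file.path(dir, "signals")
  if (!dir.exists(sigdir)) dir.create(sigdir)
  for (i in seq_len(nrow(cohort$samples))) {
    sid <- cohort$samples$sample_id[i]
    sig <- tibble(`Name` = cohort$probes$probe_id,
                  `Log R Ratio` = cohort$lrr[i, ],
                  `B Allele Freq` = cohort$baf[i, ])
    readr::write_tsv(sig, file.path(sigdir, paste0(sid, ".txt")))
  }
  readr::write_tsv(cohort$truth, file.path(dir, "truth.bed"))
  if (!is.null(cohort$genotypes)) {
    geno <- as_tibble(cohort$genotypes, rownames = "sample_id")
    readr::write_tsv(geno, file.path(dir, "genotypes.tsv"))
  }
  invisible(dir)
}
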