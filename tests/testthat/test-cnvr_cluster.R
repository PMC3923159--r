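iv <- function(chrom, start, end) tibble::tibble(chrom = chrom, start = start,
                                                 end = end)

test_that("mutual overlap is the smaller reciprocal fraction", {
  expect_equal(mutual_overlap(iv("chr1", 100, 200), iv("chr1", 100, 200)), 1)
  expect_equal(mutual_overlap(iv("chr1", 100, 200), iv("chr1", 300, 400)), 0)
  expect_equal(mutual_overlap(iv("chr1", 100, 200), iv("chr1", 150, 350)), 0.25)
  expect_equal(mutual_overlap(iv("chr1", 100, 200), iv("chr2", 100, 200)), 0)
  expect_error(mutual_overlap(iv("chr1", 100, 100), iv("chr1", 100, 200)),
               class = "cnvrisk_domain_error")
})

mk_calls <- function(starts, ends, type = "deletion", chrom = "chr1") {
  n <- length(starts)
  tibble::tibble(sample_id = sprintf("S%02d", seq_len(n)), chrom = chrom,
                 start = starts, end = ends,
                 copy_number = ifelse(type == "deletion", 1L, 3L),
                 type = type, n_probes = 10L, confidence = 20, caller = "A")
}

test_that("clustering forms connected components with relaxed boundaries", {
  one <- mk_calls(100, 200)
  out <- cluster_cnvrs(one)
  expect_equal(nrow(out), 1)
  expect_true(out$singleton)
  expect_equal(c(out$start, out$end), c(100, 200))

  two <- mk_calls(c(100, 100), c(200, 200))
  out <- cluster_cnvrs(two)
  expect_equal(nrow(out), 1)
  expect_false(out$singleton)
  expect_equal(out$type_class, "deletion")
  expect_equal(out$n_members, 2L)

  # transitive chain: A-B and B-C overlap 50%, A and C are disjoint
  chain <- mk_calls(c(0, 500, 1000), c(1000, 1500, 2000))
  expect_equal(mutual_overlap(chain[1, ], chain[2, ]), 0.5)
  expect_equal(mutual_overlap(chain[1, ], chain[3, ]), 0)
  out <- cluster_cnvrs(chain, 0.40)
  expect_equal(nrow(out), 1)
  expect_equal(out$n_members, 3L)
  expect_equal(c(out$start, out$end), c(0, 2000))

  # mixed types cluster together and classify multiallelic
  mixed <- dplyr::bind_rows(mk_calls(0, 1000),
                            mk_calls(0, 1000, type = "duplication"))
  expect_equal(cluster_cnvrs(mixed)$type_class, "multiallelic")

  expect_equal(nrow(cluster_cnvrs(mk_calls(numeric(0), numeric(0)))), 0)
})

test_that("clustering is order-invariant and partitions the calls", {
  calls <- random_calls(60, seed = 3)
  a <- cluster_cnvrs(calls)
  b <- cluster_cnvrs(calls[sample.int(nrow(calls)), ])
  expect_equal(a[setdiff(names(a), "members")],
               b[setdiff(names(b), "members")], ignore_attr = TRUE)
  expect_equal(sum(a$n_members), nrow(calls))
  # assignment maps every call to exactly one CNVR
  assign <- cnvr_assignment(calls, a)
  expect_true(all(assign %in% a$cnvr_id))
})

test_that("clustering matches the quadratic all-pairs oracle", {
  for (seed in 1:10) {
    calls <- random_calls(50, seed = seed)
    out <- cluster_cnvrs(calls, 0.40)
    ord <- attr(out, "call_order")
    sorted <- calls[ord, ]
    oracle <- brute_force_cnvrs(sorted, 0.40)
    mine <- match(attr(out, "assignment"), out$cnvr_id)
    expect_equal(partition_signature(mine), partition_signature(oracle))
  }
})

test_that("raising the overlap threshold refines the partition", {
  calls <- random_calls(80, seed = 13)
  coarse <- cluster_cnvrs(calls, 0.3)
  fine <- cluster_cnvrs(calls, 0.6)
  a_coarse <- cnvr_assignment(calls, coarse)
  a_fine <- cnvr_assignment(calls, fine)
  # every fine cluster must live inside a single coarse cluster
  split_fine <- split(a_coarse, a_fine)
  expect_true(all(vapply(split_fine, function(x) length(unique(x)) == 1,
                         logical(1))))
  expect_gte(nrow(fine), nrow(coarse))
})

test_that("reference annotation uses one-directional query coverage", {
  ref <- tibble::tibble(chrom = "chr1", start = 500, end = 2000,
                        type = "deletion", locus_id = "L1")
  q <- mk_calls(c(500, 0, 0), c(2000, 1000, 100))
  q$end[3] <- 1000; q$start[3] <- 0 # 39% covered variant below
  q2 <- q; q2$start <- c(500, 0, 0); q2$end <- c(2000, 1000, 820)
  ref39 <- ref; ref39$start <- 500; ref39$end <- 820

  out <- annotate_overlap(q[1, ], ref, threshold = 0.40)
  expect_true(out$overlapped)
  expect_equal(out$best_fraction, 1)

  out <- annotate_overlap(q[2, ], ref, threshold = 0.40)
  expect_true(out$overlapped) # covered 500/1000 = 0.5
  expect_equal(out$best_fraction, 0.5)

  out <- annotate_overlap(q[2, ], ref39, threshold = 0.40)
  expect_false(out$overlapped) # covered 320/1000 = 0.32 < 0.40
  expect_equal(out$best_fraction, 0.32)

  # same-type requirement
  dup <- q[2, ]; dup$type <- "duplication"; dup$copy_number <- 3L
  expect_false(annotate_overlap(dup, ref, threshold = 0.4,
                                same_type = TRUE)$overlapped)
  expect_true(annotate_overlap(dup, ref, threshold = 0.4,
                               same_type = FALSE)$overlapped)

  expect_error(annotate_overlap(q, ref, threshold = 1.2),
               class = "cnvrisk_usage_error")
})

test_that("packaged reference loci count overlapping samples per group", {
  ref <- fpc_reference_loci()
  expect_equal(nrow(ref), 7)
  expect_true(all(ref$end > ref$start))
  expect_setequal(unique(ref$type), c("deletion", "duplication"))

  # one case call fully inside the first locus, one control call elsewhere
  calls <- tibble::tibble(
    sample_id = c("case1", "ctrl1"),
    chrom = c(ref$chrom[1], ref$chrom[2]),
    start = c(ref$start[1], ref$start[2]),
    end = c(ref$end[1], ref$end[2]),
    copy_number = 1L, type = "deletion",
    n_probes = 10L, confidence = 20, caller = "consensus")
  samples <- tibble::tibble(sample_id = c("case1", "ctrl1"),
                            status = c("case", "control"),
                            family_history = c("yes", "no"))
  counts <- reference_locus_counts(calls, ref, samples)
  expect_equal(counts$n_cases[1], 1L)
  expect_equal(counts$n_cases_famhx[1], 1L)
  expect_equal(counts$n_controls[1], 0L)
  expect_equal(counts$n_controls[2], 1L)
  expect_equal(sum(counts$n_cases), 1L)
})
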