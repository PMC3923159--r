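# SNP-level cohort statistics: HWE exact test, SNP QC filters, ancestry PCA,
# and Fisher's exact tests for cohort-characteristics tables.

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the observed allele counts, heterozygote
#' counts are distributed hypergeometrically under HWE; the two-sided
#' p-value is the total probability of heterozygote counts whose conditional
#' probability does not exceed that of the observed table (mid-p off).
#' Probabilities are computed by the standard recurrence over heterozygote
#' counts. Monomorphic tables return 1 by convention.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (major homozygote, heterozygote,
#'   minor homozygote; order does not matter).
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop_domain("genotype counts must be >= 0")
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop_domain("at least one genotype required")
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  if (rare == 0) return(1.0)
  # heterozygote counts share the parity of the rare-allele count;
  # unnormalized masses by the upward recurrence
  # P(het + 2) = P(het) * 4 hom_r hom_c / ((het + 2)(het + 1))
  het_values <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(het_values))
  probs[1] <- 1
  for (i in seq_along(het_values)[-1]) {
    het <- het_values[i - 1]
    hom_r <- (rare - het) / 2
    hom_c <- n - het - hom_r
    probs[i] <- probs[i - 1] * 4 * hom_r * hom_c / ((het + 2) * (het + 1))
  }
  probs <- probs / sum(probs)
  obs <- probs[match(n_ab, het_values)]
  if (is.na(obs)) stop_domain("heterozygote count inconsistent with allele counts")
  sum(probs[probs <= obs * (1 + 1e-12)])
}

#' SNP quality-control filter
#'
#' Drops SNPs with call rate below `call_rate_min` (all samples), minor
#' allele frequency below `maf_min` (all samples), or HWE exact p-value
#' below `hwe_min` computed in controls only. All comparisons are strict,
#' so a SNP exactly at a threshold is kept.
#'
#' @param geno Sample-by-SNP dosage matrix with entries in
#'   `{0, 1, 2, NA}` and sample-id rownames.
#' @param controls Character vector of control sample ids (subset of
#'   rownames).
#' @param call_rate_min,maf_min,hwe_min Thresholds.
#' @return A list: `geno` (retained columns), `report` (per-SNP tibble with
#'   `call_rate`, `maf`, `hwe_p`, `keep`, `reason`).
#' @export
snp_qc_filter <- function(geno, controls, call_rate_min = 0.95,
                          maf_min = 0.05, hwe_min = 1e-7) {
  if (length(controls) == 0) {
    stop_usage("control set is empty but an HWE threshold is set")
  }
  if (!all(controls %in% rownames(geno))) stop_usage("unknown control sample ids")
  call_rate <- colMeans(!is.na(geno))
  p_alt <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  gc_ctrl <- geno[controls, , drop = FALSE]
  hwe_p <- vapply(seq_len(ncol(geno)), function(j) {
    g <- gc_ctrl[, j]
    g <- g[!is.na(g)]
    if (length(g) == 0) return(1.0)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  v_cr <- call_rate < call_rate_min
  v_maf <- maf < maf_min
  v_hwe <- hwe_p < hwe_min
  keep <- !(v_cr | v_maf | v_hwe)
  reason <- pmap(list(v_cr, v_maf, v_hwe), function(a, b, c) {
    paste(c("call_rate", "maf", "hwe")[c(a, b, c)], collapse = ",")
  })
  report <- tibble(snp_id = colnames(geno) %||% as.character(seq_len(ncol(geno))),
                   call_rate = unname(call_rate), maf = unname(maf),
                   hwe_p = hwe_p, keep = unname(keep),
                   reason = unname(unlist(reason)))
  list(geno = geno[, keep, drop = FALSE], report = report)
}

#' Ancestry principal components from a genotype matrix
#'
#' Mean-imputes missing dosages per SNP, centres each SNP and scales it by
#' the binomial standard deviation `sqrt(2 p (1 - p))`, then takes the top
#' singular vectors. Component signs are made deterministic by orienting the
#' largest-magnitude loading positive.
#'
#' @param geno Sample-by-SNP dosage matrix (post-QC).
#' @param n_components Number of components (default 4).
#' @return A list: `scores` (tibble `sample_id`, `PC1`..), `var_explained`.
#' @export
genotype_pca <- function(geno, n_components = 4) {
  if (ncol(geno) < n_components) {
    stop_domain("fewer SNPs than requested components")
  }
  p <- colMeans(geno, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  geno <- geno[, keep, drop = FALSE]; p <- p[keep]
  m <- geno
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (any(nas)) m[nas, j] <- 2 * p[j]
  }
  m <- sweep(m, 2, 2 * p, "-")
  m <- sweep(m, 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(m, nu = n_components, nv = n_components)
  scores <- sv$u[, seq_len(n_components), drop = FALSE] %*%
    diag(sv$d[seq_len(n_components)], n_components)
  for (k in seq_len(n_components)) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) scores[, k] <- -scores[, k]
  }
  colnames(scores) <- paste0("PC", seq_len(n_components))
  out <- as_tibble(scores)
  out$sample_id <- rownames(geno) %||% as.character(seq_len(nrow(geno)))
  list(scores = relocate(out, "sample_id"),
       var_explained = sv$d[seq_len(n_components)]^2 / sum(sv$d^2))
}

#' Fisher's exact test for an r x c count table
#'
#' For 2x2 tables the two-sided p-value uses the doubling convention (twice
#' the smaller one-sided tail, capped at 1); see the methods vignette for
#' why this convention is the default. Larger tables use the exact network
#' algorithm when the table is small enough (`n <= 500` and at most 8
#' cells), and otherwise Monte Carlo with `B` draws (with its standard
#' error reported).
#'
#' @param table Matrix of non-negative integer counts, at least 2x2.
#' @param two_sided For 2x2 tables: `"doubling"` (default) or `"minlike"`
#'   (sum of table probabilities not exceeding the observed one).
#' @param seed Seed for the Monte Carlo fallback.
#' @param mc_b Number of Monte Carlo draws.
#' @return A one-row tibble: `p_value`, `method`, `mc_se`.
#' @export
fisher_exact <- function(table, two_sided = c("doubling", "minlike"),
                         seed = 1L, mc_b = 1e6) {
  two_sided <- match.arg(two_sided)
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop_domain("counts must be non-negative integers")
  }
  if (nrow(table) < 2 || ncol(table) < 2) stop_usage("table must be at least 2x2")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(tibble(p_value = 1.0, method = "degenerate", mc_se = NA_real_))
  }
  if (nrow(table) == 2 && ncol(table) == 2) {
    if (two_sided == "doubling") {
      p1 <- fisher.test(table, alternative = "greater")$p.value
      p2 <- fisher.test(table, alternative = "less")$p.value
      p <- min(1, 2 * min(p1, p2))
    } else {
      p <- fisher.test(table)$p.value
    }
    return(tibble(p_value = p, method = paste0("exact_2x2_", two_sided),
                  mc_se = NA_real_))
  }
  n <- sum(table)
  if (n <= 500 && length(table) <= 8) {
    p <- fisher.test(table, workspace = 2e7)$p.value
    return(tibble(p_value = p, method = "exact_network", mc_se = NA_real_))
  }
  withr::local_seed(seed)
  p <- fisher.test(table, simulate.p.value = TRUE, B = mc_b)$p.value
  tibble(p_value = p, method = "monte_carlo", mc_se = sqrt(p * (1 - p) / mc_b))
}

#' Cohort characteristics table with Fisher's exact tests
#'
#' Tabulates categorical sample-sheet variables by case/control status and
#' attaches the Fisher exact p-value per variable, the summary layout used
#' to describe a case-control cohort.
#'
#' @param samples Sample sheet tibble with a `status` column.
#' @param variables Categorical columns to tabulate.
#' @return A tibble with one row per variable level: counts, per-group
#'   percentages, and the per-variable p-value on the first level row.
#' @export
cohort_characteristics <- function(samples,
                                   variables = c("gender", "family_history",
                                                 "dna_source", "platform")) {
  rows <- list()
  for (v in intersect(variables, names(samples))) {
    tab <- table(samples[[v]], samples$status)
    if (nrow(tab) < 2) next
    tab <- tab[, c("case", "control"), drop = FALSE]
    p <- fisher_exact(tab)$p_value
    lev <- rownames(tab)
    rows[[v]] <- tibble(
      variable = v, level = lev,
      n_cases = as.integer(tab[, "case"]),
      pct_cases = round(100 * tab[, "case"] / sum(tab[, "case"]), 1),
      n_controls = as.integer(tab[, "control"]),
      pct_controls = round(100 * tab[, "control"] / sum(tab[, "control"]), 1),
      p_value = c(p, rep(NA_real_, length(lev) - 1))
    )
  }
  bind_rows(rows)
}
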