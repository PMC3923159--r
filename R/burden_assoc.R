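# Per-individual CNV burden and case-control burden association.

#' Per-individual CNV burden counts
#'
#' CNV burden is the number of QC-passing consensus calls made in an
#' individual, counted for deletions and duplications together and
#' separately; singleton counts are restricted to calls whose CNVR contains
#' exactly one member. Samples with no calls receive zeros.
#'
#' @param calls Final consensus call tibble.
#' @param cnvrs CNVRs from [cluster_cnvrs()] on those calls.
#' @param samples Sample sheet; every call's `sample_id` must appear here.
#' @return A tibble with one row per sample: the counts `n_all`, `n_del`,
#'   `n_dup`, `n_all_singleton`, `n_del_singleton`, `n_dup_singleton`,
#'   joined with the sample metadata.
#' @export
burden_counts <- function(calls, cnvrs, samples) {
  if (!all(calls$sample_id %in% samples$sample_id)) {
    abort("call references a sample missing from the sheet",
          class = "cnvrisk_data_error")
  }
  singleton_ids <- cnvrs$cnvr_id[cnvrs$singleton]
  assign <- if (nrow(calls) > 0) cnvr_assignment(calls, cnvrs) else character(0)
  calls$is_singleton <- assign %in% singleton_ids
  counts <- calls |>
    group_by(.data$sample_id) |>
    summarise(n_all = dplyr::n(),
              n_del = sum(.data$type == "deletion"),
              n_dup = sum(.data$type == "duplication"),
              n_all_singleton = sum(.data$is_singleton),
              n_del_singleton = sum(.data$is_singleton & .data$type == "deletion"),
              n_dup_singleton = sum(.data$is_singleton & .data$type == "duplication"),
              .groups = "drop")
  samples |>
    left_join(counts, by = "sample_id") |>
    mutate(across(c("n_all", "n_del", "n_dup", "n_all_singleton",
                    "n_del_singleton", "n_dup_singleton"),
                  ~ as.integer(tidyr::replace_na(.x, 0L))))
}

#' Screen technical factors for association with CNV burden
#'
#' One univariate ordinary-least-squares fit per factor of the total burden
#' `n_all` on that factor. Categorical factors use reference-level dummy
#' coding (first level in sheet order is the reference, displayed with a
#' zero effect); continuous factors contribute one slope. A factor is
#' flagged for downstream covariate adjustment when any of its levels is
#' associated at `p < 0.1`.
#'
#' @param burden A [burden_counts()] table.
#' @param factors Character vector of column names to screen.
#' @param p_flag Flagging threshold (default 0.1).
#' @return A tibble with columns `factor`, `level`, `beta`, `p_value`,
#'   `reference`, `flagged`.
#' @export
technical_factor_screen <- function(burden,
                                    factors = c("dna_source", "age", "gender",
                                                "batch", "platform"),
                                    p_flag = 0.1) {
  out <- list()
  for (f in factors) {
    v <- burden[[f]]
    if (is.null(v)) stop_usage(paste0("unknown factor: ", f))
    if (is.character(v) || is.factor(v)) {
      v <- factor(v, levels = unique(as.character(v)))
      if (nlevels(v) < 2) {
        warn(paste0("factor ", f, " has a single level; skipped"))
        next
      }
      fit <- lm(burden$n_all ~ v)
      sm <- summary(fit)$coefficients
      lev <- levels(v)
      rows <- tibble(factor = f, level = lev,
                     beta = c(0, sm[-1, 1]),
                     p_value = c(NA_real_, sm[-1, 4]),
                     reference = c(TRUE, rep(FALSE, length(lev) - 1)))
    } else {
      fit <- lm(burden$n_all ~ v)
      sm <- summary(fit)$coefficients
      rows <- tibble(factor = f, level = f, beta = sm[2, 1],
                     p_value = sm[2, 4], reference = FALSE)
    }
    rows$flagged <- any(rows$p_value < p_flag, na.rm = TRUE)
    out[[f]] <- rows
  }
  bind_rows(out)
}

subgroup_filter <- function(burden, subgroup) {
  switch(subgroup,
    all = burden,
    family_history = burden |>
      filter(.data$status == "control" |
               (.data$status == "case" & .data$family_history == "yes")),
    early_onset = burden |> filter(.data$age <= 50),
    stop_usage("unknown subgroup")
  )
}

fit_logistic <- function(y, design_df) {
  design_df <- droplevels(design_df)
  fit <- suppressWarnings(
    glm(y ~ ., data = design_df, family = binomial(),
        control = glm.control(epsilon = 1e-8, maxit = 100)))
  if (!fit$converged) {
    abort("logistic regression did not converge",
          class = "cnvrisk_convergence_error")
  }
  fit
}

#' Case-control CNV burden association
#'
#' Logistic regression of case/control status on per-individual CNV burden.
#' Reports the per-unit-of-burden odds ratio and the 1-df Wald p-value under
#' both a univariate model and a multivariate model adjusted for the given
#' covariates, together with the group burden means and their ratio.
#' Subgroups: `family_history` keeps cases with a family history and all
#' controls; `early_onset` keeps cases diagnosed at age 50 or younger and
#' controls aged 50 or younger.
#'
#' @param burden A [burden_counts()] table.
#' @param cnv_type `"all"`, `"del"` or `"dup"`.
#' @param subgroup `"all"`, `"family_history"` or `"early_onset"`.
#' @param covariates Covariate column names for the multivariate model,
#'   drawn from the sheet (e.g. `age`, `gender`, ancestry PCs, `batch`,
#'   `platform`); empty for none, in which case the multivariate estimate
#'   equals the univariate one.
#' @param singleton_only Count only singleton calls.
#' @return A one-row tibble with subgroup/type labels, group means and
#'   ratio, univariate `or`/`p_value` and multivariate `or_adj`/`p_value_adj`.
#' @export
burden_logistic <- function(burden, cnv_type = c("all", "del", "dup"),
                            subgroup = c("all", "family_history", "early_onset"),
                            covariates = character(0),
                            singleton_only = FALSE) {
  cnv_type <- match.arg(cnv_type)
  subgroup <- match.arg(subgroup)
  dat <- subgroup_filter(burden, subgroup)
  if (length(unique(dat$status)) < 2 || min(table(dat$status)) < 2) {
    stop_usage("subgroup leaves fewer than 2 samples in an outcome class")
  }
  col <- paste0("n_", cnv_type, if (singleton_only) "_singleton" else "")
  x <- dat[[col]]
  if (var(x) == 0) {
    abort("zero-variance burden predictor", class = "cnvrisk_convergence_error")
  }
  y <- as.integer(dat$status == "case")
  mean_cases <- mean(x[y == 1]); mean_controls <- mean(x[y == 0])

  uni <- fit_logistic(y, data.frame(burden = x))
  su <- summary(uni)$coefficients["burden", ]

  if (length(covariates) > 0) {
    covs <- dat[covariates]
    # drop single-level categorical covariates inside the subgroup
    keep <- vapply(covs, function(v) {
      !(is.character(v) || is.factor(v)) || length(unique(v)) > 1
    }, logical(1))
    design <- data.frame(burden = x, covs[keep])
    multi <- fit_logistic(y, design)
    sm <- summary(multi)$coefficients["burden", ]
  } else {
    sm <- su
  }

  tibble(subgroup = subgroup, cnv_type = cnv_type,
         singleton_only = singleton_only,
         n_cases = sum(y), n_controls = sum(1 - y),
         mean_cases = mean_cases, mean_controls = mean_controls,
         ratio = mean_cases / mean_controls,
         or = exp(su[1]), p_value = su[4],
         or_adj = exp(sm[1]), p_value_adj = sm[4],
         covariates = paste(covariates, collapse = ","))
}

#' Full burden-association scan
#'
#' Runs [burden_logistic()] over the standard grid: three subgroups (all;
#' cases with family history vs all controls; early-onset cases vs young
#' controls) by three CNV types (all, deletions, duplications), optionally
#' restricted to singleton calls. Cells in which the model cannot be fit
#' (zero-variance burden, non-convergence) are returned with `NA` estimates
#' rather than dropped.
#'
#' @inheritParams burden_logistic
#' @return A tibble with one row per subgroup-by-type cell.
#' @export
burden_scan <- function(burden, covariates = character(0), singleton_only = FALSE) {
  grid <- expand.grid(subgroup = c("all", "family_history", "early_onset"),
                      cnv_type = c("all", "del", "dup"),
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$subgroup, c("all", "family_history", "early_onset"))), ]
  rows <- pmap(grid, function(subgroup, cnv_type) {
    tryCatch(
      burden_logistic(burden, cnv_type, subgroup, covariates, singleton_only),
      error = function(e) tibble(
        subgroup = subgroup, cnv_type = cnv_type,
        singleton_only = singleton_only,
        n_cases = NA_integer_, n_controls = NA_integer_,
        mean_cases = NA_real_, mean_controls = NA_real_, ratio = NA_real_,
        or = NA_real_, p_value = NA_real_, or_adj = NA_real_,
        p_value_adj = NA_real_, covariates = paste(covariates, collapse = ","))
    )
  })
  bind_rows(rows)
}
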