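# In silico CNVR genotyping by constrained Gaussian mixtures and
# mixture+logit likelihood-ratio risk testing.
#
# The signal model: a per-sample summary score x_i of the probes inside a
# CNVR follows a K-component Gaussian mixture whose components correspond to
# integer copy-number classes. Component means may be free or constrained to
# be linear in copy number ("proportional"); variances may be free,
# proportional to copy number (with a floor so copy number 0 keeps positive
# variance), or constant. The risk model ties case/control status to the
# latent class through a logistic link on copy number; association is tested
# by a 1-df likelihood ratio comparing the joint fit with and without the
# copy-number effect.

#' Summarize in-region probe intensities per sample
#'
#' Either the row mean over the probes inside the region (missing excluded)
#' or the projection onto the first principal axis of the column-centred
#' in-region matrix, sign-aligned so the score correlates non-negatively
#' with the row mean.
#'
#' @param lrr Sample-by-probe LRR matrix with sample-id rownames.
#' @param probes Probe map aligned to the columns of `lrr`.
#' @param region A one-row data frame with `chrom`, `start`, `end`.
#' @param method `"mean"` or `"pc1"`.
#' @return A tibble with `sample_id` and `score`, carrying attributes
#'   `n_probes` and `method`; `NULL`-like "region skipped" error when no
#'   probe falls inside the region.
#' @export
summarize_region <- function(lrr, probes, region, method = c("mean", "pc1")) {
  method <- match.arg(method)
  ix <- which(probes$chrom == region$chrom[1] &
                probes$pos > region$start[1] & probes$pos <= region$end[1])
  if (length(ix) == 0) {
    abort("no probes inside the region", class = "cnvrisk_region_skipped")
  }
  m <- lrr[, ix, drop = FALSE]
  if (nrow(m) < 2) stop_usage("summarize_region needs at least 2 samples")
  if (method == "mean") {
    score <- rowMeans(m, na.rm = TRUE)
  } else {
    # mean-impute missing entries per probe before the SVD
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- mean(m[, j], na.rm = TRUE)
    }
    mc <- scale(m, center = TRUE, scale = FALSE)
    if (all(abs(mc) < 1e-12)) {
      abort("zero-variance matrix under pc1", class = "cnvrisk_degenerate_summary")
    }
    sv <- svd(mc, nu = 1, nv = 0)
    score <- sv$u[, 1] * sv$d[1]
    rm <- rowMeans(m)
    if (sum(score * (rm - mean(rm))) < 0) score <- -score
  }
  out <- tibble(sample_id = rownames(lrr) %||% as.character(seq_len(nrow(lrr))),
                score = as.numeric(score))
  attr(out, "n_probes") <- length(ix)
  attr(out, "method") <- method
  out
}

# number of free parameters of a (K, mean_model, var_model) cell
mixture_n_par <- function(K, mean_model, var_model) {
  p_mean <- if (mean_model == "free" || K == 1) K else 2
  p_var <- if (var_model == "free") K else 1
  (K - 1) + p_mean + p_var
}

# copy-number labels for components ordered by mean: modal component -> 2,
# neighbours consecutive, shifted to stay non-negative
anchor_copy_numbers <- function(weights) {
  modal <- which.max(weights)
  cn <- seq_along(weights) - modal + 2L
  if (min(cn) < 0L) cn <- cn - min(cn)
  cn
}

# quantile-split initialization (+ seed-jittered restarts)
init_mixture <- function(x, K, jitter_sd = 0) {
  qs <- quantile(x, probs = seq(0, 1, length.out = K + 1), type = 7)
  grp <- cut(x, breaks = unique(qs), include.lowest = TRUE, labels = FALSE)
  if (length(unique(qs)) - 1 < K) grp <- rep(seq_len(K), length.out = length(x))
  mu <- tapply(x, grp, mean)
  mu <- as.numeric(mu)[order(as.numeric(mu))]
  if (length(mu) < K) mu <- seq(min(x), max(x), length.out = K)
  s2 <- max(var(x) / K^2, 1e-6)
  if (jitter_sd > 0) mu <- sort(mu + rnorm(K, 0, jitter_sd * sqrt(s2)))
  list(mu = mu, s2 = rep(s2, K), pi = rep(1 / K, K))
}

# one EM run; y (0/1 status) and beta switch on the joint mixture+logit model
mixture_em <- function(x, K, mean_model, var_model, init, cn,
                       y = NULL, fit_beta = FALSE, alpha0 = 0, beta0 = 0,
                       max_iter = 500, tol = 1e-8) {
  n <- length(x)
  mu <- init$mu; s2 <- init$s2; pi_k <- init$pi
  alpha <- alpha0; beta <- beta0
  var_floor <- 1e-8
  w_var <- cn + 0.5 # proportional-variance weights (floor keeps CN0 positive)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E-step
    ld <- vapply(seq_len(K),
                 function(k) dnorm(x, mu[k], sqrt(s2[k]), log = TRUE) + log(pi_k[k]),
                 numeric(n))
    if (!is.null(y)) {
      p_k <- plogis(alpha + beta * cn)
      ld <- ld + vapply(seq_len(K),
                        function(k) ifelse(y == 1, log(p_k[k]), log1p(-p_k[k])),
                        numeric(n))
    }
    lse <- row_logsumexp(ld)
    ll <- sum(lse)
    r <- exp(ld - lse)
    nk <- colSums(r)
    if (any(nk < 1) || any(s2 < var_floor)) {
      return(list(collapsed = TRUE))
    }
    # M-step: weights
    pi_k <- nk / n
    # M-step: means
    if (mean_model == "free" || K == 1) {
      mu <- colSums(r * x) / nk
    } else {
      w <- sweep(r, 2, s2, "/")
      sw <- sum(w); swc <- sum(sweep(w, 2, cn, "*"))
      swcc <- sum(sweep(w, 2, cn^2, "*"))
      swx <- sum(w * x); swcx <- sum(sweep(w, 2, cn, "*") * x)
      det <- sw * swcc - swc^2
      if (abs(det) < 1e-12) return(list(collapsed = TRUE))
      a <- (swcc * swx - swc * swcx) / det
      b <- (sw * swcx - swc * swx) / det
      mu <- a + b * cn
    }
    # M-step: variances
    ss_k <- colSums(r * outer(x, mu, "-")^2)
    if (var_model == "free") {
      s2 <- ss_k / nk
    } else if (var_model == "constant") {
      s2 <- rep(sum(ss_k) / n, K)
    } else { # proportional
      s <- sum(ss_k / w_var) / n
      s2 <- s * w_var
    }
    if (any(s2 < var_floor)) return(list(collapsed = TRUE))
    # M-step: logistic part (weighted IRLS on the expanded data)
    if (fit_beta) {
      cr <- rep(cn, each = n)
      yr <- rep(y, K)
      wr <- as.numeric(r)
      th <- c(alpha, beta)
      for (it2 in 1:25) {
        eta <- th[1] + th[2] * cr
        p <- plogis(eta)
        wls <- wr * p * (1 - p)
        if (sum(wls) < 1e-12) break
        z <- eta + (yr - p) / pmax(p * (1 - p), 1e-12)
        X <- cbind(1, cr)
        XtW <- t(X * wls)
        th_new <- tryCatch(solve(XtW %*% X, XtW %*% z), error = function(e) NULL)
        if (is.null(th_new)) break
        th_new <- as.numeric(th_new)
        if (max(abs(th_new - th)) < 1e-10) { th <- th_new; break }
        th <- th_new
      }
      alpha <- th[1]; beta <- th[2]
    } else if (!is.null(y)) {
      # beta fixed; alpha is free only in the alternative fit. Under the
      # null (beta = 0) the Bernoulli factor is class-independent and
      # alpha = logit(mean(y)) is the exact MLE.
      alpha <- qlogis(mean(y))
    }
    ll_trace <- c(ll_trace, ll)
    if (iter > 1 && ll < ll_old - 1e-6) {
      # EM must not decrease the likelihood beyond numerical noise
      return(list(collapsed = TRUE))
    }
    if (iter > 1 && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  # final E-step quantities at the converged parameters
  ld <- vapply(seq_len(K),
               function(k) dnorm(x, mu[k], sqrt(s2[k]), log = TRUE) + log(pi_k[k]),
               numeric(n))
  if (!is.null(y)) {
    p_k <- plogis(alpha + beta * cn)
    ld <- ld + vapply(seq_len(K),
                      function(k) ifelse(y == 1, log(p_k[k]), log1p(-p_k[k])),
                      numeric(n))
  }
  lse <- row_logsumexp(ld)
  list(collapsed = FALSE, mu = mu, s2 = s2, pi = pi_k,
       alpha = alpha, beta = beta,
       loglik = sum(lse), posterior = exp(ld - lse),
       converged = converged, n_iter = length(ll_trace),
       ll_trace = ll_trace)
}

#' Fit a constrained Gaussian mixture to region summary scores
#'
#' Expectation-maximization under the chosen mean/variance constraints,
#' initialized from a K-quantile split of the scores plus seed-jittered
#' restarts; the best log-likelihood is retained. Components are relabelled
#' in increasing mean order and assigned integer copy numbers so that the
#' modal (highest-weight) component is copy number 2. Proportional means are
#' `a + b * c_k` for consecutive copy numbers `c_k`; proportional variances
#' are `s * (c_k + 1/2)` so copy number 0 retains positive variance.
#'
#' @param scores Numeric vector of per-sample summary scores (or a
#'   [summarize_region()] tibble).
#' @param K Number of copy-number components (1..5), with `n >= 5 K`.
#' @param mean_model `"free"` or `"proportional"`.
#' @param var_model `"free"`, `"proportional"` or `"constant"`.
#' @param seed Integer seed for the jittered restarts.
#' @param restarts Number of additional jittered starts (default 5).
#' @return An object of class `cnv_mixture`, or a fit-failed object (class
#'   `cnv_mixture_failed`) when every start collapses.
#' @export
fit_mixture <- function(scores, K, mean_model = c("free", "proportional"),
                        var_model = c("free", "proportional", "constant"),
                        seed = 1L, restarts = 5L) {
  mean_model <- match.arg(mean_model)
  var_model <- match.arg(var_model)
  x <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
  n <- length(x)
  if (K < 1 || K > 5) stop_usage("K must be in 1..5")
  if (n < 5 * K) stop_usage("need at least 5 observations per component")
  withr::local_seed(seed)

  best <- NULL
  for (rs in 0:restarts) {
    init <- init_mixture(x, K, jitter_sd = if (rs == 0) 0 else 0.25)
    # provisional copy numbers anchored at the initial occupancy (modal -> 2);
    # they enter the proportional mean/variance structure and stay fixed in EM
    occ <- tabulate(apply(outer(x, init$mu, function(a, b) abs(a - b)), 1,
                          which.min), nbins = K)
    cn <- anchor_copy_numbers(occ)
    fit <- mixture_em(x, K, mean_model, var_model, init, cn)
    if (!fit$collapsed && (is.null(best) || fit$loglik > best$loglik)) {
      best <- fit
      best$cn <- cn
    }
  }
  if (is.null(best)) {
    return(structure(list(K = K, mean_model = mean_model, var_model = var_model,
                          converged = FALSE, reason = "all restarts collapsed"),
                     class = c("cnv_mixture_failed", "cnv_mixture")))
  }
  # relabel components in increasing mean order
  ord <- order(best$mu)
  mu <- best$mu[ord]; s2 <- best$s2[ord]; pi_k <- best$pi[ord]
  post <- best$posterior[, ord, drop = FALSE]
  copy_numbers <- anchor_copy_numbers(pi_k)
  n_par <- mixture_n_par(K, mean_model, var_model)
  structure(list(
    K = K, mean_model = mean_model, var_model = var_model,
    means = mu, variances = s2, weights = pi_k,
    posterior = post, loglik = best$loglik,
    bic = -2 * best$loglik + n_par * log(n),
    n_par = n_par, n = n, converged = best$converged,
    copy_numbers = copy_numbers, scores = x,
    sample_id = if (is.data.frame(scores)) scores$sample_id else NULL
  ), class = "cnv_mixture")
}

#' @export
print.cnv_mixture <- function(x, ...) {
  if (inherits(x, "cnv_mixture_failed")) {
    cat("<cnv_mixture> FAILED:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("<cnv_mixture> K=%d mean=%s var=%s  loglik=%.2f BIC=%.2f%s\n",
              x$K, x$mean_model, x$var_model, x$loglik, x$bic,
              if (x$converged) "" else " (not converged)"))
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_mixture
#' @param x A `cnv_mixture` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cnv_mixture <- function(x, ...) {
  if (inherits(x, "cnv_mixture_failed")) {
    return(tibble(component = integer(), copy_number = integer(),
                  mean = numeric(), variance = numeric(), weight = numeric()))
  }
  tibble(component = seq_len(x$K), copy_number = x$copy_numbers,
         mean = x$means, variance = x$variances, weight = x$weights)
}

#' @rdname fit_mixture
#' @exportS3Method generics::glance
glance.cnv_mixture <- function(x, ...) {
  if (inherits(x, "cnv_mixture_failed")) {
    return(tibble(K = x$K, mean_model = x$mean_model, var_model = x$var_model,
                  loglik = NA_real_, bic = NA_real_, n_par = NA_integer_,
                  n = NA_integer_, converged = FALSE))
  }
  tibble(K = x$K, mean_model = x$mean_model, var_model = x$var_model,
         loglik = x$loglik, bic = x$bic, n_par = x$n_par, n = x$n,
         converged = x$converged)
}

#' Posterior-modal copy-number genotypes
#'
#' @param fit A converged [fit_mixture()] object.
#' @return Integer vector of per-sample copy numbers.
#' @export
assign_genotypes <- function(fit) {
  if (inherits(fit, "cnv_mixture_failed")) stop_usage("fit failed; no genotypes")
  fit$copy_numbers[max.col(fit$posterior, ties.method = "first")]
}

#' Select the mixture model for a locus over a (K, model) grid
#'
#' Fits every combination of component count and mean/variance model,
#' discards collapsed or non-converged fits, and returns the fit with the
#' lowest BIC. Exact BIC ties are broken toward smaller K, then simpler
#' models (constant before proportional before free variances; proportional
#' before free means). Loci observed in fewer than two samples are excluded
#' up front as too problematic for in silico genotyping (rare/singleton
#' events), as are loci where every cell fails.
#'
#' @param scores Numeric scores or a [summarize_region()] tibble.
#' @param k_grid Integer vector of component counts to try.
#' @param model_grid Data frame with columns `mean_model`, `var_model`, or
#'   `NULL` for the full 2x3 grid.
#' @param seed Seed forwarded to [fit_mixture()].
#' @param n_events Optional number of samples in which the locus was
#'   observed; loci with fewer than 2 are excluded as rare/singleton.
#' @return The best `cnv_mixture`, or a `cnv_mixture_excluded` object with
#'   a `reason` field.
#' @export
select_model <- function(scores, k_grid = 1:5, model_grid = NULL, seed = 1L,
                         n_events = NULL) {
  if (length(k_grid) == 0) stop_usage("empty K grid")
  if (!is.null(n_events) && n_events < 2) {
    return(structure(list(reason = "rare or singleton event", converged = FALSE),
                     class = c("cnv_mixture_excluded", "cnv_mixture_failed",
                               "cnv_mixture")))
  }
  if (is.null(model_grid)) {
    model_grid <- expand.grid(mean_model = c("proportional", "free"),
                              var_model = c("constant", "proportional", "free"),
                              stringsAsFactors = FALSE)
  }
  x <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
  # tie-break order: smaller K first, then simpler variance then mean models
  var_rank <- c(constant = 1, proportional = 2, free = 3)
  mean_rank <- c(proportional = 1, free = 2)
  cells <- expand.grid(K = sort(k_grid), row = seq_len(nrow(model_grid)))
  cells$var_rank <- var_rank[model_grid$var_model[cells$row]]
  cells$mean_rank <- mean_rank[model_grid$mean_model[cells$row]]
  cells <- cells[order(cells$K, cells$var_rank, cells$mean_rank), ]

  best <- NULL
  for (i in seq_len(nrow(cells))) {
    K <- cells$K[i]
    if (length(x) < 5 * K) next
    mm <- model_grid$mean_model[cells$row[i]]
    vm <- model_grid$var_model[cells$row[i]]
    fit <- fit_mixture(scores, K, mm, vm, seed = seed)
    if (inherits(fit, "cnv_mixture_failed") || !fit$converged) next
    if (is.null(best) || fit$bic < best$bic) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(reason = "too problematic for in silico CNVR genotyping",
                          converged = FALSE),
                     class = c("cnv_mixture_excluded", "cnv_mixture_failed",
                               "cnv_mixture")))
  }
  best
}

#' Joint mixture + logistic likelihood-ratio association test
#'
#' Jointly fits (by EM) a Gaussian mixture for the summary signal and a
#' logistic model tying case/control status to the latent copy number:
#' `L = prod_i sum_k pi_k N(x_i; mu_k, s2_k) Bern(y_i; logistic(alpha +
#' beta c_k))`. The null fit constrains `beta = 0`; the statistic is
#' `2 (loglik_alt - loglik_null)` floored at 0 and referred to chi-square
#' with 1 df.
#'
#' @param scores Numeric scores or a [summarize_region()] tibble.
#' @param status Per-sample `"case"`/`"control"` (or 0/1) vector aligned to
#'   the scores.
#' @param K,mean_model,var_model Mixture specification (e.g. from
#'   [select_model()]).
#' @param seed Seed for restarts.
#' @return A one-row tibble: `lrt_stat`, `lrt_p`, `beta`, `K`, `mean_model`,
#'   `var_model`, `excluded`, `reason`.
#' @export
lrt_association <- function(scores, status, K, mean_model = "free",
                            var_model = "constant", seed = 1L) {
  x <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
  y <- if (is.character(status) || is.factor(status)) {
    as.integer(as.character(status) == "case")
  } else as.integer(status)
  if (length(unique(y)) < 2) stop_usage("both outcome classes must be present")
  excluded_row <- function(reason) {
    tibble(lrt_stat = NA_real_, lrt_p = NA_real_, beta = NA_real_,
           K = K, mean_model = mean_model, var_model = var_model,
           excluded = TRUE, reason = reason)
  }
  # null fit: plain mixture; the Bernoulli factor separates with
  # alpha = logit(mean(y))
  null_fit <- fit_mixture(x, K, mean_model, var_model, seed = seed)
  if (inherits(null_fit, "cnv_mixture_failed")) {
    return(excluded_row("null fit failed"))
  }
  ll_null <- null_fit$loglik +
    sum(y) * log(mean(y)) + sum(1 - y) * log(1 - mean(y))

  # alternative fit: EM over the joint model, initialized at the null optimum
  cn <- null_fit$copy_numbers
  init <- list(mu = null_fit$means, s2 = null_fit$variances,
               pi = null_fit$weights)
  withr::local_seed(seed)
  alt <- mixture_em(x, K, mean_model, var_model, init, cn,
                    y = y, fit_beta = TRUE,
                    alpha0 = qlogis(mean(y)), beta0 = 0)
  if (isTRUE(alt$collapsed)) {
    return(excluded_row("alternative fit collapsed"))
  }
  lrt <- max(0, 2 * (alt$loglik - ll_null))
  tibble(lrt_stat = lrt, lrt_p = pchisq(lrt, df = 1, lower.tail = FALSE),
         beta = alt$beta, K = K, mean_model = mean_model,
         var_model = var_model, excluded = FALSE, reason = NA_character_)
}

#' Per-copy odds ratio by multivariate logistic regression
#'
#' Assigns each sample its posterior-modal copy number and fits a logistic
#' regression of status on copy number plus covariates; reports the
#' per-copy odds ratio with its 95% Wald interval and 1-df Wald p-value.
#'
#' @param fit A converged [fit_mixture()] object.
#' @param status Per-sample case/control vector aligned to the fit's scores.
#' @param covariates Optional data frame of covariates (age, gender,
#'   ancestry PCs, ...), same row order.
#' @return A one-row tibble: `per_copy_or`, `or_lo`, `or_hi`, `wald_p`,
#'   `excluded`, `reason`.
#' @export
percopy_logistic <- function(fit, status, covariates = NULL) {
  y <- if (is.character(status) || is.factor(status)) {
    as.integer(as.character(status) == "case")
  } else as.integer(status)
  excluded_row <- function(reason) {
    tibble(per_copy_or = NA_real_, or_lo = NA_real_, or_hi = NA_real_,
           wald_p = NA_real_, excluded = TRUE, reason = reason)
  }
  if (inherits(fit, "cnv_mixture_failed")) return(excluded_row("fit failed"))
  cn <- assign_genotypes(fit)
  if (length(unique(cn)) < 2) return(excluded_row("single observed copy-number class"))
  design <- data.frame(copy_number = cn)
  if (!is.null(covariates)) {
    covariates <- droplevels(as.data.frame(covariates))
    keep <- vapply(covariates, function(v) length(unique(v)) > 1, logical(1))
    design <- cbind(design, covariates[keep])
  }
  gfit <- tryCatch(fit_logistic(y, design), error = function(e) NULL)
  if (is.null(gfit)) return(excluded_row("logistic fit did not converge"))
  sm <- summary(gfit)$coefficients
  if (!"copy_number" %in% rownames(sm)) return(excluded_row("rank-deficient design"))
  b <- sm["copy_number", 1]; se <- sm["copy_number", 2]
  tibble(per_copy_or = exp(b), or_lo = exp(b - 1.96 * se),
         or_hi = exp(b + 1.96 * se), wald_p = sm["copy_number", 4],
         excluded = FALSE, reason = NA_character_)
}

#' Bonferroni annotation of locus-level association results
#'
#' @param results Tibble with an `lrt_p` column (one row per tested locus).
#' @param alpha Family-wise level (default 0.05).
#' @return `results` with added columns `bonferroni_threshold`,
#'   `significant_bonferroni`, `significant_nominal`; excluded loci (NA p)
#'   are not counted as tested.
#' @export
multiple_testing <- function(results, alpha = 0.05) {
  if (nrow(results) == 0) return(results)
  tested <- sum(!is.na(results$lrt_p))
  thr <- alpha / max(tested, 1)
  results |>
    mutate(bonferroni_threshold = thr,
           significant_bonferroni = !is.na(.data$lrt_p) & .data$lrt_p < thr,
           significant_nominal = !is.na(.data$lrt_p) & .data$lrt_p < alpha)
}

#' Locus-by-locus CNVR genotyping and risk association over a cohort
#'
#' For each CNVR: restricts to the requested platform subset, summarizes the
#' in-region probe intensities, selects the mixture model by BIC, runs the
#' joint mixture+logit likelihood-ratio test, and follows up with the
#' per-copy multivariate logistic model. Loci that cannot be genotyped
#' (rare/singleton, collapsed fits, degenerate summaries) are returned as
#' excluded rows with a reason.
#'
#' @param cohort A `cnv_cohort`.
#' @param cnvrs CNVR tibble from [cluster_cnvrs()].
#' @param platform_filter Restrict to samples on this platform (`NULL` for
#'   all).
#' @param summary_method `"mean"` or `"pc1"`.
#' @param k_grid Component counts to try.
#' @param covariates Covariate column names from the sample sheet for the
#'   per-copy logistic follow-up.
#' @param alpha Family-wise level for [multiple_testing()].
#' @param seed Integer seed.
#' @return A tibble with one row per CNVR: locus info, selected model, LRT
#'   statistic and p, per-copy OR with CI, and multiple-testing flags.
#' @export
cnvr_association <- function(cohort, cnvrs, platform_filter = "duo",
                             summary_method = c("mean", "pc1"),
                             k_grid = 1:4, covariates = character(0),
                             alpha = 0.05, seed = 1L) {
  summary_method <- match.arg(summary_method)
  samples <- cohort$samples
  keep <- if (is.null(platform_filter)) rep(TRUE, nrow(samples)) else
    samples$platform == platform_filter
  samples <- samples[keep, ]
  lrr <- cohort$lrr[keep, , drop = FALSE]

  rows <- lapply(seq_len(nrow(cnvrs)), function(i) {
    region <- cnvrs[i, ]
    base <- tibble(cnvr_id = region$cnvr_id,
                   locus = format_region(region),
                   type_class = region$type_class)
    sc <- tryCatch(summarize_region(lrr, cohort$probes, region, summary_method),
                   error = function(e) NULL)
    if (is.null(sc)) {
      return(bind_cols(base, tibble(lrt_stat = NA_real_, lrt_p = NA_real_,
                                    excluded = TRUE, reason = "degenerate summary")))
    }
    fit <- select_model(sc, k_grid = k_grid, seed = seed,
                        n_events = region$n_members)
    if (inherits(fit, "cnv_mixture_failed")) {
      return(bind_cols(base, tibble(lrt_stat = NA_real_, lrt_p = NA_real_,
                                    excluded = TRUE, reason = fit$reason)))
    }
    lrt <- lrt_association(sc, samples$status, fit$K, fit$mean_model,
                           fit$var_model, seed = seed)
    covs <- if (length(covariates) > 0) samples[covariates] else NULL
    orr <- percopy_logistic(fit, samples$status, covs)
    bind_cols(base,
              lrt[c("lrt_stat", "lrt_p", "beta", "K", "mean_model", "var_model")],
              orr[c("per_copy_or", "or_lo", "or_hi", "wald_p")],
              tibble(excluded = lrt$excluded, reason = lrt$reason))
  })
  multiple_testing(bind_rows(rows), alpha = alpha)
}

#' Published locus-level likelihood-ratio results (176 CNVR loci)
#'
#' Per-locus likelihood-ratio statistics and p-values for the 176
#' successfully genotyped CNVR loci of a published pancreatic cancer
#' case-control scan, shipped as a plain-text fixture; used to exercise
#' multiple-testing bookkeeping on a real result table.
#'
#' @return A tibble with `cnvr`, `locus`, `type`, `likelihood_ratio`,
#'   `p_value`.
#' @export
published_cnvr_lrt <- function() {
  path <- system.file("extdata", "published_cnvr_lrt.tsv", package = "cnvrisk",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}
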