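# ggplot2 displays for signals, mixture fits and burden tables.

#' Plot LRR/BAF signal tracks for one sample
#'
#' Two stacked panels (LRR and BAF against genomic position) for one
#' chromosome of one sample, with call spans shaded.
#'
#' @param cohort A `cnv_cohort`.
#' @param sample_id Sample to plot.
#' @param chrom Chromosome to plot.
#' @param calls Optional call tibble; this sample's calls on `chrom` are
#'   shaded (deletions blue, duplications red).
#' @return A ggplot object.
#' @export
plot_lrr_baf <- function(cohort, sample_id, chrom, calls = NULL) {
  i <- match(sample_id, cohort$samples$sample_id)
  if (is.na(i)) stop_usage("unknown sample_id")
  sel <- cohort$probes$chrom == chrom
  dat <- tibble(pos = cohort$probes$pos[sel],
                LRR = cohort$lrr[i, sel], BAF = cohort$baf[i, sel]) |>
    pivot_longer(c("LRR", "BAF"), names_to = "track", values_to = "value") |>
    mutate(track = factor(.data$track, levels = c("LRR", "BAF")))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::facet_wrap(~track, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = paste0(chrom, " position (bp)"), y = NULL,
                  title = sample_id) +
    ggplot2::theme_minimal()
  if (!is.null(calls)) {
    cc <- calls[calls$sample_id == sample_id & calls$chrom == chrom, ]
    if (nrow(cc) > 0) {
      p <- p + ggplot2::geom_rect(
        data = tibble(start = cc$start, end = cc$end, type = cc$type),
        ggplot2::aes(xmin = .data$start, xmax = .data$end,
                     ymin = -Inf, ymax = Inf, fill = .data$type),
        alpha = 0.2, inherit.aes = FALSE) +
        ggplot2::scale_fill_manual(values = c(deletion = "blue",
                                              duplication = "red"))
    }
  }
  p
}

#' Diagnostic plot for a fitted copy-number mixture
#'
#' Histogram of the summary scores overlaid with the weighted component
#' densities, labelled by assigned copy number -- the per-locus clustering
#' diagnostic a reviewer inspects before trusting an in silico genotype.
#'
#' @param object A `cnv_mixture`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cnv_mixture <- function(object, bins = 40, ...) {
  if (inherits(object, "cnv_mixture_failed")) stop_usage("cannot plot a failed fit")
  x <- object$scores
  grid <- seq(min(x), max(x), length.out = 400)
  dens <- purrr::map(seq_len(object$K), function(k) {
    tibble(score = grid,
           density = object$weights[k] *
             dnorm(grid, object$means[k], sqrt(object$variances[k])),
           copy_number = factor(object$copy_numbers[k]))
  }) |> bind_rows()
  ggplot2::ggplot(tibble(score = x), ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey50") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density,
                                    colour = .data$copy_number),
                       linewidth = 0.8) +
    ggplot2::labs(x = "summary score", y = "density", colour = "copy number") +
    ggplot2::theme_minimal()
}

#' Burden distribution by case/control status
#'
#' @param burden A [burden_counts()] table.
#' @param what Which count column to display.
#' @return A ggplot object.
#' @export
plot_burden <- function(burden, what = "n_all") {
  ggplot2::ggplot(burden, ggplot2::aes(x = .data$status, y = .data[[what]],
                                       fill = .data$status)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = paste0("CNV burden (", what, ")")) +
    ggplot2::theme_minimal()
}
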