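# ggplot2 views of a pipeline run: the discovery funnel and per-sample
# homozygosity tracks with the HBD regions highlighted.

#' Plot the variant discovery funnel
#'
#' Bar chart of surviving variant-site counts after each funnel stage.
#'
#' @param object An `hbd_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hbd_run <- function(object, ...) {
  f <- object$funnel |>
    mutate(stage = factor(.data$stage, levels = .data$stage))
  start <- tibble(stage = factor("input"), n_out = f$n_in[1])
  dat <- bind_rows(start, f |> select(all_of(c("stage", "n_out")))) |>
    mutate(stage = factor(.data$stage,
                          levels = c("input", levels(f$stage))))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$stage, y = .data$n_out)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), vjust = -0.3,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "variant sites",
                  title = "Variant discovery funnel") +
    ggplot2::theme_minimal()
}

#' Plot per-sample homozygosity tracks for one chromosome
#'
#' One horizontal track per genotyped individual showing marker zygosity
#' calls, the detected homozygous stretches, and (shaded) the case-shared,
#' control-excluded HBD regions — the same view used to display a mapped
#' recessive locus.
#'
#' @param run An `hbd_run`.
#' @param chrom Chromosome to display.
#' @return A ggplot object.
#' @export
plot_homozygosity <- function(run, chrom) {
  mk <- run$markers |> filter(.data$chrom == .env$chrom)
  st <- run$stretches |> filter(.data$chrom == .env$chrom)
  hbd <- run$hbd_regions |> filter(.data$chrom == .env$chrom)
  samples <- sort(unique(mk$sample_id))
  mk$y <- match(mk$sample_id, samples)
  st$y <- match(st$sample_id, samples)
  p <- ggplot2::ggplot()
  if (nrow(hbd)) {
    p <- p + ggplot2::geom_rect(
      data = hbd,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = 0.5, ymax = length(samples) + 0.5,
      fill = "firebrick", alpha = 0.15)
  }
  p +
    ggplot2::geom_point(
      data = mk,
      ggplot2::aes(x = .data$pos / 1e6, y = .data$y,
                   colour = .data$zygosity),
      size = 0.3, alpha = 0.6) +
    ggplot2::geom_segment(
      data = st,
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$y - 0.3, yend = .data$y - 0.3),
      linewidth = 1.2, colour = "purple") +
    ggplot2::scale_y_continuous(breaks = seq_along(samples),
                                labels = samples) +
    ggplot2::labs(x = sprintf("%s position (Mb)", chrom), y = NULL,
                  colour = "zygosity",
                  title = "Homozygosity tracks and HBD regions") +
    ggplot2::theme_minimal()
}
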