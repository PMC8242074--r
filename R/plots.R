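#' Plot a normalized copy-number profile with its segments
#'
#' Bin-level copy number along the genome, faceted nowhere but coloured by
#' chromosome parity, with segment means overlaid as horizontal bars.
#'
#' @param profile `cna_profile` tibble (one sample, or pass `sample` to
#'   pick one).
#' @param segments optional `cna_segments` tibble.
#' @param sample sample id to plot (default: first).
#' @return a ggplot object.
#' @export
plot_profile <- function(profile, segments = NULL, sample = NULL) {
  sample <- sample %||% profile$sample_id[1]
  d <- profile[profile$sample_id == sample & profile$mask, , drop = FALSE]
  d$parity <- factor(chrom_rank(d$chrom) %% 2)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$x)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$parity),
                        size = 0.3, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("grey55", "grey30")) +
    ggplot2::geom_hline(yintercept = 2, linetype = 2, colour = "steelblue") +
    ggplot2::labs(x = "genome bin", y = "copy number", title = sample) +
    ggplot2::theme_minimal()
  if (!is.null(segments)) {
    s <- segments[segments$sample_id == sample, , drop = FALSE]
    p <- p + ggplot2::geom_segment(
      data = s, colour = "firebrick", linewidth = 1,
      ggplot2::aes(x = .data$start_bin, xend = .data$end_bin,
                   y = .data$seg_mean, yend = .data$seg_mean))
  }
  p
}

#' Plot cohort recurrence tracks
#'
#' Gain fraction drawn upward, loss fraction downward, per genome bin.
#'
#' @param recurrence tibble from [recurrence_profile()].
#' @return a ggplot object.
#' @export
plot_recurrence <- function(recurrence) {
  ggplot2::ggplot(recurrence, ggplot2::aes(x = .data$bin)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$gain_frac), fill = "firebrick",
                      width = 1) +
    ggplot2::geom_col(ggplot2::aes(y = -.data$loss_frac), fill = "steelblue",
                      width = 1) +
    ggplot2::labs(x = "genome bin", y = "fraction of samples (gain up, loss down)") +
    ggplot2::theme_minimal()
}

#' Plot CNAscore distributions by group
#'
#' @param scores tibble `sample_id`, `cna_score`.
#' @param groups named vector or sample sheet.
#' @return a ggplot object.
#' @export
plot_score_distributions <- function(scores, groups) {
  if (is.data.frame(groups)) groups <- setNames(groups$group, groups$sample_id)
  d <- dplyr::mutate(scores, group = unname(groups[.data$sample_id]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cna_score, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(x = "CNAscore", y = "normalized frequency") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cna_segments <- function(object, profile = NULL, ...) {
  if (!is.null(profile)) return(plot_profile(profile, object, ...))
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$start_bin, xend = .data$end_bin,
                                  y = .data$seg_mean, yend = .data$seg_mean)) +
    ggplot2::geom_segment(colour = "firebrick", linewidth = 1) +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::geom_hline(yintercept = 2, linetype = 2, colour = "steelblue") +
    ggplot2::labs(x = "genome bin", y = "segment copy number") +
    ggplot2::theme_minimal()
}
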