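#' Tidy and summarise segmentation results
#'
#' `tidy()` returns the segment table as a plain tibble with genomic
#' coordinates when `bins` is supplied; `glance()` returns one row per
#' sample (segment count, chromosomes touched, mean segment length).
#'
#' @param x a `cna_segments` object from [cbs_segment()].
#' @param bins optional [genome_bins] tibble to add `start`/`end`
#'   coordinates.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.cna_segments <- function(x, bins = NULL, ...) {
  out <- tibble::as_tibble(x)
  if (!is.null(bins)) {
    bins <- genome_bins(bins)
    out$start <- bins$start[out$start_bin]
    out$end <- bins$end[out$end_bin]
  }
  out
}

#' @rdname tidy.cna_segments
#' @export
glance.cna_segments <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_segments = dplyr::n(),
                     n_chroms = length(unique(.data$chrom)),
                     mean_seg_bins = mean(.data$n_bins), .groups = "drop")
}

#' Tidy and summarise CNAscore results
#'
#' `tidy()` returns the per-chromosome jump/deviation terms; `glance()`
#' returns one row per sample with the total CNAscore.
#'
#' @param x a `cna_score` object from [cna_score()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.cna_score <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.cna_score
#' @export
glance.cna_score <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(cna_score = sum(.data$term), .groups = "drop")
}
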