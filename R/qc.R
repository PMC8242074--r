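#' Median absolute pairwise difference (MAPD)
#'
#' `MAPD = median(|x[i+1] - x[i]|)` over bins ordered by genomic position,
#' computed on usable (masked-in) bins. It measures amplification /
#' counting noise while staying robust to true copy-number steps, which
#' contribute only a handful of large pairwise differences. By default,
#' successive pairs that span a chromosome boundary are excluded (they
#' inject step-like jumps into a noise statistic); `genome_wide = TRUE`
#' keeps them, matching the literal genome-ordered definition.
#'
#' @param profile a `cna_profile` tibble (one or many samples), or a bare
#'   numeric vector of copy-number values (then treated as one chromosome).
#' @param genome_wide include cross-chromosome successive pairs.
#' @param log2_scale compute MAPD on log2(x/2) instead of linear copy
#'   number (for comparability with platforms that define the cutoff on
#'   log scale).
#' @return a tibble `sample_id`, `mapd` (or a bare number for vector
#'   input).
#' @examples
#' compute_mapd(c(2.0, 2.2, 1.9, 2.1)) # 0.2
#' @export
compute_mapd <- function(profile, genome_wide = FALSE, log2_scale = FALSE) {
  if (is.numeric(profile) && is.null(dim(profile))) {
    return(mapd_one(profile, rep("1", length(profile)), genome_wide, log2_scale))
  }
  stopifnot(all(c("sample_id", "bin", "chrom", "x") %in% names(profile)))
  mask <- if ("mask" %in% names(profile)) profile$mask else TRUE
  profile[mask, , drop = FALSE] |>
    dplyr::arrange(.data$sample_id, .data$bin) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(mapd = mapd_one(.data$x, .data$chrom, genome_wide, log2_scale),
                     .groups = "drop")
}

mapd_one <- function(x, chrom, genome_wide, log2_scale) {
  if (length(x) < 2) abort("MAPD needs at least 2 usable bins")
  if (log2_scale) x <- log2(pmax(x, .Machine$double.eps) / 2)
  d <- abs(diff(x))
  if (!genome_wide) d <- d[chrom[-1] == chrom[-length(chrom)]]
  if (!length(d)) abort("no within-chromosome successive pairs available")
  median(d)
}

#' Apply the sample-inclusion rule
#'
#' A sample is qualified when it has more than `read_floor` mapped reads
#' AND MAPD strictly below `mapd_ceiling` (both boundaries exclusive;
#' defaults 100 000 reads and 0.23). Failing criteria are listed in
#' `reasons`.
#'
#' @param metrics tibble with columns `sample_id`, `mapped_reads`, `mapd`.
#' @param read_floor minimum mapped reads (exclusive).
#' @param mapd_ceiling maximum MAPD (exclusive).
#' @return the tibble with added `passed` (logical) and `reasons`
#'   (comma-separated string, empty when passed).
#' @examples
#' qc_filter(tibble::tibble(sample_id = "s1",
#'                          mapped_reads = 150000, mapd = 0.20))
#' @export
qc_filter <- function(metrics, read_floor = 1e5, mapd_ceiling = 0.23) {
  stopifnot(all(c("sample_id", "mapped_reads", "mapd") %in% names(metrics)))
  if (any(!is.finite(metrics$mapped_reads)) || any(!is.finite(metrics$mapd)) ||
      any(metrics$mapped_reads < 0) || any(metrics$mapd < 0)) {
    abort("mapped_reads and mapd must be finite and nonnegative")
  }
  reads_ok <- metrics$mapped_reads > read_floor
  mapd_ok <- metrics$mapd < mapd_ceiling
  reasons <- character(nrow(metrics))
  reasons[!reads_ok] <- "mapped_reads"
  reasons[!mapd_ok] <- ifelse(reasons[!mapd_ok] == "", "mapd",
                              paste(reasons[!mapd_ok], "mapd", sep = ","))
  dplyr::mutate(tibble::as_tibble(metrics),
                passed = reads_ok & mapd_ok, reasons = reasons)
}

#' Compute QC metrics for normalized profiles
#'
#' Convenience wrapper: computes MAPD per sample from the profile, joins
#' the mapped-read totals, and applies [qc_filter()].
#'
#' @param profile `cna_profile` tibble.
#' @param mapped_reads named vector or tibble (`sample_id`,
#'   `mapped_reads`); if `NULL`, totals are taken as the per-sample sum of
#'   the `count` column.
#' @inheritParams qc_filter
#' @inheritParams compute_mapd
#' @return QC tibble: `sample_id`, `mapped_reads`, `mapd`, `passed`,
#'   `reasons`.
#' @export
qc_metrics <- function(profile, mapped_reads = NULL, read_floor = 1e5,
                       mapd_ceiling = 0.23, genome_wide = FALSE) {
  m <- compute_mapd(profile, genome_wide = genome_wide)
  if (is.null(mapped_reads)) {
    tot <- profile |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(mapped_reads = sum(.data$count), .groups = "drop")
  } else if (is.data.frame(mapped_reads)) {
    tot <- mapped_reads
  } else {
    tot <- tibble::tibble(sample_id = names(mapped_reads),
                          mapped_reads = as.numeric(mapped_reads))
  }
  qc_filter(dplyr::left_join(m, tot, by = "sample_id"),
            read_floor = read_floor, mapd_ceiling = mapd_ceiling)
}
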