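#' Per-sample CNAscore
#'
#' The CNAscore summarises genome complexity as a sum over the 24
#' chromosomes of two components computed from the segment means `s_i`
#' (in genomic order within the chromosome):
#'
#' * a jump component `mean(|s_i - s_{i-1}|)` over successive segment
#'   pairs (0 when the chromosome has fewer than 2 segments), measuring
#'   chromosomal instability; and
#' * a deviation component `0.5 * |mean(s_i) - norm|`, measuring departure
#'   from the chromosome's sex-specific neutral ploidy (autosomes 2, male
#'   X/Y 1, female Y 0).
#'
#' `mean(s_i)` is the unweighted mean over segments by default (the
#' literal formula); `weighted = TRUE` weights each segment by its bin
#' count, which stops a short focal event from dominating a whole
#' chromosome. Chromosomes with no segments contribute 0.
#'
#' @param segments `cna_segments` tibble from [cbs_segment()].
#' @param samples sample sheet tibble (for `sex`), or a single sex string
#'   applied to all samples.
#' @param weighted length-weight the deviation component's mean.
#' @return tibble of class `cna_score`: `sample_id`, `chrom`, `jump`,
#'   `deviation`, `term` (their sum); use [glance()] or
#'   [cna_score_total()] for per-sample totals.
#' @examples
#' segs <- tibble::tibble(sample_id = "s", chrom = "1",
#'                        start_bin = c(1, 51), end_bin = c(50, 100),
#'                        n_bins = 50L, seg_mean = c(2, 3))
#' cna_score_total(segs, "female")$cna_score  # 1 + 0.5*|2.5-2| = 1.25
#' @export
cna_score <- function(segments, samples, weighted = FALSE) {
  sex <- sex_lookup(samples, unique(segments$sample_id))
  if (nrow(segments) == 0) abort("empty profile: no segments at all")
  per <- segments |>
    dplyr::group_by(.data$sample_id, .data$chrom) |>
    dplyr::arrange(.data$start_bin, .by_group = TRUE) |>
    dplyr::summarise(
      jump = if (dplyr::n() < 2) 0 else mean(abs(diff(.data$seg_mean))),
      mean_s = if (weighted) sum(.data$seg_mean * .data$n_bins) / sum(.data$n_bins)
               else mean(.data$seg_mean),
      .groups = "drop")
  per$norm <- expected_ploidy(sex[per$sample_id], per$chrom, quiet = TRUE)
  per <- per |>
    dplyr::mutate(deviation = ifelse(is.na(.data$norm), 0,
                                     0.5 * abs(.data$mean_s - .data$norm)),
                  term = .data$jump + .data$deviation) |>
    dplyr::select("sample_id", "chrom", "jump", "deviation", "term")
  structure(per, class = c("cna_score", class(tibble::tibble())))
}

#' @rdname cna_score
#' @return `cna_score_total`: tibble `sample_id`, `cna_score`.
#' @export
cna_score_total <- function(segments, samples, weighted = FALSE) {
  cna_score(segments, samples, weighted = weighted) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(cna_score = sum(.data$term), .groups = "drop")
}

sex_lookup <- function(samples, sample_ids) {
  if (is.character(samples) && length(samples) == 1 &&
      samples %in% c("male", "female", "unknown")) {
    return(setNames(rep(samples, length(sample_ids)), sample_ids))
  }
  stopifnot(is.data.frame(samples), all(c("sample_id", "sex") %in% names(samples)))
  miss <- setdiff(sample_ids, samples$sample_id)
  if (length(miss)) abort(paste0("samples missing from sheet: ",
                                 paste(miss, collapse = ", ")))
  setNames(samples$sex, samples$sample_id)[sample_ids]
}

#' Gain/loss calling configuration
#'
#' Thresholds on segment copy number: for diploid chromosomes a gain is
#' CN > 2.4 and a loss CN < 1.7; for haploid chromosomes (male X/Y) a gain
#' is CN > 1.5 and a loss CN < 0.5. Chromosomes with neutral copy number 0
#' (female Y) are never called. Segments spanning fewer than
#' `min_call_bins` usable bins are not called.
#'
#' @param diploid_gain,diploid_loss,haploid_gain,haploid_loss thresholds.
#' @param min_call_bins minimum segment size (bins) for a call.
#' @return list of class `calling_config`.
#' @export
calling_config <- function(diploid_gain = 2.4, diploid_loss = 1.7,
                           haploid_gain = 1.5, haploid_loss = 0.5,
                           min_call_bins = 5L) {
  stopifnot(diploid_gain > diploid_loss, haploid_gain > haploid_loss)
  structure(list(diploid_gain = diploid_gain, diploid_loss = diploid_loss,
                 haploid_gain = haploid_gain, haploid_loss = haploid_loss,
                 min_call_bins = as.integer(min_call_bins)),
            class = "calling_config")
}

#' Call copy-number gains and losses from segments
#'
#' Applies the strict-inequality thresholds of [calling_config()] per
#' segment, with the ploidy class of each chromosome taken from
#' [expected_ploidy()]. Neutral segments produce no row.
#'
#' @param segments `cna_segments` tibble.
#' @param samples sample sheet (or single sex string).
#' @param config a [calling_config()].
#' @return tibble `sample_id`, `chrom`, `start_bin`, `end_bin`, `n_bins`,
#'   `seg_mean`, `state` ("gain"/"loss"), `ploidy_class`.
#' @export
call_segments <- function(segments, samples, config = calling_config()) {
  sex <- sex_lookup(samples, unique(segments$sample_id))
  norm <- expected_ploidy(sex[segments$sample_id], segments$chrom, quiet = TRUE)
  s <- segments$seg_mean
  state <- rep(NA_character_, nrow(segments))
  dip <- !is.na(norm) & norm == 2
  hap <- !is.na(norm) & norm == 1
  state[dip & s > config$diploid_gain] <- "gain"
  state[dip & s < config$diploid_loss] <- "loss"
  state[hap & s > config$haploid_gain] <- "gain"
  state[hap & s < config$haploid_loss] <- "loss"
  state[segments$n_bins < config$min_call_bins] <- NA_character_
  keep <- !is.na(state)
  out <- tibble::as_tibble(segments)[keep, c("sample_id", "chrom", "start_bin",
                                             "end_bin", "n_bins", "seg_mean")]
  out$state <- state[keep]
  out$ploidy_class <- ifelse(hap[keep], "haploid", "diploid")
  out
}

#' Per-sample and per-patient CNA status
#'
#' A sample is CNA-positive when it has at least one gain/loss call. A
#' patient is CNA-positive when at least `min_positive_samples` of their
#' QC-passed lesional (non-normal-tissue) samples are positive;
#' normal-tissue samples never count. Patients with zero QC-passed
#' lesional samples are indeterminate (`NA`).
#'
#' @param calls call tibble from [call_segments()].
#' @param sample_ids the QC-passed samples under consideration (samples
#'   with zero calls must still appear in the result).
#' @return `sample_status`: tibble `sample_id`, `cna_positive`.
#' @export
sample_status <- function(calls, sample_ids) {
  tibble::tibble(sample_id = sample_ids,
                 cna_positive = sample_ids %in% unique(calls$sample_id))
}

#' @rdname sample_status
#' @param status tibble from [sample_status()] (QC-passed samples only).
#' @param samples sample sheet tibble.
#' @param min_positive_samples positives needed to flag a patient.
#' @return `patient_status`: tibble `patient_id`, `n_lesional`,
#'   `n_positive`, `cna_positive` (logical, `NA` = indeterminate).
#' @export
patient_status <- function(status, samples, min_positive_samples = 1L) {
  stopifnot(all(c("sample_id", "patient_id", "tissue") %in% names(samples)))
  samples |>
    dplyr::left_join(status, by = "sample_id") |>
    dplyr::filter(.data$tissue != "normal") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_lesional = sum(!is.na(.data$cna_positive)),
      n_positive = sum(.data$cna_positive, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(cna_positive = dplyr::if_else(
      .data$n_lesional == 0, NA,
      .data$n_positive >= min_positive_samples))
}
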