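#' Per-bin recurrence of gains and losses
#'
#' For every genome bin, the fraction of samples (or patients) whose calls
#' of each direction cover the bin — the aggregation track drawn under
#' cohort heatmaps ("percentage of samples harboring CNAs"). Gain and loss
#' fractions share one denominator: the number of units considered.
#'
#' @param calls call tibble from [call_segments()].
#' @param bins a [genome_bins] tibble.
#' @param sample_ids QC-passed sample ids forming the denominator.
#' @param samples sample sheet; required for `by = "patient"`.
#' @param by count "sample"s (default) or "patient"s (a patient covers a
#'   bin when any of their samples does).
#' @return tibble `bin`, `chrom`, `gain_frac`, `loss_frac`, `n_units`.
#' @export
recurrence_profile <- function(calls, bins, sample_ids,
                               samples = NULL, by = c("sample", "patient")) {
  by <- match.arg(by)
  bins <- genome_bins(bins)
  if (length(sample_ids) == 0) abort("recurrence needs at least one sample")
  calls <- calls[calls$sample_id %in% sample_ids, , drop = FALSE]
  if (by == "patient") {
    if (is.null(samples)) abort("patient-level recurrence needs the sample sheet")
    unit_of <- setNames(samples$patient_id, samples$sample_id)
    calls$unit <- unit_of[calls$sample_id]
    n_units <- length(unique(unit_of[sample_ids]))
  } else {
    calls$unit <- calls$sample_id
    n_units <- length(unique(sample_ids))
  }
  gain <- loss <- numeric(nrow(bins))
  for (st in c("gain", "loss")) {
    cc <- calls[calls$state == st, , drop = FALSE]
    cov <- numeric(nrow(bins))
    for (u in unique(cc$unit)) {
      covered <- rep(FALSE, nrow(bins))
      e <- cc[cc$unit == u, , drop = FALSE]
      for (k in seq_len(nrow(e))) covered[e$start_bin[k]:e$end_bin[k]] <- TRUE
      cov <- cov + covered
    }
    if (st == "gain") gain <- cov / n_units else loss <- cov / n_units
  }
  tibble::tibble(bin = bins$bin, chrom = bins$chrom,
                 gain_frac = gain, loss_frac = loss, n_units = n_units)
}

#' Smallest common region of recurrent CNAs
#'
#' Given one or more altered intervals per patient on a single chromosome
#' and direction, finds the region supported by the largest number of
#' distinct patients — the intersection over one interval per supporting
#' patient, located by sweeping interval endpoints. Ties in support are
#' broken toward the widest region. Regions supported by fewer than
#' `min_patients` patients are discarded (an empty result, not an error).
#'
#' @param intervals tibble with columns `patient_id`, `start_bin`,
#'   `end_bin` (inclusive bin indices on one chromosome).
#' @param min_patients minimum distinct supporting patients.
#' @return tibble `start_bin`, `end_bin`, `n_patients`, `patients`
#'   (list-column), with zero rows when no region qualifies.
#' @examples
#' smallest_common_region(tibble::tibble(
#'   patient_id = c("a", "b", "c"),
#'   start_bin = c(10, 20, 5), end_bin = c(60, 80, 55)))  # [20, 55] by 3
#' @export
smallest_common_region <- function(intervals, min_patients = 2L) {
  stopifnot(all(c("patient_id", "start_bin", "end_bin") %in% names(intervals)))
  if (nrow(intervals) == 0 ||
      length(unique(intervals$patient_id)) < min_patients) {
    return(empty_scr())
  }
  # endpoint sweep: elementary intervals between consecutive breakpoints
  # have constant coverage, so evaluating each one is exhaustive
  pts <- sort(unique(c(intervals$start_bin, intervals$end_bin + 1L)))
  elem <- lapply(seq_len(length(pts) - 1L), function(k) {
    s <- pts[k]; e <- pts[k + 1L] - 1L
    sup <- sort(unique(intervals$patient_id[intervals$start_bin <= s &
                                              intervals$end_bin >= e]))
    list(s = s, e = e, sup = sup)
  })
  nsup <- vapply(elem, function(z) length(z$sup), integer(1))
  maxsup <- max(nsup)
  if (maxsup < min_patients) return(empty_scr())
  # fuse contiguous runs of max-support pieces with identical supporters,
  # then break support ties toward the widest region
  best <- NULL
  k <- 1L
  while (k <= length(elem)) {
    if (nsup[k] < maxsup) { k <- k + 1L; next }
    run <- elem[[k]]
    j <- k + 1L
    while (j <= length(elem) && nsup[j] == maxsup &&
           elem[[j]]$s == run$e + 1L && identical(elem[[j]]$sup, run$sup)) {
      run$e <- elem[[j]]$e
      j <- j + 1L
    }
    if (is.null(best) || (run$e - run$s) > (best$e - best$s)) best <- run
    k <- j
  }
  tibble::tibble(start_bin = best$s, end_bin = best$e,
                 n_patients = maxsup, patients = list(best$sup))
}

empty_scr <- function() {
  tibble::tibble(start_bin = integer(), end_bin = integer(),
                 n_patients = integer(), patients = list())
}

#' Hotspot regions across the genome
#'
#' Runs [smallest_common_region()] for every chromosome and direction over
#' patient-level call intervals.
#'
#' @param calls call tibble.
#' @param samples sample sheet (maps samples to patients).
#' @param min_patients minimum supporting patients per region.
#' @return tibble `chrom`, `direction`, `start_bin`, `end_bin`,
#'   `n_patients`, `patients`.
#' @export
find_hotspots <- function(calls, samples, min_patients = 2L) {
  if (nrow(calls) == 0) {
    return(tibble::tibble(chrom = character(), direction = character(),
                          start_bin = integer(), end_bin = integer(),
                          n_patients = integer(), patients = list()))
  }
  pid <- setNames(samples$patient_id, samples$sample_id)
  iv <- dplyr::mutate(calls, patient_id = pid[.data$sample_id])
  iv |>
    dplyr::group_by(.data$chrom, direction = .data$state) |>
    dplyr::group_modify(~ smallest_common_region(.x, min_patients)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$n_patients >= min_patients)
}

#' Concordance of CNA patterns between two samples
#'
#' Direction-matched Jaccard index over altered bins: a bin counts as
#' shared only when both samples call it with the same direction; the
#' union covers bins altered in either sample. Two samples with no
#' alterations at all are defined as fully concordant (1.0) and flagged
#' with attribute `both_negative`. Symmetric; equal to 1 on
#' self-comparison.
#'
#' @param calls_a,calls_b call tibbles for the two samples (same bin
#'   coordinate system).
#' @return a number in \[0, 1\] with attribute `both_negative`.
#' @export
pattern_concordance <- function(calls_a, calls_b) {
  expand <- function(calls, st) {
    cc <- calls[calls$state == st, , drop = FALSE]
    if (!nrow(cc)) return(integer())
    unique(unlist(lapply(seq_len(nrow(cc)),
                         function(k) cc$start_bin[k]:cc$end_bin[k])))
  }
  ga <- expand(calls_a, "gain"); la <- expand(calls_a, "loss")
  gb <- expand(calls_b, "gain"); lb <- expand(calls_b, "loss")
  union_n <- length(union(union(ga, la), union(gb, lb)))
  if (union_n == 0) return(structure(1.0, both_negative = TRUE))
  shared <- length(intersect(ga, gb)) + length(intersect(la, lb))
  structure(shared / union_n, both_negative = FALSE)
}

#' Summarise CNAscore distributions by group
#'
#' Per group: sample count, min, max, median, and the fraction of samples
#' with a score above a reference cutoff. The default cutoff is the
#' maximum score observed in the `"normal"` group — the data-driven
#' ceiling of scores from unaltered tissue — recomputed from the input,
#' never hard-coded.
#'
#' @param scores tibble `sample_id`, `cna_score`.
#' @param groups named vector or sample sheet mapping samples to groups.
#' @param cutoff reference cutoff; `NULL` = max of the normal group.
#' @return tibble `group`, `n`, `min`, `max`, `median`, `frac_above`,
#'   plus attribute `cutoff`.
#' @export
score_distributions <- function(scores, groups, cutoff = NULL) {
  if (is.data.frame(groups)) groups <- setNames(groups$group, groups$sample_id)
  sc <- dplyr::mutate(scores, group = unname(groups[.data$sample_id]))
  if (any(is.na(sc$group))) {
    warn("samples without a group are omitted")
    sc <- sc[!is.na(sc$group), , drop = FALSE]
  }
  if (nrow(sc) == 0) abort("no grouped scores to summarise")
  if (is.null(cutoff)) {
    norm <- sc$cna_score[sc$group == "normal"]
    if (!length(norm)) {
      warn("no normal group present; cutoff defaults to +Inf")
      cutoff <- Inf
    } else cutoff <- max(norm)
  }
  out <- sc |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), min = min(.data$cna_score),
                     max = max(.data$cna_score),
                     median = median(.data$cna_score),
                     frac_above = mean(.data$cna_score > cutoff),
                     .groups = "drop")
  attr(out, "cutoff") <- cutoff
  out
}

#' Diagnostic-support flags per patient
#'
#' Reduces a patient's calls and scores to three molecular flags:
#' `cna_positive` (any lesional sample carries a call),
#' `chr7_or_chr12_pattern` (any call lies on chromosome 7 or 12, the
#' recurrent hotspots supporting an OF diagnosis), and
#' `genome_complexity` (calls span at least `complexity_chroms` distinct
#' chromosomes, or the median lesional CNAscore exceeds
#' `complexity_score_cutoff` — the pattern seen in osteosarcoma-like
#' genomes). The summary label only states molecular support; absence of
#' CNAs never rules anything out and the label says so.
#'
#' @param calls call tibble (QC-passed samples).
#' @param scores tibble `sample_id`, `cna_score`.
#' @param samples sample sheet.
#' @param complexity_chroms chromosome-count trigger (default 8).
#' @param complexity_score_cutoff CNAscore trigger (default `Inf` =
#'   chromosome count only).
#' @param min_positive_samples passed to [patient_status()].
#' @return tibble `patient_id`, `cna_positive`, `chr7_or_chr12_pattern`,
#'   `genome_complexity`, `label`.
#' @export
classify_patients <- function(calls, scores, samples,
                              complexity_chroms = 8L,
                              complexity_score_cutoff = Inf,
                              min_positive_samples = 1L) {
  qc_passed <- unique(scores$sample_id)
  st <- sample_status(calls, qc_passed)
  pst <- patient_status(st, samples, min_positive_samples)
  pid <- setNames(samples$patient_id, samples$sample_id)
  lesional <- samples$sample_id[samples$tissue != "normal"]
  out <- lapply(seq_len(nrow(pst)), function(k) {
    p <- pst$patient_id[k]
    if (is.na(pst$cna_positive[k])) {
      return(tibble::tibble(patient_id = p, cna_positive = NA,
                            chr7_or_chr12_pattern = NA,
                            genome_complexity = NA,
                            label = "insufficient QC-passed samples"))
    }
    sids <- intersect(samples$sample_id[pid[samples$sample_id] == p], lesional)
    cc <- calls[calls$sample_id %in% sids, , drop = FALSE]
    hot <- any(cc$chrom %in% c("7", "12"))
    med_score <- median(scores$cna_score[scores$sample_id %in% sids])
    complexity <- length(unique(cc$chrom)) >= complexity_chroms ||
      (is.finite(complexity_score_cutoff) && !is.na(med_score) &&
         med_score > complexity_score_cutoff)
    label <- if (complexity) {
      "complexity warning: alterations across many chromosomes"
    } else if (pst$cna_positive[k] && hot) {
      "OF-supporting: recurrent chromosome 7/12 alteration pattern"
    } else if (pst$cna_positive[k]) {
      "CNA-positive without hotspot pattern"
    } else {
      "no molecular support; absence of CNAs does not rule out a lesion"
    }
    tibble::tibble(patient_id = p, cna_positive = pst$cna_positive[k],
                   chr7_or_chr12_pattern = hot,
                   genome_complexity = complexity, label = label)
  })
  dplyr::bind_rows(out)
}
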