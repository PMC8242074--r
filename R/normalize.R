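#' Neutral copy number of a chromosome given sex
#'
#' The neutral ("norm") value is the copy number a chromosome has in the
#' absence of any alteration: 2 for autosomes, 1 for male X and Y, 2 for
#' female X and 0 for female Y. For sex `"unknown"` the X is treated as
#' diploid (with an informative message) and the Y is excluded (returns
#' `NA`), so that ambiguous sex never generates sex-chromosome calls.
#'
#' @param sex one of "male", "female", "unknown" (recycled).
#' @param chrom chromosome name(s).
#' @param quiet suppress the unknown-sex caveat message.
#' @return numeric vector of neutral copy numbers (`NA` = excluded).
#' @examples
#' expected_ploidy("female", "7")  # 2
#' expected_ploidy("male", "chrX") # 1
#' expected_ploidy("female", "Y")  # 0
#' @export
expected_ploidy <- function(sex, chrom, quiet = FALSE) {
  chrom <- normalize_chrom(chrom, strict = TRUE)
  n <- max(length(sex), length(chrom))
  sex <- rep_len(sex, n); chrom <- rep_len(chrom, n)
  if (any(!sex %in% c("male", "female", "unknown"))) {
    abort("sex must be one of male, female, unknown")
  }
  out <- rep(2, n)
  is_x <- chrom == "X"; is_y <- chrom == "Y"
  out[is_x & sex == "male"] <- 1
  out[is_y & sex == "male"] <- 1
  out[is_x & sex == "female"] <- 2
  out[is_y & sex == "female"] <- 0
  if (any(is_x & sex == "unknown") && !quiet) {
    inform("sex unknown: treating chromosome X as diploid")
  }
  out[is_y & sex == "unknown"] <- NA_real_
  out
}

#' LOWESS GC normalization of bin counts
#'
#' Fits a locally weighted (LOWESS) regression of weight-corrected bin
#' counts against GC fraction, divides each count by its fitted value to
#' cancel the multiplicative GC bias, then rescales the profile so that the
#' median over usable autosomal bins is exactly 2 (the diploid anchor).
#' Bins with zero weight or a non-positive fitted value are masked out.
#' Deterministic for fixed inputs.
#'
#' Works on one or many samples: `counts` is a long tibble with columns
#' `sample_id` (optional for a single sample), `bin`, `count`.
#'
#' @param counts long count tibble (or a bare numeric vector aligned to
#'   `bins`).
#' @param bins a [genome_bins] tibble.
#' @param span LOWESS span (fraction of points in each local fit).
#' @param iterations robustifying iterations.
#' @param min_bins minimum number of usable bins required for a stable fit.
#' @return a copy-number profile tibble of class `cna_profile` with columns
#'   `sample_id`, `bin`, `chrom`, `gc`, `count`, `x` (linear copy number,
#'   diploid baseline 2) and `mask` (TRUE = usable).
#' @export
gc_normalize <- function(counts, bins, span = 0.3, iterations = 3L,
                         min_bins = 200L) {
  bins <- genome_bins(bins)
  stopifnot(span > 0, span <= 1)
  if (is.numeric(counts) && is.null(dim(counts))) {
    counts <- tibble::tibble(sample_id = "sample",
                             bin = bins$bin, count = counts)
  }
  if (!"sample_id" %in% names(counts)) counts$sample_id <- "sample"
  stopifnot(all(c("bin", "count") %in% names(counts)))
  out <- counts |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(~ gc_normalize_one(.x, bins, span, iterations, min_bins)) |>
    dplyr::ungroup()
  class(out) <- c("cna_profile", class(tibble::tibble()))
  out
}

gc_normalize_one <- function(counts, bins, span, iterations, min_bins) {
  if (nrow(counts) != nrow(bins) || any(sort(counts$bin) != bins$bin)) {
    abort("counts must cover every bin exactly once")
  }
  counts <- counts[order(counts$bin), , drop = FALSE]
  cnt <- as.numeric(counts$count)
  if (any(cnt < 0 | !is.finite(cnt))) abort("counts must be finite and nonnegative")
  if (all(cnt == 0)) abort("empty sample: all bin counts are zero")
  mask <- bins$weight > 0
  y <- ifelse(mask, cnt / pmax(bins$weight, .Machine$double.eps), NA_real_)
  use <- which(mask)
  if (length(use) < min_bins) {
    abort(paste0("only ", length(use), " usable bins; at least ", min_bins,
                 " required for LOWESS"))
  }
  fit <- lowess(bins$gc[use], y[use], f = span, iter = iterations)
  fitted <- approx(fit$x, fit$y, xout = bins$gc, rule = 2, ties = mean)$y
  mask <- mask & fitted > 0
  x <- rep(NA_real_, nrow(bins))
  x[mask] <- y[mask] / fitted[mask]
  auto <- mask & !(bins$chrom %in% c("X", "Y"))
  med <- median(x[auto])
  if (!is.finite(med) || med <= 0) abort("degenerate profile: autosomal median not positive")
  x <- x * 2 / med
  tibble::tibble(bin = bins$bin, chrom = bins$chrom, gc = bins$gc,
                 count = cnt, x = x, mask = mask)
}

#' Write normalized profiles to TSV
#'
#' One row per (sample, bin): `sample_id`, `chrom`, `start`, `end`, `x`,
#' `mask`.
#'
#' @param profile a `cna_profile` tibble from [gc_normalize()].
#' @param bins a [genome_bins] tibble.
#' @param path output path.
#' @export
write_profile <- function(profile, bins, path) {
  bins <- genome_bins(bins)
  out <- profile |>
    dplyr::left_join(bins[, c("bin", "start", "end")], by = "bin") |>
    dplyr::transmute(.data$sample_id, .data$chrom, .data$start, .data$end,
                     x = .data$x, mask = .data$mask)
  readr::write_tsv(out, path)
  invisible(path)
}
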