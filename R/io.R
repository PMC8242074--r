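#' Tabulate mapped-read positions into genome bins
#'
#' Reads a BED-like / tabular file of mapped-read positions (columns
#' chrom, pos; extra columns ignored; no header) and counts how many
#' records fall in each bin under the half-open `[start, end)` test.
#' Records on a known chromosome but outside every bin count toward
#' `total_mapped` but not toward any bin ("dropped in genome"); records on
#' unknown chromosomes are dropped with a warning and excluded from
#' `total_mapped`.
#'
#' @param path file of chrom/pos records, or a data frame with columns
#'   `chrom` and `pos`.
#' @param bins a [genome_bins] tibble.
#' @param sample_id label attached to the returned counts.
#' @return a tibble with columns `sample_id`, `bin`, `count`; attributes
#'   `total_mapped`, `n_assigned`, `n_dropped_in_genome`,
#'   `n_unknown_chrom`.
#' @export
read_positions <- function(path, bins, sample_id = "sample") {
  bins <- genome_bins(bins)
  if (is.data.frame(path)) {
    pos <- tibble::as_tibble(path)
    if (!all(c("chrom", "pos") %in% names(pos))) abort("need columns chrom and pos")
  } else {
    pos <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    if (nrow(pos) == 0) {
      pos <- tibble::tibble(chrom = character(), pos = numeric())
    } else {
      if (ncol(pos) < 2) abort("position records need at least 2 columns (chrom, pos)")
      pos <- tibble::tibble(chrom = pos[[1]], pos = suppressWarnings(as.numeric(pos[[2]])))
      if (any(!is.finite(pos$pos))) abort("non-numeric position field")
    }
  }
  n_in <- nrow(pos)
  pos$chrom <- normalize_chrom(pos$chrom)
  n_unknown <- sum(is.na(pos$chrom))
  if (n_unknown > 0) {
    warn(paste0(n_unknown, " record(s) on unknown chromosomes dropped"))
    pos <- pos[!is.na(pos$chrom), , drop = FALSE]
  }
  counts <- integer(nrow(bins))
  dropped_in_genome <- 0L
  for (ch in unique(pos$chrom)) {
    bidx <- which(bins$chrom == ch)
    p <- pos$pos[pos$chrom == ch]
    if (!length(bidx)) { dropped_in_genome <- dropped_in_genome + length(p); next }
    starts <- bins$start[bidx]; ends <- bins$end[bidx]
    k <- findInterval(p, starts)           # bins sorted, nonoverlapping
    inside <- k >= 1 & p < ends[pmax(k, 1)]
    dropped_in_genome <- dropped_in_genome + sum(!inside)
    tab <- tabulate(k[inside], nbins = length(bidx))
    counts[bidx] <- counts[bidx] + tab
  }
  out <- tibble::tibble(sample_id = sample_id, bin = bins$bin, count = counts)
  attr(out, "total_mapped") <- n_in - n_unknown
  attr(out, "n_assigned") <- sum(counts)
  attr(out, "n_dropped_in_genome") <- dropped_in_genome
  attr(out, "n_unknown_chrom") <- n_unknown
  out
}

#' Read / write a bins-by-samples count matrix
#'
#' The on-disk format is a TSV with header and columns `chrom`, `start`,
#' `end` followed by one integer column per sample; rows are bins in genome
#' order and must match `bins` exactly.
#'
#' @param path file path.
#' @param bins a [genome_bins] tibble.
#' @return `read_counts`: a long tibble with columns `sample_id`, `bin`,
#'   `count`.
#' @export
read_counts <- function(path, bins) {
  bins <- genome_bins(bins)
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("chrom", "start", "end") %in% names(m))) {
    abort("count matrix needs chrom/start/end columns")
  }
  if (nrow(m) != nrow(bins) ||
      any(normalize_chrom(m$chrom) != bins$chrom) ||
      any(m$start != bins$start)) {
    abort("count matrix rows do not match the supplied bins")
  }
  samples <- setdiff(names(m), c("chrom", "start", "end"))
  if (!length(samples)) abort("count matrix has no sample columns")
  m$bin <- bins$bin
  tidyr::pivot_longer(m[, c("bin", samples)], cols = -"bin",
                      names_to = "sample_id", values_to = "count") |>
    dplyr::arrange(.data$sample_id, .data$bin) |>
    dplyr::relocate("sample_id")
}

#' @rdname read_counts
#' @param counts long tibble (`sample_id`, `bin`, `count`).
#' @export
write_counts <- function(counts, bins, path) {
  bins <- genome_bins(bins)
  wide <- tidyr::pivot_wider(counts, id_cols = "bin",
                             names_from = "sample_id", values_from = "count")
  wide <- dplyr::arrange(wide, .data$bin)
  if (nrow(wide) != nrow(bins)) abort("counts do not cover every bin")
  out <- dplyr::bind_cols(bins[, c("chrom", "start", "end")],
                          wide[, -1, drop = FALSE])
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV with header and columns `sample_id`, `patient_id`, `tissue`
#' (fibrous / calcified / normal), `sex` (male / female / unknown),
#' `group` (free label such as OF, FD, OS, normal) and an optional
#' `timepoint`.
#'
#' @param path file path or data frame.
#' @return validated tibble.
#' @export
read_sample_sheet <- function(path) {
  s <- if (is.data.frame(path)) tibble::as_tibble(path)
       else readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "patient_id", "tissue", "sex", "group")
  miss <- setdiff(need, names(s))
  if (length(miss)) abort(paste0("sample sheet missing column(s): ",
                                 paste(miss, collapse = ", ")))
  if (anyDuplicated(s$sample_id)) abort("sample_id values must be unique")
  if (any(is.na(s$patient_id))) abort("every sample must reference a patient_id")
  bad_t <- setdiff(unique(s$tissue), c("fibrous", "calcified", "normal"))
  if (length(bad_t)) abort(paste0("unknown tissue type(s): ", paste(bad_t, collapse = ", ")))
  bad_s <- setdiff(unique(s$sex), c("male", "female", "unknown"))
  if (length(bad_s)) abort(paste0("unknown sex value(s): ", paste(bad_s, collapse = ", ")))
  s
}

#' Write segment profiles in SEG format
#'
#' Standard SEG columns: `ID`, `chrom`, `loc.start`, `loc.end`,
#' `num.mark`, `seg.mean`. By this package's convention `seg.mean` holds
#' the segment's copy-number value on the linear scale (diploid baseline
#' 2), not log2 ratio. Values survive a write/read round trip to within
#' 1e-9. Segment sets must partition each chromosome's bins.
#'
#' @param segments segment tibble as returned by [cbs_segment()].
#' @param bins a [genome_bins] tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, bins, path) {
  bins <- genome_bins(bins)
  validate_segments(segments, bins)
  out <- data.frame(
    ID = segments$sample_id,
    chrom = segments$chrom,
    loc.start = format(bins$start[segments$start_bin], scientific = FALSE, trim = TRUE),
    loc.end = format(bins$end[segments$end_bin], scientific = FALSE, trim = TRUE),
    num.mark = segments$n_bins,
    seg.mean = formatC(segments$seg_mean, digits = 17, format = "g"))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path, bins) {
  bins <- genome_bins(bins)
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("ID", "chrom", "loc.start", "loc.end", "num.mark", "seg.mean")
  miss <- setdiff(need, names(m))
  if (length(miss)) abort(paste0("SEG file missing column(s): ", paste(miss, collapse = ", ")))
  chrom <- normalize_chrom(m$chrom, strict = TRUE)
  key <- paste(bins$chrom, bins$start)
  start_bin <- match(paste(chrom, m$loc.start), key)
  key_end <- paste(bins$chrom, bins$end)
  end_bin <- match(paste(chrom, m$loc.end), key_end)
  if (any(is.na(start_bin)) || any(is.na(end_bin))) {
    abort("SEG coordinates do not align to the supplied bins")
  }
  seg <- tibble::tibble(sample_id = as.character(m$ID), chrom = chrom,
                        start_bin = start_bin, end_bin = end_bin,
                        n_bins = as.integer(m$num.mark),
                        seg_mean = as.numeric(m$seg.mean)) |>
    dplyr::arrange(.data$sample_id, .data$start_bin)
  validate_segments(seg, bins)
  seg
}

# segments must partition each (sample, chromosome): ordered, nonoverlapping,
# jointly covering the chromosome's segmented bins with no gaps between
# consecutive segment spans.
validate_segments <- function(segments, bins = NULL) {
  need <- c("sample_id", "chrom", "start_bin", "end_bin", "n_bins", "seg_mean")
  miss <- setdiff(need, names(segments))
  if (length(miss)) abort(paste0("segment table missing column(s): ",
                                 paste(miss, collapse = ", ")))
  if (any(segments$end_bin < segments$start_bin)) abort("segment end_bin < start_bin")
  split_idx <- split(seq_len(nrow(segments)),
                     paste(segments$sample_id, segments$chrom, sep = "\r"))
  for (idx in split_idx) {
    s <- segments[idx, , drop = FALSE]
    s <- s[order(s$start_bin), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start_bin[-1] <= s$end_bin[-nrow(s)])) {
      abort(paste0("segments overlap or do not partition chromosome ", s$chrom[1],
                   " of sample ", s$sample_id[1]))
    }
  }
  invisible(segments)
}
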