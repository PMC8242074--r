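#' Canonical chromosome order
#'
#' The pipeline works on the 24 human chromosomes in the order
#' 1..22, X, Y; all downstream per-chromosome sums (notably the CNAscore)
#' run over this order. Names are stored unprefixed ("7", not "chr7").
#'
#' @keywords internal
chrom_levels <- function() c(as.character(1:22), "X", "Y")

#' Normalize chromosome names
#'
#' Accepts "chr7"/"7" style names and returns the unprefixed form. Unknown
#' chromosomes (not 1..22, X, Y) are returned as `NA` unless `strict = TRUE`,
#' in which case they raise an error.
#'
#' @param chrom character vector of chromosome names.
#' @param strict error on unknown chromosomes instead of returning `NA`.
#' @return character vector of normalized names.
#' @export
normalize_chrom <- function(chrom, strict = FALSE) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(chrom))
  x[x == "23"] <- "X"
  x[x == "24"] <- "Y"
  bad <- !(x %in% chrom_levels())
  if (any(bad)) {
    if (strict) {
      abort(paste0("unknown chromosome name(s): ",
                   paste(unique(chrom[bad]), collapse = ", ")))
    }
    x[bad] <- NA_character_
  }
  x
}

chrom_rank <- function(chrom) match(chrom, chrom_levels())

#' Construct and validate a genome bin table
#'
#' Bins are the coordinate system for the whole pipeline: ordered,
#' nonoverlapping, half-open `[start, end)` intervals with a GC fraction
#' and an optional positive weight (a stand-in for mappability-scaled
#' "dynamic" bins; defaults to 1). The returned tibble carries a 1-based
#' `bin` index in genome order (chromosomes 1..22, X, Y).
#'
#' @param bins data frame with columns `chrom`, `start`, `end`, `gc` and
#'   optionally `weight`.
#' @return a tibble of class `genome_bins` with columns
#'   `bin`, `chrom`, `start`, `end`, `gc`, `weight`.
#' @examples
#' genome_bins(tibble::tibble(
#'   chrom = "1", start = c(0, 1e6), end = c(1e6, 2e6), gc = c(0.4, 0.5)))
#' @export
genome_bins <- function(bins) {
  stopifnot(is.data.frame(bins))
  need <- c("chrom", "start", "end", "gc")
  miss <- setdiff(need, names(bins))
  if (length(miss)) abort(paste0("bins missing column(s): ", paste(miss, collapse = ", ")))
  b <- tibble::as_tibble(bins)
  b$chrom <- normalize_chrom(b$chrom, strict = TRUE)
  if (!"weight" %in% names(b)) b$weight <- 1
  if (any(!is.finite(b$start)) || any(!is.finite(b$end))) abort("non-finite bin coordinates")
  if (any(b$end <= b$start)) abort("bin end must be greater than start (half-open [start, end))")
  if (any(b$gc < 0 | b$gc > 1 | !is.finite(b$gc))) abort("gc fraction must lie in [0, 1]")
  if (any(b$weight < 0 | !is.finite(b$weight))) abort("bin weights must be finite and >= 0")
  # enforce genome order without silently reordering user input
  rk <- chrom_rank(b$chrom)
  ord <- order(rk, b$start)
  if (any(ord != seq_len(nrow(b)))) {
    abort("bins must be sorted in genome order (chrom 1..22, X, Y; ascending start)")
  }
  by_chrom <- split(seq_len(nrow(b)), b$chrom)
  for (idx in by_chrom) {
    if (length(idx) > 1L) {
      s <- b$start[idx]; e <- b$end[idx]
      if (any(s[-1] < e[-length(e)])) abort("bins overlap within a chromosome")
    }
  }
  b$bin <- seq_len(nrow(b))
  b <- dplyr::relocate(b, "bin")
  class(b) <- c("genome_bins", class(tibble::tibble()))
  b
}

#' Read bin definitions from a BED-like file
#'
#' Expects a tab-separated file with no header and at least four columns:
#' chrom, start, end, gc (0-based half-open coordinates, BED dialect), plus
#' an optional fifth weight column. Lines starting with `#` or `track` are
#' skipped.
#'
#' @param path file path.
#' @return a [genome_bins] tibble.
#' @export
read_bins <- function(path) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) abort("no bin records found")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 4L)) {
    abort(paste0("malformed bin record (need >= 4 tab-separated fields) at line ",
                 lineno[which(nfield < 4L)[1]]))
  }
  num <- function(k) suppressWarnings(as.numeric(vapply(parts, `[[`, "", k)))
  start <- num(2); end <- num(3); gc <- num(4)
  bad <- which(!is.finite(start) | !is.finite(end) | !is.finite(gc))
  if (length(bad)) abort(paste0("malformed numeric field at line ", lineno[bad[1]]))
  b <- tibble::tibble(chrom = vapply(parts, `[[`, "", 1),
                      start = start, end = end, gc = gc)
  if (all(nfield >= 5L)) {
    w <- num(5)
    if (any(!is.finite(w))) abort(paste0("malformed weight field at line ",
                                         lineno[which(!is.finite(w))[1]]))
    b$weight <- w
  }
  genome_bins(b)
}

#' Write bin definitions to a BED-like file
#'
#' @param bins a [genome_bins] tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bins <- function(bins, path) {
  b <- genome_bins(bins)
  out <- data.frame(chrom = b$chrom,
                    start = format(b$start, scientific = FALSE, trim = TRUE),
                    end = format(b$end, scientific = FALSE, trim = TRUE),
                    gc = formatC(b$gc, digits = 17, format = "g"),
                    weight = formatC(b$weight, digits = 17, format = "g"))
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

# hg19 chromosome lengths (bp), 1..22, X, Y
hg19_lengths <- function() {
  c(`1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
    `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
    `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
    `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
    `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
    `21` = 48129895, `22` = 51304566, X = 155270560, Y = 59373566)
}

#' Build a synthetic genome of 1 Mb bins with hg19-like proportions
#'
#' Tiles 24 chromosomes, with lengths proportional to hg19, into
#' nonoverlapping 1 Mb bins. `scale = 1` yields the full-size genome
#' (~3,100 bins); smaller scales shrink every chromosome proportionally for
#' fast simulation, but every chromosome must keep at least 10 bins so that
#' segmentation minimum widths stay meaningful. Per-bin GC is drawn from a
#' smooth autocorrelated (AR(1)) process mapped into \[0.3, 0.6\].
#'
#' @param scale chromosome length multiplier in (0, 1].
#' @param seed integer seed for the GC process.
#' @param bin_width bin width in bases (default 1e6).
#' @param chroms chromosomes to include (default all 24).
#' @return a [genome_bins] tibble.
#' @export
make_genome <- function(scale = 1, seed = 1L, bin_width = 1e6,
                        chroms = chrom_levels()) {
  stopifnot(scale > 0, scale <= 1, bin_width > 0)
  chroms <- normalize_chrom(chroms, strict = TRUE)
  chroms <- chroms[order(chrom_rank(chroms))]
  len <- hg19_lengths()[chroms] * scale
  nbin <- floor(len / bin_width)
  if (any(nbin < 10L)) {
    abort(paste0("scale ", scale, " leaves chromosome(s) ",
                 paste(chroms[nbin < 10L], collapse = ", "),
                 " with fewer than 10 bins; segmentation minimum width ",
                 "would be meaningless. Increase scale."))
  }
  withr_seed <- function(expr) { # local RNG so callers' streams are untouched
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
    set.seed(seed)
    expr
  }
  gc_all <- withr_seed({
    unlist(lapply(nbin, function(n) {
      # AR(1) latent process, squashed into (0.3, 0.6)
      z <- numeric(n); z[1] <- stats::rnorm(1)
      if (n > 1) for (i in 2:n) z[i] <- 0.9 * z[i - 1] + sqrt(1 - 0.9^2) * stats::rnorm(1)
      0.45 + 0.15 * tanh(z / 2)
    }))
  })
  b <- tibble::tibble(
    chrom = rep(chroms, nbin),
    start = unlist(lapply(nbin, function(n) (seq_len(n) - 1) * bin_width)),
    end   = unlist(lapply(nbin, function(n) seq_len(n) * bin_width)),
    gc    = gc_all)
  genome_bins(b)
}

n_bins_per_chrom <- function(bins) {
  tab <- table(factor(bins$chrom, levels = chrom_levels()))
  tab[tab > 0]
}
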