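#' Segmentation configuration
#'
#' Parameters of the circular binary segmentation: `alpha` is the
#' permutation-test significance level for declaring a changepoint,
#' `min_width` the minimum number of bins a changed segment may span,
#' `undo_sd` the post-hoc merge threshold in units of the sample's noise
#' SD, and `nperm` the number of permutations per test. Defaults follow
#' the analysis settings alpha = 0.1, min.width = 5, undo.SD = 0.1.
#'
#' @param alpha significance level in (0, 1).
#' @param min_width minimum bins per changed segment (>= 2).
#' @param undo_sd merge threshold in noise-SD units (0 disables undo).
#' @param nperm permutations per test (>= 100).
#' @param scale segment on `"linear"` copy number (default; the calling
#'   thresholds are linear) or on `"log"` (log2(x/2), segment means
#'   back-transformed as `2 * 2^mean`).
#' @param seed optional integer seed set before segmentation.
#' @return a list of class `cbs_config`.
#' @export
cbs_config <- function(alpha = 0.1, min_width = 5L, undo_sd = 0.1,
                       nperm = 1000L, scale = c("linear", "log"),
                       seed = NULL) {
  stopifnot(alpha > 0, alpha < 1, min_width >= 2, nperm >= 100, undo_sd >= 0)
  structure(list(alpha = alpha, min_width = as.integer(min_width),
                 undo_sd = undo_sd, nperm = as.integer(nperm),
                 scale = match.arg(scale), seed = seed),
            class = "cbs_config")
}

#' Circular binary segmentation of copy-number profiles
#'
#' Partitions each chromosome of each sample into segments of constant
#' copy number. Per chromosome the algorithm recursively (1) scans all
#' arcs (i, j] of the circularized bin sequence for the maximal
#' mean-difference statistic, restricted so both the arc and its
#' complement span at least `min_width` bins; (2) assesses that maximum
#' against `nperm` within-chromosome permutations, declaring a change when
#' the permutation p-value is at most `alpha`; (3) recurses into the
#' resulting pieces. After convergence, adjacent segments whose means
#' differ by less than `undo_sd` times the sample's MAPD-derived noise SD
#' (MAPD / (sqrt(2) * 0.6745)) are merged back. Segment means are
#' recomputed from the bin values. Masked-out bins are excluded; segments
#' are reported in global bin indices spanning their member bins.
#'
#' @param profile `cna_profile` tibble (one or many samples).
#' @param bins a [genome_bins] tibble (used for coordinates on write-out;
#'   optional).
#' @param config a [cbs_config()].
#' @return tibble of class `cna_segments`: `sample_id`, `chrom`,
#'   `start_bin`, `end_bin` (global bin indices, inclusive), `n_bins`
#'   (usable bins in the segment), `seg_mean` (linear copy number).
#' @export
cbs_segment <- function(profile, bins = NULL, config = cbs_config()) {
  stopifnot(inherits(config, "cbs_config"),
            all(c("sample_id", "bin", "chrom", "x") %in% names(profile)))
  if (!is.null(config$seed)) set.seed(config$seed)
  mask <- if ("mask" %in% names(profile)) profile$mask else TRUE
  prof <- profile[mask & is.finite(profile$x), , drop = FALSE]
  out <- prof |>
    dplyr::arrange(.data$sample_id, .data$bin) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(d, key) {
      sd_est <- tryCatch(mapd_one(d$x, d$chrom, FALSE, FALSE),
                         error = function(e) 0) / (sqrt(2) * stats::qnorm(0.75))
      d |>
        dplyr::group_by(chrom = factor(.data$chrom, levels = chrom_levels())) |>
        dplyr::group_modify(~ segment_chrom(.x$x, .x$bin, config, sd_est)) |>
        dplyr::ungroup() |>
        dplyr::mutate(chrom = as.character(.data$chrom))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$sample_id, .data$start_bin)
  out <- structure(out, class = c("cna_segments", class(tibble::tibble())),
                   config = config)
  out
}

# Segment one chromosome. `x` are usable bin values in order, `gbin` their
# global bin indices. Returns tibble(start_bin, end_bin, n_bins, seg_mean).
segment_chrom <- function(x, gbin, config, sd_est) {
  n <- length(x)
  if (n == 0) {
    return(tibble::tibble(start_bin = integer(), end_bin = integer(),
                          n_bins = integer(), seg_mean = numeric()))
  }
  y <- if (config$scale == "log") log2(pmax(x, 1e-6) / 2) else x
  bounds <- cbs_recurse(y, 1L, n, config)
  segs <- undo_splits(bounds, y, config$undo_sd,
                      if (config$scale == "log")
                        sd_est / (2 * log(2)) else sd_est)
  means <- vapply(seq_len(nrow(segs)), function(k) {
    m <- mean(y[segs$start[k]:segs$end[k]])
    if (config$scale == "log") 2 * 2^m else m
  }, numeric(1))
  tibble::tibble(start_bin = gbin[segs$start], end_bin = gbin[segs$end],
                 n_bins = segs$end - segs$start + 1L, seg_mean = means)
}

# Recursive CBS on y[lo..hi]; returns a data.frame of local segment
# boundaries (start, end) in 1-based positions of y.
cbs_recurse <- function(y, lo, hi, config) {
  n <- hi - lo + 1L
  single <- data.frame(start = lo, end = hi)
  if (n < 2L * config$min_width) return(single)
  seg <- y[lo:hi]
  scan <- cbs_scan_cpp(seg, config$min_width)
  if (!is.finite(scan$stat) || scan$stat <= 0) return(single)
  cnt <- cbs_perm_count_cpp(seg, config$min_width, config$nperm,
                            scan$stat, config$alpha)
  pval <- (cnt + 1) / (config$nperm + 1)
  if (pval > config$alpha) return(single)
  i <- scan$i; j <- scan$j  # arc is (i, j] in local 0-based prefix indices
  cuts <- c(if (i > 0) lo + i - 1L, if (j < n) lo + j - 1L)
  if (!length(cuts)) return(single)
  starts <- c(lo, cuts + 1L)
  ends <- c(cuts, hi)
  do.call(rbind, lapply(seq_along(starts), function(k) {
    cbs_recurse(y, starts[k], ends[k], config)
  }))
}

#' Merge adjacent segments with nearly equal means ("undo splits")
#'
#' Repeatedly merges the adjacent pair of segments whose means differ the
#' least, as long as that difference is below `undo_sd * sd_est`; means
#' are recomputed from the data after every merge. `sd_est` is the
#' sample's noise scale, by convention MAPD / (sqrt(2) * 0.6745).
#'
#' @param segments data frame with columns `start`, `end` (1-based
#'   positions into `x`).
#' @param x the bin values the segments partition.
#' @param undo_sd threshold in SD units.
#' @param sd_est noise SD estimate.
#' @return the merged segment data frame.
#' @export
undo_splits <- function(segments, x, undo_sd, sd_est) {
  segs <- segments[order(segments$start), , drop = FALSE]
  if (undo_sd <= 0 || sd_est <= 0 || nrow(segs) < 2) return(segs)
  thr <- undo_sd * sd_est
  repeat {
    if (nrow(segs) < 2) break
    means <- vapply(seq_len(nrow(segs)),
                    function(k) mean(x[segs$start[k]:segs$end[k]]), numeric(1))
    d <- abs(diff(means))
    k <- which.min(d)
    if (d[k] >= thr) break
    segs$end[k] <- segs$end[k + 1L]
    segs <- segs[-(k + 1L), , drop = FALSE]
  }
  segs
}

#' Exhaustive least-squares changepoint oracle
#'
#' Dynamic-programming search for the partition of `x` into exactly
#' `k_max` contiguous segments minimizing the residual sum of squares.
#' Intended as an independent reference for validating the segmentation on
#' small instances; limited to 200 values and 4 segments.
#'
#' @param x numeric values (length <= 200).
#' @param k_max number of segments (<= 4).
#' @return tibble `start`, `end`, `seg_mean` of the optimal partition.
#' @export
oracle_segment <- function(x, k_max = 2L) {
  n <- length(x)
  if (n > 200) abort("oracle_segment is limited to 200 values")
  if (k_max > 4) abort("oracle_segment is limited to 4 segments")
  k_max <- min(k_max, n)
  S <- c(0, cumsum(x)); S2 <- c(0, cumsum(x^2))
  sse <- function(i, j) { # x[i..j]
    s <- S[j + 1] - S[i]; q <- S2[j + 1] - S2[i]
    q - s^2 / (j - i + 1)
  }
  # dp[k, j]: min SSE of x[1..j] in k segments
  dp <- matrix(Inf, k_max, n)
  back <- matrix(0L, k_max, n)
  for (j in 1:n) dp[1, j] <- sse(1, j)
  if (k_max > 1) for (k in 2:k_max) {
    for (j in k:n) {
      best <- Inf; bi <- 0L
      for (i in (k - 1):(j - 1)) {
        v <- dp[k - 1, i] + sse(i + 1, j)
        if (v < best) { best <- v; bi <- i }
      }
      dp[k, j] <- best; back[k, j] <- bi
    }
  }
  ends <- integer(k_max); ends[k_max] <- n
  if (k_max > 1) for (k in k_max:2) ends[k - 1] <- back[k, ends[k]]
  starts <- c(1L, head(ends, -1) + 1L)
  tibble::tibble(start = starts, end = ends,
                 seg_mean = vapply(seq_len(k_max),
                                   function(k) mean(x[starts[k]:ends[k]]),
                                   numeric(1)))
}
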