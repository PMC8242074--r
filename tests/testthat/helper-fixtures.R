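# shared in-code fixtures; nothing is read from disk

# single-chromosome bin table with constant-width bins
toy_bins <- function(n, chrom = "1", width = 1e6, gc = NULL) {
  genome_bins(tibble::tibble(
    chrom = chrom,
    start = (seq_len(n) - 1) * width,
    end = seq_len(n) * width,
    gc = gc %||% rep(0.45, n)))
}

# bare profile tibble for direct MAPD / segmentation tests
toy_profile <- function(x, chrom = "1", sample_id = "s1") {
  tibble::tibble(sample_id = sample_id, bin = seq_along(x),
                 chrom = chrom, gc = 0.45, count = 100, x = x, mask = TRUE)
}

# memoized mid-size test genome (scale 0.25, ~770 bins)
test_genome <- local({
  cache <- new.env(parent = emptyenv())
  function(scale = 0.25, seed = 11L) {
    key <- paste0("g", scale, "_", seed)
    if (is.null(cache[[key]])) cache[[key]] <- make_genome(scale, seed = seed)
    cache[[key]]
  }
})

# segment table row constructor
seg_row <- function(sample_id, chrom, start_bin, end_bin, seg_mean) {
  tibble::tibble(sample_id = sample_id, chrom = chrom,
                 start_bin = as.integer(start_bin),
                 end_bin = as.integer(end_bin),
                 n_bins = as.integer(end_bin - start_bin + 1L),
                 seg_mean = seg_mean)
}
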