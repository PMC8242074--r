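test_that("make_genome tiles hg19-proportional chromosomes into 1 Mb bins", {
  g <- make_genome(scale = 1, seed = 4)
  expect_equal(length(unique(g$chrom)), 24)
  # hg19 total ~3.1 Gb -> ~3,100 bins at 1 Mb
  expect_gte(nrow(g), 2700)
  expect_lte(nrow(g), 3100)
  expect_true(all(g$gc >= 0.3 & g$gc <= 0.6))
  expect_identical(make_genome(scale = 0.25, seed = 9),
                   make_genome(scale = 0.25, seed = 9))
  # a scale leaving any chromosome under 10 bins is refused
  expect_error(make_genome(scale = 0.05), "fewer than 10 bins")
})

test_that("simulated flat diploid counts match the expected depth per bin", {
  # 2,860 autosomal bins, no GC bias: expectation 1e6/2860 per bin
  bins <- genome_bins(tibble::tibble(
    chrom = rep(as.character(1:22), each = 130),
    start = rep((0:129) * 1e6, 22), end = rep((1:130) * 1e6, 22),
    gc = 0.45))
  sim <- simulate_sample(bins, sex = "female", depth = 1e6,
                         gc_bias = c(1, 0, 0), dispersion = 0, seed = 21)
  expect_equal(mean(sim$counts$count), 1e6 / 2860, tolerance = 5 * 2860 / 1e6)
  # expected-count conservation is exact by construction
  expect_equal(sum(sim$truth$mu), 1e6, tolerance = 1e-9)
})

test_that("an injected CN 3 event scales expected counts by 3/2", {
  bins <- test_genome()
  ev <- cna_events("2", 10, 59, 3)
  sim <- simulate_sample(bins, sex = "female", depth = 1e6,
                         gc_bias = c(1, 0, 0), dispersion = 0,
                         events = ev, seed = 8)
  off <- min(bins$bin[bins$chrom == "2"]) - 1L
  in_ev <- sim$counts$count[(off + 10):(off + 59)]
  genome_med <- median(sim$counts$count[true_cn(bins, "female", NULL) == 2])
  expect_equal(mean(in_ev) / genome_med, 1.5, tolerance = 0.05)
})

test_that("dispersion raises MAPD", {
  bins <- test_genome()
  m <- sapply(c(0, 0.02), function(phi) {
    median(sapply(1:20, function(r) {
      sim <- simulate_sample(bins, depth = 2.5e5, dispersion = phi,
                             seed = 100 + r)
      compute_mapd(gc_normalize(sim$counts, bins))$mapd
    }))
  })
  expect_gt(m[2], m[1])
})

test_that("simulation is deterministic under a fixed seed", {
  bins <- test_genome()
  a <- simulate_sample(bins, seed = 5)$counts$count
  b <- simulate_sample(bins, seed = 5)$counts$count
  c <- simulate_sample(bins, seed = 6)$counts$count
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("noiseless high-depth samples recover true CN after normalization", {
  bins <- test_genome()
  ev <- cna_events(c("3", "5"), c(5, 20), c(30, 44), c(3, 1))
  sim <- simulate_sample(bins, sex = "male", depth = 1e8, dispersion = 0,
                         events = ev, seed = 13)
  prof <- gc_normalize(sim$counts, bins)
  cn <- true_cn(bins, "male", ev)
  ok <- prof$mask
  # within 2% of a diploid copy (0.04 CN units) per bin
  expect_lt(max(abs(prof$x[ok] - cn[ok])), 0.05)
})

test_that("sex baselines and impossible events are enforced", {
  bins <- test_genome()
  cn_f <- true_cn(bins, "female")
  cn_m <- true_cn(bins, "male")
  expect_equal(unique(cn_f[bins$chrom == "X"]), 2)
  expect_equal(unique(cn_f[bins$chrom == "Y"]), 0)
  expect_equal(unique(cn_m[bins$chrom == "X"]), 1)
  expect_equal(unique(cn_m[bins$chrom == "Y"]), 1)
  expect_error(true_cn(bins, "female", cna_events("Y", 1, 5, 2)), "female")
  expect_error(cna_events("1", c(1, 5), c(10, 12), c(3, 1)), "overlap")
})

test_that("calibrate_dispersion hits targets and reports the Poisson floor", {
  bins <- test_genome()
  phi <- calibrate_dispersion(0.20, bins, depth = 2.5e5, n_reps = 11,
                              seed = 77)
  expect_gte(attr(phi, "achieved_mapd"), 0.18)
  expect_lte(attr(phi, "achieved_mapd"), 0.22)
  expect_error(calibrate_dispersion(0.01, bins, depth = 2.5e5, n_reps = 5,
                                    seed = 78),
               "Poisson floor")
})

test_that("simulate_cohort wires groups, tissues and shared truths", {
  bins <- test_genome()
  co <- simulate_cohort(bins, n_of = 2, n_fd = 2, n_os = 1,
                        depth = 2e5, seed = 3)
  sheet <- co$samples
  expect_setequal(unique(sheet$group), c("FD", "normal", "OF", "OS"))
  # FD-like lesional samples are event-free
  fd_samples <- sheet$sample_id[sheet$group == "FD"]
  expect_false(any(co$truth$events$sample_id %in% fd_samples))
  # normal-tissue samples are always event-free
  norm_samples <- sheet$sample_id[sheet$tissue == "normal"]
  expect_false(any(co$truth$events$sample_id %in% norm_samples))
  # lesional samples of one OF patient share one event list
  of1 <- sheet$sample_id[sheet$patient_id == "OF01" & sheet$tissue != "normal"]
  evs <- lapply(of1, function(s) {
    e <- co$truth$events[co$truth$events$sample_id == s,
                         c("chrom", "start_bin", "end_bin", "cn")]
    e[order(e$chrom, e$start_bin), ]
  })
  expect_equal(evs[[1]], evs[[2]])
  # OS-like patients carry events on many distinct chromosomes
  os_ev <- co$truth$events[co$truth$events$patient_id == "OS01", ]
  expect_gte(length(unique(os_ev$chrom)), 8)
  # true CN is consistent with the event lists
  s1 <- of1[1]
  cn <- co$truth$cn$cn[co$truth$cn$sample_id == s1]
  ev1 <- co$truth$events[co$truth$events$sample_id == s1, ]
  expect_equal(cn, true_cn(bins, sheet$sex[sheet$sample_id == s1], ev1))
})
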