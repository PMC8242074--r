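test_that("CNAscore is zero for a neutral genome and matches hand examples", {
  # flat diploid: autosomes 2, X 2 (female), no Y segments
  flat <- dplyr::bind_rows(lapply(c(as.character(1:22), "X"), function(ch) {
    seg_row("s", ch, 1, 10, 2)
  }))
  expect_equal(cna_score_total(flat, "female")$cna_score, 0)
  # one chromosome, segments 2 and 3: 1 + 0.5 * |2.5 - 2| = 1.25
  two <- seg_row("s", "1", c(1, 51), c(50, 100), c(2, 3))
  expect_equal(cna_score_total(two, "female")$cna_score, 1.25,
               tolerance = 1e-12)
  # two chromosomes, one segment each at 3: 0.5 + 0.5
  gains <- seg_row("s", c("1", "2"), 1, 10, 3)
  expect_equal(cna_score_total(gains, "female")$cna_score, 1, tolerance = 1e-12)
  expect_error(cna_score(two[0, ], "female"), "empty profile")
})

test_that("CNAscore totals add over chromosome terms", {
  set.seed(70)
  segs <- dplyr::bind_rows(lapply(as.character(1:8), function(ch) {
    seg_row("s", ch, c(1, 21), c(20, 45), 2 + runif(2, -1, 1))
  }))
  per <- cna_score(segs, "male")
  expect_equal(sum(per$term), cna_score_total(segs, "male")$cna_score,
               tolerance = 1e-9)
  expect_true(all(per$jump >= 0 & per$deviation >= 0))
})

test_that("haploid chromosomes use norm 1 and female Y contributes nothing", {
  xseg <- seg_row("s", "X", 1, 10, 1)
  expect_equal(cna_score_total(xseg, "male")$cna_score, 0)
  expect_equal(cna_score_total(xseg, "female")$cna_score, 0.5)
  yseg <- seg_row("s", "Y", 1, 10, 0)
  expect_equal(cna_score_total(yseg, "female")$cna_score, 0)
})

test_that("length weighting tames a focal supergain's deviation term", {
  segs <- seg_row("s", "12", c(1, 51, 59), c(50, 58, 120), c(2, 9.4, 2))
  unw <- cna_score_total(segs, "female")$cna_score
  wt <- cna_score_total(segs, "female", weighted = TRUE)$cna_score
  expect_gt(unw, wt)
})

test_that("gain/loss calls follow the strict printed thresholds", {
  segs <- seg_row("s", "1", c(1, 11, 21), c(10, 20, 30), c(2.5, 1.6, 2.3))
  calls <- call_segments(segs, "female")
  expect_equal(calls$state, c("gain", "loss"))
  # boundary values are not calls (strict inequalities)
  bnd <- seg_row("s", "2", c(1, 11), c(10, 20), c(2.4, 1.7))
  expect_equal(nrow(call_segments(bnd, "female")), 0)
  # haploid rules on male X
  mx <- seg_row("s", "X", c(1, 11), c(10, 20), c(1.5, 0.4))
  mcalls <- call_segments(mx, "male")
  expect_equal(mcalls$state, "loss")
  expect_equal(mcalls$ploidy_class, "haploid")
  # female Y is never called
  fy <- seg_row("s", "Y", 1, 10, 1.8)
  expect_equal(nrow(call_segments(fy, "female")), 0)
  # short segments are not called
  short <- seg_row("s", "3", 1, 3, 5)
  expect_equal(nrow(call_segments(short, "female")), 0)
})

test_that("sample and patient status aggregate calls correctly", {
  calls <- seg_row("s1", "1", 1, 10, 3)
  calls$state <- "gain"
  st <- sample_status(calls, c("s1", "s2"))
  expect_equal(st$cna_positive, c(TRUE, FALSE))

  samples <- tibble::tibble(
    sample_id = c("s1", "s2", "s3", "s4"),
    patient_id = c("p1", "p1", "p1", "p2"),
    tissue = c("fibrous", "calcified", "normal", "fibrous"),
    sex = "female", group = "OF")
  st <- sample_status(calls, c("s1", "s2", "s3", "s4"))
  ps <- patient_status(st, samples)
  expect_equal(ps$cna_positive[ps$patient_id == "p1"], TRUE)
  expect_equal(ps$cna_positive[ps$patient_id == "p2"], FALSE)
  # stricter positivity threshold
  ps2 <- patient_status(st, samples, min_positive_samples = 2)
  expect_equal(ps2$cna_positive[ps2$patient_id == "p1"], FALSE)
  # a normal-tissue call never flips a patient
  ncall <- calls; ncall$sample_id <- "s3"
  stn <- sample_status(ncall, c("s1", "s2", "s3"))
  stn$cna_positive[stn$sample_id != "s3"] <- FALSE
  expect_equal(patient_status(stn, samples[1:3, ])$cna_positive, FALSE)
  # no QC-passed lesional samples -> indeterminate
  ps3 <- patient_status(sample_status(calls[0, ], "s3"), samples[1:3, ])
  expect_true(is.na(ps3$cna_positive))
})

test_that("adding a gain never decreases the expected CNAscore", {
  bins <- test_genome()
  base <- ev_scores <- numeric(20)
  ev <- cna_events("8", 5, 24, 3)
  for (r in 1:20) {
    s0 <- simulate_sample(bins, depth = 2.5e5, dispersion = 0.002,
                          seed = 400 + r)
    s1 <- simulate_sample(bins, depth = 2.5e5, dispersion = 0.002,
                          events = ev, seed = 400 + r)
    cfg <- cbs_config(seed = 500 + r)
    base[r] <- cna_score_total(
      cbs_segment(gc_normalize(s0$counts, bins), bins, cfg), "female")$cna_score
    ev_scores[r] <- cna_score_total(
      cbs_segment(gc_normalize(s1$counts, bins), bins, cfg), "female")$cna_score
  }
  expect_gt(mean(ev_scores), mean(base))
})
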