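make_call <- function(sample_id, chrom, s, e, state, mean = 3) {
  out <- seg_row(sample_id, chrom, s, e, mean)
  out$state <- state
  out
}

test_that("recurrence fractions count covering samples per bin", {
  bins <- toy_bins(200)
  expect_error(recurrence_profile(tibble::tibble(), bins, character()),
               "at least one sample")
  none <- recurrence_profile(make_call("s", "1", 1, 5, "gain")[0, ], bins,
                             c("a", "b"))
  expect_true(all(none$gain_frac == 0 & none$loss_frac == 0))
  calls <- dplyr::bind_rows(make_call("a", "1", 100, 150, "gain"),
                            make_call("b", "1", 100, 150, "gain"),
                            make_call("b", "1", 10, 20, "loss", 1))
  rec <- recurrence_profile(calls, bins, c("a", "b", "c", "d"))
  expect_equal(unique(rec$gain_frac[100:150]), 0.5)
  expect_equal(unique(rec$gain_frac[-(100:150)]), 0)
  expect_equal(unique(rec$loss_frac[10:20]), 0.25)
  expect_true(all(rec$gain_frac >= 0 & rec$gain_frac <= 1))
  expect_equal(unique(rec$n_units), 4)
})

test_that("patient-level recurrence deduplicates a patient's samples", {
  bins <- toy_bins(50)
  samples <- tibble::tibble(sample_id = c("a1", "a2", "b1"),
                            patient_id = c("pa", "pa", "pb"),
                            tissue = "fibrous", sex = "female", group = "OF")
  calls <- dplyr::bind_rows(make_call("a1", "1", 5, 10, "gain"),
                            make_call("a2", "1", 5, 10, "gain"),
                            make_call("b1", "1", 5, 10, "gain"))
  rec <- recurrence_profile(calls, bins, samples$sample_id, samples,
                            by = "patient")
  expect_equal(unique(rec$gain_frac[5:10]), 1)  # 2 of 2 patients
  expect_equal(unique(rec$n_units), 2)
})

test_that("smallest common region matches the endpoint-sweep example", {
  iv <- tibble::tibble(patient_id = c("a", "b", "c"),
                       start_bin = c(10, 20, 5), end_bin = c(60, 80, 55))
  scr <- smallest_common_region(iv)
  expect_equal(scr$start_bin, 20)
  expect_equal(scr$end_bin, 55)
  expect_equal(scr$n_patients, 3)
  # identical intervals come back unchanged
  same <- tibble::tibble(patient_id = c("a", "b"), start_bin = 7, end_bin = 30)
  scr2 <- smallest_common_region(same)
  expect_equal(c(scr2$start_bin, scr2$end_bin), c(7, 30))
  # disjoint intervals from two patients: empty result, not an error
  dis <- tibble::tibble(patient_id = c("a", "b"),
                        start_bin = c(1, 50), end_bin = c(10, 60))
  expect_equal(nrow(smallest_common_region(dis)), 0)
})

test_that("hotspot regions lie inside every supporting interval", {
  set.seed(81)
  samples <- tibble::tibble(sample_id = paste0("s", 1:4),
                            patient_id = paste0("p", 1:4),
                            tissue = "fibrous", sex = "female", group = "OF")
  calls <- dplyr::bind_rows(lapply(1:4, function(k) {
    s <- sample(10:20, 1)
    make_call(paste0("s", k), "7", s, s + sample(20:30, 1), "loss", 1)
  }))
  hs <- find_hotspots(calls, samples)
  expect_equal(nrow(hs), 1)
  sup <- hs$patients[[1]]
  iv <- calls[match(paste0("s", sub("p", "", sup)), calls$sample_id), ]
  expect_true(all(hs$start_bin >= iv$start_bin & hs$end_bin <= iv$end_bin))
})

test_that("pattern concordance is a direction-matched Jaccard index", {
  a <- make_call("a", "1", 1, 100, "gain")
  b <- make_call("b", "1", 51, 150, "gain")
  expect_equal(as.numeric(pattern_concordance(a, b)), 50 / 150)
  expect_equal(as.numeric(pattern_concordance(a, a)), 1)
  expect_equal(as.numeric(pattern_concordance(a, b)),
               as.numeric(pattern_concordance(b, a)))
  dis <- make_call("b", "2", 1, 10, "loss", 1)
  expect_equal(as.numeric(pattern_concordance(a, dis)), 0)
  # same bins, opposite direction: shared 0, union counted once per bin
  flip <- make_call("b", "1", 1, 100, "loss", 1)
  expect_equal(as.numeric(pattern_concordance(a, flip)), 0)
  empty <- a[0, ]
  both <- pattern_concordance(empty, empty)
  expect_equal(as.numeric(both), 1)
  expect_true(attr(both, "both_negative"))
})

test_that("score distributions summarise groups against the normal ceiling", {
  scores <- tibble::tibble(sample_id = paste0("s", 1:9),
                           cna_score = c(1, 2, 3, 1, 1, 1, 2, 2.5, 4))
  groups <- setNames(rep(c("OF", "normal", "FD"), each = 3), paste0("s", 1:9))
  sd1 <- score_distributions(scores, groups)
  expect_equal(attr(sd1, "cutoff"), 1)  # max of normal group
  of <- sd1[sd1$group == "OF", ]
  expect_equal(of$median, 2)
  expect_equal(of$frac_above, 2 / 3)
  # explicit cutoff
  sd2 <- score_distributions(scores[1:3, ], c(s1 = "g", s2 = "g", s3 = "g"),
                             cutoff = 2.5)
  expect_equal(sd2$frac_above, 1 / 3)
  expect_equal(sd2$min, 1); expect_equal(sd2$max, 3)
})

test_that("patient flags encode hotspot pattern and genome complexity", {
  samples <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                            patient_id = c("p1", "p2", "p3"),
                            tissue = "fibrous", sex = "female", group = "OF")
  scores <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                           cna_score = c(3, 1, 5))
  # chromosome 12 supergain only
  c1 <- make_call("s1", "12", 5, 12, "gain", 9.4)
  # no calls; events on 9 chromosomes
  c3 <- dplyr::bind_rows(lapply(as.character(1:9), function(ch)
    make_call("s3", ch, 1, 15, "gain")))
  flags <- classify_patients(dplyr::bind_rows(c1, c3), scores, samples)
  f1 <- flags[flags$patient_id == "p1", ]
  expect_true(f1$cna_positive && f1$chr7_or_chr12_pattern)
  expect_false(f1$genome_complexity)
  f2 <- flags[flags$patient_id == "p2", ]
  expect_false(f2$cna_positive)
  expect_match(f2$label, "does not rule out")
  f3 <- flags[flags$patient_id == "p3", ]
  expect_true(f3$genome_complexity)
})

test_that("tidiers and plots expose results in standard shapes", {
  prof <- toy_profile(c(rep(2, 60), rep(3.5, 60)))
  segs <- cbs_segment(prof, config = cbs_config(seed = 17))
  td <- tidy(segs, bins = toy_bins(120))
  expect_true(all(c("start", "end") %in% names(td)))
  gl <- glance(segs)
  expect_equal(gl$n_segments, nrow(segs))
  sc <- cna_score(segs, "female")
  expect_equal(glance(sc)$cna_score, sum(tidy(sc)$term))
  expect_s3_class(plot_profile(prof, segs), "ggplot")
  expect_s3_class(autoplot(segs), "ggplot")
  rec <- recurrence_profile(make_call("s1", "1", 10, 30, "gain"),
                            toy_bins(120), "s1")
  expect_s3_class(plot_recurrence(rec), "ggplot")
  expect_s3_class(
    plot_score_distributions(tibble::tibble(sample_id = c("a", "b"),
                                            cna_score = c(1, 2)),
                             c(a = "OF", b = "FD")), "ggplot")
})

test_that("run_pipeline is deterministic and recovers a small cohort", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  bins <- test_genome(scale = 0.3, seed = 19)
  res1 <- run_pipeline(out1, bins = bins,
                       sim = list(n_of = 1, n_fd = 1, depth = 3e5,
                                  dispersion = 0.002),
                       seed = 23)
  res2 <- run_pipeline(out2, bins = bins,
                       sim = list(n_of = 1, n_fd = 1, depth = 3e5,
                                  dispersion = 0.002),
                       seed = 23)
  files <- c("qc.tsv", "segments.seg", "calls.tsv", "cnascore.tsv",
             "recurrence.tsv", "hotspots.tsv", "flags.json", "run_log.tsv")
  for (f in files) {
    expect_true(file.exists(file.path(out1, f)))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)),
                     label = paste("contents of", f))
  }
  # truth recovery on this toy cohort: the OF patient is positive, FD is not
  flags <- res1$flags
  expect_true(flags$cna_positive[flags$patient_id == "OF01"])
  expect_false(flags$cna_positive[flags$patient_id == "FD01"])
  # errors are stage-named
  expect_error(run_pipeline(withr::local_tempdir()), "supply either")
})
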