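#' Run the full CNA profiling pipeline
#'
#' Drives preprocess -> QC -> segmentation -> scoring/calling -> cohort
#' aggregation and writes all tabular outputs into `out_dir`: `qc.tsv`,
#' `segments.seg`, `calls.tsv`, `cnascore.tsv`, `recurrence.tsv`,
#' `hotspots.tsv`, `flags.json` and `run_log.tsv` (every parameter and
#' seed). QC failures are recorded and the failing samples excluded from
#' downstream stages, never fatal. With a fixed `seed` the run is
#' idempotent: numeric outputs are byte-identical across repeats.
#'
#' Inputs are either a precomputed cohort (`bins` + `counts` + `samples`,
#' each an object or a file path) or a synthetic cohort specification
#' `sim` (a list of arguments for [simulate_cohort()]; `bins` may then be
#' omitted to use [make_genome()] defaults).
#'
#' @param out_dir output directory (created if needed).
#' @param bins [genome_bins] tibble or BED path.
#' @param counts long count tibble or count-matrix TSV path.
#' @param samples sample sheet tibble or TSV path.
#' @param sim optional list of [simulate_cohort()] arguments.
#' @param seed integer seed governing all randomness in the run.
#' @param span,iterations LOWESS settings for [gc_normalize()].
#' @param read_floor,mapd_ceiling QC thresholds.
#' @param seg_config a [cbs_config()].
#' @param call_config a [calling_config()].
#' @param min_patients hotspot support threshold.
#' @param min_positive_samples patient-positivity threshold.
#' @return invisibly, a list with every intermediate table (`bins`,
#'   `profile`, `qc`, `segments`, `scores`, `calls`, `recurrence`,
#'   `hotspots`, `flags`, and `truth` when simulated).
#' @export
run_pipeline <- function(out_dir, bins = NULL, counts = NULL, samples = NULL,
                         sim = NULL, seed = 1L, span = 0.3, iterations = 3L,
                         read_floor = 1e5, mapd_ceiling = 0.23,
                         seg_config = cbs_config(),
                         call_config = calling_config(),
                         min_patients = 2L, min_positive_samples = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  truth <- NULL
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  if (!is.null(sim)) {
    if (is.null(bins)) bins <- make_genome(scale = sim$scale %||% 0.3,
                                           seed = seed)
    sim$scale <- NULL
    sim$bins <- if (is.character(bins)) read_bins(bins) else genome_bins(bins)
    if (is.null(sim$seed)) sim$seed <- seed
    cohort <- stage("simulate", do.call(simulate_cohort, sim))
    bins <- sim$bins; counts <- cohort$counts; samples <- cohort$samples
    truth <- cohort$truth
  } else {
    if (is.null(bins) || is.null(counts) || is.null(samples)) {
      abort("supply either `sim` or all of bins, counts, samples")
    }
    if (is.character(bins)) bins <- read_bins(bins)
    bins <- genome_bins(bins)
    if (is.character(counts)) counts <- read_counts(counts, bins)
    if (is.character(samples) || is.data.frame(samples)) {
      samples <- read_sample_sheet(samples)
    }
  }

  profile <- stage("preprocess",
                   gc_normalize(counts, bins, span = span,
                                iterations = iterations))
  qc <- stage("qc", qc_metrics(profile, read_floor = read_floor,
                               mapd_ceiling = mapd_ceiling))
  passed <- qc$sample_id[qc$passed]
  if (!length(passed)) abort("pipeline stage 'qc' failed: no sample passed QC")
  prof_ok <- profile[profile$sample_id %in% passed, , drop = FALSE]
  segments <- stage("segmentation", cbs_segment(prof_ok, bins, seg_config))
  scores <- stage("scoring", cna_score_total(segments, samples))
  calls <- stage("calling", call_segments(segments, samples, call_config))
  recurrence <- stage("cohort", recurrence_profile(calls, bins, passed))
  hotspots <- stage("cohort", find_hotspots(calls, samples, min_patients))
  flags <- stage("cohort", classify_patients(
    calls, scores, samples, min_positive_samples = min_positive_samples))

  readr::write_tsv(qc, file.path(out_dir, "qc.tsv"))
  write_segments(segments, bins, file.path(out_dir, "segments.seg"))
  readr::write_tsv(calls, file.path(out_dir, "calls.tsv"))
  readr::write_tsv(scores, file.path(out_dir, "cnascore.tsv"))
  readr::write_tsv(recurrence, file.path(out_dir, "recurrence.tsv"))
  hs <- hotspots
  hs$patients <- vapply(hs$patients, paste, "", collapse = ",")
  readr::write_tsv(hs, file.path(out_dir, "hotspots.tsv"))
  jsonlite::write_json(flags, file.path(out_dir, "flags.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  log <- tibble::tibble(
    key = c("seed", "span", "iterations", "read_floor", "mapd_ceiling",
            "alpha", "min_width", "undo_sd", "nperm", "scale",
            "diploid_gain", "diploid_loss", "haploid_gain", "haploid_loss",
            "min_call_bins", "min_patients", "min_positive_samples",
            "n_samples", "n_passed"),
    value = as.character(c(seed, span, iterations, read_floor, mapd_ceiling,
                           seg_config$alpha, seg_config$min_width,
                           seg_config$undo_sd, seg_config$nperm,
                           seg_config$scale, call_config$diploid_gain,
                           call_config$diploid_loss, call_config$haploid_gain,
                           call_config$haploid_loss,
                           call_config$min_call_bins, min_patients,
                           min_positive_samples, length(unique(qc$sample_id)),
                           length(passed))))
  readr::write_tsv(log, file.path(out_dir, "run_log.tsv"))
  if (!is.null(truth)) {
    jsonlite::write_json(truth$events, file.path(out_dir, "truth_events.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(bins = bins, samples = samples, profile = profile, qc = qc,
                 segments = segments, scores = scores, calls = calls,
                 recurrence = recurrence, hotspots = hotspots, flags = flags,
                 truth = truth, out_dir = out_dir))
}
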