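#' Construct a table of copy-number alteration events
#'
#' Events are rectangles of altered copy number on one chromosome,
#' addressed in per-chromosome bin indices (1-based, inclusive). `cn` is
#' the true copy number of the region (1 = one-copy loss on a diploid
#' chromosome, 3 = single-copy gain, values near 10 = focal supergain).
#' Events belonging to one sample must not overlap.
#'
#' @param chrom,start_bin,end_bin,cn event fields (recycled to a common
#'   length).
#' @return tibble with columns `chrom`, `start_bin`, `end_bin`, `cn`.
#' @export
cna_events <- function(chrom = character(), start_bin = integer(),
                       end_bin = integer(), cn = numeric()) {
  ev <- tibble::tibble(chrom = normalize_chrom(chrom, strict = TRUE),
                       start_bin = as.integer(start_bin),
                       end_bin = as.integer(end_bin), cn = as.numeric(cn))
  if (any(ev$end_bin < ev$start_bin)) abort("event end_bin < start_bin")
  if (any(ev$cn < 0)) abort("event copy number must be nonnegative")
  for (ch in unique(ev$chrom)) {
    e <- ev[ev$chrom == ch, , drop = FALSE]
    e <- e[order(e$start_bin), , drop = FALSE]
    if (nrow(e) > 1 && any(e$start_bin[-1] <= e$end_bin[-nrow(e)])) {
      abort(paste0("events overlap on chromosome ", ch))
    }
  }
  ev
}

chrom_offsets <- function(bins) {
  off <- bins |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(first = min(.data$bin), n = dplyr::n(), .groups = "drop")
  setNames(split(off[, c("first", "n")], seq_len(nrow(off))), off$chrom)
}

#' True per-bin copy number implied by sex and events
#'
#' Baseline is the sex-determined neutral ploidy per chromosome
#' (autosomes 2; male X/Y 1; female X 2, Y 0) with events overlaid.
#'
#' @param bins a [genome_bins] tibble.
#' @param sex sample sex.
#' @param events a [cna_events()] tibble (or `NULL`).
#' @return numeric vector of true copy numbers aligned to `bins`.
#' @export
true_cn <- function(bins, sex = "female", events = NULL) {
  bins <- genome_bins(bins)
  cn <- expected_ploidy(sex, bins$chrom, quiet = TRUE)
  cn[is.na(cn)] <- 0
  if (!is.null(events) && nrow(events)) {
    events <- cna_events(events$chrom, events$start_bin, events$end_bin, events$cn)
    if (sex == "female" && any(events$chrom == "Y")) {
      abort("events on chromosome Y are impossible in a female sample")
    }
    off <- chrom_offsets(bins)
    for (k in seq_len(nrow(events))) {
      ch <- events$chrom[k]
      if (is.null(off[[ch]])) abort(paste0("event on chromosome ", ch, " absent from bins"))
      first <- off[[ch]]$first; nb <- off[[ch]]$n
      if (events$end_bin[k] > nb) {
        abort(paste0("event exceeds chromosome ", ch, " (", nb, " bins)"))
      }
      idx <- (first + events$start_bin[k] - 1):(first + events$end_bin[k] - 1)
      cn[idx] <- events$cn[k]
    }
  }
  cn
}

# quadratic multiplicative GC bias b(gc) = a0 + a1*gc + a2*gc^2
gc_bias_curve <- function(gc, coef) {
  b <- coef[1] + coef[2] * gc + coef[3] * gc^2
  if (any(b <= 0)) abort("gc bias curve must be strictly positive over the gc range")
  b
}

#' Default GC bias curve coefficients
#'
#' A mild unimodal quadratic peaking near GC 0.45
#' (b(gc) = 1.2 - 3*(gc - 0.45)^2), strictly positive on \[0, 1\] —
#' the smooth multiplicative bias LOWESS normalization is built to remove.
#' Use `c(1, 0, 0)` for no bias.
#'
#' @return numeric coefficient vector (intercept, linear, quadratic).
#' @export
default_gc_bias <- function() c(0.5925, 2.7, -3)

#' Simulate shallow-WGS bin counts for one sample
#'
#' Counts follow a Gamma-Poisson (negative binomial) model: bin `i` has
#' expectation `depth * w_i * (cn_i / 2) * b(gc_i) / Z` with `Z` chosen so
#' expected counts sum exactly to `depth` (~1e6 mapped reads emulates the
#' study's ~0.1x coverage), and extra-Poisson spread controlled by a single
#' `dispersion` parameter (variance `mu + dispersion * mu^2`;
#' `dispersion = 0` gives pure Poisson). Dispersion is the knob that moves
#' the profile's MAPD.
#'
#' @param bins a [genome_bins] tibble.
#' @param sex sample sex ("male" / "female").
#' @param depth expected total mapped reads.
#' @param gc_bias quadratic bias coefficients (see [default_gc_bias()]).
#' @param dispersion negative-binomial over-dispersion (>= 0).
#' @param events a [cna_events()] tibble or `NULL`.
#' @param sample_id label for the returned counts.
#' @param seed optional integer seed (otherwise uses the current RNG
#'   stream).
#' @return list with `counts` (tibble `sample_id`, `bin`, `count`) and
#'   `truth` (list: `events`, `cn` per-bin true copy number,
#'   `nominal_mapd` of the noise regime, `mu` expected counts).
#' @export
simulate_sample <- function(bins, sex = "female", depth = 1e6,
                            gc_bias = default_gc_bias(), dispersion = 0.0033,
                            events = NULL, sample_id = "sim", seed = NULL) {
  bins <- genome_bins(bins)
  stopifnot(depth > 0, dispersion >= 0)
  if (!is.null(seed)) set.seed(seed)
  cn <- true_cn(bins, sex, events)
  b <- gc_bias_curve(bins$gc, gc_bias)
  raw <- bins$weight * (cn / 2) * b
  if (sum(raw) <= 0) abort("degenerate simulation: zero total expectation")
  mu <- depth * raw / sum(raw)
  count <- if (dispersion == 0) rpois(length(mu), mu)
           else rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  mean_pos <- mean(mu[mu > 0])
  nominal_mapd <- sqrt(2) * stats::qnorm(0.75) * 2 *
    sqrt(1 / mean_pos + dispersion)
  counts <- tibble::tibble(sample_id = sample_id, bin = bins$bin, count = count)
  attr(counts, "total_mapped") <- sum(count)
  list(counts = counts,
       truth = list(events = events %||% cna_events(), cn = cn,
                    nominal_mapd = nominal_mapd, mu = mu))
}

#' Calibrate dispersion to a target MAPD
#'
#' Monotone bisection: simulates event-free samples at candidate
#' dispersions, normalizes them, and measures the median MAPD over
#' `n_reps` replicates until it lands within `tol` (relative) of
#' `target_mapd`. Targets below the Poisson floor (the MAPD of a
#' zero-dispersion sample at this depth) are unattainable and raise an
#' error stating the floor.
#'
#' @param target_mapd desired median MAPD (> 0).
#' @inheritParams simulate_sample
#' @param n_reps replicates per evaluation (>= 20 recommended).
#' @param tol relative tolerance on the achieved median MAPD.
#' @param max_iter bisection iterations.
#' @return the calibrated dispersion, with attribute `achieved_mapd`.
#' @export
calibrate_dispersion <- function(target_mapd, bins, sex = "female",
                                 depth = 1e6, gc_bias = default_gc_bias(),
                                 n_reps = 21L, tol = 0.05, max_iter = 40L,
                                 seed = NULL) {
  stopifnot(target_mapd > 0)
  bins <- genome_bins(bins)
  if (!is.null(seed)) set.seed(seed)
  eval_mapd <- function(phi) {
    m <- vapply(seq_len(n_reps), function(r) {
      sim <- simulate_sample(bins, sex = sex, depth = depth,
                             gc_bias = gc_bias, dispersion = phi)
      prof <- gc_normalize(sim$counts, bins)
      compute_mapd(prof)$mapd
    }, numeric(1))
    median(m)
  }
  floor_mapd <- eval_mapd(0)
  if (target_mapd <= floor_mapd * (1 - tol)) {
    abort(paste0("target MAPD ", target_mapd, " is below the Poisson floor ",
                 signif(floor_mapd, 4), " at depth ", depth,
                 "; increase the target or lower the depth"))
  }
  if (abs(floor_mapd - target_mapd) / target_mapd <= tol) {
    return(structure(0, achieved_mapd = floor_mapd))
  }
  # analytic warm start: mapd ~ sqrt(2)*qnorm(.75)*2*sqrt(1/mu + phi)
  hi <- (target_mapd / (sqrt(2) * stats::qnorm(0.75) * 2))^2
  hi <- max(hi * 2, 1e-4)
  while (eval_mapd(hi) < target_mapd && hi < 10) hi <- hi * 2
  lo <- 0
  phi <- hi / 2
  for (it in seq_len(max_iter)) {
    phi <- (lo + hi) / 2
    m <- eval_mapd(phi)
    if (abs(m - target_mapd) / target_mapd <= tol) {
      return(structure(phi, achieved_mapd = m))
    }
    if (m < target_mapd) lo <- phi else hi <- phi
  }
  structure(phi, achieved_mapd = eval_mapd(phi))
}

# ---- cohort-level simulation ------------------------------------------------

# OF-like event menu: a segmental one-copy loss on chromosome 7 and a
# short-arm single-copy gain on chromosome 12, with small per-patient jitter
# in the breakpoints (the study's patients shared similar, not identical,
# breakpoints); optionally a focal supergain nested in the chr12 gain.
of_event_menu <- function(bins, jitter = 2L, supergain = FALSE,
                          supergain_cn = 9.4) {
  off <- chrom_offsets(bins)
  n7 <- off[["7"]]$n; n12 <- off[["12"]]$n
  j <- function() sample.int(2L * jitter + 1L, 1L) - jitter - 1L
  s7 <- max(1L, round(n7 * 0.35) + j())
  e7 <- min(n7, round(n7 * 0.65) + j())
  s12 <- max(1L, 1L + abs(j()))
  e12 <- min(n12, round(n12 * 0.35) + j())
  ev <- cna_events(c("7", "12"), c(s7, s12), c(e7, e12), c(1, 3))
  if (supergain) {
    sg_len <- min(8L, max(3L, e12 - s12 - 3L))
    sg_s <- s12 + max(1L, round((e12 - s12 - sg_len) / 2))
    sg_e <- sg_s + sg_len - 1L
    ev <- dplyr::bind_rows(
      ev[ev$chrom == "7", ],
      cna_events("12",
                 c(s12, sg_s, sg_e + 1L),
                 c(sg_s - 1L, sg_e, e12),
                 c(3, supergain_cn, 3)))
    ev <- ev[ev$end_bin >= ev$start_bin, , drop = FALSE]
  }
  ev
}

# OS-like menu: gains/losses scattered over many chromosomes (the
# genome-complexity pattern), default 9 of chromosomes 1..10.
os_event_menu <- function(bins, n_chroms = 9L) {
  off <- chrom_offsets(bins)
  chs <- as.character(sort(sample(1:10, n_chroms)))
  ev <- lapply(chs, function(ch) {
    n <- off[[ch]]$n
    len <- max(10L, round(n * runif(1, 0.3, 0.6)))
    s <- sample.int(max(1L, n - len), 1L)
    cna_events(ch, s, min(n, s + len - 1L), sample(c(1, 3), 1L))
  })
  dplyr::bind_rows(ev)
}

#' Simulate a multi-patient minibulk cohort with known truth
#'
#' Patients come in three flavours mirroring the study design: "OF"-like
#' patients carry a shared chromosome 7 segmental loss plus a chromosome 12
#' short-arm gain (a configurable fraction also receive a nested focal
#' supergain, CN ~9.4); "FD"-like patients are CNA-free; "OS"-like patients
#' carry events on many (default 9) chromosomes. Every lesional sample of
#' a patient shares the patient's event set; each patient also contributes
#' an event-free normal-tissue sample. Sexes alternate male/female.
#'
#' @param bins a [genome_bins] tibble.
#' @param n_of,n_fd,n_os patients per group.
#' @param tissues lesional tissue labels sampled per patient (a normal
#'   sample is always added).
#' @param supergain_frac fraction of OF-like patients receiving a focal
#'   supergain on chromosome 12.
#' @inheritParams simulate_sample
#' @param seed integer seed (drives event jitter and counting noise).
#' @return list with `counts` (long tibble), `samples` (sample sheet
#'   tibble), `truth` (list: `events` with `patient_id`, `cn` long tibble
#'   of per-sample true copy number).
#' @export
simulate_cohort <- function(bins, n_of = 3L, n_fd = 3L, n_os = 0L,
                            tissues = c("fibrous", "calcified"),
                            supergain_frac = 1 / 3,
                            depth = 1e6, gc_bias = default_gc_bias(),
                            dispersion = 0.0033, seed = 1L) {
  bins <- genome_bins(bins)
  stopifnot(n_of >= 0, n_fd >= 0, n_os >= 0, n_of + n_fd + n_os >= 1)
  set.seed(seed)
  pats <- tibble::tibble(
    patient_id = c(sprintf("OF%02d", seq_len(n_of)),
                   sprintf("FD%02d", seq_len(n_fd)),
                   sprintf("OS%02d", seq_len(n_os))),
    group = rep(c("OF", "FD", "OS"), c(n_of, n_fd, n_os)))
  pats$sex <- rep_len(c("female", "male"), nrow(pats))
  n_sg <- if (n_of > 0) max(0L, round(n_of * supergain_frac)) else 0L
  sg_flag <- rep(FALSE, n_of)
  if (n_sg > 0) sg_flag[seq_len(n_sg)] <- TRUE
  events <- vector("list", nrow(pats))
  for (k in seq_len(nrow(pats))) {
    events[[k]] <- switch(pats$group[k],
      OF = of_event_menu(bins, supergain = sg_flag[match(pats$patient_id[k],
                                                         pats$patient_id[pats$group == "OF"])]),
      FD = cna_events(),
      OS = os_event_menu(bins))
  }
  names(events) <- pats$patient_id

  counts_l <- list(); sheet_l <- list(); cn_l <- list(); ev_l <- list()
  for (k in seq_len(nrow(pats))) {
    pid <- pats$patient_id[k]; sex <- pats$sex[k]
    tiss <- c(tissues, "normal")
    for (t in seq_along(tiss)) {
      sid <- paste0(pid, "_", tiss[t], if (tiss[t] != "normal") t else "")
      ev <- if (tiss[t] == "normal") NULL else events[[pid]]
      sim <- simulate_sample(bins, sex = sex, depth = depth, gc_bias = gc_bias,
                             dispersion = dispersion, events = ev,
                             sample_id = sid)
      counts_l[[sid]] <- sim$counts
      cn_l[[sid]] <- tibble::tibble(sample_id = sid, bin = bins$bin,
                                    cn = sim$truth$cn)
      sheet_l[[sid]] <- tibble::tibble(
        sample_id = sid, patient_id = pid, tissue = tiss[t], sex = sex,
        group = if (tiss[t] == "normal") "normal" else pats$group[k])
      if (!is.null(ev) && nrow(ev)) {
        ev_l[[sid]] <- dplyr::mutate(ev, sample_id = sid, patient_id = pid,
                                     .before = 1)
      }
    }
  }
  list(counts = dplyr::bind_rows(counts_l),
       samples = read_sample_sheet(dplyr::bind_rows(sheet_l)),
       truth = list(events = dplyr::bind_rows(ev_l),
                    patient_events = events,
                    cn = dplyr::bind_rows(cn_l)))
}
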