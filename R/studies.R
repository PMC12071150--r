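#' Reference four-population study design
#'
#' The simulated counterpart of the admixed-cattle sampling design: a deeply
#' diverged outgroup (buffalo-like), a wild donor (banteng/gaur-like, with
#' private fixed differences), a reference domestic ancestry (Indian
#' indicine-like) and an admixed target (Hunan-like).
#'
#' @return Data frame of population parameters for [sim_config()].
#' @export
study_populations <- function() {
  data.frame(name = c("OUT", "WILD", "IND", "HN"),
             n = c(15, 15, 20, 20),
             f = c(0.7, 0.5, 0.025, 0.025),
             fixed_diff = c(0.10, 0.05, 0, 0),
             stringsAsFactors = FALSE)
}

#' ROH detection / classification / FROH recovery study
#'
#' Simulates one 5 Mb chromosome for `n_samples` diploids (sites ascertained
#' to those polymorphic in the sample, as in a real variant panel; a high
#' mosaic switch rate keeps background founder-IBD negligible), plants one
#' autozygous segment per sample from three log-length classes centred at
#' 0.2, 1 and ~4 Mb, and measures detection boundary error, mixture-mean
#' recovery, classification accuracy against the planted labels and
#' per-sample FROH error against the planted autozygous fraction.
#'
#' @param seed Integer seed.
#' @param per_class Segments (= samples) per length class (default 300).
#' @return List of summary metrics (`n_segments`, `boundary_err_max_bp`,
#'   `scan_window_bp`, `mixture_mean_err_log10`, `class_accuracy`,
#'   `froh_err_max`, `mixture`).
#' @export
roh_recovery_study <- function(seed = 1, per_class = 300) {
  classes <- data.frame(
    class = c("short", "medium", "long"), n = per_class,
    min_bp = c(10^5.18, 10^5.88, 10^6.5),
    max_bp = c(10^5.42, 10^6.12, 10^6.672))
  centers <- (log10(classes$min_bp) + log10(classes$max_bp)) / 2
  pops <- data.frame(name = "HN", n = 3 * per_class, f = 0.02)
  sim <- simulate_panel(sim_config(5e6, 20000, pops, switch_rate = 1e-4,
                                   seed = seed))
  pan <- sim$panels$HN
  f <- site_freq(pan)$freq
  pan <- subset_sites(pan, f > 0 & f < 1)
  pl <- plant_autozygosity(pan, classes, seed = seed + 1,
                           samples = pan$sample_ids)
  segs <- detect_roh_all(pl$panel)
  truth <- pl$truth$autozygous_segments
  m <- merge(segs, truth, by = "sample", suffixes = c("", ".t"))
  m <- m[m$start0 < m$end0.t & m$end0 > m$start0.t, , drop = FALSE]
  boundary_err <- pmax(abs(m$start0 - m$start0.t), abs(m$end0 - m$end0.t))
  mix <- fit_length_mixture(segs$length, seed = seed)
  cl <- classify_roh(segs, mix)
  m2 <- merge(cl, truth, by = "sample", suffixes = c("", ".t"))
  m2 <- m2[m2$start0 < m2$end0.t & m2$end0 > m2$start0.t, , drop = FALSE]
  fr <- froh(segs, pl$panel$chrom_length)
  planted <- (truth$end0 - truth$start0) / pl$panel$chrom_length
  names(planted) <- truth$sample
  scan_window_bp <- 100 * pl$panel$chrom_length / n_sites(pl$panel)
  list(n_segments = nrow(segs),
       n_matched = nrow(m),
       boundary_err_max_bp = max(boundary_err),
       scan_window_bp = scan_window_bp,
       mixture_mean_err_log10 = max(abs(mix$means - centers)),
       class_accuracy = mean(m2$class == m2$class.t),
       froh_err_max = max(abs(fr$froh - planted[fr$sample])),
       mixture = mix)
}

#' Neutral iHS calibration study
#'
#' Simulates one neutral 10 Mb panel of 50 diploids, runs the full
#' iHS scan (MAF 0.05) and standardization in 10 derived-frequency bins,
#' and reports the per-bin fraction of |iHS| >= 2 (the two-sided normal
#' expectation is ~0.046).
#'
#' @param seed Integer seed.
#' @return List with `bin_fracs`, `overall_frac`, `n_scored`.
#' @export
ihs_neutral_study <- function(seed = 1) {
  pops <- data.frame(name = "HN", n = 50, f = 0.02)
  sim <- simulate_panel(sim_config(1e7, 20000, pops, seed = seed))
  scan <- ihs_scan(sim$panels$HN, min_mac = 5)
  std <- standardize_ihs(scan, n_bins = 10)
  fr <- tapply(abs(std$ihs) >= 2, std$bin, mean)
  list(bin_fracs = as.numeric(fr), overall_frac = mean(abs(std$ihs) >= 2),
       n_scored = nrow(std))
}

#' Planted-sweep recovery study
#'
#' For each seed, simulates a 6 Mb panel of 50 diploids, plants a 200 kb
#' sweep (carrier frequency 0.9) at the chromosome centre, and asks whether
#' the intersection of the theta-pi lower-1% candidates and the iHS top-5%
#' windows overlaps the swept interval.
#'
#' @param seeds Integer vector of replicate seeds.
#' @return List with `hits` (logical per seed) and `recovery_rate`.
#' @export
sweep_recovery_study <- function(seeds = 1:5) {
  pops <- data.frame(name = "HN", n = 50, f = 0.02)
  hits <- vapply(seeds, function(s) {
    sim <- simulate_panel(sim_config(6e6, 12000, pops, seed = s))
    sw <- plant_sweep(sim$panels$HN, 2.9e6, 3.1e6, carrier_freq = 0.9,
                      seed = s + 1000)
    pan <- sw$panel
    spec <- window_spec()
    pic <- pi_candidate_cutoff(pi_window(pan, spec = spec))
    std <- standardize_ihs(ihs_scan(pan), n_bins = 10)
    iws <- ihs_window_scan(std, spec, chrom_length = pan$chrom_length)
    inter <- candidate_intersection(pic$candidates, iws$candidates)$intervals
    nrow(intersect_intervals(
      inter, data.frame(chrom = "chr1", start0 = 2.9e6, end0 = 3.1e6))) > 0
  }, logical(1))
  list(hits = hits, recovery_rate = mean(hits))
}

dstat_z_one <- function(seed, plant) {
  sim <- simulate_panel(sim_config(4e7, 24000, study_populations(),
                                   seed = seed))
  if (plant) {
    pl <- plant_introgression(sim$panels$HN, sim$panels$WILD, n_tracts = 16,
                              tract_length = 2.5e5, recipient_freq = 1.0,
                              seed = seed + 5000, donor_name = "WILD")
    sim$panels$HN <- pl$panel
  }
  m <- merge_panels(sim$panels)
  fr <- site_frequencies(m$panel, m$popmap, c("IND", "HN", "WILD", "OUT"))
  block_jackknife(fr$freq[, 1], fr$freq[, 2], fr$freq[, 3], fr$freq[, 4],
                  fr$pos, block_size = 1e6)$z
}

#' D-statistic type-I error study (no gene flow)
#'
#' Simulates replicates of the four-population design with exchangeable
#' P1/P2 and no planted introgression, and reports the fraction of block-
#' jackknife |Z| scores above 3.
#'
#' @param seeds Integer vector of replicate seeds (200 by default).
#' @return List with `z` (vector), `rate_abs_z_gt3`.
#' @export
dstat_null_study <- function(seeds = 1:200) {
  z <- vapply(seeds, dstat_z_one, numeric(1), plant = FALSE)
  list(z = z, rate_abs_z_gt3 = mean(abs(z) > 3))
}

#' D-statistic power study (10 percent planted donor ancestry)
#'
#' As [dstat_null_study()], but with 16 x 250 kb donor tracts planted into
#' every target haplotype (10 percent of the 40 Mb genome).
#'
#' @param seeds Integer vector of replicate seeds.
#' @return List with `z` (vector), `rate_z_gt3`.
#' @export
dstat_power_study <- function(seeds = 1:20) {
  z <- vapply(seeds, dstat_z_one, numeric(1), plant = TRUE)
  list(z = z, rate_z_gt3 = mean(z > 3))
}

#' U-scan tract recovery study
#'
#' Plants five 200 kb donor tracts at recipient frequency 0.3 into a 10 Mb
#' target panel, runs the U(1%, 20%, 100%) window scan, merges flagged
#' windows into tracts, applies the ILS length filter, and measures the
#' fraction of planted tract bases recovered and the fraction of truth-free
#' windows falsely flagged.
#'
#' @param seeds Integer vector of replicate seeds.
#' @return List with per-seed `coverage` and `false_flag_rate`, plus their
#'   means.
#' @export
uscan_recovery_study <- function(seeds = 1:5) {
  cov <- numeric(length(seeds))
  fpr <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    s <- seeds[i]
    sim <- simulate_panel(sim_config(1e7, 20000, study_populations(),
                                     seed = s))
    pl <- plant_introgression(sim$panels$HN, sim$panels$WILD, n_tracts = 5,
                              tract_length = 2e5, recipient_freq = 0.3,
                              seed = s + 2000, donor_name = "WILD")
    sim$panels$HN <- pl$panel
    m <- merge_panels(sim$panels)
    us <- u_scan(m$panel, m$popmap, "IND", "HN", "WILD", uscan_config(),
                 window_spec())
    tracts <- filter_tracts(windows_to_tracts(us$flagged), ils_model())
    tr <- merge_intervals(data.frame(
      chrom = "chr1", start0 = unique(pl$truth$introgressed_tracts$start0),
      end0 = unique(pl$truth$introgressed_tracts$end0)))
    called <- tracts[, c("chrom", "start0", "end0")]
    cov[i] <- if (nrow(called)) {
      interval_bp(intersect_intervals(called, tr)) / interval_bp(tr)
    } else 0
    win <- us$windows
    truth_free <- !vapply(seq_len(nrow(win)), function(j) {
      any(win$start0[j] < tr$end0 & win$end0[j] > tr$start0)
    }, logical(1))
    flagged <- win$value >= 1
    fpr[i] <- sum(flagged & truth_free) / sum(truth_free)
  }
  list(coverage = cov, false_flag_rate = fpr,
       mean_coverage = mean(cov), mean_false_flag_rate = mean(fpr))
}

#' Pipeline determinism study
#'
#' Runs the full pipeline twice with the same configuration and seed and
#' compares the output manifests file by file.
#'
#' @param config Pipeline configuration (default: [default_config()]).
#' @param dir Parent directory for the two runs (default: a temp dir).
#' @return List with `identical` (logical) and the two manifests.
#' @export
pipeline_determinism_study <- function(config = default_config(),
                                       dir = tempfile("detstudy")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config$outdir <- file.path(dir, "run1")
  r1 <- run_pipeline(config)
  config$outdir <- file.path(dir, "run2")
  r2 <- run_pipeline(config)
  list(identical = identical(r1$manifest$md5, r2$manifest$md5) &&
         identical(r1$manifest$file, r2$manifest$file),
       manifest1 = r1$manifest, manifest2 = r2$manifest)
}
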