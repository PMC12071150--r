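#' Simulation configuration
#'
#' Parameters of the founder-mosaic multi-population simulator.  Ancestral
#' derived-allele frequencies are drawn from a neutral-like spectrum
#' (density proportional to 1/x, the standard infinite-sites expectation;
#' or a symmetric Beta); each population's frequencies drift away under the
#' Balding-Nichols model with that population's `f`; founder haplotypes are
#' drawn site-wise from the population frequencies; and each sampled
#' haplotype is a mosaic of the founders with a per-bp switch probability,
#' which induces realistic LD and EHH decay.
#'
#' @param chrom_length Chromosome length in bp.
#' @param n_sites Number of SNP sites to place uniformly on the chromosome.
#' @param populations Data frame with columns `name`, `n` (diploids), `f`
#'   (Balding-Nichols drift, in `[0, 1)`) and optionally `fixed_diff`
#'   (fraction of sites carrying a population-private fixed derived allele,
#'   emulating substitutions on a deeply diverged lineage's stem branch;
#'   default 0).
#' @param n_founders Founder haplotypes per population (default 300; the
#'   finite pool leaves a mild excess of intermediate-frequency alleles).
#' @param switch_rate Per-bp probability of switching founder along a
#'   haplotype (default 1e-5, i.e. 100 kb mosaic segments on average).
#' @param spectrum Ancestral-frequency spectrum: `"neutral"` (default,
#'   density ~ 1/x on `(p_min, 1)`) or `"beta"` (symmetric
#'   `Beta(beta_shape, beta_shape)`).
#' @param beta_shape Shape of the symmetric Beta when `spectrum = "beta"`.
#' @param p_min Lower frequency bound of the neutral spectrum
#'   (default 5e-4).
#' @param seed Integer seed; the simulator is fully reproducible given the
#'   config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(chrom_length, n_sites, populations, n_founders = 300,
                       switch_rate = 1e-5,
                       spectrum = c("neutral", "beta"), beta_shape = 0.8,
                       p_min = 5e-4, seed = 1) {
  spectrum <- match.arg(spectrum)
  populations <- as.data.frame(populations)
  stopifnot(all(c("name", "n", "f") %in% names(populations)))
  if (is.null(populations$fixed_diff)) populations$fixed_diff <- 0
  if (any(populations$fixed_diff < 0 | populations$fixed_diff >= 1)) {
    stop("fixed_diff must lie in [0, 1)")
  }
  if (n_sites < 2) stop("need at least 2 sites")
  if (any(populations$f < 0 | populations$f >= 1)) stop("all f must lie in [0, 1)")
  if (switch_rate < 0) stop("switch_rate must be >= 0")
  if (n_founders < 2 && switch_rate > 0) {
    stop("n_founders must be >= 2 when switch_rate > 0")
  }
  structure(list(chrom_length = as.numeric(chrom_length),
                 n_sites = as.integer(n_sites),
                 populations = populations,
                 n_founders = as.integer(n_founders),
                 switch_rate = switch_rate, spectrum = spectrum,
                 beta_shape = beta_shape, p_min = p_min,
                 seed = as.integer(seed)),
            class = "sim_config")
}

empty_sim_truth <- function() {
  list(
    introgressed_tracts = data.frame(
      haplotype = character(), chrom = character(), start0 = numeric(),
      end0 = numeric(), donor = character(), stringsAsFactors = FALSE),
    autozygous_segments = data.frame(
      sample = character(), chrom = character(), start0 = numeric(),
      end0 = numeric(), class = character(), stringsAsFactors = FALSE),
    sweep_intervals = data.frame(
      chrom = character(), start0 = numeric(), end0 = numeric(),
      stringsAsFactors = FALSE))
}

mosaic_haplotypes <- function(founders, positions, switch_rate, n_hap) {
  n_sites <- nrow(founders)
  n_f <- ncol(founders)
  H <- matrix(0L, n_sites, n_hap)
  p_switch <- -expm1(-switch_rate * diff(positions))
  rows <- seq_len(n_sites)
  for (h in seq_len(n_hap)) {
    if (switch_rate > 0) {
      seg <- cumsum(c(0L, as.integer(stats::runif(n_sites - 1L) < p_switch)))
    } else {
      seg <- rep(0L, n_sites)
    }
    fid <- sample.int(n_f, max(seg) + 1L, replace = TRUE)
    H[, h] <- founders[cbind(rows, fid[seg + 1L])]
  }
  H
}

#' Simulate phased multi-population haplotype panels
#'
#' @param cfg A [sim_config()].
#' @return List with `panels` (named list of `haplotype_panel`, one per
#'   population), `truth` (empty ground-truth record, see the planting
#'   functions) and `ancestral_freq` (the shared ancestral frequencies).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  positions <- sort(sample.int(cfg$chrom_length, cfg$n_sites))
  if (cfg$spectrum == "neutral") {
    # density ~ 1/x on (p_min, 1): inverse-CDF of a log-uniform draw
    p_anc <- exp(stats::runif(cfg$n_sites, log(cfg$p_min), 0))
  } else {
    p_anc <- stats::rbeta(cfg$n_sites, cfg$beta_shape, cfg$beta_shape)
  }
  p_anc <- pmin(pmax(p_anc, 1e-6), 1 - 1e-6)
  panels <- list()
  for (k in seq_len(nrow(cfg$populations))) {
    pop <- cfg$populations[k, ]
    f <- pop$f
    if (f > 0) {
      a <- p_anc * (1 - f) / f
      b <- (1 - p_anc) * (1 - f) / f
      p_k <- stats::rbeta(cfg$n_sites, a, b)
    } else {
      p_k <- p_anc
    }
    if (pop$fixed_diff > 0) {
      # private stem-branch substitutions: fixed derived in this population
      priv <- sample.int(cfg$n_sites, round(pop$fixed_diff * cfg$n_sites))
      p_k[priv] <- 1
    }
    founders <- matrix(
      stats::rbinom(cfg$n_sites * cfg$n_founders, 1L, p_k),
      nrow = cfg$n_sites, ncol = cfg$n_founders)
    H <- mosaic_haplotypes(founders, positions, cfg$switch_rate, 2L * pop$n)
    ids <- sprintf("%s_%02d", pop$name, seq_len(pop$n))
    panels[[pop$name]] <- haplotype_panel(
      "chr1", positions, H, ids, phased = TRUE,
      site_depth = NULL, site_dr = NULL, chrom_length = cfg$chrom_length)
  }
  list(panels = panels, truth = empty_sim_truth(), ancestral_freq = p_anc)
}

#' Plant donor-introgression tracts into a recipient panel
#'
#' For each tract a random fraction `recipient_freq` of recipient haplotypes
#' has the interval replaced by a copy of one randomly chosen donor
#' haplotype, emulating wild-species introgression at a controlled recipient
#' frequency.  Tracts are placed uniformly and do not overlap each other.
#'
#' @param panel Recipient `haplotype_panel`.
#' @param donor Donor `haplotype_panel` sharing positions with `panel`.
#' @param n_tracts Number of tracts to plant.
#' @param tract_length Tract length in bp.
#' @param recipient_freq Fraction of recipient haplotypes carrying each
#'   tract, in `(0, 1]`.
#' @param seed Integer seed.
#' @param donor_name Donor label recorded in the truth table.
#' @return List with the modified `panel` and a `truth` record of every
#'   replaced (haplotype, interval).
#' @export
plant_introgression <- function(panel, donor, n_tracts, tract_length,
                                recipient_freq, seed = 1,
                                donor_name = "donor") {
  if (!identical(panel$positions, donor$positions)) {
    stop("donor and recipient panels must share positions")
  }
  if (n_tracts > 0 && (recipient_freq <= 0 || recipient_freq > 1)) {
    stop("recipient_freq must lie in (0, 1]")
  }
  truth <- empty_sim_truth()
  if (n_tracts == 0) return(list(panel = panel, truth = truth))
  set.seed(seed)
  starts <- place_intervals(n_tracts, tract_length, panel$chrom_length)
  n_hap <- n_haplotypes(panel)
  n_rec <- max(1L, round(recipient_freq * n_hap))
  recs <- list()
  for (t in seq_len(n_tracts)) {
    s0 <- starts[t]; e0 <- s0 + tract_length
    idx <- sites_in_window(panel, s0, e0)
    haps <- sort(sample.int(n_hap, n_rec))
    dh <- sample.int(n_haplotypes(donor), 1L)
    if (length(idx)) {
      panel$alleles[idx, haps] <- donor$alleles[idx, dh]
    }
    recs[[t]] <- data.frame(
      haplotype = colnames(panel$alleles)[haps], chrom = panel$chrom,
      start0 = s0, end0 = e0, donor = donor_name, stringsAsFactors = FALSE)
  }
  truth$introgressed_tracts <- do.call(rbind, recs)
  list(panel = panel, truth = truth)
}

# non-overlapping uniform interval placement with bounded retries
place_intervals <- function(n, len, chrom_length, occupied = NULL,
                            max_tries = 1000L) {
  if (len >= chrom_length) stop("interval longer than chromosome")
  starts <- numeric(0)
  occ_s <- if (is.null(occupied)) numeric(0) else occupied$start0
  occ_e <- if (is.null(occupied)) numeric(0) else occupied$end0
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- floor(stats::runif(1, 0, chrom_length - len))
      if (!any(s < c(occ_e, starts + len) & s + len > c(occ_s, starts))) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place non-overlapping interval after retries")
    starts <- c(starts, s)
  }
  starts
}

#' Plant autozygous (ROH) segments
#'
#' For each planted segment one diploid sample has its second haplotype
#' overwritten by its first over the interval, producing perfect
#' autozygosity.  Segment lengths are drawn log10-uniformly within each
#' class's range; within a sample segments never overlap (bounded retries).
#'
#' @param panel A `haplotype_panel`.
#' @param classes Data frame with columns `class`, `n`, `min_bp`, `max_bp`;
#'   rows ordered short < medium < long with disjoint length ranges.
#' @param seed Integer seed.
#' @param samples Optional character vector assigning a sample to each
#'   planted segment (length `sum(classes$n)`); default: sampled at random.
#' @param margin Minimum distance of a segment from the chromosome ends, bp.
#' @return List with the modified `panel` and a `truth` record of segments
#'   and their intended classes.
#' @export
plant_autozygosity <- function(panel, classes, seed = 1, samples = NULL,
                               margin = 0) {
  classes <- as.data.frame(classes)
  stopifnot(all(c("class", "n", "min_bp", "max_bp") %in% names(classes)))
  if (any(diff(c(rbind(classes$min_bp, classes$max_bp))) < 0)) {
    stop("class length ranges must be disjoint and increasing")
  }
  set.seed(seed)
  total <- sum(classes$n)
  if (is.null(samples)) {
    samples <- sample(panel$sample_ids, total, replace = TRUE)
  }
  if (length(samples) != total) stop("one sample per planted segment required")
  recs <- vector("list", total)
  occ <- new.env(parent = emptyenv())
  k <- 0L
  for (ci in seq_len(nrow(classes))) {
    cl <- classes[ci, ]
    for (j in seq_len(cl$n)) {
      k <- k + 1L
      smp <- samples[k]
      len <- round(10 ^ stats::runif(1, log10(cl$min_bp), log10(cl$max_bp)))
      prev <- if (!is.null(occ[[smp]])) occ[[smp]] else
        data.frame(start0 = numeric(0), end0 = numeric(0))
      ok <- FALSE
      for (try in seq_len(200L)) {
        s0 <- floor(stats::runif(1, margin, panel$chrom_length - len - margin))
        e0 <- s0 + len
        if (!any(s0 < prev$end0 & e0 > prev$start0)) { ok <- TRUE; break }
      }
      if (!ok) stop(sprintf("could not place segment in sample %s after retries", smp))
      occ[[smp]] <- rbind(prev, data.frame(start0 = s0, end0 = e0))
      cols <- sample_haplotypes(panel, smp)
      idx <- sites_in_window(panel, s0, e0)
      if (length(idx)) panel$alleles[idx, cols[2]] <- panel$alleles[idx, cols[1]]
      recs[[k]] <- data.frame(sample = smp, chrom = panel$chrom, start0 = s0,
                              end0 = e0, class = cl$class,
                              stringsAsFactors = FALSE)
    }
  }
  truth <- empty_sim_truth()
  truth$autozygous_segments <- do.call(rbind, recs)
  list(panel = panel, truth = truth)
}

#' Plant a selective-sweep interval
#'
#' A fraction `carrier_freq` of haplotypes is overwritten by one randomly
#' chosen "core" haplotype inside the interval, creating the extended
#' homozygosity and diversity deficit of a recent sweep.
#'
#' @param panel A `haplotype_panel`.
#' @param start0,end0 Sweep interval, 0-based half-open.
#' @param carrier_freq Fraction of haplotypes carrying the core haplotype,
#'   in `(0, 1]`.
#' @param seed Integer seed.
#' @return List with the modified `panel` and a `truth` record of the
#'   interval.
#' @export
plant_sweep <- function(panel, start0, end0, carrier_freq, seed = 1) {
  if (carrier_freq <= 0 || carrier_freq > 1) {
    stop("carrier_freq must lie in (0, 1]")
  }
  if (start0 < 0 || end0 > panel$chrom_length || end0 <= start0) {
    stop("sweep interval must lie within the chromosome")
  }
  set.seed(seed)
  n_hap <- n_haplotypes(panel)
  core <- sample.int(n_hap, 1L)
  n_car <- max(1L, round(carrier_freq * n_hap))
  carriers <- sort(sample.int(n_hap, n_car))
  carriers <- union(core, carriers)[seq_len(n_car)]
  idx <- sites_in_window(panel, start0, end0)
  if (length(idx)) {
    panel$alleles[idx, carriers] <- panel$alleles[idx, core]
  }
  truth <- empty_sim_truth()
  truth$sweep_intervals <- data.frame(chrom = panel$chrom, start0 = start0,
                                      end0 = end0, stringsAsFactors = FALSE)
  list(panel = panel, truth = truth)
}

#' Combine ground-truth records
#' @param ... `truth` lists as produced by the planting functions.
#' @return One combined truth list.
#' @export
combine_truth <- function(...) {
  ts <- list(...)
  out <- empty_sim_truth()
  for (t in ts) {
    for (nm in names(out)) out[[nm]] <- rbind(out[[nm]], t[[nm]])
  }
  out
}

#' Write ground-truth tables to a directory
#'
#' One BED-like TSV per truth category; round-trips losslessly via
#' [read_truth()].
#'
#' @param truth A truth list.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(truth)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(truth[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read ground-truth tables written by [write_truth()]
#' @param dir Directory holding the truth TSVs.
#' @return A truth list.
#' @export
read_truth <- function(dir) {
  out <- empty_sim_truth()
  for (nm in names(out)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    if (file.exists(p)) {
      df <- utils::read.table(p, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE,
                              colClasses = vapply(out[[nm]], class, ""))
      if (nrow(df)) out[[nm]] <- df
    }
  }
  out
}
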