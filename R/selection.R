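#' Selection-scan cutoffs
#'
#' @param pi_quantile Tail probability for the theta-pi normal cutoff
#'   (default 0.01, i.e. the most extreme 1 percent).
#' @param pi_tail `"lower"` (default; sweeps deplete diversity) or
#'   `"upper"`.
#' @param ihs_abs_threshold |iHS| threshold counting a SNP as extreme
#'   (default 2).
#' @param ihs_window_top_fraction Fraction of windows flagged as iHS
#'   candidates (default 0.05).
#' @return A `selection_cutoffs` list.
#' @export
selection_cutoffs <- function(pi_quantile = 0.01, pi_tail = c("lower", "upper"),
                              ihs_abs_threshold = 2,
                              ihs_window_top_fraction = 0.05) {
  pi_tail <- match.arg(pi_tail)
  if (pi_quantile <= 0 || pi_quantile >= 1) stop("pi_quantile must lie in (0,1)")
  if (ihs_window_top_fraction <= 0 || ihs_window_top_fraction > 1) {
    stop("ihs_window_top_fraction must lie in (0,1]")
  }
  structure(list(pi_quantile = pi_quantile, pi_tail = pi_tail,
                 ihs_abs_threshold = ihs_abs_threshold,
                 ihs_window_top_fraction = ihs_window_top_fraction),
            class = "selection_cutoffs")
}

#' Extended haplotype homozygosity around a core allele
#'
#' EHH at flanking site j is the probability that two random carriers of
#' the core allele are identical over every site from the core to j:
#' `sum_h C(n_h, 2) / C(n, 2)` over haplotype classes h.  The curve is 1 at
#' the core and non-increasing outwards; computation stops once EHH falls
#' below `truncation` (the crossing value is included) or `max_extent` bp
#' from the core is reached.
#'
#' @param panel A phased `haplotype_panel` (allele 0 = ancestral).
#' @param popmap Population map, or `NULL` for all haplotypes.
#' @param group Group label.
#' @param core_index Site index of the core SNP.
#' @param core_allele `"derived"` (allele 1) or `"ancestral"` (allele 0).
#' @param truncation EHH truncation level (default 0.05).
#' @param max_extent Maximum flank extent in bp (default 1 Mb).
#' @return Data frame with `side` (`"left"`/`"right"`/`"core"`), `site`,
#'   `pos`, `ehh`.
#' @export
ehh <- function(panel, popmap = NULL, group = NULL, core_index,
                core_allele = c("derived", "ancestral"),
                truncation = 0.05, max_extent = 1e6) {
  if (!panel$phased) stop("phase required for EHH")
  core_allele <- match.arg(core_allele)
  hap <- group_haplotypes(panel, popmap, group)
  want <- if (core_allele == "derived") 1L else 0L
  a <- panel$alleles[core_index, hap]
  carriers <- hap[!is.na(a) & a == want]
  if (length(carriers) < 2L) stop("core allele count must be >= 2")
  H <- panel$alleles[, carriers, drop = FALSE]
  car0 <- seq_len(ncol(H)) - 1L
  left <- cpp_ehh_side(H, panel$positions, car0, core_index - 1L, -1L,
                       truncation, max_extent)
  right <- cpp_ehh_side(H, panel$positions, car0, core_index - 1L, 1L,
                        truncation, max_extent)
  rbind(
    data.frame(side = "core", site = core_index,
               pos = panel$positions[core_index], ehh = 1),
    if (nrow(left)) data.frame(side = "left", site = left$site,
                               pos = panel$positions[left$site],
                               ehh = left$ehh),
    if (nrow(right)) data.frame(side = "right", site = right$site,
                                pos = panel$positions[right$site],
                                ehh = right$ehh))
}

#' Unstandardized iHS at one core site
#'
#' iHH for each core allele is the trapezoidal integral of its EHH curve
#' over physical distance, both flanks summed, truncated at `truncation`
#' and with each inter-SNP gap capped at `max_gap` bp.  The unstandardized
#' score is `ln(iHH_ancestral / iHH_derived)`.  Sites where either allele's
#' EHH fails to decay below `truncation` within `max_extent` (or before the
#' chromosome ends) are flagged and carry `NA` scores.
#'
#' @inheritParams ehh
#' @param max_gap Cap on the integration width of an inter-SNP gap, bp
#'   (default 200 kb).
#' @return One-row data frame: `site`, `pos`, `freq_der`, `ihh_a`, `ihh_d`,
#'   `uihs`, `flagged`.
#' @export
ihs_unstandardized <- function(panel, popmap = NULL, group = NULL, core_index,
                               truncation = 0.05, max_extent = 1e6,
                               max_gap = 2e5) {
  if (!panel$phased) stop("phase required for iHS")
  hap <- group_haplotypes(panel, popmap, group)
  H <- panel$alleles[, hap, drop = FALSE]
  a <- H[core_index, ]
  if (sum(a == 1L, na.rm = TRUE) < 2L || sum(a == 0L, na.rm = TRUE) < 2L) {
    stop("both core alleles need count >= 2")
  }
  r <- cpp_ihh_site(H, panel$positions, core_index - 1L, truncation,
                    max_extent, max_gap)
  # truncation <= 0 means "integrate the full extent": no decay flag applies
  flagged <- (truncation > 0 && r[3] == 1) || r[1] <= 0 || r[2] <= 0
  data.frame(site = core_index, pos = panel$positions[core_index],
             freq_der = mean(a == 1L, na.rm = TRUE),
             ihh_a = r[1], ihh_d = r[2],
             uihs = if (flagged) NA_real_ else log(r[1] / r[2]),
             flagged = flagged)
}

#' Genome-wide unstandardized iHS scan
#'
#' @inheritParams ihs_unstandardized
#' @param min_mac Minimum minor-allele count for a core site (default 2).
#' @return Data frame with one row per scored site: `site`, `pos`,
#'   `freq_der`, `ihh_a`, `ihh_d`, `uihs`, `flagged`.  Flagged sites keep
#'   `NA` scores and are excluded downstream.
#' @export
ihs_scan <- function(panel, popmap = NULL, group = NULL, truncation = 0.05,
                     max_extent = 1e6, max_gap = 2e5, min_mac = 2L) {
  if (!panel$phased) stop("phase required for iHS")
  hap <- group_haplotypes(panel, popmap, group)
  H <- panel$alleles[, hap, drop = FALSE]
  m <- cpp_ihs_scan(H, panel$positions, truncation, max_extent, max_gap,
                    as.integer(min_mac))
  flagged <- (if (truncation > 0) m[, 4] == 1 else !is.finite(m[, 1])) |
    !is.finite(m[, 2]) | !is.finite(m[, 3]) | m[, 2] <= 0 | m[, 3] <= 0
  uihs <- ifelse(flagged, NA_real_, log(m[, 2] / m[, 3]))
  data.frame(site = seq_len(n_sites(panel)), pos = panel$positions,
             freq_der = m[, 1], ihh_a = m[, 2], ihh_d = m[, 3],
             uihs = uihs, flagged = flagged)
}

#' Standardize iHS within derived-allele-frequency bins
#'
#' Scores are standardized (mean 0, sd 1) within equal-width
#' derived-frequency bins; bins holding fewer than `min_bin` scored sites
#' are merged with their nearest neighbour, and bins with zero variance are
#' excluded with a warning.
#'
#' @param results Scan table from [ihs_scan()].
#' @param n_bins Number of frequency bins before merging (default 50).
#' @param min_bin Minimum scored sites per bin (default 20).
#' @return The scored subset of `results` with columns `bin` and `ihs`
#'   added.
#' @export
standardize_ihs <- function(results, n_bins = 50L, min_bin = 20L) {
  d <- results[!results$flagged & !is.na(results$uihs), , drop = FALSE]
  if (!nrow(d)) stop("no scored sites to standardize")
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- findInterval(d$freq_der, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  # merge small bins into their nearest occupied neighbour
  repeat {
    tab <- table(bin)
    small <- names(tab)[tab < min_bin]
    if (!length(small) || length(tab) == 1L) break
    b <- as.integer(small[1])
    occupied <- setdiff(as.integer(names(tab)), b)
    nb <- occupied[which.min(abs(occupied - b))]
    bin[bin == b] <- nb
  }
  keep <- rep(TRUE, nrow(d))
  ihs <- rep(NA_real_, nrow(d))
  for (b in unique(bin)) {
    i <- bin == b
    s <- stats::sd(d$uihs[i])
    if (sum(i) < 2L || s == 0) {
      warning(sprintf("frequency bin %d has no score variance; excluded", b))
      keep[i] <- FALSE
    } else {
      ihs[i] <- (d$uihs[i] - mean(d$uihs[i])) / s
    }
  }
  d$bin <- bin
  d$ihs <- ihs
  d[keep, , drop = FALSE]
}

#' Windowed proportion of |iHS| >= threshold and candidate windows
#'
#' Per sliding window, the proportion of scored SNPs with `|iHS| >=
#' ihs_abs_threshold`.  Windows with fewer than `min_sites` scored SNPs are
#' flagged undefined rather than reported as zero.  Candidate windows are
#' the top `ihs_window_top_fraction` by proportion; ties at the cut are
#' broken toward fewer candidates (only windows strictly above the value of
#' the first excluded rank are kept).
#'
#' @param results Standardized scan table from [standardize_ihs()].
#' @param spec A [window_spec()].
#' @param cutoffs A [selection_cutoffs()].
#' @param min_sites Minimum scored SNPs per window (default 10).
#' @param chrom,chrom_length Chromosome label and length for the windows.
#' @return List with `windows` (proportion table) and `candidates`
#'   (subset flagged as candidates).
#' @export
ihs_window_scan <- function(results, spec = window_spec(),
                            cutoffs = selection_cutoffs(), min_sites = 10L,
                            chrom = "chr1", chrom_length = NULL) {
  if (is.null(chrom_length)) chrom_length <- max(results$pos)
  win <- iter_windows(results$pos, spec, chrom_length)
  extreme <- abs(results$ihs) >= cutoffs$ihs_abs_threshold
  cs_n <- cumsum(c(0, rep(1, nrow(results))))
  cs_x <- cumsum(c(0, as.numeric(extreme)))
  m <- ifelse(win$empty, 0, cs_n[win$last_site + 1L] - cs_n[win$first_site])
  m[win$empty] <- 0
  x <- ifelse(win$empty, 0, cs_x[win$last_site + 1L] - cs_x[win$first_site])
  x[win$empty] <- 0
  undef <- m < min_sites
  prop <- ifelse(undef, NA_real_, x / m)
  out <- data.frame(chrom = chrom, start0 = win$start0, end0 = win$end0,
                    n_sites = m, statistic = "prop_abs_ihs_ge_thr",
                    value = prop, undefined = undef)
  defined <- out[!out$undefined, , drop = FALSE]
  k <- floor(cutoffs$ihs_window_top_fraction * nrow(defined))
  cand <- defined[0, ]
  if (k > 0 && nrow(defined)) {
    v <- sort(defined$value, decreasing = TRUE)
    cut_val <- if (k < nrow(defined)) v[k + 1L] else -Inf
    cand <- defined[defined$value > cut_val, , drop = FALSE]
  }
  list(windows = out, candidates = cand)
}

#' Theta-pi candidate cutoff via the normal inverse survival function
#'
#' Fits a normal distribution to the window theta-pi values and takes the
#' `pi_quantile` tail quantile as the cutoff (lower tail by default, since
#' sweeps deplete diversity).  Windows beyond the cutoff are candidates.
#'
#' @param pi_windows Window table from [pi_window()].
#' @param cutoffs A [selection_cutoffs()].
#' @param min_windows Minimum number of defined windows (default 100).
#' @return List with `threshold`, `mu`, `sigma` and `candidates`.
#' @export
pi_candidate_cutoff <- function(pi_windows, cutoffs = selection_cutoffs(),
                                min_windows = 100L) {
  d <- pi_windows[!pi_windows$undefined, , drop = FALSE]
  if (nrow(d) < min_windows) {
    stop(sprintf("need >= %d defined windows for the normal cutoff", min_windows))
  }
  mu <- mean(d$value)
  sigma <- stats::sd(d$value)
  if (sigma == 0) stop("window theta-pi has zero variance")
  if (cutoffs$pi_tail == "lower") {
    thr <- stats::qnorm(cutoffs$pi_quantile, mu, sigma)
    cand <- d[d$value < thr, , drop = FALSE]
  } else {
    thr <- stats::qnorm(1 - cutoffs$pi_quantile, mu, sigma)
    cand <- d[d$value > thr, , drop = FALSE]
  }
  list(threshold = thr, mu = mu, sigma = sigma, candidates = cand)
}

#' Intersect two candidate window/interval sets
#'
#' Intervals from each set are merged and intersected (half-open).  When a
#' gene BED is supplied, genes overlapping candidates of both sets are
#' reported by name.
#'
#' @param a,b Interval data frames (`chrom`, `start0`, `end0`), e.g. the
#'   `candidates` of the theta-pi and iHS scans.
#' @param gene_bed Optional gene interval data frame with a `name` column
#'   (e.g. from [read_bed()]).
#' @return List with `intervals` (the intersection) and `genes` (character
#'   vector, only when `gene_bed` given).
#' @export
candidate_intersection <- function(a, b, gene_bed = NULL) {
  ints <- intersect_intervals(a, b)
  out <- list(intervals = ints)
  if (!is.null(gene_bed)) {
    if (!all(c("chrom", "start0", "end0", "name") %in% names(gene_bed))) {
      stop("gene_bed needs chrom, start0, end0, name columns")
    }
    am <- merge_intervals(a)
    bm <- merge_intervals(b)
    hit <- function(g, set) {
      any(set$chrom == g$chrom & set$start0 < g$end0 & set$end0 > g$start0)
    }
    sel <- vapply(seq_len(nrow(gene_bed)), function(i) {
      g <- gene_bed[i, ]
      hit(g, am) && hit(g, bm)
    }, logical(1))
    out$genes <- gene_bed$name[sel]
  }
  out
}
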