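#' Per-site derived-allele frequencies for a set of groups
#'
#' @param panel A `haplotype_panel`.
#' @param popmap Population map.
#' @param groups Character vector of group labels.
#' @return List with `pos` (1-based positions) and `freq`, a sites x groups
#'   matrix of derived-allele frequencies (`NaN` where a group has no
#'   called haplotype).
#' @export
site_frequencies <- function(panel, popmap, groups) {
  freq <- sapply(groups, function(g) {
    site_freq(panel, group_haplotypes(panel, popmap, g))$freq
  })
  list(pos = panel$positions, freq = freq)
}

#' Patterson's D (ABBA-BABA) from population frequencies
#'
#' The outgroup defines the ancestral state: sites where the outgroup is
#' (nearly) fixed for allele 1 are flipped so that its frequency is ~0, and
#' sites where the outgroup is polymorphic beyond `outgroup_tol` are
#' dropped.  Then
#' `ABBA = sum (1-p1) p2 p3 (1-pO)`, `BABA = sum p1 (1-p2) p3 (1-pO)` and
#' `D = (ABBA - BABA) / (ABBA + BABA)`.
#'
#' @param p1,p2,p3,po Numeric vectors of derived-allele frequencies for the
#'   roles P1 (sister), P2 (test), P3 (donor), O (outgroup).
#' @param outgroup_tol Outgroup polymorphism tolerance (default 0.01):
#'   sites with outgroup frequency inside `(tol, 1 - tol)` are dropped.
#' @param positions Optional positions, retained for block jackknifing.
#' @return A `dstat_result` list: `abba`, `baba`, `d`, `n_sites`,
#'   `undefined`, plus per-site terms (`site_abba`, `site_baba`,
#'   `site_pos`).
#' @export
d_statistic <- function(p1, p2, p3, po, outgroup_tol = 0.01,
                        positions = NULL) {
  stopifnot(length(p1) == length(p2), length(p2) == length(p3),
            length(p3) == length(po))
  ok <- !(is.na(p1) | is.na(p2) | is.na(p3) | is.na(po))
  flip <- ok & po >= 1 - outgroup_tol
  keep <- ok & (po <= outgroup_tol | flip)
  q1 <- ifelse(flip, 1 - p1, p1)[keep]
  q2 <- ifelse(flip, 1 - p2, p2)[keep]
  q3 <- ifelse(flip, 1 - p3, p3)[keep]
  qo <- ifelse(flip, 1 - po, po)[keep]
  abba_s <- (1 - q1) * q2 * q3 * (1 - qo)
  baba_s <- q1 * (1 - q2) * q3 * (1 - qo)
  abba <- sum(abba_s)
  baba <- sum(baba_s)
  structure(list(
    abba = abba, baba = baba,
    d = if (abba + baba > 0) (abba - baba) / (abba + baba) else NA_real_,
    undefined = abba + baba == 0,
    n_sites = sum(keep),
    site_abba = abba_s, site_baba = baba_s,
    site_pos = if (!is.null(positions)) positions[keep] else NULL),
    class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("D = %.4f (ABBA %.2f, BABA %.2f, %d sites)",
              x$d, x$abba, x$baba, x$n_sites))
  if (!is.null(x$z)) cat(sprintf(", SE %.4f, Z %.2f [%d blocks]",
                                 x$se, x$z, x$n_blocks))
  cat("\n")
  invisible(x)
}

#' Block-jackknife standard error and Z score for Patterson's D
#'
#' Delete-one jackknife over contiguous genomic blocks, weighted by each
#' block's informative-site count (sites with nonzero ABBA + BABA), using
#' the weighted-jackknife variance of Busing et al.  `Z = D / SE`.
#'
#' @param p1,p2,p3,po Per-site derived-allele frequencies (see
#'   [d_statistic()]).
#' @param positions 1-based site positions.
#' @param block_size Block length in bp (default 5 Mb).
#' @param outgroup_tol Passed to [d_statistic()].
#' @param min_blocks Minimum number of informative blocks (default 20).
#' @return A `dstat_result` with `se`, `z` and `n_blocks` added.  When
#'   every block yields the same D the SE is 0 and Z is `Inf` with
#'   `z_degenerate = TRUE`.
#' @export
block_jackknife <- function(p1, p2, p3, po, positions, block_size = 5e6,
                            outgroup_tol = 0.01, min_blocks = 20L) {
  full <- d_statistic(p1, p2, p3, po, outgroup_tol, positions)
  if (full$undefined) stop("D undefined: no informative sites")
  informative <- full$site_abba + full$site_baba > 0
  blk <- floor(full$site_pos / block_size)
  keep_blocks <- sort(unique(blk[informative]))
  g <- length(keep_blocks)
  if (g < min_blocks) {
    stop(sprintf(
      "only %d informative blocks (< %d); use a longer region or smaller block_size",
      g, min_blocks))
  }
  m_j <- vapply(keep_blocks, function(b) sum(informative & blk == b),
                numeric(1))
  n_tot <- sum(m_j)
  abba_j <- vapply(keep_blocks, function(b) sum(full$site_abba[blk == b]),
                   numeric(1))
  baba_j <- vapply(keep_blocks, function(b) sum(full$site_baba[blk == b]),
                   numeric(1))
  d_hat <- full$d
  d_del <- (full$abba - abba_j - (full$baba - baba_j)) /
    (full$abba - abba_j + (full$baba - baba_j))
  h_j <- n_tot / m_j
  theta_j <- g * d_hat - sum((1 - m_j / n_tot) * d_del)
  var_j <- sum((h_j * d_hat - (h_j - 1) * d_del - theta_j)^2 / (h_j - 1)) / g
  se <- sqrt(max(var_j, 0))
  out <- full
  out$se <- se
  out$n_blocks <- g
  # identical per-block estimates leave only floating-point dust in var_j
  out$z_degenerate <- se <= 1e-12 * max(1, abs(d_hat))
  out$z <- if (out$z_degenerate) {
    if (d_hat == 0) 0 else sign(d_hat) * Inf
  } else d_hat / se
  out
}

#' U-scan configuration
#'
#' Thresholds of the adaptive-introgression site count
#' `U_{A,B,C}(w, x, y)`: the donor C must carry an allele at frequency
#' >= `y`, the control A at frequency < `w`, and the target B at
#' frequency > `x`.  The classic cattle setting is U20 with
#' (w, x, y) = (1%, 20%, 100%).
#'
#' @param w Maximum control-population frequency (default 0.01).
#' @param x Minimum target-population frequency, exclusive (default 0.20).
#' @param y Minimum donor frequency (default 1.0, i.e. fixed).
#' @param u_min Minimum U count for a window to be flagged (default 1).
#' @return A `uscan_config` list.
#' @export
uscan_config <- function(w = 0.01, x = 0.20, y = 1.00, u_min = 1L) {
  if (!(w >= 0 && w < x && x <= y && y <= 1)) {
    stop("need 0 <= w < x <= y <= 1")
  }
  structure(list(w = w, x = x, y = y, u_min = as.integer(u_min)),
            class = "uscan_config")
}

#' Windowed U-statistic scan for adaptive introgression
#'
#' Per site, the condition is evaluated for each allele oriented to the
#' donor's (nearly) fixed allele: the site counts toward U when
#' `freq_C >= y`, `freq_A < w` and `freq_B > x` for the same allele.  U is
#' the per-window count of such sites; windows with `U >= u_min` are
#' flagged as candidates.
#'
#' @param panel A `haplotype_panel` holding all three populations.
#' @param popmap Population map.
#' @param group_a Control group (outgroup-like, e.g. Indian indicine).
#' @param group_b Target group (e.g. Hunan cattle).
#' @param group_c Donor group (e.g. banteng or gaur).
#' @param cfg A [uscan_config()].
#' @param spec A [window_spec()].
#' @return List with `sites` (logical per-site indicator), `windows`
#'   (window table with U counts) and `flagged` (windows with
#'   `U >= u_min`).
#' @export
u_scan <- function(panel, popmap, group_a, group_b, group_c,
                   cfg = uscan_config(), spec = window_spec()) {
  fa <- site_freq(panel, group_haplotypes(panel, popmap, group_a))$freq
  fb <- site_freq(panel, group_haplotypes(panel, popmap, group_b))$freq
  fc <- site_freq(panel, group_haplotypes(panel, popmap, group_c))$freq
  ok <- !(is.na(fa) | is.na(fb) | is.na(fc))
  if (!any(ok)) stop("no shared called sites across the three groups")
  eps <- 1e-12
  hit1 <- ok & fc >= cfg$y - eps & fa < cfg$w & fb > cfg$x
  hit0 <- ok & (1 - fc) >= cfg$y - eps & (1 - fa) < cfg$w & (1 - fb) > cfg$x
  hit <- hit1 | hit0
  win <- iter_windows(panel, spec)
  cs <- cumsum(c(0, as.numeric(hit)))
  U <- ifelse(win$empty, 0, cs[win$last_site + 1L] - cs[win$first_site])
  U[win$empty] <- 0
  windows <- data.frame(chrom = panel$chrom, start0 = win$start0,
                        end0 = win$end0, n_sites = win$n_sites,
                        statistic = "u_count", value = U,
                        undefined = win$empty)
  list(sites = hit, windows = windows,
       flagged = windows[U >= cfg$u_min, , drop = FALSE])
}

#' Incomplete-lineage-sorting tract-length model
#'
#' Under ILS the expected length of a shared ancestral tract is
#' `L = 1 / (r * t)` bp (`r` per-bp per-generation recombination rate, `t`
#' generations since donor divergence); the probability that an ILS tract
#' is at least `m` bp long is the gamma survival function with shape 2 and
#' rate `1/L`.  The default `L` is the published cattle/banteng-gaur value
#' 206.52 bp.
#'
#' @param L Expected shared-tract length in bp (default 206.52).
#' @param r,t Alternative parameterization; when both are given,
#'   `L = 1 / (r * t)` (and must agree with `L` if that is also supplied).
#' @param alpha ILS probability cutoff for tract retention (default 0.05).
#' @return An `ils_model` list.
#' @export
ils_model <- function(L = 206.52, r = NULL, t = NULL, alpha = 0.05) {
  if (!is.null(r) && !is.null(t)) {
    L_rt <- 1 / (r * t)
    if (!missing(L) && abs(L - L_rt) > 1e-6 * L_rt) {
      stop("L inconsistent with 1/(r*t)")
    }
    L <- L_rt
  }
  if (L <= 0) stop("L must be positive")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  structure(list(L = L, r = r, t = t, alpha = alpha), class = "ils_model")
}

#' ILS survival probability of a tract length
#'
#' `P(length >= m) = 1 - GammaCDF(m; shape = 2, rate = 1/L)`, which equals
#' `(1 + m/L) exp(-m/L)`.
#'
#' @param m Tract length(s) in bp, >= 0.
#' @param model An [ils_model()].
#' @return Probability vector in `[0, 1]`.
#' @export
ils_survival <- function(m, model = ils_model()) {
  if (any(m < 0)) stop("tract length must be >= 0")
  1 - stats::pgamma(m, shape = 2, rate = 1 / model$L)
}

#' Smallest tract length retained by the ILS filter
#'
#' The smallest `m` with `ils_survival(m) < alpha`, found by monotone
#' root-finding; scales linearly with `L`.
#'
#' @param model An [ils_model()].
#' @return Length in bp (0 when `alpha = 1`).
#' @export
min_retained_length <- function(model = ils_model()) {
  if (model$alpha >= 1) return(0)
  f <- function(m) ils_survival(m, model) - model$alpha
  hi <- model$L
  while (f(hi) > 0) hi <- hi * 2
  stats::uniroot(f, c(0, hi), tol = 1e-9)$root
}

#' Filter candidate tracts by ILS probability
#'
#' Retains tracts whose probability of arising by incomplete lineage
#' sorting alone, `ils_survival(length)`, is below `model$alpha`; every
#' tract is annotated with that probability.
#'
#' @param tracts Data frame with `chrom`, `start0`, `end0` (and optionally
#'   more columns).
#' @param model An [ils_model()].
#' @return The tract table with `length` and `p_ils` columns added and an
#'   attribute `"removed"` (the filtered-out rows); only retained rows are
#'   returned.
#' @export
filter_tracts <- function(tracts, model = ils_model()) {
  if (!nrow(tracts)) {
    tracts$length <- numeric(0)
    tracts$p_ils <- numeric(0)
    return(tracts)
  }
  tracts$length <- tracts$end0 - tracts$start0
  tracts$p_ils <- ils_survival(tracts$length, model)
  keep <- tracts$p_ils < model$alpha
  out <- tracts[keep, , drop = FALSE]
  attr(out, "removed") <- tracts[!keep, , drop = FALSE]
  out
}

#' Merge flagged scan windows into candidate tracts
#'
#' Overlapping or adjacent flagged windows are merged into maximal
#' intervals, the tract input for the ILS filter.
#'
#' @param flagged Window table (e.g. the `flagged` element of [u_scan()]).
#' @return Interval data frame (`chrom`, `start0`, `end0`).
#' @export
windows_to_tracts <- function(flagged) {
  merge_intervals(flagged[, c("chrom", "start0", "end0")])
}

#' Overlap introgressed tracts from two donors
#'
#' Returns the merged intervals labelled `donor1`, `donor2` or `both`
#' according to which donor's tract set covers them.
#'
#' @param tracts_donor1,tracts_donor2 Interval data frames.
#' @param names Labels for the two donors.
#' @return Interval data frame with a `donor` column.
#' @export
donor_overlap <- function(tracts_donor1, tracts_donor2,
                          names = c("donor1", "donor2")) {
  a <- merge_intervals(tracts_donor1[, c("chrom", "start0", "end0")])
  b <- merge_intervals(tracts_donor2[, c("chrom", "start0", "end0")])
  both <- intersect_intervals(a, b)
  only_a <- setdiff_intervals(a, b)
  only_b <- setdiff_intervals(b, a)
  lab <- function(d, l) {
    if (nrow(d)) d$donor <- l
    else d$donor <- character(0)
    d
  }
  out <- rbind(lab(both, "both"), lab(only_a, names[1]), lab(only_b, names[2]))
  out <- out[order(out$chrom, out$start0), , drop = FALSE]
  rownames(out) <- NULL
  out
}
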