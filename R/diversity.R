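#' Windowed nucleotide diversity (theta-pi)
#'
#' Per sliding window, theta-pi is the sum over sites of the mean pairwise
#' haplotype difference `2 p q n / (n - 1)` (with `n` the per-site called
#' haplotype count) divided by the window size in bp, i.e. a per-bp value
#' using the full window length as denominator (the VCFtools convention),
#' not the callable-site count.
#'
#' @param panel A `haplotype_panel`.
#' @param popmap Population map, or `NULL` for all haplotypes.
#' @param group Group label within `popmap`.
#' @param spec A [window_spec()].
#' @return Data frame of windows with columns `chrom`, `start0`, `end0`,
#'   `n_sites`, `statistic`, `value`, `undefined` (empty windows keep value
#'   0 but are flagged).
#' @export
pi_window <- function(panel, popmap = NULL, group = NULL,
                      spec = window_spec()) {
  hap <- group_haplotypes(panel, popmap, group)
  if (length(hap) < 2L) stop("need at least 2 haplotypes")
  contrib <- site_pi_contrib(panel, hap)
  win <- iter_windows(panel, spec)
  cum <- cumsum(c(0, contrib))
  val <- ifelse(win$empty, 0, cum[win$last_site + 1L] - cum[win$first_site])
  # guard: all-NA index arithmetic for empty windows
  val[win$empty] <- 0
  data.frame(chrom = panel$chrom, start0 = win$start0, end0 = win$end0,
             n_sites = win$n_sites, statistic = "pi",
             value = val / spec$size, undefined = win$empty)
}

# per-site mean pairwise difference 2 p q n/(n-1); 0 where < 2 called
site_pi_contrib <- function(panel, hap_idx) {
  f <- site_freq(panel, hap_idx)
  n <- f$n_called
  p <- f$freq
  out <- ifelse(n >= 2, 2 * p * (1 - p) * n / (n - 1), 0)
  out[is.na(out)] <- 0
  out
}

#' Windowed Tajima's D
#'
#' Standard Tajima's D per sliding window from the number of segregating
#' sites S and the mean pairwise difference, using the usual a1, a2, b1, b2,
#' c1, c2, e1, e2 constants for the group's haplotype count.  Sites with any
#' missing call in the group are excluded.  Windows with fewer than
#' `min_segsites` segregating sites are flagged undefined (value `NA`), not
#' reported as zero.
#'
#' @inheritParams pi_window
#' @param min_segsites Minimum segregating sites per window (default 3).
#' @return Data frame of windows (statistic `"tajimas_d"`).
#' @export
tajimas_d_window <- function(panel, popmap = NULL, group = NULL,
                             spec = window_spec(), min_segsites = 3L) {
  hap <- group_haplotypes(panel, popmap, group)
  n <- length(hap)
  if (n < 4L) stop("need at least 4 haplotypes for Tajima's D")
  sub <- panel$alleles[, hap, drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0L
  cnt <- rowSums(sub, na.rm = TRUE)
  seg <- complete & cnt > 0L & cnt < n
  p <- cnt / n
  pi_site <- ifelse(seg, 2 * p * (1 - p) * n / (n - 1), 0)
  k <- tajima_constants(n)
  win <- iter_windows(panel, spec)
  cs_seg <- cumsum(c(0, as.numeric(seg)))
  cs_pi <- cumsum(c(0, pi_site))
  S <- ifelse(win$empty, 0, cs_seg[win$last_site + 1L] - cs_seg[win$first_site])
  S[win$empty] <- 0
  PI <- ifelse(win$empty, 0, cs_pi[win$last_site + 1L] - cs_pi[win$first_site])
  PI[win$empty] <- 0
  undef <- S < min_segsites
  D <- rep(NA_real_, nrow(win))
  ok <- !undef
  D[ok] <- (PI[ok] - S[ok] / k$a1) /
    sqrt(k$e1 * S[ok] + k$e2 * S[ok] * (S[ok] - 1))
  data.frame(chrom = panel$chrom, start0 = win$start0, end0 = win$end0,
             n_sites = win$n_sites, statistic = "tajimas_d",
             value = D, undefined = undef)
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Hudson's FST between two groups
#'
#' Ratio-of-averages Hudson estimator:
#' `sum[(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)] /
#'  sum[p1(1-p2) + p2(1-p1)]`
#' over sites polymorphic in at least one group (sites monomorphic for the
#' same allele in both groups are excluded; they contribute nothing to
#' either sum).
#'
#' @param panel A `haplotype_panel`.
#' @param popmap Population map.
#' @param group_a,group_b Group labels.
#' @param site_idx Optional site indices to restrict to.
#' @return List (`pairwise_fst`) with `fst`, `n_sites`, `groups`.
#' @export
hudson_fst_pair <- function(panel, popmap, group_a, group_b,
                            site_idx = NULL) {
  ha <- group_haplotypes(panel, popmap, group_a)
  hb <- group_haplotypes(panel, popmap, group_b)
  fa <- site_freq(panel, ha)
  fb <- site_freq(panel, hb)
  keep <- fa$n_called >= 2 & fb$n_called >= 2
  if (!is.null(site_idx)) keep <- keep & seq_len(n_sites(panel)) %in% site_idx
  p1 <- fa$freq[keep]; n1 <- fa$n_called[keep]
  p2 <- fb$freq[keep]; n2 <- fb$n_called[keep]
  poly <- !(p1 == p2 & (p1 == 0 | p1 == 1))
  p1 <- p1[poly]; n1 <- n1[poly]; p2 <- p2[poly]; n2 <- n2[poly]
  if (!length(p1)) stop("no usable (polymorphic) sites for FST")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  structure(list(groups = c(group_a, group_b),
                 fst = sum(num) / sum(den), n_sites = length(p1)),
            class = "pairwise_fst")
}

#' Pairwise Hudson FST matrix over all groups
#'
#' @param panel A `haplotype_panel`.
#' @param popmap Population map.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = groups.
#' @export
fst_matrix <- function(panel, popmap) {
  groups <- unique(popmap$group)
  m <- matrix(0, length(groups), length(groups),
              dimnames = list(groups, groups))
  if (length(groups) > 1L) {
    for (i in seq_along(groups)[-length(groups)]) {
      for (j in seq((i + 1L), length(groups))) {
        v <- hudson_fst_pair(panel, popmap, groups[i], groups[j])$fst
        m[i, j] <- v
        m[j, i] <- v
      }
    }
  }
  m
}

#' Linkage-disequilibrium decay curve
#'
#' Haplotypic r-squared, `(p_AB - p_A p_B)^2 / (p_A q_A p_B q_B)`, for SNP
#' pairs within `max_dist`, averaged in physical-distance bins.  Sites that
#' are monomorphic or carry missing calls in the group are skipped.
#'
#' @param panel A phased `haplotype_panel`.
#' @param popmap Population map, or `NULL` for all haplotypes.
#' @param group Group label.
#' @param max_dist Maximum pair distance in bp (default 100 kb).
#' @param bin_width Distance bin width in bp (default 5 kb).
#' @param site_subset Optional site indices to restrict the scan to (the
#'   subset is used for both pair members).
#' @return Data frame with `bin_mid`, `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(panel, popmap = NULL, group = NULL, max_dist = 1e5,
                     bin_width = 5e3, site_subset = NULL) {
  if (!panel$phased) stop("phase required for haplotypic LD")
  hap <- group_haplotypes(panel, popmap, group)
  X <- panel$alleles[, hap, drop = FALSE]
  ok <- rowSums(is.na(X)) == 0L
  p <- rowMeans(X)
  poly <- ok & p > 0 & p < 1
  if (!is.null(site_subset)) {
    poly <- poly & seq_len(n_sites(panel)) %in% site_subset
  }
  idx <- which(poly)
  if (length(idx) < 2L) stop("need at least two polymorphic sites")
  X <- X[idx, , drop = FALSE]
  pos <- panel$positions[idx]
  p <- p[idx]
  nb <- ceiling(max_dist / bin_width)
  sum_r2 <- numeric(nb)
  n_pair <- integer(nb)
  n <- ncol(X)
  for (i in seq_along(idx)[-length(idx)]) {
    j <- which(pos > pos[i] & pos <= pos[i] + max_dist)
    j <- j[j > i]
    if (!length(j)) next
    pAB <- as.vector(X[j, , drop = FALSE] %*% X[i, ]) / n
    d <- pAB - p[j] * p[i]
    r2 <- d^2 / (p[i] * (1 - p[i]) * p[j] * (1 - p[j]))
    b <- pmin(nb, ceiling((pos[j] - pos[i]) / bin_width))
    sum_r2 <- sum_r2 + tabulate_sum(b, r2, nb)
    n_pair <- n_pair + tabulate(b, nb)
  }
  data.frame(bin_mid = (seq_len(nb) - 0.5) * bin_width,
             mean_r2 = ifelse(n_pair > 0, sum_r2 / n_pair, NA_real_),
             n_pairs = n_pair)
}

tabulate_sum <- function(bin, x, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(x, bin)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
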