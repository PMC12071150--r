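# Independent brute-force oracles and tiny panel builders.  Every oracle here
# follows the textbook definition directly (per-pair loops, explicit gamete
# tables), deliberately sharing no code with the package implementations.

make_panel <- function(alleles, positions = NULL, chrom_length = NULL,
                       phased = TRUE) {
  alleles <- as.matrix(alleles)
  if (is.null(positions)) positions <- seq_len(nrow(alleles)) * 100
  haplotype_panel("chr1", positions, alleles,
                  sprintf("s%02d", seq_len(ncol(alleles) / 2)),
                  phased = phased, chrom_length = chrom_length)
}

random_panel <- function(n_sites, n_dip, seed, chrom_length = n_sites * 100) {
  set.seed(seed)
  pos <- sort(sample.int(chrom_length, n_sites))
  p <- runif(n_sites, 0.05, 0.95)
  H <- matrix(rbinom(n_sites * 2 * n_dip, 1, p), n_sites, 2 * n_dip)
  haplotype_panel("chr1", pos, H, sprintf("s%02d", seq_len(n_dip)),
                  chrom_length = chrom_length)
}

two_group_popmap <- function(panel, n_a) {
  data.frame(sample_id = panel$sample_ids,
             group = rep(c("A", "B"),
                         c(n_a, length(panel$sample_ids) - n_a)))
}

# summed per-site mean pairwise difference over all called haplotype pairs
oracle_pi_sum <- function(X) {
  n <- ncol(X)
  tot <- 0
  for (s in seq_len(nrow(X))) {
    d <- 0; np <- 0
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      if (!is.na(X[s, i]) && !is.na(X[s, j])) {
        d <- d + (X[s, i] != X[s, j]); np <- np + 1
      }
    }
    if (np > 0) tot <- tot + d / np
  }
  unname(tot)
}

# textbook Tajima's D on a complete 0/1 matrix (sites x haplotypes)
oracle_tajimas_d <- function(X) {
  n <- ncol(X)
  k <- rowSums(X)
  seg <- k > 0 & k < n
  S <- sum(seg)
  if (S < 1) return(NA_real_)
  pi_hat <- 0
  for (s in which(seg)) pi_hat <- pi_hat + k[s] * (n - k[s]) / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Hudson FST estimator evaluated site-by-site in a plain loop
oracle_hudson_fst <- function(p1, n1, p2, n2) {
  num <- 0; den <- 0
  for (s in seq_along(p1)) {
    if (p1[s] == p2[s] && (p1[s] == 0 || p1[s] == 1)) next
    num <- num + (p1[s] - p2[s])^2 - p1[s] * (1 - p1[s]) / (n1[s] - 1) -
      p2[s] * (1 - p2[s]) / (n2[s] - 1)
    den <- den + p1[s] * (1 - p2[s]) + p2[s] * (1 - p1[s])
  }
  num / den
}

# haplotypic r^2 from the explicit 2x2 gamete table
oracle_r2 <- function(x, y) {
  n <- length(x)
  pAB <- sum(x == 1 & y == 1) / n
  pA <- mean(x); pB <- mean(y)
  (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# EHH at flank j for carriers of `allele` at `core`: count identical spans
oracle_ehh <- function(H, core, allele, j) {
  car <- which(H[core, ] == allele)
  n <- length(car)
  rng <- if (j >= core) core:j else j:core
  cnt <- 0
  for (i in seq_len(n - 1)) for (k in seq((i + 1), n)) {
    if (all(H[rng, car[i]] == H[rng, car[k]])) cnt <- cnt + 1
  }
  cnt / choose(n, 2)
}

# naive term-by-term ABBA/BABA sums (already polarized frequencies)
oracle_d <- function(p1, p2, p3, po) {
  abba <- 0; baba <- 0
  for (s in seq_along(p1)) {
    abba <- abba + (1 - p1[s]) * p2[s] * p3[s] * (1 - po[s])
    baba <- baba + p1[s] * (1 - p2[s]) * p3[s] * (1 - po[s])
  }
  (abba - baba) / (abba + baba)
}

acc_pops <- function() {
  data.frame(name = c("OUT", "WILD", "IND", "HN"), n = c(15, 15, 20, 20),
             f = c(0.7, 0.5, 0.025, 0.025), fixed_diff = c(0.10, 0.05, 0, 0))
}
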