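test_that("EHH is 1 at the core and matches combinatorial counting", {
  # 8 haplotypes; derived carriers split 4/2 at the first right flank:
  # EHH = (C(4,2) + C(2,2)) / C(6,2) = 7/15
  H <- rbind(
    c(1L, 1L, 1L, 1L, 1L, 1L, 0L, 0L),  # core: 6 derived carriers
    c(0L, 0L, 0L, 0L, 1L, 1L, 0L, 1L),  # carriers split 4 / 2
    c(0L, 0L, 1L, 1L, 1L, 1L, 1L, 0L))  # then 2 / 2 / 2
  pan <- make_panel(H, positions = c(100, 200, 300), chrom_length = 400)
  e <- ehh(pan, core_index = 1, core_allele = "derived", truncation = 0)
  expect_equal(e$ehh[e$side == "core"], 1)
  r <- e[e$side == "right", ]
  expect_equal(r$ehh[1], 7 / 15, tolerance = 1e-12)
  expect_equal(r$ehh[1], oracle_ehh(H, 1, 1L, 2), tolerance = 1e-12)
  expect_equal(r$ehh[2], oracle_ehh(H, 1, 1L, 3), tolerance = 1e-12)
  expect_error(ehh(pan, core_index = 3, core_allele = "ancestral",
                   truncation = 0), NA)
  pan$phased <- FALSE
  expect_error(ehh(pan, core_index = 1), "phase required")
})

test_that("EHH equals the brute-force oracle on random panels and decays", {
  pan <- random_panel(15, 6, seed = 41, chrom_length = 2000)
  core <- 8L
  for (allele in c("derived", "ancestral")) {
    a <- if (allele == "derived") 1L else 0L
    if (sum(pan$alleles[core, ] == a) < 2) next
    e <- ehh(pan, core_index = core, core_allele = allele, truncation = 0)
    for (side in c("left", "right")) {
      d <- e[e$side == side, ]
      for (i in seq_len(nrow(d))) {
        expect_equal(d$ehh[i], oracle_ehh(pan$alleles, core, a, d$site[i]),
                     tolerance = 1e-12)
      }
      expect_true(all(diff(d$ehh) <= 1e-12))
    }
  }
})

test_that("iHS matches an independent EHH-integration oracle", {
  pan <- random_panel(11, 4, seed = 42, chrom_length = 1200)
  # first site away from the edges where both alleles have two carriers
  counts <- rowSums(pan$alleles)
  core <- intersect(which(counts >= 2 & counts <= 6), 4:8)[1]
  res <- ihs_unstandardized(pan, core_index = core, truncation = 0,
                            max_extent = 1e6, max_gap = 2e5)
  # oracle: trapezoid over per-flank EHH values from oracle_ehh
  ihh_oracle <- function(allele) {
    tot <- 0
    for (dir in c(-1, 1)) {
      e_prev <- 1
      p_prev <- pan$positions[core]
      j <- core + dir
      while (j >= 1 && j <= nrow(pan$alleles)) {
        e <- oracle_ehh(pan$alleles, core, allele, j)
        tot <- tot + 0.5 * (e_prev + e) * abs(pan$positions[j] - p_prev)
        e_prev <- e
        p_prev <- pan$positions[j]
        j <- j + dir
      }
    }
    tot
  }
  expect_equal(res$ihh_a, ihh_oracle(0L), tolerance = 1e-10)
  expect_equal(res$ihh_d, ihh_oracle(1L), tolerance = 1e-10)
  expect_equal(res$uihs, log(ihh_oracle(0L) / ihh_oracle(1L)),
               tolerance = 1e-10)
})

test_that("iHS is zero under mirror symmetry and flips sign on repolarization", {
  # ancestral and derived carriers with mirror-image haplotype structure
  left <- rbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
  core <- c(0L, 0L, 1L, 1L)
  H <- rbind(left, core, left[2:1, c(3, 4, 1, 2)])
  pan <- make_panel(H, positions = c(100, 200, 300, 400, 500),
                    chrom_length = 600)
  res <- ihs_unstandardized(pan, core_index = 3, truncation = 0)
  expect_equal(res$uihs, 0, tolerance = 1e-12)
  # swapping ancestral/derived labels negates the unstandardized score
  pan2 <- random_panel(11, 5, seed = 43, chrom_length = 1100)
  r1 <- ihs_unstandardized(pan2, core_index = 6, truncation = 0)
  pan3 <- pan2
  pan3$alleles[6, ] <- 1L - pan3$alleles[6, ]
  r2 <- ihs_unstandardized(pan3, core_index = 6, truncation = 0)
  expect_equal(r1$uihs, -r2$uihs, tolerance = 1e-10)
})

test_that("standardization centres bins and excludes zero-variance bins", {
  pops <- data.frame(name = "A", n = 25, f = 0.02)
  sim <- simulate_panel(sim_config(2e6, 4000, pops, seed = 44))
  scan <- ihs_scan(sim$panels$A)
  std <- standardize_ihs(scan)
  for (b in unique(std$bin)) {
    expect_lt(abs(mean(std$ihs[std$bin == b])), 1e-9)
    expect_lt(abs(stats::sd(std$ihs[std$bin == b]) - 1), 1e-9)
  }
  # standardizing standardized scores is idempotent up to bin noise
  std2 <- std
  std2$uihs <- std2$ihs
  std2 <- standardize_ihs(std2, n_bins = 50)
  m <- merge(std, std2, by = "site")
  expect_lt(max(abs(m$ihs.x - m$ihs.y)), 1e-9)
  # a constant-score bin is dropped with a warning
  fake <- data.frame(site = 1:60, pos = 1:60 * 1000,
                     freq_der = c(rep(0.05, 30), rep(0.6, 30)),
                     ihh_a = 1, ihh_d = 1,
                     uihs = c(rep(0.7, 30), rnorm(30)), flagged = FALSE)
  expect_warning(out <- standardize_ihs(fake, n_bins = 2, min_bin = 5),
                 "variance")
  expect_true(all(out$freq_der > 0.5))
})

test_that("window proportions flag sparse windows and break ties downward", {
  res <- data.frame(site = 1:100, pos = seq(500, 5e4, length.out = 100),
                    ihs = c(rep(3, 10), rep(0, 90)))
  cuts <- selection_cutoffs(ihs_window_top_fraction = 0.2)
  out <- ihs_window_scan(res, window_spec(10000, 10000), cuts,
                         chrom_length = 5e4, min_sites = 10)
  expect_equal(nrow(out$windows), 5L)
  expect_equal(out$windows$value[1], 0.5)
  expect_equal(out$candidates$start0, 0)
  # all-zero scores leave no candidates under the tie rule
  res0 <- transform(res, ihs = 0)
  out0 <- ihs_window_scan(res0, window_spec(10000, 10000), cuts,
                          chrom_length = 5e4)
  expect_equal(nrow(out0$candidates), 0L)
  # a window with too few scored SNPs is flagged, not reported as zero
  res2 <- res[c(1:50, 95:100), ]
  out2 <- ihs_window_scan(res2, window_spec(10000, 10000),
                          chrom_length = 5e4, min_sites = 10)
  expect_true(any(out2$windows$undefined))
  expect_true(all(is.na(out2$windows$value[out2$windows$undefined])))
})

test_that("the theta-pi cutoff equals the fitted normal quantile", {
  set.seed(45)
  vals <- rnorm(500, 3.5e-3, 5e-4)
  piw <- data.frame(chrom = "chr1", start0 = (0:499) * 2e4,
                    end0 = (0:499) * 2e4 + 5e4, n_sites = 50,
                    statistic = "pi", value = vals, undefined = FALSE)
  out <- pi_candidate_cutoff(piw)
  expect_equal(out$threshold,
               mean(vals) + qnorm(0.01) * stats::sd(vals), tolerance = 1e-12)
  expect_true(all(out$candidates$value < out$threshold))
  # upper tail selects high-diversity windows instead
  up <- pi_candidate_cutoff(piw, selection_cutoffs(pi_tail = "upper"))
  expect_true(all(up$candidates$value > up$threshold))
  expect_error(pi_candidate_cutoff(piw[1:50, ]), "windows")
  piw$value <- 1e-3
  expect_error(pi_candidate_cutoff(piw), "zero variance")
})

test_that("candidate intersection matches a quadratic interval oracle", {
  expect_equal(nrow(candidate_intersection(
    data.frame(chrom = "chr1", start0 = 0, end0 = 10),
    data.frame(chrom = "chr1", start0 = 20, end0 = 30))$intervals), 0L)
  a <- data.frame(chrom = "chr1", start0 = c(0, 50), end0 = c(10, 70))
  expect_equal(candidate_intersection(a, a)$intervals, merge_intervals(a))
  set.seed(46)
  mk <- function() {
    s <- sort(sample(0:200, 12)) * 10
    data.frame(chrom = "chr1", start0 = s,
               end0 = s + sample(10:100, 12, replace = TRUE))
  }
  x <- mk(); y <- mk()
  got <- candidate_intersection(x, y)$intervals
  # oracle: which unit positions are covered by both merged sets
  cover <- function(d, n = 2200) {
    v <- logical(n)
    for (i in seq_len(nrow(d))) v[(d$start0[i] + 1):d$end0[i]] <- TRUE
    v
  }
  both <- cover(x) & cover(y)
  expect_equal(interval_bp(got), sum(both))
  for (i in seq_len(nrow(got))) {
    expect_true(all(both[(got$start0[i] + 1):got$end0[i]]))
  }
  # gene reporting requires overlap with both candidate sets
  genes <- data.frame(chrom = "chr1", start0 = c(0, 1900), end0 = c(50, 2000),
                      name = c("g1", "g2"))
  res <- candidate_intersection(
    data.frame(chrom = "chr1", start0 = 0, end0 = 30),
    data.frame(chrom = "chr1", start0 = 40, end0 = 45), gene_bed = genes)
  expect_equal(res$genes, "g1")
})
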