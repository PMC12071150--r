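small_cfg <- function(seed = 1, ...) {
  pops <- data.frame(name = c("A", "B"), n = c(10, 10), f = c(0.01, 0.3))
  sim_config(1e6, 1000, pops, seed = seed, ...)
}

test_that("simulated panels have the configured dimensions and validate", {
  sim <- simulate_panel(small_cfg())
  expect_named(sim$panels, c("A", "B"))
  for (p in sim$panels) {
    expect_equal(n_sites(p), 1000L)
    expect_equal(n_haplotypes(p), 20L)
    expect_true(all(p$alleles %in% 0:1))
    expect_true(all(diff(p$positions) > 0))
  }
  expect_equal(nrow(sim$truth$introgressed_tracts), 0L)
})

test_that("the same seed reproduces byte-identical VCF output", {
  v1 <- withr::local_tempfile(fileext = ".vcf")
  v2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(merge_panels(simulate_panel(small_cfg(7))$panels)$panel, v1)
  write_vcf(merge_panels(simulate_panel(small_cfg(7))$panels)$panel, v2)
  expect_equal(unname(tools::md5sum(v1)), unname(tools::md5sum(v2)))
})

test_that("degenerate founder configuration errors", {
  pops <- data.frame(name = "A", n = 5, f = 0.1)
  expect_error(sim_config(1e5, 100, pops, n_founders = 1, switch_rate = 1e-5),
               "n_founders")
  expect_error(sim_config(1e5, 100, data.frame(name = "A", n = 5, f = 1)),
               "f must lie")
})

test_that("between-population FST increases with drift F", {
  wins <- 0L
  for (s in 1:5) {
    pops <- data.frame(name = c("R", "LO", "HI"), n = c(10, 10, 10),
                       f = c(0.01, 0.01, 0.3))
    sim <- simulate_panel(sim_config(2e6, 1500, pops, seed = s))
    m <- merge_panels(sim$panels)
    lo <- hudson_fst_pair(m$panel, m$popmap, "R", "LO")$fst
    hi <- hudson_fst_pair(m$panel, m$popmap, "R", "HI")$fst
    if (hi > lo) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("LD decays with distance for a finite founder pool", {
  pops <- data.frame(name = "A", n = 40, f = 0.02)
  sim <- simulate_panel(sim_config(4e6, 6000, pops, n_founders = 30,
                                   seed = 5))
  ld <- ld_decay(sim$panels$A, max_dist = 2e5, bin_width = 5e4)
  expect_true(all(diff(ld$mean_r2) <= 0))
  expect_true(all(ld$mean_r2 >= 0 & ld$mean_r2 <= 1))
})

test_that("introgression planting changes alleles only inside truth tracts", {
  pops <- data.frame(name = c("D", "R"), n = c(10, 10), f = c(0.5, 0.02))
  sim <- simulate_panel(sim_config(2e6, 2000, pops, seed = 9))
  before <- sim$panels$R$alleles
  pl <- plant_introgression(sim$panels$R, sim$panels$D, n_tracts = 3,
                            tract_length = 1e5, recipient_freq = 0.4,
                            seed = 2)
  changed <- which(pl$panel$alleles != before, arr.ind = TRUE)
  pos0 <- sim$panels$R$positions[changed[, 1]] - 1
  tr <- pl$truth$introgressed_tracts
  inside <- sapply(seq_along(pos0), function(i) {
    any(pos0[i] >= tr$start0 & pos0[i] < tr$end0 &
          tr$haplotype == colnames(pl$panel$alleles)[changed[i, 2]])
  })
  expect_true(all(inside))
  expect_equal(nrow(tr), 3 * round(0.4 * 20))
})

test_that("planted tract frequency matches a direct recount", {
  pops <- data.frame(name = c("D", "R"), n = c(10, 25), f = c(0.6, 0.02))
  sim <- simulate_panel(sim_config(2e6, 3000, pops, seed = 10))
  pl <- plant_introgression(sim$panels$R, sim$panels$D, n_tracts = 1,
                            tract_length = 5e5, recipient_freq = 0.3,
                            seed = 3)
  tr <- pl$truth$introgressed_tracts
  expect_equal(nrow(tr), round(0.3 * 50))  # 30% of 50 haplotypes replaced
  idx <- sites_in_window(pl$panel, tr$start0[1], tr$end0[1])
  rep_cols <- match(tr$haplotype, colnames(pl$panel$alleles))
  donor_hap <- pl$panel$alleles[idx, rep_cols[1]]
  # frequency recount: replaced haplotypes all carry the donor haplotype,
  # the rest keep their original alleles
  others <- setdiff(seq_len(50), rep_cols)
  expected <- (length(rep_cols) * donor_hap +
                 rowSums(sim$panels$R$alleles[idx, others])) / 50
  expect_equal(unname(site_freq(pl$panel)$freq[idx]), unname(expected),
               tolerance = 1e-12)
  # so the planted donor-allele frequency alone is recipient_freq exactly
  expect_equal(length(rep_cols) / 50, 0.3)
})

test_that("introgression planting is the identity for zero tracts", {
  pops <- data.frame(name = c("D", "R"), n = c(5, 5), f = c(0.5, 0.02))
  sim <- simulate_panel(sim_config(5e5, 500, pops, seed = 11))
  pl <- plant_introgression(sim$panels$R, sim$panels$D, n_tracts = 0,
                            tract_length = 1e5, recipient_freq = 0.3)
  expect_identical(pl$panel$alleles, sim$panels$R$alleles)
  expect_equal(nrow(pl$truth$introgressed_tracts), 0L)
  expect_error(plant_introgression(sim$panels$R, sim$panels$D, 1, 1e5, 1.5),
               "recipient_freq")
})

test_that("autozygosity planting makes the sample homozygous inside segments", {
  pops <- data.frame(name = "A", n = 10, f = 0.02)
  sim <- simulate_panel(sim_config(4e6, 4000, pops, seed = 12))
  classes <- data.frame(class = "long", n = 2, min_bp = 1.8e6, max_bp = 2.2e6)
  pl <- plant_autozygosity(sim$panels$A, classes, seed = 4)
  tr <- pl$truth$autozygous_segments
  expect_equal(nrow(tr), 2L)
  for (i in seq_len(nrow(tr))) {
    cols <- sample_haplotypes(pl$panel, tr$sample[i])
    idx <- sites_in_window(pl$panel, tr$start0[i], tr$end0[i])
    expect_true(all(pl$panel$alleles[idx, cols[1]] ==
                      pl$panel$alleles[idx, cols[2]]))
  }
  # zero segments is the identity
  pl0 <- plant_autozygosity(sim$panels$A,
                            data.frame(class = "short", n = 0,
                                       min_bp = 1e5, max_bp = 2e5))
  expect_identical(pl0$panel$alleles, sim$panels$A$alleles)
})

test_that("sweep planting zeroes diversity at full carrier frequency", {
  pops <- data.frame(name = "A", n = 20, f = 0.02)
  sim <- simulate_panel(sim_config(2e6, 3000, pops, seed = 13))
  sw <- plant_sweep(sim$panels$A, 8e5, 1.2e6, carrier_freq = 1.0, seed = 5)
  idx <- sites_in_window(sw$panel, 8e5, 1.2e6)
  f <- site_freq(sw$panel)$freq[idx]
  expect_true(all(f %in% c(0, 1)))
  # partial sweep depresses windowed diversity below the genome median
  sw2 <- plant_sweep(sim$panels$A, 8e5, 1.2e6, carrier_freq = 0.9, seed = 5)
  piw <- pi_window(sw2$panel, spec = window_spec())
  inside <- piw$start0 >= 8e5 & piw$end0 <= 1.2e6
  expect_lt(mean(piw$value[inside]), stats::median(piw$value[!inside]))
  # alleles outside the interval are untouched
  out_idx <- setdiff(seq_len(3000), idx)
  expect_identical(sw2$panel$alleles[out_idx, ],
                   sim$panels$A$alleles[out_idx, ])
  expect_error(plant_sweep(sim$panels$A, 8e5, 1.2e6, 0), "carrier_freq")
})

test_that("truth tables round-trip losslessly", {
  pops <- data.frame(name = c("D", "R"), n = c(5, 8), f = c(0.5, 0.02))
  sim <- simulate_panel(sim_config(1e6, 800, pops, seed = 14))
  pl <- plant_introgression(sim$panels$R, sim$panels$D, 2, 1e5, 0.5, seed = 6)
  sw <- plant_sweep(pl$panel, 2e5, 3e5, 0.8, seed = 7)
  truth <- combine_truth(pl$truth, sw$truth)
  dir <- withr::local_tempdir()
  write_truth(truth, dir)
  back <- read_truth(dir)
  expect_equal(back$introgressed_tracts, truth$introgressed_tracts)
  expect_equal(back$sweep_intervals, truth$sweep_intervals)
  expect_equal(nrow(back$autozygous_segments), 0L)
})
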