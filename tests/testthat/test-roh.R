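# a diploid panel built directly from a genotype vector (0 hom-ref, 1 het,
# 2 hom-alt) for one sample, with filler homozygous samples alongside
panel_from_genotypes <- function(geno, spacing = 500) {
  n <- length(geno)
  h1 <- ifelse(geno >= 1L, 1L, 0L)
  h2 <- ifelse(geno == 2L, 1L, 0L)
  h1[geno == 1L] <- 1L
  h2[geno == 1L] <- 0L
  make_panel(cbind(h1, h2), positions = seq_len(n) * spacing,
             chrom_length = (n + 1) * spacing)
}

test_that("a regular heterozygote pattern yields no ROH under defaults", {
  geno <- rep(0L, 5000)
  geno[seq(5, 5000, by = 5)] <- 1L  # het at every 5th SNP
  pan <- panel_from_genotypes(geno)
  expect_equal(nrow(detect_roh(pan, "s01")), 0L)
})

test_that("a fully homozygous region is found with tight boundaries", {
  set.seed(31)
  n <- 12000
  geno <- rbinom(n, 1L, 0.35)          # het-rich background
  run <- 4001:10000                    # 3 Mb at 500 bp spacing
  geno[run] <- 0L
  pan <- panel_from_genotypes(geno)
  segs <- detect_roh(pan, "s01")
  expect_equal(nrow(segs), 1L)
  # boundaries within one scanning window (100 SNPs x 500 bp = 50 kb)
  expect_lt(abs(segs$start0 - (4001 * 500 - 1)), 50000)
  expect_lt(abs(segs$end0 - 10000 * 500), 50000)
  expect_gte(segs$n_snps, 200L)
})

test_that("runs split at SNP gaps larger than --homozyg-gap", {
  geno <- rep(0L, 3000)
  pos <- seq_len(3000) * 500
  pos[1501:3000] <- pos[1501:3000] + 1.5e6   # 1.5 Mb SNP-free gap
  h <- ifelse(geno >= 1L, 1L, 0L)
  pan <- make_panel(cbind(h, h * 0L), positions = pos,
                    chrom_length = max(pos) + 500)
  segs <- detect_roh(pan, "s01")
  expect_equal(nrow(segs), 2L)
  expect_true(all(segs$n_snps >= 200))
  # without the gap the same genotypes give a single run
  pan2 <- panel_from_genotypes(rep(0L, 3000))
  expect_equal(nrow(detect_roh(pan2, "s01")), 1L)
})

test_that("an everywhere-homozygous sample is one SNP-dense run", {
  pan <- panel_from_genotypes(rep(0L, 2000))
  segs <- detect_roh(pan, "s01")
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$n_snps, 2000L)
})

test_that("the length mixture recovers well-separated components", {
  set.seed(32)
  lengths <- 10^c(rnorm(1000, 5.3, 0.08), rnorm(1000, 6.0, 0.08),
                  rnorm(1000, 6.6, 0.08))
  fit <- fit_length_mixture(lengths, seed = 1)
  expect_lt(max(abs(fit$means - c(5.3, 6.0, 6.6))), 0.04)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-8)
  expect_true(all(diff(fit$means) > 0))
  expect_true(fit$boundaries_bp[1] > 10^5.3 && fit$boundaries_bp[1] < 10^6.0)
  expect_true(fit$boundaries_bp[2] > 10^6.0 && fit$boundaries_bp[2] < 10^6.6)
  # EM log-likelihood is non-decreasing along the winning trace
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
})

test_that("the mixture agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")  # Mclust() resolves helpers when attached
  set.seed(33)
  lengths <- 10^c(rnorm(600, 5.3, 0.1), rnorm(600, 6.0, 0.1),
                  rnorm(600, 6.6, 0.1))
  fit <- fit_length_mixture(lengths, seed = 2)
  mc <- Mclust(log10(lengths), G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
})

test_that("degenerate mixture inputs error clearly", {
  expect_error(fit_length_mixture(rep(1e5, 10)), "insufficient")
  expect_error(fit_length_mixture(rep(1e5, 50)), "variance")
})

test_that("classification is a partition with the left-closed convention", {
  segs <- data.frame(sample = "s1", chrom = "chr1",
                     start0 = c(0, 1e6, 2e6, 3e6),
                     end0 = c(0, 1e6, 2e6, 3e6) + c(4e5, 5e5, 1.2e6, 3e6),
                     length = c(4e5, 5e5, 1.2e6, 3e6),
                     n_snps = 500L, class = "unclassified")
  cl <- classify_roh(segs, c(5e5, 2e6))
  expect_equal(cl$class, c("short", "medium", "medium", "long"))
  expect_equal(nrow(classify_roh(segs[0, ], c(5e5, 2e6))), 0L)
  expect_error(classify_roh(segs, c(2e6, 5e5)), "ordered")
})

test_that("FROH is total merged ROH length over autosome length", {
  segs <- data.frame(sample = "s1", chrom = "chr1",
                     start0 = c(0, 100e6, 120e6),
                     end0 = c(50e6, 130e6, 170e6),
                     length = c(50e6, 30e6, 50e6), n_snps = 1000L,
                     class = "short")
  fr <- froh(segs, 2500e6)
  expect_equal(fr$froh, (50e6 + 70e6) / 2500e6)  # overlap merged
  expect_equal(nrow(froh(segs[0, ], 2500e6)), 0L)
  bad <- segs
  bad$end0 <- bad$start0 + 2000e6
  expect_error(froh(bad, 1000e6), "exceeds")
  # adding a disjoint segment never decreases FROH
  more <- rbind(segs, data.frame(sample = "s1", chrom = "chr1",
                                 start0 = 200e6, end0 = 210e6, length = 10e6,
                                 n_snps = 500L, class = "short"))
  expect_gt(froh(more, 2500e6)$froh, fr$froh)
})

test_that("class summaries match stats::cor and flag tiny groups", {
  set.seed(34)
  samples <- sprintf("s%02d", 1:8)
  segs <- do.call(rbind, lapply(samples, function(s) {
    data.frame(sample = s, chrom = "chr1", start0 = 0,
               end0 = 1, length = rlnorm(6, 13, 0.8), n_snps = 300L,
               class = sample(c("short", "medium", "long"), 6, replace = TRUE))
  }))
  pm <- data.frame(sample_id = samples, group = rep(c("G1", "G2"), c(6, 2)))
  cs <- class_summaries(segs, pm)
  expect_equal(sum(cs$group_class$cumulative_bp), sum(segs$length))
  g1 <- cs$correlations[cs$correlations$group == "G1", ]
  per <- sapply(c("short", "medium", "long"), function(cl) {
    sapply(samples[1:6], function(s) {
      sum(segs$length[segs$sample == s & segs$class == cl])
    })
  })
  expect_equal(g1$r[g1$pair == "short_medium"],
               stats::cor(per[, "short"], per[, "medium"]),
               tolerance = 1e-12)
  expect_equal(g1$r[g1$pair == "short_long"],
               stats::cor(per[, "short"], per[, "long"]), tolerance = 1e-12)
  g2 <- cs$correlations[cs$correlations$group == "G2", ]
  expect_true(all(g2$undefined))
})
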