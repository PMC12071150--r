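test_that("D statistic reproduces hand cases and the naive-loop oracle", {
  # single site ABBA pattern: p1=0, p2=1, p3=1, pO=0
  d <- d_statistic(0, 1, 1, 0)
  expect_equal(d$abba, 1)
  expect_equal(d$baba, 0)
  expect_equal(d$d, 1)
  # exchanging P1 and P2 negates D
  set.seed(51)
  p1 <- runif(100); p2 <- runif(100); p3 <- runif(100)
  po <- sample(c(0, 0.005, 1, 0.5), 100, replace = TRUE)
  d12 <- d_statistic(p1, p2, p3, po)
  d21 <- d_statistic(p2, p1, p3, po)
  expect_equal(d12$d, -d21$d, tolerance = 1e-12)
  # matches term-by-term summation after the same polarization
  keep <- po <= 0.01 | po >= 0.99
  flip <- po >= 0.99
  q <- function(p) ifelse(flip, 1 - p, p)[keep]
  expect_equal(d12$d, oracle_d(q(p1), q(p2), q(p3), q(po)), tolerance = 1e-12)
  expect_equal(d12$n_sites, sum(keep))
  # all-zero frequencies are undefined, not zero
  expect_true(d_statistic(0, 0, 0, 0)$undefined)
})

test_that("D is invariant to allele-label swap when polarization recomputes", {
  set.seed(52)
  p1 <- runif(60); p2 <- runif(60); p3 <- runif(60)
  po <- sample(c(0, 1), 60, replace = TRUE)
  d1 <- d_statistic(p1, p2, p3, po)
  swap <- rbinom(60, 1, 0.5) == 1
  s <- function(p) ifelse(swap, 1 - p, p)
  d2 <- d_statistic(s(p1), s(p2), s(p3), s(po))
  expect_equal(d1$d, d2$d, tolerance = 1e-12)
})

test_that("block jackknife handles degenerate identical blocks", {
  pos <- seq(1, 40e6, length.out = 4000)
  p3 <- rep(1, 4000); po <- rep(0, 4000)
  p1 <- rep(0.2, 4000); p2 <- rep(0.2, 4000)
  bj <- block_jackknife(p1, p2, p3, po, pos, block_size = 1e6)
  expect_equal(bj$se, 0)
  expect_true(bj$z_degenerate)
  expect_equal(bj$z, 0)  # D is exactly 0 here
  p2b <- rep(0.3, 4000)
  bj2 <- block_jackknife(p1, p2b, p3, po, pos, block_size = 1e6)
  expect_true(is.infinite(bj2$z) && bj2$z > 0)
  expect_error(block_jackknife(p1, p2, p3, po, pos, block_size = 39e6),
               "blocks")
})

test_that("U counts follow the direct condition and threshold monotonicity", {
  mk_panel_freqs <- function(fa, fb, fc, n = 20) {
    # build a panel whose per-group frequencies are exact
    haps <- function(f) {
      k <- round(f * n)
      t(vapply(k, function(ki) c(rep(1L, ki), rep(0L, n - ki)),
               integer(n)))
    }
    H <- cbind(haps(fa), haps(fb), haps(fc))
    pan <- make_panel(H, positions = (seq_along(fa)) * 1000,
                      chrom_length = 60000)
    pm <- data.frame(sample_id = pan$sample_ids,
                     group = rep(c("A", "B", "C"), each = n / 2))
    list(pan = pan, pm = pm)
  }
  x <- mk_panel_freqs(fa = c(0, 0, 0), fb = c(0.25, 0.25, 0.25),
                      fc = c(1, 1, 1))
  us <- u_scan(x$pan, x$pm, "A", "B", "C", uscan_config(),
               window_spec(60000, 60000))
  expect_equal(us$windows$value[1], 3)
  # target frequency at 0.1 fails the x threshold
  y <- mk_panel_freqs(fa = c(0, 0, 0), fb = c(0.1, 0.1, 0.1), fc = c(1, 1, 1))
  expect_equal(u_scan(y$pan, y$pm, "A", "B", "C", uscan_config(),
                      window_spec(60000, 60000))$windows$value[1], 0)
  # monotonicity in the thresholds on a random panel
  pops <- data.frame(name = c("A", "B", "C"), n = c(10, 10, 10),
                     f = c(0.02, 0.05, 0.5), fixed_diff = c(0, 0, 0.05))
  sim <- simulate_panel(sim_config(2e6, 3000, pops, seed = 53))
  m <- merge_panels(sim$panels)
  u_of <- function(w, x) {
    sum(u_scan(m$panel, m$popmap, "A", "B", "C", uscan_config(w = w, x = x),
               window_spec())$sites)
  }
  expect_lte(u_of(0.01, 0.4), u_of(0.01, 0.2))   # non-increasing in x
  expect_gte(u_of(0.05, 0.2), u_of(0.01, 0.2))   # non-decreasing in w
  expect_error(uscan_config(w = 0.5, x = 0.2), "w < x")
})

test_that("ILS survival equals the closed form and scales with L", {
  model <- ils_model()
  expect_equal(model$L, 206.52)
  expect_equal(ils_survival(0, model), 1)
  m <- seq(0, 5000, by = 50)
  expect_equal(ils_survival(m, model),
               (1 + m / model$L) * exp(-m / model$L), tolerance = 1e-12)
  expect_equal(ils_survival(3 * 206.52, model), 4 * exp(-3),
               tolerance = 1e-12)
  expect_error(ils_survival(-1, model), ">= 0")
  # survival is strictly decreasing
  expect_true(all(diff(ils_survival(m, model)) < 0))
  # alternative (r, t) parameterization must be consistent
  m2 <- ils_model(r = 1e-8, t = 484213.44)
  expect_equal(m2$L, 1 / (1e-8 * 484213.44))
  expect_error(ils_model(L = 100, r = 1e-8, t = 4.8e5), "inconsistent")
})

test_that("the retained-length threshold solves the survival equation", {
  model <- ils_model()
  m_min <- min_retained_length(model)
  expect_equal(ils_survival(m_min, model), 0.05, tolerance = 1e-6)
  expect_equal(m_min, 979.7, tolerance = 1e-3)
  expect_equal(min_retained_length(ils_model(alpha = 1)), 0)
  # doubling L doubles the threshold (m/L depends only on alpha)
  expect_equal(min_retained_length(ils_model(L = 2 * 206.52)), 2 * m_min,
               tolerance = 1e-6)
})

test_that("tract filtering retains exactly the sub-alpha survival calls", {
  model <- ils_model()
  tracts <- data.frame(chrom = "chr1",
                       start0 = c(0, 5000, 20000),
                       end0 = c(100, 15000, 20500))
  out <- filter_tracts(tracts, model)
  p <- ils_survival(tracts$end0 - tracts$start0, model)
  expect_equal(out$start0, tracts$start0[p < 0.05])
  expect_equal(out$p_ils, p[p < 0.05])
  expect_gt(ils_survival(100, model), 0.9)   # 100 bp tract: removed
  removed <- attr(out, "removed")
  expect_equal(removed$start0, c(0, 20000))  # 100 bp and 500 bp tracts
  expect_equal(out$start0, 5000)             # the 10 kb tract survives
  expect_equal(nrow(filter_tracts(tracts[0, ], model)), 0L)
})

test_that("donor overlap labels intervals by covering donor", {
  t1 <- data.frame(chrom = "chr1", start0 = c(0, 100), end0 = c(50, 200))
  t2 <- data.frame(chrom = "chr1", start0 = 150, end0 = 300)
  ov <- donor_overlap(t1, t2, names = c("banteng", "gaur"))
  expect_equal(ov$donor[ov$start0 == 150], "both")
  expect_equal(sort(ov$start0[ov$donor == "banteng"]), c(0, 100))
  expect_equal(ov$start0[ov$donor == "gaur"], 200)
  # disjoint and identical edge cases
  expect_true(all(donor_overlap(t1, data.frame(chrom = "chr1", start0 = 900,
                                               end0 = 950))$donor != "both"))
  same <- donor_overlap(t1, t1)
  expect_true(all(same$donor == "both"))
  # random sets agree with a quadratic coverage oracle
  set.seed(54)
  mk <- function() {
    s <- sort(sample(0:150, 8)) * 10
    data.frame(chrom = "chr1", start0 = s,
               end0 = s + sample(20:200, 8, replace = TRUE))
  }
  a <- mk(); b <- mk()
  ov2 <- donor_overlap(a, b)
  cov <- function(d, n = 2000) {
    v <- logical(n)
    for (i in seq_len(nrow(d))) v[(d$start0[i] + 1):d$end0[i]] <- TRUE
    v
  }
  expect_equal(interval_bp(ov2[ov2$donor == "both", ]),
               sum(cov(a) & cov(b)))
  expect_equal(interval_bp(ov2[ov2$donor == "donor1", ]),
               sum(cov(a) & !cov(b)))
  expect_equal(interval_bp(ov2[ov2$donor == "donor2", ]),
               sum(!cov(a) & cov(b)))
})
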