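#' ROH detection parameters
#'
#' Defaults reproduce the PLINK `--homozyg` settings used for cattle
#' resequencing panels: `--homozyg-gap 1000 --homozyg-kb 100 --homozyg-snp
#' 200 --homozyg-window-het 1 --homozyg-window-snp 100
#' --homozyg-window-threshold 0.05`.
#'
#' @param max_gap_kb Maximum inter-SNP gap inside a run, kb (default 1000).
#' @param min_length_kb Minimum reported run length, kb (default 100).
#' @param min_snps Minimum SNPs per reported run (default 200).
#' @param window_het_max Maximum heterozygous calls tolerated per scanning
#'   window (default 1).
#' @param window_snps Scanning-window size in SNPs (default 100).
#' @param window_threshold Minimum fraction of homozygous scanning windows
#'   covering a SNP for it to be ROH-eligible (default 0.05).
#' @return An `roh_params` list.
#' @export
roh_params <- function(max_gap_kb = 1000, min_length_kb = 100,
                       min_snps = 200, window_het_max = 1,
                       window_snps = 100, window_threshold = 0.05) {
  if (any(c(max_gap_kb, min_length_kb, min_snps, window_snps) <= 0)) {
    stop("ROH parameters must be positive")
  }
  if (window_threshold <= 0 || window_threshold > 1) {
    stop("window_threshold must lie in (0, 1]")
  }
  structure(list(max_gap_kb = max_gap_kb, min_length_kb = min_length_kb,
                 min_snps = min_snps, window_het_max = window_het_max,
                 window_snps = as.integer(window_snps),
                 window_threshold = window_threshold),
            class = "roh_params")
}

#' Detect runs of homozygosity for one sample
#'
#' PLINK-style scanning-window algorithm: a window of `window_snps`
#' consecutive SNPs is "homozygous" when it holds at most `window_het_max`
#' heterozygous calls (missing genotypes count as neither); each SNP's hit
#' rate is the fraction of windows containing it that are homozygous; SNPs
#' with hit rate >= `window_threshold` are ROH-eligible; maximal runs of
#' eligible SNPs are split at inter-SNP gaps exceeding `max_gap_kb` and
#' reported when they hold at least `min_snps` SNPs and span at least
#' `min_length_kb`.
#'
#' @param panel A `haplotype_panel`.
#' @param sample Sample id.
#' @param params An [roh_params()].
#' @return Data frame of segments: `sample`, `chrom`, `start0`, `end0`,
#'   `length`, `n_snps`, `class` (initially `"unclassified"`).
#' @export
detect_roh <- function(panel, sample, params = roh_params()) {
  cols <- sample_haplotypes(panel, sample)
  h1 <- panel$alleles[, cols[1]]
  h2 <- panel$alleles[, cols[2]]
  het <- as.integer(h1 != h2)          # NA where either call missing
  het[is.na(het)] <- 0L                # missing: neither het nor hom
  M <- length(het)
  w <- params$window_snps
  empty <- data.frame(sample = character(), chrom = character(),
                      start0 = numeric(), end0 = numeric(),
                      length = numeric(), n_snps = integer(),
                      class = character(), stringsAsFactors = FALSE)
  if (M < w) return(empty)
  nwin <- M - w + 1L
  cs <- cumsum(c(0L, het))
  hom_win <- (cs[(w + 1L):(M + 1L)] - cs[1:nwin]) <= params$window_het_max
  # hit rate of SNP k over windows [max(1, k-w+1), min(k, nwin)]
  csw <- cumsum(c(0L, as.integer(hom_win)))
  k <- seq_len(M)
  lo <- pmax(1L, k - w + 1L)
  hi <- pmin(k, nwin)
  hits <- csw[hi + 1L] - csw[lo]
  rate <- hits / (hi - lo + 1L)
  eligible <- rate >= params$window_threshold
  runs <- rle(eligible)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  segs <- list()
  pos <- panel$positions
  max_gap <- params$max_gap_kb * 1000
  for (r in which(runs$values)) {
    i0 <- starts[r]; i1 <- ends[r]
    idx <- i0:i1
    gaps <- diff(pos[idx])
    brk <- which(gaps > max_gap)
    piece_start <- c(i0, idx[brk + 1L])
    piece_end <- c(idx[brk], i1)
    for (p in seq_along(piece_start)) {
      a <- piece_start[p]; b <- piece_end[p]
      n_snp <- b - a + 1L
      s0 <- pos[a] - 1
      e0 <- pos[b]
      if (n_snp >= params$min_snps &&
          (e0 - s0) >= params$min_length_kb * 1000) {
        segs[[length(segs) + 1L]] <- data.frame(
          sample = sample, chrom = panel$chrom, start0 = s0, end0 = e0,
          length = e0 - s0, n_snps = n_snp, class = "unclassified",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(segs)) return(empty)
  do.call(rbind, segs)
}

#' Detect ROH for many samples
#' @param panel A `haplotype_panel`.
#' @param samples Sample ids (default: all).
#' @param params An [roh_params()].
#' @return Row-bound segment table across samples.
#' @export
detect_roh_all <- function(panel, samples = panel$sample_ids,
                           params = roh_params()) {
  do.call(rbind, lapply(samples, function(s) detect_roh(panel, s, params)))
}

#' Fit a three-component Gaussian mixture to ROH lengths
#'
#' Unsupervised EM fit of a `n_components` Gaussian mixture to ROH lengths
#' (on the log10 scale by default, since length distributions are strongly
#' right-skewed).  Components are ordered by mean; the boundary between
#' adjacent components is the length where their weighted densities cross
#' (the unique crossing between the two means), giving the short/medium and
#' medium/long thresholds.  EM restarts use k-means++-style seeding; the
#' restart with the best log-likelihood wins, ties broken by lowest restart
#' index.
#'
#' @param lengths Numeric vector of ROH lengths in bp (at least 30).
#' @param n_components Number of mixture components (default 3).
#' @param seed Integer seed for the restarts.
#' @param restarts Number of EM restarts (default 10).
#' @param scale `"log10"` (default) or `"linear"`.
#' @param max_iter,tol EM iteration controls.
#' @return An `roh_mixture` list: `means`, `sds`, `weights` (on the fit
#'   scale, ordered by mean), `boundaries_bp`, `loglik`, `scale`.
#' @export
fit_length_mixture <- function(lengths, n_components = 3L, seed = 1,
                               restarts = 10L, scale = c("log10", "linear"),
                               max_iter = 500L, tol = 1e-8) {
  scale <- match.arg(scale)
  if (length(lengths) < 30L) stop("insufficient data: need >= 30 ROH lengths")
  x <- if (scale == "log10") log10(lengths) else as.numeric(lengths)
  if (stats::sd(x) < 1e-8) stop("degenerate input: ROH lengths have near-zero variance")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- em_gmm_1d(x, n_components, max_iter, tol)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik + 1e-9)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("EM failed on every restart")
  o <- order(best$means)
  means <- best$means[o]; sds <- best$sds[o]; weights <- best$weights[o]
  bnd <- vapply(seq_len(n_components - 1L), function(i) {
    density_crossing(means[i], sds[i], weights[i],
                     means[i + 1L], sds[i + 1L], weights[i + 1L])
  }, numeric(1))
  boundaries_bp <- if (scale == "log10") 10^bnd else bnd
  structure(list(means = means, sds = sds, weights = weights,
                 boundaries = bnd, boundaries_bp = boundaries_bp,
                 loglik = best$loglik, loglik_trace = best$trace,
                 scale = scale),
            class = "roh_mixture")
}

# one EM run with k-means++-style center seeding
em_gmm_1d <- function(x, k, max_iter, tol) {
  n <- length(x)
  centers <- x[sample.int(n, 1L)]
  while (length(centers) < k) {
    d2 <- vapply(x, function(v) min((v - centers)^2), numeric(1))
    if (sum(d2) <= 0) {
      centers <- c(centers, x[sample.int(n, 1L)])
    } else {
      centers <- c(centers, x[sample.int(n, 1L, prob = d2)])
    }
  }
  assign <- apply(outer(x, centers, function(a, b) (a - b)^2), 1L, which.min)
  mu <- vapply(seq_len(k), function(j) {
    if (any(assign == j)) mean(x[assign == j]) else centers[j]
  }, numeric(1))
  sg <- vapply(seq_len(k), function(j) {
    s <- if (sum(assign == j) > 1L) stats::sd(x[assign == j]) else stats::sd(x) / k
    max(s, 1e-3, na.rm = TRUE)
  }, numeric(1))
  w <- vapply(seq_len(k), function(j) max(mean(assign == j), 1e-3), numeric(1))
  w <- w / sum(w)
  ll_old <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sg[j]),
                   numeric(length(x)))
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    resp <- dens / tot
    nk <- colSums(resp)
    nk[nk < 1e-10] <- 1e-10
    mu <- colSums(resp * x) / nk
    sg <- sqrt(colSums(resp * (outer(x, mu, "-"))^2) / nk)
    sg <- pmax(sg, 1e-4)
    w <- nk / length(x)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(means = mu, sds = sg, weights = w, loglik = ll, trace = trace)
}

# crossing point of two weighted normal densities between their means
density_crossing <- function(m1, s1, w1, m2, s2, w2) {
  f <- function(x) {
    log(w1) + stats::dnorm(x, m1, s1, log = TRUE) -
      log(w2) - stats::dnorm(x, m2, s2, log = TRUE)
  }
  lo <- m1; hi <- m2
  # densities may not cross strictly between means for very unequal weights;
  # widen slightly before giving up on the bracket
  if (f(lo) * f(hi) > 0) {
    lo <- m1 - 2 * s1
    hi <- m2 + 2 * s2
  }
  if (f(lo) * f(hi) > 0) return((m1 + m2) / 2)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Classify ROH segments by fitted length boundaries
#'
#' `length < b1` is short, `b1 <= length < b2` medium, `length >= b2` long
#' (left-closed convention: a length equal to a boundary takes the longer
#' class).
#'
#' @param segments Segment table from [detect_roh_all()].
#' @param mixture An `roh_mixture` from [fit_length_mixture()], or a numeric
#'   vector `c(b1, b2)` of boundaries in bp.
#' @return The segment table with `class` filled in.
#' @export
classify_roh <- function(segments, mixture) {
  b <- if (inherits(mixture, "roh_mixture")) mixture$boundaries_bp else mixture
  if (length(b) != 2L || any(diff(b) <= 0)) stop("need ordered boundaries b1 < b2")
  if (!nrow(segments)) return(segments)
  segments$class <- ifelse(segments$length < b[1], "short",
                           ifelse(segments$length < b[2], "medium", "long"))
  segments
}

#' Genomic inbreeding coefficient FROH
#'
#' `FROH = L(ROH) / L(Autosomes)`: the summed length of a sample's ROH
#' segments (overlaps merged first) over the total autosomal length.
#'
#' @param segments Segment table (one or more samples).
#' @param autosome_length Total autosome length in bp.
#' @return Data frame with `sample`, `l_roh`, `l_autosomes`, `froh`.
#' @export
froh <- function(segments, autosome_length) {
  if (autosome_length <= 0) stop("autosome_length must be positive")
  samples <- unique(segments$sample)
  out <- lapply(samples, function(s) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    m <- merge_intervals(data.frame(chrom = seg$chrom, start0 = seg$start0,
                                    end0 = seg$end0))
    l <- sum(m$end0 - m$start0)
    if (l > autosome_length) {
      stop(sprintf("ROH total (%g bp) exceeds autosome length for %s", l, s))
    }
    data.frame(sample = s, l_roh = l, l_autosomes = autosome_length,
               froh = l / autosome_length, stringsAsFactors = FALSE)
  })
  if (!length(out)) {
    return(data.frame(sample = character(), l_roh = numeric(),
                      l_autosomes = numeric(), froh = numeric()))
  }
  do.call(rbind, out)
}

#' Per-group ROH class summaries and class-length correlations
#'
#' For each group: count and cumulative length per length class, plus the
#' Pearson correlation of per-sample cumulative short-vs-medium and
#' short-vs-long lengths (undefined and flagged for groups with fewer than
#' 3 samples or zero variance).
#'
#' @param segments Classified segment table.
#' @param popmap Population map.
#' @return List with `group_class` (count/cumulative length table) and
#'   `correlations` (`group`, `pair`, `r`, `n`, `undefined`).
#' @export
class_summaries <- function(segments, popmap) {
  segments$group <- popmap$group[match(segments$sample, popmap$sample_id)]
  if (anyNA(segments$group)) stop("segment samples missing from population map")
  classes <- c("short", "medium", "long")
  gc <- do.call(rbind, lapply(split(segments, segments$group), function(d) {
    do.call(rbind, lapply(classes, function(cl) {
      dd <- d[d$class == cl, , drop = FALSE]
      data.frame(group = d$group[1], class = cl, n_segments = nrow(dd),
                 cumulative_bp = sum(dd$length), stringsAsFactors = FALSE)
    }))
  }))
  rownames(gc) <- NULL
  per_sample <- function(d) {
    samples <- unique(d$sample)
    sapply(classes, function(cl) {
      vapply(samples, function(s) sum(d$length[d$sample == s & d$class == cl]),
             numeric(1))
    })
  }
  cors <- do.call(rbind, lapply(split(segments, segments$group), function(d) {
    m <- per_sample(d)
    if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, classes))
    n <- nrow(m)
    one <- function(a, b) {
      if (n < 3 || stats::sd(m[, a]) == 0 || stats::sd(m[, b]) == 0) {
        c(r = NA_real_, undefined = 1)
      } else {
        c(r = stats::cor(m[, a], m[, b]), undefined = 0)
      }
    }
    sm <- one("short", "medium")
    sl <- one("short", "long")
    data.frame(group = d$group[1], pair = c("short_medium", "short_long"),
               r = c(sm["r"], sl["r"]), n = n,
               undefined = as.logical(c(sm["undefined"], sl["undefined"])),
               stringsAsFactors = FALSE)
  }))
  rownames(cors) <- NULL
  list(group_class = gc, correlations = cors)
}
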