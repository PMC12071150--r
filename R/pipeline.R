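#' Default pipeline configuration
#'
#' A complete demo configuration: four populations (an outgroup, a wild
#' donor, a divergent reference ancestry and an admixed target) with
#' planted introgression tracts, autozygous segments and a sweep, plus the
#' study's windowing and scan parameters.  Any part may be overridden by
#' the supplied list / YAML.
#'
#' @param n_diploids Diploids per population (default 50).
#' @param n_sites SNP count (default 100000).
#' @param chrom_length Chromosome length in bp (default 50 Mb).
#' @return Nested configuration list.
#' @export
default_config <- function(n_diploids = 50, n_sites = 100000,
                           chrom_length = 5e7) {
  list(
    outdir = "bovintro_run",
    seed = 1L,
    stages = c("simulate", "filter", "diversity", "roh", "selection",
               "introgression"),
    sim = list(
      chrom_length = chrom_length,
      n_sites = n_sites,
      n_founders = 300,
      switch_rate = 1e-5,
      populations = list(
        list(name = "OUT", n = n_diploids, f = 0.7, fixed_diff = 0.10),
        list(name = "WILD", n = n_diploids, f = 0.5, fixed_diff = 0.05),
        list(name = "IND", n = n_diploids, f = 0.02, fixed_diff = 0),
        list(name = "HN", n = n_diploids, f = 0.03, fixed_diff = 0)),
      introgression = list(donor = "WILD", target = "HN", n_tracts = 4,
                           tract_length = 2e5, recipient_freq = 0.3),
      autozygosity = list(target = "HN", classes = list(
        list(class = "short", n = 15, min_bp = 10^5.18, max_bp = 10^5.42),
        list(class = "medium", n = 15, min_bp = 10^5.88, max_bp = 10^6.12),
        list(class = "long", n = 15, min_bp = 10^6.5, max_bp = 10^6.7))),
      sweep = list(group = "HN", start0 = round(chrom_length * 0.45),
                   end0 = round(chrom_length * 0.45) + 2e5,
                   carrier_freq = 0.9),
      depth_mean = 12),
    window = list(size = 50000, step = 20000),
    filter = list(depth_low_frac = 1 / 3, depth_high_frac = 3, dr_min = 0.9),
    roh = list(max_gap_kb = 1000, min_length_kb = 100, min_snps = 200,
               window_het_max = 1, window_snps = 100,
               window_threshold = 0.05),
    selection = list(group = "HN", pi_quantile = 0.01, pi_tail = "lower",
                     ihs_abs_threshold = 2, ihs_window_top_fraction = 0.05,
                     truncation = 0.05, max_extent = 1e6, max_gap = 2e5,
                     min_mac = 2),
    uscan = list(w = 0.01, x = 0.20, y = 1.00, u_min = 1),
    ils = list(L = 206.52, alpha = 0.05),
    roles = list(p1 = "IND", p2 = "HN", p3 = "WILD", outgroup = "OUT"),
    dstat = list(block_size = 1e6, min_blocks = 20))
}

config_keys <- function() names(default_config())

#' Validate a pipeline configuration
#'
#' Schema check: unknown top-level keys are rejected, required keys and
#' basic ranges verified.  Violations are returned, not raised.
#'
#' @param config Configuration list or path to a YAML file.
#' @return Character vector of violations; empty when the config is valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  v <- character(0)
  unknown <- setdiff(names(config), config_keys())
  if (length(unknown)) {
    v <- c(v, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  for (req in c("outdir", "seed", "stages", "sim")) {
    if (is.null(config[[req]])) v <- c(v, paste0("missing key: ", req))
  }
  if (!is.null(config$sim)) {
    s <- config$sim
    if (is.null(s$n_sites) || s$n_sites < 2) {
      v <- c(v, "sim.n_sites must be >= 2")
    }
    if (is.null(s$populations) || !length(s$populations)) {
      v <- c(v, "sim.populations must be non-empty")
    } else {
      fs <- vapply(s$populations, function(p) p$f %||% -1, numeric(1))
      if (any(fs < 0 | fs >= 1)) v <- c(v, "population f must lie in [0, 1)")
    }
    if (!is.null(s$switch_rate) && s$switch_rate < 0) {
      v <- c(v, "sim.switch_rate must be >= 0")
    }
  }
  if (!is.null(config$window)) {
    w <- config$window
    if (!is.null(w$size) && !is.null(w$step) &&
        (w$step <= 0 || w$step > w$size)) {
      v <- c(v, "window.step must satisfy 0 < step <= size")
    }
  }
  if (!is.null(config$stages)) {
    known <- c("simulate", "filter", "diversity", "roh", "selection",
               "introgression")
    bad <- setdiff(config$stages, known)
    if (length(bad)) v <- c(v, paste0("unknown stage(s): ",
                                      paste(bad, collapse = ", ")))
  }
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable per-stage seed fan-out from the global seed
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Run the full scan pipeline on a simulated panel
#'
#' Executes the requested stages in dependency order on one simulated
#' chromosome: simulate (panels + planted truth + merged VCF), filter
#' (depth/DR site filter), diversity (windowed theta-pi, Tajima's D, FST
#' matrix, LD decay), roh (detection, mixture classification, FROH),
#' selection (iHS scan + theta-pi cutoff + candidate intersection) and
#' introgression (D statistic with jackknife Z, U scan, ILS-filtered
#' tracts).  Every output file is recorded in a manifest JSON with an MD5
#' checksum, so reruns with the same config and seed can be verified
#' byte-identical.
#'
#' @param config Configuration list (see [default_config()]) or YAML path.
#' @return Invisibly, a list with `outdir`, `manifest` (data frame) and the
#'   in-memory stage results.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  viol <- validate_config(config)
  if (length(viol)) {
    stop("invalid config:\n", paste0(" - ", viol, collapse = "\n"))
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  results <- list()
  note <- function(stage, path) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = basename(path),
      md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE)
  }
  stages <- config$stages
  run_stage <- function(name, fun) {
    if (!(name %in% stages)) return(invisible(NULL))
    tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  state <- new.env(parent = emptyenv())

  run_stage("simulate", function() {
    s <- config$sim
    pops <- do.call(rbind, lapply(s$populations, function(p) {
      data.frame(name = p$name, n = p$n, f = p$f,
                 fixed_diff = p$fixed_diff %||% 0, stringsAsFactors = FALSE)
    }))
    cfg <- sim_config(s$chrom_length, s$n_sites, pops,
                      n_founders = s$n_founders %||% 300,
                      switch_rate = s$switch_rate %||% 1e-5,
                      seed = stage_seed(config$seed, "simulate"))
    sim <- simulate_panel(cfg)
    truth <- sim$truth
    if (!is.null(s$sweep)) {
      sw <- s$sweep
      ps <- plant_sweep(sim$panels[[sw$group]], sw$start0, sw$end0,
                        sw$carrier_freq,
                        seed = stage_seed(config$seed, "sweep"))
      sim$panels[[sw$group]] <- ps$panel
      truth <- combine_truth(truth, ps$truth)
    }
    if (!is.null(s$introgression)) {
      it <- s$introgression
      pi_ <- plant_introgression(sim$panels[[it$target]],
                                 sim$panels[[it$donor]], it$n_tracts,
                                 it$tract_length, it$recipient_freq,
                                 seed = stage_seed(config$seed, "introgression_plant"),
                                 donor_name = it$donor)
      sim$panels[[it$target]] <- pi_$panel
      truth <- combine_truth(truth, pi_$truth)
    }
    if (!is.null(s$autozygosity)) {
      az <- s$autozygosity
      classes <- do.call(rbind, lapply(az$classes, as.data.frame))
      pa <- plant_autozygosity(sim$panels[[az$target]], classes,
                               seed = stage_seed(config$seed, "autozygosity"))
      sim$panels[[az$target]] <- pa$panel
      truth <- combine_truth(truth, pa$truth)
    }
    merged <- merge_panels(sim$panels)
    # synthetic site metadata: gamma-distributed depth, DR = 1
    set.seed(stage_seed(config$seed, "metadata"))
    dm <- s$depth_mean %||% 12
    merged$panel$site_depth <- round(stats::rgamma(n_sites(merged$panel),
                                                   shape = 8,
                                                   rate = 8 / dm), 2)
    merged$panel$site_dr <- rep(1, n_sites(merged$panel))
    state$panel <- merged$panel
    state$popmap <- merged$popmap
    state$truth <- truth
    vcf <- file.path(outdir, "panel.vcf")
    write_vcf(merged$panel, vcf); note("simulate", vcf)
    pm <- file.path(outdir, "popmap.tsv")
    write_popmap(merged$popmap, pm); note("simulate", pm)
    md <- file.path(outdir, "site_metadata.tsv")
    write_site_metadata(merged$panel, md); note("simulate", md)
    for (p in write_truth(truth, file.path(outdir, "truth"))) {
      note("simulate", p)
    }
    results$truth <<- truth
  })

  run_stage("filter", function() {
    f <- config$filter %||% list()
    cfg <- site_filter_config(f$depth_low_frac %||% 1 / 3,
                              f$depth_high_frac %||% 3,
                              f$dr_min %||% 0.9)
    filtered <- filter_sites(state$panel, cfg)
    removed <- attr(filtered, "removed")
    state$panel <- filtered
    p <- file.path(outdir, "filter_summary.tsv")
    utils::write.table(
      data.frame(rule = names(removed), removed = as.integer(removed),
                 retained = n_sites(filtered)),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    note("filter", p)
    results$filter <<- removed
  })

  spec <- window_spec(config$window$size %||% 50000,
                      config$window$step %||% 20000)

  run_stage("diversity", function() {
    groups <- unique(state$popmap$group)
    pis <- do.call(rbind, lapply(groups, function(g) {
      d <- pi_window(state$panel, state$popmap, g, spec)
      d$group <- g
      d
    }))
    p <- file.path(outdir, "pi_windows.tsv")
    write_window_stats(pis, p); note("diversity", p)
    td <- do.call(rbind, lapply(groups, function(g) {
      d <- tajimas_d_window(state$panel, state$popmap, g, spec)
      d$group <- g
      d
    }))
    p <- file.path(outdir, "tajimas_d_windows.tsv")
    write_window_stats(td, p); note("diversity", p)
    fm <- fst_matrix(state$panel, state$popmap)
    p <- file.path(outdir, "fst_matrix.tsv")
    utils::write.table(fm, p, sep = "\t", quote = FALSE)
    note("diversity", p)
    tgt <- config$selection$group %||% groups[length(groups)]
    ld <- ld_decay(state$panel, state$popmap, tgt)
    p <- file.path(outdir, "ld_decay.tsv")
    utils::write.table(ld, p, sep = "\t", quote = FALSE, row.names = FALSE)
    note("diversity", p)
    results$pi <<- pis
    results$fst <<- fm
    results$ld <<- ld
  })

  run_stage("roh", function() {
    r <- config$roh %||% list()
    params <- roh_params(r$max_gap_kb %||% 1000, r$min_length_kb %||% 100,
                         r$min_snps %||% 200, r$window_het_max %||% 1,
                         r$window_snps %||% 100,
                         r$window_threshold %||% 0.05)
    segs <- detect_roh_all(state$panel, params = params)
    p <- file.path(outdir, "roh_segments.tsv")
    utils::write.table(segs, p, sep = "\t", quote = FALSE, row.names = FALSE)
    note("roh", p)
    mix <- NULL
    if (nrow(segs) >= 30) {
      mix <- fit_length_mixture(segs$length,
                                seed = stage_seed(config$seed, "roh_mixture"))
      segs <- classify_roh(segs, mix)
      p <- file.path(outdir, "roh_classified.tsv")
      utils::write.table(segs, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      note("roh", p)
      p <- file.path(outdir, "roh_mixture.json")
      jsonlite::write_json(mix[c("means", "sds", "weights",
                                 "boundaries_bp", "scale")],
                           p, digits = NA)
      note("roh", p)
    }
    fr <- froh(segs, autosome_length = state$panel$chrom_length)
    p <- file.path(outdir, "froh.tsv")
    utils::write.table(fr, p, sep = "\t", quote = FALSE, row.names = FALSE)
    note("roh", p)
    results$roh <<- segs
    results$roh_mixture <<- mix
    results$froh <<- fr
  })

  run_stage("selection", function() {
    sel <- config$selection %||% list()
    grp <- sel$group
    cut <- selection_cutoffs(sel$pi_quantile %||% 0.01,
                             sel$pi_tail %||% "lower",
                             sel$ihs_abs_threshold %||% 2,
                             sel$ihs_window_top_fraction %||% 0.05)
    scan <- ihs_scan(state$panel, state$popmap, grp,
                     truncation = sel$truncation %||% 0.05,
                     max_extent = sel$max_extent %||% 1e6,
                     max_gap = sel$max_gap %||% 2e5,
                     min_mac = sel$min_mac %||% 2)
    std <- standardize_ihs(scan)
    p <- file.path(outdir, "ihs_sites.tsv")
    utils::write.table(std, p, sep = "\t", quote = FALSE, row.names = FALSE)
    note("selection", p)
    iws <- ihs_window_scan(std, spec, cut, chrom = state$panel$chrom,
                           chrom_length = state$panel$chrom_length)
    p <- file.path(outdir, "ihs_windows.tsv")
    write_window_stats(iws$windows, p); note("selection", p)
    piw <- pi_window(state$panel, state$popmap, grp, spec)
    pic <- pi_candidate_cutoff(piw, cut)
    p <- file.path(outdir, "pi_candidates.bed")
    write_bed(pic$candidates, p); note("selection", p)
    p <- file.path(outdir, "ihs_candidates.bed")
    write_bed(iws$candidates, p); note("selection", p)
    inter <- candidate_intersection(pic$candidates, iws$candidates)
    p <- file.path(outdir, "selection_intersection.bed")
    write_bed(inter$intervals, p); note("selection", p)
    results$ihs <<- std
    results$ihs_candidates <<- iws$candidates
    results$pi_candidates <<- pic$candidates
    results$selection_intersection <<- inter$intervals
  })

  run_stage("introgression", function() {
    roles <- config$roles
    fr <- site_frequencies(state$panel, state$popmap,
                           c(roles$p1, roles$p2, roles$p3, roles$outgroup))
    ds <- block_jackknife(fr$freq[, 1], fr$freq[, 2], fr$freq[, 3],
                          fr$freq[, 4], fr$pos,
                          block_size = config$dstat$block_size %||% 5e6,
                          min_blocks = config$dstat$min_blocks %||% 20)
    p <- file.path(outdir, "dstat.json")
    jsonlite::write_json(
      list(p1 = roles$p1, p2 = roles$p2, p3 = roles$p3,
           outgroup = roles$outgroup, abba = ds$abba, baba = ds$baba,
           d = ds$d, se = ds$se, z = ds$z, n_blocks = ds$n_blocks),
      p, auto_unbox = TRUE, digits = NA)
    note("introgression", p)
    u <- config$uscan %||% list()
    ucfg <- uscan_config(u$w %||% 0.01, u$x %||% 0.20, u$y %||% 1.00,
                         u$u_min %||% 1L)
    us <- u_scan(state$panel, state$popmap, roles$p1, roles$p2, roles$p3,
                 ucfg, spec)
    p <- file.path(outdir, "uscan_windows.tsv")
    write_window_stats(us$windows, p); note("introgression", p)
    ils <- ils_model(config$ils$L %||% 206.52,
                     alpha = config$ils$alpha %||% 0.05)
    tracts <- filter_tracts(windows_to_tracts(us$flagged), ils)
    p <- file.path(outdir, "introgressed_tracts.bed")
    write_bed(tracts, p); note("introgression", p)
    results$dstat <<- ds
    results$uscan <<- us
    results$tracts <<- tracts
  })

  manifest_df <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(stage = character(), file = character(), md5 = character())
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(
    list(seed = config$seed, stages = stages, files = manifest_df,
         config = config),
    mpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(outdir = outdir, manifest = manifest_df,
                 results = results))
}
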