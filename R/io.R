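#' Read a phased VCF into a haplotype panel
#'
#' Parses a VCF v4.x file (via vcfR) into a [haplotype_panel()].  Only
#' biallelic SNP records are kept when `biallelic_only` is `TRUE`
#' (multi-allelic records are dropped, not split).  Genotypes must use the
#' GT field; the panel is marked phased only when every non-missing genotype
#' uses the `|` separator.
#'
#' @param path Path to a VCF (optionally bgzipped).
#' @param region Optional `"chrom"` or `"chrom:start-end"` restriction
#'   (1-based, inclusive).
#' @param biallelic_only Drop records with more than one ALT allele
#'   (default `TRUE`).
#' @return A `haplotype_panel`.
#' @export
read_vcf <- function(path, region = NULL, biallelic_only = TRUE) {
  if (!file.exists(path)) stop(sprintf("VCF not found: %s", path))
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) {
                  stop(sprintf("malformed VCF '%s': %s", path, conditionMessage(e)))
                })
  fix <- v@fix
  chroms <- fix[, "CHROM"]
  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    r <- parse_region(region)
    keep <- keep & chroms == r$chrom
    if (!is.na(r$start)) {
      pos <- as.numeric(fix[, "POS"])
      keep <- keep & pos >= r$start & pos <= r$end
    }
  }
  if (biallelic_only) {
    alt <- fix[, "ALT"]
    keep <- keep & !grepl(",", alt, fixed = TRUE) & !is.na(alt)
  }
  if (!any(keep)) stop("no records retained from VCF")
  fix <- fix[keep, , drop = FALSE]
  if (length(unique(fix[, "CHROM"])) > 1L) {
    stop("VCF spans multiple chromosomes; read one at a time via region=")
  }
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  sep <- substr(gt, 2, 2)
  phased <- all(sep[!is.na(gt) & gt != "."] %in% c("|", ""))
  a1 <- suppressWarnings(as.integer(substr(gt, 1, 1)))
  a2 <- suppressWarnings(as.integer(substr(gt, 3, 3)))
  n <- nrow(gt)
  alleles <- matrix(NA_integer_, nrow = n, ncol = 2L * ncol(gt))
  alleles[, seq(1L, 2L * ncol(gt), by = 2L)] <- a1
  alleles[, seq(2L, 2L * ncol(gt), by = 2L)] <- a2
  haplotype_panel(fix[1, "CHROM"], as.numeric(fix[, "POS"]), alleles,
                  colnames(gt), phased = phased)
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
  if (!length(m)) stop(sprintf("cannot parse region '%s'", region))
  list(chrom = m[2],
       start = if (m[4] == "") NA_real_ else as.numeric(m[4]),
       end = if (m[5] == "") NA_real_ else as.numeric(m[5]))
}

#' Write a haplotype panel to a VCF v4.2 file
#'
#' Emits one biallelic SNP record per site with placeholder REF/ALT
#' nucleotides (`A`/`C`: allele 0 maps to REF, allele 1 to ALT) and phased
#' (`0|1`) or unphased (`0/1`) GT fields.
#'
#' @param panel A `haplotype_panel`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(panel, path) {
  sep <- if (panel$phased) "|" else "/"
  odd <- seq(1L, n_haplotypes(panel), by = 2L)
  a1 <- panel$alleles[, odd, drop = FALSE]
  a2 <- panel$alleles[, odd + 1L, drop = FALSE]
  g1 <- ifelse(is.na(a1), ".", a1)
  g2 <- ifelse(is.na(a2), ".", a2)
  gt <- matrix(paste0(g1, sep, g2), nrow = n_sites(panel))
  body <- cbind(panel$chrom, format(panel$positions, scientific = FALSE, trim = TRUE),
                ".", "A", "C", ".", "PASS", ".", "GT", gt)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", panel$chrom,
            as.integer(panel$chrom_length)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' @param path Tab-separated file with columns `sample_id` and `group`
#'   (header optional; detected from the first line).
#' @return Data frame with character columns `sample_id`, `group`.
#' @export
read_popmap <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^sample_id\t", first)
  df <- if (has_header) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE,
                      col.names = c("sample_id", "group"))
  }
  names(df)[1:2] <- c("sample_id", "group")
  df <- df[, c("sample_id", "group")]
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) {
    stop("duplicated sample ids in population map: ",
         paste(unique(dup), collapse = ", "))
  }
  df
}

#' Write a sample-to-population map
#' @param popmap Data frame with columns `sample_id`, `group`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(popmap[, c("sample_id", "group")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-site depth/DR metadata sidecar
#'
#' The dominance ratio (DR) has no standard VCF encoding, so depth and DR
#' travel in a TSV sidecar keyed by position.
#'
#' @param panel A `haplotype_panel` with `site_depth`/`site_dr` set.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_site_metadata <- function(panel, path) {
  df <- data.frame(chrom = panel$chrom, pos = panel$positions,
                   depth = if (is.null(panel$site_depth)) NA else panel$site_depth,
                   dr = if (is.null(panel$site_dr)) NA else panel$site_dr)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach a depth/DR sidecar to a panel
#' @param panel A `haplotype_panel`.
#' @param path Sidecar TSV written by [write_site_metadata()].
#' @return The panel with `site_depth` and `site_dr` filled in.
#' @export
read_site_metadata <- function(panel, path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  i <- match(panel$positions, df$pos)
  if (anyNA(i)) stop("sidecar is missing positions present in the panel")
  panel$site_depth <- df$depth[i]
  panel$site_dr <- df$dr[i]
  panel
}

#' Write intervals as BED (0-based half-open)
#' @param intervals Data frame with columns `chrom`, `start0`, `end0` and
#'   optionally `name`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  cols <- c("chrom", "start0", "end0")
  if ("name" %in% names(intervals)) cols <- c(cols, "name")
  df <- intervals[, cols, drop = FALSE]
  df$start0 <- format(df$start0, scientific = FALSE, trim = TRUE)
  df$end0 <- format(df$end0, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#' @param path BED path (0-based half-open; 3 or more columns).
#' @return Data frame with columns `chrom`, `start0`, `end0` and `name` when
#'   a fourth column is present.
#' @export
read_bed <- function(path) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("malformed BED '%s': %s", path,
                                     conditionMessage(e))))
  if (ncol(df) < 3L) stop(sprintf("malformed BED '%s': fewer than 3 columns", path))
  if (!is.numeric(df[[2]]) || !is.numeric(df[[3]])) {
    stop(sprintf("malformed BED '%s': non-numeric coordinates", path))
  }
  names(df)[1:3] <- c("chrom", "start0", "end0")
  if (ncol(df) >= 4L) names(df)[4] <- "name"
  df[, seq_len(min(4L, ncol(df))), drop = FALSE]
}

#' Write a per-window statistic table
#' @param windows Data frame of window statistics (chrom, start0, end0,
#'   n_sites, value, ...).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_window_stats <- function(windows, path) {
  utils::write.table(windows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
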