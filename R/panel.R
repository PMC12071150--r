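#' Phased haplotype panel
#'
#' The central in-memory container: a matrix of biallelic alleles over
#' `n_sites` rows and `2 * n_samples` haplotype columns, with 1-based physical
#' positions.  Allele 0 is the ancestral (REF) allele and 1 the derived (ALT)
#' allele; missing calls are `NA` and are excluded from every statistic.
#' Consecutive column pairs belong to one diploid sample.
#'
#' @param chrom Chromosome label (single string).
#' @param positions Integer vector of 1-based bp coordinates, strictly
#'   increasing.
#' @param alleles Integer matrix (`n_sites` x `n_haplotypes`) with entries in
#'   `{0, 1, NA}`.
#' @param sample_ids Character vector of diploid sample names;
#'   `length(sample_ids) * 2 == ncol(alleles)`.
#' @param phased Logical; whether haplotype columns carry phase information.
#' @param site_depth Optional numeric vector of per-site mean sequencing
#'   depth (x coverage).
#' @param site_dr Optional numeric vector of per-site dominance ratio in
#'   `[0, 1]` (a site-quality scalar supplied alongside the VCF).
#' @param chrom_length Optional chromosome length in bp; defaults to the last
#'   position.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(chrom, positions, alleles, sample_ids,
                            phased = TRUE, site_depth = NULL, site_dr = NULL,
                            chrom_length = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  positions <- as.numeric(positions)
  if (length(chrom) != 1L) stop("chrom must be a single label")
  if (nrow(alleles) != length(positions)) {
    stop("alleles must have one row per position")
  }
  if (length(positions) > 1L && any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing")
  }
  if (any(positions < 1)) stop("positions are 1-based and must be >= 1")
  vals <- alleles[!is.na(alleles)]
  if (length(vals) && !all(vals %in% c(0L, 1L))) {
    stop("alleles must be 0, 1 or NA")
  }
  if (2L * length(sample_ids) != ncol(alleles)) {
    stop("haplotype count must equal 2 x sample count")
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (!is.null(site_depth) && length(site_depth) != length(positions)) {
    stop("site_depth length mismatch")
  }
  if (!is.null(site_dr)) {
    if (length(site_dr) != length(positions)) stop("site_dr length mismatch")
    if (any(site_dr < 0 | site_dr > 1, na.rm = TRUE)) {
      stop("site_dr must lie in [0, 1]")
    }
  }
  if (is.null(chrom_length)) {
    chrom_length <- if (length(positions)) max(positions) else 1
  }
  colnames(alleles) <- paste0(rep(sample_ids, each = 2L), c("_1", "_2"))
  structure(
    list(chrom = as.character(chrom), positions = positions,
         alleles = alleles, sample_ids = as.character(sample_ids),
         phased = isTRUE(phased), site_depth = site_depth, site_dr = site_dr,
         chrom_length = as.numeric(chrom_length)),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "haplotype_panel: %s, %d sites x %d haplotypes (%d samples), %s\n",
    x$chrom, n_sites(x), n_haplotypes(x), length(x$sample_ids),
    if (x$phased) "phased" else "unphased"))
  invisible(x)
}

#' Number of sites in a panel
#' @param panel A `haplotype_panel`.
#' @return Integer count.
#' @export
n_sites <- function(panel) length(panel$positions)

#' Number of haplotypes in a panel
#' @param panel A `haplotype_panel`.
#' @return Integer count.
#' @export
n_haplotypes <- function(panel) ncol(panel$alleles)

#' Subset a panel to a set of site indices
#'
#' Order is preserved; site metadata (depth, DR) is carried along.
#'
#' @param panel A `haplotype_panel`.
#' @param idx Increasing integer site indices (or logical mask).
#' @return A `haplotype_panel` with the selected sites.
#' @export
subset_sites <- function(panel, idx) {
  if (is.logical(idx)) idx <- which(idx)
  haplotype_panel(
    panel$chrom, panel$positions[idx],
    panel$alleles[idx, , drop = FALSE], panel$sample_ids,
    phased = panel$phased,
    site_depth = panel$site_depth[idx], site_dr = panel$site_dr[idx],
    chrom_length = panel$chrom_length)
}

#' Haplotype column indices of a diploid sample
#' @param panel A `haplotype_panel`.
#' @param sample Sample id present in the panel.
#' @return Integer vector of the sample's two haplotype columns.
#' @export
sample_haplotypes <- function(panel, sample) {
  i <- match(sample, panel$sample_ids)
  if (is.na(i)) stop(sprintf("sample '%s' not in panel", sample))
  c(2L * i - 1L, 2L * i)
}

#' Haplotype column indices of a population group
#'
#' @param panel A `haplotype_panel`.
#' @param popmap A population map (see [read_popmap()]), or `NULL` to select
#'   every haplotype.
#' @param group Group label; ignored when `popmap` is `NULL`.
#' @return Integer vector of haplotype columns belonging to the group.
#' @export
group_haplotypes <- function(panel, popmap = NULL, group = NULL) {
  if (is.null(popmap)) return(seq_len(n_haplotypes(panel)))
  check_popmap(panel, popmap)
  ids <- popmap$sample_id[popmap$group == group]
  if (!length(ids)) stop(sprintf("group '%s' absent from population map", group))
  ids <- intersect(panel$sample_ids, ids)
  if (!length(ids)) stop(sprintf("no panel sample belongs to group '%s'", group))
  as.vector(vapply(ids, function(s) sample_haplotypes(panel, s), integer(2)))
}

#' Validate that every panel sample is mapped to exactly one group
#' @param panel A `haplotype_panel`.
#' @param popmap Population map data frame.
#' @return Invisibly `TRUE`; errors listing unmapped samples otherwise.
#' @export
check_popmap <- function(panel, popmap) {
  missing <- setdiff(panel$sample_ids, popmap$sample_id)
  if (length(missing)) {
    stop("samples missing from population map: ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Column-bind panels that share sites
#'
#' Merges per-population panels (identical chrom/positions) into one panel
#' and returns the corresponding population map.
#'
#' @param panels Named list of `haplotype_panel` objects; names are group
#'   labels.
#' @return List with elements `panel` (merged) and `popmap` (data frame with
#'   columns `sample_id`, `group`).
#' @export
merge_panels <- function(panels) {
  stopifnot(length(panels) >= 1L, !is.null(names(panels)))
  ref <- panels[[1L]]
  for (p in panels[-1L]) {
    if (!identical(p$positions, ref$positions) || p$chrom != ref$chrom) {
      stop("panels must share chromosome and positions to merge")
    }
  }
  alleles <- do.call(cbind, lapply(panels, function(p) p$alleles))
  ids <- unlist(lapply(panels, function(p) p$sample_ids), use.names = FALSE)
  popmap <- data.frame(
    sample_id = ids,
    group = rep(names(panels), vapply(panels, function(p) length(p$sample_ids),
                                      integer(1))),
    stringsAsFactors = FALSE)
  list(panel = haplotype_panel(ref$chrom, ref$positions, alleles, ids,
                               phased = ref$phased,
                               site_depth = ref$site_depth,
                               site_dr = ref$site_dr,
                               chrom_length = ref$chrom_length),
       popmap = popmap)
}

#' Per-site derived-allele frequency within a haplotype set
#'
#' Frequencies use the per-site count of called (non-missing) haplotypes.
#'
#' @param panel A `haplotype_panel`.
#' @param hap_idx Haplotype column indices (default: all).
#' @return Data frame with columns `freq` (derived-allele frequency, `NaN`
#'   when no haplotype is called) and `n_called`.
#' @export
site_freq <- function(panel, hap_idx = seq_len(n_haplotypes(panel))) {
  sub <- panel$alleles[, hap_idx, drop = FALSE]
  n_called <- rowSums(!is.na(sub))
  cnt <- rowSums(sub, na.rm = TRUE)
  data.frame(freq = cnt / n_called, n_called = n_called)
}
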