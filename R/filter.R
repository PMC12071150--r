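#' Site-filter configuration
#'
#' Depth bounds are expressed relative to the mean site depth: a site is
#' kept when its depth lies in `[depth_low_frac * mean, depth_high_frac *
#' mean]` and its dominance ratio exceeds `dr_min`.
#'
#' @param depth_low_frac Lower bound as a fraction of mean depth
#'   (default 1/3).
#' @param depth_high_frac Upper bound as a multiple of mean depth
#'   (default 3).
#' @param dr_min Dominance-ratio threshold; sites with DR > `dr_min` are
#'   retained (default 0.9).
#' @param biallelic_only Logical; kept for symmetry with VCF reading
#'   (panels are already biallelic).
#' @return A `site_filter_config` list.
#' @export
site_filter_config <- function(depth_low_frac = 1 / 3, depth_high_frac = 3,
                               dr_min = 0.9, biallelic_only = TRUE) {
  if (!(depth_low_frac > 0 && depth_low_frac < depth_high_frac)) {
    stop("need 0 < depth_low_frac < depth_high_frac")
  }
  structure(list(depth_low_frac = depth_low_frac,
                 depth_high_frac = depth_high_frac,
                 dr_min = dr_min, biallelic_only = isTRUE(biallelic_only)),
            class = "site_filter_config")
}

#' Filter panel sites on depth and dominance ratio
#'
#' @param panel A `haplotype_panel` carrying `site_depth` and `site_dr`.
#' @param cfg A [site_filter_config()].
#' @return The filtered panel; attribute `"removed"` holds the count removed
#'   by each rule (a site failing both rules is counted under both).
#' @export
filter_sites <- function(panel, cfg = site_filter_config()) {
  if (is.null(panel$site_depth)) stop("depth filter requested but site_depth absent")
  if (is.null(panel$site_dr)) stop("DR filter requested but site_dr absent")
  mean_depth <- mean(panel$site_depth)
  lo <- cfg$depth_low_frac * mean_depth
  hi <- cfg$depth_high_frac * mean_depth
  depth_ok <- panel$site_depth >= lo & panel$site_depth <= hi
  dr_ok <- panel$site_dr > cfg$dr_min
  keep <- depth_ok & dr_ok
  if (!any(keep)) stop("site filter removed every site")
  out <- subset_sites(panel, keep)
  attr(out, "removed") <- c(depth = sum(!depth_ok), dr = sum(!dr_ok))
  out
}
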