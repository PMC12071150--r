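#' Sliding-window specification
#'
#' @param size Window size in bp (default 50 kb).
#' @param step Step between window starts in bp (default 20 kb);
#'   `0 < step <= size`.
#' @return A `window_spec` list.
#' @export
window_spec <- function(size = 50000, step = 20000) {
  if (size <= 0) stop("window size must be positive")
  if (step <= 0 || step > size) stop("step must satisfy 0 < step <= size")
  structure(list(size = as.numeric(size), step = as.numeric(step)),
            class = "window_spec")
}

#' Enumerate sliding windows over a panel
#'
#' Windows are `[start, start + size)` in 0-based half-open coordinates,
#' advancing by `step` from position 0 while the start lies inside the
#' chromosome.  Empty windows are kept and flagged.
#'
#' @param panel A `haplotype_panel`, or a numeric vector of 1-based
#'   positions.
#' @param spec A [window_spec()].
#' @param chrom_length Chromosome length in bp; defaults to the panel's.
#' @return Data frame with columns `start0`, `end0`, `first_site`,
#'   `last_site` (site index range, `NA` when empty), `n_sites`, `empty`.
#' @export
iter_windows <- function(panel, spec, chrom_length = NULL) {
  if (inherits(panel, "haplotype_panel")) {
    pos0 <- panel$positions - 1
    if (is.null(chrom_length)) chrom_length <- panel$chrom_length
  } else {
    pos0 <- as.numeric(panel) - 1
    if (is.null(chrom_length)) chrom_length <- max(pos0) + 1
  }
  starts <- seq(0, max(0, chrom_length - 1), by = spec$step)
  starts <- starts[starts < chrom_length]
  ends <- starts + spec$size
  # sites are sorted: locate [start, end) ranges by binary search
  first <- findInterval(starts - 0.5, pos0) + 1L
  last <- findInterval(ends - 0.5, pos0)
  n <- pmax(0L, last - first + 1L)
  data.frame(start0 = starts, end0 = ends,
             first_site = ifelse(n > 0L, first, NA_integer_),
             last_site = ifelse(n > 0L, last, NA_integer_),
             n_sites = n, empty = n == 0L)
}

#' Indices of sites falling in one window
#' @param panel A `haplotype_panel`.
#' @param start0,end0 Window bounds, 0-based half-open.
#' @return Integer site indices.
#' @export
sites_in_window <- function(panel, start0, end0) {
  pos0 <- panel$positions - 1
  which(pos0 >= start0 & pos0 < end0)
}
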