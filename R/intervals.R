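#' Merge overlapping or touching intervals
#' @param intervals Data frame with `chrom`, `start0`, `end0`.
#' @return Merged, sorted interval data frame.
#' @export
merge_intervals <- function(intervals) {
  if (!nrow(intervals)) {
    return(data.frame(chrom = character(), start0 = numeric(),
                      end0 = numeric(), stringsAsFactors = FALSE))
  }
  out <- lapply(split(intervals, intervals$chrom), function(d) {
    d <- d[order(d$start0, d$end0), , drop = FALSE]
    s <- d$start0; e <- d$end0
    ms <- s[1]; me <- e[1]
    res_s <- numeric(0); res_e <- numeric(0)
    for (i in seq_along(s)[-1]) {
      if (s[i] <= me) {
        me <- max(me, e[i])
      } else {
        res_s <- c(res_s, ms); res_e <- c(res_e, me)
        ms <- s[i]; me <- e[i]
      }
    }
    data.frame(chrom = d$chrom[1], start0 = c(res_s, ms),
               end0 = c(res_e, me), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Intersect two interval sets
#'
#' Both sets are merged first; the result is the set of half-open intervals
#' covered by both.
#'
#' @param a,b Interval data frames (`chrom`, `start0`, `end0`).
#' @return Interval data frame of intersections.
#' @export
intersect_intervals <- function(a, b) {
  empty <- data.frame(chrom = character(), start0 = numeric(),
                      end0 = numeric(), stringsAsFactors = FALSE)
  if (!nrow(a) || !nrow(b)) return(empty)
  a <- merge_intervals(a)
  b <- merge_intervals(b)
  res <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    aa <- a[a$chrom == ch, ]
    bb <- b[b$chrom == ch, ]
    for (i in seq_len(nrow(aa))) {
      s <- pmax(aa$start0[i], bb$start0)
      e <- pmin(aa$end0[i], bb$end0)
      keep <- s < e
      if (any(keep)) {
        res[[length(res) + 1L]] <- data.frame(
          chrom = ch, start0 = s[keep], end0 = e[keep],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start0), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subtract interval set b from a
#' @param a,b Interval data frames.
#' @return Parts of `a` not covered by `b`.
#' @export
setdiff_intervals <- function(a, b) {
  if (!nrow(a)) return(a[, c("chrom", "start0", "end0")])
  a <- merge_intervals(a)
  if (!nrow(b)) return(a)
  b <- merge_intervals(b)
  res <- list()
  for (i in seq_len(nrow(a))) {
    ch <- a$chrom[i]
    s <- a$start0[i]; e <- a$end0[i]
    bb <- b[b$chrom == ch & b$start0 < e & b$end0 > s, , drop = FALSE]
    cur <- s
    if (nrow(bb)) {
      bb <- bb[order(bb$start0), , drop = FALSE]
      for (j in seq_len(nrow(bb))) {
        if (bb$start0[j] > cur) {
          res[[length(res) + 1L]] <- data.frame(chrom = ch, start0 = cur,
                                                end0 = bb$start0[j])
        }
        cur <- max(cur, bb$end0[j])
      }
    }
    if (cur < e) {
      res[[length(res) + 1L]] <- data.frame(chrom = ch, start0 = cur, end0 = e)
    }
  }
  if (!length(res)) {
    return(data.frame(chrom = character(), start0 = numeric(),
                      end0 = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Total bp covered by an interval set
#' @param intervals Interval data frame.
#' @return Numeric bp count (overlaps merged first).
#' @export
interval_bp <- function(intervals) {
  m <- merge_intervals(intervals)
  sum(m$end0 - m$start0)
}
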