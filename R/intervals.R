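#' Merge overlapping or nearby intervals
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param gap Intervals closer than this (bp) are merged (default 0:
#'   merge only on overlap/adjacency).
#' @return Tibble of merged intervals, sorted.
#' @export
merge_intervals <- function(intervals, gap = 0) {
  if (nrow(intervals) == 0) return(intervals)
  x <- dplyr::arrange(intervals, .data$chrom, .data$start)
  out <- list()
  cur <- x[1, c("chrom", "start", "end")]
  for (i in seq_len(nrow(x))[-1]) {
    if (x$chrom[i] == cur$chrom && x$start[i] <= cur$end + gap) {
      cur$end <- max(cur$end, x$end[i])
    } else {
      out[[length(out) + 1]] <- cur
      cur <- x[i, c("chrom", "start", "end")]
    }
  }
  out[[length(out) + 1]] <- cur
  dplyr::bind_rows(out)
}

#' Intersect two interval sets
#'
#' @param a,b Tibbles with `chrom`, `start`, `end`.
#' @return Tibble of the pairwise intersections (>= 1 bp, half-open).
#' @export
intersect_intervals <- function(a, b) {
  out <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- a[a$chrom == ch, ]; bi <- b[b$chrom == ch, ]
    for (i in seq_len(nrow(ai))) {
      s <- pmax(ai$start[i], bi$start); e <- pmin(ai$end[i], bi$end)
      hit <- which(s < e)
      if (length(hit))
        out[[length(out) + 1]] <- tibble::tibble(chrom = ch,
                                                 start = s[hit],
                                                 end = e[hit])
    }
  }
  if (length(out) == 0)
    return(tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0)))
  merge_intervals(dplyr::bind_rows(out))
}

#' Mutual-overlap sites of several named tracks
#'
#' Successively intersects the interval sets of the named marks, yielding
#' the genomic sites where all of them co-occur.
#'
#' @param tracks Tibble with `mark`, `chrom`, `start`, `end` (cohort-level
#'   tracks; a `sample` column, if present, is ignored after unioning).
#' @param marks Character vector of mark names.
#' @return Tibble of co-occurrence intervals.
#' @export
intersect_tracks <- function(tracks, marks) {
  stopifnot(all(marks %in% tracks$mark))
  sets <- lapply(marks, function(m)
    merge_intervals(tracks[tracks$mark == m, c("chrom", "start", "end")]))
  Reduce(intersect_intervals, sets)
}

#' Which points fall inside any interval
#'
#' @param chrom,pos Vectors of point coordinates.
#' @param intervals Tibble with `chrom`, `start`, `end`.
#' @param extend Extend each interval by this many bp on both ends.
#' @return Logical vector (position contained, half-open).
#' @export
points_in_intervals <- function(chrom, pos, intervals, extend = 0) {
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    iv <- intervals[intervals$chrom == ch, ]
    idx <- which(chrom == ch)
    if (nrow(iv) == 0 || length(idx) == 0) next
    ord <- order(iv$start)
    st <- iv$start[ord] - extend; en <- iv$end[ord] + extend
    j <- findInterval(pos[idx], st)
    out[idx] <- j >= 1 & pos[idx] < en[pmax(j, 1)]
    # nested/unsorted ends: fall back to any-overlap check where needed
    miss <- idx[!out[idx]]
    if (length(miss))
      out[miss] <- vapply(pos[miss], function(p)
        any(p >= st & p < en), logical(1))
  }
  out
}
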