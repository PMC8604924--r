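#' Filtering thresholds for copy-number data
#'
#' Defaults follow the operating points used for 10 kb windowed copy-number
#' data from high-coverage sequencing of proliferating lines: windows whose
#' across-sample median (or quartiles) deviate by more than 0.4 copies from
#' the genome-wide "common" copy number are dropped; individual data points
#' are dropped at 0.6 copies from common or 0.25 copies from the window
#' median; profiles are smoothed across gaps shorter than 300 kb and
#' segments shorter than 300 kb are discarded.
#'
#' @param common_delta,quartile_delta,abs_outlier,rel_outlier Copy-number
#'   deltas (copies).
#' @param gap_smooth_max,min_segment Lengths in bp.
#' @return List of class `filter_thresholds`.
#' @export
filter_thresholds <- function(common_delta = 0.4, quartile_delta = 0.4,
                              abs_outlier = 0.6, rel_outlier = 0.25,
                              gap_smooth_max = 300e3, min_segment = 300e3) {
  vals <- list(common_delta = common_delta, quartile_delta = quartile_delta,
               abs_outlier = abs_outlier, rel_outlier = rel_outlier,
               gap_smooth_max = gap_smooth_max, min_segment = min_segment)
  if (any(unlist(vals) <= 0)) stop("all thresholds must be positive")
  structure(vals, class = "filter_thresholds")
}

#' Genome-wide "common" copy number
#'
#' The median, over unmasked windows, of each window's across-sample median.
#'
#' @param matrix An [rt_matrix()].
#' @return Scalar copy number.
#' @export
common_copy_number <- function(matrix) {
  keep <- setdiff(seq_len(ncol(matrix$values)), matrix$mask_windows)
  med <- apply(matrix$values[, keep, drop = FALSE], 2, stats::median,
               na.rm = TRUE)
  stats::median(med, na.rm = TRUE)
}

overlapping_windows <- function(grid, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(nrow(intervals))) {
    hits <- c(hits, which(grid$chrom == intervals$chrom[i] &
                            grid$start < intervals$end[i] &
                            grid$end > intervals$start[i]))
  }
  sort(unique(hits))
}

#' Global window filter
#'
#' Removes windows whose copy number is unreliable across the whole cohort:
#' windows overlapping assembly gaps or known structural variants, windows
#' whose across-sample median deviates from the common copy number by more
#' than `common_delta`, and windows whose 25th or 75th across-sample
#' percentile deviates by more than `quartile_delta` (which catches outlier
#' windows the median misses).
#'
#' @param raw An [rt_matrix()] in `"raw"` state.
#' @param thresholds A [filter_thresholds()].
#' @param known_sv_intervals Optional tibble (`chrom`, `start`, `end`) of
#'   SV/CNV intervals to exclude.
#' @param gap_intervals Optional tibble of assembly-gap intervals.
#' @return The matrix with the global mask set and masked values moved to
#'   `removed_values`.
#' @export
filter_windows_global <- function(raw, thresholds = filter_thresholds(),
                                  known_sv_intervals = NULL,
                                  gap_intervals = NULL) {
  stopifnot(inherits(raw, "rt_matrix"))
  if (ncol(raw$values) == 0) stop("empty matrix")
  v <- raw$values
  common <- common_copy_number(raw)
  med <- apply(v, 2, stats::median, na.rm = TRUE)
  q25 <- apply(v, 2, stats::quantile, probs = 0.25, na.rm = TRUE)
  q75 <- apply(v, 2, stats::quantile, probs = 0.75, na.rm = TRUE)
  crit <- list(
    gaps = overlapping_windows(raw$grid, gap_intervals),
    sv = overlapping_windows(raw$grid, known_sv_intervals),
    median = which(abs(med - common) > thresholds$common_delta),
    quartile = which(abs(q25 - common) > thresholds$quartile_delta |
                       abs(q75 - common) > thresholds$quartile_delta))
  mask <- sort(unique(c(raw$mask_windows, unlist(crit))))
  if (length(mask) >= ncol(v)) {
    dominant <- names(which.max(lengths(crit)))
    stop("all windows removed by global filtering (dominating criterion: ",
         dominant, ")")
  }
  removed <- raw$removed_values
  removed[, mask] <- v[, mask]
  v[, mask] <- NA_real_
  out <- rt_matrix(v, raw$grid, state = "raw", mask_windows = mask,
                   removed_values = removed)
  attr(out, "filter_counts") <- lengths(crit)
  out
}

#' Per-sample outlier point filter
#'
#' Masks, in individual samples, data points at least `abs_outlier` copies
#' from the common copy number or at least `rel_outlier` copies from that
#' window's across-sample median, plus points inside sample-specific CNV
#' intervals. Masked raw values are retained in `removed_values` for the
#' downstream rtQTL artifact filter. The result is the "filtered raw" data.
#'
#' @param matrix An [rt_matrix()] after [filter_windows_global()].
#' @param thresholds A [filter_thresholds()].
#' @param per_sample_cnv_intervals Optional tibble (`sample`, `chrom`,
#'   `start`, `end`).
#' @return The matrix in `"filtered_raw"` state.
#' @export
filter_points_per_sample <- function(matrix,
                                     thresholds = filter_thresholds(),
                                     per_sample_cnv_intervals = NULL) {
  stopifnot(inherits(matrix, "rt_matrix"))
  v <- matrix$values
  common <- common_copy_number(matrix)
  med <- apply(v, 2, stats::median, na.rm = TRUE)
  bad <- abs(v - common) >= thresholds$abs_outlier |
    abs(sweep(v, 2, med)) >= thresholds$rel_outlier
  bad[is.na(bad)] <- FALSE
  if (!is.null(per_sample_cnv_intervals) &&
      nrow(per_sample_cnv_intervals) > 0) {
    for (i in seq_len(nrow(per_sample_cnv_intervals))) {
      iv <- per_sample_cnv_intervals[i, ]
      si <- match(iv$sample, rownames(v))
      if (is.na(si)) next
      w <- which(matrix$grid$chrom == iv$chrom &
                   matrix$grid$start < iv$end & matrix$grid$end > iv$start)
      bad[si, w] <- !is.na(v[si, w])
    }
  }
  removed <- matrix$removed_values
  removed[bad] <- v[bad]
  v[bad] <- NA_real_
  rt_matrix(v, matrix$grid, state = "filtered_raw",
            mask_windows = matrix$mask_windows, removed_values = removed)
}

sample_segments <- function(grid, unmasked_idx, gap_smooth_max, min_segment) {
  # split one sample's unmasked windows (one chromosome) into smoothing
  # segments: break where the gap between consecutive windows >= gap max,
  # drop segments spanning less than min_segment
  if (length(unmasked_idx) == 0) return(list())
  gaps <- grid$start[unmasked_idx[-1]] - grid$end[unmasked_idx[-length(unmasked_idx)]]
  brk <- cumsum(c(0, gaps >= gap_smooth_max))
  segs <- split(unmasked_idx, brk)
  Filter(function(s) {
    grid$end[s[length(s)]] - grid$start[s[1]] >= min_segment
  }, segs)
}

#' Z-normalize and spline-smooth replication timing profiles
#'
#' Per sample, unmasked autosomal values are standardized to mean 0 and SD 1
#' and then smoothed with a cubic smoothing spline, fitted separately per
#' contiguous segment of each chromosome. Gaps shorter than
#' `gap_smooth_max` are bridged by the spline; longer gaps split the
#' profile, and segments spanning less than `min_segment` are dropped
#' (short segments are dominated by edge effects and single outliers).
#'
#' @param matrix An [rt_matrix()] in `"filtered_raw"` state.
#' @param spar Smoothing parameter passed to [stats::smooth.spline()]. The
#'   default was calibrated on the default synthetic cohort to maximise
#'   per-sample correlation between the smoothed profile and the known
#'   generating curve (about 0.98 at the default), while keeping the
#'   smoothed data representative of the filtered-raw data.
#' @param gap_smooth_max,min_segment Lengths in bp.
#' @return An [rt_matrix()] in `"smoothed"` state (Z units).
#' @export
normalize_and_smooth <- function(matrix, spar = 0.5,
                                 gap_smooth_max = 300e3,
                                 min_segment = 300e3) {
  stopifnot(inherits(matrix, "rt_matrix"))
  v <- matrix$values
  out <- matrix(NA_real_, nrow(v), ncol(v), dimnames = dimnames(v))
  centers <- window_centers(matrix$grid)
  chrom_idx <- split(seq_len(nrow(matrix$grid)), matrix$grid$chrom)
  for (i in seq_len(nrow(v))) {
    ok <- which(!is.na(v[i, ]))
    if (length(ok) < 2) stop("sample ", rownames(v)[i],
                             ": fewer than 2 unmasked points")
    s <- stats::sd(v[i, ok])
    if (s == 0) stop("sample ", rownames(v)[i], ": zero variance")
    z <- (v[i, ] - mean(v[i, ok])) / s
    for (ci in chrom_idx) {
      idx <- intersect(ci, ok)
      for (seg in sample_segments(matrix$grid, idx, gap_smooth_max,
                                  min_segment)) {
        if (length(seg) < 10) next
        fit <- stats::smooth.spline(centers[seg], z[seg], spar = spar)
        out[i, seg] <- stats::predict(fit, centers[seg])$y
      }
    }
  }
  rt_matrix(out, matrix$grid, state = "smoothed",
            mask_windows = matrix$mask_windows,
            removed_values = matrix$removed_values)
}

#' Principal-component correction of smoothed profiles
#'
#' Removes technical structure shared across cell lines by subtracting the
#' reconstruction from selected sample-space principal components of the
#' windows-by-samples matrix. When `k` is given the top `k` components are
#' removed; otherwise components are flagged technical if they explain more
#' than `var_min` of the variance and their sample loadings correlate with
#' no genotype PC (max |r| < `r_max`) — the intent being to remove batch
#' structure while keeping genetic structure. Output profiles are
#' re-standardized per sample.
#'
#' @param matrix An [rt_matrix()] in `"smoothed"` state.
#' @param k Number of leading components to remove, or `NULL` for the
#'   selection rule.
#' @param genotype_pcs Optional matrix (samples x PCs) used by the
#'   selection rule.
#' @param var_min,r_max Selection-rule tunables.
#' @return An [rt_matrix()] in `"smoothed"` state.
#' @export
pc_correct <- function(matrix, k = NULL, genotype_pcs = NULL,
                       var_min = 0.01, r_max = 0.2) {
  stopifnot(inherits(matrix, "rt_matrix"))
  v <- matrix$values
  n <- nrow(v)
  if (!is.null(k)) {
    if (k >= n) stop("k must be smaller than the number of samples")
    if (k == 0) return(matrix)
  }
  complete <- which(colSums(is.na(v)) == 0)
  x <- t(v[, complete, drop = FALSE])        # windows x samples
  # PCs of the deviation from the cohort-mean profile: the shared timing
  # programme itself must not be removable as a "component"
  mu <- rowMeans(x)
  xc <- x - mu
  pc <- stats::prcomp(xc, center = TRUE, scale. = FALSE)
  varexp <- pc$sdev^2 / sum(pc$sdev^2)
  sel <- if (!is.null(k)) {
    seq_len(k)
  } else if (is.null(genotype_pcs)) {
    integer(0)
  } else {
    which(vapply(seq_len(ncol(pc$rotation)), function(j) {
      varexp[j] > var_min &&
        max(abs(suppressWarnings(stats::cor(pc$rotation[, j],
                                            genotype_pcs))), na.rm = TRUE) < r_max
    }, logical(1)))
  }
  residual <- xc
  if (length(sel) > 0) {
    recon <- pc$x[, sel, drop = FALSE] %*% t(pc$rotation[, sel, drop = FALSE])
    residual <- xc - recon
    v[, complete] <- t(mu + residual)
  }
  for (i in seq_len(n)) {
    ok <- !is.na(v[i, ])
    v[i, ok] <- (v[i, ok] - mean(v[i, ok])) / stats::sd(v[i, ok])
  }
  out <- rt_matrix(v, matrix$grid, state = "smoothed",
                   mask_windows = matrix$mask_windows,
                   removed_values = matrix$removed_values)
  attr(out, "removed_pcs") <- sel
  attr(out, "residual") <- residual
  attr(out, "rotation") <- pc$rotation
  out
}
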