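interval_gap <- function(rs, re, ps, pe) {
  # gap between two half-open intervals; 0 when they overlap
  pmax(pmax(ps - re, rs - pe), 0)
}

region_peak_distance <- function(regions, peaks) {
  vapply(seq_len(nrow(regions)), function(i) {
    pk <- peaks[peaks$chrom == regions$chrom[i], ]
    if (nrow(pk) == 0) return(Inf)
    min(interval_gap(regions$start[i], regions$end[i], pk$start, pk$end))
  }, numeric(1))
}

#' Distances from predicted regions to replication-timing peaks
#'
#' Physical distance is zero for regions overlapping a peak boundary
#' interval, otherwise the bp gap to the nearest peak boundary. Fractional
#' distance divides the physical distance by half the span between the two
#' peak centers flanking the region midpoint (0 at a peak, 1 midway
#' between adjacent peaks); at chromosome ends the single flanking span is
#' used.
#'
#' @param regions Tibble with `chrom`, `start`, `end`.
#' @param peaks Peak tibble with `chrom`, `start`, `end`, `center`.
#' @param mode `"physical"` (bp) or `"fractional"`.
#' @return Tibble: the regions plus a `distance` column; attribute
#'   `"summary"` holds the median.
#' @export
distances_to_peaks <- function(regions, peaks,
                               mode = c("physical", "fractional")) {
  mode <- match.arg(mode)
  if (nrow(peaks) == 0) stop("empty peak set")
  d <- region_peak_distance(regions, peaks)
  if (mode == "fractional") {
    mid <- (regions$start + regions$end) / 2
    d <- vapply(seq_len(nrow(regions)), function(i) {
      if (d[i] == 0) return(0)
      ctr <- sort(peaks$center[peaks$chrom == regions$chrom[i]])
      if (length(ctr) == 0) return(NA_real_)
      below <- ctr[ctr <= mid[i]]; above <- ctr[ctr > mid[i]]
      span <- if (length(below) && length(above)) {
        (min(above) - max(below)) / 2
      } else if (length(below) >= 2) {
        (below[length(below)] - below[length(below) - 1]) / 2
      } else if (length(above) >= 2) {
        (above[2] - above[1]) / 2
      } else return(NA_real_)
      d[i] / span
    }, numeric(1))
  }
  out <- dplyr::mutate(regions, distance = d)
  attr(out, "summary") <- stats::median(d[is.finite(d)])
  out
}

shift_regions <- function(regions, chrom_lengths, shift_min, shift_max) {
  shift <- sample(c(-1, 1), nrow(regions), replace = TRUE) *
    stats::runif(nrow(regions), shift_min, shift_max)
  out <- regions
  for (i in seq_len(nrow(out))) {
    L <- chrom_lengths[[out$chrom[i]]]
    s <- out$start[i] + shift[i]; e <- out$end[i] + shift[i]
    if (s < 0) { w <- e - s; s <- -e; e <- s + w }          # reflect at 0
    if (e > L) { w <- e - s; e <- 2 * L - e; s <- e - w }   # reflect at L
    out$start[i] <- min(s, e); out$end[i] <- max(s, e)
  }
  attr(out, "shift") <- shift
  out
}

#' Shift-permutation baseline for region-to-peak distances
#'
#' Randomly shifts the regions by 1-2 Mb (either direction, reflected at
#' chromosome ends), recomputes distances per permutation, and summarises
#' the improvement of the observed distances over the null: fold =
#' null median / observed median; significance by a one-sided Wilcoxon
#' rank-sum test of observed vs pooled null distances.
#'
#' @param regions,peaks As in [distances_to_peaks()].
#' @param chrom_lengths Named list/vector of chromosome lengths (bp).
#' @param n_perm Number of shifts (default 100).
#' @param shift_min,shift_max Shift magnitude range (bp).
#' @param seed Seed.
#' @return List: `observed` (distances), `null` (matrix regions x perms),
#'   `fold`, `p`, `shifts` (matrix of applied signed shifts).
#' @export
shift_permutation_baseline <- function(regions, peaks, chrom_lengths,
                                       n_perm = 100, shift_min = 1e6,
                                       shift_max = 2e6, seed = 1L) {
  if (any(unlist(chrom_lengths) < 2 * shift_max))
    stop("chromosome shorter than twice the maximum shift")
  obs <- region_peak_distance(regions, peaks)
  set.seed(seed)
  shifts <- matrix(NA_real_, nrow(regions), n_perm)
  null <- matrix(NA_real_, nrow(regions), n_perm)
  for (b in seq_len(n_perm)) {
    shifted <- shift_regions(regions, chrom_lengths, shift_min, shift_max)
    shifts[, b] <- attr(shifted, "shift")
    null[, b] <- region_peak_distance(shifted, peaks)
  }
  fold <- stats::median(null) / max(stats::median(obs), 1)
  p <- stats::wilcox.test(obs, as.vector(null),
                          alternative = "less", exact = FALSE)$p.value
  list(observed = obs, null = null, fold = fold, p = p, shifts = shifts)
}

#' PPV and sensitivity of peak prediction at a distance cutoff
#'
#' PPV: fraction of predicted regions within `cutoff` of a peak boundary.
#' Sensitivity: fraction of peaks within `cutoff` of a predicted region.
#' Each is compared to the shift-permutation baseline by a Z-test.
#'
#' @param regions,peaks As in [distances_to_peaks()].
#' @param cutoff Distance cutoff in bp (default 10 kb).
#' @param chrom_lengths Named chromosome lengths for the baseline shifts.
#' @param n_perm Permutations for the baseline.
#' @param seed Seed.
#' @return One-row tibble: `ppv`, `sensitivity`, baseline means/SDs and
#'   one-sided Z-test p-values.
#' @export
ppv_sensitivity <- function(regions, peaks, cutoff = 10e3,
                            chrom_lengths = NULL, n_perm = 100,
                            seed = 1L) {
  ppv_of <- function(reg) mean(region_peak_distance(reg, peaks) <= cutoff)
  sens_of <- function(reg) mean(region_peak_distance(peaks, reg) <= cutoff)
  ppv <- ppv_of(regions); sens <- sens_of(regions)
  if (is.null(chrom_lengths)) {
    return(tibble::tibble(ppv = ppv, sensitivity = sens))
  }
  set.seed(seed)
  base <- vapply(seq_len(n_perm), function(b) {
    sh <- shift_regions(regions, chrom_lengths, 1e6, 2e6)
    c(ppv_of(sh), sens_of(sh))
  }, numeric(2))
  z_ppv <- (ppv - mean(base[1, ])) / max(stats::sd(base[1, ]), 1e-12)
  z_sens <- (sens - mean(base[2, ])) / max(stats::sd(base[2, ]), 1e-12)
  tibble::tibble(ppv = ppv, sensitivity = sens,
                 ppv_baseline = mean(base[1, ]),
                 sens_baseline = mean(base[2, ]),
                 ppv_z = z_ppv, ppv_p = stats::pnorm(z_ppv, lower.tail = FALSE),
                 sens_z = z_sens,
                 sens_p = stats::pnorm(z_sens, lower.tail = FALSE))
}

window_region_distance <- function(grid_sub, regions) {
  ctr <- (grid_sub$start + grid_sub$end) / 2
  vapply(seq_len(nrow(grid_sub)), function(i) {
    rg <- regions[regions$chrom == grid_sub$chrom[i], ]
    if (nrow(rg) == 0) return(Inf)
    min(interval_gap(ctr[i], ctr[i], rg$start, rg$end))
  }, numeric(1))
}

#' ROC curve for interval-based peak prediction
#'
#' Samples `n_pos` grid windows lying inside peak boundaries as positives
#' and `n_neg` windows at least `neg_min_dist` from the nearest peak
#' center as negatives (sampling without replacement; classes shrink with
#' a warning if too few windows are eligible). A window is predicted
#' "peak" when it lies within the cutoff distance of a region; sweeping
#' the cutoff grid traces the ROC, and AUC is the trapezoid over the
#' sorted curve.
#'
#' @param regions Predicted region tibble.
#' @param grid An [rt_grid()] (the analyzable windows).
#' @param peaks Peak tibble with boundaries and centers.
#' @param n_pos,n_neg Class sample sizes (default 1000 each).
#' @param neg_min_dist Minimum distance of negatives from peaks (bp).
#' @param cutoff_grid Distance cutoffs (bp); defaults sweep 0 to 1 Mb.
#' @param exclude_windows Window ids to exclude (e.g. masked windows).
#' @param seed Seed for the class sampling.
#' @return List: `roc` (tibble cutoff/TPR/FPR), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(regions, grid, peaks, n_pos = 1000, n_neg = 1000,
                      neg_min_dist = 750e3, cutoff_grid = NULL,
                      exclude_windows = integer(0), seed = 1L) {
  if (is.null(cutoff_grid))
    cutoff_grid <- c(0, 1e3, 2.5e3, 5e3, 10e3, 25e3, 50e3, 75e3, 1e5,
                     1.5e5, 2.5e5, 5e5, 7.5e5, 1e6, Inf)
  usable <- grid[!(grid$window %in% exclude_windows), ]
  ctr <- (usable$start + usable$end) / 2
  in_peak <- points_in_intervals(usable$chrom, ctr, peaks)
  dist_center <- vapply(seq_len(nrow(usable)), function(i) {
    nearest_distance(ctr[i], peaks$center[peaks$chrom == usable$chrom[i]])
  }, numeric(1))
  pos_pool <- which(in_peak)
  neg_pool <- which(dist_center > neg_min_dist)
  if (length(neg_pool) == 0) stop("no eligible negative windows")
  if (length(pos_pool) < n_pos) {
    warning("only ", length(pos_pool), " positive windows available")
    n_pos <- length(pos_pool)
  }
  if (length(neg_pool) < n_neg) {
    warning("only ", length(neg_pool), " negative windows available")
    n_neg <- length(neg_pool)
  }
  set.seed(seed)
  pos <- pos_pool[sample.int(length(pos_pool), n_pos)]
  neg <- neg_pool[sample.int(length(neg_pool), n_neg)]
  d_pos <- window_region_distance(usable[pos, ], regions)
  d_neg <- window_region_distance(usable[neg, ], regions)
  roc <- purrr::map(cutoff_grid, function(cf) {
    tibble::tibble(cutoff = cf,
                   tpr = mean(d_pos <= cf),
                   fpr = mean(d_neg <= cf))
  }) |> dplyr::bind_rows() |> dplyr::arrange(.data$fpr, .data$tpr)
  # trapezoid over the (0,0)-(1,1)-anchored curve
  fx <- c(0, roc$fpr, 1); fy <- c(0, roc$tpr, 1)
  auc <- sum(diff(fx) * (utils::head(fy, -1) + utils::tail(fy, -1)) / 2)
  list(roc = roc, auc = auc, n_pos = n_pos, n_neg = n_neg)
}

#' Label predicted regions as shared or cell-type-specific
#'
#' A region is cell-type-specific when the other cell type has no
#' combination region within `dist` of it.
#'
#' @param regions_a,regions_b Region tibbles for the two cell types.
#' @param dist Matching distance in bp (default 100 kb).
#' @return `regions_a` with a logical `specific` column.
#' @export
label_cell_type_specific <- function(regions_a, regions_b, dist = 100e3) {
  d <- vapply(seq_len(nrow(regions_a)), function(i) {
    rb <- regions_b[regions_b$chrom == regions_a$chrom[i], ]
    if (nrow(rb) == 0) return(Inf)
    min(interval_gap(regions_a$start[i], regions_a$end[i],
                     rb$start, rb$end))
  }, numeric(1))
  dplyr::mutate(regions_a, specific = d > dist)
}
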