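local_extrema_idx <- function(v, what = c("maxima", "minima")) {
  # indices of strict local extrema within contiguous non-NA runs;
  # plateaus contribute their leftmost window
  what <- match.arg(what)
  if (what == "minima") v <- -v
  n <- length(v)
  out <- integer(0)
  runs <- split(seq_len(n), cumsum(is.na(v))[seq_len(n)])
  for (r in runs) {
    r <- r[!is.na(v[r])]
    if (length(r) < 3) next
    x <- v[r]
    i <- 2
    while (i <= length(x) - 1) {
      if (x[i] > x[i - 1]) {
        j <- i
        while (j < length(x) && x[j + 1] == x[j]) j <- j + 1
        if (j < length(x) && x[j + 1] < x[i]) out <- c(out, r[i])
        i <- j + 1
      } else i <- i + 1
    }
  }
  out
}

cluster_positions_1d <- function(pos, link_dist) {
  # single-linkage agglomerative clustering of 1-D positions cut at
  # link_dist: clusters are maximal runs with consecutive gaps <= link_dist
  ord <- order(pos)
  gaps <- diff(pos[ord])
  cl_sorted <- cumsum(c(1, gaps > link_dist))
  cl <- integer(length(pos))
  cl[ord] <- cl_sorted
  cl
}

#' Call replication-timing peak clusters across a cohort
#'
#' Local maxima of each sample's smoothed profile are pooled and clustered
#' by single-linkage agglomerative clustering with a 200 kb distance
#' cutoff. Within a cluster a sample contributing several peaks keeps only
#' the one nearest the cluster center. Cluster boundaries are the full
#' member range (`boundary_mode = "range"`) or the 5th-95th percentile of
#' member positions (`"trimmed"`, robust to outlier-prone cohorts).
#' Clusters supported by no more than `min_support` of the samples are
#' dropped. Peaks proxy replication initiation sites; with
#' `what = "minima"` the same machinery yields valleys (termini).
#'
#' @param matrix An [rt_matrix()] in `"smoothed"` state.
#' @param link_dist Single-linkage cutoff (bp).
#' @param min_support Minimum supporting sample fraction (exclusive).
#' @param boundary_mode `"range"` or `"trimmed"`.
#' @param what `"maxima"` (peaks) or `"minima"` (valleys).
#' @return Tibble with one row per cluster: `cluster`, `chrom`, `center`,
#'   `start`, `end`, `support`, `n_members`, and a `members` list-column of
#'   per-sample positions.
#' @export
call_peak_clusters <- function(matrix, link_dist = 200e3,
                               min_support = 0.10,
                               boundary_mode = c("range", "trimmed"),
                               what = c("maxima", "minima")) {
  stopifnot(inherits(matrix, "rt_matrix"))
  boundary_mode <- match.arg(boundary_mode)
  what <- match.arg(what)
  centers <- window_centers(matrix$grid)
  n_samples <- nrow(matrix$values)
  peaks <- list()
  for (i in seq_len(n_samples)) {
    for (ci in split(seq_len(nrow(matrix$grid)), matrix$grid$chrom)) {
      idx <- local_extrema_idx(matrix$values[i, ci], what = what)
      if (length(idx)) {
        peaks[[length(peaks) + 1]] <- tibble::tibble(
          sample = rownames(matrix$values)[i],
          chrom = matrix$grid$chrom[ci[1]], pos = centers[ci[idx]])
      }
    }
  }
  if (length(peaks) == 0) {
    warning("no local ", what, " found")
    return(tibble::tibble(cluster = integer(0), chrom = character(0),
                          center = numeric(0), start = numeric(0),
                          end = numeric(0), support = numeric(0),
                          n_members = integer(0), members = list()))
  }
  pk <- dplyr::bind_rows(peaks)
  out <- pk |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(cl = cluster_positions_1d(.data$pos, link_dist)) |>
    dplyr::group_by(.data$chrom, .data$cl) |>
    dplyr::group_map(function(g, key) {
      ctr <- mean(g$pos)
      # one peak per sample: keep the member nearest the cluster center
      g <- g |>
        dplyr::mutate(d = abs(.data$pos - ctr)) |>
        dplyr::group_by(.data$sample) |>
        dplyr::slice_min(.data$d, n = 1, with_ties = FALSE) |>
        dplyr::ungroup()
      ctr <- mean(g$pos)   # recomputed once after pruning
      bnd <- if (boundary_mode == "range") range(g$pos) else
        stats::quantile(g$pos, c(0.05, 0.95), names = FALSE)
      tibble::tibble(chrom = key$chrom, center = ctr, start = bnd[1],
                     end = bnd[2], support = nrow(g) / n_samples,
                     n_members = nrow(g),
                     members = list(dplyr::select(g, "sample", "pos")))
    }) |>
    dplyr::bind_rows() |>
    dplyr::filter(.data$support > min_support) |>
    dplyr::arrange(.data$chrom, .data$center) |>
    dplyr::mutate(cluster = dplyr::row_number(), .before = 1)
  out
}

pairwise_welch <- function(x) {
  # x: samples x windows raw values (NAs allowed); all pairwise Welch
  # t-test p-values from per-sample means/variances over the windows
  n_i <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  v <- apply(x, 1, stats::var, na.rm = TRUE)
  se2 <- outer(v / n_i, v / n_i, "+")
  tt <- outer(m, m, "-") / sqrt(se2)
  df <- se2^2 / (outer((v / n_i)^2 / (n_i - 1), (v / n_i)^2 / (n_i - 1), "+"))
  p <- 2 * stats::pt(-abs(tt), df)
  p[upper.tri(p)]
}

region_sig_pair_frac <- function(raw, win_idx, alpha = 0.05) {
  if (length(win_idx) < 3) return(0)
  x <- raw$values[, win_idx, drop = FALSE]
  enough <- rowSums(!is.na(x)) >= 3
  if (sum(enough) < 2) return(0)
  p <- pairwise_welch(x[enough, , drop = FALSE])
  mean(p < alpha, na.rm = TRUE)
}

#' Call inter-individual replication-timing variant regions
#'
#' Computes the across-sample SD of smoothed timing per window, smooths it,
#' and takes local SD maxima exceeding the genome-wide mean SD as candidate
#' variant regions. Candidates are confirmed by pairwise Welch t-tests on
#' filtered-raw values in a 500 kb window centered at the SD peak, with
#' Bonferroni correction over (sample pairs x candidates). Confirmed
#' regions are extended outward in 200 kb test windows sliding 100 kb until
#' fewer than 0.1% of sample pairs differ at nominal 0.05. Overlapping
#' regions are merged when across-sample values at their SD peaks correlate
#' above `merge_cor`, otherwise split at the intervening SD minimum.
#' Regions driven by no more than `driver_frac` of the samples (removing
#' the most extreme `ceiling(driver_frac * n)` samples abolishes the
#' SD-peak criterion) are removed.
#'
#' @param raw [rt_matrix()] in `"filtered_raw"` state.
#' @param smoothed [rt_matrix()] in `"smoothed"` state, same grid.
#' @param test_window,extend_step,extend_slide Lengths in bp.
#' @param alpha Significance level before Bonferroni.
#' @param stop_frac Significant-pair fraction below which extension stops.
#' @param merge_cor Correlation threshold for merging overlapping regions.
#' @param driver_frac Maximum sample fraction allowed to drive a region.
#' @param spar Smoothing parameter for the SD track.
#' @return Tibble of variant regions: `region`, `chrom`, `start`, `end`,
#'   `sd_peak_pos`, `sd_at_peak`, `n_significant_pairs`.
#' @export
call_rt_variants <- function(raw, smoothed, test_window = 500e3,
                             alpha = 0.05, extend_step = 200e3,
                             extend_slide = 100e3, stop_frac = 0.001,
                             merge_cor = 0.9, driver_frac = 0.01,
                             spar = 0.7) {
  stopifnot(inherits(raw, "rt_matrix"), inherits(smoothed, "rt_matrix"))
  n <- nrow(smoothed$values)
  if (n < 2) stop("need at least 2 samples")
  grid <- smoothed$grid
  centers <- window_centers(grid)
  sd_track <- apply(smoothed$values, 2, stats::sd, na.rm = TRUE)
  sd_track[colSums(!is.na(smoothed$values)) < 2] <- NA
  sd_smooth <- rep(NA_real_, length(sd_track))
  for (ci in split(seq_len(nrow(grid)), grid$chrom)) {
    ok <- ci[!is.na(sd_track[ci])]
    if (length(ok) >= 10) {
      fit <- stats::smooth.spline(centers[ok], sd_track[ok], spar = spar)
      sd_smooth[ok] <- stats::predict(fit, centers[ok])$y
    }
  }
  sd_mean <- mean(sd_smooth, na.rm = TRUE)
  cand <- local_extrema_idx(sd_smooth, "maxima")
  cand <- cand[sd_smooth[cand] > sd_mean]
  if (length(cand) == 0)
    return(tibble::tibble(region = integer(0), chrom = character(0),
                          start = numeric(0), end = numeric(0),
                          sd_peak_pos = numeric(0), sd_at_peak = numeric(0),
                          n_significant_pairs = integer(0)))

  n_pairs <- n * (n - 1) / 2
  bonf <- alpha / (n_pairs * length(cand))
  confirmed <- list()
  for (w in cand) {
    in_win <- which(grid$chrom == grid$chrom[w] &
                      abs(centers - centers[w]) <= test_window / 2)
    x <- raw$values[, in_win, drop = FALSE]
    enough <- rowSums(!is.na(x)) >= 3
    if (sum(enough) < 2) next
    p <- pairwise_welch(x[enough, , drop = FALSE])
    nsig <- sum(p < bonf, na.rm = TRUE)
    if (nsig == 0) next
    confirmed[[length(confirmed) + 1]] <- list(w = w, nsig = nsig)
  }
  if (length(confirmed) == 0)
    return(tibble::tibble(region = integer(0), chrom = character(0),
                          start = numeric(0), end = numeric(0),
                          sd_peak_pos = numeric(0), sd_at_peak = numeric(0),
                          n_significant_pairs = integer(0)))

  extend_edge <- function(w, dir) {
    chrom <- grid$chrom[w]
    edge <- centers[w]
    repeat {
      lo <- if (dir > 0) edge else edge - extend_step
      hi <- if (dir > 0) edge + extend_step else edge
      win <- which(grid$chrom == chrom & centers >= lo & centers <= hi)
      if (length(win) == 0) break
      if (region_sig_pair_frac(raw, win, alpha) < stop_frac) break
      edge <- edge + dir * extend_slide
      if (edge < 0 || edge > max(centers[grid$chrom == chrom])) break
    }
    edge
  }
  regions <- purrr::map(confirmed, function(cf) {
    tibble::tibble(chrom = grid$chrom[cf$w],
                   start = extend_edge(cf$w, -1L),
                   end = extend_edge(cf$w, +1L),
                   sd_peak_pos = centers[cf$w],
                   sd_at_peak = sd_smooth[cf$w],
                   n_significant_pairs = cf$nsig,
                   widx = cf$w)
  }) |> dplyr::bind_rows() |>
    dplyr::mutate(start = pmin(.data$start, .data$sd_peak_pos - extend_slide),
                  end = pmax(.data$end, .data$sd_peak_pos + extend_slide)) |>
    dplyr::arrange(.data$chrom, .data$start)

  # merge/split overlapping regions
  merged <- list()
  i <- 1
  while (i <= nrow(regions)) {
    cur <- regions[i, ]
    j <- i + 1
    while (j <= nrow(regions) && regions$chrom[j] == cur$chrom &&
           regions$start[j] <= cur$end) {
      r <- suppressWarnings(stats::cor(smoothed$values[, cur$widx],
                                       smoothed$values[, regions$widx[j]],
                                       use = "pairwise.complete.obs"))
      if (!is.na(r) && r > merge_cor) {
        keep <- if (regions$sd_at_peak[j] > cur$sd_at_peak) regions[j, ] else cur
        cur <- keep
        cur$start <- min(cur$start, regions$start[j])
        cur$end <- max(cur$end, regions$end[j])
      } else {
        between <- which(grid$chrom == cur$chrom &
                           centers > cur$sd_peak_pos &
                           centers < regions$sd_peak_pos[j])
        minima <- between[which.min(sd_smooth[between])]
        if (length(minima) == 1) {
          cut <- centers[minima]
          cur$end <- min(cur$end, cut)
          regions$start[j] <- max(regions$start[j], cut)
        }
        break
      }
      j <- j + 1
    }
    merged[[length(merged) + 1]] <- cur
    i <- j
  }
  out <- dplyr::bind_rows(merged)

  # driver rule: region must survive removal of the most extreme samples
  n_drop <- ceiling(driver_frac * n)
  keep <- vapply(seq_len(nrow(out)), function(k) {
    vals <- smoothed$values[, out$widx[k]]
    dev <- abs(vals - mean(vals, na.rm = TRUE))
    drop <- order(dev, decreasing = TRUE)[seq_len(n_drop)]
    stats::sd(vals[-drop], na.rm = TRUE) > sd_mean
  }, logical(1))
  out <- out[keep, , drop = FALSE]
  out |>
    dplyr::select(-"widx") |>
    dplyr::mutate(region = dplyr::row_number(), .before = 1)
}
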