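nearest_distance <- function(pos, targets) {
  if (length(targets) == 0) return(rep(Inf, length(pos)))
  vapply(pos, function(p) min(abs(p - targets)), numeric(1))
}

#' Count LD partners of each variant
#'
#' Number of variants within `radius` bp whose dosage r-squared with the
#' index variant reaches `r2_min` (the index variant itself included).
#'
#' @param genotypes A [genotype_table()].
#' @param radius Search radius in bp.
#' @param r2_min LD threshold.
#' @return Integer vector, one count per variant.
#' @export
ld_partner_counts <- function(genotypes, radius = 1e6, r2_min = 0.2) {
  info <- genotypes$info
  counts <- integer(nrow(info))
  for (ch in unique(info$chrom)) {
    idx <- which(info$chrom == ch)
    pos <- info$pos[idx]
    chunk <- 200L
    for (lo in seq(1, length(idx), by = chunk)) {
      hi <- min(lo + chunk - 1, length(idx))
      nb <- which(pos >= pos[lo] - radius & pos <= pos[hi] + radius)
      r2 <- ld_r2(genotypes, info$variant_id[idx[lo:hi]],
                  info$variant_id[idx[nb]])
      near <- outer(pos[lo:hi], pos[nb],
                    function(a, b) abs(a - b) <= radius)
      counts[idx[lo:hi]] <- rowSums(r2 >= r2_min & near)
    }
  }
  counts
}

#' Build matched control variants for each rtQTL
#'
#' For each signal's tag variant, finds all variants genome-wide that are
#' at least 2 Mb away, match the tag's minor allele frequency within 0.05,
#' its distances to the nearest replication initiation site (peak) and
#' terminus (valley) within 50 kb, its cohort-mean replication timing
#' within 0.5 Z units, and have at least as many LD partners. Signals with
#' fewer than `min_matches` matched tags are flagged excluded from
#' enrichment denominators.
#'
#' @param signals Signal tibble.
#' @param genotypes A [genotype_table()].
#' @param peaks Peak-cluster tibble (uses `center`).
#' @param valleys Valley-cluster tibble (uses `center`).
#' @param matrix Smoothed [rt_matrix()] (timing source).
#' @param min_matches Minimum matched tags (default 200).
#' @param maf_tol,dist_tol,timing_tol Matching tolerances.
#' @return List of class `matched_controls`: per-signal tibble with a
#'   `matched` list-column of variant ids and an `excluded` flag, plus the
#'   per-variant annotation table used for matching.
#' @export
build_matched_controls <- function(signals, genotypes, peaks, valleys,
                                   matrix, min_matches = 200,
                                   maf_tol = 0.05, dist_tol = 50e3,
                                   timing_tol = 0.5) {
  info <- genotypes$info
  centers <- window_centers(matrix$grid)
  mean_timing <- colMeans(matrix$values, na.rm = TRUE)
  timing_at <- vapply(seq_len(nrow(info)), function(i) {
    w <- which(matrix$grid$chrom == info$chrom[i])
    w <- w[!is.na(mean_timing[w])]
    if (length(w) == 0) return(NA_real_)
    mean_timing[w[which.min(abs(centers[w] - info$pos[i]))]]
  }, numeric(1))
  dist_peak <- vapply(seq_len(nrow(info)), function(i)
    nearest_distance(info$pos[i],
                     peaks$center[peaks$chrom == info$chrom[i]]),
    numeric(1))
  dist_valley <- vapply(seq_len(nrow(info)), function(i)
    nearest_distance(info$pos[i],
                     valleys$center[valleys$chrom == info$chrom[i]]),
    numeric(1))
  partners <- ld_partner_counts(genotypes)
  ann <- info |>
    dplyr::mutate(timing = timing_at, dist_peak = dist_peak,
                  dist_valley = dist_valley, ld_partners = partners)
  per_signal <- purrr::map(seq_len(nrow(signals)), function(i) {
    sig <- signals[i, ]
    ti <- match(sig$tag_variant, ann$variant_id)
    far <- ann$chrom != ann$chrom[ti] |
      abs(ann$pos - ann$pos[ti]) >= 2e6
    ok <- far &
      abs(ann$maf - ann$maf[ti]) < maf_tol &
      abs(ann$dist_peak - ann$dist_peak[ti]) < dist_tol &
      abs(ann$dist_valley - ann$dist_valley[ti]) < dist_tol &
      !is.na(ann$timing) & !is.na(ann$timing[ti]) &
      abs(ann$timing - ann$timing[ti]) < timing_tol &
      ann$ld_partners >= ann$ld_partners[ti]
    matched <- ann$variant_id[which(ok)]
    nm <- length(matched)
    tibble::tibble(signal = sig$signal, tag_variant = sig$tag_variant,
                   n_matched = nm, matched = list(matched),
                   excluded = nm < min_matches)
  }) |> dplyr::bind_rows()
  structure(list(per_signal = per_signal, annotation = ann),
            class = "matched_controls")
}

control_snp_set <- function(controls, signals, genotypes, seed) {
  # one permutation draw: per signal, a random matched tag and its LD
  # partners, at the cardinality of the real signal
  set.seed(seed)
  rows <- list()
  ann <- controls$annotation
  for (i in seq_len(nrow(controls$per_signal))) {
    cs <- controls$per_signal[i, ]
    if (cs$excluded) next
    mt <- sample(cs$matched[[1]], 1)
    sig <- signals[signals$signal == cs$signal, ]
    need <- sig$n_members
    mi <- match(mt, ann$variant_id)
    nb <- which(ann$chrom == ann$chrom[mi] &
                  abs(ann$pos - ann$pos[mi]) <= 1e6)
    r2 <- ld_r2(genotypes, mt, ann$variant_id[nb])[1, ]
    partners <- nb[r2 >= 0.2]
    partners <- partners[order(-r2[r2 >= 0.2])]
    take <- partners[seq_len(min(need, length(partners)))]
    rows[[length(rows) + 1]] <- tibble::tibble(
      signal = cs$signal, variant_id = ann$variant_id[take],
      chrom = ann$chrom[take], pos = ann$pos[take])
  }
  dplyr::bind_rows(rows)
}

#' Matched-control permutation enrichment of a feature at rtQTLs
#'
#' The observed statistic is the fraction of (non-excluded) rtQTLs with at
#' least one member SNP inside the feature. In each permutation every
#' rtQTL is replaced by a random matched tag variant plus its LD partners
#' at the real signal's cardinality; the binomial parameter is the mean
#' permutation overlap fraction. Significance is a one-tailed binomial
#' test in the direction of the observed fold.
#'
#' @param signals Signal tibble.
#' @param feature Tibble of feature intervals (`chrom`, `start`, `end`).
#' @param controls A [build_matched_controls()] result.
#' @param genotypes A [genotype_table()].
#' @param n_perm Number of permutations (default 100).
#' @param extend Extend feature intervals by this many bp.
#' @param seed Base seed for the permutation draws.
#' @return One-row tibble: `n_rtqtls`, `n_overlapping`, `expected_fraction`,
#'   `fold`, `p`.
#' @export
feature_enrichment <- function(signals, feature, controls, genotypes,
                               n_perm = 100, extend = 0, seed = 1L) {
  if (nrow(feature) == 0) stop("feature is empty")
  use <- signals[signals$signal %in%
                   controls$per_signal$signal[!controls$per_signal$excluded], ]
  info <- genotypes$info
  overlap_one <- function(member_ids) {
    mi <- match(member_ids, info$variant_id)
    any(points_in_intervals(info$chrom[mi], info$pos[mi], feature, extend))
  }
  obs_hits <- vapply(use$members, function(m) overlap_one(m$variant_id),
                     logical(1))
  k <- sum(obs_hits); n <- nrow(use)
  perm_frac <- vapply(seq_len(n_perm), function(b) {
    snp <- control_snp_set(controls, signals, genotypes, seed + b)
    hit <- snp |>
      dplyr::group_by(.data$signal) |>
      dplyr::summarise(hit = any(points_in_intervals(.data$chrom, .data$pos,
                                                     feature, extend)))
    mean(hit$hit)
  }, numeric(1))
  param <- min(max(mean(perm_frac), 1e-6), 1 - 1e-6)
  fold <- (k / n) / param
  p <- if (fold >= 1) {
    stats::pbinom(k - 1, n, param, lower.tail = FALSE)
  } else {
    stats::pbinom(k, n, param)
  }
  tibble::tibble(n_rtqtls = n, n_overlapping = k,
                 expected_fraction = mean(perm_frac), fold = fold, p = p)
}

#' Iterative search for enriched feature combinations at rtQTL SNPs
#'
#' Level 1 tests each feature for enrichment at individual rtQTL SNPs
#' against matched-control SNPs by Fisher's exact test (two-sided, so
#' depletion is reportable), Benjamini-Hochberg corrected at `fdr`. Each
#' subsequent level restricts both rtQTL and control SNPs to those
#' carrying an enriched combination from the previous level and tests each
#' additional feature (one-sided, enrichment) under that restriction. The
#' search stops when a level adds no enriched combination.
#'
#' @param features Tibble with `mark`, `chrom`, `start`, `end`
#'   (cohort-level union tracks).
#' @param rtqtl_snps Tibble with `chrom`, `pos` for the rtQTL SNPs.
#' @param control_snps Tibble with `chrom`, `pos` for matched-control SNPs
#'   (e.g. pooled [control_snp_set()] draws).
#' @param fdr BH FDR within each level (default 0.05).
#' @param extend Extend feature intervals by this many bp.
#' @param max_level Safety cap on combination size.
#' @return Tibble of enriched combinations: `level`, `combination`
#'   (list-column of mark names), `n_rtqtl`, `n_control`, `odds_ratio`,
#'   `p`, `p_adj`.
#' @export
combination_search <- function(features, rtqtl_snps, control_snps,
                               fdr = 0.05, extend = 0, max_level = 6) {
  marks <- unique(features$mark)
  rt_has <- vapply(marks, function(m)
    points_in_intervals(rtqtl_snps$chrom, rtqtl_snps$pos,
                        features[features$mark == m, ], extend),
    logical(nrow(rtqtl_snps)))
  ct_has <- vapply(marks, function(m)
    points_in_intervals(control_snps$chrom, control_snps$pos,
                        features[features$mark == m, ], extend),
    logical(nrow(control_snps)))
  colnames(rt_has) <- colnames(ct_has) <- marks

  test_one <- function(rt_sub, ct_sub, mark, alternative) {
    a <- sum(rt_sub[, mark]); b <- nrow(rt_sub) - a
    c_ <- sum(ct_sub[, mark]); d <- nrow(ct_sub) - c_
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                             alternative = alternative)
    tibble::tibble(n_rtqtl = a, n_control = c_,
                   odds_ratio = unname(ft$estimate), p = ft$p.value)
  }

  results <- list()
  frontier <- list(character(0))      # combinations to extend
  level <- 1
  while (length(frontier) > 0 && level <= max_level) {
    lvl_rows <- list()
    for (combo in frontier) {
      rt_sub <- rt_has[rowSums(rt_has[, combo, drop = FALSE]) ==
                         length(combo), , drop = FALSE]
      ct_sub <- ct_has[rowSums(ct_has[, combo, drop = FALSE]) ==
                         length(combo), , drop = FALSE]
      if (nrow(rt_sub) == 0 || nrow(ct_sub) == 0) next
      for (m in setdiff(marks, combo)) {
        alt <- if (level == 1) "two.sided" else "greater"
        row <- test_one(rt_sub, ct_sub, m, alt)
        row$combination <- list(sort(c(combo, m)))
        row$level <- level
        lvl_rows[[length(lvl_rows) + 1]] <- row
      }
    }
    if (length(lvl_rows) == 0) break
    lvl <- dplyr::bind_rows(lvl_rows) |>
      dplyr::mutate(key = vapply(.data$combination, paste,
                                 character(1), collapse = "+")) |>
      dplyr::group_by(.data$key) |>
      dplyr::slice_min(.data$p, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::mutate(p_adj = stats::p.adjust(.data$p, method = "BH"))
    enr <- lvl |>
      dplyr::filter(.data$p_adj <= fdr,
                    level == 1 | .data$odds_ratio > 1)
    if (nrow(enr) == 0) break
    results[[level]] <- dplyr::select(enr, "level", "combination",
                                      "n_rtqtl", "n_control",
                                      "odds_ratio", "p", "p_adj")
    frontier <- enr$combination
    level <- level + 1
  }
  if (length(results) == 0)
    return(tibble::tibble(level = integer(0), combination = list(),
                          n_rtqtl = integer(0), n_control = integer(0),
                          odds_ratio = numeric(0), p = numeric(0),
                          p_adj = numeric(0)))
  dplyr::bind_rows(results)
}

#' Build hyperacetylated trimethylation (me3-ac-hyper) regions
#'
#' Takes the mutual-overlap sites of a five-mark combination, keeps those
#' overlapping peaks from at least `min_ac` distinct variable acetylation
#' marks, and merges surviving regions that co-occur within `merge_gap`.
#'
#' @param five_mark_sites Tibble of site intervals (`chrom`, `start`,
#'   `end`), e.g. from [intersect_tracks()].
#' @param acetylation_tracks Tibble with `mark`, `chrom`, `start`, `end`
#'   for the variable acetylation marks.
#' @param min_ac Minimum acetylation marks overlapped (default 11).
#' @param merge_gap Merge distance in bp (default 10 kb).
#' @return Tibble of regions with `n_acetyl` counts (counts are the
#'   maximum over the merged constituents).
#' @export
build_me3achyper <- function(five_mark_sites, acetylation_tracks,
                             min_ac = 11, merge_gap = 10e3) {
  if (nrow(five_mark_sites) == 0)
    return(tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0), n_acetyl = integer(0)))
  ac_marks <- unique(acetylation_tracks$mark)
  n_ac <- vapply(seq_len(nrow(five_mark_sites)), function(i) {
    site <- five_mark_sites[i, ]
    sum(vapply(ac_marks, function(m) {
      iv <- acetylation_tracks[acetylation_tracks$mark == m &
                                 acetylation_tracks$chrom == site$chrom, ]
      any(iv$start < site$end & iv$end > site$start)
    }, logical(1)))
  }, integer(1))
  keep <- five_mark_sites[n_ac >= min_ac, ]
  if (nrow(keep) == 0)
    return(tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0), n_acetyl = integer(0)))
  keep$n_acetyl <- n_ac[n_ac >= min_ac]
  merged <- merge_intervals(keep, gap = merge_gap)
  merged$n_acetyl <- vapply(seq_len(nrow(merged)), function(i)
    max(keep$n_acetyl[keep$chrom == merged$chrom[i] &
                        keep$start < merged$end[i] + merge_gap &
                        keep$end > merged$start[i] - merge_gap]),
    integer(1))
  dplyr::arrange(merged, .data$chrom, .data$start)
}

#' Allelic covariation of histone marks with rtQTL genotype
#'
#' Aggregating over rtQTL sites, tests per mark whether cell lines carrying
#' the early-replicating genotype are more (or less) likely to harbor the
#' mark near the site than lines carrying the late-replicating genotype.
#' The observed early-carrier count is compared with a two-tailed binomial
#' whose parameter is `p_late * (p_perm_early / p_perm_late)`: the late
#' fraction rescaled by the ratio seen in permutations with matched random
#' SNPs and randomly assigned early alleles (the ratio is clipped to
#' [0.01, 100] to guard the small permutation count). Bonferroni-adjusted
#' over marks.
#'
#' @param sites Tibble with `variant_id`, `chrom`, `pos`, `beta` (early
#'   orientation) for the rtQTL SNPs tested.
#' @param genotypes A [genotype_table()].
#' @param tracks Per-sample mark tibble (`mark`, `sample`, `chrom`,
#'   `start`, `end`).
#' @param controls Optional [build_matched_controls()] result for the
#'   permutation SNPs; when `NULL`, random variants are drawn.
#' @param radius Mark presence = any interval of the mark within this
#'   distance of the site (bp).
#' @param n_perm Number of permutations (default 10).
#' @param seed Seed.
#' @return Tibble per mark: fractions, binomial parameter, two-tailed `p`,
#'   `p_bonferroni`, `log_ratio`.
#' @export
allelic_covariation <- function(sites, genotypes, tracks, controls = NULL,
                                radius = 10e3, n_perm = 10, seed = 1L) {
  marks <- unique(tracks$mark)
  samples <- rownames(genotypes$dosage)
  presence <- function(mark, site_chrom, site_pos, smp) {
    iv <- tracks[tracks$mark == mark & tracks$sample == smp &
                   tracks$chrom == site_chrom, ]
    any(iv$start - radius <= site_pos & iv$end + radius > site_pos)
  }
  carrier_fracs <- function(site_tbl, early_sign) {
    # per mark: fraction of (site, early-hom) and (site, late-hom) sample
    # combos carrying the mark
    res <- matrix(0, length(marks), 2,
                  dimnames = list(marks, c("early", "late")))
    denom <- c(early = 0, late = 0)
    num <- matrix(0, length(marks), 2,
                  dimnames = list(marks, c("early", "late")))
    for (i in seq_len(nrow(site_tbl))) {
      st <- site_tbl[i, ]
      d <- genotypes$dosage[, st$variant_id]
      early_dose <- if (early_sign[i] >= 0) d else 2 - d
      eh <- samples[early_dose == 2]; lh <- samples[early_dose == 0]
      if (length(eh) == 0 || length(lh) == 0) next
      denom <- denom + c(length(eh), length(lh))
      for (m in marks) {
        num[m, "early"] <- num[m, "early"] +
          sum(vapply(eh, function(s) presence(m, st$chrom, st$pos, s),
                     logical(1)))
        num[m, "late"] <- num[m, "late"] +
          sum(vapply(lh, function(s) presence(m, st$chrom, st$pos, s),
                     logical(1)))
      }
    }
    list(num = num, denom = denom)
  }
  obs <- carrier_fracs(sites, sites$beta)
  if (all(obs$denom == 0)) stop("zero eligible sites")
  p_early <- stats::setNames(obs$num[, "early"] / obs$denom[["early"]], marks)
  p_late <- stats::setNames(obs$num[, "late"] / obs$denom[["late"]], marks)

  set.seed(seed)
  ratio_num <- ratio_den <- stats::setNames(numeric(length(marks)), marks)
  for (b in seq_len(n_perm)) {
    if (!is.null(controls)) {
      pool <- unique(unlist(controls$per_signal$matched))
      ids <- sample(pool, min(nrow(sites), length(pool)))
    } else {
      ids <- sample(genotypes$info$variant_id, nrow(sites))
    }
    mi <- match(ids, genotypes$info$variant_id)
    ptbl <- tibble::tibble(variant_id = ids,
                           chrom = genotypes$info$chrom[mi],
                           pos = genotypes$info$pos[mi])
    signs <- sample(c(-1, 1), nrow(ptbl), replace = TRUE)
    pf <- carrier_fracs(ptbl, signs)
    if (any(pf$denom == 0)) next
    ratio_num <- ratio_num + pf$num[, "early"] / pf$denom[["early"]]
    ratio_den <- ratio_den + pf$num[, "late"] / pf$denom[["late"]]
  }
  ratio <- pmin(pmax(ratio_num / pmax(ratio_den, 1e-12), 0.01), 100)
  ratio[ratio_den == 0 & ratio_num == 0] <- 1

  rows <- purrr::map(seq_along(marks), function(mi2) {
    m <- marks[mi2]
    param <- min(max(p_late[m] * ratio[m], 1e-9), 1 - 1e-9)
    k <- obs$num[m, "early"]; n <- obs$denom[["early"]]
    p <- stats::binom.test(k, n, param)$p.value
    lr <- log((p_early[[m]] + 1e-9) / (p_late[[m]] + 1e-9))
    tibble::tibble(mark = m, k_early = unname(k), n_early = n,
                   p_early = p_early[[m]], p_late = p_late[[m]],
                   perm_ratio = ratio[[m]], parameter = unname(param),
                   p = p, log_ratio = lr)
  }) |> dplyr::bind_rows()
  rows$p_bonferroni <- pmin(rows$p * nrow(rows), 1)
  rows
}

#' Transcription-factor motif-score association with replication timing
#'
#' For each TF, member SNPs falling in its motif contribute the difference
#' in motif score between the early- and late-replicating allele, weighted
#' by its magnitude (one SNP per rtQTL: the lowest-p member in the motif
#' table). Observed weighted early-higher vs late-higher totals are
#' compared with a permutation baseline (matched/random SNPs with randomly
#' assigned early alleles) in a 2x2 chi-squared test (no continuity
#' correction), BH-adjusted at 10% FDR. TFs overlapping fewer than
#' `min_rtqtls` rtQTLs are excluded.
#'
#' @param signals Signal tibble (members carry `p` and `beta`).
#' @param motif_scores Tibble with `variant_id`, `tf`, `score_ref`,
#'   `score_alt`.
#' @param control_variants Character vector of control variant ids with
#'   motif entries.
#' @param n_perm Permutations for the baseline (default 100).
#' @param min_rtqtls Minimum rtQTLs overlapping the TF motif (default 15).
#' @param seed Seed.
#' @return Tibble per TF: weighted counts, baseline, `chisq`, `p`,
#'   `p_adj`, `log2_ratio`.
#' @export
tf_motif_association <- function(signals, motif_scores, control_variants,
                                 n_perm = 100, min_rtqtls = 15, seed = 1L) {
  tfs <- unique(motif_scores$tf)
  set.seed(seed)
  rows <- list()
  for (tf in tfs) {
    ms <- motif_scores[motif_scores$tf == tf, ]
    per_qtl <- purrr::map(seq_len(nrow(signals)), function(i) {
      mem <- signals$members[[i]]
      hit <- dplyr::inner_join(mem, ms, by = "variant_id")
      if (nrow(hit) == 0) return(NULL)
      best <- hit[which.min(hit$p), ]
      delta_alt <- best$score_alt - best$score_ref
      # orient to the early allele via the association direction
      delta_early <- if (best$beta >= 0) delta_alt else -delta_alt
      tibble::tibble(signal = signals$signal[i], delta = delta_early)
    }) |> dplyr::bind_rows()
    if (nrow(per_qtl) < min_rtqtls) next
    w_early <- sum(abs(per_qtl$delta[per_qtl$delta > 0]))
    w_late <- sum(abs(per_qtl$delta[per_qtl$delta < 0]))
    if (w_early + w_late == 0) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        tf = tf, weighted_early = 0, weighted_late = 0,
        baseline_early = NA_real_, baseline_late = NA_real_, chisq = 0,
        p = 1, log2_ratio = 0)
      next
    }
    ctrl <- ms[ms$variant_id %in% control_variants, ]
    if (nrow(ctrl) == 0) next
    perm <- vapply(seq_len(n_perm), function(b) {
      pick <- ctrl[sample.int(nrow(ctrl), nrow(per_qtl),
                              replace = nrow(ctrl) < nrow(per_qtl)), ]
      sgn <- sample(c(-1, 1), nrow(pick), replace = TRUE)
      dlt <- (pick$score_alt - pick$score_ref) * sgn
      c(sum(abs(dlt[dlt > 0])), sum(abs(dlt[dlt < 0])))
    }, numeric(2))
    b_early <- mean(perm[1, ]); b_late <- mean(perm[2, ])
    tab <- matrix(c(w_early, w_late, b_early, b_late), 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    chisq <- sum((tab - expd)^2 / expd)
    rows[[length(rows) + 1]] <- tibble::tibble(
      tf = tf, weighted_early = w_early, weighted_late = w_late,
      baseline_early = b_early, baseline_late = b_late, chisq = chisq,
      p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
      log2_ratio = log2((w_early + 1e-9) / (w_late + 1e-9)))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
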