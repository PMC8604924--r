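#' Peel significant variants into independent association signals
#'
#' Greedy LD clumping: the variant with the lowest p-value becomes the tag
#' of a new signal and every remaining significant variant in LD with it
#' (r-squared at least `ld_min`) joins that signal; the procedure repeats
#' on the remainder until no significant variants are left, so every
#' significant variant belongs to exactly one signal. Signals with fewer
#' than `min_members` variants or a tag p-value of `tag_p_max` or more are
#' dropped as weak associations. Ties in tag selection break to the
#' smaller genomic coordinate.
#'
#' @param assoc Tibble with `variant_id`, `p`, `beta` for the significant
#'   variants of one window/region.
#' @param genotypes A [genotype_table()] (LD source).
#' @param ld_min LD r-squared defining signal membership.
#' @param min_members Minimum variants per retained signal.
#' @param tag_p_max Maximum tag p-value (exclusive).
#' @return Tibble with one row per signal: `tag_variant`, `top_p`,
#'   `beta_tag`, `n_members`, `members` (list-column), `provenance`.
#' @export
define_signals <- function(assoc, genotypes, ld_min = 0.2,
                           min_members = 10, tag_p_max = 1e-3) {
  pool <- assoc |>
    dplyr::left_join(dplyr::select(genotypes$info, "variant_id", "pos"),
                     by = "variant_id") |>
    dplyr::arrange(.data$p, .data$pos)
  out <- list()
  while (nrow(pool) > 0) {
    tag <- pool[1, ]
    r2 <- ld_r2(genotypes, tag$variant_id, pool$variant_id)[1, ]
    in_sig <- r2 >= ld_min
    members <- pool[in_sig, c("variant_id", "p", "beta")]
    pool <- pool[!in_sig, , drop = FALSE]
    out[[length(out) + 1]] <- tibble::tibble(
      tag_variant = tag$variant_id, top_p = tag$p, beta_tag = tag$beta,
      n_members = nrow(members), members = list(members),
      provenance = "ld_greedy")
  }
  dplyr::bind_rows(out) |>
    dplyr::filter(.data$n_members >= min_members, .data$top_p < tag_p_max)
}

tag_window_p <- function(ctx, variant_id, windows) {
  # association p of one variant's dosage with a set of smoothed windows
  vidx <- match(variant_id, ctx$vinfo$variant_id)
  cols <- match(windows, ctx$testable)
  ok <- !is.na(cols)
  p <- rep(NA_real_, length(windows))
  if (any(ok)) {
    r <- drop(crossprod(ctx$Yu[, cols[ok], drop = FALSE], ctx$Du[, vidx]))
    p[ok] <- r_to_p(r, ctx$dof)
  }
  p
}

#' Consolidate signals across windows and split by conditional analysis
#'
#' Signals discovered in different windows are merged (union-find) when
#' (1) their tag variants are in LD (r-squared >= `ld_min`), (2) the window
#' phenotypes are correlated (R-squared >= `r2_min`), and (3) the windows
#' are less than `dist_max` apart. Each consolidated signal is then
#' re-examined conditionally: every member variant is tested with the tag
#' dosage added to the covariates, and if any member stays significant
#' after Bonferroni correction over the member count, the signal is split
#' into two (members assigned to whichever tag they are in stronger LD
#' with), provided both parts still satisfy the member-count and tag-p
#' rules.
#'
#' @param signals Tibble of per-window signals, with a `window` column.
#' @param ctx A [scan_context()] over the mapping phenotype.
#' @param genotypes A [genotype_table()].
#' @param ld_min Tag LD threshold (default 0.2).
#' @param r2_min Window-correlation threshold (default 0.1).
#' @param dist_max Maximum window distance in bp (default 2 Mb).
#' @return Consolidated signal tibble.
#' @export
consolidate_and_split <- function(signals, ctx, genotypes, ld_min = 0.2,
                                  r2_min = 0.1, dist_max = 2e6) {
  if (nrow(signals) == 0) return(signals)
  k <- nrow(signals)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  tag_r2 <- ld_r2(genotypes, signals$tag_variant)
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    wi <- signals$window[i]; wj <- signals$window[j]
    if (ctx$grid$chrom[wi] != ctx$grid$chrom[wj]) next
    if (abs(ctx$centers[wi] - ctx$centers[wj]) >= dist_max) next
    if (tag_r2[i, j] < ld_min) next
    ci <- match(wi, ctx$testable); cj <- match(wj, ctx$testable)
    if (is.na(ci) || is.na(cj)) next
    r <- sum(ctx$Yu[, ci] * ctx$Yu[, cj])
    if (r^2 < r2_min) next
    parent[find(i)] <- find(j)
  }
  comp <- vapply(seq_len(k), find, integer(1))
  merged <- lapply(split(seq_len(k), comp), function(idx) {
    grp <- signals[idx, ]
    best <- which.min(grp$top_p)
    members <- dplyr::bind_rows(grp$members) |>
      dplyr::group_by(.data$variant_id) |>
      dplyr::slice_min(.data$p, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    tibble::tibble(
      tag_variant = grp$tag_variant[best], top_p = grp$top_p[best],
      beta_tag = grp$beta_tag[best], window = grp$window[best],
      threshold_pt = grp$threshold_pt[best],
      n_members = nrow(members), members = list(members),
      provenance = "ld_greedy")
  })
  merged <- dplyr::bind_rows(merged)

  # conditional association within each consolidated signal
  out <- list()
  for (i in seq_len(nrow(merged))) {
    sig <- merged[i, ]
    split_sigs <- conditional_split_one(sig, ctx, genotypes)
    out[[length(out) + 1]] <- split_sigs
  }
  dplyr::bind_rows(out) |>
    dplyr::mutate(signal = dplyr::row_number(), .before = 1)
}

conditional_split_one <- function(sig, ctx, genotypes, alpha = 0.05) {
  members <- sig$members[[1]]
  m <- nrow(members)
  wcol <- match(sig$window, ctx$testable)
  if (is.na(wcol) || m < 2) return(sig)
  tag_idx <- match(sig$tag_variant, ctx$vinfo$variant_id)
  other <- setdiff(members$variant_id, sig$tag_variant)
  vidx <- match(other, ctx$vinfo$variant_id)
  # residualize phenotype and member dosages on the tag dosage as well
  extra <- cbind(ctx$covariates, tag = ctx$Du[, tag_idx])
  y2 <- drop(residualize(ctx$Yu[, wcol, drop = FALSE], extra))
  D2 <- residualize(ctx$Du[, vidx, drop = FALSE], extra)
  yn <- sqrt(sum((y2 - mean(y2))^2))
  if (yn == 0) return(sig)
  r <- drop(crossprod(unit_cols(D2), (y2 - mean(y2)) / yn))
  p_cond <- r_to_p(r, ctx$dof - 1)
  sig_cond <- which(p_cond < alpha / m)
  if (length(sig_cond) == 0) return(sig)
  new_tag <- other[sig_cond[which.min(p_cond[sig_cond])]]
  r2_tag <- ld_r2(genotypes, sig$tag_variant, members$variant_id)[1, ]
  r2_new <- ld_r2(genotypes, new_tag, members$variant_id)[1, ]
  to_new <- r2_new > r2_tag
  m_new <- members[to_new, ]; m_old <- members[!to_new, ]
  # the member-count and tag-p rules were enforced at identification; a
  # conditionally split signal keeps its members however they partition
  ok <- function(mm, tag) nrow(mm) >= 1 && tag %in% mm$variant_id
  if (!ok(m_old, sig$tag_variant) || !ok(m_new, new_tag)) return(sig)
  part <- function(mm, prov) {
    best <- mm[which.min(mm$p), ]
    tibble::tibble(tag_variant = best$variant_id, top_p = best$p,
                   beta_tag = best$beta, window = sig$window,
                   threshold_pt = sig$threshold_pt, n_members = nrow(mm),
                   members = list(mm), provenance = prov)
  }
  dplyr::bind_rows(part(m_old, "ld_greedy"), part(m_new, "conditional_split"))
}

#' Associated region of a signal
#'
#' Starting from the window most strongly associated with the signal's tag
#' variant, extends bi-directionally while the tag-window association stays
#' nominally significant (p <= 0.05), yielding a contiguous window
#' interval.
#'
#' @param sig One signal row.
#' @param ctx A [scan_context()].
#' @param search_radius How far (bp) around the signal's window to search
#'   for the strongest association (default 2 Mb).
#' @param alpha Stopping significance level.
#' @return Tibble `chrom`, `start`, `end`, `strongest_window`, `n_windows`.
#' @export
associated_region <- function(sig, ctx, search_radius = 2e6, alpha = 0.05) {
  w0 <- sig$window
  chrom <- ctx$grid$chrom[w0]
  cand <- which(ctx$grid$chrom == chrom &
                  abs(ctx$centers - ctx$centers[w0]) <= search_radius)
  cand <- intersect(cand, ctx$testable)
  p <- tag_window_p(ctx, sig$tag_variant, cand)
  strongest <- cand[which.min(p)]
  on_chr <- intersect(which(ctx$grid$chrom == chrom), ctx$testable)
  pos <- match(strongest, on_chr)
  p_chr <- rep(NA_real_, length(on_chr))
  idx_in_cand <- match(on_chr, cand)
  p_chr[!is.na(idx_in_cand)] <- p[idx_in_cand[!is.na(idx_in_cand)]]
  lo <- pos
  while (lo > 1) {
    pl <- p_chr[lo - 1]
    if (is.na(pl)) pl <- tag_window_p(ctx, sig$tag_variant, on_chr[lo - 1])
    if (is.na(pl) || pl > alpha) break
    p_chr[lo - 1] <- pl; lo <- lo - 1
  }
  hi <- pos
  while (hi < length(on_chr)) {
    ph <- p_chr[hi + 1]
    if (is.na(ph)) ph <- tag_window_p(ctx, sig$tag_variant, on_chr[hi + 1])
    if (is.na(ph) || ph > alpha) break
    p_chr[hi + 1] <- ph; hi <- hi + 1
  }
  win <- on_chr[lo:hi]
  tibble::tibble(chrom = chrom, start = min(ctx$grid$start[win]),
                 end = max(ctx$grid$end[win]), strongest_window = strongest,
                 n_windows = length(win))
}

assoc_p_with_na <- function(dose, vals, covariates, min_n = 6) {
  # per-column association of dosage with a value matrix containing NAs
  vapply(seq_len(ncol(vals)), function(j) {
    ok <- which(!is.na(vals[, j]))
    if (length(ok) < min_n) return(NA_real_)
    C <- covariates[ok, , drop = FALSE]
    dof <- length(ok) - 2 - ncol(C)
    if (dof < 1) return(NA_real_)
    y <- drop(residualize(vals[ok, j, drop = FALSE], C))
    d <- drop(residualize(dose[ok, drop = FALSE], C))
    if (stats::sd(d) == 0 || stats::sd(y) == 0) return(NA_real_)
    r_to_p(stats::cor(d, y), dof)
  }, numeric(1))
}

allowed_orders <- function(top_p) {
  if (top_p <= 5e-8) 4 else if (top_p <= 5e-6) 2 else 1
}

#' CNV-artifact filter for a putative rtQTL
#'
#' Re-tests the tag variant against the smoothed, filtered-raw, and removed
#' (masked during filtering) data over the associated region to reject
#' associations driven by short copy-number variants rather than timing:
#' the tag must associate (p < 0.05) with at least five raw windows; the
#' minimum raw p-value must not be more than one order of magnitude below
#' the smoothed minimum (relaxed to two/four orders when the top p-value is
#' at most 5e-6 / 5e-8); the removed-data minimum p (within 1 Mb of the
#' region) must likewise not undercut the raw minimum; no more than two
#' removed-data windows (three for top p <= 5e-8) may beat the raw
#' minimum; and the raw minimum must be below 0.01 with an associated
#' region longer than one window.
#'
#' @param sig One signal row (with region columns).
#' @param ctx A [scan_context()] over the smoothed phenotype.
#' @param raw [rt_matrix()] in `"filtered_raw"` state.
#' @param genotypes A [genotype_table()].
#' @return One-row tibble of per-criterion verdicts and overall `pass`.
#' @export
artifact_filter <- function(sig, ctx, raw, genotypes) {
  dose <- genotypes$dosage[, sig$tag_variant, drop = FALSE]
  grid <- raw$grid
  centers <- window_centers(grid)
  region <- which(grid$chrom == sig$region_chrom &
                    centers >= sig$region_start & centers <= sig$region_end)
  flank <- which(grid$chrom == sig$region_chrom &
                   centers >= sig$region_start - 1e6 &
                   centers <= sig$region_end + 1e6)
  p_raw <- assoc_p_with_na(dose, raw$values[, region, drop = FALSE],
                           ctx$covariates)
  p_smooth <- tag_window_p(ctx, sig$tag_variant, region)
  p_removed <- assoc_p_with_na(dose,
                               raw$removed_values[, flank, drop = FALSE],
                               ctx$covariates)
  min_raw <- suppressWarnings(min(p_raw, na.rm = TRUE))
  min_smooth <- suppressWarnings(min(p_smooth, na.rm = TRUE))
  min_removed <- suppressWarnings(min(p_removed, na.rm = TRUE))
  orders <- allowed_orders(sig$top_p)
  crit1 <- sum(p_raw < 0.05, na.rm = TRUE) >= 5
  crit2 <- is.infinite(min_smooth) ||
    log10(min_raw) > log10(min_smooth) - orders
  crit3 <- is.infinite(min_removed) ||
    log10(min_removed) > log10(min_raw) - orders
  max_removed_windows <- if (sig$top_p <= 5e-8) 3 else 2
  crit4 <- sum(p_removed < min_raw, na.rm = TRUE) <= max_removed_windows
  crit5 <- is.finite(min_raw) && min_raw < 0.01 && sig$region_n_windows > 1
  tibble::tibble(raw_support = crit1, raw_vs_smoothed = crit2,
                 removed_vs_raw = crit3, removed_windows = crit4,
                 raw_strength = crit5,
                 pass = crit1 && crit2 && crit3 && crit4 && crit5)
}

#' Map cis-rtQTLs on a cohort
#'
#' End-to-end two-step mapping: scans every testable window for its
#' strongest cis association with a permutation/beta-approximated
#' window-level p-value; flags significant windows by Benjamini-Hochberg at
#' `fdr`; derives a per-window empirical-FDR variant threshold from 500
#' permutations; peels significant variants into independent signals by
#' greedy LD clumping; consolidates signals across windows and splits them
#' by conditional analysis; determines each signal's associated region; and
#' applies the CNV-artifact filter.
#'
#' @param smoothed [rt_matrix()] in `"smoothed"` state.
#' @param raw [rt_matrix()] in `"filtered_raw"` state.
#' @param genotypes [genotype_table()] (QC applied internally).
#' @param covariates Covariate matrix, or `NULL` to build none.
#' @param fdr Window-level and variant-level FDR (default 0.10).
#' @param n_perm,perm_cap Window-scan permutation budget.
#' @param n_perm_threshold Permutations for the variant threshold.
#' @param seed Seed for all permutation streams.
#' @param keep_failing Keep signals failing the artifact filter (flagged)
#'   instead of dropping them.
#' @return List with `signals` (tibble), `windows` (window results with
#'   significance flags), and `context` (the [scan_context()]).
#' @export
map_rtqtls <- function(smoothed, raw, genotypes, covariates = NULL,
                       fdr = 0.10, n_perm = 1000, perm_cap = 10000,
                       n_perm_threshold = 500, seed = 1L,
                       keep_failing = FALSE) {
  genotypes <- qc_variants(genotypes)
  ctx <- scan_context(smoothed, genotypes, covariates)
  wr <- scan_windows(ctx, n_perm = n_perm, perm_cap = perm_cap, seed = seed)
  wr <- significant_windows(wr, fdr)
  sig_win <- wr$window[wr$significant]
  per_window <- list()
  for (w in sig_win) {
    ws <- window_scan(ctx, w, n_perm = n_perm_threshold,
                      perm_cap = n_perm_threshold, seed = seed,
                      keep_perm = TRUE)
    pt <- variant_threshold(ws$assoc$p, ws$perm_p, fdr = fdr)
    if (is.na(pt)) next
    hits <- ws$assoc[ws$assoc$p <= pt, ]
    if (nrow(hits) == 0) next
    sigs <- define_signals(hits, genotypes)
    if (nrow(sigs) == 0) next
    sigs$window <- w
    sigs$threshold_pt <- pt
    per_window[[length(per_window) + 1]] <- sigs
  }
  if (length(per_window) == 0) {
    return(list(signals = tibble::tibble(), windows = wr, context = ctx))
  }
  signals <- dplyr::bind_rows(per_window)
  signals <- consolidate_and_split(signals, ctx, genotypes)
  regions <- purrr::map(seq_len(nrow(signals)), function(i) {
    associated_region(signals[i, ], ctx)
  }) |> dplyr::bind_rows()
  signals <- signals |>
    dplyr::mutate(region_chrom = regions$chrom,
                  region_start = regions$start,
                  region_end = regions$end,
                  strongest_window = regions$strongest_window,
                  region_n_windows = regions$n_windows)
  verdicts <- purrr::map(seq_len(nrow(signals)), function(i) {
    artifact_filter(signals[i, ], ctx, raw, genotypes)
  }) |> dplyr::bind_rows()
  signals <- dplyr::bind_cols(signals, verdicts)
  if (!keep_failing) signals <- dplyr::filter(signals, .data$pass)
  list(signals = signals, windows = wr, context = ctx)
}

#' Merge rtQTL lists from two cohorts
#'
#' Signals from cohort B are dropped when they replicate a cohort-A signal:
#' some member variant with a p-value no more than two orders of magnitude
#' above B's top p-value also belongs to an A signal, with the same
#' direction of effect in both cohorts. Kept signals are annotated by
#' source.
#'
#' @param signals_a,signals_b Signal tibbles from [map_rtqtls()].
#' @param orders Allowed p-value gap in orders of magnitude (default 2).
#' @return Combined signal tibble with a `source` column.
#' @export
merge_cohorts <- function(signals_a, signals_b, orders = 2) {
  mem_a <- signals_a |>
    dplyr::select("signal", "members") |>
    tidyr::unnest("members") |>
    dplyr::select(signal_a = "signal", "variant_id", beta_a = "beta")
  drop_b <- vapply(seq_len(nrow(signals_b)), function(i) {
    mb <- signals_b$members[[i]]
    near_top <- mb[mb$p <= signals_b$top_p[i] * 10^orders, ]
    hit <- dplyr::inner_join(near_top, mem_a, by = "variant_id",
                             relationship = "many-to-many")
    any(sign(hit$beta) == sign(hit$beta_a))
  }, logical(1))
  dplyr::bind_rows(
    dplyr::mutate(signals_a, source = "A"),
    dplyr::mutate(signals_b[!drop_b, ], source = "B"))
}

#' Validation binomial parameter
#'
#' Probability that a signal validates by chance in at least one of `d`
#' independent datasets when validation requires nominal `p < alpha` with
#' a matching direction of effect (hence `alpha/2` per dataset):
#' `1 - (1 - alpha/2)^d`.
#'
#' @param d Number of validation datasets.
#' @param alpha Nominal significance level (default 0.05).
#' @return Scalar parameter in (0, 1).
#' @export
validation_binomial_parameter <- function(d, alpha = 0.05) {
  if (d < 1) stop("validation requires at least one dataset")
  1 - (1 - alpha / 2)^d
}

#' Validate discovery signals in independent cohorts
#'
#' Each signal's tag variant (or, when absent, a member variant within two
#' orders of magnitude of the top p-value) is tested against the validation
#' window nearest the discovery locus of strongest association. A signal is
#' validated if it reaches nominal p < `alpha` with the same direction of
#' effect in at least one dataset. Signals with no testable variant in any
#' dataset (non-polymorphic, missing all three genotype classes, or
#' inconsistent alternative allele) are excluded from the denominator. A
#' cohort-level exact binomial test compares the validated count with the
#' chance expectation [validation_binomial_parameter()].
#'
#' @param signals Discovery signal tibble.
#' @param validations List of validation cohorts, each a list with
#'   elements `ctx` (a [scan_context()]) and `genotypes`.
#' @param alpha Nominal level (default 0.05).
#' @return List with `per_signal` (tibble) and `binomial` (tibble:
#'   `n_testable`, `n_validated`, `parameter`, `p`).
#' @export
validate_signals <- function(signals, validations, alpha = 0.05) {
  d <- length(validations)
  param <- validation_binomial_parameter(d, alpha)
  rows <- purrr::map(seq_len(nrow(signals)), function(i) {
    sig <- signals[i, ]
    testable <- FALSE; validated <- FALSE
    for (val in validations) {
      cand <- sig$members[[1]] |>
        dplyr::filter(.data$p <= sig$top_p * 100) |>
        dplyr::arrange(.data$p)
      cand <- cand[cand$variant_id %in% val$ctx$vinfo$variant_id, ]
      if (sig$tag_variant %in% val$ctx$vinfo$variant_id)
        cand <- dplyr::bind_rows(
          sig$members[[1]][sig$members[[1]]$variant_id == sig$tag_variant, ],
          cand)
      usable <- NULL
      for (j in seq_len(nrow(cand))) {
        dvec <- val$genotypes$dosage[, cand$variant_id[j]]
        if (length(unique(dvec)) == 3) { usable <- cand[j, ]; break }
      }
      if (is.null(usable)) next
      testable <- TRUE
      # nearest testable validation window to the discovery locus
      w0 <- sig$strongest_window
      chrom <- val$ctx$grid$chrom[val$ctx$testable]
      dists <- abs(val$ctx$centers[val$ctx$testable] -
                     val$ctx$centers[sig$strongest_window])
      dists[chrom != sig$region_chrom] <- Inf
      wv <- val$ctx$testable[which.min(dists)]
      vidx <- match(usable$variant_id, val$ctx$vinfo$variant_id)
      wcol <- match(wv, val$ctx$testable)
      r <- sum(val$ctx$Yu[, wcol] * val$ctx$Du[, vidx])
      p <- r_to_p(r, val$ctx$dof)
      if (p < alpha && sign(r) == sign(usable$beta)) validated <- TRUE
    }
    tibble::tibble(signal = sig$signal, testable = testable,
                   validated = validated)
  }) |> dplyr::bind_rows()
  n_testable <- sum(rows$testable)
  if (n_testable == 0) stop("zero testable signals")
  n_validated <- sum(rows$validated)
  bt <- stats::binom.test(n_validated, n_testable, param,
                          alternative = "greater")
  list(per_signal = rows,
       binomial = tibble::tibble(n_testable = n_testable,
                                 n_validated = n_validated,
                                 parameter = param, p = bt$p.value))
}
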