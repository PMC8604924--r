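early_allele_dosage <- function(genotypes, variant_id, beta) {
  # dosage of the early-replicating allele: the alternative allele when the
  # association beta is positive (more alt alleles -> earlier), else the
  # reference allele
  d <- genotypes$dosage[, variant_id]
  if (beta >= 0) d else 2 - d
}

#' Group rtQTL signals into multi-rtQTL regions
#'
#' Builds a graph over signals with an edge when their most strongly
#' associated timing loci are correlated across individuals (R-squared of
#' at least `r2_min`) and less than `dist_max` apart; connected components
#' with two or more members are candidate multi-rtQTL regions. Each member
#' must then add explanatory power: a nested-model F-test compares the
#' regression of the primary locus phenotype on all member tag dosages
#' against the model dropping the candidate, and members failing p < 0.05
#' are pruned (LD between tags does not by itself block membership). The
#' primary signal is the one with the lowest top p-value.
#'
#' @param signals Signal tibble from [map_rtqtls()] (needs
#'   `strongest_window`).
#' @param ctx A [scan_context()].
#' @param genotypes A [genotype_table()].
#' @param r2_min Locus correlation threshold (default 0.2).
#' @param dist_max Maximum locus distance in bp (default 2 Mb).
#' @return Tibble of regions: `region`, `chrom`, `primary_signal`,
#'   `n_rtqtls`, `member_signals` (list of signal ids ordered primary
#'   first), `focal_window`.
#' @export
find_multi_regions <- function(signals, ctx, genotypes, r2_min = 0.2,
                               dist_max = 2e6) {
  empty <- tibble::tibble(region = integer(0), chrom = character(0),
                          primary_signal = integer(0), n_rtqtls = integer(0),
                          member_signals = list(), focal_window = integer(0))
  if (nrow(signals) < 2) return(empty)
  k <- nrow(signals)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    wi <- signals$strongest_window[i]; wj <- signals$strongest_window[j]
    if (ctx$grid$chrom[wi] != ctx$grid$chrom[wj]) next
    if (abs(ctx$centers[wi] - ctx$centers[wj]) >= dist_max) next
    ci <- match(wi, ctx$testable); cj <- match(wj, ctx$testable)
    if (is.na(ci) || is.na(cj)) next
    if (sum(ctx$Yu[, ci] * ctx$Yu[, cj])^2 < r2_min) next
    parent[find(i)] <- find(j)
  }
  comp <- vapply(seq_len(k), find, integer(1))
  out <- list()
  for (idx in split(seq_len(k), comp)) {
    if (length(idx) < 2) next
    grp <- signals[idx, ] |> dplyr::arrange(.data$top_p)
    focal <- grp$strongest_window[1]
    wcol <- match(focal, ctx$testable)
    y <- ctx$Yu[, wcol]
    # prune members that add no explanatory power (weakest first)
    repeat {
      if (nrow(grp) < 2) break
      D <- ctx$Du[, match(grp$tag_variant, ctx$vinfo$variant_id),
                  drop = FALSE]
      full <- stats::lm(y ~ D)
      drop_p <- vapply(seq_len(nrow(grp)), function(m) {
        red <- stats::lm(y ~ D[, -m, drop = FALSE])
        stats::anova(red, full)$`Pr(>F)`[2]
      }, numeric(1))
      worst <- which.max(drop_p)
      if (drop_p[worst] < 0.05) break
      grp <- grp[-worst, , drop = FALSE]
    }
    if (nrow(grp) < 2) next
    out[[length(out) + 1]] <- tibble::tibble(
      chrom = ctx$grid$chrom[focal], primary_signal = grp$signal[1],
      n_rtqtls = nrow(grp), member_signals = list(grp$signal),
      focal_window = focal)
  }
  if (length(out) == 0) return(empty)
  dplyr::bind_rows(out) |>
    dplyr::mutate(region = dplyr::row_number(), .before = 1)
}

#' Pooled additivity of early-replicating alleles
#'
#' For each multi-rtQTL region, counts the early-replicating alleles each
#' individual carries across the member rtQTLs and regresses replication
#' timing at the focal locus on that count, pooling regions. With
#' `scale = "relative"` the focal-locus timing is Z-scored across samples
#' before pooling (the convention for visualising pooled regions); with
#' `scale = "profile"` timing stays in profile Z units so the fitted slope
#' is directly comparable to an effect size per allele.
#'
#' @param regions Tibble from [find_multi_regions()] (a single-signal
#'   per-region tibble also works for plain additivity checks).
#' @param signals Signal tibble.
#' @param matrix Smoothed [rt_matrix()] (phenotype source).
#' @param genotypes A [genotype_table()].
#' @param scale `"relative"` or `"profile"`.
#' @return Object of class `rt_additivity`: the pooled data, `lm` fit,
#'   slope and p-value. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
pooled_additivity <- function(regions, signals, matrix, genotypes,
                              scale = c("relative", "profile")) {
  scale <- match.arg(scale)
  vals <- matrix$values
  if (scale == "profile") {
    # re-standardize each profile so timing is in per-sample Z units (the
    # smoothing step leaves the profile slightly shrunk by residual noise)
    for (i in seq_len(nrow(vals))) {
      ok <- !is.na(vals[i, ])
      vals[i, ok] <- (vals[i, ok] - mean(vals[i, ok])) /
        stats::sd(vals[i, ok])
    }
  }
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    reg <- regions[i, ]
    ids <- reg$member_signals[[1]]
    grp <- signals[match(ids, signals$signal), ]
    dose <- rowSums(vapply(seq_len(nrow(grp)), function(m) {
      early_allele_dosage(genotypes, grp$tag_variant[m], grp$beta_tag[m])
    }, numeric(nrow(genotypes$dosage))))
    y <- vals[, reg$focal_window]
    if (scale == "relative") y <- (y - mean(y, na.rm = TRUE)) /
        stats::sd(y, na.rm = TRUE)
    rows[[length(rows) + 1]] <- tibble::tibble(
      region = reg$region, sample = rownames(matrix$values),
      n_early = dose, timing = y)
  }
  data <- dplyr::bind_rows(rows) |> dplyr::filter(!is.na(.data$timing))
  if (length(unique(data$n_early)) < 2)
    stop("need at least 2 distinct early-allele counts")
  fit <- stats::lm(timing ~ n_early, data = data)
  sm <- summary(fit)
  structure(list(data = data, fit = fit,
                 slope = unname(stats::coef(fit)["n_early"]),
                 p = sm$coefficients["n_early", "Pr(>|t|)"],
                 r_squared = sm$r.squared, scale = scale),
            class = "rt_additivity")
}

#' @export
print.rt_additivity <- function(x, ...) {
  cat(sprintf("<rt_additivity> slope %.3f per early allele (p = %.3g, R2 = %.3f, %d obs)\n",
              x$slope, x$p, x$r_squared, nrow(x$data)))
  invisible(x)
}

#' Likelihood-ratio test of additive vs. synergistic architecture
#'
#' Null model: timing is linear in the early-allele dosage 0..4 of a
#' two-rtQTL region. Alternative: the dosage values assigned to the 0- and
#' 4-allele carriers are free parameters estimated from the data (so those
#' two groups may be more extreme than additivity predicts). Both models
#' are Gaussian with a common profiled-out variance; -2 log LR is compared
#' to chi-squared with 2 degrees of freedom. Regions lacking carriers of
#' both 0 and 4 early alleles are not eligible.
#'
#' @param timing Numeric vector of focal-locus timing per sample.
#' @param dosage Integer vector of early-allele counts in 0..4.
#' @return Tibble `lrt`, `p`, `n` (or `NULL` if the region is ineligible).
#' @export
additive_vs_synergistic_lrt <- function(timing, dosage) {
  ok <- !is.na(timing) & !is.na(dosage)
  timing <- timing[ok]; dosage <- dosage[ok]
  if (!any(dosage == 0) || !any(dosage == 4)) return(NULL)
  n <- length(timing)
  sse0 <- sum(stats::lm.fit(cbind(1, dosage), timing)$residuals^2)
  mid <- dosage >= 1 & dosage <= 3
  X <- cbind(1, d = dosage * mid, e0 = as.numeric(dosage == 0),
             e4 = as.numeric(dosage == 4))
  sse1 <- sum(stats::lm.fit(X, timing)$residuals^2)
  lrt <- n * log(sse0 / sse1)
  tibble::tibble(lrt = max(lrt, 0),
                 p = stats::pchisq(max(lrt, 0), df = 2, lower.tail = FALSE),
                 n = n)
}

#' Pairwise genotype-genotype interaction scan
#'
#' For each (window, variant pair), fits
#' `timing ~ g1 + g2 + g1:g2` with genotypes coded -1/0/1 and extracts the
#' interaction-term p-value, Bonferroni-corrected over tested pairs.
#' Collinear pairs are skipped.
#'
#' @param matrix Smoothed [rt_matrix()].
#' @param genotypes A [genotype_table()].
#' @param pairs Tibble with `window`, `variant_a`, `variant_b`.
#' @return Tibble with interaction `beta`, `p` and `p_bonferroni` per pair.
#' @export
interaction_scan <- function(matrix, genotypes, pairs) {
  res <- purrr::map(seq_len(nrow(pairs)), function(i) {
    y <- matrix$values[, pairs$window[i]]
    g1 <- genotypes$dosage[, pairs$variant_a[i]] - 1
    g2 <- genotypes$dosage[, pairs$variant_b[i]] - 1
    ok <- !is.na(y)
    X <- cbind(1, g1, g2, g12 = g1 * g2)[ok, ]
    if (qr(X)$rank < 4) return(NULL)
    fit <- stats::lm.fit(X, y[ok])
    rss <- sum(fit$residuals^2)
    dof <- sum(ok) - 4
    XtXinv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(rss / dof * XtXinv[4, 4])
    tt <- fit$coefficients[4] / se
    tibble::tibble(window = pairs$window[i],
                   variant_a = pairs$variant_a[i],
                   variant_b = pairs$variant_b[i],
                   beta = unname(fit$coefficients[4]),
                   p = 2 * stats::pt(-abs(tt), dof))
  }) |> dplyr::bind_rows()
  if (nrow(res) > 0)
    res$p_bonferroni <- pmin(res$p * nrow(res), 1)
  res
}

#' Prune correlated windows for the interaction scan
#' @param matrix Smoothed [rt_matrix()].
#' @param r_max Correlation threshold above which windows collapse.
#' @return Integer vector of retained window ids.
#' @export
prune_windows <- function(matrix, r_max = 0.5) {
  testable <- which(colSums(is.na(matrix$values)) == 0)
  kept <- integer(0)
  for (w in testable) {
    if (length(kept) == 0) { kept <- w; next }
    r <- suppressWarnings(stats::cor(matrix$values[, w],
                                     matrix$values[, kept, drop = FALSE]))
    if (all(abs(r) <= r_max, na.rm = TRUE)) kept <- c(kept, w)
  }
  kept
}

#' Prune variants by LD for the interaction scan
#' @param genotypes A [genotype_table()].
#' @param r2_max LD threshold above which variants are pruned.
#' @return Character vector of retained variant ids.
#' @export
prune_variants <- function(genotypes, r2_max = 0.5) {
  ids <- genotypes$info$variant_id
  kept <- character(0)
  for (v in ids) {
    if (length(kept) == 0) { kept <- v; next }
    if (all(ld_r2(genotypes, v, kept)[1, ] <= r2_max)) kept <- c(kept, v)
  }
  kept
}

#' Spatial proximity of primary and secondary rtQTLs
#'
#' Compares the median Hi-C contact score over primary-secondary pairs with
#' a permutation distribution in which each pair keeps its genomic distance
#' but both loci shift together by a random 1-2 Mb offset (either
#' direction). Significance is a one-sided Z-test on the observed median
#' against the permutation mean and SD; a Shapiro-Wilk p-value for the
#' permutation medians is reported as a normality check.
#'
#' @param pairs Tibble with `pos_a`, `pos_b` (bp, one chromosome).
#' @param contact Square dense contact matrix for that chromosome.
#' @param bin_size Contact-matrix bin width in bp.
#' @param n_perm Number of permutations (default 100).
#' @param shift_min,shift_max Shift magnitude range (bp).
#' @param seed Seed for the shifts.
#' @return Tibble `observed_median`, `perm_mean`, `perm_sd`, `z`, `p`,
#'   `shapiro_p`.
#' @export
spatial_proximity_test <- function(pairs, contact, bin_size,
                                   n_perm = 100, shift_min = 1e6,
                                   shift_max = 2e6, seed = 1L) {
  nb <- nrow(contact)
  lookup <- function(pa, pb) {
    ba <- floor(pa / bin_size) + 1
    bb <- floor(pb / bin_size) + 1
    if (any(ba < 1 | ba > nb | bb < 1 | bb > nb))
      stop("pair falls outside the contact matrix")
    contact[cbind(ba, bb)]
  }
  obs <- stats::median(lookup(pairs$pos_a, pairs$pos_b))
  set.seed(seed)
  perm_meds <- vapply(seq_len(n_perm), function(b) {
    repeat {
      shift <- sample(c(-1, 1), nrow(pairs), replace = TRUE) *
        stats::runif(nrow(pairs), shift_min, shift_max)
      pa <- pairs$pos_a + shift; pb <- pairs$pos_b + shift
      if (all(pa >= 0 & pb >= 0 & pa < nb * bin_size & pb < nb * bin_size))
        return(stats::median(lookup(pa, pb)))
    }
  }, numeric(1))
  mu <- mean(perm_meds); sdv <- stats::sd(perm_meds)
  z <- if (sdv == 0) {
    if (obs == mu) 0 else sign(obs - mu) * Inf
  } else (obs - mu) / sdv
  sw <- try(stats::shapiro.test(perm_meds)$p.value, silent = TRUE)
  tibble::tibble(observed_median = obs, perm_mean = mu, perm_sd = sdv,
                 z = z, p = stats::pnorm(z, lower.tail = FALSE),
                 shapiro_p = if (inherits(sw, "try-error")) NA_real_ else sw)
}
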