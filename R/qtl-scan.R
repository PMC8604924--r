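#' Variant QC ahead of rtQTL mapping
#'
#' Keeps biallelic variants with MAF of at least `maf_min`, a Hardy-Weinberg
#' chi-squared p-value of at least `hwe_p`, and all three genotype classes
#' observed in the cohort.
#'
#' @param genotypes A [genotype_table()].
#' @param maf_min Minimum minor allele frequency.
#' @param hwe_p Minimum Hardy-Weinberg equilibrium p-value.
#' @return A filtered [genotype_table()].
#' @export
qc_variants <- function(genotypes, maf_min = 0.05, hwe_p = 1e-3) {
  d <- genotypes$dosage
  n0 <- colSums(d == 0); n1 <- colSums(d == 1); n2 <- colSums(d == 2)
  n <- nrow(d)
  p_alt <- (n1 + 2 * n2) / (2 * n)
  e0 <- n * (1 - p_alt)^2; e1 <- n * 2 * p_alt * (1 - p_alt); e2 <- n * p_alt^2
  chisq <- (n0 - e0)^2 / pmax(e0, 1e-12) + (n1 - e1)^2 / pmax(e1, 1e-12) +
    (n2 - e2)^2 / pmax(e2, 1e-12)
  hwe <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  keep <- genotypes$info$maf >= maf_min & hwe >= hwe_p &
    n0 > 0 & n1 > 0 & n2 > 0
  subset_variants(genotypes, genotypes$info$variant_id[keep])
}

#' Construct mapping covariates
#'
#' Genotype principal components (population structure) plus phenotype
#' principal components of the filtered-raw timing data (batch and other
#' systematic structure), GTEx-style.
#'
#' @param raw_matrix [rt_matrix()] in `"filtered_raw"` (or later) state.
#' @param genotypes A [genotype_table()].
#' @param n_geno_pcs Number of genotype PCs (default 3).
#' @param n_pheno_pcs Number of phenotype PCs.
#' @return Matrix samples x covariates (no intercept column; the intercept
#'   is implicit in residualization).
#' @export
build_covariates <- function(raw_matrix, genotypes, n_geno_pcs = 3,
                             n_pheno_pcs = 0) {
  n <- nrow(genotypes$dosage)
  out <- NULL
  if (n_geno_pcs > 0) {
    d <- genotypes$dosage
    d <- d[, apply(d, 2, stats::sd) > 0, drop = FALSE]
    gp <- stats::prcomp(d, center = TRUE, scale. = TRUE)
    out <- gp$x[, seq_len(min(n_geno_pcs, ncol(gp$x))), drop = FALSE]
    colnames(out) <- paste0("genoPC", seq_len(ncol(out)))
  }
  if (n_pheno_pcs > 0) {
    v <- raw_matrix$values
    complete <- colSums(is.na(v)) == 0
    pp <- stats::prcomp(v[, complete, drop = FALSE], center = TRUE)
    px <- pp$x[, seq_len(min(n_pheno_pcs, ncol(pp$x))), drop = FALSE]
    colnames(px) <- paste0("phenoPC", seq_len(ncol(px)))
    out <- cbind(out, px)
  }
  if (is.null(out)) out <- matrix(numeric(0), n, 0)
  rownames(out) <- rownames(genotypes$dosage)
  out
}

residualize <- function(y, covariates) {
  # residuals of y (vector or matrix) on [1, covariates]
  C <- cbind(1, covariates)
  qr_c <- qr(C)
  y - C %*% qr.coef(qr_c, y)
}

#' Two-sided regression p-value from correlations
#' @param r Correlation(s) between residualized dosage and phenotype.
#' @param dof Residual degrees of freedom.
#' @return p-value(s).
#' @keywords internal
r_to_p <- function(r, dof) {
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  t <- r * sqrt(dof) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), dof)
}

unit_cols <- function(x) {
  x <- sweep(x, 2, colMeans(x))
  nrm <- sqrt(colSums(x^2))
  nrm[nrm == 0] <- Inf
  sweep(x, 2, nrm, "/")
}

#' Prepare a cohort for repeated window scans
#'
#' Residualizes all window phenotypes and all variant dosages on the
#' covariates once and unit-normalizes them, so per-window association and
#' permutation statistics reduce to cross-products.
#'
#' @param matrix [rt_matrix()] in `"smoothed"` state (the mapping
#'   phenotype).
#' @param genotypes A QC'd [genotype_table()].
#' @param covariates Matrix from [build_covariates()] (may have 0 columns).
#' @param cis_radius Cis window half-width in bp (default 1 Mb).
#' @return A list of class `scan_context`.
#' @export
scan_context <- function(matrix, genotypes, covariates = NULL,
                         cis_radius = 1e6) {
  if (is.null(covariates))
    covariates <- matrix(numeric(0), nrow(matrix$values), 0)
  testable <- which(colSums(is.na(matrix$values)) == 0)
  Y <- residualize(matrix$values[, testable, drop = FALSE], covariates)
  D <- residualize(genotypes$dosage, covariates)
  ynorm <- sqrt(colSums(sweep(Y, 2, colMeans(Y))^2))
  dnorm <- sqrt(colSums(sweep(D, 2, colMeans(D))^2))
  structure(list(
    Yu = unit_cols(Y), Du = unit_cols(D),
    ynorm = ynorm, dnorm = dnorm,
    testable = testable, grid = matrix$grid,
    centers = window_centers(matrix$grid),
    vinfo = genotypes$info, covariates = covariates,
    dof = nrow(matrix$values) - 2 - ncol(covariates),
    n = nrow(matrix$values), cis_radius = cis_radius),
    class = "scan_context")
}

cis_variants_of <- function(ctx, window) {
  ctr <- ctx$centers[window]
  which(ctx$vinfo$chrom == ctx$grid$chrom[window] &
          abs(ctx$vinfo$pos - ctr) <= ctx$cis_radius)
}

#' Scan one replication-timing window for cis associations
#'
#' Regresses the (covariate-residualized) window phenotype on every cis
#' variant dosage, records the strongest nominal p-value, and computes a
#' window-level p-value by permuting the residualized phenotype and fitting
#' a beta distribution to the permutation null of the minimum p-value.
#' Permutations run in chunks with early stopping once 100 null exceedances
#' have been observed (unbiased for windows near significance), up to
#' `perm_cap`.
#'
#' @param ctx A [scan_context()].
#' @param window Window id (column of the grid).
#' @param n_perm Minimum number of permutations.
#' @param perm_cap Maximum number of permutations.
#' @param seed Integer; the permutation stream is seeded per window id so
#'   results are reproducible window by window.
#' @param keep_perm Keep the full matrix of permutation p-values (needed by
#'   [variant_threshold()]).
#' @return List with `window` (one-row tibble: `window`, `min_p_nominal`,
#'   `window_p`, `n_cis_variants`, `n_perm_used`) and `assoc` (tibble of
#'   per-variant results: `variant_id`, `beta`, `t_stat`, `p`), plus
#'   `perm_p` when requested.
#' @export
window_scan <- function(ctx, window, n_perm = 1000, perm_cap = 10000,
                        seed = 1L, keep_perm = FALSE) {
  wcol <- match(window, ctx$testable)
  if (is.na(wcol)) stop("window ", window, " is not testable (masked)")
  cis <- cis_variants_of(ctx, window)
  if (length(cis) == 0) return(NULL)
  y <- ctx$Yu[, wcol]
  Dc <- ctx$Du[, cis, drop = FALSE]
  r_obs <- drop(crossprod(Dc, y))
  p_obs <- r_to_p(r_obs, ctx$dof)
  # beta on the dosage scale: r * sd(y_res)/sd(d_res); with unit columns the
  # ratio of original norms is recovered from the residualized inputs
  min_p <- min(p_obs)
  max_r <- max(abs(r_obs))

  set.seed((seed + 7L * window) %% .Machine$integer.max)
  exceed <- 0L; used <- 0L
  null_max_r <- numeric(0)
  perm_p <- if (keep_perm) NULL else NULL
  perm_chunks <- list()
  chunk <- 100L
  while (used < perm_cap) {
    b <- min(chunk, perm_cap - used)
    P <- vapply(seq_len(b), function(i) y[sample.int(ctx$n)],
                numeric(ctx$n))
    Rm <- abs(crossprod(Dc, P))            # |r| for all cis x perms
    cmax <- Rm[cbind(max.col(t(Rm)), seq_len(b))]
    null_max_r <- c(null_max_r, cmax)
    if (keep_perm) perm_chunks[[length(perm_chunks) + 1]] <- Rm
    exceed <- exceed + sum(cmax >= max_r)
    used <- used + b
    if (used >= n_perm && exceed >= 100L) break
  }
  null_min_p <- r_to_p(null_max_r, ctx$dof)
  emp_p <- (1 + sum(null_min_p <= min_p)) / (1 + used)
  window_p <- beta_approx_p(min_p, null_min_p, emp_p)

  assoc <- tibble::tibble(
    variant_id = ctx$vinfo$variant_id[cis],
    beta = unname(r_obs * ctx$ynorm[wcol] / ctx$dnorm[cis]),  # Z per dose
    t_stat = unname(r_obs * sqrt(ctx$dof) / sqrt(pmax(1 - r_obs^2, 1e-15))),
    p = unname(p_obs))
  out <- list(
    window = tibble::tibble(window = window, min_p_nominal = min_p,
                            window_p = window_p,
                            n_cis_variants = length(cis),
                            n_perm_used = used),
    assoc = assoc)
  if (keep_perm)
    out$perm_p <- r_to_p(do.call(cbind, perm_chunks), ctx$dof)
  out
}

beta_approx_p <- function(min_p, null_min_p, emp_p) {
  # method-of-moments beta fit to the permutation null of the minimum
  # p-value, refined by maximum likelihood; degenerate fits fall back to
  # the pseudocount empirical p
  m <- mean(null_min_p); v <- stats::var(null_min_p)
  if (!is.finite(v) || v <= 0 || m <= 0 || m >= 1) return(emp_p)
  common <- m * (1 - m) / v - 1
  a <- m * common; b <- (1 - m) * common
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) return(emp_p)
  if (emp_p > 0.05) {
    # far from significance: the method-of-moments fit is accurate enough
    p <- stats::pbeta(min_p, a, b)
    return(if (is.finite(p)) max(p, .Machine$double.xmin) else emp_p)
  }
  nll <- function(par) {
    if (any(par <= 0)) return(Inf)
    -sum(stats::dbeta(pmin(pmax(null_min_p, 1e-300), 1 - 1e-16),
                      par[1], par[2], log = TRUE))
  }
  fit <- try(stats::optim(c(a, b), nll, method = "Nelder-Mead"),
             silent = TRUE)
  if (!inherits(fit, "try-error") && fit$convergence == 0 &&
      all(fit$par > 0)) {
    a <- fit$par[1]; b <- fit$par[2]
  }
  p <- stats::pbeta(min_p, a, b)
  if (!is.finite(p)) emp_p else max(p, .Machine$double.xmin)
}

#' Scan all testable windows of a cohort
#'
#' @param ctx A [scan_context()].
#' @param windows Window ids to scan (default: all testable).
#' @param n_perm,perm_cap,seed Passed to [window_scan()].
#' @return Tibble of window results.
#' @export
scan_windows <- function(ctx, windows = ctx$testable, n_perm = 1000,
                         perm_cap = 10000, seed = 1L) {
  res <- purrr::map(windows, function(w) {
    ws <- window_scan(ctx, w, n_perm = n_perm, perm_cap = perm_cap,
                      seed = seed)
    if (is.null(ws)) NULL else ws$window
  })
  dplyr::bind_rows(res)
}

#' Flag windows harboring rtQTLs at a given FDR
#'
#' Benjamini-Hochberg over window-level p-values.
#'
#' @param window_results Tibble from [scan_windows()].
#' @param fdr False discovery rate (default 0.10; 0.05 supported).
#' @return The tibble with a logical `significant` column.
#' @export
significant_windows <- function(window_results, fdr = 0.10) {
  window_results |>
    dplyr::mutate(q = stats::p.adjust(.data$window_p, method = "BH"),
                  significant = .data$q <= fdr)
}

#' Per-window empirical-FDR variant significance threshold
#'
#' At a candidate threshold `p_t`, every permutation variant passing `p_t`
#' is a false positive, so the FDR is estimated as the mean permutation
#' count passing `p_t` divided by the observed count passing `p_t`. The
#' threshold is the largest observed p-value whose estimated FDR does not
#' exceed `fdr`; the candidate grid is the sorted observed p-values.
#'
#' @param real_p Observed per-variant p-values for the window.
#' @param perm_p Matrix of permutation p-values (variants x permutations).
#' @param fdr Target FDR (default 0.10).
#' @return The threshold `p_t`, or `NA` if no threshold satisfies the
#'   bound (no significant variants in the window).
#' @export
variant_threshold <- function(real_p, perm_p, fdr = 0.10) {
  grid <- sort(unique(real_p))
  sp <- sort(as.vector(perm_p))
  B <- ncol(perm_p)
  perm_mean <- findInterval(grid, sp) / B
  real_count <- findInterval(grid, sort(real_p))
  ok <- perm_mean / real_count <= fdr
  if (!any(ok)) return(NA_real_)
  max(grid[ok])
}

#' Genomic inflation factor
#'
#' Ratio of the median observed association chi-squared statistic to the
#' analytic median of the 1-df chi-squared distribution.
#'
#' @param chisq Numeric vector of 1-df chi-squared statistics (e.g.
#'   squared association t/z statistics from null windows).
#' @return Scalar lambda.
#' @export
genomic_inflation <- function(chisq) {
  if (length(chisq) == 0) stop("empty input")
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Select the number of phenotype PCs for mapping
#'
#' Runs a reduced-permutation window scan for each candidate number of
#' phenotype PCs and returns the one yielding the most
#' significant windows at the given FDR (ties take the smallest k).
#'
#' @param raw_matrix `"filtered_raw"` [rt_matrix()] (PC source).
#' @param smoothed [rt_matrix()] in `"smoothed"` state (mapping phenotype).
#' @param genotypes QC'd [genotype_table()].
#' @param k_range Candidate numbers of phenotype PCs.
#' @param fdr Window-level FDR.
#' @param n_perm Reduced permutation budget per window.
#' @param n_geno_pcs Genotype PCs (default 3).
#' @param windows Optional subset of windows to scan (speeds the sweep).
#' @param seed Seed for the permutation streams.
#' @return List with `k` (chosen), and `counts` (tibble k x
#'   significant-window count).
#' @export
select_phenotype_pcs <- function(raw_matrix, smoothed, genotypes,
                                 k_range = 0:10, fdr = 0.10, n_perm = 100,
                                 n_geno_pcs = 3, windows = NULL,
                                 seed = 1L) {
  n <- nrow(raw_matrix$values)
  if (max(k_range) > n - n_geno_pcs - 4)
    stop("k_range exceeds the sample-size budget for covariates")
  counts <- purrr::map(k_range, function(k) {
    cov <- build_covariates(raw_matrix, genotypes, n_geno_pcs, k)
    ctx <- scan_context(smoothed, genotypes, cov)
    wins <- if (is.null(windows)) ctx$testable else
      intersect(windows, ctx$testable)
    wr <- scan_windows(ctx, wins, n_perm = n_perm, perm_cap = n_perm,
                       seed = seed)
    tibble::tibble(k = k,
                   n_significant = sum(significant_windows(wr, fdr)$significant))
  }) |> dplyr::bind_rows()
  best <- counts |>
    dplyr::filter(.data$n_significant == max(.data$n_significant)) |>
    dplyr::slice_min(.data$k, n = 1)
  list(k = best$k, counts = counts)
}
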