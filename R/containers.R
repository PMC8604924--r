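#' Build a genomic window grid
#'
#' The analysis operates on a fixed grid of non-overlapping, constant-width
#' windows (0-based half-open coordinates). Each row is one window; windows
#' are sorted by chromosome then start.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp. `window_size` must
#'   divide it.
#' @param window_size Window width in bp (default 10000, i.e. 10 kb).
#' @return A tibble with columns `window` (integer id), `chrom`, `start`,
#'   `end`, of class `rt_grid`.
#' @export
rt_grid <- function(n_chromosomes, chrom_length, window_size = 10000L) {
  stopifnot(n_chromosomes >= 1, chrom_length > 0, window_size > 0)
  if (chrom_length %% window_size != 0) {
    stop("`window_size` must divide `chrom_length`")
  }
  n_win <- chrom_length %/% window_size
  grid <- tidyr::expand_grid(
    chrom = paste0("chr", seq_len(n_chromosomes)),
    start = as.numeric(seq(0L, chrom_length - window_size, by = window_size))
  ) |>
    dplyr::mutate(
      end = .data$start + window_size,
      window = dplyr::row_number(),
      .before = 1
    ) |>
    dplyr::select("window", "chrom", "start", "end")
  class(grid) <- c("rt_grid", class(grid))
  grid
}

#' Window centers of a grid
#' @param grid An `rt_grid` tibble.
#' @return Numeric vector of window midpoints (bp).
#' @export
window_centers <- function(grid) (grid$start + grid$end) / 2

#' Construct a replication-timing matrix
#'
#' Couples a samples-by-windows value matrix to its genomic grid, tracking
#' the processing state and the masks accumulated by filtering. Values at
#' masked positions are `NA`; the raw values removed by per-sample filtering
#' are retained in `removed_values` because the rtQTL artifact filter needs
#' to re-test them.
#'
#' @param values Numeric matrix, samples in rows, windows in columns
#'   (`ncol(values) == nrow(grid)`). Row names are sample ids.
#' @param grid An `rt_grid`.
#' @param state One of `"raw"`, `"filtered_raw"`, `"smoothed"`.
#' @param mask_windows Integer indices of globally removed windows.
#' @param removed_values Matrix of the same shape holding raw values at
#'   masked positions, `NA` elsewhere.
#' @return An object of class `rt_matrix`.
#' @export
rt_matrix <- function(values, grid, state = "raw",
                      mask_windows = integer(0),
                      removed_values = NULL) {
  stopifnot(is.matrix(values), ncol(values) == nrow(grid))
  state <- match.arg(state, c("raw", "filtered_raw", "smoothed"))
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("s", seq_len(nrow(values)))
  }
  if (is.null(removed_values)) {
    removed_values <- matrix(NA_real_, nrow(values), ncol(values),
                             dimnames = dimnames(values))
  }
  structure(
    list(values = values, grid = grid, state = state,
         mask_windows = sort(unique(as.integer(mask_windows))),
         removed_values = removed_values),
    class = "rt_matrix"
  )
}

#' @export
print.rt_matrix <- function(x, ...) {
  cat(sprintf("<rt_matrix [%s]> %d samples x %d windows (%d globally masked, %d point-masked)\n",
              x$state, nrow(x$values), ncol(x$values),
              length(x$mask_windows), sum(is.na(x$values)) ))
  invisible(x)
}

#' @export
dim.rt_matrix <- function(x) dim(x$values)

#' Long-format view of an rt_matrix
#'
#' @param x An `rt_matrix`.
#' @param ... Unused.
#' @return Tibble with `sample`, `window`, `chrom`, `start`, `end`, `value`
#'   (masked positions dropped).
#' @method as_tibble rt_matrix
#' @export
as_tibble.rt_matrix <- function(x, ...) {
  long <- tibble::tibble(
    sample = rep(rownames(x$values), times = ncol(x$values)),
    window = rep(x$grid$window, each = nrow(x$values)),
    value = as.vector(x$values)
  )
  long |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::left_join(x$grid, by = "window") |>
    dplyr::select("sample", "window", "chrom", "start", "end", "value")
}

#' Construct a genotype table
#'
#' Biallelic variants with per-sample alternative-allele dosages (0/1/2).
#' The alternative allele is the "early" allele for planted rtQTL effects in
#' the synthetic generator; in mapping the sign of beta determines which
#' allele is early.
#'
#' @param dosage Integer matrix, samples x variants; column names variant ids.
#' @param info Tibble with columns `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`; `maf` is (re)computed from the dosages.
#' @return Object of class `genotype_table`.
#' @export
genotype_table <- function(dosage, info) {
  stopifnot(is.matrix(dosage), ncol(dosage) == nrow(info),
            all(c("variant_id", "chrom", "pos") %in% names(info)))
  colnames(dosage) <- info$variant_id
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("s", seq_len(nrow(dosage)))
  }
  af <- colMeans(dosage) / 2
  info$maf <- pmin(af, 1 - af)
  structure(list(dosage = dosage, info = tibble::as_tibble(info)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d samples x %d variants, MAF %.3f-%.3f\n",
              nrow(x$dosage), ncol(x$dosage),
              min(x$info$maf), max(x$info$maf)))
  invisible(x)
}

#' Pairwise LD (r-squared) between variants
#'
#' LD is computed from cohort dosages (squared Pearson correlation), the
#' package's default LD provider.
#'
#' @param genotypes A `genotype_table`.
#' @param ids_a,ids_b Variant ids; `ids_b` defaults to `ids_a`.
#' @return Matrix of r-squared values, `length(ids_a)` x `length(ids_b)`.
#' @export
ld_r2 <- function(genotypes, ids_a, ids_b = ids_a) {
  a <- genotypes$dosage[, ids_a, drop = FALSE]
  b <- genotypes$dosage[, ids_b, drop = FALSE]
  r <- suppressWarnings(stats::cor(a, b))
  r[is.na(r)] <- 0
  r^2
}

#' Subset a genotype table by variant
#' @param genotypes A `genotype_table`.
#' @param variant_ids Ids to keep (in this order).
#' @return A `genotype_table`.
#' @export
subset_variants <- function(genotypes, variant_ids) {
  keep <- match(variant_ids, genotypes$info$variant_id)
  if (anyNA(keep)) stop("unknown variant ids")
  genotype_table(genotypes$dosage[, keep, drop = FALSE],
                 genotypes$info[keep, ])
}
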