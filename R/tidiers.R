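#' Tidy a pooled-additivity fit
#'
#' @param x An `rt_additivity` object.
#' @param ... Unused.
#' @return Tibble with one row per regression term.
#' @method tidy rt_additivity
#' @export
tidy.rt_additivity <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(co), estimate = co[, "Estimate"],
                 std_error = co[, "Std. Error"],
                 statistic = co[, "t value"],
                 p_value = co[, "Pr(>|t|)"])
}

#' One-row summary of a pooled-additivity fit
#'
#' @param x An `rt_additivity` object.
#' @param ... Unused.
#' @return One-row tibble: slope per early allele, its p-value, the fit
#'   R-squared and observation count.
#' @method glance rt_additivity
#' @export
glance.rt_additivity <- function(x, ...) {
  tibble::tibble(slope = x$slope, p_value = x$p, r_squared = x$r_squared,
                 n_obs = nrow(x$data),
                 n_regions = length(unique(x$data$region)))
}

#' Tidy a signal table into one row per member variant
#'
#' @param x The `signals` tibble from [map_rtqtls()].
#' @param ... Unused.
#' @return Long tibble with `signal`, `tag_variant`, `variant_id`, `p`,
#'   `beta`.
#' @export
tidy_signal_members <- function(x, ...) {
  x |>
    dplyr::select("signal", "tag_variant", "members") |>
    tidyr::unnest("members")
}
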