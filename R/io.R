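fmt_num <- function(x) {
  ifelse(is.na(x), "NA", format(signif(x, 6), trim = TRUE,
                                scientific = FALSE))
}

#' Write a timing/copy-number matrix as TSV
#'
#' Columns: `window_id`, `chrom`, `start`, `end`, then one column per
#' sample. Floating-point values are written at 6 significant digits.
#'
#' @param matrix An [rt_matrix()].
#' @param path Output path.
#' @export
write_timing_tsv <- function(matrix, path) {
  df <- data.frame(window_id = matrix$grid$window,
                   chrom = matrix$grid$chrom,
                   start = matrix$grid$start, end = matrix$grid$end)
  vals <- t(matrix$values)
  for (j in seq_len(ncol(vals))) df[[colnames(vals)[j]]] <- fmt_num(vals[, j])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a timing/copy-number matrix TSV
#' @param path Path written by [write_timing_tsv()].
#' @param state State to stamp on the result.
#' @return An [rt_matrix()].
#' @export
read_timing_tsv <- function(path, state = "raw") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  grid <- tibble::as_tibble(df[, c("window_id", "chrom", "start", "end")])
  names(grid)[1] <- "window"
  vals <- t(as.matrix(df[, -(1:4), drop = FALSE]))
  rt_matrix(vals, grid, state = state)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param intervals Tibble with `chrom`, `start`, `end`; further columns
#'   are appended as BED extra fields.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  core <- data.frame(chrom = intervals$chrom,
                     start = format(intervals$start, scientific = FALSE,
                                    trim = TRUE),
                     end = format(intervals$end, scientific = FALSE,
                                  trim = TRUE))
  extra <- intervals[, setdiff(names(intervals), c("chrom", "start", "end")),
                     drop = FALSE]
  extra <- extra[, !vapply(extra, is.list, logical(1)), drop = FALSE]
  for (nm in names(extra)) {
    core[[nm]] <- if (is.numeric(extra[[nm]])) fmt_num(extra[[nm]]) else
      extra[[nm]]
  }
  utils::write.table(core, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file
#' @param path BED path.
#' @param extra_names Names for columns beyond chrom/start/end.
#' @return Tibble.
#' @export
read_bed <- function(path, extra_names = NULL) {
  df <- utils::read.table(path, header = FALSE, sep = "\t")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (!is.null(extra_names) && ncol(df) > 3)
    names(df)[4:(3 + length(extra_names))] <- extra_names
  tibble::as_tibble(df)
}

#' Write genotypes as a dosage TSV
#' @param genotypes A [genotype_table()].
#' @param path Output path.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- data.frame(variant_id = genotypes$info$variant_id,
                   chrom = genotypes$info$chrom,
                   pos = genotypes$info$pos,
                   t(genotypes$dosage), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a dosage TSV
#' @param path Path written by [write_dosage_tsv()].
#' @return A [genotype_table()].
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  info <- tibble::as_tibble(df[, c("variant_id", "chrom", "pos")])
  info$ref <- "A"; info$alt <- "G"
  dos <- t(as.matrix(df[, -(1:3), drop = FALSE]))
  genotype_table(dos, info)
}

#' Write genotypes as a minimal VCF (GT only)
#' @param genotypes A [genotype_table()].
#' @param path Output path.
#' @export
write_vcf_minimal <- function(genotypes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       rownames(genotypes$dosage)), collapse = "\t")),
             con)
  gt_str <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(genotypes$dosage))) {
    info <- genotypes$info[j, ]
    writeLines(paste(c(info$chrom, format(info$pos, scientific = FALSE),
                       info$variant_id, info$ref, info$alt, ".", "PASS",
                       ".", "GT",
                       gt_str[genotypes$dosage[, j] + 1]), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Read a minimal VCF (GT fields)
#' @param path VCF path.
#' @return A [genotype_table()].
#' @export
read_vcf_minimal <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  cols <- strsplit(lines[hdr], "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[(hdr + 1):length(lines)]
  parts <- strsplit(body, "\t")
  info <- tibble::tibble(
    variant_id = vapply(parts, `[`, character(1), 3),
    chrom = vapply(parts, `[`, character(1), 1),
    pos = as.numeric(vapply(parts, `[`, character(1), 2)),
    ref = vapply(parts, `[`, character(1), 4),
    alt = vapply(parts, `[`, character(1), 5))
  dos <- vapply(parts, function(p) {
    gt <- p[-(1:9)]
    vapply(strsplit(gt, "[/|]"), function(a) sum(a == "1"), numeric(1))
  }, numeric(length(samples)))
  rownames(dos) <- samples
  genotype_table(dos, info)
}

#' Write the synthetic truth table as JSON
#' @param truth Truth list from [simulate_cohort()].
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  out <- list(planted_rtqtls = truth$planted_rtqtls,
              true_peaks = truth$true_peaks,
              true_cnvs = truth$true_cnvs,
              mark_couplings = truth$mark_couplings)
  jsonlite::write_json(out, path, digits = 8, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages in dependency order — simulate, profile (filter,
#' normalize, smooth), features (peaks, valleys, variant regions), rtQTL
#' mapping, multi-rtQTL analysis, and (when histone tracks are simulated)
#' prediction — writing versioned TSV/BED/JSON outputs and a run manifest
#' with parameters, seed and stage counts.
#'
#' @param config A [cohort_config()].
#' @param outdir Output directory (created if needed).
#' @param stages Character vector of stages to run (dependencies of the
#'   requested stages are always run in-memory).
#' @param n_perm,perm_cap Permutation budget for mapping.
#' @param fdr Mapping FDR.
#' @return Invisibly, a list of the in-memory stage results plus the
#'   manifest.
#' @export
run_rt_pipeline <- function(config, outdir,
                            stages = c("simulate", "profile", "features",
                                       "rtqtl", "multi", "prediction"),
                            n_perm = 200, perm_cap = 1000, fdr = 0.10) {
  known <- c("simulate", "profile", "features", "rtqtl", "multi",
             "chromatin", "prediction")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   parameters = config[!vapply(config, is.list, logical(1))])
  cohort <- simulate_cohort(config)
  if ("simulate" %in% stages) {
    write_timing_tsv(cohort$depth, file.path(outdir, "copy_number.tsv"))
    write_dosage_tsv(cohort$genotypes, file.path(outdir, "dosage.tsv"))
    write_vcf_minimal(cohort$genotypes, file.path(outdir, "genotypes.vcf"))
    write_truth_json(cohort$truth, file.path(outdir, "truth.json"))
    if (!is.null(cohort$tracks))
      write_bed(cohort$tracks[, c("chrom", "start", "end", "mark",
                                  "sample")],
                file.path(outdir, "tracks.bed"))
  }
  filtered <- filter_windows_global(cohort$depth)
  filtered <- filter_points_per_sample(filtered)
  smoothed <- normalize_and_smooth(filtered)
  smoothed <- pc_correct(smoothed, k = 0)
  manifest$profile <- list(
    n_masked_windows = length(filtered$mask_windows),
    n_masked_points = sum(is.na(filtered$values)) -
      nrow(filtered$values) * length(filtered$mask_windows))
  if ("profile" %in% stages)
    write_timing_tsv(smoothed, file.path(outdir, "timing_smoothed.tsv"))
  peaks <- call_peak_clusters(smoothed)
  valleys <- call_peak_clusters(smoothed, what = "minima")
  variants <- call_rt_variants(filtered, smoothed)
  manifest$features <- list(n_peaks = nrow(peaks),
                            n_valleys = nrow(valleys),
                            n_variant_regions = nrow(variants))
  if ("features" %in% stages) {
    write_bed(dplyr::select(peaks, "chrom", "start", "end", "support"),
              file.path(outdir, "peaks.bed"))
    write_bed(dplyr::select(variants, "chrom", "start", "end"),
              file.path(outdir, "variant_regions.bed"))
  }
  result <- list(cohort = cohort, smoothed = smoothed, filtered = filtered,
                 peaks = peaks, valleys = valleys,
                 variant_regions = variants)
  if (any(c("rtqtl", "multi") %in% stages)) {
    mapped <- map_rtqtls(smoothed, filtered, cohort$genotypes,
                         fdr = fdr, n_perm = n_perm, perm_cap = perm_cap,
                         seed = config$seed)
    manifest$rtqtl <- list(n_signals = nrow(mapped$signals),
                           n_significant_windows =
                             sum(mapped$windows$significant))
    result$mapped <- mapped
    if (nrow(mapped$signals) > 0 && "rtqtl" %in% stages) {
      write_bed(mapped$signals |>
                  dplyr::transmute(chrom = .data$region_chrom,
                                   start = .data$region_start,
                                   end = .data$region_end,
                                   tag = .data$tag_variant,
                                   top_p = .data$top_p),
                file.path(outdir, "rtqtl_regions.bed"))
      jsonlite::write_json(
        mapped$signals |> dplyr::select(-"members"),
        file.path(outdir, "rtqtl_signals.json"), digits = 8,
        auto_unbox = TRUE)
    }
    if ("multi" %in% stages && nrow(mapped$signals) > 1) {
      multi <- find_multi_regions(mapped$signals, mapped$context,
                                  cohort$genotypes)
      manifest$multi <- list(n_multi_regions = nrow(multi))
      result$multi <- multi
    }
  }
  manifest$versions <- list(package = "rtqtl",
                            version = as.character(utils::packageVersion("rtqtl")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       digits = 8, auto_unbox = TRUE)
  result$manifest <- manifest
  invisible(result)
}
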