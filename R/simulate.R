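#' Synthetic cohort configuration
#'
#' Describes a cohort of proliferating cell lines whose windowed DNA copy
#' number carries an S-phase replication-timing signal, genotypes in LD
#' blocks, planted additive rtQTL effects on local timing, optional CNVs,
#' and histone-mark tracks whose presence can co-vary with rtQTL genotype.
#'
#' The defaults describe the data regime the pipeline targets: 10 kb
#' windows, ~45% of cells in S phase (mid-range of the 35-55% band typical
#' of cultured pluripotent lines), mean depth 500 reads per window, rtQTL
#' effects of 0.6 timing Z-units per early allele tapering over a 400 kb
#' half-width, and a baseline timing curve with initiation peaks every 1 Mb.
#'
#' @param n_samples Number of cell lines.
#' @param n_chromosomes,chrom_length,window_size Genome layout (bp).
#' @param s_phase_fraction Proportion of cells in S phase, in (0,1).
#' @param depth_per_window Mean read count per window at copy number 2.
#' @param noise_sd Extra Gaussian noise on observed copy number (copies).
#' @param n_rtqtls Number of planted rtQTLs (each on its own timing peak).
#' @param effect_size Timing shift per early allele (Z units).
#' @param effect_halfwidth Distance (bp) over which the rtQTL effect tapers
#'   linearly to zero around the affected peak.
#' @param rtqtl_maf Target minor allele frequency for planted causal
#'   variants.
#' @param maf_range Length-2 vector, population MAF range in (0, 0.5].
#' @param ld_block_size LD block length (bp); dosages are independent across
#'   blocks.
#' @param ld_mutation_rate Per-variant haplotype "mutation" probability in
#'   the within-block copying chain; 0 gives perfect LD inside a block.
#' @param variant_spacing Distance between consecutive variants (bp).
#' @param peak_period Distance between baseline timing peaks (bp).
#' @param logistic_scale Scale of the logistic map from timing Z-score to
#'   replicated fraction; larger values make the map more linear over the
#'   observed Z range.
#' @param cnv_spec List of CNV classes, each a list with `length` (bp),
#'   `delta` (copies) and `carrier_frac`.
#' @param epigenome_spec Tibble as built by [epigenome_spec()], or `NULL`.
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 100,
                          n_chromosomes = 2,
                          chrom_length = 10e6,
                          window_size = 10000,
                          s_phase_fraction = 0.45,
                          depth_per_window = 3000,
                          noise_sd = 0.02,
                          n_rtqtls = 10,
                          effect_size = 0.6,
                          effect_halfwidth = 400e3,
                          rtqtl_maf = 0.3,
                          maf_range = c(0.05, 0.5),
                          ld_block_size = 100e3,
                          ld_mutation_rate = 0.05,
                          variant_spacing = 4000,
                          peak_period = 1e6,
                          logistic_scale = 3,
                          cnv_spec = list(),
                          epigenome_spec = NULL,
                          seed = 1L) {
  stopifnot(n_samples >= 1, n_chromosomes >= 1, chrom_length > 0,
            window_size > 0)
  if (chrom_length %% window_size != 0)
    stop("`window_size` must divide `chrom_length`")
  if (!(s_phase_fraction > 0 && s_phase_fraction < 1))
    stop("`s_phase_fraction` must be in (0, 1)")
  if (length(maf_range) != 2 || maf_range[1] >= maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("`maf_range` must be increasing and within (0, 0.5]")
  if (ld_block_size < window_size)
    stop("`ld_block_size` must be at least `window_size`")
  if (n_rtqtls > 0 && effect_halfwidth > chrom_length)
    stop("rtQTL effect interval exceeds chromosome length")
  structure(
    list(n_samples = as.integer(n_samples),
         n_chromosomes = as.integer(n_chromosomes),
         chrom_length = chrom_length, window_size = window_size,
         s_phase_fraction = s_phase_fraction,
         depth_per_window = depth_per_window, noise_sd = noise_sd,
         n_rtqtls = as.integer(n_rtqtls), effect_size = effect_size,
         effect_halfwidth = effect_halfwidth, rtqtl_maf = rtqtl_maf,
         maf_range = maf_range, ld_block_size = ld_block_size,
         ld_mutation_rate = ld_mutation_rate,
         variant_spacing = variant_spacing, peak_period = peak_period,
         logistic_scale = logistic_scale,
         cnv_spec = cnv_spec, epigenome_spec = epigenome_spec,
         seed = as.integer(seed)),
    class = "cohort_config")
}

#' Epigenome simulation settings
#'
#' One row per histone mark: Poisson background interval rate, probability
#' of placement at each true timing peak, and genotype-coupling odds at
#' planted rtQTL peaks. Odds of 1 mean mark presence is independent of
#' genotype (the null used for calibration checks); odds `o` shift the
#' presence log-odds by `log(o)` per early allele relative to heterozygotes.
#'
#' @param marks Character vector of mark names.
#' @param background_rate Background intervals per Mb per sample.
#' @param at_peak_prob Probability a mark is placed at a true peak.
#' @param coupling_odds Genotype-coupling odds at planted rtQTL peaks.
#' @param width Interval width (bp).
#' @return Tibble with one row per mark.
#' @export
epigenome_spec <- function(marks, background_rate = 2, at_peak_prob = 0.5,
                           coupling_odds = 1, width = 5000) {
  tibble::tibble(
    mark = marks,
    background_rate = rep_len(background_rate, length(marks)),
    at_peak_prob = rep_len(at_peak_prob, length(marks)),
    coupling_odds = rep_len(coupling_odds, length(marks)),
    width = rep_len(width, length(marks)))
}

baseline_timing <- function(config, grid) {
  # smooth multi-peak curve shared by all samples; peaks every peak_period,
  # phase offset per chromosome so peak positions differ between chromosomes
  centers <- window_centers(grid)
  chrom_idx <- as.integer(factor(grid$chrom, levels = unique(grid$chrom)))
  phase <- (chrom_idx - 1) * pi / 4
  # sqrt(2) amplitude gives the baseline unit genome-wide variance, so
  # planted effects are in true timing Z units
  sqrt(2) * sin(2 * pi * centers / config$peak_period + phase)
}

true_peak_positions <- function(config, grid) {
  # analytic maxima of the baseline sinusoid, per chromosome
  P <- config$peak_period
  out <- lapply(seq_len(config$n_chromosomes), function(ci) {
    phase <- (ci - 1) * pi / 4
    k <- seq(-1, ceiling(config$chrom_length / P) + 1)
    pos <- P * (1 / 4 + k) - P * phase / (2 * pi)
    pos <- pos[pos > 0 & pos < config$chrom_length]
    tibble::tibble(chrom = paste0("chr", ci), pos = pos)
  })
  dplyr::bind_rows(out) |> dplyr::arrange(.data$chrom, .data$pos)
}

#' Simulate a genotype table with LD-block structure
#'
#' Variants are placed on a regular grid along each chromosome. Within an
#' LD block each haplotype is a copying chain: the allele at a variant
#' repeats the allele at the previous variant with probability
#' `1 - ld_mutation_rate`, otherwise it is redrawn at the block allele
#' frequency. Blocks are independent, so r-squared decays with index
#' separation inside blocks and is ~0 across block boundaries.
#'
#' @param config A [cohort_config()].
#' @return A [genotype_table()].
#' @export
simulate_genotypes <- function(config) {
  set.seed(config$seed + 1L)
  n <- config$n_samples
  pos1 <- seq(config$variant_spacing / 2, config$chrom_length,
              by = config$variant_spacing)
  info <- tidyr::expand_grid(
    chrom = paste0("chr", seq_len(config$n_chromosomes)),
    pos = pos1) |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::mutate(variant_id = sprintf("v%05d", dplyr::row_number()),
                  ref = "A", alt = "G",
                  block = paste0(.data$chrom, "_b",
                                 floor(.data$pos / config$ld_block_size)))
  mu <- config$ld_mutation_rate
  dos <- matrix(0L, n, nrow(info))
  for (blk in split(seq_len(nrow(info)), info$block)) {
    f <- stats::runif(1, config$maf_range[1], config$maf_range[2])
    h1 <- h2 <- matrix(0L, n, length(blk))
    h1[, 1] <- stats::rbinom(n, 1, f)
    h2[, 1] <- stats::rbinom(n, 1, f)
    for (j in seq_along(blk)[-1]) {
      redraw1 <- stats::runif(n) < mu
      redraw2 <- stats::runif(n) < mu
      h1[, j] <- ifelse(redraw1, stats::rbinom(n, 1, f), h1[, j - 1])
      h2[, j] <- ifelse(redraw2, stats::rbinom(n, 1, f), h2[, j - 1])
    }
    dos[, blk] <- h1 + h2
  }
  genotype_table(dos, dplyr::select(info, "variant_id", "chrom", "pos",
                                    "ref", "alt"))
}

pick_causal_variants <- function(config, genotypes, peaks) {
  # one causal variant per selected peak: nearest variant with all three
  # genotype classes and empirical MAF close to the target
  eligible <- apply(genotypes$dosage, 2, function(d) length(unique(d)) == 3)
  info <- genotypes$info |>
    dplyr::mutate(eligible = eligible,
                  maf_ok = abs(.data$maf - config$rtqtl_maf) < 0.12)
  # spread rtQTLs over peaks deterministically: every other peak first
  ord <- order(seq_len(nrow(peaks)) %% 2, seq_len(nrow(peaks)))
  chosen <- list()
  used <- character(0)
  for (i in ord) {
    if (length(chosen) >= config$n_rtqtls) break
    pk <- peaks[i, ]
    cand <- info |>
      dplyr::filter(.data$chrom == pk$chrom, .data$eligible, .data$maf_ok,
                    !(.data$variant_id %in% used),
                    abs(.data$pos - pk$pos) < 200e3)
    if (nrow(cand) == 0) next
    best <- cand[which.min(abs(cand$pos - pk$pos)), ]
    used <- c(used, best$variant_id)
    chosen[[length(chosen) + 1]] <- tibble::tibble(
      variant_id = best$variant_id, chrom = pk$chrom, peak_pos = pk$pos,
      start = max(0, pk$pos - config$effect_halfwidth),
      end = min(config$chrom_length, pk$pos + config$effect_halfwidth),
      effect = config$effect_size, maf = best$maf)
  }
  dplyr::bind_rows(chosen)
}

#' Simulate a full synthetic cohort
#'
#' Generates per-sample true replication timing (a shared multi-peak
#' baseline plus planted additive rtQTL shifts with a linear distance
#' taper), maps timing to expected copy number through
#' `2*(1 - s) + s*(1 + f(timing))` where `s` is the S-phase fraction and
#' `f` is a logistic map of the timing Z-score onto replicated fraction
#' [0, 1], draws Poisson read counts around the expected depth, overlays
#' CNVs, and converts back to observed copy number with additive Gaussian
#' noise. Also simulates genotypes and (optionally) per-sample histone
#' tracks, and returns the planted-truth table used as the oracle by every
#' downstream test.
#'
#' @param config A [cohort_config()].
#' @param planted Optional tibble overriding the planted-rtQTL table
#'   (columns as in the truth: `variant_id`, `chrom`, `peak_pos`, `start`,
#'   `end`, `effect`); used e.g. to simulate validation cohorts carrying
#'   the same causal structure as a discovery cohort under a new seed.
#' @return List with elements `depth` (an [rt_matrix()] of observed copy
#'   number, state `"raw"`), `genotypes` (a [genotype_table()]), `tracks`
#'   (tibble of per-sample mark intervals, or `NULL`), and `truth` (list:
#'   `true_timing` matrix, `planted_rtqtls`, `true_peaks`, `true_cnvs`,
#'   `mark_couplings`).
#' @export
simulate_cohort <- function(config, planted = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  grid <- rt_grid(config$n_chromosomes, config$chrom_length,
                  config$window_size)
  genotypes <- simulate_genotypes(config)
  peaks <- true_peak_positions(config, grid)

  set.seed(config$seed + 2L)
  n <- config$n_samples
  W <- nrow(grid)
  base <- baseline_timing(config, grid)
  timing <- matrix(rep(base, each = n), n, W)
  rownames(timing) <- rownames(genotypes$dosage)

  planted <- if (!is.null(planted) || config$n_rtqtls > 0) {
    pq <- planted %||% pick_causal_variants(config, genotypes, peaks)
    if (!all(pq$variant_id %in% genotypes$info$variant_id))
      stop("planted causal variant absent from the genotype table")
    if (any(pq$end > config$chrom_length | pq$start < 0))
      stop("planted effect interval exceeds the chromosome")
    if (is.null(planted) && nrow(pq) < config$n_rtqtls)
      warning(sprintf("only %d of %d rtQTLs could be planted", nrow(pq),
                      config$n_rtqtls))
    centers <- window_centers(grid)
    for (i in seq_len(nrow(pq))) {
      on_chr <- grid$chrom == pq$chrom[i]
      kern <- pmax(0, 1 - abs(centers - pq$peak_pos[i]) /
                     config$effect_halfwidth) * on_chr
      dose <- genotypes$dosage[, pq$variant_id[i]]
      timing <- timing + pq$effect[i] * outer(dose, kern)
    }
    pq
  } else {
    tibble::tibble(variant_id = character(0), chrom = character(0),
                   peak_pos = numeric(0), start = numeric(0),
                   end = numeric(0), effect = numeric(0), maf = numeric(0))
  }

  s <- config$s_phase_fraction
  # replicated fraction in [0, 1]: logistic in timing, with a scale chosen
  # so the map is close to linear over the observed Z range (mid-S-phase
  # response) while staying monotone and bounded
  frac <- stats::plogis(timing / config$logistic_scale)
  cn <- 2 * (1 - s) + s * (1 + frac)

  cnvs <- simulate_cnvs(config, grid)
  if (nrow(cnvs) > 0) {
    centers <- window_centers(grid)
    for (i in seq_len(nrow(cnvs))) {
      w <- which(grid$chrom == cnvs$chrom[i] & centers >= cnvs$start[i] &
                   centers < cnvs$end[i])
      si <- match(cnvs$sample[i], rownames(timing))
      cn[si, w] <- cn[si, w] + cnvs$delta[i]
    }
  }

  counts <- matrix(stats::rpois(n * W, config$depth_per_window *
                                  pmax(cn, 0) / 2), n, W)
  cn_obs <- 2 * counts / config$depth_per_window
  if (config$noise_sd > 0)
    cn_obs <- cn_obs + matrix(stats::rnorm(n * W, 0, config$noise_sd), n, W)
  rownames(cn_obs) <- rownames(timing)

  tracks <- NULL
  couplings <- NULL
  truth <- list(true_timing = timing, planted_rtqtls = planted,
                true_peaks = peaks, true_cnvs = cnvs,
                mark_couplings = couplings,
                counts = counts, expected_cn = cn)
  if (!is.null(config$epigenome_spec)) {
    tracks <- simulate_epigenome(truth, genotypes, config$epigenome_spec,
                                 config)
    truth$mark_couplings <- attr(tracks, "couplings")
  }
  list(depth = rt_matrix(cn_obs, grid, state = "raw"),
       genotypes = genotypes, tracks = tracks, truth = truth)
}

simulate_cnvs <- function(config, grid) {
  out <- list()
  samples <- paste0("s", seq_len(config$n_samples))
  for (spec in config$cnv_spec) {
    if (spec$length > config$chrom_length)
      stop("CNV length exceeds chromosome length")
    carriers <- samples[stats::runif(config$n_samples) < spec$carrier_frac]
    for (smp in carriers) {
      chrom <- paste0("chr", sample.int(config$n_chromosomes, 1))
      start <- stats::runif(1, 0, config$chrom_length - spec$length)
      out[[length(out) + 1]] <- tibble::tibble(
        sample = smp, chrom = chrom, start = start,
        end = start + spec$length, delta = spec$delta)
    }
  }
  if (length(out) == 0)
    return(tibble::tibble(sample = character(0), chrom = character(0),
                          start = numeric(0), end = numeric(0),
                          delta = numeric(0)))
  dplyr::bind_rows(out)
}

#' Simulate per-sample histone-mark interval tracks
#'
#' Background intervals are placed uniformly at the specified Poisson rate
#' per Mb. At each true timing peak a mark is co-placed with the configured
#' probability (shared across samples, emulating cell-type-level chromatin).
#' At peaks affected by a planted rtQTL, per-sample presence is drawn with a
#' genotype-conditional probability: presence log-odds shift by
#' `log(coupling_odds)` per early allele relative to heterozygotes, so odds
#' of 1 decouple marks from genotype.
#'
#' @param truth Truth list from [simulate_cohort()].
#' @param genotypes A [genotype_table()].
#' @param spec Tibble from [epigenome_spec()].
#' @param config The [cohort_config()].
#' @return Tibble with columns `mark`, `sample`, `chrom`, `start`, `end`;
#'   attribute `"couplings"` records the genotype-conditional placement
#'   probabilities per mark.
#' @export
simulate_epigenome <- function(truth, genotypes, spec, config) {
  set.seed(config$seed + 3L)
  samples <- rownames(genotypes$dosage)
  genome_mb <- config$n_chromosomes * config$chrom_length / 1e6
  peaks <- truth$true_peaks
  planted <- truth$planted_rtqtls
  rows <- list()
  coup <- list()
  for (m in seq_len(nrow(spec))) {
    mk <- spec[m, ]
    # cohort-level placement decision per peak
    at_peak <- stats::runif(nrow(peaks)) < mk$at_peak_prob
    for (smp in samples) {
      nbg <- stats::rpois(1, mk$background_rate * genome_mb)
      if (nbg > 0) {
        chrom <- paste0("chr", sample.int(config$n_chromosomes, nbg,
                                          replace = TRUE))
        st <- stats::runif(nbg, 0, config$chrom_length - mk$width)
        rows[[length(rows) + 1]] <- tibble::tibble(
          mark = mk$mark, sample = smp, chrom = chrom, start = st,
          end = st + mk$width)
      }
    }
    for (p in seq_len(nrow(peaks))) {
      pk <- peaks[p, ]
      qtl <- planted[planted$chrom == pk$chrom &
                       abs(planted$peak_pos - pk$pos) < 1, ]
      if (nrow(qtl) == 1 && mk$coupling_odds != 1) {
        dose <- genotypes$dosage[, qtl$variant_id]
        pr <- stats::plogis(stats::qlogis(mk$at_peak_prob) +
                              (dose - 1) * log(mk$coupling_odds))
        present <- stats::runif(length(pr)) < pr
        coup[[length(coup) + 1]] <- tibble::tibble(
          mark = mk$mark, variant_id = qtl$variant_id,
          p_late = stats::plogis(stats::qlogis(mk$at_peak_prob) -
                                   log(mk$coupling_odds)),
          p_het = mk$at_peak_prob,
          p_early = stats::plogis(stats::qlogis(mk$at_peak_prob) +
                                    log(mk$coupling_odds)))
        if (any(present)) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            mark = mk$mark, sample = samples[present], chrom = pk$chrom,
            start = pk$pos - mk$width / 2, end = pk$pos + mk$width / 2)
        }
      } else if (at_peak[p]) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          mark = mk$mark, sample = samples, chrom = pk$chrom,
          start = pk$pos - mk$width / 2, end = pk$pos + mk$width / 2)
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(mark = character(0), sample = character(0),
                   chrom = character(0), start = numeric(0),
                   end = numeric(0))
  attr(out, "couplings") <- if (length(coup)) dplyr::bind_rows(coup) else NULL
  out
}
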