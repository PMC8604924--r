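# a small mapped-like world for enrichment tests, built directly so control
# matching has plenty of candidates
chromatin_world <- function(seed = 50, n = 60, n_var = 800,
                            n_signals = 20) {
  set.seed(seed)
  spacing <- 20000
  doses <- matrix(rbinom(n * n_var, 2, 0.3), n, n_var)
  g <- toy_genotypes(doses, spacing = spacing)
  L <- spacing * (n_var + 1)
  # flat peak/valley geography and timing so matching is permissive
  peaks <- tibble::tibble(chrom = "chr1",
                          center = seq(1e6, L - 1e6, by = 2e6))
  valleys <- tibble::tibble(chrom = "chr1",
                            center = seq(2e6, L - 1e6, by = 2e6))
  n_win <- floor(L / 1e5)
  vals <- matrix(rnorm(n * n_win, sd = 0.05), n, n_win)
  m <- rt_matrix(vals, rt_grid(1, n_win * 1e5, 1e5), state = "smoothed")
  tag_idx <- round(seq(20, n_var - 20, length.out = n_signals))
  signals <- dplyr::bind_rows(lapply(seq_len(n_signals), function(i) {
    ids <- g$info$variant_id[(tag_idx[i] - 2):(tag_idx[i] + 2)]
    tibble::tibble(signal = i, tag_variant = g$info$variant_id[tag_idx[i]],
                   top_p = 1e-6, beta_tag = 0.5, window = 1,
                   threshold_pt = 1e-3, n_members = length(ids),
                   members = list(tibble::tibble(variant_id = ids,
                                                 p = 1e-5, beta = 0.5)),
                   provenance = "ld_greedy")
  }))
  list(genotypes = g, peaks = peaks, valleys = valleys, matrix = m,
       signals = signals, tag_idx = tag_idx, spacing = spacing)
}

cw <- NULL
get_cw <- function() {
  if (is.null(.fixtures$cw)) {
    .fixtures$cw <- chromatin_world()
    .fixtures$cw$controls <- build_matched_controls(
      .fixtures$cw$signals, .fixtures$cw$genotypes, .fixtures$cw$peaks,
      .fixtures$cw$valleys, .fixtures$cw$matrix, min_matches = 20)
  }
  .fixtures$cw
}

test_that("matched controls honour every matching invariant", {
  w <- get_cw()
  ctl <- w$controls
  ann <- ctl$annotation
  for (i in seq_len(nrow(ctl$per_signal))) {
    cs <- ctl$per_signal[i, ]
    ti <- match(cs$tag_variant, ann$variant_id)
    mi <- match(cs$matched[[1]], ann$variant_id)
    if (length(mi) == 0) next
    expect_true(all(abs(ann$pos[mi] - ann$pos[ti]) >= 2e6))
    expect_true(all(abs(ann$maf[mi] - ann$maf[ti]) < 0.05))
    expect_true(all(abs(ann$dist_peak[mi] - ann$dist_peak[ti]) < 50e3))
    expect_true(all(abs(ann$dist_valley[mi] - ann$dist_valley[ti]) < 50e3))
    expect_true(all(abs(ann$timing[mi] - ann$timing[ti]) < 0.5))
    expect_true(all(ann$ld_partners[mi] >= ann$ld_partners[ti]))
    # the tag itself can never be its own control
    expect_false(cs$tag_variant %in% cs$matched[[1]])
  }
})

test_that("signals with too few matches are excluded from denominators", {
  w <- get_cw()
  strict <- build_matched_controls(w$signals, w$genotypes, w$peaks,
                                   w$valleys, w$matrix,
                                   min_matches = 10^6)
  expect_true(all(strict$per_signal$excluded))
})

test_that("a genome-wide feature shows no enrichment", {
  w <- get_cw()
  L <- w$spacing * 900
  feature <- tibble::tibble(chrom = "chr1", start = 0, end = L)
  out <- feature_enrichment(w$signals, feature, w$controls, w$genotypes,
                            n_perm = 20, seed = 3)
  expect_equal(out$fold, 1, tolerance = 1e-3)
  expect_gt(out$p, 0.9)
})

test_that("a feature planted exactly at rtQTL SNPs is extremely enriched", {
  w <- get_cw()
  snp_pos <- w$genotypes$info$pos[w$tag_idx]
  feature <- tibble::tibble(chrom = "chr1", start = snp_pos - 100,
                            end = snp_pos + 100)
  out <- feature_enrichment(w$signals, feature, w$controls, w$genotypes,
                            n_perm = 50, seed = 4)
  expect_equal(out$n_overlapping, out$n_rtqtls)
  expect_lt(out$p, 1e-10)
  expect_gt(out$fold, 5)
  # the reported p is the closed-form binomial tail for the reported counts
  param <- min(max(out$expected_fraction, 1e-6), 1 - 1e-6)
  expect_equal(out$p, pbinom(out$n_overlapping - 1, out$n_rtqtls, param,
                             lower.tail = FALSE))
})

test_that("combination search recovers a planted three-mark module and stops", {
  set.seed(51)
  n_rt <- 200; n_ctl <- 2000
  rt_snps <- tibble::tibble(chrom = "chr1",
                            pos = seq(1e5, 2e7, length.out = n_rt))
  ctl_snps <- tibble::tibble(chrom = "chr1",
                             pos = seq(1e5, 2e7, length.out = n_ctl) + 17)
  marks <- paste0("m", 1:8)
  rows <- list()
  carry_rt <- runif(n_rt) < 0.40        # 40% of rtQTL SNPs carry the module
  carry_ctl <- runif(n_ctl) < 0.02      # 2% of controls
  for (mk in marks[1:3]) {
    # module placement plus independent background occurrences, so each
    # restricted level retains a carrier/non-carrier contrast
    bg_rt <- runif(n_rt) < 0.15; bg_ctl <- runif(n_ctl) < 0.15
    at <- c(rt_snps$pos[carry_rt | bg_rt], ctl_snps$pos[carry_ctl | bg_ctl])
    rows[[length(rows) + 1]] <- tibble::tibble(
      mark = mk, chrom = "chr1", start = at - 50, end = at + 50)
  }
  for (mk in marks[4:8]) {              # independent background marks
    at_rt <- runif(n_rt) < 0.10; at_ctl <- runif(n_ctl) < 0.10
    rows[[length(rows) + 1]] <- tibble::tibble(
      mark = mk, chrom = "chr1",
      start = c(rt_snps$pos[at_rt], ctl_snps$pos[at_ctl]) - 50,
      end = c(rt_snps$pos[at_rt], ctl_snps$pos[at_ctl]) + 50)
  }
  features <- dplyr::bind_rows(rows)
  out <- combination_search(features, rt_snps, ctl_snps, fdr = 0.05)
  expect_true(all(1:3 %in% unique(out$level)) || max(out$level) == 3)
  lvl3 <- out[out$level == 3, ]
  expect_true(any(vapply(lvl3$combination, function(cc)
    setequal(cc, c("m1", "m2", "m3")), logical(1))))
  # no spurious four-mark level
  expect_lte(max(out$level), 3)
  # level-1 calls agree with independent Fisher tests on the raw overlaps
  lvl1 <- out[out$level == 1, ]
  for (i in seq_len(nrow(lvl1))) {
    mk <- lvl1$combination[[i]][1]
    iv <- features[features$mark == mk, ]
    a <- sum(points_in_intervals(rt_snps$chrom, rt_snps$pos, iv))
    c_ <- sum(points_in_intervals(ctl_snps$chrom, ctl_snps$pos, iv))
    ft <- fisher.test(matrix(c(a, n_rt - a, c_, n_ctl - c_), 2,
                             byrow = TRUE))
    expect_equal(lvl1$p[i], ft$p.value, tolerance = 1e-12)
  }
})

test_that("combination search terminates with nothing when features are null", {
  set.seed(52)
  rt_snps <- tibble::tibble(chrom = "chr1", pos = seq(1e5, 1e7, 5e4))
  ctl_snps <- tibble::tibble(chrom = "chr1", pos = seq(1.2e5, 1e7, 2e4))
  pos_all <- c(rt_snps$pos, ctl_snps$pos)
  at <- sample(pos_all, 40)
  features <- tibble::tibble(mark = "m1", chrom = "chr1",
                             start = at - 50, end = at + 50)
  out <- combination_search(features, rt_snps, ctl_snps, fdr = 0.05)
  expect_equal(nrow(out), 0)
})

test_that("hyperacetylated trimethylation regions obey count and merge rules", {
  sites <- tibble::tibble(chrom = "chr1",
                          start = c(1e6, 1.5e6, 1.508e6, 3e6),
                          end = c(1e6, 1.5e6, 1.508e6, 3e6) + 2000)
  # 12 acetylation marks cover sites 2 and 3; only 10 cover site 1; none
  # cover site 4
  ac <- dplyr::bind_rows(
    lapply(1:12, function(k) tibble::tibble(
      mark = paste0("ac", k), chrom = "chr1",
      start = 1.49e6, end = 1.52e6)),
    lapply(1:10, function(k) tibble::tibble(
      mark = paste0("ac", k), chrom = "chr1",
      start = 0.99e6, end = 1.01e6)))
  out <- build_me3achyper(sites, ac, min_ac = 11, merge_gap = 10e3)
  expect_equal(nrow(out), 1)      # sites 2 and 3 qualify and merge (8 kb)
  expect_equal(out$start, 1.5e6)
  expect_equal(out$end, 1.51e6)
  expect_gte(out$n_acetyl, 11)
  # empty input
  empty <- build_me3achyper(sites[0, ], ac)
  expect_equal(nrow(empty), 0)
})

test_that("allelic covariation finds a planted genotype-mark coupling", {
  set.seed(53)
  n <- 8; n_sites <- 80
  doses <- matrix(sample(0:2, n * n_sites, replace = TRUE), n, n_sites)
  g <- toy_genotypes(doses, spacing = 50000)
  sites <- tibble::tibble(variant_id = g$info$variant_id,
                          chrom = "chr1", pos = g$info$pos, beta = 1)
  marks <- c("coupled", paste0("null", 1:9))
  rows <- list()
  for (s in seq_len(n_sites)) for (i in seq_len(n)) {
    smp <- rownames(g$dosage)[i]
    pr_c <- c(0.2, 0.5, 0.8)[doses[i, s] + 1]
    if (runif(1) < pr_c)
      rows[[length(rows) + 1]] <- tibble::tibble(
        mark = "coupled", sample = smp, chrom = "chr1",
        start = sites$pos[s] - 500, end = sites$pos[s] + 500)
    for (mk in marks[-1]) if (runif(1) < 0.5)
      rows[[length(rows) + 1]] <- tibble::tibble(
        mark = mk, sample = smp, chrom = "chr1",
        start = sites$pos[s] - 500, end = sites$pos[s] + 500)
  }
  tracks <- dplyr::bind_rows(rows)
  out <- allelic_covariation(sites, g, tracks, radius = 1000,
                             n_perm = 10, seed = 9)
  cp <- out[out$mark == "coupled", ]
  expect_lt(cp$p_bonferroni, 0.05)
  expect_gt(cp$log_ratio, 0)
  # internal consistency: parameter = p_late * clipped permutation ratio,
  # and the p-value is the exact binomial oracle at the reported counts
  expect_equal(cp$parameter,
               min(max(cp$p_late * cp$perm_ratio, 1e-9), 1 - 1e-9))
  expect_equal(cp$p, binom.test(cp$k_early, cp$n_early,
                                cp$parameter)$p.value)
  # null marks stay null after Bonferroni
  expect_lt(sum(out$p_bonferroni[out$mark != "coupled"] < 0.05), 2)
})

test_that("a mark present everywhere cannot covary with genotype", {
  set.seed(54)
  n <- 6; n_sites <- 20
  doses <- matrix(sample(0:2, n * n_sites, replace = TRUE), n, n_sites)
  g <- toy_genotypes(doses, spacing = 50000)
  sites <- tibble::tibble(variant_id = g$info$variant_id,
                          chrom = "chr1", pos = g$info$pos, beta = 1)
  tracks <- tidyr::expand_grid(mark = "ubiq", sample = rownames(g$dosage),
                               s = seq_len(n_sites)) |>
    dplyr::mutate(chrom = "chr1", start = sites$pos[s] - 500,
                  end = sites$pos[s] + 500) |>
    dplyr::select(-"s")
  out <- allelic_covariation(sites, g, tracks, radius = 1000, n_perm = 5,
                             seed = 10)
  expect_equal(out$p_early, 1)
  expect_equal(out$p_late, 1)
  expect_equal(out$p, 1)
})

test_that("TF motif association weights, excludes, and matches the chi-squared formula", {
  set.seed(55)
  # two rtQTLs with early-higher deltas 2 and 1 -> totals (3, 0)
  sig2 <- dplyr::bind_rows(
    tibble::tibble(signal = 1, tag_variant = "v1", top_p = 1e-6,
                   beta_tag = 1, n_members = 1,
                   members = list(tibble::tibble(variant_id = "v1",
                                                 p = 1e-6, beta = 1))),
    tibble::tibble(signal = 2, tag_variant = "v2", top_p = 1e-6,
                   beta_tag = 1, n_members = 1,
                   members = list(tibble::tibble(variant_id = "v2",
                                                 p = 1e-6, beta = 1))))
  ctl_ids <- paste0("c", 1:200)
  motif <- dplyr::bind_rows(
    tibble::tibble(variant_id = c("v1", "v2"), tf = "TFX",
                   score_ref = c(0, 1), score_alt = c(2, 2)),
    tibble::tibble(variant_id = ctl_ids, tf = "TFX",
                   score_ref = runif(200), score_alt = runif(200)))
  out <- tf_motif_association(sig2, motif, ctl_ids, n_perm = 50,
                              min_rtqtls = 2, seed = 11)
  expect_equal(out$weighted_early, 3)
  expect_equal(out$weighted_late, 0)
  tab <- matrix(c(out$weighted_early, out$weighted_late,
                  out$baseline_early, out$baseline_late), 2, byrow = TRUE)
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(out$chisq, sum((tab - expd)^2 / expd), tolerance = 1e-12)
  # < 15 overlapping rtQTLs -> excluded by default
  out15 <- tf_motif_association(sig2, motif, ctl_ids, n_perm = 10)
  expect_equal(nrow(out15), 0)
  # zero score differences contribute nothing and give p = 1
  motif0 <- motif
  motif0$score_alt[1:2] <- motif0$score_ref[1:2]
  out0 <- tf_motif_association(sig2, motif0, ctl_ids, n_perm = 10,
                               min_rtqtls = 2)
  expect_equal(out0$p, 1)
  expect_equal(out0$weighted_early + out0$weighted_late, 0)
})

test_that("shrinking a feature to its rtQTL-intersecting subset never lowers fold", {
  w <- get_cw()
  snp_pos <- w$genotypes$info$pos[w$tag_idx]
  wide <- tibble::tibble(chrom = "chr1",
                         start = c(snp_pos - 100, seq(1e5, 5e6, 5e5)),
                         end = c(snp_pos + 100, seq(1e5, 5e6, 5e5) + 2e5))
  mi <- match(unlist(lapply(w$signals$members, `[[`, "variant_id")),
              w$genotypes$info$variant_id)
  hit <- vapply(seq_len(nrow(wide)), function(i)
    any(w$genotypes$info$pos[mi] >= wide$start[i] &
          w$genotypes$info$pos[mi] < wide$end[i]), logical(1))
  narrow <- wide[hit, ]
  e_wide <- feature_enrichment(w$signals, wide, w$controls, w$genotypes,
                               n_perm = 30, seed = 6)
  e_narrow <- feature_enrichment(w$signals, narrow, w$controls,
                                 w$genotypes, n_perm = 30, seed = 6)
  expect_gte(e_narrow$fold, e_wide$fold)
})
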