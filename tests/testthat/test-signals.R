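# dosage copies with per-sample flip probability, to sculpt LD
noisy_copies <- function(d, k, flip = 0.03, maf = 0.4) {
  sapply(seq_len(k), function(i)
    ifelse(runif(length(d)) < flip, rbinom(length(d), 2, maf), d))
}

test_that("greedy LD peeling yields one signal when everything is linked", {
  set.seed(20)
  n <- 150
  d <- rbinom(n, 2, 0.4)
  dos <- cbind(d, noisy_copies(d, 11))
  g <- toy_genotypes(dos)
  assoc <- tibble::tibble(variant_id = g$info$variant_id,
                          p = c(1e-8, runif(11, 1e-6, 1e-4)),
                          beta = 0.5)
  sig <- define_signals(assoc, g)
  expect_equal(nrow(sig), 1)
  expect_equal(sig$tag_variant, "t001")
  expect_equal(sig$n_members, 12)
})

test_that("signals with too few members or weak tags are dropped", {
  set.seed(21)
  n <- 150
  d <- rbinom(n, 2, 0.4)
  g9 <- toy_genotypes(cbind(d, noisy_copies(d, 8)))     # 9 members
  assoc9 <- tibble::tibble(variant_id = g9$info$variant_id,
                           p = runif(9, 1e-8, 1e-6), beta = 1)
  expect_equal(nrow(define_signals(assoc9, g9)), 0)
  g12 <- toy_genotypes(cbind(d, noisy_copies(d, 11)))
  weak <- tibble::tibble(variant_id = g12$info$variant_id,
                         p = runif(12, 2e-3, 1e-2), beta = 1)
  expect_equal(nrow(define_signals(weak, g12)), 0)
})

test_that("two causal variants in separate LD blocks give two signals with correct tags", {
  set.seed(22)
  n <- 200
  d1 <- rbinom(n, 2, 0.4); d2 <- rbinom(n, 2, 0.4)
  dos <- cbind(d1, noisy_copies(d1, 10), d2, noisy_copies(d2, 10))
  g <- toy_genotypes(dos)
  ids <- g$info$variant_id
  assoc <- tibble::tibble(
    variant_id = ids,
    p = c(1e-10, runif(10, 1e-7, 1e-5), 1e-9, runif(10, 1e-7, 1e-5)),
    beta = 0.4)
  sig <- define_signals(assoc, g)
  expect_equal(nrow(sig), 2)
  expect_setequal(sig$tag_variant, c(ids[1], ids[12]))
  # every significant variant lands in exactly one signal
  all_members <- unlist(lapply(sig$members, `[[`, "variant_id"))
  expect_equal(sort(all_members), sort(ids))
  # brute-force greedy oracle reproduces the same partition
  pool <- assoc[order(assoc$p), ]
  r2m <- ld_r2(g, ids)
  oracle <- list()
  left <- pool$variant_id
  while (length(left) > 0) {
    ord <- left[order(assoc$p[match(left, assoc$variant_id)])]
    tag <- ord[1]
    mem <- left[r2m[tag, left] >= 0.2]
    oracle[[tag]] <- sort(mem)
    left <- setdiff(left, mem)
  }
  got <- lapply(sig$members, function(m) sort(m$variant_id))
  names(got) <- sig$tag_variant
  expect_mapequal(got, oracle[names(got)])
})

make_signal_row <- function(tag, members_tbl, window, top_p = NULL) {
  top_p <- top_p %||% min(members_tbl$p)
  tibble::tibble(tag_variant = tag, top_p = top_p,
                 beta_tag = members_tbl$beta[members_tbl$variant_id == tag],
                 window = window, threshold_pt = 1e-3,
                 n_members = nrow(members_tbl),
                 members = list(members_tbl), provenance = "ld_greedy")
}

test_that("the same signal found in nearby correlated windows is consolidated once", {
  set.seed(23)
  n <- 120
  d <- rbinom(n, 2, 0.4)
  dos <- cbind(d, noisy_copies(d, 10))
  g <- toy_genotypes(dos, spacing = 5000)
  y <- 0.5 * d + rnorm(n, sd = 0.3)
  n_win <- 300
  vals <- matrix(rnorm(n * n_win, sd = 0.05), n, n_win)
  vals[, c(10, 60)] <- vals[, c(10, 60)] + y     # 500 kb apart, correlated
  vals[, 280] <- vals[, 280] + y                 # 2.7 Mb away
  m <- toy_matrix(vals); m$state <- "smoothed"
  ctx <- scan_context(m, g)
  members <- tibble::tibble(variant_id = g$info$variant_id,
                            p = c(1e-9, runif(10, 1e-6, 1e-4)), beta = 0.5)
  sigs <- dplyr::bind_rows(
    make_signal_row("t001", members, window = 10),
    make_signal_row("t001", members, window = 60),
    make_signal_row("t001", members, window = 280))
  out <- consolidate_and_split(sigs, ctx, g)
  # windows 10 and 60 merge (distance < 2 Mb, correlated, self-LD);
  # window 280 stays separate on distance alone
  expect_equal(nrow(out), 2)
})

test_that("conditional analysis splits two causal variants in weak LD", {
  set.seed(24)
  n <- 250
  d1 <- rbinom(n, 2, 0.5)
  d2 <- ifelse(runif(n) < 0.62, d1, rbinom(n, 2, 0.5))
  r2 <- cor(d1, d2)^2
  expect_gt(r2, 0.2); expect_lt(r2, 0.6)
  dos <- cbind(d1, noisy_copies(d1, 10, flip = 0.02),
               d2, noisy_copies(d2, 10, flip = 0.02))
  g <- toy_genotypes(dos, spacing = 5000)
  y <- 0.6 * d1 + 0.6 * d2 + rnorm(n, sd = 0.4)
  vals <- matrix(rnorm(n * 50, sd = 0.05), n, 50)
  vals[, 25] <- y
  m <- toy_matrix(vals); m$state <- "smoothed"
  ctx <- scan_context(m, g)
  ws <- window_scan(ctx, 25, n_perm = 50, perm_cap = 50, seed = 1)
  hits <- ws$assoc[ws$assoc$p < 1e-3, ]
  sig <- define_signals(hits, g)
  sig$window <- 25; sig$threshold_pt <- 1e-3
  out <- consolidate_and_split(sig, ctx, g)
  if (nrow(sig) == 1) {
    expect_equal(nrow(out), 2)
    expect_true("conditional_split" %in% out$provenance)
    tags <- out$tag_variant
    blk <- function(id) if (match(id, g$info$variant_id) <= 11) 1 else 2
    expect_setequal(vapply(tags, blk, numeric(1)), c(1, 2))
  } else {
    expect_equal(nrow(out), 2)   # already split by LD peeling
  }
})

test_that("associated regions match a per-window regression oracle", {
  mc <- mapped_cohort()
  sig <- mc$mapped$signals
  ctx <- mc$mapped$context
  skip_if(nrow(sig) == 0)
  for (i in seq_len(min(3, nrow(sig)))) {
    s <- sig[i, ]
    dose <- mc$mapped$context$Du[, match(s$tag_variant, ctx$vinfo$variant_id)]
    on_chr <- intersect(which(ctx$grid$chrom == s$region_chrom),
                        ctx$testable)
    p <- vapply(on_chr, function(w) {
      yv <- mc$smoothed$values[, w]
      summary(lm(yv ~ dose))$coefficients["dose", 4]
    }, numeric(1))
    centers <- ctx$centers[on_chr]
    inside <- centers >= s$region_start & centers <= s$region_end
    # all windows inside the region are significant by the oracle
    expect_true(all(p[inside] <= 0.05 + 1e-9))
    # the windows just outside the boundary are not
    lo <- which(inside)[1]; hi <- rev(which(inside))[1]
    if (lo > 1) expect_gt(p[lo - 1], 0.05)
    if (hi < length(on_chr)) expect_gt(p[hi + 1], 0.05)
  }
})

artifact_fixture <- function(raw_vals, smooth_vals, removed_vals, dose,
                             top_p = 1e-4) {
  n <- length(dose); n_win <- ncol(raw_vals)
  grid <- rt_grid(1, n_win * 10000, 10000)
  raw <- rt_matrix(raw_vals, grid, state = "filtered_raw",
                   removed_values = removed_vals)
  sm <- rt_matrix(smooth_vals, grid, state = "smoothed")
  g <- toy_genotypes(cbind(tag = dose), spacing = 5000)
  ctx <- scan_context(sm, g)
  sig <- tibble::tibble(
    signal = 1, tag_variant = "t001", top_p = top_p, beta_tag = 0.5,
    window = 5, threshold_pt = 1e-3, n_members = 10,
    members = list(tibble::tibble(variant_id = "t001", p = top_p,
                                  beta = 0.5)),
    provenance = "ld_greedy", region_chrom = "chr1",
    region_start = 0, region_end = n_win * 10000,
    strongest_window = 5, region_n_windows = n_win)
  artifact_filter(sig, ctx, raw, g)
}

test_that("raw support below five windows fails the first artifact criterion", {
  set.seed(25)
  n <- 100; n_win <- 8
  dose <- rbinom(n, 2, 0.4)
  raw <- matrix(rnorm(n * n_win, sd = 1), n, n_win)
  raw[, 3:6] <- raw[, 3:6] + dose * 2          # only 4 supported windows
  sm <- matrix(dose * 2 + rnorm(n * n_win, sd = 0.5), n, n_win)
  removed <- matrix(NA_real_, n, n_win)
  v <- artifact_fixture(raw, sm, removed, dose)
  expect_false(v$raw_support)
  expect_false(v$pass)
})

test_that("raw associations much stronger than smoothed flag a CNV artifact", {
  set.seed(26)
  n <- 100; n_win <- 8
  dose <- rbinom(n, 2, 0.4)
  raw <- matrix(dose * 2, n, n_win) + rnorm(n * n_win, sd = 1e-3)
  sm <- matrix(dose * 0.3 + rnorm(n * n_win, sd = 1), n, n_win)
  removed <- matrix(NA_real_, n, n_win)
  v <- artifact_fixture(raw, sm, removed, dose, top_p = 1e-4)
  expect_true(v$raw_support)
  expect_false(v$raw_vs_smoothed)   # > 1 order of magnitude stronger in raw
})

test_that("removed-data associations stronger than raw flag an artifact", {
  set.seed(27)
  n <- 100; n_win <- 8
  dose <- rbinom(n, 2, 0.4)
  raw <- matrix(dose * 0.8, n, n_win) + rnorm(n * n_win, sd = 1)
  sm <- matrix(dose * 0.8, n, n_win) + rnorm(n * n_win, sd = 1)
  removed <- matrix(NA_real_, n, n_win)
  removed[, 1:3] <- matrix(dose * 3, n, 3) + rnorm(n * 3, sd = 1e-3)
  v <- artifact_fixture(raw, sm, removed, dose, top_p = 1e-4)
  expect_false(v$removed_vs_raw)
  expect_false(v$removed_windows)   # 3 windows beat raw, only 2 allowed
})

test_that("weak raw associations fail the final artifact criterion", {
  set.seed(28)
  n <- 100; n_win <- 8
  dose <- rbinom(n, 2, 0.4)
  raw <- matrix(rnorm(n * n_win), n, n_win)   # no raw association at all
  sm <- matrix(dose * 1 + rnorm(n * n_win, sd = 0.8), n, n_win)
  removed <- matrix(NA_real_, n, n_win)
  v <- artifact_fixture(raw, sm, removed, dose)
  expect_false(v$raw_strength)
})

test_that("cohort merging drops only replicated same-direction signals", {
  mk <- function(tag, p, beta, extra_member = NULL) {
    ids <- c(tag, extra_member)
    mem <- tibble::tibble(variant_id = ids,
                          p = p * c(1, 50)[seq_along(ids)], beta = beta)
    tibble::tibble(signal = 1, tag_variant = tag, top_p = p,
                   beta_tag = beta, n_members = nrow(mem),
                   members = list(mem))
  }
  a <- mk("v1", 1e-8, 0.5)
  # identical signal, same direction -> dropped from B
  b_same <- mk("v1", 1e-7, 0.4)
  out <- merge_cohorts(a, b_same)
  expect_equal(nrow(out), 1)
  expect_equal(out$source, "A")
  # shared variant, opposite direction -> both kept
  b_opp <- mk("v1", 1e-7, -0.4)
  expect_equal(nrow(merge_cohorts(a, b_opp)), 2)
  # shared variant three orders above B's top p -> both kept
  b_far <- mk("v9", 1e-9, 0.5, extra_member = "v1")
  b_far$members[[1]]$p[2] <- 1e-9 * 1e3
  expect_equal(nrow(merge_cohorts(a, b_far)), 2)
})

test_that("the validation binomial parameter follows the closed form", {
  expect_equal(round(validation_binomial_parameter(4), 4), 0.0963)
  expect_equal(validation_binomial_parameter(1), 0.025)
  expect_error(validation_binomial_parameter(0), "at least one")
})

test_that("signals validate in an independent cohort with shared causal structure", {
  mc <- mapped_cohort()
  skip_if(nrow(mc$mapped$signals) == 0)
  cfg2 <- mc$config
  cfg2$seed <- 77L
  co2 <- simulate_cohort(cfg2, planted = mc$cohort$truth$planted_rtqtls)
  f2 <- filter_points_per_sample(filter_windows_global(co2$depth))
  sm2 <- normalize_and_smooth(f2)
  g2 <- qc_variants(co2$genotypes)
  ctx2 <- scan_context(sm2, g2)
  res <- validate_signals(mc$mapped$signals,
                          list(list(ctx = ctx2, genotypes = g2)))
  expect_gte(sum(res$per_signal$validated), 0.6 * nrow(mc$mapped$signals))
  expect_lt(res$binomial$p, 0.01)
  expect_equal(res$binomial$parameter, 0.025)
  # exact binomial oracle
  k <- res$binomial$n_validated; nn <- res$binomial$n_testable
  expect_equal(res$binomial$p,
               pbinom(k - 1, nn, 0.025, lower.tail = FALSE))
})
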