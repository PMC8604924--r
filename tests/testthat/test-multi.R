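fake_signal <- function(id, tag, top_p, beta, window) {
  tibble::tibble(signal = id, tag_variant = tag, top_p = top_p,
                 beta_tag = beta, window = window, threshold_pt = 1e-3,
                 n_members = 10,
                 members = list(tibble::tibble(variant_id = tag,
                                               p = top_p, beta = beta)),
                 provenance = "ld_greedy", strongest_window = window)
}

multi_fixture <- function(n = 200, effects = c(1.0, 0.7, 0.5),
                          windows = c(30, 50, 70), noise = 0.6,
                          seed = 30) {
  set.seed(seed)
  doses <- sapply(effects, function(e) rbinom(n, 2, 0.4))
  y <- drop(doses %*% effects) + rnorm(n, sd = noise)
  vals <- matrix(rnorm(n * 300, sd = 0.1), n, 300)
  for (w in windows) vals[, w] <- y + rnorm(n, sd = 0.05)
  m <- toy_matrix(vals); m$state <- "smoothed"
  g <- toy_genotypes(doses, spacing = 5000)
  ctx <- scan_context(m, g)
  ids <- g$info$variant_id
  sigs <- dplyr::bind_rows(lapply(seq_along(effects), function(i)
    fake_signal(i, ids[i], 10^(-20 * effects[i]), effects[i], windows[i])))
  list(matrix = m, genotypes = g, ctx = ctx, signals = sigs,
       doses = doses, effects = effects, y = y)
}

test_that("a single signal never forms a multi-rtQTL region", {
  fx <- multi_fixture(effects = 1.0, windows = 30)
  out <- find_multi_regions(fx$signals[1, ], fx$ctx, fx$genotypes)
  expect_equal(nrow(out), 0)
})

test_that("loci further than 2 Mb apart are not grouped", {
  fx <- multi_fixture(effects = c(1.0, 0.8), windows = c(10, 260), seed = 31)
  out <- find_multi_regions(fx$signals, fx$ctx, fx$genotypes)
  expect_equal(nrow(out), 0)
})

test_that("three rtQTLs on one locus group into one region, strongest primary", {
  fx <- multi_fixture()
  out <- find_multi_regions(fx$signals, fx$ctx, fx$genotypes)
  expect_equal(nrow(out), 1)
  expect_equal(out$n_rtqtls, 3)
  expect_equal(out$primary_signal, 1)   # largest planted effect
  expect_setequal(out$member_signals[[1]], 1:3)
})

test_that("members adding no explanatory power are pruned", {
  fx <- multi_fixture(effects = c(1.0, 0.8, 0), seed = 32)
  out <- find_multi_regions(fx$signals, fx$ctx, fx$genotypes)
  expect_equal(nrow(out), 1)
  expect_setequal(out$member_signals[[1]], 1:2)
})

test_that("pooled additivity recovers the planted per-allele effect", {
  set.seed(33)
  n <- 150
  eff <- 0.5
  regions <- list(); signals <- list(); vals <- NULL
  n_reg <- 6
  vals <- matrix(rnorm(n * n_reg * 10, sd = 1), n, n_reg * 10)
  doses <- matrix(rbinom(n * n_reg, 2, 0.35), n, n_reg)
  for (r in seq_len(n_reg)) {
    w <- r * 10 - 5
    vals[, w] <- eff * doses[, r] + rnorm(n, sd = 0.3)
  }
  m <- toy_matrix(vals); m$state <- "smoothed"
  g <- toy_genotypes(doses, spacing = 5000)
  sigs <- dplyr::bind_rows(lapply(seq_len(n_reg), function(r)
    fake_signal(r, g$info$variant_id[r], 1e-10, eff, r * 10 - 5)))
  regs <- tibble::tibble(region = seq_len(n_reg), chrom = "chr1",
                         primary_signal = seq_len(n_reg), n_rtqtls = 1,
                         member_signals = as.list(seq_len(n_reg)),
                         focal_window = seq_len(n_reg) * 10 - 5)
  # "relative" scale: slope in across-sample SD units of each locus
  fit_rel <- pooled_additivity(regs, sigs, m, g, scale = "relative")
  expect_lt(fit_rel$p, 1e-6)
  sd_locus <- sqrt(eff^2 * 2 * 0.35 * 0.65 + 0.3^2)
  expect_equal(fit_rel$slope, eff / sd_locus, tolerance = 0.15)
  # OLS identity oracle on the pooled table
  oracle <- lm(timing ~ n_early, data = fit_rel$data)
  expect_equal(fit_rel$slope, unname(coef(oracle)[2]), tolerance = 1e-12)
  expect_equal(glance(fit_rel)$slope, fit_rel$slope)
  expect_equal(nrow(tidy(fit_rel)), 2)
})

test_that("permuting allele labels breaks the pooled association", {
  set.seed(34)
  n <- 120
  vals <- matrix(rnorm(n * 20, sd = 1), n, 20)
  d <- rbinom(n, 2, 0.4)
  vals[, 10] <- 0.6 * d + rnorm(n, sd = 0.3)
  m <- toy_matrix(vals); m$state <- "smoothed"
  g <- toy_genotypes(cbind(d = sample(d)))   # permuted dosage labels
  sigs <- fake_signal(1, "t001", 1e-8, 0.6, 10)
  regs <- tibble::tibble(region = 1, chrom = "chr1", primary_signal = 1,
                         n_rtqtls = 1, member_signals = list(1),
                         focal_window = 10)
  fit <- pooled_additivity(regs, sigs, m, g)
  expect_gt(fit$p, 0.05)
})

test_that("the additive-vs-synergistic LRT matches a grid-search oracle", {
  set.seed(35)
  dosage <- c(0, 0, 1, 1, 2, 2, 3, 3, 4, 4)
  timing <- c(-2.1, -1.8, -0.9, -1.1, 0.1, -0.2, 0.8, 1.1, 2.6, 2.9)
  got <- additive_vs_synergistic_lrt(timing, dosage)
  expect_gte(got$lrt, 0)
  # oracle: profile likelihood by brute-force grid search over the free
  # dosage values of the 0- and 4-allele groups, OLS for intercept/slope
  # at each grid point
  n <- length(timing)
  sse_null <- sum(resid(lm(timing ~ dosage))^2)
  sse_at <- function(x0, x4) {
    d <- dosage
    d[dosage == 0] <- x0
    d[dosage == 4] <- x4
    sum(lm.fit(cbind(1, d), timing)$residuals^2)
  }
  scan2 <- function(g0, g4) {
    best <- c(NA, NA, Inf)
    for (x0 in g0) for (x4 in g4) {
      s <- sse_at(x0, x4)
      if (s < best[3]) best <- c(x0, x4, s)
    }
    best
  }
  coarse <- scan2(seq(-4, 2, by = 0.05), seq(2, 8, by = 0.05))
  fine <- scan2(seq(coarse[1] - 0.06, coarse[1] + 0.06, by = 5e-4),
                seq(coarse[2] - 0.06, coarse[2] + 0.06, by = 5e-4))
  oracle_lrt <- n * log(sse_null / fine[3])
  expect_equal(got$lrt, oracle_lrt, tolerance = 1e-4)
  expect_equal(got$p, pchisq(got$lrt, 2, lower.tail = FALSE))
  # the chi-squared reference: statistic 5.991 sits at p = 0.05
  expect_equal(pchisq(5.991, 2, lower.tail = FALSE), 0.05, tolerance = 1e-3)
})

test_that("regions without both extreme dosage groups are ineligible", {
  expect_null(additive_vs_synergistic_lrt(rnorm(10), rep(1:3, c(3, 4, 3))))
})

test_that("the LRT is calibrated under additive truth", {
  set.seed(36)
  ps <- replicate(400, {
    n <- 80
    d1 <- rbinom(n, 2, 0.5); d2 <- rbinom(n, 2, 0.5)
    dose <- d1 + d2
    if (!any(dose == 0) || !any(dose == 4)) return(NA_real_)
    y <- 0.4 * dose + rnorm(n)
    additive_vs_synergistic_lrt(y, dose)$p
  })
  ps <- ps[!is.na(ps)]
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the LRT is never negative", {
  set.seed(37)
  for (i in 1:25) {
    n <- 60
    dose <- sample(0:4, n, replace = TRUE)
    y <- rnorm(n)
    out <- additive_vs_synergistic_lrt(y, dose)
    if (!is.null(out)) expect_gte(out$lrt, -1e-9)
  }
})

test_that("interaction scan uses -1/0/1 coding and finds planted epistasis", {
  set.seed(38)
  n <- 150
  g1 <- rbinom(n, 2, 0.5); g2 <- rbinom(n, 2, 0.5)
  # additive truth: interaction coefficient near zero
  y_add <- (g1 - 1) + (g2 - 1) + rnorm(n, sd = 1e-6)
  vals <- matrix(0, n, 3)
  vals[, 1] <- y_add
  # planted pure interaction in the -1/0/1 coding
  y_int <- (g1 - 1) * (g2 - 1) + rnorm(n, sd = 0.3)
  vals[, 2] <- y_int
  m <- toy_matrix(vals); m$state <- "smoothed"
  g <- toy_genotypes(cbind(g1, g2))
  pairs <- tibble::tibble(window = c(1, 2), variant_a = "t001",
                          variant_b = "t002")
  out <- interaction_scan(m, g, pairs)
  expect_lt(abs(out$beta[1]), 1e-4)
  expect_lt(out$p[2] * 1000, 1e-6)   # survives Bonferroni at 1000 pairs
  # coding check: recover unit coefficient for the planted term
  expect_equal(out$beta[2], 1, tolerance = 0.15)
})

test_that("window and variant pruning respect their thresholds", {
  set.seed(39)
  n <- 80
  base <- rnorm(n)
  vals <- cbind(base + rnorm(n, sd = 0.1),       # r ~ 0.99 with col 1
                base + rnorm(n, sd = 0.1),
                rnorm(n))
  m <- toy_matrix(vals); m$state <- "smoothed"
  kept_w <- prune_windows(m, r_max = 0.5)
  expect_equal(length(kept_w), 2)
  d <- rbinom(n, 2, 0.4)
  g <- toy_genotypes(cbind(d, d, rbinom(n, 2, 0.4)))
  kept_v <- prune_variants(g, r2_max = 0.5)
  expect_equal(length(kept_v), 2)
})

test_that("spatial proximity is null on a constant contact matrix", {
  pairs <- tibble::tibble(pos_a = c(5.2e6, 7.1e6), pos_b = c(5.9e6, 8.4e6))
  contact <- matrix(3.5, 120, 120)
  out <- spatial_proximity_test(pairs, contact, bin_size = 1e5)
  expect_equal(out$z, 0)
  expect_equal(out$p, 0.5)
})

test_that("planted contact enrichment at rtQTL pairs is detected", {
  set.seed(40)
  nb <- 150
  contact <- matrix(runif(nb * nb), nb, nb)
  pairs <- tibble::tibble(pos_a = seq(4e6, 9e6, length.out = 6),
                          pos_b = seq(4.5e6, 9.5e6, length.out = 6))
  ba <- floor(pairs$pos_a / 1e5) + 1; bb <- floor(pairs$pos_b / 1e5) + 1
  contact[cbind(ba, bb)] <- 10
  out <- spatial_proximity_test(pairs, contact, bin_size = 1e5, seed = 2)
  expect_lt(out$p, 0.05)
  expect_gt(out$observed_median, out$perm_mean)
})
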