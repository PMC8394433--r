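prof <- make_profile(26, 1)
cfg <- classification_config()

test_that("the ±10% stable band is applied inclusively", {
  fit <- list(means = c(26.0, 23.3, 28.6, 23.4, 28.7),
              proportions = rep(0.2, 5))
  flags <- classify_components(fit, prof_mean26 <- local({
    p <- prof; p$mean <- 26.0; p
  }), cfg)
  # 26.0 stable; 23.3 (|d|=2.7 > 2.6) unstable; 28.6 (= +10%) stable
  # 23.4 (|d|=2.6) stable; 28.7 unstable
  expect_identical(flags, c(TRUE, FALSE, TRUE, TRUE, FALSE))
})

test_that("the decision cascade maps every configuration to one status", {
  grid <- expand.grid(
    n_reads = c(0L, 50L, 5000L),
    all_stable = c(TRUE, FALSE),
    total_unstable = c(0.001, 0.019, 0.3),
    lrt_p = c(0.0001, 0.5, NA),
    power = c(0.95, 0.5, NA))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got <- memsi:::.decide_status(g$n_reads, g$all_stable, g$total_unstable,
                                  g$lrt_p, g$power, cfg)
    want <- if (g$n_reads < cfg$min_reads) "non_contributory"
    else if (g$all_stable || g$total_unstable < cfg$min_unstable_proportion)
      "stable"
    else if (!is.na(g$lrt_p) && g$lrt_p < cfg$lrt_alpha) "unstable"
    else if (!is.na(g$power) && g$power > cfg$power_threshold) "stable"
    else "non_contributory"
    expect_identical(got, want)
    expect_true(got %in% c("stable", "unstable", "non_contributory"))
  }
})

test_that("LRT is zero for all-stable fits and matches a direct oracle", {
  set.seed(41)
  h <- draw_hist(prof, 1000)
  fit1 <- em_fit(h, prof, k = 1)
  out <- lrt(h, fit1, prof, cfg)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)

  # strong instability: 30% at -6 nt, depth 2000
  set.seed(42)
  h2 <- draw_hist(prof, 2000, f_unst = 0.30, shift = -6)
  fit2 <- em_fit(h2, prof, k = 3)
  out2 <- lrt(h2, fit2, prof, cfg)
  expect_gte(out2$statistic, 0)
  expect_lt(out2$p_value, 1e-6)
  # oracle: best single component constrained to the stable band, by grid
  lens <- as.integer(names(h2$counts))
  cnt <- as.numeric(h2$counts)
  band <- seq(prof$mean - 2.6, prof$mean + 2.6, by = 0.01)
  ll_red_oracle <- max(vapply(band, function(m) {
    f <- pmax(memsi:::.shifted_density(prof, m, lens), 1e-12)
    sum(cnt * log(f))
  }, 0))
  expect_gte(out2$log_likelihood_reduced, ll_red_oracle - 0.5)
  expect_equal(out2$p_value,
               pchisq(out2$statistic, out2$df, lower.tail = FALSE))

  # nested models: statistic never meaningfully negative
  set.seed(43)
  for (i in 1:10) {
    h3 <- draw_hist(prof, 300, f_unst = runif(1, 0, 0.3))
    f3 <- em_fit(h3, prof, k = 3)
    expect_gte(lrt(h3, f3, prof, cfg)$statistic, 0)
  }
})

test_that("power is 0 without reads, ~1 at huge depth, monotone in n", {
  expect_equal(estimate_power(0, prof, cfg), 0)
  cfg_fast <- classification_config(power_mc_replicates = 50L, seed = 7L)
  p_big <- estimate_power(1e6, prof, cfg_fast)
  expect_gte(p_big, 0.99)
  p_small <- estimate_power(300, prof, cfg_fast)
  p_mid <- estimate_power(3000, prof, cfg_fast)
  expect_lte(p_small, p_mid + 0.1)
  expect_lte(p_mid, p_big + 0.1)
})

test_that("minimum interpretable reads agrees with a fresh-seed simulation", {
  cfg_b <- classification_config(power_mc_replicates = 100L, seed = 19L)
  n_min <- min_interpretable_reads(prof, cfg_b, n_max = 16384L)
  expect_false(is.na(n_min))
  expect_gt(n_min, 100)
  # independent Monte Carlo at the reported n with a different seed
  cfg_fresh <- classification_config(power_mc_replicates = 300L, seed = 91L)
  p_fresh <- estimate_power(n_min, prof, cfg_fresh)
  expect_lt(abs(p_fresh - cfg_b$power_threshold),
            0.15 * cfg_b$power_threshold)
})

test_that("call_microsatellite follows the cascade end to end", {
  set.seed(51)
  # pure stable
  h <- draw_hist(prof, 2000)
  cl <- call_microsatellite(h, prof, cfg)
  expect_identical(cl$status, "stable")
  expect_equal(nrow(cl$unstable_components), 0L)

  # sub-threshold instability (1% true fraction fits below the 2% gate)
  set.seed(52)
  h1 <- draw_hist(prof, 2000, f_unst = 0.01)
  cl1 <- call_microsatellite(h1, prof, cfg)
  expect_identical(cl1$status, "stable")

  # clear instability is called and quantified
  set.seed(53)
  h30 <- draw_hist(prof, 2000, f_unst = 0.30, shift = -6)
  cl30 <- call_microsatellite(h30, prof, cfg)
  expect_identical(cl30$status, "unstable")
  expect_equal(sum(cl30$unstable_components$proportion), 0.30,
               tolerance = 0.05)
  main <- which.max(cl30$unstable_components$proportion)
  expect_equal(cl30$unstable_components$mean_shift[main], -6,
               tolerance = 0.5)

  # constitutive lack of coverage
  h0 <- length_histogram(integer(0), "SIM")
  expect_identical(call_microsatellite(h0, prof, cfg)$status,
                   "non_contributory")

  # ~50% single unstable allele raises the polymorphism flag
  set.seed(54)
  h50 <- draw_hist(prof, 2000, f_unst = 0.5, shift = -4)
  cl50 <- call_microsatellite(h50, prof, cfg)
  expect_identical(cl50$status, "unstable")
  expect_true(cl50$suspected_polymorphism)
  expect_false(cl30$suspected_polymorphism)
})

test_that("increasing instability never flips unstable back to stable", {
  fracs <- c(0.02, 0.05, 0.10, 0.30, 0.60)
  for (seed in 1:3) {
    # common random numbers couple the draws across fractions
    set.seed(seed)
    n <- 2000
    u <- runif(n)
    ls <- sample(prof$lengths, n, TRUE, prob = prof$pmf)
    alt <- shift_profile(prof, prof$mean - 6)
    lu <- sample(alt$lengths, n, TRUE, prob = alt$pmf)
    seen_unstable <- FALSE
    for (f in fracs) {
      lens <- ifelse(u < f, lu, ls)
      h <- length_histogram(lens, "SIM")
      st <- call_microsatellite(h, prof, cfg)$status
      if (seen_unstable) expect_false(st == "stable")
      if (st == "unstable") seen_unstable <- TRUE
    }
    expect_true(seen_unstable)
  }
})

test_that("call_sample applies the >=2-of-5 MSI rule and its edge cases", {
  mk <- function(locus, status) {
    structure(list(locus = locus, status = status,
                   unstable_components = data.frame(),
                   n_reads = 1000L, lrt_statistic = NA_real_,
                   lrt_p = NA_real_, power = NA_real_,
                   suspected_polymorphism = FALSE, fit = NULL),
              class = "msat_call")
  }
  loci <- c("BAT-25", "BAT-26", "NR-21", "NR-24", "NR-27")
  build <- function(statuses) mapply(mk, loci, statuses, SIMPLIFY = FALSE)

  expect_identical(
    call_sample(build(c("unstable", "unstable", "stable", "stable",
                        "stable")))$status, "MSI")
  expect_identical(
    call_sample(build(c("unstable", "stable", "stable", "stable",
                        "stable")))$status, "MSS")
  expect_identical(
    call_sample(build(c("unstable", "unstable", "unstable", "unstable",
                        "non_contributory")))$status, "MSI")
  expect_identical(
    call_sample(build(c("stable", "stable", "non_contributory",
                        "non_contributory", "non_contributory")))$status,
    "non_contributory")

  dup <- build(rep("stable", 5))
  dup[[2]] <- mk("BAT-25", "stable")
  expect_error(call_sample(dup), "duplicate")
  expect_error(call_sample(build(rep("stable", 5))[1:4], panel = loci),
               "missing")
  expect_error(call_sample(build(rep("stable", 5)), panel = loci[1:4]),
               "unexpected")
})
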