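prof <- make_profile(26, 1)

test_that("mixture_pmf is the proportion-weighted sum of shifted profiles", {
  one <- list(means = prof$mean, proportions = 1)
  m1 <- mixture_pmf(one, prof)
  expect_equal(m1$probability[match(prof$lengths, m1$length)], prof$pmf,
               tolerance = 1e-12)

  two <- list(means = c(prof$mean, prof$mean - 5), proportions = c(0.5, 0.5))
  m2 <- mixture_pmf(two, prof)
  sa <- shift_profile(prof, prof$mean)
  sb <- shift_profile(prof, prof$mean - 5)
  at <- function(pr, l) {
    i <- match(l, pr$lengths); ifelse(is.na(i), 0, pr$pmf[i])
  }
  expect_equal(m2$probability,
               0.5 * at(sa, m2$length) + 0.5 * at(sb, m2$length),
               tolerance = 1e-12)
  expect_equal(sum(m2$probability), 1, tolerance = 1e-9)
})

test_that("log_likelihood matches direct and per-read computation", {
  fit <- list(means = prof$mean, proportions = 1)
  h1 <- length_histogram(counts = c("26" = 1), locus = "SIM")
  p26 <- prof$pmf[match(26L, prof$lengths)]
  expect_equal(log_likelihood(h1, fit, prof), log(p26), tolerance = 1e-12)

  # linear in counts
  set.seed(2)
  h <- draw_hist(prof, 500)
  hd <- length_histogram(counts = 2 * h$counts, locus = "SIM")
  expect_equal(log_likelihood(hd, fit, prof),
               2 * log_likelihood(h, fit, prof), tolerance = 1e-9)

  # brute-force per-read oracle
  fit2 <- list(means = c(prof$mean, prof$mean - 4),
               proportions = c(0.8, 0.2))
  reads <- rep(as.integer(names(h$counts)), h$counts)
  per_read <- sum(vapply(reads, function(l)
    log(memsi:::.mixture_density(prof, fit2$means, fit2$proportions, l)),
    0))
  expect_equal(log_likelihood(h, fit2, prof), per_read, tolerance = 1e-8)

  expect_error(log_likelihood(length_histogram(integer(0), "SIM"), fit, prof),
               "empty")
})

test_that("label permutation leaves the mixture and likelihood unchanged", {
  set.seed(4)
  h <- draw_hist(prof, 800, f_unst = 0.2)
  fit <- list(means = c(26, 21, 29), proportions = c(0.7, 0.2, 0.1))
  perm <- list(means = fit$means[c(3, 1, 2)],
               proportions = fit$proportions[c(3, 1, 2)])
  expect_equal(mixture_pmf(fit, prof)$probability,
               mixture_pmf(perm, prof)$probability, tolerance = 1e-12)
  expect_equal(log_likelihood(h, fit, prof), log_likelihood(h, perm, prof),
               tolerance = 1e-12)
})

test_that("EM recovers a single population as one stable component", {
  # counts exactly proportional to the profile pmf
  cnts <- round(prof$pmf * 1e4)
  keep <- cnts > 0
  h <- length_histogram(counts = setNames(cnts[keep],
                                          prof$lengths[keep]), "SIM")
  fit <- em_fit(h, prof, k = 3)
  near <- abs(fit$means - prof$mean) <= 0.1 * prof$mean
  expect_gte(sum(fit$proportions[near]), 0.98)
  expect_true(fit$converged)

  # point mass at the mean
  hp <- length_histogram(counts = c("26" = 1000), "SIM")
  fitp <- em_fit(hp, prof, k = 3)
  expect_equal(fitp$means[1], 26, tolerance = 0.1)
})

test_that("EM matches the exhaustive grid-search oracle on two components", {
  set.seed(77)
  h <- draw_hist(prof, 10000, f_unst = 0.30, shift = -5)
  fit <- em_fit(h, prof, k = 3)
  comp <- which(abs(fit$means - (prof$mean - 5)) < 1)
  expect_length(comp, 1)
  expect_equal(fit$proportions[comp], 0.30, tolerance = 0.03)
  expect_equal(fit$means[comp], prof$mean - 5, tolerance = 0.3)

  oracle <- grid_fit2(h, prof)
  expect_gte(fit$log_likelihood, oracle$ll - 0.5)
})

test_that("EM log-likelihood is monotone within every run", {
  set.seed(123)
  for (i in 1:100) {
    f_unst <- runif(1, 0, 0.6)
    shift <- sample(c(-8, -6, -4, 3), 1)
    n <- sample(c(50, 200, 1000), 1)
    h <- draw_hist(prof, n, f_unst = f_unst, shift = shift)
    k <- sample(1:3, 1)
    fit <- em_fit(h, prof, k = k, config = em_config(seed = i))
    expect_gte(min(diff(fit$ll_trace)), -1e-9)
    expect_equal(sum(fit$proportions), 1, tolerance = 1e-9)
    expect_true(all(fit$means >= prof$lengths[1] - 1e-9 &
                      fit$means <= prof$lengths[length(prof$lengths)] + 1e-9))
  }
})

test_that("components converging to the same mean are merged", {
  # two initial components both drawn to one population must not split it
  set.seed(9)
  h <- draw_hist(prof, 2000)
  fit <- em_fit(h, prof, k = 3)
  if (length(fit$means) > 1)
    expect_true(all(abs(diff(sort(fit$means))) > 0.25))
})
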