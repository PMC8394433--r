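#' Decision-cascade configuration
#'
#' Houses the calling constants: a component is stable when its mean sits
#' within ±`stable_mean_tolerance` (default 10%, inclusive) of the reference
#' mean; unstable components must jointly represent at least
#' `min_unstable_proportion` (default 2%) of the mixture; the nested
#' likelihood-ratio test uses `lrt_alpha`; a non-significant test is
#' reported stable only when the Monte Carlo power exceeds
#' `power_threshold` (default 80%), otherwise the locus is
#' non-contributory. A sample is MSI when at least
#' `min_unstable_loci_for_msi` loci are unstable, MSS when at least
#' `min_contributory_loci` loci are contributory.
#'
#' @param stable_mean_tolerance fraction of the reference mean.
#' @param min_unstable_proportion minimum summed unstable proportion.
#' @param power_threshold LRT power required to call "stable" after a
#'   non-significant test.
#' @param lrt_alpha significance level of the LRT.
#' @param power_mc_replicates Monte Carlo replicates per power estimate.
#' @param power_effect_shift mean shift (nt) of the power alternative.
#' @param power_read_grid read counts are rounded DOWN to this grid before
#'   power estimation so estimates can be cached (0 = exact counts).
#' @param min_reads histograms below this are non-contributory outright.
#' @param seed seed for the Monte Carlo power machinery.
#' @param min_unstable_loci_for_msi MSI rule (default: 2 of 5).
#' @param min_contributory_loci loci required to claim MSS.
#' @param polymorphism_band proportion window (around 50%) in which a single
#'   unstable component raises a germline-polymorphism suspicion flag.
#' @return An object of class `classification_config`.
#' @export
classification_config <- function(stable_mean_tolerance = 0.10,
                                  min_unstable_proportion = 0.02,
                                  power_threshold = 0.80,
                                  lrt_alpha = 0.01,
                                  power_mc_replicates = 200L,
                                  power_effect_shift = -6,
                                  power_read_grid = 250L,
                                  min_reads = 100L,
                                  seed = 1L,
                                  min_unstable_loci_for_msi = 2L,
                                  min_contributory_loci = 4L,
                                  polymorphism_band = c(0.40, 0.60)) {
  stopifnot(stable_mean_tolerance > 0, stable_mean_tolerance < 1,
            min_unstable_proportion > 0, min_unstable_proportion < 1,
            power_threshold > 0, power_threshold < 1,
            lrt_alpha > 0, lrt_alpha < 1, power_mc_replicates >= 1,
            min_unstable_loci_for_msi >= 1, min_contributory_loci >= 1)
  structure(list(stable_mean_tolerance = stable_mean_tolerance,
                 min_unstable_proportion = min_unstable_proportion,
                 power_threshold = power_threshold,
                 lrt_alpha = lrt_alpha,
                 power_mc_replicates = as.integer(power_mc_replicates),
                 power_effect_shift = power_effect_shift,
                 power_read_grid = as.integer(power_read_grid),
                 min_reads = as.integer(min_reads),
                 seed = as.integer(seed),
                 min_unstable_loci_for_msi = as.integer(min_unstable_loci_for_msi),
                 min_contributory_loci = as.integer(min_contributory_loci),
                 polymorphism_band = polymorphism_band),
            class = "classification_config")
}

#' Flag each mixture component as stable or potentially unstable
#'
#' Component `n` is stable iff `|m_n - mean| <= tol * mean` (inclusive
#' boundary), where `mean` is the reference mean and `tol` the configured
#' stable-mean tolerance.
#'
#' @param fit an `msat_mixture_fit`.
#' @param profile an [reference_profile()].
#' @param config a [classification_config()].
#' @return Logical vector, `TRUE` = stable, one entry per component.
#' @export
classify_components <- function(fit, profile,
                                config = classification_config()) {
  # 1e-9 guard keeps the documented inclusive boundary robust to FP rounding
  abs(fit$means - profile$mean) <=
    config$stable_mean_tolerance * profile$mean + 1e-9
}

# Refit keeping only the stable components (constrained to the stable band);
# the reduced model always retains at least one component. The common
# one-component case is a one-dimensional likelihood in the location, so it
# is maximised directly (coarse grid + local refinement), which is robust
# even when the stable model is badly misspecified for the data; the rare
# multi-component case falls back to constrained EM.
.reduced_fit <- function(histogram, full_fit, profile, config, em) {
  stable <- classify_components(full_fit, profile, config)
  tol <- config$stable_mean_tolerance * profile$mean
  bounds <- c(profile$mean - tol, profile$mean + tol)
  lens <- as.integer(names(histogram$counts))
  cnt <- as.numeric(histogram$counts)
  if (sum(stable) <= 1) {
    ll1 <- function(m) {
      f <- .shifted_density(profile, m, lens)
      f[f < 1e-12] <- 1e-12
      sum(cnt * log(f))
    }
    grid <- seq(bounds[1], bounds[2], length.out = 61)
    lls <- vapply(grid, ll1, 0)
    i <- which.max(lls)
    lo <- grid[max(1, i - 1)]
    hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(ll1, c(lo, hi), maximum = TRUE, tol = 1e-6)
    if (opt$objective >= lls[i]) {
      best_m <- opt$maximum
      best_ll <- opt$objective
    } else {
      best_m <- grid[i]
      best_ll <- lls[i]
    }
    return(list(means = best_m, proportions = 1, log_likelihood = best_ll,
                k = 1L))
  }
  means0 <- full_fit$means[stable]
  props0 <- full_fit$proportions[stable]
  props0 <- props0 / sum(props0)
  run <- .em_run(lens, cnt, profile, means0, props0, em, mean_bounds = bounds)
  list(means = run$means, proportions = run$props,
       log_likelihood = run$log_likelihood, k = length(run$means))
}

#' Likelihood-ratio test of the unstable components
#'
#' Compares the full mixture fit to a reduced model refitted by EM from the
#' stable components alone (renormalised, constrained to the stable band).
#' The statistic is `2 * (logL_full - logL_reduced)`; the p-value comes from
#' the chi-square upper tail with 2 degrees of freedom (mean + proportion)
#' per removed unstable component — a standard nested-model count that
#' boundary effects render conservative.
#'
#' @param histogram an `msat_histogram`.
#' @param full_fit the k=3 [em_fit()] of the histogram.
#' @param profile an [reference_profile()].
#' @param config a [classification_config()].
#' @param em an [em_config()] for the reduced refit.
#' @return List with `statistic`, `p_value`, `df`, `log_likelihood_full`,
#'   `log_likelihood_reduced`.
#' @export
lrt <- function(histogram, full_fit, profile,
                config = classification_config(), em = em_config()) {
  stable <- classify_components(full_fit, profile, config)
  n_unstable <- sum(!stable)
  if (n_unstable == 0)
    return(list(statistic = 0, p_value = 1, df = 0L,
                log_likelihood_full = full_fit$log_likelihood,
                log_likelihood_reduced = full_fit$log_likelihood))
  red <- .reduced_fit(histogram, full_fit, profile, config, em)
  stat <- 2 * (full_fit$log_likelihood - red$log_likelihood)
  stat <- max(stat, 0)
  df <- 2L * n_unstable
  list(statistic = stat, p_value = pchisq(stat, df, lower.tail = FALSE),
       df = df, log_likelihood_full = full_fit$log_likelihood,
       log_likelihood_reduced = red$log_likelihood)
}

# Core significance machinery on one histogram: fit, classify, test.
# Returns everything call_microsatellite needs.
.assess_histogram <- function(histogram, profile, config, em) {
  fit <- em_fit(histogram, profile, k = 3L, config = em)
  stable <- classify_components(fit, profile, config)
  total_unstable <- sum(fit$proportions[!stable])
  res <- list(fit = fit, stable = stable, total_unstable = total_unstable,
              lrt = NULL, significant = FALSE)
  if (any(!stable) && total_unstable >= config$min_unstable_proportion) {
    res$lrt <- lrt(histogram, fit, profile, config, em)
    res$significant <- res$lrt$p_value < config$lrt_alpha
  }
  res
}

#' Monte Carlo power of the likelihood-ratio test
#'
#' Estimates, for `n_reads` observations, the probability that the calling
#' cascade detects the minimal relevant instability: a mixture with
#' `min_unstable_proportion` of reads shifted by `power_effect_shift` nt
#' (defaults: 2% at -6 nt, i.e. the decision threshold paired with a
#' typical colorectal deletion). Each replicate draws a multinomial
#' histogram from that alternative, refits the mixture and applies the LRT
#' at `lrt_alpha`. Seeded and deterministic; results are cached per
#' (profile, read count, configuration).
#'
#' @param n_reads number of contributing reads (>= 0).
#' @param profile an [reference_profile()].
#' @param config a [classification_config()].
#' @param replicates optional override of `config$power_mc_replicates`.
#' @return Estimated power in `[0, 1]`; monotone non-decreasing in
#'   `n_reads` up to Monte Carlo error.
#' @export
estimate_power <- function(n_reads, profile,
                           config = classification_config(),
                           replicates = NULL) {
  n_reads <- as.integer(n_reads)
  stopifnot(n_reads >= 0)
  if (n_reads == 0) return(0)
  reps <- if (is.null(replicates)) config$power_mc_replicates
          else as.integer(replicates)
  key <- paste(profile$locus, profile$n_source_reads,
               format(profile$mean, digits = 12), n_reads,
               config$min_unstable_proportion, config$power_effect_shift,
               config$lrt_alpha, reps, config$seed, sep = "|")
  hit <- get0(key, envir = .memsi_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)

  alt_mean <- max(0, profile$mean + config$power_effect_shift)
  unstable <- shift_profile(profile, alt_mean)
  support <- sort(unique(c(profile$lengths, unstable$lengths)))
  p0 <- config$min_unstable_proportion
  at <- function(prof, l) {
    idx <- match(l, prof$lengths)
    ifelse(is.na(idx), 0, prof$pmf[idx])
  }
  alt_pmf <- (1 - p0) * at(profile, support) + p0 * at(unstable, support)
  em_light <- em_config(n_restarts = 1L, max_iterations = 200L,
                        seed = config$seed)
  rejections <- with_seed(derive_seed(config$seed, n_reads), {
    draws <- rmultinom(reps, n_reads, alt_pmf)
    vapply(seq_len(reps), function(r) {
      cnts <- draws[, r]
      keep <- cnts > 0
      h <- length_histogram(counts = setNames(cnts[keep], support[keep]),
                            locus = profile$locus)
      # power of the TEST itself: reject when the LRT is significant,
      # whatever the fitted unstable proportion
      fit <- em_fit(h, profile, k = 3L, config = em_light)
      if (all(classify_components(fit, profile, config))) return(FALSE)
      lrt(h, fit, profile, config, em_light)$p_value < config$lrt_alpha
    }, logical(1))
  })
  pw <- mean(rejections)
  assign(key, pw, envir = .memsi_cache)
  pw
}

#' Smallest read count interpretable at the configured power
#'
#' Bisects [estimate_power()] for the smallest `n_reads` whose power for the
#' minimal relevant instability exceeds `power_threshold`. This is the
#' machinery behind per-locus minimum-coverage requirements.
#'
#' @param profile an [reference_profile()].
#' @param config a [classification_config()].
#' @param n_max upper bracket for the search.
#' @return Integer read count (or `NA` if even `n_max` is under-powered).
#' @export
min_interpretable_reads <- function(profile,
                                    config = classification_config(),
                                    n_max = 20000L) {
  pw <- function(n) estimate_power(n, profile, config)
  if (pw(n_max) <= config$power_threshold) return(NA_integer_)
  lo <- 0L
  hi <- as.integer(n_max)
  while (hi - lo > 1L) {
    mid <- as.integer((lo + hi) %/% 2)
    if (pw(mid) > config$power_threshold) hi <- mid else lo <- mid
  }
  hi
}

# The decision cascade as a pure function of its inputs (exhaustively
# testable). lrt_p / power may be NA when their branch is not reached.
.decide_status <- function(n_reads, all_stable, total_unstable, lrt_p, power,
                           config) {
  if (n_reads < config$min_reads) return("non_contributory")
  if (all_stable || total_unstable < config$min_unstable_proportion)
    return("stable")
  if (!is.na(lrt_p) && lrt_p < config$lrt_alpha) return("unstable")
  if (!is.na(power) && power > config$power_threshold) return("stable")
  "non_contributory"
}

#' Call one microsatellite stable / unstable / non-contributory
#'
#' The full decision cascade. An empty or sub-minimal histogram is
#' non-contributory. Otherwise the k=3 mixture is fitted: if every component
#' is stable, or the unstable components jointly represent less than the 2%
#' minimum, the locus is stable. Otherwise the likelihood-ratio test runs:
#' significant means unstable (with each retained unstable component's mean
#' shift and proportion quantified); non-significant means stable when the
#' test was powered (> 80% for the minimal relevant instability at this
#' locus's read count), non-contributory when it was not. A single unstable
#' component near 50% proportion additionally raises a
#' suspected-polymorphism flag.
#'
#' @param histogram an `msat_histogram` (may be empty).
#' @param profile an [reference_profile()].
#' @param config a [classification_config()].
#' @param em an [em_config()].
#' @return An object of class `msat_call`: `locus`, `status`,
#'   `unstable_components` (data.frame `mean`, `mean_shift`, `proportion`),
#'   `n_reads`, `lrt_statistic`, `lrt_p`, `power`,
#'   `suspected_polymorphism`, `fit`.
#' @export
call_microsatellite <- function(histogram, profile,
                                config = classification_config(),
                                em = em_config()) {
  stopifnot(inherits(histogram, "msat_histogram"),
            inherits(profile, "msat_reference"))
  empty_components <- data.frame(mean = numeric(), mean_shift = numeric(),
                                 proportion = numeric())
  res <- list(locus = histogram$locus, status = NA_character_,
              unstable_components = empty_components,
              n_reads = histogram$n_reads,
              lrt_statistic = NA_real_, lrt_p = NA_real_, power = NA_real_,
              suspected_polymorphism = FALSE, fit = NULL)
  if (histogram$n_reads < config$min_reads) {
    res$status <- "non_contributory"
    return(structure(res, class = "msat_call"))
  }
  a <- .assess_histogram(histogram, profile, config, em)
  res$fit <- a$fit
  if (!is.null(a$lrt)) {
    res$lrt_statistic <- a$lrt$statistic
    res$lrt_p <- a$lrt$p_value
  }
  power <- NA_real_
  if (!is.null(a$lrt) && !a$significant) {
    n_pow <- if (config$power_read_grid > 0)
      max(config$power_read_grid,
          (histogram$n_reads %/% config$power_read_grid) *
            config$power_read_grid)
    else histogram$n_reads
    power <- estimate_power(n_pow, profile, config)
    res$power <- power
  }
  res$status <- .decide_status(histogram$n_reads, all(a$stable),
                               a$total_unstable, res$lrt_p, power, config)
  if (res$status == "unstable") {
    keep <- !a$stable & a$fit$proportions >= config$min_unstable_proportion
    if (!any(keep)) {
      res$status <- "stable"   # no individually reportable unstable allele
    } else {
      res$unstable_components <- data.frame(
        mean = a$fit$means[keep],
        mean_shift = a$fit$means[keep] - profile$mean,
        proportion = a$fit$proportions[keep])
      band <- config$polymorphism_band
      res$suspected_polymorphism <- sum(keep) == 1 &&
        res$unstable_components$proportion[1] >= band[1] &&
        res$unstable_components$proportion[1] <= band[2]
    }
  }
  structure(res, class = "msat_call")
}

#' @export
print.msat_call <- function(x, ...) {
  cat(sprintf("<msat_call> %s: %s (%d reads)\n", x$locus, x$status, x$n_reads))
  if (nrow(x$unstable_components))
    for (i in seq_len(nrow(x$unstable_components)))
      cat(sprintf("  unstable allele: shift %+.2f nt, proportion %.3f\n",
                  x$unstable_components$mean_shift[i],
                  x$unstable_components$proportion[i]))
  if (!is.na(x$lrt_p)) cat(sprintf("  LRT p = %.3g\n", x$lrt_p))
  if (!is.na(x$power)) cat(sprintf("  power = %.2f\n", x$power))
  if (x$suspected_polymorphism) cat("  suspected polymorphism (~50% allele)\n")
  invisible(x)
}

#' Combine per-locus calls into the sample MSI / MSS verdict
#'
#' MSI requires at least `min_unstable_loci_for_msi` unstable loci (default
#' 2 of 5). Otherwise the sample is MSS when enough loci were contributory
#' (default 4), and non-contributory when the panel carries too little
#' evidence to claim stability.
#'
#' @param calls list of exactly the panel's [call_microsatellite()] results,
#'   one per locus (no duplicates, none missing).
#' @param config a [classification_config()].
#' @param sample sample identifier.
#' @param panel optional character vector of expected locus names to
#'   validate against.
#' @return An object of class `msat_sample_call`: `sample`, `status`
#'   (`"MSI"`, `"MSS"` or `"non_contributory"`), `calls`, `n_unstable`,
#'   `n_contributory`.
#' @export
call_sample <- function(calls, config = classification_config(),
                        sample = "sample", panel = NULL) {
  stopifnot(length(calls) >= 1,
            all(vapply(calls, inherits, TRUE, "msat_call")))
  loci <- vapply(calls, `[[`, "", "locus")
  if (anyDuplicated(loci))
    stop("duplicate locus call: ", loci[duplicated(loci)][1])
  if (!is.null(panel)) {
    missing <- setdiff(panel, loci)
    extra <- setdiff(loci, panel)
    if (length(missing)) stop("missing locus call: ", missing[1])
    if (length(extra)) stop("unexpected locus call: ", extra[1])
  }
  status_vec <- vapply(calls, `[[`, "", "status")
  n_unstable <- sum(status_vec == "unstable")
  n_contributory <- sum(status_vec != "non_contributory")
  status <- if (n_unstable >= config$min_unstable_loci_for_msi) "MSI"
  else if (n_contributory >= config$min_contributory_loci) "MSS"
  else "non_contributory"
  structure(list(sample = sample, status = status,
                 calls = setNames(calls, loci),
                 n_unstable = n_unstable, n_contributory = n_contributory),
            class = "msat_sample_call")
}

#' @export
print.msat_sample_call <- function(x, ...) {
  cat(sprintf("<msat_sample_call> %s: %s (%d unstable, %d contributory)\n",
              x$sample, x$status, x$n_unstable, x$n_contributory))
  for (cl in x$calls) cat(sprintf("  %-8s %s\n", cl$locus, cl$status))
  invisible(x)
}
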