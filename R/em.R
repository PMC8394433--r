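#' EM fitting hyperparameters
#'
#' @param max_iterations iteration cap per run.
#' @param loglik_tolerance stop when the log-likelihood gain falls below this.
#' @param n_restarts number of initialisations; the best final
#'   log-likelihood wins. Restart 1 uses `init_offsets` exactly, later
#'   restarts jitter them (uniform ±2 nt) from `seed`.
#' @param init_offsets starting offsets (nt, relative to the reference mean)
#'   of the second and third components. The deletion-biased defaults (-5,
#'   -10) reflect the usual direction of poly-A instability; jittered
#'   restarts still explore insertions.
#' @param init_proportions starting mixture proportions (first `k` entries,
#'   renormalised).
#' @param seed integer seed for restart jitter.
#' @return An object of class `em_config`.
#' @export
em_config <- function(max_iterations = 500L, loglik_tolerance = 1e-6,
                      n_restarts = 3L, init_offsets = c(-5, -10),
                      init_proportions = c(0.90, 0.05, 0.05), seed = 1L) {
  stopifnot(max_iterations >= 1, loglik_tolerance > 0, n_restarts >= 1,
            length(init_offsets) >= 2, length(init_proportions) >= 3,
            all(init_proportions > 0))
  structure(list(max_iterations = as.integer(max_iterations),
                 loglik_tolerance = loglik_tolerance,
                 n_restarts = as.integer(n_restarts),
                 init_offsets = init_offsets,
                 init_proportions = init_proportions,
                 seed = as.integer(seed)),
            class = "em_config")
}

# Mixture density at integer lengths; floor keeps logs finite for stray
# observations outside every shifted support.
.mixture_density <- function(profile, means, props, at, floor = 1e-12) {
  f <- numeric(length(at))
  for (n in seq_along(means))
    f <- f + props[n] * .shifted_density(profile, means[n], at)
  pmax(f, floor)
}

#' Mixture probability mass function
#'
#' Pointwise `sum_n P_n * shift_profile(profile, m_n)` over the union of the
#' shifted supports.
#'
#' @param fit an `msat_mixture_fit` (see [em_fit()]), or a list with
#'   `means` and `proportions`.
#' @param profile an [reference_profile()].
#' @return `data.frame(length, probability)`; probabilities sum to 1.
#' @export
mixture_pmf <- function(fit, profile) {
  means <- fit$means; props <- fit$proportions
  stopifnot(length(means) == length(props), all(props >= -1e-12),
            abs(sum(props) - 1) < 1e-9)
  ks <- floor(means - profile$mean)
  lo <- max(0L, profile$lengths[1] + as.integer(min(ks)))
  hi <- profile$lengths[length(profile$lengths)] + as.integer(max(ks)) + 1L
  at <- lo:hi
  p <- .mixture_density(profile, means, props, at, floor = 0)
  p <- p / sum(p)
  data.frame(length = at, probability = p)
}

#' Log-likelihood of a histogram under a mixture fit
#'
#' `sum_length count(length) * log f(length)` where `f` is the mixture
#' density. The reference profile's pseudocount floor keeps the result
#' finite everywhere on the shifted supports.
#'
#' @param histogram an `msat_histogram` with at least one read.
#' @param fit a mixture fit (or list with `means`, `proportions`).
#' @param profile an [reference_profile()].
#' @return A single number.
#' @export
log_likelihood <- function(histogram, fit, profile) {
  stopifnot(inherits(histogram, "msat_histogram"))
  if (histogram$n_reads < 1) stop("empty histogram has no likelihood")
  lens <- as.integer(names(histogram$counts))
  f <- .mixture_density(profile, fit$means, fit$proportions, lens)
  sum(histogram$counts * log(f))
}

# Single EM run from one initialisation. The M-step proportion update is
# exact; the location update (responsibility-weighted mean length) is exact
# only for symmetric shapes, so it is safeguarded: if the joint update would
# lower the log-likelihood the location step is halved towards the previous
# means (at worst keeping them), which provably cannot decrease the
# likelihood. mean_bounds optionally clamps means (used by the constrained
# reduced-model fit of the LRT).
.em_run <- function(lens, cnt, profile, means, props, config,
                    mean_bounds = NULL) {
  lo <- profile$lengths[1]
  hi <- profile$lengths[length(profile$lengths)]
  clamp <- function(m) {
    m <- pmin(pmax(m, lo), hi)
    if (!is.null(mean_bounds)) m <- pmin(pmax(m, mean_bounds[1]), mean_bounds[2])
    m
  }
  means <- clamp(means)
  k <- length(means)
  N <- sum(cnt)
  nl <- length(lens)
  pmf0 <- c(0, profile$pmf)
  np <- length(profile$pmf)
  pmean <- profile$mean
  idx0 <- as.integer(lens) - lo + 1L
  shifted <- function(m) {   # inlined .shifted_density on the fixed grid
    sp <- .shift_parts(m - pmean)
    kk <- sp$k
    w <- sp$w
    i1 <- idx0 - kk
    i1[i1 < 1L | i1 > np] <- 0L
    i2 <- idx0 - kk - 1L
    i2[i2 < 1L | i2 > np] <- 0L
    (1 - w) * pmf0[i1 + 1L] + w * pmf0[i2 + 1L]
  }
  dens_matrix <- function(mn) {
    G <- matrix(0, nl, k)
    for (n in seq_len(k)) G[, n] <- shifted(mn[n])
    G
  }
  G <- dens_matrix(means)
  ll_prev <- -Inf
  means_prev <- means
  ll <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  niter <- 0L
  for (iter in 0:config$max_iterations) {
    f <- G %*% props; f[f < 1e-12] <- 1e-12
    ll <- sum(cnt * log(f))
    if (iter > 0L && ll < ll_prev - 1e-9) {
      # safeguard: halve the location step towards the previous means (with
      # the updated proportions, which alone can never lower the likelihood)
      tries <- 0L
      while (ll < ll_prev - 1e-9 && tries < 12L) {
        means <- (means + means_prev) / 2
        if (max(abs(means - means_prev)) < 1e-12) means <- means_prev
        G <- dens_matrix(means)
        f <- G %*% props; f[f < 1e-12] <- 1e-12
        ll <- sum(cnt * log(f))
        tries <- tries + 1L
      }
      if (ll < ll_prev - 1e-9) {
        means <- means_prev
        G <- dens_matrix(means)
        f <- G %*% props; f[f < 1e-12] <- 1e-12
        ll <- sum(cnt * log(f))
      }
    }
    trace <- c(trace, ll)
    if (iter > 0L) {
      niter <- iter
      if (ll - ll_prev < config$loglik_tolerance) {
        converged <- TRUE
        break
      }
    }
    if (iter == config$max_iterations) break
    # E-step responsibilities, then the joint M-step update
    R <- sweep(G, 2, props, `*`) / as.numeric(f)
    w <- as.numeric(crossprod(R, cnt))
    means_prev <- means
    ll_prev <- ll
    means <- clamp(ifelse(
      w > 1e-12, as.numeric(crossprod(R * lens, cnt)) / pmax(w, 1e-300),
      means))
    props <- w / N
    props <- props / sum(props)
    G <- dens_matrix(means)
  }
  list(means = means, props = props, log_likelihood = ll,
       n_iterations = niter, converged = converged, trace = trace)
}

# Merge components whose means ended within `tol` nt of each other
# (proportion-weighted mean, summed proportion) to avoid double-counting one
# allele as two components.
.merge_components <- function(means, props, tol = 0.25) {
  repeat {
    k <- length(means)
    if (k <= 1) break
    merged <- FALSE
    for (i in seq_len(k - 1)) {
      j <- which(abs(means[(i + 1):k] - means[i]) <= tol)
      if (length(j)) {
        j <- i + j[1]
        wsum <- props[i] + props[j]
        means[i] <- if (wsum > 0)
          (means[i] * props[i] + means[j] * props[j]) / wsum
        else mean(c(means[i], means[j]))
        props[i] <- wsum
        means <- means[-j]; props <- props[-j]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  list(means = means, props = props)
}

#' Fit the length distribution with a shifted-reference mixture by EM
#'
#' Models the observed histogram as a mixture of up to `k` (<= 3) copies of
#' the reference profile, each translated to its own expected length `m_n`
#' and weighted `P_n`. The E-step computes length-bin responsibilities; the
#' M-step sets each proportion to the responsibility-weighted read fraction
#' and each mean to the responsibility-weighted mean length (safeguarded so
#' the log-likelihood never decreases). The best of `n_restarts`
#' initialisations is returned; components converging within 0.25 nt are
#' merged before reporting, and components are ordered by decreasing
#' proportion.
#'
#' @param histogram an `msat_histogram` with at least one read.
#' @param profile an [reference_profile()] for the same locus.
#' @param k number of components (1, 2 or 3).
#' @param config an [em_config()].
#' @return An object of class `msat_mixture_fit`: `means`, `proportions`
#'   (post-merge, proportion-descending), `k` (requested), `log_likelihood`,
#'   `n_iterations`, `converged`, and `ll_trace` (per-iteration
#'   log-likelihood of the winning run).
#' @export
em_fit <- function(histogram, profile, k = 3L, config = em_config()) {
  stopifnot(inherits(histogram, "msat_histogram"),
            inherits(profile, "msat_reference"), k %in% 1:3)
  if (histogram$n_reads < 1) stop("cannot fit an empty histogram")
  lens <- as.integer(names(histogram$counts))
  cnt <- as.numeric(histogram$counts)
  offsets0 <- c(0, config$init_offsets)[seq_len(k)]
  props0 <- config$init_proportions[seq_len(k)]
  props0 <- props0 / sum(props0)
  jitters <- with_seed(config$seed, {
    js <- matrix(0, nrow = config$n_restarts, ncol = k)
    if (config$n_restarts > 1 && k > 1)
      js[-1, -1] <- runif((config$n_restarts - 1) * (k - 1), -2, 2)
    js
  })
  best <- NULL
  for (r in seq_len(config$n_restarts)) {
    means0 <- profile$mean + offsets0 + jitters[r, ]
    run <- .em_run(lens, cnt, profile, means0, props0, config)
    if (is.null(best) || run$log_likelihood > best$log_likelihood) best <- run
  }
  mg <- .merge_components(best$means, best$props)
  ord <- order(mg$props, decreasing = TRUE)
  ll <- sum(cnt * log(.mixture_density(profile, mg$means, mg$props, lens)))
  structure(list(means = mg$means[ord], proportions = mg$props[ord],
                 k = as.integer(k), log_likelihood = ll,
                 n_iterations = best$n_iterations,
                 converged = best$converged, ll_trace = best$trace),
            class = "msat_mixture_fit")
}

#' @export
print.msat_mixture_fit <- function(x, ...) {
  cat(sprintf("<msat_mixture_fit> %d component(s), logL %.3f (%s, %d iter)\n",
              length(x$means), x$log_likelihood,
              if (x$converged) "converged" else "not converged",
              x$n_iterations))
  for (i in seq_along(x$means))
    cat(sprintf("  m%d = %.3f nt   P%d = %.4f\n", i, x$means[i], i,
                x$proportions[i]))
  invisible(x)
}
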