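# Shared fixtures, all generated in code.

# Analytic reference profile: a stutter-shaped pmf centred on `center`,
# padded and floored exactly as build_reference would do.
make_profile <- function(center = 26, sd = 1, locus = "SIM",
                         pseudocount = 1e-6) {
  sp <- stutter_pmf(sd, kmax = 6)
  lens <- center + sp$offset
  support <- (min(lens) - 3L):(max(lens) + 3L)
  p <- numeric(length(support))
  p[match(lens, support)] <- sp$probability
  p <- pmax(p, pseudocount)
  p <- p / sum(p)
  reference_profile(support, p, locus = locus, n_source_reads = 10000L,
                    pseudocount = pseudocount)
}

# Multinomial histogram drawn from a (1-f) stable + f shifted mixture.
# Uses the current RNG stream.
draw_hist <- function(prof, n, f_unst = 0, shift = -6) {
  support <- prof$lengths
  pmf <- prof$pmf
  if (f_unst > 0) {
    alt <- shift_profile(prof, prof$mean + shift)
    support <- sort(unique(c(support, alt$lengths)))
    at <- function(pr, l) {
      i <- match(l, pr$lengths)
      ifelse(is.na(i), 0, pr$pmf[i])
    }
    pmf <- (1 - f_unst) * at(prof, support) + f_unst * at(alt, support)
  }
  cnts <- stats::rmultinom(1, n, pmf)[, 1]
  keep <- cnts > 0
  length_histogram(counts = stats::setNames(cnts[keep], support[keep]),
                   locus = prof$locus)
}

# Exhaustive two-component grid-search fit: m1 fixed at the profile mean,
# (m2, P2) on a grid, maximising the same log-likelihood the EM uses.
grid_fit2 <- function(h, prof, m_step = 0.1, p_step = 0.01) {
  lens <- as.integer(names(h$counts))
  cnt <- as.numeric(h$counts)
  g1 <- memsi:::.shifted_density(prof, prof$mean, lens)
  p2 <- seq(0, 1, by = p_step)
  best <- list(ll = -Inf, m2 = NA, p2 = NA)
  for (m2 in seq(prof$lengths[1], prof$lengths[length(prof$lengths)],
                 by = m_step)) {
    g2 <- memsi:::.shifted_density(prof, m2, lens)
    f <- g1 %o% (1 - p2) + g2 %o% p2
    f[f < 1e-12] <- 1e-12
    ll <- colSums(cnt * log(f))
    i <- which.max(ll)
    if (ll[i] > best$ll) best <- list(ll = ll[i], m2 = m2, p2 = p2[i])
  }
  best
}

# Lazily built end-to-end fixtures (synthetic panel + reference profiles
# from simulated MSS control FASTQs), shared across test files.
.fixture_env <- new.env()
sim_fixtures <- function() {
  if (!is.null(.fixture_env$fx)) return(.fixture_env$fx)
  panel <- synthetic_panel(seed = 101L)
  dir <- file.path(tempdir(), "memsi-fixtures")
  dir.create(dir, showWarnings = FALSE)
  specs <- lapply(panel, function(loc)
    simulated_locus_spec(loc, msi_alleles(loc$stable_length, 0),
                         stutter_sd = 1, depth = 4000L,
                         seed = 900L + loc$stable_length))
  r1 <- file.path(dir, "ctrl_R1.fastq.gz")
  r2 <- file.path(dir, "ctrl_R2.fastq.gz")
  simulate_sample_fastq(specs, r1, r2)
  profiles <- build_reference_from_fastq(r1, r2, panel)
  .fixture_env$fx <- list(panel = panel, profiles = profiles, dir = dir)
  .fixture_env$fx
}

# Simulate one multi-locus sample and return its FASTQ pair paths.
sim_sample <- function(panel, fraction, depth = 2000L, stutter_sd = 1,
                       shift = -6L, seed = 1L, dir = tempdir(),
                       tag = "s") {
  specs <- lapply(seq_along(panel), function(i) {
    loc <- panel[[i]]
    simulated_locus_spec(loc, msi_alleles(loc$stable_length, fraction, shift),
                         stutter_sd = stutter_sd, depth = depth,
                         seed = memsi:::derive_seed(seed, i))
  })
  r1 <- file.path(dir, paste0(tag, "_R1.fastq.gz"))
  r2 <- file.path(dir, paste0(tag, "_R2.fastq.gz"))
  simulate_sample_fastq(specs, r1, r2)
  list(r1 = r1, r2 = r2)
}
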