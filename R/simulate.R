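#' Replication-slippage (stutter) offset model
#'
#' PCR amplification of a homopolymer slips: most copies keep the true
#' length, and slipped copies are usually one or a few bases SHORTER, with
#' occasional insertions. The model is a two-sided geometric: with
#' probability `pi` the offset is non-zero; its magnitude is geometric
#' (ratio `r` between successive magnitudes) and its sign is a deletion
#' with 3:1 odds. Given a target offset standard deviation `stutter_sd`,
#' `stutter_params()` solves for `(pi, r)` in closed form (`r` is kept at
#' 0.5 and `pi` adjusted while `pi <= 1` permits it, i.e. up to
#' `stutter_sd = sqrt(5)`; beyond that `pi = 1` and `r` grows).
#'
#' @param stutter_sd target standard deviation of the offset (nt, >= 0).
#' @return `stutter_params`: list with `pi`, `r`, `mean` (the closed-form
#'   expected offset, negative because deletion-biased) and `sd`.
#' @export
stutter_params <- function(stutter_sd) {
  stopifnot(stutter_sd >= 0)
  if (stutter_sd == 0)
    return(list(pi = 0, r = 0.5, mean = 0, sd = 0))
  v <- stutter_sd^2
  if (v <= 5) {
    r <- 0.5
    pi <- 3 - sqrt(9 - v)
  } else {
    # pi = 1; solve (r + 3/4) = v (1 - r)^2 for r in [0, 1)
    a <- v; b <- -(2 * v + 1); cc <- v - 3 / 4
    r <- (-b - sqrt(b^2 - 4 * a * cc)) / (2 * a)
    pi <- 1
  }
  list(pi = pi, r = r, mean = -pi / (2 * (1 - r)),
       sd = sqrt(pi * (1 + r) / (1 - r)^2 - (pi / (2 * (1 - r)))^2))
}

#' @rdname stutter_params
#' @param kmax largest offset magnitude tabulated.
#' @return `stutter_pmf`: `data.frame(offset, probability)` of the exact
#'   offset distribution (tail beyond `kmax` folded into the last bins).
#' @export
stutter_pmf <- function(stutter_sd, kmax = 15L) {
  p <- stutter_params(stutter_sd)
  k <- seq_len(kmax)
  geom <- (1 - p$r) * p$r^(k - 1)
  geom[kmax] <- p$r^(kmax - 1)            # fold the geometric tail
  data.frame(
    offset = c(-rev(k), 0, k),
    probability = c(rev(p$pi * 0.75 * geom), 1 - p$pi, p$pi * 0.25 * geom))
}

# n random offsets under the stutter model (uses the current RNG stream).
.stutter_offsets <- function(n, stutter_sd) {
  p <- stutter_params(stutter_sd)
  if (p$pi == 0 || n == 0) return(integer(n))
  nz <- runif(n) < p$pi
  sgn <- ifelse(runif(n) < 0.75, -1L, 1L)
  mag <- rgeom(n, 1 - p$r) + 1L
  as.integer(nz) * sgn * mag
}

#' Draw observed read lengths for an allele under stutter noise
#'
#' `allele_length` plus a stutter offset (see [stutter_params()]), clamped
#' at zero. Uses R's global RNG stream; seed it for reproducibility.
#'
#' @param allele_length true allele repeat length (nt).
#' @param stutter_sd stutter standard deviation (nt).
#' @param n number of draws.
#' @return Integer vector of `n` lengths.
#' @export
sample_read_length <- function(allele_length, stutter_sd, n = 1L) {
  pmax(0L, as.integer(allele_length) + .stutter_offsets(n, stutter_sd))
}

#' Describe one simulated locus
#'
#' @param locus an [msat_locus()].
#' @param alleles `data.frame(length, fraction)`; fractions sum to 1.
#' @param stutter_sd stutter offset standard deviation (nt).
#' @param depth number of read PAIRS to simulate (each pair contributes two
#'   mates downstream).
#' @param seed RNG seed; the same spec is byte-identical across runs.
#' @param read_length mate length (nt).
#' @return An object of class `sim_locus_spec`.
#' @export
simulated_locus_spec <- function(locus, alleles, stutter_sd = 1, depth = 2000L,
                                 seed = 1L, read_length = 150L) {
  stopifnot(inherits(locus, "msat_locus"),
            is.data.frame(alleles), all(c("length", "fraction") %in%
                                          names(alleles)),
            abs(sum(alleles$fraction) - 1) < 1e-9,
            all(alleles$length >= 0), all(alleles$fraction >= 0),
            depth >= 0, stutter_sd >= 0)
  structure(list(locus = locus, alleles = alleles, stutter_sd = stutter_sd,
                 depth = as.integer(depth), seed = as.integer(seed),
                 read_length = as.integer(read_length)),
            class = "sim_locus_spec")
}

#' Stable/unstable allele table for a given unstable fraction
#'
#' @param stable_length stable allele repeat length (nt).
#' @param unstable_fraction fraction of unstable alleles in `[0, 1]`.
#' @param shift length shift of the unstable allele (nt, default -6).
#' @return `data.frame(length, fraction)` for [simulated_locus_spec()].
#' @export
msi_alleles <- function(stable_length, unstable_fraction, shift = -6L) {
  stopifnot(unstable_fraction >= 0, unstable_fraction <= 1)
  if (unstable_fraction == 0)
    return(data.frame(length = as.integer(stable_length), fraction = 1))
  data.frame(
    length = as.integer(c(stable_length, stable_length + shift)),
    fraction = c(1 - unstable_fraction, unstable_fraction))
}

# Generate reads for one spec: amplicon = left context + flank5 +
# repeat-base run of the sampled length + flank3 + right context, padded
# with random sequence to read_length; R1 is the amplicon, R2 its reverse
# complement (full read-through, the usual small-amplicon geometry).
.simulate_read_batch <- function(spec) {
  with_seed(spec$seed, {
    n <- spec$depth
    loc <- spec$locus
    if (n == 0)
      return(list(ids = character(0), seq1 = character(0),
                  seq2 = character(0),
                  truth = data.frame(read_id = character(0),
                                     locus = character(0),
                                     allele_length = integer(0),
                                     sampled_length = integer(0))))
    idx <- sample.int(nrow(spec$alleles), n, replace = TRUE,
                      prob = spec$alleles$fraction)
    len <- pmax(0L, spec$alleles$length[idx] +
                  .stutter_offsets(n, spec$stutter_sd))
    core <- nchar(loc$flank5) + len + nchar(loc$flank3)
    if (any(core > spec$read_length))
      stop("flank-repeat-flank construct longer than read_length")
    left_n <- (spec$read_length - core) %/% 2L
    right_n <- spec$read_length - core - left_n
    tot <- sum(left_n) + sum(right_n)
    pool <- paste(sample(c("A", "C", "G", "T"), tot, replace = TRUE),
                  collapse = "")
    le <- cumsum(left_n)
    left_ctx <- substring(pool, le - left_n + 1L, le)
    re <- sum(left_n) + cumsum(right_n)
    right_ctx <- substring(pool, re - right_n + 1L, re)
    amplicon <- paste0(left_ctx, loc$flank5, strrep(loc$repeat_base, len),
                       loc$flank3, right_ctx)
    ids <- sprintf("%s_%06d", gsub("[^A-Za-z0-9._-]", "_", loc$name),
                   seq_len(n))
    list(ids = ids, seq1 = amplicon, seq2 = .revcomp(amplicon),
         truth = data.frame(read_id = ids, locus = loc$name,
                            allele_length = spec$alleles$length[idx],
                            sampled_length = len))
  })
}

.write_fastq <- function(ids, seqs, path, mate) {
  if (!length(ids)) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    close(con)
    return(invisible(path))
  }
  qual <- strrep("I", nchar(seqs))
  lines <- as.vector(rbind(paste0("@", ids, "/", mate), seqs, "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(as.character(lines), con)
  invisible(path)
}

#' Simulate amplicon paired-end FASTQ reads for one locus
#'
#' Writes an R1/R2 pair (gzip when the path ends in `.gz`) whose mates
#' carry the flank5–homopolymer–flank3 construct embedded in random
#' context, with constant base quality, and returns the per-read truth
#' table. Fully reproducible from `spec$seed`.
#'
#' @param spec a [simulated_locus_spec()].
#' @param r1,r2 output FASTQ paths.
#' @return Invisibly, `data.frame(read_id, locus, allele_length,
#'   sampled_length)`.
#' @export
simulate_fastq <- function(spec, r1, r2) {
  g <- .simulate_read_batch(spec)
  .write_fastq(g$ids, g$seq1, r1, 1L)
  .write_fastq(g$ids, g$seq2, r2, 2L)
  invisible(g$truth)
}

#' @rdname simulate_fastq
#' @param specs list of [simulated_locus_spec()] (one per locus); reads are
#'   pooled into a single R1/R2 pair, as in a multiplexed amplicon library.
#' @export
simulate_sample_fastq <- function(specs, r1, r2) {
  gens <- lapply(specs, .simulate_read_batch)
  ids <- unlist(lapply(gens, `[[`, "ids"))
  .write_fastq(ids, unlist(lapply(gens, `[[`, "seq1")), r1, 1L)
  .write_fastq(ids, unlist(lapply(gens, `[[`, "seq2")), r2, 2L)
  invisible(do.call(rbind, lapply(gens, `[[`, "truth")))
}

# Random flank free of >= 3-base runs of the repeat base, not bordering the
# repeat with its own base (keeps the repeat boundary unambiguous).
.synthetic_flank <- function(repeat_base, side, width, seed) {
  with_seed(seed, {
    run3 <- strrep(repeat_base, 3)
    repeat {
      s <- paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
                 collapse = "")
      edge <- if (side == 5) substr(s, width, width) else substr(s, 1, 1)
      if (!grepl(run3, s, fixed = TRUE) && edge != repeat_base) return(s)
    }
  })
}

#' Synthetic five-locus Bethesda-like panel
#'
#' The five poly-A mononucleotide microsatellites of the Bethesda panel
#' with their nominal stable repeat lengths (BAT-25: 25, BAT-26: 26,
#' NR-21: 21, NR-24: 24, NR-27: 27) and SYNTHETIC flanking sequences:
#' random 20-mers free of repeat-base runs, fixed per locus by `seed`. Real
#' assay flanks are primer-panel specific and must be supplied by the user
#' for real data; this panel exercises the pipeline end to end on simulated
#' reads.
#'
#' @param seed seed fixing the synthetic flanks.
#' @param flank_width flank length (nt).
#' @return Named list of five [msat_locus()] objects with `stable_length`
#'   set.
#' @export
synthetic_panel <- function(seed = 101L, flank_width = 20L) {
  defs <- data.frame(
    name = c("BAT-25", "BAT-26", "NR-21", "NR-24", "NR-27"),
    stable_length = c(25L, 26L, 21L, 24L, 27L))
  loci <- lapply(seq_len(nrow(defs)), function(i) {
    msat_locus(defs$name[i], "A",
               flank5 = .synthetic_flank("A", 5, flank_width,
                                         derive_seed(seed, 2L * i)),
               flank3 = .synthetic_flank("A", 3, flank_width,
                                         derive_seed(seed, 2L * i + 1L)),
               stable_length = defs$stable_length[i])
  })
  setNames(loci, defs$name)
}

#' Default positive-control unstable fractions for the synthetic panel
#'
#' Per-locus unstable-allele fractions of a typical MSI positive control
#' (73%, 77%, 74%, 70%, 77% for BAT-25, BAT-26, NR-21, NR-24, NR-27).
#'
#' @return Named numeric vector.
#' @export
positive_control_fractions <- function() {
  c("BAT-25" = 0.73, "BAT-26" = 0.77, "NR-21" = 0.74,
    "NR-24" = 0.70, "NR-27" = 0.77)
}

#' Simulate a dilution series of an MSI positive control
#'
#' In-silico analogue of diluting an MSI positive control into an MSS
#' negative control: sample `d` carries, at each locus, an unstable-allele
#' fraction of `positive_fractions[locus] * dilutions[d]`. One pooled R1/R2
#' FASTQ pair is written per dilution; the manifest records the expected
#' fractions (the truth for quantification-linearity checks).
#'
#' @param panel named list of [msat_locus()] with `stable_length` set (see
#'   [synthetic_panel()]).
#' @param positive_fractions named per-locus unstable fractions of the
#'   undiluted positive control.
#' @param dilutions numeric dilution factors (1 = undiluted, 0 = pure MSS).
#' @param depth read pairs per locus per sample.
#' @param stutter_sd stutter standard deviation (nt).
#' @param shift unstable-allele length shift (nt).
#' @param seed base seed; per-sample/locus seeds are derived from it.
#' @param out_dir output directory for the FASTQ files.
#' @return `data.frame(sample, dilution, locus, expected_fraction, r1, r2)`.
#' @export
simulate_dilution_series <- function(panel,
                                     positive_fractions =
                                       positive_control_fractions(),
                                     dilutions = c(1, 1/4, 1/8, 1/12,
                                                   1/16, 1/20),
                                     depth = 2000L, stutter_sd = 1,
                                     shift = -6L, seed = 1L,
                                     out_dir = tempdir()) {
  stopifnot(all(names(panel) %in% names(positive_fractions)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- NULL
  for (d in seq_along(dilutions)) {
    specs <- lapply(seq_along(panel), function(i) {
      loc <- panel[[i]]
      f <- positive_fractions[[loc$name]] * dilutions[d]
      simulated_locus_spec(
        loc, msi_alleles(loc$stable_length, f, shift),
        stutter_sd = stutter_sd, depth = depth,
        seed = derive_seed(seed, d * 100L + i))
    })
    sample_id <- sprintf("dilution_%02d", d)
    r1 <- file.path(out_dir, paste0(sample_id, "_R1.fastq.gz"))
    r2 <- file.path(out_dir, paste0(sample_id, "_R2.fastq.gz"))
    simulate_sample_fastq(specs, r1, r2)
    out <- rbind(out, data.frame(
      sample = sample_id, dilution = dilutions[d],
      locus = names(panel),
      expected_fraction = unname(positive_fractions[names(panel)] *
                                   dilutions[d]),
      r1 = r1, r2 = r2))
  }
  out
}
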