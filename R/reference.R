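#' Construct a reference length profile
#'
#' Low-level constructor; most users should call [build_reference()].
#' Probabilities must live on a contiguous integer support and sum to 1.
#'
#' @param lengths contiguous ascending integer lengths (nt).
#' @param pmf probabilities, same length as `lengths`, summing to 1.
#' @param locus locus identifier.
#' @param n_source_reads number of control reads behind the profile.
#' @param pseudocount the probability floor applied at build time.
#' @return An object of class `msat_reference` with fields `locus`,
#'   `lengths`, `pmf`, `mean`, `n_source_reads`, `pseudocount`.
#' @export
reference_profile <- function(lengths, pmf, locus = "locus",
                              n_source_reads = 0L, pseudocount = 0) {
  lengths <- as.integer(lengths)
  stopifnot(length(lengths) == length(pmf), length(lengths) >= 1,
            all(diff(lengths) == 1L), all(lengths >= 0), all(pmf >= 0))
  if (abs(sum(pmf) - 1) > 1e-9)
    stop("profile probabilities must sum to 1 (got ", format(sum(pmf)), ")")
  structure(list(locus = locus, lengths = lengths, pmf = as.numeric(pmf),
                 mean = sum(lengths * pmf),
                 n_source_reads = as.integer(n_source_reads),
                 pseudocount = pseudocount),
            class = "msat_reference")
}

#' @export
print.msat_reference <- function(x, ...) {
  cat(sprintf(
    "<msat_reference> %s: support [%d, %d], mean %.3f nt, %d source reads\n",
    x$locus, min(x$lengths), max(x$lengths), x$mean, x$n_source_reads))
  invisible(x)
}

#' Build an empirical reference profile from MSS control histograms
#'
#' Histograms from one locus (typically many MSS control samples, or one
#' histogram over their merged reads) are summed; the probability mass
#' function is the normalised counts over the closed support
#' `[min observed - pad, max observed + pad]`, floored at `pseudocount`
#' per bin and renormalised. The floor prevents minus-infinite
#' log-likelihoods for lengths unseen in controls; the padding accommodates
#' sampling noise near the support edge in test samples.
#'
#' @param histograms one `msat_histogram` or a list of them (same locus).
#' @param min_reads minimum total control reads required.
#' @param pseudocount per-bin probability floor.
#' @param pad support padding in bins on each side.
#' @return An [reference_profile()] object.
#' @export
build_reference <- function(histograms, min_reads = 500L,
                            pseudocount = 1e-6, pad = 3L) {
  if (inherits(histograms, "msat_histogram")) histograms <- list(histograms)
  stopifnot(length(histograms) >= 1)
  locus <- histograms[[1]]$locus
  all_counts <- integer(0)
  for (h in histograms) {
    stopifnot(inherits(h, "msat_histogram"))
    if (!identical(h$locus, locus))
      stop("histograms from different loci: ", locus, " vs ", h$locus)
    for (nm in names(h$counts))
      all_counts[nm] <- (if (nm %in% names(all_counts)) all_counts[nm] else 0L) +
        h$counts[[nm]]
  }
  total <- sum(all_counts)
  if (total < min_reads)
    stop(sprintf(
      "insufficient control reads for '%s': %d observed, %d required (deficit %d)",
      locus, total, as.integer(min_reads), as.integer(min_reads) - total))
  obs <- as.integer(names(all_counts))
  lo <- max(0L, min(obs) - as.integer(pad))
  hi <- max(obs) + as.integer(pad)
  support <- lo:hi
  cnt <- setNames(numeric(length(support)), support)
  cnt[names(all_counts)] <- all_counts
  p <- cnt / total
  p <- pmax(p, pseudocount)
  p <- p / sum(p)
  reference_profile(support, as.numeric(p), locus = locus,
                    n_source_reads = total, pseudocount = pseudocount)
}

# Shifted-profile density evaluated at arbitrary integer lengths.
# Fractional shifts interpolate the two adjacent integer translations so the
# expected value is exact. No truncation at zero (used inside the EM, where
# means stay within the padded support).
.shift_parts <- function(d) {
  k <- floor(d)
  w <- d - k
  # snap near-integer shifts so integer translations compose exactly
  if (w > 1 - 1e-9) { k <- k + 1; w <- 0 }
  if (w < 1e-9) w <- 0
  list(k = as.integer(k), w = w)
}

.shifted_density <- function(profile, m, at) {
  sp <- .shift_parts(m - profile$mean)
  k <- sp$k
  w <- sp$w
  pmf0 <- c(0, profile$pmf)          # index 1 holds zero for out-of-support
  np <- length(profile$pmf)
  idx <- as.integer(at) - as.integer(k) - profile$lengths[1] + 1L
  i1 <- idx; i1[i1 < 1L | i1 > np] <- 0L
  i2 <- idx - 1L; i2[i2 < 1L | i2 > np] <- 0L
  (1 - w) * pmf0[i1 + 1L] + w * pmf0[i2 + 1L]
}

#' Translate a reference profile to a new mean length
#'
#' The empirical shape is kept: mass is translated by
#' `d = target_mean - profile$mean` bins; fractional shifts linearly
#' interpolate the two adjacent integer translations, which makes the
#' resulting expected value equal `target_mean` exactly. Mass that would
#' land below length 0 is truncated and the distribution renormalised (in
#' which case the mean moves accordingly).
#'
#' @param profile an [reference_profile()].
#' @param target_mean desired expected length (>= 0, nt).
#' @return A new `msat_reference` with the shifted pmf.
#' @export
shift_profile <- function(profile, target_mean) {
  stopifnot(inherits(profile, "msat_reference"), target_mean >= 0)
  k <- .shift_parts(target_mean - profile$mean)$k
  support <- (profile$lengths[1] + k):
    (profile$lengths[length(profile$lengths)] + k + 1L)
  q <- .shifted_density(profile, target_mean, support)
  keep <- support >= 0L
  support <- support[keep]
  q <- q[keep]
  if (!length(q) || sum(q) <= 0)
    stop("shift_profile: all mass truncated below length 0")
  q <- q / sum(q)
  # trim zero-probability edge bins that interpolation may leave behind
  nz <- which(q > 0)
  support <- support[min(nz):max(nz)]
  q <- q[min(nz):max(nz)]
  reference_profile(support, q, locus = profile$locus,
                    n_source_reads = profile$n_source_reads,
                    pseudocount = profile$pseudocount)
}

.profile_format_version <- 1L

#' Save or load a reference profile (versioned plain text)
#'
#' Human-readable, auditable format: a `memsi_reference_profile <version>`
#' tag line, `key<TAB>value` header fields, then a `length<TAB>probability`
#' table at full double precision. Loading validates the schema version,
#' that probabilities sum to 1 and that the stored mean matches the table.
#'
#' @param profile an [reference_profile()].
#' @param path file path.
#' @return `load_profile` returns the `msat_reference`.
#' @export
save_profile <- function(profile, path) {
  stopifnot(inherits(profile, "msat_reference"))
  lines <- c(
    paste0("memsi_reference_profile\t", .profile_format_version),
    paste0("locus\t", profile$locus),
    paste0("n_source_reads\t", profile$n_source_reads),
    paste0("pseudocount\t", format(profile$pseudocount, digits = 17)),
    paste0("mean\t", format(profile$mean, digits = 17)),
    "length\tprobability",
    paste0(profile$lengths, "\t", format(profile$pmf, digits = 17)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname save_profile
#' @export
load_profile <- function(path) {
  lines <- readLines(path)
  tag <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(tag) != 2 || tag[1] != "memsi_reference_profile")
    stop("not a memsi reference profile file: ", path)
  if (as.integer(tag[2]) != .profile_format_version)
    stop(sprintf("unsupported profile schema version %s (expected %d)",
                 tag[2], .profile_format_version))
  hdr_end <- which(lines == "length\tprobability")[1]
  if (is.na(hdr_end)) stop("profile file missing length/probability table")
  kv <- strsplit(lines[2:(hdr_end - 1)], "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  tab <- strsplit(lines[(hdr_end + 1):length(lines)], "\t", fixed = TRUE)
  lengths <- as.integer(vapply(tab, `[`, "", 1))
  pmf <- as.numeric(vapply(tab, `[`, "", 2))
  if (abs(sum(pmf) - 1) > 1e-9)
    stop("invalid profile: probabilities sum to ", format(sum(pmf)))
  prof <- reference_profile(
    lengths, pmf, locus = vals[keys == "locus"],
    n_source_reads = as.integer(vals[keys == "n_source_reads"]),
    pseudocount = as.numeric(vals[keys == "pseudocount"]))
  stored_mean <- as.numeric(vals[keys == "mean"])
  if (abs(stored_mean - prof$mean) > 1e-6)
    stop("invalid profile: stored mean ", stored_mean,
         " does not match table mean ", prof$mean)
  prof
}
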