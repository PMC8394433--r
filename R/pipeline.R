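#' Build reference profiles from MSS control FASTQs
#'
#' Extracts every locus's length histogram from the pooled mates of the
#' control FASTQ pairs (the in-silico analogue of a merged FASTQ of MSS
#' samples) and normalises each into a reference profile.
#'
#' @param r1,r2 character vectors of control FASTQ paths (R2 entries may be
#'   `NA` for unpaired files).
#' @param panel named list of [msat_locus()].
#' @param rule a [homopolymer_rule()].
#' @param min_reads,pseudocount,pad passed to [build_reference()].
#' @param seed_len seed screen length for [build_histogram()].
#' @return Named list of [reference_profile()] objects.
#' @export
build_reference_from_fastq <- function(r1, r2 = NULL, panel,
                                       rule = homopolymer_rule(),
                                       min_reads = 500L, pseudocount = 1e-6,
                                       pad = 3L, seed_len = 8L) {
  mates <- character(0)
  for (i in seq_along(r1)) {
    mates <- c(mates, read_fastq_mates(
      r1[i], if (!is.null(r2) && !is.na(r2[i])) r2[i] else NULL))
  }
  lapply(panel, function(loc)
    build_reference(build_histogram(mates, loc, rule, seed_len),
                    min_reads = min_reads, pseudocount = pseudocount,
                    pad = pad))
}

#' Call a sample's MSI status from FASTQ
#'
#' End-to-end pipeline: read mates, build one length histogram per panel
#' locus, run the decision cascade per locus, and combine into the sample
#' verdict.
#'
#' @param r1,r2 FASTQ paths (R2 optional).
#' @param panel named list of [msat_locus()].
#' @param profiles named list of [reference_profile()] covering the panel.
#' @param config a [classification_config()].
#' @param em an [em_config()].
#' @param rule a [homopolymer_rule()].
#' @param seed_len seed screen length for [build_histogram()].
#' @param sample sample identifier for the report.
#' @return An `msat_sample_call`.
#' @export
call_sample_fastq <- function(r1, r2 = NULL, panel, profiles,
                              config = classification_config(),
                              em = em_config(), rule = homopolymer_rule(),
                              seed_len = 8L, sample = basename(r1)) {
  stopifnot(all(names(panel) %in% names(profiles)))
  mates <- read_fastq_mates(r1, r2)
  calls <- lapply(panel, function(loc)
    call_microsatellite(build_histogram(mates, loc, rule, seed_len),
                        profiles[[loc$name]], config, em))
  call_sample(calls, config, sample = sample, panel = names(panel))
}
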