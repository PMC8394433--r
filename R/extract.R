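#' Locate the inter-flank span of a microsatellite in one read
#'
#' Both flanks of the locus are searched in the read (and in its reverse
#' complement) by Smith-Waterman local alignment. A span is returned only
#' when BOTH flanks align with a score of at least `min_score_fraction`
#' times their perfect-match score and the accepted 5'-flank alignment ends
#' strictly before the accepted 3'-flank alignment begins. When both
#' orientations qualify, the one with the higher combined flank score wins
#' (forward on ties).
#'
#' @param read_sequence a single non-empty read sequence.
#' @param locus an [msat_locus()].
#' @return `NULL` when the locus is not anchored; otherwise an integer
#'   vector `c(start, end)` — the 0-based, half-open inter-flank span on the
#'   oriented sequence (the read itself for strand `"+"`, its reverse
#'   complement for `"-"`; attribute `strand` says which). Absence of
#'   anchors is a normal outcome, not an error.
#' @export
#' @examples
#' loc <- msat_locus("demo", "A", "CTGCGAGAAGGTACTCACCC", "GGGTTGCAGCAATTCACTGT")
#' rd <- paste0(loc$flank5, strrep("A", 26), loc$flank3)
#' find_flanks(rd, loc)  # span of length 26
find_flanks <- function(read_sequence, locus) {
  stopifnot(is.character(read_sequence), length(read_sequence) == 1,
            nzchar(read_sequence))
  h <- .flank_spans(read_sequence, locus)
  if (!h$ok[1]) return(NULL)
  structure(c(start = h$start0[1], end = h$end0[1]), strand = h$strand[1])
}

# Vectorised anchoring over a character vector of mates.
# Returns data.frame(ok, start0, end0, strand) with 0-based half-open spans.
.flank_spans <- function(seqs, locus) {
  sc <- locus$sw_scoring
  frac <- if (is.null(locus$min_flank_identity)) sc$min_score_fraction
          else locus$min_flank_identity
  thr5 <- frac * sc$match * nchar(locus$flank5)
  thr3 <- frac * sc$match * nchar(locus$flank3)
  n <- length(seqs)

  one_orientation <- function(ss) {
    start0 <- rep(NA_integer_, length(ss))
    end0 <- rep(NA_integer_, length(ss))
    total <- rep(-Inf, length(ss))
    a5 <- .sw_batch(ss, locus$flank5, sc$match, sc$mismatch,
                    sc$gap_open, sc$gap_extend)
    ok5 <- a5$score >= thr5
    if (any(ok5)) {
      a3 <- .sw_batch(ss[ok5], locus$flank3, sc$match, sc$mismatch,
                      sc$gap_open, sc$gap_extend)
      ok3 <- a3$score >= thr3 & !is.na(a3$start) & !is.na(a5$end[ok5]) &
        a3$start > a5$end[ok5]
      ok3[is.na(ok3)] <- FALSE
      idx <- which(ok5)[ok3]
      start0[idx] <- a5$end[ok5][ok3]       # 1-based flank5 end == 0-based span start
      end0[idx] <- a3$start[ok3] - 1L       # 0-based half-open span end
      total[idx] <- a5$score[ok5][ok3] + a3$score[ok3]
    }
    list(start0 = start0, end0 = end0, total = total)
  }

  fw <- one_orientation(seqs)
  rv <- one_orientation(.revcomp(seqs))
  ok_f <- !is.na(fw$start0)
  ok_r <- !is.na(rv$start0)
  use_rev <- (ok_r & !ok_f) | (ok_r & ok_f & rv$total > fw$total)
  data.frame(
    ok = ok_f | ok_r,
    start0 = ifelse(use_rev, rv$start0, fw$start0),
    end0 = ifelse(use_rev, rv$end0, fw$end0),
    strand = ifelse(use_rev, "-", "+"),
    stringsAsFactors = FALSE)
}

#' Measure the microsatellite length carried by one read
#'
#' Applies [find_flanks()], trims the read to the inter-flank span and
#' retains it only when the trimmed sequence passes the homopolymer rule.
#' The reported length is the full span length: sequencing errors inside the
#' repeat do not shorten it, mimicking fragment sizing in MSI-PCR.
#'
#' @inheritParams find_flanks
#' @param rule a [homopolymer_rule()].
#' @return Integer length in nt, or `NULL` when the read is excluded.
#' @export
extract_length <- function(read_sequence, locus, rule = homopolymer_rule()) {
  len <- .extract_lengths(read_sequence, locus, rule, seed_len = 0L)
  if (is.na(len)) NULL else len
}

# Vectorised extraction; NA where a mate does not contribute.
# seed_len > 0 enables a mapper-style exact-seed screen before the SW pass.
.extract_lengths <- function(seqs, locus, rule = homopolymer_rule(),
                             seed_len = 8L) {
  out <- rep(NA_integer_, length(seqs))
  if (!length(seqs)) return(out)
  cand <- rep(TRUE, length(seqs))
  if (seed_len > 0L) {
    cand_f <- .seed_hits(seqs, locus$flank5, seed_len) &
      .seed_hits(seqs, locus$flank3, seed_len)
    cand_r <- .seed_hits(seqs, .revcomp(locus$flank5), seed_len) &
      .seed_hits(seqs, .revcomp(locus$flank3), seed_len)
    cand <- cand_f | cand_r
  }
  if (!any(cand)) return(out)
  ss <- seqs[cand]
  sp <- .flank_spans(ss, locus)
  hit <- which(sp$ok)
  if (!length(hit)) return(out)
  oriented <- ifelse(sp$strand[hit] == "-", .revcomp(ss[hit]), ss[hit])
  trimmed <- substr(oriented, sp$start0[hit] + 1L, sp$end0[hit])
  len <- sp$end0[hit] - sp$start0[hit]
  rs <- .run_stats(trimmed, locus$repeat_base)
  keep <- len > 0L & rs$run >= rule$min_run &
    rs$count >= rule$min_content * len
  out[which(cand)[hit[keep]]] <- len[keep]
  out
}

#' Construct a length histogram
#'
#' @param lengths integer vector of observed microsatellite lengths (one per
#'   contributing mate), or a named count vector via `counts`.
#' @param locus locus identifier (character) or an [msat_locus()].
#' @param counts alternative input: named non-negative integer vector whose
#'   names are lengths.
#' @return An object of class `msat_histogram` with fields `locus`, `counts`
#'   (named count vector, ascending lengths) and `n_reads`.
#' @export
length_histogram <- function(lengths = NULL, locus = "locus", counts = NULL) {
  if (inherits(locus, "msat_locus")) locus <- locus$name
  if (is.null(counts)) {
    lengths <- as.integer(lengths[!is.na(lengths)])
    stopifnot(all(lengths >= 0))
    counts <- table(lengths)
    counts <- setNames(as.integer(counts), names(counts))
  } else {
    stopifnot(!is.null(names(counts)), all(counts >= 0))
    counts <- counts[order(as.integer(names(counts)))]
    counts <- setNames(as.integer(counts), names(counts))
    counts <- counts[counts > 0 | length(counts) == 0]
    stopifnot(all(as.integer(names(counts)) >= 0))
  }
  structure(list(locus = locus, counts = counts,
                 n_reads = sum(counts)),
            class = "msat_histogram")
}

#' @export
print.msat_histogram <- function(x, ...) {
  cat(sprintf("<msat_histogram> %s: %d reads over %d lengths\n",
              x$locus, x$n_reads, length(x$counts)))
  if (length(x$counts)) print(x$counts)
  invisible(x)
}

#' Build the length histogram of a locus from reads
#'
#' Every mate is scanned independently (no pair-level deduplication) with
#' [find_flanks()] semantics plus the homopolymer retention rule; the
#' histogram is the tally of retained inter-flank lengths. The result is
#' independent of read order. A mapper-style exact-seed screen (`seed_len`
#' consecutive flank bases, both strands) cheaply discards mates that cannot
#' anchor before the exact Smith-Waterman pass; set `seed_len = 0` to
#' disable it.
#'
#' @param reads character vector of mate sequences (see
#'   [read_fastq_mates()]).
#' @param locus an [msat_locus()].
#' @param rule a [homopolymer_rule()].
#' @param seed_len exact-seed screen length in nt (0 disables).
#' @return An `msat_histogram`.
#' @export
build_histogram <- function(reads, locus, rule = homopolymer_rule(),
                            seed_len = 8L) {
  lens <- .extract_lengths(reads, locus, rule, seed_len)
  length_histogram(lens, locus)
}

#' @rdname build_histogram
#' @param r1,r2 FASTQ paths (R2 optional), passed to [read_fastq_mates()].
#' @export
build_histogram_fastq <- function(r1, r2 = NULL, locus,
                                  rule = homopolymer_rule(), seed_len = 8L) {
  build_histogram(read_fastq_mates(r1, r2), locus, rule, seed_len)
}

#' Write or read per-locus histograms as TSV
#'
#' Columns: `locus`, `length`, `count`.
#'
#' @param histograms a single `msat_histogram` or a list of them.
#' @param path file path.
#' @return `read_histograms` returns a named list of `msat_histogram`.
#' @export
write_histograms <- function(histograms, path) {
  if (inherits(histograms, "msat_histogram")) histograms <- list(histograms)
  df <- do.call(rbind, lapply(histograms, function(h) {
    if (!length(h$counts))
      return(data.frame(locus = character(), length = integer(),
                        count = integer()))
    data.frame(locus = h$locus, length = as.integer(names(h$counts)),
               count = as.integer(h$counts))
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_histograms
#' @export
read_histograms <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("locus", "length", "count") %in% names(df)))
  lapply(split(df, df$locus), function(d)
    length_histogram(counts = setNames(d$count, d$length), locus = d$locus[1]))
}
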