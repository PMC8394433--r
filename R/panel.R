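#' Smith-Waterman scoring parameters for flank anchoring
#'
#' Scoring used when locating a locus flanking sequence inside a read with
#' local alignment. A flank anchor is accepted when its local-alignment score
#' reaches `min_score_fraction` times the flank's perfect-match score
#' (`match * nchar(flank)`). A gap of length L costs
#' `gap_open + L * gap_extend`; ambiguous bases (N) score as mismatches.
#'
#' The defaults (+1/-1, gap open 2, gap extend 1, fraction 0.8) tolerate the
#' scattered substitution errors typical of FFPE amplicon reads while
#' rejecting spurious anchors.
#'
#' @param match positive integer match reward.
#' @param mismatch non-negative integer mismatch penalty.
#' @param gap_open non-negative integer gap-opening penalty.
#' @param gap_extend non-negative integer per-base gap-extension penalty.
#' @param min_score_fraction fraction in (0, 1] of the perfect-match score
#'   required to accept a flank anchor.
#' @return An object of class `alignment_scoring`.
#' @export
#' @examples
#' alignment_scoring()
alignment_scoring <- function(match = 1L, mismatch = 1L, gap_open = 2L,
                              gap_extend = 1L, min_score_fraction = 0.8) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  stopifnot(match > 0, mismatch >= 0, gap_open >= 0, gap_extend >= 0,
            is.numeric(min_score_fraction), length(min_score_fraction) == 1,
            min_score_fraction > 0, min_score_fraction <= 1)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend,
                 min_score_fraction = min_score_fraction),
            class = "alignment_scoring")
}

valid_dna <- function(x) grepl("^[ACGTNacgtn]+$", x)

#' Define a microsatellite locus
#'
#' A locus is identified in reads purely by its 5' and 3' flanking sequences,
#' given on the same strand in `flank5 -> repeat -> flank3` order. The repeat
#' itself is described only by its repeated base: the extraction step
#' measures the full inter-flank span, so the definition is robust to
#' sequencing errors inside the repeat.
#'
#' @param name locus identifier (e.g. "BAT-26"), unique within a panel.
#' @param repeat_base the repeated nucleotide, one of A/C/G/T.
#' @param flank5,flank3 flanking sequences (ACGTN, at least 10 nt each);
#'   neither may itself be a run of `repeat_base`.
#' @param min_flank_identity optional per-locus override of the scoring's
#'   `min_score_fraction` (fraction in (0, 1]).
#' @param sw_scoring an [alignment_scoring()] object.
#' @param stable_length optional expected stable-allele repeat length in nt;
#'   metadata used by the simulator, ignored by the caller itself.
#' @return An object of class `msat_locus`.
#' @export
#' @examples
#' loc <- msat_locus("BAT-26", "A",
#'                   flank5 = "CTGCGAGAAGGTACTCACCC",
#'                   flank3 = "GGGTTGCAGCAATTCACTGT")
msat_locus <- function(name, repeat_base, flank5, flank3,
                       min_flank_identity = NULL,
                       sw_scoring = alignment_scoring(),
                       stable_length = NA_integer_) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  repeat_base <- toupper(repeat_base)
  stopifnot(repeat_base %in% c("A", "C", "G", "T"))
  flank5 <- toupper(flank5); flank3 <- toupper(flank3)
  stopifnot(valid_dna(flank5), valid_dna(flank3),
            nchar(flank5) >= 10, nchar(flank3) >= 10)
  only <- function(s) all(strsplit(s, "")[[1]] == repeat_base)
  if (only(flank5) || only(flank3))
    stop("a flank of '", name, "' is itself a run of the repeat base")
  if (!is.null(min_flank_identity))
    stopifnot(min_flank_identity > 0, min_flank_identity <= 1)
  stopifnot(inherits(sw_scoring, "alignment_scoring"))
  structure(list(name = name, repeat_base = repeat_base,
                 flank5 = flank5, flank3 = flank3,
                 min_flank_identity = min_flank_identity,
                 sw_scoring = sw_scoring,
                 stable_length = as.integer(stable_length)),
            class = "msat_locus")
}

#' @export
print.msat_locus <- function(x, ...) {
  cat(sprintf("<msat_locus> %s  poly-%s\n  flank5: %s\n  flank3: %s\n",
              x$name, x$repeat_base, x$flank5, x$flank3))
  invisible(x)
}

#' Homopolymer retention rule for trimmed inter-flank sequences
#'
#' After trimming a read to its inter-flank span, the span is retained only
#' if it actually contains a homopolymeric stretch of the locus repeat base:
#' the longest run of the repeat base must reach `min_run` nucleotides AND
#' the repeat base must make up at least `min_content` of the trimmed
#' sequence. This excludes chimeric or mispriming artefacts while tolerating
#' isolated sequencing errors inside the repeat.
#'
#' @param min_run minimum run length of the repeat base (nt).
#' @param min_content minimum fraction of the trimmed sequence made of the
#'   repeat base.
#' @return An object of class `homopolymer_rule`.
#' @export
homopolymer_rule <- function(min_run = 8L, min_content = 0.8) {
  stopifnot(min_run >= 1, min_content >= 0, min_content <= 1)
  structure(list(min_run = as.integer(min_run), min_content = min_content),
            class = "homopolymer_rule")
}

#' Read or write a locus panel definition file
#'
#' Plain tab-separated text with columns `name`, `repeat_base`, `flank5`,
#' `flank3` and optionally `stable_length` plus scoring overrides (`match`,
#' `mismatch`, `gap_open`, `gap_extend`, `min_score_fraction`).
#'
#' @param path file path.
#' @param panel for `write_panel`, a list of [msat_locus()] objects.
#' @return `read_panel` returns a named list of `msat_locus` objects.
#' @export
read_panel <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "repeat_base", "flank5", "flank3")
  if (!all(need %in% names(df)))
    stop("panel file must have columns: ", paste(need, collapse = ", "))
  loci <- lapply(seq_len(nrow(df)), function(i) {
    sc <- alignment_scoring(
      match = if ("match" %in% names(df)) df$match[i] else 1L,
      mismatch = if ("mismatch" %in% names(df)) df$mismatch[i] else 1L,
      gap_open = if ("gap_open" %in% names(df)) df$gap_open[i] else 2L,
      gap_extend = if ("gap_extend" %in% names(df)) df$gap_extend[i] else 1L,
      min_score_fraction = if ("min_score_fraction" %in% names(df))
        df$min_score_fraction[i] else 0.8)
    msat_locus(df$name[i], df$repeat_base[i], df$flank5[i], df$flank3[i],
               sw_scoring = sc,
               stable_length = if ("stable_length" %in% names(df))
                 df$stable_length[i] else NA_integer_)
  })
  if (anyDuplicated(df$name)) stop("duplicate locus names in panel")
  setNames(loci, df$name)
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  df <- do.call(rbind, lapply(panel, function(l) {
    data.frame(name = l$name, repeat_base = l$repeat_base,
               flank5 = l$flank5, flank3 = l$flank3,
               stable_length = l$stable_length,
               match = l$sw_scoring$match, mismatch = l$sw_scoring$mismatch,
               gap_open = l$sw_scoring$gap_open,
               gap_extend = l$sw_scoring$gap_extend,
               min_score_fraction = l$sw_scoring$min_score_fraction)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
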