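#' Read FASTQ mates as plain sequences
#'
#' Loads one or two (R1/R2) FASTQ files, optionally gzip-compressed, and
#' returns the read sequences as an upper-case character vector. Base
#' qualities are deliberately ignored: the caller works on unfiltered
#' reads. Each 4-line record is structurally validated; a malformed record
#' raises a classed error (`memsi_fastq_error`) naming the record index.
#'
#' @param r1 path to the R1 FASTQ (or a single interleaved/unpaired FASTQ).
#' @param r2 optional path to the R2 FASTQ.
#' @return Character vector of mate sequences (R1 mates then R2 mates).
#' @export
read_fastq_mates <- function(r1, r2 = NULL) {
  out <- .read_one_fastq(r1)
  if (!is.null(r2)) out <- c(out, .read_one_fastq(r2))
  out
}

.fastq_error <- function(path, record) {
  stop(errorCondition(
    sprintf("malformed FASTQ record %d in '%s'", record, path),
    class = "memsi_fastq_error"))
}

.read_one_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path, warn = FALSE)   # transparently gunzips
  if (!length(lines)) return(character(0))
  if (length(lines) %% 4 != 0) .fastq_error(path, length(lines) %/% 4 + 1)
  hdr <- lines[seq(1, length(lines), 4)]
  seqs <- toupper(lines[seq(2, length(lines), 4)])
  plus <- lines[seq(3, length(lines), 4)]
  qual <- lines[seq(4, length(lines), 4)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seqs) != nchar(qual) |
                 !grepl("^[ACGTNRYSWKMBDHV]*$", seqs))
  if (length(bad)) .fastq_error(path, bad[1])
  seqs
}
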