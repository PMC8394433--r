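loc <- msat_locus("BAT-26x", "A",
                  flank5 = "CTGCGAGAAGGTACTCACCC",
                  flank3 = "GGGTTGCAGCAATTCACTGT")

test_that("exact flanks are anchored and the inter-flank span measured", {
  rd <- paste0(loc$flank5, strrep("A", 26), loc$flank3)
  sp <- find_flanks(rd, loc)
  expect_equal(unname(sp["end"] - sp["start"]), 26)
  expect_identical(attr(sp, "strand"), "+")
  expect_equal(extract_length(rd, loc), 26)

  # a single identified flank is never enough
  expect_null(find_flanks(paste0(loc$flank5, strrep("A", 26)), loc))
  expect_null(find_flanks(strrep("C", 80), loc))

  # strand symmetry: the reverse complement yields the same span length
  rc <- memsi:::.revcomp(paste0(loc$flank5, strrep("A", 20), loc$flank3))
  sp <- find_flanks(rc, loc)
  expect_equal(unname(sp["end"] - sp["start"]), 20)
  expect_identical(attr(sp, "strand"), "-")

  # degenerate span (adjacent flanks) and non-homopolymeric spans excluded
  expect_null(extract_length(paste0(loc$flank5, loc$flank3), loc))
  expect_null(extract_length(
    paste0(loc$flank5, strrep("ACGT", 5), loc$flank3), loc))
  # flanks found but homopolymer rule fails -> find_flanks still reports span
  expect_equal(
    unname(find_flanks(paste0(loc$flank5, strrep("ACGT", 5), loc$flank3),
                       loc)["end"]), 40)
})

test_that("anchoring accepts or rejects mutated flanks exactly as SW does", {
  skip_if_not_installed("Biostrings")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  set.seed(71)
  for (i in 1:25) {
    fl <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
    ctx <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    flm <- strsplit(fl, "")[[1]]
    nmut <- sample(0:4, 1)
    if (nmut > 0) flm[sample(20, nmut)] <- sample(c("A", "C", "G", "T"),
                                                  nmut, TRUE)
    rd <- paste0(substr(ctx, 1, 50), paste(flm, collapse = ""),
                 substr(ctx, 51, 120))
    mine <- memsi:::.sw_batch(rd, fl, 1L, 1L, 2L, 1L)
    ora <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(fl), Biostrings::DNAString(rd), type = "local",
      substitutionMatrix = mat, gapOpening = 2, gapExtension = 1)
    expect_equal(mine$score, Biostrings::score(ora))
  }
  # one substitution in a 20-nt flank still anchors at min_score_fraction 0.8
  flm <- strsplit(loc$flank5, "")[[1]]
  flm[10] <- setdiff(c("A", "C", "G", "T"), flm[10])[1]
  rd <- paste0(paste(flm, collapse = ""), strrep("A", 26), loc$flank3)
  expect_equal(extract_length(rd, loc), 26)
  # five substitutions (score 10 < 16) do not
  flm <- strsplit(loc$flank5, "")[[1]]
  orig <- flm[seq(2, 10, 2)]
  flm[seq(2, 10, 2)] <- vapply(orig, function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], "")
  rd <- paste0(paste(flm, collapse = ""), strrep("A", 26), loc$flank3)
  expect_null(find_flanks(rd, loc))
})

test_that("reverse complement helper matches Biostrings", {
  skip_if_not_installed("Biostrings")
  set.seed(5)
  seqs <- vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), 40, TRUE), collapse = ""), "")
  expect_identical(
    memsi:::.revcomp(seqs),
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs))))
})

test_that("histograms count both mates, ignore order, skip non-anchored reads", {
  reads <- rep(paste0(loc$flank5, strrep("A", 26), loc$flank3), 100)
  h <- build_histogram(reads, loc)
  expect_equal(unclass(h$counts), c("26" = 100L))
  expect_equal(h$n_reads, 100L)

  set.seed(3)
  mixed <- c(reads,
             vapply(1:50, function(i)
               paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = ""),
               ""))
  h1 <- build_histogram(mixed, loc)
  h2 <- build_histogram(sample(mixed), loc)
  expect_identical(h1$counts, h2$counts)
  expect_lte(h1$n_reads, length(mixed))
})

test_that("simulator round trip: noiseless reads are recovered exactly", {
  panel <- synthetic_panel()
  bat26 <- panel[["BAT-26"]]
  dir <- tempdir()
  spec <- simulated_locus_spec(bat26, msi_alleles(26, 0), stutter_sd = 0,
                               depth = 300L, seed = 9L)
  r1 <- file.path(dir, "rt_R1.fastq.gz")
  r2 <- file.path(dir, "rt_R2.fastq.gz")
  truth <- simulate_fastq(spec, r1, r2)
  h <- build_histogram_fastq(r1, r2, bat26)
  # both mates of each of the 300 pairs contribute
  expect_equal(unclass(h$counts), c("26" = 600L))
  expect_equal(nrow(truth), 300L)
})

test_that("mixture fractions propagate through extraction (binomial bound)", {
  panel <- synthetic_panel()
  bat26 <- panel[["BAT-26"]]
  dir <- tempdir()
  spec <- simulated_locus_spec(
    bat26, data.frame(length = c(26L, 21L), fraction = c(0.7, 0.3)),
    stutter_sd = 0, depth = 5000L, seed = 13L)
  r1 <- file.path(dir, "mx_R1.fastq.gz")
  r2 <- file.path(dir, "mx_R2.fastq.gz")
  simulate_fastq(spec, r1, r2)
  h <- build_histogram_fastq(r1, r2, bat26)
  expect_equal(h$n_reads, 10000L)
  frac21 <- h$counts[["21"]] / h$n_reads
  se <- sqrt(0.3 * 0.7 / 5000)  # pairs are the independent unit
  expect_lt(abs(frac21 - 0.3), 3 * se)
})

test_that("the exact-seed screen is equivalent to the exhaustive SW path", {
  panel <- synthetic_panel()
  dir <- tempdir()
  specs <- lapply(panel[c("BAT-26", "NR-21")], function(l)
    simulated_locus_spec(l, msi_alleles(l$stable_length, 0.2), stutter_sd = 1,
                         depth = 150L, seed = 21L))
  r1 <- file.path(dir, "sc_R1.fastq.gz")
  r2 <- file.path(dir, "sc_R2.fastq.gz")
  simulate_sample_fastq(specs, r1, r2)
  mates <- read_fastq_mates(r1, r2)
  for (l in panel[c("BAT-26", "NR-21")]) {
    h_screen <- build_histogram(mates, l, seed_len = 8L)
    h_full <- build_histogram(mates, l, seed_len = 0L)
    expect_identical(h_screen$counts, h_full$counts)
  }
})

test_that("malformed FASTQ records are reported by index", {
  path <- file.path(tempdir(), "bad.fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII",
               "@r2", "ACGT", "+", "III"), path)   # quality too short
  expect_error(read_fastq_mates(path), "record 2", class = "memsi_fastq_error")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), path)
  expect_error(read_fastq_mates(path), class = "memsi_fastq_error")
  expect_error(read_fastq_mates(file.path(tempdir(), "nope.fastq")),
               "not found")
})
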