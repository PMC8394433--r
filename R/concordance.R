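#' Build a 2x2 contingency table
#'
#' Rows are the evaluated method's categories, columns the comparator's
#' (gold standard), in (positive, negative) order:
#' `a` = both positive, `b` = row-positive only, `c` = column-positive
#' only, `d` = both negative.
#'
#' @param a,b,c,d non-negative integer cell counts (total >= 1).
#' @return A 2x2 integer matrix with informative dimnames.
#' @export
#' @examples
#' contingency_2x2(28, 0, 0, 118)
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == round(cells)), sum(cells) >= 1)
  matrix(as.integer(cells), nrow = 2, byrow = TRUE,
         dimnames = list(method = c("positive", "negative"),
                         comparator = c("positive", "negative")))
}

.as_table2 <- function(t) {
  if (is.matrix(t)) {
    stopifnot(all(dim(t) == c(2, 2)), all(t >= 0), sum(t) >= 1)
    return(t)
  }
  stop("expected a 2x2 matrix (see contingency_2x2)")
}

#' Cohen's kappa for a 2x2 table
#'
#' Chance-corrected agreement `(Po - Pe) / (1 - Pe)`, where `Po` is the
#' observed diagonal fraction and `Pe` the chance agreement expected from
#' the marginals. The degenerate table with all mass in one cell has
#' `Pe = 1` and is defined as perfect agreement (kappa = 1).
#'
#' @param t a 2x2 matrix (see [contingency_2x2()]).
#' @return Kappa in `[-1, 1]`.
#' @export
#' @examples
#' cohen_kappa(contingency_2x2(26, 0, 3, 104))  # 0.931
cohen_kappa <- function(t) {
  t <- .as_table2(t)
  n <- sum(t)
  po <- (t[1, 1] + t[2, 2]) / n
  pe <- (sum(t[1, ]) * sum(t[, 1]) + sum(t[2, ]) * sum(t[, 2])) / n^2
  if (abs(1 - pe) < 1e-12) return(1)
  (po - pe) / (1 - pe)
}

#' Diagnostic performance of a 2x2 table (gold standard on columns)
#'
#' Sensitivity `a/(a+c)`, specificity `d/(b+d)`, positive and negative
#' predictive values `a/(a+b)` and `d/(c+d)`, and prevalence `(a+c)/n`,
#' all as percentages. A metric whose margin is zero is reported `NA`
#' (absent), not 0.
#'
#' @param t a 2x2 matrix (see [contingency_2x2()]).
#' @return Named numeric vector (percent): `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `prevalence`.
#' @export
diagnostic_metrics <- function(t) {
  t <- .as_table2(t)
  a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
  n <- a + b + c + d
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  c(sensitivity = pct(a, a + c), specificity = pct(d, b + d),
    ppv = pct(a, a + b), npv = pct(d, c + d),
    prevalence = pct(a + c, n))
}

# One flat row per (sample, locus) for reporting.
.sample_call_rows <- function(sc) {
  do.call(rbind, lapply(sc$calls, function(cl) {
    up <- sum(cl$unstable_components$proportion)
    sh <- if (nrow(cl$unstable_components))
      cl$unstable_components$mean_shift[
        which.max(cl$unstable_components$proportion)]
    else NA_real_
    data.frame(sample = sc$sample, sample_status = sc$status,
               locus = cl$locus, status = cl$status, n_reads = cl$n_reads,
               unstable_proportion = if (cl$status == "unstable") up
               else NA_real_,
               mean_shift = sh, lrt_p = cl$lrt_p, power = cl$power,
               suspected_polymorphism = cl$suspected_polymorphism)
  }))
}

#' Render a deterministic calling report
#'
#' One TSV row per (sample, locus) with the sample verdict, per-locus
#' status, read count, quantified unstable proportion and mean shift, LRT
#' p-value, power where computed and the polymorphism flag. Header comments
#' record the package version and the thresholds/seed in force. Optional
#' concordance tables are appended as comment lines (kappa to 3 d.p.,
#' percentages to 1 d.p.). Output is byte-identical for identical inputs.
#'
#' @param sample_calls list of `msat_sample_call` objects (may be empty).
#' @param tables optional named list of 2x2 matrices to summarise.
#' @param config the [classification_config()] used (recorded in the
#'   header).
#' @param path optional file to write.
#' @return Character vector of report lines, invisibly when `path` is
#'   given.
#' @export
render_report <- function(sample_calls, tables = NULL, config = NULL,
                          path = NULL) {
  hdr <- c(sprintf("# memsi %s call report",
                   as.character(packageVersion("memsi"))))
  if (!is.null(config))
    hdr <- c(hdr, sprintf(
      "# thresholds: stable_band=±%.0f%% min_unstable=%.0f%% alpha=%g power>%.0f%% seed=%d",
      100 * config$stable_mean_tolerance,
      100 * config$min_unstable_proportion, config$lrt_alpha,
      100 * config$power_threshold, config$seed))
  cols <- c("sample", "sample_status", "locus", "status", "n_reads",
            "unstable_proportion", "mean_shift", "lrt_p", "power",
            "suspected_polymorphism")
  body <- character(0)
  if (length(sample_calls)) {
    df <- do.call(rbind, lapply(sample_calls, .sample_call_rows))
    fmt <- function(x, f) ifelse(is.na(x), "NA", sprintf(f, x))
    body <- paste(df$sample, df$sample_status, df$locus, df$status,
                  df$n_reads, fmt(df$unstable_proportion, "%.4f"),
                  fmt(df$mean_shift, "%.2f"), fmt(df$lrt_p, "%.3g"),
                  fmt(df$power, "%.3f"), df$suspected_polymorphism,
                  sep = "\t")
  }
  tab_lines <- character(0)
  if (!is.null(tables)) {
    for (nm in names(tables)) {
      t <- .as_table2(tables[[nm]])
      m <- diagnostic_metrics(t)
      fmt1 <- function(x) ifelse(is.na(x), "NA", sprintf("%.1f", x))
      tab_lines <- c(tab_lines, sprintf(
        "# %s: n=%d kappa=%.3f sens=%s%% spec=%s%% ppv=%s%% npv=%s%% prev=%s%%",
        nm, sum(t), cohen_kappa(t), fmt1(m["sensitivity"]),
        fmt1(m["specificity"]), fmt1(m["ppv"]), fmt1(m["npv"]),
        fmt1(m["prevalence"])))
    }
  }
  lines <- c(hdr, tab_lines, paste(cols, collapse = "\t"), body)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
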