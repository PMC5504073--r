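#' Two-sided Fisher's exact test p-value
#'
#' Exact two-sided p for a 2x2 table `[[a, b], [c, d]]` by the probability
#' method (sum of hypergeometric probabilities not exceeding that of the
#' observed table), computed through [stats::fisher.test()]. An all-zero
#' table is defined to give p = 1.
#'
#' @param a,b,c,d Non-negative integer cell counts (row 1 = `a b`,
#'   row 2 = `c d`).
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (a + b + c + d == 0) return(1)
  stats::fisher.test(matrix(c(a, b, c, d), 2L, 2L, byrow = TRUE))$p.value
}

#' Odds ratio of a 2x2 table
#'
#' Either the conditional maximum-likelihood estimate under the noncentral
#' hypergeometric distribution (the value reported alongside Fisher's exact
#' test, via [stats::fisher.test()]) or the sample estimate `(a*d)/(b*c)`.
#' Degenerate margins (an empty row or column) give `NA`; `a*d > 0` with
#' `b*c == 0` gives `+Inf`.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param estimator `"cmle"` (default) or `"sample"`.
#' @return The odds ratio (possibly `Inf` or `NA`).
#' @export
odds_ratio <- function(a, b, c, d, estimator = c("cmle", "sample")) {
  estimator <- match.arg(estimator)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0)
    return(NA_real_)
  if (estimator == "sample") {
    if (b * c == 0 && a * d == 0) return(NA_real_)
    return((a * d) / (b * c))
  }
  unname(stats::fisher.test(matrix(c(a, b, c, d), 2L, 2L,
                                   byrow = TRUE))$estimate)
}

#' Multiple-testing corrected q-values
#'
#' Storey-style q-values with the fixed-lambda estimator of the null
#' proportion, `pi0 = min(1, mean(p > lambda) / (1 - lambda))`, then the
#' step-up `q_i = min over p_j >= p_i of pi0 * m * p_j / rank_j`; or
#' Benjamini-Hochberg (`pi0 = 1`) via [stats::p.adjust()]. Storey's
#' estimator is unstable for few tests, so callers testing under ~50
#' families typically use `"bh"`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param method `"storey"` or `"bh"`.
#' @param lambda Tuning parameter of the pi0 estimator (default 0.5).
#' @param pi0 Optional override of the estimated null proportion.
#' @return Vector of q-values, a monotone transform of `pvals`.
#' @export
qvalues <- function(pvals, method = c("storey", "bh"), lambda = 0.5,
                    pi0 = NULL) {
  method <- match.arg(method)
  if (length(pvals) == 0L) return(numeric(0))
  stopifnot(all(pvals >= 0 & pvals <= 1))
  if (method == "bh") return(stats::p.adjust(pvals, method = "BH"))
  if (is.null(pi0))
    pi0 <- min(1, mean(pvals > lambda) / (1 - lambda))
  if (pi0 <= 0) pi0 <- 1 / length(pvals)   # guard: all p small
  pi0 * stats::p.adjust(pvals, method = "BH")
}

#' One row of the repeat-association table
#'
#' Builds the 2x2 table `[[a, n_peaks - a], [c, n_controls - c]]` comparing
#' how often a repeat family's copies are touched by peak summit windows
#' versus by sampled control regions, and computes the exact test and the
#' odds ratio. This is the per-family statistic of the repeat-association
#' analysis.
#'
#' @param a Family copies overlapping >= 1 peak window.
#' @param c Family copies overlapping >= 1 control region.
#' @param n_peaks Total peak windows.
#' @param n_controls Total control regions.
#' @param or_estimator Passed to [odds_ratio()].
#' @return List with `odds_ratio` and `p`.
#' @export
contingency_row <- function(a, c, n_peaks, n_controls,
                            or_estimator = "cmle") {
  b <- n_peaks - a; d <- n_controls - c
  if (a + c == 0)
    return(list(odds_ratio = NA_real_, p = 1))
  list(odds_ratio = odds_ratio(a, b, c, d, estimator = or_estimator),
       p = fisher_exact(a, b, c, d))
}

#' Repeat-family association with CTCF binding
#'
#' The full association pipeline: consensus peaks with merged-run fold
#' enrichment >= `fe_min` are reduced to summit +/- `flank` windows;
#' `n_controls` non-overlapping N-free control regions of `control_length`
#' bp are sampled from the genome; for every repeat family the number of
#' copies touched by peak windows (`n_peak`) and by control regions
#' (`n_control`) enters a 2x2 exact test with conditional-MLE odds ratio;
#' p-values are corrected to q-values across families. A family is called
#' significantly peak-associated when `q < 1e-10` and odds ratio `> 10`.
#'
#' @param consensus Consensus peak `GRanges`.
#' @param repeats Repeat `GRanges` (see [read_repeat_annotation()]).
#' @param genome `DNAStringSet` genome.
#' @param fe_min Fold-enrichment filter (default 5).
#' @param flank Summit-window half-width (default 50).
#' @param n_controls Number of control regions (default 50000; scale to the
#'   genome at hand).
#' @param control_length Control-region length in bp (default 100).
#' @param qvalue_method `"storey"`, `"bh"`, or `"auto"` (Storey when >= 50
#'   families, BH otherwise).
#' @param or_estimator `"cmle"` (default) or `"sample"`.
#' @param seed RNG seed for control sampling.
#' @return A data.frame sorted by decreasing odds ratio with columns
#'   `family_id`, `class_label`, `n_genome`, `n_peak`, `n_control`,
#'   `odds_ratio`, `p`, `q`, `significant`; attributes `n_peaks`,
#'   `n_controls`, `seed`.
#' @export
enrichment_analysis <- function(consensus, repeats, genome, fe_min = 5,
                                flank = 50L, n_controls = 50000L,
                                control_length = 100L,
                                qvalue_method = c("auto", "storey", "bh"),
                                or_estimator = c("cmle", "sample"),
                                seed = 1L) {
  qvalue_method <- match.arg(qvalue_method)
  or_estimator <- match.arg(or_estimator)
  sel <- consensus[consensus$signalValue >= fe_min]
  windows <- summit_windows(sel, flank, seqlengths = genome)
  controls <- sample_control_regions(genome, n_controls,
                                     length = control_length, seed = seed)
  a <- count_family_overlaps(windows, repeats)
  cc <- count_family_overlaps(controls, repeats)
  fam <- names(a)
  info <- unique(data.frame(
    family_id = repeats$family_id, class_label = repeats$class_label,
    stringsAsFactors = FALSE))
  n_genome <- table(factor(repeats$family_id, levels = fam))
  n_peaks <- length(windows)
  rows <- lapply(fam, function(f)
    contingency_row(a[[f]], cc[[f]], n_peaks, n_controls,
                    or_estimator = or_estimator))
  p <- vapply(rows, `[[`, numeric(1), "p")
  or <- vapply(rows, `[[`, numeric(1), "odds_ratio")
  m <- if (qvalue_method == "auto") {
    if (length(p) >= 50L) "storey" else "bh"
  } else qvalue_method
  q <- qvalues(p, method = m)
  out <- data.frame(
    family_id = fam,
    class_label = info$class_label[match(fam, info$family_id)],
    n_genome = as.integer(n_genome[fam]),
    n_peak = as.integer(a[fam]),
    n_control = as.integer(cc[fam]),
    odds_ratio = or, p = p, q = q,
    significant = !is.na(or) & q < 1e-10 & or > 10,
    stringsAsFactors = FALSE)
  out <- out[order(-out$odds_ratio, out$family_id, na.last = TRUE), ]
  rownames(out) <- NULL
  attr(out, "n_peaks") <- n_peaks
  attr(out, "n_controls") <- as.integer(n_controls)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "qvalue_method") <- m
  out
}

#' Write a repeat-association report
#'
#' TSV mirroring the association table's columns plus run metadata in
#' `#`-prefixed header lines.
#'
#' @param result An [enrichment_analysis()] data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_report <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# n_peaks=", attr(result, "n_peaks")),
    paste0("# n_controls=", attr(result, "n_controls")),
    paste0("# seed=", attr(result, "seed")),
    paste0("# qvalue_method=", attr(result, "qvalue_method"))), con)
  utils::write.table(result, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
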