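## Base coding used throughout the motif machinery: A=1, C=2, G=3, T=4, N=5.
## Complement of code b is 5-b; code 5 (N) scores NA so any window touching
## an N (or a sequence boundary in concatenated scans) drops out.
BASES <- c("A", "C", "G", "T")

encode_dna <- function(s) {
  code <- rep(5L, 256L)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  code[utf8ToInt("a")] <- 1L; code[utf8ToInt("c")] <- 2L
  code[utf8ToInt("g")] <- 3L; code[utf8ToInt("t")] <- 4L
  lapply(as.character(s), function(x) code[utf8ToInt(x)])
}

decode_dna <- function(codes) paste(c(BASES, "N")[codes], collapse = "")

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

## Concatenate coded sequences with `sep` N's between them so that windows
## never straddle two sequences. Returns codes plus the offset (0-based) at
## which each sequence begins in the concatenation.
concat_codes <- function(codes, sep) {
  n <- length(codes)
  lens <- lengths(codes)
  offsets <- cumsum(c(0L, head(lens + sep, -1L)))
  out <- rep(5L, sum(lens) + sep * (n - 1L) + sep)
  for (i in seq_len(n)) out[offsets[i] + seq_len(lens[i])] <- codes[[i]]
  list(codes = out[seq_len(sum(lens) + sep * max(n - 1L, 0L))],
       offsets = offsets, lens = lens)
}

## Sum of per-column lookups over every length-w window of `codes`:
## score[i] = sum_j mat[codes[i+j-1], j], with mat a 5 x w matrix whose N row
## is NA. w vectorised adds over the full concatenation.
window_sums <- function(codes, mat) {
  w <- ncol(mat)
  P <- length(codes) - w + 1L
  if (P < 1L) return(numeric(0))
  sc <- mat[codes[seq_len(P)], 1L]
  for (j in seq_len(w)[-1L])
    sc <- sc + mat[codes[j:(j + P - 1L)], j]
  sc
}

#' Construct a position weight matrix
#'
#' The PWM is the package's motif representation: a 4 x width matrix of
#' per-position base probabilities (rows A, C, G, T), together with the
#' pseudocount used in its estimation, the consensus string (most probable
#' base per column) and the per-column information content in bits (relative
#' to a uniform background).
#'
#' @param probs 4 x width numeric matrix of column-stochastic probabilities
#'   (rows in A, C, G, T order).
#' @param pseudo Pseudocount recorded for provenance (default 0.01).
#' @return An object of class `"pwm"`.
#' @export
new_pwm <- function(probs, pseudo = 0.01) {
  stopifnot(is.matrix(probs), nrow(probs) == 4L, ncol(probs) >= 1L)
  if (any(abs(colSums(probs) - 1) > 1e-9))
    stop("PWM columns must sum to 1")
  if (any(probs <= 0))
    stop("PWM entries must be > 0 (apply a pseudocount)")
  rownames(probs) <- BASES
  ic <- 2 + colSums(probs * log2(probs))
  structure(list(probs = probs, width = ncol(probs), pseudo = pseudo,
                 consensus = paste(BASES[apply(probs, 2L, which.max)],
                                   collapse = ""),
                 ic = ic),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM width", x$width, " consensus", x$consensus,
      sprintf(" (%.2f bits total)\n", sum(x$ic)))
  invisible(x)
}

#' PWM from base counts
#'
#' @param counts 4 x width matrix of (possibly fractional) base counts.
#' @param pseudo Pseudocount added to every cell before normalising.
#' @return A [new_pwm()] object.
#' @export
pwm_from_counts <- function(counts, pseudo = 0.01) {
  counts <- counts + pseudo
  new_pwm(sweep(counts, 2L, colSums(counts), "/"), pseudo = pseudo)
}

#' PWM from a consensus word
#'
#' Assigns probability `match` to the consensus base and `(1-match)/3` to the
#' others — the standard seed for EM restarts and for planted-motif truth.
#'
#' @param word Consensus string over ACGT.
#' @param match Probability of the consensus base (default 0.7).
#' @return A [new_pwm()] object.
#' @export
pwm_from_consensus <- function(word, match = 0.7) {
  codes <- encode_dna(word)[[1]]
  stopifnot(all(codes <= 4L))
  probs <- matrix((1 - match) / 3, 4L, length(codes))
  probs[cbind(codes, seq_along(codes))] <- match
  new_pwm(probs, pseudo = 0)
}

#' Reverse complement of a PWM
#' @param pwm A [new_pwm()] object.
#' @return The reverse-complement PWM.
#' @export
pwm_revcomp <- function(pwm) {
  new_pwm(pwm$probs[4:1, pwm$width:1, drop = FALSE], pseudo = pwm$pseudo)
}

#' Serialise / read a PWM in MEME minimal motif format
#'
#' @param pwm A [new_pwm()] object.
#' @param path Output path.
#' @param name Motif name.
#' @param background0 Optional order-0 background written on the
#'   `Background letter frequencies` line (uniform if omitted).
#' @return `path` invisibly, or for the reader a [new_pwm()] object.
#' @export
write_meme <- function(pwm, path, name = "MOTIF1", background0 = NULL) {
  bg <- if (is.null(background0)) rep(0.25, 4) else background0$p0
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
             "Background letter frequencies",
             paste(sprintf("%s %.6f", BASES, bg), collapse = " "), "",
             paste("MOTIF", name),
             sprintf("letter-probability matrix: alength= 4 w= %d", pwm$width),
             apply(pwm$probs, 2L, function(col)
               paste(sprintf("%.6f", col), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_meme
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  i <- grep("^letter-probability matrix", lines)[1L]
  if (is.na(i)) stop("MEME format error: no letter-probability matrix in '", path, "'")
  w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[i]))
  rows <- lines[(i + 1L):(i + w)]
  probs <- t(vapply(strsplit(trimws(rows), "\\s+"),
                    function(f) as.numeric(f[1:4]), numeric(4L)))
  new_pwm(t(probs) / rep(colSums(t(probs)), each = 4L), pseudo = 0.01)
}

#' Train a Markov background model on sequences
#'
#' Estimates an order-0 or order-1 Markov model of the genomic background
#' from training sequences (for peak-motif work: an order-1 model on the
#' top-2,000 peak windows with pseudocount 0.01). Counts are taken over
#' consecutive non-N positions, by default on both strands so the model is
#' reverse-complement symmetric; the pseudocount is added to every (context,
#' base) cell before normalising.
#'
#' @param seqs Character vector or `DNAStringSet` of training sequences.
#' @param order 0 or 1.
#' @param pseudo Pseudocount (default 0.01).
#' @param both_strands Count reverse complements too (default TRUE).
#' @return An object of class `"markov_bg"` with elements `order`, `p0`
#'   (marginal base probabilities), `trans` (4 x 4 row-stochastic transition
#'   matrix, `NULL` for order 0), `pseudo`, `source`.
#' @export
train_markov_background <- function(seqs, order = 1L, pseudo = 0.01,
                                    both_strands = TRUE) {
  stopifnot(order %in% c(0L, 1L))
  seqs <- as.character(seqs)
  if (length(seqs) == 0L || sum(nchar(seqs)) == 0L)
    stop("cannot train background on empty input")
  if (both_strands) seqs <- c(seqs, revcomp(seqs))
  codes <- encode_dna(seqs)
  cc <- concat_codes(codes, sep = 1L)$codes
  valid <- cc <= 4L
  base_counts <- tabulate(cc[valid], nbins = 4L)
  p0 <- (base_counts + pseudo) / sum(base_counts + pseudo)
  names(p0) <- BASES
  trans <- NULL
  if (order == 1L) {
    a <- cc[-length(cc)]; b <- cc[-1L]
    ok <- a <= 4L & b <= 4L
    tc <- matrix(tabulate((a[ok] - 1L) * 4L + b[ok], nbins = 16L),
                 4L, 4L, byrow = TRUE, dimnames = list(BASES, BASES))
    tc <- tc + pseudo
    if (sum(ok) < 1L)
      stop("too little sequence to train an order-", order, " background")
    if (pseudo == 0 && any(rowSums(tc) == 0))
      tc[rowSums(tc) == 0, ] <- 1   # unseen context: fall back to uniform
    trans <- tc / rowSums(tc)
  }
  structure(list(order = order, p0 = p0, trans = trans, pseudo = pseudo,
                 source = paste(length(seqs), "sequences")),
            class = "markov_bg")
}

#' Order-0 marginal of a Markov background
#'
#' PWM p-values are computed against an order-0 model; this extracts the
#' marginal base distribution from an order-1 (or order-0) background.
#'
#' @param bg A `"markov_bg"` object.
#' @return An order-0 `"markov_bg"`.
#' @export
background_order0 <- function(bg) {
  stopifnot(is(bg, "markov_bg"))
  structure(list(order = 0L, p0 = bg$p0, trans = NULL, pseudo = bg$pseudo,
                 source = bg$source),
            class = "markov_bg")
}

## log-probability of every length-w window of a coded concatenation under an
## order-1 background: log p0(first base) + sum of transition logs. Windows
## touching an N are left to the caller's NA mask (their PWM score is NA).
window_bg_logprob <- function(codes, w, bg) {
  lp0 <- log(bg$p0)[pmin(codes, 4L)]
  P <- length(codes) - w + 1L
  if (bg$order == 0L) {
    cs <- cumsum(lp0)
    return(cs[w:length(codes)] - c(0, cs)[seq_len(P)])
  }
  lt <- log(bg$trans)
  a <- codes[-length(codes)]; b <- codes[-1L]
  tl <- lt[cbind(pmin(a, 4L), pmin(b, 4L))]
  tl[a > 4L | b > 4L] <- 0
  cs <- c(0, cumsum(tl))
  ## window [i, i+w): first-base marginal + transitions i .. i+w-2
  lp0[seq_len(P)] + cs[(seq_len(P)) + w - 1L] - cs[seq_len(P)]
}

#' Exact PWM score-to-p-value table by dynamic programming
#'
#' Computes, for a PWM under an order-0 background, the exact null
#' distribution of the log-odds score of a random width-w sequence, by
#' discretising column scores to a common integer grid (rounding down, so
#' reported p-values are conservative) and convolving column by column. The
#' same integerised matrix drives scanning, so scanner scores and p-values
#' are exactly consistent: `p(s)` is the probability that a random background
#' word attains integer score `>= s`.
#'
#' @param pwm A [new_pwm()] object, or a raw 4 x w log-odds score matrix
#'   (rows A, C, G, T), in which case it is used as-is.
#' @param background0 Order-0 `"markov_bg"`; also used as the log-odds
#'   denominator when `pwm` is a probability PWM.
#' @param granularity Number of score bins per column (>= 100, default 1000).
#' @param pseudo Pseudocount mixed into PWM columns before taking log-odds
#'   (default the PWM's own; mirrors motif-scan pseudocount handling).
#' @return An object of class `"pwm_score_table"`: `int_scores` (4 x w
#'   integer matrix), `delta` (bin width in bits), `offset` (score of integer
#'   0, bits), `pvalues` (vector over integer totals), plus the inputs.
#' @export
score_pvalue_table <- function(pwm, background0, granularity = 1000L,
                               pseudo = NULL) {
  stopifnot(granularity >= 100L)
  bg0 <- background0$p0
  if (is(pwm, "pwm")) {
    if (is.null(pseudo)) pseudo <- if (pwm$pseudo > 0) pwm$pseudo else 0.01
    probs <- sweep(pwm$probs + pseudo, 2L, colSums(pwm$probs + pseudo), "/")
    lo <- log2(probs / bg0)
  } else {
    stopifnot(is.matrix(pwm), nrow(pwm) == 4L)
    lo <- pwm
  }
  w <- ncol(lo)
  col_min <- apply(lo, 2L, min)
  col_range <- apply(lo, 2L, max) - col_min
  delta <- max(col_range, 1e-12) / granularity
  I <- matrix(as.integer(floor(sweep(lo, 2L, col_min, "-") / delta + 1e-9)),
              4L, w)
  ## null distribution over integer totals, one convolution per column
  d <- 1
  for (j in seq_len(w)) {
    mx <- max(I[, j])
    nd <- numeric(length(d) + mx)
    for (b in 1:4) {
      sh <- I[b, j]
      nd[(sh + 1L):(sh + length(d))] <- nd[(sh + 1L):(sh + length(d))] +
        bg0[b] * d
    }
    d <- nd
  }
  pv <- rev(cumsum(rev(d)))
  pv <- pmin(pv, 1)
  structure(list(int_scores = I, delta = delta, offset = sum(col_min),
                 pvalues = pv, granularity = as.integer(granularity),
                 background0 = background0, width = w, log_odds = lo),
            class = "pwm_score_table")
}

#' P-value of a scanner score
#'
#' @param table A [score_pvalue_table()] object.
#' @param int_score Integer score(s) as emitted by the scanner.
#' @return P-value(s); scores above the attainable maximum get the minimum
#'   tabulated p.
#' @export
table_pvalue <- function(table, int_score) {
  k <- pmin(pmax(int_score, 0L), length(table$pvalues) - 1L)
  table$pvalues[k + 1L]
}

#' Bits score of an integer scanner score
#' @param table A [score_pvalue_table()] object.
#' @param int_score Integer score(s).
#' @return Log-odds score in bits (lower edge of the score bin).
#' @export
table_bits <- function(table, int_score) {
  table$offset + int_score * table$delta
}
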