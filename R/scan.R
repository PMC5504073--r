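## sequence extraction for windows (clipped windows assumed in-bounds)
get_window_seqs <- function(genome, gr) {
  chr <- as.character(GenomicRanges::seqnames(gr))
  out <- character(length(gr))
  for (ch in unique(chr)) {
    idx <- which(chr == ch)
    v <- Biostrings::Views(genome[[ch]],
                           start = GenomicRanges::start(gr)[idx],
                           end = GenomicRanges::end(gr)[idx])
    out[idx] <- as.character(v)
  }
  nm <- S4Vectors::mcols(gr)$name
  names(out) <- if (!is.null(nm)) nm else as.character(seq_along(gr))
  out
}

## scan raw sequences with an integerised score table; returns a data.frame
## of hits (seq index, 1-based position of the forward-strand footprint,
## strand, integer score, p-value)
scan_seqs <- function(seqs, table, thresh_p, strand = c("both", "forward")) {
  strand <- match.arg(strand)
  stopifnot(thresh_p > 0, thresh_p <= 1)
  w <- table$width
  codes <- encode_dna(seqs)
  cc <- concat_codes(codes, sep = w)
  P_all <- length(cc$codes) - w + 1L
  win_of <- rep(NA_integer_, P_all); pos_of <- rep(NA_integer_, P_all)
  for (i in seq_along(seqs)) {
    Pi <- cc$lens[i] - w + 1L
    if (Pi >= 1L) {
      win_of[cc$offsets[i] + seq_len(Pi)] <- i
      pos_of[cc$offsets[i] + seq_len(Pi)] <- seq_len(Pi)
    }
  }
  kmin <- match(TRUE, table$pvalues <= thresh_p) - 1L
  if (is.na(kmin)) kmin <- length(table$pvalues)   # nothing can pass
  collect <- function(I, strand_char) {
    look <- rbind(I, rep(NA_real_, w))      # 5 x w, N row NA
    sc <- window_sums(cc$codes, look)
    hit <- which(!is.na(sc) & !is.na(win_of) & sc >= kmin)
    if (length(hit) == 0L)
      return(data.frame(seq = integer(0), pos = integer(0),
                        strand = character(0), int_score = integer(0),
                        pvalue = numeric(0)))
    data.frame(seq = win_of[hit], pos = pos_of[hit], strand = strand_char,
               int_score = as.integer(sc[hit]),
               pvalue = table_pvalue(table, sc[hit]))
  }
  I <- table$int_scores
  out <- collect(I, "+")
  if (strand == "both") {
    Irc <- I[4:1, w:1, drop = FALSE]
    out <- rbind(out, collect(Irc, "-"))
  }
  out[order(out$seq, out$pos, out$strand), , drop = FALSE]
}

#' Scan peak windows for PWM matches with exact p-values
#'
#' Scores every position of every window on both strands (minus-strand
#' matches are reported on the forward-strand footprint) with the
#' integerised log-odds of [score_pvalue_table()] and reports positions with
#' p-value at or below `thresh_p` — the semantics of classical PWM scanners
#' run with a p-value threshold. Windows containing `N` at a candidate
#' position skip that position.
#'
#' @param genome `DNAStringSet` genome.
#' @param windows `GRanges` of scan windows (e.g. [summit_windows()] with
#'   flank 100); the `name` column becomes `peak_id`.
#' @param pwm A [new_pwm()] object.
#' @param background0 Order-0 `"markov_bg"` (see [background_order0()]).
#' @param thresh_p Report positions with `p <= thresh_p` (default 1e-4).
#' @param strand `"both"` (default) or `"forward"`.
#' @param pseudo Pseudocount mixed into the PWM before log-odds (default
#'   0.01).
#' @param table Optionally a precomputed [score_pvalue_table()].
#' @return `GRanges` of motif hits with metadata `peak_id`, `int_score`,
#'   `score` (bits), `pvalue`; width equals the PWM width.
#' @export
scan_pwm <- function(genome, windows, pwm, background0, thresh_p = 1e-4,
                     strand = c("both", "forward"), pseudo = 0.01,
                     table = NULL) {
  strand <- match.arg(strand)
  if (is.null(table))
    table <- score_pvalue_table(pwm, background0, pseudo = pseudo)
  seqs <- get_window_seqs(genome, windows)
  h <- scan_seqs(seqs, table, thresh_p, strand)
  gstart <- GenomicRanges::start(windows)[h$seq] + h$pos - 1L
  GenomicRanges::GRanges(
    seqnames = as.character(GenomicRanges::seqnames(windows))[h$seq],
    ranges = IRanges::IRanges(start = gstart, width = table$width),
    strand = h$strand,
    peak_id = names(seqs)[h$seq],
    int_score = h$int_score,
    score = table_bits(table, h$int_score),
    pvalue = h$pvalue)
}

#' Best motif hit per peak
#'
#' Keeps, for every peak with at least one hit, the hit with the lowest
#' p-value; ties are broken deterministically by higher score, then leftmost
#' start, then `+` strand.
#'
#' @param hits Hit `GRanges` from [scan_pwm()] (metadata `peak_id`,
#'   `int_score`, `pvalue`).
#' @return A `GRanges` with one hit per represented peak.
#' @export
best_hit_per_peak <- function(hits) {
  if (length(hits) == 0L) return(hits)
  o <- order(hits$pvalue, -hits$int_score, GenomicRanges::start(hits),
             as.character(GenomicRanges::strand(hits)) != "+")
  h <- hits[o]
  h[!duplicated(h$peak_id)]
}

#' Upstream extension windows of core motif hits
#'
#' For each core hit, extracts the `ext` bases immediately 5' of the motif
#' footprint *on the motif's own strand*: for a `+` hit the `ext` bases to
#' the left, forward orientation; for a `-` hit the `ext` bases to the
#' right, reverse-complemented. Windows truncated by a contig edge are
#' dropped with a warning. These oriented windows are where the second part
#' of the two-part CTCF recognition sequence (the upstream / M2 motif) is
#' sought.
#'
#' @param core_hits Hit `GRanges` from [scan_pwm()] / [best_hit_per_peak()].
#' @param genome `DNAStringSet` genome.
#' @param ext Extension length in bp (default 20).
#' @return Named character vector of oriented upstream sequences (names =
#'   `peak_id`).
#' @export
upstream_windows <- function(core_hits, genome, ext = 20L) {
  if (length(core_hits) == 0L) return(setNames(character(0), character(0)))
  chr <- as.character(GenomicRanges::seqnames(core_hits))
  strand <- as.character(GenomicRanges::strand(core_hits))
  lens <- setNames(Biostrings::width(genome), names(genome))[chr]
  s <- ifelse(strand == "+", GenomicRanges::start(core_hits) - ext,
              GenomicRanges::end(core_hits) + 1L)
  e <- s + ext - 1L
  ok <- s >= 1L & e <= lens
  if (any(!ok))
    warning(sum(!ok), " upstream window(s) truncated at contig edge; dropped")
  gr <- GenomicRanges::GRanges(chr[ok], IRanges::IRanges(s[ok], e[ok]),
                               name = core_hits$peak_id[ok])
  seqs <- get_window_seqs(genome, gr)
  minus <- strand[ok] == "-"
  seqs[minus] <- revcomp(seqs[minus])
  seqs
}

#' The two-part CTCF motif pipeline
#'
#' End-to-end motif stage over a consensus peak set: (1) train an order-1
#' Markov background on the summit +/- `flank` windows of the top
#' `top_n` peaks by fold enrichment; (2) discover the 16-bp core motif there
#' by ZOOPS EM; (3) scan all peak windows for the core at `p <= core_thresh`
#' and keep the best hit per peak; (4) extend each core hit `ext` bp to its
#' 5' side and discover the upstream (M2) motif in those oriented windows;
#' (5) scan the extensions at `p <= up_thresh` for per-peak upstream flags.
#'
#' @param consensus Consensus peak `GRanges` (see [consensus_peaks()]).
#' @param genome `DNAStringSet` genome.
#' @param top_n Training-set size (default 2000).
#' @param core_width,up_width Motif widths (defaults 16 and 10).
#' @param core_thresh,up_thresh Scan p-value thresholds (1e-4, 1e-3).
#' @param ext Upstream extension length (default 20).
#' @param flank Scan-window half-width around summits (default 100).
#' @param pseudo Pseudocount for background, PWM estimation and scanning.
#' @param n_starts,seed EM restart controls.
#' @param min_core_ic Minimum information content (bits) of the best core
#'   PWM column; below it the run aborts with "no motif".
#' @return List of class `"two_part"`: `core_pwm`, `upstream_pwm` (may be
#'   NULL when no upstream windows exist), `core_em`, `upstream_em`,
#'   `core_hits`, `best_core`, `peak_flags` (data.frame `peak_id`,
#'   `signalValue`, `has_core`, `has_upstream`), `background`, `background0`,
#'   `params`.
#' @export
two_part_pipeline <- function(consensus, genome, top_n = 2000L,
                              core_width = 16L, up_width = 10L,
                              core_thresh = 1e-4, up_thresh = 1e-3,
                              ext = 20L, flank = 100L, pseudo = 0.01,
                              n_starts = 5L, seed = 1L, min_core_ic = 0.5) {
  stopifnot(length(consensus) > 0L)
  top <- top_peaks_by_fe(consensus, top_n)
  train_win <- summit_windows(top, flank, seqlengths = genome)
  train_seqs <- get_window_seqs(genome, train_win)
  bg1 <- train_markov_background(train_seqs, order = 1L, pseudo = pseudo)
  bg0 <- background_order0(bg1)
  core_em <- em_discover(train_seqs, core_width, bg1, n_starts = n_starts,
                         seed = seed, pseudo = pseudo)
  if (max(core_em$pwm$ic) < min_core_ic)
    stop("no motif: core discovery did not exceed ", min_core_ic,
         " bits in any column")
  all_win <- summit_windows(consensus, flank, seqlengths = genome)
  core_pwm <- core_em$pwm
  core_tab <- score_pvalue_table(core_pwm, bg0, pseudo = pseudo)
  core_hits <- scan_pwm(genome, all_win, core_pwm, bg0,
                        thresh_p = core_thresh, table = core_tab)
  best_core <- best_hit_per_peak(core_hits)
  ## a single-motif EM fixes the core orientation only up to strand; the
  ## two-part arrangement itself disambiguates it: discover the upstream
  ## motif in the 5' extensions under both orientations and keep the one
  ## with the more informative upstream PWM (ties keep the EM orientation)
  flip_strand <- function(gr) {
    st <- as.character(GenomicRanges::strand(gr))
    GenomicRanges::strand(gr) <- ifelse(st == "+", "-", "+")
    gr
  }
  upstream_em <- NULL; up_hits <- NULL; up_tab <- NULL
  up_seqs <- upstream_windows(best_core, genome, ext = ext)
  if (length(up_seqs) >= 10L) {
    fit_up <- function(seqs)
      em_discover(seqs, up_width, bg1, n_starts = n_starts,
                  seed = seed + 1L, pseudo = pseudo, both_strands = FALSE)
    upstream_em <- fit_up(up_seqs)
    best_core_rc <- flip_strand(best_core)
    up_seqs_rc <- upstream_windows(best_core_rc, genome, ext = ext)
    upstream_em_rc <- fit_up(up_seqs_rc)
    if (sum(upstream_em_rc$pwm$ic) > sum(upstream_em$pwm$ic)) {
      core_pwm <- pwm_revcomp(core_pwm)
      core_hits <- flip_strand(core_hits)
      best_core <- best_core_rc
      up_seqs <- up_seqs_rc
      upstream_em <- upstream_em_rc
    }
    up_tab <- score_pvalue_table(upstream_em$pwm, bg0, pseudo = pseudo)
    up_hits <- scan_seqs(up_seqs, up_tab, up_thresh, strand = "forward")
  }
  ids <- if (!is.null(consensus$name)) consensus$name
         else as.character(seq_along(consensus))
  has_core <- ids %in% best_core$peak_id
  up_peaks <- if (!is.null(up_hits) && nrow(up_hits) > 0L)
    unique(names(up_seqs)[up_hits$seq]) else character(0)
  flags <- data.frame(peak_id = ids,
                      signalValue = consensus$signalValue,
                      has_core = has_core,
                      has_upstream = has_core & ids %in% up_peaks,
                      stringsAsFactors = FALSE)
  structure(list(core_pwm = core_pwm,
                 upstream_pwm = if (!is.null(upstream_em)) upstream_em$pwm,
                 core_em = core_em, upstream_em = upstream_em,
                 core_hits = core_hits, best_core = best_core,
                 core_table = core_tab, upstream_table = up_tab,
                 peak_flags = flags, background = bg1, background0 = bg0,
                 params = list(top_n = top_n, core_width = core_width,
                               up_width = up_width, core_thresh = core_thresh,
                               up_thresh = up_thresh, ext = ext,
                               flank = flank, pseudo = pseudo, seed = seed)),
            class = "two_part")
}

#' Motif occurrence by fold-enrichment bin
#'
#' Tabulates, per fold-enrichment bin, the number of peaks and the fractions
#' harbouring the core motif and the full core + upstream arrangement — the
#' diagnostic that higher-enrichment peaks carry the recognition sequence
#' more often.
#'
#' @param two_part A [two_part_pipeline()] result.
#' @param bin_edges Increasing numeric vector of bin edges covering all fold
#'   enrichments; bins are left-closed `[a, b)`.
#' @return A data.frame with columns `bin`, `n_peaks`, `frac_core`,
#'   `frac_core_plus_upstream`.
#' @export
fe_bin_proportions <- function(two_part,
                               bin_edges = c(0, 5, 10, 20, 40, Inf)) {
  fl <- two_part$peak_flags
  if (any(fl$signalValue < min(bin_edges)) ||
      any(fl$signalValue >= max(bin_edges)))
    stop("bin_edges must cover all fold enrichments")
  bin <- cut(fl$signalValue, bin_edges, right = FALSE)
  agg <- function(x) tapply(x, bin, sum)
  n <- tapply(fl$has_core, bin, length)
  n[is.na(n)] <- 0L
  out <- data.frame(bin = levels(bin),
                    n_peaks = as.integer(n),
                    frac_core = as.numeric(agg(fl$has_core)) / pmax(n, 1L),
                    frac_core_plus_upstream =
                      as.numeric(agg(fl$has_upstream)) / pmax(n, 1L))
  out$frac_core[out$n_peaks == 0L] <- 0
  out$frac_core_plus_upstream[out$n_peaks == 0L] <- 0
  rownames(out) <- NULL
  out
}
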