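#' Summit positions of peaks
#'
#' @param peaks Peak `GRanges` (see [read_narrowpeak()]).
#' @return Integer vector of 1-based summit positions,
#'   `start(peaks) + peaks$peak`.
#' @export
peak_summits <- function(peaks) {
  GenomicRanges::start(peaks) + S4Vectors::mcols(peaks)$peak
}

#' Fixed-width windows around peak summits
#'
#' Builds the `summit +/- flank` windows used both for motif scanning
#' (flank = 100) and for repeat-association counting (flank = 50). Each
#' window covers `2*flank` bases centred on the summit (half-open in 0-based
#' terms: `[summit0 - flank, summit0 + flank)`). When chromosome lengths are
#' known the windows are clipped to the chromosome and a message reports how
#' many were clipped; a window on a chromosome absent from `seqlengths` is an
#' error.
#'
#' @param peaks Peak `GRanges` with a `peak` summit-offset column.
#' @param flank Half-width in bp (> 0).
#' @param seqlengths Optional named integer vector of chromosome lengths (or a
#'   `DNAStringSet` genome, whose widths are used).
#' @return A `GRanges` of windows, parallel to `peaks`, carrying the peak
#'   metadata.
#' @export
summit_windows <- function(peaks, flank, seqlengths = NULL) {
  stopifnot(flank > 0)
  summit0 <- peak_summits(peaks) - 1L         # 0-based summit
  start1 <- summit0 - as.integer(flank) + 1L  # 1-based window start
  end1 <- summit0 + as.integer(flank)
  win <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(peaks),
    ranges = IRanges::IRanges(start = pmax(start1, 1L), end = end1))
  S4Vectors::mcols(win) <- S4Vectors::mcols(peaks)
  if (!is.null(seqlengths)) {
    if (is(seqlengths, "DNAStringSet"))
      seqlengths <- setNames(Biostrings::width(seqlengths), names(seqlengths))
    chr <- as.character(GenomicRanges::seqnames(win))
    if (!all(chr %in% names(seqlengths)))
      stop("unknown chromosome in peaks: ",
           setdiff(unique(chr), names(seqlengths))[1L])
    lim <- unname(seqlengths[chr])
    clipped <- sum(start1 < 1L | end1 > lim)
    if (clipped > 0)
      message(clipped, " summit window(s) clipped at chromosome bounds")
    GenomicRanges::end(win) <- pmin(GenomicRanges::end(win), lim)
  }
  win
}

#' Count repeat copies touched by peak windows, per family
#'
#' For every repeat family, counts how many of its copies overlap at least
#' one window by `min_overlap_bp` or more shared bases. A copy touching
#' several windows is counted once (the quantity is "repeat regions
#' overlapping peaks", not overlap events).
#'
#' @param windows A `GRanges` of query windows.
#' @param repeats Repeat `GRanges` with a `family_id` column.
#' @param min_overlap_bp Minimum shared bases to call an overlap (default 1).
#' @return Named integer vector, one entry per family present in `repeats`
#'   (zero for families touching no window).
#' @export
count_family_overlaps <- function(windows, repeats, min_overlap_bp = 1L) {
  stopifnot(min_overlap_bp >= 1L)
  fam <- S4Vectors::mcols(repeats)$family_id
  hit <- IRanges::overlapsAny(repeats, windows,
                              minoverlap = as.integer(min_overlap_bp),
                              ignore.strand = TRUE)
  counts <- tapply(hit, fam, sum)
  out <- setNames(as.integer(counts), names(counts))
  out[sort(unique(fam))]
}

#' Sample non-overlapping N-free control regions
#'
#' Draws `n` fixed-length regions from a genome, uniformly over all eligible
#' start positions, rejecting candidates that contain an `N` or overlap an
#' already accepted region. This reproduces the construction of control
#' region sets used to assess repeat association (e.g. 50,000 regions of
#' 100 bp with no undetermined base). Sampling is fully determined by `seed`;
#' after `50 * n` rejected draws a capacity error is raised naming the
#' shortfall.
#'
#' @param genome A `DNAStringSet` genome (see [read_fasta()]).
#' @param n Number of regions.
#' @param length Region length in bp (default 100).
#' @param seed Integer RNG seed.
#' @return A `GRanges` of `n` pairwise non-overlapping regions, sorted, with
#'   metadata `seed` and `region_length` attached as [S4Vectors::metadata()].
#' @export
sample_control_regions <- function(genome, n, length = 100L, seed = 1L) {
  stopifnot(is(genome, "DNAStringSet"), n >= 1L, length >= 1L)
  len <- as.integer(length)
  widths <- Biostrings::width(genome)
  keep <- widths >= len
  if (!any(keep))
    stop("control-region capacity error: no chromosome is >= ", len, " bp")
  chroms <- names(genome)[keep]
  widths <- widths[keep]
  ## per-chromosome N mask and occupancy vector; a candidate start s (1-based)
  ## is eligible iff positions s..s+len-1 are N-free and unoccupied
  nmask <- lapply(chroms, function(ch) {
    as.integer(Biostrings::letterFrequencyInSlidingView(
      genome[[ch]], len, "N")) > 0L
  })
  names(nmask) <- chroms
  occ <- lapply(setNames(widths, chroms), function(w) logical(w))
  n_starts <- widths - len + 1L
  cum <- cumsum(as.numeric(n_starts))
  total <- cum[base::length(cum)]
  if (total < n)
    stop("control-region capacity error: ", total,
         " candidate start positions for ", n, " regions")
  set.seed(as.integer(seed))
  picked_chr <- character(n); picked_start <- integer(n)
  got <- 0L; tries <- 0L; cap <- 50L * as.numeric(n)
  while (got < n) {
    if (tries >= cap)
      stop("control-region capacity error: sampled only ", got, " of ", n,
           " regions after ", format(cap, scientific = FALSE), " draws")
    tries <- tries + 1L
    u <- floor(stats::runif(1L) * total) + 1
    ci <- findInterval(u - 0.5, c(0, cum)) # chromosome index
    s <- as.integer(u - c(0, cum)[ci])     # 1-based start on that chromosome
    if (nmask[[ci]][s]) next
    span <- s:(s + len - 1L)
    if (any(occ[[ci]][span])) next
    occ[[ci]][span] <- TRUE
    got <- got + 1L
    picked_chr[got] <- chroms[ci]
    picked_start[got] <- s
  }
  gr <- GenomicRanges::GRanges(
    seqnames = picked_chr,
    ranges = IRanges::IRanges(start = picked_start, width = len))
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  S4Vectors::metadata(gr) <- list(seed = as.integer(seed), region_length = len,
                                  n_regions = as.integer(n))
  gr
}

#' Export intervals as BED
#'
#' Minimal BED3/BED4 writer for windows and control-region sets.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param names Optional character vector for column 4.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, names = NULL) {
  cols <- list(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1L,
               GenomicRanges::end(gr))
  if (!is.null(names)) cols <- c(cols, list(names))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}
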