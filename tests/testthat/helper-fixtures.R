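## shared fixtures, built once per test run

.cache <- new.env(parent = emptyenv())

## the full-scale simulated bundle (the package's default study conditions),
## with the two-part motif pipeline already run on the embryo sample
default_bundle <- function() {
  if (is.null(.cache$bundle)) {
    cfg <- generator_config(seed = 1)
    g <- make_genome(cfg)
    pl <- plant_repeats_and_sites(g, cfg)
    calls <- simulate_peak_calls(pl$truth, cfg, "embryo")
    cons <- consensus_peaks(calls$rep1, calls$rep2, calls$merged)
    tp <- suppressMessages(two_part_pipeline(cons, pl$genome, seed = 1))
    .cache$bundle <- list(cfg = cfg, pl = pl, calls = calls, cons = cons,
                          tp = tp)
  }
  .cache$bundle
}

## a down-scaled generator config for fast unit tests
small_config <- function(seed = 3L, ...) {
  generator_config(
    seed = seed,
    chrom_length = 300000L,
    n_true_sites = 150L,
    n_noise_peaks = 100L,
    repeat_families = data.frame(
      family_id = c("274", "501"),
      class_label = c("DNA/hAT-Tip100", "LTR/Gypsy"),
      consensus_length = c(120L, 300L),
      n_copies = c(60L, 40L),
      divergence = c(0.1, 0.1),
      stringsAsFactors = FALSE),
    ...)
}

## random peak GRanges on a toy chromosome set
random_peaks <- function(n, chrom_lens = c(chrA = 100000L, chrB = 80000L),
                         prefix = "p") {
  chrom <- sample(names(chrom_lens), n, replace = TRUE)
  width <- sample(50:400, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(chrom_lens[chrom[i]] - width[i], 1L), integer(1L))
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, width = width),
    strand = "*",
    name = sprintf("%s%04d", prefix, seq_len(n)),
    score = sample(0:1000, n, replace = TRUE),
    signalValue = round(stats::rlnorm(n, log(10), 0.6), 4),
    pValue = NA_real_, qValue = NA_real_,
    peak = as.integer(floor(width * stats::runif(n, 0.1, 0.9))))
}

## brute-force interval overlap (1-based closed), the oracle for all
## findOverlaps-backed operations
overlaps_brute <- function(s1, e1, s2, e2, min_bp = 1L) {
  pmin(e1, e2) - pmax(s1, s2) + 1L >= min_bp
}

## two-sided Fisher p by full hypergeometric enumeration (probability
## method), independent of fisher.test
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0L, k - n2); hi <- min(k, m)
  supp <- lo:hi
  pr <- stats::dhyper(supp, m, n2, k)
  sum(pr[pr <= stats::dhyper(a, m, n2, k) * (1 + 1e-7)])
}
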