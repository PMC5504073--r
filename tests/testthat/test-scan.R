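uniform_bg <- function() {
  structure(list(order = 0L, p0 = c(A = .25, C = .25, G = .25, T = .25),
                 trans = NULL, pseudo = 0.01, source = "test"),
            class = "markov_bg")
}

## a toy genome with one strong motif instance at a known offset
toy_scan_fixture <- function(seed = 61) {
  set.seed(seed)
  motif <- "CCAGCAGGTGGCGCTA"
  chrom <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  substr(chrom, 1001, 1016) <- motif
  g <- Biostrings::DNAStringSet(c(chr1 = chrom))
  win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(901, 1100),
                                name = "pk1")
  list(genome = g, windows = win, motif = motif,
       pwm = pwm_from_consensus(motif, 0.9))
}

test_that("scanning finds a planted consensus at its exact offset", {
  fx <- toy_scan_fixture()
  hits <- scan_pwm(fx$genome, fx$windows, fx$pwm, uniform_bg(),
                   thresh_p = 1e-6)
  expect_length(hits, 1L)
  expect_equal(GenomicRanges::start(hits), 1001L)
  expect_equal(GenomicRanges::end(hits), 1016L)
  expect_identical(as.character(GenomicRanges::strand(hits)), "+")
  expect_identical(hits$peak_id, "pk1")
  expect_lte(hits$pvalue, 1e-6)
})

test_that("scanning is strand-symmetric under window reverse complement", {
  fx <- toy_scan_fixture(62)
  set.seed(63)
  ## several windows over random sequence at a permissive threshold
  win <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(1, 501, 1501), width = 300),
                                name = paste0("w", 1:3))
  tab <- score_pvalue_table(fx$pwm, uniform_bg())
  h_fwd <- scan_pwm(fx$genome, win, fx$pwm, uniform_bg(), thresh_p = 1e-2,
                    table = tab)
  ## scan the reverse-complemented genome over the mirrored windows
  L <- Biostrings::width(fx$genome)[1]
  grc <- Biostrings::reverseComplement(fx$genome)
  names(grc) <- names(fx$genome)
  win_rc <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(L - GenomicRanges::end(win) + 1,
                     L - GenomicRanges::start(win) + 1),
    name = win$name)
  h_rc <- scan_pwm(grc, win_rc, fx$pwm, uniform_bg(), thresh_p = 1e-2,
                   table = tab)
  expect_equal(length(h_fwd), length(h_rc))
  ## footprints mirror, strands flip, scores identical
  key_fwd <- paste(h_fwd$peak_id, L - GenomicRanges::end(h_fwd) + 1,
                   c("+" = "-", "-" = "+")[
                     as.character(GenomicRanges::strand(h_fwd))],
                   h_fwd$int_score)
  key_rc <- paste(h_rc$peak_id, GenomicRanges::start(h_rc),
                  as.character(GenomicRanges::strand(h_rc)), h_rc$int_score)
  expect_setequal(key_fwd, key_rc)
})

test_that("threshold 1 reports every candidate position on both strands", {
  fx <- toy_scan_fixture(64)
  win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 300),
                                name = "w")
  hits <- scan_pwm(fx$genome, win, fx$pwm, uniform_bg(), thresh_p = 1)
  L <- 200L; w <- 16L
  expect_length(hits, 2L * (L - w + 1L))
})

test_that("N-containing candidate positions are skipped", {
  fx <- toy_scan_fixture(65)
  chrom <- as.character(fx$genome[[1]])
  substr(chrom, 150, 160) <- "NNNNNNNNNNN"
  g <- Biostrings::DNAStringSet(c(chr1 = chrom))
  win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 300),
                                name = "w")
  hits <- scan_pwm(g, win, fx$pwm, uniform_bg(), thresh_p = 1)
  expect_false(any(GenomicRanges::start(hits) <= 160 &
                     GenomicRanges::end(hits) >= 150))
  ## every reported footprint is N-free; count matches the N-free windows
  expect_length(hits, 2L * sum(!overlaps_brute(
    (101:285), (101:285) + 15L, 150L, 160L)))
})

test_that("best hit per peak takes the lowest p with deterministic ties", {
  mk <- function(start, strand, p, int, id = "pk") GenomicRanges::GRanges(
    "c1", IRanges::IRanges(start, width = 16), strand = strand,
    peak_id = id, int_score = int, score = int / 100, pvalue = p)
  h <- c(mk(10, "+", 1e-5, 500), mk(40, "-", 1e-6, 600))
  expect_equal(GenomicRanges::start(best_hit_per_peak(h)), 40L)
  ## single hit -> itself
  expect_length(best_hit_per_peak(h[1]), 1L)
  ## exact tie: leftmost start wins, then + strand
  t1 <- c(mk(50, "-", 1e-5, 500), mk(20, "-", 1e-5, 500))
  expect_equal(GenomicRanges::start(best_hit_per_peak(t1)), 20L)
  t2 <- c(mk(20, "-", 1e-5, 500), mk(20, "+", 1e-5, 500))
  expect_identical(as.character(GenomicRanges::strand(
    best_hit_per_peak(t2))), "+")
  ## multiple peaks: one row each
  t3 <- c(mk(10, "+", 1e-4, 400, "a"), mk(90, "+", 1e-7, 700, "a"),
          mk(10, "+", 1e-3, 300, "b"))
  bb <- best_hit_per_peak(t3)
  expect_setequal(bb$peak_id, c("a", "b"))
  expect_equal(GenomicRanges::start(bb[bb$peak_id == "a"]), 90L)
})

test_that("upstream windows follow the motif-strand 5' convention", {
  g <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 100),
                                               collapse = "")))
  hit_plus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 116),
                                     strand = "+", peak_id = "p1",
                                     int_score = 1L, score = 1, pvalue = 1e-5)
  up <- upstream_windows(hit_plus, g, ext = 20)
  ## + hit at 0-based [100,116) -> window [80,100), forward
  expect_identical(unname(up),
                   as.character(Biostrings::subseq(g[[1]], 81, 100)))
  hit_minus <- hit_plus
  GenomicRanges::strand(hit_minus) <- "-"
  upm <- upstream_windows(hit_minus, g, ext = 20)
  ## - hit -> [116,136), reverse complemented
  expect_identical(unname(upm), as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(as.character(
      Biostrings::subseq(g[[1]], 117, 136))))))
  ## truncated at the contig edge -> dropped with a warning
  hit_edge <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5, 20),
                                     strand = "+", peak_id = "p2",
                                     int_score = 1L, score = 1, pvalue = 1e-5)
  expect_warning(up2 <- upstream_windows(hit_edge, g, ext = 20), "truncated")
  expect_length(up2, 0L)
})
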