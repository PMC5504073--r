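test_that("FASTA reading case-folds, masks ambiguity codes and validates", {
  tf <- withr::local_tempfile()
  writeLines(c(">s1 some description", "acgt", ">s2", "NNN"), tf)
  g <- read_fasta(tf)
  expect_identical(names(g), c("s1", "s2"))
  expect_identical(as.character(g[["s1"]]), "ACGT")
  expect_identical(as.character(g[["s2"]]), "NNN")

  writeLines(c(">s1", "ACGTRY"), tf)
  expect_warning(g2 <- read_fasta(tf), "non-ACGTN")
  expect_identical(as.character(g2[["s1"]]), "ACGTNN")

  writeLines(c(">s1", "ACGT", ">s1", "GGGG"), tf)
  expect_error(read_fasta(tf), "duplicate")
  writeLines(character(0), tf)
  expect_error(read_fasta(tf), "no records")
})

test_that("FASTA writer round-trips byte-identically", {
  set.seed(11)
  tf1 <- withr::local_tempfile(); tf2 <- withr::local_tempfile()
  g <- Biostrings::DNAStringSet(vapply(1:4, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), sample(30:301, 1),
                 replace = TRUE), collapse = ""), ""))
  names(g) <- paste0("scaf", 1:4)
  write_fasta(g, tf1)
  write_fasta(read_fasta(tf1), tf2)
  expect_identical(readLines(tf1), readLines(tf2))
})

test_that("narrowPeak parsing handles the ENCODE dialect and rejects bad input", {
  tf <- withr::local_tempfile()
  writeLines("chr1\t100\t300\tp1\t0\t.\t12.5\t-1\t-1\t80", tf)
  pk <- read_narrowpeak(tf)
  expect_equal(GenomicRanges::start(pk), 101L)  # 0-based -> 1-based
  expect_equal(GenomicRanges::end(pk), 300L)
  expect_equal(pk$signalValue, 12.5)
  expect_equal(pk$peak, 80L)
  expect_true(is.na(pk$pValue))
  expect_equal(peak_summits(pk), 181L)

  writeLines(character(0), tf)
  expect_length(read_narrowpeak(tf), 0L)

  writeLines("chr1\t100\t300\tp1\t0\t.\t12.5\t-1\t-1", tf)
  expect_error(read_narrowpeak(tf), "line 1.*10|10.*line 1")
  writeLines(c("chr1\t0\t10\tp1\t0\t.\t2\t-1\t-1\t5",
               "chr1\t5\t20\tp2\t0\t.\t2\t-1\t-1\t-1"), tf)
  expect_error(read_narrowpeak(tf), "summit")
})

test_that("narrowPeak write/read is the identity on canonical files", {
  set.seed(12)
  tf1 <- withr::local_tempfile(); tf2 <- withr::local_tempfile()
  pk <- random_peaks(60)
  write_narrowpeak(pk, tf1)
  pk2 <- read_narrowpeak(tf1)
  write_narrowpeak(pk2, tf2)
  expect_identical(readLines(tf1), readLines(tf2))
  expect_equal(GenomicRanges::start(pk2), GenomicRanges::start(pk))
  expect_equal(pk2$signalValue, pk$signalValue)
  expect_equal(pk2$peak, pk$peak)
})

test_that("repeat annotation dialects normalise coordinates identically", {
  tf <- withr::local_tempfile()
  ## rmout is 1-based closed: begin 101 end 200 covers the same bases as
  ## BED 100..200
  writeLines(c(
    "   SW  perc perc perc  query      position in query",
    "score  div. del. ins.  sequence    begin     end",
    "",
    "  263 10.2 0.0 0.0  chr1  101  200  (0)  +  274  DNA/hAT-Tip100  1  100  (0)  1",
    "  263 12.0 0.0 0.0  chr1  500  500  (0)  C  501  LTR/Gypsy  1  1  (0)  2"), tf)
  ro <- read_repeat_annotation(tf, "rmout")
  expect_equal(GenomicRanges::start(ro), c(101L, 500L))
  expect_equal(GenomicRanges::end(ro), c(200L, 500L))   # length-1 boundary copy
  expect_equal(GenomicRanges::width(ro)[2L], 1L)
  expect_identical(ro$family_id, c("274", "501"))
  expect_identical(as.character(GenomicRanges::strand(ro)), c("+", "-"))
  expect_equal(ro$divergence_pct, c(10.2, 12.0))

  tb <- withr::local_tempfile()
  writeLines(c("chr1\t100\t200\t274#DNA/hAT-Tip100",
               "chr1\t499\t500\t501#LTR/Gypsy"), tb)
  rb <- read_repeat_annotation(tb, "bed")
  expect_equal(GenomicRanges::start(rb), GenomicRanges::start(ro))
  expect_equal(GenomicRanges::end(rb), GenomicRanges::end(ro))
  expect_identical(rb$family_id, ro$family_id)
  expect_identical(rb$class_label, c("DNA/hAT-Tip100", "LTR/Gypsy"))

  writeLines("chr1\t10\t20", tb)
  expect_error(read_repeat_annotation(tb, "bed"), "line 1")
})

test_that("repeat writers round-trip through both dialects", {
  b <- default_bundle()
  rep1 <- b$pl$repeats[1:50]
  tb <- withr::local_tempfile(); to <- withr::local_tempfile()
  write_repeat_annotation(rep1, tb, "bed")
  write_repeat_annotation(rep1, to, "rmout")
  rb <- read_repeat_annotation(tb, "bed")
  ro <- read_repeat_annotation(to, "rmout")
  expect_equal(GenomicRanges::start(rb), GenomicRanges::start(rep1))
  expect_equal(GenomicRanges::start(ro), GenomicRanges::start(rep1))
  expect_identical(rb$family_id, rep1$family_id)
  expect_identical(ro$family_id, rep1$family_id)
})

test_that("Hox gene names parse to paralog groups per the naming rules", {
  ph <- parse_hox_name(c("HoxA5", "Hox5", "Hox13", "Hoxα4", "Hoxd11",
                         "Evx", "Evx2", "GeneX", "Hox14"))
  expect_equal(ph$paralog_group[1:5], c(5L, 5L, 13L, 4L, 11L))
  expect_true(all(ph$is_evx[6:7]))
  expect_true(is.na(ph$paralog_group[8]))   # unparseable, retained
  expect_true(is.na(ph$paralog_group[9]))   # group out of 1..13
})

test_that("gene annotation parses identically from BED and GFF3", {
  genes <- GenomicRanges::GRanges(
    "chrH", IRanges::IRanges(c(100, 5000, 9000), width = 2000),
    strand = c("+", "+", "-"),
    name = c("Hox1", "Hox4", "Evx"),
    paralog_group = c(1L, 4L, NA), is_evx = c(FALSE, FALSE, TRUE))
  tb <- withr::local_tempfile(); tg <- withr::local_tempfile()
  write_gene_annotation(genes, tb, "bed")
  write_gene_annotation(genes, tg, "gff3")
  gb <- read_gene_annotation(tb, "bed")
  gg <- read_gene_annotation(tg, "gff3")
  expect_identical(gb$name, gg$name)
  expect_identical(gb$paralog_group, gg$paralog_group)
  expect_identical(gb$is_evx, gg$is_evx)
  expect_equal(GenomicRanges::start(gb), GenomicRanges::start(gg))
  expect_equal(GenomicRanges::end(gb), GenomicRanges::end(gg))
  expect_warning(
    read_gene_annotation({
      writeLines("chrH\t0\t10\tMysteryGene", tb); tb
    }, "bed"), "unparseable")
})
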