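toy_cluster <- function(axis = "+", chrom = "chrH") {
  ## five Hox genes, 2-kb bodies, 8-kb intergenic, plus Evx at the 5' end
  starts <- 20000 + (0:5) * 10000
  if (axis == "+") {
    nm <- c(paste0("Hox", 1:5), "Evx")
  } else {
    nm <- c("Evx", paste0("Hox", 5:1))
  }
  ph <- parse_hox_name(nm)
  genes <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(starts, width = 2000), strand = "+",
    name = nm, paralog_group = ph$paralog_group, is_evx = ph$is_evx)
  hox_cluster(genes, species = "toy", cluster_name = axis)
}

toy_cluster_peak <- function(summit, chrom = "chrH", name = "pk1") {
  GenomicRanges::GRanges(
    chrom, IRanges::IRanges(summit - 100, summit + 99),
    name = name, score = 0L, signalValue = 15,
    pValue = NA_real_, qValue = NA_real_, peak = 100L)
}

test_that("cluster axis is inferred and validated from paralog order", {
  expect_identical(toy_cluster("+")$axis, "+")
  expect_identical(toy_cluster("-")$axis, "-")
  bad <- GenomicRanges::GRanges(
    "c", IRanges::IRanges(c(1, 100, 200), width = 50), strand = "+",
    name = c("Hox1", "Hox5", "Hox3"),
    paralog_group = c(1L, 5L, 3L), is_evx = FALSE)
  expect_error(hox_cluster(bad), "monotone")
})

test_that("cluster peak selection is summit-based with half-open flanks", {
  cl <- toy_cluster("+")
  inside <- toy_cluster_peak(50000)
  expect_length(peaks_in_cluster(inside, cl, 10000), 1L)
  ## span is [20000, 71999]; summit beyond span+flank excluded
  past <- toy_cluster_peak(cl$span_end + 10001)
  expect_length(peaks_in_cluster(past, cl, 10000), 0L)
  edge <- toy_cluster_peak(cl$span_end + 10000)
  expect_length(peaks_in_cluster(edge, cl, 10000), 1L)
  ## brute-force filter agreement on random summits
  set.seed(81)
  summits <- sample(1:150000, 200)
  pks <- do.call(c, lapply(seq_along(summits), function(i)
    toy_cluster_peak(summits[i], name = paste0("p", i))))
  got <- peaks_in_cluster(pks, cl, 5000)$name
  want <- paste0("p", which(summits >= cl$span_start - 5000 &
                              summits <= cl$span_end + 5000))
  expect_setequal(got, want)
})

test_that("orientation normalises to the cluster axis in both layouts", {
  set.seed(82)
  motif <- "CCAGCAGGTGGCGCTA"
  bg0 <- structure(list(order = 0L, p0 = c(A = .25, C = .25, G = .25,
                                           T = .25),
                        trans = NULL, pseudo = 0.01, source = "t"),
                   class = "markov_bg")
  pwm <- pwm_from_consensus(motif, 0.9)
  mk_genome <- function() Biostrings::DNAStringSet(c(chrH = paste(
    sample(c("A", "C", "G", "T"), 150000, TRUE), collapse = "")))
  for (axis in c("+", "-")) {
    cl <- toy_cluster(axis)
    g <- mk_genome()
    s <- as.character(g[[1]])
    substr(s, 45001, 45016) <- motif          # a + strand instance
    g <- Biostrings::DNAStringSet(c(chrH = s))
    pk <- toy_cluster_peak(45008)
    calls <- suppressMessages(call_binding_sites(pk, cl, pwm, g, bg0))
    ## + strand hit: forward when the axis is +, reverse when it is -
    expect_identical(calls$orientation,
                     if (axis == "+") "forward" else "reverse")
    expect_true(calls$has_core_motif)
  }
})

test_that("segment assignment, Hox1-4 counts and outward flags", {
  cl <- toy_cluster("+")
  ## summits: between Hox2-Hox3, between Hox4-Hox5, inside Hox3, 3' flank
  pks <- do.call(c, lapply(seq_along(c(36000, 56000, 41000, 15000)),
                           function(i) toy_cluster_peak(
                             c(36000, 56000, 41000, 15000)[i],
                             name = paste0("p", i))))
  ## no motifs needed: feed an empty-genome scan via orientation none
  calls <- data.frame(
    peak_id = pks$name, summit = peak_summits(pks),
    position = peak_summits(pks) - cl$span_start,
    orientation = c("forward", "reverse", "none", "reverse"),
    has_core_motif = c(TRUE, TRUE, FALSE, TRUE),
    pvalue = NA_real_, overlaps_repeat = NA)
  segs <- ctcfLandscape:::segment_of(cl, calls$position)
  calls$segment <- segs$segment; calls$segment_key <- segs$segment_key
  expect_identical(calls$segment,
                   c("between Hox2 and Hox3", "between Hox4 and Hox5",
                     "within Hox3", "3'-flank"))
  pr <- cluster_profile(calls, cl)
  expect_equal(pr$total, 4L)
  expect_equal(pr$hox1_4, 1L)     # only the Hox2-Hox3 site; 4-5 is outside
  ## nearest oriented call at the low end is the flank site, reverse ->
  ## outward; highest is the Hox4-Hox5 site, reverse -> not outward
  expect_true(pr$outward_low)
  expect_false(pr$outward_high)
})

test_that("axis flip is an involution on calls and conserves profiles", {
  hx <- make_toy_hox("lamprey", seed = 4)
  bg0 <- structure(list(order = 0L, p0 = c(A = .3, C = .2, G = .2, T = .3),
                        trans = NULL, pseudo = 0.01, source = "t"),
                   class = "markov_bg")
  pwm <- pwm_from_consensus(hx$core_consensus, 0.9)
  profs <- lapply(1:2, function(i) {
    cl <- hx$clusters[[i]]
    pk <- peaks_in_cluster(hx$peaks, cl)
    calls <- suppressMessages(call_binding_sites(pk, cl, pwm, hx$genome,
                                                 bg0,
                                                 repeats = hx$repeats))
    cluster_profile(calls, cl)
  })
  ## the two clusters are the same plan on opposite axes: totals, Hox1-4
  ## counts and outward flags agree
  expect_equal(profs[[1]]$total, profs[[2]]$total)
  expect_equal(profs[[1]]$hox1_4, profs[[2]]$hox1_4)
  expect_equal(profs[[1]]$outward_low, profs[[2]]$outward_low)
  expect_equal(profs[[1]]$outward_high, profs[[2]]$outward_high)
  cmp <- compare_profiles(profs)
  ## planted shared interior segments occupy both clusters
  expect_true(all(c("5-6", "8-9") %in% cmp$shared_segments))
  expect_equal(unname(cmp$max_per_species["toy"]),
               max(cmp$totals))
})

test_that("profile comparison handles identical and disjoint occupancy", {
  mk_prof <- function(nm, segs, counts) {
    structure(list(cluster_name = nm, species = "sp",
                   segment_counts = stats::setNames(as.table(counts), segs),
                   segment_keys = stats::setNames(segs, segs),
                   total = sum(counts), hox1_4 = 0L,
                   outward_low = NA, outward_high = NA),
              class = "cluster_profile")
  }
  a <- mk_prof("a", c("1-2", "5-6"), c(2L, 1L))
  b <- mk_prof("b", c("1-2", "5-6"), c(1L, 3L))
  cmp <- compare_profiles(list(a, b))
  expect_setequal(cmp$shared_segments, c("1-2", "5-6"))
  d <- mk_prof("d", c("8-9"), 2L)
  cmp2 <- compare_profiles(list(a, d))
  expect_length(cmp2$shared_segments, 0L)
  expect_equal(dim(cmp2$occupancy), c(2L, 3L))
})
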