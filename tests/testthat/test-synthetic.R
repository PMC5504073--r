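test_that("genome simulation is seeded and respects the transition matrix", {
  ## degenerate chain: from A always to A, started at A
  idA <- diag(4); dimnames(idA) <- list(c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T"))
  cfgA <- generator_config(seed = 2, n_chroms = 1L, chrom_length = 500L,
                           transition = idA,
                           p0 = c(A = 1, C = 0, G = 0, T = 0))
  g <- make_genome(cfgA)
  expect_identical(as.character(g[[1]]),
                   paste(rep("A", 500), collapse = ""))
  ## uniform chain: base frequencies near 1/4 at 1 Mb
  uni <- matrix(0.25, 4, 4, dimnames = dimnames(idA))
  cfgU <- generator_config(seed = 2, n_chroms = 1L, chrom_length = 1000000L,
                           transition = uni,
                           p0 = c(A = .25, C = .25, G = .25, T = .25))
  gu <- make_genome(cfgU)
  fr <- Biostrings::alphabetFrequency(gu[[1]])[c("A", "C", "G", "T")] / 1e6
  expect_true(all(abs(fr - 0.25) < 0.01))
  ## determinism
  expect_identical(as.character(make_genome(cfgU)[[1]]),
                   as.character(gu[[1]]))
  ## N blocks appear when requested
  cfgN <- generator_config(seed = 2, n_chroms = 1L, chrom_length = 50000L,
                           n_blocks = 2L, n_block_length = 1000L)
  gn <- make_genome(cfgN)
  expect_gte(Biostrings::alphabetFrequency(gn[[1]])[["N"]], 1000L)
})

test_that("planted repeats honour copy numbers, divergence and site carriage", {
  cfg <- small_config(seed = 5)
  pl <- plant_repeats_and_sites(make_genome(cfg), cfg)
  cnt <- table(pl$repeats$family_id)
  expect_equal(as.integer(cnt[cfg$repeat_families$family_id]),
               cfg$repeat_families$n_copies)
  ## observed per-copy divergence within 2 s.e. of the configured rate
  ## (substitutions can silently revert nothing here: every hit changes
  ## the base, so the realised rate estimates the Bernoulli rate)
  div <- pl$repeats$divergence_pct / 100
  rate <- cfg$repeat_families$divergence[1]
  L <- sum(cfg$repeat_families$consensus_length *
             cfg$repeat_families$n_copies)
  se <- sqrt(rate * (1 - rate) / L)
  expect_lt(abs(stats::weighted.mean(div, GenomicRanges::width(pl$repeats)) -
                  rate), 2 * se + 0.002)
  ## no overlapping copies
  expect_equal(sum(GenomicRanges::countOverlaps(pl$repeats, pl$repeats,
                                                ignore.strand = TRUE)),
               length(pl$repeats))
  ## family-borne sites sit inside copies of the motif family
  sites <- pl$truth$sites
  fam_sites <- sites[!is.na(sites$family_id), ]
  expect_equal(nrow(fam_sites),
               round(cfg$n_true_sites * cfg$fraction_in_family))
  sgr <- GenomicRanges::GRanges(fam_sites$chrom,
                                IRanges::IRanges(fam_sites$core_start,
                                                 fam_sites$core_end))
  fam_copies <- pl$repeats[pl$repeats$family_id == cfg$motif_family]
  expect_true(all(IRanges::overlapsAny(sgr, fam_copies, type = "within")))
  ## the genome carries the (possibly mutated) core at every site
  g <- pl$genome
  cc <- cfg$core_consensus
  mism <- vapply(seq_len(nrow(sites)), function(i) {
    s <- as.character(Biostrings::subseq(g[[sites$chrom[i]]],
                                         sites$core_start[i],
                                         sites$core_end[i]))
    if (sites$strand[i] == "-")
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    sum(strsplit(s, "")[[1]] != strsplit(cc, "")[[1]])
  }, numeric(1))
  expect_lt(mean(mism) / nchar(cc), cfg$site_mutation_rate + 0.02)
})

test_that("all sites land in family copies when fraction_in_family is 1", {
  cfg <- small_config(seed = 6, n_true_sites = 40L, fraction_in_family = 1)
  pl <- suppressWarnings(plant_repeats_and_sites(make_genome(cfg), cfg))
  expect_true(all(pl$truth$sites$family_id == cfg$motif_family))
})

test_that("noiseless full-detection calls recover the planted sites exactly", {
  cfg <- small_config(seed = 7, detection_prob = 1, n_noise_peaks = 0L,
                      summit_jitter_sd = 0)
  pl <- plant_repeats_and_sites(make_genome(cfg), cfg)
  calls <- simulate_peak_calls(pl$truth, cfg, "embryo")
  cons <- consensus_peaks(calls$rep1, calls$rep2, calls$merged)
  ids <- calls$map$site_id[match(cons$name, calls$map$name)]
  want <- pl$truth$sites$site_id[pl$truth$sample_sites$embryo]
  expect_setequal(ids, want)
  ## summit sits at the site centre when jitter is off
  expect_setequal(peak_summits(cons),
                  pl$truth$sites$center[pl$truth$sample_sites$embryo])
})

test_that("detection probability drives consensus recovery at the p^2 rate", {
  b <- default_bundle()
  p <- b$cfg$detection_prob
  idx <- match(b$cons$name, b$calls$map$name)
  rec <- unique(stats::na.omit(b$calls$map$site_id[idx]))
  n <- length(b$pl$truth$sample_sites$embryo)
  se <- sqrt(p^2 * (1 - p^2) / n)
  expect_lt(abs(length(rec) / n - p^2), 3 * se)
})

test_that("fold enrichment separates motif-bearing peaks from noise", {
  cfg <- small_config(seed = 8)
  pl <- plant_repeats_and_sites(make_genome(cfg), cfg)
  calls <- simulate_peak_calls(pl$truth, cfg, "embryo")
  is_site <- !is.na(calls$map$site_id[match(calls$merged$name,
                                            calls$map$name)])
  expect_gt(mean(calls$merged$signalValue[is_site]),
            mean(calls$merged$signalValue[!is_site]))
})

test_that("two samples share the configured fraction of consensus peaks", {
  ## complete detection isolates the designed 75% overlap from detection
  ## noise; run-independent noise peaks never reach consensus
  cfg <- small_config(seed = 9, detection_prob = 1,
                      chrom_length = 500000L, n_true_sites = 400L,
                      n_noise_peaks = 150L, fraction_in_family = 0.1)
  pl <- plant_repeats_and_sites(make_genome(cfg), cfg)
  ce <- with(simulate_peak_calls(pl$truth, cfg, "embryo"),
             consensus_peaks(rep1, rep2, merged))
  clv <- with(simulate_peak_calls(pl$truth, cfg, "liver"),
              consensus_peaks(rep1, rep2, merged))
  sf <- shared_fraction(ce, clv)
  expect_lt(abs(sf$frac_a_in_b - cfg$shared_site_fraction), 0.05)
  expect_lt(abs(sf$frac_b_in_a - cfg$shared_site_fraction), 0.05)
})

test_that("dataset bundles validate, are seeded byte-identically, and the
           validator names missing pieces", {
  for (seed in 1:10) {
    cfg <- generator_config(
      seed = seed, chrom_length = 100000L, n_true_sites = 50L,
      n_noise_peaks = 30L, min_site_spacing = 300L,
      repeat_families = data.frame(
        family_id = c("274", "501"),
        class_label = c("DNA/hAT-Tip100", "LTR/Gypsy"),
        consensus_length = c(120L, 200L), n_copies = c(25L, 15L),
        divergence = c(0.1, 0.1), stringsAsFactors = FALSE))
    dir <- withr::local_tempdir()
    write_dataset(dir, cfg)
    expect_true(validate_dataset(dir))
    if (seed == 1) {
      dir2 <- withr::local_tempdir()
      write_dataset(dir2, cfg)
      for (f in list.files(dir))
        expect_identical(readLines(file.path(dir, f)),
                         readLines(file.path(dir2, f)),
                         label = paste("file", f))
      file.remove(file.path(dir2, "embryo_rep2.narrowPeak"))
      expect_error(validate_dataset(dir2), "embryo_rep2")
    }
  }
})
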