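#' Configuration for the synthetic CTCF landscape generator
#'
#' Bundles every knob of the simulator that emulates the study system: an
#' order-1 Markov genome, repeat families with divergent copies (one family
#' carrying the core motif in its consensus, so binding sites propagate with
#' the repeat, hAT-Tip100-style), planted two-part binding sites with
#' fold-enrichment coupled to motif presence, replicate-specific peak
#' detection, and two samples sharing most of their sites. Defaults are the
#' package's study conditions: a 4-Mb genome (2 chromosomes), 5 repeat
#' families of 120-350 copies, 1,500 true sites of which 20% ride inside
#' copies of the motif-carrying family, 50% of sites carrying the upstream
#' motif, per-replicate detection probability 0.85, and a 75% shared-site
#' fraction between the "embryo" and "liver" samples.
#'
#' @param seed Master seed; every stage derives its RNG state from it.
#' @param ... Overrides for any default field (unknown names are an error).
#' @return A list of class `"ctcf_sim_config"`.
#' @export
generator_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_chroms = 2L,
    chrom_length = 2000000L,
    ## order-1 background with mild AT richness and CpG depletion
    transition = matrix(c(.32, .18, .26, .24,
                          .30, .25, .08, .37,
                          .26, .22, .26, .26,
                          .22, .20, .28, .30),
                        4L, 4L, byrow = TRUE,
                        dimnames = list(BASES, BASES)),
    p0 = c(A = .3, C = .2, G = .2, T = .3),
    n_blocks = 0L, n_block_length = 5000L,
    repeat_families = data.frame(
      family_id = c("274", "501", "612", "733", "844"),
      class_label = c("DNA/hAT-Tip100", "LTR/Gypsy", "LINE/L2",
                      "DNA/hAT-Charlie", "SINE/tRNA-V"),
      consensus_length = c(120L, 420L, 350L, 240L, 300L),
      n_copies = c(350L, 250L, 300L, 220L, 120L),
      divergence = rep(0.10, 5L),
      stringsAsFactors = FALSE),
    motif_family = "274",
    core_offset = 41L,      # core occupies consensus positions 41..56
    upstream_offset = 25L,  # upstream motif at 25..34 (6-bp gap to core)
    core_consensus = "CCAGCAGGTGGCGCTA",
    upstream_consensus = "TGCAGTACCA",
    n_true_sites = 1500L,
    fraction_in_family = 0.2,
    upstream_fraction = 0.5,
    site_mutation_rate = 0.05,
    min_site_spacing = 500L,
    fe_meanlog_signal = log(15), fe_sdlog_signal = 0.5,
    fe_meanlog_noise = log(3.5), fe_sdlog_noise = 0.4,
    detection_prob = 0.85,
    n_noise_peaks = 800L,
    summit_jitter_sd = 5,
    peak_width_mean = 250, peak_width_sd = 40,
    samples = c("embryo", "liver"),
    shared_site_fraction = 0.75,
    n_controls = 2000L, control_length = 100L,
    hox_preset = "lamprey")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown generator field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(all(abs(rowSums(cfg$transition) - 1) < 1e-9),
            cfg$fraction_in_family >= 0, cfg$fraction_in_family <= 1,
            cfg$upstream_fraction >= 0, cfg$upstream_fraction <= 1,
            cfg$detection_prob > 0, cfg$detection_prob <= 1,
            cfg$chrom_length > 0)
  structure(cfg, class = "ctcf_sim_config")
}

## order-1 Markov chain of length L as a base-code vector
markov_chain_codes <- function(L, p0, trans) {
  cum <- t(apply(trans, 1L, cumsum))
  c1 <- cum[, 1L]; c2 <- cum[, 2L]; c3 <- cum[, 3L]
  u <- stats::runif(L)
  s <- integer(L)
  s[1L] <- findInterval(u[1L], cumsum(p0)) + 1L
  for (t in 2:L) {
    prev <- s[t - 1L]
    ut <- u[t]
    s[t] <- 1L + (ut > c1[prev]) + (ut > c2[prev]) + (ut > c3[prev])
  }
  s
}

#' Simulate a background genome
#'
#' Order-1 Markov chromosomes, optionally interrupted by blocks of `N`
#' (for exercising N-aware control sampling). Fully reproducible from the
#' config seed.
#'
#' @param cfg A [generator_config()].
#' @return A `DNAStringSet` with chromosomes `chr1 ... chrN`.
#' @export
make_genome <- function(cfg) {
  set.seed(cfg$seed)
  chroms <- lapply(seq_len(cfg$n_chroms), function(i) {
    codes <- markov_chain_codes(cfg$chrom_length, cfg$p0, cfg$transition)
    if (cfg$n_blocks > 0L) {
      for (b in seq_len(cfg$n_blocks)) {
        at <- sample.int(cfg$chrom_length - cfg$n_block_length, 1L)
        codes[at:(at + cfg$n_block_length - 1L)] <- 5L
      }
    }
    decode_dna(codes)
  })
  g <- Biostrings::DNAStringSet(unlist(chroms))
  names(g) <- paste0("chr", seq_len(cfg$n_chroms))
  g
}

## per-base substitution at `rate`; substitutions are to a uniformly chosen
## different base (no indels)
mutate_seq <- function(s, rate) {
  codes <- encode_dna(s)[[1]]
  hit <- which(stats::runif(length(codes)) < rate & codes <= 4L)
  if (length(hit) > 0L)
    codes[hit] <- ((codes[hit] - 1L + sample(1:3, length(hit),
                                             replace = TRUE)) %% 4L) + 1L
  decode_dna(codes)
}

random_seq <- function(L, p0) {
  decode_dna(sample.int(4L, L, replace = TRUE, prob = p0))
}

#' Plant repeat families and two-part binding sites into a genome
#'
#' Generates a consensus sequence per repeat family (the motif-carrying
#' family's consensus embeds the core motif), scatters mutated copies
#' without overlap on both strands, then plants the true binding sites: a
#' configured fraction live inside copies of the motif family (their core —
#' and, for a random `upstream_fraction`, the upstream motif 5' of it — is
#' refreshed at the site mutation rate), the rest are written into repeat-
#' free background with random strands. Site cores keep a minimum spacing so
#' peaks of neighbouring sites stay distinct.
#'
#' @param genome A `DNAStringSet` from [make_genome()].
#' @param cfg The [generator_config()] used.
#' @return List: `genome` (modified), `repeats` (`GRanges` with `family_id`,
#'   `class_label`, `divergence_pct`), `truth` (list with the `sites`
#'   data.frame, per-sample site indices, family consensuses and the
#'   config).
#' @export
plant_repeats_and_sites <- function(genome, cfg) {
  set.seed(cfg$seed + 1L)
  fam <- cfg$repeat_families
  planted <- sum(fam$consensus_length * fam$n_copies)
  if (planted > 0.2 * sum(Biostrings::width(genome)))
    stop("planted repeat material exceeds 20% of the genome")
  glen <- Biostrings::width(genome)
  chroms <- names(genome)
  occ <- lapply(glen, function(L) logical(L))
  for (i in seq_along(genome)) {   # N blocks are off limits
    nb <- as.integer(Biostrings::letterFrequencyInSlidingView(
      genome[[i]], 1L, "N")) > 0L
    occ[[i]][nb] <- TRUE
  }
  ## per-base character vectors: in-place writes instead of whole-string
  ## copies when planting thousands of features
  gchar <- lapply(as.character(genome), function(s) strsplit(s, "")[[1L]])
  write_at <- function(ci, at, seq_str) {
    gchar[[ci]][at:(at + nchar(seq_str) - 1L)] <<- strsplit(seq_str, "")[[1L]]
  }

  consensus <- character(nrow(fam))
  for (f in seq_len(nrow(fam))) {
    consensus[f] <- random_seq(fam$consensus_length[f], cfg$p0)
    if (fam$family_id[f] == cfg$motif_family) {
      substr(consensus[f], cfg$core_offset,
             cfg$core_offset + nchar(cfg$core_consensus) - 1L) <-
        cfg$core_consensus
    }
  }
  names(consensus) <- fam$family_id

  place_interval <- function(len, gap = 10L) {
    for (try in seq_len(2000L)) {
      ci <- sample.int(length(chroms), 1L, prob = glen)
      s <- sample.int(glen[ci] - len - 2L * gap, 1L) + gap
      span <- (s - gap):(s + len - 1L + gap)
      if (!any(occ[[ci]][span])) {
        occ[[ci]][span] <<- TRUE
        return(c(ci, s))
      }
    }
    stop("placement capacity error: could not place a ", len, "-bp interval")
  }

  rep_chr <- integer(0); rep_start <- integer(0); rep_len <- integer(0)
  rep_fam <- character(0); rep_strand <- character(0); rep_div <- numeric(0)
  copy_seqs <- character(0)
  for (f in seq_len(nrow(fam))) {
    for (k in seq_len(fam$n_copies[f])) {
      len <- fam$consensus_length[f]
      at <- place_interval(len)
      cs <- mutate_seq(consensus[f], fam$divergence[f])
      strand <- sample(c("+", "-"), 1L)
      written <- if (strand == "-") revcomp(cs) else cs
      write_at(at[1L], at[2L], written)
      rep_chr <- c(rep_chr, at[1L]); rep_start <- c(rep_start, at[2L])
      rep_len <- c(rep_len, len); rep_fam <- c(rep_fam, fam$family_id[f])
      rep_strand <- c(rep_strand, strand)
      rep_div <- c(rep_div, 100 * mean(
        encode_dna(cs)[[1]] != encode_dna(consensus[f])[[1]]))
      copy_seqs <- c(copy_seqs, cs)
    }
  }
  repeats <- GenomicRanges::GRanges(
    seqnames = chroms[rep_chr],
    ranges = IRanges::IRanges(start = rep_start, width = rep_len),
    strand = rep_strand,
    family_id = rep_fam,
    class_label = fam$class_label[match(rep_fam, fam$family_id)],
    divergence_pct = round(rep_div, 1))

  ## ---- binding sites -----------------------------------------------------
  wc <- nchar(cfg$core_consensus); wu <- nchar(cfg$upstream_consensus)
  gap_up <- cfg$core_offset - (cfg$upstream_offset + wu)  # bp between motifs
  n_fam_sites <- round(cfg$n_true_sites * cfg$fraction_in_family)
  site_chr <- integer(0); site_start <- integer(0); site_strand <- character(0)
  site_up <- logical(0); site_fam <- character(0)
  centers <- lapply(seq_along(chroms), function(i) integer(0))
  far_enough <- function(ci, center) {
    all(abs(centers[[ci]] - center) >= cfg$min_site_spacing)
  }

  write_site <- function(ci, core_start, strand, with_up) {
    core <- mutate_seq(cfg$core_consensus, cfg$site_mutation_rate)
    if (strand == "+") {
      write_at(ci, core_start, core)
      if (with_up) {
        up <- mutate_seq(cfg$upstream_consensus, cfg$site_mutation_rate)
        write_at(ci, core_start - gap_up - wu, up)
      }
    } else {
      write_at(ci, core_start, revcomp(core))
      if (with_up) {
        up <- mutate_seq(cfg$upstream_consensus, cfg$site_mutation_rate)
        write_at(ci, core_start + wc + gap_up, revcomp(up))
      }
    }
  }

  ## sites carried by the motif family: refresh the core (+- upstream)
  ## inside chosen copies, in the copy's orientation
  fam_idx <- which(rep_fam == cfg$motif_family)
  if (n_fam_sites > length(fam_idx))
    stop("fraction_in_family asks for ", n_fam_sites,
         " family sites but only ", length(fam_idx), " copies exist")
  for (j in sample(fam_idx)) {
    if (length(site_chr) >= n_fam_sites) break
    ci <- rep_chr[j]; s <- rep_start[j]; len <- rep_len[j]
    core_start <- if (rep_strand[j] == "+") s + cfg$core_offset - 1L
                  else s + len - (cfg$core_offset - 1L) - wc
    center <- core_start + wc %/% 2L
    if (!far_enough(ci, center)) next
    with_up <- stats::runif(1L) < cfg$upstream_fraction
    write_site(ci, core_start, rep_strand[j], with_up)
    centers[[ci]] <- c(centers[[ci]], center)
    site_chr <- c(site_chr, ci); site_start <- c(site_start, core_start)
    site_strand <- c(site_strand, rep_strand[j])
    site_up <- c(site_up, with_up); site_fam <- c(site_fam, cfg$motif_family)
  }
  if (length(site_chr) < n_fam_sites)
    stop("placement capacity error: only ", length(site_chr), " of ",
         n_fam_sites, " family-borne sites placed at spacing ",
         cfg$min_site_spacing)

  ## background sites in repeat-free, N-free sequence
  n_bg <- cfg$n_true_sites - n_fam_sites
  margin <- wu + gap_up + 5L
  for (k in seq_len(n_bg)) {
    placed <- FALSE
    for (try in seq_len(2000L)) {
      ci <- sample.int(length(chroms), 1L, prob = glen)
      core_start <- sample.int(glen[ci] - 2L * margin - wc, 1L) + margin
      span <- (core_start - margin):(core_start + wc - 1L + margin)
      center <- core_start + wc %/% 2L
      if (any(occ[[ci]][span]) || !far_enough(ci, center)) next
      occ[[ci]][span] <- TRUE
      strand <- sample(c("+", "-"), 1L)
      with_up <- stats::runif(1L) < cfg$upstream_fraction
      write_site(ci, core_start, strand, with_up)
      centers[[ci]] <- c(centers[[ci]], center)
      site_chr <- c(site_chr, ci); site_start <- c(site_start, core_start)
      site_strand <- c(site_strand, strand)
      site_up <- c(site_up, with_up); site_fam <- c(site_fam, NA_character_)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("placement capacity error: background site ", k,
           " could not be placed")
  }

  n <- length(site_chr)
  sites <- data.frame(
    site_id = sprintf("site%04d", seq_len(n)),
    chrom = chroms[site_chr],
    core_start = site_start,
    core_end = site_start + wc - 1L,
    center = site_start + wc %/% 2L,
    strand = site_strand,
    has_upstream = site_up,
    family_id = site_fam,
    stringsAsFactors = FALSE)

  ## sample membership: with shared fraction f and total pool T, each sample
  ## holds n_s = T/(2-f) sites of which f*n_s are shared; family-borne sites
  ## are placed in the shared block so both samples carry the association
  f <- cfg$shared_site_fraction
  n_s <- round(n / (2 - f))
  n_shared <- round(f * n_s)
  if (n_fam_sites > n_shared)
    warning("family-borne sites exceed the shared block; the repeat ",
            "association is carried by one sample only")
  sample_sites <- list(seq_len(n_s),
                       if (n_s < n) c(seq_len(n_shared), seq(n_s + 1L, n))
                       else seq_len(n_shared))
  names(sample_sites) <- cfg$samples

  genome2 <- Biostrings::DNAStringSet(vapply(gchar, paste, "", collapse = ""))
  names(genome2) <- chroms
  list(genome = genome2, repeats = repeats,
       truth = list(config = cfg, sites = sites,
                    sample_sites = sample_sites,
                    family_consensus = consensus,
                    n_shared = n_shared, n_per_sample = n_s))
}

#' Simulate replicate peak calls for one sample
#'
#' Each of the sample's true sites is detected independently in replicate 1
#' and replicate 2 with the configured probability; the merged-replicates
#' run detects the union. Every detected site yields a peak with its own
#' width, summit jitter and log-normal fold-enrichment draw (the signal
#' distribution sits above the noise distribution, coupling fold enrichment
#' to motif presence). Noise peaks with low fold enrichment and no planted
#' motif are placed uniformly and independently per run, so they do not
#' survive the three-way consensus.
#'
#' @param truth The `truth` element of [plant_repeats_and_sites()].
#' @param cfg The [generator_config()] used.
#' @param sample Sample name (one of `cfg$samples`).
#' @return List: `rep1`, `rep2`, `merged` (peak `GRanges` in narrowPeak
#'   layout), `detected` (site indices per run), `map` (data.frame mapping
#'   merged peak names to `site_id`, `NA` for noise).
#' @export
simulate_peak_calls <- function(truth, cfg, sample = cfg$samples[1L]) {
  si <- match(sample, cfg$samples)
  stopifnot(!is.na(si))
  set.seed(cfg$seed + 10L + si)
  idx <- truth$sample_sites[[sample]]
  sites <- truth$sites[idx, , drop = FALSE]
  d1 <- stats::runif(nrow(sites)) < cfg$detection_prob
  d2 <- stats::runif(nrow(sites)) < cfg$detection_prob
  dm <- d1 | d2
  glen <- c(stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                            paste0("chr", seq_len(cfg$n_chroms))))

  site_peaks <- function(det, run) {
    s <- sites[det, , drop = FALSE]
    n <- nrow(s)
    if (n == 0L) return(list(gr = empty_peaks(), site_id = character(0)))
    width <- pmin(pmax(round(stats::rnorm(n, cfg$peak_width_mean,
                                          cfg$peak_width_sd)), 120L), 450L)
    summit <- s$center + round(stats::rnorm(n, 0, cfg$summit_jitter_sd))
    off <- round(width * stats::runif(n, 0.3, 0.7))
    start <- pmax(summit - off, 1L)
    end <- pmin(start + width - 1L, glen[s$chrom])
    summit <- pmin(pmax(summit, start), end)
    fe <- stats::rlnorm(n, cfg$fe_meanlog_signal, cfg$fe_sdlog_signal)
    gr <- GenomicRanges::GRanges(
      seqnames = s$chrom, ranges = IRanges::IRanges(start, end),
      strand = "*",
      name = sprintf("%s_%s_p%04d", sample, run, seq_len(n)),
      score = as.integer(pmin(round(10 * fe), 1000L)),
      signalValue = round(fe, 4), pValue = NA_real_, qValue = NA_real_,
      peak = as.integer(summit - start))
    list(gr = gr, site_id = s$site_id)
  }
  ## noise summits keep clear of true-site neighbourhoods: spurious
  ## enrichment elsewhere in the genome, not at binding sites
  site_centers <- split(truth$sites$center, truth$sites$chrom)
  clear_of_sites <- function(chrom, pos) {
    vapply(seq_along(pos), function(i) {
      ctr <- site_centers[[chrom[i]]]
      is.null(ctr) || min(abs(ctr - pos[i])) > 600L
    }, logical(1L))
  }
  noise_peaks <- function(run) {
    n <- cfg$n_noise_peaks
    if (n == 0L) return(empty_peaks())
    chrom <- character(0); center <- integer(0)
    while (length(center) < n) {
      m <- n - length(center)
      ch <- sample(names(glen), m, replace = TRUE)
      ps <- vapply(ch, function(c2) sample.int(glen[c2] - 900L, 1L) + 450L,
                   integer(1L))
      ok <- clear_of_sites(ch, ps)
      chrom <- c(chrom, ch[ok]); center <- c(center, ps[ok])
    }
    width <- pmin(pmax(round(stats::rnorm(n, cfg$peak_width_mean,
                                          cfg$peak_width_sd)), 120L), 450L)
    start <- pmax(center - width %/% 2L, 1L)
    fe <- stats::rlnorm(n, cfg$fe_meanlog_noise, cfg$fe_sdlog_noise)
    GenomicRanges::GRanges(
      seqnames = chrom, ranges = IRanges::IRanges(start, width = width),
      strand = "*",
      name = sprintf("%s_%s_n%04d", sample, run, seq_len(n)),
      score = as.integer(pmin(round(10 * fe), 1000L)),
      signalValue = round(fe, 4), pValue = NA_real_, qValue = NA_real_,
      peak = as.integer(width %/% 2L))
  }
  p1 <- site_peaks(d1, "rep1"); p2 <- site_peaks(d2, "rep2")
  pm <- site_peaks(dm, "merged")
  rep1 <- c(p1$gr, noise_peaks("rep1"))
  rep2 <- c(p2$gr, noise_peaks("rep2"))
  nm <- noise_peaks("merged")
  merged <- c(pm$gr, nm)
  map <- data.frame(name = merged$name,
                    site_id = c(pm$site_id, rep(NA_character_, length(nm))),
                    stringsAsFactors = FALSE)
  list(rep1 = GenomicRanges::sort(rep1, ignore.strand = TRUE),
       rep2 = GenomicRanges::sort(rep2, ignore.strand = TRUE),
       merged = GenomicRanges::sort(merged, ignore.strand = TRUE),
       detected = list(rep1 = sites$site_id[d1], rep2 = sites$site_id[d2],
                       merged = sites$site_id[dm]),
       map = map)
}
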