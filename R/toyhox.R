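#' Generate a toy Hox-cluster dataset with ground truth
#'
#' Builds two small Hox clusters (10 paralog groups plus Evx, one cluster on
#' each genomic strand so axis normalisation is exercised) on their own
#' chromosomes, plants oriented core-motif instances at chosen positions,
#' and emits the matching significant-peak calls. Both presets place
#' outward-pointing sites beyond both cluster ends and interior sites in the
#' 5-6 and 8-9 intergenic segments (shared across the two clusters), plus
#' one peak with no motif. The `"lamprey"` preset additionally places four
#' repeat-borne sites in the Hox1-4 region (segments 1-2, 2-3, 2-3, 3-4);
#' the `"gnathostome"` preset places none there.
#'
#' @param preset `"lamprey"` or `"gnathostome"`.
#' @param seed Integer seed.
#' @param cfg Optional [generator_config()] supplying background and motif
#'   parameters (defaults are used when omitted).
#' @return List: `genome` (`DNAStringSet`), `genes` (list of two gene
#'   `GRanges`), `clusters` (list of [hox_cluster()]), `peaks`
#'   (significant-peak `GRanges`), `repeats` (`GRanges`, empty for the
#'   gnathostome preset), `truth` (per-site data.frame with planted segment,
#'   orientation and Hox1-4 membership), `core_consensus`.
#' @export
make_toy_hox <- function(preset = c("lamprey", "gnathostome"), seed = 1L,
                         cfg = generator_config(seed)) {
  preset <- match.arg(preset)
  set.seed(cfg$seed + 20L + (preset == "lamprey"))
  gene_w <- 2000L; gap <- 8000L; lead <- 20000L
  n_hox <- 10L
  chrom_len <- 160000L
  wc <- nchar(cfg$core_consensus)

  ## cluster 1: groups increase with coordinate (axis +); cluster 2: the
  ## mirror layout (axis -)
  layout_genes <- function(chrom, axis) {
    starts <- lead + (seq_len(n_hox + 1L) - 1L) * (gene_w + gap)
    if (axis == "+") {
      nm <- c(paste0("Hox", seq_len(n_hox)), "Evx")
      grp <- c(seq_len(n_hox), NA_integer_)
      is_evx <- c(rep(FALSE, n_hox), TRUE)
    } else {
      nm <- c("Evx", paste0("Hox", rev(seq_len(n_hox))))
      grp <- c(NA_integer_, rev(seq_len(n_hox)))
      is_evx <- c(TRUE, rep(FALSE, n_hox))
    }
    GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = starts, width = gene_w),
      strand = "+",
      name = nm, paralog_group = grp, is_evx = is_evx)
  }
  genes <- list(layout_genes("hoxchr1", "+"), layout_genes("hoxchr2", "-"))
  clusters <- list(
    hox_cluster(genes[[1L]], species = "toy", cluster_name = "alpha"),
    hox_cluster(genes[[2L]], species = "toy", cluster_name = "beta"))

  ## site plan in normalised coordinates (0 = low-paralog/3' end);
  ## seg_centre(g) = centre of the segment between Hox g and Hox g+1
  seg_centre <- function(g) g * (gene_w + gap) - gap / 2
  plan <- data.frame(
    npos = c(-3000, seg_centre(5), seg_centre(8),
             (n_hox) * (gene_w + gap) + gene_w + 3000),
    orientation = c("reverse", "forward", "forward", "forward"),
    segment_key = c("3'-flank", "5-6", "8-9", "5'-flank"),
    repeat_borne = FALSE, in_1_4 = FALSE,
    stringsAsFactors = FALSE)
  if (preset == "lamprey") {
    extra <- data.frame(
      npos = c(seg_centre(1), seg_centre(2) - 1000, seg_centre(2) + 1000,
               seg_centre(3)),
      orientation = c("forward", "reverse", "forward", "reverse"),
      segment_key = c("1-2", "2-3", "2-3", "3-4"),
      repeat_borne = TRUE, in_1_4 = TRUE,
      stringsAsFactors = FALSE)
    plan <- rbind(plan, extra)
  }

  gseq <- c(random_seq(chrom_len, cfg$p0), random_seq(chrom_len, cfg$p0))
  names(gseq) <- c("hoxchr1", "hoxchr2")
  truth <- NULL
  peak_rows <- list()
  rep_rows <- list()
  for (ci in 1:2) {
    cl <- clusters[[ci]]
    for (r in seq_len(nrow(plan))) {
      npos <- plan$npos[r]
      gpos <- if (cl$axis == "+") cl$span_start + npos else cl$span_end - npos
      core_start <- as.integer(gpos - wc %/% 2L)
      ## orientation forward = motif 5'->3' toward higher paralog groups
      strand <- if ((plan$orientation[r] == "forward") == (cl$axis == "+"))
        "+" else "-"
      core <- mutate_seq(cfg$core_consensus, 0.02)
      written <- if (strand == "-") revcomp(core) else core
      substr(gseq[cl$chrom], core_start, core_start + wc - 1L) <- written
      if (plan$repeat_borne[r]) {
        ## embed the site in a copy of the motif-carrying family
        cons <- random_seq(120L, cfg$p0)
        rs <- core_start - cfg$core_offset + 1L
        pre <- substr(cons, 1L, cfg$core_offset - 1L)
        post <- substr(cons, cfg$core_offset + wc, 120L)
        substr(gseq[cl$chrom], rs, core_start - 1L) <- pre
        substr(gseq[cl$chrom], core_start + wc, rs + 119L) <- post
        substr(gseq[cl$chrom], core_start, core_start + wc - 1L) <- written
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          chrom = cl$chrom, start = rs, end = rs + 119L,
          stringsAsFactors = FALSE)
      }
      peak_rows[[length(peak_rows) + 1L]] <- data.frame(
        chrom = cl$chrom, summit = core_start + wc %/% 2L,
        cluster = cl$cluster_name, segment_key = plan$segment_key[r],
        orientation = plan$orientation[r], in_1_4 = plan$in_1_4[r],
        repeat_borne = plan$repeat_borne[r], has_motif = TRUE,
        stringsAsFactors = FALSE)
    }
    ## one motif-free binding site (green-bar case) between Hox6 and Hox7
    npos <- seg_centre(6)
    gpos <- if (cl$axis == "+") cl$span_start + npos else cl$span_end - npos
    peak_rows[[length(peak_rows) + 1L]] <- data.frame(
      chrom = cl$chrom, summit = as.integer(gpos), cluster = cl$cluster_name,
      segment_key = "6-7", orientation = "none", in_1_4 = FALSE,
      repeat_borne = FALSE, has_motif = FALSE, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, peak_rows)
  n <- nrow(truth)
  width <- 300L
  summit <- truth$summit + round(stats::rnorm(n, 0, 2))
  start <- summit - 150L
  fe <- round(15 + 20 * stats::runif(n), 4)
  peaks <- GenomicRanges::GRanges(
    seqnames = truth$chrom,
    ranges = IRanges::IRanges(start = start, width = width),
    strand = "*",
    name = sprintf("hox_p%03d", seq_len(n)),
    score = as.integer(round(10 * fe)),
    signalValue = fe, pValue = NA_real_, qValue = NA_real_,
    peak = as.integer(summit - start))
  truth$peak_id <- peaks$name
  repeats <- if (length(rep_rows) > 0L) {
    rr <- do.call(rbind, rep_rows)
    GenomicRanges::GRanges(
      seqnames = rr$chrom, ranges = IRanges::IRanges(rr$start, rr$end),
      family_id = cfg$motif_family,
      class_label = "DNA/hAT-Tip100", divergence_pct = NA_real_)
  } else empty_repeats()
  genome <- Biostrings::DNAStringSet(gseq)
  list(genome = genome, genes = genes, clusters = clusters, peaks = peaks,
       repeats = repeats, truth = truth, preset = preset,
       core_consensus = cfg$core_consensus)
}
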