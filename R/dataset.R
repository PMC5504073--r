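dataset_files <- function(samples) {
  c("genome.fa", "repeats.bed", "repeats.out",
    as.vector(outer(samples, c("rep1", "rep2", "merged"),
                    function(s, r) paste0(s, "_", r, ".narrowPeak"))),
    "hox_genome.fa", "hox_peaks.narrowPeak", "hox_genes.bed",
    "hox_genes.gff3", "hox_repeats.bed", "truth.json")
}

#' Write a complete synthetic dataset bundle
#'
#' Runs the whole generator and writes every file the pipeline consumes:
#' the genome FASTA, replicate-1 / replicate-2 / merged narrowPeak calls for
#' each sample, the repeat annotation in both the BED and the RepeatMasker
#' `.out` dialect, the toy Hox bundle (its own genome, significant peaks,
#' gene annotation in BED and GFF3, repeat BED), and the ground truth as
#' JSON. The bundle is byte-identical for identical configs.
#'
#' @param outdir Output directory (created if needed).
#' @param cfg A [generator_config()].
#' @return The ground-truth list, invisibly (with
#'   `$outdir` attached).
#' @export
write_dataset <- function(outdir, cfg = generator_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  g <- make_genome(cfg)
  pl <- plant_repeats_and_sites(g, cfg)
  write_fasta(pl$genome, file.path(outdir, "genome.fa"))
  write_repeat_annotation(pl$repeats, file.path(outdir, "repeats.bed"), "bed")
  write_repeat_annotation(pl$repeats, file.path(outdir, "repeats.out"), "rmout")
  calls <- lapply(cfg$samples, function(s)
    simulate_peak_calls(pl$truth, cfg, s))
  names(calls) <- cfg$samples
  for (s in cfg$samples)
    for (r in c("rep1", "rep2", "merged"))
      write_narrowpeak(calls[[s]][[r]],
                       file.path(outdir, paste0(s, "_", r, ".narrowPeak")))
  hox <- make_toy_hox(cfg$hox_preset, cfg = cfg)
  write_fasta(hox$genome, file.path(outdir, "hox_genome.fa"))
  write_narrowpeak(hox$peaks, file.path(outdir, "hox_peaks.narrowPeak"))
  all_genes <- suppressWarnings(do.call(c, hox$genes))
  write_gene_annotation(all_genes, file.path(outdir, "hox_genes.bed"), "bed")
  write_gene_annotation(all_genes, file.path(outdir, "hox_genes.gff3"), "gff3")
  write_repeat_annotation(hox$repeats, file.path(outdir, "hox_repeats.bed"),
                          "bed")
  truth <- pl$truth
  truth$config <- unclass(truth$config)
  truth$config$transition <- as.vector(t(truth$config$transition))
  truth$config$repeat_families <- as.list(truth$config$repeat_families)
  truth$family_copy_counts <- as.list(table(pl$repeats$family_id))
  truth$peak_counts <- lapply(calls, function(cl)
    list(rep1 = length(cl$rep1), rep2 = length(cl$rep2),
         merged = length(cl$merged)))
  truth$detected <- lapply(calls, `[[`, "detected")
  truth$merged_map <- lapply(calls, `[[`, "map")
  truth$hox <- hox$truth
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  out <- pl$truth
  out$outdir <- outdir
  invisible(out)
}

#' Validate a written dataset bundle against its ground truth
#'
#' Re-reads every file of a [write_dataset()] bundle and asserts internal
#' consistency: all files present (a missing file is named in the error),
#' genome ids and lengths match the config, per-family repeat copy counts
#' match the truth and the two annotation dialects agree interval-for-
#' interval, peak counts match the simulated detection record, the genome
#' sequence at every planted site is close to the core consensus (Hamming
#' distance within the mutation budget), and the Hox gene annotations parse
#' to the expected paralog groups in both formats.
#'
#' @param outdir Bundle directory.
#' @return `TRUE`, invisibly; otherwise an error describing the first
#'   inconsistency.
#' @export
validate_dataset <- function(outdir) {
  truth <- jsonlite::read_json(file.path(outdir, "truth.json"),
                               simplifyVector = TRUE)
  samples <- truth$config$samples
  for (f in dataset_files(samples))
    if (!file.exists(file.path(outdir, f)))
      stop("dataset bundle is missing file '", f, "'")
  genome <- read_fasta(file.path(outdir, "genome.fa"))
  if (length(genome) != truth$config$n_chroms ||
      !all(Biostrings::width(genome) == truth$config$chrom_length))
    stop("genome.fa does not match the configured chromosomes")
  rb <- read_repeat_annotation(file.path(outdir, "repeats.bed"), "bed")
  ro <- read_repeat_annotation(file.path(outdir, "repeats.out"), "rmout")
  cb <- table(rb$family_id); co <- table(ro$family_id)
  want <- unlist(truth$family_copy_counts)
  if (!identical(as.integer(cb[names(want)]), unname(as.integer(want))))
    stop("repeats.bed family copy counts disagree with the ground truth")
  if (!identical(as.integer(co[names(want)]), unname(as.integer(want))))
    stop("repeats.out family copy counts disagree with the ground truth")
  if (length(rb) != length(ro) ||
      !all(GenomicRanges::start(rb) == GenomicRanges::start(ro)) ||
      !all(GenomicRanges::end(rb) == GenomicRanges::end(ro)))
    stop("repeat annotation dialects disagree on intervals")
  for (s in samples)
    for (r in c("rep1", "rep2", "merged")) {
      pk <- read_narrowpeak(file.path(outdir, paste0(s, "_", r,
                                                     ".narrowPeak")))
      if (length(pk) != truth$peak_counts[[s]][[r]])
        stop("peak count mismatch for ", s, " ", r)
    }
  ## planted cores: Hamming distance to consensus within the mutation budget
  sites <- truth$sites
  core <- truth$config$core_consensus
  wc <- nchar(core)
  budget <- max(8L, ceiling(3 * wc * truth$config$site_mutation_rate + 3))
  cc <- encode_dna(core)[[1]]
  for (i in seq_len(nrow(sites))) {
    s <- as.character(Biostrings::subseq(genome[[sites$chrom[i]]],
                                         sites$core_start[i],
                                         sites$core_end[i]))
    if (sites$strand[i] == "-") s <- revcomp(s)
    if (sum(encode_dna(s)[[1]] != cc) > budget)
      stop("site ", sites$site_id[i], " sequence is too far from the core ",
           "consensus")
  }
  gb <- read_gene_annotation(file.path(outdir, "hox_genes.bed"), "bed")
  gg <- read_gene_annotation(file.path(outdir, "hox_genes.gff3"), "gff3")
  if (length(gb) != length(gg) ||
      !identical(gb$name, gg$name) ||
      !identical(gb$paralog_group, gg$paralog_group) ||
      !all(GenomicRanges::start(gb) == GenomicRanges::start(gg)))
    stop("hox gene annotations disagree between BED and GFF3")
  invisible(TRUE)
}
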