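#' @importFrom methods is
#' @importFrom stats setNames
#' @importFrom utils head
NULL

#' Read a genome FASTA file
#'
#' Loads a genome assembly (or any nucleotide FASTA) into a
#' [Biostrings::DNAStringSet]. Sequences are case-folded to upper case and any
#' IUPAC ambiguity code other than A/C/G/T/N is replaced by `N`; a warning
#' reports how many letters were masked. The result is the package's genome
#' container: all downstream windows, scans and control-region sampling index
#' into it by sequence name.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet` over the alphabet \{A,C,G,T,N\}, named by record id
#'   (first whitespace-delimited token of the header).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L)
    stop("FASTA format error: no records in '", path, "'")
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("FASTA format error: duplicate sequence id '",
         names(x)[duplicated(names(x))][1L], "'")
  if (any(Biostrings::width(x) == 0L))
    stop("FASTA format error: empty sequence record")
  af <- Biostrings::alphabetFrequency(x)
  bad <- sum(af[, !colnames(af) %in% c("A", "C", "G", "T", "N"), drop = FALSE])
  if (bad > 0) {
    warning(bad, " non-ACGTN letter(s) replaced by N")
    x <- Biostrings::replaceAmbiguities(x, new = "N")
  }
  x
}

#' Write a genome FASTA file
#'
#' Canonical writer paired with [read_fasta()]: 60-column wrapped upper-case
#' sequence, one record per id. `write_fasta(read_fasta(f))` reproduces any
#' file written by this function byte for byte.
#'
#' @param genome A named `DNAStringSet` (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  if (is.character(genome))
    genome <- Biostrings::DNAStringSet(genome)
  stopifnot(!is.null(names(genome)), all(nzchar(names(genome))))
  Biostrings::writeXStringSet(genome, path, width = 60L)
  invisible(path)
}

## numeric formatting shared by the tabular writers: plain decimal notation,
## trailing zeros stripped, so written files are canonical and re-readable
## byte-identically.
format_plain <- function(x, digits = 6L) {
  out <- sprintf(paste0("%.", digits, "f"), x)
  out <- sub("0+$", "", out)
  out <- sub("\\.$", "", out)
  out[x == floor(x) & abs(x) < 1e15] <- sprintf("%d", as.integer(x[x == floor(x) & abs(x) < 1e15]))
  out
}

read_tsv_lines <- function(path) {
  lines <- readLines(path)
  lines[nzchar(lines)]
}

#' Read ENCODE narrowPeak peak calls
#'
#' Parses the 10-column narrowPeak dialect (BED6+4) emitted by MACS2 and
#' similar peak callers into a [GenomicRanges::GRanges]. File coordinates are
#' 0-based half-open and are converted to the 1-based closed convention of
#' `GRanges`. Metadata columns: `name`, `score`, `signalValue` (fold
#' enrichment over input), `pValue` and `qValue` (-log10, `-1` = missing, kept
#' as `NA`), and `peak` (summit offset from the 0-based start). The pipeline
#' requires summits, so a `-1` summit offset is a format error.
#'
#' @param path Path to a narrowPeak file.
#' @return A `GRanges` with one range per peak. The 1-based summit position is
#'   `start(gr) + gr$peak`.
#' @export
read_narrowpeak <- function(path) {
  stopifnot(file.exists(path))
  lines <- read_tsv_lines(path)
  if (length(lines) == 0L) return(empty_peaks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 10L))
    stop("narrowPeak format error at line ", which(nf != 10L)[1L],
         ": expected 10 tab-separated columns, got ", nf[nf != 10L][1L])
  m <- matrix(unlist(fields), ncol = 10L, byrow = TRUE)
  start0 <- as.integer(m[, 2L]); end0 <- as.integer(m[, 3L])
  if (any(is.na(start0)) || any(is.na(end0)) || any(start0 < 0L) || any(start0 >= end0))
    stop("narrowPeak format error: invalid interval at line ",
         which(is.na(start0) | is.na(end0) | start0 < 0L | start0 >= end0)[1L])
  summit <- as.integer(m[, 10L])
  if (any(is.na(summit) | summit < 0L))
    stop("narrowPeak format error: missing summit (column 10 is -1 or invalid) at line ",
         which(is.na(summit) | summit < 0L)[1L],
         "; the pipeline requires peak summits")
  if (any(summit >= end0 - start0))
    stop("narrowPeak format error: summit offset outside peak at line ",
         which(summit >= end0 - start0)[1L])
  fe <- as.numeric(m[, 7L])
  if (any(is.na(fe) | fe <= 0))
    stop("narrowPeak format error: signalValue (fold enrichment) must be > 0, line ",
         which(is.na(fe) | fe <= 0)[1L])
  strand <- m[, 6L]
  if (!all(strand %in% c("+", "-", ".")))
    stop("narrowPeak format error: bad strand at line ",
         which(!strand %in% c("+", "-", "."))[1L])
  p <- as.numeric(m[, 8L]); q <- as.numeric(m[, 9L])
  gr <- GenomicRanges::GRanges(
    seqnames = m[, 1L],
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = ifelse(strand == ".", "*", strand),
    name = m[, 4L],
    score = as.integer(m[, 5L]),
    signalValue = fe,
    pValue = ifelse(p < 0, NA_real_, p),
    qValue = ifelse(q < 0, NA_real_, q),
    peak = summit
  )
  gr
}

empty_peaks <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = character(0), score = integer(0), signalValue = numeric(0),
    pValue = numeric(0), qValue = numeric(0), peak = integer(0))
  gr
}

#' Write peaks as narrowPeak
#'
#' Canonical writer paired with [read_narrowpeak()]; `NA` -log10 p/q values
#' are written as `-1` per the ENCODE convention.
#'
#' @param peaks A peak `GRanges` as returned by [read_narrowpeak()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  mc <- S4Vectors::mcols(peaks)
  strand <- as.character(GenomicRanges::strand(peaks))
  strand[strand == "*"] <- "."
  lines <- paste(
    as.character(GenomicRanges::seqnames(peaks)),
    GenomicRanges::start(peaks) - 1L,
    GenomicRanges::end(peaks),
    mc$name,
    mc$score,
    strand,
    format_plain(mc$signalValue),
    format_plain(ifelse(is.na(mc$pValue), -1, mc$pValue)),
    format_plain(ifelse(is.na(mc$qValue), -1, mc$qValue)),
    mc$peak,
    sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read repeat annotations (RepeatMasker .out or BED dialect)
#'
#' Loads repeat copies as a `GRanges` with metadata columns `family_id` (the
#' repeat library entry, e.g. `"274"`), `class_label` (e.g.
#' `"DNA/hAT-Tip100"`) and `divergence_pct` (percent divergence from the
#' library consensus; `NA` in the BED dialect). The RepeatMasker `.out`
#' dialect has a 2-line header plus blank line and 1-based closed query
#' coordinates; the BED dialect encodes `family_id#class` in column 4 with
#' 0-based half-open coordinates. Both are normalised to the `GRanges`
#' convention.
#'
#' @param path Path to the annotation file.
#' @param dialect `"rmout"` or `"bed"`.
#' @return A `GRanges` of repeat copies.
#' @export
read_repeat_annotation <- function(path, dialect = c("rmout", "bed")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  if (dialect == "bed") {
    lines <- read_tsv_lines(path)
    if (length(lines) == 0L) return(empty_repeats())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 4L))
      stop("repeat BED format error at line ", which(nf < 4L)[1L],
           ": need >= 4 columns")
    m <- vapply(fields, function(f) f[1:4], character(4L))
    name <- m[4L, ]
    hash <- regexpr("#", name, fixed = TRUE)
    if (any(hash < 0L))
      stop("repeat BED format error at line ", which(hash < 0L)[1L],
           ": column 4 must be family_id#class")
    start0 <- as.integer(m[2L, ]); end0 <- as.integer(m[3L, ])
    if (any(is.na(start0) | is.na(end0) | start0 >= end0))
      stop("repeat BED format error at line ",
           which(is.na(start0) | is.na(end0) | start0 >= end0)[1L])
    return(GenomicRanges::GRanges(
      seqnames = m[1L, ],
      ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
      family_id = substr(name, 1L, hash - 1L),
      class_label = substr(name, hash + 1L, nchar(name)),
      divergence_pct = NA_real_))
  }
  ## rmout: 2 header lines + 1 blank, then whitespace-separated columns
  lines <- readLines(path)
  if (length(lines) > 0L && grepl("^\\s*SW", lines[1L]))
    lines <- lines[-seq_len(min(3L, length(lines)))]
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_repeats())
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 14L))
    stop("rmout format error at line ", lineno[nf < 14L][1L],
         ": expected >= 14 whitespace-separated columns")
  m <- vapply(fields, function(f) f[1:14], character(14L))
  begin1 <- as.integer(m[6L, ]); end1 <- as.integer(m[7L, ])
  if (any(is.na(begin1) | is.na(end1) | begin1 > end1 | begin1 < 1L))
    stop("rmout format error at line ",
         lineno[is.na(begin1) | is.na(end1) | begin1 > end1 | begin1 < 1L][1L],
         ": bad query coordinates")
  GenomicRanges::GRanges(
    seqnames = m[5L, ],
    ranges = IRanges::IRanges(start = begin1, end = end1),
    strand = ifelse(m[9L, ] == "C", "-", "+"),
    family_id = m[10L, ],
    class_label = m[11L, ],
    divergence_pct = as.numeric(m[2L, ]))
}

empty_repeats <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    family_id = character(0), class_label = character(0),
    divergence_pct = numeric(0))
  gr
}

#' Write repeat annotations
#'
#' Writers paired with [read_repeat_annotation()]. The BED dialect emits
#' `chrom start end family_id#class` (0-based half-open); the rmout dialect
#' emits the RepeatMasker `.out` layout (3 header lines, 1-based closed
#' coordinates, `C` for minus strand).
#'
#' @param repeats Repeat `GRanges` as from [read_repeat_annotation()].
#' @param path Output path.
#' @param dialect `"bed"` or `"rmout"`.
#' @return `path`, invisibly.
#' @export
write_repeat_annotation <- function(repeats, path, dialect = c("bed", "rmout")) {
  dialect <- match.arg(dialect)
  mc <- S4Vectors::mcols(repeats)
  if (dialect == "bed") {
    lines <- paste(as.character(GenomicRanges::seqnames(repeats)),
                   GenomicRanges::start(repeats) - 1L,
                   GenomicRanges::end(repeats),
                   paste0(mc$family_id, "#", mc$class_label),
                   sep = "\t")
    writeLines(lines, path)
    return(invisible(path))
  }
  strand <- as.character(GenomicRanges::strand(repeats))
  div <- ifelse(is.na(mc$divergence_pct), 0, mc$divergence_pct)
  header <- c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    "")
  lines <- paste(
    "  100", format_plain(div, 1L), "0.0 0.0",
    as.character(GenomicRanges::seqnames(repeats)),
    GenomicRanges::start(repeats),
    GenomicRanges::end(repeats),
    "(0)",
    ifelse(strand == "-", "C", "+"),
    mc$family_id,
    mc$class_label,
    "1",
    GenomicRanges::end(repeats) - GenomicRanges::start(repeats) + 1L,
    "(0)",
    seq_along(repeats))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Parse a Hox gene name into its paralog group
#'
#' Recognises the field's naming patterns: `Hox` followed by an optional
#' cluster designator (a Latin letter as in `HoxA5`, or a Greek letter as in
#' the lamprey clusters, e.g. `"Hoxα4"`) and a paralog-group number 1-13;
#' and `Evx`, the even-skipped homologue flanking the 5' end of vertebrate
#' clusters. Matching is case-insensitive in the `Hox`/`Evx` prefix.
#'
#' @param name Character vector of gene names.
#' @return A data.frame with columns `name`, `paralog_group` (integer, `NA`
#'   when unparseable) and `is_evx` (logical).
#' @export
parse_hox_name <- function(name) {
  is_evx <- grepl("^[Ee][Vv][Xx]", name)
  pat <- "^[Hh][Oo][Xx]([A-Za-zα-ω]?)(1[0-3]|[1-9])([^0-9].*)?$"
  grp <- rep(NA_integer_, length(name))
  mm <- regmatches(name, regexec(pat, name))
  for (i in seq_along(name))
    if (length(mm[[i]]) > 0L) grp[i] <- as.integer(mm[[i]][3L])
  data.frame(name = name, paralog_group = grp, is_evx = is_evx,
             stringsAsFactors = FALSE)
}

#' Read Hox gene annotations (BED or GFF3)
#'
#' Loads gene models as a `GRanges` with metadata `name`, `paralog_group` and
#' `is_evx` (see [parse_hox_name()]). Gene names that encode neither a Hox
#' paralog group nor Evx are retained with `paralog_group = NA` and a warning.
#' BED is read as BED6 (column 4 = name); GFF3 is read via
#' [rtracklayer::import()], keeping `type == "gene"` records (all records if
#' none are typed `gene`) and taking the `Name` attribute (falling back to
#' `ID`).
#'
#' @param path Path to the annotation file.
#' @param format `"bed"` or `"gff3"`.
#' @return A gene `GRanges`, sorted by position.
#' @export
read_gene_annotation <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  if (format == "bed") {
    lines <- read_tsv_lines(path)
    lines <- lines[!grepl("^(track|browser|#)", lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 4L))
      stop("gene BED format error at line ", which(nf < 4L)[1L],
           ": need >= 4 columns")
    chrom <- vapply(fields, `[`, "", 1L)
    start0 <- as.integer(vapply(fields, `[`, "", 2L))
    end0 <- as.integer(vapply(fields, `[`, "", 3L))
    nm <- vapply(fields, `[`, "", 4L)
    strand <- vapply(fields, function(f) if (length(f) >= 6L) f[6L] else "+", "")
    gr <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
      strand = ifelse(strand %in% c("+", "-"), strand, "*"))
  } else {
    g <- rtracklayer::import(path, format = "gff3")
    if ("type" %in% names(S4Vectors::mcols(g)) &&
        any(as.character(g$type) == "gene"))
      g <- g[as.character(g$type) == "gene"]
    nm <- if (!is.null(g$Name)) as.character(g$Name) else as.character(g$ID)
    gr <- GenomicRanges::granges(g)
  }
  ph <- parse_hox_name(nm)
  if (any(is.na(ph$paralog_group) & !ph$is_evx))
    warning("gene name(s) with unparseable Hox paralog group: ",
            paste(head(nm[is.na(ph$paralog_group) & !ph$is_evx], 3L),
                  collapse = ", "))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = nm, paralog_group = ph$paralog_group, is_evx = ph$is_evx)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write Hox gene annotations
#'
#' BED6 or GFF3 writer paired with [read_gene_annotation()].
#'
#' @param genes Gene `GRanges` as from [read_gene_annotation()].
#' @param path Output path.
#' @param format `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  strand <- as.character(GenomicRanges::strand(genes))
  strand[strand == "*"] <- "+"
  if (format == "bed") {
    lines <- paste(as.character(GenomicRanges::seqnames(genes)),
                   GenomicRanges::start(genes) - 1L,
                   GenomicRanges::end(genes),
                   genes$name, 0L, strand, sep = "\t")
    writeLines(lines, path)
  } else {
    lines <- paste(as.character(GenomicRanges::seqnames(genes)),
                   "ctcfLandscape", "gene",
                   GenomicRanges::start(genes),
                   GenomicRanges::end(genes),
                   ".", strand, ".",
                   paste0("ID=", genes$name, ";Name=", genes$name),
                   sep = "\t")
    writeLines(c("##gff-version 3", lines), path)
  }
  invisible(path)
}
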