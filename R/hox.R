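#' Construct a Hox cluster frame
#'
#' Wraps an ordered set of Hox (and optionally Evx) gene models into the
#' coordinate frame used for cross-cluster comparison. The cluster axis is
#' the direction in which paralog-group numbers increase along the
#' chromosome; all binding-site positions and orientations are normalised to
#' it, so clusters encoded on either strand are comparable. In the
#' normalised frame position 0 is the low-paralog (3') end and coordinates
#' grow toward the high-paralog (5') end, where Evx sits.
#'
#' @param genes Gene `GRanges` from [read_gene_annotation()]; all on one
#'   chromosome, with >= 2 genes carrying a paralog group.
#' @param species,cluster_name Labels carried through to profiles.
#' @return Object of class `"hox_cluster"`: `genes` (sorted by coordinate),
#'   `species`, `cluster_name`, `axis` (`"+"`/`"-"`), `chrom`, `span_start`,
#'   `span_end`.
#' @export
hox_cluster <- function(genes, species = NA_character_,
                        cluster_name = NA_character_) {
  stopifnot(is(genes, "GRanges"))
  chrom <- unique(as.character(GenomicRanges::seqnames(genes)))
  if (length(chrom) != 1L)
    stop("a Hox cluster must lie on a single chromosome")
  genes <- GenomicRanges::sort(genes, ignore.strand = TRUE)
  grp <- genes$paralog_group
  hox <- which(!is.na(grp) & !genes$is_evx)
  if (length(hox) < 2L)
    stop("need >= 2 genes with a parseable paralog group")
  axis <- if (stats::cor(GenomicRanges::start(genes)[hox], grp[hox]) >= 0)
    "+" else "-"
  ordered_grp <- if (axis == "+") grp[hox] else rev(grp[hox])
  if (is.unsorted(ordered_grp))
    stop("paralog groups are not monotone along the cluster axis")
  structure(list(genes = genes, species = species,
                 cluster_name = cluster_name, axis = axis, chrom = chrom,
                 span_start = min(GenomicRanges::start(genes)),
                 span_end = max(GenomicRanges::end(genes))),
            class = "hox_cluster")
}

#' @export
print.hox_cluster <- function(x, ...) {
  cat("Hox cluster", x$cluster_name, "(", x$species, ") on", x$chrom,
      sprintf("[%d-%d] axis %s, %d genes\n", x$span_start, x$span_end,
              x$axis, length(x$genes)))
  invisible(x)
}

## normalised position: 0 at the low-paralog (3') end, increasing with
## paralog group
norm_pos <- function(cluster, genomic_pos) {
  if (cluster$axis == "+") genomic_pos - cluster$span_start
  else cluster$span_end - genomic_pos
}

## genes in normalised order with normalised body intervals
norm_genes <- function(cluster) {
  g <- cluster$genes
  lo <- norm_pos(cluster, GenomicRanges::start(g))
  hi <- norm_pos(cluster, GenomicRanges::end(g))
  df <- data.frame(name = g$name, group = g$paralog_group,
                   is_evx = g$is_evx,
                   lo = pmin(lo, hi), hi = pmax(lo, hi),
                   stringsAsFactors = FALSE)
  df[order(df$lo), , drop = FALSE]
}

#' Significant peaks within a Hox cluster
#'
#' Peaks whose summit falls within the cluster span extended by `flank_bp`
#' on both sides, sorted along the normalised cluster axis.
#'
#' @param peaks Significant-peak `GRanges`.
#' @param cluster A [hox_cluster()].
#' @param flank_bp Extension beyond the outermost gene bodies (default
#'   10000).
#' @return `GRanges` subset of `peaks`, axis-sorted.
#' @export
peaks_in_cluster <- function(peaks, cluster, flank_bp = 10000L) {
  chr <- as.character(GenomicRanges::seqnames(peaks))
  s <- peak_summits(peaks)
  keep <- chr == cluster$chrom &
    s >= cluster$span_start - flank_bp &
    s <= cluster$span_end + flank_bp
  out <- peaks[keep]
  out[order(norm_pos(cluster, peak_summits(out)))]
}

## intergenic segment of a normalised position: within-gene positions get
## the gene name; outside the gene span, "3'-flank"/"5'-flank"; otherwise
## "between A and B" plus a paralog-pair key for cross-cluster comparison
segment_of <- function(cluster, npos) {
  ng <- norm_genes(cluster)
  k <- nrow(ng)
  seg <- character(length(npos)); key <- character(length(npos))
  for (i in seq_along(npos)) {
    p <- npos[i]
    inside <- which(p >= ng$lo & p <= ng$hi)
    if (length(inside) > 0L) {
      seg[i] <- paste0("within ", ng$name[inside[1L]])
      key[i] <- NA_character_
    } else if (p < ng$lo[1L]) {
      seg[i] <- "3'-flank"; key[i] <- "3'-flank"
    } else if (p > ng$hi[k]) {
      seg[i] <- "5'-flank"; key[i] <- "5'-flank"
    } else {
      j <- max(which(ng$hi < p))
      seg[i] <- paste0("between ", ng$name[j], " and ", ng$name[j + 1L])
      lab <- function(r) if (ng$is_evx[r]) "Evx" else as.character(ng$group[r])
      key[i] <- paste0(lab(j), "-", lab(j + 1L))
    }
  }
  data.frame(segment = seg, segment_key = key, stringsAsFactors = FALSE)
}

#' Call oriented binding sites in a Hox cluster
#'
#' For each cluster peak, scans the summit +/- `flank` window for the core
#' motif (best hit by p-value, threshold `thresh_p`), normalises the hit
#' strand to the cluster axis (orientation `"forward"` = the motif's 5'->3'
#' points toward higher paralog groups), and assigns the summit to its
#' intergenic segment. Peaks without a passing hit are retained with
#' orientation `"none"` (the green-bar case). When a repeat annotation is
#' supplied, each call is flagged if its peak overlaps a repeat copy.
#'
#' @param cluster_peaks `GRanges` from [peaks_in_cluster()].
#' @param cluster A [hox_cluster()].
#' @param core_pwm Core motif [new_pwm()].
#' @param genome `DNAStringSet` genome.
#' @param background0 Order-0 background for scan p-values.
#' @param thresh_p Scan threshold (default 1e-3, the cross-species setting).
#' @param repeats Optional repeat `GRanges` for the overlap flag.
#' @param flank Scan-window half-width (default 100).
#' @return data.frame of class `"binding_site_calls"`: `peak_id`, `summit`,
#'   `position` (normalised), `orientation`, `has_core_motif`, `pvalue`,
#'   `overlaps_repeat`, `segment`, `segment_key`; sorted by `position`.
#' @export
call_binding_sites <- function(cluster_peaks, cluster, core_pwm, genome,
                               background0, thresh_p = 1e-3, repeats = NULL,
                               flank = 100L) {
  n <- length(cluster_peaks)
  ids <- if (!is.null(cluster_peaks$name)) cluster_peaks$name
         else as.character(seq_len(n))
  orientation <- rep("none", n)
  pval <- rep(NA_real_, n)
  if (n > 0L) {
    win <- summit_windows(cluster_peaks, flank, seqlengths = genome)
    hits <- scan_pwm(genome, win, core_pwm, background0,
                     thresh_p = thresh_p)
    best <- best_hit_per_peak(hits)
    idx <- match(best$peak_id, ids)
    hs <- as.character(GenomicRanges::strand(best))
    fwd <- (hs == "+") == (cluster$axis == "+")
    orientation[idx] <- ifelse(fwd, "forward", "reverse")
    pval[idx] <- best$pvalue
  }
  summit <- peak_summits(cluster_peaks)
  npos <- norm_pos(cluster, summit)
  segs <- segment_of(cluster, npos)
  ovl <- if (!is.null(repeats))
    IRanges::overlapsAny(cluster_peaks, repeats, ignore.strand = TRUE)
  else rep(NA, n)
  out <- data.frame(peak_id = ids, summit = summit, position = npos,
                    orientation = orientation,
                    has_core_motif = orientation != "none",
                    pvalue = pval, overlaps_repeat = ovl,
                    segment = segs$segment, segment_key = segs$segment_key,
                    stringsAsFactors = FALSE)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("binding_site_calls", "data.frame")
  out
}

#' Per-cluster binding-site profile
#'
#' Aggregates binding-site calls into the quantities compared across
#' clusters: counts per intergenic segment, the count in the Hox1-4 region
#' (all intergenic segments lying strictly between the group-1 and group-4
#' gene bodies), and whether the oriented call nearest each cluster end
#' points outward (away from the span between the first and last gene
#' bodies: `"reverse"` at the 3' end, `"forward"` at the 5' end).
#'
#' @param calls A [call_binding_sites()] data.frame.
#' @param cluster The matching [hox_cluster()].
#' @return Object of class `"cluster_profile"`: `cluster_name`, `species`,
#'   `segment_counts` (named, all segments incl. flanks), `total`,
#'   `hox1_4`, `outward_low`, `outward_high` (logical or NA when no oriented
#'   call exists).
#' @export
cluster_profile <- function(calls, cluster) {
  counts <- table(calls$segment)
  ng <- norm_genes(cluster)
  hox <- ng[!ng$is_evx & !is.na(ng$group), , drop = FALSE]
  hox1_4 <- 0L
  if (any(hox$group <= 1) && any(hox$group >= 4)) {
    lo_end <- max(hox$hi[hox$group == min(hox$group[hox$group >= 1])])
    hi_start <- min(hox$lo[hox$group == max(hox$group[hox$group <= 4])])
    intergenic <- is.na(calls$segment_key) == FALSE &
      !calls$segment_key %in% c("3'-flank", "5'-flank")
    hox1_4 <- sum(intergenic & calls$position > lo_end &
                    calls$position < hi_start)
  }
  oriented <- calls[calls$orientation != "none", , drop = FALSE]
  outward_low <- outward_high <- NA
  if (nrow(oriented) > 0L) {
    outward_low <- oriented$orientation[which.min(oriented$position)] ==
      "reverse"
    outward_high <- oriented$orientation[which.max(oriented$position)] ==
      "forward"
  }
  structure(list(cluster_name = cluster$cluster_name,
                 species = cluster$species,
                 segment_counts = counts,
                 segment_keys = stats::setNames(calls$segment_key,
                                                calls$segment)[
                   !duplicated(calls$segment)],
                 total = nrow(calls), hox1_4 = as.integer(hox1_4),
                 outward_low = outward_low, outward_high = outward_high),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat("Cluster", x$cluster_name, "(", x$species, "):", x$total,
      "sites;", x$hox1_4, "in the Hox1-4 region; outward ends:",
      x$outward_low, "/", x$outward_high, "\n")
  invisible(x)
}

#' Compare binding-site profiles across clusters
#'
#' Builds the cluster x intergenic-segment occupancy matrix (columns keyed
#' by paralog-group pairs so homologous segments align across clusters and
#' species), per-cluster totals, the maximum per species, and the list of
#' segments occupied in at least `min_clusters` clusters — the formalisation
#' of "shared positioning" of binding sites between clusters.
#'
#' @param profiles List of [cluster_profile()] objects (>= 2).
#' @param min_clusters Occupancy threshold for the shared-segment list
#'   (default 2).
#' @return List: `occupancy` (integer matrix), `totals`, `max_per_species`,
#'   `shared_segments`.
#' @export
compare_profiles <- function(profiles, min_clusters = 2L) {
  stopifnot(length(profiles) >= 2L)
  seg_counts <- lapply(profiles, function(p) {
    key <- p$segment_keys[names(p$segment_counts)]
    ok <- !is.na(key) & !key %in% c("3'-flank", "5'-flank")
    tapply(as.integer(p$segment_counts)[ok], key[ok], sum)
  })
  keys <- sort(unique(unlist(lapply(seg_counts, names))))
  occ <- matrix(0L, length(profiles), length(keys),
                dimnames = list(vapply(profiles, function(p)
                  paste(p$species, p$cluster_name), ""), keys))
  for (i in seq_along(profiles))
    occ[i, names(seg_counts[[i]])] <- as.integer(seg_counts[[i]])
  totals <- vapply(profiles, `[[`, numeric(1), "total")
  species <- vapply(profiles, function(p) as.character(p$species), "")
  list(occupancy = occ,
       totals = stats::setNames(totals, rownames(occ)),
       max_per_species = tapply(totals, species, max),
       shared_segments = keys[colSums(occ > 0L) >= min_clusters])
}
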