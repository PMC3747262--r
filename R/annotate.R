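# Annotation of called regions: nearest gene and signed TSS distance,
# promoter membership (TSS -2000 bp to +1000 bp, strand-oriented), and
# overlap with regulatory-element interval tracks (TFBS, DNase clusters,
# histone-mark peaks).

#' Assign the nearest gene, TSS distance and promoter flag
#'
#' Distances are measured from the region midpoint to the gene's TSS,
#' signed in the gene's orientation: negative = upstream of the TSS.
#' The nearest gene minimizes the absolute distance among genes on the
#' region's chromosome (ties broken by lexicographically smaller
#' `gene_id`). A region is a promoter region when its anchor falls within
#' TSS -2000 bp to +1000 bp; with `promoter_rule = "midpoint"` (default)
#' the anchor is the midpoint, with `"overlap"` any 1-bp overlap of the
#' region with the window counts. Regions on chromosomes without genes
#' are returned unannotated (`NA`), not dropped.
#'
#' @param regions Region `data.frame` with `region_id`, `chrom`, `start`,
#'   `end`.
#' @param genes Gene model `data.frame` (`gene_id`, `chrom`, `tss`,
#'   `strand`, `tes`).
#' @param promoter_window Upstream/downstream extent of the promoter in
#'   bp, default `c(-2000, 1000)`.
#' @param promoter_rule `"midpoint"` or `"overlap"`.
#' @return `data.frame`: `region_id`, `nearest_gene`, `tss_distance`,
#'   `promoter`.
#' @export
assign_nearest_gene <- function(regions, genes,
                                promoter_window = c(-2000, 1000),
                                promoter_rule = c("midpoint", "overlap")) {
  promoter_rule <- match.arg(promoter_rule)
  mid <- (regions$start + regions$end) / 2
  out <- data.frame(region_id = regions$region_id,
                    nearest_gene = NA_character_,
                    tss_distance = NA_real_, promoter = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(regions))) {
    g <- genes[genes$chrom == regions$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) next
    # signed, strand-oriented distance of the midpoint to each TSS
    d <- ifelse(g$strand == "+", mid[i] - g$tss, g$tss - mid[i])
    ord <- order(abs(d), g$gene_id)
    j <- ord[1]
    out$nearest_gene[i] <- g$gene_id[j]
    out$tss_distance[i] <- d[j]
    if (promoter_rule == "midpoint") {
      out$promoter[i] <- d[j] >= promoter_window[1] &
        d[j] <= promoter_window[2]
    } else {
      # strand-oriented edges of the region
      e1 <- ifelse(g$strand[j] == "+", regions$start[i] - g$tss[j],
                   g$tss[j] - regions$end[i])
      e2 <- ifelse(g$strand[j] == "+", regions$end[i] - g$tss[j],
                   g$tss[j] - regions$start[i])
      out$promoter[i] <- min(e1, e2) <= promoter_window[2] &
        max(e1, e2) >= promoter_window[1]
    }
  }
  out
}

#' Overlap regions with regulatory-element tracks
#'
#' An element overlaps a region when the half-open intervals intersect in
#' at least 1 bp. Element names are aggregated per (region, track),
#' deduplicated, in stable genomic order. Implemented with
#' [IRanges::findOverlaps()] per chromosome.
#'
#' @param regions Region `data.frame` (`region_id`, `chrom`, `start`,
#'   `end`).
#' @param tracks Named list of interval `data.frame`s as returned by
#'   [read_bed()] or [simulate_tracks()]; names are the track names.
#' @return Long `data.frame`: `region_id`, `track`, `element` (one row
#'   per distinct overlapping element).
#' @export
overlap_tracks <- function(regions, tracks) {
  if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
    stop_data("overlap_tracks: tracks must be a named list")
  }
  res <- list()
  for (tn in names(tracks)) {
    tr <- tracks[[tn]]
    if (nrow(tr) == 0) next
    tr <- tr[order(tr$chrom, tr$start), , drop = FALSE]
    elem_names <- if ("name" %in% names(tr)) tr$name else
      sprintf("%s:%d-%d", tr$chrom, tr$start, tr$end)
    for (ch in intersect(unique(regions$chrom), unique(tr$chrom))) {
      ri <- which(regions$chrom == ch)
      ti <- which(tr$chrom == ch)
      # 0-based half-open -> 1-based closed for IRanges
      q <- IRanges::IRanges(start = regions$start[ri] + 1L,
                            end = regions$end[ri])
      s <- IRanges::IRanges(start = tr$start[ti] + 1L, end = tr$end[ti])
      hits <- IRanges::findOverlaps(q, s)
      if (length(hits) == 0) next
      res[[length(res) + 1]] <- data.frame(
        region_id = regions$region_id[ri][S4Vectors::queryHits(hits)],
        track = tn,
        element = elem_names[ti][S4Vectors::subjectHits(hits)],
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0) {
    return(data.frame(region_id = character(0), track = character(0),
                      element = character(0)))
  }
  out <- do.call(rbind, res)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Count regions with at least one overlap, per track
#'
#' @param overlaps Long overlap table from [overlap_tracks()].
#' @param tracks Optional character vector of track names to report
#'   (tracks without any overlap are reported as 0).
#' @return Named integer vector: per track, the number of distinct
#'   regions with >= 1 overlapping element.
#' @export
summarize_overlaps <- function(overlaps, tracks = NULL) {
  tracks <- tracks %||% unique(overlaps$track)
  counts <- vapply(tracks, function(tn) {
    length(unique(overlaps$region_id[overlaps$track == tn]))
  }, integer(1))
  stats::setNames(as.integer(counts), tracks)
}

#' Annotate called regions
#'
#' Combines [assign_nearest_gene()] and [overlap_tracks()] into one
#' record per region, with overlapping element names collapsed per track
#' into comma-separated strings (mirroring how DMR tables are usually
#' reported: distance from TSS, direction, TF names, DNase flag).
#'
#' @param calls Region call `data.frame` from [call_regions()] (or any
#'   region table with `region_id`, `chrom`, `start`, `end`).
#' @param genes Gene model table.
#' @param tracks Named list of annotation tracks.
#' @inheritParams assign_nearest_gene
#' @return `data.frame`: one row per region with nearest-gene fields plus
#'   one character column per track.
#' @export
annotate_regions <- function(calls, genes, tracks,
                             promoter_window = c(-2000, 1000),
                             promoter_rule = "midpoint") {
  ann <- assign_nearest_gene(calls, genes, promoter_window, promoter_rule)
  ov <- overlap_tracks(calls, tracks)
  for (tn in names(tracks)) {
    col <- vapply(calls$region_id, function(rid) {
      e <- ov$element[ov$region_id == rid & ov$track == tn]
      if (length(e) == 0) "" else paste(unique(e), collapse = ",")
    }, character(1))
    ann[[tn]] <- unname(col)
  }
  ann
}
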