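## Candidate-gene assignment: each marker gets its containing transcript
## (distance 0) or the nearest flanking transcripts up- and downstream in
## genome-coordinate (strand-agnostic) sense, plus GO/EC term collection
## and coordinate overlap with externally supplied QTL intervals.

#' Assign flanking transcripts to markers
#'
#' A marker lying inside a transcript (1-based closed interval) is
#' assigned that transcript at distance 0. Otherwise the nearest
#' transcript ending before the marker (upstream, distance
#' `pos - end`) and the nearest starting after it (downstream, distance
#' `start - pos`) are assigned; a missing side is reported as `NA`.
#' Equidistant ties are broken by the smaller start coordinate. Markers on
#' chromosomes absent from the annotation get no assignment, with a
#' warning.
#'
#' @param markers data.frame with columns `id`, `chrom`, `pos`.
#' @param annot data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), plus any of `strand`, `product`, `GO`, `EC`.
#' @return list: `assignment` (data.frame `marker`, `containing`,
#'   `upstream`, `upstream_dist`, `downstream`, `downstream_dist`),
#'   `meanDistance` (per-marker nearest distance, contained markers
#'   counted as 0) and `meanDistanceFlanking` (contained markers
#'   excluded) — both conventions are reported.
#' @export
assignFlankingGenes <- function(markers, annot) {
  if (any(annot$start > annot$end)) stop("annotation with start > end")
  res <- data.frame(marker = markers$id, containing = NA_character_,
                    upstream = NA_character_, upstream_dist = NA_real_,
                    downstream = NA_character_, downstream_dist = NA_real_,
                    stringsAsFactors = FALSE)
  missingChrom <- setdiff(unique(markers$chrom), unique(annot$chrom))
  if (length(missingChrom))
    warning("no annotation on chromosome(s): ",
            paste(missingChrom, collapse = ", "))
  for (i in seq_len(nrow(markers))) {
    a <- annot[annot$chrom == markers$chrom[i], , drop = FALSE]
    if (nrow(a) == 0) next
    a <- a[order(a$start, a$end), , drop = FALSE]
    pos <- markers$pos[i]
    inside <- which(a$start <= pos & a$end >= pos)
    if (length(inside)) {
      res$containing[i] <- a$gene_id[inside[1]]  # ties: smaller start
      next
    }
    up <- which(a$end < pos)
    if (length(up)) {
      dUp <- pos - a$end[up]
      j <- up[order(dUp, a$start[up])][1]
      res$upstream[i] <- a$gene_id[j]
      res$upstream_dist[i] <- pos - a$end[j]
    }
    dn <- which(a$start > pos)
    if (length(dn)) {
      dDn <- a$start[dn] - pos
      j <- dn[order(dDn, a$start[dn])][1]
      res$downstream[i] <- a$gene_id[j]
      res$downstream_dist[i] <- a$start[j] - pos
    }
  }
  nearest <- ifelse(!is.na(res$containing), 0,
                    pmin(res$upstream_dist, res$downstream_dist,
                         na.rm = TRUE))
  nearest[is.infinite(nearest)] <- NA
  list(assignment = res,
       meanDistance = mean(nearest, na.rm = TRUE),
       meanDistanceFlanking = mean(nearest[is.na(res$containing)],
                                   na.rm = TRUE))
}

.splitTerms <- function(x) {
  out <- unlist(strsplit(x, "[;,] *"))
  out[nzchar(out)]
}

#' Collect GO and EC terms per marker set
#'
#' De-duplicated GO and EC terms of the genes assigned to each marker set
#' (containing plus flanking genes), with gene provenance. A term shared
#' by several genes or markers is counted once per set.
#'
#' @param assign result of [assignFlankingGenes()] (or its `assignment`
#'   data.frame).
#' @param annot annotation data.frame with `gene_id`, `GO`, `EC` columns
#'   (terms `;`- or `,`-separated).
#' @param sets named list of marker-id vectors (e.g. `snpsGWAS`,
#'   `snpsLD`).
#' @return data.frame (`set`, `type`, `term`, `genes`).
#' @export
collectTerms <- function(assign, annot, sets) {
  if (is.list(assign) && !is.data.frame(assign)) assign <- assign$assignment
  out <- list()
  for (sn in names(sets)) {
    rows <- assign[assign$marker %in% sets[[sn]], , drop = FALSE]
    genes <- unique(stats::na.omit(c(rows$containing, rows$upstream,
                                     rows$downstream)))
    terms <- list(GO = list(), EC = list())
    for (g in genes) {
      arow <- annot[annot$gene_id == g, , drop = FALSE]
      if (nrow(arow) == 0) next
      for (ty in c("GO", "EC")) {
        if (is.null(arow[[ty]])) next
        for (tm in .splitTerms(as.character(arow[[ty]][1])))
          terms[[ty]][[tm]] <- union(terms[[ty]][[tm]], g)
      }
    }
    for (ty in c("GO", "EC"))
      if (length(terms[[ty]]))
        out[[length(out) + 1]] <- data.frame(
          set = sn, type = ty, term = names(terms[[ty]]),
          genes = vapply(terms[[ty]], paste, "", collapse = ";"),
          stringsAsFactors = FALSE)
  }
  if (length(out)) {
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  } else data.frame(set = character(), type = character(),
                    term = character(), genes = character())
}

#' Overlap markers with QTL intervals
#'
#' A marker overlaps a QTL when its position lies inside the closed
#' interval `[start, end]` (both boundaries inclusive).
#'
#' @param markers data.frame with `id`, `chrom`, `pos`.
#' @param qtlIntervals data.frame with `chrom`, `start`, `end`, `label`.
#' @return list: `perMarker` (data.frame `marker`, `qtl`), `counts`
#'   (markers per QTL label) and `nMarkersOverlapping`.
#' @export
qtlOverlap <- function(markers, qtlIntervals) {
  if (any(qtlIntervals$start > qtlIntervals$end))
    stop("malformed QTL interval: start > end")
  mg <- GenomicRanges::GRanges(markers$chrom,
                               IRanges::IRanges(markers$pos, markers$pos))
  qg <- GenomicRanges::GRanges(qtlIntervals$chrom,
                               IRanges::IRanges(qtlIntervals$start,
                                                qtlIntervals$end))
  ov <- GenomicRanges::findOverlaps(mg, qg)
  perMarker <- data.frame(
    marker = markers$id[S4Vectors::queryHits(ov)],
    qtl = qtlIntervals$label[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE)
  counts <- table(factor(perMarker$qtl, levels = qtlIntervals$label))
  list(perMarker = perMarker,
       counts = as.integer(counts) |> setNames(qtlIntervals$label),
       nMarkersOverlapping = length(unique(perMarker$marker)))
}
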