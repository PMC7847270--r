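#' Read a BED file of intervals
#'
#' Thin wrapper over \code{rtracklayer::import.bed} that attaches the
#' genome layout and errors on out-of-bounds records.
#'
#' @param path BED3/BED6/BED12 file.
#' @param layout Optional \code{Seqinfo}; when given, chromosomes are
#'   validated against it.
#' @param extra_cols Named character vector of extra column types after
#'   the standard six (e.g. \code{c(class = "character")} for a
#'   RepeatMasker-style class column).
#' @return \code{GRanges}.
#' @export
read_bed <- function(path, layout = NULL, extra_cols = NULL) {
  gr <- rtracklayer::import(path, format = "BED", extraCols = extra_cols)
  if (!is.null(layout)) gr <- apply_layout(gr, layout)
  gr
}

#' Write intervals as BED6
#'
#' @param gr \code{GRanges}; \code{name}/\code{score} metadata columns are
#'   used when present.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Collapse a GTF/GFF annotation to plain intervals
#'
#' Imports a GTF/GFF3, optionally keeps only some feature types, and
#' returns the merged (strand-ignorant) footprint of all retained
#' features.  1-based GFF coordinates are handled by the importer.
#'
#' @param path GTF or GFF3 file.
#' @param layout Optional \code{Seqinfo}.
#' @param feature_types Character vector of \code{type} values to keep
#'   (default: all features).
#' @return Merged unstranded \code{GRanges}.
#' @export
read_annotation <- function(path, layout = NULL, feature_types = NULL) {
  gr <- rtracklayer::import(path)
  if (!is.null(feature_types) && "type" %in% names(mcols(gr))) {
    gr <- gr[as.character(gr$type) %in% feature_types]
  }
  gr <- reduce(granges(gr), ignore.strand = TRUE)
  if (!is.null(layout)) gr <- apply_layout(gr, layout)
  gr
}

#' Extend intervals by a flank and clip to chromosome ends
#'
#' Each interval is grown by \code{flank} bp on both sides, clipped to
#' \code{[1, chromosome length]}, and the result is merged.
#'
#' @param gr \code{GRanges}.
#' @param flank Non-negative flank in bp.
#' @param layout \code{Seqinfo}.
#' @return Merged unstranded \code{GRanges}.
#' @export
extend_and_clip <- function(gr, flank, layout) {
  stopifnot(flank >= 0)
  gr <- apply_layout(granges(gr), layout)
  gr <- suppressWarnings(resize(gr, width(gr) + 2 * flank, fix = "center",
                                ignore.strand = TRUE))
  gr <- trim(gr)
  reduce(gr, ignore.strand = TRUE)
}

#' Complement of an interval set within a genome
#'
#' @param gr Merged \code{GRanges}.
#' @param layout \code{Seqinfo}.
#' @return Merged unstranded \code{GRanges} covering exactly the bases not
#'   in \code{gr}; together they tile the genome.
#' @export
interval_complement <- function(gr, layout) {
  gr <- apply_layout(reduce(granges(gr), ignore.strand = TRUE), layout)
  GenomicRanges::setdiff(genome_granges(layout), gr, ignore.strand = TRUE)
}

#' Merge intervals separated by less than a maximum gap
#'
#' Intervals whose gap (distance between the end of one and the start of
#' the next) is strictly smaller than \code{max_gap} are unioned;
#' overlapping or touching intervals are always merged.
#'
#' @param gr \code{GRanges}.
#' @param max_gap Non-negative gap in bp; a gap of exactly \code{max_gap}
#'   is \emph{not} merged.
#' @return Merged unstranded \code{GRanges}.
#' @export
merge_within <- function(gr, max_gap) {
  stopifnot(max_gap >= 0)
  # reduce() merges ranges whose gap is < min.gapwidth, which is exactly
  # the strict "< max_gap" contract; overlapping ranges always merge.
  reduce(granges(gr), min.gapwidth = max_gap, ignore.strand = TRUE)
}

#' Fraction of each query interval covered by a subject set
#'
#' @param query \code{GRanges}.
#' @param subject Merged \code{GRanges}.
#' @return Numeric vector in \code{[0, 1]}, parallel to \code{query}.
#' @export
base_overlap_fraction <- function(query, subject) {
  subject <- reduce(granges(subject), ignore.strand = TRUE)
  ov <- findOverlaps(query, subject, ignore.strand = TRUE)
  if (!length(ov)) return(numeric(length(query)))
  w <- pmin(end(query)[queryHits(ov)], end(subject)[subjectHits(ov)]) -
    pmax(start(query)[queryHits(ov)], start(subject)[subjectHits(ov)]) + 1
  covered <- rep(0, length(query))
  agg <- tapply(as.numeric(w), queryHits(ov), sum)
  covered[as.integer(names(agg))] <- agg
  covered / as.numeric(width(query))
}
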