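#' Construct an aligned-read container
#'
#' Reads are stranded \code{GRanges} whose range is the start--end span of
#' the alignment, with metadata columns \code{weight} (default 1;
#' deduplicated single-placement alignments carry unit weight),
#' optional \code{seq} (read-oriented sequence) and optional \code{blocks}
#' (absolute-coordinate \code{IRangesList} for spliced/split alignments).
#'
#' @param gr \code{GRanges} of alignment spans.
#' @param seq Optional character vector of read-oriented sequences.
#' @param weight Numeric weights (recycled).
#' @param blocks Optional \code{IRangesList} of absolute block coordinates,
#'   one element per read; defaults to the unsplit span.
#' @return \code{GRanges} with normalized metadata columns.
#' @export
aligned_reads <- function(gr, seq = NULL, weight = 1, blocks = NULL) {
  gr <- granges(gr)
  mcols(gr)$weight <- rep_len(as.numeric(weight), length(gr))
  if (!is.null(seq)) {
    stopifnot(length(seq) == length(gr))
    lens <- read_lengths_internal(gr, blocks)
    has <- !is.na(seq)
    if (any(nchar(seq[has]) != lens[has])) {
      stop("sequence length must equal total aligned length")
    }
    mcols(gr)$seq <- as.character(seq)
  }
  if (!is.null(blocks)) {
    stopifnot(length(blocks) == length(gr))
    mcols(gr)$blocks <- as(blocks, "IRangesList")
  }
  gr
}

read_lengths_internal <- function(gr, blocks) {
  if (is.null(blocks)) return(width(gr))
  as.numeric(sum(width(blocks)))
}

#' Aligned lengths of reads (sum of block widths)
#' @param reads Aligned-read \code{GRanges}.
#' @return Numeric vector of aligned lengths in nt.
#' @export
read_lengths <- function(reads) {
  if (!is.null(mcols(reads)$blocks)) {
    as.numeric(sum(width(mcols(reads)$blocks)))
  } else {
    as.numeric(width(reads))
  }
}

read_weights <- function(reads) {
  w <- mcols(reads)$weight
  if (is.null(w)) rep(1, length(reads)) else as.numeric(w)
}

# Expand block structure into one GRanges row per aligned segment,
# carrying the parent read's weight.
blocks_granges <- function(reads) {
  bl <- mcols(reads)$blocks
  if (is.null(bl)) {
    gr <- granges(reads)
    mcols(gr)$weight <- read_weights(reads)
    return(gr)
  }
  n <- S4Vectors::elementNROWS(bl)
  gr <- GRanges(rep(seqnames(reads), n), unlist(bl, use.names = FALSE),
                strand = rep(strand(reads), n),
                seqinfo = seqinfo(reads))
  mcols(gr)$weight <- rep(read_weights(reads), n)
  gr
}

#' Read aligned reads from BED
#'
#' BED6 spans and BED12 block structure are both supported; an optional
#' seventh \code{seq} column (as written by \code{\link{write_reads_bed}})
#' carries read-oriented sequences.
#'
#' @param path BED file.
#' @param layout Optional \code{Seqinfo} for validation.
#' @param with_seq Set \code{TRUE} if the file carries the extra
#'   \code{seq} column.
#' @return Aligned-read \code{GRanges}.
#' @export
read_reads_bed <- function(path, layout = NULL, with_seq = FALSE) {
  extra <- if (with_seq) c(seq = "character") else NULL
  gr <- rtracklayer::import(path, format = "BED", extraCols = extra)
  if (!is.null(layout)) gr <- apply_layout(gr, layout)
  out <- granges(gr)
  mcols(out)$weight <- rep(1, length(gr))
  if (!is.null(mcols(gr)$name)) mcols(out)$name <- mcols(gr)$name
  if (with_seq) mcols(out)$seq <- mcols(gr)$seq
  bl <- mcols(gr)$blocks
  if (!is.null(bl)) {
    # rtracklayer returns BED12 blocks relative to the range start
    mcols(out)$blocks <- IRanges::shift(bl, start(gr) - 1L)
  }
  out
}

#' Write aligned reads as BED6 (+ optional seq column)
#'
#' @param reads Aligned-read \code{GRanges} (unsplit).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  nm <- mcols(reads)$name
  if (is.null(nm)) nm <- paste0("read", seq_along(reads))
  dt <- data.table::data.table(
    chrom = as.character(seqnames(reads)),
    start = start(reads) - 1L,
    end = end(reads),
    name = nm,
    score = 0L,
    strand = as.character(strand(reads))
  )
  if (!is.null(mcols(reads)$seq)) dt$seq <- mcols(reads)$seq
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Count reads fully contained in regions
#'
#' A read contributes its weight to a region iff 100\% of its aligned
#' bases lie inside that region (the \code{-F 1.0} containment contract).
#' With \code{split = TRUE} the aligned bases are the read's blocks; with
#' \code{split = FALSE} they are the full start--end span.  For
#' contiguous regions the two agree at full containment, because the
#' blocks are bracketed by the span.
#'
#' @param regions Merged or mutually non-overlapping \code{GRanges}.
#' @param reads Aligned-read \code{GRanges}.
#' @param split Use block-aware containment (see Details).
#' @param strand_mode \code{"ignore"}, \code{"same"} or \code{"opposite"}
#'   relative to the region strand.
#' @return Numeric vector of weighted counts, parallel to \code{regions}.
#' @export
count_contained <- function(regions, reads, split = TRUE,
                            strand_mode = c("ignore", "same", "opposite")) {
  strand_mode <- match.arg(strand_mode)
  if (!length(regions)) return(numeric(0))
  counts <- numeric(length(regions))
  if (!length(reads)) return(counts)
  # span containment; blocks lie within the span, so for contiguous
  # regions this is also the split=TRUE criterion
  ov <- findOverlaps(granges(reads), granges(regions), type = "within",
                     ignore.strand = TRUE)
  if (!length(ov)) return(counts)
  keep <- rep(TRUE, length(ov))
  if (strand_mode != "ignore") {
    rs <- as.character(strand(reads))[queryHits(ov)]
    gs <- as.character(strand(regions))[subjectHits(ov)]
    same <- rs == gs & rs != "*" & gs != "*"
    keep <- if (strand_mode == "same") same else {
      rs != gs & rs != "*" & gs != "*"
    }
  }
  ov <- ov[keep]
  if (!length(ov)) return(counts)
  w <- read_weights(reads)[queryHits(ov)]
  agg <- tapply(w, subjectHits(ov), sum)
  counts[as.integer(names(agg))] <- agg
  counts
}

#' Reads per kilobase per million mapped reads
#'
#' @param count Read count(s).
#' @param region_length Region length(s) in bp, > 0.
#' @param library_size Total mapped reads, > 0.
#' @return \code{count / (region_length/1e3) / (library_size/1e6)}.
#' @export
rpkm <- function(count, region_length, library_size) {
  stopifnot(all(region_length > 0))
  if (any(library_size <= 0)) stop("library_size must be positive")
  count / (region_length / 1e3) / (library_size / 1e6)
}

#' Build a per-base coverage track from reads
#'
#' Sums read weights over aligned blocks at every base.  With
#' \code{per_million = TRUE} the track is scaled to reads-per-million
#' mapped (RPM), using the total read weight as library size unless
#' overridden.
#'
#' @param reads Aligned-read \code{GRanges}.
#' @param layout \code{Seqinfo}.
#' @param per_million Scale by \code{1e6 / library_size}.
#' @param library_size Mapped-read total used for scaling; defaults to the
#'   summed weight of \code{reads}.
#' @return A \code{coverage_track}: list with \code{cov} (RleList),
#'   \code{library_size}, \code{per_million}.
#' @export
coverage_from_reads <- function(reads, layout, per_million = TRUE,
                                library_size = NULL) {
  reads <- apply_layout(reads, layout)
  bl <- blocks_granges(reads)
  if (is.null(library_size)) library_size <- sum(read_weights(reads))
  cov <- coverage(bl, weight = mcols(bl)$weight)
  if (per_million) {
    if (library_size <= 0) stop("library_size must be positive")
    cov <- cov * (1e6 / library_size)
  }
  structure(list(cov = cov, library_size = library_size,
                 per_million = per_million),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$cov), "chromosome(s),",
      "library_size =", x$library_size,
      if (x$per_million) "(RPM-scaled)" else "(raw)", "\n")
  invisible(x)
}

#' Per-base mean of coverage tracks
#'
#' @param tracks List of \code{coverage_track}s over the same layout
#'   (typically replicates of one condition).
#' @return A \code{coverage_track} whose values are the per-base
#'   arithmetic mean.
#' @export
mean_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  nm <- lapply(tracks, function(t) names(t$cov))
  if (!all(vapply(nm, identical, TRUE, nm[[1]]))) {
    stop("coverage tracks have mismatched layouts")
  }
  lens <- lapply(tracks, function(t) S4Vectors::elementNROWS(t$cov))
  if (!all(vapply(lens, identical, TRUE, lens[[1]]))) {
    stop("coverage tracks have mismatched chromosome lengths")
  }
  cov <- Reduce(`+`, lapply(tracks, `[[`, "cov")) / length(tracks)
  structure(list(cov = cov,
                 library_size = mean(vapply(tracks, `[[`, 1,
                                            "library_size")),
                 per_million = tracks[[1]]$per_million),
            class = "coverage_track")
}

#' Mean coverage of a track inside intervals
#' @param track \code{coverage_track}.
#' @param gr \code{GRanges}.
#' @return Numeric vector of per-interval mean coverage.
#' @export
track_mean <- function(track, gr) {
  if (!length(gr)) return(numeric(0))
  out <- numeric(length(gr))
  for (chr in unique(as.character(seqnames(gr)))) {
    i <- which(as.character(seqnames(gr)) == chr)
    v <- IRanges::Views(track$cov[[chr]], start(gr)[i], end(gr)[i])
    out[i] <- IRanges::viewMeans(v)
  }
  out
}

#' Write a coverage track as bedGraph
#' @param track \code{coverage_track}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(track$cov)) {
    r <- track$cov[[chr]]
    rl <- S4Vectors::runLength(r)
    rv <- S4Vectors::runValue(r)
    ends <- cumsum(as.numeric(rl))
    starts <- ends - as.numeric(rl)
    keep <- rv != 0
    if (!any(keep)) next
    writeLines(paste(chr, format(starts[keep], scientific = FALSE,
                                 trim = TRUE),
                     format(ends[keep], scientific = FALSE, trim = TRUE),
                     sprintf("%.6f", rv[keep]), sep = "\t"), con)
  }
  invisible(path)
}
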