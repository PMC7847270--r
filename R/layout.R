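#' Read a chromosome-sizes file into a genome layout
#'
#' Parses the standard two-column \code{chrom.sizes} TSV (name, length in
#' bp) into a \link[GenomeInfoDb]{Seqinfo} object.  Declaration order is
#' preserved and used for all downstream sorting.
#'
#' @param path Path to a two-column tab-separated file.
#' @return A \code{Seqinfo} with one entry per chromosome.
#' @export
#' @examples
#' tf <- tempfile()
#' writeLines(c("chr1\t1000", "chr2\t500"), tf)
#' read_layout(tf)
read_layout <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 1L) < 2L
  if (any(bad)) {
    stop("malformed chrom.sizes line(s): ", paste(which(bad), collapse = ", "))
  }
  nm <- vapply(fields, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (anyNA(len)) stop("non-numeric chromosome length in ", path)
  genome_layout(nm, len)
}

#' Construct a genome layout from names and lengths
#'
#' @param chroms Character vector of unique chromosome names.
#' @param lengths Positive integer lengths (bp), parallel to \code{chroms}.
#' @return A \link[GenomeInfoDb]{Seqinfo}.
#' @export
genome_layout <- function(chroms, lengths) {
  if (anyDuplicated(chroms)) {
    stop("duplicate chromosome name(s): ",
         paste(unique(chroms[duplicated(chroms)]), collapse = ", "))
  }
  if (any(lengths < 1) || anyNA(lengths)) {
    stop("all chromosome lengths must be >= 1")
  }
  GenomeInfoDb::Seqinfo(seqnames = as.character(chroms),
                        seqlengths = as.integer(lengths))
}

#' Write a genome layout as a chrom.sizes file
#' @param layout A \code{Seqinfo}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_layout <- function(layout, path) {
  writeLines(paste(GenomeInfoDb::seqnames(layout),
                   GenomeInfoDb::seqlengths(layout), sep = "\t"), path)
  invisible(path)
}

#' Whole-genome GRanges for a layout
#' @param layout A \code{Seqinfo}.
#' @return Unstranded \code{GRanges}, one range per chromosome.
#' @export
genome_granges <- function(layout) {
  gr <- GRanges(GenomeInfoDb::seqnames(layout),
                IRanges(1L, GenomeInfoDb::seqlengths(layout)),
                seqinfo = layout)
  names(gr) <- NULL
  gr
}

# Attach/validate layout seqinfo on a GRanges; errors on unknown chromosomes
# or out-of-bounds ranges.
apply_layout <- function(gr, layout) {
  unknown <- setdiff(as.character(unique(seqnames(gr))),
                     GenomeInfoDb::seqnames(layout))
  if (length(unknown)) {
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  }
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(layout)
  suppressWarnings(GenomeInfoDb::seqinfo(gr) <- layout)
  sl <- GenomeInfoDb::seqlengths(layout)[as.character(seqnames(gr))]
  if (any(start(gr) < 1L) || any(end(gr) > sl)) {
    stop("interval(s) outside chromosome bounds")
  }
  gr
}

total_bases <- function(gr) sum(as.numeric(width(gr)))
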