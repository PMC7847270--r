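#' Build the intergenic region set
#'
#' Every annotated interval (plus optional contaminant intervals such as
#' unannotated rRNA loci) is extended by \code{flank} bp and the
#' complement of the merged result is returned.
#'
#' @param annotation \code{GRanges} of annotated features (e.g. a GTF
#'   collapsed with \code{\link{read_annotation}}).
#' @param layout \code{Seqinfo}.
#' @param flank Extension in bp (default 2500).
#' @param contaminants Optional \code{GRanges} removed alongside the
#'   annotation.
#' @return Merged unstranded \code{GRanges} of intergenic regions.
#' @export
build_intergenic <- function(annotation, layout, flank = 2500,
                             contaminants = NULL) {
  ann <- granges(annotation)
  if (!is.null(contaminants) && length(contaminants)) {
    ann <- c(ann, granges(contaminants))
  }
  if (!length(ann)) return(genome_granges(layout))
  interval_complement(extend_and_clip(ann, flank, layout), layout)
}

#' Quantify intergenic transcription in one library
#'
#' Reads are counted per intergenic region under full containment
#' (100\% of aligned bases inside the region); the intergenic proportion
#' is the summed contained count over the total mapped reads.  Per-region
#' expression is reported as (count + 1) per kilobase per million mapped,
#' a pseudocounted FPKM suitable for log display.
#'
#' @param regions Merged intergenic \code{GRanges}.
#' @param reads Aligned-read \code{GRanges}.
#' @param sample Sample identifier recorded in the output.
#' @return List with \code{summary} (one-row data.frame: sample,
#'   total_mapped, intergenic_reads, proportion) and \code{regions}
#'   (per-region data.frame with count and fpkm1).
#' @export
summarize_intergenic <- function(regions, reads, sample = "sample") {
  total <- sum(read_weights(reads))
  if (total <= 0) stop("library has zero mapped reads")
  counts <- count_contained(regions, reads, split = TRUE)
  fpkm1 <- rpkm(counts + 1, width(regions), total)
  list(
    summary = data.frame(sample = sample, total_mapped = total,
                         intergenic_reads = sum(counts),
                         proportion = sum(counts) / total,
                         stringsAsFactors = FALSE),
    regions = data.frame(chrom = as.character(seqnames(regions)),
                         start = start(regions) - 1L,
                         end = end(regions),
                         count = counts, fpkm1 = fpkm1,
                         stringsAsFactors = FALSE)
  )
}
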