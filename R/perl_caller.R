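#' Configuration for the PERL caller
#'
#' Defaults are the published operating point of the stepwise caller:
#' per-base normalized-coverage cutoff 0.25, 3000 bp joining of
#' above-cutoff bases, merging of expressed regions closer than 3 kb,
#' exclusion of clusters sharing more than 10\% of their bases with
#' whole-fish clusters, a 250 kb minimum size, and removal of candidates
#' already present at 1--2 dpf.
#'
#' @param coverage_cutoff Per-base cutoff on replicate-mean RPM coverage
#'   (bases \emph{at or above} the cutoff pass).
#' @param join_gap Above-cutoff bases within this many bp (inclusive) are
#'   joined into one expressed region.
#' @param merge_gap Expressed regions separated by \emph{less than} this
#'   many bp are merged into one cluster.
#' @param specificity_max_overlap PGC clusters overlapping whole-fish
#'   clusters by more than this base fraction are dropped.
#' @param min_size Minimum cluster size in bp (inclusive).
#' @param candidate_timepoints Timepoints at which PERLs may be called.
#' @param exclusion_timepoints Early timepoints used to drop
#'   constitutively expressed regions.
#' @param exclusion_max_overlap Max base-overlap fraction with early PGC
#'   clusters before a candidate is dropped.
#' @return A \code{perl_config} list.
#' @export
perl_config <- function(coverage_cutoff = 0.25,
                        join_gap = 3000,
                        merge_gap = 3000,
                        specificity_max_overlap = 0.10,
                        min_size = 250000,
                        candidate_timepoints = c("3dpf", "6dpf", "10dpf"),
                        exclusion_timepoints = c("1dpf", "2dpf"),
                        exclusion_max_overlap = 0.10) {
  stopifnot(coverage_cutoff > 0, join_gap >= 0, merge_gap >= 0,
            specificity_max_overlap >= 0, specificity_max_overlap <= 1,
            exclusion_max_overlap >= 0, exclusion_max_overlap <= 1,
            min_size >= 1)
  structure(list(coverage_cutoff = coverage_cutoff, join_gap = join_gap,
                 merge_gap = merge_gap,
                 specificity_max_overlap = specificity_max_overlap,
                 min_size = min_size,
                 candidate_timepoints = candidate_timepoints,
                 exclusion_timepoints = exclusion_timepoints,
                 exclusion_max_overlap = exclusion_max_overlap),
            class = "perl_config")
}

#' Call expressed regions from a replicate-mean coverage track
#'
#' Maximal runs of bases with coverage at or above the cutoff are
#' extracted and runs within \code{join_gap} bp of each other (inclusive)
#' are joined into single regions.
#'
#' @param track Replicate-mean \code{coverage_track} (RPM scale).
#' @param cfg \code{\link{perl_config}}.
#' @return Merged unstranded \code{GRanges} of expressed regions.
#' @export
call_expressed_regions <- function(track, cfg = perl_config()) {
  rl <- IRanges::slice(track$cov, lower = cfg$coverage_cutoff,
                       rangesOnly = TRUE)
  gr <- GRanges(rep(names(rl), S4Vectors::elementNROWS(rl)),
                unlist(rl, use.names = FALSE))
  if (!length(gr)) return(gr)
  # inclusive join: bases within join_gap are joined (gap <= join_gap)
  reduce(gr, min.gapwidth = cfg$join_gap + 1, ignore.strand = TRUE)
}

#' Merge expressed regions into contiguous expression clusters
#'
#' Regions separated by less than \code{merge_gap} bp are unioned; the
#' replicate-mean coverage of each resulting cluster is recorded.
#'
#' @param ers Expressed regions from \code{\link{call_expressed_regions}}.
#' @param track The same coverage track (for per-cluster mean coverage);
#'   optional.
#' @param cfg \code{\link{perl_config}}.
#' @return \code{GRanges} with a \code{mean_coverage} metadata column.
#' @export
build_clusters <- function(ers, track = NULL, cfg = perl_config()) {
  cl <- merge_within(ers, cfg$merge_gap)
  mcols(cl)$mean_coverage <- if (!is.null(track)) {
    track_mean(track, cl)
  } else {
    NA_real_
  }
  cl
}

#' Drop PGC clusters substantially shared with whole-fish clusters
#'
#' A PGC cluster is removed when more than
#' \code{specificity_max_overlap} of its bases overlap the union of the
#' whole-fish clusters from the same timepoint (strictly greater than;
#' exactly at the threshold is retained).
#'
#' @param pgc,fish Cluster \code{GRanges} from the same timepoint.
#' @param cfg \code{\link{perl_config}}.
#' @return The retained PGC clusters.
#' @export
filter_pgc_specific <- function(pgc, fish, cfg = perl_config()) {
  if (!length(pgc) || !length(fish)) return(pgc)
  frac <- base_overlap_fraction(pgc, fish)
  pgc[frac <= cfg$specificity_max_overlap]
}

#' Keep clusters at least the minimum PERL size
#' @param clusters Cluster \code{GRanges}.
#' @param cfg \code{\link{perl_config}}.
#' @return Clusters with width >= \code{min_size}.
#' @export
filter_size <- function(clusters, cfg = perl_config()) {
  clusters[width(clusters) >= cfg$min_size]
}

#' Drop candidates already expressed at early timepoints
#'
#' Candidates whose base-overlap fraction with the union of PGC clusters
#' at any exclusion timepoint exceeds \code{exclusion_max_overlap} are
#' removed.
#'
#' @param candidates Candidate cluster \code{GRanges}.
#' @param early_clusters Named list (by timepoint) of early PGC cluster
#'   \code{GRanges}; missing/empty entries are ignored.
#' @param cfg \code{\link{perl_config}}.
#' @return Retained candidates.
#' @export
exclude_early <- function(candidates, early_clusters,
                          cfg = perl_config()) {
  if (!length(candidates) || !length(early_clusters)) return(candidates)
  drop <- rep(FALSE, length(candidates))
  for (cl in early_clusters) {
    if (is.null(cl) || !length(cl)) next
    drop <- drop |
      (base_overlap_fraction(candidates, cl) > cfg$exclusion_max_overlap)
  }
  candidates[!drop]
}

#' Combine per-timepoint candidates into one PERL catalog
#'
#' Overlapping or touching candidates from different timepoints are
#' union-merged; each PERL records which timepoints contributed, and ids
#' are assigned in (chromosome, start) order.
#'
#' @param per_tp Named list (by timepoint) of filtered candidate
#'   \code{GRanges}.
#' @return \code{GRanges} with \code{id} and \code{source_timepoints}
#'   metadata columns.
#' @export
combine_timepoints <- function(per_tp) {
  per_tp <- per_tp[vapply(per_tp, length, 1L) > 0]
  if (!length(per_tp)) {
    out <- GRanges()
    mcols(out)$id <- character(0)
    mcols(out)$source_timepoints <- character(0)
    return(out)
  }
  all_cand <- unlist(GRangesList(lapply(per_tp, granges)),
                     use.names = FALSE)
  tp_of <- rep(names(per_tp), vapply(per_tp, length, 1L))
  merged <- reduce(all_cand, min.gapwidth = 1, ignore.strand = TRUE)
  merged <- sort(merged)
  ov <- findOverlaps(merged, all_cand, ignore.strand = TRUE)
  src <- split(tp_of[subjectHits(ov)], queryHits(ov))
  tps <- vapply(seq_along(merged), function(i) {
    s <- src[[as.character(i)]]
    paste(unique(s[order(match(s, names(per_tp)))]), collapse = ",")
  }, "")
  mcols(merged)$id <- sprintf("PERL_%03d", seq_along(merged))
  mcols(merged)$source_timepoints <- tps
  merged
}

#' Quantify PERLs per sample (RPKM and piRNA density)
#'
#' RPKM uses fully-contained read counts; piRNA density uses only small
#' RNA reads of 23--33 nt (inclusive).  Replicates are quantified
#' separately and averaged.
#'
#' @param perls PERL \code{GRanges}.
#' @param reads_by_sample Named list: sample -> list of replicate
#'   aligned-read \code{GRanges} (total RNA).
#' @param small_rna_by_sample Same shape, small RNA reads (may be NULL).
#' @param min_len,max_len Inclusive piRNA length window.
#' @return \code{data.frame} with one row per PERL and one column per
#'   sample for RPKM (\code{rpkm_*}) and piRNA density (\code{pirna_*}).
#' @export
quantify_perls <- function(perls, reads_by_sample,
                           small_rna_by_sample = NULL,
                           min_len = 23, max_len = 33) {
  df <- data.frame(id = mcols(perls)$id,
                   chrom = as.character(seqnames(perls)),
                   start = start(perls) - 1L, end = end(perls),
                   stringsAsFactors = FALSE)
  rep_mean_rpkm <- function(reps, region_filter = NULL) {
    vals <- vapply(reps, function(rd) {
      if (!is.null(region_filter)) rd <- region_filter(rd)
      lib <- sum(read_weights(rd))
      if (lib == 0) return(rep(0, length(perls)))
      rpkm(count_contained(perls, rd, split = TRUE),
           width(perls), lib)
    }, numeric(length(perls)))
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(perls))
    rowMeans(vals)
  }
  for (s in names(reads_by_sample)) {
    df[[paste0("rpkm_", s)]] <- rep_mean_rpkm(reads_by_sample[[s]])
  }
  if (!is.null(small_rna_by_sample)) {
    pirna_only <- function(rd) {
      len <- read_lengths(rd)
      rd[len >= min_len & len <= max_len]
    }
    for (s in names(small_rna_by_sample)) {
      reps <- small_rna_by_sample[[s]]
      vals <- vapply(reps, function(rd) {
        lib <- sum(read_weights(rd))  # depth = all mapped small RNAs
        sel <- pirna_only(rd)
        if (lib == 0) return(rep(0, length(perls)))
        rpkm(count_contained(perls, sel, split = TRUE),
             width(perls), lib)
      }, numeric(length(perls)))
      if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(perls))
      df[[paste0("pirna_", s)]] <- rowMeans(vals)
    }
  }
  df
}

#' Run the full stepwise PERL caller
#'
#' For every (timepoint, tissue) the replicate coverage tracks are
#' RPM-scaled, averaged, thresholded into expressed regions and merged
#' into clusters.  PGC clusters at candidate timepoints are then filtered
#' for specificity against whole-fish clusters, for size, and against
#' early (1--2 dpf) PGC expression, and finally union-merged across
#' timepoints into one PERL catalog.
#'
#' @param pgc_reads Named list: timepoint -> list of replicate
#'   aligned-read \code{GRanges} for PGC total RNA.
#' @param fish_reads Same shape for whole-fish total RNA.
#' @param layout \code{Seqinfo}.
#' @param cfg \code{\link{perl_config}}.
#' @return List with \code{perls} (GRanges), \code{clusters} (nested list
#'   tissue -> timepoint of cluster GRanges) and \code{config}.
#' @export
call_perls <- function(pgc_reads, fish_reads, layout,
                       cfg = perl_config()) {
  cluster_one <- function(reps) {
    tracks <- lapply(reps, coverage_from_reads, layout = layout,
                     per_million = TRUE)
    m <- mean_tracks(tracks)
    build_clusters(call_expressed_regions(m, cfg), m, cfg)
  }
  clusters <- list(
    PGC = lapply(pgc_reads, cluster_one),
    fish = lapply(fish_reads, cluster_one)
  )
  early <- clusters$PGC[intersect(cfg$exclusion_timepoints,
                                  names(clusters$PGC))]
  per_tp <- list()
  for (tp in intersect(cfg$candidate_timepoints, names(clusters$PGC))) {
    cand <- clusters$PGC[[tp]]
    fish_cl <- clusters$fish[[tp]]
    if (!is.null(fish_cl)) cand <- filter_pgc_specific(cand, fish_cl, cfg)
    cand <- filter_size(cand, cfg)
    cand <- exclude_early(cand, early, cfg)
    per_tp[[tp]] <- cand
  }
  perls <- combine_timepoints(per_tp)
  list(perls = perls, clusters = clusters, config = cfg)
}
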