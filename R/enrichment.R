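#' Size- and chromosome-matched shuffled background sets
#'
#' For each input region and each of \code{n_sets} background sets, an
#' interval of identical length is placed uniformly at random on the
#' same chromosome, rejecting placements that overlap \code{excluded}
#' (by default the input regions themselves).  Placements within a set
#' may overlap each other.
#'
#' @param regions \code{GRanges} (e.g. the PERL catalog).
#' @param layout \code{Seqinfo}.
#' @param n_sets Number of background sets (default 100).
#' @param excluded \code{GRanges} that backgrounds must not touch;
#'   defaults to \code{regions}.
#' @param max_tries Rejection-sampling attempts per placement before a
#'   hard error.
#' @param seed Optional integer seed (sets the RNG).
#' @return List of \code{n_sets} \code{GRanges}, each parallel to
#'   \code{regions}.
#' @export
shuffle_background <- function(regions, layout, n_sets = 100,
                               excluded = regions, max_tries = 1000,
                               seed = NULL) {
  stopifnot(n_sets >= 1)
  if (!is.null(seed)) set.seed(seed)
  regions <- apply_layout(granges(regions), layout)
  excl <- reduce(granges(excluded), ignore.strand = TRUE)
  sl <- GenomeInfoDb::seqlengths(layout)
  chr <- as.character(seqnames(regions))
  len <- width(regions)
  max_start <- sl[chr] - len + 1L
  if (any(max_start < 1L)) {
    stop("region longer than its chromosome: ",
         paste(which(max_start < 1L), collapse = ", "))
  }
  lapply(seq_len(n_sets), function(s) {
    starts <- integer(length(regions))
    for (i in seq_along(regions)) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        st <- sample.int(max_start[i], 1L)
        cand <- GRanges(chr[i], IRanges(st, width = len[i]))
        if (!length(findOverlaps(cand, excl, ignore.strand = TRUE))) {
          starts[i] <- st
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place background for region ", i, " (",
             chr[i], ":", start(regions)[i], "-", end(regions)[i],
             ") after ", max_tries, " tries")
      }
    }
    GRanges(chr, IRanges(starts, width = len), seqinfo = layout)
  })
}

#' Base-overlap enrichment of regions against matched backgrounds
#'
#' Computes the per-region fraction of bases covered by a feature set,
#' the same quantity for every background placement (averaged across
#' the background sets per matched region), a one-sided empirical p
#' (fraction of background sets whose mean fraction reaches the
#' observed mean) and a two-sided rank-sum p on the per-region values.
#'
#' @param regions \code{GRanges}.
#' @param feature_set Merged \code{GRanges} of one feature class.
#' @param backgrounds List of background \code{GRanges} from
#'   \code{\link{shuffle_background}}.
#' @return List with \code{observed} (per-region fractions),
#'   \code{background} (per-region set-averaged fractions),
#'   \code{set_means}, \code{observed_mean}, \code{empirical_p},
#'   \code{wilcox_p}.
#' @export
overlap_enrichment <- function(regions, feature_set, backgrounds) {
  obs <- base_overlap_fraction(regions, feature_set)
  bg <- vapply(backgrounds, base_overlap_fraction,
               numeric(length(regions)), subject = feature_set)
  if (is.null(dim(bg))) bg <- matrix(bg, nrow = length(regions))
  set_means <- colMeans(bg)
  per_region_bg <- rowMeans(bg)
  wp <- if (length(obs) > 0 &&
            length(unique(c(obs, per_region_bg))) > 1) {
    suppressWarnings(stats::wilcox.test(obs, per_region_bg,
                                        alternative = "two.sided",
                                        exact = FALSE)$p.value)
  } else {
    NA_real_
  }
  list(observed = obs, background = per_region_bg,
       set_means = set_means, observed_mean = mean(obs),
       empirical_p = mean(set_means >= mean(obs)), wilcox_p = wp)
}

#' A/B compartment composition of regions
#'
#' @param regions \code{GRanges}.
#' @param compartments Non-overlapping \code{GRanges} with a label
#'   metadata column (\code{name} or \code{label}) taking values A/B.
#' @return List with \code{region_fractions} (per-region A/B/neither
#'   base fractions), \code{overall} (base-weighted A vs B fraction of
#'   region bases, normalized over annotated bases) and
#'   \code{genome_wide} (same for the whole genome annotation).
#' @export
compartment_split <- function(regions, compartments) {
  lab <- mcols(compartments)$label
  if (is.null(lab)) lab <- mcols(compartments)$name
  stopifnot(!is.null(lab), all(lab %in% c("A", "B")))
  a <- reduce(granges(compartments[lab == "A"]))
  b <- reduce(granges(compartments[lab == "B"]))
  if (length(GenomicRanges::intersect(a, b, ignore.strand = TRUE))) {
    stop("A and B compartment annotations overlap")
  }
  fa <- base_overlap_fraction(regions, a)
  fb <- base_overlap_fraction(regions, b)
  w <- as.numeric(width(regions))
  tot_a <- sum(fa * w)
  tot_b <- sum(fb * w)
  overall <- c(A = tot_a, B = tot_b) / max(tot_a + tot_b, 1e-300)
  gw <- c(A = total_bases(a), B = total_bases(b))
  gw <- gw / sum(gw)
  list(region_fractions = data.frame(A = fa, B = fb,
                                     neither = pmax(0, 1 - fa - fb)),
       overall = overall, genome_wide = gw)
}

#' piRNA density of regions versus matched backgrounds
#'
#' RPKM of length-filtered small RNA reads in each region and in each
#' matched background placement (averaged across sets), compared by a
#' two-sided rank-sum test.
#'
#' @param regions \code{GRanges}.
#' @param backgrounds List of background \code{GRanges}.
#' @param reads Small RNA aligned-read \code{GRanges}.
#' @param min_len,max_len Inclusive piRNA length window (23--33 nt).
#' @param library_size Mapped-read total for RPKM; defaults to the
#'   summed weight of \code{reads} before length filtering.
#' @return List with \code{observed}, \code{background} (per-region
#'   set-averaged RPKM) and \code{wilcox_p} (NA when degenerate).
#' @export
density_comparison <- function(regions, backgrounds, reads,
                               min_len = 23, max_len = 33,
                               library_size = NULL) {
  if (is.null(library_size)) library_size <- sum(read_weights(reads))
  len <- read_lengths(reads)
  sel <- reads[len >= min_len & len <= max_len]
  dens <- function(gr) {
    if (library_size <= 0) return(rep(0, length(gr)))
    rpkm(count_contained(gr, sel, split = TRUE), width(gr),
         library_size)
  }
  obs <- dens(regions)
  bg <- vapply(backgrounds, dens, numeric(length(regions)))
  if (is.null(dim(bg))) bg <- matrix(bg, nrow = length(regions))
  per_region_bg <- rowMeans(bg)
  wp <- if (any(obs > 0) || any(per_region_bg > 0)) {
    suppressWarnings(stats::wilcox.test(obs, per_region_bg,
                                        alternative = "two.sided",
                                        exact = FALSE)$p.value)
  } else {
    NA_real_
  }
  list(observed = obs, background = per_region_bg, wilcox_p = wp)
}

#' Region expression across timepoints with paired rank tests
#'
#' Replicate-mean RPKM per region per timepoint, plus a paired
#' (signed-rank) Wilcoxon test between consecutive timepoints.
#'
#' @param regions \code{GRanges} with an \code{id} metadata column.
#' @param reads_by_tp Named list: timepoint -> list of replicate
#'   aligned-read \code{GRanges}.
#' @return List with \code{rpkm} (regions x timepoints matrix) and
#'   \code{tests} (data.frame: from, to, p).
#' @export
expression_over_time <- function(regions, reads_by_tp) {
  stopifnot(length(reads_by_tp) >= 2)
  tps <- names(reads_by_tp)
  mat <- matrix(0, length(regions), length(tps),
                dimnames = list(mcols(regions)$id, tps))
  for (tp in tps) {
    vals <- vapply(reads_by_tp[[tp]], function(rd) {
      lib <- sum(read_weights(rd))
      if (lib == 0) return(rep(0, length(regions)))
      rpkm(count_contained(regions, rd, split = TRUE), width(regions),
           lib)
    }, numeric(length(regions)))
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(regions))
    mat[, tp] <- rowMeans(vals)
  }
  tests <- data.frame(from = tps[-length(tps)], to = tps[-1],
                      p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tests))) {
    d <- mat[, tests$to[i]] - mat[, tests$from[i]]
    tests$p[i] <- if (all(d == 0)) 1 else {
      suppressWarnings(stats::wilcox.test(mat[, tests$to[i]],
                                          mat[, tests$from[i]],
                                          paired = TRUE,
                                          exact = FALSE)$p.value)
    }
  }
  list(rpkm = mat, tests = tests)
}
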