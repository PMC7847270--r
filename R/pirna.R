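#' Assign small RNA reads to features by full containment
#'
#' A read is assigned to every stranded feature that fully contains it;
#' the orientation is \code{sense} when read and feature strands agree
#' and \code{antisense} otherwise.  Reads contained in no feature are
#' not reported.
#'
#' @param reads Aligned-read \code{GRanges} (stranded).
#' @param features Stranded \code{GRanges}; metadata columns (e.g.
#'   \code{name}, \code{class}) are carried through by index.
#' @return \code{data.frame} with columns \code{read} (index into
#'   \code{reads}), \code{feature} (index into \code{features}) and
#'   \code{orientation}.
#' @export
assign_to_features <- function(reads, features) {
  ov <- findOverlaps(granges(reads), granges(features), type = "within",
                     ignore.strand = TRUE)
  rs <- as.character(strand(reads))[queryHits(ov)]
  fs <- as.character(strand(features))[subjectHits(ov)]
  data.frame(read = queryHits(ov), feature = subjectHits(ov),
             orientation = ifelse(rs == fs, "sense", "antisense"),
             stringsAsFactors = FALSE)
}

#' Read-length histograms per feature class and orientation
#'
#' @param reads Aligned-read \code{GRanges}.
#' @param assignment Output of \code{\link{assign_to_features}}.
#' @param classes Character vector of class labels parallel to the
#'   features used for the assignment.
#' @return \code{data.frame} with columns class, orientation, length,
#'   count (weighted).
#' @export
length_profiles <- function(reads, assignment, classes) {
  if (!nrow(assignment)) {
    return(data.frame(class = character(0), orientation = character(0),
                      length = integer(0), count = numeric(0)))
  }
  len <- read_lengths(reads)[assignment$read]
  w <- read_weights(reads)[assignment$read]
  key <- data.frame(class = classes[assignment$feature],
                    orientation = assignment$orientation,
                    length = len, stringsAsFactors = FALSE)
  agg <- stats::aggregate(w, key, sum)
  names(agg)[4] <- "count"
  agg[order(agg$class, agg$orientation, agg$length), , drop = FALSE]
}

#' Per-element sense/antisense bias
#'
#' @param reads Aligned-read \code{GRanges}.
#' @param assignment Output of \code{\link{assign_to_features}}.
#' @param element_ids Character ids parallel to the features.
#' @return \code{data.frame} with element, sense_count, antisense_count
#'   and sense_fraction; elements with zero assigned reads are omitted.
#' @export
strand_bias <- function(reads, assignment, element_ids) {
  if (!nrow(assignment)) {
    return(data.frame(element = character(0), sense_count = numeric(0),
                      antisense_count = numeric(0),
                      sense_fraction = numeric(0)))
  }
  w <- read_weights(reads)[assignment$read]
  el <- element_ids[assignment$feature]
  sense <- tapply(w * (assignment$orientation == "sense"), el, sum)
  anti <- tapply(w * (assignment$orientation == "antisense"), el, sum)
  out <- data.frame(element = names(sense),
                    sense_count = as.numeric(sense),
                    antisense_count = as.numeric(anti),
                    stringsAsFactors = FALSE)
  out$sense_fraction <- out$sense_count /
    (out$sense_count + out$antisense_count)
  out[order(out$element), , drop = FALSE]
}

#' Compare per-element sense fractions between two conditions
#'
#' Two-sided Wilcoxon rank-sum test on the per-element sense-fraction
#' distributions (unpaired).
#'
#' @param frac_a,frac_b Numeric vectors of per-element sense fractions.
#' @return The \code{htest} object.
#' @export
strand_bias_compare <- function(frac_a, frac_b) {
  stats::wilcox.test(frac_a, frac_b, alternative = "two.sided",
                     exact = FALSE, correct = TRUE)
}

#' Ping-pong 5'-overlap profile and Z-score
#'
#' For every opposite-strand read pair on the same chromosome that
#' genomically overlaps by at least one base, the 5'-to-5' overlap
#' \code{k} (10 for a canonical ping-pong pair) is tallied with the
#' product of the two read weights, for \code{k} in 1..\code{max_k}.
#' The Z-score is \code{(P10 - M)/SD} where M and SD are the mean and
#' standard deviation of the background tallies at k = 1--9 and
#' 11--30.
#'
#' @param reads Stranded aligned-read \code{GRanges}.
#' @param max_k Largest overlap tallied (default 30).
#' @param sd_type \code{"sample"} (n-1 denominator, default) or
#'   \code{"population"}.
#' @return A \code{pingpong_profile}: list with \code{counts} (named
#'   numeric of length \code{max_k}), \code{P10}, \code{M}, \code{SD},
#'   \code{Z}.
#' @export
pingpong <- function(reads, max_k = 30,
                     sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  counts <- setNames(numeric(max_k), seq_len(max_k))
  plus <- reads[strand(reads) == "+"]
  minus <- reads[strand(reads) == "-"]
  if (length(plus) && length(minus)) {
    ov <- findOverlaps(granges(plus), granges(minus),
                       ignore.strand = TRUE)
    if (length(ov)) {
      # 5' of a + read is its start; 5' of a - read is its end
      k <- end(minus)[subjectHits(ov)] - start(plus)[queryHits(ov)] + 1L
      keep <- k >= 1L & k <= max_k
      if (any(keep)) {
        w <- read_weights(plus)[queryHits(ov)][keep] *
          read_weights(minus)[subjectHits(ov)][keep]
        agg <- tapply(w, k[keep], sum)
        counts[as.integer(names(agg))] <- agg
      }
    }
  }
  pingpong_z(counts, sd_type = sd_type)
}

#' Ping-pong Z-score from an overlap histogram
#'
#' @param counts Numeric vector of pair counts for overlaps 1..30 (or
#'   1..\code{length(counts)}); position 10 is the signal bin.
#' @param sd_type \code{"sample"} or \code{"population"} SD of the
#'   background bins.
#' @return A \code{pingpong_profile} list (see \code{\link{pingpong}}).
#' @export
pingpong_z <- function(counts, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  counts <- setNames(as.numeric(counts), seq_along(counts))
  bg <- counts[-10]
  m <- mean(bg)
  s <- if (sd_type == "sample") stats::sd(bg) else {
    sqrt(mean((bg - m)^2))
  }
  p10 <- counts[[10]]
  if (is.na(s) || s == 0) {
    warning("background SD is zero; ping-pong Z undefined")
    z <- NA_real_
  } else {
    z <- (p10 - m) / s
  }
  structure(list(counts = counts, P10 = p10, M = m, SD = s, Z = z),
            class = "pingpong_profile")
}

#' @export
print.pingpong_profile <- function(x, ...) {
  cat("ping-pong profile: P10 =", x$P10, " M =", signif(x$M, 5),
      " SD =", signif(x$SD, 5), " Z =", signif(x$Z, 5), "\n")
  invisible(x)
}

#' Positional nucleotide bias and downstream-U fraction
#'
#' Tallies, for each read position, how often each base occurs across
#' the read sequences (read orientation; U reported for T).  When a
#' genome is supplied, the fraction of reads whose genomic base
#' immediately 3' of the read end, taken on the read's strand, is U is
#' also computed (the downstream-U processing signature); reads at a
#' chromosome edge are skipped for that metric.
#'
#' @param reads Aligned-read \code{GRanges} with a \code{seq} column.
#' @param genome Optional \code{DNAStringSet} named by chromosome.
#' @return List with \code{freq} (4 x max-length matrix, rows A/C/G/U,
#'   per-position frequencies summing to 1 over covering reads),
#'   \code{counts} (same shape, weighted counts) and
#'   \code{downstream_u_fraction} (NA without a genome).
#' @export
nucleotide_bias <- function(reads, genome = NULL) {
  seqs <- mcols(reads)$seq
  if (is.null(seqs)) stop("reads carry no sequences")
  w <- read_weights(reads)
  nc <- nchar(seqs)
  maxlen <- max(nc)
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0, 4, maxlen,
                   dimnames = list(c("A", "C", "G", "U"),
                                   seq_len(maxlen)))
  for (pos in seq_len(maxlen)) {
    at <- nc >= pos
    b <- substr(seqs[at], pos, pos)
    for (i in seq_along(bases)) {
      counts[i, pos] <- sum(w[at][b == bases[i]])
    }
  }
  tot <- colSums(counts)
  freq <- sweep(counts, 2, ifelse(tot > 0, tot, 1), "/")
  du <- NA_real_
  if (!is.null(genome)) {
    sl <- setNames(Biostrings::width(genome), names(genome))
    chr <- as.character(seqnames(reads))
    plus <- as.character(strand(reads)) == "+"
    pos <- ifelse(plus, end(reads) + 1L, start(reads) - 1L)
    ok <- pos >= 1L & pos <= sl[chr]
    if (any(ok)) {
      b <- character(sum(ok))
      idx <- which(ok)
      for (c1 in unique(chr[idx])) {
        sel <- chr[idx] == c1
        at <- IRanges(pos[idx][sel], width = 1L)
        b[sel] <- as.character(Biostrings::extractAt(genome[[c1]], at))
      }
      # on the read strand: a genomic A downstream of a - read is a U
      is_u <- ifelse(plus[idx], b == "T", b == "A")
      du <- sum(w[idx] * is_u) / sum(w[idx])
    }
  }
  list(freq = freq, counts = counts, downstream_u_fraction = du)
}

#' Per-element piRNA count matrix across timepoints
#'
#' Counts assigned reads (full containment, both orientations) per
#' element and library, scaled to counts per million mapped reads.
#'
#' @param reads_by_tp Named list: timepoint -> aligned-read
#'   \code{GRanges}.
#' @param features Stranded element \code{GRanges}.
#' @param element_ids Character ids parallel to \code{features}.
#' @return Numeric matrix, elements x timepoints (CPM).
#' @export
te_count_matrix <- function(reads_by_tp, features, element_ids) {
  mat <- matrix(0, length(features), length(reads_by_tp),
                dimnames = list(element_ids, names(reads_by_tp)))
  for (tp in names(reads_by_tp)) {
    rd <- reads_by_tp[[tp]]
    lib <- sum(read_weights(rd))
    cnt <- count_contained(features, rd, split = TRUE,
                           strand_mode = "ignore")
    mat[, tp] <- if (lib > 0) cnt / lib * 1e6 else 0
  }
  mat
}

#' Hierarchical clustering of element profiles
#'
#' Rows are clustered on Pearson-correlation distance (1 - r) with Ward
#' linkage applied to the unsquared dissimilarities (\code{ward.D}), and
#' the tree is cut into \code{k} clusters.  Zero-variance rows are
#' dropped with a warning (correlation undefined).
#'
#' @param mat Numeric matrix (rows = elements or genes).
#' @param k Number of clusters.
#' @return List with \code{cluster} (named integer vector),
#'   \code{hclust}, and \code{dropped} (rownames of zero-variance rows).
#' @export
cluster_profiles <- function(mat, k) {
  v <- apply(mat, 1, stats::var)
  dropped <- rownames(mat)[v == 0 | is.na(v)]
  if (length(dropped)) {
    warning(length(dropped), " zero-variance row(s) excluded from ",
            "correlation clustering")
    mat <- mat[!(rownames(mat) %in% dropped), , drop = FALSE]
  }
  stopifnot(nrow(mat) >= k)
  d <- stats::as.dist(1 - stats::cor(t(mat), method = "pearson"))
  hc <- stats::hclust(d, method = "ward.D")
  cl <- stats::cutree(hc, k = k)
  list(cluster = cl, hclust = hc, dropped = dropped)
}

#' Hypergeometric clade enrichment of a cluster
#'
#' Upper-tail hypergeometric probability P(X >= k) of seeing \code{k}
#' members of a clade in a cluster of size \code{n} drawn from a
#' universe of \code{N} elements of which \code{K} belong to the clade.
#'
#' @param members Character vector: elements in the cluster.
#' @param universe Character vector: all clustered elements.
#' @param clades Named character vector: clade label per universe
#'   element.
#' @return \code{data.frame} with clade, N, K, n, k and p-value.
#' @export
clade_enrichment <- function(members, universe, clades) {
  stopifnot(all(members %in% universe))
  clades <- clades[universe]
  n <- length(members)
  out <- lapply(sort(unique(clades)), function(cl) {
    K <- sum(clades == cl)
    k <- sum(clades[members] == cl)
    if (k > min(K, n)) stop("impossible clade count for ", cl)
    data.frame(clade = cl, N = length(universe), K = K, n = n, k = k,
               p = stats::phyper(k - 1, K, length(universe) - K, n,
                                 lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
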