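#' Read a differential-expression results table
#'
#' Expects a TSV with a \code{gene} column plus per-timepoint
#' \code{fc_<tp>} (fold change, PGC vs fish) and \code{fdr_<tp>}
#' columns; any additional columns (e.g. per-sample expression) are
#' carried through.
#'
#' @param path TSV path.
#' @return \code{data.frame}.
#' @export
read_de_table <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  if (!"gene" %in% names(df)) stop("DE table lacks a 'gene' column")
  df
}

#' PGC-specific genes per timepoint
#'
#' A gene is PGC-specific at timepoint t iff its fold change is at
#' least \code{min_fc} and its FDR is strictly below \code{max_fdr}.
#'
#' @param de \code{data.frame} with \code{gene}, \code{fc_<tp>} and
#'   \code{fdr_<tp>} columns.
#' @param timepoints Character timepoint labels; defaults to those found
#'   in the fc columns.
#' @param min_fc Fold-change threshold (inclusive; default 30).
#' @param max_fdr FDR threshold (exclusive; default 0.01).
#' @return Named list: timepoint -> character vector of genes.
#' @export
pgc_specific_by_timepoint <- function(de, timepoints = NULL,
                                      min_fc = 30, max_fdr = 0.01) {
  stopifnot(min_fc > 1, max_fdr > 0, max_fdr < 1)
  if (is.null(timepoints)) {
    timepoints <- sub("^fc_", "", grep("^fc_", names(de), value = TRUE))
  }
  out <- list()
  for (tp in timepoints) {
    fc_col <- paste0("fc_", tp)
    fdr_col <- paste0("fdr_", tp)
    if (!fc_col %in% names(de) || !fdr_col %in% names(de)) {
      stop("missing column for timepoint ", tp)
    }
    sel <- de[[fc_col]] >= min_fc & de[[fdr_col]] < max_fdr
    sel[is.na(sel)] <- FALSE
    out[[tp]] <- de$gene[sel]
  }
  out
}

#' Exclusive intersection counts (UpSet accounting) and the stable set
#'
#' For every non-empty combination of the input sets, counts the genes
#' belonging to exactly that combination.  The "stable" set (PSG when
#' applied to PGC-specific genes across all five timepoints) is the
#' intersection of all sets.
#'
#' @param sets Named list of character vectors.
#' @return List with \code{counts} (data.frame: combination, degree,
#'   count), \code{membership} (data.frame gene/combination) and
#'   \code{stable} (character vector in every set).
#' @export
upset_counts <- function(sets) {
  stopifnot(length(sets) >= 2, !is.null(names(sets)))
  genes <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = length(genes))
  combo <- apply(memb, 1, function(r) {
    paste(names(sets)[r], collapse = "&")
  })
  tab <- table(combo)
  counts <- data.frame(combination = names(tab),
                       degree = lengths(strsplit(names(tab), "&",
                                                 fixed = TRUE)),
                       count = as.integer(tab),
                       stringsAsFactors = FALSE)
  counts <- counts[order(-counts$degree, counts$combination), ,
                   drop = FALSE]
  rownames(counts) <- NULL
  list(counts = counts,
       membership = data.frame(gene = genes, combination = combo,
                               stringsAsFactors = FALSE),
       stable = genes[rowSums(memb) == length(sets)])
}

#' Row-wise z-scaling of expression profiles
#'
#' Each row is centered to mean 0 and scaled to sample SD 1.
#' Zero-variance rows cannot be scaled and are returned separately.
#'
#' @param mat Numeric matrix (genes x samples), >= 2 columns.
#' @return List with \code{scaled} (matrix of scalable rows) and
#'   \code{flagged} (rownames of zero-variance rows).
#' @export
zscale_profiles <- function(mat) {
  stopifnot(ncol(mat) >= 2)
  v <- apply(mat, 1, stats::var)
  flagged <- rownames(mat)[v == 0 | is.na(v)]
  keep <- !(rownames(mat) %in% flagged)
  scaled <- t(scale(t(mat[keep, , drop = FALSE])))
  list(scaled = scaled, flagged = flagged)
}

#' Cluster gene expression profiles (Pearson distance, ward.D)
#'
#' Rows are clustered on 1 - Pearson correlation with \code{ward.D}
#' linkage and the tree is cut at \code{k}.  Cluster labels are
#' relabeled deterministically: decreasing cluster size, ties broken by
#' the lexicographically first row name.
#'
#' @param scaled Z-scaled matrix from \code{\link{zscale_profiles}}.
#' @param k Number of clusters (default 4).
#' @return List with \code{cluster} (named integer), \code{hclust} and
#'   \code{centroids} (k x samples matrix of per-cluster mean profiles).
#' @export
cluster_genes <- function(scaled, k = 4) {
  res <- cluster_profiles(scaled, k)
  cl <- res$cluster
  sizes <- table(cl)
  first <- vapply(names(sizes), function(g) {
    min(names(cl)[cl == as.integer(g)])
  }, "")
  ord <- order(-as.integer(sizes), first)
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(sizes)
  cl <- setNames(relabel[cl], names(cl))
  centroids <- t(vapply(seq_len(k), function(g) {
    colMeans(scaled[names(cl)[cl == g], , drop = FALSE])
  }, numeric(ncol(scaled))))
  rownames(centroids) <- paste0("cluster", seq_len(k))
  list(cluster = cl, hclust = res$hclust, centroids = centroids)
}
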