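suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

toy_layout <- function(lens = c(chr1 = 10000, chr2 = 5000)) {
  genome_layout(names(lens), unname(lens))
}

# random unsplit reads on a layout
random_reads <- function(layout, n, len_range = c(20, 80)) {
  chroms <- GenomeInfoDb::seqnames(layout)
  sl <- GenomeInfoDb::seqlengths(layout)
  chr <- sample(chroms, n, replace = TRUE)
  len <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  st <- floor(runif(n) * (sl[chr] - len)) + 1L
  aligned_reads(GRanges(chr, IRanges(st, width = len),
                        strand = sample(c("+", "-"), n, replace = TRUE),
                        seqinfo = layout))
}

# random merged region set on a single chromosome
random_regions <- function(chrom, chrom_len, n = 10) {
  st <- sort(sample.int(chrom_len - 50, n))
  w <- sample(20:500, n, replace = TRUE)
  reduce(GRanges(chrom, IRanges(st, width = pmin(w, chrom_len - st + 1))))
}

# per-base brute-force containment counting oracle (single chromosome)
oracle_count_contained <- function(regions, reads, chrom_len) {
  id <- integer(chrom_len)
  for (i in seq_along(regions)) {
    id[start(regions)[i]:end(regions)[i]] <- i
  }
  counts <- numeric(length(regions))
  bl <- mcols(reads)$blocks
  w <- perlscan:::read_weights(reads)
  for (j in seq_along(reads)) {
    bases <- if (!is.null(bl)) {
      unlist(lapply(seq_along(bl[[j]]), function(b) {
        start(bl[[j]])[b]:end(bl[[j]])[b]
      }))
    } else {
      start(reads)[j]:end(reads)[j]
    }
    u <- unique(id[bases])
    if (length(u) == 1 && u > 0) counts[u] <- counts[u] + w[j]
  }
  counts
}

# O(n^2) all-pairs ping-pong oracle
oracle_pingpong <- function(reads, max_k = 30) {
  counts <- setNames(numeric(max_k), seq_len(max_k))
  w <- perlscan:::read_weights(reads)
  s <- as.character(strand(reads))
  chr <- as.character(seqnames(reads))
  ip <- which(s == "+")
  im <- which(s == "-")
  for (i in ip) {
    for (j in im) {
      if (chr[i] != chr[j]) next
      if (start(reads)[j] > end(reads)[i] ||
          start(reads)[i] > end(reads)[j]) next  # must overlap
      k <- end(reads)[j] - start(reads)[i] + 1L
      if (k >= 1 && k <= max_k) counts[k] <- counts[k] + w[i] * w[j]
    }
  }
  counts
}

# repeated-pairwise-merge fixpoint oracle for merge_within
oracle_merge_fixpoint <- function(gr, max_gap) {
  df <- data.frame(chr = as.character(seqnames(gr)), s = start(gr),
                   e = end(gr), stringsAsFactors = FALSE)
  df <- df[order(df$chr, df$s, df$e), ]
  repeat {
    changed <- FALSE
    i <- 1
    while (i < nrow(df)) {
      same <- df$chr[i] == df$chr[i + 1]
      gap <- df$s[i + 1] - df$e[i] - 1  # bp between the two
      if (same && (gap < max_gap || gap < 0)) {
        df$e[i] <- max(df$e[i], df$e[i + 1])
        df <- df[-(i + 1), , drop = FALSE]
        changed <- TRUE
      } else {
        i <- i + 1
      }
    }
    if (!changed) break
  }
  GRanges(df$chr, IRanges(df$s, df$e))
}

# threshold-then-join expressed-region oracle on a dense vector
oracle_expressed_regions <- function(values, cutoff, join_gap) {
  pass <- which(values >= cutoff)
  if (!length(pass)) return(cbind(start = integer(0), end = integer(0)))
  brk <- which(diff(pass) > join_gap + 1)
  st <- pass[c(1, brk + 1)]
  en <- pass[c(brk, length(pass))]
  cbind(start = st, end = en)
}

# order/seqlevel-insensitive range comparison
expect_same_ranges <- function(a, b) {
  norm <- function(g) {
    df <- as.data.frame(granges(g))[, 1:3]
    df$seqnames <- as.character(df$seqnames)
    df <- df[order(df$seqnames, df$start), ]
    rownames(df) <- NULL
    df
  }
  testthat::expect_equal(norm(a), norm(b))
}

jaccard_bp <- function(a, b) {
  i <- sum(width(GenomicRanges::intersect(a, b, ignore.strand = TRUE)))
  u <- sum(width(GenomicRanges::union(a, b, ignore.strand = TRUE)))
  if (u == 0) return(NA_real_)
  i / u
}

# memoized small synthetic dataset shared by the unit tests
.shared <- new.env()
shared_sim <- function() {
  if (is.null(.shared$sim)) {
    cfg <- sim_config(n_chroms = 2, chrom_length = 2e6, n_genes = 40,
                      n_perls = 2, perl_length = c(3e5, 4e5),
                      smallrna_n_reads = 4000, n_psg = 12)
    .shared$sim <- simulate_dataset(cfg, seed = 11, out_dir = NULL)
  }
  .shared$sim
}
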