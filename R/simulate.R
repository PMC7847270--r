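#' Configuration for the synthetic dataset generator
#'
#' The generator plants the structure the pipeline is designed to
#' detect: large (300--600 kb) bidirectionally transcribed loci that
#' appear only in PGC libraries at 6 and 10 dpf, retrotransposon
#' enrichment inside those loci, TE-derived small RNA libraries with a
#' maternal antisense bias that decays by 6 dpf and a ping-pong pair
#' fraction that rises by 6 dpf, 1U/10A sequence biases, alternating
#' A/B compartments that preferentially host the planted loci in B,
#' and a DE table with four temporal archetypes plus a planted
#' stable PGC-specific gene set.
#'
#' @param n_chroms Number of chromosomes (default 3).
#' @param chrom_length Chromosome length in bp (default 10 Mb).
#' @param n_genes Number of genes (default 300).
#' @param gene_length Gene length range in bp.
#' @param n_perls Number of planted loci (default 6).
#' @param perl_length Planted locus length range (default 300--600 kb).
#' @param te_density Named base-density targets for classes LTR, LINE
#'   (non-LTR retro) and DNA.
#' @param te_length TE element length range in bp.
#' @param perl_te_retro_boost Density multiplier for retrotransposon
#'   classes (LTR, LINE) inside planted loci (default 3).
#' @param perl_in_b_prob Probability a planted locus is forced into B
#'   compartment blocks (default 0.8).
#' @param compartment_block A/B block size in bp.
#' @param timepoints Developmental timepoints.
#' @param replicates Replicates per library (default 3).
#' @param read_length Total RNA read length (default 75).
#' @param bg_rate Background transcription, reads per base per
#'   replicate library (default 1e-5; see vignette for the choice).
#' @param gene_peak_rate Per-base read rate of a gene at the peak of its
#'   archetype.
#' @param perl_rate Per-base read rate inside planted loci in PGC
#'   libraries at the induced timepoints; gives replicate-mean RPM
#'   coverage far above twice the caller cutoff.
#' @param perl_timepoints Timepoints at which planted loci are induced.
#' @param smallrna_n_reads Reads per small RNA library (default 30000).
#' @param smallrna_len_mean,smallrna_len_sd,smallrna_len_range Read
#'   length model: Normal(27, 1.5) rounded, clipped to 18--40 nt.
#' @param antisense_fraction Named per-timepoint probability a small RNA
#'   is antisense to its TE (0.9 maternal/early decaying to 0.6 late).
#' @param pingpong_fraction Named per-timepoint fraction of reads
#'   emitted as 10-nt 5'-overlap opposite-strand partners (0.02 early,
#'   0.3 at >= 6 dpf).
#' @param u1_bias Probability position 1 of an antisense read is forced
#'   to U (default 0.8).
#' @param a10_bias Probability position 10 of a sense partner read is
#'   forced to A (default 0.7).
#' @param n_psg Planted stable PGC-specific genes in the DE table.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_chroms = 3,
                       chrom_length = 1e7,
                       n_genes = 300,
                       gene_length = c(2000, 8000),
                       n_perls = 6,
                       perl_length = c(3e5, 6e5),
                       te_density = c(LTR = 0.05, LINE = 0.05,
                                      DNA = 0.10),
                       te_length = c(300, 3000),
                       perl_te_retro_boost = 3,
                       perl_in_b_prob = 0.8,
                       compartment_block = 5e5,
                       timepoints = c("0hpf", "1dpf", "2dpf", "3dpf",
                                      "6dpf", "10dpf"),
                       replicates = 3,
                       read_length = 75,
                       bg_rate = 1e-5,
                       gene_peak_rate = 0.02,
                       perl_rate = 0.01,
                       perl_timepoints = c("6dpf", "10dpf"),
                       smallrna_n_reads = 30000,
                       smallrna_len_mean = 27,
                       smallrna_len_sd = 1.5,
                       smallrna_len_range = c(18, 40),
                       antisense_fraction = c("0hpf" = 0.9,
                                              "1dpf" = 0.9,
                                              "2dpf" = 0.9,
                                              "3dpf" = 0.9,
                                              "6dpf" = 0.6,
                                              "10dpf" = 0.6),
                       pingpong_fraction = c("0hpf" = 0.02,
                                             "1dpf" = 0.02,
                                             "2dpf" = 0.02,
                                             "3dpf" = 0.02,
                                             "6dpf" = 0.3,
                                             "10dpf" = 0.3),
                       u1_bias = 0.8,
                       a10_bias = 0.7,
                       n_psg = 40) {
  stopifnot(all(te_density >= 0), all(te_density <= 1),
            all(antisense_fraction >= 0), all(antisense_fraction <= 1),
            all(pingpong_fraction >= 0), all(pingpong_fraction <= 1),
            perl_length[1] >= 1, n_psg <= n_genes)
  structure(as.list(environment()), class = "sim_config")
}

# archetype multipliers over the six timepoints
gene_archetypes <- function(timepoints) {
  m <- rbind(
    maternal_decay = c(1, 0.8, 0.5, 0.25, 0.1, 0.05),
    peak_6dpf      = c(0.05, 0.05, 0.1, 0.3, 1, 0.3),
    late_rise      = c(0.05, 0.05, 0.05, 0.1, 0.4, 1),
    peak_2_3dpf    = c(0.1, 0.3, 1, 1, 0.3, 0.1)
  )
  colnames(m) <- timepoints
  m
}

# sample n starts for elements of the given widths uniformly within a
# merged region set, so that each element fits inside one region
sample_in_regions <- function(regions, n, widths) {
  widths <- rep_len(widths, n)
  chr <- character(n)
  st <- integer(n)
  rw <- as.numeric(width(regions))
  for (i in seq_len(n)) {
    avail <- rw - widths[i] + 1
    ok <- avail > 0
    if (!any(ok)) stop("no region can host an element of width ",
                       widths[i])
    p <- ifelse(ok, avail, 0)
    r <- sample.int(length(regions), 1L, prob = p)
    chr[i] <- as.character(seqnames(regions))[r]
    st[i] <- start(regions)[r] + sample.int(avail[r], 1L) - 1L
  }
  GRanges(chr, IRanges(st, width = widths))
}

# greedy non-overlapping placement of TE-like elements in a region set
# until target_bases are covered
place_elements <- function(regions, target_bases, len_range,
                           occupied = GRanges()) {
  placed <- GRanges()
  covered <- 0
  guard <- 0
  while (covered < target_bases && guard < 200) {
    guard <- guard + 1
    m <- max(20L, ceiling((target_bases - covered) /
                            mean(len_range) * 1.5))
    m <- min(m, 5000L)
    w <- round(runif(m, len_range[1], len_range[2]))
    cand <- sample_in_regions(regions, m, w)
    block <- reduce(c(granges(placed), granges(occupied)))
    if (length(block)) {
      cand <- cand[!overlapsAny(cand, block, ignore.strand = TRUE)]
    }
    if (!length(cand)) next
    # de-overlap within the batch: greedy left-to-right scan
    cand <- sort(cand)
    keep <- logical(length(cand))
    last_end <- setNames(rep(0, length(unique(seqnames(cand)))),
                         unique(as.character(seqnames(cand))))
    cs <- as.character(seqnames(cand))
    for (i in seq_along(cand)) {
      if (start(cand)[i] > last_end[[cs[i]]]) {
        keep[i] <- TRUE
        last_end[[cs[i]]] <- end(cand)[i]
      }
    }
    cand <- cand[keep]
    need <- covered + cumsum(as.numeric(width(cand))) <=
      target_bases + mean(len_range)
    cand <- cand[need]
    placed <- c(placed, cand)
    covered <- covered + sum(as.numeric(width(cand)))
  }
  placed
}

#' Simulate the synthetic genome and annotations
#'
#' Generates an i.i.d.-uniform nucleotide genome, plants the PERL loci,
#' places non-overlapping genes outside them (10 kb buffer), places TE
#' copies to hit the per-class base densities (retro classes boosted
#' inside planted loci), and lays down alternating A/B compartment
#' blocks with planted loci preferentially relabeled into B.
#'
#' @param cfg \code{\link{sim_config}}.
#' @param seed Optional integer seed.
#' @return List with \code{genome} (DNAStringSet), \code{layout}
#'   (Seqinfo), \code{perls}, \code{genes}, \code{tes} (with
#'   \code{class}, \code{name}), \code{compartments} (with
#'   \code{label}), and \code{archetype} (named per-gene labels).
#' @export
simulate_genome <- function(cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  layout <- genome_layout(chroms, rep(cfg$chrom_length, cfg$n_chroms))
  genome <- DNAStringSet(vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), cfg$chrom_length,
                 replace = TRUE), collapse = "")
  }, ""))
  names(genome) <- chroms

  # plant PERLs: round-robin over chromosomes, one per equal slot with
  # 5% margins so loci are well separated
  per_chrom <- ceiling(cfg$n_perls / cfg$n_chroms)
  perl_list <- list()
  idx <- 1
  for (ch in chroms) {
    for (s in seq_len(per_chrom)) {
      if (idx > cfg$n_perls) break
      len <- round(runif(1, cfg$perl_length[1], cfg$perl_length[2]))
      slot_lo <- (s - 1) / per_chrom * cfg$chrom_length
      slot_hi <- s / per_chrom * cfg$chrom_length
      lo <- slot_lo + 0.05 * cfg$chrom_length
      hi <- slot_hi - 0.05 * cfg$chrom_length - len
      if (hi <= lo) stop("planted loci do not fit; reduce n_perls or ",
                         "perl_length")
      st <- round(runif(1, lo, hi))
      perl_list[[idx]] <- GRanges(ch, IRanges(st, width = len))
      idx <- idx + 1
    }
  }
  perls <- sort(unlist(GRangesList(perl_list)))
  mcols(perls)$id <- sprintf("planted_%02d", seq_along(perls))

  # genes: uniform, non-overlapping, >= 10 kb away from planted loci
  forbidden <- reduce(resize(perls, width(perls) + 2e4, fix = "center"))
  genes <- GRanges()
  space <- interval_complement(forbidden, layout)
  while (length(genes) < cfg$n_genes) {
    m <- (cfg$n_genes - length(genes)) * 2L
    w <- round(runif(m, cfg$gene_length[1], cfg$gene_length[2]))
    cand <- sample_in_regions(space, m, w)
    if (length(genes)) {
      cand <- cand[!overlapsAny(cand, genes, ignore.strand = TRUE)]
    }
    # drop later candidates overlapping earlier ones in the batch
    ok <- !logical(length(cand))
    if (length(cand) > 1) {
      hits <- findOverlaps(cand, cand, ignore.strand = TRUE)
      hits <- hits[queryHits(hits) > subjectHits(hits)]
      ok[unique(queryHits(hits))] <- FALSE
    }
    cand <- cand[ok]
    genes <- c(genes, utils::head(cand, cfg$n_genes - length(genes)))
  }
  genes <- sort(genes)
  strand(genes) <- sample(c("+", "-"), length(genes), replace = TRUE)
  mcols(genes)$gene_id <- sprintf("gene%03d", seq_along(genes))
  arch <- rownames(gene_archetypes(cfg$timepoints))
  archetype <- setNames(sample(arch, length(genes), replace = TRUE),
                        mcols(genes)$gene_id)

  # TEs: per-class densities, retro classes boosted inside planted loci
  inside <- reduce(granges(perls))
  outside <- interval_complement(inside, layout)
  tes <- GRanges()
  for (cl in names(cfg$te_density)) {
    d_out <- cfg$te_density[[cl]]
    d_in <- d_out * if (cl %in% c("LTR", "LINE")) {
      cfg$perl_te_retro_boost
    } else {
      1
    }
    p_out <- place_elements(outside, d_out * total_bases(outside),
                            cfg$te_length, occupied = tes)
    p_in <- place_elements(inside, d_in * total_bases(inside),
                           cfg$te_length, occupied = tes)
    p <- c(p_out, p_in)
    if (length(p)) mcols(p)$class <- cl
    tes <- c(tes, p)
  }
  tes <- sort(tes)
  strand(tes) <- sample(c("+", "-"), length(tes), replace = TRUE)
  mcols(tes)$name <- sprintf("%s_%04d", mcols(tes)$class,
                             seq_along(tes))

  # A/B compartments: alternating blocks, planted loci pushed into B
  comp_list <- list()
  for (ch in chroms) {
    bl <- seq(1, cfg$chrom_length, by = cfg$compartment_block)
    g <- GRanges(ch, IRanges(bl, width = pmin(cfg$compartment_block,
                                              cfg$chrom_length - bl + 1)))
    mcols(g)$label <- rep(c("A", "B"),
                          length.out = length(g))
    comp_list[[ch]] <- g
  }
  compartments <- unlist(GRangesList(comp_list))
  for (i in seq_along(perls)) {
    target <- if (runif(1) < cfg$perl_in_b_prob) "B" else "A"
    hit <- overlapsAny(compartments, perls[i], ignore.strand = TRUE)
    mcols(compartments)$label[hit] <- target
  }
  list(genome = genome, layout = layout, perls = perls, genes = genes,
       tes = tes, compartments = compartments, archetype = archetype)
}

#' Simulate total RNA read libraries
#'
#' Reads of fixed length are placed by Poisson processes: a genome-wide
#' background rate, per-gene rates following each gene's temporal
#' archetype (identical in PGC and whole-fish libraries), and -- in PGC
#' libraries at the induced timepoints only -- a bidirectional boost
#' inside the planted loci.
#'
#' @param cfg \code{\link{sim_config}}.
#' @param art Output of \code{\link{simulate_genome}}.
#' @param seed Optional integer seed.
#' @return Nested list \code{reads[[tissue]][[timepoint]]} of length-
#'   \code{replicates} lists of aligned-read \code{GRanges}.
#' @export
simulate_totalrna <- function(cfg, art, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rl <- cfg$read_length
  arch_m <- gene_archetypes(cfg$timepoints)
  genome_gr <- genome_granges(art$layout)
  out <- list()
  for (tissue in c("PGC", "fish")) {
    out[[tissue]] <- list()
    for (tp in cfg$timepoints) {
      reps <- list()
      for (r in seq_len(cfg$replicates)) {
        parts <- list()
        # background
        n_bg <- rpois(1, cfg$bg_rate * total_bases(genome_gr))
        if (n_bg > 0) {
          bg <- sample_in_regions(genome_gr, n_bg, rl)
          strand(bg) <- sample(c("+", "-"), n_bg, replace = TRUE)
          parts$bg <- bg
        }
        # genes
        mult <- arch_m[art$archetype, tp]
        lam <- cfg$gene_peak_rate * mult * width(art$genes)
        n_g <- rpois(length(lam), lam)
        gidx <- rep(seq_along(art$genes), n_g)
        if (length(gidx)) {
          avail <- width(art$genes)[gidx] - rl + 1L
          st <- start(art$genes)[gidx] +
            floor(runif(length(gidx)) * avail)
          gg <- GRanges(seqnames(art$genes)[gidx],
                        IRanges(st, width = rl),
                        strand = strand(art$genes)[gidx])
          parts$genes <- gg
        }
        # planted loci, PGC at induced timepoints only
        if (tissue == "PGC" && tp %in% cfg$perl_timepoints) {
          lam_p <- cfg$perl_rate * width(art$perls)
          n_p <- rpois(length(lam_p), lam_p)
          pidx <- rep(seq_along(art$perls), n_p)
          if (length(pidx)) {
            avail <- width(art$perls)[pidx] - rl + 1L
            st <- start(art$perls)[pidx] +
              floor(runif(length(pidx)) * avail)
            pg <- GRanges(seqnames(art$perls)[pidx],
                          IRanges(st, width = rl),
                          strand = sample(c("+", "-"), length(pidx),
                                          replace = TRUE))
            parts$perls <- pg
          }
        }
        rd <- if (length(parts)) {
          sort(unlist(GRangesList(lapply(parts, granges))))
        } else {
          GRanges()
        }
        if (length(rd)) rd <- apply_layout(rd, art$layout)
        mcols(rd)$weight <- rep(1, length(rd))
        reps[[r]] <- rd
      }
      out[[tissue]][[tp]] <- reps
    }
  }
  out
}

# draw read lengths from the rounded, clipped normal model
draw_lengths <- function(n, cfg) {
  l <- round(rnorm(n, cfg$smallrna_len_mean, cfg$smallrna_len_sd))
  pmin(pmax(l, cfg$smallrna_len_range[1]), cfg$smallrna_len_range[2])
}

force_base <- function(seqs, pos, base, prob) {
  hit <- nchar(seqs) >= pos & runif(length(seqs)) < prob
  substr(seqs[hit], pos, pos) <- base
  seqs
}

#' Simulate small RNA libraries with planted piRNA signatures
#'
#' PGC small RNA reads are sampled inside TE copies with a per-timepoint
#' antisense fraction, Normal(27, 1.5) lengths clipped to 18--40 nt,
#' and a per-timepoint fraction of reads emitted as opposite-strand
#' partners with exactly 10 nt of 5' overlap (the ping-pong geometry).
#' Sequences are copied from the genome with position 1 of antisense
#' reads forced to U and position 10 of sense partners forced to A at
#' the configured probabilities.
#'
#' @param cfg \code{\link{sim_config}}.
#' @param art Output of \code{\link{simulate_genome}}.
#' @param seed Optional integer seed.
#' @return List with \code{reads[[timepoint]]} (length-\code{replicates}
#'   lists of read \code{GRanges} with \code{seq}) and \code{truth}
#'   (per-library planted pair and orientation tallies).
#' @export
simulate_smallrna <- function(cfg, art, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tes <- art$tes[width(art$tes) >= cfg$smallrna_len_range[2] + 12]
  te_strand <- as.character(strand(tes))
  out <- list()
  truth <- list()
  for (tp in cfg$timepoints) {
    af <- cfg$antisense_fraction[[tp]]
    pf <- cfg$pingpong_fraction[[tp]]
    reps <- list()
    tr <- list()
    for (r in seq_len(cfg$replicates)) {
      n <- cfg$smallrna_n_reads
      n_pp <- round(pf * n)
      n_ord <- n - n_pp
      # ordinary reads
      ti <- sample.int(length(tes), n_ord, replace = TRUE,
                       prob = width(tes))
      len <- draw_lengths(n_ord, cfg)
      avail <- width(tes)[ti] - len + 1L
      st <- start(tes)[ti] + floor(runif(n_ord) * avail)
      anti <- runif(n_ord) < af
      rs <- ifelse(anti,
                   ifelse(te_strand[ti] == "+", "-", "+"),
                   te_strand[ti])
      gr <- GRanges(seqnames(tes)[ti], IRanges(st, width = len),
                    strand = rs)
      # partners: primaries drawn from the ordinary antisense reads
      pair_primary <- integer(0)
      if (n_pp > 0) {
        cand <- which(anti)
        if (!length(cand)) cand <- seq_len(n_ord)
        pair_primary <- sample(cand, n_pp, replace = n_pp > length(cand))
        plen <- draw_lengths(n_pp, cfg)
        pstrand <- ifelse(as.character(strand(gr))[pair_primary] == "-",
                          "+", "-")
        # 10 nt 5'-overlap geometry relative to the primary 5' end
        p5 <- ifelse(as.character(strand(gr))[pair_primary] == "+",
                     start(gr)[pair_primary], end(gr)[pair_primary])
        pst <- ifelse(pstrand == "+", p5 - 9L, p5 + 9L - plen + 1L)
        sl <- GenomeInfoDb::seqlengths(art$layout)[
          as.character(seqnames(gr))[pair_primary]]
        pst <- pmax(1L, pmin(as.integer(pst), as.integer(sl - plen + 1L)))
        pgr <- GRanges(seqnames(gr)[pair_primary],
                       IRanges(pst, width = plen), strand = pstrand)
        gr <- c(gr, pgr)
      }
      gr <- apply_layout(gr, art$layout)
      seqs <- extract_read_seqs(art$genome, gr)
      is_anti <- c(anti, rep(FALSE, n_pp))
      is_partner <- c(rep(FALSE, n_ord), rep(TRUE, n_pp))
      seqs[is_anti] <- force_base(seqs[is_anti], 1L, "T", cfg$u1_bias)
      seqs[is_partner] <- force_base(seqs[is_partner], 10L, "A",
                                     cfg$a10_bias)
      mcols(gr)$weight <- rep(1, length(gr))
      mcols(gr)$seq <- seqs
      mcols(gr)$name <- c(sprintf("rd%05d", seq_len(n_ord)),
                          if (n_pp > 0) sprintf("pp%05d", seq_len(n_pp)))
      reps[[r]] <- gr
      tr[[r]] <- list(n = n, n_pairs = n_pp,
                      n_antisense = sum(is_anti),
                      pair_primary = pair_primary)
    }
    out[[tp]] <- reps
    truth[[tp]] <- tr
  }
  list(reads = out,
       truth = list(per_tp = truth,
                    antisense_fraction = cfg$antisense_fraction,
                    pingpong_fraction = cfg$pingpong_fraction))
}

# extract read-oriented sequences (reverse-complemented on minus)
extract_read_seqs <- function(genome, gr) {
  seqs <- character(length(gr))
  chr <- as.character(seqnames(gr))
  for (c1 in unique(chr)) {
    i <- which(chr == c1)
    s <- Biostrings::extractAt(genome[[c1]],
                               IRanges(start(gr)[i], end(gr)[i]))
    neg <- as.character(strand(gr))[i] == "-"
    if (any(neg)) s[neg] <- Biostrings::reverseComplement(s[neg])
    seqs[i] <- as.character(s)
  }
  seqs
}

#' Simulate a differential-expression table with planted structure
#'
#' Genes follow four temporal archetypes; a planted subset passes the
#' stable PGC-specificity thresholds (fc >= 30 and fdr < 0.01) at all
#' five dpf timepoints, and every other gene fails at one timepoint at
#' least.  A per-timepoint expression matrix consistent with the
#' archetypes (noise SD 0.1 on the unit-scaled profiles) is attached
#' for clustering.
#'
#' @param cfg \code{\link{sim_config}}.
#' @param archetype Named per-gene archetype labels (from
#'   \code{\link{simulate_genome}}); regenerated when NULL.
#' @param seed Optional integer seed.
#' @return List with \code{table} (data.frame: gene, archetype,
#'   fc_*/fdr_* for 1,2,3,6,10 dpf, expr_* for all timepoints) and
#'   \code{truth} (psg gene ids, archetype labels).
#' @export
simulate_de_table <- function(cfg = sim_config(), archetype = NULL,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("gene%03d", seq_len(cfg$n_genes))
  arch_m <- gene_archetypes(cfg$timepoints)
  if (is.null(archetype)) {
    archetype <- setNames(sample(rownames(arch_m), cfg$n_genes,
                                 replace = TRUE), genes)
  }
  psg <- sort(sample(genes, cfg$n_psg))
  de_tps <- setdiff(cfg$timepoints, "0hpf")
  df <- data.frame(gene = genes, archetype = archetype[genes],
                   stringsAsFactors = FALSE)
  for (tp in de_tps) {
    pass <- genes %in% psg | runif(cfg$n_genes) < 0.15
    fc <- ifelse(pass, runif(cfg$n_genes, 30, 200),
                 runif(cfg$n_genes, 0.1, 29))
    fdr <- ifelse(pass, runif(cfg$n_genes, 0, 0.009),
                  runif(cfg$n_genes, 0.02, 0.9))
    df[[paste0("fc_", tp)]] <- fc
    df[[paste0("fdr_", tp)]] <- fdr
  }
  # any non-planted gene passing everywhere is knocked out at one tp
  pass_all <- rep(TRUE, cfg$n_genes)
  for (tp in de_tps) {
    pass_all <- pass_all & df[[paste0("fc_", tp)]] >= 30 &
      df[[paste0("fdr_", tp)]] < 0.01
  }
  fix <- which(pass_all & !(genes %in% psg))
  if (length(fix)) {
    tp_fix <- sample(de_tps, length(fix), replace = TRUE)
    for (i in seq_along(fix)) {
      df[fix[i], paste0("fdr_", tp_fix[i])] <- runif(1, 0.02, 0.9)
    }
  }
  for (tp in cfg$timepoints) {
    prof <- arch_m[archetype[genes], tp]
    df[[paste0("expr_", tp)]] <- prof + rnorm(cfg$n_genes, 0, 0.1)
  }
  list(table = df, truth = list(psg = psg, archetype = archetype))
}

#' Simulate and write the full synthetic dataset
#'
#' Runs \code{\link{simulate_genome}}, \code{\link{simulate_totalrna}},
#' \code{\link{simulate_smallrna}} and \code{\link{simulate_de_table}}
#' under a single seed and writes every artifact in standard formats:
#' FASTA, chrom.sizes, GTF, BED (TE classes as a 7th column, A/B labels
#' as BED4 names), per-library read BEDs, the DE TSV and a
#' \code{truth.json} ground-truth bundle.
#'
#' @param cfg \code{\link{sim_config}}.
#' @param seed Integer seed; the whole dataset is a pure function of
#'   (cfg, seed).
#' @param out_dir Output directory (created); when NULL nothing is
#'   written and only objects are returned.
#' @return Invisible list with all simulated objects, the truth bundle
#'   and (when written) file paths.
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = 7,
                             out_dir = NULL) {
  set.seed(seed)
  art <- simulate_genome(cfg)
  totalrna <- simulate_totalrna(cfg, art)
  smallrna <- simulate_smallrna(cfg, art)
  de <- simulate_de_table(cfg, archetype = art$archetype)
  truth <- list(
    seed = seed,
    perls = data.frame(chrom = as.character(seqnames(art$perls)),
                       start = start(art$perls) - 1L,
                       end = end(art$perls),
                       id = mcols(art$perls)$id),
    psg = de$truth$psg,
    archetype = as.list(de$truth$archetype),
    antisense_fraction = as.list(cfg$antisense_fraction),
    pingpong_fraction = as.list(cfg$pingpong_fraction)
  )
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "totalrna"), showWarnings = FALSE)
    dir.create(file.path(out_dir, "smallrna"), showWarnings = FALSE)
    paths <- list(
      fasta = file.path(out_dir, "genome.fa"),
      chrom_sizes = file.path(out_dir, "chrom.sizes"),
      gtf = file.path(out_dir, "genes.gtf"),
      te_bed = file.path(out_dir, "te.bed"),
      compartments_bed = file.path(out_dir, "compartments.bed"),
      de_table = file.path(out_dir, "de_table.tsv"),
      truth = file.path(out_dir, "truth.json")
    )
    Biostrings::writeXStringSet(art$genome, paths$fasta)
    write_layout(art$layout, paths$chrom_sizes)
    gtf <- art$genes
    mcols(gtf)$type <- "exon"
    mcols(gtf)$source <- "perlscan_sim"
    mcols(gtf)$transcript_id <- paste0(mcols(gtf)$gene_id, ".1")
    rtracklayer::export(gtf, paths$gtf, format = "gtf")
    data.table::fwrite(data.table::data.table(
      chrom = as.character(seqnames(art$tes)),
      start = start(art$tes) - 1L, end = end(art$tes),
      name = mcols(art$tes)$name, score = 0L,
      strand = as.character(strand(art$tes)),
      class = mcols(art$tes)$class
    ), paths$te_bed, sep = "\t", col.names = FALSE, quote = FALSE)
    data.table::fwrite(data.table::data.table(
      chrom = as.character(seqnames(art$compartments)),
      start = start(art$compartments) - 1L,
      end = end(art$compartments),
      name = mcols(art$compartments)$label
    ), paths$compartments_bed, sep = "\t", col.names = FALSE,
    quote = FALSE)
    for (tissue in names(totalrna)) {
      for (tp in names(totalrna[[tissue]])) {
        for (r in seq_along(totalrna[[tissue]][[tp]])) {
          write_reads_bed(totalrna[[tissue]][[tp]][[r]],
                          file.path(out_dir, "totalrna",
                                    sprintf("%s_%s_rep%d.bed", tissue,
                                            tp, r)))
        }
      }
    }
    for (tp in names(smallrna$reads)) {
      for (r in seq_along(smallrna$reads[[tp]])) {
        write_reads_bed(smallrna$reads[[tp]][[r]],
                        file.path(out_dir, "smallrna",
                                  sprintf("PGC_%s_rep%d.bed", tp, r)))
      }
    }
    data.table::fwrite(de$table, paths$de_table, sep = "\t",
                       quote = FALSE)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(list(cfg = cfg, art = art, totalrna = totalrna,
                 smallrna = smallrna, de = de, truth = truth,
                 paths = paths))
}
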