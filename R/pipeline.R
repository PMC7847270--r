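#' Run the full synthetic-data analysis pipeline
#'
#' Simulates the dataset, then runs every analysis stage from the files
#' on disk: PERL calling, intergenic quantification, small RNA
#' statistics (ping-pong, strand bias, length and nucleotide profiles,
#' TE clustering with clade enrichment), matched-background enrichment,
#' and gene-set selection/clustering.  All randomness derives from
#' \code{seed}; a manifest with input digests and per-stage row counts
#' is written last.  Reruns with identical configuration and seed
#' produce byte-identical output tables.
#'
#' @param out_dir Output directory; data land in \code{out_dir/data},
#'   tables in \code{out_dir/results}.
#' @param seed Master integer seed.
#' @param cfg \code{\link{sim_config}} for the generator.
#' @param pcfg \code{\link{perl_config}} for the caller.
#' @param n_sets Number of shuffled background sets (default 100).
#' @return Invisible list with the key in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(out_dir, seed = 7, cfg = sim_config(),
                         pcfg = perl_config(), n_sets = 100) {
  res_dir <- file.path(out_dir, "results")
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(out_dir, "data")

  ## stage 1: simulate
  sim <- simulate_dataset(cfg, seed = seed, out_dir = data_dir)
  digests <- tools::md5sum(sort(list.files(data_dir, recursive = TRUE,
                                           full.names = TRUE)))
  names(digests) <- sub(paste0("^", data_dir, "/?"), "",
                        names(digests))

  ## inputs are consumed from the emitted files
  layout <- read_layout(file.path(data_dir, "chrom.sizes"))
  # BED name column carries the element id; class rides in column 7
  tes <- read_bed(file.path(data_dir, "te.bed"), layout,
                  extra_cols = c(class = "character"))
  tes_cl <- mcols(tes)$class
  comp <- read_bed(file.path(data_dir, "compartments.bed"), layout)
  mcols(comp)$label <- mcols(comp)$name
  read_lib <- function(tissue, tp, r, small = FALSE) {
    d <- if (small) "smallrna" else "totalrna"
    read_reads_bed(file.path(data_dir, d,
                             sprintf("%s_%s_rep%d.bed", tissue, tp, r)),
                   layout, with_seq = small)
  }
  tp_all <- cfg$timepoints
  pgc_reads <- lapply(setNames(tp_all, tp_all), function(tp) {
    lapply(seq_len(cfg$replicates), read_lib, tissue = "PGC", tp = tp)
  })
  fish_reads <- lapply(setNames(tp_all, tp_all), function(tp) {
    lapply(seq_len(cfg$replicates), read_lib, tissue = "fish", tp = tp)
  })
  small_reads <- lapply(setNames(tp_all, tp_all), function(tp) {
    lapply(seq_len(cfg$replicates), read_lib, tissue = "PGC", tp = tp,
           small = TRUE)
  })
  small_pooled <- lapply(small_reads, function(reps) {
    do.call(c, reps)
  })

  manifest <- list(package = "perlscan",
                   version = as.character(utils::packageVersion("perlscan")),
                   seed = seed,
                   config = list(perl = unclass(pcfg),
                                 n_sets = n_sets,
                                 n_chroms = cfg$n_chroms,
                                 chrom_length = cfg$chrom_length,
                                 n_perls = cfg$n_perls),
                   inputs = as.list(digests),
                   stages = list())
  tsv <- function(df, name) {
    p <- file.path(res_dir, name)
    data.table::fwrite(df, p, sep = "\t", quote = FALSE)
    manifest$stages[[name]] <<- list(path = name, rows = nrow(df))
    p
  }

  ## stage 2: PERL calling + quantification
  called <- call_perls(pgc_reads, fish_reads, layout, pcfg)
  perls <- called$perls
  quant <- quantify_perls(perls,
                          reads_by_sample = setNames(
                            pgc_reads[tp_all],
                            paste0("PGC_", tp_all)),
                          small_rna_by_sample = setNames(
                            small_reads[tp_all],
                            paste0("PGC_", tp_all)))
  tsv(cbind(quant,
            source_timepoints = mcols(perls)$source_timepoints),
      "perls.tsv")
  perl_bed <- granges(perls)
  mcols(perl_bed)$name <- mcols(perls)$id
  rpkm_cols <- grep("^rpkm_", names(quant))
  mcols(perl_bed)$score <- round(rowMeans(
    as.matrix(quant[, rpkm_cols, drop = FALSE])) * 100)
  write_bed(perl_bed, file.path(res_dir, "perls.bed"))

  ## stage 3: intergenic expression
  ann <- read_annotation(file.path(data_dir, "genes.gtf"), layout)
  interg <- build_intergenic(ann, layout, flank = 2500)
  ig_rows <- list()
  for (tissue in c("PGC", "fish")) {
    rd_list <- if (tissue == "PGC") pgc_reads else fish_reads
    for (tp in tp_all) {
      for (r in seq_len(cfg$replicates)) {
        ig_rows[[length(ig_rows) + 1]] <- summarize_intergenic(
          interg, rd_list[[tp]][[r]],
          sample = sprintf("%s_%s_rep%d", tissue, tp, r))$summary
      }
    }
  }
  tsv(do.call(rbind, ig_rows), "intergenic.tsv")

  ## stage 4: small RNA statistics
  genome <- Biostrings::readDNAStringSet(file.path(data_dir,
                                                   "genome.fa"))
  names(genome) <- sub(" .*", "", names(genome))
  pp_rows <- list()
  sb_rows <- list()
  nb_rows <- list()
  len_rows <- list()
  sb_frac <- list()
  for (tp in tp_all) {
    rd <- small_pooled[[tp]]
    pp <- pingpong(rd)
    pp_rows[[tp]] <- data.frame(timepoint = tp,
                                k = seq_along(pp$counts),
                                count = as.numeric(pp$counts),
                                P10 = pp$P10, M = pp$M, SD = pp$SD,
                                Z = pp$Z)
    asg <- assign_to_features(rd, tes)
    sb <- strand_bias(rd, asg, mcols(tes)$name)
    sb_frac[[tp]] <- sb$sense_fraction
    sb_rows[[tp]] <- data.frame(timepoint = tp,
                                n_elements = nrow(sb),
                                mean_sense_fraction =
                                  mean(sb$sense_fraction),
                                mean_antisense_fraction =
                                  1 - mean(sb$sense_fraction))
    lp <- length_profiles(rd, asg, tes_cl)
    if (nrow(lp)) lp <- cbind(timepoint = tp, lp)
    len_rows[[tp]] <- lp
    nb <- nucleotide_bias(rd, genome)
    nb_rows[[tp]] <- data.frame(timepoint = tp,
                                u1_fraction = nb$freq["U", 1],
                                a10_fraction = nb$freq["A", 10],
                                downstream_u =
                                  nb$downstream_u_fraction)
  }
  tsv(do.call(rbind, pp_rows), "pingpong.tsv")
  sb_tab <- do.call(rbind, sb_rows)
  sb_tab$wilcox_p_vs_1dpf <- vapply(tp_all, function(tp) {
    if (tp == "1dpf") return(NA_real_)
    strand_bias_compare(sb_frac[[tp]], sb_frac[["1dpf"]])$p.value
  }, 0)
  tsv(sb_tab, "strand_bias.tsv")
  tsv(do.call(rbind, len_rows), "length_profiles.tsv")
  tsv(do.call(rbind, nb_rows), "nucbias.tsv")
  te_mat <- te_count_matrix(small_pooled, tes, mcols(tes)$name)
  keep <- rowSums(te_mat) > 0
  te_cl_res <- suppressWarnings(cluster_profiles(
    te_mat[keep, , drop = FALSE], k = 2))
  cl_df <- data.frame(element = names(te_cl_res$cluster),
                      cluster = as.integer(te_cl_res$cluster))
  cl_df$class <- tes_cl[match(cl_df$element, mcols(tes)$name)]
  tsv(cl_df[order(cl_df$element), ], "te_clusters.tsv")
  enr_rows <- lapply(sort(unique(cl_df$cluster)), function(g) {
    ce <- clade_enrichment(cl_df$element[cl_df$cluster == g],
                           cl_df$element,
                           setNames(cl_df$class, cl_df$element))
    cbind(cluster = g, ce)
  })
  tsv(do.call(rbind, enr_rows), "clade_enrichment.tsv")

  ## stage 5: matched-background enrichment
  if (length(perls)) {
    bgs <- shuffle_background(perls, layout, n_sets = n_sets,
                              seed = (seed + 1009L) %% .Machine$integer.max)
    enr <- lapply(sort(unique(tes_cl)), function(cl) {
      fs <- reduce(granges(tes[tes_cl == cl]))
      oe <- overlap_enrichment(perls, fs, bgs)
      data.frame(feature = cl, observed_mean = oe$observed_mean,
                 background_mean = mean(oe$set_means),
                 empirical_p = oe$empirical_p, wilcox_p = oe$wilcox_p)
    })
    comp_res <- compartment_split(perls, comp)
    enr <- c(enr, list(
      data.frame(feature = "compartment_B",
                 observed_mean = comp_res$overall[["B"]],
                 background_mean = comp_res$genome_wide[["B"]],
                 empirical_p = NA_real_, wilcox_p = NA_real_)))
    dens <- density_comparison(perls, bgs, small_pooled[["6dpf"]])
    enr <- c(enr, list(
      data.frame(feature = "pirna_density_6dpf",
                 observed_mean = mean(dens$observed),
                 background_mean = mean(dens$background),
                 empirical_p = NA_real_, wilcox_p = dens$wilcox_p)))
    tsv(do.call(rbind, enr), "enrichment.tsv")
    eot <- expression_over_time(perls, pgc_reads)
    expr_df <- data.frame(id = rownames(eot$rpkm), eot$rpkm,
                          check.names = FALSE)
    tsv(expr_df, "perl_expression.tsv")
    tsv(eot$tests, "perl_expression_tests.tsv")
  }

  ## stage 6: gene sets
  de <- read_de_table(file.path(data_dir, "de_table.tsv"))
  sets <- pgc_specific_by_timepoint(de)
  up <- upset_counts(sets)
  tsv(up$counts, "upset_counts.tsv")
  writeLines(up$stable, file.path(res_dir, "psg.txt"))
  manifest$stages[["psg.txt"]] <- list(path = "psg.txt",
                                       rows = length(up$stable))
  expr <- as.matrix(de[, grep("^expr_", names(de)), drop = FALSE])
  rownames(expr) <- de$gene
  zs <- zscale_profiles(expr)
  clg <- cluster_genes(zs$scaled, k = 4)
  tsv(data.frame(gene = names(clg$cluster),
                 cluster = as.integer(clg$cluster),
                 archetype = de$archetype[match(names(clg$cluster),
                                                de$gene)]),
      "gene_clusters.tsv")

  jsonlite::write_json(manifest, file.path(res_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sim = sim, perls = perls, quant = quant,
                 intergenic = interg, manifest = manifest,
                 gene_clusters = clg, psg = up$stable))
}
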