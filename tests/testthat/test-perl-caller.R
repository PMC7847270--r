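make_track <- function(values, chrom = "chr1") {
  cov <- IRanges::RleList(setNames(list(S4Vectors::Rle(values)), chrom),
                          compress = FALSE)
  structure(list(cov = cov, library_size = 1e6, per_million = TRUE),
            class = "coverage_track")
}

test_that("expressed-region calling thresholds and joins runs", {
  cfg <- perl_config()
  # flat zero coverage -> nothing
  expect_length(call_expressed_regions(make_track(numeric(100)), cfg), 0)
  # two runs above cutoff with a 4-bp gap join under join_gap
  v <- numeric(50)
  v[11:20] <- 0.3
  v[25:30] <- 0.3
  er <- call_expressed_regions(make_track(v), cfg)
  expect_equal(c(start(er), end(er)), c(11, 30))
  # gap above join_gap stays split
  er2 <- call_expressed_regions(make_track(v),
                                perl_config(join_gap = 3))
  expect_length(er2, 2)
  # bases exactly at the cutoff pass (inclusive)
  v3 <- numeric(20)
  v3[5] <- 0.25
  expect_length(call_expressed_regions(make_track(v3), cfg), 1)
})

test_that("expressed-region calling equals a per-base scan oracle", {
  set.seed(21)
  for (i in 1:10) {
    v <- round(runif(3000) * 0.6, 2)
    v[sample(3000, 2000)] <- 0
    jg <- sample(c(0, 2, 10, 40), 1)
    er <- call_expressed_regions(make_track(v),
                                 perl_config(join_gap = jg))
    orc <- oracle_expressed_regions(v, 0.25, jg)
    expect_equal(start(er), unname(orc[, "start"]))
    expect_equal(end(er), unname(orc[, "end"]))
  }
})

test_that("cluster building merges below 3 kb and is idempotent", {
  cfg <- perl_config()
  ers <- GRanges("chr1", IRanges(c(1, 2001), c(1000, 3000)))  # gap 1000
  cl <- build_clusters(ers, cfg = cfg)
  expect_length(cl, 1)
  expect_equal(c(start(cl), end(cl)), c(1, 3000))
  ers2 <- GRanges("chr1", IRanges(c(1, 4001), c(1000, 5000)))  # gap 3000
  expect_length(build_clusters(ers2, cfg = cfg), 2)
  cl2 <- build_clusters(ers2, cfg = cfg)
  expect_identical(granges(build_clusters(cl2, cfg = cfg)),
                   granges(cl2))
})

test_that("specificity, size and early-expression filters apply their
           thresholds strictly", {
  cfg <- perl_config()
  pgc <- GRanges("chr1", IRanges(1, 100000))
  expect_length(filter_pgc_specific(
    pgc, GRanges("chr1", IRanges(1, 15000)), cfg), 0)      # 15%
  expect_length(filter_pgc_specific(
    pgc, GRanges("chr1", IRanges(1, 5000)), cfg), 1)       # 5%
  expect_length(filter_pgc_specific(
    pgc, GRanges("chr1", IRanges(1, 10000)), cfg), 1)      # exactly 10%

  sizes <- GRanges("chr1", IRanges(c(1, 5e6), width = c(249999, 250000)))
  expect_equal(width(filter_size(sizes, cfg)), 250000)
  expect_length(filter_size(GRanges(), cfg), 0)

  cand <- GRanges("chr1", IRanges(1, 300000))
  early_all <- list("1dpf" = GRanges("chr1", IRanges(1, 300000)))
  expect_length(exclude_early(cand, early_all, cfg), 0)
  expect_length(exclude_early(cand, list(), cfg), 1)
  early_small <- list("2dpf" = GRanges("chr1", IRanges(1, 24000)))
  expect_length(exclude_early(cand, early_small, cfg), 1)  # 8%
})

test_that("cross-timepoint combination union-merges and records sources", {
  per_tp <- list(
    "6dpf" = GRanges("chr1", IRanges(c(1, 1e6), width = c(3e5, 3e5))),
    "10dpf" = GRanges(c("chr1", "chr2"),
                      IRanges(c(2e5, 1), width = c(3e5, 3e5)))
  )
  out <- combine_timepoints(per_tp)
  expect_equal(length(out), 3)
  expect_equal(mcols(out)$id, sprintf("PERL_%03d", 1:3))
  expect_equal(mcols(out)$source_timepoints,
               c("6dpf,10dpf", "6dpf", "10dpf"))
  # disjoint candidates stay distinct; union-find oracle on bases
  merged_manual <- reduce(c(per_tp[[1]], per_tp[[2]]), min.gapwidth = 1)
  expect_identical(granges(out), granges(sort(merged_manual)))
})

test_that("raising the cutoff never increases total expressed bases", {
  set.seed(33)
  v <- round(runif(5000) * 0.8, 2)
  tot <- vapply(c(0.1, 0.25, 0.5), function(ct) {
    er <- call_expressed_regions(make_track(v),
                                 perl_config(coverage_cutoff = ct))
    sum(as.numeric(width(er)))
  }, 0)
  expect_true(all(diff(tot) <= 0))
})

test_that("the caller recovers planted loci on synthetic data", {
  sim <- shared_sim()
  called <- call_perls(sim$totalrna$PGC, sim$totalrna$fish,
                       sim$art$layout)
  perls <- called$perls
  expect_equal(length(perls), length(sim$art$perls))
  for (i in seq_along(sim$art$perls)) {
    hit <- subsetByOverlaps(perls, sim$art$perls[i])
    expect_equal(length(hit), 1)
    expect_gte(jaccard_bp(hit, sim$art$perls[i]), 0.9)
  }
  # every call intersects a planted locus, meets the size floor, and
  # stays PGC-specific against the fish clusters of its source timepoints
  expect_true(all(overlapsAny(perls, sim$art$perls)))
  expect_true(all(width(perls) >= 250000))
  for (tp in c("6dpf", "10dpf")) {
    frac <- base_overlap_fraction(perls, called$clusters$fish[[tp]])
    expect_true(all(frac <= 0.10))
  }
})

test_that("PERL quantification averages replicate RPKM and filters
           piRNA lengths", {
  perls <- GRanges("chr1", IRanges(1, 5e5))
  mcols(perls)$id <- "PERL_001"
  mk <- function(n, len = 50) {
    aligned_reads(GRanges("chr1", IRanges(seq(1, by = 600, length.out = n),
                                          width = len), strand = "+"))
  }
  # 100 contained reads, 500 kb, forced library 1e6 -> RPKM 0.2
  rd <- mk(100)
  expect_equal(rpkm(count_contained(perls, rd), width(perls), 1e6), 0.2)
  q <- quantify_perls(perls, list(s1 = list(mk(100), mk(300))))
  direct <- mean(c(rpkm(100, 5e5, 100), rpkm(300, 5e5, 300)))
  expect_equal(q$rpkm_s1, direct)
  # 22-nt reads fall outside the 23-33 piRNA window
  small <- aligned_reads(GRanges("chr1", IRanges(c(101, 201), width = c(22, 27))))
  q2 <- quantify_perls(perls, list(s1 = list(mk(10))),
                       small_rna_by_sample = list(s1 = list(small)))
  expect_equal(q2$pirna_s1, rpkm(1, 5e5, 2))
})

test_that("identical inputs and config give identical caller output", {
  sim <- shared_sim()
  a <- call_perls(sim$totalrna$PGC, sim$totalrna$fish, sim$art$layout)
  b <- call_perls(sim$totalrna$PGC, sim$totalrna$fish, sim$art$layout)
  expect_identical(as.data.frame(a$perls), as.data.frame(b$perls))
})
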