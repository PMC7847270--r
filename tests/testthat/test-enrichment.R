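test_that("shuffled backgrounds match length and chromosome and avoid
           the excluded set", {
  lay <- toy_layout(c(chr1 = 1e5, chr2 = 8e4))
  perls <- GRanges(c("chr1", "chr2"), IRanges(c(1001, 2001),
                                              width = c(5000, 3000)))
  bgs <- shuffle_background(perls, lay, n_sets = 25, seed = 5)
  expect_length(bgs, 25)
  for (bg in bgs) {
    expect_equal(as.character(seqnames(bg)), as.character(seqnames(perls)))
    expect_equal(width(bg), width(perls))
    expect_length(findOverlaps(bg, perls, ignore.strand = TRUE), 0)
  }
})

test_that("impossible placements raise a hard error", {
  lay <- toy_layout(c(chr1 = 1000))
  r <- GRanges("chr1", IRanges(101, 200))
  expect_error(shuffle_background(r, lay, n_sets = 1,
                                  excluded = genome_granges(lay),
                                  max_tries = 50, seed = 1),
               "could not place")
  # region longer than its chromosome
  expect_error(shuffle_background(GRanges("chr1", IRanges(1, 1000)),
                                  lay, n_sets = 1,
                                  excluded = GRanges("chr1",
                                                     IRanges(1, 1))),
               "longer|could not place")
})

test_that("placement is uniform over the valid start set", {
  lay <- toy_layout(c(chr1 = 1000))
  r <- GRanges("chr1", IRanges(1, 100))
  bgs <- shuffle_background(r, lay, n_sets = 5000, excluded = r,
                            seed = 99)
  starts <- vapply(bgs, start, 0L)
  # enumerated valid starts: 101..901 (0-based 100..900)
  expect_true(all(starts >= 101 & starts <= 901))
  h <- table(cut(starts, breaks = seq(100.5, 901.5, length.out = 21)))
  p <- suppressWarnings(stats::chisq.test(h)$p.value)
  expect_gt(p, 0.001)
})

test_that("background overlap converges to the uniform feature density", {
  lay <- toy_layout(c(chr1 = 1e6))
  # features occupy exactly 20% of the chromosome, uniformly
  feat <- GRanges("chr1", IRanges(seq(1, 1e6, by = 1000), width = 200))
  perls <- GRanges("chr1", IRanges(c(10001, 500001), width = c(20000,
                                                               30000)))
  bgs <- shuffle_background(perls, lay, n_sets = 100, seed = 12)
  oe <- overlap_enrichment(perls, reduce(feat), bgs)
  mc_sd <- sd(oe$set_means) / sqrt(length(oe$set_means))
  expect_lt(abs(mean(oe$set_means) - 0.20), 3 * max(mc_sd, 1e-4))
  # saturated and empty feature sets behave degenerately
  sat <- overlap_enrichment(perls, genome_granges(lay), bgs)
  expect_equal(sat$observed, c(1, 1))
  expect_equal(sat$background, c(1, 1))
  expect_equal(sat$empirical_p, 1)
  emp <- overlap_enrichment(perls, GRanges(), bgs)
  expect_equal(emp$observed, c(0, 0))
})

test_that("compartment composition is base-weighted and validated", {
  comp <- GRanges("chr1", IRanges(c(1, 50001), width = 5e4),
                  label = c("A", "B"))
  inB <- GRanges("chr1", IRanges(60001, 70000))
  cs <- compartment_split(inB, comp)
  expect_equal(unname(cs$overall), c(0, 1))
  expect_equal(cs$region_fractions$B, 1)
  expect_equal(unname(cs$genome_wide), c(0.5, 0.5))
  # partially annotated region: the rest is "neither"
  half <- GRanges("chr1", IRanges(95001, 115000))
  cs2 <- compartment_split(half, comp)
  expect_equal(cs2$region_fractions$neither, 0.75)
  expect_equal(unname(cs2$overall), c(0, 1))
  bad <- GRanges("chr1", IRanges(c(1, 400), width = 1000),
                 label = c("A", "B"))
  expect_error(compartment_split(inB, bad), "overlap")
})

test_that("piRNA density separates planted regions from background", {
  set.seed(61)
  lay <- toy_layout(c(chr1 = 2e6))
  perls <- GRanges("chr1", IRanges(seq(1e4, by = 9e4, length.out = 20),
                                   width = 4e4))
  rd <- aligned_reads(GRanges("chr1",
                              IRanges(unlist(lapply(seq_along(perls),
                                                    function(i) {
                                start(perls)[i] + sample.int(39000, 30)
                              })), width = 27), strand = "+"))
  bgs <- shuffle_background(perls, lay, n_sets = 20, seed = 8)
  dc <- density_comparison(perls, bgs, rd)
  expect_true(all(dc$observed > 0))
  expect_equal(dc$background, rep(0, 20))
  expect_lt(dc$wilcox_p, 0.01)
  # doubling the library leaves RPKM densities unchanged
  dc2 <- density_comparison(perls, bgs, rd,
                            library_size = sum(perlscan:::read_weights(rd)))
  dc3 <- density_comparison(perls, bgs, c(rd, rd),
                            library_size = 2 * sum(perlscan:::read_weights(rd)))
  expect_equal(dc3$observed, dc2$observed)
  # no reads at all -> degenerate, reported NA
  dc0 <- density_comparison(perls, bgs, rd[0], library_size = 1)
  expect_true(is.na(dc0$wilcox_p))
})

test_that("expression over time detects induction with a paired test", {
  set.seed(71)
  lay <- toy_layout(c(chr1 = 2e6))
  perls <- GRanges("chr1", IRanges(seq(1e4, by = 9e4, length.out = 20),
                                   width = 4e4))
  mcols(perls)$id <- sprintf("P%02d", 1:20)
  mk <- function(per_perl) {
    aligned_reads(GRanges("chr1",
                          IRanges(unlist(lapply(seq_along(perls),
                                                function(i) {
                            start(perls)[i] + sample.int(39000, per_perl)
                          })), width = 50), strand = "+"))
  }
  # constant off-target reads keep the library size comparable, so the
  # induction shows up in RPKM (all-in-region libraries would cancel)
  filler <- aligned_reads(GRanges("chr1", IRanges(rep(1950001, 2000),
                                                  width = 50),
                                  strand = "+"))
  low <- c(mk(5), filler)
  eot <- expression_over_time(perls,
                              list("3dpf" = list(low),
                                   "6dpf" = list(c(mk(50), filler))))
  expect_equal(dim(eot$rpkm), c(20L, 2L))
  expect_lt(eot$tests$p[1], 0.01)
  same <- expression_over_time(perls, list(a = list(low),
                                           b = list(low)))
  expect_equal(same$tests$p, 1)
})
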