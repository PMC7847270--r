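test_that("feature assignment is containment-based and orientation-aware", {
  feats <- GRanges("chr1", IRanges(c(101, 501), width = 200),
                   strand = c("+", "-"))
  rd <- aligned_reads(GRanges("chr1",
                              IRanges(c(111, 151, 291, 511), width = 25),
                              strand = c("+", "-", "+", "+")))
  a <- assign_to_features(rd, feats)
  expect_equal(a$read, c(1, 2, 4))  # read 3 straddles the boundary
  expect_equal(a$orientation, c("sense", "antisense", "antisense"))
})

test_that("length profiles tally weighted read lengths per class", {
  feats <- GRanges("chr1", IRanges(101, 400), strand = "+")
  rd <- aligned_reads(GRanges("chr1", IRanges(c(111, 151, 191),
                                              width = 27),
                              strand = "-"))
  a <- assign_to_features(rd, feats)
  lp <- length_profiles(rd, a, "LTR")
  expect_equal(lp$count[lp$length == 27 & lp$orientation == "antisense"],
               3)
  expect_equal(nrow(length_profiles(rd, a[0, ], "LTR")), 0)

  # simulated Normal(27, 1.5) lengths: the histogram mode is 27
  set.seed(3)
  n <- 5000
  len <- pmin(pmax(round(rnorm(n, 27, 1.5)), 18), 40)
  big <- aligned_reads(GRanges("chr1", IRanges(rep(101, n), width = len),
                               strand = "-"))
  feats2 <- GRanges("chr1", IRanges(1, 1000), strand = "+")
  lp2 <- length_profiles(big, assign_to_features(big, feats2), "LTR")
  expect_equal(lp2$length[which.max(lp2$count)], 27)
})

test_that("strand bias fractions and cross-condition rank test", {
  feats <- GRanges("chr1", IRanges(c(101, 501), width = 300),
                   strand = "+")
  rd <- aligned_reads(GRanges("chr1",
                              IRanges(c(rep(111, 10), rep(151, 90),
                                        rep(511, 5)), width = 25),
                              strand = c(rep("+", 10), rep("-", 90),
                                         rep("+", 5))))
  sb <- strand_bias(rd, assign_to_features(rd, feats), c("e1", "e2"))
  expect_equal(sb$sense_fraction[sb$element == "e1"], 0.10)
  expect_equal(sb$sense_fraction[sb$element == "e2"], 1.0)

  set.seed(17)
  fa <- pmin(pmax(rnorm(200, 0.1, 0.05), 0), 1)
  fb <- pmin(pmax(rnorm(200, 0.4, 0.05), 0), 1)
  expect_lt(strand_bias_compare(fa, fb)$p.value, 1e-6)
})

test_that("ping-pong Z-score matches direct arithmetic", {
  # P10 equal to the background mean gives Z = 0
  c0 <- c(rep(1, 9), 2, rep(1, 5), rep(3, 14), 2)
  bg <- c0[-10]
  expect_equal(pingpong_z(c0)$Z, (2 - mean(bg)) / sd(bg))
  # fifteen 4s + fourteen 6s background, P10 = 20
  c1 <- c(rep(4, 9), 20, rep(4, 6), rep(6, 14))
  m <- 144 / 29
  s <- sqrt((15 * (4 - m)^2 + 14 * (6 - m)^2) / 28)
  expect_equal(pingpong_z(c1)$Z, (20 - m) / s, tolerance = 1e-12)
  expect_warning(z0 <- pingpong_z(rep(2, 30)), "SD is zero")
  expect_true(is.na(z0$Z))
})

test_that("ping-pong tallies equal the all-pairs oracle exactly", {
  set.seed(23)
  lay <- toy_layout(c(a = 2000, b = 1500))
  for (i in 1:10) {
    rd <- random_reads(lay, sample(20:200, 1), c(18, 35))
    if (i > 7) mcols(rd)$weight <- sample(1:3, length(rd), replace = TRUE)
    pp <- pingpong(rd)
    expect_identical(unname(pp$counts), unname(oracle_pingpong(rd)))
  }
})

test_that("pairs must overlap and the 5'-overlap is strand-correct", {
  # + read 5' at 11, - read 5' at 20 -> k = 10
  rd <- aligned_reads(GRanges("c", IRanges(c(11, 1), c(37, 20)),
                              strand = c("+", "-")))
  expect_warning(pp <- pingpong(rd), "SD")  # single filled bin
  expect_equal(unname(pp$counts[10]), 1)
  # same 5' distance (k = 10) but no genomic overlap is not tallied
  rd2 <- aligned_reads(GRanges("c", IRanges(c(31, 38), c(37, 40)),
                               strand = c("+", "-")))
  expect_equal(sum(suppressWarnings(pingpong(rd2))$counts), 0)
  rd3 <- aligned_reads(GRanges("c", IRanges(c(100, 1), c(127, 20)),
                               strand = c("+", "-")))
  expect_equal(sum(suppressWarnings(pingpong(rd3))$counts), 0)
})

test_that("nucleotide bias counts positions and the downstream base", {
  rd <- aligned_reads(GRanges("chr1", IRanges(c(1, 11), width = 4),
                              strand = "+"),
                      seq = c("TGCA", "TTTA"))
  nb <- nucleotide_bias(rd)
  expect_equal(unname(nb$freq["U", 1]), 1)
  expect_equal(unname(nb$freq["A", 4]), 1)
  expect_equal(colSums(nb$freq), rep(1, 4), ignore_attr = TRUE)

  genome <- Biostrings::DNAStringSet(c(chr1 = "AATGGCCTTA"))
  # + read ending at 3 -> downstream base G (not U)
  plus <- aligned_reads(GRanges("chr1", IRanges(1, 3), strand = "+"),
                        seq = "AAT")
  expect_equal(nucleotide_bias(plus, genome)$downstream_u_fraction, 0)
  # - read starting at 2 -> genomic base 1 is A -> U on the read strand
  minus <- aligned_reads(GRanges("chr1", IRanges(2, 4), strand = "-"),
                         seq = "CAT")
  expect_equal(nucleotide_bias(minus, genome)$downstream_u_fraction, 1)
  # read at the chromosome edge is skipped for the downstream metric
  edge <- aligned_reads(GRanges("chr1", IRanges(8, 10), strand = "+"),
                        seq = "TTA")
  both <- c(plus, edge)
  expect_equal(nucleotide_bias(both, genome)$downstream_u_fraction, 0)
})

test_that("profile clustering recovers planted archetypes", {
  set.seed(31)
  arch1 <- c(5, 4, 3, 2, 1, 0.5)
  arch2 <- c(0.5, 0.5, 1, 2, 5, 2)
  mat <- rbind(
    t(replicate(10, arch1 + rnorm(6, 0, 0.1))),
    t(replicate(10, arch2 + rnorm(6, 0, 0.1)))
  )
  rownames(mat) <- paste0("e", 1:20)
  res <- cluster_profiles(mat, k = 2)
  truth <- rep(1:2, each = 10)
  tab <- table(res$cluster, truth)
  expect_equal(sum(apply(tab, 2, max)), 20)  # 100% purity
  # identical rows land together; anticorrelation maxes the distance
  mat2 <- rbind(a = arch1, b = arch1, c = -arch1)
  d <- 1 - cor(t(mat2))
  expect_equal(unname(d["a", "b"]), 0)
  expect_equal(unname(d["a", "c"]), 2)
  expect_warning(cluster_profiles(rbind(mat, flat = rep(1, 6)), 2),
                 "zero-variance")
})

test_that("clade enrichment equals the exact hypergeometric tail", {
  # N=10, K=4, n=5, k=4 -> C(4,4)C(6,1)/C(10,5)
  universe <- paste0("e", 1:10)
  clades <- setNames(rep(c("x", "y"), c(4, 6)), universe)
  ce <- clade_enrichment(universe[c(1:4, 10)], universe, clades)
  expect_equal(ce$p[ce$clade == "x"],
               choose(4, 4) * choose(6, 1) / choose(10, 5),
               tolerance = 1e-12)
  # k = 0 -> upper tail includes everything
  ce0 <- clade_enrichment(universe[5:9], universe, clades)
  expect_equal(ce0$p[ce0$clade == "x"], 1)
  # cluster = universe -> p = 1 for every clade
  ceU <- clade_enrichment(universe, universe, clades)
  expect_equal(ceU$p, c(1, 1))
})
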