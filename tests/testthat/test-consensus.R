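# Multi-mapper resolution, read extension, consensus pileup and comparison.

make_placements <- function(read_id, start, strand = "+", chrom = "cons",
                            read_length = 50L, n_hits = 1L) {
  aligned_reads(read_id = read_id, chrom = chrom, start = start,
                strand = strand, read_length = read_length,
                mapq = 37L, n_hits = n_hits)
}

test_that("unique reads pass through multimapper resolution unchanged", {
  p <- make_placements("r1", 100L)
  expect_identical(assign_multimappers(p, seed = 1)$start, 100L)
})

test_that("multimapper selection is uniform across tied placements", {
  p <- make_placements(rep("r1", 4L), c(0L, 100L, 200L, 300L), n_hits = 4L)
  picks <- vapply(1:4000, function(s) assign_multimappers(p, seed = s)$start,
                  integer(1))
  freq <- as.numeric(table(factor(picks, levels = c(0, 100, 200, 300)))) / 4000
  se <- sqrt(0.25 * 0.75 / 4000)
  expect_true(all(abs(freq - 0.25) < 3 * se + 1e-9))
})

test_that("multimapper selection is deterministic and order-invariant", {
  p <- make_placements(rep(c("a", "b"), each = 3L),
                       c(0L, 10L, 20L, 5L, 15L, 25L), n_hits = 3L)
  r1 <- assign_multimappers(p, seed = 99)
  r2 <- assign_multimappers(p, seed = 99)
  expect_identical(r1, r2)
  shuf <- p[c(4L, 1L, 6L, 3L, 2L, 5L), ]
  expect_identical(assign_multimappers(shuf, seed = 99), r1)
})

test_that("directional extension follows the stated 3'-extension rule", {
  p <- make_placements(c("a", "b", "c"), c(100L, 100L, 100L),
                       strand = c("+", "-", "+"))
  fp <- extend_read(p, 150L)
  expect_equal(fp$start[1], 100L); expect_equal(fp$end[1], 300L)
  expect_equal(fp$start[2], 0L);   expect_equal(fp$end[2], 150L)  # clipped
  fp0 <- extend_read(p, 0L)
  expect_equal(fp0$end - fp0$start, rep(50L, 3L))                 # identity
})

test_that("a single extended read yields the hand-computed RPKM", {
  p <- make_placements("r1", 0L)
  pr <- profile_consensus(p, 1000L, extension = 150L, bin_width = 1L,
                          library_size = 1e6)
  expect_equal(pr$values[1:200], rep(1000, 200))   # depth 1 -> RPKM 1000
  expect_equal(pr$values[201:1000], rep(0, 800))
  expect_equal(profile_consensus(make_placements(character(0), integer(0)),
                                 1000L, library_size = 1e6)$values,
               rep(0, 1000))
})

test_that("pileup matches a brute-force footprint overlap count", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(30:100, 1)
    L <- 800L
    p <- make_placements(sprintf("r%d", 1:n),
                         start = sample(0:900, n, replace = TRUE),
                         strand = sample(c("+", "-"), n, replace = TRUE))
    pr <- profile_consensus(p, L, extension = 150L, library_size = 1e6)
    fp <- extend_read(p, 150L)
    want <- oracle_depth(pmax(fp$start, 0L), pmin(fp$end, L), L)
    expect_equal(pr$raw_depth, want)
    # conservation: total depth equals summed clipped footprint lengths
    expect_equal(sum(pr$raw_depth),
                 sum(pmax(0L, pmin(fp$end, L) - pmax(fp$start, 0L))))
  }
})

test_that("RPKM scales inversely with library size", {
  p <- make_placements(sprintf("r%d", 1:20), sample(0:500, 20))
  a <- profile_consensus(p, 600L, library_size = 1e6)
  b <- profile_consensus(p, 600L, library_size = 2e6)
  expect_equal(a$values, 2 * b$values)
  expect_error(profile_consensus(p, 600L, library_size = 0), "library_size")
})

test_that("profiles are invariant to placement order and flip under strand reversal", {
  set.seed(5)
  n <- 40L; L <- 500L
  p <- make_placements(sprintf("r%d", 1:n), sample(0:450, n, replace = TRUE),
                       strand = sample(c("+", "-"), n, replace = TRUE))
  pr <- profile_consensus(p, L, extension = 100L, library_size = 1e6)
  shuf <- p[sample(n), ]
  expect_equal(profile_consensus(shuf, L, extension = 100L,
                                 library_size = 1e6)$values, pr$values)
  # reverse-complement view: flip starts and strands
  flipped <- p
  flipped$start <- L - (p$start + p$read_length)
  flipped$strand <- ifelse(p$strand == "+", "-", "+")
  prf <- profile_consensus(flipped, L, extension = 100L, library_size = 1e6)
  expect_equal(prf$values, rev(pr$values))
})

test_that("binned profiles average per-base depth within bins", {
  p <- make_placements("r1", 0L)
  pr <- profile_consensus(p, 100L, extension = 0L, bin_width = 25L,
                          library_size = 1e6)
  expect_equal(length(pr$values), 4L)
  expect_equal(pr$values[1:2], c(1000, 1000))  # 50-bp footprint fills bins 1+2
  expect_equal(pr$values[3:4], c(0, 0))
  # partial overlap: mean depth within the bin
  pr2 <- profile_consensus(make_placements("r1", 10L), 100L, extension = 0L,
                           bin_width = 25L, library_size = 1e6)
  expect_equal(pr2$values, c(1000 * 15 / 25, 1000, 1000 * 10 / 25, 0))
})

test_that("condition comparison handles identity, scaling and mismatches", {
  p <- make_placements(sprintf("r%d", 1:10), sample(0:400, 10))
  a <- profile_consensus(p, 500L, library_size = 1e6)
  b <- profile_consensus(p, 500L, library_size = 1e7)   # a scaled by 10
  expect_equal(compare_conditions(a, a)$ratio, rep(1, 500))
  cmp <- compare_conditions(a, b)
  expect_true(all(abs(cmp$ratio[a$values > 0] - 10) < 1e-3))
  expect_equal(cmp$mean_ratio, 10, tolerance = 1e-4)
  bad <- profile_consensus(p, 400L, library_size = 1e6)
  expect_error(compare_conditions(a, bad), "length or bin width")
})

test_that("shape correlation rejects mismatched references", {
  p <- make_placements("r1", 0L)
  pr <- profile_consensus(p, 500L, library_size = 1e6)
  expect_error(profile_shape_correlation(pr, rep(1, 400)))
})
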