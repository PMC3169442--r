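# Intactness selection, read filtering, deduplication, flank agglomeration
# and the mappability check.

flank_reads <- function(read_id, start, strand = "+", chrom = "chr1",
                        mapq = 37L, n_hits = 1L, read_length = 50L) {
  aligned_reads(read_id = read_id, chrom = chrom, start = start,
                strand = strand, read_length = read_length, mapq = mapq,
                n_hits = n_hits)
}

one_element <- function(start = 10000L, end = 12000L, strand = "+") {
  data.frame(chrom = "chr1", start = start, end = end, strand = strand,
             family = "IAPsim", divergence = 0.01, stringsAsFactors = FALSE)
}

test_that("intactness selection applies length and divergence thresholds", {
  ann <- data.frame(chrom = "chr1",
                    start = c(0L, 5000L, 10000L), end = c(4000L, 7000L, 14000L),
                    strand = "+", family = "IAPsim",
                    divergence = c(0.01, 0.01, 0.2), stringsAsFactors = FALSE)
  expect_equal(nrow(select_intact_elements(ann, 0, 1)), 3L)    # vacuous
  sel <- select_intact_elements(ann, 3000L, 0.1)
  expect_equal(sel$start, 0L)                                  # planted truth
  expect_identical(select_intact_elements(sel, 3000L, 0.1)$start, sel$start)
})

test_that("quality filter is strict and removes multi-mappers", {
  r <- flank_reads(c("a", "b", "c", "d"), c(0L, 10L, 20L, 30L),
                   mapq = c(7L, 8L, 30L, 30L), n_hits = c(1L, 1L, 1L, 2L))
  f <- filter_flank_reads(r, min_quality = 7L)
  expect_identical(f$read_id, c("b", "c"))     # quality exactly 7 removed
  expect_equal(attr(f, "removed"), c(low_quality = 1L, multi_mapping = 1L))
})

test_that("deduplication collapses same-location reads, keeps strands apart", {
  r <- flank_reads(c("a", "b", "c", "d"), c(100L, 100L, 100L, 200L),
                   strand = c("+", "+", "-", "+"))
  d <- dedup_reads(r)
  expect_equal(nrow(d), 3L)                     # one of a/b gone
  expect_equal(attr(d, "n_removed"), 1L)
  expect_setequal(paste(d$start, d$strand), c("100 +", "100 -", "200 +"))
  expect_identical(dedup_reads(d)$read_id, d$read_id)   # idempotent
  shuf <- r[c(3L, 1L, 4L, 2L), ]
  expect_identical(dedup_reads(shuf), d)                # order-invariant
})

test_that("a single in-flank footprint lands at the hand-computed density", {
  el <- one_element()
  r <- flank_reads("r1", 9000L)    # + read, footprint [9000, 9200)
  fl <- agglomerate_flanks(r, el, flank_size = 7000L, extension = 150L,
                           library_size = 1e6)
  want <- rep(0, 14000)
  rel <- (9000:9199) - 10000L                  # -1000..-801
  want[rel + 7000L + 1L] <- 1 / 1 / (1e6 / 1e6)
  expect_equal(fl$density, want)
})

test_that("duplicating the element set leaves per-position density unchanged", {
  el <- one_element()
  el2 <- rbind(el, el)
  r <- flank_reads(sprintf("r%d", 1:30), sample(8000:14000, 30))
  f1 <- agglomerate_flanks(r, el, flank_size = 2000L, library_size = 1e6)
  f2 <- agglomerate_flanks(r, el2, flank_size = 2000L, library_size = 1e6)
  expect_equal(f1$density, f2$density)
})

test_that("agglomeration matches the brute-force relative-position count", {
  set.seed(33)
  for (rep in 1:5) {
    els <- rbind(one_element(3000L, 4000L, sample(c("+", "-"), 1)),
                 one_element(8000L, 9500L, sample(c("+", "-"), 1)))
    n <- 40L
    r <- flank_reads(sprintf("r%d", 1:n), sample(2000:11000, n),
                     strand = sample(c("+", "-"), n, replace = TRUE))
    fl <- agglomerate_flanks(r, els, flank_size = 800L, extension = 150L,
                             library_size = 1e6)
    fp <- extend_read(r, 150L)
    want <- oracle_flank_counts(fp, els, 800L)
    expect_equal(fl$counts, want)
    expect_equal(fl$density, want / 2 / 1)
  }
})

test_that("flank profiles are invariant under genome reverse-complement", {
  set.seed(44)
  G <- 20000L
  el <- one_element(9000L, 11000L, "+")
  n <- 60L
  r <- flank_reads(sprintf("r%d", 1:n), sample(6000:14000, n),
                   strand = sample(c("+", "-"), n, replace = TRUE))
  fl <- agglomerate_flanks(r, el, flank_size = 1500L, extension = 120L,
                           library_size = 1e6)
  # mirrored coordinates: element and reads flipped through the genome
  elf <- el; elf$start <- G - el$end; elf$end <- G - el$start
  elf$strand <- "-"
  rf <- r
  rf$start <- G - (r$start + r$read_length)
  rf$strand <- ifelse(r$strand == "+", "-", "+")
  flf <- agglomerate_flanks(rf, elf, flank_size = 1500L, extension = 120L,
                            library_size = 1e6)
  expect_equal(flf$density, fl$density)
})

test_that("filter -> dedup -> agglomerate is invariant to read order", {
  set.seed(55)
  el <- one_element()
  n <- 80L
  r <- flank_reads(sprintf("r%d", 1:n),
                   sample(8500:13500, n, replace = TRUE),
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   mapq = sample(c(5L, 37L), n, replace = TRUE),
                   n_hits = sample(c(1L, 1L, 1L, 2L), n, replace = TRUE))
  run <- function(x) agglomerate_flanks(
    dedup_reads(filter_flank_reads(x, 7L)), el,
    flank_size = 2000L, library_size = 1e6)
  expect_equal(run(r[sample(n), ])$density, run(r)$density)
})

test_that("start-count mode counts read starts only", {
  el <- one_element()
  r <- flank_reads("r1", 9500L)
  fl <- agglomerate_flanks(r, el, flank_size = 1000L, library_size = 1e6,
                           mode = "starts")
  expect_equal(sum(fl$counts), 1)
  expect_equal(fl$rel_position[fl$counts > 0], 9500L - 10000L)
})

test_that("mappability is ~1 on random sequence and 0 on exact duplicates", {
  core <- random_dna(10000, seed = 66)
  dup <- random_dna(400, seed = 67)
  g <- c(chr1 = paste0(core, dup, random_dna(500, seed = 68), dup))
  w <- data.frame(chrom = "chr1",
                  start = c(0L, 10000L), end = c(5000L, 10351L))
  m <- mappability_profile(g, 50L, w)
  expect_gt(m[1], 0.999)
  expect_equal(m[2], 0)          # every 50-mer inside the duplicated span
})

test_that("mappability matches the all-vs-all k-mer oracle", {
  set.seed(77)
  for (rep in 1:3) {
    piece <- random_dna(300)
    g <- c(a = paste0(random_dna(500), piece, random_dna(200)),
           b = paste0(piece, random_dna(400)))
    k <- sample(c(20L, 30L), 1)
    want <- oracle_mappability(g, k)
    w <- data.frame(chrom = c("a", "b"), start = c(0L, 100L),
                    end = c(nchar(g[["a"]]), 500L))
    got <- mappability_profile(g, k, w)
    expect_equal(got[1], mean(want$a[1:(nchar(g[["a"]]) - k + 1L)]))
    expect_equal(got[2], mean(want$b[101:500]))
  }
})
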