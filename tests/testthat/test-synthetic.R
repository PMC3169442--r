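# Generators: planted structure, distributional properties, determinism.

test_that("planted copies reproduce the consensus at zero divergence", {
  fam <- erv_family_model(random_dna(400, seed = 2), ltr_length = 60,
                          copies = 3L, per_copy_divergence = 0)
  g <- build_genome(fam, 8000, seed = 5)
  expect_equal(nrow(g$annotations), 3L)
  for (i in 1:3) {
    sub <- substring(g$genome[[1L]], g$annotations$start[i] + 1L,
                     g$annotations$end[i])
    if (g$annotations$strand[i] == "-") sub <- revcomp(sub)
    expect_identical(sub, fam$consensus)
  }
})

test_that("copy divergence matches the binomial expectation", {
  fam <- erv_family_model(random_dna(2000, seed = 3), copies = 10L,
                          per_copy_divergence = 0.05)
  g <- build_genome(fam, 60000, seed = 8)
  nsub <- g$annotations$n_subs
  expected <- 2000 * 0.05
  se <- sqrt(2000 * 0.05 * 0.95 / 10)
  expect_lt(abs(mean(nsub) - expected), 3 * se)
})

test_that("genome building is deterministic given the seed", {
  fam <- erv_family_model(random_dna(300, seed = 4), copies = 2L)
  g1 <- build_genome(fam, 6000, seed = 42)
  g2 <- build_genome(fam, 6000, seed = 42)
  expect_identical(g1, g2)
})

test_that("impossible placements raise a placement error", {
  fam <- erv_family_model(random_dna(100, seed = 1), copies = 4L,
                          per_copy_divergence = 0)
  expect_error(build_genome(fam, 900, seed = 1, min_gap = 400),
               "could not place")
})

test_that("read starts are uniform without enrichment structure", {
  fam <- erv_family_model(random_dna(200, seed = 6), copies = 1L,
                          flank_decay_scale = 100)
  g <- build_genome(fam, 20000, seed = 9)
  ann0 <- g$annotations[0, , drop = FALSE]   # no elements -> flat weights
  lib <- library_model(n_reads = 1000L, enrichment_fold = 1, seed = 10)
  rejections <- 0L
  for (s in 1:40) {
    sim <- simulate_chip_reads(g$genome, ann0, fam, lib, "wt", seed = s)
    ks <- suppressWarnings(stats::ks.test(sim$truth$frag_start, "punif",
                                          0, 20000 - 200))
    if (ks$p.value < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 2L)   # ~alpha * runs expected by chance
})

test_that("wt / ko body read counts follow the closed-form weight ratio", {
  fam <- erv_family_model(random_dna(1000, seed = 12),
                          body_profile = rep(1, 1000),  # flat: tractable
                          copies = 1L, per_copy_divergence = 0,
                          flank_decay_scale = 200)
  g <- build_genome(fam, 40000, seed = 13)
  lib <- library_model(n_reads = 50000L, enrichment_fold = 10,
                       ko_attenuation = 0.1, background_rate = 1, seed = 14)
  wt <- simulate_chip_reads(g$genome, g$annotations, fam, lib, "wt", seed = 15)
  ko <- simulate_chip_reads(g$genome, g$annotations, fam, lib, "ko", seed = 16)
  got <- sum(wt$truth$origin != "background") /
    sum(ko$truth$origin != "background")
  want <- expected_body_ratio(g$genome, g$annotations, fam, lib)
  expect_lt(abs(got / want - 1), 0.1)
  # and the naive (background + fold) / (background + fold * attenuation)
  # form is the dominant term of that expectation
  expect_lt(abs(want / ((1 + 10) / (1 + 1)) - 1), 0.35)
})

test_that("read simulation is bit-reproducible under a fixed seed", {
  fam <- erv_family_model(random_dna(300, seed = 20), copies = 2L)
  g <- build_genome(fam, 10000, seed = 21)
  lib <- library_model(n_reads = 1000L, seed = 22)
  s1 <- simulate_chip_reads(g$genome, g$annotations, fam, lib, "wt")
  s2 <- simulate_chip_reads(g$genome, g$annotations, fam, lib, "wt")
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
})

test_that("bisulphite conversion follows the per-site rules exactly", {
  ref <- "ACGTCCGATCGAC"   # CpGs at 2, 6, 10; non-CpG Cs at 5, 13
  m1 <- methylation_model(ref, per_cpg_meth_prob = 1, conversion_rate = 1,
                          n_clones = 5L, seed = 1)
  s1 <- simulate_bisulfite_clones(m1)
  for (cl in s1$clones) {
    v <- strsplit(cl, "")[[1L]]
    expect_identical(v[c(2L, 6L, 10L)], c("C", "C", "C"))  # methylated kept
    expect_identical(v[c(5L, 13L)], c("T", "T"))           # non-CpG converted
  }
  m0 <- methylation_model(ref, per_cpg_meth_prob = 0, conversion_rate = 1,
                          n_clones = 5L, seed = 2)
  s0 <- simulate_bisulfite_clones(m0)
  for (cl in s0$clones)
    expect_false(grepl("C", cl, fixed = TRUE))             # every C reads T
})

test_that("incomplete conversion matches its binomial rate", {
  ref <- random_dna(2000, seed = 30)
  n_noncpg <- length(setdiff(which(strsplit(ref, "")[[1L]] == "C"),
                             cpg_positions(ref)))
  mod <- methylation_model(ref, per_cpg_meth_prob = 0.5,
                           conversion_rate = 0.95, n_clones = 20L, seed = 31)
  sim <- simulate_bisulfite_clones(mod)
  conv <- vapply(sim$clones, function(cl) {
    v <- strsplit(cl, "")[[1L]]
    nc <- setdiff(which(strsplit(ref, "")[[1L]] == "C"), cpg_positions(ref))
    sum(v[nc] == "T")
  }, numeric(1))
  ntot <- n_noncpg * 20
  se <- sqrt(ntot * 0.95 * 0.05)
  expect_lt(abs(sum(conv) - 0.95 * ntot), 3 * se)
  # truth matrix shape and determinism
  expect_identical(dim(sim$truth), c(20L, length(cpg_positions(ref))))
  expect_identical(simulate_bisulfite_clones(mod)$clones, sim$clones)
})

test_that("noise-free Ct tables encode folds as exact cycle differences", {
  ct <- simulate_ct_table(c(wt = 1, ko = 8), ct_noise_sd = 0, seed = 1)
  twt <- ct$ct[ct$sample == "wt" & ct$target == "target"]
  tko <- ct$ct[ct$sample == "ko" & ct$target == "target"]
  expect_equal(unique(twt) - unique(tko), 3)   # log2(8) cycles
  ct1 <- simulate_ct_table(c(a = 1, b = 1, c = 1), ct_noise_sd = 0, seed = 2)
  expect_length(unique(ct1$ct[ct1$target == "target"]), 1L)
})

test_that("planted fold is recovered from a noisy Ct table", {
  ct <- simulate_ct_table(c(wt = 1, mut = 4), replicates = 1000L,
                          ct_noise_sd = 0.1, seed = 3)
  res <- delta_delta_ct(ct, "target", "Actb", "wt")
  expect_lt(abs(res$fold[res$sample == "mut"] - 4) / 4, 0.02)
})
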