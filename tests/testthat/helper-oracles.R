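# Independent brute-force oracles used to verify the package implementation.
# These deliberately share no code with the package internals: plain loops
# and string operations only.

oracle_code <- function(s) {
  map <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  unname(map[strsplit(toupper(s), "")[[1L]]])
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(toupper(s), "")[[1L]]])), collapse = "")
}

# exhaustive Hamming scan over all positions and both strands; returns the
# minimum-distance placements per read, mirroring align_reads_minimal output
oracle_align <- function(reads, genome, max_mismatches) {
  if (is.null(names(reads))) names(reads) <- sprintf("r%d", seq_along(reads))
  gcodes <- lapply(genome, oracle_code)
  out <- list()
  for (ri in seq_along(reads)) {
    L <- nchar(reads[[ri]])
    hits <- list()
    for (ci in seq_along(genome)) {
      g <- gcodes[[ci]]
      np <- length(g) - L + 1L
      if (np < 1L) next
      for (str in c("+", "-")) {
        rseq <- if (str == "+") reads[[ri]] else oracle_revcomp(reads[[ri]])
        rc <- oracle_code(rseq)
        mm <- integer(np)
        for (j in 0:(L - 1L)) mm <- mm + (g[(1L + j):(np + j)] != rc[j + 1L])
        ok <- which(mm <= max_mismatches)
        if (length(ok) > 0L)
          hits[[length(hits) + 1L]] <- data.frame(
            chrom = names(genome)[ci], start = ok - 1L, strand = str,
            mm = mm[ok], stringsAsFactors = FALSE)
      }
    }
    if (length(hits) == 0L) next
    h <- do.call(rbind, hits)
    h <- h[h$mm == min(h$mm), , drop = FALSE]
    h$read_id <- names(reads)[ri]
    h$n_hits <- nrow(h)
    out[[length(out) + 1L]] <- h
  }
  if (length(out) == 0L)
    return(data.frame(read_id = character(0), chrom = character(0),
                      start = integer(0), strand = character(0),
                      mm = integer(0), n_hits = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$read_id, res$chrom, res$start, res$strand), ,
             drop = FALSE]
  rownames(res) <- NULL
  res[, c("read_id", "chrom", "start", "strand", "mm", "n_hits")]
}

# per-position count of footprints [s, e) overlapping each position 0..L-1
oracle_depth <- function(s, e, L) {
  vapply(0:(L - 1L), function(p) sum(s <= p & p < e), numeric(1))
}

# flank relative-position counts by explicit per-read per-position loops;
# footprints are 0-based half-open [s, e); returns counts indexed by
# relative position -flank..flank-1 (element-relative, minus-strand flipped)
oracle_flank_counts <- function(fp, elements, flank) {
  counts <- rep(0, 2L * flank)
  for (i in seq_len(nrow(elements))) {
    s0 <- elements$start[i]; e0 <- elements$end[i]
    flip <- elements$strand[i] == "-"
    for (j in seq_len(nrow(fp))) {
      if (fp$chrom[j] != elements$chrom[i]) next
      for (p in seq(fp$start[j], fp$end[j] - 1L)) {
        rel <- NA
        if (p >= s0 - flank && p < s0)
          rel <- if (!flip) p - s0 else s0 - 1L - p
        else if (p >= e0 && p < e0 + flank)
          rel <- if (!flip) p - e0 else -(p - e0) - 1L
        if (!is.na(rel)) counts[rel + flank + 1L] <- counts[rel + flank + 1L] + 1
      }
    }
  }
  counts
}

# all-vs-all k-mer uniqueness: position p mappable iff its k-mer occurs
# exactly once in the genome counting both strands (distinct placements)
oracle_mappability <- function(genome, k) {
  allk <- character(0); where <- list()
  for (ch in names(genome)) {
    s <- toupper(genome[[ch]])
    n <- nchar(s) - k + 1L
    km <- if (n >= 1L) substring(s, 1:n, 1:n + k - 1L) else character(0)
    where[[ch]] <- km
    allk <- c(allk, km)
  }
  allrc <- vapply(allk, oracle_revcomp, character(1), USE.NAMES = FALSE)
  lapply(where, function(km) {
    vapply(km, function(x) {
      hits <- sum(allk == x | allrc == x)
      as.integer(hits == 1L)
    }, integer(1), USE.NAMES = FALSE)
  })
}

# exhaustive double-loop in-silico PCR scan (both orientations)
oracle_pcr <- function(genome, fwd, rev, max_product, max_mismatches) {
  mmcount <- function(a, b) sum(oracle_code(a) != oracle_code(b))
  prods <- list()
  for (ch in names(genome)) {
    s <- toupper(genome[[ch]])
    n <- nchar(s)
    for (orient in 1:2) {
      left <- if (orient == 1L) fwd else rev
      right <- if (orient == 1L) rev else fwd
      rcr <- oracle_revcomp(right)
      ll <- nchar(left); rl <- nchar(rcr)
      for (i in 1:(n - ll + 1L)) {
        if (mmcount(substring(s, i, i + ll - 1L), left) > max_mismatches) next
        for (j in i:min(n - rl + 1L, i + max_product - rl)) {
          plen <- j + rl - 1L - i + 1L
          if (plen < max(ll, rl)) next
          if (mmcount(substring(s, j, j + rl - 1L), rcr) <= max_mismatches)
            prods[[length(prods) + 1L]] <- data.frame(
              chrom = ch, start = i - 1L, end = j + rl - 1L,
              stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(prods) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  out <- do.call(rbind, prods)
  out <- out[!duplicated(paste(out$chrom, out$start, out$end)), , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# pooled-variance two-sample t-test from first principles
oracle_ttest <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# all label reassignments of a 3-vs-3 comparison; returns the t statistic of
# every assignment (20 of them)
oracle_permutation_ts <- function(a, b) {
  x <- c(a, b)
  combn(6, 3, function(idx) oracle_ttest(x[idx], x[-idx])$t)
}

# mutate a sequence at `nmut` random positions (test fixture helper)
mutate_seq <- function(s, nmut) {
  v <- strsplit(s, "")[[1L]]
  pos <- sample(length(v), nmut)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  paste(v, collapse = "")
}
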