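# Agglomerated element-relative read-density profiles in the genomic flanks
# of intact repeat elements: intactness selection, quality/uniqueness
# filtering, positional deduplication, double normalization, and a k-mer
# mappability uniformity check.

#' Select intact elements
#'
#' Intactness is parameterised as a minimum interval length and a maximum
#' divergence from the family consensus.
#'
#' @param annotations annotation data.frame (chrom, start, end, strand,
#'   family, divergence, ...).
#' @param min_length minimum element length (bases).
#' @param max_divergence maximum divergence (substitutions per base).
#' @return the passing subset, with an `intact` column set TRUE and an
#'   `n_selected` attribute. Idempotent.
#' @export
select_intact_elements <- function(annotations, min_length = 0L,
                                   max_divergence = 1) {
  len <- annotations$end - annotations$start
  div <- annotations$divergence %||% rep(0, nrow(annotations))
  keep <- len >= min_length & div <= max_divergence
  out <- annotations[keep, , drop = FALSE]
  out$intact <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  attr(out, "n_selected") <- nrow(out)
  out
}

#' Quality and uniqueness filter for flank reads
#'
#' Keeps reads with map quality strictly above `min_quality` and exactly one
#' alignment location (n_hits == 1). Removal counts per reason are attached
#' as the `removed` attribute.
#'
#' @param reads read-placement data.frame.
#' @param min_quality strict lower quality bound (a read at exactly this
#'   quality is removed).
#' @return filtered data.frame.
#' @export
filter_flank_reads <- function(reads, min_quality = 7L) {
  validate_reads(reads)
  low_q <- reads$mapq <= min_quality
  multi <- reads$n_hits != 1L
  out <- reads[!low_q & !multi, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(low_quality = sum(low_q & !multi),
                            multi_mapping = sum(multi))
  out
}

#' Collapse duplicate read placements
#'
#' If multiple reads map to the same location — the same (chrom, start,
#' strand) — only one copy is counted. Output is sorted by position and the
#' operation is idempotent and input-order invariant.
#'
#' @param reads read-placement data.frame.
#' @return deduplicated data.frame with attribute `n_removed`.
#' @export
dedup_reads <- function(reads) {
  validate_reads(reads)
  ord <- order(reads$chrom, reads$start, reads$strand, reads$read_id)
  r <- reads[ord, , drop = FALSE]
  dup <- duplicated(paste(r$chrom, r$start, r$strand, sep = "\r"))
  out <- r[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(dup)
  out
}

#' Agglomerated flank density profile
#'
#' For each element, extended-read footprints overlapping the flank windows
#' [start - flank_size, start) and [end, end + flank_size) are mapped to
#' element-relative coordinates; minus-strand elements are orientation-
#' flipped so that negative relative positions are always the biological 5'
#' (upstream) flank. Per-position overlap counts are summed over elements
#' and normalized by the number of elements and by library size (per
#' million reads): density = counts / n_elements / (library_size / 1e6).
#'
#' Footprint positions falling inside the element body contribute nothing;
#' only in-flank overlap is counted.
#'
#' @param reads filtered, deduplicated read-placement data.frame.
#' @param elements annotation data.frame of (intact) elements.
#' @param flank_size flank window size on each side (bases).
#' @param extension directional extension (bases).
#' @param library_size total aligned reads in the genome for this library.
#' @param mode "coverage" counts every footprint-overlapped position;
#'   "starts" counts only the (unextended) read start position.
#' @param flip_minus orientation-flip minus-strand elements (default TRUE).
#' @return object of class `flank_profile`: rel_position (-flank_size ..
#'   flank_size - 1; negative = 5' flank, non-negative = distance into the
#'   3' flank), density, counts, n_elements, library_size, flank_size.
#' @export
agglomerate_flanks <- function(reads, elements, flank_size = 7000L,
                               extension = 150L, library_size,
                               mode = c("coverage", "starts"),
                               flip_minus = TRUE) {
  mode <- match.arg(mode)
  if (nrow(elements) == 0L) stopf("no elements to agglomerate over")
  if (missing(library_size) || library_size <= 0)
    stopf("library_size must be a positive read count")
  validate_reads(reads)
  counts <- rep(0, 2L * flank_size)  # index i <-> rel position i - flank - 1
  if (nrow(reads) > 0L) {
    fp <- if (mode == "coverage") extend_read(reads, extension) else
      data.frame(chrom = reads$chrom, start = reads$start,
                 end = reads$start + 1L, stringsAsFactors = FALSE)
    add_cov <- function(idx_start, idx_end) {
      ok <- idx_end >= idx_start
      if (!any(ok)) return(invisible())
      cov <- IRanges::coverage(IRanges::IRanges(start = idx_start[ok],
                                                end = idx_end[ok]),
                               width = 2L * flank_size)
      counts <<- counts + as.numeric(cov)
    }
    for (i in seq_len(nrow(elements))) {
      s0 <- elements$start[i]; e0 <- elements$end[i]
      onchr <- fp$chrom == elements$chrom[i]
      flipped <- flip_minus && elements$strand[i] == "-"
      # left genomic flank [s0 - flank, s0): footprint overlap clipped to it,
      # then mapped to array index (rel position + flank + 1)
      ls <- pmax(fp$start[onchr], s0 - flank_size)
      le <- pmin(fp$end[onchr], s0)            # exclusive
      hit <- le > ls
      ls <- ls[hit]; le <- le[hit]
      if (length(ls) > 0L) {
        if (!flipped) add_cov(ls - (s0 - flank_size) + 1L, le - (s0 - flank_size))
        else add_cov((s0 + flank_size) - (le - 1L), (s0 + flank_size) - ls)
      }
      # right genomic flank [e0, e0 + flank)
      rs <- pmax(fp$start[onchr], e0)
      re <- pmin(fp$end[onchr], e0 + flank_size)
      hit <- re > rs
      rs <- rs[hit]; re <- re[hit]
      if (length(rs) > 0L) {
        if (!flipped) add_cov(rs - e0 + flank_size + 1L, re - e0 + flank_size)
        else add_cov(flank_size - (re - 1L - e0), flank_size - (rs - e0))
      }
    }
  }
  n_el <- nrow(elements)
  structure(list(family = unique(elements$family)[1L],
                 flank_size = as.integer(flank_size),
                 rel_position = (-flank_size):(flank_size - 1L),
                 counts = counts,
                 density = counts / n_el / (library_size / 1e6),
                 n_elements = n_el, library_size = library_size,
                 extension = as.integer(extension), mode = mode),
            class = "flank_profile")
}

#' @export
print.flank_profile <- function(x, ...) {
  cat(sprintf("Flank profile: %s, +/-%d bp, %d elements, library %g\n",
              x$family, x$flank_size, x$n_elements, x$library_size))
  cat(sprintf("  density: mean %.4g, max %.4g (%s mode)\n",
              mean(x$density), max(x$density), x$mode))
  invisible(x)
}

#' @method plot flank_profile
#' @export
plot.flank_profile <- function(x, ..., xlab = "Position relative to element (bp)",
                               ylab = "Normalized read density", type = "l") {
  graphics::plot(x$rel_position, x$density, type = type, xlab = xlab,
                 ylab = ylab, main = sprintf("%s flanks", x$family), ...)
  graphics::abline(v = -0.5, lty = 2)
  invisible(x)
}

#' @method as.data.frame flank_profile
#' @export
as.data.frame.flank_profile <- function(x, ...) {
  data.frame(rel_position = x$rel_position,
             side = ifelse(x$rel_position < 0, "5p", "3p"),
             distance = ifelse(x$rel_position < 0, -x$rel_position - 1L,
                               x$rel_position),
             density = x$density, stringsAsFactors = FALSE)
}

#' Fit an exponential decay to a flank profile
#'
#' Bins the profile by distance from the element boundary (both flanks
#' pooled), then fits density ~ C + A * exp(-distance / lambda) by
#' nonlinear least squares. Recovers the decay scale of heterochromatin
#' spreading from simulated or real agglomerated profiles.
#'
#' @param profile `flank_profile` object.
#' @param bin_width distance bin width (bases).
#' @return list with lambda, A, C, the binned data (distance, density) and
#'   the `nls` fit.
#' @export
fit_flank_decay <- function(profile, bin_width = 250L) {
  df <- as.data.frame(profile)
  b <- floor(df$distance / bin_width)
  dat <- data.frame(distance = (sort(unique(b)) + 0.5) * bin_width,
                    density = as.numeric(rowsum(df$density, b)) /
                      as.numeric(rowsum(rep(1, nrow(df)), b)))
  C0 <- min(dat$density); A0 <- max(dat$density) - C0
  if (A0 <= 0) stopf("flank profile has no decaying component to fit")
  fit <- stats::nls(density ~ C + A * exp(-distance / lambda), data = dat,
                    start = list(C = C0, A = A0,
                                 lambda = profile$flank_size / 4),
                    algorithm = "port",
                    lower = c(C = 0, A = 0, lambda = 1),
                    control = stats::nls.control(maxiter = 200, warnOnly = TRUE))
  cf <- stats::coef(fit)
  list(lambda = unname(cf["lambda"]), A = unname(cf["A"]),
       C = unname(cf["C"]), data = dat, fit = fit)
}

#' k-mer mappability of genomic windows
#'
#' Mappability at position p is 1 if the read_length-mer starting at p
#' occurs exactly once in the genome over both strands, else 0. Returns the
#' mean mappability of each window — the uniformity check that rules out
#' mapping bias in flank profiles.
#'
#' @param genome named character vector of sequences.
#' @param read_length k-mer length (bases).
#' @param windows data.frame with columns chrom, start, end (0-based
#'   half-open).
#' @return numeric vector of per-window mean mappability in [0, 1].
#' @export
mappability_profile <- function(genome, read_length, windows) {
  k <- as.integer(read_length)
  kmers <- list(); rckmers <- list()
  for (ch in names(genome)) {
    s <- genome[[ch]]
    n <- nchar(s) - k + 1L
    if (n < 1L) { kmers[[ch]] <- character(0); rckmers[[ch]] <- character(0); next }
    p <- seq_len(n)
    kmers[[ch]] <- substring(s, p, p + k - 1L)
    rc <- revcomp(s)
    rckmers[[ch]] <- substring(rc, nchar(s) - (p + k - 1L) + 1L, nchar(s) - p + 1L)
  }
  allk <- unlist(kmers, use.names = FALSE)
  cnt <- table(allk)
  hits_of <- function(km) {
    h <- as.integer(cnt[km]); h[is.na(h)] <- 0L
    rck <- revcomp(km)
    h2 <- as.integer(cnt[rck]); h2[is.na(h2)] <- 0L
    ifelse(rck == km, h, h + h2)
  }
  vapply(seq_len(nrow(windows)), function(i) {
    ch <- windows$chrom[i]
    if (!ch %in% names(genome)) stopf("window chrom '%s' not in genome", ch)
    n <- length(kmers[[ch]])
    p0 <- windows$start[i] + 1L              # 1-based kmer start
    p1 <- min(windows$end[i], n)             # last start with a full k-mer
    if (p1 < p0) return(NA_real_)
    km <- kmers[[ch]][p0:p1]
    mean(hits_of(km) == 1L)
  }, numeric(1))
}
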