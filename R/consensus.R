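# ChIP-seq metaprofile along a repeat consensus: multi-mapper resolution,
# directional read extension, per-bin RPKM pileup, and wt/KO comparison.

#' Resolve multi-mapping reads by random selection
#'
#' For each read with several equally good placements, exactly one placement
#' is retained, chosen uniformly at random. Selections depend only on the
#' seed and the set of placements, not on input row order: groups are put in
#' canonical order (read id, then chrom/start/strand) before a single seeded
#' stream draws one selection per group.
#'
#' @param placements read-placement data.frame; rows sharing a read_id are
#'   one read's equally good placements.
#' @param seed integer RNG seed.
#' @return data.frame with exactly one row per read_id, ordered by read_id.
#' @export
assign_multimappers <- function(placements, seed = 1L) {
  validate_reads(placements)
  if (nrow(placements) == 0L) return(placements)
  ord <- order(placements$read_id, placements$chrom, placements$start,
               placements$strand)
  p <- placements[ord, , drop = FALSE]
  grp <- match(p$read_id, unique(p$read_id))
  sizes <- tabulate(grp)
  first <- cumsum(c(0L, sizes[-length(sizes)])) + 1L
  pick <- with_seed(seed, {
    u <- stats::runif(length(sizes))
    first + pmin(floor(u * sizes), sizes - 1L)
  })
  out <- p[pick, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Directionally extend reads
#'
#' Extends each read footprint by `extension` bases at its 3' end: a "+"
#' read becomes [start, start + read_length + extension), a "-" read
#' [start - extension, start + read_length), clipped at 0. Vectorised.
#'
#' @param reads read-placement data.frame.
#' @param extension extension length in bases (>= 0).
#' @return data.frame with columns chrom, start, end (0-based half-open),
#'   strand.
#' @export
extend_read <- function(reads, extension = 150L) {
  stopifnot(extension >= 0L)
  validate_reads(reads)
  plus <- reads$strand == "+"
  start <- ifelse(plus, reads$start, pmax(0L, reads$start - extension))
  end <- ifelse(plus, reads$start + reads$read_length + extension,
                reads$start + reads$read_length)
  data.frame(chrom = reads$chrom, start = as.integer(start),
             end = as.integer(end), strand = reads$strand,
             stringsAsFactors = FALSE)
}

#' Pileup profile along a consensus sequence
#'
#' Computes the per-bin normalized coverage of directionally extended reads
#' along a consensus. Footprints are clipped to [0, consensus_length). Raw
#' per-bin coverage is the mean per-base depth over the bin; the reported
#' value is RPKM under the bin-as-region convention:
#' mean depth x 1e9 / library_size.
#'
#' @param placements read-placement data.frame, already multi-mapper
#'   resolved (one row per read).
#' @param consensus_length length of the consensus (bases).
#' @param extension directional extension (bases).
#' @param bin_width bin width (bases); default 1 (per-position profile).
#' @param library_size normalization denominator: total reads uniquely
#'   mapped to the reference genome for this library.
#' @param consensus_name label stored in the profile.
#' @return object of class `consensus_profile`: fields consensus_name,
#'   length, bin_width, bin_start (0-based), values (RPKM per bin),
#'   n_reads_used, library_size, extension.
#' @export
profile_consensus <- function(placements, consensus_length, extension = 150L,
                              bin_width = 1L, library_size,
                              consensus_name = "consensus") {
  if (missing(library_size) || library_size <= 0)
    stopf("library_size must be a positive read count")
  stopifnot(consensus_length >= 1L, bin_width >= 1L)
  validate_reads(placements)
  depth <- rep(0, consensus_length)
  if (nrow(placements) > 0L) {
    fp <- extend_read(placements, extension)
    s <- pmax(fp$start, 0L)
    e <- pmin(fp$end, consensus_length)
    keep <- e > s
    if (any(keep)) {
      cov <- IRanges::coverage(IRanges::IRanges(start = s[keep] + 1L,
                                                end = e[keep]),
                               width = consensus_length)
      depth <- as.numeric(cov)
    }
  }
  nbins <- ceiling(consensus_length / bin_width)
  bin <- rep(seq_len(nbins), each = bin_width, length.out = consensus_length)
  mean_depth <- as.numeric(rowsum(depth, bin)) / bin_width
  structure(list(consensus_name = consensus_name,
                 length = as.integer(consensus_length),
                 bin_width = as.integer(bin_width),
                 bin_start = as.integer((seq_len(nbins) - 1L) * bin_width),
                 values = mean_depth * 1e9 / library_size,
                 raw_depth = depth,
                 n_reads_used = nrow(placements),
                 library_size = library_size,
                 extension = as.integer(extension)),
            class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf("Consensus metaprofile: %s (%d bp, bin %d bp)\n",
              x$consensus_name, x$length, x$bin_width))
  cat(sprintf("  reads used: %d; library size: %g\n",
              x$n_reads_used, x$library_size))
  cat(sprintf("  RPKM: mean %.3f, max %.3f\n", mean(x$values), max(x$values)))
  invisible(x)
}

#' @method plot consensus_profile
#' @export
plot.consensus_profile <- function(x, ...,
                                   xlab = "Position on consensus (bp)",
                                   ylab = "RPKM", type = "l") {
  graphics::plot(x$bin_start + x$bin_width / 2, x$values, type = type,
                 xlab = xlab, ylab = ylab,
                 main = sprintf("%s metaprofile", x$consensus_name), ...)
  invisible(x)
}

#' Shape correlation between a metaprofile and a reference body profile
#'
#' Pearson correlation between the per-position profile values and a
#' per-position reference enrichment shape, excluding `edge_exclusion`
#' positions at each end of the consensus. The exclusion (default one
#' extended-fragment footprint) removes the ramp zones where coverage is
#' structurally deficient because reads must lie fully within the element
#' to align to the consensus.
#'
#' @param profile `consensus_profile` with bin_width 1.
#' @param reference numeric per-position reference shape, length equal to
#'   the consensus.
#' @param edge_exclusion positions dropped at each end; default
#'   extension + 50 (one footprint for 50-bp reads).
#' @return Pearson correlation coefficient.
#' @export
profile_shape_correlation <- function(profile, reference,
                                      edge_exclusion = profile$extension + 50L) {
  stopifnot(inherits(profile, "consensus_profile"), profile$bin_width == 1L,
            length(reference) == profile$length)
  keep <- (edge_exclusion + 1L):(profile$length - edge_exclusion)
  if (length(keep) < 3L) stopf("edge exclusion leaves too few positions")
  stats::cor(profile$values[keep], reference[keep])
}

#' Compare two condition profiles (e.g. wild type vs KO)
#'
#' Elementwise ratio of two profiles over the same consensus with a small
#' pseudocount (1e-6 x the larger profile maximum) guarding empty bins, and
#' a mean-signal summary per condition.
#'
#' @param profile_a,profile_b `consensus_profile` objects over the same
#'   consensus with the same bin width (numerator / denominator, e.g.
#'   wt / KO).
#' @return object of class `profile_comparison`: bin_start, ratio,
#'   mean_a, mean_b, mean_ratio, pseudocount.
#' @export
compare_conditions <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "consensus_profile"),
            inherits(profile_b, "consensus_profile"))
  if (profile_a$length != profile_b$length ||
      profile_a$bin_width != profile_b$bin_width)
    stopf("profiles differ in consensus length or bin width")
  eps <- 1e-6 * max(c(profile_a$values, profile_b$values, 1e-12))
  ratio <- (profile_a$values + eps) / (profile_b$values + eps)
  ma <- mean(profile_a$values); mb <- mean(profile_b$values)
  structure(list(bin_start = profile_a$bin_start, ratio = ratio,
                 mean_a = ma, mean_b = mb,
                 mean_ratio = (ma + eps) / (mb + eps), pseudocount = eps),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf("Profile comparison: mean RPKM %.3f vs %.3f (ratio %.2f)\n",
              x$mean_a, x$mean_b, x$mean_ratio))
  cat(sprintf("  pseudocount %.3g; per-bin ratio range [%.2f, %.2f]\n",
              x$pseudocount, min(x$ratio), max(x$ratio)))
  invisible(x)
}
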