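# Bisulphite clone methylation calling, conversion-rate QC, four-category
# clone binning, and in-silico PCR primer-site enumeration.

#' Call per-CpG methylation of one bisulphite clone
#'
#' The clone is compared position-by-position against the unconverted
#' reference (end-gap-free, substitutions only; a length mismatch is an
#' alignment error). At each reference CpG, clone C is called methylated,
#' T unmethylated, anything else missing. The conversion rate is the
#' fraction of non-CpG reference C positions read as T among those with an
#' unambiguous C/T base — the per-clone QC statistic.
#'
#' Clones are assumed to represent the converted top strand (C->T space). A
#' clone whose reference-G positions read as A more often than its
#' reference-C positions read as T is flagged as a likely bottom-strand
#' (G->A) clone and rejected when `check_strand` is TRUE.
#'
#' @param clone_seq clone sequence (same length as the reference).
#' @param reference unconverted reference sequence.
#' @param clone_id identifier stored in the result.
#' @param check_strand reject apparent bottom-strand clones.
#' @return object of class `bisulfite_clone`: clone_id, calls (character
#'   vector in {"methylated","unmethylated",NA}, named by CpG position),
#'   conversion_rate, n_cpg, cpg_positions.
#' @export
call_clone <- function(clone_seq, reference, clone_id = "clone",
                       check_strand = TRUE) {
  reference <- toupper(reference)
  clone_seq <- toupper(clone_seq)
  if (nchar(clone_seq) != nchar(reference))
    stopf("alignment error: clone '%s' length %d != reference length %d (indels are not supported)",
          clone_id, nchar(clone_seq), nchar(reference))
  cpg <- cpg_positions(reference)
  if (length(cpg) == 0L) stopf("reference contains no CpG site")
  ref <- strsplit(reference, "")[[1L]]
  cl <- strsplit(clone_seq, "")[[1L]]
  noncpg_c <- setdiff(which(ref == "C"), cpg)
  conv <- sum(cl[noncpg_c] == "T")
  unconv <- sum(cl[noncpg_c] == "C")
  conversion_rate <- if (conv + unconv > 0L) conv / (conv + unconv) else NA_real_
  if (check_strand) {
    gpos <- which(ref == "G")
    ga <- sum(cl[gpos] == "A"); gg <- sum(cl[gpos] == "G")
    g_to_a <- if (ga + gg > 0L) ga / (ga + gg) else 0
    c_to_t <- if (is.na(conversion_rate)) 0 else conversion_rate
    if (g_to_a > 0.5 && g_to_a > c_to_t)
      stopf("clone '%s' looks like a bottom-strand (G->A) bisulphite product; only top-strand clones are supported",
            clone_id)
  }
  calls <- ifelse(cl[cpg] == "C", "methylated",
                  ifelse(cl[cpg] == "T", "unmethylated", NA_character_))
  names(calls) <- cpg
  structure(list(clone_id = clone_id, calls = calls,
                 conversion_rate = conversion_rate,
                 n_cpg = length(cpg), cpg_positions = cpg),
            class = "bisulfite_clone")
}

#' @export
print.bisulfite_clone <- function(x, ...) {
  nm <- sum(x$calls == "methylated", na.rm = TRUE)
  nu <- sum(x$calls == "unmethylated", na.rm = TRUE)
  cat(sprintf("Bisulphite clone %s: %d/%d CpGs methylated (%d missing), conversion %.1f%%\n",
              x$clone_id, nm, nm + nu, sum(is.na(x$calls)),
              100 * x$conversion_rate))
  invisible(x)
}

#' Methylated-CpG fraction of a clone
#'
#' Missing calls are excluded from numerator and denominator; NA when no
#' site was called.
#'
#' @param clone `bisulfite_clone` object.
#' @return numeric in [0, 1] or NA.
#' @export
clone_meth_fraction <- function(clone) {
  nm <- sum(clone$calls == "methylated", na.rm = TRUE)
  nu <- sum(clone$calls == "unmethylated", na.rm = TRUE)
  if (nm + nu == 0L) NA_real_ else nm / (nm + nu)
}

#' Conversion-rate QC filter
#'
#' Retains clones whose non-CpG conversion rate is strictly above
#' `min_conversion` (default 0.98, i.e. the "> 98%" criterion). Clones with
#' an undefined conversion rate are removed.
#'
#' @param clones list of `bisulfite_clone` objects.
#' @param min_conversion strict lower bound.
#' @return filtered list with attribute `removed_ids`.
#' @export
filter_clones <- function(clones, min_conversion = 0.98) {
  cr <- vapply(clones, function(x) x$conversion_rate %||% NA_real_, numeric(1))
  keep <- !is.na(cr) & cr > min_conversion
  out <- clones[keep]
  attr(out, "removed_ids") <-
    vapply(clones[!keep], `[[`, character(1), "clone_id")
  out
}

#' Bin clones into methylation categories
#'
#' Each clone is scored by its methylated-CpG fraction and binned into
#' equal-width categories of [0, 1] (default four: [0,0.25], (0.25,0.5],
#' (0.5,0.75], (0.75,1]); results are the percentage of clones per bin per
#' sample. Clones with no called site are excluded with a warning.
#'
#' @param samples named list; each entry a list of `bisulfite_clone`
#'   objects for one sample/cell line.
#' @param bin_edges increasing numeric vector of bin boundaries over [0,1].
#' @return object of class `methylation_binning`: `percentages` (matrix
#'   samples x bins), `bin_edges`, `n_clones` per sample.
#' @export
bin_clones <- function(samples, bin_edges = c(0, 0.25, 0.5, 0.75, 1)) {
  stopifnot(is.list(samples), !is.null(names(samples)),
            length(bin_edges) >= 2L, !is.unsorted(bin_edges),
            bin_edges[1L] == 0, bin_edges[length(bin_edges)] == 1)
  nb <- length(bin_edges) - 1L
  labs <- paste0(ifelse(seq_len(nb) == 1L, "[", "("),
                 bin_edges[-length(bin_edges)], ",", bin_edges[-1L], "]")
  pct <- matrix(NA_real_, nrow = length(samples), ncol = nb,
                dimnames = list(names(samples), labs))
  n_clones <- integer(length(samples))
  for (i in seq_along(samples)) {
    fr <- vapply(samples[[i]], clone_meth_fraction, numeric(1))
    if (anyNA(fr)) {
      warning(sprintf("sample '%s': %d clone(s) with no called CpG excluded",
                      names(samples)[i], sum(is.na(fr))))
      fr <- fr[!is.na(fr)]
    }
    if (length(fr) == 0L) stopf("sample '%s' has no scorable clone",
                                names(samples)[i])
    b <- cut(fr, breaks = bin_edges, include.lowest = TRUE, right = TRUE)
    pct[i, ] <- 100 * as.numeric(table(b)) / length(fr)
    n_clones[i] <- length(fr)
  }
  structure(list(percentages = pct, bin_edges = bin_edges,
                 n_clones = stats::setNames(n_clones, names(samples))),
            class = "methylation_binning")
}

#' @export
print.methylation_binning <- function(x, ...) {
  cat("Methylation binning (% of clones per category):\n")
  print(round(x$percentages, 1))
  invisible(x)
}

#' @method plot methylation_binning
#' @export
plot.methylation_binning <- function(x, ...) {
  graphics::barplot(t(x$percentages), beside = TRUE,
                    legend.text = colnames(x$percentages),
                    ylab = "% of clones", ...)
  invisible(x)
}

#' Methylation call matrix
#'
#' Lollipop-style matrix of calls: clones in rows, CpG positions in
#' columns; 1 methylated, 0 unmethylated, NA missing.
#'
#' @param clones list of `bisulfite_clone` objects sharing an amplicon.
#' @return integer matrix.
#' @export
meth_matrix <- function(clones) {
  stopifnot(length(clones) > 0L)
  pos <- clones[[1L]]$cpg_positions
  m <- t(vapply(clones, function(cl) {
    if (!identical(cl$cpg_positions, pos))
      stopf("clones come from different amplicons")
    ifelse(cl$calls == "methylated", 1L,
           ifelse(cl$calls == "unmethylated", 0L, NA_integer_))
  }, integer(length(pos))))
  rownames(m) <- vapply(clones, `[[`, character(1), "clone_id")
  colnames(m) <- paste0("CpG_", pos)
  m
}

#' In-silico PCR
#'
#' Enumerates genomic loci amplifiable by a primer pair: sites where the
#' forward primer matches one strand and the reverse complement of the
#' reverse primer matches the same strand downstream, within `max_product`
#' bases, each with at most `max_mismatches` mismatches. Both orientations
#' are scanned and product intervals are deduplicated.
#'
#' @param genome named character vector of sequences.
#' @param forward_primer,reverse_primer primer sequences (5'->3', >= 15 nt).
#' @param max_product maximum product length (bases).
#' @param max_mismatches per-primer mismatch allowance.
#' @return data.frame of product loci: chrom, start, end (0-based
#'   half-open), strand (strand matched by the forward primer).
#' @export
insilico_pcr <- function(genome, forward_primer, reverse_primer,
                         max_product = 1000L, max_mismatches = 0L) {
  stopifnot(nchar(forward_primer) >= 15L, nchar(reverse_primer) >= 15L,
            max_product > max(nchar(forward_primer), nchar(reverse_primer)))
  fwd <- toupper(forward_primer); rev <- toupper(reverse_primer)
  res <- list()
  scan <- function(ch, seq, left, right, strand) {
    # left primer on + strand, rc(right) downstream on + strand
    lh <- Biostrings::matchPattern(left, Biostrings::DNAString(seq),
                                   max.mismatch = max_mismatches)
    rh <- Biostrings::matchPattern(revcomp(right), Biostrings::DNAString(seq),
                                   max.mismatch = max_mismatches)
    ls <- BiocGenerics::start(lh); re <- BiocGenerics::end(rh)
    rs <- BiocGenerics::start(rh)
    if (length(ls) == 0L || length(re) == 0L) return(NULL)
    out <- list()
    for (a in seq_along(ls)) {
      ok <- which(rs >= ls[a] &
                  re - ls[a] + 1L <= max_product &
                  re - ls[a] + 1L >= max(nchar(left), nchar(right)))
      if (length(ok) > 0L)
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = ls[a] - 1L, end = re[ok], strand = strand,
          stringsAsFactors = FALSE)
    }
    if (length(out) > 0L) do.call(rbind, out) else NULL
  }
  for (ch in names(genome)) {
    seq <- genome[[ch]]
    res[[length(res) + 1L]] <- scan(ch, seq, fwd, rev, "+")
    res[[length(res) + 1L]] <- scan(ch, seq, rev, fwd, "-")
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[!duplicated(paste(out$chrom, out$start, out$end)), , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}
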