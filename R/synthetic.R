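# Synthetic-data generators: toy genomes with planted ERV copies, ChIP-seq
# read libraries with known enrichment structure (wild-type and attenuated
# "KO"), bisulphite clone sets, and qPCR Ct tables. Every generator is
# seeded, bit-reproducible, and returns its ground truth alongside the data.

#' ERV family model
#'
#' Describes one repeat family for the simulator: its consensus sequence, a
#' per-position relative enrichment profile along the element body (the
#' "high but nonuniform" mark level over the element), an exponential decay
#' scale for enrichment spreading into the genomic flanks, the number of
#' genomic copies, and per-copy sequence divergence.
#'
#' @param consensus consensus sequence (single character string).
#' @param ltr_length length of the long terminal repeats, in bases (metadata
#'   used by [default_body_profile()]).
#' @param body_profile numeric vector of non-negative per-position weights,
#'   same length as the consensus; defaults to a smooth LTR-elevated shape.
#' @param flank_decay_scale exponential decay scale lambda (bases) of flank
#'   enrichment.
#' @param copies number of genomic copies to plant.
#' @param per_copy_divergence per-base substitution probability of each copy
#'   relative to the consensus (0 <= d < 0.2).
#' @param name family label.
#' @return object of class `erv_family_model`.
#' @export
erv_family_model <- function(consensus, ltr_length = 300L,
                             body_profile = NULL,
                             flank_decay_scale = 2000,
                             copies = 3L, per_copy_divergence = 0.02,
                             name = "ERVsim") {
  L <- nchar(consensus)
  stopifnot(L > 0L, flank_decay_scale > 0,
            per_copy_divergence >= 0, per_copy_divergence < 0.2, copies >= 1L)
  if (is.null(body_profile)) body_profile <- default_body_profile(L, ltr_length)
  if (length(body_profile) != L)
    stopf("body_profile length (%d) must equal consensus length (%d)",
          length(body_profile), L)
  if (any(body_profile < 0) || all(body_profile == 0))
    stopf("body_profile weights must be >= 0 with at least one positive")
  structure(list(consensus = toupper(consensus), ltr_length = as.integer(ltr_length),
                 body_profile = as.numeric(body_profile),
                 flank_decay_scale = flank_decay_scale,
                 copies = as.integer(copies),
                 per_copy_divergence = per_copy_divergence, name = name),
            class = "erv_family_model")
}

#' Smooth default body-enrichment profile
#'
#' A slowly varying nonuniform shape: elevated Gaussian bumps centred on the
#' two LTRs plus a broad internal bump over a moderate baseline. Variation
#' is on a scale much larger than one extended-read footprint, so pileup
#' profiles can recover the shape.
#'
#' @param length consensus length (bases).
#' @param ltr_length LTR length (bases); bump width scales with it.
#' @return numeric vector of length `length`.
#' @export
default_body_profile <- function(length, ltr_length = 300L) {
  x <- seq_len(length)
  w <- max(ltr_length, length / 8)
  0.5 +
    1.5 * exp(-((x - ltr_length / 2)^2) / (2 * w^2)) +
    1.5 * exp(-((x - (length - ltr_length / 2))^2) / (2 * w^2)) +
    1.0 * exp(-((x - 0.45 * length)^2) / (2 * (length / 6)^2))
}

#' ChIP library model
#'
#' Parameters of one simulated ChIP-seq library: depth, read geometry,
#' uniform background weight, fold enrichment over element bodies/flanks,
#' and the attenuation multiplier applied to enrichment in the "KO"
#' condition (emulating loss of the writer enzyme).
#'
#' @param n_reads number of reads.
#' @param read_length read length (bases).
#' @param fragment_extension fragment length minus read length (bases); the
#'   directional-extension length used downstream.
#' @param background_rate relative weight per background base.
#' @param enrichment_fold body/flank enrichment multiplier (>= 1).
#' @param ko_attenuation multiplier in (0, 1] applied to enrichment in the
#'   KO condition.
#' @param seed RNG seed for read sampling.
#' @return object of class `library_model`.
#' @export
library_model <- function(n_reads = 2e5, read_length = 50L,
                          fragment_extension = 150L, background_rate = 1,
                          enrichment_fold = 10, ko_attenuation = 0.1,
                          seed = 1L) {
  stopifnot(n_reads > 0, enrichment_fold >= 1,
            ko_attenuation > 0, ko_attenuation <= 1)
  structure(list(n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 fragment_extension = as.integer(fragment_extension),
                 background_rate = background_rate,
                 enrichment_fold = enrichment_fold,
                 ko_attenuation = ko_attenuation, seed = as.integer(seed)),
            class = "library_model")
}

#' Build a toy genome with planted ERV copies
#'
#' Generates a random background genome and inserts `copies` mutated copies
#' of each family consensus at non-overlapping positions on random strands.
#' Copies are substitution-only (no indels), so each maps linearly onto its
#' consensus.
#'
#' @param families list of [erv_family_model()] objects (or a single one).
#' @param genome_length total genome length (bases); planted elements must
#'   total less than half of it.
#' @param seed RNG seed.
#' @param min_gap minimum distance (bases) between planted elements and from
#'   the genome ends; raise it when clean flank windows are needed.
#' @param chrom_name chromosome name.
#' @return list with `genome` (named character vector of one chromosome)
#'   and `annotations` (data.frame: chrom, start, end, strand, family, name,
#'   divergence, n_subs the realised substitution count).
#' @export
build_genome <- function(families, genome_length, seed = 1L, min_gap = 0L,
                         chrom_name = "chr1") {
  if (inherits(families, "erv_family_model")) families <- list(families)
  lens <- vapply(families, function(f) nchar(f$consensus) * f$copies, numeric(1))
  if (sum(lens) >= genome_length / 2)
    stopf("total planted element length (%d) must be < genome_length / 2",
          sum(lens))
  with_seed(seed, {
    bg <- paste(sample(c("A", "C", "G", "T"), genome_length, replace = TRUE),
                collapse = "")
    placed <- data.frame(start = integer(0), end = integer(0))
    ann <- list()
    for (f in families) {
      Lc <- nchar(f$consensus)
      for (ci in seq_len(f$copies)) {
        pos <- NA_integer_
        for (try in seq_len(1000L)) {
          cand <- sample.int(genome_length - Lc - 2L * min_gap + 1L, 1L) +
            min_gap - 1L  # 0-based start in [min_gap, G - Lc - min_gap]
          ok <- nrow(placed) == 0L ||
            all(cand >= placed$end + min_gap | cand + Lc <= placed$start - min_gap)
          if (ok) { pos <- cand; break }
        }
        if (is.na(pos))
          stopf("could not place copy %d of family %s without overlap", ci, f$name)
        strand <- sample(c("+", "-"), 1L)
        cps <- strsplit(f$consensus, "")[[1L]]
        mut <- which(stats::runif(Lc) < f$per_copy_divergence)
        for (m in mut)
          cps[m] <- sample(setdiff(c("A", "C", "G", "T"), cps[m]), 1L)
        copyseq <- paste(cps, collapse = "")
        if (strand == "-") copyseq <- revcomp(copyseq)
        substr(bg, pos + 1L, pos + Lc) <- copyseq
        placed <- rbind(placed, data.frame(start = pos, end = pos + Lc))
        ann[[length(ann) + 1L]] <- data.frame(
          chrom = chrom_name, start = pos, end = pos + Lc, strand = strand,
          family = f$name, name = sprintf("%s:%d", f$name, ci),
          divergence = f$per_copy_divergence, n_subs = length(mut),
          stringsAsFactors = FALSE)
      }
    }
    ann <- do.call(rbind, ann)
    ann <- ann[order(ann$start), , drop = FALSE]
    rownames(ann) <- NULL
    list(genome = stats::setNames(bg, chrom_name), annotations = ann)
  })
}

#' Per-base fragment-start weight field of the ChIP simulator
#'
#' The sampling weights that define the simulated libraries: background
#' everywhere; plus enrichment_fold x body_profile (mapped through each
#' copy's coordinates) inside elements; plus enrichment_fold x
#' exp(-d / lambda) at distance d from the nearest element boundary outside
#' them. In the "ko" condition the element and flank terms are multiplied
#' by `ko_attenuation`.
#'
#' @param genome named character vector (single chromosome).
#' @param annotations annotation data.frame from [build_genome()].
#' @param family the [erv_family_model()].
#' @param library the [library_model()].
#' @param condition "wt" or "ko".
#' @return numeric weight vector over genome positions (1-based index).
#' @export
chip_weight_field <- function(genome, annotations, family, library,
                              condition = c("wt", "ko")) {
  condition <- match.arg(condition)
  stopifnot(length(genome) == 1L)
  G <- nchar(genome[[1L]])
  eff <- library$enrichment_fold *
    (if (condition == "ko") library$ko_attenuation else 1)
  w <- rep(library$background_rate, G)
  ann <- annotations[annotations$family == family$name, , drop = FALSE]
  q <- 0:(G - 1L)
  inelem <- rep(FALSE, G)
  for (i in seq_len(nrow(ann))) {
    s0 <- ann$start[i]; e0 <- ann$end[i]
    idx <- (s0 + 1L):e0
    x <- if (ann$strand[i] == "+") (s0:(e0 - 1L)) - s0 else e0 - 1L - (s0:(e0 - 1L))
    w[idx] <- w[idx] + eff * family$body_profile[x + 1L]
    inelem[idx] <- TRUE
  }
  if (nrow(ann) > 0L) {
    d <- rep(Inf, G)
    for (i in seq_len(nrow(ann))) {
      s0 <- ann$start[i]; e0 <- ann$end[i]
      di <- ifelse(q < s0, s0 - q - 1L, ifelse(q >= e0, q - e0, 0L))
      d <- pmin(d, di)
    }
    fl <- !inelem
    w[fl] <- w[fl] + eff * exp(-d[fl] / family$flank_decay_scale)
  }
  w
}

#' Simulate a ChIP-seq read library
#'
#' Samples fragment 5'-end placements from the weight field of
#' [chip_weight_field()], assigns each fragment a uniform random strand, and
#' reads `read_length` bases from the fragment's 5' end (reverse-complemented
#' for "-" reads). Fragment length is read_length + fragment_extension, so
#' downstream directional extension reconstructs the fragment. The true
#' origin of every read is returned.
#'
#' @inheritParams chip_weight_field
#' @param seed RNG seed; defaults to the library model's seed.
#' @return list with `reads` (named character vector), `truth` (data.frame:
#'   read_id, chrom, frag_start, start, strand, origin — element name or
#'   "background"), `condition`, and the models used.
#' @export
simulate_chip_reads <- function(genome, annotations, family, library,
                                condition = c("wt", "ko"), seed = NULL) {
  condition <- match.arg(condition)
  stopifnot(length(genome) == 1L)
  seed <- seed %||% library$seed
  G <- nchar(genome[[1L]])
  L <- library$read_length
  FL <- L + library$fragment_extension
  if (FL > G) stopf("fragment length exceeds genome length")
  w <- chip_weight_field(genome, annotations, family, library, condition)
  nstart <- G - FL + 1L
  with_seed(seed, {
    fs <- sample.int(nstart, library$n_reads, replace = TRUE,
                     prob = w[seq_len(nstart)])  # 1-based fragment start
    strand <- sample(c("+", "-"), library$n_reads, replace = TRUE)
    read_start1 <- ifelse(strand == "+", fs, fs + FL - L)  # 1-based leftmost
    seqs <- substring(genome[[1L]], read_start1, read_start1 + L - 1L)
    neg <- strand == "-"
    if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
    ids <- sprintf("%s_%s_r%07d", family$name, condition,
                   seq_len(library$n_reads))
    names(seqs) <- ids
    origin <- rep("background", library$n_reads)
    ann <- annotations[annotations$family == family$name, , drop = FALSE]
    for (i in seq_len(nrow(ann))) {
      hit <- (fs - 1L) >= ann$start[i] & (fs - 1L) < ann$end[i]
      origin[hit] <- ann$name[i]
    }
    truth <- data.frame(read_id = ids, chrom = names(genome)[1L],
                        frag_start = fs - 1L, start = read_start1 - 1L,
                        strand = strand, origin = origin,
                        stringsAsFactors = FALSE)
    list(reads = seqs, truth = truth, condition = condition,
         family = family, library = library)
  })
}

#' Read-placement table from simulator ground truth
#'
#' Converts the `truth` component of [simulate_chip_reads()] into the
#' canonical read-placement table (all placements unique, fixed mapq), for
#' exercising genomic-coordinate stages without running an aligner.
#'
#' @param sim result of [simulate_chip_reads()].
#' @param mapq map quality to assign.
#' @return read-placement data.frame.
#' @export
truth_alignments <- function(sim, mapq = 37L) {
  aligned_reads(read_id = sim$truth$read_id, chrom = sim$truth$chrom,
                start = sim$truth$start, strand = sim$truth$strand,
                read_length = sim$library$read_length, mapq = mapq, n_hits = 1L)
}

#' Closed-form expected wild-type / KO body signal ratio
#'
#' The generator's own expectation for the ratio of mean element-body read
#' densities between the wt and ko libraries: the total body weight share of
#' each condition's weight field (restricted to valid fragment starts),
#' ratioed. Used to check profiler recovery.
#'
#' @inheritParams chip_weight_field
#' @return single numeric ratio.
#' @export
expected_body_ratio <- function(genome, annotations, family, library) {
  G <- nchar(genome[[1L]])
  nstart <- G - (library$read_length + library$fragment_extension) + 1L
  ann <- annotations[annotations$family == family$name, , drop = FALSE]
  body <- rep(FALSE, nstart)
  for (i in seq_len(nrow(ann))) {
    idx <- (ann$start[i] + 1L):min(ann$end[i], nstart)
    body[idx] <- TRUE
  }
  wwt <- chip_weight_field(genome, annotations, family, library, "wt")[seq_len(nstart)]
  wko <- chip_weight_field(genome, annotations, family, library, "ko")[seq_len(nstart)]
  (sum(wwt[body]) / sum(wwt)) / (sum(wko[body]) / sum(wko))
}

#' Bisulphite clone-set model
#'
#' @param reference unconverted reference sequence of the amplicon (must
#'   contain at least one CpG).
#' @param per_cpg_meth_prob probability that each CpG of each clone is
#'   methylated.
#' @param conversion_rate probability that an unmethylated C reads as T
#'   after bisulphite conversion (methylated CpG Cs never convert).
#' @param n_clones number of clones.
#' @param seed RNG seed.
#' @return object of class `methylation_model`.
#' @export
methylation_model <- function(reference, per_cpg_meth_prob = 0.8,
                              conversion_rate = 0.99, n_clones = 30L,
                              seed = 1L) {
  stopifnot(per_cpg_meth_prob >= 0, per_cpg_meth_prob <= 1,
            conversion_rate >= 0, conversion_rate <= 1, n_clones >= 1L)
  reference <- toupper(reference)
  if (length(cpg_positions(reference)) == 0L)
    stopf("reference contains no CpG site")
  structure(list(reference = reference,
                 per_cpg_meth_prob = per_cpg_meth_prob,
                 conversion_rate = conversion_rate,
                 n_clones = as.integer(n_clones), seed = as.integer(seed)),
            class = "methylation_model")
}

#' CpG positions of a sequence
#'
#' @param seq character string.
#' @return integer vector of 1-based positions of the C of each CpG.
#' @export
cpg_positions <- function(seq) {
  p <- gregexpr("CG", toupper(seq), fixed = TRUE)[[1L]]
  if (p[1L] == -1L) integer(0) else as.integer(p)
}

#' Simulate bisulphite-converted clone sequences
#'
#' Each clone methylates every CpG independently with `per_cpg_meth_prob`;
#' unmethylated Cs (CpG and non-CpG alike) convert to T with
#' `conversion_rate`; methylated CpG Cs never convert. Clones are returned
#' with the true methylation matrix.
#'
#' @param model [methylation_model()].
#' @return list with `clones` (named character vector), `truth` (logical
#'   matrix clones x CpG sites), `cpg_positions`, and the model.
#' @export
simulate_bisulfite_clones <- function(model) {
  ref <- strsplit(model$reference, "")[[1L]]
  cpg <- cpg_positions(model$reference)
  cpos <- which(ref == "C")
  noncpg_c <- setdiff(cpos, cpg)
  with_seed(model$seed, {
    truth <- matrix(stats::runif(model$n_clones * length(cpg)) <
                      model$per_cpg_meth_prob,
                    nrow = model$n_clones)
    clones <- character(model$n_clones)
    for (i in seq_len(model$n_clones)) {
      cl <- ref
      unmeth_cpg <- cpg[!truth[i, ]]
      conv_cand <- c(unmeth_cpg, noncpg_c)
      conv <- conv_cand[stats::runif(length(conv_cand)) < model$conversion_rate]
      cl[conv] <- "T"
      clones[i] <- paste(cl, collapse = "")
    }
    names(clones) <- sprintf("clone%03d", seq_len(model$n_clones))
    rownames(truth) <- names(clones)
    colnames(truth) <- paste0("CpG_", cpg)
    list(clones = clones, truth = truth, cpg_positions = cpg, model = model)
  })
}

#' Simulate a qPCR Ct table
#'
#' Target Ct for each sample is baseline - log2(fold) plus Gaussian noise
#' (100% amplification efficiency: one cycle per two-fold); the reference
#' gene is constant across samples plus noise. Replicate structure matches
#' technical-replicate qRT-PCR practice.
#'
#' @param true_folds named numeric vector: true expression of each sample
#'   relative to the control (the sample with fold 1, conventionally first).
#' @param replicates technical replicates per (sample, gene).
#' @param ct_noise_sd Gaussian noise SD in cycles.
#' @param seed RNG seed.
#' @param target,reference_gene assay labels.
#' @param baseline_ct target Ct of a fold-1 sample.
#' @param reference_ct reference-gene Ct.
#' @return data.frame with columns sample, target, replicate, ct.
#' @export
simulate_ct_table <- function(true_folds, replicates = 3L, ct_noise_sd = 0.1,
                              seed = 1L, target = "target",
                              reference_gene = "Actb", baseline_ct = 25,
                              reference_ct = 18) {
  stopifnot(all(true_folds > 0), replicates >= 2L, !is.null(names(true_folds)))
  with_seed(seed, {
    rows <- list()
    for (s in names(true_folds)) {
      tct <- baseline_ct - log2(true_folds[[s]]) +
        stats::rnorm(replicates, 0, ct_noise_sd)
      rct <- reference_ct + stats::rnorm(replicates, 0, ct_noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, target = c(rep(target, replicates),
                               rep(reference_gene, replicates)),
        replicate = rep(seq_len(replicates), 2L), ct = c(tct, rct),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
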