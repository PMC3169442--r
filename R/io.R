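# Readers/writers for the plain-text formats the pipeline touches (FASTA,
# SAM subset, BED-like annotations, TSV alignment tables) and the minimal
# deterministic read aligner for desk-scale synthetic genomes.
#
# Coordinate convention: all internal intervals and read starts are 0-based
# half-open. SAM ingestion (1-based POS) is the only conversion boundary.

#' Read a FASTA file
#'
#' Strict reader for the A/C/G/T/N alphabet: sequences are uppercased on
#' ingest and any malformed header or illegal character raises an error that
#' names the offending line.
#'
#' @param path path to a FASTA file.
#' @return named character vector, one uppercased sequence per record,
#'   in file order. An empty file yields an empty vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines)
  idx <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(stats::setNames(character(0), character(0)))
  hdr <- startsWith(lines, ">")
  if (!hdr[1L])
    stopf("FASTA format error at line %d: expected '>' header", idx[1L])
  bad <- which(!hdr & grepl("[^ACGTNacgtn]", lines))
  if (length(bad) > 0L)
    stopf("FASTA format error at line %d: illegal character in sequence",
          idx[bad[1L]])
  names_raw <- sub("^>\\s*", "", lines[hdr])
  names_raw <- sub("\\s.*$", "", names_raw)
  if (any(names_raw == ""))
    stopf("FASTA format error at line %d: empty header name",
          idx[hdr][which(names_raw == "")[1L]])
  rec <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  out <- stats::setNames(rep("", sum(hdr)), names_raw)
  out[as.integer(names(seqs))] <- seqs
  empty <- which(out == "")
  if (length(empty) > 0L)
    stopf("FASTA format error: record '%s' has no sequence",
          names_raw[empty[1L]])
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width in bases.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# canonical column layout of a read-placement table
.read_cols <- c("read_id", "chrom", "start", "strand", "read_length",
                "mapq", "n_hits")

#' Construct a read-placement table
#'
#' The package-wide representation of aligned reads: one row per placement,
#' 0-based leftmost start, strand in {+,-}, `n_hits` the number of equally
#' good alignment locations (a read is unique iff `n_hits == 1`).
#'
#' @param read_id,chrom,start,strand,read_length,mapq,n_hits column vectors,
#'   recycled to a common length.
#' @return data.frame with the canonical columns.
#' @export
aligned_reads <- function(read_id = character(0), chrom = character(0),
                          start = integer(0), strand = character(0),
                          read_length = 50L, mapq = 37L, n_hits = 1L) {
  n <- length(read_id)
  rcy <- function(x) if (length(x) == n) x else rep_len(x, n)
  df <- data.frame(read_id = as.character(read_id),
                   chrom = rcy(as.character(chrom)),
                   start = rcy(as.integer(start)),
                   strand = rcy(as.character(strand)),
                   read_length = rcy(as.integer(read_length)),
                   mapq = rcy(as.integer(mapq)),
                   n_hits = rcy(as.integer(n_hits)),
                   stringsAsFactors = FALSE)
  validate_reads(df)
  df
}

validate_reads <- function(df) {
  miss <- setdiff(.read_cols, names(df))
  if (length(miss) > 0L)
    stopf("read table missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$start < 0L)) stopf("read table: negative start position")
  if (!all(df$strand %in% c("+", "-"))) stopf("read table: strand must be + or -")
  if (any(df$n_hits < 1L)) stopf("read table: n_hits must be >= 1")
  if (any(df$mapq < 0L)) stopf("read table: map_quality must be >= 0")
  invisible(df)
}

#' Read alignments from SAM or TSV
#'
#' The SAM dialect uses only QNAME/FLAG/RNAME/POS/MAPQ/CIGAR of the 11
#' mandatory columns. POS (1-based) is converted to the internal 0-based
#' start; FLAG bit 16 sets strand "-"; unmapped records (FLAG bit 4 or RNAME
#' "*") are skipped and counted in the `n_unmapped` attribute. Only CIGARs
#' composed of M/=/X runs are accepted; I/D/N/S operations are rejected. The
#' number of equally good hits is taken from an `NH:i:` tag when present,
#' else 1.
#'
#' The TSV dialect is headerless with columns
#' chrom, start, strand, read_length, mapq, n_hits[, read_id]; missing read
#' ids are auto-numbered.
#'
#' @param path input file.
#' @param dialect "sam" or "tsv".
#' @return read-placement data.frame (see [aligned_reads()]) with attribute
#'   `n_unmapped` (SAM only).
#' @export
read_alignments <- function(path, dialect = c("sam", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (dialect == "tsv") return(.read_alignments_tsv(path))
  .read_alignments_sam(path)
}

.read_alignments_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(aligned_reads())
  parts <- strsplit(lines, "[\t ]+")
  nf <- lengths(parts)
  if (any(nf < 6L))
    stopf("TSV alignment format error at line %d: expected >= 6 columns",
          which(nf < 6L)[1L])
  m <- do.call(rbind, lapply(parts, function(p) p[1:6]))
  ids <- vapply(seq_along(parts), function(i)
    if (nf[i] >= 7L) parts[[i]][7L] else sprintf("r%d", i), character(1))
  start <- suppressWarnings(as.integer(m[, 2L]))
  if (anyNA(start) || any(start < 0L))
    stopf("TSV alignment format error: bad start position at line %d",
          which(is.na(start) | start < 0L)[1L])
  aligned_reads(read_id = ids, chrom = m[, 1L], start = start,
                strand = m[, 3L], read_length = as.integer(m[, 4L]),
                mapq = as.integer(m[, 5L]), n_hits = as.integer(m[, 6L]))
}

.read_alignments_sam <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ln <- seq_along(lines)
  keep <- !startsWith(lines, "@") & !grepl("^\\s*$", lines)
  lines <- lines[keep]; ln <- ln[keep]
  if (length(lines) == 0L) {
    out <- aligned_reads(); attr(out, "n_unmapped") <- 0L; return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L))
    stopf("SAM format error at line %d: fewer than 11 mandatory columns",
          ln[which(nf < 11L)[1L]])
  flag <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  if (anyNA(flag))
    stopf("SAM format error at line %d: non-numeric FLAG",
          ln[which(is.na(flag))[1L]])
  rname <- vapply(parts, `[[`, "", 3L)
  unmapped <- bitwAnd(flag, 4L) > 0L | rname == "*"
  secondary <- bitwAnd(flag, 256L) > 0L
  n_unmapped <- sum(unmapped)
  sel <- which(!unmapped & !secondary)
  if (length(sel) == 0L) {
    out <- aligned_reads(); attr(out, "n_unmapped") <- n_unmapped; return(out)
  }
  parts <- parts[sel]; ln <- ln[sel]; flag <- flag[sel]; rname <- rname[sel]
  pos <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 4L)))
  if (anyNA(pos) || any(pos < 1L))
    stopf("SAM format error at line %d: bad POS",
          ln[which(is.na(pos) | pos < 1L)[1L]])
  mapq <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 5L)))
  if (anyNA(mapq) || any(mapq < 0L))
    stopf("SAM format error at line %d: bad MAPQ",
          ln[which(is.na(mapq) | mapq < 0L)[1L]])
  cigar <- vapply(parts, `[[`, "", 6L)
  bad <- !grepl("^([0-9]+[M=X])+$", cigar)
  if (any(bad))
    stopf("SAM format error at line %d: unsupported CIGAR '%s' (only M/=/X runs accepted)",
          ln[which(bad)[1L]], cigar[which(bad)[1L]])
  rlen <- vapply(cigar, function(cg) {
    sum(as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1L]]))
  }, integer(1), USE.NAMES = FALSE)
  nh <- vapply(parts, function(p) {
    if (length(p) > 11L) {
      tag <- grep("^NH:i:", p[12:length(p)], value = TRUE)
      if (length(tag) > 0L) return(as.integer(sub("^NH:i:", "", tag[1L])))
    }
    1L
  }, integer(1))
  out <- aligned_reads(read_id = vapply(parts, `[[`, "", 1L), chrom = rname,
                       start = pos - 1L,
                       strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                       read_length = rlen, mapq = mapq, n_hits = nh)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Write a read-placement table as TSV
#'
#' Headerless columns chrom, start, strand, read_length, mapq, n_hits,
#' read_id; the exact inverse of the TSV dialect of [read_alignments()].
#'
#' @param reads read-placement data.frame.
#' @param path output path.
#' @export
write_alignments_tsv <- function(reads, path) {
  validate_reads(reads)
  utils::write.table(
    reads[, c("chrom", "start", "strand", "read_length", "mapq", "n_hits",
              "read_id")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read element annotations from BED6
#'
#' BED columns chrom, start, end, name, score, strand with the package's
#' conventions: name is "family:copy" (family recovered as the part before
#' the first colon) and score stores divergence in substitutions per
#' kilobase (divergence = score / 1000).
#'
#' @param path BED file.
#' @return annotation data.frame with columns chrom, start, end, strand,
#'   family, name, divergence.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      family = character(0), name = character(0),
                      divergence = numeric(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 6L))
    stopf("BED format error at line %d: expected 6 columns",
          which(lengths(parts) < 6L)[1L])
  m <- do.call(rbind, lapply(parts, `[`, 1:6))
  start <- as.integer(m[, 2L]); end <- as.integer(m[, 3L])
  if (any(is.na(start) | is.na(end) | start < 0L | end <= start))
    stopf("BED format error: invalid interval")
  data.frame(chrom = m[, 1L], start = start, end = end, strand = m[, 6L],
             family = sub(":.*$", "", m[, 4L]), name = m[, 4L],
             divergence = as.numeric(m[, 5L]) / 1000,
             stringsAsFactors = FALSE)
}

#' Write element annotations to BED6
#'
#' @param annotations annotation data.frame (see [read_annotations()]).
#' @param path output path.
#' @export
write_annotations <- function(annotations, path) {
  nm <- annotations$name %||% paste0(annotations$family, ":",
                                     seq_len(nrow(annotations)))
  df <- data.frame(annotations$chrom, annotations$start, annotations$end, nm,
                   round((annotations$divergence %||% 0) * 1000),
                   annotations$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Minimal deterministic read aligner
#'
#' Exhaustive ungapped (Hamming-distance) alignment of fixed-length reads
#' against a small genome, on both strands. For each read every placement
#' within `max_mismatches` is enumerated; only the placements at the minimum
#' observed distance are reported, with `n_hits` set to their count, so that
#' the choice among ties can be delegated to [assign_multimappers()]. Reads
#' with no acceptable placement are omitted and counted in the
#' `n_unaligned` attribute.
#'
#' Internally a pigeonhole seed-and-extend search (max_mismatches + 1
#' disjoint exact k-mer seeds, vectorised Hamming verification) is used; it
#' is exact for Hamming distance <= max_mismatches.
#'
#' @param reads named character vector of read sequences (names are read
#'   ids; unnamed reads are auto-numbered).
#' @param genome named character vector of reference sequences.
#' @param max_mismatches maximum Hamming distance (small, <= 3).
#' @return read-placement data.frame with one row per minimum-distance
#'   placement (a multi-mapping read has n_hits > 1 rows, all with the same
#'   n_hits), plus attributes `n_unaligned` and `unaligned_ids`. Unique
#'   placements get mapq 37, ties mapq 0.
#' @export
align_reads_minimal <- function(reads, genome, max_mismatches = 2L) {
  stopifnot(max_mismatches >= 0L, max_mismatches <= 3L)
  if (is.null(names(reads)) || any(!nzchar(names(reads))))
    names(reads) <- sprintf("r%d", seq_along(reads))
  if (anyDuplicated(names(reads))) stopf("duplicate read ids")
  if (length(reads) == 0L) {
    out <- aligned_reads(); attr(out, "n_unaligned") <- 0L; return(out)
  }
  if (min(nchar(reads)) > min(nchar(genome)))
    stopf("read length exceeds shortest reference sequence")

  hits <- vector("list", 2L * length(genome))
  h <- 0L
  for (grp in split(seq_along(reads), nchar(reads))) {
    rd <- reads[grp]
    L <- nchar(rd[[1L]])
    fw <- .encode_matrix(rd, L)
    rv <- .encode_matrix(revcomp(rd), L)
    for (ci in seq_along(genome)) {
      g <- encode_seq(genome[[ci]])
      if (length(g) < L) next
      for (str in c("+", "-")) {
        rm_ <- if (str == "+") fw else rv
        pl <- .seed_extend(rm_, g, L, max_mismatches)
        if (nrow(pl) > 0L) {
          pl$read <- grp[pl$read]
          pl$chrom <- names(genome)[ci]
          pl$strand <- str
          h <- h + 1L
          hits[[h]] <- pl
        }
      }
    }
  }
  hits <- if (h > 0L) do.call(rbind, hits[seq_len(h)]) else
    data.frame(read = integer(0), pos = integer(0), mm = integer(0),
               chrom = character(0), strand = character(0))
  if (nrow(hits) > 0L) {
    best <- tapply(hits$mm, hits$read, min)
    hits <- hits[hits$mm == best[as.character(hits$read)], , drop = FALSE]
    nh <- table(hits$read)
    hits$n_hits <- as.integer(nh[as.character(hits$read)])
    hits <- hits[order(hits$read, hits$chrom, hits$pos, hits$strand), ,
                 drop = FALSE]
  } else hits$n_hits <- integer(0)
  aligned_ids <- unique(hits$read)
  unaligned <- setdiff(seq_along(reads), aligned_ids)
  out <- aligned_reads(read_id = names(reads)[hits$read], chrom = hits$chrom,
                       start = hits$pos - 1L, strand = hits$strand,
                       read_length = nchar(reads)[hits$read],
                       mapq = ifelse(hits$n_hits == 1L, 37L, 0L),
                       n_hits = hits$n_hits)
  out$mismatches <- hits$mm
  attr(out, "n_unaligned") <- length(unaligned)
  attr(out, "unaligned_ids") <- names(reads)[unaligned]
  out
}

.encode_matrix <- function(seqs, L) {
  v <- .base_code[utf8ToInt(paste(seqs, collapse = ""))]
  v[v == -1L] <- -2L  # read N: distinct from genome N so N-N mismatches
  matrix(v, nrow = length(seqs), ncol = L, byrow = TRUE)
}

# kmer ids along encoded genome g; NA where the window holds a non-ACGT base
.kmer_ids <- function(g, k) {
  np <- length(g) - k + 1L
  if (np < 1L) return(integer(0))
  id <- integer(np); bad <- logical(np)
  for (i in 0:(k - 1L)) {
    c_ <- g[(1L + i):(np + i)]
    bad <- bad | c_ < 0L
    id <- id * 4L + pmax(c_, 0L)
  }
  id[bad] <- NA_integer_
  id
}

# all placements of the encoded reads (rows of rm_) in encoded genome g with
# Hamming distance <= maxmm; returns data.frame(read, pos, mm), pos 1-based
.seed_extend <- function(rm_, g, L, maxmm) {
  n <- nrow(rm_)
  nseed <- maxmm + 1L
  k <- min(13L, L %/% nseed)
  empty <- data.frame(read = integer(0), pos = integer(0), mm = integer(0))
  if (k < 4L) {  # tiny reads: direct scan
    np <- length(g) - L + 1L
    if (np < 1L) return(empty)
    res <- vector("list", n)
    for (i in seq_len(n)) {
      mm <- integer(np)
      for (j in 0:(L - 1L)) mm <- mm + (g[(1L + j):(np + j)] != rm_[i, j + 1L])
      ok <- which(mm <= maxmm)
      res[[i]] <- if (length(ok) > 0L)
        data.frame(read = i, pos = ok, mm = mm[ok]) else empty
    }
    return(do.call(rbind, res))
  }
  gid <- .kmer_ids(g, k)
  valid <- which(!is.na(gid))
  if (length(valid) == 0L) return(empty)
  tab <- split(valid, gid[valid])
  tabnames <- names(tab)
  np <- length(g) - L + 1L
  if (np < 1L) return(empty)

  cand_read <- integer(0); cand_pos <- integer(0)
  for (s in 0:(nseed - 1L)) {
    off <- s * k
    qid <- integer(n); qbad <- logical(n)
    for (i in 0:(k - 1L)) {
      c_ <- rm_[, off + i + 1L]
      qbad <- qbad | c_ < 0L
      qid <- qid * 4L + pmax(c_, 0L)
    }
    qid[qbad] <- NA_integer_
    mt <- match(as.character(qid), tabnames)
    hit <- which(!is.na(mt))
    if (length(hit) == 0L) next
    pl <- tab[mt[hit]]
    cnt <- lengths(pl)
    cand_read <- c(cand_read, rep(hit, cnt))
    cand_pos <- c(cand_pos, unlist(pl, use.names = FALSE) - off)
  }
  ok <- cand_pos >= 1L & cand_pos <= np
  cand_read <- cand_read[ok]; cand_pos <- cand_pos[ok]
  if (length(cand_read) == 0L) return(empty)
  key <- as.numeric(cand_read) * (length(g) + 2) + cand_pos
  dup <- duplicated(key)
  cand_read <- cand_read[!dup]; cand_pos <- cand_pos[!dup]

  # vectorised Hamming verification, chunked to bound memory
  chunk <- max(1L, 2000000L %/% L)
  keep_read <- integer(0); keep_pos <- integer(0); keep_mm <- integer(0)
  for (b in seq(1L, length(cand_read), by = chunk)) {
    e <- min(b + chunk - 1L, length(cand_read))
    cr <- cand_read[b:e]; cp <- cand_pos[b:e]
    gm <- matrix(g[outer(cp, 0:(L - 1L), `+`)], nrow = length(cp))
    mm <- rowSums(gm != rm_[cr, , drop = FALSE])
    ok <- mm <= maxmm
    keep_read <- c(keep_read, cr[ok])
    keep_pos <- c(keep_pos, cp[ok])
    keep_mm <- c(keep_mm, as.integer(mm[ok]))
  }
  data.frame(read = keep_read, pos = keep_pos, mm = keep_mm)
}
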