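# Shared low-level helpers: sequence handling, base encoding, seeded RNG scope.

# base -> integer code; genome N and read N get distinct negative codes so an
# N never matches anything, including another N
.base_code <- local({
  v <- rep(-9L, 256L)
  v[utf8ToInt("A")] <- 0L; v[utf8ToInt("a")] <- 0L
  v[utf8ToInt("C")] <- 1L; v[utf8ToInt("c")] <- 1L
  v[utf8ToInt("G")] <- 2L; v[utf8ToInt("g")] <- 2L
  v[utf8ToInt("T")] <- 3L; v[utf8ToInt("t")] <- 3L
  v[utf8ToInt("N")] <- -1L; v[utf8ToInt("n")] <- -1L
  v
})

encode_seq <- function(s) .base_code[utf8ToInt(s)]

#' Reverse complement of DNA sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence
#'
#' Uniform i.i.d. A/C/G/T sequence, used for synthetic backgrounds and
#' consensus stand-ins.
#'
#' @param length sequence length in bases.
#' @param seed integer RNG seed.
#' @return single character string.
#' @export
random_dna <- function(length, seed = NULL) {
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                        collapse = ""))
}

# evaluate expr under set.seed(seed) (when non-NULL), restoring the caller's
# RNG state afterwards so package functions never clobber the session RNG
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed) %% .Machine$integer.max)
  }
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
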