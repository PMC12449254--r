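# Internal coordinate convention: all base-pair coordinates are 0-based,
# half-open intervals, on the coding strand of the gene unless noted.
# User-facing residue numbers are 1-based. GenBank I/O converts to the
# 1-based closed convention of the flat-file format.

DNA_ALPHABET <- c("A", "C", "G", "T")

#' @importFrom Biostrings DNAString reverseComplement
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate a coding DNA string codon by codon
#'
#' Standard genetic code only. Length must be a multiple of 3.
#' @param seq DNA string (A/C/G/T), length a multiple of 3.
#' @return Character vector of 1-letter amino acids ('*' for stop).
#' @keywords internal
translate_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    stop("sequence length ", n, " is not a multiple of 3", call. = FALSE)
  }
  if (n == 0L) return(character(0))
  codons <- substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  unname(GENETIC_CODE_1[codons])
}

# standard code as a named vector; Biostrings::GENETIC_CODE uses the same
# table but we keep a local copy so codon lookups are plain subsetting
GENETIC_CODE_1 <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

split_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3L == 0L)
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
  if (grepl("[^ACGT]", seq)) {
    stop(what, " contains characters outside A/C/G/T", call. = FALSE)
  }
  invisible(seq)
}

#' Extract a subsequence from a circular sequence
#'
#' Coordinates are 0-based half-open and may be negative or exceed the
#' sequence length; they are reduced modulo the length (circular plasmid).
#' @keywords internal
circular_subseq <- function(seq, from, to) {
  n <- nchar(seq)
  len <- to - from
  stopifnot(len >= 0L)
  if (len == 0L) return("")
  if (len > n) stop("requested interval longer than the circular sequence", call. = FALSE)
  from <- ((from %% n) + n) %% n
  if (from + len <= n) {
    substr(seq, from + 1L, from + len)
  } else {
    paste0(substr(seq, from + 1L, n), substr(seq, 1L, from + len - n))
  }
}

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic integer stream derivation (all values < 2^31). Used to give
# every simulated gene/panel an independent, reproducible seed.
derive_seed <- function(base_seed, ...) {
  parts <- c(base_seed, ...)
  h <- 0
  for (p in parts) {
    h <- (h * 69069 + as.numeric(p) + 1) %% 2147483629
  }
  as.integer(h %% 2147483587 + 1)
}

gc_fraction <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(NA_real_)
  gc <- nchar(gsub("[AT]", "", seq))
  gc / n
}
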