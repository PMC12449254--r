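# Codon usage tables: relative synonymous codon frequencies computed from a
# CDS collection (e.g. all annotated CDSs of the expression organism), used
# to pick preferred codons for introduced residues and silent alternatives
# for marker codons.

#' Compute a codon usage table from coding sequences
#'
#' Tallies codons over all records and normalizes counts within each
#' amino-acid family, giving relative synonymous codon frequencies. Records
#' whose length is not a multiple of 3 are skipped with a warning; codons
#' containing non-ACGT characters are skipped silently. Stop codons are
#' tallied under \code{'*'} but never used for design.
#'
#' @param cds_records Character vector of CDS DNA strings, or a
#'   \code{DNAStringSet}.
#' @param organism_label Free-text label for the source organism.
#' @return A \code{codon_usage} object: \code{organism} and \code{freq}, a
#'   named list mapping each observed amino acid to a named numeric vector
#'   of relative codon frequencies summing to 1.
#' @examples
#' tab <- compute_codon_usage("ATGGCAGCAGCGGAATAA", "toy")
#' tab$freq[["A"]]
#' @export
compute_codon_usage <- function(cds_records, organism_label = "unknown") {
  if (methods::is(cds_records, "DNAStringSet")) {
    cds_records <- as.character(cds_records)
  }
  cds_records <- toupper(cds_records)
  counts <- integer(0)
  n_bad <- 0L
  all_codons <- character(0)
  for (rec in cds_records) {
    if (nchar(rec) %% 3L != 0L) {
      n_bad <- n_bad + 1L
      next
    }
    all_codons <- c(all_codons, split_codons(rec))
  }
  if (n_bad > 0L) {
    warning(n_bad, " CDS record(s) skipped (length not a multiple of 3)",
            call. = FALSE)
  }
  all_codons <- all_codons[!grepl("[^ACGT]", all_codons)]
  if (length(all_codons) == 0L) {
    stop("no usable codons in the provided CDS records", call. = FALSE)
  }
  tab <- table(all_codons)
  codons <- names(tab)
  aas <- unname(GENETIC_CODE_1[codons])
  freq <- list()
  for (aa in sort(unique(aas))) {
    sel <- aas == aa
    v <- as.numeric(tab[sel])
    names(v) <- codons[sel]
    v <- v / sum(v)
    freq[[aa]] <- v[order(names(v))]
  }
  structure(list(organism = organism_label, freq = freq),
            class = "codon_usage")
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf("codon_usage for '%s': %d amino acid(s) observed\n",
              x$organism, length(x$freq)))
  invisible(x)
}

#' Most frequent codon for an amino acid
#'
#' Ties are broken alphabetically so outputs are deterministic.
#'
#' @param table A \code{codon_usage} object.
#' @param aa 1-letter amino acid.
#' @return A codon (3-mer string).
#' @export
most_frequent_codon <- function(table, aa) {
  stopifnot(inherits(table, "codon_usage"))
  v <- table$freq[[aa]]
  if (is.null(v)) {
    stop("amino acid '", aa, "' not observed in codon usage table for '",
         table$organism, "'", call. = FALSE)
  }
  # freq vectors are stored in alphabetical codon order; which.max takes the
  # first maximum, i.e. the alphabetical tie-break
  names(v)[which.max(v)]
}

#' Highest-frequency silent alternative for a codon
#'
#' Returns a synonymous codon different from the input: the
#' highest-frequency alternative observed in the table, falling back to the
#' alphabetically first standard-code synonym when the table lists none.
#' Returns \code{NA} for single-codon amino acids (Met, Trp), which have no
#' silent alternative.
#'
#' @param table A \code{codon_usage} object.
#' @param codon A 3-mer codon.
#' @return A codon string, or \code{NA_character_} when no silent
#'   alternative exists.
#' @export
silent_alternative <- function(table, codon) {
  stopifnot(inherits(table, "codon_usage"))
  codon <- toupper(codon)
  aa <- GENETIC_CODE_1[[codon]]
  if (is.null(aa)) stop("not a codon: '", codon, "'", call. = FALSE)
  if (aa == "*") return(NA_character_)  # stop codons are never designed on
  synonyms <- sort(names(GENETIC_CODE_1)[GENETIC_CODE_1 == aa])
  alternatives <- setdiff(synonyms, codon)
  if (length(alternatives) == 0L) return(NA_character_)
  v <- table$freq[[aa]]
  observed <- v[names(v) %in% alternatives]
  if (length(observed) > 0L) {
    names(observed)[which.max(observed)]
  } else {
    alternatives[1]
  }
}

#' Read or write a codon usage table as TSV
#'
#' Plain three-column TSV (\code{aa}, \code{codon}, \code{frequency}) for
#' offline reuse of precomputed tables.
#'
#' @param path File path.
#' @param table A \code{codon_usage} object (for writing).
#' @param organism_label Label attached on reading.
#' @return \code{read_codon_usage}: a \code{codon_usage} object.
#' @export
read_codon_usage <- function(path, organism_label = NULL) {
  if (!file.exists(path)) stop("codon usage table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("aa", "codon", "frequency")
  if (!all(need %in% names(df))) {
    stop("codon usage TSV must have columns aa, codon, frequency", call. = FALSE)
  }
  freq <- list()
  for (aa in sort(unique(df$aa))) {
    sub <- df[df$aa == aa, ]
    bad <- toupper(sub$codon)[unname(GENETIC_CODE_1[toupper(sub$codon)]) != aa]
    if (length(bad) > 0L) {
      stop("codon(s) ", paste(bad, collapse = ","),
           " do not translate to '", aa, "'", call. = FALSE)
    }
    v <- sub$frequency
    names(v) <- toupper(sub$codon)
    if (abs(sum(v) - 1) > 1e-6) {
      stop("frequencies for '", aa, "' sum to ", sum(v), ", expected 1",
           call. = FALSE)
    }
    freq[[aa]] <- v[order(names(v))]
  }
  if (length(freq) == 0L) stop("empty codon usage table", call. = FALSE)
  structure(list(organism = organism_label %||% basename(path), freq = freq),
            class = "codon_usage")
}

#' @rdname read_codon_usage
#' @export
write_codon_usage <- function(table, path) {
  stopifnot(inherits(table, "codon_usage"))
  rows <- do.call(rbind, lapply(names(table$freq), function(aa) {
    v <- table$freq[[aa]]
    data.frame(aa = aa, codon = names(v), frequency = unname(v),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Encode a peptide with the most frequent codon for each residue.
encode_peptide <- function(table, peptide) {
  aas <- strsplit(peptide, "")[[1]]
  paste(vapply(aas, function(a) most_frequent_codon(table, a), character(1)),
        collapse = "")
}
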