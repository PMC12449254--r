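# Input parsing and validation: gene FASTA, mutation list, gene location on
# the plasmid; plus the order-sheet and per-mutant GenBank writers.

#' Read the gene of interest from a FASTA file
#'
#' @param path Path to a FASTA file containing exactly one record: the coding
#'   sequence (CDS) of the gene of interest, length a multiple of 3.
#' @return A list with \code{gene_id} and \code{cds}.
#' @importFrom Biostrings readDNAStringSet
#' @export
read_gene_fasta <- function(path) {
  if (!file.exists(path)) stop("gene FASTA not found: ", path, call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) {
    stop("gene FASTA must contain exactly one record, found ", length(set),
         call. = FALSE)
  }
  cds <- toupper(as.character(set[[1]]))
  check_dna(cds, "gene CDS")
  if (nchar(cds) %% 3L != 0L) {
    stop("gene CDS length (", nchar(cds), ") is not a multiple of 3", call. = FALSE)
  }
  list(gene_id = strsplit(names(set)[1], "\\s+")[[1]][1], cds = cds)
}

## ---- mutation specs ---------------------------------------------------

AA_LETTERS <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
                "S","T","V","W","Y")

#' Parse one mutation label
#'
#' Grammar: \code{XnY} for a point mutation (wild-type amino acid X at
#' residue n replaced by Y); point specs joined by \code{+} for a combined
#' mutation whose members must co-occur in one fragment; \code{del<i>-<j>}
#' for deletion of residues i..j inclusive; \code{ins<i>-<PEPTIDE>} for
#' insertion of a peptide after residue i.
#'
#' @param label A single mutation label.
#' @return A \code{mutation_spec} object.
#' @export
parse_mutation <- function(label) {
  label <- trimws(label)
  point_re <- sprintf("^([%s])([0-9]+)([%s])$",
                      paste(AA_LETTERS, collapse = ""),
                      paste(AA_LETTERS, collapse = ""))
  parse_point <- function(tok) {
    m <- regmatches(tok, regexec(point_re, tok))[[1]]
    if (length(m) == 0L) return(NULL)
    list(wt = m[2], res = as.integer(m[3]), mut = m[4], label = tok)
  }
  if (grepl("^del[0-9]+-[0-9]+$", label)) {
    ij <- as.integer(strsplit(sub("^del", "", label), "-")[[1]])
    if (ij[1] > ij[2]) stop("deletion '", label, "': first > last", call. = FALSE)
    spec <- list(kind = "deletion", label = label, first = ij[1], last = ij[2])
  } else if (grepl("^ins[0-9]+-[A-Z]+$", label)) {
    m <- regmatches(label, regexec("^ins([0-9]+)-([A-Z]+)$", label))[[1]]
    pep <- m[3]
    bad <- setdiff(strsplit(pep, "")[[1]], AA_LETTERS)
    if (length(bad) > 0L) {
      stop("insertion '", label, "': invalid amino acid(s) ",
           paste(bad, collapse = ","), call. = FALSE)
    }
    spec <- list(kind = "insertion", label = label,
                 anchor = as.integer(m[2]), peptide = pep)
  } else if (grepl("\\+", label)) {
    toks <- strsplit(label, "\\+")[[1]]
    members <- lapply(toks, parse_point)
    if (any(vapply(members, is.null, logical(1))) || length(members) < 2L) {
      stop("malformed combined mutation '", label, "'", call. = FALSE)
    }
    spec <- list(kind = "combined", label = label, members = members)
  } else {
    p <- parse_point(label)
    if (is.null(p)) stop("malformed mutation '", label, "'", call. = FALSE)
    spec <- c(list(kind = "point", label = label), p[c("wt", "res", "mut")])
  }
  structure(spec, class = "mutation_spec")
}

#' Parse a mutation list file
#'
#' One mutation per non-empty line; lines starting with \code{#} are
#' comments. See \code{\link{parse_mutation}} for the grammar. Duplicate
#' labels are an error.
#'
#' @param path Path to a plain-text mutation file.
#' @return A list of \code{mutation_spec} objects.
#' @export
parse_mutation_file <- function(path) {
  if (!file.exists(path)) stop("mutation file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(keep) == 0L) stop("no mutations in ", path, call. = FALSE)
  specs <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    specs[[i]] <- tryCatch(parse_mutation(lines[keep[i]]),
      error = function(e) {
        stop("line ", keep[i], " of ", path, ": ", conditionMessage(e),
             call. = FALSE)
      })
  }
  labels <- vapply(specs, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("duplicate mutation label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  specs
}

# signed length change of the mutant CDS in bp
net_indel_bp <- function(spec) {
  switch(spec$kind,
         insertion = 3L * nchar(spec$peptide),
         deletion  = -3L * (spec$last - spec$first + 1L),
         0L)
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat(sprintf("mutation_spec [%s] %s\n", x$kind, x$label))
  invisible(x)
}

## ---- locating the gene ------------------------------------------------

#' Locate the gene of interest on the plasmid
#'
#' Searches both strands of the circular plasmid for a unique occurrence of
#' the CDS (allowing the match to wrap the origin).
#'
#' @param p A \code{\link{plasmid}}.
#' @param gene A list with \code{gene_id} and \code{cds} as returned by
#'   \code{\link{read_gene_fasta}}, or a plain CDS string.
#' @return A \code{gene_context} object: \code{gene_id}, \code{cds},
#'   \code{plasmid_offset} (0-based start of the occurrence on the plasmid
#'   forward strand), \code{strand}, \code{n_codons}.
#' @export
locate_gene <- function(p, gene) {
  stopifnot(inherits(p, "plasmid"))
  if (is.character(gene)) gene <- list(gene_id = "gene", cds = toupper(gene))
  cds <- gene$cds
  check_dna(cds, "gene CDS")
  if (nchar(cds) %% 3L != 0L) {
    stop("gene CDS length is not a multiple of 3", call. = FALSE)
  }
  n <- nchar(p$sequence)
  if (nchar(cds) > n) stop("gene longer than plasmid", call. = FALSE)
  # search in the doubled sequence to catch origin-spanning matches; keep
  # only starts in [0, n)
  doubled <- paste0(p$sequence, substr(p$sequence, 1L, nchar(cds) - 1L))
  find_starts <- function(pattern) {
    hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(doubled))
    starts <- BiocGenerics::start(hits) - 1L
    starts[starts < n]
  }
  fwd <- find_starts(cds)
  rev <- find_starts(revcomp(cds))
  total <- length(fwd) + length(rev)
  if (total == 0L) {
    stop("gene not found on either strand of plasmid '", p$name, "'",
         call. = FALSE)
  }
  if (total > 1L) {
    stop("gene occurs ", total, " times on plasmid '", p$name,
         "'; cannot determine a unique location", call. = FALSE)
  }
  structure(list(gene_id = gene$gene_id, cds = cds,
                 plasmid_offset = if (length(fwd)) fwd[1] else rev[1],
                 strand = if (length(fwd)) "+" else "-",
                 n_codons = nchar(cds) %/% 3L),
            class = "gene_context")
}

#' @export
print.gene_context <- function(x, ...) {
  cat(sprintf("gene_context '%s': %d codons, offset %d, strand %s\n",
              x$gene_id, x$n_codons, x$plasmid_offset, x$strand))
  invisible(x)
}

# Map a coding-frame interval (0-based half-open bp on the coding strand;
# may extend beyond the CDS into the plasmid backbone) to the plasmid
# forward-strand interval [from, to) (unreduced; callers apply mod n).
frame_to_plasmid <- function(gene, from, to) {
  lc <- nchar(gene$cds)
  if (gene$strand == "+") {
    c(gene$plasmid_offset + from, gene$plasmid_offset + to)
  } else {
    c(gene$plasmid_offset + lc - to, gene$plasmid_offset + lc - from)
  }
}

# Extract the coding-strand sequence of a coding-frame interval.
frame_subseq <- function(p, gene, from, to) {
  iv <- frame_to_plasmid(gene, from, to)
  s <- circular_subseq(p$sequence, iv[1], iv[2])
  if (gene$strand == "-") revcomp(s) else s
}

## ---- validation -------------------------------------------------------

#' Validate mutation specs against the gene
#'
#' Checks residue bounds and, for point/combined specs, that the stated
#' wild-type amino acid matches the translation of the corresponding codon.
#'
#' @param muts List of \code{mutation_spec}.
#' @param gene A \code{gene_context}.
#' @return The validated list, unchanged.
#' @export
validate_mutations <- function(muts, gene) {
  prot <- translate_codons(gene$cds)
  nres <- gene$n_codons
  check_point <- function(pt, label) {
    if (pt$res < 1L || pt$res > nres) {
      stop("mutation '", label, "': residue ", pt$res,
           " outside gene (1-", nres, ")", call. = FALSE)
    }
    found <- prot[pt$res]
    if (found != pt$wt) {
      stop("mutation '", label, "': expected ", pt$wt, " at residue ",
           pt$res, " but the gene encodes ", found, call. = FALSE)
    }
  }
  for (m in muts) {
    switch(m$kind,
      point = check_point(m, m$label),
      combined = for (pt in m$members) check_point(pt, m$label),
      deletion = {
        if (m$first < 1L || m$last > nres) {
          stop("deletion '", m$label, "': residues outside gene (1-", nres,
               ")", call. = FALSE)
        }
      },
      insertion = {
        if (m$anchor < 1L || m$anchor > nres) {
          stop("insertion '", m$label, "': anchor outside gene (1-", nres,
               ")", call. = FALSE)
        }
      })
  }
  muts
}

## ---- outputs ----------------------------------------------------------

#' Write the order sheet
#'
#' One CSV row per fragment (96-well plate layout, filled row-major A1..H12,
#' continuing on further plates) and one row per primer.
#'
#' @param fragments List of \code{fragment} objects.
#' @param primers List of \code{primer} objects (may be empty).
#' @param settings A \code{\link{design_settings}} object.
#' @param out_path Output CSV path.
#' @return Invisibly, the data frame written.
#' @export
write_order_sheet <- function(fragments, primers, settings, out_path) {
  well_of <- function(i) {
    j <- (i - 1L) %% 96L
    sprintf("%s%d", LETTERS[j %/% 12L + 1L], j %% 12L + 1L)
  }
  plate_of <- function(i) (i - 1L) %/% 96L + 1L
  rows <- list()
  for (i in seq_along(fragments)) {
    f <- fragments[[i]]
    rows[[length(rows) + 1L]] <- data.frame(
      type = "dsDNA_fragment", name = f$name,
      plate = plate_of(i), well = well_of(i),
      sequence = f$full_seq, length_bp = nchar(f$full_seq),
      cost = nchar(f$full_seq) * settings$cost_per_bp,
      stringsAsFactors = FALSE)
  }
  for (pr in primers) {
    rows[[length(rows) + 1L]] <- data.frame(
      type = "primer", name = pr$name, plate = NA_integer_, well = "",
      sequence = pr$sequence, length_bp = nchar(pr$sequence), cost = NA_real_,
      stringsAsFactors = FALSE)
  }
  sheet <- do.call(rbind, rows)
  utils::write.csv(sheet, out_path, row.names = FALSE)
  invisible(sheet)
}

# Build the full mutant plasmid: wild-type plasmid with the fragment's
# region replaced by the mutant region sequence. Returns a plasmid object
# annotated with the mutation, marker, region and primer features.
build_mutant_plasmid <- function(p, gene, fragment, primers = list()) {
  reg <- fragment$region
  iv <- frame_to_plasmid(gene, reg$start, reg$end)
  n <- nchar(p$sequence)
  ps <- ((iv[1] %% n) + n) %% n
  pe <- ps + (iv[2] - iv[1])
  insert <- fragment$mutant_region_seq
  if (gene$strand == "-") insert <- revcomp(insert)
  if (pe <= n) {
    new_seq <- paste0(substr(p$sequence, 1L, ps),
                      insert,
                      substr(p$sequence, pe + 1L, n))
    shift_at <- pe  # positions >= pe move by net
  } else {
    # region wraps the origin: rotate so it is contiguous, keep the rotated
    # frame (documented origin shift)
    rot <- ps
    seq_rot <- circular_subseq(p$sequence, rot, rot + n)
    len_reg <- iv[2] - iv[1]
    new_seq <- paste0(insert, substr(seq_rot, len_reg + 1L, n))
    ps <- 0L
    shift_at <- len_reg
  }
  net <- nchar(fragment$mutant_region_seq) - (reg$end - reg$start)

  feats <- empty_features()
  # fragment region on the mutant plasmid
  feats <- rbind(feats, data.frame(
    type = "misc_feature", label = paste0("fragment_region_", reg$cluster_index),
    start = ps, end = ps + nchar(insert),
    strand = if (gene$strand == "-") "-" else "+", stringsAsFactors = FALSE))
  # per-codon features (mutated codons and silent markers), mapped through
  # the mutant region codon table
  codmap <- fragment$codon_map
  if (!is.null(codmap) && nrow(codmap) > 0L) {
    pre_len <- fragment$pre_len
    for (i in seq_len(nrow(codmap))) {
      if (!codmap$mutated[i] && !codmap$marker[i]) next
      # frame offset of codon i within the mutant region
      off <- pre_len + 3L * (i - 1L)
      if (gene$strand == "+") {
        fs <- ps + off
      } else {
        fs <- ps + nchar(insert) - off - 3L
      }
      feats <- rbind(feats, data.frame(
        type = "misc_feature",
        label = if (codmap$marker[i]) {
          sprintf("silent_marker_%s>%s", codmap$wt_codon[i], codmap$codon[i])
        } else {
          sprintf("mutation_%s", codmap$note[i])
        },
        start = fs, end = fs + 3L,
        strand = if (gene$strand == "-") "-" else "+", stringsAsFactors = FALSE))
    }
  }
  # primer features (coordinates on the wild-type plasmid, shifted past the
  # substitution point)
  shift <- function(pos) ifelse(pos >= shift_at, pos + net, pos)
  for (pr in primers) {
    s0 <- pr$plasmid_position
    e0 <- s0 + nchar(pr$sequence)
    if (s0 >= shift_at || e0 <= ps) {
      feats <- rbind(feats, data.frame(
        type = "primer_bind", label = pr$name,
        start = shift(s0), end = shift(s0) + nchar(pr$sequence),
        strand = pr$strand, stringsAsFactors = FALSE))
    }
  }
  plasmid(paste0(p$name, "_", fragment$name), new_seq, circular = TRUE,
          features = feats)
}

#' Write a mutant plasmid GenBank file
#'
#' The file contains the full mutant plasmid sequence (wild-type plasmid
#' with the fragment's region substituted) with features for the fragment
#' region, every mutated codon, every silent marker codon, and the primers.
#'
#' @param p Wild-type \code{\link{plasmid}}.
#' @param gene \code{gene_context} of the gene of interest.
#' @param fragment A designed \code{fragment}.
#' @param primers List of \code{primer} objects to annotate.
#' @param out_path Output path (.gb).
#' @return Invisibly, the mutant \code{plasmid} object written.
#' @export
write_mutant_genbank <- function(p, gene, fragment, primers, out_path) {
  mut <- build_mutant_plasmid(p, gene, fragment, primers)
  write_genbank(mut, out_path)
  invisible(mut)
}
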