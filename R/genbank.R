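# Minimal GenBank flat-file reader/writer for plasmid maps.
#
# Scope: LOCUS name/length/topology, FEATURES with simple `a..b` and
# `complement(a..b)` locations plus /label-style qualifiers, and the ORIGIN
# sequence block. This covers plasmid maps as exported by common sequence
# editors; rich location grammar (join, fuzzy ends) is out of scope and
# rejected with a clear error. Feature intervals are converted between
# GenBank's 1-based closed convention and the package's 0-based half-open
# internal convention at this boundary only.

GB_DATE <- "01-JAN-1980"  # fixed LOCUS date so outputs are byte-reproducible

empty_features <- function() {
  data.frame(type = character(0), label = character(0),
             start = integer(0), end = integer(0),
             strand = character(0), stringsAsFactors = FALSE)
}

#' Construct a plasmid object
#'
#' @param name Plasmid name (LOCUS identifier).
#' @param sequence DNA string, alphabet A/C/G/T.
#' @param circular Logical; this tool only designs on circular plasmids.
#' @param features Data frame with columns \code{type}, \code{label},
#'   \code{start}, \code{end} (0-based half-open), \code{strand}
#'   (\code{"+"} or \code{"-"}).
#' @return An object of class \code{plasmid}.
#' @export
plasmid <- function(name, sequence, circular = TRUE, features = empty_features()) {
  sequence <- toupper(sequence)
  check_dna(sequence, "plasmid sequence")
  n <- nchar(sequence)
  if (nrow(features) > 0L) {
    features$start <- ((features$start %% n) + n) %% n
    bad <- features$end < features$start | features$end - features$start > n
    if (any(bad)) stop("feature interval outside plasmid", call. = FALSE)
  }
  structure(list(name = name, sequence = sequence, circular = isTRUE(circular),
                 features = features),
            class = "plasmid")
}

#' @export
print.plasmid <- function(x, ...) {
  cat(sprintf("plasmid '%s': %d bp, %s, %d feature(s)\n", x$name,
              nchar(x$sequence), if (x$circular) "circular" else "linear",
              nrow(x$features)))
  invisible(x)
}

#' Read a plasmid from a GenBank file
#'
#' Parses LOCUS, FEATURES (simple and \code{complement()} locations) and
#' ORIGIN. SnapGene \code{.dna} files are a proprietary binary format and are
#' refused; export to GenBank first.
#'
#' @param path Path to a \code{.gb}/\code{.gbk} file.
#' @return A \code{\link{plasmid}} object.
#' @export
read_genbank <- function(path) {
  if (grepl("\\.dna$", path, ignore.case = TRUE)) {
    stop("SnapGene .dna is a proprietary binary format and is not supported; ",
         "export the plasmid as GenBank (.gb) instead", call. = FALSE)
  }
  if (!file.exists(path)) stop("GenBank file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^LOCUS", lines[1])) {
    stop("not a GenBank file (missing LOCUS line): ", path, call. = FALSE)
  }
  locus <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  name <- if (length(locus) >= 2L) locus[2] else "plasmid"
  circular <- any(grepl("circular", lines[1], ignore.case = TRUE))

  feat_start <- grep("^FEATURES", lines)
  origin_start <- grep("^ORIGIN", lines)
  if (length(origin_start) == 0L) stop("GenBank file has no ORIGIN block", call. = FALSE)
  origin_start <- origin_start[1]

  # sequence
  end_line <- grep("^//", lines)
  end_line <- if (length(end_line)) end_line[1] else length(lines) + 1L
  seq_lines <- lines[seq(origin_start + 1L, end_line - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  check_dna(sequence, "plasmid sequence")

  # features
  features <- empty_features()
  if (length(feat_start) == 1L && feat_start < origin_start) {
    flines <- lines[seq(feat_start + 1L, origin_start - 1L)]
    key_idx <- grep("^ {5}\\S", flines)
    for (i in seq_along(key_idx)) {
      first <- key_idx[i]
      last <- if (i < length(key_idx)) key_idx[i + 1L] - 1L else length(flines)
      header <- strsplit(trimws(flines[first]), "\\s+")[[1]]
      type <- header[1]
      loc <- paste(header[-1], collapse = "")
      strand <- "+"
      if (grepl("^complement\\(", loc)) {
        strand <- "-"
        loc <- sub("^complement\\(", "", sub("\\)$", "", loc))
      }
      if (!grepl("^[0-9]+\\.\\.[0-9]+$", loc)) {
        stop("unsupported feature location '", loc, "' (only a..b and ",
             "complement(a..b) are handled)", call. = FALSE)
      }
      ab <- as.integer(strsplit(loc, "\\.\\.")[[1]])
      label <- type
      qual <- flines[seq(first, last)]
      m <- regmatches(qual, regexpr('/(label|name|gene|note)="?[^"]*"?', qual))
      if (length(m) > 0L) {
        label <- sub('^/[a-z]+="?', "", m[[1]])
        label <- sub('"$', "", label)
      }
      features <- rbind(features, data.frame(
        type = type, label = label,
        start = ab[1] - 1L, end = ab[2], strand = strand,
        stringsAsFactors = FALSE))
    }
  }
  plasmid(name, sequence, circular = circular, features = features)
}

#' Write a plasmid to a GenBank file
#'
#' The LOCUS date is a fixed constant so that repeated runs produce
#' byte-identical files.
#'
#' @param p A \code{\link{plasmid}} object.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_genbank <- function(p, path) {
  stopifnot(inherits(p, "plasmid"))
  n <- nchar(p$sequence)
  topo <- if (p$circular) "circular" else "linear"
  out <- c(sprintf("LOCUS       %-17s %d bp    DNA     %-8s SYN %s",
                   substr(gsub("\\s", "_", p$name), 1L, 17L), n, topo, GB_DATE),
           sprintf("DEFINITION  %s.", p$name),
           "FEATURES             Location/Qualifiers")
  if (nrow(p$features) > 0L) {
    for (i in seq_len(nrow(p$features))) {
      f <- p$features[i, ]
      loc <- sprintf("%d..%d", f$start + 1L, f$end)
      if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
      out <- c(out,
               sprintf("     %-16s%s", f$type, loc),
               sprintf("                     /label=\"%s\"", f$label))
    }
  }
  out <- c(out, "ORIGIN")
  starts <- seq(1L, n, by = 60L)
  for (s in starts) {
    chunk <- substr(p$sequence, s, min(s + 59L, n))
    tens <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", s, paste(tolower(tens), collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}
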