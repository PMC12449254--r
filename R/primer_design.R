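# Primer design: plasmid-linearization pair (opens the vector for IVA
# insertion of the fragment) and sequencing primers, using a deterministic
# window-scan over candidate lengths with nearest-neighbor melting
# temperatures and bespoke secondary-structure / off-target checks.

# Unified nearest-neighbor dinucleotide parameters (dH kcal/mol, dS
# cal/(mol K)) for DNA/DNA duplexes, with terminal initiation corrections.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
NN_INIT_DH <- c(GC = 0.1, AT = 2.3)   # per G/C or A/T duplex end
NN_INIT_DS <- c(GC = -2.8, AT = 4.1)

#' Nearest-neighbor melting temperature
#'
#' Two-state nearest-neighbor model with the unified dinucleotide parameter
#' set, 50 mM monovalent salt (entropic correction 0.368 (N-1) ln[Na+])
#' and 500 nM total oligonucleotide (annealing concentration CT/4).
#'
#' @param seq DNA string (A/C/G/T), length at least 8.
#' @param na_mM Monovalent cation concentration in mM (default 50).
#' @param oligo_nM Total oligonucleotide concentration in nM (default 500).
#' @return Melting temperature in degrees Celsius.
#' @examples
#' melting_temperature("ACGTACGTACGTACGT")
#' @export
melting_temperature <- function(seq, na_mM = 50, oligo_nM = 500) {
  seq <- toupper(seq)
  check_dna(seq, "primer sequence")
  n <- nchar(seq)
  if (n < 8L) stop("sequence too short for the nearest-neighbor model (< 8 nt)",
                   call. = FALSE)
  steps <- substring(seq, 1:(n - 1L), 2:n)
  dH <- sum(NN_DH[steps])
  dS <- sum(NN_DS[steps])
  for (end_base in c(substr(seq, 1L, 1L), substr(seq, n, n))) {
    cls <- if (end_base %in% c("G", "C")) "GC" else "AT"
    dH <- dH + NN_INIT_DH[[cls]]
    dS <- dS + NN_INIT_DS[[cls]]
  }
  dS <- dS + 0.368 * (n - 1L) * log(na_mM / 1000)
  ct <- oligo_nM * 1e-9
  tm_k <- 1000 * dH / (dS + 1.987 * log(ct / 4))
  tm_k - 273.15
}

primer_obj <- function(name, sequence, plasmid_position, strand, flags = character(0)) {
  structure(list(name = name, sequence = sequence,
                 plasmid_position = plasmid_position, strand = strand,
                 tm = melting_temperature(sequence),
                 gc_fraction = gc_fraction(sequence),
                 flags = flags),
            class = "primer")
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("primer '%s' (%s strand @%d): %s  Tm %.1f C, GC %.2f%s\n",
              x$name, x$strand, x$plasmid_position, x$sequence, x$tm,
              x$gc_fraction,
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Secondary-structure flags for a primer
#'
#' Exhaustive scan: a \code{hairpin} flag is raised when the primer
#' contains an inverted repeat with stem length at least 4 bp separated by
#' a loop of at least 3 nt; a \code{self_dimer} flag when the longest
#' antiparallel complementary run between the primer and a second copy of
#' itself reaches 8 bp.
#'
#' @param sequence Primer DNA string (or a \code{primer} object).
#' @return Character vector drawn from \code{c("hairpin", "self_dimer")}.
#' @export
check_secondary_structure <- function(sequence) {
  if (inherits(sequence, "primer")) sequence <- sequence$sequence
  seq <- toupper(sequence)
  n <- nchar(seq)
  flags <- character(0)
  rc <- revcomp(seq)
  # hairpin: seq[i..i+s) pairs with seq[j..j+s) reversed-complemented,
  # loop = j - (i+s) >= 3, stem s >= 4
  found <- FALSE
  for (s in 4L:max(4L, n %/% 2L)) {
    if (found || 2L * s + 3L > n) break
    for (i in 1L:(n - 2L * s - 3L + 1L)) {
      stem1 <- substr(seq, i, i + s - 1L)
      for (j in seq(i + s + 3L, n - s + 1L)) {
        stem2 <- substr(seq, j, j + s - 1L)
        if (stem2 == revcomp(stem1)) {
          found <- TRUE
          break
        }
      }
      if (found) break
    }
  }
  if (found) flags <- c(flags, "hairpin")
  # self-dimer: longest common substring between seq and its reverse
  # complement (an antiparallel self-complementary run)
  longest <- 0L
  prev <- integer(n + 1L)
  for (i in 1L:n) {
    cur <- integer(n + 1L)
    ci <- substr(seq, i, i)
    for (j in 1L:n) {
      if (ci == substr(rc, j, j)) {
        cur[j + 1L] <- prev[j] + 1L
        if (cur[j + 1L] > longest) longest <- cur[j + 1L]
      }
    }
    prev <- cur
  }
  if (longest >= 8L) flags <- c(flags, "self_dimer")
  flags
}

#' Off-target binding flag for a primer on a circular plasmid
#'
#' The primer's 3'-terminal 12-mer is counted across both strands of the
#' circular plasmid; more than one occurrence raises the \code{off_target}
#' flag (the intended site is one occurrence).
#'
#' @param primer A \code{primer} object or a plain sequence.
#' @param p A \code{\link{plasmid}}.
#' @return Character vector, either empty or \code{"off_target"}.
#' @export
check_off_target <- function(primer, p) {
  seq <- if (inherits(primer, "primer")) primer$sequence else toupper(primer)
  k <- 12L
  if (nchar(seq) < k) stop("primer shorter than the 12-nt seed", call. = FALSE)
  seed <- substr(seq, nchar(seq) - k + 1L, nchar(seq))
  if (count_occurrences_circular(p$sequence, seed) > 1L) "off_target"
  else character(0)
}

# occurrences of `pattern` on both strands of the circular sequence,
# counting start positions within one period
count_occurrences_circular <- function(sequence, pattern) {
  n <- nchar(sequence)
  k <- nchar(pattern)
  doubled <- paste0(sequence, substr(sequence, 1L, k - 1L))
  count_in <- function(pat) {
    hits <- Biostrings::matchPattern(pat, Biostrings::DNAString(doubled))
    sum(BiocGenerics::start(hits) <= n)
  }
  count_in(pattern) + count_in(revcomp(pattern))
}

# All primer candidates anchored (5' end for "+", 3' boundary for "-") at a
# fixed plasmid position, one per scanned length, inside the Tm window and
# binding uniquely on the plasmid. Secondary-structure/off-target flags and
# a GC window miss are recorded as penalties rather than hard rejections:
# linearization primers are position-locked by the IVA geometry, so when no
# flag-free length exists the best flagged candidate is still usable (and
# reported with its flags). `n_issues` counts flags plus any GC miss.
scan_primer_candidates <- function(p, name, pos, strand, settings,
                                   require_gc = FALSE) {
  n <- nchar(p$sequence)
  lens <- seq(settings$primer_len_range[1], settings$primer_len_range[2])
  window <- settings$primer_tm_window
  out <- list()
  for (L in lens) {
    sq <- if (strand == "+") circular_subseq(p$sequence, pos, pos + L)
          else revcomp(circular_subseq(p$sequence, pos - L, pos))
    tm <- melting_temperature(sq)
    if (tm < window[1] || tm > window[2]) next
    if (count_occurrences_circular(p$sequence, sq) != 1L) next
    flags <- c(check_secondary_structure(sq),
               check_off_target(structure(list(sequence = sq), class = "primer"), p))
    issues <- length(flags)
    if (require_gc) {
      gc <- gc_fraction(sq)
      if (gc < settings$primer_gc_window[1] || gc > settings$primer_gc_window[2]) {
        issues <- issues + 1L
      }
    }
    start0 <- if (strand == "+") ((pos %% n) + n) %% n
              else (((pos - L) %% n) + n) %% n
    pr <- primer_obj(name, sq, start0, strand, flags = flags)
    pr$n_issues <- issues
    out[[length(out) + 1L]] <- pr
  }
  out
}

# best single candidate: fewest issues, then Tm closest to the window
# midpoint; warns when the winner carries flags
scan_primer <- function(p, name, pos, strand, settings, require_gc = FALSE,
                        warn_flagged = TRUE) {
  cands <- scan_primer_candidates(p, name, pos, strand, settings, require_gc)
  if (length(cands) == 0L) return(NULL)
  target <- mean(settings$primer_tm_window)
  issues <- vapply(cands, `[[`, integer(1), "n_issues")
  tms <- vapply(cands, `[[`, numeric(1), "tm")
  ord <- order(issues, abs(tms - target))
  best <- cands[[ord[1]]]
  if (warn_flagged && best$n_issues > 0L) {
    warning("primer '", name, "' carries diagnostic flag(s): ",
            paste(c(best$flags,
                    if (best$n_issues > length(best$flags)) "gc_window"),
                  collapse = ","), call. = FALSE)
  }
  best
}

#' Design the plasmid-linearization primer pair
#'
#' Outward-facing pair that amplifies the whole plasmid minus the fragment
#' region: the forward primer anneals starting exactly at the region's 3'
#' boundary, the reverse primer ends exactly at the region's 5' boundary on
#' the opposite strand, so the fragment's homology flanks exactly overlap
#' the linearized plasmid ends.
#'
#' @param p The \code{\link{plasmid}}.
#' @param region_plasmid Length-2 numeric: 0-based half-open plasmid
#'   interval of the fragment region (may wrap the origin: end < start
#'   before modular reduction is not allowed; pass start + len as end).
#' @param settings A \code{\link{design_settings}}.
#' @param name_prefix Prefix for primer names.
#' @return A \code{primer_pair}: \code{forward}, \code{reverse},
#'   \code{product_length_bp}, \code{purpose}.
#' @export
design_linearization_pair <- function(p, region_plasmid, settings,
                                      name_prefix = "lin") {
  n <- nchar(p$sequence)
  rs <- region_plasmid[1]
  re <- region_plasmid[2]
  stopifnot(re >= rs, re - rs <= n)
  fwds <- scan_primer_candidates(p, paste0(name_prefix, "_fwd"), re, "+", settings)
  revs <- scan_primer_candidates(p, paste0(name_prefix, "_rev"), rs, "-", settings)
  if (length(fwds) == 0L) {
    stop("no forward linearization primer passes the Tm window and checks ",
         "at the region 3' boundary", call. = FALSE)
  }
  if (length(revs) == 0L) {
    stop("no reverse linearization primer passes the Tm window and checks ",
         "at the region 5' boundary", call. = FALSE)
  }
  # jointly pick the pair: fewest diagnostic flags, then smallest Tm
  # difference, then closest to the window midpoint
  target <- mean(settings$primer_tm_window)
  best <- NULL
  best_key <- c(Inf, Inf, Inf)
  for (f in fwds) for (r in revs) {
    if (abs(f$tm - r$tm) > settings$primer_pair_dtm_max) next
    key <- c(f$n_issues + r$n_issues, abs(f$tm - r$tm),
             abs(f$tm - target) + abs(r$tm - target))
    if (key[1] < best_key[1] ||
        (key[1] == best_key[1] && (key[2] < best_key[2] ||
          (key[2] == best_key[2] && key[3] < best_key[3])))) {
      best_key <- key
      best <- list(f = f, r = r)
    }
  }
  if (is.null(best)) {
    stop(sprintf(
      "no linearization primer pair within the %.1f C pair Tm limit",
      settings$primer_pair_dtm_max), call. = FALSE)
  }
  fwd <- best$f
  rev <- best$r
  for (pr in list(fwd, rev)) {
    if (length(pr$flags) > 0L) {
      warning("linearization primer '", pr$name, "' carries flag(s): ",
              paste(pr$flags, collapse = ","), call. = FALSE)
    }
  }
  structure(list(forward = fwd, reverse = rev,
                 product_length_bp = n - (re - rs),
                 purpose = "linearization"),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("primer_pair (%s): product %d bp\n", x$purpose,
              x$product_length_bp))
  print(x$forward)
  print(x$reverse)
  invisible(x)
}

#' Design sequencing primers covering a fragment region
#'
#' Plus-strand primers: the first 100-200 bp upstream of the region start,
#' then one every at most \code{sequencing_spacing_bp} until the region end
#' is covered. Each primer must meet the Tm and GC windows, show no
#' secondary-structure flags, and bind uniquely on the plasmid; a site that
#' fails is slid by up to 50 bp in either direction.
#'
#' @param p The \code{\link{plasmid}}.
#' @param region_plasmid Length-2 numeric 0-based half-open plasmid interval.
#' @param settings A \code{\link{design_settings}}.
#' @param name_prefix Prefix for primer names.
#' @return List of \code{primer} objects.
#' @export
design_sequencing_primers <- function(p, region_plasmid, settings,
                                      name_prefix = "seq") {
  rs <- region_plasmid[1]
  re <- region_plasmid[2]
  region_len <- re - rs
  spacing <- settings$sequencing_spacing_bp
  n_primers <- max(1L, as.integer(ceiling((region_len + 200) / spacing)))
  sites <- rs - 150 + (seq_len(n_primers) - 1L) * spacing
  primers <- vector("list", n_primers)
  for (i in seq_len(n_primers)) {
    pr <- NULL
    fallback <- NULL
    for (off in c(0L, -10L, 10L, -20L, 20L, -30L, 30L, -40L, 40L, -50L, 50L)) {
      cand <- suppressWarnings(
        scan_primer(p, sprintf("%s_%d", name_prefix, i),
                    sites[i] + off, "+", settings, require_gc = TRUE))
      if (is.null(cand)) next
      if (cand$n_issues == 0L) {
        pr <- cand
        break
      }
      if (is.null(fallback) || cand$n_issues < fallback$n_issues) fallback <- cand
    }
    if (is.null(pr) && !is.null(fallback)) {
      pr <- fallback
      warning("sequencing primer '", pr$name, "' carries flag(s): ",
              paste(c(pr$flags, if (pr$n_issues > length(pr$flags)) "gc_window"),
                    collapse = ","), call. = FALSE)
    }
    if (is.null(pr)) {
      stop("no sequencing primer found near plasmid position ",
           ((sites[i] %% nchar(p$sequence)) + nchar(p$sequence)) %% nchar(p$sequence),
           " (Tm/GC windows and uniqueness could not all be met within +/-50 bp)",
           call. = FALSE)
    }
    primers[[i]] <- pr
  }
  primers
}
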