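# Turning a cluster of mutations into concrete synthesizable fragments:
# region definition, codon-optimized mutagenesis, Tm-constrained homology
# flanks, and silent marker codons.

#' Define the fragment region for a cluster
#'
#' The smallest codon-aligned CDS interval containing all member extents,
#' expanded symmetrically until the region (a) reaches the interior floor
#' (minimum fragment length minus both flanks) and (b) still yields a
#' minimum-length fragment for the member with the largest deletion. If the
#' expansion hits a CDS boundary the remainder is shifted to the other side;
#' if the CDS itself is too short the region continues into the plasmid
#' backbone (keeping codon phase within the CDS).
#'
#' @param points Data frame rows (from \code{\link{mutation_points}}) of the
#'   cluster members.
#' @param gene A \code{gene_context}.
#' @param settings A \code{\link{design_settings}}.
#' @param cluster_index Integer id used in names and annotations.
#' @return A \code{fragment_region}: \code{start}, \code{end} (0-based
#'   half-open bp in the coding frame; may extend beyond the CDS),
#'   \code{cluster_index}, \code{mutations} (labels), \code{max_net}.
#' @export
define_region <- function(points, gene, settings, cluster_index = 1L) {
  g <- cluster_geometry(points$ext_start, points$ext_end, points$net, settings)
  if (!g$valid) {
    stop("region too large: cluster of ", paste(unique(points$label), collapse = ","),
         " cannot fit a fragment of at most ", settings$max_fragment_bp,
         " bp", call. = FALSE)
  }
  lo <- min(points$ext_start)
  hi <- max(points$ext_end)
  pad <- g$region_needed - (hi - lo)
  left <- 3L * ((pad %/% 3L) %/% 2L)
  right <- pad - left
  start <- lo - left
  end <- hi + right
  lc <- nchar(gene$cds)
  # shift the overhang to the other side at CDS boundaries
  if (start < 0L && end - start <= lc) {
    end <- end - start
    start <- 0L
  }
  if (end > lc && end - start <= lc) {
    start <- start - (end - lc)
    end <- lc
    if (start < 0L) {  # CDS shorter than the region: spill into backbone
      start <- 0L
      end <- g$region_needed
    }
  }
  structure(list(start = start, end = end, cluster_index = cluster_index,
                 mutations = unique(points$label), max_net = max(points$net),
                 region_needed = g$region_needed),
            class = "fragment_region")
}

#' @export
print.fragment_region <- function(x, ...) {
  cat(sprintf("fragment_region %d: CDS bp [%d, %d), %d mutation(s)\n",
              x$cluster_index, x$start, x$end, length(x$mutations)))
  invisible(x)
}

#' Apply mutations to the wild-type region sequence
#'
#' Point substitutions use the most frequent codon for the target amino
#' acid; insertions are encoded codon-by-codon with most-frequent codons;
#' deletions excise whole codons. Returns the mutant region sequence
#' together with a codon-level map used for marker placement and
#' annotation.
#'
#' @param region A \code{fragment_region}.
#' @param specs List of \code{mutation_spec} to apply (the specs of one
#'   mutant; typically a single spec, or one combined spec).
#' @param p The \code{\link{plasmid}}.
#' @param gene A \code{gene_context}.
#' @param table A \code{codon_usage} table.
#' @return List with \code{seq} (mutant region DNA), \code{codon_map}
#'   (data frame: codon, wt_codon, orig_res, mutated, marker, note),
#'   \code{pre_len}, \code{post_len} (bp of backbone sequence retained at
#'   the region ends when the region extends beyond the CDS).
#' @export
apply_mutations <- function(region, specs, p, gene, table) {
  lc <- nchar(gene$cds)
  cds_from <- max(region$start, 0L)
  cds_to <- min(region$end, lc)
  stopifnot(cds_from %% 3L == 0L, cds_to %% 3L == 0L)
  pre <- if (region$start < 0L) frame_subseq(p, gene, region$start, 0L) else ""
  post <- if (region$end > lc) frame_subseq(p, gene, lc, region$end) else ""
  codons <- split_codons(substr(gene$cds, cds_from + 1L, cds_to))
  first_res <- cds_from %/% 3L + 1L  # 1-based residue of the first codon
  nres <- length(codons)
  cmap <- data.frame(codon = codons, wt_codon = codons,
                     orig_res = seq(first_res, length.out = nres),
                     mutated = FALSE, marker = FALSE, note = "",
                     stringsAsFactors = FALSE)

  res_row <- function(r) {
    i <- which(cmap$orig_res == r & !is.na(cmap$orig_res))
    if (length(i) != 1L) {
      stop("residue ", r, " not inside the fragment region", call. = FALSE)
    }
    i
  }
  apply_point <- function(pt, label) {
    i <- res_row(pt$res)
    cmap$codon[i] <<- most_frequent_codon(table, pt$mut)
    cmap$mutated[i] <<- TRUE
    cmap$note[i] <<- label
  }
  for (m in specs) {
    switch(m$kind,
      point = apply_point(m, m$label),
      combined = for (pt in m$members) apply_point(pt, m$label),
      deletion = {
        rows <- vapply(seq(m$first, m$last), res_row, integer(1))
        cmap <- cmap[-rows, , drop = FALSE]
      },
      insertion = {
        i <- res_row(m$anchor)
        ins_codons <- split_codons(encode_peptide(table, m$peptide))
        ins <- data.frame(codon = ins_codons, wt_codon = NA_character_,
                          orig_res = NA_integer_, mutated = TRUE,
                          marker = FALSE, note = m$label,
                          stringsAsFactors = FALSE)
        cmap <- rbind(cmap[seq_len(i), , drop = FALSE], ins,
                      if (i < nrow(cmap)) cmap[seq(i + 1L, nrow(cmap)), , drop = FALSE])
      })
  }
  rownames(cmap) <- NULL
  list(seq = paste0(pre, paste(cmap$codon, collapse = ""), post),
       codon_map = cmap, pre_len = nchar(pre), post_len = nchar(post))
}

#' Design a homology flank
#'
#' The wild-type plasmid subsequence abutting the region boundary on the
#' given side, with the length (scanned from the minimum up to
#' \code{max_flank_bp}, optionally capped by a length budget) whose melting
#' temperature falls inside the flank Tm window and is closest to the
#' window midpoint. If no length reaches the window the closest Tm is used
#' and a warning attribute is attached.
#'
#' @param p The \code{\link{plasmid}}.
#' @param gene A \code{gene_context}.
#' @param boundary Coding-frame bp position of the region boundary.
#' @param side \code{"5prime"} (flank upstream of the boundary) or
#'   \code{"3prime"} (downstream).
#' @param settings A \code{\link{design_settings}}.
#' @param max_len Optional cap on the flank length (fragment length budget).
#' @return Flank DNA string; attribute \code{tm} holds its Tm, attribute
#'   \code{warning} is set when the Tm window could not be reached.
#' @export
design_flank <- function(p, gene, boundary, side = c("5prime", "3prime"),
                         settings, max_len = NULL) {
  side <- match.arg(side)
  window <- settings$flank_tm_window
  target <- mean(window)
  hi <- min(settings$max_flank_bp, max_len %||% settings$max_flank_bp)
  hi <- max(hi, settings$min_flank_bp)
  lens <- seq(settings$min_flank_bp, hi)
  seqs <- vapply(lens, function(L) {
    if (side == "5prime") frame_subseq(p, gene, boundary - L, boundary)
    else frame_subseq(p, gene, boundary, boundary + L)
  }, character(1))
  tms <- vapply(seqs, melting_temperature, numeric(1))
  inside <- tms >= window[1] & tms <= window[2]
  if (any(inside)) {
    pick <- which(inside)[which.min(abs(tms[inside] - target))]
    out <- seqs[pick]
    attr(out, "tm") <- tms[pick]
  } else {
    pick <- which.min(abs(tms - target))
    out <- seqs[pick]
    attr(out, "tm") <- tms[pick]
    attr(out, "warning") <- sprintf(
      "no flank length in [%d, %d] reaches Tm window [%.1f, %.1f]; closest Tm %.1f C",
      settings$min_flank_bp, hi, window[1], window[2], tms[pick])
  }
  out
}

#' Place silent marker codons near the fragment ends
#'
#' At each end of the mutant region the configured number of codons nearest
#' the end that lie inside the CDS, do not belong to an intended mutation,
#' and have a usable silent alternative are swapped to that alternative.
#' The protein sequence is unchanged; the codon changes act as a cheap
#' sequencing-detectable fingerprint of successful fragment insertion.
#'
#' @param applied Result of \code{\link{apply_mutations}}.
#' @param table A \code{codon_usage} table.
#' @param settings A \code{\link{design_settings}}.
#' @return \code{applied} with markers applied: updated \code{seq},
#'   \code{codon_map}, plus \code{silent_markers} (data frame: codon_index,
#'   wt_codon, new_codon) and optionally a \code{marker_warning}.
#' @export
place_silent_markers <- function(applied, table, settings) {
  cmap <- applied$codon_map
  n <- nrow(cmap)
  per_end <- settings$silent_markers_per_end
  if (per_end == 0L || n == 0L) {
    applied$silent_markers <- data.frame(codon_index = integer(0),
                                         wt_codon = character(0),
                                         new_codon = character(0))
    return(applied)
  }
  usable <- function(i) {
    if (cmap$mutated[i] || cmap$marker[i]) return(FALSE)
    !is.na(silent_alternative(table, cmap$codon[i]))
  }
  chosen <- integer(0)
  for (idx_order in list(seq_len(n), rev(seq_len(n)))) {
    found <- 0L
    for (i in idx_order) {
      if (found >= per_end) break
      if (i %in% chosen) next
      if (usable(i)) {
        chosen <- c(chosen, i)
        found <- found + 1L
      }
    }
  }
  markers <- data.frame(codon_index = sort(chosen),
                        wt_codon = cmap$codon[sort(chosen)],
                        new_codon = vapply(cmap$codon[sort(chosen)],
                                           function(cd) silent_alternative(table, cd),
                                           character(1)),
                        stringsAsFactors = FALSE)
  cmap$codon[markers$codon_index] <- markers$new_codon
  cmap$marker[markers$codon_index] <- TRUE
  applied$codon_map <- cmap
  applied$seq <- paste0(
    if (applied$pre_len > 0L) substr(applied$seq, 1L, applied$pre_len) else "",
    paste(cmap$codon, collapse = ""),
    if (applied$post_len > 0L) substr(applied$seq,
                                      nchar(applied$seq) - applied$post_len + 1L,
                                      nchar(applied$seq)) else "")
  applied$silent_markers <- markers
  if (length(chosen) < 2L * per_end) {
    applied$marker_warning <- sprintf(
      "only %d of %d requested silent markers could be placed",
      length(chosen), 2L * per_end)
  }
  applied
}

#' Assemble the final fragment
#'
#' Concatenates 5' flank, mutant region and 3' flank, checks the total
#' length against the provider limits and computes the synthesis cost.
#'
#' @param name Fragment name.
#' @param region A \code{fragment_region}.
#' @param applied Result of \code{\link{place_silent_markers}}.
#' @param flank5,flank3 Homology flank strings from \code{\link{design_flank}}.
#' @param settings A \code{\link{design_settings}}.
#' @return An object of class \code{fragment}.
#' @export
assemble_fragment <- function(name, region, applied, flank5, flank3, settings) {
  full <- paste0(flank5, applied$seq, flank3)
  len <- nchar(full)
  if (len < settings$min_fragment_bp || len > settings$max_fragment_bp) {
    stop("fragment '", name, "' length ", len, " bp outside provider range [",
         settings$min_fragment_bp, ", ", settings$max_fragment_bp, "]",
         call. = FALSE)
  }
  warnings <- c(attr(flank5, "warning"), attr(flank3, "warning"),
                applied$marker_warning)
  structure(list(name = name, region = region,
                 mutant_region_seq = applied$seq,
                 codon_map = applied$codon_map, pre_len = applied$pre_len,
                 flank5 = as.character(flank5), flank3 = as.character(flank3),
                 full_seq = full,
                 silent_markers = applied$silent_markers,
                 cost = len * settings$cost_per_bp,
                 warnings = warnings),
            class = "fragment")
}

#' @export
print.fragment <- function(x, ...) {
  cat(sprintf("fragment '%s': %d bp (flanks %d/%d), %d silent marker(s), cost %.2f\n",
              x$name, nchar(x$full_seq), nchar(x$flank5), nchar(x$flank3),
              nrow(x$silent_markers), x$cost))
  invisible(x)
}

#' Design all fragments for a selected clustering
#'
#' For every cluster a shared fragment region and shared flanks are
#' designed; every mutation spec of the cluster then yields one mutant
#' fragment (codon-optimized changes plus silent markers) over that region.
#'
#' @param p The \code{\link{plasmid}}.
#' @param gene A \code{gene_context}.
#' @param muts List of validated \code{mutation_spec}.
#' @param clustering A selected \code{clustering} over
#'   \code{mutation_points(muts, gene)}.
#' @param table A \code{codon_usage} table.
#' @param settings A \code{\link{design_settings}}.
#' @return List with \code{regions} (one per cluster) and \code{fragments}
#'   (one per mutation spec).
#' @export
design_fragments <- function(p, gene, muts, clustering, table, settings) {
  points <- mutation_points(muts, gene)
  by_label <- stats::setNames(muts, vapply(muts, `[[`, character(1), "label"))
  regions <- list()
  fragments <- list()
  for (ci in seq_len(clustering$k)) {
    rows <- clustering$clusters[[ci]]$rows
    cl_points <- points[rows, , drop = FALSE]
    region <- define_region(cl_points, gene, settings, cluster_index = ci)
    region_len <- region$end - region$start
    # keep the worst-case mutant fragment within the provider maximum when
    # choosing flank lengths
    budget <- settings$max_fragment_bp - (region_len + region$max_net)
    flank5 <- design_flank(p, gene, region$start, "5prime", settings,
                           max_len = budget - settings$min_flank_bp)
    flank3 <- design_flank(p, gene, region$end, "3prime", settings,
                           max_len = budget - nchar(flank5))
    regions[[ci]] <- region
    for (lab in unique(cl_points$label)) {
      spec <- by_label[[lab]]
      applied <- apply_mutations(region, list(spec), p, gene, table)
      applied <- place_silent_markers(applied, table, settings)
      name <- sprintf("%s_%s_r%d_%s", p$name, gene$gene_id, ci,
                      gsub("[^A-Za-z0-9+-]", "", lab))
      fragments[[length(fragments) + 1L]] <-
        assemble_fragment(name, region, applied, flank5, flank3, settings)
    }
  }
  list(regions = regions, fragments = fragments)
}
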