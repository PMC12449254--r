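# End-to-end orchestration of the design workflow and plain-text reporting.

#' Run the full design workflow
#'
#' Reads all inputs, locates and validates the gene and mutations, clusters
#' the mutations into fragment regions, designs all mutant fragments and
#' primers, and writes one GenBank file per mutant, a CSV order sheet and a
#' text region map into \code{out_dir}. On any stage failure the partial
#' outputs are removed and the error names the offending mutations.
#'
#' @param plasmid_path GenBank plasmid file.
#' @param gene_path FASTA file with the gene CDS.
#' @param mutations_path Plain-text mutation list.
#' @param codon_usage_path Optional CDS FASTA or codon-usage TSV used for
#'   codon preferences; when \code{NULL} the usage of the gene of interest
#'   itself is used (a crude stand-in; supply the expression organism's CDS
#'   collection for real designs).
#' @param settings_path Optional YAML settings file.
#' @param out_dir Output directory (created if needed).
#' @param optimize Clustering objective, \code{"quantity"} or
#'   \code{"length"}; overrides the settings file when given.
#' @param seed Optional integer overriding the settings seed (recorded for
#'   provenance; the design itself is deterministic).
#' @return A \code{design_bundle}: \code{fragments},
#'   \code{linearization_pairs} (one per region), \code{sequencing_primers}
#'   (per region), \code{clustering}, \code{regions}, \code{paths},
#'   \code{summary}.
#' @export
design_run <- function(plasmid_path, gene_path, mutations_path,
                       codon_usage_path = NULL, settings_path = NULL,
                       out_dir, optimize = NULL, seed = NULL) {
  settings <- if (is.null(settings_path)) design_settings()
              else read_settings(settings_path)
  if (!is.null(optimize)) settings$optimization_mode <-
      match.arg(optimize, c("quantity", "length"))
  if (!is.null(seed)) settings$random_seed <- as.integer(seed)

  p <- read_genbank(plasmid_path)
  gene_rec <- read_gene_fasta(gene_path)
  gene <- locate_gene(p, gene_rec)
  muts <- validate_mutations(parse_mutation_file(mutations_path), gene)
  table <- load_codon_source(codon_usage_path, gene)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail_cleanup <- function() unlink(written)

  bundle <- tryCatch({
    points <- mutation_points(muts, gene)
    cands <- find_valid_clusterings(points, settings)
    sel <- select_clustering(cands, settings$optimization_mode)
    design <- design_fragments(p, gene, muts, sel, table, settings)

    lin_pairs <- list()
    seq_primers <- list()
    for (ci in seq_along(design$regions)) {
      reg <- design$regions[[ci]]
      iv <- region_plasmid_interval(gene, reg, nchar(p$sequence))
      lin_pairs[[ci]] <- design_linearization_pair(
        p, iv, settings, name_prefix = sprintf("lin_r%d", ci))
      seq_primers[[ci]] <- design_sequencing_primers(
        p, iv, settings, name_prefix = sprintf("seq_r%d", ci))
    }

    gb_paths <- character(0)
    for (i in seq_along(design$fragments)) {
      fr <- design$fragments[[i]]
      ci <- fr$region$cluster_index
      path <- file.path(out_dir, paste0(fr$name, ".gb"))
      write_mutant_genbank(p, gene, fr,
                           c(list(lin_pairs[[ci]]$forward,
                                  lin_pairs[[ci]]$reverse),
                             seq_primers[[ci]]),
                           path)
      written <- c(written, path)
      gb_paths <- c(gb_paths, path)
    }
    all_primers <- c(
      unlist(lapply(lin_pairs, function(pp) list(pp$forward, pp$reverse)),
             recursive = FALSE),
      unlist(seq_primers, recursive = FALSE))
    sheet_path <- file.path(out_dir, "order_sheet.csv")
    write_order_sheet(design$fragments, all_primers, settings, sheet_path)
    written <- c(written, sheet_path)
    map_path <- file.path(out_dir, "region_map.txt")
    writeLines(render_region_map(gene, design$regions, points), map_path)
    written <- c(written, map_path)

    total_cost <- sum(vapply(design$fragments, `[[`, numeric(1), "cost"))
    structure(list(
      fragments = design$fragments,
      linearization_pairs = lin_pairs,
      sequencing_primers = seq_primers,
      clustering = sel, regions = design$regions,
      settings = settings,
      paths = list(genbank = gb_paths, order_sheet = sheet_path,
                   region_map = map_path),
      summary = list(n_mutations = length(muts),
                     n_regions = length(design$regions),
                     n_fragments = length(design$fragments),
                     total_cost = total_cost)),
      class = "design_bundle")
  }, error = function(e) {
    on_fail_cleanup()
    stop(conditionMessage(e), call. = FALSE)
  })
  bundle
}

load_codon_source <- function(codon_usage_path, gene) {
  if (is.null(codon_usage_path)) {
    return(compute_codon_usage(gene$cds, paste0(gene$gene_id, "_self")))
  }
  ext <- tolower(tools::file_ext(codon_usage_path))
  if (ext %in% c("tsv", "txt", "tab")) {
    read_codon_usage(codon_usage_path)
  } else {
    set <- Biostrings::readDNAStringSet(codon_usage_path)
    suppressWarnings(compute_codon_usage(set, basename(codon_usage_path)))
  }
}

# plasmid interval of a fragment region as c(start, start + len), unreduced
region_plasmid_interval <- function(gene, region, plasmid_len) {
  iv <- frame_to_plasmid(gene, region$start, region$end)
  start <- ((iv[1] %% plasmid_len) + plasmid_len) %% plasmid_len
  c(start, start + (iv[2] - iv[1]))
}

#' @export
print.design_bundle <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "design_bundle: %d mutation(s) -> %d fragment region(s), %d fragment(s), total cost %.2f\n",
    s$n_mutations, s$n_regions, s$n_fragments, s$total_cost))
  invisible(x)
}

#' Run the synthetic validation sweep and write the result
#'
#' @param out_dir Output directory for the TSV.
#' @param types,lengths,genes,replicates,n_codons,base_seed Passed to
#'   \code{\link{run_sweep}}.
#' @param settings_path Optional YAML settings file.
#' @return The \code{sweep_result}, invisibly; written to
#'   \code{out_dir/sweep.tsv}.
#' @export
validate_run <- function(out_dir,
                         types = c("deletion", "insertion", "paired"),
                         lengths = seq(1L, 600L, by = 5L),
                         genes = 3L, replicates = 10L, n_codons = 800L,
                         base_seed = 42L, settings_path = NULL) {
  settings <- if (is.null(settings_path)) design_settings()
              else read_settings(settings_path)
  sweep <- run_sweep(types = types, lengths = lengths, genes = genes,
                     replicates = replicates, n_codons = n_codons,
                     base_seed = base_seed, settings = settings)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_sweep_tsv(sweep, file.path(out_dir, "sweep.tsv"))
  invisible(sweep)
}

#' Render a plain-text map of fragment regions and mutations on the gene
#'
#' Fixed-width ASCII tracks: a bp ruler, the gene, one span line per
#' fragment region, and mutation marks with their labels.
#'
#' @param gene A \code{gene_context}.
#' @param regions List of \code{fragment_region}.
#' @param points Data frame from \code{\link{mutation_points}}.
#' @param width Map width in characters (default 80).
#' @return Character vector of lines.
#' @export
render_region_map <- function(gene, regions, points, width = 80L) {
  lc <- nchar(gene$cds)
  lo <- min(0L, vapply(regions, `[[`, numeric(1), "start"))
  hi <- max(lc, vapply(regions, `[[`, numeric(1), "end"))
  span <- hi - lo
  col <- function(bp) {
    1L + as.integer(round((bp - lo) / span * (width - 1L)))
  }
  blank <- function() rep(" ", width)
  lines <- character(0)

  ruler <- blank()
  for (bp in pretty(c(lo, hi), n = 5L)) {
    if (bp < lo || bp > hi) next
    lab <- format(as.integer(bp))
    at <- min(col(bp), width - nchar(lab) + 1L)
    ruler[seq(at, at + nchar(lab) - 1L)] <- strsplit(lab, "")[[1]]
  }
  lines <- c(lines, paste(ruler, collapse = ""))

  gene_line <- blank()
  gene_line[col(0L):col(lc)] <- "="
  g_lab <- sprintf("[%s %d bp]", gene$gene_id, lc)
  lines <- c(lines, paste(paste(gene_line, collapse = ""), g_lab))

  for (r in regions) {
    rl <- blank()
    rl[col(r$start):col(r$end)] <- "#"
    lines <- c(lines, paste0(paste(rl, collapse = ""),
                             sprintf(" region %d [%d, %d)",
                                     r$cluster_index, r$start, r$end)))
  }
  ml <- blank()
  for (i in seq_len(nrow(points))) ml[col(points$pos[i])] <- "*"
  lines <- c(lines, paste(ml, collapse = ""))
  for (lab in unique(points$label)) {
    at <- col(min(points$pos[points$label == lab]))
    ll <- blank()
    txt <- strsplit(lab, "")[[1]]
    at <- min(at, width - length(txt) + 1L)
    ll[seq(at, at + length(txt) - 1L)] <- txt
    lines <- c(lines, paste(ll, collapse = ""))
  }
  lines
}
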