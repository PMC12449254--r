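# Synthetic validation: random genes and mutation panels with a
# controlled-length insertion, deletion, or paired mutation; the sweep
# reports the fraction of panels for which a complete fragment design
# exists under the given provider limits.

non_stop_codons <- function() sort(names(GENETIC_CODE_1)[GENETIC_CODE_1 != "*"])

#' Generate a random gene embedded in a toy circular plasmid
#'
#' The CDS is \code{ATG}, then uniformly drawn non-stop codons, then
#' \code{TAA}, inserted into a random 2 kb backbone to form a circular toy
#' plasmid. Deterministic per seed. The CDS is guaranteed to occur uniquely
#' on the plasmid (regenerated otherwise).
#'
#' @param n_codons Number of codons including start and stop (>= 50).
#' @param seed Integer seed.
#' @param backbone_bp Backbone length in bp (default 2000).
#' @return List with \code{plasmid} (a \code{\link{plasmid}}) and
#'   \code{gene} (a \code{gene_context}).
#' @export
random_gene <- function(n_codons, seed, backbone_bp = 2000L) {
  stopifnot(n_codons >= 50L)
  with_seed(seed, {
    for (attempt in 1:10) {
      cds <- paste0("ATG",
                    paste(sample(non_stop_codons(), n_codons - 2L, replace = TRUE),
                          collapse = ""),
                    "TAA")
      bb <- paste(sample(DNA_ALPHABET, backbone_bp, replace = TRUE), collapse = "")
      at <- backbone_bp %/% 2L
      pl <- plasmid(sprintf("toy%d", seed),
                    paste0(substr(bb, 1L, at), cds,
                           substr(bb, at + 1L, backbone_bp)))
      gene <- tryCatch(locate_gene(pl, list(gene_id = sprintf("gene%d", seed),
                                            cds = cds)),
                       error = function(e) NULL)
      if (!is.null(gene)) return(list(plasmid = pl, gene = gene))
    }
    stop("failed to build a toy plasmid with a unique gene placement",
         call. = FALSE)
  })
}

#' Build a random test panel
#'
#' Five random point mutations (random target amino acid different from the
#' wild type) plus one controlled-length variant: a deletion of
#' \code{variant_length} residues, an insertion of \code{variant_length}
#' random residues, or a combined pair of point mutations exactly
#' \code{variant_length} residues apart. All residues involved are
#' distinct.
#'
#' @param gene_set Result of \code{\link{random_gene}}.
#' @param variant_type One of \code{"deletion"}, \code{"insertion"},
#'   \code{"paired"}.
#' @param variant_length Length in residues (deletion/insertion length, or
#'   residue distance between the paired sites).
#' @param seed Integer seed.
#' @param n_points Number of random point mutations (default 5).
#' @return A \code{test_case}: \code{gene_set}, \code{panel} (list of
#'   \code{mutation_spec}), \code{variant_type}, \code{variant_length},
#'   \code{seed}.
#' @export
make_test_case <- function(gene_set, variant_type = c("deletion", "insertion", "paired"),
                           variant_length, seed, n_points = 5L) {
  variant_type <- match.arg(variant_type)
  gene <- gene_set$gene
  nres <- gene$n_codons
  prot <- translate_codons(gene$cds)
  with_seed(seed, {
    # the controlled variant first, then points avoiding its residues
    L <- as.integer(variant_length)
    if (variant_type == "deletion") {
      if (L > nres - 10L) stop("gene too short for a deletion of ", L,
                               " residues", call. = FALSE)
      first <- sample(2:(nres - L), 1L)
      variant <- parse_mutation(sprintf("del%d-%d", first, first + L - 1L))
      used <- seq(first, first + L - 1L)
    } else if (variant_type == "insertion") {
      anchor <- sample(2:(nres - 1L), 1L)
      pep <- paste(sample(AA_LETTERS, L, replace = TRUE), collapse = "")
      variant <- parse_mutation(sprintf("ins%d-%s", anchor, pep))
      used <- anchor
    } else {
      if (L > nres - 3L) stop("gene too short for paired sites ", L,
                              " residues apart", call. = FALSE)
      a <- sample(2:(nres - L - 1L), 1L)
      b <- a + L
      mk <- function(r) {
        wt <- prot[r]
        mut <- sample(setdiff(AA_LETTERS, wt), 1L)
        sprintf("%s%d%s", wt, r, mut)
      }
      variant <- parse_mutation(paste(mk(a), mk(b), sep = "+"))
      used <- c(a, b)
    }
    pool <- setdiff(2:(nres - 1L), used)
    pts <- sort(sample(pool, n_points))
    panel <- c(lapply(pts, function(r) {
      wt <- prot[r]
      mut <- sample(setdiff(AA_LETTERS, wt), 1L)
      parse_mutation(sprintf("%s%d%s", wt, r, mut))
    }), list(variant))
    structure(list(gene_set = gene_set, panel = panel,
                   variant_type = variant_type, variant_length = L,
                   seed = seed),
              class = "test_case")
  })
}

#' Can a complete fragment design be produced for a test case?
#'
#' Runs clustering, region definition, mutagenesis, flank design, marker
#' placement and fragment assembly for the whole panel; \code{TRUE} iff no
#' stage reports a design failure. Deterministic for a given case and
#' settings.
#'
#' @param case A \code{test_case}.
#' @param settings A \code{\link{design_settings}}.
#' @param table Optional \code{codon_usage} table; defaults to the usage of
#'   the case's own gene.
#' @return Logical.
#' @export
is_designable <- function(case, settings = design_settings(), table = NULL) {
  p <- case$gene_set$plasmid
  gene <- case$gene_set$gene
  if (is.null(table)) table <- compute_codon_usage(gene$cds, gene$gene_id)
  tryCatch({
    muts <- validate_mutations(case$panel, gene)
    points <- mutation_points(muts, gene)
    cands <- find_valid_clusterings(points, settings)
    sel <- select_clustering(cands, settings$optimization_mode)
    design_fragments(p, gene, muts, sel, table, settings)
    TRUE
  }, error = function(e) FALSE)
}

#' Closed-form designability bound for a controlled variant
#'
#' Whether the controlled variant of a test panel can, on geometric grounds
#' alone, be placed in a valid fragment under the size limits. The random
#' point mutations of a panel never change the answer: they can always be
#' isolated in their own minimum-size fragments. A deletion shrinks the
#' mutant fragment (the wild-type region grows but the synthesized molecule
#' stays at the minimum length), so deletions are never blocked by the
#' provider maximum; an insertion adds 3L bp on top of the minimum region;
#' paired sites L residues apart span 3(L+1) bp of wild-type sequence.
#'
#' @param variant_type \code{"deletion"}, \code{"insertion"} or
#'   \code{"paired"}.
#' @param variant_length Variant length in residues.
#' @param settings A \code{\link{design_settings}}.
#' @return Logical.
#' @export
designable_bound <- function(variant_type, variant_length,
                             settings = design_settings()) {
  L <- as.integer(variant_length)
  core <- core_min_bp(settings)
  cmax <- core_max_bp(settings)
  switch(variant_type,
    deletion = core <= cmax,
    insertion = core + 3L * L <= cmax,
    paired = max(3L * (L + 1L), core) <= cmax)
}

#' Sweep design success rates over variant lengths
#'
#' For every combination of variant type and length, \code{genes}
#' independent random genes times \code{replicates} random panels are
#' generated (with seeds derived from \code{base_seed}) and the fraction of
#' designable cases is reported.
#'
#' @param types Character vector of variant types.
#' @param lengths Integer vector of variant lengths (residues).
#' @param genes Number of random genes (default 3).
#' @param replicates Panels per gene and condition (default 10).
#' @param n_codons Gene length in codons (default 800).
#' @param base_seed Base seed for the whole sweep.
#' @param settings A \code{\link{design_settings}}.
#' @return Data frame (class \code{sweep_result}): \code{variant_type},
#'   \code{variant_length}, \code{n_total}, \code{n_designable},
#'   \code{success_rate}; attribute \code{base_seed}.
#' @export
run_sweep <- function(types = c("deletion", "insertion", "paired"),
                      lengths = seq(1L, 600L, by = 5L),
                      genes = 3L, replicates = 10L, n_codons = 800L,
                      base_seed = 42L, settings = design_settings()) {
  gene_sets <- lapply(seq_len(genes), function(g) {
    random_gene(n_codons, derive_seed(base_seed, 101L, g))
  })
  tables <- lapply(gene_sets, function(gs) {
    compute_codon_usage(gs$gene$cds, gs$gene$gene_id)
  })
  rows <- list()
  for (ty in types) {
    tcode <- match(ty, c("deletion", "insertion", "paired"))
    for (L in lengths) {
      ok <- 0L
      total <- 0L
      for (g in seq_len(genes)) {
        for (r in seq_len(replicates)) {
          case <- make_test_case(gene_sets[[g]], ty, L,
                                 derive_seed(base_seed, tcode, L, g, r))
          total <- total + 1L
          if (is_designable(case, settings, tables[[g]])) ok <- ok + 1L
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variant_type = ty, variant_length = L, n_total = total,
        n_designable = ok, success_rate = ok / total,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "base_seed") <- base_seed
  class(out) <- c("sweep_result", class(out))
  out
}

#' Write a sweep result as TSV
#'
#' A provenance header records the base seed.
#'
#' @param sweep A \code{sweep_result}.
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
write_sweep_tsv <- function(sweep, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# base_seed: %d", attr(sweep, "base_seed")), con)
  utils::write.table(as.data.frame(sweep), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
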