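# A fully synthetic stand-in for a realistic structure-guided mutagenesis
# campaign on a large bacterial gene: 24 mutations (18 point, 4 combined
# doubles, 2 deletions) concentrated in three functional hot-spot windows
# of a 1500-codon gene, the layout typical of active-site scanning on a
# replicative DNA polymerase. All sequences are random (labelled synthetic
# throughout); no real gene or published mutation list is reproduced here.

#' Synthetic large-gene case study
#'
#' Builds a synthetic 1500-codon gene on a toy plasmid together with a
#' 24-mutation panel (18 point mutations, 4 double mutations, 2 deletions)
#' whose sites are drawn from three hot-spot windows separated by long
#' unmutated stretches, emulating a structure-guided mutant library on a
#' large gene. Deterministic per seed.
#'
#' @param seed Integer seed (default 7).
#' @return List with \code{plasmid}, \code{gene}, \code{panel} (list of 24
#'   \code{mutation_spec}), and \code{windows} (the three hot-spot residue
#'   windows).
#' @export
synthetic_case_study <- function(seed = 7L) {
  gs <- random_gene(1500L, derive_seed(seed, 1L), backbone_bp = 2400L)
  gene <- gs$gene
  prot <- translate_codons(gene$cds)
  windows <- list(c(100L, 200L), c(700L, 800L), c(1300L, 1400L))
  with_seed(derive_seed(seed, 2L), {
    draw_res <- function(win, n, used) {
      pool <- setdiff(seq(win[1], win[2]), used)
      sort(sample(pool, n))
    }
    mk_point <- function(r) {
      wt <- prot[r]
      sprintf("%s%d%s", wt, r, sample(setdiff(AA_LETTERS, wt), 1L))
    }
    used <- integer(0)
    labels <- character(0)
    # 6 points per window
    for (w in windows) {
      rs <- draw_res(w, 6L, used)
      used <- c(used, rs)
      labels <- c(labels, vapply(rs, mk_point, character(1)))
    }
    # 4 doubles: both sites within one window (sites 10-40 residues apart)
    for (w in windows[c(1L, 2L, 3L, 1L)]) {
      a <- draw_res(c(w[1], w[2] - 40L), 1L, used)
      gap <- sample(10:40, 1L)
      b <- a + gap
      while (b %in% used) b <- b + 1L
      used <- c(used, a, b)
      labels <- c(labels, paste(mk_point(a), mk_point(b), sep = "+"))
    }
    # 2 deletions of 4-8 residues, one in window 2, one in window 3
    for (w in windows[c(2L, 3L)]) {
      len <- sample(4:8, 1L)
      a <- draw_res(c(w[1], w[2] - len), 1L, used)
      while (any(seq(a, a + len - 1L) %in% used)) a <- a + 1L
      used <- c(used, seq(a, a + len - 1L))
      labels <- c(labels, sprintf("del%d-%d", a, a + len - 1L))
    }
    panel <- lapply(labels, parse_mutation)
    list(plasmid = gs$plasmid, gene = gene,
         panel = validate_mutations(panel, gene), windows = windows)
  })
}

#' Write the synthetic case study inputs to files
#'
#' Convenience helper producing the three input files (plasmid GenBank,
#' gene FASTA, mutation list) for use with \code{\link{design_run}} or the
#' command-line interface.
#'
#' @param dir Output directory.
#' @param seed Passed to \code{\link{synthetic_case_study}}.
#' @return Named list of file paths.
#' @export
write_case_study_inputs <- function(dir, seed = 7L) {
  cs <- synthetic_case_study(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(plasmid = file.path(dir, "synthetic_plasmid.gb"),
                gene = file.path(dir, "synthetic_gene.fasta"),
                mutations = file.path(dir, "mutations.txt"))
  write_genbank(cs$plasmid, paths$plasmid)
  writeLines(c(paste0(">", cs$gene$gene_id), cs$gene$cds), paths$gene)
  writeLines(c("# synthetic 24-mutation panel",
               vapply(cs$panel, `[[`, character(1), "label")),
             paths$mutations)
  paths
}
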