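# Shared fixtures: small deterministic plasmids, genes and codon tables
# built in code (no stored binary data).

# a fixed 60-codon gene embedded mid-backbone in a 700 bp toy plasmid
toy_gene_set <- function(seed = 101L, n_codons = 60L, backbone_bp = 700L) {
  random_gene(n_codons, seed, backbone_bp = backbone_bp)
}

toy_codon_table <- function(gene_set) {
  compute_codon_usage(gene_set$gene$cds, "toy")
}

# codon table covering every amino acid (uniform over the standard code),
# standing in for a full expression-organism usage table
rich_codon_table <- function() {
  compute_codon_usage(paste(names(Biostrings::GENETIC_CODE), collapse = ""),
                      "uniform")
}

# minimal hand-built plasmid with a known gene at a known offset
fixed_plasmid_and_gene <- function() {
  cds <- paste0(
    "ATG",
    "GCA", "CTG", "AAA", "GAA", "TTT", "GGC", "CAT", "ATT", "CTG",
    "GCA", "CTG", "AAA", "GAA", "TTT", "GGC", "CAT", "ATT", "AGC",
    "TAA")
  up <- "TTGACAGCTAGCTCAGTCCTAGGTATAATGCTAGC"
  down <- "CGCTGAGCAATAACTAGCATAACCCCTTGGGGCCT"
  p <- plasmid("pToy", paste0(up, cds, down))
  gene <- locate_gene(p, list(gene_id = "toyGene", cds = cds))
  list(plasmid = p, gene = gene, cds = cds)
}

# write a mutation list file and return its path
write_mutfile <- function(lines) {
  path <- tempfile("muts", fileext = ".txt")
  writeLines(lines, path)
  path
}

# protein-level edit oracle: apply a mutation spec directly to the
# wild-type protein (independent of the DNA-level pipeline)
expected_protein <- function(prot, spec) {
  if (spec$kind == "point") {
    prot[spec$res] <- spec$mut
  } else if (spec$kind == "combined") {
    for (pt in spec$members) prot[pt$res] <- pt$mut
  } else if (spec$kind == "deletion") {
    prot <- prot[-seq(spec$first, spec$last)]
  } else if (spec$kind == "insertion") {
    prot <- append(prot, strsplit(spec$peptide, "")[[1]], after = spec$anchor)
  }
  prot
}

# extract the mutant CDS (coding strand) from a mutant plasmid, given the
# wild-type gene context and the net bp change
mutant_cds <- function(mut_plasmid, gene, net) {
  lc <- nchar(gene$cds) + net
  s <- mut_plasmid$sequence
  n <- nchar(s)
  if (gene$strand == "+") {
    fraglib:::circular_subseq(s, gene$plasmid_offset, gene$plasmid_offset + lc)
  } else {
    fraglib:::revcomp(
      fraglib:::circular_subseq(s, gene$plasmid_offset, gene$plasmid_offset + lc))
  }
}
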