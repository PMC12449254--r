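settings <- design_settings()

test_that("regions are codon-aligned, centered, and shifted at CDS boundaries", {
  gs <- toy_gene_set(seed = 61L, n_codons = 1200L, backbone_bp = 1000L)
  prot <- translate_codons_test(gs$gene$cds)
  mk <- function(r) sprintf("%s%d%s", prot[r], r, if (prot[r] == "A") "G" else "A")

  # single interior point: 270 bp region centered on its codon
  specs <- validate_mutations(list(parse_mutation(mk(500))), gs$gene)
  pts <- mutation_points(specs, gs$gene)
  reg <- define_region(pts, gs$gene, settings)
  expect_equal(reg$end - reg$start, 270L)
  expect_equal(reg$start %% 3L, 0L)
  expect_true(reg$start <= 3 * 499 && 3 * 500 <= reg$end)
  mid <- (reg$start + reg$end) / 2
  expect_lt(abs(mid - (3 * 499 + 1.5)), 3)

  # point at residue 2: region pinned to the CDS start
  specs2 <- validate_mutations(list(parse_mutation(mk(2))), gs$gene)
  reg2 <- define_region(mutation_points(specs2, gs$gene), gs$gene, settings)
  expect_equal(c(reg2$start, reg2$end), c(0L, 270L))

  # 100-residue deletion: region grows so the mutant keeps the minimum length
  del <- validate_mutations(list(parse_mutation("del500-599")), gs$gene)
  reg3 <- define_region(mutation_points(del, gs$gene), gs$gene, settings)
  expect_gte(reg3$end - reg3$start, 570L)
})

test_that("short genes spill regions into the backbone, keeping codon phase", {
  gs <- toy_gene_set(seed = 62L, n_codons = 60L, backbone_bp = 700L)  # 180 bp CDS
  prot <- translate_codons_test(gs$gene$cds)
  specs <- validate_mutations(
    list(parse_mutation(sprintf("%s30A", prot[30]))), gs$gene)
  reg <- define_region(mutation_points(specs, gs$gene), gs$gene, settings)
  expect_equal(reg$end - reg$start, 270L)
  expect_true(reg$start < 0L || reg$end > 180L)
  expect_equal(reg$start %% 3L, 0L)
  # the extracted region sequence matches the plasmid around the gene
  seq <- fraglib:::frame_subseq(gs$plasmid, gs$gene, reg$start, reg$end)
  expect_equal(nchar(seq), 270L)
  cds_part <- fraglib:::frame_subseq(gs$plasmid, gs$gene, 0L, 180L)
  expect_equal(cds_part, gs$gene$cds)
})

test_that("apply_mutations edits codons as the usage table dictates", {
  fx <- fixed_plasmid_and_gene()
  tab <- compute_codon_usage(c("ATGGGCGGCGGATAA"), "toy")  # Gly argmax GGC
  gene <- fx$gene
  region <- structure(list(start = 0L, end = nchar(fx$cds), cluster_index = 1L,
                           mutations = "x", max_net = 0L),
                      class = "fragment_region")
  # A2G with Gly argmax GGC
  spec <- validate_mutations(list(parse_mutation("A2G")), gene)
  ap <- apply_mutations(region, spec, fx$plasmid, gene, tab)
  expect_equal(substr(ap$seq, 4, 6), "GGC")
  expect_equal(sum(ap$codon_map$mutated), 1L)

  # deletion of 3 residues: exactly 9 bp shorter
  del <- validate_mutations(list(parse_mutation("del4-6")), gene)
  apd <- apply_mutations(region, del, fx$plasmid, gene, tab)
  expect_equal(nchar(apd$seq), nchar(fx$cds) - 9L)

  # no mutations: identity
  ap0 <- apply_mutations(region, list(), fx$plasmid, gene, tab)
  expect_equal(ap0$seq, fx$cds)

  # insertion: peptide encoded with most frequent codons after the anchor
  ins <- validate_mutations(list(parse_mutation("ins3-GG")), gene)
  api <- apply_mutations(region, ins, fx$plasmid, gene, tab)
  expect_equal(substr(api$seq, 10, 15), "GGCGGC")
  expect_equal(nchar(api$seq), nchar(fx$cds) + 6L)
})

test_that("flanks are exact plasmid subsequences tuned into the Tm window", {
  gs <- toy_gene_set(seed = 63L, n_codons = 400L, backbone_bp = 900L)
  for (side in c("5prime", "3prime")) {
    fl <- design_flank(gs$plasmid, gs$gene, 300L, side, settings)
    expect_gte(nchar(fl), settings$min_flank_bp)
    tm <- attr(fl, "tm")
    if (is.null(attr(fl, "warning"))) {
      expect_gte(tm, settings$flank_tm_window[1])
      expect_lte(tm, settings$flank_tm_window[2])
    }
    # exact wild-type subsequence abutting the boundary
    ref <- if (side == "5prime") {
      fraglib:::frame_subseq(gs$plasmid, gs$gene, 300L - nchar(fl), 300L)
    } else {
      fraglib:::frame_subseq(gs$plasmid, gs$gene, 300L, 300L + nchar(fl))
    }
    expect_identical(as.character(fl), ref)
  }
})

test_that("AT-rich context extends the flank beyond the minimum length", {
  # all-A plasmid region: a 15-mer poly-A melts far below 47 C
  expect_lt(melting_temperature(strrep("A", 15)), 47)
  p <- plasmid("pA", paste0(strrep("A", 120), "ATGGCATAA", strrep("A", 120)))
  gene <- locate_gene(p, "ATGGCATAA")
  fl <- design_flank(p, gene, 0L, "5prime", settings)
  expect_gt(nchar(fl), settings$min_flank_bp)
})

test_that("silent markers toggle codons without touching the protein", {
  # a run of Ala codons with usage {GCA, GCG}: ends toggle GCA -> GCG
  cds <- paste0("ATG", strrep("GCA", 10), "TAA")
  p <- plasmid("pAla", paste0(strrep("ACGT", 30), cds, strrep("TGCA", 30)))
  gene <- locate_gene(p, cds)
  tab <- compute_codon_usage("ATGGCAGCAGCGGAATAA", "toy")
  region <- structure(list(start = 0L, end = nchar(cds), cluster_index = 1L,
                           mutations = character(0), max_net = 0L),
                      class = "fragment_region")
  ap <- apply_mutations(region, list(), p, gene, tab)
  marked <- place_silent_markers(ap, tab, settings)
  mk <- marked$silent_markers
  expect_equal(nrow(mk), 4L)
  # ATG (Met) at codon 1 and TAA are skipped; scan moves inward
  expect_equal(mk$codon_index, c(2L, 3L, 10L, 11L))
  expect_equal(unique(mk$wt_codon), "GCA")
  expect_equal(unique(mk$new_codon), "GCG")
  expect_equal(translate_codons_test(marked$seq), translate_codons_test(cds))
})

test_that("fragment assembly enforces the provider length window exactly", {
  region <- structure(list(start = 0L, end = 270L, cluster_index = 1L,
                           mutations = "m", max_net = 0L),
                      class = "fragment_region")
  fake_applied <- function(len) {
    list(seq = strrep("A", len),
         codon_map = data.frame(), pre_len = 0L, post_len = 0L,
         silent_markers = data.frame(codon_index = integer(0),
                                     wt_codon = character(0),
                                     new_codon = character(0)))
  }
  fl <- strrep("G", 15)
  ok <- assemble_fragment("f", region, fake_applied(1470), fl, fl, settings)
  expect_equal(nchar(ok$full_seq), 1500L)
  expect_equal(ok$cost, 1500 * settings$cost_per_bp)
  expect_error(
    assemble_fragment("f", region, fake_applied(1471), fl, fl, settings),
    "outside provider range")
  expect_error(
    assemble_fragment("f", region, fake_applied(100), strrep("G", 15),
                      strrep("G", 15), settings),
    "outside provider range")
})

test_that("designed fragments carry faithful flank homology and protein edits", {
  set.seed(64)
  for (i in 1:8) {
    gs <- toy_gene_set(seed = 7000L + i, n_codons = 350L, backbone_bp = 900L)
    tab <- rich_codon_table()
    specs <- random_mixed_panel(gs, seed = 7100L + i, max_specs = 4L)
    pts <- mutation_points(specs, gs$gene)
    sel <- tryCatch(
      select_clustering(find_valid_clusterings(pts, settings), "quantity"),
      error = function(e) NULL)
    if (is.null(sel)) next
    d <- design_fragments(gs$plasmid, gs$gene, specs, sel, tab, settings)
    expect_length(d$fragments, length(specs))
    wt_prot <- translate_codons_test(gs$gene$cds)
    doubled <- paste0(gs$plasmid$sequence, gs$plasmid$sequence)
    for (fr in d$fragments) {
      len <- nchar(fr$full_seq)
      expect_gte(len, settings$min_fragment_bp)
      expect_lte(len, settings$max_fragment_bp)
      expect_equal(fr$cost, len * settings$cost_per_bp)
      # flank homology: both flanks are exact plasmid subsequences
      for (fl in c(fr$flank5, fr$flank3)) {
        expect_gte(nchar(fl), settings$min_flank_bp)
        expect_true(grepl(fl, doubled, fixed = TRUE) ||
                    grepl(fraglib:::revcomp(fl), doubled, fixed = TRUE))
      }
      # protein-level fidelity through the full mutant plasmid
      mut <- fraglib:::build_mutant_plasmid(gs$plasmid, gs$gene, fr)
      spec_lab <- sub("^.*_r[0-9]+_", "", fr$name)
      this <- specs[[which(gsub("[^A-Za-z0-9+-]", "",
                                vapply(specs, `[[`, character(1), "label")) ==
                           spec_lab)]]
      cds2 <- mutant_cds(mut, gs$gene, fraglib:::net_indel_bp(this))
      expect_equal(translate_codons_test(cds2),
                   expected_protein(wt_prot, this))
    }
  }
})
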