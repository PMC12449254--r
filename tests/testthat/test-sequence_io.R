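test_that("mutation grammar parses every kind and rejects malformed input", {
  pt <- parse_mutation("L123A")
  expect_equal(pt$kind, "point")
  expect_equal(pt[c("wt", "res", "mut")], list(wt = "L", res = 123L, mut = "A"))

  cb <- parse_mutation("G45D+S210R")
  expect_equal(cb$kind, "combined")
  expect_length(cb$members, 2L)
  expect_equal(cb$members[[2]]$res, 210L)

  dl <- parse_mutation("del70-75")
  expect_equal(dl$kind, "deletion")
  expect_equal(c(dl$first, dl$last), c(70L, 75L))

  ins <- parse_mutation("ins12-GSGS")
  expect_equal(ins$kind, "insertion")
  expect_equal(ins$anchor, 12L)
  expect_equal(ins$peptide, "GSGS")

  expect_error(parse_mutation("del75-70"), "first > last")
  expect_error(parse_mutation("L123"), "malformed")
  expect_error(parse_mutation("X123A"), "malformed")
  expect_error(parse_mutation("ins5-GXZ"), "malformed|invalid")
})

test_that("mutation files skip comments, keep labels, reject duplicates", {
  path <- write_mutfile(c("# panel one", "L3A", "", "del5-7", "L3A"))
  expect_error(parse_mutation_file(path), "duplicate.*L3A")
  path2 <- write_mutfile(c("# ok", "L3A", "K4E+F6W"))
  specs <- parse_mutation_file(path2)
  expect_equal(vapply(specs, `[[`, character(1), "label"), c("L3A", "K4E+F6W"))
  bad <- write_mutfile(c("L3A", "whoops!"))
  expect_error(parse_mutation_file(bad), "line 2")
  expect_error(parse_mutation_file(write_mutfile("# only comments")),
               "no mutations")
})

test_that("locate_gene finds unique occurrences on either strand, circularly", {
  fx <- fixed_plasmid_and_gene()
  expect_equal(fx$gene$plasmid_offset, 35L)
  expect_equal(fx$gene$strand, "+")

  # reverse-complemented plasmid: gene on the minus strand
  prc <- plasmid("pToyRC", fraglib:::revcomp(fx$plasmid$sequence))
  generc <- locate_gene(prc, fx$cds)
  expect_equal(generc$strand, "-")
  expect_equal(fraglib:::frame_subseq(prc, generc, 0L, nchar(fx$cds)), fx$cds)

  # duplicated gene -> ambiguity
  pd <- plasmid("pDup", paste0(fx$cds, "ACGTACGTCCTA", fx$cds))
  expect_error(locate_gene(pd, fx$cds), "2 times")
  # absent gene
  expect_error(locate_gene(plasmid("pE", strrep("ACGT", 50)), fx$cds),
               "not found")
})

test_that("locate_gene recovers construction offsets over random instances", {
  set.seed(400)
  for (i in 1:15) {
    n_codons <- sample(50:120, 1)
    gs <- random_gene(n_codons, seed = 1000L + i,
                      backbone_bp = sample(300:900, 1))
    # wrap the origin through a random rotation
    rot <- sample(0:(nchar(gs$plasmid$sequence) - 1L), 1)
    seq_rot <- fraglib:::circular_subseq(gs$plasmid$sequence, rot,
                                         rot + nchar(gs$plasmid$sequence))
    g2 <- locate_gene(plasmid("rot", seq_rot), gs$gene$cds)
    expect_equal(fraglib:::frame_subseq(plasmid("rot", seq_rot), g2,
                                        0L, nchar(gs$gene$cds)),
                 gs$gene$cds)
  }
})

test_that("validate_mutations agrees with an independent translation oracle", {
  fx <- fixed_plasmid_and_gene()
  prot <- translate_codons_test(fx$cds)
  # accepted: correct wild-type amino acids
  ok <- lapply(c(sprintf("%s2K", prot[2]), sprintf("%s5W+%s9D", prot[5], prot[9]),
                 "del4-6", "ins3-GG"), parse_mutation)
  expect_identical(validate_mutations(ok, fx$gene), ok)
  # rejected: wrong wild type, naming the found residue
  wrong_wt <- setdiff(c("A", "L", "K"), prot[2])[1]
  expect_error(validate_mutations(list(parse_mutation(sprintf("%s2K", wrong_wt))),
                                  fx$gene),
               paste0("encodes ", prot[2]))
  expect_error(validate_mutations(list(parse_mutation("del1-9999")), fx$gene),
               "outside gene")
  expect_error(validate_mutations(list(parse_mutation("A9999C")), fx$gene),
               "outside gene")
})

test_that("GenBank write/read round-trips sequence and feature intervals", {
  fx <- fixed_plasmid_and_gene()
  p <- fx$plasmid
  p$features <- data.frame(type = c("CDS", "misc_feature"),
                           label = c("toyGene", "markerX"),
                           start = c(35L, 3L), end = c(35L + nchar(fx$cds), 9L),
                           strand = c("+", "-"), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".gb")
  write_genbank(p, path)
  q <- read_genbank(path)
  expect_equal(q$sequence, p$sequence)
  expect_true(q$circular)
  expect_equal(q$features[c("type", "label", "start", "end", "strand")],
               p$features[c("type", "label", "start", "end", "strand")])
  # writing again reproduces identical bytes (fixed LOCUS date)
  path2 <- tempfile(fileext = ".gb")
  write_genbank(q, path2)
  expect_identical(readLines(path), readLines(path2))
  expect_error(read_genbank(tempfile(fileext = ".dna")), "SnapGene")
})

test_that("order sheet follows the 96-well row-major plate layout and costs", {
  fake_frag <- function(name, len) {
    structure(list(name = name, full_seq = strrep("A", len)), class = "fragment")
  }
  frags <- lapply(1:97, function(i) fake_frag(sprintf("f%02d", i), 300))
  s <- design_settings(cost_per_bp = 0.05)
  path <- tempfile(fileext = ".csv")
  sheet <- write_order_sheet(frags, list(), s, path)
  expect_equal(sheet$well[1:3], c("A1", "A2", "A3"))
  expect_equal(sheet$well[13], "B1")     # row-major: 12 columns per row
  expect_equal(sheet$plate[96], 1L)
  expect_equal(sheet$well[96], "H12")
  expect_equal(sheet$plate[97], 2L)
  expect_equal(sheet$well[97], "A1")
  expect_equal(sheet$cost[1], 300 * 0.05)
  expect_true(file.exists(path))
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 97L)
})

test_that("a point-mutant GenBank differs from wild type at exactly the mutated codon plus the marker codons", {
  gs <- toy_gene_set(seed = 505L, n_codons = 120L)
  tab <- toy_codon_table(gs)
  gene <- gs$gene
  prot <- translate_codons_test(gene$cds)
  spec <- validate_mutations(list(parse_mutation(sprintf("%s60W", prot[60]))),
                             gene)
  sel <- select_clustering(
    find_valid_clusterings(mutation_points(spec, gene), design_settings()),
    "quantity")
  d <- design_fragments(gs$plasmid, gene, spec, sel, tab, design_settings())
  fr <- d$fragments[[1]]
  path <- tempfile(fileext = ".gb")
  mut <- write_mutant_genbank(gs$plasmid, gene, fr, list(), path)
  back <- read_genbank(path)
  expect_identical(back$sequence, mut$sequence)
  expect_equal(nchar(mut$sequence), nchar(gs$plasmid$sequence))  # no indel

  a <- strsplit(gs$plasmid$sequence, "")[[1]]
  b <- strsplit(mut$sequence, "")[[1]]
  diffs <- which(a != b)
  # map differing positions to residue numbers (plus strand, no indel)
  res_of <- (diffs - gene$plasmid_offset - 1L) %/% 3L + 1L
  marker_res <- fr$codon_map$orig_res[fr$codon_map$marker]
  expect_setequal(unique(res_of), c(60L, marker_res))
  expect_length(marker_res, 4L)  # two silent markers per end by default
})
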