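settings <- design_settings()

test_that("mutation points use codon-aligned extents and representative positions", {
  fx <- toy_gene_set(seed = 11L, n_codons = 200L)
  prot <- translate_codons_test(fx$gene$cds)
  specs <- validate_mutations(lapply(
    c(sprintf("%s1%s", prot[1], if (prot[1] == "A") "G" else "A"),
      "del10-20", "ins5-WW",
      sprintf("%s30A+%s80C", prot[30], prot[80])), parse_mutation), fx$gene)
  pts <- mutation_points(specs, fx$gene)
  # point at residue 1: extent [0,3), position 1
  expect_equal(unlist(pts[1, c("ext_start", "ext_end", "pos")]),
               c(ext_start = 0, ext_end = 3, pos = 1))
  # deletion 10-20: extent [27,60), floor midpoint 43
  expect_equal(unlist(pts[2, c("ext_start", "ext_end", "pos", "net")]),
               c(ext_start = 27, ext_end = 60, pos = 43, net = -33))
  # insertion after residue 5: insertion point at bp 15, anchor codon covered
  expect_equal(unlist(pts[3, c("ext_start", "ext_end", "pos", "net")]),
               c(ext_start = 12, ext_end = 15, pos = 15, net = 6))
  # combined: one row per member, same group id
  expect_equal(pts$group[4:5], c(1L, 1L))
  expect_equal(pts$pos[4:5], c(3 * 29 + 1, 3 * 79 + 1))
})

test_that("constrained distances shrink only within combined groups", {
  pts <- data.frame(label = c("a", "b+c", "b+c"), member = c("a", "b", "c"),
                    pos = c(100, 400, 700), ext_start = c(99, 399, 699),
                    ext_end = c(102, 402, 702), net = 0L,
                    group = c(NA, 1L, 1L))
  d <- constrained_distance_matrix(pts)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), rep(0, 3))
  expect_equal(d[1, 2], 300)        # unpaired: plain bp distance
  expect_equal(d[2, 3], 300 * 0.01) # paired: shrunk
  expect_equal(constrained_distance_matrix(pts[1, ]), matrix(0, 1, 1))
})

test_that("PAM assignments hit the trivial and well-separated cases", {
  pos <- c(0, 10, 1000, 1010)
  pts <- data.frame(label = letters[1:4], member = letters[1:4], pos = pos,
                    ext_start = pos, ext_end = pos + 3, net = 0L,
                    group = NA_integer_)
  d <- constrained_distance_matrix(pts)
  expect_equal(cluster_k(d, 1L), rep(1L, 4))
  expect_equal(length(unique(cluster_k(d, 4L))), 4L)
  a2 <- cluster_k(d, 2L)
  expect_equal(a2[1], a2[2])
  expect_equal(a2[3], a2[4])
  expect_false(a2[1] == a2[3])
  expect_error(cluster_k(d, 5L), "k must be")
  # determinism
  expect_identical(cluster_k(d, 2L), cluster_k(d, 2L))
})

test_that("cluster geometry reproduces the worked size-limit cases", {
  g1 <- fraglib:::cluster_geometry(0L, 3L, 0L, settings)   # single point
  expect_equal(g1$implied_len, 300L)
  expect_true(g1$valid)
  # two points spanning exactly the interior ceiling: 1470 + 30 = 1500
  g2 <- fraglib:::cluster_geometry(c(0L, 1467L), c(3L, 1470L), c(0L, 0L), settings)
  expect_equal(g2$implied_len, 1500L)
  expect_true(g2$valid)
  # three bp more: invalid
  g3 <- fraglib:::cluster_geometry(c(0L, 1470L), c(3L, 1473L), c(0L, 0L), settings)
  expect_false(g3$valid)
  # a 100-residue deletion forces the region up to 570 bp
  g4 <- fraglib:::cluster_geometry(0L, 300L, -300L, settings)
  expect_equal(g4$region_needed, 570L)
  expect_true(g4$valid)
})

test_that("find_valid_clusterings enumerates and errors as the size rules dictate", {
  gs <- toy_gene_set(seed = 21L, n_codons = 1400L, backbone_bp = 1000L)
  prot <- translate_codons_test(gs$gene$cds)
  mk <- function(r) sprintf("%s%d%s", prot[r], r, if (prot[r] == "A") "G" else "A")
  # three mutations: two close, one far (not coverable by a single region)
  specs <- validate_mutations(lapply(c(mk(34), mk(50), mk(1167)), parse_mutation),
                              gs$gene)
  pts <- mutation_points(specs, gs$gene)
  cands <- find_valid_clusterings(pts, settings)
  ks <- vapply(cands, `[[`, numeric(1), "k")
  expect_false(1 %in% ks)   # span ~3.4 kb cannot fit 1500 bp
  expect_true(2 %in% ks)
  sel <- select_clustering(cands, "quantity")
  expect_equal(sel$n_fragments, 2L)

  # a combined pair 600 residues apart can never co-cluster
  far <- validate_mutations(list(parse_mutation(paste(mk(30), mk(630), sep = "+"))),
                            gs$gene)
  expect_error(find_valid_clusterings(mutation_points(far, gs$gene), settings),
               "combined mutation")

  # single mutation: exactly one clustering with k = 1
  single <- validate_mutations(list(parse_mutation(mk(700))), gs$gene)
  one <- find_valid_clusterings(mutation_points(single, gs$gene), settings)
  expect_length(one, 1L)
  expect_equal(one[[1]]$k, 1L)
})

test_that("selection trades off fragment count against total length as configured", {
  gs <- toy_gene_set(seed = 22L, n_codons = 600L, backbone_bp = 1000L)
  prot <- translate_codons_test(gs$gene$cds)
  mk <- function(r) sprintf("%s%d%s", prot[r], r, if (prot[r] == "A") "G" else "A")
  # three spread-out points that fit either one large or three small regions
  specs <- validate_mutations(lapply(c(mk(10), mk(240), mk(470)), parse_mutation),
                              gs$gene)
  pts <- mutation_points(specs, gs$gene)
  cands <- find_valid_clusterings(pts, settings)
  q <- select_clustering(cands, "quantity")
  l <- select_clustering(cands, "length")
  oracle <- oracle_enumerate_partitions(pts, settings)
  expect_equal(q$n_fragments, oracle$min_count)
  expect_equal(q$n_fragments, 1L)
  expect_equal(l$total_fragment_bp, 900L)  # three minimum-size fragments
  expect_equal(l$n_fragments, 3L)
  # single candidate returned unchanged
  expect_identical(select_clustering(cands[1], "quantity"), cands[[1]])
  expect_error(select_clustering(list(), "quantity"), "no valid clustering")
})

test_that("combined mutations are co-clustered in every returned clustering", {
  set.seed(99)
  for (i in 1:10) {
    gs <- toy_gene_set(seed = 3000L + i, n_codons = 500L, backbone_bp = 800L)
    specs <- random_mixed_panel(gs, seed = 5000L + i)
    pts <- mutation_points(specs, gs$gene)
    cands <- tryCatch(find_valid_clusterings(pts, settings),
                      error = function(e) list())
    for (cl in cands) {
      for (g in unique(stats::na.omit(pts$group))) {
        expect_length(unique(cl$assignment[pts$group %in% g]), 1L)
      }
    }
  }
})

test_that("relaxing the maximum fragment size never increases the region count", {
  relaxed <- design_settings(max_fragment_bp = 3000L)
  set.seed(31)
  for (i in 1:10) {
    gs <- toy_gene_set(seed = 4000L + i, n_codons = 600L, backbone_bp = 800L)
    specs <- random_mixed_panel(gs, seed = 6000L + i)
    pts <- mutation_points(specs, gs$gene)
    n1 <- tryCatch(select_clustering(find_valid_clusterings(pts, settings),
                                     "quantity")$n_fragments,
                   error = function(e) NA_integer_)
    if (is.na(n1)) next
    n2 <- select_clustering(find_valid_clusterings(pts, relaxed),
                            "quantity")$n_fragments
    expect_lte(n2, n1)
  }
})
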