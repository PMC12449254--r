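# Independent brute-force oracles for the clustering module. These
# re-derive cluster validity from the size rules and enumerate partitions
# exhaustively; they share no search code with the package.

# validity of one cluster of points, derived independently from the rules:
# the shared wild-type region must cover all member extents, be at least
# the interior floor, keep the largest-deletion member's fragment at the
# minimum length, and every member's mutant fragment (region + its net
# indel + two minimal flanks) must fit the provider maximum
oracle_cluster_valid <- function(ext_start, ext_end, net, settings) {
  span <- max(ext_end) - min(ext_start)
  floor_bp <- settings$min_fragment_bp - 2L * settings$min_flank_bp
  region <- max(span, floor_bp, floor_bp - min(net))
  region <- 3L * ceiling(region / 3)
  all(region + net + 2L * settings$min_flank_bp <= settings$max_fragment_bp)
}

oracle_cluster_implied_len <- function(ext_start, ext_end, net, settings) {
  span <- max(ext_end) - min(ext_start)
  floor_bp <- settings$min_fragment_bp - 2L * settings$min_flank_bp
  region <- max(span, floor_bp, floor_bp - min(net))
  3L * ceiling(region / 3) + 2L * settings$min_flank_bp
}

oracle_partition_valid <- function(points, asg, settings) {
  for (c in unique(asg)) {
    idx <- which(asg == c)
    if (!oracle_cluster_valid(points$ext_start[idx], points$ext_end[idx],
                              points$net[idx], settings)) {
      return(FALSE)
    }
  }
  for (g in unique(stats::na.omit(points$group))) {
    if (length(unique(asg[points$group %in% g])) > 1L) return(FALSE)
  }
  TRUE
}

oracle_partition_total_bp <- function(points, asg, settings) {
  sum(vapply(unique(asg), function(c) {
    idx <- which(asg == c)
    oracle_cluster_implied_len(points$ext_start[idx], points$ext_end[idx],
                               points$net[idx], settings)
  }, numeric(1)))
}

# exhaustive enumeration over ALL set partitions (restricted growth
# strings); returns the minimum number of clusters and minimum total bp
# among valid partitions, or NULL when none is valid
oracle_enumerate_partitions <- function(points, settings) {
  n <- nrow(points)
  best_count <- Inf
  best_bp <- Inf
  asg <- integer(n)
  recurse <- function(i, maxc) {
    if (i > n) {
      if (oracle_partition_valid(points, asg, settings)) {
        best_count <<- min(best_count, max(asg))
        best_bp <<- min(best_bp, oracle_partition_total_bp(points, asg, settings))
      }
      return(invisible(NULL))
    }
    for (c in seq_len(maxc + 1L)) {
      asg[i] <<- c
      recurse(i + 1L, max(maxc, c))
    }
  }
  recurse(1L, 0L)
  if (!is.finite(best_count)) return(NULL)
  list(min_count = best_count, min_bp_any = best_bp)
}

# minimum total bp among valid CONTIGUOUS-block partitions (blocks of
# points consecutive in position order), enumerated via compositions
oracle_min_bp_contiguous <- function(points, settings) {
  n <- nrow(points)
  ord <- order(points$pos, points$ext_start)
  pts <- points[ord, , drop = FALSE]
  best <- Inf
  # each of the n-1 gaps is either a cut or not
  for (mask in 0:(2^(n - 1L) - 1L)) {
    cuts <- which(bitwAnd(mask, 2L^(seq_len(max(n - 1L, 0L)) - 1L)) > 0L)
    asg <- cumsum(c(1L, as.integer(seq_len(n - 1L) %in% cuts)))
    if (!oracle_partition_valid(pts, asg, settings)) next
    bp <- oracle_partition_total_bp(pts, asg, settings)
    if (bp < best) best <- bp
  }
  if (is.finite(best)) best else NULL
}

# greedy left-to-right interval cover with width = max span of any valid
# cluster; a lower bound on the number of clusters in any valid partition
oracle_greedy_lower_bound <- function(points, settings) {
  width <- settings$max_fragment_bp - 2L * settings$min_flank_bp
  pos <- sort(points$ext_start)
  ends <- sort(points$ext_end)
  count <- 0L
  i <- 1L
  pts <- points[order(points$ext_start), , drop = FALSE]
  n <- nrow(pts)
  while (i <= n) {
    count <- count + 1L
    anchor <- pts$ext_start[i]
    while (i <= n && pts$ext_end[i] - anchor <= width) i <- i + 1L
  }
  count
}

# random mixed mutation panel on a random gene, for oracle-equivalence
# checks; returns validated specs
random_mixed_panel <- function(gene_set, seed, max_specs = 6L) {
  gene <- gene_set$gene
  prot <- translate_codons_test(gene$cds)
  nres <- gene$n_codons
  set.seed(seed)
  n_specs <- sample(2:max_specs, 1L)
  used <- integer(0)
  labels <- character(0)
  aa20 <- setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z"))
  mkpt <- function(r) sprintf("%s%d%s", prot[r], r,
                              sample(setdiff(aa20, prot[r]), 1L))
  for (i in seq_len(n_specs)) {
    kind <- sample(c("point", "combined", "deletion", "insertion"), 1L,
                   prob = c(0.55, 0.2, 0.15, 0.1))
    if (kind == "point") {
      r <- sample(setdiff(2:(nres - 1L), used), 1L)
      used <- c(used, r)
      labels <- c(labels, mkpt(r))
    } else if (kind == "combined") {
      gap <- sample(1:min(450L, nres - 4L), 1L)
      cand <- setdiff(2:(nres - gap - 1L), used)
      if (length(cand) == 0L) next
      a <- cand[sample.int(length(cand), 1L)]
      b <- a + gap
      if (b %in% used) next
      used <- c(used, a, b)
      labels <- c(labels, paste(mkpt(a), mkpt(b), sep = "+"))
    } else if (kind == "deletion") {
      len <- sample(1:min(120L, nres - 10L), 1L)
      cand <- setdiff(2:(nres - len - 1L), used)
      if (length(cand) == 0L) next
      a <- cand[sample.int(length(cand), 1L)]
      if (any(seq(a, a + len - 1L) %in% used)) next
      used <- c(used, seq(a, a + len - 1L))
      labels <- c(labels, sprintf("del%d-%d", a, a + len - 1L))
    } else {
      len <- sample(1:120, 1L)
      r <- sample(setdiff(2:(nres - 1L), used), 1L)
      used <- c(used, r)
      pep <- paste(sample(aa20, len, replace = TRUE), collapse = "")
      labels <- c(labels, sprintf("ins%d-%s", r, pep))
    }
  }
  validate_mutations(lapply(unique(labels), parse_mutation), gene)
}

# independent codon-by-codon translation (no package code)
translate_codons_test <- function(seq) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(seq)
  codons <- substring(seq, seq(1, n, 3), seq(3, n, 3))
  unname(gc[codons])
}
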