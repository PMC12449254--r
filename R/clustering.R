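# Grouping mutations into fragment regions.
#
# Mutations are mapped to representative bp positions on the CDS and
# partitioned with K-medoids (PAM) on a constraint-modified distance matrix:
# members of a combined mutation have their mutual distances shrunk so the
# search is steered towards co-clustering them, and a hard post-check
# rejects any clustering that still separates them. The PAM sweep over
# cluster counts is complemented by an exact branch-and-bound search so the
# selected clustering is optimal for the chosen objective (fragment-region
# count or total region length) whenever the search completes within its
# node budget.

PAIR_DISTANCE_FACTOR <- 0.01

#' Map mutation specs to clustering points
#'
#' Each point mutation contributes one point (codon interval); a combined
#' mutation contributes one point per member; insertions and deletions
#' contribute one point at the midpoint of the affected interval.
#'
#' @param muts List of validated \code{mutation_spec}.
#' @param gene A \code{gene_context}.
#' @return Data frame with one row per point: \code{label} (owning spec),
#'   \code{member}, \code{pos}, \code{ext_start}, \code{ext_end} (0-based
#'   half-open bp on the CDS), \code{net} (signed bp length change of the
#'   owning spec), \code{group} (combined-group id or \code{NA}).
#' @export
mutation_points <- function(muts, gene) {
  rows <- list()
  gid <- 0L
  for (m in muts) {
    if (m$kind == "point") {
      s <- 3L * (m$res - 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        label = m$label, member = m$label, pos = s + 1,
        ext_start = s, ext_end = s + 3L, net = 0L, group = NA_integer_,
        stringsAsFactors = FALSE)
    } else if (m$kind == "combined") {
      gid <- gid + 1L
      for (pt in m$members) {
        s <- 3L * (pt$res - 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          label = m$label, member = pt$label, pos = s + 1,
          ext_start = s, ext_end = s + 3L, net = 0L, group = gid,
          stringsAsFactors = FALSE)
      }
    } else if (m$kind == "deletion") {
      s <- 3L * (m$first - 1L)
      e <- 3L * m$last
      rows[[length(rows) + 1L]] <- data.frame(
        label = m$label, member = m$label, pos = floor((s + e) / 2),
        ext_start = s, ext_end = e, net = net_indel_bp(m), group = NA_integer_,
        stringsAsFactors = FALSE)
    } else if (m$kind == "insertion") {
      # the insertion point is the codon boundary after the anchor; the
      # extent covers the anchor codon so the region always contains it
      b <- 3L * m$anchor
      rows[[length(rows) + 1L]] <- data.frame(
        label = m$label, member = m$label, pos = b,
        ext_start = b - 3L, ext_end = b, net = net_indel_bp(m),
        group = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Constraint-modified distance matrix between mutation points
#'
#' Plain absolute bp distance, multiplied by a small co-clustering factor
#' (0.01) for pairs belonging to the same combined mutation.
#'
#' @param points Data frame from \code{\link{mutation_points}}.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
constrained_distance_matrix <- function(points) {
  n <- nrow(points)
  d <- abs(outer(points$pos, points$pos, "-"))
  if (n > 1L) {
    same <- !is.na(points$group) &
      outer(points$group, points$group, function(a, b) !is.na(a) & !is.na(b) & a == b)
    d[same] <- d[same] * PAIR_DISTANCE_FACTOR
  }
  diag(d) <- 0
  d
}

#' K-medoids assignment for a fixed cluster count
#'
#' Partitioning around medoids (PAM) on a precomputed dissimilarity matrix.
#' The PAM build/swap procedure is deterministic, so identical inputs give
#' identical assignments; \code{seed} is accepted for interface stability
#' and recorded but not consumed.
#'
#' @param dmat Symmetric distance matrix.
#' @param k Number of clusters, \code{1 <= k <= nrow(dmat)}.
#' @param seed Unused; retained for call-signature compatibility.
#' @return Integer vector of cluster indices (1..k), one per point.
#' @export
cluster_k <- function(dmat, k, seed = NULL) {
  n <- nrow(dmat)
  if (k < 1L || k > n) stop("k must be in [1, ", n, "]", call. = FALSE)
  if (k == n) return(seq_len(n))
  if (k == 1L) return(rep(1L, n))
  fit <- cluster::pam(stats::as.dist(dmat), k = k, diss = TRUE)
  as.integer(fit$clustering)
}

# Geometry of one cluster of points under the provider size limits.
#
# span:          wild-type bp span covered by the member extents
# region_needed: smallest codon-aligned wild-type region that (a) covers the
#                span, (b) is at least the interior floor (min fragment
#                minus both flanks), and (c) still yields a fragment of at
#                least the minimum length for the member with the largest
#                deletion
# valid:         TRUE iff every member's mutant fragment (region + its net
#                indel + two minimal flanks) fits the provider maximum
cluster_geometry <- function(ext_start, ext_end, net, settings) {
  span <- max(ext_end) - min(ext_start)
  core <- core_min_bp(settings)
  region_needed <- max(span, core + max(0L, -min(net)), core)
  region_needed <- 3L * ceiling(region_needed / 3)
  valid <- region_needed + max(net) <= core_max_bp(settings)
  list(span = span, region_needed = region_needed, valid = valid,
       implied_len = region_needed + 2L * settings$min_flank_bp)
}

# Assemble a clustering object from a point-level assignment vector.
as_clustering <- function(points, assignment, settings, origin = "pam") {
  ks <- sort(unique(assignment))
  assignment <- match(assignment, ks)  # renumber 1..k
  k <- length(ks)
  clusters <- vector("list", k)
  all_valid <- TRUE
  total <- 0L
  for (c in seq_len(k)) {
    idx <- which(assignment == c)
    g <- cluster_geometry(points$ext_start[idx], points$ext_end[idx],
                          points$net[idx], settings)
    g$rows <- idx
    g$labels <- unique(points$label[idx])
    clusters[[c]] <- g
    all_valid <- all_valid && g$valid
    total <- total + g$implied_len
  }
  # hard constraint: a combined mutation's members must share one cluster
  groups <- stats::na.omit(unique(points$group))
  for (gid in groups) {
    if (length(unique(assignment[points$group %in% gid])) > 1L) {
      all_valid <- FALSE
    }
  }
  structure(list(k = k, assignment = assignment, valid = all_valid,
                 n_fragments = k, total_fragment_bp = total,
                 clusters = clusters, origin = origin),
            class = "clustering")
}

#' @export
print.clustering <- function(x, ...) {
  cat(sprintf("clustering: %d region(s), %d bp total, %s\n",
              x$n_fragments, x$total_fragment_bp,
              if (x$valid) "valid" else "INVALID"))
  invisible(x)
}

canonical_assignment <- function(a) {
  paste(match(a, unique(a)), collapse = ",")
}

# Exact best valid partition for one objective via branch and bound over
# assignments in position order. objective = "quantity" (min count, then bp)
# or "length" (min bp, then count). Returns an assignment vector or NULL if
# no valid partition exists (or the node budget was exhausted with no
# incumbent).
exact_best_partition <- function(points, settings, objective,
                                 node_budget = 200000L) {
  n <- nrow(points)
  ord <- order(points$ext_start, points$pos)
  s <- points$ext_start[ord]
  e <- points$ext_end[ord]
  net <- points$net[ord]
  grp <- points$group[ord]
  core_max <- core_max_bp(settings)
  core <- core_min_bp(settings)

  key_of <- function(count, bp) {
    if (objective == "quantity") c(count, bp) else c(bp, count)
  }
  lex_lt <- function(a, b) a[1] < b[1] || (a[1] == b[1] && a[2] < b[2])

  best_key <- c(Inf, Inf)
  best_assign <- NULL
  nodes <- 0L
  budget_hit <- FALSE

  implied <- function(span, minnet) {
    rn <- max(span, core + max(0L, -minnet), core)
    3L * ceiling(rn / 3) + 2L * settings$min_flank_bp
  }

  # clusters: matrix columns min_s, max_e, min_net, max_net; assign: vector
  recurse <- function(i, cl, assign, count, bp) {
    nodes <<- nodes + 1L
    if (nodes > node_budget) {
      budget_hit <<- TRUE
      return(invisible(NULL))
    }
    lb <- key_of(count, bp)
    if (!lex_lt(lb, best_key)) return(invisible(NULL))
    if (i > n) {
      best_key <<- lb
      out <- integer(n)
      out[ord] <- assign
      best_assign <<- out
      return(invisible(NULL))
    }
    gmate <- if (!is.na(grp[i])) {
      prev <- which(!is.na(grp[seq_len(i - 1L)]) & grp[seq_len(i - 1L)] == grp[i])
      if (length(prev) > 0L) assign[prev[1]] else NA_integer_
    } else NA_integer_

    try_join <- function(ci) {
      new_min_s <- min(cl[ci, 1L], s[i])
      new_max_e <- max(cl[ci, 2L], e[i])
      new_min_net <- min(cl[ci, 3L], net[i])
      new_max_net <- max(cl[ci, 4L], net[i])
      span <- new_max_e - new_min_s
      rn <- max(span, core + max(0L, -new_min_net), core)
      rn <- 3L * ceiling(rn / 3)
      if (rn + new_max_net > core_max) return(invisible(NULL))
      old_impl <- implied(cl[ci, 2L] - cl[ci, 1L], cl[ci, 3L])
      new_impl <- rn + 2L * settings$min_flank_bp
      cl2 <- cl
      cl2[ci, ] <- c(new_min_s, new_max_e, new_min_net, new_max_net)
      assign[i] <- ci
      recurse(i + 1L, cl2, assign, count, bp - old_impl + new_impl)
    }

    if (!is.na(gmate)) {
      # forced join with the earlier member of the same combined group
      try_join(gmate)
      return(invisible(NULL))
    }
    nc <- nrow(cl)
    for (ci in seq_len(max(nc, 0L))) {
      # skip clusters no future point (all have ext_start >= s[i]) can join
      if (s[i] - cl[ci, 1L] > core_max) next
      try_join(ci)
    }
    # open a new cluster (valid iff the point's own fragment fits)
    if (implied(e[i] - s[i], net[i]) - 2L * settings$min_flank_bp +
        net[i] <= core_max) {
      cl2 <- rbind(cl, c(s[i], e[i], net[i], net[i]))
      assign[i] <- nc + 1L
      recurse(i + 1L, cl2, assign, count + 1L,
              bp + implied(e[i] - s[i], net[i]))
    }
    invisible(NULL)
  }

  cl0 <- matrix(numeric(0), ncol = 4L)
  recurse(1L, cl0, integer(n), 0L, 0L)
  list(assignment = best_assign, complete = !budget_hit)
}

#' Enumerate valid clusterings of the mutation points
#'
#' Sweeps the cluster count k = 1, 2, ... with PAM on the
#' constraint-modified distance matrix, recording every clustering in which
#' all clusters satisfy the fragment size limits and all combined mutations
#' are co-clustered. The sweep stops once every cluster's wild-type span has
#' fallen below the interior size floor (further splitting cannot help) or
#' at k = n. Two exact branch-and-bound searches (one per objective) then
#' add the provably best valid partitions, so downstream selection attains
#' the optimum even where the medoid heuristic misses it.
#'
#' @param points Data frame from \code{\link{mutation_points}}.
#' @param settings A \code{\link{design_settings}} object.
#' @return List of valid \code{clustering} objects (deduplicated).
#' @export
find_valid_clusterings <- function(points, settings) {
  n <- nrow(points)
  if (n < 1L) stop("no mutation points to cluster", call. = FALSE)
  dmat <- constrained_distance_matrix(points)
  out <- list()
  seen <- character(0)
  add <- function(cl) {
    key <- canonical_assignment(cl$assignment)
    if (cl$valid && !(key %in% seen)) {
      seen <<- c(seen, key)
      out[[length(out) + 1L]] <<- cl
    }
  }
  core <- core_min_bp(settings)
  for (k in seq_len(n)) {
    cl <- as_clustering(points, cluster_k(dmat, k), settings, origin = "pam")
    add(cl)
    spans <- vapply(cl$clusters, `[[`, numeric(1), "span")
    if (all(spans < core)) break
  }
  for (obj in c("quantity", "length")) {
    ex <- exact_best_partition(points, settings, obj)
    if (!is.null(ex$assignment)) {
      add(as_clustering(points, ex$assignment, settings,
                        origin = paste0("exact_", obj)))
    }
  }
  if (length(out) == 0L) {
    # diagnose the blocking constraint
    groups <- stats::na.omit(unique(points$group))
    for (gid in groups) {
      idx <- which(points$group %in% gid)
      g <- cluster_geometry(points$ext_start[idx], points$ext_end[idx],
                            points$net[idx], settings)
      if (!g$valid) {
        stop("no valid clustering: combined mutation '",
             points$label[idx[1]], "' spans ", g$span,
             " bp, which cannot fit one fragment of at most ",
             settings$max_fragment_bp, " bp", call. = FALSE)
      }
    }
    for (i in seq_len(n)) {
      g <- cluster_geometry(points$ext_start[i], points$ext_end[i],
                            points$net[i], settings)
      if (!g$valid) {
        stop("no valid clustering: mutation '", points$label[i],
             "' alone requires a fragment longer than ",
             settings$max_fragment_bp, " bp", call. = FALSE)
      }
    }
    stop("no valid clustering found under the current size limits",
         call. = FALSE)
  }
  ks <- vapply(out, `[[`, numeric(1), "k")
  out[order(ks)]
}

#' Select a clustering by optimization mode
#'
#' \code{"quantity"} minimizes the number of fragment regions (ties broken
#' by smaller total region length); \code{"length"} minimizes the total
#' region length (ties broken by fewer regions). Remaining ties go to the
#' candidate with the smaller k encountered first.
#'
#' @param candidates List of valid \code{clustering} objects.
#' @param mode \code{"quantity"} or \code{"length"}.
#' @return The selected \code{clustering}.
#' @export
select_clustering <- function(candidates, mode = c("quantity", "length")) {
  mode <- match.arg(mode)
  if (length(candidates) == 0L) {
    stop("no valid clustering to select from", call. = FALSE)
  }
  nf <- vapply(candidates, `[[`, numeric(1), "n_fragments")
  bp <- vapply(candidates, `[[`, numeric(1), "total_fragment_bp")
  ks <- vapply(candidates, `[[`, numeric(1), "k")
  ord <- if (mode == "quantity") {
    order(nf, bp, ks, seq_along(candidates))
  } else {
    order(bp, nf, ks, seq_along(candidates))
  }
  candidates[[ord[1]]]
}
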