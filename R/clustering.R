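# OPTSIL-style threshold clustering with a linkage-fraction parameter F,
# cluster homogeneity statistics, partition agreement (adjusted Rand),
# reference-partition optimization, and the clustering-consistency
# criterion used to select the subspecies distance threshold.

#' Threshold clustering with a linkage fraction
#'
#' Agglomerative scheme: start from singletons and repeatedly merge the
#' cluster pair with the smallest average inter-cluster distance among the
#' pairs passing the linkage test, until no pair qualifies. The linkage
#' test for threshold \code{T} and fraction \code{F}: at least one
#' inter-cluster strain pair has \code{d <= T}, and the fraction of
#' inter-cluster pairs with \code{d <= T} is \code{>= F}. Thus \code{F = 0}
#' is single linkage (the result equals connected components of the graph
#' \code{d <= T}) and \code{F = 1} is complete linkage. Ties between
#' candidate merges are broken toward the pair with the lexicographically
#' smallest member labels.
#'
#' @param m Labeled symmetric distance matrix (or \code{gbdp_matrix}).
#' @param T Distance threshold, \code{T >= 0}.
#' @param F Linkage fraction in \code{[0, 1]}.
#' @return A \code{\link{partition}} carrying \code{T} and \code{F}.
#' @export
threshold_cluster <- function(m, T, F = 0) {
  if (inherits(m, "gbdp_matrix")) m <- m$distances
  m <- dist_matrix(m)
  stopifnot(T >= 0, F >= 0, F <= 1)
  labs <- rownames(m)
  clusters <- as.list(labs)
  repeat {
    nc <- length(clusters)
    if (nc < 2) break
    best <- NULL
    for (i in seq_len(nc - 1)) {
      for (j in (i + 1):nc) {
        dd <- m[clusters[[i]], clusters[[j]], drop = FALSE]
        n_le <- sum(dd <= T)
        if (n_le < 1 || n_le / length(dd) < F) next
        cand <- list(avg = mean(dd), i = i, j = j,
                     key = sort(c(clusters[[i]], clusters[[j]])))
        if (is.null(best) || cand$avg < best$avg - 1e-15 ||
            (abs(cand$avg - best$avg) <= 1e-15 &&
             key_less(cand$key, best$key)))
          best <- cand
      }
    }
    if (is.null(best)) break
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  # deterministic cluster numbering: by smallest member label
  ord <- order(vapply(clusters, function(cl) min(cl), character(1)))
  assignment <- unlist(lapply(seq_along(ord), function(r)
    setNames(rep(r, length(clusters[[ord[r]]])), clusters[[ord[r]]])))
  partition(assignment, T = T, F = F)
}

# lexicographic comparison of two character vectors
key_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Within-cluster homogeneity statistics
#'
#' @param m Labeled symmetric distance matrix.
#' @param p A \code{\link{partition}} whose labels are contained in the
#'   matrix labels.
#' @return List of class \code{cluster_stats}: \code{$per_cluster} (cluster,
#'   size, average and maximum within-cluster distance; NA for singletons)
#'   and \code{$summary} (min, median, max of the averages and of the maxima
#'   across clusters of size >= 2; the median is the lower of the two middle
#'   values for even counts). If no cluster has two members,
#'   \code{$summary} is \code{NULL} and \code{$no_multi_member} is TRUE.
#' @export
cluster_stats <- function(m, p) {
  if (inherits(m, "gbdp_matrix")) m <- m$distances
  m <- dist_matrix(m)
  if (!all(names(p) %in% rownames(m)))
    stopf("partition labels missing from the distance matrix")
  ids <- sort(unique(as.integer(p)))
  per <- do.call(rbind, lapply(ids, function(k) {
    members <- names(p)[p == k]
    if (length(members) < 2)
      return(data.frame(cluster = k, size = length(members),
                        avg_within = NA_real_, max_within = NA_real_))
    dd <- m[members, members]
    vals <- dd[upper.tri(dd)]
    data.frame(cluster = k, size = length(members),
               avg_within = mean(vals), max_within = max(vals))
  }))
  multi <- per[per$size >= 2, , drop = FALSE]
  summary <- NULL
  if (nrow(multi) > 0)
    summary <- data.frame(
      stat = c("avg_within", "max_within"),
      min = c(min(multi$avg_within), min(multi$max_within)),
      median = c(median_low(multi$avg_within), median_low(multi$max_within)),
      max = c(max(multi$avg_within), max(multi$max_within)))
  structure(list(per_cluster = per, summary = summary,
                 no_multi_member = nrow(multi) == 0),
            class = "cluster_stats")
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat(sprintf("<cluster_stats> %d clusters\n", nrow(x$per_cluster)))
  if (x$no_multi_member) cat("  no multi-member clusters\n")
  else print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Partition agreement: adjusted Rand index
#'
#' Chance-adjusted Rand index computed from the contingency table of the two
#' partitions; 1 iff the partitions are identical up to relabeling, about 0
#' for independent partitions.
#'
#' @param p,q \code{\link{partition}}s over identical label sets.
#' @return Adjusted Rand index in \code{[-1, 1]}.
#' @export
partition_agreement <- function(p, q) {
  if (!setequal(names(p), names(q)))
    stopf("partitions are over different label sets")
  q <- q[names(p)]
  tab <- table(as.integer(p), as.integer(q))
  n <- length(p)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  max_idx <- (a + b) / 2
  if (abs(max_idx - expected) < 1e-300) # degenerate: both trivial partitions
    return(if (partitions_identical(p, q)) 1 else 0)
  (sum_ij - expected) / (max_idx - expected)
}

partitions_identical <- function(p, q) {
  q <- q[names(p)]
  all(match(as.integer(p), unique(as.integer(p))) ==
        match(as.integer(q), unique(as.integer(q))))
}

#' Optimize clustering parameters against a reference partition
#'
#' Exhaustive grid search over (T, F) maximizing
#' \code{\link{partition_agreement}} with the reference; ties are resolved
#' toward smaller T, then smaller F.
#'
#' @param m Labeled symmetric distance matrix.
#' @param reference Reference \code{\link{partition}} (e.g. phylotypes)
#'   covering at least two matrix labels.
#' @param T_grid Thresholds to scan; default: midpoints between consecutive
#'   sorted unique off-diagonal distances.
#' @param F_grid Linkage fractions to scan; default \code{c(0, 0.5, 1)}.
#' @return List: \code{T}, \code{F}, \code{agreement}, \code{partition},
#'   \code{n_clusters}, and the full \code{grid} of results.
#' @export
optimize_against_reference <- function(m, reference, T_grid = NULL,
                                       F_grid = c(0, 0.5, 1)) {
  if (inherits(m, "gbdp_matrix")) m <- m$distances
  m <- dist_matrix(m)
  if (length(reference) < 2) stopf("reference must cover >= 2 labels")
  T_grid <- T_grid %||% default_t_grid(list(m), below_min = TRUE)
  if (length(T_grid) < 1 || length(F_grid) < 1) stopf("empty parameter grid")
  best <- NULL
  rows <- list()
  for (T in sort(T_grid)) {
    for (F in sort(F_grid)) {
      p <- threshold_cluster(m, T, F)
      agr <- partition_agreement(p, reference)
      rows[[length(rows) + 1]] <-
        data.frame(T = T, F = F, agreement = agr,
                   n_clusters = length(unique(p)))
      if (is.null(best) || agr > best$agreement + 1e-12)
        best <- list(T = T, F = F, agreement = agr, partition = p,
                     n_clusters = length(unique(p)))
    }
  }
  c(best, list(grid = do.call(rbind, rows)))
}

# midpoints between consecutive sorted unique off-diagonal distances,
# pooled over a list of matrices. below_min additionally prepends a point
# below the smallest distance so the all-singleton partition is attainable
# (wanted when optimizing against a reference; not in the consistency scan,
# whose plateau widths must be measured within the observed distance range).
default_t_grid <- function(matrices, below_min = FALSE) {
  vals <- sort(unique(unlist(lapply(matrices, function(m)
    m[upper.tri(m)]))))
  if (length(vals) < 2) return(vals)
  mids <- (head(vals, -1) + vals[-1]) / 2
  if (below_min) c(vals[1] / 2, mids) else mids
}

#' Clustering consistency at a threshold
#'
#' Scores how stable the threshold partition is to the linkage parameter:
#' for each within-species distance matrix, partitions are computed at
#' (T, F = 0) (single linkage) and (T, F = 1) (complete linkage) and their
#' agreement taken; identical partitions score 1 (including the
#' all-singleton and single-cluster cases where the adjusted Rand index is
#' undefined). On perfectly ultrametric data the two linkages coincide and
#' consistency is 1 at every threshold; deviations from ultrametricity --
#' the source of threshold-clustering paradoxes -- push it below 1.
#'
#' @param matrices Non-empty list of within-species distance matrices.
#' @param T Distance threshold.
#' @return Mean consistency over the matrices, in \code{[0, 1]} for
#'   practical purposes (an adjusted Rand index can be slightly negative).
#' @export
clustering_consistency <- function(matrices, T) {
  if (!is.list(matrices) || length(matrices) == 0)
    stopf("need a non-empty list of distance matrices")
  mean(vapply(matrices, function(m) {
    p0 <- threshold_cluster(m, T, 0)
    p1 <- threshold_cluster(m, T, 1)
    if (partitions_identical(p0, p1)) 1 else partition_agreement(p0, p1)
  }, numeric(1)))
}

#' Select the subspecies distance threshold by clustering consistency
#'
#' Scans a threshold grid, computes \code{\link{clustering_consistency}}
#' for each T, finds maximal-consistency plateaus (consecutive grid points
#' at the maximum) and returns the midpoint of the widest plateau (ties:
#' the one with smaller T). A plateau touching the end of the grid is
#' flagged degenerate (no substructure above the covered range); an
#' all-non-positive profile yields a "no consistent threshold" result
#' rather than an error.
#'
#' @param matrices List of within-species distance matrices.
#' @param model A \code{\link{ddh_model}} used to express the selected
#'   threshold as a dDDH value.
#' @param T_grid Thresholds to scan; default: midpoints between consecutive
#'   pooled unique off-diagonal distances.
#' @return List: \code{T_star}, \code{ddh_star}, \code{status} (one of
#'   \code{"ok"}, \code{"degenerate_plateau"},
#'   \code{"no_consistent_threshold"}) and the full \code{profile}
#'   (T, ddh, consistency).
#' @export
optimize_subspecies_threshold <- function(matrices, model = ddh_model(),
                                          T_grid = NULL) {
  if (!is.list(matrices) || length(matrices) == 0)
    stopf("need a non-empty list of distance matrices")
  T_grid <- sort(T_grid %||% default_t_grid(matrices))
  cons <- vapply(T_grid, function(T) clustering_consistency(matrices, T),
                 numeric(1))
  profile <- data.frame(T = T_grid,
                        ddh = distance_to_ddh(pmin(pmax(T_grid, 0), 1),
                                              model),
                        consistency = cons)
  cmax <- max(cons)
  if (cmax <= 0)
    return(list(T_star = NA_real_, ddh_star = NA_real_,
                status = "no_consistent_threshold", profile = profile))
  at_max <- cons >= cmax - 1e-12
  runs <- rle(at_max)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  # consistency is a step function of T; a grid point stands for the whole
  # step interval around it, so a plateau of grid points s..e extends
  # half-way toward the nearest off-plateau grid points on either side
  ng <- length(T_grid)
  lo_T <- vapply(starts[cand], function(s)
    if (s == 1L) T_grid[1] else (T_grid[s] + T_grid[s - 1]) / 2, numeric(1))
  hi_T <- vapply(ends[cand], function(e)
    if (e == ng) T_grid[ng] else (T_grid[e] + T_grid[e + 1]) / 2, numeric(1))
  pick <- which.max(hi_T - lo_T) # first maximum = smallest T on ties
  T_star <- (lo_T[pick] + hi_T[pick]) / 2
  status <- if (starts[cand[pick]] == 1L || ends[cand[pick]] == ng)
    "degenerate_plateau" else "ok"
  list(T_star = T_star,
       ddh_star = distance_to_ddh(min(max(T_star, 0), 1), model),
       status = status, profile = profile)
}
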