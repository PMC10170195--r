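# Protein maps: partition counted localization clusters into per-protein
# positions and compute per-ROI nanocluster statistics (densities,
# clustered fraction, size classes, equivalent diameter, first-neighbour
# distance).

#' Partition a localization cluster into protein positions
#'
#' k-means with `k = n_proteins` over the cluster's localizations:
#' k-means++ seeding, a fixed number of restarts, best within-cluster
#' sum of squares kept; deterministic given `seed`. With fewer
#' localizations than proteins the available distinct points are returned
#' and the remainder filled with the centroid (flagged).
#'
#' @param xy Two-column matrix or data.frame of localization coordinates
#'   (nm).
#' @param n_proteins Number of proteins `k` (>= 1).
#' @param seed Integer seed.
#' @param n_restarts Independent k-means++ restarts (default 5).
#' @return A list: `positions` (k x 2 matrix), `inertia` (total
#'   within-cluster sum of squares), `degenerate` (`TRUE` if there were
#'   fewer distinct points than `k`).
#' @export
kmeans_partition <- function(xy, n_proteins, seed = 1L, n_restarts = 5L) {
  xy <- as.matrix(xy)[, 1:2, drop = FALSE]
  storage.mode(xy) <- "double"
  k <- as.integer(n_proteins)
  if (k < 1) stop("'n_proteins' must be >= 1", call. = FALSE)
  if (k == 1L) {
    ctr <- matrix(colMeans(xy), 1, 2)
    inertia <- sum(sweep(xy, 2, ctr[1, ])^2)
    return(list(positions = ctr, inertia = inertia, degenerate = FALSE))
  }
  distinct <- unique(xy)
  if (nrow(distinct) <= k) {
    ctr <- distinct
    if (nrow(ctr) < k) {
      fill <- matrix(colMeans(xy), k - nrow(ctr), 2, byrow = TRUE)
      ctr <- rbind(ctr, fill)
    }
    return(list(positions = unname(ctr), inertia = 0, degenerate = TRUE))
  }
  set.seed(derive_seed(seed, "kmeans"))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- kmeanspp_init(xy, k)
    km <- suppressWarnings(
      stats::kmeans(xy, centers = init, iter.max = 100L))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  list(positions = unname(best$centers), inertia = best$tot.withinss,
       degenerate = FALSE)
}

# k-means++ seeding: subsequent centres drawn with probability
# proportional to squared distance from the nearest centre chosen so far.
kmeanspp_init <- function(xy, k) {
  n <- nrow(xy)
  centres <- matrix(NA_real_, k, 2)
  centres[1, ] <- xy[sample.int(n, 1L), ]
  d2 <- (xy[, 1] - centres[1, 1])^2 + (xy[, 2] - centres[1, 2])^2
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      pick <- sample.int(n, 1L)
    } else {
      pick <- sample.int(n, 1L, prob = d2)
    }
    centres[j, ] <- xy[pick, ]
    d2 <- pmin(d2, (xy[, 1] - centres[j, 1])^2 + (xy[, 2] - centres[j, 2])^2)
  }
  # kmeans() rejects duplicate centres; nudge exact duplicates apart
  dup <- duplicated(centres)
  if (any(dup)) {
    centres[dup, ] <- centres[dup, , drop = FALSE] +
      matrix(stats::rnorm(2 * sum(dup), 0, 1e-6), ncol = 2)
  }
  centres
}

#' Group protein positions into protein clusters
#'
#' Single-linkage grouping: two proteins are linked if they originate from
#' the same localization cluster (parentage is never split) or lie within
#' `linking_radius` of each other. Connected components with at least
#' `min_cluster_size` members constitute protein clusters; smaller groups
#' count as unclustered proteins. The conventional minimum cluster size is
#' 3 proteins.
#'
#' @param proteins A data.frame with `x`, `y` (nm) and `parent` (id of the
#'   originating localization cluster).
#' @param linking_radius Linking distance in nm (default 60, chosen between
#'   the intra-cluster and background nearest-neighbour scales; see the
#'   package vignette).
#' @param min_cluster_size Minimum proteins per cluster (default 3).
#' @return The input data.frame with added columns `group` (component id),
#'   `protein_cluster` (cluster id among groups of >= `min_cluster_size`,
#'   0 otherwise) and `clustered` (logical).
#' @export
group_proteins <- function(proteins, linking_radius = 60,
                           min_cluster_size = 3L) {
  n <- nrow(proteins)
  if (n == 0) {
    proteins$group <- integer(0)
    proteins$protein_cluster <- integer(0)
    proteins$clustered <- logical(0)
    return(proteins)
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  # same-parent linkage
  by_parent <- split(seq_len(n), proteins$parent)
  for (ix in by_parent) {
    if (length(ix) > 1) for (j in ix[-1]) union_(ix[1], j)
  }
  # radius linkage via grid neighbour search
  if (linking_radius > 0 && n > 1) {
    nb <- grid_neighbours(proteins$x, proteins$y, linking_radius)
    for (i in seq_len(n)) {
      for (j in nb[[i]]) if (j > i) union_(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  group <- match(roots, unique(roots))
  sizes <- tabulate(group)
  is_cluster_group <- sizes[group] >= min_cluster_size
  cluster_ids <- integer(n)
  if (any(is_cluster_group)) {
    cg <- unique(group[is_cluster_group])
    cluster_ids[is_cluster_group] <- match(group[is_cluster_group], cg)
  }
  proteins$group <- group
  proteins$protein_cluster <- cluster_ids
  proteins$clustered <- is_cluster_group
  proteins
}

#' Size class of a protein cluster
#'
#' Clusters are classified as `small` (fewer than 6 proteins), `medium`
#' (6-12, both ends inclusive) or `large` (more than 12). Groups below the
#' 3-protein minimum are not clusters and are rejected.
#'
#' @param n_proteins Cluster size(s), each >= 3.
#' @return Character vector of `"small"`, `"medium"`, `"large"`.
#' @export
classify_cluster <- function(n_proteins) {
  if (any(n_proteins < 3)) {
    stop("a protein cluster has at least 3 members", call. = FALSE)
  }
  ifelse(n_proteins < 6, "small",
         ifelse(n_proteins <= 12, "medium", "large"))
}

# Shoelace area of a polygon given vertex coordinates (not closed).
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Convex-hull area of a point set (0 for < 3 distinct points).
hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts)
  polygon_area(pts[h, 1], pts[h, 2])
}

#' Equivalent diameter of a cluster footprint
#'
#' Diameter of the circle with the same area as the convex hull of the
#' supplied points: `2 * sqrt(hull_area / pi)`.
#'
#' @param x,y Point coordinates (nm); typically the localizations of a
#'   protein cluster.
#' @return Diameter in nm (0 if fewer than 3 distinct points).
#' @export
equivalent_diameter <- function(x, y) {
  2 * sqrt(hull_area(x, y) / pi)
}

# median nearest-neighbour distance among points (NA for < 2 points)
median_nn_distance <- function(x, y) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  stats::median(apply(d, 1, min))
}

#' Assemble a protein map from counted localization clusters
#'
#' Runs [kmeans_partition()] on every retained localization cluster with
#' its qPAINT copy number, then [group_proteins()] over the pooled protein
#' positions.
#'
#' @param tab The ROI's [loc_table()].
#' @param clusters A [loc_clusters()] object (after filtering).
#' @param counts Integer copy numbers, one per cluster (e.g. from
#'   [count_proteins()]).
#' @param area_um2 ROI area in um^2.
#' @param seed Integer seed (k-means restarts).
#' @param linking_radius,min_cluster_size Passed to [group_proteins()].
#' @return An object of class `protein_map`: `proteins` (data.frame `x`,
#'   `y`, `parent`, `group`, `protein_cluster`, `clustered`), `clusters`
#'   (the input localization clusters), `loc_table`, `area_um2`.
#' @export
build_protein_map <- function(tab, clusters, counts, area_um2, seed = 1L,
                              linking_radius = 60, min_cluster_size = 3L) {
  stopifnot(inherits(clusters, "loc_clusters"),
            length(counts) == nrow(clusters$summary))
  pos <- vector("list", length(counts))
  for (i in seq_along(counts)) {
    ix <- clusters$members[[i]]
    km <- kmeans_partition(cbind(tab$x[ix], tab$y[ix]), counts[i],
                           seed = derive_seed(seed, paste0("km", i)))
    pos[[i]] <- data.frame(x = km$positions[, 1], y = km$positions[, 2],
                           parent = clusters$summary$cluster[i])
  }
  proteins <- if (length(pos)) do.call(rbind, pos) else
    data.frame(x = numeric(0), y = numeric(0), parent = integer(0))
  proteins <- group_proteins(proteins, linking_radius = linking_radius,
                             min_cluster_size = min_cluster_size)
  structure(list(proteins = proteins, clusters = clusters,
                 loc_table = tab, area_um2 = area_um2),
            class = "protein_map")
}

#' @export
print.protein_map <- function(x, ...) {
  cat(sprintf("Protein map: %d proteins (%.3g um^2), %d protein clusters\n",
              nrow(x$proteins), x$area_um2,
              length(unique(x$proteins$protein_cluster[
                x$proteins$protein_cluster > 0]))))
  invisible(x)
}

#' Per-ROI summary statistics
#'
#' Computes the per-ROI quantities used to characterize membrane protein
#' nanoclustering: protein and cluster densities, the percentage of
#' clustered proteins, counts of small/medium/large clusters, the median
#' equivalent diameter of clusters (from the convex hull of each cluster's
#' member localizations), and the median first-neighbour distance between
#' protein positions.
#'
#' @param map A [build_protein_map()] result.
#' @return A one-row data.frame: `n_proteins`, `protein_density` (/um^2),
#'   `n_clusters`, `cluster_density` (/um^2), `pct_clustered` (%; `NA`
#'   when the ROI holds no proteins), `n_small`, `n_medium`, `n_large`,
#'   `median_eq_diameter` (nm), `median_first_neighbour` (nm).
#' @export
summarize_roi <- function(map) {
  stopifnot(inherits(map, "protein_map"))
  if (map$area_um2 <= 0) stop("ROI area must be > 0", call. = FALSE)
  p <- map$proteins
  n_prot <- nrow(p)
  cl_ids <- sort(unique(p$protein_cluster[p$protein_cluster > 0]))
  n_cl <- length(cl_ids)
  sizes <- if (n_cl) as.integer(table(factor(p$protein_cluster[
    p$protein_cluster > 0], levels = cl_ids))) else integer(0)
  classes <- if (n_cl) classify_cluster(sizes) else character(0)

  eq_diam <- if (n_cl) {
    vapply(cl_ids, function(cid) {
      parents <- unique(p$parent[p$protein_cluster == cid])
      sel <- unlist(map$clusters$members[
        match(parents, map$clusters$summary$cluster)])
      equivalent_diameter(map$loc_table$x[sel], map$loc_table$y[sel])
    }, 0)
  } else numeric(0)

  data.frame(
    n_proteins = n_prot,
    protein_density = n_prot / map$area_um2,
    n_clusters = n_cl,
    cluster_density = n_cl / map$area_um2,
    pct_clustered = if (n_prot) 100 * sum(p$clustered) / n_prot else NA_real_,
    n_small = sum(classes == "small"),
    n_medium = sum(classes == "medium"),
    n_large = sum(classes == "large"),
    median_eq_diameter = if (n_cl) stats::median(eq_diam) else NA_real_,
    median_first_neighbour = median_nn_distance(p$x, p$y)
  )
}

#' Morphology index of a closed contour
#'
#' `perimeter^2 / (4 * pi * area)`: 1 for a circle (in the continuum
#' limit), larger for elongated or spread shapes; invariant to scale.
#'
#' @param x,y Vertex coordinates of a simple (non-self-intersecting)
#'   polygon, not closed (first vertex not repeated).
#' @return The dimensionless morphology index (>= 1 up to discretization).
#' @export
morphology_index <- function(x, y) {
  n <- length(x)
  if (n < 3) stop("a polygon needs at least 3 vertices", call. = FALSE)
  if (is_self_intersecting(x, y)) {
    stop("polygon is self-intersecting", call. = FALSE)
  }
  area <- polygon_area(x, y)
  if (area <= 0) stop("polygon area must be > 0", call. = FALSE)
  j <- c(seq_len(n)[-1], 1)
  perimeter <- sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
  perimeter^2 / (4 * pi * area)
}

# Segment-intersection test over all non-adjacent edge pairs.
is_self_intersecting <- function(x, y) {
  n <- length(x)
  seg <- cbind(x, y, x[c(seq_len(n)[-1], 1)], y[c(seq_len(n)[-1], 1)])
  cross <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      d1 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}
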