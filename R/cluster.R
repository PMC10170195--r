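# Cluster detection: kinetics-derived DBSCAN parameters, DBSCAN itself,
# and the mean-frame filter that removes nonspecific signal.

#' Derive the DBSCAN minPts threshold from Poisson statistics
#'
#' Localization counts per docking strand are modelled as Poisson with mean
#' `mean_locs` (the planning value of
#' [expected_localizations_per_site()]). The threshold returned is the
#' largest integer `m` such that `P(Poisson(mean_locs) <= m - 1)` is at
#' most `tail_epsilon`: a genuine docking site then fails to reach `m`
#' localizations with probability at most `tail_epsilon`, while sparser
#' point groups are treated as noise. The default `tail_epsilon = 5e-6` is
#' calibrated once against the exact Poisson CDF so that the conventional
#' acquisition planning value of 40 localizations per site yields the
#' conventional threshold minPts = 15; it is deliberately frozen.
#'
#' @param mean_locs Expected localizations per docking site (> 0).
#' @param tail_epsilon Acceptable probability of missing a genuine site
#'   (in (0, 1)).
#' @return Integer minPts (>= 1).
#' @export
min_points_from_poisson <- function(mean_locs, tail_epsilon = 5e-6) {
  stop_if_not_scalar_number(mean_locs, "mean_locs", positive = TRUE)
  stop_if_not_scalar_number(tail_epsilon, "tail_epsilon")
  if (tail_epsilon <= 0 || tail_epsilon >= 1) {
    stop("'tail_epsilon' must be in (0, 1)", call. = FALSE)
  }
  m <- 1L
  # exact CDF scan; P(X <= m - 1) is increasing in m
  while (stats::ppois(m, mean_locs) <= tail_epsilon) m <- m + 1L
  m
}

#' DBSCAN clustering parameters
#'
#' @param eps Neighbourhood radius in nm (> 0). The recommended default is
#'   the NeNA localization-precision estimate rounded to the nearest nm
#'   (see [nena_precision()]); 10 nm is typical for DNA-PAINT.
#' @param min_pts Core-point threshold (>= 1), neighbours counted
#'   including the point itself; see [min_points_from_poisson()].
#' @return An object of class `clustering_params`.
#' @export
clustering_params <- function(eps = 10, min_pts = 15L) {
  stop_if_not_scalar_number(eps, "eps", positive = TRUE)
  stop_if_not_scalar_number(min_pts, "min_pts", positive = TRUE)
  structure(list(eps = eps, min_pts = as.integer(min_pts)),
            class = "clustering_params")
}

# Neighbour lists within eps (Euclidean, self included) via a uniform grid
# with cell side eps: all neighbours of a point lie in its 3x3 cell block.
grid_neighbours <- function(x, y, eps) {
  n <- length(x)
  cx <- floor(x / eps); cy <- floor(y / eps)
  cx <- cx - min(cx); cy <- cy - min(cy)
  ncol_grid <- max(cx) + 1
  key <- cx * (max(cy) + 3) + cy  # unique per cell
  cell_of <- split(seq_len(n), key)
  cell_index <- as.numeric(names(cell_of))
  # map from key to candidate points of the 3x3 block
  lookup <- new.env(hash = TRUE, size = length(cell_of))
  for (i in seq_along(cell_of)) {
    assign(as.character(cell_index[i]), cell_of[[i]], envir = lookup)
  }
  stride <- max(cy) + 3
  eps2 <- eps * eps
  nb <- vector("list", n)
  for (i in seq_along(cell_of)) {
    pts <- cell_of[[i]]
    k <- cell_index[i]
    cand <- integer(0)
    for (dxy in c(-stride - 1, -stride, -stride + 1, -1, 0, 1,
                  stride - 1, stride, stride + 1)) {
      got <- lookup[[as.character(k + dxy)]]
      if (!is.null(got)) cand <- c(cand, got)
    }
    for (p in pts) {
      d2 <- (x[cand] - x[p])^2 + (y[cand] - y[p])^2
      nb[[p]] <- cand[d2 <= eps2]
    }
  }
  nb
}

#' DBSCAN over a localization table
#'
#' Standard DBSCAN semantics: a core point has at least `min_pts`
#' neighbours within `eps` (Euclidean, counting itself); clusters are the
#' density-connected components of core points, plus border points
#' (non-core points within `eps` of a core point). A border point reachable
#' from several clusters is assigned to the cluster discovered first in
#' input row order, making the labelling deterministic. Noise is labelled
#' 0.
#'
#' @param tab A [loc_table()] (or any data.frame with `x`, `y`).
#' @param params A [clustering_params()].
#' @return Integer vector of cluster labels (one per row; 0 = noise).
#' @export
dbscan_localizations <- function(tab, params) {
  stopifnot(inherits(params, "clustering_params"))
  n <- nrow(tab)
  if (n == 0) return(integer(0))
  nb <- grid_neighbours(tab$x, tab$y, params$eps)
  core <- lengths(nb) >= params$min_pts
  labels <- integer(n)        # 0 = unvisited/noise
  cluster_id <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cluster_id <- cluster_id + 1L
    labels[i] <- cluster_id
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cluster_id
        if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  labels
}

# Max pairwise distance within a point set; goes through the convex hull
# for larger sets.
max_extent <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  if (n > 60) {
    h <- grDevices::chull(x, y)
    x <- x[h]; y <- y[h]
  }
  sqrt(max(stats::dist(cbind(x, y))^2))
}

#' Assemble localization clusters from DBSCAN labels
#'
#' @param tab The [loc_table()] that was clustered.
#' @param labels Labels from [dbscan_localizations()].
#' @return An object of class `loc_clusters`: a list with `summary` (one
#'   row per cluster: `cluster`, `n_locs`, `x`, `y` centroid, `max_extent`
#'   nm, `mean_frame`), `members` (list of row-index vectors into `tab`),
#'   `frames` (list of sorted distinct member frames), and `n_frames`.
#' @export
loc_clusters <- function(tab, labels) {
  stopifnot(nrow(tab) == length(labels))
  ids <- sort(unique(labels[labels > 0]))
  members <- split(seq_along(labels), labels)[as.character(ids)]
  frames <- lapply(members, function(ix) sort(unique(tab$frame[ix])))
  summary <- data.frame(
    cluster = ids,
    n_locs = lengths(members),
    x = vapply(members, function(ix) mean(tab$x[ix]), 0),
    y = vapply(members, function(ix) mean(tab$y[ix]), 0),
    max_extent = vapply(members, function(ix) max_extent(tab$x[ix], tab$y[ix]), 0),
    mean_frame = vapply(members, function(ix) mean(tab$frame[ix]), 0)
  )
  rownames(summary) <- NULL
  structure(list(summary = summary, members = unname(members),
                 frames = unname(frames), n_frames = n_frames_of(tab)),
            class = "loc_clusters")
}

#' @export
print.loc_clusters <- function(x, ...) {
  cat(sprintf("%d localization clusters (%d localizations clustered)\n",
              nrow(x$summary), sum(x$summary$n_locs)))
  invisible(x)
}

# subset a loc_clusters object by row index into summary
subset_clusters <- function(cl, keep) {
  structure(list(summary = cl$summary[keep, , drop = FALSE],
                 members = cl$members[keep],
                 frames = cl$frames[keep],
                 n_frames = cl$n_frames),
            class = "loc_clusters")
}

#' Mean-frame filter for nonspecific signal
#'
#' A docking site visited by imagers throughout the acquisition has a mean
#' localization frame near half the total frame count, whereas transiently
#' present nonspecific signal concentrates early or late. The filter fits a
#' Gaussian to the distribution of per-cluster mean frames (via the sample
#' mean and standard deviation, equivalent to a least-squares histogram fit
#' for large n but free of a binning choice) and removes clusters outside
#' `mean +/- 1 SD`. A cluster whose mean frame equals the fitted mean is
#' never removed.
#'
#' @param clusters A [loc_clusters()] object.
#' @return A list: `clusters` (retained), `rejected` (removed),
#'   `mu`, `sigma` (fitted, frames), `n_rejected`.
#' @export
mean_frame_filter <- function(clusters) {
  stopifnot(inherits(clusters, "loc_clusters"))
  mf <- clusters$summary$mean_frame
  if (length(mf) < 3) {
    warning("fewer than 3 clusters; mean-frame filter passes all through")
    return(list(clusters = clusters, rejected = subset_clusters(clusters, FALSE),
                mu = if (length(mf)) mean(mf) else NA_real_,
                sigma = NA_real_, n_rejected = 0L))
  }
  mu <- mean(mf)
  sigma <- stats::sd(mf)
  if (sigma == 0) {
    warning("degenerate mean-frame distribution (sd = 0); passing all through")
    return(list(clusters = clusters, rejected = subset_clusters(clusters, FALSE),
                mu = mu, sigma = 0, n_rejected = 0L))
  }
  keep <- mf >= mu - sigma & mf <= mu + sigma
  list(clusters = subset_clusters(clusters, keep),
       rejected = subset_clusters(clusters, !keep),
       mu = mu, sigma = sigma, n_rejected = sum(!keep))
}
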