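# Shared fixtures and independent oracles used across test files.

# Minimal localization table from vectors.
make_tab <- function(frame, x, y, uncertainty = rep(5, length(x)),
                     n_frames = NULL) {
  loc_table(data.frame(frame = frame, x = x, y = y,
                       uncertainty = uncertainty),
            n_frames = n_frames)
}

# Localizations of fixed emitters re-localized in every frame with
# isotropic Gaussian error: the NeNA test bed.
fixed_emitter_tab <- function(n_emitters, n_frames, sigma, extent = 20000,
                              seed = 1) {
  set.seed(seed)
  ex <- stats::runif(n_emitters, 0, extent)
  ey <- stats::runif(n_emitters, 0, extent)
  frame <- rep(seq_len(n_frames) - 1L, each = n_emitters)
  make_tab(frame,
           rep(ex, n_frames) + stats::rnorm(n_emitters * n_frames, 0, sigma),
           rep(ey, n_frames) + stats::rnorm(n_emitters * n_frames, 0, sigma),
           n_frames = n_frames)
}

# O(n^2) reference DBSCAN: literal textbook semantics, no spatial index.
# Independent of the package implementation.
brute_dbscan <- function(x, y, eps, min_pts) {
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, 0L) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]])
      }
    }
  }
  labels
}

# Are two labelings identical up to renaming of cluster ids (noise = 0
# must match exactly)?
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == 0L, b == 0L)) return(FALSE)
  ok <- TRUE
  for (id in unique(a[a != 0L])) {
    members <- which(a == id)
    ok <- ok && length(unique(b[members])) == 1L
  }
  for (id in unique(b[b != 0L])) {
    members <- which(b == id)
    ok <- ok && length(unique(a[members])) == 1L
  }
  ok
}

# Cluster of n_sites co-located docking sites -> pooled event frames.
simulate_cluster_frames <- function(n_sites, acq, kin, seed) {
  ev <- simulate_binding_timeseries(n_sites, acq, kin, seed)
  sort(unique(unlist(event_frames(ev, n_sites))))
}

default_acq <- acquisition_params()
default_kin <- kinetics_model()
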