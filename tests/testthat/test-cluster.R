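test_that("minPts derivation matches the exact Poisson CDF oracle", {
  # brute-force oracle: scan the exact CDF for the largest qualifying m
  oracle <- function(mean_locs, eps) {
    m_grid <- 1:200
    ok <- stats::ppois(m_grid - 1, mean_locs) <= eps
    max(m_grid[ok])
  }
  expect_equal(min_points_from_poisson(5, 0.5), oracle(5, 0.5))
  expect_equal(min_points_from_poisson(40, 1e-4), oracle(40, 1e-4))
  # the frozen package default reproduces the conventional minPts = 15
  # at the 40-localizations planning mean
  expect_equal(min_points_from_poisson(40), 15L)
})

test_that("minPts is monotone in its arguments", {
  eps_grid <- c(1e-8, 1e-6, 1e-4, 1e-2, 0.5)
  vals <- vapply(eps_grid, function(e) min_points_from_poisson(40, e), 0L)
  expect_true(all(diff(vals) >= 0))  # shrinking epsilon lowers the cutoff
  mean_grid <- c(5, 10, 20, 40, 80)
  vals2 <- vapply(mean_grid, function(m) min_points_from_poisson(m, 1e-4), 0L)
  expect_true(all(diff(vals2) >= 0))
})

test_that("DBSCAN separates well-isolated blobs and rejects sparse noise", {
  set.seed(5)
  blob <- function(cx, cy, n) cbind(stats::rnorm(n, cx, 30),
                                    stats::rnorm(n, cy, 30))
  pts <- rbind(blob(0, 0, 50), blob(1000, 0, 50))
  tab <- make_tab(rep(0L, 100), pts[, 1], pts[, 2])
  labels <- dbscan_localizations(tab, clustering_params(eps = 30,
                                                        min_pts = 15))
  expect_equal(length(unique(labels[labels > 0])), 2L)
  left <- unique(labels[1:50][labels[1:50] > 0])
  right <- unique(labels[51:100][labels[51:100] > 0])
  expect_length(left, 1L)
  expect_length(right, 1L)
  expect_false(left == right)
  # fewer points than min_pts: everything is noise
  few <- make_tab(rep(0L, 10), stats::rnorm(10), stats::rnorm(10))
  expect_true(all(dbscan_localizations(few, clustering_params(10, 15)) == 0))
})

test_that("DBSCAN agrees with the quadratic brute-force oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- c(200, 350, 500, 120)[seed]
    # mixture of blobs and uniform background, in nm scale
    k <- 4
    centres <- matrix(stats::runif(2 * k, 0, 2000), k)
    pts <- do.call(rbind, lapply(seq_len(k), function(i) {
      cbind(stats::rnorm(n %/% (k + 1), centres[i, 1], 15),
            stats::rnorm(n %/% (k + 1), centres[i, 2], 15))
    }))
    pts <- rbind(pts, cbind(stats::runif(n - nrow(pts), 0, 2000),
                            stats::runif(n - nrow(pts), 0, 2000)))
    tab <- make_tab(rep(0L, nrow(pts)), pts[, 1], pts[, 2])
    params <- clustering_params(eps = 25, min_pts = 10)
    mine <- dbscan_localizations(tab, params)
    ref <- brute_dbscan(pts[, 1], pts[, 2], 25, 10)
    expect_true(same_partition(mine, ref))
  }
})

test_that("DBSCAN labels are invariant to global translation", {
  set.seed(9)
  pts <- cbind(stats::rnorm(120, 0, 20), stats::rnorm(120, 0, 20))
  tab1 <- make_tab(rep(0L, 120), pts[, 1], pts[, 2])
  tab2 <- make_tab(rep(0L, 120), pts[, 1] + 5e5, pts[, 2] - 3e5)
  p <- clustering_params(eps = 15, min_pts = 8)
  expect_true(same_partition(dbscan_localizations(tab1, p),
                             dbscan_localizations(tab2, p)))
})

test_that("cluster summaries report centroid, extent and mean frame", {
  tab <- make_tab(c(0L, 10L, 20L), c(0, 30, 0), c(0, 0, 40),
                  n_frames = 100L)
  cl <- loc_clusters(tab, labels = c(1L, 1L, 1L))
  expect_equal(cl$summary$n_locs, 3L)
  expect_equal(cl$summary$x, 10)
  expect_equal(cl$summary$max_extent, 50)  # 3-4-5 triangle hypotenuse
  expect_equal(cl$summary$mean_frame, 10)
})

test_that("mean-frame filter removes early-biased clusters and keeps
           mid-acquisition ones", {
  # 12 persistent clusters around mid-acquisition + 2 early transients
  tabs <- list()
  mk <- function(id, frames) {
    data.frame(frame = as.integer(frames),
               x = id * 1000 + stats::rnorm(length(frames), 0, 5),
               y = id * 1000 + stats::rnorm(length(frames), 0, 5),
               uncertainty = 5)
  }
  set.seed(2)
  rows <- do.call(rbind, c(
    lapply(1:12, function(i) mk(i, sample(0:14999, 40))),
    lapply(13:14, function(i) mk(i, sample(0:500, 40)))))
  tab <- loc_table(rows, n_frames = 15000L)
  labels <- rep(1:14, each = 40)
  cl <- loc_clusters(tab, labels)
  res <- mean_frame_filter(cl)
  kept <- res$clusters$summary$cluster
  expect_false(any(13:14 %in% kept))
  expect_true(all(1:12 %in% kept))
  # a cluster at the fitted mean is never removed
  at_mu <- which.min(abs(cl$summary$mean_frame - res$mu))
  expect_true(cl$summary$cluster[at_mu] %in% kept)
})

test_that("mean-frame filter passes through degenerate inputs with a
           warning", {
  tab <- make_tab(rep(c(0L, 100L), 20),
                  rep(1:2, each = 20) * 1000 + stats::rnorm(40, 0, 3),
                  rep(1:2, each = 20) * 1000, n_frames = 200L)
  cl <- loc_clusters(tab, rep(1:2, 20))
  expect_warning(res <- mean_frame_filter(cl), "fewer than 3")
  expect_equal(nrow(res$clusters$summary), 2L)
})

test_that("rejected fraction tracks a planted transient contamination", {
  # 90% persistent sites + 10% transient (first-decile) sites
  set.seed(31)
  n_pers <- 90; n_trans <- 10
  mk_frames <- function(lo, hi) sort(sample(lo:hi, 40))
  mf <- c(vapply(seq_len(n_pers),
                 function(i) mean(mk_frames(0, 14999)), 0),
          vapply(seq_len(n_trans),
                 function(i) mean(mk_frames(0, 1499)), 0))
  rows <- do.call(rbind, lapply(seq_along(mf), function(i) {
    data.frame(frame = as.integer(round(mf[i])),
               x = i * 500 + stats::rnorm(20, 0, 4), y = i * 500,
               uncertainty = 5)
  }))
  # emulate per-cluster mean frames directly through single-frame clusters
  tab <- loc_table(rows, n_frames = 15000L)
  cl <- loc_clusters(tab, rep(seq_along(mf), each = 20))
  res <- mean_frame_filter(cl)
  rejected_frac <- res$n_rejected / length(mf)
  # all transients fall far outside the band; a few persistent tails go too
  expect_gte(rejected_frac, 0.10)
  expect_lte(rejected_frac, 0.25)
  expect_false(any((n_pers + 1):(n_pers + n_trans) %in%
                     res$clusters$summary$cluster))
})
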