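test_that("k-means with k = 1 returns the centroid", {
  set.seed(1)
  xy <- cbind(stats::rnorm(40, 100, 9), stats::rnorm(40, 50, 9))
  res <- kmeans_partition(xy, 1)
  expect_equal(res$positions, matrix(colMeans(xy), 1, 2))
})

test_that("k-means resolves two well-separated sites", {
  set.seed(2)
  xy <- rbind(cbind(stats::rnorm(40, 0, 9), stats::rnorm(40, 0, 9)),
              cbind(stats::rnorm(40, 100, 9), stats::rnorm(40, 0, 9)))
  res <- kmeans_partition(xy, 2, seed = 3)
  got <- res$positions[order(res$positions[, 1]), ]
  expect_lt(sqrt(sum((got[1, ] - c(0, 0))^2)), 5)
  expect_lt(sqrt(sum((got[2, ] - c(100, 0))^2)), 5)
})

test_that("k equal to the point count gives zero inertia", {
  xy <- cbind(c(0, 10, 20, 35), c(0, 5, 10, 2))
  res <- kmeans_partition(xy, 4, seed = 1)
  expect_equal(res$inertia, 0)
  expect_equal(nrow(res$positions), 4L)
})

test_that("k-means is deterministic given a seed and pads degenerate
           clusters", {
  set.seed(5)
  xy <- cbind(stats::rnorm(60, 0, 20), stats::rnorm(60, 0, 20))
  a <- kmeans_partition(xy, 3, seed = 7)
  b <- kmeans_partition(xy, 3, seed = 7)
  expect_identical(a, b)
  deg <- kmeans_partition(xy[1:2, ], 4, seed = 1)
  expect_true(deg$degenerate)
  expect_equal(nrow(deg$positions), 4L)
})

test_that("grouping honours the 3-protein minimum cluster size", {
  # one localization cluster that counted 2 proteins: no protein cluster
  p2 <- data.frame(x = c(0, 30), y = c(0, 0), parent = c(1L, 1L))
  g2 <- group_proteins(p2)
  expect_equal(sum(g2$clustered), 0L)
  p3 <- data.frame(x = c(0, 30, 60), y = c(0, 0, 0), parent = 1L)
  g3 <- group_proteins(p3)
  expect_true(all(g3$clustered))
  expect_equal(length(unique(g3$protein_cluster)), 1L)
})

test_that("grouping links nearby parents but not distant monomers", {
  p <- data.frame(
    x = c(0, 40, 80, 2000, 5000), y = rep(0, 5),
    parent = 1:5)
  g <- group_proteins(p, linking_radius = 60)
  expect_true(all(g$clustered[1:3]))
  expect_false(any(g$clustered[4:5]))
})

test_that("cluster size classes partition the size axis at 6 and 12", {
  expect_equal(classify_cluster(c(5, 6, 12, 13)),
               c("small", "medium", "medium", "large"))
  expect_equal(classify_cluster(3), "small")
  expect_error(classify_cluster(2), "at least 3")
  classes <- classify_cluster(3:100)
  expect_true(all(classes %in% c("small", "medium", "large")))
  expect_equal(sum(classes == "small"), 3L)   # sizes 3, 4, 5
  expect_equal(sum(classes == "medium"), 7L)  # sizes 6..12
  expect_equal(sum(classes == "large"), 88L)  # sizes 13..100
})

test_that("ROI summary computes densities, size-class counts and
           neighbour distances", {
  # hand-built map: clusters of 3, 6, 12, 13 proteins plus 8 monomers
  sizes <- c(3L, 6L, 12L, 13L)
  centres <- cbind(c(500, 1500, 2500, 500), c(500, 500, 500, 2500))
  set.seed(10)
  prot <- do.call(rbind, lapply(seq_along(sizes), function(i) {
    data.frame(x = centres[i, 1] + stats::rnorm(sizes[i], 0, 20),
               y = centres[i, 2] + stats::rnorm(sizes[i], 0, 20),
               parent = i)
  }))
  mono <- data.frame(x = seq(200, 3400, length.out = 8), y = 3300,
                     parent = 4 + seq_len(8))
  prot <- rbind(prot, mono)
  # localization table: 30 locs per protein position
  rows <- do.call(rbind, lapply(seq_len(nrow(prot)), function(i) {
    data.frame(frame = 0L, x = prot$x[i] + stats::rnorm(30, 0, 9),
               y = prot$y[i] + stats::rnorm(30, 0, 9), uncertainty = 5)
  }))
  tab <- loc_table(rows, n_frames = 1L)
  labels <- rep(prot$parent, each = 30)
  clusters <- loc_clusters(tab, labels)
  counts <- c(sizes, rep(1L, 8))
  map <- build_protein_map(tab, clusters, counts, area_um2 = 12.25,
                           seed = 2)
  s <- summarize_roi(map)
  expect_equal(s$n_proteins, sum(sizes) + 8L)
  expect_equal(s$n_small, 1L)
  expect_equal(s$n_medium, 2L)
  expect_equal(s$n_large, 1L)
  expect_equal(s$n_clusters, 4L)
  expect_equal(s$pct_clustered, 100 * sum(sizes) / (sum(sizes) + 8))
  expect_equal(s$protein_density, (sum(sizes) + 8) / 12.25)
  expect_gt(s$median_eq_diameter, 0)
})

test_that("density arithmetic matches the steady-state regime", {
  expect_equal(282 / 12.25, 23.02, tolerance = 1e-3)
})

test_that("three collinear proteins 30 nm apart have a 30 nm median
           first-neighbour distance", {
  p <- data.frame(x = c(0, 30, 60), y = c(0, 0, 0), parent = 1L)
  rows <- data.frame(frame = rep(0L, 9), x = rep(p$x, each = 3),
                     y = 0, uncertainty = 5)
  tab <- loc_table(rows, n_frames = 1L)
  clusters <- loc_clusters(tab, rep(1L, 9))
  map <- build_protein_map(tab, clusters, counts = 3L, area_um2 = 12.25)
  expect_equal(summarize_roi(map)$median_first_neighbour, 30)
})

test_that("protein conservation: clustered plus unclustered equals the
           counted total", {
  cfg <- qpaint_config()
  sim <- simulate_dna_paint(cfg$generator, cfg$acquisition, cfg$kinetics,
                            seed = 77)
  res <- analyze_roi(sim$locs, cfg)
  p <- res$map$proteins
  expect_equal(sum(p$clustered) + sum(!p$clustered), nrow(p))
  expect_equal(nrow(p), sum(res$per_cluster$n_proteins))
  s <- res$summary
  expect_gte(s$pct_clustered, 0)
  expect_lte(s$pct_clustered, 100)
  # each size class count refers to clusters of >= 3 proteins
  expect_equal(s$n_small + s$n_medium + s$n_large, s$n_clusters)
})

test_that("an empty ROI reports missing percentages rather than zeros", {
  tab <- make_tab(integer(0), numeric(0), numeric(0), numeric(0),
                  n_frames = 10L)
  clusters <- loc_clusters(tab, integer(0))
  map <- build_protein_map(tab, clusters, counts = integer(0),
                           area_um2 = 12.25)
  s <- summarize_roi(map)
  expect_equal(s$n_proteins, 0L)
  expect_equal(s$protein_density, 0)
  expect_true(is.na(s$pct_clustered))
})

test_that("morphology index is 1 for a circle, 4/pi for a square, and
           scale-free", {
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  expect_equal(morphology_index(cos(th), sin(th)), 1, tolerance = 1e-3)
  sq <- morphology_index(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(sq, 4 / pi, tolerance = 1e-12)
  expect_equal(morphology_index(c(0, 5, 5, 0), c(0, 0, 5, 5)), sq)
  # bow-tie: self-intersecting
  expect_error(morphology_index(c(0, 1, 0, 1), c(0, 1, 1, 0)),
               "self-intersecting")
  expect_error(morphology_index(c(0, 1), c(0, 1)), "3 vertices")
})
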