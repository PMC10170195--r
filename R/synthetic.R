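# Synthetic DNA-PAINT data with known ground truth.
#
# The generator produces (i) a ground-truth protein map (monomers plus
# nanoclusters), (ii) per-site binding time series from two-state imager
# kinetics, and (iii) a frame-resolved localization table with Gaussian
# localization error and uniform single-frame nonspecific background.
# Every downstream pipeline stage can therefore be validated by parameter
# recovery against the planted truth.

#' Configuration of the ground-truth protein map generator
#'
#' Describes the spatial ground truth the simulator plants: overall protein
#' density, the fraction of proteins residing in nanoclusters (>= 3
#' proteins), the mixture of cluster-size classes, and the cluster scatter
#' model. Defaults emulate a resting fibroblast membrane in the regime
#' reported for podoplanin: 23 proteins/um^2 with 44% of proteins clustered.
#'
#' @param density Protein density in proteins/um^2 (> 0).
#' @param width_um,height_um ROI extent in micrometres (> 0); default
#'   3.5 x 3.5 um.
#' @param fraction_clustered Target fraction of proteins placed in clusters
#'   of >= 3 (in `[0, 1]`).
#' @param size_class_weights Named weights over the three cluster-size
#'   classes `small` (3-5 proteins), `medium` (6-12) and `large` (>= 13);
#'   normalized internally.
#' @param size_class_ranges Named list giving the inclusive size range
#'   drawn within each class; sizes are uniform within the range. All
#'   bounds must be >= 3 (the minimum cluster size).
#' @param cluster_radius_scale Scatter scale of cluster members around their
#'   centre, in nm: the Gaussian SD (`cluster_shape = "gaussian"`) or the
#'   disc radius (`cluster_shape = "disc"`).
#' @param cluster_shape Either `"gaussian"` or `"disc"`.
#' @param background_rate Nonspecific single-frame localization rate, in
#'   localizations/um^2/frame.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(density = 23,
                             width_um = 3.5, height_um = 3.5,
                             fraction_clustered = 0.44,
                             size_class_weights = c(small = 0.70,
                                                    medium = 0.25,
                                                    large = 0.05),
                             size_class_ranges = list(small = c(3L, 5L),
                                                      medium = c(6L, 12L),
                                                      large = c(13L, 20L)),
                             cluster_radius_scale = 40,
                             cluster_shape = c("gaussian", "disc"),
                             background_rate = 0.01) {
  stop_if_not_scalar_number(density, "density", positive = TRUE)
  stop_if_not_scalar_number(width_um, "width_um", positive = TRUE)
  stop_if_not_scalar_number(height_um, "height_um", positive = TRUE)
  stop_if_not_scalar_number(fraction_clustered, "fraction_clustered",
                            nonnegative = TRUE)
  if (fraction_clustered > 1) {
    stop("'fraction_clustered' must be in [0, 1]", call. = FALSE)
  }
  if (length(size_class_weights) != 3L ||
      !setequal(names(size_class_weights), c("small", "medium", "large")) ||
      any(size_class_weights < 0) || sum(size_class_weights) <= 0) {
    stop("'size_class_weights' must be nonnegative weights named small, medium, large",
         call. = FALSE)
  }
  if (!setequal(names(size_class_ranges), c("small", "medium", "large")) ||
      any(vapply(size_class_ranges, length, 0L) != 2L) ||
      any(unlist(size_class_ranges) < 3) ||
      any(vapply(size_class_ranges, function(r) r[2] < r[1], TRUE))) {
    stop("'size_class_ranges' must give ranges [lo, hi] with lo >= 3 for small, medium, large",
         call. = FALSE)
  }
  stop_if_not_scalar_number(cluster_radius_scale, "cluster_radius_scale",
                            positive = TRUE)
  stop_if_not_scalar_number(background_rate, "background_rate",
                            nonnegative = TRUE)
  cluster_shape <- match.arg(cluster_shape)
  w <- size_class_weights[c("small", "medium", "large")]
  structure(
    list(density = density, width_um = width_um, height_um = height_um,
         fraction_clustered = fraction_clustered,
         size_class_weights = w / sum(w),
         size_class_ranges = lapply(
           size_class_ranges[c("small", "medium", "large")], as.integer),
         cluster_radius_scale = cluster_radius_scale,
         cluster_shape = cluster_shape,
         background_rate = background_rate),
    class = "generator_config"
  )
}

# Draw one cluster size from the small/medium/large mixture.
draw_cluster_size <- function(config) {
  cls <- sample(c("small", "medium", "large"), 1L,
                prob = config$size_class_weights)
  r <- config$size_class_ranges[[cls]]
  if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)
}

#' Simulate a ground-truth protein map
#'
#' Places `Poisson(density * area)` proteins in the ROI: a target fraction
#' in nanoclusters whose sizes are drawn from the configured
#' small/medium/large mixture and whose members scatter around uniformly
#' placed centres (Gaussian or uniform-disc), the remainder as uniformly
#' distributed monomers. Positions are guaranteed to lie inside the ROI
#' (out-of-ROI scatter draws are rejected and redrawn).
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; the map is fully reproducible given the seed.
#' @return An object of class `ground_truth_map`: a list with `proteins`
#'   (data.frame `protein_id`, `x`, `y` in nm, `cluster_id`; 0 = monomer),
#'   `width_nm`, `height_nm`, `area_um2`, and the echoed `config` and
#'   `seed`.
#' @export
simulate_protein_map <- function(config, seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(derive_seed(seed, "protein_map"))
  width_nm <- config$width_um * 1000
  height_nm <- config$height_um * 1000
  area <- config$width_um * config$height_um
  n_total <- stats::rpois(1L, config$density * area)

  # Partition the protein budget into clusters until the clustered count is
  # as close as possible to the target fraction.
  target <- round(config$fraction_clustered * n_total)
  sizes <- integer(0)
  cum <- 0L
  while (cum < target) {
    s <- draw_cluster_size(config)
    if (cum + s - target > target - cum) break
    sizes <- c(sizes, s)
    cum <- cum + s
  }
  n_mono <- n_total - cum

  xs <- numeric(0); ys <- numeric(0); cid <- integer(0)
  if (length(sizes) > 0) {
    centres_x <- stats::runif(length(sizes), 0, width_nm)
    centres_y <- stats::runif(length(sizes), 0, height_nm)
    for (i in seq_along(sizes)) {
      m <- sizes[i]
      px <- numeric(m); py <- numeric(m)
      for (j in seq_len(m)) {
        repeat {
          if (config$cluster_shape == "gaussian") {
            dx <- stats::rnorm(1, 0, config$cluster_radius_scale)
            dy <- stats::rnorm(1, 0, config$cluster_radius_scale)
          } else {
            r <- config$cluster_radius_scale * sqrt(stats::runif(1))
            th <- stats::runif(1, 0, 2 * pi)
            dx <- r * cos(th); dy <- r * sin(th)
          }
          x <- centres_x[i] + dx; y <- centres_y[i] + dy
          if (x >= 0 && x < width_nm && y >= 0 && y < height_nm) break
        }
        px[j] <- x; py[j] <- y
      }
      xs <- c(xs, px); ys <- c(ys, py); cid <- c(cid, rep(i, m))
    }
  }
  if (n_mono > 0) {
    xs <- c(xs, stats::runif(n_mono, 0, width_nm))
    ys <- c(ys, stats::runif(n_mono, 0, height_nm))
    cid <- c(cid, rep(0L, n_mono))
  }
  proteins <- data.frame(protein_id = seq_along(xs), x = xs, y = ys,
                         cluster_id = cid)
  structure(
    list(proteins = proteins, width_nm = width_nm, height_nm = height_nm,
         area_um2 = area, config = config, seed = seed),
    class = "ground_truth_map"
  )
}

#' @export
print.ground_truth_map <- function(x, ...) {
  n <- nrow(x$proteins)
  ncl <- length(unique(x$proteins$cluster_id[x$proteins$cluster_id > 0]))
  cat(sprintf(
    "Ground-truth map: %d proteins in %.3g um^2 (%.1f /um^2), %d clusters, %.1f%% clustered\n",
    n, x$area_um2, n / x$area_um2, ncl,
    if (n > 0) 100 * mean(x$proteins$cluster_id > 0) else 0))
  invisible(x)
}

#' Simulate per-site binding time series
#'
#' Simulates the two-state imager binding process for `site_count`
#' independent docking sites over one acquisition: waiting (dark) times are
#' `Exponential(rate = k_on * imager_conc)` and bright durations
#' `Exponential(mean = tau_bright)`. Each bright event is then discretized
#' to camera frames.
#'
#' Discretization models (`discretize`):
#' \describe{
#'   \item{`"round"` (default)}{an event of duration `d` occupies
#'     `max(1, round(d / frame_time))` consecutive frames starting at the
#'     frame containing its onset. Every binding event yields at least one
#'     localization, so the observed event sequence — and hence all dark-time
#'     statistics used by qPAINT — exactly mirrors the underlying kinetics.}
#'   \item{`"fractional"`}{the event occupies the frames it overlaps, but
#'     each partially covered edge frame is detected with probability equal
#'     to its covered fraction (photon-budget-limited detection). Under this
#'     model the expected localization count per site equals the planning
#'     formula of [expected_localizations_per_site()] exactly; very short
#'     events can be missed entirely.}
#'   \item{`"overlap"`}{the event occupies every frame it overlaps, however
#'     briefly; an upper-bound model.}
#' }
#'
#' @param site_count Number of independent docking sites (>= 1).
#' @param acq An [acquisition_params()].
#' @param kin A [kinetics_model()].
#' @param seed Integer seed.
#' @param discretize Frame-discretization model; see Details.
#' @return A data.frame of bright events with columns `site`, `start_s`
#'   (onset, seconds), `dur_s` (true continuous duration as drawn, seconds),
#'   `first_frame`, `last_frame` (0-based, `NA` if the event produced no
#'   localization), and `truncated` (event still bright at acquisition end).
#' @export
simulate_binding_timeseries <- function(site_count, acq, kin, seed,
                                        discretize = c("round", "fractional",
                                                       "overlap")) {
  stopifnot(inherits(acq, "acquisition_params"),
            inherits(kin, "kinetics_model"))
  if (site_count < 1) stop("'site_count' must be >= 1", call. = FALSE)
  discretize <- match.arg(discretize)
  set.seed(derive_seed(seed, "binding"))
  rate <- binding_rate(kin)
  t_total <- acq$n_frames * acq$frame_time
  ft <- acq$frame_time
  nf <- acq$n_frames

  if (rate == 0) {
    return(data.frame(site = integer(0), start_s = numeric(0),
                      dur_s = numeric(0), first_frame = integer(0),
                      last_frame = integer(0), truncated = logical(0)))
  }

  out <- vector("list", site_count)
  for (s in seq_len(site_count)) {
    starts <- numeric(0); durs <- numeric(0)
    t <- 0
    # draw waits/durations in blocks for speed
    repeat {
      n_blk <- max(16L, ceiling((t_total - t) * rate * 1.5))
      w <- stats::rexp(n_blk, rate)
      d <- stats::rexp(n_blk, 1 / kin$tau_bright)
      st <- t + cumsum(w) + c(0, cumsum(d[-n_blk]))
      keep <- st < t_total
      starts <- c(starts, st[keep]); durs <- c(durs, d[keep])
      if (!all(keep)) break
      t <- st[n_blk] + d[n_blk]
      if (t >= t_total) break
    }
    n <- length(starts)
    if (n == 0) next
    end_obs <- pmin(starts + durs, t_total)
    f0 <- pmin(floor(starts / ft), nf - 1)
    first <- rep(NA_integer_, n); last <- rep(NA_integer_, n)
    if (discretize == "round") {
      k <- pmax(1, round(durs / ft))
      first <- as.integer(f0)
      last <- as.integer(pmin(f0 + k - 1, nf - 1))
    } else {
      f1 <- pmin(floor(end_obs / ft - 1e-12), nf - 1)
      first <- as.integer(f0); last <- as.integer(pmax(f1, f0))
      if (discretize == "fractional") {
        # thin partially covered edge frames with prob = covered fraction
        cov_lead <- (pmin(end_obs, (f0 + 1) * ft) - starts) / ft
        cov_trail <- (end_obs - pmax(starts, last * ft)) / ft
        drop_lead <- stats::runif(n) >= pmin(cov_lead, 1)
        # leading and trailing frame coincide for single-frame events
        single <- last == first
        first[!single & drop_lead] <- first[!single & drop_lead] + 1L
        drop_trail <- stats::runif(n) >= pmin(cov_trail, 1)
        last[!single & drop_trail] <- last[!single & drop_trail] - 1L
        miss <- single & drop_lead
        gone <- miss | (last < first)
        first[gone] <- NA_integer_; last[gone] <- NA_integer_
      }
    }
    out[[s]] <- data.frame(site = s, start_s = starts, dur_s = durs,
                           first_frame = first, last_frame = last,
                           truncated = starts + durs > t_total)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(site = integer(0), start_s = numeric(0),
                      dur_s = numeric(0), first_frame = integer(0),
                      last_frame = integer(0), truncated = logical(0))
  }
  rownames(res) <- NULL
  res
}

#' Frames occupied by each site's bright events
#'
#' @param events Event table from [simulate_binding_timeseries()].
#' @param site_count Total number of sites (so sites without events are
#'   returned as empty vectors). Defaults to the largest site id present.
#' @return A list of sorted 0-based frame vectors, one per site.
#' @export
event_frames <- function(events, site_count = NULL) {
  site_count <- site_count %||%
    (if (nrow(events)) max(events$site) else 0L)
  frames <- rep(list(integer(0)), site_count)
  ev <- events[!is.na(events$first_frame), , drop = FALSE]
  if (nrow(ev)) {
    per_site <- split(ev[c("first_frame", "last_frame")], ev$site)
    for (nm in names(per_site)) {
      ps <- per_site[[nm]]
      frames[[as.integer(nm)]] <- sort(unique(unlist(
        mapply(seq, ps$first_frame, ps$last_frame, SIMPLIFY = FALSE))))
    }
  }
  frames
}

# Sample reported per-localization uncertainties: Gaussian truncated at
# 1 nm from below.
sample_uncertainty <- function(n, acq) {
  pmax(1, stats::rnorm(n, acq$uncertainty_mean, acq$uncertainty_sd))
}

#' Simulate a localization table from a ground-truth map
#'
#' Each protein carries one docking site; every occupied frame of every
#' bright event yields one localization at the protein's true position plus
#' isotropic Gaussian error with per-axis SD `acq$loc_precision_sigma` (no
#' temporal merging: a k-frame event yields k rows). Nonspecific background
#' adds single-frame localizations uniform in space and time at
#' `config$background_rate` localizations/um^2/frame.
#'
#' @param map A [simulate_protein_map()] result.
#' @param events Event table from [simulate_binding_timeseries()] with one
#'   site per protein (site i = protein i).
#' @param acq An [acquisition_params()].
#' @param seed Integer seed (localization noise and background).
#' @return A [loc_table()] with columns `frame`, `x`, `y`, `uncertainty`
#'   and an extra column `site` (ground-truth protein id; 0 for background
#'   rows). The table is sorted by frame, then x, then y.
#' @export
simulate_localizations <- function(map, events, acq, seed) {
  stopifnot(inherits(map, "ground_truth_map"),
            inherits(acq, "acquisition_params"))
  set.seed(derive_seed(seed, "localizations"))
  n_prot <- nrow(map$proteins)
  frames <- event_frames(events, site_count = n_prot)
  n_per_site <- lengths(frames)
  total <- sum(n_per_site)
  site <- rep(seq_len(n_prot), n_per_site)
  frame <- unlist(frames, use.names = FALSE)
  if (is.null(frame)) frame <- integer(0)
  x <- map$proteins$x[site] +
    stats::rnorm(total, 0, acq$loc_precision_sigma)
  y <- map$proteins$y[site] +
    stats::rnorm(total, 0, acq$loc_precision_sigma)
  unc <- sample_uncertainty(total, acq)

  # uniform spatio-temporal single-frame background
  bg_rate <- map$config$background_rate
  n_bg <- if (bg_rate > 0) {
    stats::rpois(1L, bg_rate * map$area_um2 * acq$n_frames)
  } else 0L
  if (n_bg > 0) {
    frame <- c(frame, sample.int(acq$n_frames, n_bg, replace = TRUE) - 1L)
    x <- c(x, stats::runif(n_bg, 0, map$width_nm))
    y <- c(y, stats::runif(n_bg, 0, map$height_nm))
    unc <- c(unc, sample_uncertainty(n_bg, acq))
    site <- c(site, rep(0L, n_bg))
  }
  tab <- data.frame(frame = as.integer(frame), x = x, y = y,
                    uncertainty = unc, site = as.integer(site))
  tab <- tab[order(tab$frame, tab$x, tab$y), , drop = FALSE]
  rownames(tab) <- NULL
  loc_table(tab, n_frames = acq$n_frames, pixel_size = acq$pixel_size)
}

#' Simulate a complete synthetic DNA-PAINT ROI
#'
#' Convenience wrapper chaining [simulate_protein_map()],
#' [simulate_binding_timeseries()] (one docking site per protein) and
#' [simulate_localizations()] under child seeds derived from one master
#' seed.
#'
#' @param config A [generator_config()].
#' @param acq An [acquisition_params()].
#' @param kin A [kinetics_model()].
#' @param seed Master seed.
#' @param discretize Passed to [simulate_binding_timeseries()].
#' @return A list with `truth` (ground-truth map), `events` (binding
#'   events) and `locs` (localization table).
#' @export
simulate_dna_paint <- function(config, acq, kin, seed,
                               discretize = "round") {
  truth <- simulate_protein_map(config, seed)
  n <- nrow(truth$proteins)
  if (n == 0) {
    events <- data.frame(site = integer(0), start_s = numeric(0),
                         dur_s = numeric(0), first_frame = integer(0),
                         last_frame = integer(0), truncated = logical(0))
  } else {
    events <- simulate_binding_timeseries(n, acq, kin,
                                          seed = derive_seed(seed, "events"),
                                          discretize = discretize)
  }
  locs <- simulate_localizations(truth, events, acq,
                                 seed = derive_seed(seed, "noise"))
  list(truth = truth, events = events, locs = locs)
}
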