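# Pipeline orchestration: reproducible simulate and analyze runs with a
# single human-readable configuration, per-stage logging, and manifests.
#
# Analysis stage order is fixed: uncertainty filter -> ROI selection ->
# DBSCAN -> mean-frame filter -> dark times -> calibration -> counting ->
# k-means partition -> per-ROI summaries.

#' Assemble a pipeline run configuration
#'
#' All defaults are the standard DNA-PAINT acquisition and analysis
#' settings used throughout the package: 15,000 frames at 100 ms, 130 nm
#' pixels, 1 nM imager with k_on 1e7 /M/s and tau_bright 0.27 s, 13 nm
#' uncertainty filter, DBSCAN eps 10 nm / minPts 15, 3.5 um square ROIs,
#' calibration on clusters under 100 nm extent, 3-protein minimum cluster
#' size and small/medium/large classes at <6 / 6-12 / >12.
#'
#' @param acquisition,kinetics,generator,clustering Parameter objects from
#'   [acquisition_params()], [kinetics_model()], [generator_config()],
#'   [clustering_params()].
#' @param max_uncertainty Localization-uncertainty threshold in nm.
#' @param calibration_max_extent Spatial eligibility for calibration
#'   clusters (nm).
#' @param calibration_q_i1 Optional externally supplied single-protein
#'   index (Hz); when set, the calibrate stage is skipped.
#' @param linking_radius,min_cluster_size Protein grouping parameters (nm,
#'   proteins).
#' @param roi_width,roi_height ROI extent in nm.
#' @param discretize Simulator frame-discretization model.
#' @param seed Master seed for the run.
#' @return An object of class `qpaint_config` (a named list; round-trips
#'   losslessly through [write_config()] / [read_config()]).
#' @export
qpaint_config <- function(acquisition = acquisition_params(),
                          kinetics = kinetics_model(),
                          generator = generator_config(),
                          clustering = clustering_params(),
                          max_uncertainty = 13,
                          calibration_max_extent = 100,
                          calibration_q_i1 = NULL,
                          linking_radius = 60,
                          min_cluster_size = 3L,
                          roi_width = 3500, roi_height = 3500,
                          discretize = "round",
                          seed = 1L) {
  stopifnot(inherits(acquisition, "acquisition_params"),
            inherits(kinetics, "kinetics_model"),
            inherits(generator, "generator_config"),
            inherits(clustering, "clustering_params"))
  structure(
    list(acquisition = acquisition, kinetics = kinetics,
         generator = generator, clustering = clustering,
         max_uncertainty = max_uncertainty,
         calibration_max_extent = calibration_max_extent,
         calibration_q_i1 = calibration_q_i1,
         linking_radius = linking_radius,
         min_cluster_size = as.integer(min_cluster_size),
         roi_width = roi_width, roi_height = roi_height,
         discretize = discretize, seed = as.integer(seed)),
    class = "qpaint_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A [qpaint_config()].
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns the reconstructed `qpaint_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "qpaint_config"))
  plain <- lapply(config, function(x) {
    if (is.object(x)) unclass(x) else x
  })
  plain$generator$size_class_weights <-
    as.list(plain$generator$size_class_weights)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (block in c("acquisition", "kinetics", "generator", "clustering")) {
    if (is.null(raw[[block]])) {
      stop(sprintf("configuration is missing the '%s' block", block),
           call. = FALSE)
    }
  }
  gw <- unlist(raw$generator$size_class_weights)
  gr <- lapply(raw$generator$size_class_ranges, unlist)
  qpaint_config(
    acquisition = do.call(acquisition_params, raw$acquisition),
    kinetics = do.call(kinetics_model, raw$kinetics),
    generator = do.call(generator_config, utils::modifyList(
      raw$generator, list(size_class_weights = gw,
                          size_class_ranges = gr))),
    clustering = do.call(clustering_params, raw$clustering),
    max_uncertainty = raw$max_uncertainty,
    calibration_max_extent = raw$calibration_max_extent,
    calibration_q_i1 = raw$calibration_q_i1,
    linking_radius = raw$linking_radius,
    min_cluster_size = raw$min_cluster_size,
    roi_width = raw$roi_width, roi_height = raw$roi_height,
    discretize = raw$discretize, seed = raw$seed)
}

#' Simulate a synthetic DNA-PAINT dataset to disk
#'
#' Writes the localization table (CSV), the ground-truth protein sidecar
#' (CSV), a config echo (YAML) and a JSON manifest into `out_dir`. Given
#' the same configuration and seed the outputs are identical between runs.
#'
#' @param config A [qpaint_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the simulation (`truth`, `events`,
#'   `locs`) and the written `paths`.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "qpaint_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  sim <- simulate_dna_paint(config$generator, config$acquisition,
                            config$kinetics, seed = config$seed,
                            discretize = config$discretize)
  paths <- list(
    locs = file.path(out_dir, "localizations.csv"),
    truth = file.path(out_dir, "ground_truth.csv"),
    config = file.path(out_dir, "config.yaml"),
    manifest = file.path(out_dir, "manifest.json"))
  write_localizations(sim$locs, paths$locs)
  utils::write.csv(sim$truth$proteins, paths$truth, row.names = FALSE)
  write_config(config, paths$config)
  manifest <- list(
    stage = "simulate",
    seed = config$seed,
    n_proteins = nrow(sim$truth$proteins),
    n_localizations = nrow(sim$locs),
    density_config = config$generator$density,
    config_hash = config_hash(config))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(sim, list(paths = paths)))
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))),
             collapse = "\n")
  # small rolling hash; stdlib-only fingerprint for the manifest
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Analyze one ROI's localization table
#'
#' Core in-memory pipeline for a single ROI (coordinates already relative
#' to the ROI): uncertainty filter, DBSCAN, mean-frame filter, per-cluster
#' dark times and qPAINT indexes, copy-number counting against a
#' calibration, k-means partitioning and per-ROI summary.
#'
#' @param tab The ROI's [loc_table()].
#' @param config A [qpaint_config()].
#' @param calibration A `qpaint_calibration`; if `NULL`, calibration is
#'   fitted from this ROI's own eligible clusters.
#' @return A list of class `roi_analysis`: `summary` (one-row data.frame
#'   from [summarize_roi()]), `per_cluster` (data.frame `cluster`,
#'   `n_locs`, `tau_d_s`, `q_i_hz`, `raw_ratio`, `n_proteins`), `map`
#'   (the `protein_map`), `calibration`, and `log` (per-stage record
#'   counts).
#' @export
analyze_roi <- function(tab, config = qpaint_config(), calibration = NULL) {
  stopifnot(inherits(tab, "loc_table"), inherits(config, "qpaint_config"))
  log <- list(input = nrow(tab))
  ft <- config$acquisition$frame_time

  tab <- filter_uncertainty(tab, config$max_uncertainty)
  log$after_uncertainty_filter <- nrow(tab)

  labels <- dbscan_localizations(tab, config$clustering)
  clusters <- loc_clusters(tab, labels)
  log$dbscan_clusters <- nrow(clusters$summary)

  mff <- mean_frame_filter(clusters)
  clusters <- mff$clusters
  log$after_mean_frame_filter <- nrow(clusters$summary)
  log$mean_frame_mu <- mff$mu
  log$mean_frame_sigma <- mff$sigma

  q <- cluster_qpaint_indexes(clusters, ft)
  usable <- !is.na(q)
  clusters <- subset_clusters(clusters, usable)
  q <- q[usable]
  log$clusters_with_dark_times <- length(q)

  if (is.null(calibration)) {
    calibration <- if (!is.null(config$calibration_q_i1)) {
      qpaint_calibration(config$calibration_q_i1)
    } else {
      calibrate_qpaint(clusters, frame_time = ft,
                       max_extent = config$calibration_max_extent)
    }
  }

  counts <- count_proteins(q, calibration)
  area_um2 <- config$roi_width * config$roi_height / 1e6
  map <- build_protein_map(tab, clusters, counts$n_proteins, area_um2,
                           seed = config$seed,
                           linking_radius = config$linking_radius,
                           min_cluster_size = config$min_cluster_size)
  per_cluster <- data.frame(
    cluster = clusters$summary$cluster,
    n_locs = clusters$summary$n_locs,
    max_extent = clusters$summary$max_extent,
    mean_frame = clusters$summary$mean_frame,
    tau_d_s = 1 / q,
    q_i_hz = q,
    raw_ratio = counts$raw_ratio,
    n_proteins = counts$n_proteins)
  structure(list(summary = summarize_roi(map), per_cluster = per_cluster,
                 map = map, calibration = calibration, log = log),
            class = "roi_analysis")
}

#' Analyze several ROIs with one pooled calibration
#'
#' Runs the per-ROI pipeline up to qPAINT indexes for every ROI, pools all
#' eligible small clusters across ROIs into a single calibration fit
#' (unless a calibration is supplied), then completes counting and
#' summaries per ROI.
#'
#' @param tabs A list of ROI [loc_table()]s.
#' @param config A [qpaint_config()].
#' @param calibration Optional `qpaint_calibration` to skip the pooled
#'   calibration stage.
#' @return A list: `summaries` (one row per ROI), `analyses` (list of
#'   `roi_analysis`), `calibration`.
#' @export
analyze_rois <- function(tabs, config = qpaint_config(),
                         calibration = NULL) {
  ft <- config$acquisition$frame_time
  if (is.null(calibration)) {
    if (!is.null(config$calibration_q_i1)) {
      calibration <- qpaint_calibration(config$calibration_q_i1)
    } else {
      pooled <- unlist(lapply(tabs, function(tab) {
        tab <- filter_uncertainty(tab, config$max_uncertainty)
        labels <- dbscan_localizations(tab, config$clustering)
        clusters <- mean_frame_filter(loc_clusters(tab, labels))$clusters
        q <- cluster_qpaint_indexes(clusters, ft)
        q[!is.na(q) &
            clusters$summary$max_extent < config$calibration_max_extent]
      }))
      calibration <- calibrate_qpaint(pooled)
    }
  }
  analyses <- lapply(tabs, analyze_roi, config = config,
                     calibration = calibration)
  summaries <- do.call(rbind, lapply(analyses, `[[`, "summary"))
  rownames(summaries) <- NULL
  list(summaries = summaries, analyses = analyses,
       calibration = calibration)
}

#' Analyze a localization file to disk
#'
#' File-level counterpart of [analyze_roi()]: reads a localization CSV,
#' applies the uncertainty filter, cuts seeded random ROIs (or treats the
#' whole field as one ROI when it is no larger than the configured ROI),
#' analyses them with a pooled calibration, and writes per-cluster and
#' per-ROI CSVs plus a calibration JSON and a run manifest into
#' `out_dir`.
#'
#' @param loc_path Path to a localization CSV (native schema).
#' @param config A [qpaint_config()].
#' @param out_dir Output directory.
#' @param n_rois Number of random ROIs to cut when the field is larger
#'   than one ROI (default 1).
#' @return Invisibly, the [analyze_rois()] result plus `paths`.
#' @export
run_analyze <- function(loc_path, config, out_dir, n_rois = 1L) {
  stopifnot(inherits(config, "qpaint_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  tab <- read_localizations(loc_path)
  # a field no larger than one ROI (up to localization-noise spill-over)
  # is analysed whole
  whole_field <- diff(range(tab$x)) <= 1.05 * config$roi_width &&
    diff(range(tab$y)) <= 1.05 * config$roi_height
  tabs <- if (whole_field) {
    list(tab)
  } else {
    rois <- sample_rois(tab, n_rois, width = config$roi_width,
                        height = config$roi_height,
                        seed = config$seed)
    lapply(rois, function(r) select_roi(tab, r))
  }
  res <- analyze_rois(tabs, config)

  per_cluster <- do.call(rbind, lapply(seq_along(res$analyses), function(i) {
    cbind(roi = i, res$analyses[[i]]$per_cluster)
  }))
  paths <- list(
    per_cluster = file.path(out_dir, "per_cluster.csv"),
    summaries = file.path(out_dir, "roi_summaries.csv"),
    calibration = file.path(out_dir, "calibration.json"),
    manifest = file.path(out_dir, "manifest.json"))
  utils::write.csv(per_cluster, paths$per_cluster, row.names = FALSE)
  utils::write.csv(cbind(roi = seq_len(nrow(res$summaries)),
                         res$summaries),
                   paths$summaries, row.names = FALSE)
  cal <- res$calibration
  jsonlite::write_json(
    list(q_i1_hz = cal$q_i1, peak_sigma_hz = cal$peak_sigma,
         counting_precision_proteins = cal$counting_precision,
         n_calibration_clusters = cal$n_calibration_clusters,
         method = cal$method),
    paths$calibration, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    stage = "analyze",
    stage_order = c("uncertainty_filter", "roi_selection", "dbscan",
                    "mean_frame_filter", "dark_times", "calibration",
                    "counting", "kmeans", "summaries"),
    input = loc_path,
    seed = config$seed,
    n_rois = length(tabs),
    calibration_supplied = !is.null(config$calibration_q_i1),
    config_hash = config_hash(config),
    logs = lapply(res$analyses, `[[`, "log"))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(res, list(paths = paths)))
}
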