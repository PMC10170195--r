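# qPAINT: from a cluster's event time series to a dark time, a qPAINT
# index, and (after calibration) a protein copy number.
#
# The counting principle: N = (k_on * [I] * tau_off)^-1 = tau_off1 /
# tau_off, i.e. each additional docking site in a cluster shortens the mean
# dark time proportionally, so the ratio of a cluster's qPAINT index
# q_i = 1/tau_d to the single-site calibration index q_i1 is the copy
# number.

#' Extract dark times from a cluster's event frames
#'
#' Consecutive distinct event frames `f_a < f_b` separated by `g` empty
#' frames (`f_b - f_a = g + 1`) contribute one dark time `g * frame_time`;
#' runs of consecutive frames contribute nothing. The censored intervals
#' before the first and after the last event are excluded: they are
#' right/left-censored draws whose inclusion would bias the mean dark time
#' upward.
#'
#' @param event_frames Integer vector of frames containing events
#'   (duplicates and unsorted input tolerated).
#' @param frame_time Seconds per frame.
#' @return Numeric vector of dark times in seconds (possibly empty; empty
#'   input yields an empty vector with a warning).
#' @export
extract_dark_times <- function(event_frames, frame_time) {
  stop_if_not_scalar_number(frame_time, "frame_time", positive = TRUE)
  if (length(event_frames) == 0) {
    warning("no event frames; returning no dark times")
    return(numeric(0))
  }
  f <- sort(unique(as.integer(event_frames)))
  gaps <- diff(f) - 1L
  gaps[gaps > 0] * frame_time
}

#' Fit the mean dark time
#'
#' Least-squares fit of the empirical cumulative distribution of the dark
#' times to `1 - exp(-t / tau_d)`, using every observed gap as its own
#' abscissa (no histogram binning). With fewer than `min_gaps` gaps the
#' sample mean is returned instead and flagged; a degenerate all-identical
#' sample returns that value exactly.
#'
#' @param dark_times Numeric vector of dark times (s), all > 0.
#' @param min_gaps Minimum number of gaps for a CDF fit (default 5).
#' @return A list of class `dark_time_fit`: `tau_d` (s), `n_gaps`,
#'   `method` (`"cdf_fit"` or `"sample_mean"`), `residual` (sum of squared
#'   CDF residuals; `NA` for the fallback).
#' @export
fit_dark_time <- function(dark_times, min_gaps = 5L) {
  if (length(dark_times) == 0) {
    stop("cannot fit a dark time to zero gaps", call. = FALSE)
  }
  if (any(dark_times <= 0)) stop("dark times must be > 0", call. = FALSE)
  n <- length(dark_times)
  t <- sort(dark_times)
  if (n < min_gaps || length(unique(t)) == 1L) {
    return(structure(list(tau_d = mean(t), n_gaps = n,
                          method = "sample_mean", residual = NA_real_),
                     class = "dark_time_fit"))
  }
  p <- (seq_len(n) - 0.5) / n  # plotting positions of the empirical CDF
  sse <- function(log_tau) {
    r <- p - (1 - exp(-t / exp(log_tau)))
    sum(r * r)
  }
  opt <- stats::optimize(sse, interval = log(c(mean(t) / 50, mean(t) * 50)))
  structure(list(tau_d = exp(opt$minimum), n_gaps = n,
                 method = "cdf_fit", residual = opt$objective),
            class = "dark_time_fit")
}

#' @export
print.dark_time_fit <- function(x, ...) {
  cat(sprintf("tau_d = %.4g s (%s, %d gaps)\n", x$tau_d, x$method, x$n_gaps))
  invisible(x)
}

#' qPAINT index of a cluster
#'
#' @param tau_d Mean dark time in seconds (> 0), or a
#'   [fit_dark_time()] result.
#' @return The qPAINT index `q_i = 1 / tau_d` in Hz.
#' @export
qpaint_index <- function(tau_d) {
  if (inherits(tau_d, "dark_time_fit")) tau_d <- tau_d$tau_d
  stop_if_not_scalar_number(tau_d, "tau_d", positive = TRUE)
  1 / tau_d
}

# qPAINT indexes for every cluster in a loc_clusters object.
cluster_qpaint_indexes <- function(clusters, frame_time, min_gaps = 5L) {
  vapply(clusters$frames, function(f) {
    dt <- suppressWarnings(extract_dark_times(f, frame_time))
    if (length(dt) == 0) return(NA_real_)
    qpaint_index(fit_dark_time(dt, min_gaps = min_gaps))
  }, 0)
}

#' Calibrate the single-protein qPAINT index
#'
#' Builds the histogram of qPAINT indexes of spatially small clusters
#' (maximum pairwise extent strictly below `max_extent`; such clusters
#' contain one or a few docking sites) and fits a sum of `K` Gaussians
#' whose centres are constrained to integer multiples of a shared
#' fundamental `q_i1`:
#' `f(q) = sum_k A_k exp(-(q - k q_i1)^2 / (2 s_k^2))`.
#' The fundamental is seeded from the first mode of a kernel density
#' estimate (with `mode/2` tried as an alternative seed against
#' missing-fundamental degeneracy) and refined by nonlinear least squares.
#' The counting precision is reported as `sigma_1 / q_i1` in protein
#' units.
#'
#' @param clusters A [loc_clusters()] object, or a numeric vector of
#'   qPAINT indexes (then `extents` must be given or is ignored).
#' @param frame_time Seconds per frame (needed when `clusters` is a
#'   `loc_clusters` object).
#' @param max_extent Spatial eligibility threshold in nm (default 100).
#' @param n_peaks Number of Gaussian peaks `K` (default 4).
#' @param min_clusters Minimum eligible clusters required (default 50).
#' @param n_bins Histogram bin count for the fit (default 40).
#' @return An object of class `qpaint_calibration`: `q_i1` (Hz),
#'   `peak_sigma` (Hz), `counting_precision` (proteins),
#'   `n_calibration_clusters`, `method` (`"multi_gauss"` or
#'   `"mode_fallback"`), and the fitted `peaks` data.frame.
#' @export
calibrate_qpaint <- function(clusters, frame_time = NULL, max_extent = 100,
                             n_peaks = 4L, min_clusters = 50L, n_bins = 40L) {
  if (inherits(clusters, "loc_clusters")) {
    if (is.null(frame_time)) {
      stop("'frame_time' is required with a loc_clusters input", call. = FALSE)
    }
    q <- cluster_qpaint_indexes(clusters, frame_time)
    eligible <- clusters$summary$max_extent < max_extent & !is.na(q)
    q <- q[eligible]
  } else {
    q <- clusters[!is.na(clusters)]
  }
  if (length(q) < min_clusters) {
    stop(sprintf("only %d eligible calibration clusters (need >= %d)",
                 length(q), min_clusters), call. = FALSE)
  }

  # Seed the fundamental from the FIRST substantial local mode of the index
  # density (not the global mode: in a mixture the global mode can sit on a
  # higher multiple, and halving it is not an option because a halved
  # fundamental with free amplitudes always nests the true model).
  dens <- stats::density(q, n = 512)
  is_max <- which(diff(sign(diff(dens$y))) == -2) + 1L
  is_max <- is_max[dens$y[is_max] >= 0.2 * max(dens$y)]
  q1_mode <- if (length(is_max)) dens$x[min(is_max)] else
    dens$x[which.max(dens$y)]
  # histogram only the region the K-peak model can describe: a long tail
  # of indexes beyond K multiples would otherwise dilate the bins and
  # blur the fundamental peak
  q_fit <- q[q <= (n_peaks + 2.5) * q1_mode]
  n_bins_eff <- max(n_bins, min(80L, round(2 * sqrt(length(q_fit)))))
  h <- graphics::hist(q_fit, breaks = seq(0, max(q_fit),
                                          length.out = n_bins_eff + 1L),
                      plot = FALSE)
  mids <- h$mids
  counts <- h$counts

  fit_one <- function(q1_init, k_peaks) {
    start <- list(q1 = q1_init)
    # narrow bounds per start: the multi-start grid explores candidate
    # fundamentals; within one fit the fundamental must not drift to a
    # subharmonic (q1/2 with free amplitudes always nests the truth)
    lower <- c(q1 = q1_init / 1.3)
    upper <- c(q1 = q1_init * 1.3)
    for (k in seq_len(k_peaks)) {
      a0 <- max(counts[abs(mids - k * q1_init) <= q1_init / 2],
                0.01 * max(counts))
      start[[paste0("A", k)]] <- a0
      start[[paste0("s", k)]] <- q1_init / 4
      lower <- c(lower, 0, q1_init / 50)
      upper <- c(upper, Inf, q1_init * 2)
    }
    fml <- stats::as.formula(paste(
      "counts ~",
      paste(sprintf("A%d * exp(-(mids - %d * q1)^2 / (2 * s%d^2))",
                    seq_len(k_peaks), seq_len(k_peaks), seq_len(k_peaks)),
            collapse = " + ")))
    try(minpack.lm::nlsLM(
      fml, data = data.frame(mids = mids, counts = counts),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  }

  # Multi-start over candidate fundamentals at and below the first mode
  # (a blended monomer/dimer mode sits above the true fundamental, never
  # below it). Candidates whose first peak carries almost no mass are
  # implausible as a fundamental and are discarded before RSS selection.
  cands <- list()
  for (init in q1_mode * c(1, 0.85, 0.7, 0.55)) {
    # only peaks whose centre lies inside the observed index range are
    # identifiable from the histogram; on failure retry with fewer peaks
    k_max <- max(1L, min(n_peaks, floor(max(mids) / init)))
    for (k_peaks in rev(seq_len(k_max))) {
      fit <- fit_one(init, k_peaks)
      if (inherits(fit, "try-error")) next
      cf <- stats::coef(fit)
      mass <- cf[paste0("A", seq_len(k_peaks))] *
        cf[paste0("s", seq_len(k_peaks))]
      cands[[length(cands) + 1L]] <- list(
        fit = fit, rss = sum(stats::residuals(fit)^2),
        mass1 = unname(mass[1] / sum(mass)))
      break
    }
  }
  best <- NULL
  plausible <- Filter(function(cc) cc$mass1 >= 0.15, cands)
  pool <- if (length(plausible)) plausible else cands
  for (cc in pool) {
    if (is.null(best) || cc$rss < best$rss) best <- cc
  }

  if (is.null(best)) {
    warning("multi-peak fit failed; falling back to the histogram mode ",
            "(degraded precision)")
    return(structure(
      list(q_i1 = q1_mode, peak_sigma = NA_real_,
           counting_precision = NA_real_,
           n_calibration_clusters = length(q),
           method = "mode_fallback", peaks = NULL),
      class = "qpaint_calibration"))
  }
  cf <- stats::coef(best$fit)
  q1 <- unname(cf[["q1"]])
  s1 <- unname(cf[["s1"]])
  k_fit <- sum(grepl("^A", names(cf)))
  peaks <- data.frame(
    k = seq_len(k_fit),
    centre = q1 * seq_len(k_fit),
    amplitude = unname(cf[paste0("A", seq_len(k_fit))]),
    sigma = unname(cf[paste0("s", seq_len(k_fit))])
  )
  structure(
    list(q_i1 = q1, peak_sigma = s1, counting_precision = s1 / q1,
         n_calibration_clusters = length(q),
         method = "multi_gauss", peaks = peaks),
    class = "qpaint_calibration")
}

#' Construct a calibration object directly
#'
#' For supplying an externally determined single-protein index (e.g. from a
#' previous calibration run) to [count_proteins()] or [run_analyze()].
#'
#' @param q_i1 Single-protein qPAINT index in Hz (> 0).
#' @param peak_sigma First-peak SD in Hz (optional).
#' @return A `qpaint_calibration` object.
#' @export
qpaint_calibration <- function(q_i1, peak_sigma = NA_real_) {
  stop_if_not_scalar_number(q_i1, "q_i1", positive = TRUE)
  structure(
    list(q_i1 = q_i1, peak_sigma = peak_sigma,
         counting_precision = if (is.na(peak_sigma)) NA_real_
         else peak_sigma / q_i1,
         n_calibration_clusters = NA_integer_,
         method = "supplied", peaks = NULL),
    class = "qpaint_calibration")
}

#' @export
print.qpaint_calibration <- function(x, ...) {
  cat(sprintf("qPAINT calibration: q_i1 = %.4g Hz (%s", x$q_i1, x$method))
  if (!is.na(x$counting_precision)) {
    cat(sprintf(", counting precision +/- %.2g proteins",
                x$counting_precision))
  }
  cat(")\n")
  invisible(x)
}

#' Protein copy number of a cluster
#'
#' `N = max(1, round(q_i / q_i1))`, rounding halves away from zero.
#'
#' @param q_i qPAINT index (Hz) of the cluster (vectorized).
#' @param calibration A `qpaint_calibration`.
#' @return A data.frame with `raw_ratio` (`q_i / q_i1`) and `n_proteins`.
#' @export
count_proteins <- function(q_i, calibration) {
  stopifnot(inherits(calibration, "qpaint_calibration"))
  raw <- q_i / calibration$q_i1
  data.frame(raw_ratio = raw,
             n_proteins = pmax(1L, as.integer(floor(raw + 0.5))))
}
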