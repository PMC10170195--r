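#' Acquisition parameters for a DNA-PAINT experiment
#'
#' Bundles the camera/acquisition settings that the simulator and the
#' analysis pipeline share. Defaults correspond to a typical TIRF DNA-PAINT
#' acquisition: 15,000 frames at 100 ms integration, 130 nm pixel size, and
#' ~9 nm per-axis localization precision.
#'
#' @param n_frames Number of camera frames (>= 1).
#' @param frame_time Integration time per frame in seconds (> 0).
#' @param pixel_size Camera pixel size in nm (> 0); used only when converting
#'   pixel-dialect localization files to nm.
#' @param loc_precision_sigma Per-axis standard deviation of the Gaussian
#'   localization error, in nm (>= 0).
#' @param uncertainty_mean,uncertainty_sd Parameters (nm) of the truncated
#'   Gaussian from which per-localization reported uncertainties are sampled
#'   by the simulator. Defaults keep almost all values below the standard
#'   13 nm quality threshold.
#' @return An object of class `acquisition_params`.
#' @seealso [kinetics_model()], [expected_localizations_per_site()]
#' @export
acquisition_params <- function(n_frames = 15000L,
                               frame_time = 0.1,
                               pixel_size = 130,
                               loc_precision_sigma = 9,
                               uncertainty_mean = 9,
                               uncertainty_sd = 2) {
  stop_if_not_scalar_number(n_frames, "n_frames", positive = TRUE)
  if (n_frames < 1 || n_frames != floor(n_frames)) {
    stop("'n_frames' must be a positive integer", call. = FALSE)
  }
  stop_if_not_scalar_number(frame_time, "frame_time", positive = TRUE)
  stop_if_not_scalar_number(pixel_size, "pixel_size", positive = TRUE)
  stop_if_not_scalar_number(loc_precision_sigma, "loc_precision_sigma",
                            nonnegative = TRUE)
  stop_if_not_scalar_number(uncertainty_mean, "uncertainty_mean",
                            nonnegative = TRUE)
  stop_if_not_scalar_number(uncertainty_sd, "uncertainty_sd",
                            nonnegative = TRUE)
  structure(
    list(n_frames = as.integer(n_frames), frame_time = frame_time,
         pixel_size = pixel_size, loc_precision_sigma = loc_precision_sigma,
         uncertainty_mean = uncertainty_mean, uncertainty_sd = uncertainty_sd),
    class = "acquisition_params"
  )
}

#' Imager-docking binding kinetics
#'
#' Two-state binding kinetics of the freely diffusing imager strand to a
#' docking strand: binding events arrive at rate `k_on * imager_conc`
#' (s^-1) per free site and last `Exponential(mean = tau_bright)` seconds.
#' Defaults are typical for a speed-optimized imager sequence at 1 nM:
#' k_on = 1e7 /M/s, tau_bright = 0.27 s.
#'
#' @param k_on Association rate constant in M^-1 s^-1 (> 0).
#' @param imager_conc Imager concentration in molar (>= 0; zero is allowed
#'   and yields no binding events).
#' @param tau_bright Mean bright-event duration in seconds (> 0).
#' @return An object of class `kinetics_model`.
#' @export
kinetics_model <- function(k_on = 1e7, imager_conc = 1e-9, tau_bright = 0.27) {
  stop_if_not_scalar_number(k_on, "k_on", positive = TRUE)
  stop_if_not_scalar_number(imager_conc, "imager_conc", nonnegative = TRUE)
  stop_if_not_scalar_number(tau_bright, "tau_bright", positive = TRUE)
  structure(
    list(k_on = k_on, imager_conc = imager_conc, tau_bright = tau_bright),
    class = "kinetics_model"
  )
}

#' Binding rate per free docking site
#'
#' @param kin A [kinetics_model()].
#' @return Rate in s^-1 (`k_on * imager_conc`).
#' @export
binding_rate <- function(kin) {
  stopifnot(inherits(kin, "kinetics_model"))
  kin$k_on * kin$imager_conc
}

#' Expected localizations per docking strand
#'
#' The standard planning formula for DNA-PAINT:
#' `N_frames * tau_bright * k_on * [Imager]`, i.e. the expected total bound
#' time expressed in frame units. With 15,000 frames, tau_bright = 0.27 s,
#' k_on = 1e7 /M/s and 1 nM imager this evaluates to 40.5 (floored: 40).
#' It is the usual basis for choosing the DBSCAN `minPts` threshold (see
#' [min_points_from_poisson()]).
#'
#' @param acq An [acquisition_params()].
#' @param kin A [kinetics_model()].
#' @param floor If `TRUE`, return the integer floor of the product.
#' @return Expected number of localizations (a pure number).
#' @export
expected_localizations_per_site <- function(acq, kin, floor = FALSE) {
  stopifnot(inherits(acq, "acquisition_params"),
            inherits(kin, "kinetics_model"))
  value <- acq$n_frames * kin$tau_bright * binding_rate(kin)
  if (floor) base::floor(value) else value
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat(sprintf(
    "Acquisition: %d frames x %.3g s (%.0f s total), pixel %.3g nm, sigma_loc %.3g nm\n",
    x$n_frames, x$frame_time, x$n_frames * x$frame_time, x$pixel_size,
    x$loc_precision_sigma))
  invisible(x)
}

#' @export
print.kinetics_model <- function(x, ...) {
  cat(sprintf(
    "Kinetics: k_on %.3g /M/s, [imager] %.3g M -> on-rate %.3g /s; tau_bright %.3g s\n",
    x$k_on, x$imager_conc, x$k_on * x$imager_conc, x$tau_bright))
  invisible(x)
}
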