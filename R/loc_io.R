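# Localization tables: the pipeline's universal currency.
#
# A localization table is a data.frame with one row per single-molecule
# localization event: `frame` (0-based integer), `x`, `y` (nm) and
# `uncertainty` (nm), carrying `n_frames` and `pixel_size` as attributes.
# All coordinates are nanometres everywhere inside the package; frames are
# 0-based; ROI boxes are half-open on both axes.

#' Construct (and validate) a localization table
#'
#' @param df A data.frame with columns `frame`, `x`, `y`, `uncertainty`
#'   (extra columns are preserved).
#' @param n_frames Number of frames in the acquisition; defaults to
#'   `max(frame) + 1`.
#' @param pixel_size Camera pixel size in nm (metadata only).
#' @param source Optional source file path (metadata).
#' @return The validated table with class `loc_table`.
#' @export
loc_table <- function(df, n_frames = NULL, pixel_size = NA_real_,
                      source = NA_character_) {
  required <- c("frame", "x", "y", "uncertainty")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("localization table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) > 0) {
    if (any(df$frame < 0)) stop("negative frame numbers", call. = FALSE)
    if (any(!is.finite(df$x)) || any(!is.finite(df$y))) {
      stop("non-finite coordinates", call. = FALSE)
    }
    if (any(df$uncertainty < 0)) {
      stop("negative uncertainties", call. = FALSE)
    }
  }
  df$frame <- as.integer(df$frame)
  n_frames <- n_frames %||% (if (nrow(df)) max(df$frame) + 1L else 0L)
  if (nrow(df) && any(df$frame >= n_frames)) {
    stop("frame numbers exceed n_frames - 1", call. = FALSE)
  }
  structure(df, n_frames = as.integer(n_frames), pixel_size = pixel_size,
            source = source, class = c("loc_table", "data.frame"))
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("Localization table: %d rows, %d frames\n",
              nrow(x), attr(x, "n_frames")))
  NextMethod()
}

n_frames_of <- function(tab) {
  attr(tab, "n_frames") %||% (if (nrow(tab)) max(tab$frame) + 1L else 0L)
}

# rebuild a loc_table after row subsetting, keeping metadata
restamp <- function(df, template, n_frames = NULL) {
  rownames(df) <- NULL
  loc_table(as.data.frame(df),
            n_frames = n_frames %||% attr(template, "n_frames"),
            pixel_size = attr(template, "pixel_size"),
            source = attr(template, "source"))
}

#' Read a localization table
#'
#' Reads a CSV localization file in either of two dialects:
#' \describe{
#'   \item{`"csv"`}{columns `frame`, `x_nm`, `y_nm`, `uncertainty_nm`
#'     (the package's native schema; plain `x`/`y`/`uncertainty` headers are
#'     also accepted). Coordinates already in nm.}
#'   \item{`"pixel_csv"`}{columns `frame`, `x`, `y` (camera pixels) and
#'     `uncertainty` (pixels); coordinates and uncertainty are multiplied by
#'     `pixel_size`.}
#' }
#' Row order is preserved; an empty file with a valid header yields an
#' empty table.
#'
#' @param path File path.
#' @param dialect `"csv"` (nm) or `"pixel_csv"` (camera pixels).
#' @param pixel_size nm per camera pixel; required for `"pixel_csv"`.
#' @param n_frames Optional number of frames in the acquisition.
#' @return A [loc_table()].
#' @export
read_localizations <- function(path, dialect = c("csv", "pixel_csv"),
                               pixel_size = NULL, n_frames = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm_alias <- c(x_nm = "x", y_nm = "y", uncertainty_nm = "uncertainty")
  for (a in names(nm_alias)) {
    if (a %in% names(df)) names(df)[names(df) == a] <- nm_alias[[a]]
  }
  required <- c("frame", "x", "y", "uncertainty")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("'%s' is missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (dialect == "pixel_csv") {
    if (is.null(pixel_size)) {
      stop("'pixel_size' is required for the pixel dialect", call. = FALSE)
    }
    df$x <- df$x * pixel_size
    df$y <- df$y * pixel_size
    df$uncertainty <- df$uncertainty * pixel_size
  }
  loc_table(df, n_frames = n_frames,
            pixel_size = pixel_size %||% NA_real_, source = path)
}

#' Write a localization table as CSV
#'
#' Writes the native schema `frame`, `x_nm`, `y_nm`, `uncertainty_nm`
#' (plus any extra columns), readable back with [read_localizations()].
#'
#' @param tab A [loc_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(tab, path) {
  out <- as.data.frame(tab)
  names(out)[match(c("x", "y", "uncertainty"), names(out))] <-
    c("x_nm", "y_nm", "uncertainty_nm")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Remove poorly localized events
#'
#' Drops rows whose reported localization uncertainty is strictly greater
#' than the threshold (a row at exactly the threshold is kept). The
#' standard quality threshold for DNA-PAINT data is 13 nm.
#'
#' @param tab A [loc_table()].
#' @param max_uncertainty Threshold in nm (>= 0).
#' @return The filtered [loc_table()].
#' @export
filter_uncertainty <- function(tab, max_uncertainty = 13) {
  stop_if_not_scalar_number(max_uncertainty, "max_uncertainty",
                            nonnegative = TRUE)
  restamp(tab[tab$uncertainty <= max_uncertainty, , drop = FALSE], tab)
}

#' Rectangular region of interest
#'
#' @param x0,y0 Origin in nm.
#' @param width,height Extent in nm (> 0); default 3500 x 3500 nm
#'   (3.5 x 3.5 um).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(x0 = 0, y0 = 0, width = 3500, height = 3500) {
  stop_if_not_scalar_number(width, "width", positive = TRUE)
  stop_if_not_scalar_number(height, "height", positive = TRUE)
  structure(list(x0 = x0, y0 = y0, width = width, height = height),
            class = "roi_spec")
}

#' Cut a region of interest out of a localization table
#'
#' Keeps rows with `x0 <= x < x0 + width` and `y0 <= y < y0 + height`
#' (half-open on both axes, so a point exactly on the right or top edge is
#' excluded) and re-expresses coordinates relative to the ROI origin.
#'
#' @param tab A [loc_table()].
#' @param roi A [roi_spec()].
#' @return The cropped, re-origined [loc_table()].
#' @export
select_roi <- function(tab, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  keep <- tab$x >= roi$x0 & tab$x < roi$x0 + roi$width &
    tab$y >= roi$y0 & tab$y < roi$y0 + roi$height
  out <- tab[keep, , drop = FALSE]
  out$x <- out$x - roi$x0
  out$y <- out$y - roi$y0
  restamp(out, tab)
}

#' Sample random ROIs with a minimum occupancy
#'
#' Draws candidate ROI origins uniformly over the field and keeps those
#' containing at least `min_locs` localizations — a deterministic, seeded
#' stand-in for the manual ROI picking used in interactive render tools.
#'
#' @param tab A [loc_table()].
#' @param n Number of ROIs wanted.
#' @param width,height ROI extent in nm.
#' @param min_locs Minimum localization count for a candidate to qualify.
#' @param seed Integer seed.
#' @param max_tries Candidate draws before giving up.
#' @return A list of [roi_spec()]s (possibly fewer than `n`, with a
#'   warning).
#' @export
sample_rois <- function(tab, n, width = 3500, height = 3500,
                        min_locs = 500, seed = 1L, max_tries = 200L * n) {
  set.seed(derive_seed(seed, "roi_sampling"))
  xmax <- max(tab$x) - width
  ymax <- max(tab$y) - height
  if (xmax < 0 || ymax < 0) stop("field smaller than ROI", call. = FALSE)
  rois <- list()
  tries <- 0L
  while (length(rois) < n && tries < max_tries) {
    tries <- tries + 1L
    cand <- roi_spec(stats::runif(1, 0, xmax), stats::runif(1, 0, ymax),
                     width, height)
    count <- sum(tab$x >= cand$x0 & tab$x < cand$x0 + width &
                   tab$y >= cand$y0 & tab$y < cand$y0 + height)
    if (count >= min_locs) rois[[length(rois) + 1L]] <- cand
  }
  if (length(rois) < n) {
    warning(sprintf("only %d of %d ROIs reached %d localizations",
                    length(rois), n, min_locs))
  }
  rois
}
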