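# Localization precision by nearest-neighbour analysis (NeNA).
#
# Because a DNA-PAINT binding event spans several frames, the same emitter
# is localized repeatedly in adjacent frames; the spread of those repeated
# localizations is set by the localization precision. NeNA collects, for
# every localization in frame f, the distance to its nearest neighbour in
# frame f + 1 and fits the distance density with the 2D displacement
# model: for per-axis precision sigma the displacement between two
# independent localizations of the same emitter is Rayleigh with density
# p(d) = (d / 2 sigma^2) exp(-d^2 / 4 sigma^2). A linear term absorbs the
# background of unrelated neighbour pairs (uniform 2D background gives a
# density growing linearly in d at short range).

#' Adjacent-frame nearest-neighbour distances
#'
#' @param tab A [loc_table()].
#' @param max_pair_distance Pairs farther apart than this (nm) are
#'   discarded (default 200), excluding cross-cluster pairings.
#' @return Numeric vector of distances (nm).
#' @export
adjacent_frame_nn <- function(tab, max_pair_distance = 200) {
  if (nrow(tab) == 0) return(numeric(0))
  by_frame <- split(seq_len(nrow(tab)), tab$frame)
  frames <- as.integer(names(by_frame))
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    nxt <- match(frames[i] + 1L, frames)
    if (is.na(nxt)) next
    a <- by_frame[[i]]; b <- by_frame[[nxt]]
    d <- sqrt(outer(tab$x[a], tab$x[b], "-")^2 +
                outer(tab$y[a], tab$y[b], "-")^2)
    nn <- apply(d, 1, min)
    out[[i]] <- nn[nn <= max_pair_distance]
  }
  unlist(out) %||% numeric(0)
}

#' Estimate localization precision by NeNA
#'
#' Fits the adjacent-frame nearest-neighbour distance histogram with
#' `A * (d / 2 sigma^2) exp(-d^2 / 4 sigma^2) + B * d` and returns the
#' per-axis precision `sigma`.
#'
#' @param tab A [loc_table()].
#' @param max_pair_distance Pair-distance cap in nm (default 200).
#' @param min_pairs Minimum number of pairs required (default 1000).
#' @param n_bins Histogram bins over `[0, max_pair_distance]` (default 60).
#' @return An object of class `precision_estimate`: `sigma` (nm),
#'   `n_pairs`, `background` (fitted linear coefficient), `fit` (the
#'   `nls` object).
#' @export
nena_precision <- function(tab, max_pair_distance = 200, min_pairs = 1000L,
                           n_bins = 60L) {
  d <- adjacent_frame_nn(tab, max_pair_distance)
  if (length(d) < min_pairs) {
    stop(sprintf(
      "insufficient data: %d adjacent-frame pairs within %g nm (need >= %d)",
      length(d), max_pair_distance, min_pairs), call. = FALSE)
  }
  breaks <- seq(0, max_pair_distance, length.out = n_bins + 1L)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  mids <- h$mids
  counts <- h$counts
  if (stats::median(d) < 1e-9) {
    # (near-)duplicate localizations; method-of-moments degenerate limit:
    # E[d^2] = 4 sigma^2 for the displacement model
    return(structure(list(sigma = sqrt(mean(d^2) / 4), n_pairs = length(d),
                          background = 0, fit = NULL),
                     class = "precision_estimate"))
  }
  # Rayleigh scale = sigma * sqrt(2); median of Rayleigh = scale*sqrt(2 ln 2)
  sigma0 <- max(stats::median(d) / 1.665, 0.5)
  fit <- minpack.lm::nlsLM(
    counts ~ A * (mids / (2 * sigma^2)) * exp(-mids^2 / (4 * sigma^2)) +
      B * mids,
    data = data.frame(mids = mids, counts = counts),
    start = list(A = max(counts) * 2 * sigma0, sigma = sigma0, B = 0),
    lower = c(A = 0, sigma = 1e-3, B = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  structure(list(sigma = unname(cf[["sigma"]]), n_pairs = length(d),
                 background = unname(cf[["B"]]), fit = fit),
            class = "precision_estimate")
}

#' @export
print.precision_estimate <- function(x, ...) {
  cat(sprintf("NeNA localization precision: %.3g nm (%d pairs)\n",
              x$sigma, x$n_pairs))
  invisible(x)
}
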