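# Internal helpers: argument checking and deterministic seed derivation.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_number <- function(x, name, positive = FALSE,
                                      nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0 (got %g)", name, x), call. = FALSE)
  }
  if (nonnegative && x < 0) {
    stop(sprintf("'%s' must be >= 0 (got %g)", name, x), call. = FALSE)
  }
  invisible(x)
}

#' Derive a reproducible child seed from a master seed
#'
#' All stochastic stages of the pipeline draw their RNG seed from one master
#' seed plus a stage label, so that stages are independently reproducible and
#' adding a stage never perturbs the random streams of the others.
#'
#' @param master_seed Integer master seed.
#' @param label Character stage label (e.g. `"protein_map"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, label) {
  stop_if_not_scalar_number(master_seed, "master_seed")
  m <- 2147483647  # 2^31 - 1, keeps arithmetic exact in doubles
  h <- as.numeric(master_seed) %% m
  for (b in utf8ToInt(label)) {
    h <- (h * 131 + b) %% m
  }
  as.integer(h)
}

# Sort a localization table by frame then x then y; used where deterministic
# ordering is required before seeded operations.
loc_order <- function(tab) {
  tab[order(tab$frame, tab$x, tab$y), , drop = FALSE]
}
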