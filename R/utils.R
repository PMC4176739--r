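#' Convert genetic map distance to physical distance
#'
#' The simulator and the documentation use a uniform genetic map in which one
#' Morgan corresponds to 1e8 bp (1 cM/Mb). Under this map, identity-by-descent
#' segments surviving 1e5 generations of recombination have an expected length
#' of 1e-5 Morgan, i.e. 1 kb.
#'
#' @param morgans Numeric vector of distances in Morgans.
#' @param bp_per_morgan Physical bases per Morgan (default 1e8).
#' @return Numeric vector of distances in base pairs.
#' @examples
#' morgans_to_bp(1e-5) # 1000 bp: the IBD-segment scale after 1e5 generations
#' @export
morgans_to_bp <- function(morgans, bp_per_morgan = 1e8) {
  stopifnot(is.numeric(morgans), bp_per_morgan > 0)
  morgans * bp_per_morgan
}

#' @rdname morgans_to_bp
#' @param bp Numeric vector of distances in base pairs.
#' @export
bp_to_morgans <- function(bp, bp_per_morgan = 1e8) {
  stopifnot(is.numeric(bp), bp_per_morgan > 0)
  bp / bp_per_morgan
}

#' Expected surviving IBD segment length after g generations
#'
#' Renewal argument: recombination breaks a lineage's chromosome once per
#' Morgan per generation, so after `generations` meioses the expected intact
#' segment length is `1/generations` Morgan.
#'
#' @param generations Number of generations of recombination (> 0).
#' @param bp_per_morgan Physical bases per Morgan.
#' @return Expected segment length in base pairs.
#' @export
ibd_segment_length_bp <- function(generations, bp_per_morgan = 1e8) {
  stopifnot(generations > 0)
  morgans_to_bp(1 / generations, bp_per_morgan)
}

# rolling mean with NA skipping and window truncation at the ends; centered
# window of `window` elements (window odd).
rolling_mean_na <- function(x, window) {
  stopifnot(window >= 1, window %% 2 == 1)
  n <- length(x)
  half <- (window - 1) / 2
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi], na.rm = TRUE)
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
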