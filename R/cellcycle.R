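#' Normalize a cell-cycle expression profile onto the 100-point grid
#'
#' Cell-cycle expression measurements arrive as (time, log2 ratio) pairs
#' with time expressed as percent of the division cycle (100% =
#' cytokinesis). To compare profiles from different experiments the cycle
#' is divided into 100 time points (integer percents 0-99) and the
#' expression level at each point is obtained by linear interpolation.
#' Because the cycle is periodic, the default closes the profile
#' cyclically: the segment from the last raw point wraps around 100 back
#' to the first point.
#'
#' @param time numeric vector of raw time points in \[0, 100).
#' @param value numeric vector of log2 ratios, same length.
#' @param cyclic logical; wrap-around interpolation (default) or flat
#'   extrapolation outside the raw range.
#' @return numeric vector of length 100, the grid at percents 0-99.
#' @examples
#' g <- normalizeProfile(c(0, 50), c(1, 0))
#' g[26]  # percent 25 -> 0.5
#' @export
normalizeProfile <- function(time, value, cyclic = TRUE) {
  stopifnot(length(time) == length(value))
  if (length(time) < 2L)
    stop("need at least 2 raw points to interpolate")
  if (anyDuplicated(time))
    stop("duplicate time points in profile")
  if (any(time < 0 | time >= 100))
    stop("time points must lie in [0, 100)")
  o <- order(time)
  time <- time[o]
  value <- value[o]
  n <- length(time)
  if (cyclic) {
    # extend with the wrapped images of the last and first point so every
    # grid percent is bracketed
    x <- c(time[n] - 100, time, time[1] + 100)
    y <- c(value[n], value, value[1])
    stats::approx(x, y, xout = 0:99)$y
  } else {
    stats::approx(time, value, xout = 0:99, rule = 2)$y
  }
}

#' Decide co-expression of two cycle profiles
#'
#' Two genes count as co-expressed when there is at least one grid time
#' point at which both log2 ratios exceed `threshold`. The default
#' threshold 0 reads "enriched over the asynchronous baseline in that
#' phase" (log2(synchronous/asynchronous) > 0).
#'
#' @param a,b numeric grids of length 100 (see [normalizeProfile()]).
#' @param threshold numeric expression threshold.
#' @return single logical.
#' @examples
#' a <- normalizeProfile(c(0, 50), c(1, -1))
#' coexpressed(a, a)
#' @export
coexpressed <- function(a, b, threshold = 0) {
  stopifnot(length(a) == 100L, length(b) == 100L)
  any(a > threshold & b > threshold)
}
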