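# Ecological sensitivity and social-ecological sensitivity: area-weighted
# percentile transforms, the two-dataset basin combination with global-max
# normalization, and the fuzzy-sum combination with inverted adaptive
# capacity.

#' Area-weighted percentile transform of a gridded field
#'
#' Converts a field into percentile scores such that each percentile bin
#' covers an equal share of the valid surface area: cells are sorted by
#' value, the cumulative cell area is split into `bins` equal-area
#' intervals, and every cell is scored by the bin containing the midpoint
#' of its cumulative-area span, as `k / bins`. The lowest-value cells get
#' `1/bins` and the global maxima get exactly 1. Tied values share the
#' percentile of the midpoint of their combined span (so a constant field
#' scores 0.5 everywhere with the default 100 bins). Masked cells stay
#' masked.
#'
#' @param field A [geogrid].
#' @param areas Cell areas, a [geogrid] on the same grid (km^2).
#' @param bins Number of percentile bins (default 100).
#' @return A [geogrid] of percentile scores in `{1/bins, ..., 1}`.
#' @export
area_weighted_percentile_transform <- function(field, areas, bins = 100) {
  if (!.same_grid(field, areas)) stop("field and areas must share a grid")
  if (bins < 1) stop("`bins` must be >= 1")
  valid <- which(!is.na(field$values))
  if (!length(valid)) stop("all cells are masked")
  v <- field$values[valid]
  a <- areas$values[valid]
  if (any(a <= 0)) stop("cell areas must be positive")
  o <- order(v)
  cum_end <- cumsum(a[o])
  total <- cum_end[length(cum_end)]
  cum_start <- cum_end - a[o]
  grp <- cumsum(c(TRUE, diff(v[o]) != 0))  # runs of tied values
  g_start <- tapply(cum_start, grp, min)
  g_end <- tapply(cum_end, grp, max)
  mid <- (g_start + g_end) / 2
  p_grp <- ceiling(bins * mid / total) / bins
  out <- field$values
  out[valid[o]] <- p_grp[grp]
  geogrid(out, field$lat, field$lon, units = "percentile")
}

#' Per-basin ecological sensitivity indicator E
#'
#' Combines two percentile-transformed ecological datasets: (i) the
#' area-weighted basin mean of each percentile grid, (ii) the average of
#' the two basin means, (iii) normalization of all basins by the global
#' maximum, so the most sensitive basin scores exactly 1.
#'
#' With `pairwise = TRUE` (default) a basin covered by only one of the two
#' datasets is scored from that dataset alone (pairwise-available
#' averaging); with `FALSE` such basins get `NA` (strict intersection).
#'
#' @param p1,p2 Percentile [geogrid]s (see
#'   [area_weighted_percentile_transform]).
#' @param scheme A `basin_scheme`.
#' @param pairwise Average over available datasets where one is missing.
#' @return Named numeric vector of E in (0, 1] per basin.
#' @export
ecological_sensitivity_E <- function(p1, p2, scheme, pairwise = TRUE) {
  b1 <- basin_mean_intensive(p1, scheme)
  b2 <- basin_mean_intensive(p2, scheme)
  comb <- if (pairwise) {
    m <- rowMeans(cbind(b1, b2), na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    m
  } else {
    (b1 + b2) / 2
  }
  if (all(is.na(comb))) stop("no basin has valid sensitivity inputs")
  comb / max(comb, na.rm = TRUE)
}

#' Fuzzy sum of unit-interval components
#'
#' `1 - prod(1 - x_k)`: an increasing, commutative combination operator on
#' [0, 1] that is never below its largest input, with 0 as identity and 1
#' as absorbing element. Used to combine sensitivity components without
#' subjective weights.
#'
#' @param components Numeric vector of values in [0, 1], or a list of
#'   equal-length vectors to combine elementwise.
#' @return Single value, or a vector when given a list.
#' @examples
#' fuzzy_sum(c(0.5, 0.5))           # 0.75
#' fuzzy_sum(list(c(0, 1), c(0.3, 0.2)))
#' @export
fuzzy_sum <- function(components) {
  if (is.list(components)) {
    chk <- unlist(components)
    if (any(chk < -1e-12 | chk > 1 + 1e-12, na.rm = TRUE))
      stop("fuzzy-sum components must lie in [0, 1]")
    return(1 - Reduce(`*`, lapply(components, function(x) 1 - x)))
  }
  if (any(components < -1e-12 | components > 1 + 1e-12, na.rm = TRUE))
    stop("fuzzy-sum components must lie in [0, 1]")
  1 - prod(1 - components)
}

#' Social-ecological sensitivity S
#'
#' Fuzzy sum of ecological sensitivity and inverted adaptive capacity:
#' `S = 1 - (1 - E) * (1 - (1 - A))`. Adaptive capacity enters inverted —
#' low adaptability means high sensitivity — so `A = 0` is absorbing
#' (`S = 1`) and at maximum adaptability `S` reduces to `E`.
#'
#' @param E Ecological sensitivity in [0, 1] (vectorized).
#' @param A Adaptive capacity in [0, 1].
#' @return S in [0, 1], with `S >= max(E, 1 - A)`.
#' @export
social_ecological_sensitivity_S <- function(E, A) {
  if (any(E < -1e-12 | E > 1 + 1e-12, na.rm = TRUE))
    stop("E must lie in [0, 1]")
  if (any(A < -1e-12 | A > 1 + 1e-12, na.rm = TRUE))
    stop("A must lie in [0, 1]")
  fuzzy_sum(list(E, 1 - A))
}

#' Rescale a vector to the unit interval by its range
#'
#' Min-max rescaling used to bring a native-scale adaptive-capacity
#' dataset onto [0, 1] before inversion. A constant vector maps to 0.5.
#'
#' @param x Numeric vector.
#' @return Rescaled vector in [0, 1].
#' @export
rescale_unit <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (diff(r) == 0) return(ifelse(is.na(x), NA_real_, 0.5))
  (x - r[1]) / diff(r)
}
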