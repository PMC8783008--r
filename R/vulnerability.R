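# Vulnerability V = S * B, Head/Tail Breaks classification, and the
# hotspot / transitional labelling of basins.

#' Social-ecological vulnerability V
#'
#' The product of social-ecological sensitivity and basin freshwater
#' status, `V = S * B`: the likelihood of social or ecological harm from
#' freshwater stress and storage loss.
#'
#' @param S Sensitivity in [0, 1] (vectorized).
#' @param B Basin freshwater status in [0, 1].
#' @return V in [0, 1].
#' @export
vulnerability_V <- function(S, B) {
  if (any(S < -1e-12 | S > 1 + 1e-12, na.rm = TRUE))
    stop("S must lie in [0, 1]")
  if (any(B < -1e-12 | B > 1 + 1e-12, na.rm = TRUE))
    stop("B must lie in [0, 1]")
  S * B
}

#' Head/Tail Breaks classification
#'
#' Recursive mean-partition classifier for heavy-tailed distributions.
#' The first break is the arithmetic mean of all values; the "head" is the
#' set of values strictly above it; each further break is the mean of the
#' current head. With the default three iterations this yields up to four
#' classes: class 1 `<= break_1`, class 2 `(break_1, break_2]`, class 3
#' `(break_2, break_3]`, class 4 `> break_3`. Iteration stops early when a
#' head has fewer than two members or zero variance (the remaining members
#' form the top class), so degenerate inputs yield fewer classes, never an
#' error.
#'
#' @param values Numeric vector (NAs allowed, classified as `NA`).
#' @param iterations Number of breaks to attempt (default 3).
#' @return List with `breaks` (increasing numeric vector), `class`
#'   (integer vector aligned with `values`) and `n_classes`.
#' @examples
#' head_tail_breaks(c(1, 1, 1, 1, 1, 1, 5, 5, 5, 20, 20, 50, 100))
#' @export
head_tail_breaks <- function(values, iterations = 3) {
  v <- values[is.finite(values)]
  if (!length(v)) stop("no finite values to classify")
  breaks <- numeric(0)
  cur <- v
  for (i in seq_len(iterations)) {
    m <- mean(cur)
    breaks <- c(breaks, m)
    head_v <- cur[cur > m]
    if (length(head_v) < 2 || stats::var(head_v) == 0) break
    cur <- head_v
  }
  cls <- rep(NA_integer_, length(values))
  fin <- is.finite(values)
  cls[fin] <- as.integer(1L + rowSums(outer(values[fin], breaks, `>`)))
  list(breaks = breaks, class = cls,
       n_classes = length(unique(cls[fin])))
}

#' Vulnerability class labels
#' @keywords internal
.bv_class_levels <- c("low", "transitional", "high", "very high")

#' Classify basin vulnerability into hotspot classes
#'
#' Applies [head_tail_breaks] (three iterations, four classes) to the
#' vulnerability distribution and labels classes low / transitional /
#' high / very high. Hotspots are the basins in the high and very-high
#' classes. Zero-vulnerability basins are included in the break
#' computation by default (they populate the low class); set
#' `include_zero = FALSE` to compute breaks on positive values only,
#' with zero-V basins forced to the low class.
#'
#' @param V Named numeric vector of vulnerability per basin.
#' @param iterations Head/Tail Breaks iterations (default 3).
#' @param include_zero Include V = 0 basins in break computation.
#' @param variant Tag recorded on the output (`"social-ecological"`,
#'   `"social"`, `"ecological"`, or any label).
#' @return Data frame: `basin_id`, `V`, `class` (ordered factor),
#'   `hotspot` (logical), `variant`; attribute `breaks`.
#' @export
classify_vulnerability <- function(V, iterations = 3, include_zero = TRUE,
                                   variant = "social-ecological") {
  ids <- if (!is.null(names(V))) names(V) else as.character(seq_along(V))
  fin <- is.finite(V)
  basis <- if (include_zero) V[fin] else V[fin & V > 0]
  if (!length(basis)) {
    cls <- ifelse(fin, 1L, NA_integer_)
    breaks <- numeric(0)
  } else {
    htb <- head_tail_breaks(basis, iterations)
    breaks <- htb$breaks
    cls <- rep(NA_integer_, length(V))
    cls[fin] <- as.integer(1L + rowSums(outer(V[fin], breaks, `>`)))
    if (!include_zero) cls[fin & V == 0] <- 1L
  }
  cls <- pmin(cls, 4L)
  out <- data.frame(
    basin_id = ids, V = as.numeric(V),
    class = factor(.bv_class_levels[cls], levels = .bv_class_levels,
                   ordered = TRUE),
    hotspot = !is.na(cls) & cls >= 3L,
    variant = variant,
    stringsAsFactors = FALSE)
  attr(out, "breaks") <- breaks
  out
}
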