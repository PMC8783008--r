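# Basin freshwater indicators: stress ratio, normalized stress (F),
# normalized storage trend (T), basin freshwater status (B), and the
# categorical stress x trend co-occurrence classes.

#' Freshwater stress ratio W/Q
#'
#' The ratio of annual freshwater withdrawal to annual streamflow, the
#' standard demand-driven water-scarcity measure. Basins with W/Q >= 0.10
#' are conventionally called stressed, >= 0.40 highly stressed.
#'
#' Basins with non-positive streamflow cannot be scored: they get `NA`
#' (never a silent division), and callers are expected to report them.
#'
#' @param W Withdrawal, mm/yr (vectorized, >= 0).
#' @param Q Streamflow, mm/yr.
#' @return W/Q, dimensionless; `NA` where `Q <= 0`.
#' @export
stress_ratio <- function(W, Q) {
  if (any(W < 0, na.rm = TRUE)) stop("withdrawal W must be >= 0")
  out <- ifelse(!is.na(Q) & Q > 0, W / Q, NA_real_)
  out
}

#' Normalized freshwater stress indicator F
#'
#' `F = min(W / (factor * Q), 1)`. The default normalization of 0.4 Q is
#' the conventional "high stress" level in the freshwater-stress
#' literature, so F saturates at 1 once withdrawals reach 40% of
#' streamflow.
#'
#' @inheritParams stress_ratio
#' @param factor Normalization factor applied to Q (> 0), default 0.4.
#' @return F in [0, 1]; `NA` where the basin is unscorable (`Q <= 0`).
#' @export
stress_indicator_F <- function(W, Q, factor = 0.4) {
  if (!is.numeric(factor) || factor <= 0) stop("`factor` must be > 0")
  r <- stress_ratio(W, Q)
  pmin(r / factor, 1)
}

#' Normalized storage-trend indicator T
#'
#' The total-water-storage trend normalized by the same 0.4 Q level,
#' clamped to [-1, 1], then flipped in sign so that drying (storage loss,
#' negative trend) scores positive — aligned with the stress indicator
#' where larger means worse:
#' `T = -1 * clamp(dTWS_dt / (factor * Q), -1, 1)`.
#'
#' @param dTWS_dt Storage trend, mm/yr (negative = drying).
#' @param Q Streamflow, mm/yr.
#' @param factor Normalization factor (> 0), default 0.4.
#' @return T in [-1, 1]; `NA` where `Q <= 0`.
#' @export
trend_indicator_T <- function(dTWS_dt, Q, factor = 0.4) {
  if (!is.numeric(factor) || factor <= 0) stop("`factor` must be > 0")
  norm <- ifelse(!is.na(Q) & Q > 0, dTWS_dt / (factor * Q), NA_real_)
  -1 * pmax(pmin(norm, 1), -1)
}

#' Basin freshwater status B
#'
#' The arithmetic mean of the stress and trend indicators, floored at 0
#' (wetting trends can offset stress but status never goes negative):
#' `B = max((F + T) / 2, 0)`. For earthquake-flagged basins — where the
#' satellite storage-trend observation is contaminated — status falls back
#' to the stress indicator alone: `B = F`, independent of the trend.
#'
#' @param F Stress indicator in [0, 1].
#' @param T Trend indicator in [-1, 1].
#' @param earthquake Logical flag(s), recycled; default `FALSE`.
#' @return B in [0, 1].
#' @export
basin_status_B <- function(F, T, earthquake = FALSE) {
  if (any(F < -1e-12 | F > 1 + 1e-12, na.rm = TRUE))
    stop("F must lie in [0, 1]")
  if (any(abs(T) > 1 + 1e-12, na.rm = TRUE))
    stop("T must lie in [-1, 1]")
  B <- pmax((F + T) / 2, 0)
  eq <- rep_len(as.logical(earthquake), length(B))
  B[eq] <- F[eq]
  B
}

#' Categorical stress x trend co-occurrence class
#'
#' Cross-classifies basins by stress level (not stressed / stressed /
#' highly stressed at W/Q thresholds 0.10 and 0.40) and storage-trend
#' direction (drying / no clear trend / wetting at +/- 3 mm/yr, the error
#' level of the satellite observations). The trend threshold is for
#' categorical description only and plays no role in the status indicator
#' B. Values exactly at +/- trend_threshold count as "no clear trend";
#' stress thresholds are inclusive (`>=`) by default.
#'
#' @param ratio Stress ratio W/Q.
#' @param trend Storage trend, mm/yr.
#' @param thresholds Stress thresholds (length 2, increasing).
#' @param trend_threshold Clear-trend threshold, mm/yr.
#' @param strict Use strict `>` instead of `>=` at the stress thresholds.
#' @return Character vector of labels like `"stressed & drying"`; `NA`
#'   where `ratio` is `NA`.
#' @export
cooccurrence_class <- function(ratio, trend, thresholds = c(0.10, 0.40),
                               trend_threshold = 3, strict = FALSE) {
  if (length(thresholds) != 2 || diff(thresholds) <= 0)
    stop("`thresholds` must be two increasing values")
  ge <- if (strict) `>` else `>=`
  stress <- ifelse(ge(ratio, thresholds[2]), "highly stressed",
                   ifelse(ge(ratio, thresholds[1]), "stressed",
                          "not stressed"))
  dir <- ifelse(trend < -trend_threshold, "drying",
                ifelse(trend > trend_threshold, "wetting",
                       "no clear trend"))
  out <- paste(stress, dir, sep = " & ")
  out[is.na(ratio) | is.na(trend)] <- NA_character_
  out
}
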