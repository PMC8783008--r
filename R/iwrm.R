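# National IWRM implementation scores joined to basins, transboundary
# flagging, and the IWRM-versus-vulnerability quadrant comparison.

#' Basin-level IWRM implementation score
#'
#' Summarizes national IWRM (integrated water resources management,
#' SDG 6.5.1) scores to the basin scale as the overlap-area-weighted mean
#' of the scores of all nations intersecting the basin. Basins touching a
#' nation with no score are flagged missing and reported, never silently
#' scored.
#'
#' @param scheme A `basin_scheme` with nation overlaps (see
#'   [generate_nations]).
#' @param scores Data frame with columns `nation_id` and `score`
#'   (in [0, 100]).
#' @return Data frame of class `basin_iwrm`: `basin_id`, `iwrm_score`,
#'   `n_nations`, `transboundary`; attribute `missing_basins` lists basins
#'   that could not be scored.
#' @export
basin_iwrm_score <- function(scheme, scores) {
  ov <- scheme$nation_overlap
  if (is.null(ov)) stop("scheme has no nation overlaps; run generate_nations()")
  if (any(scores$score < 0 | scores$score > 100, na.rm = TRUE))
    stop("IWRM scores must lie in [0, 100]")
  sc <- stats::setNames(scores$score, as.character(scores$nation_id))
  ov$score <- sc[as.character(ov$nation_id)]
  wsum <- tapply(ov$fraction * ov$score, ov$basin_id, sum)
  wtot <- tapply(ov$fraction, ov$basin_id, sum)
  nn <- tapply(ov$nation_id, ov$basin_id, function(x) length(unique(x)))
  ids <- scheme$ids
  key <- as.character(ids)
  out <- data.frame(
    basin_id = ids,
    iwrm_score = as.numeric(wsum[key] / wtot[key]),
    n_nations = as.integer(nn[key]),
    stringsAsFactors = FALSE)
  out$transboundary <- !is.na(out$n_nations) & out$n_nations >= 2L
  attr(out, "missing_basins") <- ids[is.na(out$iwrm_score)]
  class(out) <- c("basin_iwrm", "data.frame")
  out
}

#' IWRM versus vulnerability: quadrants and transboundary contrast
#'
#' Labels each basin by its quadrant in the IWRM-by-vulnerability plane
#' (1: high IWRM / low V; 2: low IWRM / low V; 3: low IWRM / high V;
#' 4: high IWRM / high V), and contrasts mean basin IWRM between
#' transboundary and non-transboundary hotspot basins. An empty hotspot
#' set yields `NA` means, reported as missing rather than zero.
#'
#' @param iwrm A `basin_iwrm` table from [basin_iwrm_score].
#' @param vuln A classification table from [classify_vulnerability]
#'   (columns `basin_id`, `V`, `hotspot`).
#' @param iwrm_split Score below which IWRM counts as "low" (default 50).
#' @param v_split Vulnerability at or above which V counts as "high";
#'   default: the lowest hotspot V (so "high V" = hotspot).
#' @return List with `basins` (per-basin quadrant table), `quadrant_counts`,
#'   `mean_iwrm_transboundary_hotspots`,
#'   `mean_iwrm_nontransboundary_hotspots` and
#'   `share_hotspots_transboundary`.
#' @export
iwrm_vulnerability_summary <- function(iwrm, vuln, iwrm_split = 50,
                                       v_split = NULL) {
  m <- merge(iwrm, vuln[, c("basin_id", "V", "hotspot")], by = "basin_id")
  if (!nrow(m)) stop("no common basins between the two tables")
  if (is.null(v_split)) {
    v_split <- if (any(m$hotspot, na.rm = TRUE))
      min(m$V[m$hotspot], na.rm = TRUE) else Inf
  }
  if (is.finite(v_split) &&
      (v_split < min(m$V, na.rm = TRUE) || v_split > max(m$V, na.rm = TRUE)))
    warning("v_split lies outside the observed vulnerability range")
  if (iwrm_split < min(m$iwrm_score, na.rm = TRUE) ||
      iwrm_split > max(m$iwrm_score, na.rm = TRUE))
    warning("iwrm_split lies outside the observed score range")
  high_v <- m$V >= v_split
  high_i <- m$iwrm_score >= iwrm_split
  m$quadrant <- ifelse(high_i & !high_v, 1L,
                ifelse(!high_i & !high_v, 2L,
                ifelse(!high_i & high_v, 3L, 4L)))
  hs <- m[which(m$hotspot), ]
  mean_or_na <- function(x) if (length(x)) mean(x, na.rm = TRUE) else NA_real_
  list(
    basins = m,
    quadrant_counts = table(factor(m$quadrant, levels = 1:4)),
    mean_iwrm_transboundary_hotspots = mean_or_na(hs$iwrm_score[hs$transboundary]),
    mean_iwrm_nontransboundary_hotspots = mean_or_na(hs$iwrm_score[!hs$transboundary]),
    share_hotspots_transboundary =
      if (nrow(hs)) mean(hs$transboundary) else NA_real_)
}
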