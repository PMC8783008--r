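# Exposure accounting: totals and global shares of extensive
# social-ecological variables within indicator categories and
# vulnerability classes.

#' Exposure of extensive variables by basin category
#'
#' Sums extensive variables (population, crop production, GDP, wetland
#' counts, ...) over the basins of each category and expresses each sum as
#' a share of the global total. Basins with a missing label are collected
#' in a residual `"(unlabelled)"` category, so shares over all reported
#' categories sum to 1 per variable.
#'
#' @param extensives Data frame with a `basin_id` column and one numeric
#'   column per variable.
#' @param labels Category label per basin: either a vector aligned with
#'   the rows of `extensives` or a named vector keyed by basin id.
#' @return Long-format data frame `category`, `variable`, `value`,
#'   `share`, of class `exposure_summary`.
#' @export
exposure_by_category <- function(extensives, labels) {
  if (!"basin_id" %in% names(extensives))
    stop("`extensives` must have a basin_id column")
  if (!is.null(names(labels))) {
    miss <- setdiff(as.character(extensives$basin_id), names(labels))
    if (length(miss))
      stop("no label for basins: ", paste(miss, collapse = ", "))
    labels <- labels[as.character(extensives$basin_id)]
  }
  if (length(labels) != nrow(extensives))
    stop("labels must match extensives rows")
  lab <- as.character(labels)
  lab[is.na(lab)] <- "(unlabelled)"
  vars <- setdiff(names(extensives), "basin_id")
  out <- do.call(rbind, lapply(vars, function(v) {
    x <- extensives[[v]]
    x[is.na(x)] <- 0
    sums <- tapply(x, lab, sum)
    total <- sum(x)
    data.frame(category = names(sums), variable = v,
               value = as.numeric(sums),
               share = if (total > 0) as.numeric(sums) / total
                       else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("exposure_summary", "data.frame")
  out
}

#' Adaptability x freshwater-status cross-tabulation
#'
#' Counts basins in each combination of adaptive-capacity class and
#' freshwater-status class. Class breaks default to terciles of the unit
#' interval (low / moderate / high); both axes are fully configurable.
#'
#' @param B Basin freshwater status in [0, 1] (vectorized).
#' @param A Adaptive capacity in [0, 1].
#' @param a_breaks,b_breaks Interior break points on [0, 1], increasing.
#' @param a_labels,b_labels Class labels (length = breaks + 1).
#' @return Contingency table (A classes x B classes) of basin counts;
#'   attribute `n_missing` counts basins dropped for missing inputs.
#' @export
adaptability_status_crosstab <- function(B, A,
                                         a_breaks = c(1 / 3, 2 / 3),
                                         b_breaks = c(1 / 3, 2 / 3),
                                         a_labels = c("low", "moderate", "high"),
                                         b_labels = c("low", "moderate", "severe")) {
  ok <- !is.na(B) & !is.na(A)
  acl <- cut(A[ok], breaks = c(-Inf, a_breaks, Inf), labels = a_labels)
  bcl <- cut(B[ok], breaks = c(-Inf, b_breaks, Inf), labels = b_labels)
  tab <- table(adaptability = acl, status = bcl)
  attr(tab, "n_missing") <- sum(!ok)
  tab
}
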