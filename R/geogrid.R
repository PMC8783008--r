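# Regular lat-lon grid container and basin-level zonal statistics.

#' Mean Earth radius of the authalic sphere, in kilometres
#'
#' Radius of the sphere with the same surface area as the WGS84 ellipsoid.
#' Used for all cell-area computations.
#' @export
EARTH_RADIUS_KM <- 6371.0088

#' Construct a geographic grid
#'
#' A `geogrid` holds one gridded field on a regular latitude-longitude grid.
#' Rows run north to south (decreasing latitude), columns west to east
#' (increasing longitude). Missing cells are `NA`.
#'
#' @param values Numeric matrix, `length(lat)` rows by `length(lon)` columns.
#' @param lat Cell-centre latitudes in decreasing order (degrees).
#' @param lon Cell-centre longitudes in increasing order (degrees).
#' @param units Unit string carried as metadata (e.g. `"mm yr-1"`).
#' @return An object of class `geogrid`: a list with elements `values`,
#'   `lat`, `lon`, `resolution`, `units`.
#' @examples
#' g <- geogrid(matrix(1:12, 3, 4), lat = c(1.25, 0.75, 0.25),
#'              lon = c(0.25, 0.75, 1.25, 1.75), units = "mm yr-1")
#' @export
geogrid <- function(values, lat, lon, units = "") {
  values <- as.matrix(values)
  lat <- as.numeric(lat)
  lon <- as.numeric(lon)
  if (nrow(values) != length(lat) || ncol(values) != length(lon))
    stop("dimensions of `values` must match length(lat) x length(lon)")
  if (any(abs(lat) > 90)) stop("latitudes must lie in [-90, 90]")
  res <- .grid_resolution(lat, lon)
  if (length(lat) > 1 && any(diff(lat) >= 0))
    stop("`lat` must be strictly decreasing (north to south)")
  if (length(lon) > 1 && any(diff(lon) <= 0))
    stop("`lon` must be strictly increasing (west to east)")
  bad <- !is.na(values) & !is.finite(values)
  if (any(bad)) stop("non-finite unmasked values in grid")
  structure(list(values = values, lat = lat, lon = lon,
                 resolution = res, units = units),
            class = "geogrid")
}

# infer and check the (common) grid spacing
.grid_resolution <- function(lat, lon) {
  steps <- c(if (length(lat) > 1) abs(diff(lat)),
             if (length(lon) > 1) diff(lon))
  if (!length(steps)) return(NA_real_)
  res <- stats::median(steps)
  if (any(abs(steps - res) > 1e-8 * max(1, res)))
    stop("grid spacing must be uniform")
  res
}

#' @export
print.geogrid <- function(x, ...) {
  cat(sprintf("<geogrid> %d x %d cells, %.4g deg resolution%s\n",
              nrow(x$values), ncol(x$values), x$resolution,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  cat(sprintf("  lat %0.3f..%0.3f, lon %0.3f..%0.3f, %d masked cells\n",
              max(x$lat), min(x$lat), min(x$lon), max(x$lon),
              sum(is.na(x$values))))
  invisible(x)
}

.same_grid <- function(a, b, tol = 1e-8) {
  length(a$lat) == length(b$lat) && length(a$lon) == length(b$lon) &&
    max(abs(a$lat - b$lat)) <= tol && max(abs(a$lon - b$lon)) <= tol
}

#' Spherical cell areas of a regular lat-lon grid
#'
#' Computes the exact surface area of each cell on the authalic sphere
#' (radius 6371.0088 km):
#' `area = R^2 * d_lambda * (sin(phi_top) - sin(phi_bottom))`,
#' where `d_lambda` is the longitudinal cell width in radians and
#' `phi_top`/`phi_bottom` bound the cell in latitude. Areas decrease
#' strictly with `|lat|` and a global grid sums to `4 * pi * R^2`.
#'
#' @param lat Cell-centre latitudes, decreasing (degrees).
#' @param lon Cell-centre longitudes, increasing (degrees).
#' @param resolution Cell size in degrees; both dimensions share it.
#' @return A [geogrid] of cell areas in km^2.
#' @examples
#' a <- cell_area_grid(c(0.25, -0.25), c(10.25, 10.75), 0.5)
#' @export
cell_area_grid <- function(lat, lon, resolution) {
  if (!is.numeric(resolution) || resolution <= 0)
    stop("`resolution` must be positive")
  if (any(abs(lat) > 90)) stop("latitudes must lie in [-90, 90]")
  half <- resolution / 2
  top <- pmin(lat + half, 90) * pi / 180
  bot <- pmax(lat - half, -90) * pi / 180
  band <- EARTH_RADIUS_KM^2 * (resolution * pi / 180) * (sin(top) - sin(bot))
  geogrid(matrix(band, nrow = length(lat), ncol = length(lon)),
          lat = lat, lon = lon, units = "km2")
}

#' Area-weighted basin means of an intensive field
#'
#' Intensive properties (concentrations, rates, indices) are aggregated to
#' the basin scale as area-weighted means over the basin's unmasked cells:
#' `mean_i = sum(value * area) / sum(area)`. Cells masked in the field are
#' excluded from numerator and denominator alike; basins with no valid cell
#' get `NA`.
#'
#' @param field A [geogrid] on the scheme's grid.
#' @param scheme A `basin_scheme` (see [generate_basin_scheme]).
#' @return Named numeric vector of basin means, one entry per basin id.
#' @seealso [basin_sum_extensive] for extensive (summable) fields.
#' @export
basin_mean_intensive <- function(field, scheme) {
  .check_scheme_grid(field, scheme)
  a <- scheme$assignment
  v <- field$values
  w <- scheme$cell_area
  ok <- a > 0L & !is.na(v)
  num <- rowsum((v * w)[ok], a[ok])
  den <- rowsum(w[ok], a[ok])
  out <- stats::setNames(rep(NA_real_, length(scheme$ids)),
                         as.character(scheme$ids))
  out[rownames(num)] <- num[, 1] / den[, 1]
  out
}

#' Within-basin sums of an extensive field
#'
#' Extensive properties (population, production, GDP) are aggregated as
#' plain sums over each basin's unmasked cells. The total over all basins
#' plus the total over unassigned/masked cells equals the global field sum.
#'
#' @inheritParams basin_mean_intensive
#' @return Named numeric vector of basin sums (0 for basins whose cells are
#'   all masked in the field carries `NA`), with attribute
#'   `unassigned_total`: the field total outside any scored basin.
#' @export
basin_sum_extensive <- function(field, scheme) {
  .check_scheme_grid(field, scheme)
  a <- scheme$assignment
  v <- field$values
  ok <- a > 0L & !is.na(v)
  s <- rowsum(v[ok], a[ok])
  out <- stats::setNames(rep(NA_real_, length(scheme$ids)),
                         as.character(scheme$ids))
  out[rownames(s)] <- s[, 1]
  attr(out, "unassigned_total") <- sum(v[a == 0L], na.rm = TRUE)
  out
}

.check_scheme_grid <- function(field, scheme) {
  if (!inherits(field, "geogrid")) stop("`field` must be a geogrid")
  if (!inherits(scheme, "basin_scheme")) stop("`scheme` must be a basin_scheme")
  if (nrow(field$values) != nrow(scheme$assignment) ||
      ncol(field$values) != ncol(scheme$assignment) ||
      max(abs(field$lat - scheme$lat)) > 1e-8 ||
      max(abs(field$lon - scheme$lon)) > 1e-8)
    stop("field grid does not match basin scheme grid")
  invisible(TRUE)
}

#' Drop basins from a scheme
#'
#' Removes the listed basins from the assignment and all per-basin tables
#' (areas, earthquake flags, nation overlaps) and reports how much of the
#' original tessellation is retained, by basin count and by surface area.
#'
#' @param scheme A `basin_scheme`.
#' @param drop_ids Integer ids of basins to remove (may be empty).
#' @return List with elements `scheme` (the reduced scheme) and `report`
#'   (named numeric: `count_retention`, `area_retention`, `n_dropped`).
#' @export
mask_basins <- function(scheme, drop_ids) {
  drop_ids <- as.integer(drop_ids)
  unknown <- setdiff(drop_ids, scheme$ids)
  if (length(unknown))
    stop("unknown basin ids: ", paste(unknown, collapse = ", "))
  keep <- setdiff(scheme$ids, drop_ids)
  report <- c(count_retention = length(keep) / length(scheme$ids),
              area_retention = sum(scheme$area_km2[as.character(keep)]) /
                sum(scheme$area_km2),
              n_dropped = length(drop_ids))
  out <- scheme
  out$assignment[out$assignment %in% drop_ids] <- 0L
  out$ids <- keep
  out$area_km2 <- out$area_km2[as.character(keep)]
  out$earthquake <- out$earthquake[as.character(keep)]
  if (!is.null(out$nation_overlap))
    out$nation_overlap <-
      out$nation_overlap[out$nation_overlap$basin_id %in% keep, , drop = FALSE]
  list(scheme = out, report = report)
}

#' Count points per basin
#'
#' Assigns each lon/lat point to the basin of its containing grid cell.
#' Cell ownership is half-open: a point on a cell's west or south edge
#' belongs to that cell. Points outside the grid extent (or on masked
#' cells) are counted separately, never dropped silently.
#'
#' @param lon,lat Point coordinates in degrees (equal length).
#' @param scheme A `basin_scheme`.
#' @return List with `counts` (named integer vector over all basin ids),
#'   `n_unassigned` (points out of extent or on masked cells) and
#'   `unassigned_index` (their positions in the input).
#' @export
points_in_basins <- function(lon, lat, scheme) {
  if (length(lon) != length(lat)) stop("lon and lat must have equal length")
  res <- scheme$resolution
  # grid edges; rows north->south so row index counts down from the top edge
  lon0 <- min(scheme$lon) - res / 2
  lat_top <- max(scheme$lat) + res / 2
  nr <- nrow(scheme$assignment)
  nc <- ncol(scheme$assignment)
  col <- floor((lon - lon0) / res) + 1
  # south edge inclusive => cell spans [lat_c - res/2, lat_c + res/2)
  row_s <- floor((lat - (min(scheme$lat) - res / 2)) / res) + 1
  row <- nr - row_s + 1
  inb <- !is.na(lon) & !is.na(lat) & col >= 1 & col <= nc & row >= 1 & row <= nr
  bid <- rep(0L, length(lon))
  bid[inb] <- scheme$assignment[cbind(row[inb], col[inb])]
  counts <- stats::setNames(integer(length(scheme$ids)),
                            as.character(scheme$ids))
  tab <- table(bid[bid > 0L])
  counts[names(tab)] <- as.integer(tab)
  list(counts = counts,
       n_unassigned = sum(bid == 0L),
       unassigned_index = which(bid == 0L))
}
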