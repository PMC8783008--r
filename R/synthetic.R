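# Synthetic worlds: gridded forcings, a contiguous basin tessellation,
# nations with IWRM scores, and optional planted hotspot basins.
# Everything is deterministic given the spec's seed.

#' Default per-field distribution parameters for synthetic worlds
#'
#' Each entry gives the marginal distribution parameters and the spatial
#' correlation length (in cells) of one synthetic input field. Marginals:
#' lognormal for withdrawal `W`, streamflow `Q`, the two ecological
#' sensitivity proxies and the extensive socio-economic fields; Gaussian
#' (signed) for the storage trend `dTWS`; beta (via a Gaussian copula) for
#' adaptive capacity `A`. Defaults give a stress ratio W/Q spanning [0, >1]
#' with roughly 40% of basins above the 0.10 stress threshold, signed
#' storage trends of order +/-10 mm/yr, and heavy-tailed sensitivity
#' fields.
#'
#' @return Named list of parameter lists.
#' @export
default_field_params <- function() {
  list(
    W          = list(dist = "lognormal", meanlog = log(10),  sdlog = 1.2, corr = 2),
    Q          = list(dist = "lognormal", meanlog = log(150), sdlog = 1.0, corr = 2),
    dTWS       = list(dist = "gaussian",  mean = 0, sd = 15, corr = 3),
    A          = list(dist = "beta", shape1 = 2.5, shape2 = 2.5, corr = 3),
    eco1       = list(dist = "lognormal", meanlog = 0, sdlog = 1.5, corr = 2),
    eco2       = list(dist = "lognormal", meanlog = 0, sdlog = 1.5, corr = 2),
    population = list(dist = "lognormal", meanlog = log(5e4), sdlog = 1.5, corr = 1),
    gdp        = list(dist = "lognormal", meanlog = log(5e8), sdlog = 1.8, corr = 1),
    crop       = list(dist = "lognormal", meanlog = log(1e7), sdlog = 1.5, corr = 1),
    richness   = list(dist = "lognormal", meanlog = log(200), sdlog = 0.5, corr = 3)
  )
}

#' Specify a synthetic world
#'
#' @param grid_resolution Cell size in degrees.
#' @param lat_range,lon_range Extent of the grid (degrees); the resolution
#'   must divide both extents.
#' @param n_basins Number of basins (>= 1).
#' @param n_nations Number of nations (>= 1).
#' @param mask_fraction Fraction of cells masked out as a contiguous blob
#'   (emulates data-sparse regions excluded from scoring).
#' @param field_params Per-field distribution parameters; see
#'   [default_field_params]. Partial lists are merged over the defaults.
#' @param planted_hotspots List of hotspot prescriptions, each a list with
#'   elements `basin` (id, or `NA` to pick at random), `stress_multiplier`
#'   (raises withdrawal to this multiple of the 0.10 stress threshold of
#'   local streamflow, or this multiple of its own level if larger),
#'   `trend_offset` (shifts and caps the storage trend, mm/yr; negative =
#'   drying at least that fast), `adapt_ceiling` (upper cap on adaptive
#'   capacity) and `sens_floor` (quantile of each sensitivity field used as
#'   lower floor within the basin).
#' @param earthquake_basins Basin ids whose storage-trend observations are
#'   deemed unusable (status falls back to the stress indicator alone).
#' @param seed Integer master seed; a fixed seed reproduces the world
#'   exactly.
#' @return An object of class `bv_world_spec`.
#' @examples
#' spec <- bv_world_spec(n_basins = 12, n_nations = 3, seed = 1,
#'                       lat_range = c(0, 10), lon_range = c(0, 10))
#' @export
bv_world_spec <- function(grid_resolution = 0.5,
                          lat_range = c(-30, 30),
                          lon_range = c(0, 40),
                          n_basins = 200,
                          n_nations = 20,
                          mask_fraction = 0,
                          field_params = list(),
                          planted_hotspots = list(),
                          earthquake_basins = integer(),
                          seed = 42L) {
  fp <- default_field_params()
  for (nm in names(field_params)) {
    if (!nm %in% names(fp)) stop("unknown field in field_params: ", nm)
    fp[[nm]][names(field_params[[nm]])] <- field_params[[nm]]
  }
  spec <- structure(list(
    grid_resolution = grid_resolution, lat_range = sort(lat_range),
    lon_range = sort(lon_range), n_basins = as.integer(n_basins),
    n_nations = as.integer(n_nations), mask_fraction = mask_fraction,
    field_params = fp, planted_hotspots = planted_hotspots,
    earthquake_basins = as.integer(earthquake_basins),
    seed = as.integer(seed)), class = "bv_world_spec")
  .validate_world_spec(spec)
  spec
}

.validate_world_spec <- function(spec) {
  res <- spec$grid_resolution
  if (!is.numeric(res) || res <= 0) stop("grid_resolution must be positive")
  ext <- c(diff(spec$lat_range), diff(spec$lon_range))
  if (any(ext <= 0)) stop("lat/lon ranges must have positive extent")
  if (any(abs(ext / res - round(ext / res)) > 1e-9))
    stop("grid_resolution must divide the lat and lon extents")
  if (spec$n_basins < 1L) stop("n_basins must be >= 1")
  if (spec$n_nations < 1L) stop("n_nations must be >= 1")
  if (spec$mask_fraction < 0 || spec$mask_fraction >= 1)
    stop("mask_fraction must lie in [0, 1)")
  nr <- round(diff(spec$lat_range) / res)
  nc <- round(diff(spec$lon_range) / res)
  n_open <- floor((1 - spec$mask_fraction) * nr * nc)
  if (spec$n_basins > n_open)
    stop("n_basins exceeds the number of unmasked grid cells")
  for (p in spec$field_params) {
    sc <- p[[intersect(names(p), c("sdlog", "sd"))[1]]]
    if (!is.null(sc) && sc < 0) stop("field scale parameters must be >= 0")
    if (!is.null(p$corr) && p$corr < 0) stop("correlation lengths must be >= 0")
  }
  q <- spec$field_params$Q
  if (q$sdlog < 0 || !is.finite(q$meanlog))
    stop("invalid streamflow (Q) parameters")
  invisible(TRUE)
}

.spec_lat <- function(spec) {
  res <- spec$grid_resolution
  rev(seq(spec$lat_range[1] + res / 2, spec$lat_range[2] - res / 2, by = res))
}
.spec_lon <- function(spec) {
  res <- spec$grid_resolution
  seq(spec$lon_range[1] + res / 2, spec$lon_range[2] - res / 2, by = res)
}

# Randomized multi-source dilation ("region growing") on a grid.
# Each wave assigns every unassigned open cell that touches an assigned
# cell to the region of a uniformly chosen assigned neighbour, so regions
# grow compactly and stay contiguous. Open cells unreachable from any seed
# (possible when the mask disconnects the grid) fall back to the nearest
# seed by great-circle-free grid distance.
.grow_regions <- function(nr, nc, open, seeds) {
  n <- nr * nc
  assign <- integer(n)
  assign[seeds] <- seq_along(seeds)
  idx <- seq_len(n)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  nb <- cbind(ifelse(row > 1L, idx - 1L, NA_integer_),
              ifelse(row < nr, idx + 1L, NA_integer_),
              ifelse(col > 1L, idx - nr, NA_integer_),
              ifelse(col < nc, idx + nr, NA_integer_))
  repeat {
    unas <- which(open & assign == 0L)
    if (!length(unas)) break
    nbv <- matrix(0L, length(unas), 4L)
    for (k in 1:4) {
      j <- nb[unas, k]
      ok <- !is.na(j)
      nbv[ok, k] <- assign[j[ok]]
    }
    has <- nbv > 0L
    any_nb <- rowSums(has) > 0L
    if (!any(any_nb)) break
    cand <- which(any_nb)
    score <- matrix(stats::runif(length(cand) * 4L), ncol = 4L)
    score[!has[cand, , drop = FALSE]] <- -1
    pick <- nbv[cbind(cand, max.col(score))]
    assign[unas[cand]] <- pick
  }
  left <- which(open & assign == 0L)
  if (length(left)) {
    sr <- (seeds - 1L) %% nr + 1L
    sc <- (seeds - 1L) %/% nr + 1L
    for (i in left) {
      d <- (row[i] - sr)^2 + (col[i] - sc)^2
      assign[i] <- which.min(d)
    }
  }
  matrix(assign, nr, nc)
}

#' Generate a contiguous basin tessellation
#'
#' Partitions the unmasked grid cells of a synthetic world into `n_basins`
#' contiguous basins by seeded region growing, emulating a compact drainage
#' basin scheme without hydrological routing. When `mask_fraction > 0`, a
#' contiguous blob of cells is masked first (assignment 0) and excluded
#' from every downstream computation.
#'
#' @param spec A [bv_world_spec].
#' @return An object of class `basin_scheme`: list with `assignment`
#'   (integer matrix, 0 = masked), `ids`, `area_km2` (named vector),
#'   `cell_area` (matrix, km^2), `lat`, `lon`, `resolution`, `earthquake`
#'   (named logical), and `nations`/`nation_overlap` slots filled by
#'   [generate_nations].
#' @export
generate_basin_scheme <- function(spec) {
  .validate_world_spec(spec)
  set.seed(spec$seed)
  lat <- .spec_lat(spec)
  lon <- .spec_lon(spec)
  nr <- length(lat)
  nc <- length(lon)
  n <- nr * nc
  open <- rep(TRUE, n)
  n_mask <- floor(spec$mask_fraction * n)
  if (n_mask > 0) {
    # mask the n_mask cells nearest a random seed: a compact contiguous blob
    seed1 <- sample.int(n, 1L)
    d <- .grid_distance_order(nr, nc, seed1)
    open[order(d)[seq_len(n_mask)]] <- FALSE
  }
  seeds <- sample(which(open), spec$n_basins)
  assignment <- .grow_regions(nr, nc, open, seeds)
  areas <- cell_area_grid(lat, lon, spec$grid_resolution)$values
  ids <- seq_len(spec$n_basins)
  basin_area <- stats::setNames(as.numeric(rowsum(
    areas[assignment > 0L], assignment[assignment > 0L])[as.character(ids), ]),
    as.character(ids))
  eq <- stats::setNames(ids %in% spec$earthquake_basins, as.character(ids))
  structure(list(assignment = assignment, ids = ids, area_km2 = basin_area,
                 cell_area = areas, lat = lat, lon = lon,
                 resolution = spec$grid_resolution,
                 earthquake = eq, nations = NULL, nation_overlap = NULL),
            class = "basin_scheme")
}

# squared grid distance from one cell to all cells (for mask blobs)
.grid_distance_order <- function(nr, nc, seed) {
  idx <- seq_len(nr * nc)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  (row - row[seed])^2 + (col - col[seed])^2
}

#' @export
print.basin_scheme <- function(x, ...) {
  cat(sprintf("<basin_scheme> %d basins on a %d x %d grid (%.3g deg), %d masked cells\n",
              length(x$ids), nrow(x$assignment), ncol(x$assignment),
              x$resolution, sum(x$assignment == 0L)))
  if (!is.null(x$nation_overlap))
    cat(sprintf("  %d nations, %d transboundary basins\n",
                length(unique(x$nation_overlap$nation_id)),
                sum(table(x$nation_overlap$basin_id) >= 2)))
  invisible(x)
}

# Gaussian random field: kernel-smoothed white noise, standardized to
# mean 0 / sd 1. corr_len = 0 returns independent N(0,1) noise.
.smooth_field <- function(z, corr_len) {
  if (corr_len <= 0) return(z)
  kmat <- function(n) {
    i <- seq_len(n)
    k <- exp(-outer(i, i, "-")^2 / (2 * corr_len^2))
    k / sqrt(rowSums(k^2))  # keep variance roughly uniform incl. edges
  }
  out <- kmat(nrow(z)) %*% z %*% t(kmat(ncol(z)))
  (out - mean(out)) / stats::sd(out)
}

.sim_field <- function(nr, nc, p) {
  z <- .smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), p$corr)
  switch(p$dist,
    lognormal = exp(p$meanlog + p$sdlog * z),
    gaussian  = p$mean + p$sd * z,
    beta      = stats::qbeta(stats::pnorm(z), p$shape1, p$shape2),
    stop("unknown field distribution: ", p$dist))
}

#' Generate the gridded input fields of a synthetic world
#'
#' Draws all ten input fields (withdrawal `W`, streamflow `Q`, storage
#' trend `dTWS`, adaptive capacity `A`, two ecological-sensitivity proxies
#' `eco1`/`eco2`, and extensive `population`, `gdp`, `crop`, plus
#' `richness`) as spatially correlated random fields with the marginals in
#' `spec$field_params`, applies the planted-hotspot prescriptions, and
#' masks cells excluded by the scheme.
#'
#' @param spec A [bv_world_spec].
#' @param scheme The matching `basin_scheme`.
#' @return Named list of [geogrid]s; attribute `planted` maps planted
#'   hotspots to the basin ids actually used.
#' @export
generate_fields <- function(spec, scheme) {
  .validate_world_spec(spec)
  set.seed(spec$seed + 1L)
  nr <- length(scheme$lat)
  nc <- length(scheme$lon)
  units <- c(W = "mm yr-1", Q = "mm yr-1", dTWS = "mm yr-1", A = "1",
             eco1 = "1", eco2 = "1", population = "persons",
             gdp = "currency", crop = "kcal", richness = "species")
  fields <- list()
  for (nm in names(spec$field_params)) {
    v <- .sim_field(nr, nc, spec$field_params[[nm]])
    v[scheme$assignment == 0L] <- NA_real_
    fields[[nm]] <- geogrid(v, scheme$lat, scheme$lon, units = units[[nm]])
  }
  planted <- integer(0)
  if (length(spec$planted_hotspots)) {
    free <- scheme$ids
    for (h in spec$planted_hotspots) {
      b <- h$basin
      if (is.null(b) || is.na(b)) {
        b <- sample(setdiff(free, planted), 1L)
      }
      planted <- c(planted, as.integer(b))
      inb <- scheme$assignment == b
      # planted stress is a guarantee, not a shift: withdrawals are raised
      # to `multiplier` times the 10% stress threshold of local streamflow
      # (or multiplier times their own level, whichever is larger), so the
      # planted basin is stressed regardless of its random base state
      if (!is.null(h$stress_multiplier))
        fields$W$values[inb] <- pmax(
          fields$W$values[inb] * h$stress_multiplier,
          h$stress_multiplier * 0.1 * fields$Q$values[inb])
      # likewise the trend offset caps as well as shifts: the basin ends
      # up losing storage at least |offset| mm/yr
      if (!is.null(h$trend_offset))
        fields$dTWS$values[inb] <- pmin(
          fields$dTWS$values[inb] + h$trend_offset, h$trend_offset)
      if (!is.null(h$adapt_ceiling))
        fields$A$values[inb] <- pmin(fields$A$values[inb], h$adapt_ceiling)
      if (!is.null(h$sens_floor)) {
        for (ec in c("eco1", "eco2")) {
          fl <- stats::quantile(fields[[ec]]$values, h$sens_floor, na.rm = TRUE)
          fields[[ec]]$values[inb] <- pmax(fields[[ec]]$values[inb], fl)
        }
      }
    }
  }
  attr(fields, "planted") <- planted
  fields
}

#' Generate nations and national IWRM scores
#'
#' Tessellates the unmasked grid into `n_nations` contiguous nations
#' (independently of the basin tessellation, so basins can straddle
#' several nations), computes per-basin nation overlap fractions by cell
#' area, and draws national IWRM implementation scores uniformly in
#' [0, 100].
#'
#' @param spec A [bv_world_spec].
#' @param scheme The matching `basin_scheme`.
#' @return The scheme with `nations` (integer matrix) and `nation_overlap`
#'   (data.frame: basin_id, nation_id, fraction) filled in, plus attribute
#'   `iwrm_scores`: data.frame (nation_id, score).
#' @export
generate_nations <- function(spec, scheme) {
  .validate_world_spec(spec)
  set.seed(spec$seed + 2L)
  nr <- length(scheme$lat)
  nc <- length(scheme$lon)
  open <- as.vector(scheme$assignment != 0L)
  seeds <- sample(which(open), spec$n_nations)
  nations <- .grow_regions(nr, nc, open, seeds)
  ok <- scheme$assignment > 0L
  ov <- stats::aggregate(
    list(area = scheme$cell_area[ok]),
    by = list(basin_id = scheme$assignment[ok], nation_id = nations[ok]),
    FUN = sum)
  ov <- ov[order(ov$basin_id, ov$nation_id), ]
  ov$fraction <- ov$area / scheme$area_km2[as.character(ov$basin_id)]
  ov$area <- NULL
  rownames(ov) <- NULL
  scheme$nations <- nations
  scheme$nation_overlap <- ov
  attr(scheme, "iwrm_scores") <- data.frame(
    nation_id = seq_len(spec$n_nations),
    score = stats::runif(spec$n_nations, 0, 100))
  scheme
}

#' Generate a complete synthetic world
#'
#' Convenience wrapper running [generate_basin_scheme], [generate_fields]
#' and [generate_nations] under the spec's seed.
#'
#' @param spec A [bv_world_spec].
#' @return An object of class `bv_world`: list with `spec`, `scheme`
#'   (including nations), `fields`, `iwrm_scores`, `planted`.
#' @examples
#' w <- generate_world(bv_world_spec(n_basins = 8, n_nations = 3,
#'                                   lat_range = c(0, 10),
#'                                   lon_range = c(0, 10), seed = 7))
#' @export
generate_world <- function(spec) {
  scheme <- generate_basin_scheme(spec)
  fields <- generate_fields(spec, scheme)
  scheme <- generate_nations(spec, scheme)
  structure(list(spec = spec, scheme = scheme, fields = fields,
                 iwrm_scores = attr(scheme, "iwrm_scores"),
                 planted = attr(fields, "planted")),
            class = "bv_world")
}

#' @export
print.bv_world <- function(x, ...) {
  cat(sprintf("<bv_world> seed %d: %d basins, %d nations, %d x %d grid, %d fields\n",
              x$spec$seed, length(x$scheme$ids), x$spec$n_nations,
              nrow(x$scheme$assignment), ncol(x$scheme$assignment),
              length(x$fields)))
  if (length(x$planted))
    cat("  planted hotspot basins:", paste(x$planted, collapse = ", "), "\n")
  invisible(x)
}
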