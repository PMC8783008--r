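# Plain-text serialization of synthetic worlds: ASCII-grid rasters,
# CSV tables, JSON manifest with md5 checksums.

# write a matrix as an Esri-style ASCII grid, full double precision
.write_asc <- function(values, lat, lon, res, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(values)),
    sprintf("nrows %d", nrow(values)),
    sprintf("xllcorner %.10f", min(lon) - res / 2),
    sprintf("yllcorner %.10f", min(lat) - res / 2),
    sprintf("cellsize %.10f", res),
    "NODATA_value NA"), con)
  for (i in seq_len(nrow(values)))
    writeLines(paste(sprintf("%.17g", values[i, ]), collapse = " "), con)
  invisible(path)
}

.read_asc <- function(path) {
  hdr <- readLines(path, n = 6)
  val <- function(k) as.numeric(sub(paste0(k, " "), "", hdr[grep(paste0("^", k), hdr)]))
  nc <- val("ncols"); nr <- val("nrows")
  res <- val("cellsize")
  x0 <- val("xllcorner"); y0 <- val("yllcorner")
  v <- scan(path, skip = 6, quiet = TRUE, na.strings = "NA")
  values <- matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
  lat <- rev(seq(y0 + res / 2, by = res, length.out = nr))
  lon <- seq(x0 + res / 2, by = res, length.out = nc)
  list(values = values, lat = lat, lon = lon, resolution = res)
}

#' Write a synthetic world to a directory of plain-text files
#'
#' Serializes all gridded fields and the basin/nation maps as ASCII-grid
#' rasters (full double precision, so a round trip is numerically exact),
#' per-basin and per-nation tables as CSV, the world spec as JSON, and a
#' manifest (JSON) listing every file with its md5 checksum and the
#' generating seed.
#'
#' @param world A `bv_world` from [generate_world].
#' @param dir Target directory (created if absent).
#' @return Invisibly, the manifest as a list.
#' @seealso [read_fixture_bundle], [verify_fixture_bundle]
#' @export
write_fixture_bundle <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  s <- world$scheme
  files <- character(0)
  wr <- function(rel, fun) {
    path <- file.path(dir, rel)
    ok <- tryCatch({ fun(path); TRUE },
                   error = function(e) stop("failed writing ", path, ": ",
                                            conditionMessage(e)))
    files <<- c(files, rel)
  }
  dir.create(file.path(dir, "fields"), showWarnings = FALSE)
  for (nm in names(world$fields)) {
    f <- world$fields[[nm]]
    wr(file.path("fields", paste0(nm, ".asc")),
       function(p) .write_asc(f$values, f$lat, f$lon, f$resolution, p))
  }
  wr("basins.asc", function(p)
    .write_asc(s$assignment, s$lat, s$lon, s$resolution, p))
  if (!is.null(s$nations))
    wr("nations.asc", function(p)
      .write_asc(s$nations, s$lat, s$lon, s$resolution, p))
  wr("basin_table.csv", function(p)
    utils::write.csv(data.frame(basin_id = s$ids,
                                area_km2 = as.numeric(s$area_km2),
                                earthquake = as.logical(s$earthquake)),
                     p, row.names = FALSE))
  if (!is.null(s$nation_overlap))
    wr("nation_overlap.csv", function(p)
      utils::write.csv(s$nation_overlap, p, row.names = FALSE))
  if (!is.null(world$iwrm_scores))
    wr("iwrm_scores.csv", function(p)
      utils::write.csv(world$iwrm_scores, p, row.names = FALSE))
  wr("world_spec.json", function(p) {
    sp <- world$spec
    sp$planted_hotspots <- NULL  # re-read worlds carry realized fields already
    jsonlite::write_json(unclass(sp), p, auto_unbox = TRUE, digits = NA)
  })
  manifest <- list(
    seed = world$spec$seed,
    planted = as.integer(world$planted),
    units = lapply(world$fields, function(f) f$units),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(dir, files))), files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Verify the checksums of a fixture bundle
#'
#' @param dir Bundle directory containing `manifest.json`.
#' @return Named logical vector, `TRUE` where the file on disk matches the
#'   manifest checksum.
#' @export
verify_fixture_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  rel <- names(manifest$files)
  now <- unname(tools::md5sum(file.path(dir, rel)))
  stats::setNames(!is.na(now) & now == unlist(manifest$files), rel)
}

#' Read a fixture bundle back into a synthetic world
#'
#' Reconstructs the `bv_world` written by [write_fixture_bundle]. With
#' `verify = TRUE` (default) any checksum mismatch — a tampered or
#' truncated file — is an error naming the offending files.
#'
#' @param dir Bundle directory.
#' @param verify Check manifest checksums before reading.
#' @return A `bv_world` numerically identical to the one written.
#' @export
read_fixture_bundle <- function(dir, verify = TRUE) {
  if (verify) {
    ok <- verify_fixture_bundle(dir)
    if (!all(ok))
      stop("checksum mismatch in fixture bundle: ",
           paste(names(ok)[!ok], collapse = ", "))
  }
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  spec_raw <- jsonlite::read_json(file.path(dir, "world_spec.json"),
                                  simplifyVector = TRUE)
  spec <- bv_world_spec(
    grid_resolution = spec_raw$grid_resolution,
    lat_range = spec_raw$lat_range, lon_range = spec_raw$lon_range,
    n_basins = spec_raw$n_basins, n_nations = spec_raw$n_nations,
    mask_fraction = spec_raw$mask_fraction,
    field_params = spec_raw$field_params,
    earthquake_basins = spec_raw$earthquake_basins,
    seed = spec_raw$seed)
  b <- .read_asc(file.path(dir, "basins.asc"))
  bt <- utils::read.csv(file.path(dir, "basin_table.csv"))
  areas <- cell_area_grid(b$lat, b$lon, b$resolution)$values
  assignment <- matrix(as.integer(b$values), nrow(b$values))
  # recompute basin areas from cell areas: exact, not CSV-precision-limited
  ba <- rowsum(areas[assignment > 0L], assignment[assignment > 0L])
  scheme <- structure(list(
    assignment = assignment,
    ids = bt$basin_id,
    area_km2 = stats::setNames(ba[as.character(bt$basin_id), ],
                               as.character(bt$basin_id)),
    cell_area = areas, lat = b$lat, lon = b$lon,
    resolution = b$resolution,
    earthquake = stats::setNames(bt$earthquake, as.character(bt$basin_id)),
    nations = NULL, nation_overlap = NULL), class = "basin_scheme")
  if (file.exists(file.path(dir, "nations.asc"))) {
    nmap <- .read_asc(file.path(dir, "nations.asc"))
    scheme$nations <- matrix(as.integer(nmap$values), nrow(nmap$values))
  }
  if (file.exists(file.path(dir, "nation_overlap.csv")))
    scheme$nation_overlap <- utils::read.csv(file.path(dir, "nation_overlap.csv"))
  fields <- list()
  for (nm in names(manifest$units)) {
    g <- .read_asc(file.path(dir, "fields", paste0(nm, ".asc")))
    fields[[nm]] <- geogrid(g$values, g$lat, g$lon,
                            units = manifest$units[[nm]])
  }
  iwrm <- NULL
  if (file.exists(file.path(dir, "iwrm_scores.csv")))
    iwrm <- utils::read.csv(file.path(dir, "iwrm_scores.csv"))
  structure(list(spec = spec, scheme = scheme, fields = fields,
                 iwrm_scores = iwrm,
                 planted = as.integer(unlist(manifest$planted))),
            class = "bv_world")
}
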