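# Synthetic world generator: tessellation, field marginals, nations,
# planted hotspots, fixture bundle round trips.

test_that("basin tessellation partitions the unmasked grid", {
  spec <- tiny_spec(seed = 3, n_basins = 4)
  s <- generate_basin_scheme(spec)
  expect_setequal(unique(as.vector(s$assignment)), 1:4)
  expect_equal(sum(s$area_km2), sum(s$cell_area), tolerance = 1e-9)
  # one basin swallows everything
  s1 <- generate_basin_scheme(tiny_spec(seed = 3, n_basins = 1))
  expect_true(all(s1$assignment == 1L))
  # determinism
  s2 <- generate_basin_scheme(spec)
  expect_identical(s$assignment, s2$assignment)
  # contiguity: each basin is one 4-connected component
  for (b in s$ids) {
    cells <- which(s$assignment == b, arr.ind = TRUE)
    seen <- rep(FALSE, nrow(cells))
    key <- paste(cells[, 1], cells[, 2])
    queue <- 1L; seen[1] <- TRUE
    while (length(queue)) {
      cur <- cells[queue[1], ]; queue <- queue[-1]
      nb <- rbind(cur + c(1, 0), cur - c(1, 0), cur + c(0, 1), cur - c(0, 1))
      hit <- match(paste(nb[, 1], nb[, 2]), key)
      hit <- hit[!is.na(hit)]
      hit <- hit[!seen[hit]]
      seen[hit] <- TRUE
      queue <- c(queue, hit)
    }
    expect_true(all(seen), label = sprintf("basin %d contiguous", b))
  }
})

test_that("masking removes a contiguous share of cells and spec validation works", {
  spec <- tiny_spec(seed = 9, mask_fraction = 0.2)
  s <- generate_basin_scheme(spec)
  n <- length(s$assignment)
  expect_equal(sum(s$assignment == 0L), floor(0.2 * n))
  expect_equal(sum(s$area_km2),
               sum(s$cell_area[s$assignment > 0L]), tolerance = 1e-9)
  expect_error(tiny_spec(n_basins = 1e6), "exceeds")
  expect_error(tiny_spec(grid_resolution = 0.3), "divide")
  expect_error(tiny_spec(field_params = list(Q = list(sdlog = -1))), "scale")
})

test_that("generated fields respect their supports and units", {
  w <- small_world()
  f <- w$fields
  expect_true(all(f$Q$values > 0, na.rm = TRUE))
  expect_true(all(f$W$values >= 0, na.rm = TRUE))
  expect_true(all(f$A$values >= 0 & f$A$values <= 1, na.rm = TRUE))
  expect_true(all(f$eco1$values >= 0, na.rm = TRUE))
  expect_identical(f$W$units, "mm yr-1")
  expect_identical(f$dTWS$units, "mm yr-1")
  # stress ratio spans [0, >1] somewhere in a default-parameter world
  r <- f$W$values / f$Q$values
  expect_gt(max(r, na.rm = TRUE), 1)
  expect_lt(min(r, na.rm = TRUE), 0.1)
})

test_that("zero correlation length gives spatially independent fields", {
  spec <- bv_world_spec(grid_resolution = 0.5, lat_range = c(0, 50),
                        lon_range = c(0, 50), n_basins = 10, n_nations = 2,
                        seed = 21,
                        field_params = list(dTWS = list(corr = 0)))
  s <- generate_basin_scheme(spec)
  f <- generate_fields(spec, s)
  v <- f$dTWS$values  # 100 x 100 = 1e4 cells
  lag1 <- cor(as.vector(v[, -1]), as.vector(v[, -ncol(v)]))
  expect_lt(abs(lag1), 0.05)
  # and a positive correlation length produces positive lag-1 correlation
  w2 <- small_world()
  v2 <- w2$fields$dTWS$values
  expect_gt(cor(as.vector(v2[, -1]), as.vector(v2[, -ncol(v2)])), 0.3)
})

test_that("planted hotspots push stress, drying and sensitivity beyond the field", {
  spec <- tiny_spec(seed = 13, n_basins = 20,
                    planted_hotspots = list(list(
                      basin = 5L, stress_multiplier = 10,
                      trend_offset = -50, adapt_ceiling = 0.2,
                      sens_floor = 0.8)))
  s <- generate_basin_scheme(spec)
  f <- generate_fields(spec, s)
  ratio <- basin_mean_intensive(f$W, s) / basin_mean_intensive(f$Q, s)
  trend <- basin_mean_intensive(f$dTWS, s)
  others <- setdiff(as.character(s$ids), "5")
  expect_gt(ratio["5"], median(ratio[others]))
  expect_lt(trend["5"], median(trend[others]))
  expect_lte(max(f$A$values[s$assignment == 5L]), 0.2)
  expect_identical(attr(f, "planted"), 5L)
})

test_that("nations tessellate the grid and produce transboundary basins", {
  # one nation: no transboundary basin
  s1 <- generate_nations(tiny_spec(seed = 4, n_nations = 1),
                         generate_basin_scheme(tiny_spec(seed = 4, n_nations = 1)))
  expect_true(all(table(s1$nation_overlap$basin_id) == 1))
  # many nations: at least one transboundary basin across several seeds
  for (sd in c(1, 2, 3)) {
    spec <- tiny_spec(seed = sd, n_basins = 6, n_nations = 10)
    s <- generate_nations(spec, generate_basin_scheme(spec))
    expect_gt(max(table(s$nation_overlap$basin_id)), 1)
    # overlap fractions per basin sum to 1
    frac <- tapply(s$nation_overlap$fraction, s$nation_overlap$basin_id, sum)
    expect_equal(as.numeric(frac), rep(1, length(frac)), tolerance = 1e-9)
    sc <- attr(s, "iwrm_scores")
    expect_true(all(sc$score >= 0 & sc$score <= 100))
  }
})

test_that("fixture bundles round-trip exactly, detect tampering, differ by seed", {
  w <- small_world()
  d1 <- file.path(tempdir(), "bundle1")
  unlink(d1, recursive = TRUE)
  m1 <- write_fixture_bundle(w, d1)
  back <- read_fixture_bundle(d1)
  for (nm in names(w$fields))
    expect_identical(back$fields[[nm]]$values, w$fields[[nm]]$values,
                     label = paste("field", nm))
  expect_identical(back$scheme$assignment, w$scheme$assignment)
  expect_equal(back$scheme$area_km2, w$scheme$area_km2, tolerance = 1e-12)
  expect_true(all(verify_fixture_bundle(d1)))
  # tamper with one raster -> detected
  p <- file.path(d1, "fields", "W.asc")
  txt <- readLines(p)
  txt[8] <- paste(txt[8], "")
  writeLines(txt, p)
  expect_false(all(verify_fixture_bundle(d1)))
  expect_error(read_fixture_bundle(d1), "checksum mismatch")
  # different seeds give different checksums
  d2 <- file.path(tempdir(), "bundle2")
  unlink(d2, recursive = TRUE)
  w2 <- generate_world(tiny_spec(seed = 99))
  m2 <- write_fixture_bundle(w2, d2)
  expect_false(identical(m1$files[["fields/W.asc"]], m2$files[["fields/W.asc"]]))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a fixed seed reproduces the whole world bitwise", {
  spec <- tiny_spec(seed = 77)
  w1 <- generate_world(spec)
  w2 <- generate_world(spec)
  expect_identical(w1$scheme$assignment, w2$scheme$assignment)
  for (nm in names(w1$fields))
    expect_identical(w1$fields[[nm]]$values, w2$fields[[nm]]$values)
  expect_identical(w1$iwrm_scores, w2$iwrm_scores)
})
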