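# Percentile transforms, ecological sensitivity E, fuzzy sum, and the
# social-ecological sensitivity S.

grid_of <- function(v, nr, nc) geogrid(matrix(v, nr, nc),
                                       lat = rev(seq_len(nr)) - 0.5,
                                       lon = seq_len(nc) - 0.5)

test_that("equal-area distinct values map to exact percentile ranks", {
  nr <- 10; nc <- 10
  set.seed(2)
  vals <- sample(1:100)
  f <- grid_of(vals, nr, nc)
  a <- grid_of(rep(1, 100), nr, nc)
  p <- area_weighted_percentile_transform(f, a)
  expect_equal(sort(unique(as.vector(p$values))), (1:100) / 100)
  expect_equal(as.vector(p$values)[order(vals)], (1:100) / 100)
})

test_that("a constant field scores the midpoint percentile and masks persist", {
  f <- grid_of(rep(4, 36), 6, 6)
  f$values[2, 3] <- NA
  a <- grid_of(rep(1, 36), 6, 6)
  p <- area_weighted_percentile_transform(f, a)
  expect_true(all(p$values == 0.5, na.rm = TRUE))
  expect_true(is.na(p$values[2, 3]))
  allna <- grid_of(rep(NA_real_, 36), 6, 6)
  expect_error(area_weighted_percentile_transform(allna, a), "masked")
})

test_that("percentile bins are equal-area within one cell and rank-invariant", {
  w <- small_world()
  s <- w$scheme
  areas <- geogrid(s$cell_area, s$lat, s$lon)
  f <- w$fields$eco1
  p <- area_weighted_percentile_transform(f, areas)
  # brute-force oracle agreement
  valid <- which(!is.na(f$values))
  po <- oracle_percentile(f$values[valid], areas$values[valid])
  expect_identical(p$values[valid], po)
  # equal-area bins within one cell's area
  tot <- sum(areas$values[valid])
  amax <- max(areas$values[valid])
  binsum <- tapply(areas$values[valid], p$values[valid], sum)
  expect_true(all(abs(binsum - tot / 100) <= amax + 1e-9))
  # invariance under strictly monotone transforms of the values
  g <- f; g$values <- exp(f$values / max(f$values, na.rm = TRUE) * 3)
  pg <- area_weighted_percentile_transform(g, areas)
  expect_identical(p$values, pg$values)
})

test_that("ecological sensitivity normalizes the most sensitive basin to 1", {
  # constructed: two basins with known percentile means
  b <- setNames(c(0.7, 0.35), c("1", "2"))
  expect_equal(unname(b / max(b)), c(1, 0.5))
  w <- small_world()
  s <- w$scheme
  areas <- geogrid(s$cell_area, s$lat, s$lon)
  p1 <- area_weighted_percentile_transform(w$fields$eco1, areas)
  p2 <- area_weighted_percentile_transform(w$fields$eco2, areas)
  E <- ecological_sensitivity_E(p1, p2, s)
  # oracle: basin means via the loop oracle, then average and normalize
  m1 <- oracle_basin_mean(p1$values, s$assignment, s$cell_area, s$ids)
  m2 <- oracle_basin_mean(p2$values, s$assignment, s$cell_area, s$ids)
  comb <- (m1 + m2) / 2
  expect_equal(E, comb / max(comb, na.rm = TRUE), tolerance = 1e-12)
  expect_equal(max(E, na.rm = TRUE), 1)
  expect_true(all(E > 0 & E <= 1, na.rm = TRUE))
})

test_that("pairwise-available averaging scores one-dataset basins, strict mode drops them", {
  w <- small_world()
  s <- w$scheme
  areas <- geogrid(s$cell_area, s$lat, s$lon)
  e1 <- w$fields$eco1
  e1$values[s$assignment == 1L] <- NA  # dataset 1 absent over basin 1
  p1 <- area_weighted_percentile_transform(e1, areas)
  p2 <- area_weighted_percentile_transform(w$fields$eco2, areas)
  E_pair <- ecological_sensitivity_E(p1, p2, s, pairwise = TRUE)
  E_strict <- ecological_sensitivity_E(p1, p2, s, pairwise = FALSE)
  expect_false(is.na(E_pair["1"]))
  expect_true(is.na(E_strict["1"]))
})

test_that("fuzzy sum has the algebraic identities of a fuzzy OR", {
  expect_equal(fuzzy_sum(c(0.5, 0.5)), 0.75, tolerance = 1e-12)
  expect_identical(fuzzy_sum(c(0.37, 0)), 0.37)
  expect_identical(fuzzy_sum(c(1, 0.9)), 1)
  # commutative, never below the largest input
  set.seed(5)
  for (i in 1:20) {
    x <- runif(4)
    expect_equal(fuzzy_sum(x), fuzzy_sum(rev(x)), tolerance = 1e-15)
    expect_gte(fuzzy_sum(x), max(x))
  }
  expect_error(fuzzy_sum(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("social-ecological sensitivity inverts adaptive capacity via fuzzy sum", {
  expect_equal(social_ecological_sensitivity_S(0.4, 1), 0.4, tolerance = 1e-12)
  expect_equal(social_ecological_sensitivity_S(0.4, 0), 1, tolerance = 1e-12)
  expect_equal(social_ecological_sensitivity_S(0.5, 0.5), 0.75, tolerance = 1e-12)
  set.seed(8)
  E <- runif(50); A <- runif(50)
  S <- social_ecological_sensitivity_S(E, A)
  expect_true(all(S >= pmax(E, 1 - A) - 1e-12))
  # monotone: up in E, down in A
  expect_true(all(social_ecological_sensitivity_S(pmin(E + 0.1, 1), A) >= S - 1e-12))
  expect_true(all(social_ecological_sensitivity_S(E, pmin(A + 0.1, 1)) <= S + 1e-12))
})

test_that("rescale_unit maps ranges onto [0,1] and constants to 0.5", {
  expect_equal(rescale_unit(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(rescale_unit(c(3, 3, NA)), c(0.5, 0.5, NA))
})
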