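# Monte-Carlo perturbations, retention metrics, configuration sweep.

test_that("zero magnitude is the identity and reproduces baseline classes", {
  w <- mid_world()
  spec0 <- perturbation_spec(mode = "uniform", magnitude = 0,
                             n_realizations = 3, seed = 2)
  wp <- perturb_inputs(w, spec0, 1L)
  for (nm in spec0$inputs)
    expect_equal(wp$fields[[nm]]$values, w$fields[[nm]]$values,
                 tolerance = 1e-15)
  r <- run_realizations(w, spec0, bv_config())
  expect_identical(r$summary_fraction, 1)
  sel <- !is.na(r$baseline$class) & unclass(r$baseline$class) >= 2L
  expect_true(all(r$retention[as.character(r$baseline$basin_id[sel])] == 1))
})

test_that("perturbations are deterministic in (seed, realization index)", {
  w <- mid_world()
  spec <- perturbation_spec(mode = "spatial", magnitude = 0.2,
                            n_realizations = 5, seed = 9)
  a <- perturb_inputs(w, spec, 3L)
  b <- perturb_inputs(w, spec, 3L)
  expect_identical(a$fields$W$values, b$fields$W$values)
  c2 <- perturb_inputs(w, spec, 4L)
  expect_false(identical(a$fields$W$values, c2$fields$W$values))
})

test_that("uniform mode shares one factor per field and preserves cell ranks", {
  w <- mid_world()
  spec <- perturbation_spec(mode = "uniform", magnitude = 0.2,
                            n_realizations = 1, seed = 31)
  wp <- perturb_inputs(w, spec, 1L)
  fac <- wp$fields$W$values / w$fields$W$values
  expect_lt(diff(range(fac, na.rm = TRUE)), 1e-12)  # zero within-field variance
  expect_identical(order(w$fields$W$values[!is.na(w$fields$W$values)]),
                   order(wp$fields$W$values[!is.na(wp$fields$W$values)]))
  # adaptive capacity stays within [0, 1]
  spec_big <- perturbation_spec(mode = "spatial", magnitude = 0.9,
                                n_realizations = 1, seed = 32)
  wb <- perturb_inputs(w, spec_big, 1L)
  expect_true(all(wb$fields$A$values >= 0 & wb$fields$A$values <= 1,
                  na.rm = TRUE))
  expect_true(all(wb$fields$Q$values > 0, na.rm = TRUE))
})

test_that("n = 1 equals a single perturbed pipeline run", {
  w <- mid_world()
  spec <- perturbation_spec(mode = "uniform", magnitude = 0.1,
                            n_realizations = 1, seed = 12)
  r <- run_realizations(w, spec, bv_config())
  w1 <- perturb_inputs(w, spec, 1L)
  fit1 <- basin_vulnerability(w1, bv_config(variants = "social-ecological"))
  at_least_trans <- !is.na(fit1$basins$class) &
    unclass(fit1$basins$class) >= 2L
  expect_equal(unname(r$retention), as.numeric(at_least_trans))
})

test_that("planted hotspots survive small perturbations", {
  spec <- tiny_spec(seed = 6, n_basins = 30, planted_hotspots = list(
    list(basin = 8L, stress_multiplier = 8, trend_offset = -40,
         adapt_ceiling = 0.15, sens_floor = 0.85)))
  w <- generate_world(spec)
  r <- run_realizations(w, perturbation_spec(mode = "uniform",
                                             magnitude = 0.05,
                                             n_realizations = 100, seed = 4))
  expect_gt(r$retention[["8"]], 0.9)
})

test_that("the magnitude must be stated and invalid specs are rejected", {
  expect_error(perturbation_spec(mode = "uniform"), "magnitude")
  expect_error(perturbation_spec(magnitude = -0.1), ">= 0")
  expect_error(perturbation_spec(magnitude = 0.2, n_realizations = 0), ">= 1")
  expect_error(perturbation_spec(magnitude = c(W = 0.2)), "cover")
})

test_that("identical configs agree fully; boundary-free data ignore strictness", {
  w <- mid_world()
  sweep1 <- config_sweep(w, list(a = bv_config(), b = bv_config()))
  expect_true(all(sweep1$agreement == 1))
  # stress strictness only matters at exact threshold values, absent here
  sweep2 <- config_sweep(w, list(ge = bv_config(stress_strict = FALSE),
                                 gt = bv_config(stress_strict = TRUE)))
  expect_true(all(sweep2$labels[, 1] == sweep2$labels[, 2], na.rm = TRUE))
  expect_error(config_sweep(w, list()), "at least one")
  expect_error(config_sweep(w, list(1)), "bv_config")
})

test_that("a larger normalization factor never increases F", {
  w <- mid_world()
  fits <- lapply(c(0.2, 0.4, 0.8), function(k)
    basin_vulnerability(w, bv_config(norm_factor = k)))
  F02 <- fits[[1]]$basins$F
  F04 <- fits[[2]]$basins$F
  F08 <- fits[[3]]$basins$F
  expect_true(all(F04 <= F02 + 1e-12, na.rm = TRUE))
  expect_true(all(F08 <= F04 + 1e-12, na.rm = TRUE))
})

test_that("the config grid expands axes into labelled bv_configs", {
  g <- bv_config_grid(norm_factor = c(0.2, 0.4), stress_strict = c(TRUE, FALSE))
  expect_length(g, 4)
  expect_true(all(vapply(g, inherits, logical(1), "bv_config")))
  expect_true(any(grepl("norm_factor=0.2", names(g))))
})
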