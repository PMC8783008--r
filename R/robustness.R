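# Monte-Carlo uncertainty propagation and the methodological
# configuration sweep.

#' Specify an input-perturbation experiment
#'
#' Two perturbation modes mirror the two uncertainty analyses of the
#' method: `"uniform"` multiplies every cell of an input field by one
#' factor drawn per (input, realization) from `U[1 - m, 1 + m]` (uniform
#' over/under-estimation of a dataset); `"spatial"` draws a spatially
#' correlated per-cell factor field with the same uniform marginal
#' (heterogeneous uncertainty). The magnitude has no default in the sense
#' that it must be stated explicitly: it is a configuration choice.
#'
#' @param mode `"uniform"` or `"spatial"`.
#' @param magnitude Relative magnitude m >= 0, a single number or a named
#'   vector per input (e.g. `c(W = 0.2, Q = 0.1)`).
#' @param inputs Which fields to perturb.
#' @param corr_length Correlation length in cells (spatial mode).
#' @param n_realizations Number of realizations (>= 1).
#' @param seed Master seed; per-realization streams are derived by
#'   counter-based splitting, so realizations are order-independent.
#' @return Object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(mode = c("uniform", "spatial"),
                              magnitude,
                              inputs = c("W", "Q", "dTWS", "A",
                                         "eco1", "eco2"),
                              corr_length = 3,
                              n_realizations = 100,
                              seed = 1L) {
  mode <- match.arg(mode)
  if (missing(magnitude)) stop("`magnitude` must be stated explicitly")
  if (any(magnitude < 0)) stop("magnitudes must be >= 0")
  if (is.null(names(magnitude)))
    magnitude <- stats::setNames(rep_len(magnitude, length(inputs)), inputs)
  if (!all(inputs %in% names(magnitude)))
    stop("named `magnitude` must cover all perturbed inputs")
  if (n_realizations < 1) stop("n_realizations must be >= 1")
  structure(list(mode = mode, magnitude = magnitude[inputs],
                 inputs = inputs, corr_length = corr_length,
                 n_realizations = as.integer(n_realizations),
                 seed = as.integer(seed)),
            class = "perturbation_spec")
}

# counter-based per-realization seed; keeps within 32-bit signed range
.realization_seed <- function(seed, k) {
  as.integer((as.double(seed) + 1000003 * as.double(k)) %% 2147483647)
}

#' Perturb the input fields of a world
#'
#' Applies one realization of the perturbation experiment. Deterministic
#' given `(spec$seed, realization_index)`. Bounded inputs are kept valid:
#' adaptive capacity is re-clipped to [0, 1], and factors that would drive
#' streamflow non-positive are floored at a small positive value (the
#' event is recorded in attribute `floored`).
#'
#' @param world A `bv_world`.
#' @param spec A [perturbation_spec].
#' @param realization_index Which realization (1-based counter).
#' @return The world with perturbed fields.
#' @export
perturb_inputs <- function(world, spec, realization_index = 1L) {
  set.seed(.realization_seed(spec$seed, realization_index))
  f <- world$fields
  floored <- character(0)
  nr <- length(world$scheme$lat)
  nc <- length(world$scheme$lon)
  for (nm in spec$inputs) {
    m <- spec$magnitude[[nm]]
    fac <- if (spec$mode == "uniform") {
      stats::runif(1, 1 - m, 1 + m)
    } else {
      u <- stats::pnorm(.smooth_field(matrix(stats::rnorm(nr * nc), nr, nc),
                                      spec$corr_length))
      (1 - m) + 2 * m * u
    }
    if (any(fac <= 0)) {
      fac <- pmax(fac, 1e-6)
      floored <- c(floored, nm)
    }
    f[[nm]]$values <- f[[nm]]$values * fac
    if (nm == "A") f[[nm]]$values <- pmin(pmax(f[[nm]]$values, 0), 1)
  }
  world$fields <- f
  attr(world, "floored") <- floored
  world
}

#' Monte-Carlo robustness of the hotspot classification
#'
#' Re-runs the full pipeline (aggregation, percentile transforms,
#' indicators, Head/Tail Breaks classification) under `n_realizations`
#' input perturbations and measures, per basin, the fraction of
#' realizations in which the basin is classified at least transitional.
#' The summary statistic is the fraction of baseline transitional-and-
#' hotspot basins that keep at-least-transitional class in more than half
#' of the realizations.
#'
#' @param world A `bv_world`.
#' @param spec A [perturbation_spec].
#' @param config A [bv_config]; only the primary variant is tracked.
#' @return Object of class `bv_robustness`: list with `retention` (named
#'   per-basin fractions), `summary_fraction`, `n_realizations`,
#'   `baseline` (classification table), `mode`.
#' @export
run_realizations <- function(world, spec, config = bv_config()) {
  cfg <- config
  cfg$variants <- config$variants[1]
  base <- .bv_run(world, cfg)
  base_cls <- .bv_classify(base, cfg)[[1]]
  ids <- as.character(base_cls$basin_id)
  at_least_trans <- function(tab)
    !is.na(tab$class) & unclass(tab$class) >= 2L
  hits <- stats::setNames(numeric(length(ids)), ids)
  for (k in seq_len(spec$n_realizations)) {
    wk <- perturb_inputs(world, spec, k)
    bk <- tryCatch(.bv_run(wk, cfg), error = function(e)
      stop("realization ", k, " failed: ", conditionMessage(e)))
    ck <- .bv_classify(bk, cfg)[[1]]
    hits <- hits + at_least_trans(ck)[match(ids, as.character(ck$basin_id))]
  }
  retention <- hits / spec$n_realizations
  base_sel <- at_least_trans(base_cls)
  summary_fraction <- if (any(base_sel))
    mean(retention[ids[base_sel]] > 0.5) else NA_real_
  structure(list(retention = retention,
                 summary_fraction = summary_fraction,
                 n_realizations = spec$n_realizations,
                 baseline = base_cls, mode = spec$mode),
            class = "bv_robustness")
}

#' @export
print.bv_robustness <- function(x, ...) {
  cat(sprintf(
    "<bv_robustness> %d realizations (%s mode): %.1f%% of baseline transitional+hotspot basins retained (>50%% of realizations)\n",
    x$n_realizations, x$mode, 100 * x$summary_fraction))
  invisible(x)
}

#' Sweep alternative methodological configurations
#'
#' Re-classifies one world under a list of pipeline configurations and
#' reports per-config labels, the pairwise label-agreement matrix, and the
#' set of basins consistently identified (at least transitional in a
#' majority of configurations).
#'
#' @param world A `bv_world`.
#' @param configs Non-empty list of [bv_config] objects.
#' @return List with `labels` (basins x configs matrix of class labels),
#'   `agreement` (pairwise fraction of basins with identical labels),
#'   `consistent` (basin ids at least transitional in a majority of
#'   configs).
#' @export
config_sweep <- function(world, configs) {
  if (!length(configs)) stop("at least one configuration is required")
  for (i in seq_along(configs))
    if (!inherits(configs[[i]], "bv_config"))
      stop("configs[[", i, "]] is not a bv_config")
  labs <- NULL
  trans <- NULL
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    cfg$variants <- cfg$variants[1]
    tab <- .bv_classify(.bv_run(world, cfg), cfg)[[1]]
    if (is.null(labs)) {
      labs <- matrix(NA_character_, nrow(tab), length(configs),
                     dimnames = list(as.character(tab$basin_id),
                                     names(configs) %||%
                                       paste0("config", seq_along(configs))))
      trans <- matrix(FALSE, nrow(tab), length(configs))
    }
    labs[, i] <- as.character(tab$class)
    trans[, i] <- !is.na(tab$class) & unclass(tab$class) >= 2L
  }
  k <- length(configs)
  agreement <- matrix(1, k, k, dimnames = list(colnames(labs), colnames(labs)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    same <- labs[, i] == labs[, j]
    agreement[i, j] <- mean(same | (is.na(labs[, i]) & is.na(labs[, j])),
                            na.rm = TRUE)
  }
  consistent <- rownames(labs)[rowMeans(trans) > 0.5]
  list(labels = labs, agreement = agreement, consistent = consistent)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a grid of alternative configurations
#'
#' Expands named axes of configuration values into a list of
#' [bv_config]s, e.g.
#' `bv_config_grid(norm_factor = c(0.2, 0.4, 0.8), stress_strict = c(TRUE, FALSE))`.
#'
#' @param ... Named vectors/lists of [bv_config] argument values.
#' @return Named list of `bv_config` objects.
#' @export
bv_config_grid <- function(...) {
  axes <- list(...)
  if (!length(axes)) return(list(default = bv_config()))
  grid <- expand.grid(lapply(axes, seq_along))
  out <- vector("list", nrow(grid))
  nms <- character(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    args <- list()
    for (ax in names(axes)) {
      val <- axes[[ax]][[grid[r, ax]]]
      args[[ax]] <- val
    }
    out[[r]] <- do.call(bv_config, args)
    nms[r] <- paste(vapply(names(args), function(a)
      paste0(a, "=", paste(format(args[[a]]), collapse = "/")),
      character(1)), collapse = ",")
  }
  stats::setNames(out, nms)
}
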