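# End-to-end pipeline: world -> basin indicator table -> vulnerability
# classification, exposure accounting and IWRM comparison, wrapped in one
# classed result object.

#' Pipeline configuration
#'
#' Collects every methodological knob of the vulnerability pipeline in one
#' validated object. Defaults reproduce the reference configuration:
#' 0.4 Q normalization, inclusive stress thresholds at 0.10/0.40, a
#' +/- 3 mm/yr descriptive trend threshold, 100 percentile bins with
#' midpoint tie handling, pairwise-available averaging of the two
#' ecological datasets, three Head/Tail Breaks iterations with
#' zero-vulnerability basins included in the break computation, and no
#' rescaling of an already unit-scaled adaptive capacity.
#'
#' @param norm_factor Normalization factor on Q for both F and T (> 0).
#' @param stress_thresholds Stress category thresholds on W/Q.
#' @param stress_strict Strict (`>`) instead of inclusive (`>=`) stress
#'   thresholds.
#' @param trend_threshold Clear-trend threshold (mm/yr), categorical only.
#' @param percentile_bins Bins of the area-weighted percentile transform.
#' @param eco_pairwise Pairwise-available averaging of the two ecological
#'   datasets (vs strict intersection).
#' @param rescale_A Min-max rescale adaptive capacity to [0, 1] before
#'   inversion (needed for native-scale input data).
#' @param htb_iterations Head/Tail Breaks iterations (4 classes at 3).
#' @param include_zero_v Include V = 0 basins when computing class breaks.
#' @param variants Which vulnerability variants to classify.
#' @return Object of class `bv_config` (a validated list).
#' @export
bv_config <- function(norm_factor = 0.4,
                      stress_thresholds = c(0.10, 0.40),
                      stress_strict = FALSE,
                      trend_threshold = 3,
                      percentile_bins = 100,
                      eco_pairwise = TRUE,
                      rescale_A = FALSE,
                      htb_iterations = 3,
                      include_zero_v = TRUE,
                      variants = c("social-ecological", "social",
                                   "ecological")) {
  if (norm_factor <= 0) stop("norm_factor must be > 0")
  if (length(stress_thresholds) != 2 || diff(stress_thresholds) <= 0)
    stop("stress_thresholds must be two increasing values")
  if (trend_threshold < 0) stop("trend_threshold must be >= 0")
  if (percentile_bins < 1) stop("percentile_bins must be >= 1")
  if (htb_iterations < 1) stop("htb_iterations must be >= 1")
  variants <- match.arg(variants, several.ok = TRUE)
  structure(list(norm_factor = norm_factor,
                 stress_thresholds = stress_thresholds,
                 stress_strict = stress_strict,
                 trend_threshold = trend_threshold,
                 percentile_bins = percentile_bins,
                 eco_pairwise = eco_pairwise,
                 rescale_A = rescale_A,
                 htb_iterations = htb_iterations,
                 include_zero_v = include_zero_v,
                 variants = variants),
            class = "bv_config")
}

# Sensitivity inputs for each vulnerability variant.
.variant_S <- function(variant, E, A) {
  switch(variant,
         "social-ecological" = social_ecological_sensitivity_S(E, A),
         "social" = 1 - A,
         "ecological" = E,
         stop("unknown variant: ", variant))
}

# Core numerical pass: gridded world -> per-basin indicator table.
# Shared by the main fit and every Monte-Carlo realization.
.bv_run <- function(world, config = bv_config()) {
  scheme <- world$scheme
  f <- world$fields
  areas <- geogrid(scheme$cell_area, scheme$lat, scheme$lon, units = "km2")
  W <- basin_mean_intensive(f$W, scheme)
  Q <- basin_mean_intensive(f$Q, scheme)
  dTWS <- basin_mean_intensive(f$dTWS, scheme)
  A <- basin_mean_intensive(f$A, scheme)
  if (config$rescale_A) A <- rescale_unit(A)
  p1 <- area_weighted_percentile_transform(f$eco1, areas,
                                           bins = config$percentile_bins)
  p2 <- area_weighted_percentile_transform(f$eco2, areas,
                                           bins = config$percentile_bins)
  E <- ecological_sensitivity_E(p1, p2, scheme,
                                pairwise = config$eco_pairwise)
  eq <- as.logical(scheme$earthquake[as.character(scheme$ids)])
  ratio <- stress_ratio(W, Q)
  F_ <- stress_indicator_F(W, Q, factor = config$norm_factor)
  T_ <- trend_indicator_T(dTWS, Q, factor = config$norm_factor)
  B <- basin_status_B(F_, T_, earthquake = eq)
  S <- social_ecological_sensitivity_S(E, A)
  data.frame(
    basin_id = scheme$ids,
    area_km2 = as.numeric(scheme$area_km2[as.character(scheme$ids)]),
    W = as.numeric(W), Q = as.numeric(Q), dTWS_dt = as.numeric(dTWS),
    A = as.numeric(A), E = as.numeric(E),
    earthquake = eq,
    stress_ratio = as.numeric(ratio),
    F = as.numeric(F_), T = as.numeric(T_), B = as.numeric(B),
    S = as.numeric(S),
    V = vulnerability_V(as.numeric(S), as.numeric(B)),
    cooccurrence = cooccurrence_class(
      as.numeric(ratio), as.numeric(dTWS),
      thresholds = config$stress_thresholds,
      trend_threshold = config$trend_threshold,
      strict = config$stress_strict),
    stringsAsFactors = FALSE)
}

# classification of one indicator table under a config, per variant
.bv_classify <- function(basins, config) {
  out <- list()
  for (v in config$variants) {
    S_v <- .variant_S(v, basins$E, basins$A)
    V_v <- vulnerability_V(S_v, basins$B)
    names(V_v) <- as.character(basins$basin_id)
    out[[v]] <- classify_vulnerability(V_v,
                                       iterations = config$htb_iterations,
                                       include_zero = config$include_zero_v,
                                       variant = v)
  }
  out
}

#' Run the full basin-vulnerability analysis
#'
#' The main entry point: takes a world (synthetic, from
#' [generate_world], or assembled from real gridded data in the same
#' structure) and a [bv_config], aggregates all gridded inputs to basins,
#' computes the freshwater stress, storage-trend, status, sensitivity and
#' vulnerability indicators, classifies basins with Head/Tail Breaks for
#' each requested variant, and attaches exposure summaries, the
#' adaptability-by-status cross-tabulation and (when nation data are
#' present) the IWRM comparison.
#'
#' @param world A `bv_world`.
#' @param config A [bv_config].
#' @return Object of class `basin_vulnerability`: list with `basins`
#'   (per-basin indicator + class table), `classification` (per-variant
#'   tables with class breaks), `exposure`, `crosstab`, `iwrm`, `config`,
#'   `world`.
#' @examples
#' w <- generate_world(bv_world_spec(n_basins = 10, n_nations = 3,
#'                                   lat_range = c(0, 10),
#'                                   lon_range = c(0, 10), seed = 3))
#' fit <- basin_vulnerability(w)
#' summary(fit)
#' @export
basin_vulnerability <- function(world, config = bv_config()) {
  stopifnot(inherits(world, "bv_world"))
  basins <- .bv_run(world, config)
  classification <- .bv_classify(basins, config)
  main <- classification[[config$variants[1]]]
  basins$class <- main$class[match(basins$basin_id, main$basin_id)]
  basins$hotspot <- main$hotspot[match(basins$basin_id, main$basin_id)]
  ext <- data.frame(basin_id = world$scheme$ids)
  for (nm in intersect(c("population", "crop", "gdp"), names(world$fields)))
    ext[[nm]] <- as.numeric(basin_sum_extensive(world$fields[[nm]],
                                                world$scheme))
  if ("richness" %in% names(world$fields))
    ext$richness <- as.numeric(basin_mean_intensive(world$fields$richness,
                                                    world$scheme))
  exposure <- exposure_by_category(ext,
    stats::setNames(as.character(basins$class),
                    as.character(basins$basin_id)))
  crosstab <- adaptability_status_crosstab(basins$B, basins$A)
  iwrm <- NULL
  if (!is.null(world$scheme$nation_overlap) && !is.null(world$iwrm_scores)) {
    iw <- basin_iwrm_score(world$scheme, world$iwrm_scores)
    iwrm <- iwrm_vulnerability_summary(iw, main)
  }
  structure(list(basins = basins, classification = classification,
                 exposure = exposure, crosstab = crosstab, iwrm = iwrm,
                 config = config, world = world),
            class = "basin_vulnerability")
}

#' @export
print.basin_vulnerability <- function(x, ...) {
  b <- x$basins
  cat("Basin social-ecological vulnerability analysis\n")
  cat(sprintf("  %d basins (%d scorable), %s variant(s)\n",
              nrow(b), sum(!is.na(b$V)),
              paste(x$config$variants, collapse = ", ")))
  cat(sprintf("  hotspots: %d (%.1f%%), transitional: %d (%.1f%%)\n",
              sum(b$hotspot, na.rm = TRUE),
              100 * mean(b$hotspot, na.rm = TRUE),
              sum(b$class == "transitional", na.rm = TRUE),
              100 * mean(b$class == "transitional", na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.basin_vulnerability <- function(object, ...) {
  b <- object$basins
  scored <- !is.na(b$stress_ratio)
  out <- list(
    n_basins = nrow(b),
    n_scored = sum(scored),
    class_counts = table(b$class),
    n_stressed = sum(b$stress_ratio >= object$config$stress_thresholds[1],
                     na.rm = TRUE),
    cooccurrence_counts = table(b$cooccurrence),
    breaks = lapply(object$classification, attr, "breaks"),
    exposure = object$exposure,
    iwrm = if (!is.null(object$iwrm))
      object$iwrm[c("mean_iwrm_transboundary_hotspots",
                    "mean_iwrm_nontransboundary_hotspots",
                    "share_hotspots_transboundary")])
  class(out) <- "summary.basin_vulnerability"
  out
}

#' @export
print.summary.basin_vulnerability <- function(x, ...) {
  cat(sprintf("Basins: %d (%d scorable), stressed (W/Q over threshold): %d\n",
              x$n_basins, x$n_scored, x$n_stressed))
  cat("Vulnerability classes:\n")
  print(x$class_counts)
  cat("Stress x trend co-occurrence:\n")
  print(x$cooccurrence_counts)
  if (!is.null(x$iwrm) && !is.null(x$iwrm$share_hotspots_transboundary)) {
    cat(sprintf(
      "IWRM: transboundary hotspots mean %.1f vs non-transboundary %.1f (%.0f%% of hotspots transboundary)\n",
      x$iwrm$mean_iwrm_transboundary_hotspots,
      x$iwrm$mean_iwrm_nontransboundary_hotspots,
      100 * x$iwrm$share_hotspots_transboundary))
  }
  invisible(x)
}

#' @export
as.data.frame.basin_vulnerability <- function(x, ...) x$basins

#' Map and class-distribution plot of a vulnerability analysis
#'
#' Two panels: the vulnerability field painted on the basin map, and the
#' basin-count distribution over vulnerability classes.
#'
#' @param x A `basin_vulnerability` object.
#' @param ... Unused.
#' @export
plot.basin_vulnerability <- function(x, ...) {
  b <- x$basins
  s <- x$world$scheme
  vmap <- matrix(NA_real_, nrow(s$assignment), ncol(s$assignment))
  ok <- s$assignment > 0L
  vv <- stats::setNames(b$V, as.character(b$basin_id))
  vmap[ok] <- vv[as.character(s$assignment[ok])]
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(s$lon, rev(s$lat), t(vmap[nrow(vmap):1, ]),
                  col = grDevices::hcl.colors(24, "YlOrRd", rev = TRUE),
                  xlab = "lon", ylab = "lat",
                  main = "vulnerability V")
  graphics::barplot(table(b$class), main = "basins per class",
                    ylab = "basin count", las = 2)
  invisible(x)
}

#' Monte-Carlo realizations of a fitted analysis
#'
#' `simulate()` on a `basin_vulnerability` object re-runs the pipeline
#' under random input perturbations and returns the robustness report —
#' see [run_realizations].
#'
#' @param object A `basin_vulnerability` object.
#' @param nsim Number of realizations.
#' @param seed Master seed for the perturbation streams.
#' @param mode `"uniform"` or `"spatial"` perturbations.
#' @param magnitude Relative perturbation magnitude (required; the
#'   reference magnitudes are configuration, not defaults).
#' @param ... Passed to [perturbation_spec].
#' @return A `bv_robustness` report.
#' @export
simulate.basin_vulnerability <- function(object, nsim = 100, seed = 1,
                                         mode = "uniform", magnitude, ...) {
  spec <- perturbation_spec(mode = mode, magnitude = magnitude,
                            n_realizations = nsim, seed = seed, ...)
  run_realizations(object$world, spec, object$config)
}

#' Write the per-basin result table as CSV
#'
#' Deterministic plain-text export of the fitted basin table (indicators,
#' classes, hotspot flags): identical worlds and configs produce
#' byte-identical files.
#'
#' @param object A `basin_vulnerability` object.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_basin_table <- function(object, path) {
  b <- object$basins
  num <- vapply(b, is.numeric, logical(1))
  b[num] <- lapply(b[num], function(x) sprintf("%.15g", x))
  utils::write.csv(b, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
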