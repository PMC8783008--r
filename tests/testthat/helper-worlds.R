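# Shared small synthetic worlds, built once per test run.

tiny_spec <- function(seed = 1, ...) {
  args <- list(grid_resolution = 0.5, lat_range = c(0, 10),
               lon_range = c(0, 10), n_basins = 12, n_nations = 4,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(bv_world_spec, args)
}

.world_cache <- new.env(parent = emptyenv())

cached_world <- function(key, spec) {
  if (is.null(.world_cache[[key]]))
    .world_cache[[key]] <- generate_world(spec)
  .world_cache[[key]]
}

small_world <- function() cached_world("small", tiny_spec(seed = 11))

# 50-basin world used by robustness checks
mid_world <- function() cached_world(
  "mid", bv_world_spec(grid_resolution = 1, lat_range = c(0, 20),
                       lon_range = c(0, 20), n_basins = 50,
                       n_nations = 6, seed = 5))
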