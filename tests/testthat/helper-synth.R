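# Shared small-scale experiment configurations. These shrink the spatial
# grid, session count and resting period so that suites run in minutes; the
# trial structure (balanced pseudo-random order, 5 s stimuli, 30 s
# intervals) matches the generator defaults.

flat_drift <- function(n_sessions, channels = c("calcium", "ach")) {
  setNames(lapply(channels, function(ch) rep(1, n_sessions)), channels)
}

small_config <- function(seed = 1, n_sessions = 10, grid = c(12, 6, 4),
                         noise_sd = 0.05, rest_duration = 120, ...) {
  args <- list(...)
  if (is.null(args$drift_schedule)) {
    chans <- if (!is.null(args$channel_params)) names(args$channel_params)
             else c("calcium", "ach")
    args$drift_schedule <- flat_drift(n_sessions, chans)
  }
  defaults <- list(grid_shape = grid, n_regions = 4, olfactory_regions = 1:2,
                   n_sessions = n_sessions, rest_duration = rest_duration,
                   noise_sd = noise_sd, seed = seed)
  defaults[names(args)] <- NULL
  do.call(synth_config, c(defaults, args))
}

# Config with a single planted single-voxel ensemble for audit tests.
single_voxel_spec <- function(channels, odors, voxel_region = 1,
                              amplitude = 1, odor = odors[1]) {
  spec <- lapply(channels, function(ch) {
    per <- lapply(odors, function(od) list(regions = integer(0), fraction = 0,
                                           amplitude = 0))
    names(per) <- odors
    per[[odor]] <- list(regions = voxel_region, fraction = 1e-9,
                        amplitude = amplitude)  # fraction rounds up to 1 voxel
    per
  })
  names(spec) <- channels
  spec
}

# dF/F baseline parameters suited to the shortened resting period.
test_dff <- function(exper, channel, window = 100) {
  dff_tensor(exper, channel, window = window)
}
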