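#' Configuration for the synthetic dual-channel odor-imaging experiment
#'
#' Bundles every parameter of the synthetic experiment generator. The defaults
#' reproduce the design of the emulated study: 3 odors delivered in a
#' pseudo-random order avoiding consecutive repeats, 60 sessions (one trial of
#' each odor per session, 180 trials total), 5 s stimulation with 30 s
#' inter-trial intervals, a 10-min resting period before the first trial,
#' and volumes generated directly at the 2.3 Hz analysis frame rate.
#'
#' @param grid_shape integer(3); voxels per axis (x, y, z).
#' @param n_regions number of atlas regions; the grid is split into
#'   `n_regions` equal slabs along x.
#' @param olfactory_regions integer ids of regions flagged as olfactory.
#' @param odors character vector of odor labels, in delivery-order convention.
#' @param n_sessions number of sessions; each session presents every odor once.
#' @param frame_rate volume rate in Hz.
#' @param stim_duration odor stimulus duration in seconds.
#' @param inter_trial_interval seconds between stimulus offset and next onset.
#' @param rest_duration resting-state seconds recorded before the first trial.
#' @param channel_params named list per channel with fields `delay`,
#'   `rise_tau`, `decay_tau` (seconds) and `amplitude_scale`; defaults are a
#'   fast calcium-like channel and an acetylcholine-like channel (sub-second
#'   rise, ~2 s decay). Use [serotonin_params()] for a slow 5-HT-like channel.
#' @param ensemble_spec nested list `channel -> odor -> list(regions,
#'   fraction, amplitude)` declaring the planted odor-tuned voxel ensembles;
#'   see [default_ensemble_spec()].
#' @param drift_schedule named list per channel of `n_sessions` multiplicative
#'   amplitude factors, or `NULL` to derive a per-channel preset from the
#'   channel name via [drift_preset()] (calcium-like gradual decay, flat
#'   acetylcholine, early-drop serotonin).
#' @param motion_coupling named numeric per channel: gain of the shared motion
#'   trace on fluorescence (dF/F units per unit motion).
#' @param motion_mode `"random"` (smooth positive noise), `"odor_locked"`
#'   (motion amplitude depends on odor identity; used for confound controls)
#'   or `"none"`.
#' @param noise_sd additive Gaussian noise sd, in dF/F units.
#' @param baseline_F baseline fluorescence level (arbitrary units, > 0).
#' @param seed integer seed; identical configs give bit-identical experiments.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(grid_shape = c(24, 24, 8),
                         n_regions = 8,
                         olfactory_regions = 1:4,
                         odors = c("OCT", "MCH", "EA"),
                         n_sessions = 60,
                         frame_rate = 2.3,
                         stim_duration = 5,
                         inter_trial_interval = 30,
                         rest_duration = 600,
                         channel_params = list(
                           calcium = list(delay = 0.2, rise_tau = 0.2,
                                          decay_tau = 1.5, amplitude_scale = 1),
                           ach = list(delay = 0.2, rise_tau = 0.15,
                                      decay_tau = 1.8, amplitude_scale = 1)),
                         ensemble_spec = NULL,
                         drift_schedule = NULL,
                         motion_coupling = NULL,
                         motion_mode = c("random", "odor_locked", "none"),
                         noise_sd = 0.05,
                         baseline_F = 100,
                         seed = 1L) {
  motion_mode <- match.arg(motion_mode)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
            n_regions >= 1, frame_rate > 0, stim_duration > 0,
            inter_trial_interval >= 0, rest_duration >= 0,
            n_sessions >= 1, noise_sd >= 0, baseline_F > 0)
  if (length(odors) < 1) stop("at least one odor required")
  if (n_regions > grid_shape[1])
    stop("n_regions cannot exceed the x extent of the grid")
  channels <- names(channel_params)
  if (is.null(channels) || any(channels == ""))
    stop("channel_params must be a named list")
  for (ch in channels) {
    p <- channel_params[[ch]]
    if (p$rise_tau <= 0 || p$decay_tau <= 0)
      stop("non-positive kinetic time constant for channel ", ch)
    if (p$rise_tau >= p$decay_tau)
      stop("rise_tau must be smaller than decay_tau for channel ", ch)
  }
  if (is.null(ensemble_spec))
    ensemble_spec <- default_ensemble_spec(channels, odors, olfactory_regions)
  if (is.null(drift_schedule)) {
    drift_schedule <- lapply(channels, function(ch)
      drift_preset(channel_kind(ch), n_sessions))
    names(drift_schedule) <- channels
  }
  for (ch in names(drift_schedule)) {
    d <- drift_schedule[[ch]]
    if (length(d) != n_sessions || any(d <= 0))
      stop("drift schedule for channel ", ch,
           " must be ", n_sessions, " positive multipliers")
  }
  if (is.null(motion_coupling))
    motion_coupling <- setNames(rep(0, length(channels)), channels)
  cfg <- list(grid_shape = as.integer(grid_shape), n_regions = as.integer(n_regions),
              olfactory_regions = as.integer(olfactory_regions), odors = odors,
              n_sessions = as.integer(n_sessions),
              trials_per_session = length(odors),
              frame_rate = frame_rate, stim_duration = stim_duration,
              inter_trial_interval = inter_trial_interval,
              rest_duration = rest_duration,
              channel_params = channel_params, ensemble_spec = ensemble_spec,
              drift_schedule = drift_schedule,
              motion_coupling = motion_coupling, motion_mode = motion_mode,
              noise_sd = noise_sd, baseline_F = baseline_F,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

# Map a channel name onto a qualitative drift family.
channel_kind <- function(name) {
  n <- tolower(name)
  if (grepl("cal|g7f|gcamp", n)) "calcium"
  else if (grepl("ser|5.?ht|htr", n)) "serotonin"
  else if (grepl("ach", n)) "ach"
  else "flat"
}

#' Per-session amplitude drift presets
#'
#' Qualitative drift families over sessions, expressed as multiplicative
#' amplitude factors: `"calcium"` decays linearly so that the four equal
#' stages average 1.0, 0.85, 0.70 and 0.55; `"ach"`/`"flat"` stay at 1;
#' `"serotonin"` drops from 1 to 0.7 after the first quarter of sessions.
#'
#' @param kind one of `"calcium"`, `"ach"`, `"serotonin"`, `"flat"`.
#' @param n_sessions schedule length.
#' @return numeric vector of `n_sessions` positive multipliers.
#' @export
drift_preset <- function(kind = c("flat", "calcium", "ach", "serotonin"),
                         n_sessions) {
  kind <- match.arg(kind)
  s <- seq_len(n_sessions)
  switch(kind,
    flat = ,
    ach = rep(1, n_sessions),
    calcium = {
      # linear in session index so that four equal stages average
      # 1.0, 0.85, 0.70, 0.55
      1.075 - 0.6 * (s - 0.5) / n_sessions
    },
    serotonin = ifelse(s <= ceiling(n_sessions / 4), 1, 0.7))
}

#' Default planted ensemble specification
#'
#' One odor-tuned ensemble per odor and channel, each occupying a fraction of
#' the voxels of one olfactory region (odor i in the i-th listed olfactory
#' region, recycled), with peak dF/F amplitude `amplitude`.
#'
#' @param channels channel names.
#' @param odors odor labels.
#' @param olfactory_regions olfactory region ids hosting the ensembles.
#' @param fraction member fraction of the host region's voxels.
#' @param amplitude planted peak response amplitude in dF/F units.
#' @return nested list `channel -> odor -> list(regions, fraction, amplitude)`.
#' @export
default_ensemble_spec <- function(channels, odors, olfactory_regions,
                                  fraction = 0.15, amplitude = 0.6) {
  per_odor <- lapply(seq_along(odors), function(i) {
    reg <- olfactory_regions[((i - 1) %% length(olfactory_regions)) + 1]
    list(regions = reg, fraction = fraction, amplitude = amplitude)
  })
  names(per_odor) <- odors
  spec <- lapply(channels, function(ch) per_odor)
  names(spec) <- channels
  spec
}

#' Slow serotonin-like channel kinetics
#'
#' @param amplitude_scale overall amplitude multiplier.
#' @return parameter list usable inside `channel_params`.
#' @export
serotonin_params <- function(amplitude_scale = 1) {
  list(delay = 0.3, rise_tau = 1.0, decay_tau = 6.0,
       amplitude_scale = amplitude_scale)
}

#' Pseudo-random balanced trial order without consecutive repeats
#'
#' Every session is a random permutation of the odor set, with the additional
#' constraint that no odor is presented twice in a row anywhere in the full
#' sequence (session boundaries included). Onsets are spaced by
#' `stim_duration + inter_trial_interval`, after an optional resting period.
#'
#' @param n_sessions number of sessions.
#' @param odors odor labels (at least 2 if more than one trial per session).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param frame_rate,stim_duration,inter_trial_interval,rest_duration
#'   timing parameters used to place onset frames.
#' @return data.frame with columns `trial`, `session`, `odor`, `onset_frame`.
#' @export
generate_trial_order <- function(n_sessions, odors, seed = NULL,
                                 frame_rate = 2.3, stim_duration = 5,
                                 inter_trial_interval = 30,
                                 rest_duration = 0) {
  stopifnot(n_sessions >= 1)
  n_odors <- length(odors)
  if (n_odors < 2 && n_sessions * n_odors > 1)
    stop("impossible constraint: a single odor cannot avoid consecutive repeats")
  order_vec <- with_seed(seed, {
    out <- character(0)
    for (s in seq_len(n_sessions)) {
      repeat {
        perm <- sample(odors)
        if (length(out) == 0 || perm[1] != out[length(out)]) break
      }
      out <- c(out, perm)
    }
    out
  })
  n_trials <- length(order_vec)
  period <- (stim_duration + inter_trial_interval) * frame_rate
  rest_frames <- round(rest_duration * frame_rate)
  onsets <- rest_frames + floor((seq_len(n_trials) - 1) * period) + 1L
  data.frame(trial = seq_len(n_trials),
             session = rep(seq_len(n_sessions), each = n_odors),
             odor = order_vec,
             onset_frame = as.integer(onsets),
             stringsAsFactors = FALSE)
}

#' Unit-peak double-exponential response kernel
#'
#' Causal difference-of-exponentials response shape: zero before `delay`,
#' then `exp(-(t-delay)/decay_tau) - exp(-(t-delay)/rise_tau)`, normalized so
#' that its peak equals `amplitude`. The two time constants map directly onto
#' the phase delay (time to peak) and pulse width (FWHM) response metrics.
#'
#' @param t time since odor onset, seconds (vectorized; `t >= 0` allowed).
#' @param delay onset latency in seconds.
#' @param rise_tau,decay_tau rise and decay time constants in seconds;
#'   `0 < rise_tau < decay_tau` required.
#' @param amplitude peak value in dF/F units.
#' @return numeric vector of kernel values.
#' @export
response_kernel <- function(t, delay = 0.2, rise_tau = 0.2, decay_tau = 1.5,
                            amplitude = 1) {
  if (rise_tau <= 0 || decay_tau <= 0) stop("time constants must be positive")
  if (rise_tau >= decay_tau) stop("rise_tau must be smaller than decay_tau")
  u <- t - delay
  raw <- ifelse(u >= 0, exp(-u / decay_tau) - exp(-u / rise_tau), 0)
  # analytic peak of the difference of exponentials
  t_peak <- (rise_tau * decay_tau) / (decay_tau - rise_tau) *
    log(decay_tau / rise_tau)
  peak <- exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau)
  amplitude * raw / peak
}

# Analytic time-to-peak of the kernel (seconds since odor onset).
kernel_peak_time <- function(delay, rise_tau, decay_tau) {
  delay + (rise_tau * decay_tau) / (decay_tau - rise_tau) *
    log(decay_tau / rise_tau)
}

# Kernel sampled on the frame grid, long enough to decay below 0.5% of peak.
sampled_kernel <- function(params, frame_rate, max_s = 60) {
  tt <- seq(0, max_s, by = 1 / frame_rate)
  k <- response_kernel(tt, params$delay, params$rise_tau, params$decay_tau, 1)
  last <- max(which(k > 0.005 * max(k)), 2)
  k[seq_len(min(last + 1, length(k)))]
}

#' Generate a full synthetic dual-channel experiment
#'
#' Builds raw fluorescence matrices (voxels x frames, one per channel), the
#' trial table, an atlas label volume, the behavior frame stack, and the full
#' planted ground truth. Fluorescence is
#' `baseline_F * (1 + signal + motion_coupling * motion + noise)`, clipped at
#' zero; the behavior stack is constructed so that its per-frame difference
#' energy equals the planted motion trace exactly.
#'
#' @param config a [synth_config()] object.
#' @return An object of class `odor_experiment`: list with elements
#'   `channels` (named list of voxels x frames matrices), `trials`,
#'   `atlas` (integer region id per voxel), `voxel_coords` (V x 3),
#'   `behavior` (8 x 8 x frames array), `ground_truth`, `frame_rate`,
#'   `n_frames`, `config`.
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  with_seed(cfg$seed, {
    dims <- cfg$grid_shape
    V <- prod(dims)
    coords <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                                    z = seq_len(dims[3])))
    # atlas: equal slabs along x
    slab <- ceiling(coords[, "x"] / (dims[1] / cfg$n_regions))
    atlas <- pmin(as.integer(slab), cfg$n_regions)

    trials <- generate_trial_order(cfg$n_sessions, cfg$odors, seed = NULL,
                                   frame_rate = cfg$frame_rate,
                                   stim_duration = cfg$stim_duration,
                                   inter_trial_interval = cfg$inter_trial_interval,
                                   rest_duration = cfg$rest_duration)
    period <- (cfg$stim_duration + cfg$inter_trial_interval) * cfg$frame_rate
    n_frames <- max(trials$onset_frame) + as.integer(ceiling(period)) +
      as.integer(ceiling(35 * cfg$frame_rate))

    kernels <- lapply(cfg$channel_params, sampled_kernel,
                      frame_rate = cfg$frame_rate)

    # planted ensembles: sample member voxels per channel x odor
    membership <- lapply(names(cfg$channel_params), function(ch) {
      spec <- cfg$ensemble_spec[[ch]]
      out <- list()
      for (od in names(spec)) {
        e <- spec[[od]]
        if (is.null(e) || e$amplitude == 0 || e$fraction == 0) next
        members <- integer(0)
        for (reg in e$regions) {
          pool <- which(atlas == reg)
          take <- ceiling(e$fraction * length(pool))
          if (take > length(pool))
            stop("capacity error: region ", reg, " too small for ensemble")
          members <- c(members, sort(sample(pool, take)))
        }
        out[[od]] <- list(voxels = members,
                          amplitude = rep(e$amplitude, length(members)))
      }
      out
    })
    names(membership) <- names(cfg$channel_params)

    # shared motion trace
    motion <- switch(cfg$motion_mode,
      none = rep(0, n_frames),
      random = {
        x <- stats::filter(rnorm(n_frames), rep(1 / 7, 7), sides = 1)
        x[is.na(x)] <- 0
        m <- abs(as.numeric(x))
        if (sd(m) > 0) m / sd(m) else m
      },
      odor_locked = {
        amp <- setNames(seq_along(cfg$odors) * 0.5, cfg$odors)
        kv <- kernels[[1]]
        m <- rep(0, n_frames)
        for (i in seq_len(nrow(trials))) {
          on <- trials$onset_frame[i]
          idx <- on:min(on + length(kv) - 1, n_frames)
          m[idx] <- m[idx] + amp[[trials$odor[i]]] * kv[seq_along(idx)]
        }
        m + abs(rnorm(n_frames, sd = 0.02))
      })

    channels <- list()
    for (ch in names(cfg$channel_params)) {
      p <- cfg$channel_params[[ch]]
      drift <- cfg$drift_schedule[[ch]]
      kv <- kernels[[ch]] * p$amplitude_scale
      S <- matrix(0, nrow = V, ncol = n_frames)
      mem <- membership[[ch]]
      for (od in names(mem)) {
        vox <- mem[[od]]$voxels
        amps <- mem[[od]]$amplitude
        for (i in which(trials$odor == od)) {
          on <- trials$onset_frame[i]
          idx <- on:min(on + length(kv) - 1, n_frames)
          S[vox, idx] <- S[vox, idx] +
            outer(amps, kv[seq_along(idx)] * drift[trials$session[i]])
        }
      }
      gain <- cfg$motion_coupling[[ch]] %||% 0
      if (gain != 0) S <- S + rep(gain * motion, each = V)
      if (cfg$noise_sd > 0) S <- S + rnorm(V * n_frames, sd = cfg$noise_sd)
      F <- cfg$baseline_F * (1 + S)
      F[F < 0] <- 0
      channels[[ch]] <- F
    }

    # behavior stack: uniform frames whose successive-difference magnitude
    # equals the motion trace by construction
    px <- c(8L, 8L)
    p <- numeric(n_frames)
    sgn <- 1
    for (t in 2:n_frames) {
      p[t] <- p[t - 1] + sgn * motion[t]
      sgn <- -sgn
    }
    behavior <- array(rep(p, each = prod(px)), dim = c(px, n_frames))

    ground_truth <- list(ensemble_membership = membership,
                         kernel_params = cfg$channel_params,
                         drift_schedule = cfg$drift_schedule,
                         motion_trace = motion,
                         trial_order = trials$odor)

    structure(list(channels = channels, trials = trials, atlas = atlas,
                   voxel_coords = coords, behavior = behavior,
                   ground_truth = ground_truth, frame_rate = cfg$frame_rate,
                   n_frames = n_frames, config = cfg),
              class = "odor_experiment")
  })
}

#' @export
print.odor_experiment <- function(x, ...) {
  cat("Synthetic odor-imaging experiment\n")
  cat("  grid:", paste(x$config$grid_shape, collapse = " x "),
      "(", nrow(x$voxel_coords), "voxels )\n")
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  cat("  trials:", nrow(x$trials), "(", x$config$n_sessions, "sessions x",
      x$config$trials_per_session, "odors )\n")
  cat("  frames:", x$n_frames, "at", x$frame_rate, "Hz\n")
  invisible(x)
}

#' Binary stimulus vector aligned with the recording
#'
#' @param trials trial table with `onset_frame`.
#' @param n_frames total frames in the recording.
#' @param frame_rate Hz.
#' @param stim_duration stimulus length in seconds.
#' @return integer vector of 0/1 per frame.
#' @export
stimulus_vector <- function(trials, n_frames, frame_rate, stim_duration = 5) {
  stim <- integer(n_frames)
  len <- max(1L, round(stim_duration * frame_rate))
  for (on in trials$onset_frame) {
    idx <- on:min(on + len - 1L, n_frames)
    stim[idx] <- 1L
  }
  stim
}
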