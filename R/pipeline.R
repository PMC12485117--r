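# Staged orchestration of the full synthetic-to-analysis workflow.

pipeline_stages <- c("simulate", "preprocess", "metrics", "connectivity",
                     "decode", "manifold", "behavior")

stage_deps <- list(simulate = character(0),
                   preprocess = "simulate",
                   metrics = "preprocess",
                   connectivity = "preprocess",
                   decode = "preprocess",
                   manifold = "decode",
                   behavior = "preprocess")

#' Run one pipeline stage
#'
#' Stages consume the accumulated `state` list and append their outputs plus
#' a manifest entry (configuration hash, input fingerprints). Upstream
#' stages must have run; otherwise an error names the stage to run first.
#'
#' @param stage one of `"simulate"`, `"preprocess"`, `"metrics"`,
#'   `"connectivity"`, `"decode"`, `"manifold"`, `"behavior"`.
#' @param state list carried between stages; start from `list()`.
#' @param config a [synth_config()].
#' @param spec a [decoder_spec()].
#' @return the updated `state`.
#' @export
run_stage <- function(stage, state = list(), config = synth_config(),
                      spec = decoder_spec()) {
  stage <- match.arg(stage, pipeline_stages)
  for (dep in stage_deps[[stage]]) {
    if (is.null(state[[dep]]))
      stop("missing upstream artifact: run stage '", dep, "' first")
  }
  out <- switch(stage,
    simulate = list(experiment = generate_experiment(config)),
    preprocess = {
      exper <- state$simulate$experiment
      rate <- exper$frame_rate
      dff <- list()
      for (ch in names(exper$channels)) {
        dff[[ch]] <- dff_tensor(exper, ch)
        # raw fluorescence is not needed downstream; free it to keep the
        # default-scale pipeline within desk memory
        exper$channels[[ch]] <- NULL
        state$simulate$experiment$channels[[ch]] <- NULL
      }
      post <- max(spec$feature_frames) + 1
      trials <- lapply(dff, extract_trials, trials = exper$trials,
                       pre_frames = 0, post_frames = max(post, 20))
      full <- lapply(dff, extract_trials, trials = exper$trials,
                     pre_frames = ceiling(2 * rate),
                     post_frames = ceiling(33 * rate))
      list(dff = dff, trials = trials, full_trials = full)
    },
    metrics = {
      exper <- state$simulate$experiment
      dff <- state$preprocess$dff
      stim <- stimulus_vector(exper$trials, exper$n_frames, exper$frame_rate,
                              config$stim_duration)
      lapply(names(dff), function(ch) {
        resp <- responsiveness_map(dff[[ch]], stim)
        tuning <- lapply(config$odors, function(od)
          odor_tuning(state$preprocess$trials[[ch]], od))
        names(tuning) <- config$odors
        list(responsiveness = resp,
             region_responsiveness = region_responsiveness(resp, exper$atlas),
             intensity = response_intensity(state$preprocess$trials[[ch]]),
             tuning = tuning)
      }) |> setNames(names(dff))
    },
    connectivity = {
      exper <- state$simulate$experiment
      dff <- state$preprocess$dff
      stim_frames <- which(stimulus_vector(exper$trials, exper$n_frames,
                                           exper$frame_rate,
                                           config$stim_duration) == 1)
      lapply(names(dff), function(ch) {
        reg <- region_average(dff[[ch]])
        fc <- build_fc(reg[, stim_frames, drop = FALSE], edge_rule = "all")
        comm <- detect_communities(fc, "louvain", seed = config$seed)
        olf <- as.integer(rownames(reg)) %in% config$olfactory_regions
        list(fc = fc, communities = comm,
             community_ratio = community_ratio(fc, comm$assignment, olf),
             degrees = node_degrees(fc))
      }) |> setNames(names(dff))
    },
    decode = {
      exper <- state$simulate$experiment
      trials <- state$preprocess$trials
      list(multiregion = multiregion_classify(trials[[1]],
                                              exper$voxel_coords,
                                              spec = spec))
    },
    manifold = {
      res <- state$decode$multiregion
      traces <- align_folds(project_manifold(res,
                                             state$preprocess$full_trials[[1]]))
      list(traces = traces, metrics = manifold_metrics(traces))
    },
    behavior = {
      exper <- state$simulate$experiment
      me <- motion_energy(exper$behavior, exper$frame_rate)
      feats <- behavior_features(exper$behavior, exper$trials,
                                 exper$frame_rate,
                                 window_s = config$stim_duration)
      list(motion = me,
           features = feats,
           odor_decoding = behavior_decoding(feats, exper$trials$odor,
                                             seed = config$seed))
    })
  state[[stage]] <- out
  manifest <- state$manifest %||% list(config_hash = object_fingerprint(
    list(config = unclass(config), spec = unclass(spec))))
  manifest[[stage]] <- object_fingerprint(out)
  state$manifest <- manifest
  state
}

#' Run the full pipeline
#'
#' Runs all stages in dependency order. Identical configuration and seed
#' give identical manifest fingerprints.
#'
#' @param config a [synth_config()].
#' @param spec a [decoder_spec()].
#' @param stages stages to run (dependency-ordered subset).
#' @return the final `state` list, including `manifest`.
#' @export
run_pipeline <- function(config = synth_config(), spec = decoder_spec(),
                         stages = pipeline_stages) {
  state <- list()
  for (s in pipeline_stages) {
    if (s %in% stages) state <- run_stage(s, state, config, spec)
  }
  state
}
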