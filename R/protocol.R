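#' Experiment plan: phase durations and protocol settings
#'
#' The virtual experiment runs four phases in order on one network:
#' warm-up (no input; dynamical variables converge to their homeostatic
#' equilibrium), training (sequential Poisson drive with plasticity on),
#' relaxation (input and plasticity off; thresholds re-equilibrate), and
#' testing (recall cues, first with the distractor — the experimental
#' sub-phase — then without — the control sub-phase). Plasticity is active
#' only during training; the adaptive threshold runs in every phase.
#'
#' @param warmup_s,relaxation_s phase durations (s).
#' @param training_blocks number of 1 s training blocks.
#' @param testing_experimental_s,testing_control_s testing sub-phase
#'   durations (s).
#' @param cue_rate recall cues per second.
#' @param scale multiplier applied to every duration (use < 1 for quick
#'   desk-scale runs; the published protocol is `scale = 1`).
#' @return list of class `"experiment_plan"`.
#' @export
experiment_plan <- function(warmup_s = 50, training_blocks = 50,
                            relaxation_s = 50,
                            testing_experimental_s = 100,
                            testing_control_s = 100,
                            cue_rate = 2, scale = 1) {
  p <- list(warmup_s = warmup_s * scale,
            training_blocks = max(1L, as.integer(round(training_blocks * scale))),
            relaxation_s = relaxation_s * scale,
            testing_experimental_s = testing_experimental_s * scale,
            testing_control_s = testing_control_s * scale,
            cue_rate = cue_rate)
  class(p) <- "experiment_plan"
  p
}

#' Run one protocol phase
#'
#' Advances the network for one named phase of the experiment and returns
#' the updated network together with the phase raster. State (voltages,
#' thresholds, weights, noise) carries over between phases; plasticity is
#' enabled iff `phase == "training"`.
#'
#' @param net a `"spiking_network"`.
#' @param phase one of `"warmup"`, `"training"`, `"relaxation"`,
#'   `"testing"`.
#' @param plan an [experiment_plan()].
#' @param condition for the testing phase: a distractor condition (row of
#'   [distractor_conditions()]) or `NULL` for control.
#' @param duration_s overrides the plan duration for the testing phase.
#' @return list with `net`, `spikes` (columns `time_ms`, `neuron`, `phase`),
#'   and for testing also `cue_times` (absolute, ms).
#' @export
run_phase <- function(net, phase = c("warmup", "training", "relaxation",
                                     "testing"),
                      plan = experiment_plan(), condition = NULL,
                      duration_s = NULL) {
  phase <- match.arg(phase)
  t0 <- net$state$t
  cue_times <- NULL
  if (phase == "warmup") {
    res <- run_steps(net, plan$warmup_s * 1000)
  } else if (phase == "training") {
    sched <- build_training_schedule(n_blocks = plan$training_blocks)
    ev <- compile_events(sched, net$topology)
    res <- run_steps(net, attr(sched, "total_ms"), events = ev,
                     plasticity = TRUE)
  } else if (phase == "relaxation") {
    res <- run_steps(net, plan$relaxation_s * 1000)
  } else {
    dur <- if (!is.null(duration_s)) duration_s
           else if (is.null(condition)) plan$testing_control_s
           else plan$testing_experimental_s
    sched <- build_test_schedule(condition, duration_s = dur,
                                 cue_rate = plan$cue_rate)
    ev <- compile_events(sched, net$topology)
    res <- run_steps(net, attr(sched, "total_ms"), events = ev)
    cue_times <- t0 + attr(sched, "cue_times")
  }
  res$spikes$phase <- phase
  out <- list(net = res$net, spikes = res$spikes)
  if (!is.null(cue_times)) out$cue_times <- cue_times
  out
}

#' Run one full trial of the virtual experiment
#'
#' Executes warm-up, training, relaxation, then the experimental testing
#' sub-phase (if a distractor condition is given) followed by the control
#' sub-phase, on a freshly initialized network. The post-training weight
#' matrix is snapshotted at relaxation onset (plasticity is frozen from
#' there on, so it is also the weight matrix in force during testing).
#'
#' @param condition a distractor condition (row of
#'   [distractor_conditions()]) or `NULL` for a control-only trial.
#' @param seed integer seed controlling the whole trial (topology, initial
#'   state, stimulus realizations and membrane noise).
#' @param plan an [experiment_plan()].
#' @param params a [neuron_params()] bundle.
#' @param keep_training_spikes keep the (large) warm-up/training/relaxation
#'   rasters in the result? Testing rasters are always kept.
#' @return list of class `"replay_trial"`: `condition`, `seed`, `plan`,
#'   `net` (final), `weights_trained` (E->E snapshot at relaxation onset),
#'   `spikes_experimental`, `spikes_control`, `cue_times_experimental`,
#'   `cue_times_control`, and optionally the earlier-phase rasters.
#' @export
run_trial <- function(condition = NULL, seed = 1L, plan = experiment_plan(),
                      params = neuron_params(),
                      keep_training_spikes = FALSE) {
  net <- init_network(params, seed = seed)
  ph_w <- run_phase(net, "warmup", plan)
  ph_t <- run_phase(ph_w$net, "training", plan)
  weights_trained <- weights_EE(ph_t$net)
  ph_r <- run_phase(ph_t$net, "relaxation", plan)
  out <- list(condition = condition, seed = seed, plan = plan,
              params = params, weights_trained = weights_trained)
  net <- ph_r$net
  if (!is.null(condition)) {
    ph_e <- run_phase(net, "testing", plan, condition = condition)
    out$spikes_experimental <- ph_e$spikes
    out$cue_times_experimental <- ph_e$cue_times
    net <- ph_e$net
  }
  ph_c <- run_phase(net, "testing", plan, condition = NULL)
  out$spikes_control <- ph_c$spikes
  out$cue_times_control <- ph_c$cue_times
  out$net <- ph_c$net
  if (keep_training_spikes)
    out$spikes_history <- rbind(ph_w$spikes, ph_t$spikes, ph_r$spikes)
  class(out) <- "replay_trial"
  out
}

#' Run a campaign over distractor conditions
#'
#' Runs `n_trials_per_condition` independent full trials for every
#' condition, with per-trial seeds derived deterministically from
#' `base_seed`. When `out_dir` is given, each trial is written to disk as
#' it completes together with a manifest, and an interrupted campaign can
#' be resumed: trials already listed in the manifest are skipped.
#'
#' @param conditions data frame of conditions (default all 16).
#' @param n_trials_per_condition trials per condition (default 5).
#' @param base_seed campaign seed; trial seed = `base_seed + 1000*cond + trial`.
#' @param plan an [experiment_plan()].
#' @param params a [neuron_params()] bundle.
#' @param out_dir optional output directory for incremental storage.
#' @return invisibly, a list of `"replay_trial"` objects (when `out_dir` is
#'   `NULL`) or the manifest (when writing to disk). Per-trial errors are
#'   caught, logged in the manifest, and do not abort the campaign.
#' @export
run_campaign <- function(conditions = distractor_conditions(),
                         n_trials_per_condition = 5, base_seed = 1L,
                         plan = experiment_plan(), params = neuron_params(),
                         out_dir = NULL) {
  manifest <- list(package_version = as.character(utils::packageVersion("seqreplay")),
                   base_seed = base_seed, params = unclass(params),
                   plan = unclass(plan), trials = list())
  man_path <- if (!is.null(out_dir)) file.path(out_dir, "manifest.json")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (file.exists(man_path))
      manifest <- jsonlite::read_json(man_path, simplifyVector = FALSE)
  }
  done <- vapply(manifest$trials, function(tr) tr$id, character(1))
  results <- list()
  for (ci in seq_len(nrow(conditions))) {
    for (tr in seq_len(n_trials_per_condition)) {
      cond <- conditions[ci, ]
      id <- sprintf("%s_d%d_trial%d", cond$location, cond$delay_ms, tr)
      if (id %in% done) next
      seed <- as.integer(base_seed + 1000L * ci + tr)
      entry <- list(id = id, seed = seed, location = cond$location,
                    delay_ms = cond$delay_ms)
      res <- tryCatch(
        run_trial(cond, seed = seed, plan = plan, params = params),
        error = function(e) e)
      if (inherits(res, "error")) {
        entry$status <- "error"
        entry$message <- conditionMessage(res)
      } else {
        entry$status <- "ok"
        if (!is.null(out_dir)) {
          f <- file.path(out_dir, paste0(id, ".rds"))
          saveRDS(res, f)
          entry$file <- basename(f)
        } else {
          results[[id]] <- res
        }
      }
      manifest$trials <- c(manifest$trials, list(entry))
      if (!is.null(out_dir))
        jsonlite::write_json(manifest, man_path, auto_unbox = TRUE,
                             pretty = TRUE)
    }
  }
  if (is.null(out_dir)) invisible(results) else invisible(manifest)
}
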