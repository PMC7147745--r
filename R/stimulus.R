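#' Homogeneous Poisson spike train
#'
#' @param rate_hz firing rate (Hz), non-negative.
#' @param duration_ms span (ms).
#' @param seed optional integer seed; when given the train is
#'   seeded-deterministic, otherwise the current RNG stream is used.
#' @return sorted numeric vector of spike times in `[0, duration_ms)` (ms).
#' @export
poisson_train <- function(rate_hz, duration_ms, seed = NULL) {
  if (rate_hz < 0) stop("rate_hz must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1, rate_hz * duration_ms / 1000)
  sort(stats::runif(n, 0, duration_ms))
}

#' The 16 distractor conditions
#'
#' All combinations of distractor location (first, middle and last trained
#' sequence element, plus the untrained "external" sixth group) and delay
#' after the recall cue.
#'
#' @return data frame with columns `location` (`"A"`, `"C"`, `"E"`,
#'   `"external"`) and `delay_ms` (0-3).
#' @export
distractor_conditions <- function() {
  x <- expand.grid(delay_ms = 0:3, location = c("A", "C", "E", "external"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  x[, c("location", "delay_ms")]
}

#' Training stimulus schedule
#'
#' One training block is a 1 s single-sequence instance: the Poisson source
#' of each of groups A-E is activated in order for 100 ms at 50 Hz, followed
#' by a 500 ms rest before the next block. Each group shares one source,
#' connected at 20 nS to every neuron of the group, so source spikes arrive
#' synchronously within a group.
#'
#' @param n_blocks number of 1 s training blocks (default 50, i.e. 50 s).
#' @param rate_hz Poisson source rate during an epoch (Hz).
#' @param epoch_ms duration of one group's epoch (ms).
#' @param rest_ms rest after the five epochs (ms).
#' @param ff_weight feedforward synaptic strength (nS).
#' @param groups group labels driven in sequence.
#' @return data frame of class `"stimulus_schedule"` with columns
#'   `onset_ms`, `duration_ms`, `group`, `kind`, `magnitude` (`rate_hz` for
#'   `poisson_epoch` rows); attribute `ff_weight`.
#' @export
build_training_schedule <- function(n_blocks = 50, rate_hz = 50,
                                    epoch_ms = 100, rest_ms = 500,
                                    ff_weight = 20,
                                    groups = c("A", "B", "C", "D", "E")) {
  n_g <- length(groups)
  block_ms <- n_g * epoch_ms + rest_ms
  onset <- as.vector(vapply(seq_len(n_blocks) - 1L, function(b)
    b * block_ms + (seq_len(n_g) - 1L) * epoch_ms, numeric(n_g)))
  sched <- data.frame(onset_ms = onset, duration_ms = epoch_ms,
                      group = rep(groups, n_blocks),
                      kind = "poisson_epoch", magnitude = rate_hz,
                      stringsAsFactors = FALSE)
  attr(sched, "ff_weight") <- ff_weight
  attr(sched, "total_ms") <- n_blocks * block_ms
  class(sched) <- c("stimulus_schedule", "data.frame")
  sched
}

#' Testing stimulus schedule (cues and optional distractors)
#'
#' Each recall cue is one synchronous burst onto every neuron of group A
#' delivered through the feedforward weight. With a distractor condition, a
#' second burst targets the condition's group `delay_ms` after each cue.
#' Cues repeat at `cue_rate` per second; the first cue is placed half a
#' period into the phase.
#'
#' @param condition one row of [distractor_conditions()], a list with
#'   `location` and `delay_ms`, or `NULL` for the control (cues only).
#' @param duration_s phase length (s).
#' @param cue_rate cues per second.
#' @param cue_group group receiving the recall cue.
#' @param ff_weight feedforward burst strength (nS).
#' @param burst_spikes source spikes per burst (default 1; "instantaneous").
#' @return a `"stimulus_schedule"` data frame (burst rows have
#'   `duration_ms = 0` and `magnitude = burst_spikes`), with attributes
#'   `ff_weight`, `cue_times` and `total_ms`.
#' @export
build_test_schedule <- function(condition = NULL, duration_s = 100,
                                cue_rate = 2, cue_group = "A",
                                ff_weight = 20, burst_spikes = 1) {
  period_ms <- 1000 / cue_rate
  n_cues <- floor(duration_s * cue_rate)
  cue_times <- (seq_len(n_cues) - 0.5) * period_ms
  sched <- data.frame(onset_ms = cue_times, duration_ms = 0,
                      group = cue_group, kind = "burst",
                      magnitude = burst_spikes, stringsAsFactors = FALSE)
  if (!is.null(condition)) {
    loc <- as.character(condition$location)
    grp <- if (identical(loc, "external")) "F" else loc
    dis <- data.frame(onset_ms = cue_times + condition$delay_ms,
                      duration_ms = 0, group = grp, kind = "burst",
                      magnitude = burst_spikes, stringsAsFactors = FALSE)
    sched <- rbind(sched, dis)
    sched <- sched[order(sched$onset_ms), , drop = FALSE]
    rownames(sched) <- NULL
  }
  attr(sched, "ff_weight") <- ff_weight
  attr(sched, "cue_times") <- cue_times
  attr(sched, "total_ms") <- duration_s * 1000
  class(sched) <- c("stimulus_schedule", "data.frame")
  sched
}

#' Compile a schedule into per-neuron input events
#'
#' Realizes the stochastic parts of a schedule (Poisson source spike times)
#' and expands every source spike into simultaneous conductance-increment
#' events for all neurons of the target group. Uses the current RNG stream;
#' seed upstream for reproducibility.
#'
#' Each Poisson epoch is realized from a single shared source per group:
#' every source spike reaches all neurons of the group simultaneously
#' (membrane noise then jitters their firing). The near-coincident
#' within-group spiking makes STDP segregate the within-cluster weights
#' into the observed bimodal strong/pruned structure, while the fixed
#' epoch order builds the strong one-forward chain. Bursts are likewise
#' delivered synchronously to the whole group. Set `shared = FALSE` for
#' one independent source train per target neuron instead.
#'
#' @param schedule a `"stimulus_schedule"`.
#' @param topology network topology (for group membership).
#' @param shared share one Poisson source per group (default) or give each
#'   neuron its own independent source?
#' @return data frame with columns `time_ms`, `neuron`, `w` suitable for
#'   [run_steps()], sorted by time.
#' @export
compile_events <- function(schedule, topology, shared = TRUE) {
  w_ff <- attr(schedule, "ff_weight")
  out <- vector("list", nrow(schedule))
  for (k in seq_len(nrow(schedule))) {
    row <- schedule[k, ]
    members <- group_neurons(topology, row$group)
    if (row$kind == "poisson_epoch") {
      if (shared) {
        src <- poisson_train(row$magnitude, row$duration_ms)
        if (length(src) == 0) next
        out[[k]] <- data.frame(
          time_ms = rep(row$onset_ms + src, each = length(members)),
          neuron = rep(members, times = length(src)), w = w_ff)
      } else {
        trains <- lapply(members, function(m)
          poisson_train(row$magnitude, row$duration_ms))
        if (sum(lengths(trains)) == 0) next
        out[[k]] <- data.frame(
          time_ms = row$onset_ms + unlist(trains, use.names = FALSE),
          neuron = rep(members, lengths(trains)), w = w_ff)
      }
    } else { # burst
      n_sp <- max(1L, as.integer(row$magnitude))
      out[[k]] <- data.frame(
        time_ms = rep(row$onset_ms, length(members) * n_sp),
        neuron = rep(members, times = n_sp), w = w_ff)
    }
  }
  ev <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(ev)) ev <- data.frame(time_ms = numeric(0), neuron = integer(0),
                                    w = numeric(0))
  ev[order(ev$time_ms), , drop = FALSE]
}
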