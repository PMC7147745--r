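#' Population rate trace of a neuron group
#'
#' Pools the spikes of the group and convolves with a normalized Gaussian
#' kernel (default SD 2 ms). The trace is reported as mean rate per neuron
#' in Hz: a single spike from a quiet group of 20 contributes a bump of
#' peak `1000 * dnorm(0, sd = 2) / 20` ~ 10 Hz, so the 10 Hz veto threshold
#' discriminates genuine population events from stray background spikes.
#'
#' @param spikes data frame with `time_ms` and `neuron`.
#' @param neurons neuron indices forming the group (non-empty).
#' @param t_range numeric length-2, time span of the trace (ms).
#' @param kernel_sd Gaussian kernel SD (ms).
#' @param dt trace resolution (ms).
#' @param per_neuron divide the pooled rate by the group size?
#' @return list with `time_ms` (grid) and `rate_hz`.
#' @export
population_rate <- function(spikes, neurons, t_range, kernel_sd = 2,
                            dt = 0.1, per_neuron = TRUE) {
  if (length(neurons) == 0) stop("empty neuron group", call. = FALSE)
  half <- ceiling(4 * kernel_sd / dt)
  grid <- seq(t_range[1], t_range[2], by = dt)
  st <- spikes$time_ms[spikes$neuron %in% neurons]
  st <- st[st >= t_range[1] - 4 * kernel_sd & st <= t_range[2] + 4 * kernel_sd]
  # bin on an extended grid, convolve, then crop
  ext <- c(grid[1] - half * dt, grid[length(grid)] + half * dt)
  nbins <- length(grid) + 2L * half
  counts <- tabulate(pmin(nbins, pmax(1L, floor((st - ext[1]) / dt) + 1L)),
                     nbins = nbins)
  kern <- stats::dnorm(seq(-half, half) * dt, sd = kernel_sd) # per-ms density
  dens <- stats::filter(counts, kern, sides = 2)
  rate <- as.numeric(dens[(half + 1L):(half + length(grid))]) * 1000
  rate[is.na(rate)] <- 0
  if (per_neuron) rate <- rate / length(neurons)
  list(time_ms = grid, rate_hz = rate)
}

#' Detect the dominant rate peak in a window
#'
#' Returns the time of the maximum of the rate trace within the window,
#' provided it exceeds the threshold; ties are broken toward the earliest
#' time. Returns `NA` when no supra-threshold peak exists.
#'
#' @param rate a trace from [population_rate()] (list with `time_ms`,
#'   `rate_hz`).
#' @param cue_time reference time (ms); the window is relative to it.
#' @param window numeric length-2 window around the cue (ms).
#' @param threshold minimum peak rate (Hz).
#' @return peak time relative to `cue_time` (ms), or `NA`.
#' @export
detect_peaks <- function(rate, cue_time = 0, window = c(-10, 25),
                         threshold = 10) {
  lo <- cue_time + window[1]
  hi <- cue_time + window[2]
  if (lo < rate$time_ms[1] - 1e-9 ||
      hi > rate$time_ms[length(rate$time_ms)] + 1e-9)
    stop("analysis window extends beyond the rate trace", call. = FALSE)
  sel <- rate$time_ms >= lo & rate$time_ms <= hi
  r <- rate$rate_hz[sel]
  tt <- rate$time_ms[sel]
  i <- which.max(r) # earliest index on ties
  if (r[i] <= threshold) return(NA_real_)
  tt[i] - cue_time
}

#' Extract per-cue replay events from a testing raster
#'
#' For each cue, computes the five trained-group rate traces in the analysis
#' window and detects the dominant peak of each. A cue passes the veto iff
#' all five elements have a supra-threshold peak.
#'
#' @param spikes testing-phase raster (`time_ms`, `neuron`).
#' @param cue_times absolute cue times (ms).
#' @param topology network topology.
#' @param groups labels of the trained elements, in sequence order.
#' @param window analysis window around each cue (ms).
#' @param threshold veto threshold (Hz).
#' @param kernel_sd rate kernel SD (ms).
#' @param dt trace resolution (ms).
#' @return data frame of class `"replay_events"`: `cue_time`, one peak-time
#'   column `t_A` ... per element (ms relative to cue, `NA` if missing),
#'   and `pass`.
#' @export
replay_events <- function(spikes, cue_times, topology,
                          groups = c("A", "B", "C", "D", "E"),
                          window = c(-10, 25), threshold = 10,
                          kernel_sd = 2, dt = 0.1) {
  members <- lapply(groups, function(g) group_neurons(topology, g))
  # pre-split spike times by group for speed
  sp_by_group <- lapply(members, function(m)
    sort(spikes$time_ms[spikes$neuron %in% m]))
  pad <- 4 * kernel_sd
  peaks <- matrix(NA_real_, length(cue_times), length(groups))
  for (gi in seq_along(groups)) {
    st <- sp_by_group[[gi]]
    ng <- length(members[[gi]])
    for (ci in seq_along(cue_times)) {
      t0 <- cue_times[ci]
      sub <- st[st >= t0 + window[1] - pad & st <= t0 + window[2] + pad]
      tr <- population_rate(
        data.frame(time_ms = sub, neuron = rep(members[[gi]][1], length(sub))),
        members[[gi]][1], t_range = c(t0 + window[1], t0 + window[2]),
        kernel_sd = kernel_sd, dt = dt, per_neuron = FALSE)
      tr$rate_hz <- tr$rate_hz / ng
      peaks[ci, gi] <- detect_peaks(tr, t0, window, threshold)
    }
  }
  out <- data.frame(cue_time = cue_times)
  for (gi in seq_along(groups)) out[[paste0("t_", groups[gi])]] <- peaks[, gi]
  out$pass <- rowSums(is.na(peaks)) == 0
  class(out) <- c("replay_events", "data.frame")
  out
}

#' Control replay statistics
#'
#' Pools the veto-passing replays of the control condition and summarizes,
#' per element, the mean and spread of the peak times, and per adjacent
#' pair, the mean and spread of the inter-element intervals. Spreads are
#' standard deviations floored at `sd_floor` to keep the indices finite on
#' degenerate inputs.
#'
#' @param events a `"replay_events"` data frame (control condition), or a
#'   list of them (pooled across trials).
#' @param sd_floor lower bound on every spread (ms).
#' @return list of class `"control_statistics"`: `mu` (named per-element
#'   means), `sigma`, `interval_mu`, `interval_sigma`, `pass_rate`,
#'   `n_passing`, `n_total`.
#' @export
compute_control_statistics <- function(events, sd_floor = 0.1) {
  if (is.data.frame(events)) events <- list(events)
  ev <- do.call(rbind, lapply(events, as.data.frame))
  tcols <- grep("^t_", names(ev), value = TRUE)
  pass <- ev$pass
  if (sum(pass) < 2)
    stop("need at least 2 veto-passing events to estimate spreads",
         call. = FALSE)
  pt <- as.matrix(ev[pass, tcols, drop = FALSE])
  mu <- colMeans(pt)
  sigma <- pmax(apply(pt, 2, stats::sd), sd_floor)
  iv <- pt[, -1, drop = FALSE] - pt[, -ncol(pt), drop = FALSE]
  interval_mu <- colMeans(iv)
  interval_sigma <- pmax(apply(iv, 2, stats::sd), sd_floor)
  names(interval_mu) <- names(interval_sigma) <-
    paste(tcols[-length(tcols)], tcols[-1], sep = "->")
  out <- list(mu = mu, sigma = sigma, interval_mu = interval_mu,
              interval_sigma = interval_sigma,
              pass_rate = mean(pass), n_passing = sum(pass),
              n_total = length(pass))
  class(out) <- "control_statistics"
  out
}

#' Deviance index of one replay
#'
#' Mean over the five elements of the peak-time deviation from the control
#' mean, normalized by the control spread. Negative values mean the replay
#' ran early overall, positive values late.
#'
#' @param peak_times numeric vector of the event's element peak times (ms
#'   relative to cue), in sequence order; must be complete (veto-passing).
#' @param control a [compute_control_statistics()] result.
#' @return dimensionless index.
#' @export
deviance_index <- function(peak_times, control) {
  if (anyNA(peak_times)) stop("deviance index requires a veto-passing event",
                              call. = FALSE)
  if (any(control$sigma <= 0)) stop("control spreads must be positive",
                                    call. = FALSE)
  mean((peak_times - control$mu) / control$sigma)
}

#' Disruption index of one replay
#'
#' Mean over the four adjacent element pairs of the deviation of the
#' replayed inter-element interval from the control interval, normalized by
#' the control interval spread. Order inversions produce large negative
#' contributions; the index is invariant under a uniform time shift of the
#' whole replay.
#'
#' @inheritParams deviance_index
#' @return dimensionless index.
#' @export
disruption_index <- function(peak_times, control) {
  if (anyNA(peak_times)) stop("disruption index requires a veto-passing event",
                              call. = FALSE)
  if (any(control$interval_sigma <= 0))
    stop("control spreads must be positive", call. = FALSE)
  iv <- diff(peak_times)
  ctrl_iv <- control$interval_mu
  mean((iv - ctrl_iv) / control$interval_sigma)
}

#' Summarize one distractor condition
#'
#' Computes per-event deviance and disruption indices for the veto-passing
#' replays of an experimental condition against pooled control statistics,
#' plus the condition's pass rate and its relevant/irrelevant
#' classification by the disruption-index threshold.
#'
#' @param events experimental `"replay_events"` (one or a list to pool).
#' @param control a [compute_control_statistics()] result.
#' @param condition the condition tested (carried through to the output).
#' @param threshold classification threshold on the mean disruption index.
#' @return list of class `"condition_result"`: `condition`, `pass_rate`,
#'   `n_passing`, `n_total`, `deviance` and `disruption` (per passing
#'   event), `mean_deviance`, `mean_disruption`, `classification`.
#' @export
condition_result <- function(events, control, condition = NULL,
                             threshold = -0.05) {
  if (is.data.frame(events)) events <- list(events)
  ev <- do.call(rbind, lapply(events, as.data.frame))
  tcols <- grep("^t_", names(ev), value = TRUE)
  pt <- as.matrix(ev[ev$pass, tcols, drop = FALSE])
  dev <- apply(pt, 1, deviance_index, control = control)
  dis <- apply(pt, 1, disruption_index, control = control)
  out <- list(condition = condition,
              pass_rate = mean(ev$pass),
              n_passing = nrow(pt), n_total = nrow(ev),
              deviance = as.numeric(dev), disruption = as.numeric(dis),
              mean_deviance = mean(dev), mean_disruption = mean(dis),
              classification = classify_distractor(mean(dis), threshold))
  class(out) <- "condition_result"
  out
}

#' Classify a distractor condition
#'
#' A condition is "relevant" (actively disrupts replay order) when its mean
#' disruption index falls below the threshold, "irrelevant" (adds timing
#' noise only) otherwise.
#'
#' @param mean_disruption mean disruption index over the condition's
#'   passing events (or a `"condition_result"`).
#' @param threshold classification threshold (default -0.05).
#' @return `"relevant"` or `"irrelevant"` (`NA` if unclassifiable).
#' @export
classify_distractor <- function(mean_disruption, threshold = -0.05) {
  if (inherits(mean_disruption, "condition_result"))
    mean_disruption <- mean_disruption$mean_disruption
  if (length(mean_disruption) == 0 || is.na(mean_disruption))
    return(NA_character_)
  if (mean_disruption < threshold) "relevant" else "irrelevant"
}

#' Weight-category analysis of the trained connectivity
#'
#' Partitions the above-zero E->E weights involving the trained sequence
#' elements into the eight standard categories: `all` (every above-zero
#' E->E weight), `trained_recurrent` (within one trained cluster),
#' `one_forward` (cluster n to n+1), `n_forward` (two or more steps
#' forward), `one_backward`, `n_backward`, `to_external` (trained cluster
#' to untrained portion) and `from_external`. For each, reports count,
#' mean, SD, median, and — for the bimodal categories — the per-mode
#' medians split at `mode_cut`.
#'
#' @param W_EE E->E weight matrix `[post, pre]` (nS).
#' @param group_assignment per-excitatory-neuron group labels (integers;
#'   groups `trained` are the sequence elements in order).
#' @param trained integer labels of the trained groups, in sequence order.
#' @param mode_cut weight (nS) splitting the low and high modes.
#' @param adj_EE optional adjacency; when given, zero weights on existing
#'   synapses are excluded just like absent synapses (the analysis
#'   thresholds for above-zero values either way).
#' @return list of class `"weight_categories"`: `weights` (named list of
#'   numeric vectors) and `summary` (data frame with `category`, `n`,
#'   `mean`, `sd`, `median`, `median_low`, `median_high`).
#' @export
classify_weights <- function(W_EE, group_assignment, trained = 1:5,
                             mode_cut = 1, adj_EE = NULL) {
  n <- nrow(W_EE)
  pre <- rep(seq_len(n), each = n)
  post <- rep(seq_len(n), times = n)
  w <- as.vector(W_EE)
  keep <- w > 0 & pre != post
  pre <- pre[keep]; post <- post[keep]; w <- w[keep]
  g_pre <- group_assignment[pre]
  g_post <- group_assignment[post]
  pos_pre <- match(g_pre, trained)   # NA if pre not in a trained cluster
  pos_post <- match(g_post, trained)
  step <- pos_post - pos_pre

  cats <- list(
    all = rep(TRUE, length(w)),
    trained_recurrent = !is.na(step) & step == 0,
    one_forward = !is.na(step) & step == 1,
    n_forward = !is.na(step) & step >= 2,
    one_backward = !is.na(step) & step == -1,
    n_backward = !is.na(step) & step <= -2,
    to_external = !is.na(pos_pre) & is.na(pos_post),
    from_external = is.na(pos_pre) & !is.na(pos_post)
  )
  weights <- lapply(cats, function(m) w[m])
  summ <- do.call(rbind, lapply(names(weights), function(nm) {
    x <- weights[[nm]]
    data.frame(category = nm, n = length(x),
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) > 1) stats::sd(x) else NA_real_,
               median = if (length(x)) stats::median(x) else NA_real_,
               median_low = if (any(x < mode_cut))
                 stats::median(x[x < mode_cut]) else NA_real_,
               median_high = if (any(x >= mode_cut))
                 stats::median(x[x >= mode_cut]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out <- list(weights = weights, summary = summ, mode_cut = mode_cut)
  class(out) <- "weight_categories"
  out
}

#' Histogram of a weight category
#'
#' @param wc a `"weight_categories"` result.
#' @param category category name.
#' @param bin_width histogram bin width (nS).
#' @return data frame `mid`, `count`.
#' @export
weight_histogram <- function(wc, category = "all", bin_width = 0.1) {
  x <- wc$weights[[category]]
  if (length(x) == 0) {
    warning("category '", category, "' is empty")
    return(data.frame(mid = numeric(0), count = integer(0)))
  }
  breaks <- seq(0, max(x) + bin_width, by = bin_width)
  h <- hist(x, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts)
}
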