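mk_rate <- function(time_ms, rate_hz) list(time_ms = time_ms,
                                           rate_hz = rate_hz)

test_that("population rate is a normalized Gaussian smoothing of the raster", {
  empty <- data.frame(time_ms = numeric(0), neuron = integer(0))
  tr <- population_rate(empty, neurons = 1:20, t_range = c(0, 50))
  expect_true(all(tr$rate_hz == 0))
  expect_error(population_rate(empty, integer(0), c(0, 50)), "empty")
  # single spike: bump integrates to one spike (rate in Hz, time in ms)
  one <- data.frame(time_ms = 25, neuron = 1)
  tr1 <- population_rate(one, 1:20, c(0, 50), kernel_sd = 2, dt = 0.1)
  expect_equal(sum(tr1$rate_hz) * 0.1 / 1000, 1 / 20, tolerance = 1e-3)
  expect_equal(tr1$time_ms[which.max(tr1$rate_hz)], 25)
  # peak of a pooled group of 20 simultaneous spikes is 20x one spike
  twenty <- data.frame(time_ms = rep(25, 20), neuron = 1:20)
  tr20 <- population_rate(twenty, 1:20, c(0, 50))
  expect_equal(max(tr20$rate_hz), 20 * max(tr1$rate_hz))
  # per-neuron normalization: 20 synchronous spikes from 20 neurons give
  # the full single-spike pooled peak, 1000 * dnorm(0, sd = 2)
  expect_equal(max(tr20$rate_hz), 1000 * dnorm(0, sd = 2), tolerance = 1e-2)
})

test_that("peak detector finds the window maximum above threshold", {
  tt <- seq(-10, 25, by = 0.1)
  bump <- mk_rate(tt, 40 * exp(-(tt - 5)^2 / 8))
  expect_equal(detect_peaks(bump, 0), 5)
  flat <- mk_rate(tt, rep(5, length(tt)))
  expect_true(is.na(detect_peaks(flat, 0)))
  two <- mk_rate(tt, 30 * exp(-(tt - 3)^2 / 2) + 50 * exp(-(tt - 8)^2 / 2))
  expect_equal(detect_peaks(two, 0), 8) # maximum rate wins
  # ties broken toward the earliest time
  steps <- mk_rate(tt, ifelse(abs(tt - 4) < 1e-9 | abs(tt - 9) < 1e-9,
                              30, 0))
  expect_equal(detect_peaks(steps, 0), 4)
  expect_error(detect_peaks(bump, 100), "window")
})

test_that("control statistics match hand arithmetic on a 3-event fixture", {
  ev <- data.frame(cue_time = c(0, 500, 1000),
                   t_A = c(1, 2, 3), t_B = c(3, 4, 5), t_C = c(5, 7, 9),
                   t_D = c(8, 10, 12), t_E = c(11, 13, 18),
                   pass = c(TRUE, TRUE, TRUE))
  cs <- compute_control_statistics(ev)
  expect_equal(unname(cs$mu), c(2, 4, 7, 10, 14))
  expect_equal(unname(cs$sigma), c(1, 1, 2, 2, sd(c(11, 13, 18))))
  expect_equal(unname(cs$interval_mu), c(2, 3, 3, 4))
  expect_equal(cs$pass_rate, 1)
  # non-passing events excluded from pooling
  ev$pass[3] <- FALSE
  cs2 <- compute_control_statistics(ev)
  expect_equal(cs2$n_passing, 2)
  expect_equal(unname(cs2$mu)[1], 1.5)
  expect_equal(cs2$pass_rate, 2 / 3)
  # degenerate spreads floored, not zero
  ev_id <- ev; ev_id[, 2:6] <- rep(c(1, 3, 5, 8, 11), each = 3)
  ev_id$pass <- TRUE
  cs3 <- compute_control_statistics(ev_id)
  expect_true(all(cs3$sigma == 0.1))
  expect_error(compute_control_statistics(ev[1, ]), "2")
})

test_that("deviance index matches its closed form", {
  ctrl <- list(mu = c(1, 2, 3, 5, 7), sigma = c(1, 1, 1, 1, 2),
               interval_mu = c(1, 1, 2, 2), interval_sigma = c(1, 1, 1, 1))
  expect_equal(deviance_index(c(1, 2, 3, 5, 7), ctrl), 0)     # identity
  expect_equal(deviance_index(ctrl$mu + ctrl$sigma, ctrl), 1) # 1 sigma late
  expect_equal(deviance_index(c(1, 2, 4, 6, 9), ctrl), 0.6)   # hand: 3/5
  expect_error(deviance_index(c(1, NA, 3, 5, 7), ctrl), "veto")
})

test_that("disruption index matches its closed form and is shift-invariant", {
  ctrl <- list(mu = c(1, 2, 3, 5, 7), sigma = c(1, 1, 1, 1, 2),
               interval_mu = c(1, 1, 2, 2), interval_sigma = c(1, 1, 1, 1))
  expect_equal(disruption_index(c(1, 2, 3, 5, 7), ctrl), 0)
  # one inverted pair: control interval +1 (sigma 1), trial interval -1,
  # so that pair contributes (-1 - 1)/1 = -2
  t_inv <- c(1, 3, 2, 4, 6)
  terms <- (diff(t_inv) - ctrl$interval_mu) / ctrl$interval_sigma
  expect_lte(terms[2], -2)
  expect_equal(disruption_index(t_inv, ctrl), mean(terms))
  # hand fixture
  t_h <- c(0, 2, 3, 6, 8)
  expect_equal(disruption_index(t_h, ctrl),
               mean((diff(t_h) - ctrl$interval_mu) / ctrl$interval_sigma))
  # uniform time shift changes deviance but not disruption
  sh <- c(1, 2, 3, 5, 7) + 2.5
  expect_equal(disruption_index(sh, ctrl), 0)
  expect_gt(deviance_index(sh, ctrl), 0)
})

test_that("distractor classification thresholds the mean disruption index", {
  expect_equal(classify_distractor(-0.5), "relevant")
  expect_equal(classify_distractor(0), "irrelevant")
  expect_equal(classify_distractor(-0.05), "irrelevant") # boundary: not less
  expect_equal(classify_distractor(-0.051), "relevant")
  expect_true(is.na(classify_distractor(NA_real_)))
})

test_that("weight categories match a brute-force edge labeler", {
  # 3-cluster toy layout plus untrained background
  set.seed(20)
  n <- 24
  groups <- rep(1:4, each = 6) # groups 1-3 trained, group 4 external
  W <- matrix(round(runif(n * n), 2), n, n)
  diag(W) <- 0
  W[sample(length(W), 150)] <- 0
  wc <- classify_weights(W, groups, trained = 1:3)
  # brute force over edges
  lab <- function(pre, post) {
    a <- groups[pre]; b <- groups[post]
    if (a <= 3 && b <= 3) {
      d <- b - a
      if (d == 0) "trained_recurrent"
      else if (d == 1) "one_forward" else if (d >= 2) "n_forward"
      else if (d == -1) "one_backward" else "n_backward"
    } else if (a <= 3) "to_external"
    else if (b <= 3) "from_external" else "background"
  }
  counts <- integer(0)
  tot <- 0
  for (pre in 1:n) for (post in 1:n) {
    if (pre != post && W[post, pre] > 0) {
      l <- lab(pre, post)
      counts[l] <- (if (is.na(counts[l])) 0 else counts[l]) + 1L
      tot <- tot + 1L
    }
  }
  for (cat in setdiff(names(wc$weights), "all"))
    expect_equal(length(wc$weights[[cat]]), unname(counts[cat]),
                 info = cat)
  expect_equal(length(wc$weights$all), tot)
  # categories partition the trained-involving above-zero edges
  n_cat <- sum(lengths(wc$weights[setdiff(names(wc$weights), "all")]))
  expect_equal(n_cat, tot - unname(counts["background"]))
  # mode split medians
  x <- wc$weights$trained_recurrent
  expect_equal(wc$summary$median_high[wc$summary$category ==
                                        "trained_recurrent"],
               median(x[x >= 1]))
})

test_that("replay_events applies the all-element veto per cue", {
  net <- init_network(seed = 6, n_E = 100, n_I = 20, n_groups = 5,
                      group_size = 20)
  topo <- net$topology
  # synthetic raster: cue 1 has all five groups firing in order, cue 2
  # lacks group D entirely
  mk_burst <- function(t, g) data.frame(
    time_ms = rep(t, 20), neuron = group_neurons(topo, g))
  sp <- rbind(mk_burst(101, "A"), mk_burst(102.5, "B"), mk_burst(104, "C"),
              mk_burst(105, "D"), mk_burst(106.5, "E"),
              mk_burst(201, "A"), mk_burst(202.5, "B"), mk_burst(204, "C"),
              mk_burst(206.5, "E"))
  ev <- replay_events(sp, cue_times = c(100, 200), topo)
  expect_true(ev$pass[1])
  expect_false(ev$pass[2])
  expect_equal(ev$t_A, c(1, 1))
  expect_equal(ev$t_D[1], 5)
  expect_true(is.na(ev$t_D[2]))
})
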