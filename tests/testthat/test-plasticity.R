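test_that("STDP kernel matches its closed form", {
  p <- neuron_params()
  expect_identical(stdp_kernel(0, p), 0)
  expect_equal(stdp_kernel(20, p), 0.05 * exp(-1))       # ~ +0.01839 nS
  expect_equal(stdp_kernel(-20, p), -0.05 * exp(-1))     # antisymmetric
  expect_equal(stdp_kernel(5, p), 0.05 * exp(-5 / 20))   # ~ +0.03894 nS
  # vectorized, and antisymmetric under the default parameters
  dts <- c(-50, -5, -1, 1, 5, 50)
  expect_equal(stdp_kernel(dts, p), -stdp_kernel(-dts, p))
  # asymmetric parameters break the antisymmetry
  p2 <- neuron_params(A_minus = 0.1)
  expect_equal(stdp_kernel(-20, p2), -0.1 * exp(-1))
})

test_that("normalization rescales incoming weights to the target sum", {
  p <- neuron_params() # w_total = 20
  W <- matrix(0, 4, 4)
  W[1, 2:4] <- c(4, 4, 8)
  W2 <- normalize_incoming(W, 1, p)
  expect_equal(W2[1, 2:4], c(5, 5, 10))
  expect_equal(sum(W2[1, ]), 20)
  # fixed point
  expect_equal(normalize_incoming(W2, 1, p), W2)
  # zeros stay zero, proportions preserved
  W[1, 2:4] <- c(1, 0, 3)
  expect_equal(normalize_incoming(W, 1, p)[1, 2:4], c(5, 0, 15))
  # zero incoming sum: warn and skip
  W[1, ] <- 0
  expect_warning(W3 <- normalize_incoming(W, 1, p), "zero")
  expect_equal(W3, W)
})

test_that("a single pre-post pairing potentiates by the kernel value", {
  p <- neuron_params(sigma_noise = 0, normalize = FALSE)
  net <- toy_plastic_net(n_E = 2, params = p)
  res <- force_spikes(net, times_ms = c(5, 10), neurons = c(1, 2),
                      duration_ms = 30)
  expect_equal(res$spikes$neuron, c(1, 2))
  dt_pair <- diff(res$spikes$time_ms)
  W <- weights_EE(res$net)
  # synapse 1 -> 2 potentiated, 2 -> 1 depressed (Delta t < 0)
  expect_equal(W[2, 1], 1 + 0.05 * exp(-dt_pair / 20))
  expect_equal(W[1, 2], 1 - 0.05 * exp(-dt_pair / 20))
})

test_that("repeated pre-then-post pairing grows the weight monotonically", {
  p <- neuron_params(sigma_noise = 0, normalize = FALSE)
  net <- toy_plastic_net(n_E = 2, params = p)
  w_prev <- 1
  for (rep in 1:5) {
    res <- force_spikes(net, times_ms = c(5, 10), neurons = c(1, 2),
                        duration_ms = 40)
    net <- res$net
    w_now <- weights_EE(net)[2, 1]
    expect_gt(w_now, w_prev)
    w_prev <- w_now
  }
  # repeated pre-then-post pairing at +5 ms accumulates potentiation
  expect_gt(w_prev, 1.1)
})

test_that("isolated presynaptic spike with empty history changes nothing", {
  p <- neuron_params(sigma_noise = 0)
  net <- toy_plastic_net(n_E = 3, params = p)
  W0 <- weights_EE(net)
  res <- force_spikes(net, times_ms = 5, neurons = 1, duration_ms = 20)
  expect_equal(nrow(res$spikes), 1)
  expect_equal(weights_EE(res$net), W0)
})

test_that("online nearest-neighbour STDP matches the offline brute-force oracle", {
  for (seed in 1:4) {
    p <- neuron_params(sigma_noise = 0)
    net <- toy_plastic_net(n_E = 3, params = p, seed = seed)
    adj <- net$topology$adj[1:3, 1:3]
    W0 <- weights_EE(net)
    set.seed(seed)
    # <= 10 forced spikes, spacings beyond the 10 ms refractory period
    n_sp <- sample(4:10, 1)
    times <- sort(sample(seq(5, 300, by = 12), n_sp))
    neurons <- sample(1:3, n_sp, replace = TRUE)
    res <- force_spikes(net, times, neurons, duration_ms = 320)
    sp <- res$spikes
    # oracle consumes the actually realized spike trains
    spike_times <- lapply(1:3, function(j) sp$time_ms[sp$neuron == j])
    W_oracle <- apply_stdp_offline(W0, adj, spike_times, p)
    expect_equal(weights_EE(res$net), W_oracle, tolerance = 1e-12)
  }
  # and with normalization disabled
  p <- neuron_params(sigma_noise = 0, normalize = FALSE)
  net <- toy_plastic_net(n_E = 3, params = p, seed = 11)
  adj <- net$topology$adj[1:3, 1:3]
  W0 <- weights_EE(net)
  times <- c(5, 17, 29, 41, 60, 72)
  neurons <- c(1, 2, 3, 1, 3, 2)
  res <- force_spikes(net, times, neurons, duration_ms = 100)
  sp <- res$spikes
  spike_times <- lapply(1:3, function(j) sp$time_ms[sp$neuron == j])
  expect_equal(weights_EE(res$net),
               apply_stdp_offline(W0, adj, spike_times, p),
               tolerance = 1e-12)
})

test_that("normalization holds the incoming sum through plastic simulation", {
  p <- neuron_params()
  net <- init_network(p, seed = 3, n_E = 40, n_I = 8, n_groups = 4,
                      group_size = 10)
  sched <- build_training_schedule(n_blocks = 2, groups = c("A", "B"))
  set.seed(3)
  ev <- compile_events(sched, net$topology)
  res <- run_steps(net, attr(sched, "total_ms"), events = ev,
                   plasticity = TRUE)
  W <- weights_EE(res$net)
  adj <- res$net$topology$adj[1:40, 1:40]
  W0 <- weights_EE(net)
  # every STDP-touched incoming vector was renormalized to exactly w_total
  changed <- abs(rowSums(W) - rowSums(W0)) > 1e-12
  expect_gt(sum(changed), 5)
  expect_true(all(abs(rowSums(W * adj)[changed] - p$w_total) < 1e-9))
  expect_true(all(W >= 0))
})

test_that("sequential group stimulation builds the forward/backward asymmetry", {
  # half-size network with the real group structure (10 groups, 1/10 duty
  # cycle); at higher duty cycles background spikes during the successor's
  # epoch can mask the backward depression
  p <- neuron_params()
  net <- init_network(p, seed = 8, n_E = 100, n_I = 20, n_groups = 10,
                      group_size = 10)
  topo <- net$topology
  gA <- group_neurons(topo, "A"); gB <- group_neurons(topo, "B")
  adj <- topo$adj[1:100, 1:100]
  mean_cat <- function(W, from, to) mean(W[to, from][adj[to, from]])
  # pre-normalize initial incoming sums to w_total (as holds approximately
  # at full size), so the first normalization does not rescale whole rows
  for (j in 1:100) {
    s <- sum(net$topology$W[j, 1:100])
    if (s > 0) net$topology$W[j, 1:100] <- net$topology$W[j, 1:100] * 20 / s
  }
  W0 <- weights_EE(net)
  # settle excitability, then train the A-E sequence for 10 blocks
  net <- run_steps(net, 10000, record = FALSE)$net
  sched <- build_training_schedule(n_blocks = 10)
  set.seed(8)
  ev <- compile_events(sched, topo)
  res <- run_steps(net, attr(sched, "total_ms"), events = ev,
                   plasticity = TRUE)
  W1 <- weights_EE(res$net)
  expect_gt(mean_cat(W1, gA, gB), mean_cat(W0, gA, gB)) # forward grows
  expect_lt(mean_cat(W1, gB, gA), mean_cat(W0, gB, gA)) # backward shrinks
  expect_gt(mean_cat(W1, gA, gB), mean_cat(W1, gB, gA))
})
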