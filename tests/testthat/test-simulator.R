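test_that("single Euler step reproduces hand-computed voltage updates", {
  # dv = 0.04*65^2 - 5*65 + 140 - (-13) + 10 = 7 over one 1-ms step;
  # du = a (b v - u) = 0.02 (-13 + 13) = 0
  st <- izhikevich_step(v = -65, u = -13, I = 10, a = 0.02, b = 0.2,
                        c = -65, d = 8, dt = 1, n_substeps = 1)
  expect_equal(st$v, -58)
  expect_equal(st$u, -13)
  expect_false(st$spiked)
})

test_that("threshold crossing applies the after-spike reset", {
  st <- izhikevich_step(v = 31, u = -10, I = 0, a = 0.02, b = 0.2,
                        c = -65, d = 8)
  expect_true(st$spiked)
  expect_equal(st$v, -65)
  expect_equal(st$u, -2)
})

test_that("the subthreshold dynamics settle at the stable fixed point", {
  # roots of 0.04 v^2 + (5 - b) v + 140 = 0 are -50 and -70; -70 is stable
  v <- -60; u <- -12
  for (i in 1:3000) {
    st <- izhikevich_step(v, u, I = 0, a = 0.02, b = 0.2, c = -65, d = 2)
    v <- st$v; u <- st$u
  }
  expect_equal(v, -70, tolerance = 1e-6)
  expect_equal(u, -14, tolerance = 1e-6)
})

test_that("synaptic jumps decay exponentially with tau = 10 ms", {
  # 2 M/T cells in one glomerulus; cell 1 drives cell 2 with weight w
  spec <- population_spec(1, 2, n_gc = 2, n_pc = 2, n_ffi = 1, n_fbi = 1)
  net <- empty_network(spec)
  w <- 0.7
  net <- override_blocks(net, list(
    mtmt = Matrix::sparseMatrix(i = 2, j = 1, x = w, dims = c(2, 2))))
  set.seed(201)
  params <- network_params(spec)
  odor <- generate_odor(1, frac_range = c(1, 1))
  odor$onset_latency_ms <- 0
  cfg <- sim_config(osn_amplitude = 8, record_channels = 2)
  r <- run_trial(net, params, odor, cfg, noise_off = TRUE)
  spikes <- spike_times(r, "MT")[[1]]
  expect_gt(length(spikes), 1)
  tr <- r$channels$mc_ex[1, ]
  t1 <- spikes[1]
  gap <- min(spikes[2] - t1 - 1, 8)
  expect_gt(gap, 2)
  # channel recorded at end of step t1 equals w, then decays exp(-dt/10):
  # halving every 10*ln(2) ms
  expect_equal(tr[t1 + 1], w, tolerance = 1e-10)
  expect_equal(tr[t1 + 1 + gap], w * exp(-gap / 10), tolerance = 1e-10)
  # linear superposition after the second spike
  isi <- spikes[2] - spikes[1]
  expect_equal(tr[spikes[2] + 1], w + w * exp(-isi / 10), tolerance = 1e-10)
})

test_that("MC->GC delivery is delayed by the per-synapse latency", {
  spec <- population_spec(1, 1, n_gc = 2, n_pc = 2, n_ffi = 1, n_fbi = 1)
  net <- empty_network(spec)
  net <- override_blocks(net,
    list(mtgc = Matrix::sparseMatrix(i = 1, j = 1, x = 0.9, dims = c(2, 1))),
    delays_mtgc = 5L)
  set.seed(202)
  params <- network_params(spec)
  odor <- generate_odor(1, frac_range = c(1, 1)); odor$onset_latency_ms <- 0
  cfg <- sim_config(osn_amplitude = 8, record_channels = 2)  # cell 2 = GC 1
  r <- run_trial(net, params, odor, cfg, noise_off = TRUE)
  t1 <- spike_times(r, "MT")[[1]][1]
  tr <- r$channels$mc_ex[1, ]
  # accumulator untouched until exactly 5 ms after the M/T spike
  expect_true(all(tr[seq_len(t1 + 5)] == 0))  # samples t = 0 .. t1+4
  expect_equal(tr[t1 + 5 + 1], 0.9, tolerance = 1e-10)
})

test_that("a silent, unconnected network stays silent", {
  spec <- tiny_spec()
  net <- empty_network(spec)
  set.seed(203)
  params <- network_params(spec)
  r <- run_trial(net, params, NULL, sim_config(), noise_off = TRUE)
  expect_equal(length(r$spike_time), 0)
  expect_true(all(r$counts == 0))
})

test_that("trials are deterministic given the seed and diverge across seeds", {
  spec <- tiny_spec()
  set.seed(204)
  net <- build_network(spec)
  params <- network_params(spec)
  odor <- generate_odor(spec$n_glomeruli)
  set.seed(1); r1 <- run_trial(net, params, odor)
  set.seed(1); r2 <- run_trial(net, params, odor)
  set.seed(2); r3 <- run_trial(net, params, odor)
  expect_identical(r1$counts, r2$counts)
  expect_false(identical(r1$counts, r3$counts))
})

test_that("activated glomeruli drive their M/T cells above the others", {
  spec <- mini_population_spec()
  set.seed(205)
  net <- build_network(spec)
  params <- network_params(spec)
  odor <- generate_odor(spec$n_glomeruli)
  glom <- mt_glomerulus_map(spec)
  act <- glom %in% odor$glomerulus_ids
  rate_on <- rate_off <- 0
  set.seed(206)
  for (i in 1:3) {
    r <- run_trial(net, params, odor)
    pr <- rowSums(r$counts[seq_len(spec$n_mt), ])
    rate_on <- rate_on + mean(pr[act])
    rate_off <- rate_off + mean(pr[!act])
  }
  expect_gt(rate_on, 2 * rate_off)
})

test_that("raising the glomerular amplitude raises activated M/T rates", {
  spec <- mini_population_spec()
  set.seed(207)
  net <- build_network(spec)
  params <- network_params(spec)
  odor <- generate_odor(spec$n_glomeruli)
  glom <- mt_glomerulus_map(spec)
  act <- glom %in% odor$glomerulus_ids
  rates <- vapply(c(2, 6, 14), function(amp) {
    set.seed(208)
    r <- run_trial(net, params, odor, sim_config(osn_amplitude = amp))
    mean(rowSums(r$counts[seq_len(spec$n_mt), ])[act])
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("synaptic channels only receive jumps from their source class", {
  # only GC->MC / GC->GC weights present; GCs spike from their own noise:
  # inhibitory channels move, excitatory channels never do
  spec <- tiny_spec()
  net <- empty_network(spec)
  n_mt <- spec$n_mt; n_gc <- spec$n_gc
  set.seed(209)
  net <- override_blocks(net, list(
    gcmc = Matrix::sparseMatrix(i = rep(1:n_mt, n_gc), j = rep(1:n_gc, each = n_mt),
                                x = rep(-0.5, n_mt * n_gc),
                                dims = c(n_mt, n_gc))))
  params <- network_params(spec)
  cfg <- sim_config(noise_sigma = c(MT = 0, GC = 8, PC = 0, FFI = 0, FBI = 0),
                    record_channels = seq_len(spec$n_mt + spec$n_gc))
  set.seed(210)
  r <- run_trial(net, params, NULL, cfg)
  expect_gt(length(spike_times(r, "GC")[[1]]), 0)  # noise-driven GC spikes
  expect_true(any(r$channels$gc_in < 0))
  expect_true(all(r$channels$mc_ex == 0))
  expect_true(all(r$channels$pc_ex == 0))
  expect_true(all(r$channels$mob == 0))
})

test_that("the engine matches a scalar reference implementation spike for spike", {
  spec <- tiny_spec()
  set.seed(211)
  net <- build_network(spec)
  params <- network_params(spec)
  odor <- generate_odor(spec$n_glomeruli, frac_range = c(0.5, 1))
  cfg <- sim_config(osn_amplitude = 8)
  r <- run_trial(net, params, odor, cfg, noise_off = TRUE)
  ref <- ref_sim_trial(net, params, odor, cfg)
  expect_gt(sum(ref), 0)  # the circuit is active
  expect_equal(unname(as.matrix(r$counts)), unname(ref))
})

test_that("sessions cover every odor x trial and reproduce from the seed", {
  spec <- tiny_spec()
  set.seed(212)
  net <- build_network(spec)
  params <- network_params(spec)
  panel <- generate_panel(3, spec$n_glomeruli)
  set.seed(213)
  s1 <- run_session(net, params, panel, n_trials = 2,
                    reduce = function(r) sum(r$counts))
  set.seed(213)
  s2 <- run_session(net, params, panel, n_trials = 2,
                    reduce = function(r) sum(r$counts))
  expect_length(s1, 3)
  expect_length(s1[[1]], 2)
  expect_identical(s1, s2)
})

test_that("runaway dynamics raise a divergence error naming the time", {
  spec <- tiny_spec()
  net <- empty_network(spec)
  net <- override_blocks(net, list(
    mtmt = Matrix::sparseMatrix(i = c(2, 1), j = c(1, 2), x = c(1e9, 1e9),
                                dims = c(spec$n_mt, spec$n_mt))))
  set.seed(214)
  params <- network_params(spec)
  odor <- generate_odor(spec$n_glomeruli, frac_range = c(1, 1))
  odor$onset_latency_ms[] <- 0
  expect_error(run_trial(net, params, odor, sim_config(osn_amplitude = 50),
                         noise_off = TRUE),
               "diverged")
})
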