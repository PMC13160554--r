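test_that("neurogenesis cohorts have the stated size and coverage", {
  set.seed(301)
  coh <- select_cohorts(12500, fraction = 0.1, n_reshuffle_days = 10)
  expect_length(coh, 10)
  expect_true(all(vapply(coh, length, numeric(1)) == 1250))
  all_idx <- unlist(coh)
  expect_false(any(duplicated(all_idx)))          # pairwise disjoint
  expect_setequal(all_idx, 1:12500)               # union covers every GC
  expect_error(select_cohorts(100, 0.2, 10),      # 0.2 x 10 > 1
               class = "olfdrift_bad_schedule")
  wr <- select_cohorts(100, 0.2, 10, policy = "with_replacement")
  expect_length(wr, 10)
})

test_that("reshuffling redraws cohort synapses and leaves the rest untouched", {
  spec <- mini_population_spec()
  set.seed(311)
  net <- build_network(spec)
  cohort <- 1:100
  set.seed(312)
  net2 <- reshuffle_granule_cells(net, cohort, day = 1)$network
  inC <- logical(spec$n_gc); inC[cohort] <- TRUE
  rows_of <- function(W) W@i + 1L
  cols_of <- function(W) rep.int(seq_len(ncol(W)), diff(W@p))
  keep_equal <- function(a, b, sel_a, sel_b, label) {
    ka <- cbind(rows_of(a), cols_of(a), a@x)[!sel_a, , drop = FALSE]
    kb <- cbind(rows_of(b), cols_of(b), b@x)[!sel_b, , drop = FALSE]
    expect_equal(ka, kb, label = label)
  }
  keep_equal(net$blocks$mtgc, net2$blocks$mtgc,
             inC[rows_of(net$blocks$mtgc)], inC[rows_of(net2$blocks$mtgc)],
             "mtgc")
  keep_equal(net$blocks$gcmc, net2$blocks$gcmc,
             inC[cols_of(net$blocks$gcmc)], inC[cols_of(net2$blocks$gcmc)],
             "gcmc")
  keep_equal(net$blocks$gcgc, net2$blocks$gcgc,
             inC[rows_of(net$blocks$gcgc)] | inC[cols_of(net$blocks$gcgc)],
             inC[rows_of(net2$blocks$gcgc)] | inC[cols_of(net2$blocks$gcgc)],
             "gcgc")
  keep_equal(net$blocks$fb, net2$blocks$fb,
             inC[rows_of(net$blocks$fb)], inC[rows_of(net2$blocks$fb)], "fb")
  # untouched blocks bit-identical
  for (b in c("mtmt", "mtpc", "mtffi", "pcpc", "ffipc", "fbipc"))
    expect_identical(net$blocks[[b]], net2$blocks[[b]])
  # delays of surviving MC->GC synapses preserved
  ko <- !inC[rows_of(net$blocks$mtgc)]
  kn <- !inC[rows_of(net2$blocks$mtgc)]
  expect_equal(net$delays_mtgc[ko], net2$delays_mtgc[kn])
})

test_that("reshuffling preserves the weight distributions (KS)", {
  spec <- mini_population_spec()
  set.seed(321)
  net <- build_network(spec)
  net10 <- net
  set.seed(322)
  coh <- select_cohorts(spec$n_gc, 0.1, 10)
  for (d in 1:10)
    net10 <- reshuffle_granule_cells(net10, coh[[d]], day = d)$network
  for (b in c("mtgc", "gcmc", "gcgc", "fb")) {
    D <- suppressWarnings(
      ks.test(net$blocks[[b]]@x, net10$blocks[[b]]@x)$statistic)
    expect_lt(D, 0.05, label = b)
    # density preserved too
    expect_lt(abs(length(net10$blocks[[b]]@x) / length(net$blocks[[b]]@x) - 1),
              0.1, label = b)
  }
})

test_that("a 100% reshuffle is equivalent to an independent rebuild", {
  spec <- tiny_spec()
  set.seed(331); a <- build_network(spec)
  set.seed(332); b <- build_network(spec)
  set.seed(333)
  a_shuf <- reshuffle_granule_cells(a, seq_len(spec$n_gc), day = 1)$network
  d_indep <- weight_dissimilarity(a, b)
  d_shuf <- weight_dissimilarity(a, a_shuf)
  expect_lt(abs(d_shuf - d_indep), 0.25)
})

test_that("spike efficacies follow the suppression rule", {
  expect_equal(spike_efficacy(50, tau_s = 34), 1)
  e <- spike_efficacy(c(0, 34), tau_s = 34)
  expect_equal(e, c(1, 1 - exp(-1)))
  expect_equal(e[2], 0.6321206, tolerance = 1e-6)
  expect_equal(spike_efficacy(c(10, 10), tau_s = 34)[2], 0)  # interval -> 0
  set.seed(341)
  tr <- sort(runif(100, 0, 250))
  e <- spike_efficacy(tr, tau_s = 75)
  expect_true(all(e >= 0 & e <= 1))
  expect_error(spike_efficacy(c(5, 3), 34), class = "olfdrift_unsorted_train")
})

test_that("the STDP window has the stated asymmetric exponential form", {
  expect_equal(stdp_window(13.3), 1.03 * exp(-1))
  expect_equal(stdp_window(13.3), 0.3789158, tolerance = 1e-6)
  expect_equal(stdp_window(-34.5), -0.51 * exp(-1))
  expect_equal(stdp_window(-34.5), -0.1876185, tolerance = 1e-6)
  expect_equal(stdp_window(0), 0)
  dts <- seq(-200, 200, by = 0.5)
  F <- stdp_window(dts)
  expect_true(all(F[dts > 0] > 0))
  expect_true(all(F[dts < 0] < 0))
})

test_that("per-synapse STDP parameter draws are clipped to valid signs", {
  set.seed(351)
  p <- draw_stdp_params(20000)
  expect_true(all(p$Ap > 0) && all(p$Am < 0))
  expect_true(all(p$Tp > 0) && all(p$Tm > 0))
  expect_equal(mean(p$Ap), 1.03, tolerance = 0.01)
  expect_equal(mean(p$Tm), 34.5, tolerance = 0.1)
})

test_that("a single isolated pre/post pair produces the hand-computed update", {
  spec <- tiny_spec()
  net <- empty_network(spec)
  net <- override_blocks(net,
    list(mtgc = Matrix::sparseMatrix(i = 1, j = 1, x = 0.1,
                                     dims = c(spec$n_gc, spec$n_mt))))
  net$feedback_on <- TRUE
  set.seed(361)
  reg <- abgc_registry(net)
  reg$birth_day[1] <- 1L
  reg$params$mtgc <- list(Ap = 1.03, Am = -0.51, Tp = 13.3, Tm = 34.5)
  raster <- list(spike_cell = c(1L, spec$n_mt + 1L),  # pre M/T 1, post GC 1
                 spike_time = c(10L, 20L))
  eff <- rule_for_test(net, "mtgc")
  net2 <- apply_stdp(net, reg, raster, lr_scale = 1 / abs(eff),
                     cap_scale = 1e6 / abs(eff))
  dw <- net2$blocks$mtgc@x - 0.1
  expect_equal(dw, 1.03 * exp(-10 / 13.3), tolerance = 1e-9)
  expect_equal(dw, 0.4856239, tolerance = 1e-6)
  # no spikes -> no change
  empty_raster <- list(spike_cell = integer(0), spike_time = integer(0))
  net3 <- apply_stdp(net, reg, empty_raster)
  expect_identical(net3$blocks$mtgc@x, net$blocks$mtgc@x)
})

test_that("STDP never changes a synapse's sign and respects the abGC mask", {
  spec <- mini_population_spec()
  set.seed(371)
  net <- build_network(spec)
  reg <- abgc_registry(net)
  abgc <- 1:200
  reg$birth_day[abgc] <- 1L
  params <- network_params(spec)
  set.seed(372)
  r <- run_trial(net, params, generate_odor(spec$n_glomeruli),
                 sim_config(osn_amplitude = 6))
  net2 <- apply_stdp(net, reg, r, lr_scale = 0.5, cap_scale = 2)
  inA <- logical(spec$n_gc); inA[abgc] <- TRUE
  for (b in c("mtgc", "gcmc", "gcgc", "fb")) {
    W0 <- net$blocks[[b]]; W1 <- net2$blocks[[b]]
    expect_identical(W0@i, W1@i)  # structure untouched
    expect_true(all(sign(W1@x) == sign(W0@x) | W1@x == 0), label = b)
    rows <- W0@i + 1L
    cols <- rep.int(seq_len(ncol(W0)), diff(W0@p))
    plastic <- switch(b,
      mtgc = inA[rows], fb = inA[rows], gcmc = inA[cols],
      gcgc = inA[rows] | inA[cols])
    expect_identical(W1@x[!plastic], W0@x[!plastic], label = b)
    expect_gt(sum(W1@x != W0@x), 0)  # something did change
  }
})

test_that("repeated odor exposure drives masked weights toward an asymptote", {
  spec <- mini_population_spec()
  set.seed(381)
  net <- build_network(spec)
  params <- network_params(spec)
  reg <- abgc_registry(net)
  reg$birth_day[] <- 1L  # make every GC plastic
  odor <- generate_odor(spec$n_glomeruli)
  cfg <- sim_config(osn_amplitude = 6)
  step_size <- numeric(30)
  set.seed(382)
  for (tr in 1:30) {
    r <- run_trial(net, params, odor, cfg)
    net_new <- apply_stdp(net, reg, r)
    step_size[tr] <- sum(abs(net_new$blocks$mtgc@x - net$blocks$mtgc@x)) +
      sum(abs(net_new$blocks$gcgc@x - net$blocks$gcgc@x))
    net <- net_new
  }
  expect_lt(mean(step_size[21:30]), mean(step_size[1:10]))
})
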