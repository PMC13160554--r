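# shared fixtures and the scalar reference simulator

tiny_spec <- function() {
  population_spec(n_glomeruli = 2, mt_per_glomerulus = 3, n_gc = 8,
                  n_pc = 6, n_ffi = 2, n_fbi = 2, scale_factor = 0.01)
}

# build a network and overwrite chosen blocks with hand-made matrices;
# delays can be supplied aligned with the replacement mtgc block
override_blocks <- function(net, blocks = list(), delays_mtgc = NULL) {
  for (nm in names(blocks)) {
    stopifnot(all(dim(blocks[[nm]]) == dim(net$blocks[[nm]])))
    net$blocks[[nm]] <- as(as(blocks[[nm]], "CsparseMatrix"), "generalMatrix")
  }
  if ("mtgc" %in% names(blocks)) {
    n <- length(net$blocks$mtgc@x)
    net$delays_mtgc <- if (is.null(delays_mtgc)) rep(1L, n)
                       else as.integer(delays_mtgc)
    stopifnot(length(net$delays_mtgc) == n)
  }
  net
}

# all-zero network at a given spec (keeps structure, removes every synapse)
empty_network <- function(spec) {
  rules <- default_connectivity_rules(spec)
  rules$density[] <- 0
  build_network(spec, rules, feedback_on = FALSE)
}

# Scalar (non-vectorized) reference implementation of one trial, mirroring
# the engine's update order exactly; noise must be off.  Independent oracle
# for the spike-for-spike equivalence test.
ref_sim_trial <- function(net, params, odor, config) {
  s <- net$spec
  lay <- params$layout
  n_steps <- as.integer(round(config$trial_ms / config$dt_ms))
  N <- lay$total
  off <- lay$offset  # 0-based
  dec <- exp(-config$dt_ms / config$syn_tau_ms)
  act <- if (is.null(odor)) matrix(0, s$n_glomeruli, n_steps) else
    odor_activation(odor, times = seq_len(n_steps) * config$dt_ms)
  mtglom <- mt_glomerulus_map(s)
  B <- lapply(net$blocks, as.matrix)
  # mtgc delays as a dense matrix aligned with the block pattern
  Dm <- matrix(0L, s$n_gc, s$n_mt)
  cols <- rep.int(seq_len(s$n_mt), diff(net$blocks$mtgc@p))
  Dm[cbind(net$blocks$mtgc@i + 1L, cols)] <- net$delays_mtgc

  v <- params$c
  u <- params$b * v
  ex_mob <- in_mob <- fb_gc <- mob_pcx <- ex_pcx <- in_pcx <- numeric(N)
  maxd <- max(1L, net$delays_mtgc)
  buf <- matrix(0, maxd + 1L, s$n_gc)
  counts <- matrix(0L, N, n_steps + 1)
  h <- config$dt_ms / config$n_substeps
  amp <- config$osn_amplitude
  idx <- function(p, i) off[[p]] + i
  for (t in seq_len(n_steps)) {
    ex_mob <- ex_mob * dec; in_mob <- in_mob * dec; fb_gc <- fb_gc * dec
    mob_pcx <- mob_pcx * dec; ex_pcx <- ex_pcx * dec; in_pcx <- in_pcx * dec
    slot <- t %% (maxd + 1L) + 1L
    ex_mob[off["GC"] + seq_len(s$n_gc)] <-
      ex_mob[off["GC"] + seq_len(s$n_gc)] + buf[slot, ]
    buf[slot, ] <- 0
    osn <- ifelse(act[mtglom, t] > 0, amp, 0)
    I <- numeric(N)
    for (i in seq_len(N)) {
      p <- as.character(lay$pop[i])
      I[i] <- switch(p,
        MT = ex_mob[i] + in_mob[i] + osn[i],
        GC = ex_mob[i] + in_mob[i] + if (net$feedback_on) fb_gc[i] else 0,
        PC = mob_pcx[i] + ex_pcx[i] + in_pcx[i],
        FFI = mob_pcx[i] + in_pcx[i],
        FBI = ex_pcx[i] + in_pcx[i])
    }
    spiking <- integer(0)
    for (i in seq_len(N)) {
      vi <- v[i]; ui <- u[i]; v0 <- vi
      for (ss in seq_len(config$n_substeps))
        vi <- vi + h * (0.04 * vi^2 + 5 * vi + 140 - ui + I[i])
      ui <- ui + config$dt_ms * params$a[i] * (params$b[i] * v0 - ui)
      if (vi >= 30) {
        counts[i, t + 1] <- 1L
        spiking <- c(spiking, i)
        vi <- params$c[i]
        ui <- ui + params$d[i]
      }
      v[i] <- vi; u[i] <- ui
    }
    for (i in spiking) {
      p <- as.character(lay$pop[i])
      if (p == "MT") {
        m <- i
        ex_mob[seq_len(s$n_mt)] <- ex_mob[seq_len(s$n_mt)] + B$mtmt[, m]
        for (g in which(B$mtgc[, m] != 0)) {
          sl <- (t + Dm[g, m]) %% (maxd + 1L) + 1L
          buf[sl, g] <- buf[sl, g] + B$mtgc[g, m]
        }
        mob_pcx[off["PC"] + seq_len(s$n_pc)] <-
          mob_pcx[off["PC"] + seq_len(s$n_pc)] + B$mtpc[, m]
        mob_pcx[off["FFI"] + seq_len(s$n_ffi)] <-
          mob_pcx[off["FFI"] + seq_len(s$n_ffi)] + B$mtffi[, m]
      } else if (p == "GC") {
        g <- i - off["GC"]
        in_mob[seq_len(s$n_mt)] <- in_mob[seq_len(s$n_mt)] + B$gcmc[, g]
        in_mob[off["GC"] + seq_len(s$n_gc)] <-
          in_mob[off["GC"] + seq_len(s$n_gc)] + B$gcgc[, g]
      } else if (p == "PC") {
        pcell <- i - off["PC"]
        ex_pcx[off["PC"] + seq_len(s$n_pc)] <-
          ex_pcx[off["PC"] + seq_len(s$n_pc)] + B$pcpc[, pcell]
        ex_pcx[off["FBI"] + seq_len(s$n_fbi)] <-
          ex_pcx[off["FBI"] + seq_len(s$n_fbi)] + B$pcfbi[, pcell]
        if (net$feedback_on)
          fb_gc[off["GC"] + seq_len(s$n_gc)] <-
            fb_gc[off["GC"] + seq_len(s$n_gc)] + B$fb[, pcell]
      } else if (p == "FFI") {
        f <- i - off["FFI"]
        in_pcx[off["PC"] + seq_len(s$n_pc)] <-
          in_pcx[off["PC"] + seq_len(s$n_pc)] + B$ffipc[, f]
        in_pcx[off["FFI"] + seq_len(s$n_ffi)] <-
          in_pcx[off["FFI"] + seq_len(s$n_ffi)] + B$ffiffi[, f]
      } else {
        f <- i - off["FBI"]
        in_pcx[off["PC"] + seq_len(s$n_pc)] <-
          in_pcx[off["PC"] + seq_len(s$n_pc)] + B$fbipc[, f]
        in_pcx[off["FBI"] + seq_len(s$n_fbi)] <-
          in_pcx[off["FBI"] + seq_len(s$n_fbi)] + B$fbifbi[, f]
      }
    }
  }
  counts
}

rule_for_test <- function(net, block) {
  net$rules$effective_mean[net$rules$block == block]
}

withr_local_tempdir <- function() {
  d <- tempfile("olfdrift")
  dir.create(d)
  d
}

# memoized desk-scale experiment fixtures shared across acceptance tests
.fixture_env <- new.env(parent = emptyenv())

drift_fixture <- function() {
  if (is.null(.fixture_env$drift))
    .fixture_env$drift <-
      run_drift_experiment(experiment_config(preset = "mini", seed = 1))
  .fixture_env$drift
}

stdp_fixture <- function() {
  if (is.null(.fixture_env$stdp))
    .fixture_env$stdp <-
      run_stdp_experiment(experiment_config(preset = "mini", seed = 1))
  .fixture_env$stdp
}
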