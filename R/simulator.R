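#' Simulation configuration
#'
#' @param dt_ms integration step (ms); the voltage is advanced in
#'   `n_substeps` equal sub-steps per `dt_ms` for stability.
#' @param n_substeps voltage sub-steps (2 = standard half-step scheme).
#' @param trial_ms sniff-window length; the trial is sampled on the
#'   `0..trial_ms` ms grid (251 samples at defaults).
#' @param syn_tau_ms synaptic decay time constant (ms).
#' @param noise_sigma named per-type background white-noise SDs, added to
#'   each cell's current once per ms step (MT 1.75, GC 0.8, PC 0.9;
#'   FFI/FBI none).
#' @param osn_amplitude glomerular step amplitude (current units). The
#'   default is calibrated so activated M/T cells fire in the tens of Hz.
#' @param osn_noise_sd total SD of the glomerular input noise (default
#'   25% of the amplitude).
#' @param osn_shared_frac fraction of glomerular noise variance shared
#'   across the M/T cells of one glomerulus.
#' @param record_channels integer vector of global cell indices whose
#'   synaptic-channel time courses are recorded (diagnostics).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(dt_ms = 1, n_substeps = 2, trial_ms = 250,
                       syn_tau_ms = 10,
                       noise_sigma = c(MT = 1.75, GC = 0.8, PC = 0.9,
                                       FFI = 0, FBI = 0),
                       osn_amplitude = 6,
                       osn_noise_sd = NULL,
                       osn_shared_frac = 0.5,
                       record_channels = integer(0)) {
  if (dt_ms <= 0 || syn_tau_ms <= 0)
    odx_stop("dt_ms and syn_tau_ms must be positive", "olfdrift_bad_spec")
  if (is.null(osn_noise_sd)) osn_noise_sd <- 0.25 * osn_amplitude
  cfg <- list(dt_ms = dt_ms, n_substeps = as.integer(n_substeps),
              trial_ms = trial_ms, syn_tau_ms = syn_tau_ms,
              noise_sigma = noise_sigma, osn_amplitude = osn_amplitude,
              osn_noise_sd = osn_noise_sd, osn_shared_frac = osn_shared_frac,
              record_channels = as.integer(record_channels))
  class(cfg) <- "sim_config"
  cfg
}

# flatten network + cell params + config into the engine argument list
pack_engine <- function(net, params, config, noise_off = FALSE) {
  s <- net$spec
  lay <- params$layout
  sig <- config$noise_sigma[as.character(lay$pop)]
  if (noise_off) sig <- rep(0, length(sig))
  c(list(n_mt = s$n_mt, n_gc = s$n_gc, n_pc = s$n_pc, n_ffi = s$n_ffi,
         n_fbi = s$n_fbi,
         n_steps = as.integer(round(config$trial_ms / config$dt_ms)),
         n_substeps = config$n_substeps, dt_ms = config$dt_ms,
         syn_tau_ms = config$syn_tau_ms,
         feedback_on = net$feedback_on,
         a = params$a, b = params$b, c = params$c, d = params$d,
         sigma = as.numeric(sig),
         mt_glom = as.integer(mt_glomerulus_map(s)),
         delay_mtgc = net$delays_mtgc),
    net$blocks)
}

#' Simulate one odor trial
#'
#' Runs the full network through one sniff window. Spike times are recorded
#' at the 1-ms step on which the voltage crossed 30 mV (before reset); the
#' initial state is rest (`v = c`, `u = b v`) with all synaptic channels
#' empty -- trials are independent sniffs with no carry-over.
#'
#' @param net an [build_network()] result.
#' @param params a [network_params()] result for the same spec.
#' @param odor an [generate_odor()] odor, or `NULL` for a blank (no-odor)
#'   trial.
#' @param config a [sim_config()].
#' @param noise_off disable all noise sources (deterministic dynamics).
#' @return object of class `spike_raster`: integer `counts` matrix
#'   (cells x 251 samples, column t+1 = time t ms), `spike_cell` /
#'   `spike_time` event vectors, the population factor, and recorded
#'   channel traces when requested.
#' @export
run_trial <- function(net, params, odor, config = sim_config(),
                      noise_off = FALSE) {
  s <- net$spec
  n_steps <- as.integer(round(config$trial_ms / config$dt_ms))
  if (is.null(odor)) {
    act <- matrix(0L, s$n_glomeruli, n_steps)
  } else {
    act <- odor_activation(odor, times = seq_len(n_steps) * config$dt_ms)
    storage.mode(act) <- "integer"
  }
  amp <- if (!is.null(odor) && !is.null(odor$amplitude)) odor$amplitude
         else config$osn_amplitude
  sd_tot <- if (noise_off) 0 else config$osn_noise_sd
  eng <- pack_engine(net, params, config, noise_off = noise_off)
  res <- sim_trial_cpp(eng, act, amp,
                       sd_tot * sqrt(config$osn_shared_frac),
                       sd_tot * sqrt(1 - config$osn_shared_frac),
                       config$record_channels)
  raster <- list(counts = res$counts, spike_cell = res$spike_cell,
                 spike_time = res$spike_time, pop = params$layout$pop,
                 n_steps = n_steps, dt_ms = config$dt_ms,
                 channels = res$channels)
  class(raster) <- "spike_raster"
  raster
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike raster: %d cells, %d ms, %d spikes\n",
              nrow(x$counts), x$n_steps, length(x$spike_time)))
  print(tapply(rep(1, length(x$spike_cell)), x$pop[x$spike_cell], sum))
  invisible(x)
}

#' Spike times of one population
#'
#' @param raster a `spike_raster`.
#' @param population one of `"MT"`, `"GC"`, `"PC"`, `"FFI"`, `"FBI"`.
#' @return list of increasing spike-time vectors (ms), one per cell of the
#'   population.
#' @export
spike_times <- function(raster, population = "MT") {
  cells <- which(raster$pop == population)
  idx <- raster$spike_cell %in% cells
  f <- factor(raster$spike_cell[idx], levels = cells)
  out <- split(raster$spike_time[idx], f)
  lapply(out, function(t) sort(as.numeric(t)))
}

#' Mean firing rate per population (spikes/s)
#'
#' @param raster a `spike_raster`.
#' @param window optional `c(from, to)` ms restriction.
#' @return named numeric vector over populations.
#' @export
population_rates <- function(raster, window = NULL) {
  counts <- raster$counts
  tms <- seq_len(ncol(counts)) - 1
  if (!is.null(window)) counts <- counts[, tms >= window[1] & tms <= window[2],
                                         drop = FALSE]
  dur_s <- ncol(counts) * raster$dt_ms / 1000
  tapply(rowSums(counts) / dur_s, raster$pop, mean)
}

#' Simulate a session (all odors x trials of one day)
#'
#' Trials are run with the current RNG stream (independent noise per trial)
#' and a fixed network. `reduce` is applied to each raster before storage,
#' allowing memory-light collection (e.g. [bin_spikes()]).
#'
#' @param net,params,config as in [run_trial()].
#' @param panel an [generate_panel()] odor panel.
#' @param n_trials trials per odor.
#' @param reduce function applied to each `spike_raster`.
#' @return nested list `[[odor]][[trial]]` of reduced rasters.
#' @export
run_session <- function(net, params, panel, n_trials, config = sim_config(),
                        reduce = identity) {
  out <- replicate(length(panel$odors), vector("list", n_trials),
                   simplify = FALSE)
  for (tr in seq_len(n_trials)) {
    for (k in seq_along(panel$odors)) {
      out[[k]][[tr]] <- reduce(run_trial(net, params, panel$odors[[k]], config))
    }
  }
  out
}

#' Export a raster to a spike-event CSV
#'
#' Columns: cell_id, population, spike_time_ms (plus any constant id columns
#' given in `extra`).
#'
#' @param raster a `spike_raster`.
#' @param path CSV path.
#' @param extra named list of constant columns (e.g. day, odor, trial).
#' @export
write_spikes_csv <- function(raster, path, extra = list()) {
  df <- data.frame(cell_id = raster$spike_cell,
                   population = as.character(raster$pop[raster$spike_cell]),
                   spike_time_ms = raster$spike_time)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
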