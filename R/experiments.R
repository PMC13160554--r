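# --- configuration ---------------------------------------------------------

#' Experiment configuration
#'
#' Bundles every knob of the two end-to-end experiments (drift under
#' neurogenesis without STDP; STDP stabilization with paired arms) plus the
#' named seed streams that make a run a pure function of its config.
#'
#' @param preset `"mini"` (1/10-scale populations) or `"paper_scale"`.
#' @param n_days simulation days (Day-0 .. Day-`n_days-1`).
#' @param n_odors,n_trials panel size and trials per odor per day; `NULL`
#'   picks the experiment's default (drift: 20 odors x 5 trials at mini
#'   scale, 100 x 10 at full scale; STDP: 10 odors x 50 trials).
#' @param stdp_enabled,neurogenesis_enabled,feedback_on experiment switches.
#' @param neurogenesis_fraction GC fraction reshuffled per day.
#' @param similarity_mix fraction of jittered-variant odors in the panel.
#' @param k_analysis reduced-space dimensionality (leading components).
#' @param n_across_pairs number of fixed odor pairs for across-odor
#'   correlations and decoding.
#' @param lr_scale,cap_scale STDP learning-rate / weight-cap scales
#'   relative to each block's mean strength.
#' @param inhibitory_update inhibitory STDP convention; see [apply_stdp()].
#' @param sim a [sim_config()].
#' @param watch optional data.frame (`block`, `i`, `j`) of synapses whose
#'   weights are logged after every trial.
#' @param seed master seed; independent named streams (build, cells, odors,
#'   neurogenesis, stdp, noise, analysis) are derived from it.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(preset = c("mini", "paper_scale"),
                              n_days = 11, n_odors = NULL, n_trials = NULL,
                              stdp_enabled = FALSE,
                              neurogenesis_enabled = TRUE,
                              feedback_on = TRUE,
                              neurogenesis_fraction = 0.1,
                              similarity_mix = 0.2,
                              k_analysis = 50, n_across_pairs = 10,
                              lr_scale = 0.01, cap_scale = 4,
                              inhibitory_update = c("magnitude", "signed"),
                              sim = sim_config(), watch = NULL, seed = 1) {
  inhibitory_update <- match.arg(inhibitory_update)
  preset <- match.arg(preset)
  cfg <- list(preset = preset, n_days = as.integer(n_days),
              n_odors = n_odors, n_trials = n_trials,
              stdp_enabled = stdp_enabled,
              neurogenesis_enabled = neurogenesis_enabled,
              feedback_on = feedback_on,
              neurogenesis_fraction = neurogenesis_fraction,
              similarity_mix = similarity_mix,
              k_analysis = as.integer(k_analysis),
              n_across_pairs = as.integer(n_across_pairs),
              lr_scale = lr_scale, cap_scale = cap_scale,
              inhibitory_update = inhibitory_update,
              sim = sim, watch = watch, seed = as.integer(seed))
  class(cfg) <- "experiment_config"
  cfg
}

config_spec <- function(config) {
  if (config$preset == "mini") mini_population_spec() else population_spec()
}

# named independent seed streams, all well below 2^31
derive_seeds <- function(seed) {
  base <- (as.integer(seed) %% 1000003L) * 1009L
  nm <- c("build", "cells", "odors", "neurogenesis", "stdp", "noise",
          "analysis")
  setNames(base + 101L * seq_along(nm), nm)
}

resolve_experiment <- function(config, mode) {
  mini <- config$preset == "mini"
  if (is.null(config$n_odors))
    config$n_odors <- if (mode == "stdp") 10L else if (mini) 20L else 100L
  if (is.null(config$n_trials))
    config$n_trials <- if (mode == "stdp") 50L else if (mini) 5L else 10L
  config
}

# build the shared inputs of an experiment from the seed streams
experiment_inputs <- function(config) {
  spec <- config_spec(config)
  seeds <- derive_seeds(config$seed)
  set.seed(seeds["build"])
  net <- build_network(spec, feedback_on = config$feedback_on)
  set.seed(seeds["cells"])
  params <- network_params(spec)
  set.seed(seeds["odors"])
  panel <- generate_panel(n = config$n_odors, n_glomeruli = spec$n_glomeruli,
                          similarity_mix = config$similarity_mix)
  cohorts <- NULL
  if (config$neurogenesis_enabled) {
    set.seed(seeds["neurogenesis"])
    cohorts <- select_cohorts(spec$n_gc, config$neurogenesis_fraction,
                              n_reshuffle_days = config$n_days - 1L)
  }
  set.seed(seeds["stdp"])
  registry <- abgc_registry(net)
  list(spec = spec, seeds = seeds, net = net, params = params,
       panel = panel, cohorts = cohorts, registry = registry)
}

# --- one experiment arm ----------------------------------------------------

# Runs n_days of sessions (reshuffle at day start, then n_trials cycles over
# the panel), accumulating the analysis tensors for the M/T and PC
# populations, then computes the drift report.  Noise, reshuffling and
# STDP-parameter draws come from distinct seed streams so that paired arms
# (stdp_on TRUE/FALSE) see identical networks, odors, cohorts and noise.
run_experiment_arm <- function(inp, config, stdp_on) {
  spec <- inp$spec; seeds <- inp$seeds
  net <- inp$net; params <- inp$params; panel <- inp$panel
  registry <- inp$registry
  n_days <- config$n_days; n_odors <- length(panel$odors)
  n_trials <- config$n_trials
  simcfg <- config$sim

  lay <- params$layout
  rows <- list(MT = seq_len(spec$n_mt),
               PC = lay$offset["PC"] + seq_len(spec$n_pc))
  rates_rows <- as.integer(c(rows$MT, rows$PC))
  # full 5-sample windows at 1-ms stride over the inclusive sample grid
  n_bins <- as.integer(round(simcfg$trial_ms / simcfg$dt_ms)) + 1L - 5L + 1L

  # even/odd trial-averaged trajectories (cells x bins, concatenated over
  # odor and day) plus single-trial time-collapsed vectors
  coll <- lapply(rows, function(rr) {
    nc <- length(rr)
    list(esum = matrix(0, nc, n_bins * n_odors * n_days),
         osum = matrix(0, nc, n_bins * n_odors * n_days),
         trials = array(0, c(nc, n_odors, n_trials, n_days)))
  })
  n_even <- floor(n_trials / 2); n_odd <- ceiling(n_trials / 2)

  watch <- config$watch
  wlog <- if (!is.null(watch)) vector("list", n_days * n_trials * nrow(watch))
  wk <- 0L
  dissim <- rep(NA_real_, n_days)
  net0 <- net
  if (stdp_on) {
    # privatize the plastic blocks so the fast in-place STDP path cannot
    # touch vectors shared with the paired arm's starting network
    for (b in STDP_BLOCKS) net$blocks[[b]]@x <- net$blocks[[b]]@x + 0
  }

  for (day in 0:(n_days - 1)) {
    if (day > 0 && config$neurogenesis_enabled) {
      set.seed(seeds["neurogenesis"] + 7L * day)
      rs <- reshuffle_granule_cells(net, inp$cohorts[[day]], registry, day)
      net <- rs$network; registry <- rs$registry
    }
    dissim[day + 1] <- if (day == 0) 0 else weight_dissimilarity(net0, net)
    set.seed(seeds["noise"] + 13L * day)
    for (tr in seq_len(n_trials)) {
      for (k in seq_len(n_odors)) {
        raster <- run_trial(net, params, panel$odors[[k]], simcfg)
        R <- bin_spikes(raster$counts[rates_rows, , drop = FALSE])
        ri <- 0L
        for (p in names(rows)) {
          nc <- length(rows[[p]])
          Rp <- R[ri + seq_len(nc), , drop = FALSE]
          ri <- ri + nc
          slab <- ((day * n_odors) + (k - 1L)) * n_bins + seq_len(n_bins)
          if (tr %% 2 == 0) {
            coll[[p]]$esum[, slab] <- coll[[p]]$esum[, slab] + Rp / n_even
          } else {
            coll[[p]]$osum[, slab] <- coll[[p]]$osum[, slab] + Rp / n_odd
          }
          coll[[p]]$trials[, k, tr, day + 1] <- rowMeans(Rp)
        }
        if (stdp_on)
          net <- apply_stdp(net, registry, raster,
                            lr_scale = config$lr_scale,
                            cap_scale = config$cap_scale, in_place = TRUE,
                            inhibitory_update = config$inhibitory_update)
        if (!is.null(watch)) {
          for (wi in seq_len(nrow(watch))) {
            wk <- wk + 1L
            wlog[[wk]] <- data.frame(
              day = day, trial = tr, block = watch$block[wi],
              i = watch$i[wi], j = watch$j[wi],
              weight = synapse_weight(net, watch$block[wi],
                                      watch$i[wi], watch$j[wi]))
          }
        }
      }
    }
  }
  report <- drift_report_from_collection(coll, config, seeds, n_bins,
                                         n_odors, n_days, n_trials)
  report$weight_dissimilarity <- dissim
  report$stdp_on <- stdp_on
  if (!is.null(watch)) report$watch_log <- do.call(rbind, wlog[seq_len(wk)])
  report
}

# --- drift statistics ------------------------------------------------------

corr_mat_days <- function(all_v, even_v, odd_v, n_days, n_odors) {
  M <- matrix(0, n_days, n_days)
  for (o in seq_len(n_odors)) {
    for (i in seq_len(n_days)) {
      M[i, i] <- M[i, i] +
        ensemble_correlation(even_v[, o, i], odd_v[, o, i]) / n_odors
      if (i < n_days) for (j in (i + 1):n_days) {
        r <- ensemble_correlation(all_v[, o, i], all_v[, o, j]) / n_odors
        M[i, j] <- M[i, j] + r
        M[j, i] <- M[j, i] + r
      }
    }
  }
  M
}

single_trial_corr_mat <- function(trials, n_days, n_odors, n_trials) {
  M <- matrix(0, n_days, n_days)
  day_of <- rep(seq_len(n_days), each = n_trials)
  for (o in seq_len(n_odors)) {
    V <- matrix(trials[, o, , ], nrow = dim(trials)[1])  # (trial, day) cols
    CC <- suppressWarnings(cor(V))
    for (i in seq_len(n_days)) for (j in i:n_days) {
      block <- CC[day_of == i, day_of == j, drop = FALSE]
      val <- if (i == j) mean(block[upper.tri(block)], na.rm = TRUE)
             else mean(block, na.rm = TRUE)
      M[i, j] <- M[i, j] + val / n_odors
      if (j > i) M[j, i] <- M[i, j]
    }
  }
  M
}

across_corr_mat <- function(all_v, pairs, n_days) {
  M <- matrix(0, n_days, n_days)
  for (pr in seq_len(nrow(pairs))) {
    a <- pairs[pr, 1]; b <- pairs[pr, 2]
    for (i in seq_len(n_days)) for (j in i:n_days) {
      r <- (ensemble_correlation(all_v[, a, i], all_v[, b, j]) +
            ensemble_correlation(all_v[, b, i], all_v[, a, j])) / 2
      M[i, j] <- M[i, j] + r / nrow(pairs)
      if (j > i) M[j, i] <- M[i, j]
    }
  }
  M
}

cosine_mat_days <- function(all_v, even_v, odd_v, n_days, n_odors) {
  M <- matrix(0, n_days, n_days)
  for (o in seq_len(n_odors)) {
    for (i in seq_len(n_days)) {
      wdv <- within_day_variability(even_v[, o, i], odd_v[, o, i])
      M[i, i] <- M[i, i] + cosine_similarity(all_v[, o, i], all_v[, o, i],
                                             within_day_variability = wdv) / n_odors
      if (i < n_days) for (j in (i + 1):n_days) {
        th <- cosine_similarity(all_v[, o, i], all_v[, o, j]) / n_odors
        M[i, j] <- M[i, j] + th
        M[j, i] <- M[j, i] + th
      }
    }
  }
  M
}

drift_report_from_collection <- function(coll, config, seeds, n_bins,
                                         n_odors, n_days, n_trials) {
  k <- config$k_analysis
  set.seed(seeds["analysis"])
  n_pairs <- min(config$n_across_pairs, choose(n_odors, 2))
  all_pairs <- t(utils::combn(n_odors, 2))
  pairs <- all_pairs[sample.int(nrow(all_pairs), n_pairs), , drop = FALSE]

  n_even <- floor(n_trials / 2); n_odd <- ceiling(n_trials / 2)
  pops <- lapply(names(coll), function(p) {
    cl <- coll[[p]]
    nc <- nrow(cl$esum)
    Xall <- (n_even * cl$esum + n_odd * cl$osum) / n_trials
    eig <- pooled_pca(Xall)
    kk <- min(k, nc)
    # trajectory population vectors: the cells x bins (or components x bins)
    # response flattened into one long vector per (odor, day); the matrices
    # are already stored (bin, odor, day)-major so reshaping is free
    as_traj <- function(M, nr) { dim(M) <- c(nr * n_bins, n_odors, n_days); M }
    fullA <- as_traj(Xall, nc)
    fullE <- as_traj(cl$esum, nc)
    fullO <- as_traj(cl$osum, nc)
    ZallM <- project_rates(eig, Xall, kk)
    Zall <- as_traj(ZallM, kk)
    Zev <- as_traj(project_rates(eig, cl$esum, kk), kk)
    Zod <- as_traj(project_rates(eig, cl$osum, kk), kk)
    # single-trial population vectors: time-collapsed rate vectors and their
    # reduced-space projections (projection commutes with the time average)
    proj_arr <- function(a) {
      d <- dim(a)
      z <- project_rates(eig, matrix(a, d[1]), kk)
      array(z, c(kk, d[-1]))
    }
    z_tr <- proj_arr(cl$trials)

    traj_max <- matrix(NA_real_, n_odors, n_days)
    Z3 <- project_rates(eig, Xall, min(3, kk))
    for (o in seq_len(n_odors)) for (d in seq_len(n_days)) {
      slab <- (((d - 1) * n_odors) + (o - 1)) * n_bins + seq_len(n_bins)
      traj_max[o, d] <- max_distance_point(Z3[, slab, drop = FALSE])$norm
    }

    dr <- mean(vapply(seq_len(n_odors),
                      function(o) drift_rate(Zall[, o, ]), numeric(1)))
    list(
      population = p,
      eigenvalues = eig$values,
      variance_fraction_k = variance_fraction(eig, kk),
      k = kk,
      within_full_avg = corr_mat_days(fullA, fullE, fullO, n_days, n_odors),
      within_reduced_avg = corr_mat_days(Zall, Zev, Zod, n_days, n_odors),
      within_full_single = single_trial_corr_mat(cl$trials, n_days, n_odors,
                                                 n_trials),
      within_reduced_single = single_trial_corr_mat(z_tr, n_days, n_odors,
                                                    n_trials),
      across_full = across_corr_mat(fullA, pairs, n_days),
      across_reduced = across_corr_mat(Zall, pairs, n_days),
      cosine_reduced = cosine_mat_days(Zall, Zev, Zod, n_days, n_odors),
      drift_rate = dr,
      max_distance_norms = traj_max,
      decode = decode_curves(z_tr, pairs, n_days, n_trials))
  })
  names(pops) <- names(coll)
  rep <- list(populations = pops, odor_pairs = pairs,
              n_days = n_days, n_odors = n_odors, n_trials = n_trials,
              config = config, seeds = seeds)
  class(rep) <- "drift_report"
  rep
}

# day-wise decoding: train on Day-0 single-trial reduced responses of an
# odor pair, test each later day's responses (Day-0 itself is held-out)
decode_curves <- function(z_tr, pairs, n_days, n_trials,
                          train_ratio = 0.9, k = 3, n_repeats = 30) {
  acc <- matrix(NA_real_, n_days, nrow(pairs))
  for (pr in seq_len(nrow(pairs))) {
    a <- pairs[pr, 1]; b <- pairs[pr, 2]
    tx <- t(cbind(z_tr[, a, , 1], z_tr[, b, , 1]))
    ty <- rep(c("a", "b"), each = n_trials)
    for (d in seq_len(n_days)) {
      res <- try({
        if (d == 1) {
          knn_decode(tx, ty, train_ratio, k, n_repeats)
        } else {
          ex <- t(cbind(z_tr[, a, , d], z_tr[, b, , d]))
          knn_decode_cross(tx, ty, ex, ty, train_ratio, k, n_repeats)
        }
      }, silent = TRUE)
      if (!inherits(res, "try-error")) acc[d, pr] <- res
    }
  }
  list(accuracy_by_day = rowMeans(acc, na.rm = TRUE), accuracy = acc,
       train_ratio = train_ratio, k = k)
}

#' @export
print.drift_report <- function(x, ...) {
  cat(sprintf("drift report: %d days x %d odors x %d trials (STDP %s)\n",
              x$n_days, x$n_odors, x$n_trials,
              if (isTRUE(x$stdp_on)) "on" else "off"))
  for (p in names(x$populations)) {
    pp <- x$populations[[p]]
    cat(sprintf(
      "  %s: drift %.2f deg/day | D0-D%d reduced corr %.3f (full %.3f) | var@k%d %.1f%%\n",
      p, pp$drift_rate, x$n_days - 1,
      pp$within_reduced_avg[1, x$n_days], pp$within_full_avg[1, x$n_days],
      pp$k, 100 * pp$variance_fraction_k))
  }
  invisible(x)
}

# --- public experiment drivers --------------------------------------------

#' Run the representational-drift experiment (neurogenesis, no STDP)
#'
#' Simulates `n_days` days: each day the scheduled GC cohort is reshuffled,
#' then every panel odor is presented for `n_trials` noisy trials. Produces
#' the full drift report for the M/T and PC populations: pooled-PCA
#' eigenspaces, within/across-odor correlation matrices (full-ensemble and
#' reduced-space, single-trial and trial-averaged), cosine-similarity
#' matrices, drift rates, trajectory diagnostics and KNN decoding curves.
#'
#' @param config an [experiment_config()] with `stdp_enabled = FALSE`.
#' @return object of class `drift_report`.
#' @export
run_drift_experiment <- function(config = experiment_config()) {
  if (isTRUE(config$stdp_enabled))
    odx_stop("drift experiment runs with stdp_enabled = FALSE",
             "olfdrift_bad_spec")
  config <- resolve_experiment(config, "drift")
  inp <- experiment_inputs(config)
  run_experiment_arm(inp, config, stdp_on = FALSE)
}

#' Run the paired STDP-stabilization experiment
#'
#' Runs two arms with matched build/odor/cohort/noise seeds -- one with the
#' suppression-model STDP acting on abGC-related synapses after every trial,
#' one without -- under repeated daily presentation of the same odor set,
#' and reports the paired drift statistics. The headline quantity is the
#' relative reduction of the PC-population drift rate under STDP.
#'
#' @param config an [experiment_config()].
#' @return object of class `stdp_experiment`: `with_stdp` / `without_stdp`
#'   drift reports, per-population drift rates, and `reduction_pct`.
#' @export
run_stdp_experiment <- function(config = experiment_config()) {
  config <- resolve_experiment(config, "stdp")
  inp <- experiment_inputs(config)
  arm_off <- run_experiment_arm(inp, config, stdp_on = FALSE)
  arm_on <- run_experiment_arm(inp, config, stdp_on = TRUE)
  d_off <- arm_off$populations$PC$drift_rate
  d_on <- arm_on$populations$PC$drift_rate
  out <- list(with_stdp = arm_on, without_stdp = arm_off,
              drift_rate = list(
                PC = c(with_stdp = d_on, without_stdp = d_off),
                MT = c(with_stdp = arm_on$populations$MT$drift_rate,
                       without_stdp = arm_off$populations$MT$drift_rate)),
              reduction_pct = 100 * (d_off - d_on) / d_off,
              config = config)
  class(out) <- "stdp_experiment"
  out
}

#' @export
print.stdp_experiment <- function(x, ...) {
  cat("STDP stabilization experiment (paired arms)\n")
  cat(sprintf("  PC drift: %.2f deg/day without STDP, %.2f with STDP (%.1f%% reduction)\n",
              x$drift_rate$PC["without_stdp"], x$drift_rate$PC["with_stdp"],
              x$reduction_pct))
  cat(sprintf("  MT drift: %.2f deg/day without STDP, %.2f with STDP\n",
              x$drift_rate$MT["without_stdp"], x$drift_rate$MT["with_stdp"]))
  invisible(x)
}

#' Serialize a drift report to JSON + CSV matrices
#'
#' Writes `report.json` (scalars, decoding curves, dissimilarity trace) and
#' one CSV per day-by-day matrix into `dir`.
#'
#' @param report a `drift_report`.
#' @param dir output directory.
#' @export
write_drift_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scal <- list(n_days = report$n_days, n_odors = report$n_odors,
               n_trials = report$n_trials, stdp_on = report$stdp_on,
               seed = report$config$seed,
               weight_dissimilarity = report$weight_dissimilarity)
  for (p in names(report$populations)) {
    pp <- report$populations[[p]]
    scal[[paste0(p, "_drift_rate_deg_per_day")]] <- pp$drift_rate
    scal[[paste0(p, "_variance_fraction_k", pp$k)]] <- pp$variance_fraction_k
    scal[[paste0(p, "_decode_accuracy_by_day")]] <- pp$decode$accuracy_by_day
    for (m in c("within_full_avg", "within_reduced_avg", "within_full_single",
                "within_reduced_single", "across_full", "across_reduced",
                "cosine_reduced")) {
      write.csv(pp[[m]], file.path(dir, sprintf("%s_%s.csv", p, m)),
                row.names = FALSE)
    }
  }
  jsonlite::write_json(scal, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
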