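# --- neurogenesis: daily granule-cell weight reshuffling -------------------

#' Select the daily neurogenesis cohorts
#'
#' Partitions (or samples) the granule cells into per-day reshuffle cohorts
#' of `round(fraction * n_gc)` cells. Under `without_replacement` (default)
#' the cohorts are pairwise disjoint, so after `1 / fraction` reshuffle days
#' every GC has been replaced exactly once.
#'
#' @param n_gc number of granule cells.
#' @param fraction fraction reshuffled per day (default 0.1).
#' @param n_reshuffle_days number of reshuffling days (default 10; day 0 is
#'   the unperturbed baseline).
#' @param policy cohort sampling policy.
#' @return list of integer index vectors, one per reshuffle day.
#' @export
select_cohorts <- function(n_gc, fraction = 0.1, n_reshuffle_days = 10,
                           policy = c("without_replacement",
                                      "with_replacement")) {
  policy <- match.arg(policy)
  size <- round(fraction * n_gc)
  if (size < 1)
    odx_stop("cohort size rounds to zero", "olfdrift_bad_schedule")
  if (policy == "without_replacement") {
    if (size * n_reshuffle_days > n_gc)
      odx_stop("fraction x days exceeds 1 under without_replacement",
               "olfdrift_bad_schedule")
    perm <- sample.int(n_gc)
    lapply(seq_len(n_reshuffle_days),
           function(d) sort(perm[((d - 1) * size + 1):(d * size)]))
  } else {
    lapply(seq_len(n_reshuffle_days),
           function(d) sort(sample.int(n_gc, size)))
  }
}

# per-entry row / column indices of a CSC matrix, aligned with W@x
entry_rows <- function(W) W@i + 1L
entry_cols <- function(W) rep.int(seq_len(ncol(W)), diff(W@p))

# Replace a set of entries of a sparse block: `drop` flags entries (aligned
# with W@x) to remove; (new_i, new_j, new_x) are appended.  Vectors aligned
# with the old value slot (delays, per-synapse STDP parameters) are carried
# through: kept entries keep their values, new entries take `aligned_new`.
replace_entries <- function(W, drop, new_i, new_j, new_x,
                            aligned_old = list(), aligned_new = list()) {
  keep <- !drop
  i0 <- entry_rows(W)[keep]
  j0 <- entry_cols(W)[keep]
  x0 <- W@x[keep]
  ii <- c(i0, new_i); jj <- c(j0, new_j); xx <- c(x0, new_x)
  ord <- order(jj, ii)  # CSC storage order of the rebuilt matrix
  W2 <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = dim(W))
  aligned <- if (length(aligned_old)) {
    mapply(function(o, n) c(o[keep], n)[ord], aligned_old, aligned_new,
           SIMPLIFY = FALSE)
  } else list()
  list(W = W2, aligned = aligned)
}

draw_subblock <- function(rows, cols, density, mean_strength,
                          exclude_diag_map = FALSE) {
  tr <- sample_block_triplets(length(rows), length(cols), density)
  i <- rows[tr$i]; j <- cols[tr$j]
  x <- runif(length(i), 0, 2 * abs(mean_strength)) * sign(mean_strength)
  if (exclude_diag_map) {
    keep <- i != j
    i <- i[keep]; j <- j[keep]; x <- x[keep]
  }
  list(i = i, j = j, x = x)
}

#' Reshuffle the synaptic weights of a granule-cell cohort
#'
#' Implements one day of adult neurogenesis: every GC in `cohort` is
#' replaced by an adult-born GC whose synapses are redrawn from the same
#' distributions used to build the network -- its MC->GC afferents (with
#' fresh delays), its GC->MC efferents, its GC<->GC lateral connections and
#' its PC->GC feedback afferents. Synapses not touching the cohort are
#' left bit-identical, so the global weight distribution is preserved while
#' individual values (and connectivity) change.
#'
#' @param net an `olf_network`.
#' @param cohort integer GC indices to reshuffle.
#' @param registry optional [abgc_registry()]; updated with the cohort's
#'   birth day and fresh per-synapse STDP parameters for the new synapses.
#' @param day simulation day recorded as the cohort's birth day.
#' @return list with elements `network` and `registry`.
#' @export
reshuffle_granule_cells <- function(net, cohort, registry = NULL, day = 0L) {
  s <- net$spec; rules <- net$rules
  C <- sort(unique(as.integer(cohort)))
  if (length(C) && (min(C) < 1 || max(C) > s$n_gc))
    odx_stop("cohort indices out of range", "olfdrift_bad_schedule")
  inC <- logical(s$n_gc); inC[C] <- TRUE
  with_params <- !is.null(registry)

  aligned_for <- function(block, drop, n_new) {
    old <- list(); new <- list()
    if (block == "mtgc") {
      old$delay <- net$delays_mtgc
      new$delay <- draw_mtgc_delays(n_new, net$delay_range_ms)
    }
    if (with_params) {
      old <- c(old, registry$params[[block]])
      new <- c(new, draw_stdp_params(n_new))
    }
    list(old = old, new = new)
  }
  store <- function(block, rep) {
    net$blocks[[block]] <<- rep$W
    al <- rep$aligned
    if (block == "mtgc") {
      net$delays_mtgc <<- as.integer(al$delay)
      al$delay <- NULL
    }
    if (with_params) registry$params[[block]] <<- al
  }

  # MC->GC afferents of the cohort (rows in C)
  ru <- rule_for(rules, "mtgc")
  W <- net$blocks$mtgc
  nb <- draw_subblock(C, seq_len(s$n_mt), ru$density, ru$effective_mean)
  al <- aligned_for("mtgc", NULL, length(nb$i))
  store("mtgc", replace_entries(W, inC[entry_rows(W)], nb$i, nb$j, nb$x,
                                al$old, al$new))

  # GC->MC efferents (columns in C)
  ru <- rule_for(rules, "gcmc")
  W <- net$blocks$gcmc
  nb <- draw_subblock(seq_len(s$n_mt), C, ru$density, ru$effective_mean)
  al <- aligned_for("gcmc", NULL, length(nb$i))
  store("gcmc", replace_entries(W, inC[entry_cols(W)], nb$i, nb$j, nb$x,
                                al$old, al$new))

  # GC<->GC lateral connections (rows in C, plus columns in C)
  ru <- rule_for(rules, "gcgc")
  W <- net$blocks$gcgc
  drop <- inC[entry_rows(W)] | inC[entry_cols(W)]
  nb1 <- draw_subblock(C, seq_len(s$n_gc), ru$density, ru$effective_mean,
                       exclude_diag_map = TRUE)
  rest <- which(!inC)
  nb2 <- if (length(rest)) {
    draw_subblock(rest, C, ru$density, ru$effective_mean)
  } else list(i = integer(0), j = integer(0), x = numeric(0))
  nb <- list(i = c(nb1$i, nb2$i), j = c(nb1$j, nb2$j), x = c(nb1$x, nb2$x))
  al <- aligned_for("gcgc", NULL, length(nb$i))
  store("gcgc", replace_entries(W, drop, nb$i, nb$j, nb$x, al$old, al$new))

  # PC->GC feedback afferents (rows in C), rebuilt with the structured rule
  # using the cohort's new reciprocal partners
  if (net$feedback_on) {
    W <- net$blocks$fb
    fbC <- build_feedback_block(s, rules, net$blocks, net$pc_primary_glom,
                                gc_rows = C)
    Tn <- as(fbC, "TsparseMatrix")
    al <- aligned_for("fb", NULL, length(Tn@x))
    store("fb", replace_entries(W, inC[entry_rows(W)],
                                Tn@i + 1L, Tn@j + 1L, Tn@x, al$old, al$new))
  }

  if (with_params) registry$birth_day[C] <- as.integer(day)
  list(network = net, registry = registry)
}

# --- suppression-model STDP ------------------------------------------------

#' Per-synapse STDP parameter draws
#'
#' `A+ ~ N(1.03, 0.1)` clipped positive, `A- ~ N(-0.51, 0.01)` clipped
#' negative, `tau+ ~ N(13.3, 1.7)` ms and `tau- ~ N(34.5, 1.6)` ms clipped
#' positive; one independent draw per synapse.
#'
#' @param n number of synapses.
#' @return list of numeric vectors `Ap`, `Am`, `Tp`, `Tm`.
#' @export
draw_stdp_params <- function(n) {
  list(Ap = pmax(rnorm(n, 1.03, 0.1), 1e-6),
       Am = pmin(rnorm(n, -0.51, 0.01), -1e-6),
       Tp = pmax(rnorm(n, 13.3, 1.7), 0.5),
       Tm = pmax(rnorm(n, 34.5, 1.6), 0.5))
}

STDP_BLOCKS <- c("mtgc", "gcmc", "gcgc", "fb")

#' Adult-born granule cell registry
#'
#' Tracks which GCs have gone through neurogenesis (`birth_day`, -1 = never
#' reshuffled) and holds the per-synapse STDP parameters for the four
#' STDP-eligible blocks, aligned with each block's sparse value slot. STDP
#' acts only on synapses touching an adult-born GC: those *onto* abGCs from
#' M/T cells, other GCs/SACs and PCs, and those *from* abGCs onto M/T cells
#' and other GCs/SACs.
#'
#' @param net an `olf_network`.
#' @param tau_s_pre_ms,tau_s_post_ms suppression time constants for pre- and
#'   postsynaptic spike efficacies (ms).
#' @return object of class `abgc_registry`.
#' @export
abgc_registry <- function(net, tau_s_pre_ms = 34, tau_s_post_ms = 75) {
  params <- lapply(STDP_BLOCKS,
                   function(b) draw_stdp_params(length(net$blocks[[b]]@x)))
  names(params) <- STDP_BLOCKS
  reg <- list(birth_day = rep(-1L, net$spec$n_gc), params = params,
              tau_s_pre_ms = tau_s_pre_ms, tau_s_post_ms = tau_s_post_ms)
  class(reg) <- "abgc_registry"
  reg
}

#' Spike efficacies of the suppression model
#'
#' The i-th spike of a train carries efficacy
#' `eps_i = 1 - exp(-(t_i - t_{i-1}) / tau_s)`; the first spike of the
#' train (no predecessor) has efficacy 1. Efficacies always lie in
#' \[0, 1\]: rapid bursts are suppressed, isolated spikes act fully.
#'
#' @param train increasing spike times (ms).
#' @param tau_s suppression time constant (ms).
#' @return numeric vector of efficacies.
#' @export
spike_efficacy <- function(train, tau_s) {
  if (is.unsorted(train, strictly = FALSE))
    odx_stop("spike train must be sorted ascending", "olfdrift_unsorted_train")
  if (!length(train)) return(numeric(0))
  c(1, 1 - exp(-diff(train) / tau_s))
}

#' Asymmetric exponential STDP window
#'
#' `F(dt) = A+ exp(-|dt| / tau+)` for `dt > 0` (pre leads post:
#' potentiation), `A- exp(-|dt| / tau-)` for `dt < 0` (depression), and 0 at
#' `dt = 0` (simultaneous spikes contribute nothing).
#'
#' @param delta_t `t_post - t_pre` (ms); vectorized.
#' @param A_plus,A_minus scaling factors (positive / negative).
#' @param tau_plus,tau_minus window time constants (ms).
#' @return numeric vector.
#' @export
stdp_window <- function(delta_t, A_plus = 1.03, A_minus = -0.51,
                        tau_plus = 13.3, tau_minus = 34.5) {
  out <- numeric(length(delta_t))
  pos <- delta_t > 0
  neg <- delta_t < 0
  out[pos] <- A_plus * exp(-abs(delta_t[pos]) / tau_plus)
  out[neg] <- A_minus * exp(-abs(delta_t[neg]) / tau_minus)
  out
}

# CSR-style spike-train pack for one population: offsets into time/efficacy
# arrays, one slot per cell; cells of a population are globally contiguous
train_pack <- function(raster, first_cell, n_cells, tau_s) {
  sel <- raster$spike_cell >= first_cell &
         raster$spike_cell < first_cell + n_cells
  cell <- raster$spike_cell[sel] - first_cell + 1L
  tm <- raster$spike_time[sel]
  ord <- order(cell, tm)
  cell <- cell[ord]; tm <- tm[ord]
  e <- if (length(tm)) {
    d <- c(NA_real_, diff(tm))
    first <- c(TRUE, cell[-1] != cell[-length(cell)])
    ee <- 1 - exp(-d / tau_s)
    ee[first] <- 1
    ee
  } else numeric(0)
  cnt <- tabulate(cell, nbins = n_cells)
  list(off = as.integer(c(0L, cumsum(cnt))), t = as.integer(tm), e = e)
}

#' Apply one trial's STDP update to the abGC-related synapses
#'
#' For every synapse in the plastic set (see [abgc_registry()]), the weight
#' change is `learning_rate x sum over all pre/post spike pairs of
#' eps_pre * eps_post * F(t_post - t_pre)`, applied once at trial end.
#' Excitatory weights are clipped to \[0, w_cap\]; inhibitory updates act on
#' the magnitude and are clipped to \[-w_cap, 0\], so no synapse changes
#' sign. Per block, `learning_rate = lr_scale x |mean strength|` and
#' `w_cap = cap_scale x |mean strength|`.
#'
#' @param net an `olf_network`.
#' @param registry an [abgc_registry()].
#' @param raster the completed trial's `spike_raster`.
#' @param lr_scale learning-rate scale relative to block mean strength.
#' @param cap_scale weight cap relative to block mean strength.
#' @param in_place update the weight vectors of `net` in place instead of
#'   copying them. Only safe when no other R object shares those vectors
#'   (the experiment drivers duplicate the plastic blocks once per arm and
#'   then use this fast path); the default keeps functional semantics.
#' @param inhibitory_update how the additive update acts on inhibitory
#'   synapses: `"magnitude"` (potentiation strengthens inhibition) or
#'   `"signed"` (the signed weight moves toward zero under potentiation);
#'   both clip to `[-w_cap, 0]`.
#' @return the updated `olf_network`.
#' @export
apply_stdp <- function(net, registry, raster, lr_scale = 0.01,
                       cap_scale = 4, in_place = FALSE,
                       inhibitory_update = c("magnitude", "signed")) {
  inhibitory_update <- match.arg(inhibitory_update)
  abgc <- registry$birth_day >= 0L
  if (!any(abgc)) return(net)
  s <- net$spec
  off <- c(MT = 1L, GC = s$n_mt + 1L, PC = s$n_mt + s$n_gc + 1L)
  n <- c(MT = s$n_mt, GC = s$n_gc, PC = s$n_pc)
  tpre <- registry$tau_s_pre_ms; tpos <- registry$tau_s_post_ms
  pre <- list(MT = train_pack(raster, off["MT"], n["MT"], tpre),
              GC = train_pack(raster, off["GC"], n["GC"], tpre),
              PC = train_pack(raster, off["PC"], n["PC"], tpre))
  pos <- list(MT = train_pack(raster, off["MT"], n["MT"], tpos),
              GC = train_pack(raster, off["GC"], n["GC"], tpos))
  none <- function(k) rep(FALSE, k)
  conf <- list(
    mtgc = list(pre = pre$MT, pos = pos$GC, ppre = none(s$n_mt), ppos = abgc,
                rule = "mtgc"),
    gcmc = list(pre = pre$GC, pos = pos$MT, ppre = abgc, ppos = none(s$n_mt),
                rule = "gcmc"),
    gcgc = list(pre = pre$GC, pos = pos$GC, ppre = abgc, ppos = abgc,
                rule = "gcgc"),
    fb   = list(pre = pre$PC, pos = pos$GC, ppre = none(s$n_pc), ppos = abgc,
                rule = "pcgc"))
  for (b in STDP_BLOCKS) {
    W <- net$blocks[[b]]
    if (!length(W@x)) next
    cf <- conf[[b]]
    eff <- rule_for(net$rules, cf$rule)$effective_mean
    pp <- registry$params[[b]]
    mode <- if (eff >= 0) 0L else if (inhibitory_update == "magnitude") 1L else 2L
    newx <- stdp_block_cpp(W, pp$Ap, pp$Am, pp$Tp, pp$Tm,
                           cf$ppre, cf$ppos,
                           cf$pre$off, cf$pre$t, cf$pre$e,
                           cf$pos$off, cf$pos$t, cf$pos$e,
                           lr_scale * abs(eff), cap_scale * abs(eff),
                           mode, in_place)
    if (!in_place) net$blocks[[b]]@x <- newx
  }
  net
}

#' Look up one synaptic weight
#'
#' @param net an `olf_network`.
#' @param block block name (e.g. `"mtgc"`).
#' @param i,j postsynaptic row / presynaptic column index.
#' @return the weight (0 if the synapse is absent).
#' @export
synapse_weight <- function(net, block, i, j) {
  as.numeric(net$blocks[[block]][i, j])
}
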