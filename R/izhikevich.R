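#' Draw heterogeneous Izhikevich parameters for one cell type
#'
#' Each cell gets one uniform random draw `r` in \[0, 1\] from which its
#' Izhikevich parameters (a, b, c, d) are computed:
#' \describe{
#'   \item{MT}{a = 0.1 - 0.08 r^4, b = 0.2, c = -65, d = 2 + 6 r^4
#'     (regular-spiking to chattering excitatory cells)}
#'   \item{GC, FFI_FBI}{a = 0.1 - 0.08 r^2, b = 0.2, c = -65 + 15 r^2, d = 2
#'     (fast-spiking / low-threshold-spiking interneurons)}
#'   \item{PC}{a = 0.02 + 0.08 r, b = 0.2, c = -65, d = 8 - 6 r}
#' }
#'
#' @param cell_type one of `"MT"`, `"GC"`, `"PC"`, `"FFI_FBI"`.
#' @param n number of cells.
#' @return list of class `izhikevich_params` with numeric fields
#'   `a`, `b`, `c`, `d`, `r` (length `n`).
#' @export
draw_izhikevich_params <- function(cell_type, n) {
  if (n < 1) odx_stop("n must be >= 1", "olfdrift_bad_spec")
  types <- c("MT", "GC", "PC", "FFI_FBI")
  if (length(cell_type) != 1 || !cell_type %in% types)
    odx_stop(sprintf("unknown cell_type '%s' (expected one of %s)",
                     paste(cell_type, collapse = ","),
                     paste(types, collapse = ", ")),
             "olfdrift_unknown_cell_type")
  r <- runif(n)
  p <- switch(cell_type,
    MT = list(a = 0.1 - 0.08 * r^4, c = rep(-65, n), d = 2 + 6 * r^4),
    GC = ,
    FFI_FBI = list(a = 0.1 - 0.08 * r^2, c = -65 + 15 * r^2, d = rep(2, n)),
    PC = list(a = 0.02 + 0.08 * r, c = rep(-65, n), d = 8 - 6 * r))
  out <- list(a = p$a, b = rep(0.2, n), c = p$c, d = p$d, r = r,
              cell_type = cell_type)
  class(out) <- "izhikevich_params"
  out
}

#' Draw Izhikevich parameters for every cell of a network
#'
#' Populations are drawn in the fixed order MT, GC, PC, FFI, FBI so that the
#' result is a deterministic function of the RNG state.
#'
#' @param spec a [population_spec()].
#' @return list of class `olf_cell_params` with per-cell vectors `a`, `b`,
#'   `c`, `d` over the global cell ordering, plus the population factor.
#' @export
network_params <- function(spec) {
  lay <- pop_layout(spec)
  draws <- list(
    MT  = draw_izhikevich_params("MT", spec$n_mt),
    GC  = draw_izhikevich_params("GC", spec$n_gc),
    PC  = draw_izhikevich_params("PC", spec$n_pc),
    FFI = draw_izhikevich_params("FFI_FBI", spec$n_ffi),
    FBI = draw_izhikevich_params("FFI_FBI", spec$n_fbi))
  out <- list(
    a = unlist(lapply(draws, `[[`, "a"), use.names = FALSE),
    b = unlist(lapply(draws, `[[`, "b"), use.names = FALSE),
    c = unlist(lapply(draws, `[[`, "c"), use.names = FALSE),
    d = unlist(lapply(draws, `[[`, "d"), use.names = FALSE),
    pop = lay$pop, layout = lay)
  class(out) <- "olf_cell_params"
  out
}

#' One forward-Euler step of the Izhikevich neuron
#'
#' Advances `dv/dt = 0.04 v^2 + 5 v + 140 - u + I`, `du/dt = a (b v - u)` by
#' `dt` ms. The voltage is advanced in `n_substeps` equal sub-steps (the
#' standard stabilization for this model); the recovery variable `u` is
#' advanced once using the step-start voltage. If the entry voltage already
#' satisfies the spike condition `v >= 30` mV, the after-spike reset
#' `v <- c`, `u <- u + d` is applied instead and a spike is flagged.
#'
#' All arguments are vectorized over cells.
#'
#' @param v,u membrane voltage (mV) and recovery variable.
#' @param I total input current.
#' @param a,b,c,d Izhikevich parameters.
#' @param dt time step in ms.
#' @param n_substeps voltage sub-steps per `dt` (1 = plain Euler).
#' @return list with updated `v`, `u` and logical `spiked`.
#' @export
izhikevich_step <- function(v, u, I, a, b = 0.2, c = -65, d = 2,
                            dt = 1, n_substeps = 2) {
  if (any(!is.finite(v)) || any(!is.finite(u)))
    odx_stop(sprintf("non-finite state for cell(s) %s",
                     paste(which(!is.finite(v) | !is.finite(u)), collapse = ",")),
             "olfdrift_divergence")
  n <- length(v)
  spiked <- v >= 30
  cc <- rep_len(c, n); dd <- rep_len(d, n)
  v_out <- v; u_out <- u
  idx <- !spiked
  if (any(idx)) {
    vv <- v[idx]; uu <- u[idx]
    II <- rep_len(I, n)[idx]; aa <- rep_len(a, n)[idx]; bb <- rep_len(b, n)[idx]
    v0 <- vv
    h <- dt / n_substeps
    for (s in seq_len(n_substeps))
      vv <- vv + h * (0.04 * vv^2 + 5 * vv + 140 - uu + II)
    uu <- uu + dt * aa * (bb * v0 - uu)
    v_out[idx] <- vv; u_out[idx] <- uu
  }
  v_out[spiked] <- cc[spiked]
  u_out[spiked] <- u[spiked] + dd[spiked]
  list(v = v_out, u = u_out, spiked = spiked)
}
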