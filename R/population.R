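#' Cell-population specification for the MOB--PCx network
#'
#' Defines the sizes of the five cell populations. The default corresponds to
#' the full-scale model: 50 glomeruli each driving 25 mitral/tufted (M/T)
#' cells (1250 M/T), 12,500 granule cells (GC), 10,000 piriform cells (PC),
#' and 1250 each of feedforward (FFI) and feedback (FBI) inhibitory
#' interneurons in PCx.
#'
#' @param n_glomeruli number of glomeruli (input channels).
#' @param mt_per_glomerulus M/T cells driven by each glomerulus.
#' @param n_gc number of granule cells.
#' @param n_pc number of piriform pyramidal cells.
#' @param n_ffi,n_fbi numbers of PCx feedforward / feedback interneurons.
#' @param scale_factor nominal uniform shrink factor relative to the
#'   full-scale model (metadata; 1 for full scale, 0.1 for the mini preset).
#' @return an object of class `population_spec`.
#' @seealso [mini_population_spec()]
#' @export
population_spec <- function(n_glomeruli = 50, mt_per_glomerulus = 25,
                            n_gc = 12500, n_pc = 10000,
                            n_ffi = 1250, n_fbi = 1250,
                            scale_factor = 1) {
  counts <- c(n_glomeruli, mt_per_glomerulus, n_gc, n_pc, n_ffi, n_fbi)
  if (any(counts < 1) || any(counts != round(counts)))
    odx_stop("all population counts must be integers >= 1", "olfdrift_bad_spec")
  spec <- list(
    n_glomeruli = as.integer(n_glomeruli),
    mt_per_glomerulus = as.integer(mt_per_glomerulus),
    n_mt = as.integer(n_glomeruli * mt_per_glomerulus),
    n_gc = as.integer(n_gc), n_pc = as.integer(n_pc),
    n_ffi = as.integer(n_ffi), n_fbi = as.integer(n_fbi),
    scale_factor = scale_factor)
  class(spec) <- "population_spec"
  spec
}

#' Mini (1/10-scale) population preset
#'
#' 10 glomeruli x 10 M/T cells, 1000 GCs, 800 PCs, 100 FFIs and 100 FBIs.
#' Connection densities are kept at their full-scale values; mean synaptic
#' strengths are rescaled by default so that the expected summed synaptic
#' input per cell matches the full-scale model (see
#' [default_connectivity_rules()]).
#'
#' @return a `population_spec`.
#' @export
mini_population_spec <- function() {
  population_spec(n_glomeruli = 10, mt_per_glomerulus = 10,
                  n_gc = 1000, n_pc = 800, n_ffi = 100, n_fbi = 100,
                  scale_factor = 0.1)
}

# global cell ordering: MT, GC, PC, FFI, FBI (0-based offsets for the engine)
pop_layout <- function(spec) {
  n <- c(MT = spec$n_mt, GC = spec$n_gc, PC = spec$n_pc,
         FFI = spec$n_ffi, FBI = spec$n_fbi)
  off <- cumsum(c(0, n))[1:5]
  names(off) <- names(n)
  list(n = n, offset = off, total = sum(n),
       pop = factor(rep(names(n), n), levels = names(n)))
}

#' Glomerulus index of each M/T cell
#'
#' M/T cells are laid out contiguously by glomerulus: cells
#' `1..mt_per_glomerulus` belong to glomerulus 1, and so on.
#'
#' @param spec a [population_spec()].
#' @return integer vector of length `n_mt`.
#' @export
mt_glomerulus_map <- function(spec) {
  rep(seq_len(spec$n_glomeruli), each = spec$mt_per_glomerulus)
}

#' @export
print.population_spec <- function(x, ...) {
  cat("MOB-PCx population spec:\n")
  cat(sprintf("  %d glomeruli x %d M/T = %d M/T cells; %d GCs\n",
              x$n_glomeruli, x$mt_per_glomerulus, x$n_mt, x$n_gc))
  cat(sprintf("  %d PCs, %d FFIs, %d FBIs (scale factor %g)\n",
              x$n_pc, x$n_ffi, x$n_fbi, x$scale_factor))
  invisible(x)
}
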