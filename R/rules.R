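ALL_BLOCKS <- c("mtmt_same", "mtmt_diff", "mtgc", "gcmc", "gcgc",
                "mtpc", "mtffi", "pcgc", "pcpc", "ffipc", "fbipc",
                "ffiffi", "pcfbi", "fbifbi")

# presynaptic pool size feeding one postsynaptic cell, per block
block_pre_pool <- function(spec) {
  c(mtmt_same = spec$mt_per_glomerulus - 1,  # no autapses
    mtmt_diff = spec$n_mt - spec$mt_per_glomerulus,
    mtgc = spec$n_mt, gcmc = spec$n_gc, gcgc = spec$n_gc - 1,
    mtpc = spec$n_mt, mtffi = spec$n_mt, pcgc = spec$n_pc,
    pcpc = spec$n_pc - 1, ffipc = spec$n_ffi, fbipc = spec$n_fbi,
    ffiffi = spec$n_ffi - 1, pcfbi = spec$n_pc, fbifbi = spec$n_fbi - 1)
}

#' Connectivity rules between cell types
#'
#' One row per synaptic block: connection density (fraction of nonzero
#' weights) and average synaptic strength (mean of the uniform distribution
#' from which individual weight magnitudes are drawn; the sign marks the
#' block excitatory or inhibitory). The default values are those of the
#' full-scale model. M/T cells driven by different glomeruli are never
#' connected (`mtmt_diff` density 0).
#'
#' When `preserve_input_scale` is `TRUE` (default) each block's
#' `effective_mean` is the tabled mean multiplied by the ratio of the
#' full-scale presynaptic pool size to `spec`'s pool size, so that the
#' expected summed synaptic drive per cell (density x pool x mean) is
#' invariant under population down-scaling. At full scale the multiplier is
#' exactly 1.
#'
#' @param spec a [population_spec()].
#' @param preserve_input_scale rescale mean strengths for shrunken networks?
#' @return data.frame of class `connectivity_rules` with columns `block`,
#'   `density`, `mean_strength`, `sign`, `effective_mean`.
#' @export
default_connectivity_rules <- function(spec = population_spec(),
                                       preserve_input_scale = TRUE) {
  tbl <- data.frame(
    block = ALL_BLOCKS,
    density = c(0.8, 0, 0.3, 0.02, 0.05, 0.5, 0.2, 0.9,
                0.01, 0.1, 0.8, 0.01, 0.02, 0.02),
    mean_strength = c(0.25, 0, 0.25, -0.4, -0.1, 0.06, 0.2, 0.03,
                      0.1, -0.1, -0.1, -1.0, 0.3, -0.5),
    stringsAsFactors = FALSE)
  tbl$sign <- ifelse(tbl$mean_strength < 0, "inhibitory",
                     ifelse(tbl$mean_strength > 0, "excitatory", "none"))
  mult <- rep(1, nrow(tbl))
  if (preserve_input_scale) {
    ref <- block_pre_pool(population_spec())
    cur <- block_pre_pool(spec)
    mult <- as.numeric(ref[tbl$block] / pmax(cur[tbl$block], 1))
  }
  tbl$effective_mean <- tbl$mean_strength * mult
  class(tbl) <- c("connectivity_rules", "data.frame")
  tbl
}

rule_for <- function(rules, block) {
  i <- match(block, rules$block)
  if (is.na(i))
    odx_stop(sprintf("rules table is missing block '%s'", block),
             "olfdrift_bad_rules")
  as.list(rules[i, ])
}
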