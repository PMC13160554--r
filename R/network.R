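# --- random sparse block construction -------------------------------------

# Bernoulli(density) connectivity realized as a binomial draw of the nonzero
# count followed by uniform placement without replacement (the two are
# distributionally identical and avoid materializing n_post x n_pre draws).
sample_block_triplets <- function(n_post, n_pre, density, exclude_diag = FALSE) {
  N <- as.double(n_post) * as.double(n_pre)
  if (N >= .Machine$integer.max)
    odx_stop("block too large for positional sampling", "olfdrift_bad_spec")
  nnz <- rbinom(1L, as.integer(N), density)
  pos <- if (nnz > 0) sample.int(as.integer(N), nnz) else integer(0)
  i <- (pos - 1L) %% n_post + 1L
  j <- (pos - 1L) %/% n_post + 1L
  if (exclude_diag) {
    keep <- i != j
    i <- i[keep]; j <- j[keep]
  }
  list(i = i, j = j)
}

#' Build one random synaptic weight block
#'
#' Every ordered (post, pre) pair is connected independently with probability
#' `density`; nonzero magnitudes are drawn Uniform(0, 2 |mean_strength|) so
#' that their mean equals `|mean_strength|`, and carry the sign of
#' `mean_strength`.
#'
#' @param n_post,n_pre block dimensions (rows = postsynaptic cells).
#' @param density connection probability in \[0, 1\].
#' @param mean_strength mean signed synaptic strength.
#' @param exclude_diag drop self-connections (square within-population blocks).
#' @return a `dgCMatrix` of dimension `n_post` x `n_pre`.
#' @export
build_weight_block <- function(n_post, n_pre, density, mean_strength,
                               exclude_diag = FALSE) {
  if (!is.finite(density) || density < 0 || density > 1)
    odx_stop("density must lie in [0, 1]", "olfdrift_bad_rules")
  if (density == 0 || mean_strength == 0)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n_post, n_pre)))
  tr <- sample_block_triplets(n_post, n_pre, density, exclude_diag)
  x <- runif(length(tr$i), 0, 2 * abs(mean_strength)) * sign(mean_strength)
  Matrix::sparseMatrix(i = tr$i, j = tr$j, x = x, dims = c(n_post, n_pre))
}

# MC->MC: connected only within a glomerulus (block-diagonal), no autapses
build_mtmt_block <- function(spec, rules) {
  ru <- rule_for(rules, "mtmt_same")
  m <- spec$mt_per_glomerulus
  ti <- tj <- tx <- vector("list", spec$n_glomeruli)
  for (g in seq_len(spec$n_glomeruli)) {
    tr <- sample_block_triplets(m, m, ru$density, exclude_diag = TRUE)
    off <- (g - 1L) * m
    ti[[g]] <- tr$i + off
    tj[[g]] <- tr$j + off
    tx[[g]] <- runif(length(tr$i), 0, 2 * abs(ru$effective_mean))
  }
  Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                       dims = c(spec$n_mt, spec$n_mt))
}

# logical n_mt x n_gc pattern: TRUE where M/T m and GC g are reciprocally
# connected (both MC->GC and GC->MC weights nonzero)
reciprocal_pattern <- function(blocks) {
  a <- blocks$gcmc != 0            # n_mt x n_gc
  b <- Matrix::t(blocks$mtgc != 0) # n_mt x n_gc
  a & b
}

# primary glomerulus of each PC: the glomerulus whose M/T cells provide the
# strongest summed feedforward drive (ties -> lowest index)
pc_primary_glomerulus <- function(spec, mtpc) {
  G <- Matrix::sparseMatrix(i = seq_len(spec$n_mt),
                            j = mt_glomerulus_map(spec), x = 1,
                            dims = c(spec$n_mt, spec$n_glomeruli))
  S <- as.matrix(mtpc %*% G)
  max.col(S, ties.method = "first")
}

# Centrifugal PC->GC feedback: dense but weak, magnitudes Uniform(0.01, 0.05)
# (times the input-scale multiplier), with a glomerulus-crossing structure:
# a PC whose primary feedforward drive comes from glomerulus g projects only
# to GCs NOT reciprocally connected with g's M/T cells.  `gc_rows` restricts
# construction to a subset of GC rows (used when reshuffling cohorts).
build_feedback_block <- function(spec, rules, blocks, pc_primary_glom,
                                 gc_rows = seq_len(spec$n_gc)) {
  ru <- rule_for(rules, "pcgc")
  mult <- ru$effective_mean / ru$mean_strength
  P <- reciprocal_pattern(blocks)
  glom <- mt_glomerulus_map(spec)
  ti <- tj <- tx <- vector("list", spec$n_glomeruli)
  in_rows <- logical(spec$n_gc); in_rows[gc_rows] <- TRUE
  for (g in seq_len(spec$n_glomeruli)) {
    pcs <- which(pc_primary_glom == g)
    if (!length(pcs)) next
    recip <- Matrix::colSums(P[glom == g, , drop = FALSE]) > 0
    elig <- which(in_rows & !recip)
    if (!length(elig)) next
    tr <- sample_block_triplets(length(elig), length(pcs), ru$density)
    ti[[g]] <- elig[tr$i]
    tj[[g]] <- pcs[tr$j]
    tx[[g]] <- runif(length(tr$i), 0.01 * mult, 0.05 * mult)
  }
  Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                       dims = c(spec$n_gc, spec$n_pc))
}

# optionally rewire a fraction of each M/T cell's GC->MC afferents so that
# they originate from that cell's MC->GC out-targets (raises the reciprocal
# partner count diagnostic; 0 = independent sampling)
apply_reciprocity_boost <- function(spec, gcmc, mtgc, fraction) {
  if (fraction <= 0) return(gcmc)
  Tg <- as(gcmc, "TsparseMatrix")
  i <- Tg@i + 1L; j <- Tg@j + 1L; x <- Tg@x
  Tm <- as(mtgc, "TsparseMatrix")
  out_targets <- split(Tm@i + 1L, factor(Tm@j + 1L, levels = seq_len(spec$n_mt)))
  for (m in seq_len(spec$n_mt)) {
    idx <- which(i == m)
    k <- round(fraction * length(idx))
    if (k == 0) next
    pool <- setdiff(out_targets[[m]], j[idx])
    k <- min(k, length(pool))
    if (k == 0) next
    sel <- idx[sample.int(length(idx), k)]
    j[sel] <- sample(pool, k)
  }
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = dim(gcmc))
}

# --- full network assembly -------------------------------------------------

#' Build the full MOB--PCx synaptic weight structure
#'
#' Assembles all synaptic blocks from the connectivity rules: within-MOB
#' weights (MC->MC within glomeruli, MC->GC, GC->MC, GC->GC), the
#' feedforward projection (MC->PC, MC->FFI), the PCx recurrent/inhibitory
#' weights, and the structured centrifugal PC->GC feedback. Each MC->GC
#' synapse additionally carries a transmission delay drawn
#' Uniform(`delay_range_ms`) and ceiled to the 1-ms simulation grid.
#'
#' The result is a deterministic function of the RNG state (set a seed
#' beforehand for reproducible networks).
#'
#' @param spec a [population_spec()].
#' @param rules a [default_connectivity_rules()] table.
#' @param feedback_on logical; when `FALSE` the PC->GC feedback block is the
#'   zero matrix.
#' @param delay_range_ms range of MC->GC synaptic delays (ms).
#' @param reciprocity_boost fraction of each M/T cell's GC afferents rewired
#'   to its GC out-targets (diagnostic option; default 0 = independent
#'   Bernoulli sampling).
#' @return object of class `olf_network`: list with `spec`, `rules`,
#'   `blocks` (13 named sparse blocks), `delays_mtgc` (integer ms aligned
#'   with `blocks$mtgc@x`), `pc_primary_glom`, `feedback_on`.
#' @export
build_network <- function(spec = population_spec(),
                          rules = default_connectivity_rules(spec),
                          feedback_on = TRUE,
                          delay_range_ms = c(0, 25),
                          reciprocity_boost = 0) {
  for (b in ALL_BLOCKS) rule_for(rules, b)  # rules coverage check
  bw <- function(block, n_post, n_pre, excl = FALSE) {
    ru <- rule_for(rules, block)
    build_weight_block(n_post, n_pre, ru$density, ru$effective_mean, excl)
  }
  blocks <- list()
  blocks$mtmt <- build_mtmt_block(spec, rules)
  blocks$mtgc <- bw("mtgc", spec$n_gc, spec$n_mt)
  blocks$gcmc <- bw("gcmc", spec$n_mt, spec$n_gc)
  blocks$gcmc <- apply_reciprocity_boost(spec, blocks$gcmc, blocks$mtgc,
                                         reciprocity_boost)
  blocks$gcgc <- bw("gcgc", spec$n_gc, spec$n_gc, excl = TRUE)
  blocks$mtpc <- bw("mtpc", spec$n_pc, spec$n_mt)
  blocks$mtffi <- bw("mtffi", spec$n_ffi, spec$n_mt)
  blocks$pcpc <- bw("pcpc", spec$n_pc, spec$n_pc, excl = TRUE)
  blocks$ffipc <- bw("ffipc", spec$n_pc, spec$n_ffi)
  blocks$fbipc <- bw("fbipc", spec$n_pc, spec$n_fbi)
  blocks$ffiffi <- bw("ffiffi", spec$n_ffi, spec$n_ffi, excl = TRUE)
  blocks$pcfbi <- bw("pcfbi", spec$n_fbi, spec$n_pc)
  blocks$fbifbi <- bw("fbifbi", spec$n_fbi, spec$n_fbi, excl = TRUE)
  delays <- draw_mtgc_delays(length(blocks$mtgc@x), delay_range_ms)
  pc_primary <- pc_primary_glomerulus(spec, blocks$mtpc)
  blocks$fb <- if (feedback_on) {
    build_feedback_block(spec, rules, blocks, pc_primary)
  } else {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(spec$n_gc, spec$n_pc))
  }
  net <- list(spec = spec, rules = rules, blocks = blocks,
              delays_mtgc = delays, pc_primary_glom = pc_primary,
              feedback_on = feedback_on, delay_range_ms = delay_range_ms)
  class(net) <- "olf_network"
  net
}

draw_mtgc_delays <- function(n, delay_range_ms) {
  as.integer(pmax(1, ceiling(runif(n, delay_range_ms[1], delay_range_ms[2]))))
}

#' @export
print.olf_network <- function(x, ...) {
  cat("MOB-PCx network:", x$spec$n_mt, "M/T,", x$spec$n_gc, "GC,",
      x$spec$n_pc, "PC,", x$spec$n_ffi, "FFI,", x$spec$n_fbi, "FBI\n")
  nnz <- vapply(x$blocks, function(b) length(b@x), numeric(1))
  cat("  nonzero synapses per block:\n")
  print(nnz)
  cat("  centrifugal feedback:", if (x$feedback_on) "ON" else "OFF", "\n")
  invisible(x)
}

# --- composite weight-matrix views ----------------------------------------

zero_block <- function(nr, nc) {
  Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                       dims = c(nr, nc))
}

#' Composite weight matrices
#'
#' Assemble the four composite weight matrices from the stored blocks:
#' `W_mob` (cells ordered M/T then GC), `W_ff` (rows PC then FFI, columns
#' M/T), `W_pcx` (cells ordered PC, FFI, FBI), and `W_fb` (GC rows, PC
#' columns; all-zero when feedback is off). Entry (i, j) is the synaptic
#' strength from presynaptic cell j to postsynaptic cell i.
#'
#' @param net an `olf_network`.
#' @return a `dgCMatrix`.
#' @export
W_mob <- function(net) {
  b <- net$blocks
  rbind(cbind(b$mtmt, b$gcmc), cbind(b$mtgc, b$gcgc))
}

#' @rdname W_mob
#' @export
W_ff <- function(net) rbind(net$blocks$mtpc, net$blocks$mtffi)

#' @rdname W_mob
#' @export
W_pcx <- function(net) {
  b <- net$blocks; s <- net$spec
  rbind(cbind(b$pcpc, b$ffipc, b$fbipc),
        cbind(zero_block(s$n_ffi, s$n_pc), b$ffiffi, zero_block(s$n_ffi, s$n_fbi)),
        cbind(b$pcfbi, zero_block(s$n_fbi, s$n_ffi), b$fbifbi))
}

#' @rdname W_mob
#' @export
W_fb <- function(net) net$blocks$fb

# --- diagnostics -----------------------------------------------------------

#' Reciprocally connected granule cells per M/T cell
#'
#' For each M/T cell, counts the GCs g such that both the MC->GC weight
#' (M/T onto g) and the GC->MC weight (g onto the M/T cell) are nonzero.
#'
#' @param net an `olf_network`.
#' @return integer vector of length `n_mt`.
#' @export
reciprocal_partner_count <- function(net) {
  as.integer(Matrix::rowSums(reciprocal_pattern(net$blocks)))
}

#' PC->GC projection count above a weight threshold
#'
#' Number of GC targets per PC with feedback weight magnitude above
#' `threshold` (diagnostic for the dense-but-weak feedback structure).
#'
#' @param net an `olf_network`.
#' @param threshold weight magnitude cutoff.
#' @return integer vector of length `n_pc`.
#' @export
pc_projection_count <- function(net, threshold = 0.01) {
  as.integer(Matrix::colSums(abs(net$blocks$fb) > threshold))
}

gc_weight_blocks <- function(w) {
  if (inherits(w, "olf_network"))
    return(w$blocks[c("mtgc", "gcmc", "gcgc", "fb")])
  if (is.list(w)) return(lapply(w, function(m) as(m, "CsparseMatrix")))
  list(as(w, "CsparseMatrix"))
}

#' Weight-matrix dissimilarity
#'
#' One minus the Pearson correlation of the flattened granule-cell-related
#' weight entries (MC->GC, GC->MC, GC->GC and PC->GC blocks, zeros
#' included), used to track how far daily neurogenesis has moved the
#' weights from a reference day. Identical networks give 0; two fully
#' independent redraws give a value near the independent-sampling plateau.
#'
#' @param w_a,w_b two `olf_network` objects (or lists of sparse blocks with
#'   matching shapes).
#' @return numeric in \[0, 2\].
#' @export
weight_dissimilarity <- function(w_a, w_b) {
  ga <- gc_weight_blocks(w_a); gb <- gc_weight_blocks(w_b)
  if (length(ga) != length(gb) ||
      !all(mapply(function(a, b) all(dim(a) == dim(b)), ga, gb)))
    odx_stop("weight structures have different shapes", "olfdrift_bad_spec")
  n <- sum(vapply(ga, function(m) prod(dim(m)), numeric(1)))
  sx <- sum(vapply(ga, function(m) sum(m@x), numeric(1)))
  sy <- sum(vapply(gb, function(m) sum(m@x), numeric(1)))
  sxx <- sum(vapply(ga, function(m) sum(m@x^2), numeric(1)))
  syy <- sum(vapply(gb, function(m) sum(m@x^2), numeric(1)))
  sxy <- sum(mapply(function(a, b) sum(a * b), ga, gb))
  va <- sxx - sx^2 / n
  vb <- syy - sy^2 / n
  if (va <= 0 || vb <= 0)
    odx_stop("zero-variance weight vector in dissimilarity", "olfdrift_zero_variance")
  1 - (sxy - sx * sy / n) / sqrt(va * vb)
}

# --- plain-text serialization ----------------------------------------------

#' Write / read a network as plain-text triplet files
#'
#' Each sparse block is stored as a CSV of (row, col, value) triplets, the
#' MC->GC delay array alongside, and a JSON sidecar records the population
#' spec, the connectivity rules and flags.
#'
#' @param net an `olf_network`.
#' @param dir output directory (created if needed).
#' @return `write_network` returns `dir` invisibly; `read_network` returns
#'   the reconstructed `olf_network`.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(net$blocks)) {
    tb <- as(net$blocks[[nm]], "TsparseMatrix")
    df <- data.frame(i = tb@i + 1L, j = tb@j + 1L, x = tb@x)
    if (nm == "mtgc") {
      # delays are aligned with the CSC value slot; Tsparse keeps that order
      df$delay_ms <- net$delays_mtgc
    }
    write.csv(df, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  side <- list(spec = unclass(net$spec),
               rules = as.data.frame(net$rules),
               feedback_on = net$feedback_on,
               delay_range_ms = net$delay_range_ms,
               pc_primary_glom = net$pc_primary_glom)
  jsonlite::write_json(side, file.path(dir, "network.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_network
#' @export
read_network <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "network.json"),
                              simplifyVector = TRUE)
  spec <- do.call(population_spec, side$spec[c("n_glomeruli",
    "mt_per_glomerulus", "n_gc", "n_pc", "n_ffi", "n_fbi", "scale_factor")])
  rules <- side$rules
  class(rules) <- c("connectivity_rules", "data.frame")
  dims <- network_block_dims(spec)
  blocks <- list()
  delays <- NULL
  for (nm in names(dims)) {
    df <- read.csv(file.path(dir, paste0(nm, ".csv")))
    blocks[[nm]] <- Matrix::sparseMatrix(i = as.integer(df$i),
                                         j = as.integer(df$j),
                                         x = as.numeric(df$x),
                                         dims = dims[[nm]])
    if (nm == "mtgc") {
      ord <- order(df$j, df$i)
      delays <- as.integer(df$delay_ms[ord])
    }
  }
  net <- list(spec = spec, rules = rules, blocks = blocks,
              delays_mtgc = delays,
              pc_primary_glom = side$pc_primary_glom,
              feedback_on = side$feedback_on,
              delay_range_ms = side$delay_range_ms)
  class(net) <- "olf_network"
  net
}

network_block_dims <- function(s) {
  list(mtmt = c(s$n_mt, s$n_mt), mtgc = c(s$n_gc, s$n_mt),
       gcmc = c(s$n_mt, s$n_gc), gcgc = c(s$n_gc, s$n_gc),
       mtpc = c(s$n_pc, s$n_mt), mtffi = c(s$n_ffi, s$n_mt),
       pcpc = c(s$n_pc, s$n_pc), ffipc = c(s$n_pc, s$n_ffi),
       fbipc = c(s$n_pc, s$n_fbi), ffiffi = c(s$n_ffi, s$n_ffi),
       pcfbi = c(s$n_fbi, s$n_pc), fbifbi = c(s$n_fbi, s$n_fbi),
       fb = c(s$n_gc, s$n_pc))
}
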