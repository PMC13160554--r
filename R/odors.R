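# --- model odors -----------------------------------------------------------

#' Generate one model odor
#'
#' A model odor activates between 6% and 20% of the glomeruli (3--10 of 50
#' at full scale), each with its own onset latency; the glomerular input is
#' a 90-ms step. Latencies are drawn Uniform(`latency_range_ms`) so that the
#' step always ends inside the 250-ms sniff window.
#'
#' @param n_glomeruli number of glomeruli in the model.
#' @param duration_ms step duration (ms).
#' @param latency_range_ms range of onset latencies (ms).
#' @param frac_range activated fraction bounds.
#' @return object of class `odor`: `glomerulus_ids`, `onset_latency_ms`
#'   (aligned with the ids), `duration_ms`, `amplitude` (`NULL` = use the
#'   simulator config's `osn_amplitude`).
#' @export
generate_odor <- function(n_glomeruli = 50, duration_ms = 90,
                          latency_range_ms = c(0, 160),
                          frac_range = c(0.06, 0.2)) {
  lo <- max(1L, ceiling(frac_range[1] * n_glomeruli))
  hi <- max(lo, floor(frac_range[2] * n_glomeruli))
  k <- if (lo == hi) lo else sample(seq.int(lo, hi), 1L)
  ids <- sort(sample.int(n_glomeruli, k))
  lat <- runif(k, latency_range_ms[1], latency_range_ms[2])
  odor <- list(glomerulus_ids = ids, onset_latency_ms = lat,
               duration_ms = duration_ms, amplitude = NULL,
               n_glomeruli = as.integer(n_glomeruli))
  class(odor) <- "odor"
  odor
}

#' Generate the model-odor panel
#'
#' `n` odors over `n_glomeruli` glomeruli. A fraction `similarity_mix` of
#' odors (after the first) are jittered variants of a randomly chosen
#' earlier odor -- same glomerulus set, latencies perturbed by Gaussian
#' jitter -- so that pairwise odor similarities span low to high; pure
#' independent draws would give only low similarity.
#'
#' @param n panel size (default 100).
#' @param n_glomeruli number of glomeruli.
#' @param similarity_mix fraction of jittered-variant odors.
#' @param jitter_sd_ms latency jitter SD for variants (ms).
#' @param ... passed to [generate_odor()].
#' @return object of class `odor_panel` (list with `odors`, `n_glomeruli`).
#' @export
generate_panel <- function(n = 100, n_glomeruli = 50, similarity_mix = 0.2,
                           jitter_sd_ms = 10, ...) {
  if (n < 1) odx_stop("panel needs n >= 1", "olfdrift_bad_spec")
  args <- list(...)
  lat_range <- if (!is.null(args$latency_range_ms)) args$latency_range_ms else c(0, 160)
  odors <- vector("list", n)
  for (i in seq_len(n)) {
    make_variant <- i > 1 && runif(1) < similarity_mix
    if (make_variant) {
      base <- odors[[sample.int(i - 1L, 1L)]]
      lat <- base$onset_latency_ms +
        rnorm(length(base$onset_latency_ms), 0, jitter_sd_ms)
      base$onset_latency_ms <- pmin(pmax(lat, lat_range[1]), lat_range[2])
      odors[[i]] <- base
    } else {
      odors[[i]] <- generate_odor(n_glomeruli = n_glomeruli, ...)
    }
  }
  panel <- list(odors = odors, n_glomeruli = as.integer(n_glomeruli),
                similarity_mix = similarity_mix)
  class(panel) <- "odor_panel"
  panel
}

#' @export
print.odor_panel <- function(x, ...) {
  k <- vapply(x$odors, function(o) length(o$glomerulus_ids), numeric(1))
  cat(sprintf("odor panel: %d odors over %d glomeruli (%d-%d active/odor)\n",
              length(x$odors), x$n_glomeruli, min(k), max(k)))
  invisible(x)
}

#' Noise-free glomerular activation template of an odor
#'
#' Indicator matrix over glomeruli x time samples: 1 while the glomerulus's
#' 90-ms input step is on (onset inclusive, offset exclusive). The template
#' is a pure function of the odor, hence identical across trials and days.
#'
#' @param odor an `odor`.
#' @param times sample times in ms (default the 251-sample 0..250 grid).
#' @return numeric matrix `n_glomeruli` x `length(times)`.
#' @export
odor_activation <- function(odor, times = 0:250) {
  A <- matrix(0, odor$n_glomeruli, length(times))
  for (k in seq_along(odor$glomerulus_ids)) {
    on <- odor$onset_latency_ms[k]
    A[odor$glomerulus_ids[k], ] <-
      as.numeric(times >= on & times < on + odor$duration_ms)
  }
  A
}

#' Glomerular input current to the M/T cells at one time point
#'
#' During the activation window of glomerulus g, every M/T cell of g
#' receives `amplitude` plus a noise term shared across g's M/T cells plus
#' an independent per-cell term; M/T cells of inactive glomeruli receive 0.
#' The shared/independent split realizes within-glomerulus input
#' correlation; cells of different glomeruli are uncorrelated.
#'
#' @param odor an `odor`.
#' @param mt_glom integer glomerulus index per M/T cell
#'   (see [mt_glomerulus_map()]).
#' @param t time (ms).
#' @param amplitude step amplitude (current units).
#' @param noise_sd total Gaussian noise SD.
#' @param shared_frac fraction of noise variance shared within a glomerulus.
#' @return numeric vector over M/T cells.
#' @export
osn_input <- function(odor, mt_glom, t, amplitude, noise_sd = 0,
                      shared_frac = 0.5) {
  out <- numeric(length(mt_glom))
  sd_sh <- noise_sd * sqrt(shared_frac)
  sd_in <- noise_sd * sqrt(1 - shared_frac)
  for (k in seq_along(odor$glomerulus_ids)) {
    g <- odor$glomerulus_ids[k]
    on <- odor$onset_latency_ms[k]
    if (t >= on && t < on + odor$duration_ms) {
      cells <- which(mt_glom == g)
      shared <- if (sd_sh > 0) rnorm(1, 0, sd_sh) else 0
      indiv <- if (sd_in > 0) rnorm(length(cells), 0, sd_in) else 0
      out[cells] <- amplitude + shared + indiv
    }
  }
  out
}

#' Pairwise odor-similarity matrix
#'
#' Pearson correlation between the flattened noise-free activation
#' templates (glomeruli x time) of every pair of odors in the panel.
#'
#' @param panel an `odor_panel`.
#' @param times template sample times (ms).
#' @return symmetric `n x n` correlation matrix with unit diagonal.
#' @export
odor_pairwise_correlation <- function(panel, times = 0:250) {
  n <- length(panel$odors)
  if (n < 1) odx_stop("panel is empty", "olfdrift_bad_spec")
  M <- vapply(panel$odors,
              function(o) as.vector(odor_activation(o, times)),
              numeric(panel$n_glomeruli * length(times)))
  stats::cor(M)
}

#' Write / read an odor panel as JSON
#'
#' @param panel an `odor_panel`.
#' @param path JSON file path.
#' @export
write_odor_panel <- function(panel, path) {
  od <- lapply(panel$odors, function(o)
    list(glomerulus_ids = o$glomerulus_ids,
         onset_latency_ms = o$onset_latency_ms,
         duration_ms = o$duration_ms,
         n_glomeruli = o$n_glomeruli))
  jsonlite::write_json(list(n_glomeruli = panel$n_glomeruli,
                            similarity_mix = panel$similarity_mix,
                            odors = od),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_odor_panel
#' @export
read_odor_panel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  odors <- lapply(seq_len(nrow_or_len(j$odors)), function(i) {
    o <- if (is.data.frame(j$odors)) lapply(j$odors, `[[`, i) else j$odors[[i]]
    od <- list(glomerulus_ids = as.integer(unlist(o$glomerulus_ids)),
               onset_latency_ms = as.numeric(unlist(o$onset_latency_ms)),
               duration_ms = as.numeric(o$duration_ms), amplitude = NULL,
               n_glomeruli = as.integer(o$n_glomeruli))
    class(od) <- "odor"
    od
  })
  panel <- list(odors = odors, n_glomeruli = as.integer(j$n_glomeruli),
                similarity_mix = j$similarity_mix)
  class(panel) <- "odor_panel"
  panel
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
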