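# --- rates -----------------------------------------------------------------

#' Sliding-window firing rates
#'
#' Bins a trial's spike counts into a sliding `bin_ms` window advanced by
#' `stride_ms` over the inclusive 0..trial_ms sample grid, keeping full
#' windows only: the default 251-sample grid with a 5-ms window and 1-ms
#' stride yields 247 bins. Rates are in spikes/s.
#'
#' @param x a `spike_raster` or a cells x samples integer count matrix.
#' @param bin_ms window length (ms).
#' @param stride_ms window stride (ms).
#' @param dt_ms sample spacing of the count grid (ms).
#' @return numeric matrix cells x bins with attribute `bin_ms`.
#' @export
bin_spikes <- function(x, bin_ms = 5, stride_ms = 1, dt_ms = 1) {
  counts <- if (inherits(x, "spike_raster")) x$counts else x
  nb <- as.integer(round(bin_ms / dt_ms))
  ns <- as.integer(round(stride_ms / dt_ms))
  if (nb > ncol(counts))
    odx_stop("bin longer than the trial", "olfdrift_bad_bins")
  n_bins <- ncol(counts) - nb + 1L
  R <- matrix(0, nrow(counts), n_bins)
  for (k in seq_len(nb)) R <- R + counts[, k:(k + n_bins - 1L), drop = FALSE]
  R <- R[, seq(1L, n_bins, by = ns), drop = FALSE] / (bin_ms / 1000)
  attr(R, "bin_ms") <- bin_ms
  R
}

# --- pooled PCA ------------------------------------------------------------

#' Pooled principal-component eigenspace
#'
#' Fits a single eigenspace to the trial-averaged responses of one cell
#' population concatenated over all odors and all days (cells x
#' bins*odors*days). The per-cell mean over all concatenated columns is
#' subtracted, the cells x cells covariance is formed, and its
#' eigendecomposition gives one set of eigenvectors into which every day's
#' responses can be projected and compared.
#'
#' @param X numeric matrix, cells x concatenated time columns.
#' @return object of class `pooled_eigenspace`: `mean` (per cell),
#'   orthonormal `vectors` (cells x cells, variance-ordered), `values`
#'   (non-increasing), `n_cols`.
#' @export
pooled_pca <- function(X) {
  if (!is.matrix(X) || ncol(X) < 2)
    odx_stop("need at least two concatenated columns", "olfdrift_degenerate_pca")
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / (ncol(X) - 1)
  if (all(abs(C) < 1e-12))
    odx_stop("degenerate (constant) responses: no variance to decompose",
             "olfdrift_degenerate_pca")
  ee <- eigen(C, symmetric = TRUE)
  out <- list(mean = mu, vectors = ee$vectors,
              values = pmax(ee$values, 0), n_cols = ncol(X))
  class(out) <- "pooled_eigenspace"
  out
}

#' Fraction of variance captured by the leading components
#'
#' @param eig a [pooled_pca()] eigenspace.
#' @param k number of leading components.
#' @return fraction in \[0, 1\].
#' @export
variance_fraction <- function(eig, k = 50) {
  k <- min(k, length(eig$values))
  sum(eig$values[seq_len(k)]) / sum(eig$values)
}

#' Project cell-space responses into the pooled eigenspace
#'
#' @param eig a [pooled_pca()] eigenspace.
#' @param X cells x columns matrix (or a cell-space vector).
#' @param k number of components.
#' @return k x columns matrix of projections.
#' @export
project_rates <- function(eig, X, k = 50) {
  X <- as.matrix(X)
  k <- min(k, ncol(eig$vectors))
  crossprod(eig$vectors[, seq_len(k), drop = FALSE], X - eig$mean)
}

# --- population vectors and their similarity --------------------------------

#' Collapse a response matrix into a population vector
#'
#' Default mode `"concatenate"` flattens the cells x bins (or components x
#' bins) response into one long trajectory vector, so that temporal
#' structure contributes to population-vector similarity. Mode
#' `"time_average"` collapses over time bins instead, giving a vector of
#' length = number of cells (or components); it is used for single-trial
#' statistics and decoding.
#'
#' @param M numeric matrix, cells-or-components x time bins.
#' @param mode collapse rule.
#' @return numeric vector.
#' @export
population_vector <- function(M, mode = c("concatenate", "time_average")) {
  mode <- match.arg(mode)
  M <- as.matrix(M)
  if (mode == "time_average") rowMeans(M) else as.vector(M)
}

#' Pearson correlation between two population vectors
#'
#' @param u,v equal-length population vectors.
#' @return Pearson r.
#' @export
ensemble_correlation <- function(u, v) {
  if (length(u) != length(v))
    odx_stop("population vectors differ in length", "olfdrift_bad_spec")
  if (sd(u) == 0 || sd(v) == 0)
    odx_stop("zero-variance population vector", "olfdrift_zero_variance")
  cor(u, v)
}

#' Cosine similarity between population vectors
#'
#' `theta = (u . v) / (||u|| ||v||)`. When an estimate of within-day
#' variability is supplied (see [within_day_variability()]), it is
#' subtracted -- used for same-day entries, where the raw self-similarity
#' of the trial average is 1 by construction.
#'
#' @param u,v population vectors.
#' @param within_day_variability optional variability estimate to subtract.
#' @return cosine similarity.
#' @export
cosine_similarity <- function(u, v, within_day_variability = NULL) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    odx_stop("zero population vector in cosine similarity",
             "olfdrift_zero_variance")
  th <- sum(u * v) / (nu * nv)
  if (!is.null(within_day_variability)) th <- th - within_day_variability
  th
}

#' Within-day variability estimate
#'
#' One minus the cosine similarity between the even-trial-averaged and
#' odd-trial-averaged responses of the same odor on the same day.
#'
#' @param even,odd even- / odd-trial-averaged population vectors.
#' @return variability estimate (>= 0 for similar responses).
#' @export
within_day_variability <- function(even, odd) {
  1 - cosine_similarity(even, odd)
}

#' Drift rate in degrees per day
#'
#' The mean over consecutive-day pairs of the angle
#' `acos(cosine similarity)` between trial-averaged population vectors of
#' the same odor, in degrees: the average daily angular change of the
#' representation.
#'
#' @param day_vectors matrix (dimensions x days) or list of per-day
#'   vectors, in day order.
#' @return degrees/day.
#' @export
drift_rate <- function(day_vectors) {
  if (is.list(day_vectors)) day_vectors <- do.call(cbind, day_vectors)
  D <- ncol(day_vectors)
  if (is.null(D) || D < 2)
    odx_stop("drift rate needs at least two days", "olfdrift_bad_spec")
  ang <- vapply(seq_len(D - 1), function(d) {
    th <- cosine_similarity(day_vectors[, d], day_vectors[, d + 1])
    acos(pmin(pmax(th, -1), 1)) * 180 / pi
  }, numeric(1))
  mean(ang)
}

#' Maximal-distance point of a trajectory
#'
#' The time point of a reduced-space trajectory with the largest Euclidean
#' norm (distance from the origin); ties are broken toward the earliest
#' time.
#'
#' @param trajectory components x time matrix.
#' @return list with `index` (time bin), `point`, `norm`.
#' @export
max_distance_point <- function(trajectory) {
  trajectory <- as.matrix(trajectory)
  if (ncol(trajectory) < 1)
    odx_stop("empty trajectory", "olfdrift_bad_spec")
  nrm <- sqrt(colSums(trajectory^2))
  idx <- which.max(nrm)  # which.max returns the first maximum
  list(index = idx, point = trajectory[, idx], norm = nrm[idx])
}

# --- KNN decoding ----------------------------------------------------------

knn_vote <- function(train_x, train_y, test_x, k) {
  cls <- sort(unique(train_y))
  mu <- vapply(cls, function(cl)
    colMeans(train_x[train_y == cl, , drop = FALSE]), numeric(ncol(train_x)))
  # squared Euclidean distances, all test x train pairs at once
  D2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") -
    2 * tcrossprod(test_x, train_x)
  n2 <- train_y == cls[2]
  pred <- character(nrow(test_x))
  for (r in seq_len(nrow(test_x))) {
    votes2 <- sum(n2[order(D2[r, ])[seq_len(k)]])
    pred[r] <- if (2 * votes2 > k) cls[2]
    else if (2 * votes2 < k) cls[1]
    else {  # tie (even k): the class whose training mean is nearer
      dm <- colSums((test_x[r, ] - mu)^2)
      cls[which.min(dm)]
    }
  }
  pred
}

#' K-nearest-neighbor odor decoding accuracy
#'
#' Two-class decoding of odor identity from reduced-space population
#' responses: the data are split at random into training and testing sets
#' (stratified by class), test points are classified by majority vote of
#' their `k` nearest training points (Euclidean distance; ties broken
#' toward the class with the nearer training mean), and the held-out
#' accuracy is averaged over `n_repeats` random splits.
#'
#' @param x samples x dimensions matrix of projections.
#' @param labels class label per sample (exactly two classes).
#' @param train_ratio fraction of each class used for training
#'   (0.5 / 0.7 / 0.9 in the standard grid).
#' @param k number of neighbors (3 / 5 / 7 in the standard grid).
#' @param n_repeats random splits (default 30).
#' @return mean held-out accuracy.
#' @export
knn_decode <- function(x, labels, train_ratio = 0.5, k = 3, n_repeats = 30) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2)
    odx_stop("knn_decode expects exactly two classes", "olfdrift_bad_spec")
  idx_by <- lapply(cls, function(cl) which(labels == cl))
  n_train <- vapply(idx_by, function(ii) as.integer(max(1, round(train_ratio * length(ii)))),
                    integer(1))
  if (any(n_train >= vapply(idx_by, length, integer(1))))
    odx_stop("train_ratio leaves no test samples for one class",
             "olfdrift_bad_spec")
  if (k > sum(n_train))
    odx_stop("K exceeds the training-set size", "olfdrift_knn_k")
  acc <- vapply(seq_len(n_repeats), function(rep) {
    tr <- unlist(mapply(function(ii, nt) ii[sample.int(length(ii), nt)],
                        idx_by, n_train, SIMPLIFY = FALSE))
    te <- setdiff(seq_along(labels), tr)
    pred <- knn_vote(x[tr, , drop = FALSE], labels[tr],
                     x[te, , drop = FALSE], k)
    mean(pred == labels[te])
  }, numeric(1))
  mean(acc)
}

# cross-day variant: train on (a random subset of) the reference day's
# single-trial responses, test on another day's responses
knn_decode_cross <- function(train_x, train_y, test_x, test_y,
                             train_ratio = 0.9, k = 3, n_repeats = 30) {
  cls <- sort(unique(as.character(train_y)))
  idx_by <- lapply(cls, function(cl) which(train_y == cl))
  n_train <- vapply(idx_by, function(ii) as.integer(max(1, round(train_ratio * length(ii)))),
                    integer(1))
  if (k > sum(n_train)) odx_stop("K exceeds the training-set size",
                                 "olfdrift_knn_k")
  acc <- vapply(seq_len(n_repeats), function(rep) {
    tr <- unlist(mapply(function(ii, nt) ii[sample.int(length(ii), nt)],
                        idx_by, n_train, SIMPLIFY = FALSE))
    pred <- knn_vote(train_x[tr, , drop = FALSE], as.character(train_y)[tr],
                     test_x, k)
    mean(pred == as.character(test_y))
  }, numeric(1))
  mean(acc)
}
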