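#' Instantaneous phase-locking matrix at one timepoint
#'
#' Entry (n, p) is the cosine of the phase difference between regions n and
#' p: 1 for in-phase pairs, -1 for antiphase pairs, 0 at quadrature. The
#' matrix is symmetric with unit diagonal.
#'
#' @param phases length-N phase vector in radians.
#' @return N x N matrix.
#' @export
ipl_at_time <- function(phases) {
  stopifnot(is.numeric(phases), all(is.finite(phases)))
  m <- cos(outer(phases, phases, "-"))
  # enforce exact symmetry / unit diagonal against rounding
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

#' Leading eigenvector of a symmetric matrix (power iteration)
#'
#' Returns the unit eigenvector of largest-magnitude eigenvalue, computed by
#' power iteration with a Rayleigh-quotient eigenvalue, then put under the
#' majority-non-negative sign convention. The independent oracle for this
#' routine is a full `eigen()` decomposition.
#'
#' @param m symmetric numeric matrix.
#' @param tol convergence tolerance on the iterate (default 1e-12).
#' @param max_iter iteration cap (default 10000).
#' @return list with `vector` (unit norm, sign-conventioned) and `value`.
#' @export
leading_eigenvector <- function(m, tol = 1e-12, max_iter = 10000L) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m),
            max(abs(m - t(m))) < 1e-8)
  n <- nrow(m)
  v <- rep(1 / sqrt(n), n)
  lam <- 0
  for (it in seq_len(max_iter)) {
    w <- drop(m %*% v)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) {  # v in the null space; restart from a fixed direction
      v <- c(1, rep(0, n - 1L)); next
    }
    w <- w / nw
    if (sum(abs(w - v)) < tol || sum(abs(w + v)) < tol) {
      v <- w; break
    }
    v <- w
    if (it == max_iter)
      stop("power iteration did not converge in ", max_iter, " iterations")
  }
  lam <- drop(crossprod(v, m %*% v))
  list(vector = fix_eigvec_sign(v), value = lam)
}

#' Apply the majority-non-negative sign convention
#'
#' Flips the vector so a strict majority of entries is non-negative; an
#' exact tie between strictly positive and strictly negative entries is
#' broken by making entry 1 non-negative. Idempotent.
#'
#' @param v numeric vector.
#' @return sign-conventioned vector.
#' @export
fix_eigvec_sign <- function(v) {
  npos <- sum(v > 0)
  nneg <- sum(v < 0)
  if (nneg > npos) return(-v)
  if (nneg == npos && v[1L] < 0) return(-v)
  v
}

#' Leading eigenvector time series of the phase-locking tensor
#'
#' For each timepoint computes the iPL matrix's leading eigenvector V1(t).
#' Because iPL(t) = c c' + s s' with c = cos(theta(t)), s = sin(theta(t)) is
#' rank 2 and positive semi-definite, the eigenpair is obtained exactly from
#' the 2 x 2 Gram problem -- far cheaper than a full decomposition and
#' identical to it (tested against `eigen()`).
#'
#' @param phases N x T phase matrix (radians).
#' @return list of class `eigen_series` with `vectors` (N x T, unit columns
#'   under the sign convention), `values` (leading eigenvalues),
#'   `magnetization` (per-timepoint M(t)).
#' @export
eigen_series <- function(phases) {
  stopifnot(is.matrix(phases), all(is.finite(phases)))
  N <- nrow(phases); T_ <- ncol(phases)
  vecs <- matrix(NA_real_, N, T_)
  vals <- numeric(T_)
  for (t in seq_len(T_)) {
    cc <- cos(phases[, t]); ss <- sin(phases[, t])
    C <- cbind(cc, ss)
    G <- crossprod(C)                    # 2 x 2 Gram matrix
    eg <- eigen(G, symmetric = TRUE)
    vals[t] <- eg$values[1L]
    v <- drop(C %*% eg$vectors[, 1L])
    v <- v / sqrt(sum(v^2))
    vecs[, t] <- fix_eigvec_sign(v)
  }
  structure(list(vectors = vecs, values = vals,
                 magnetization = apply(vecs, 2L, magnetization)),
            class = "eigen_series")
}

#' Magnetization of a leading eigenvector
#'
#' Ratio of antiphase to in-phase regions, M = N_anti / N_in, where the
#' in-phase pole is the (majority) non-negative pole of the
#' sign-conventioned eigenvector. M = 0 for a global mode (no antiphase
#' regions); M -> 1 as the poles balance. A criticality proxy.
#'
#' @param v sign-conventioned eigenvector.
#' @return scalar in \[0, 1\].
#' @export
magnetization <- function(v) {
  v <- fix_eigvec_sign(v)
  n_in <- sum(v >= 0)
  n_anti <- length(v) - n_in
  n_anti / n_in
}

cosine_sim <- function(x, centroids) {
  # x: N x T unit columns; centroids: N x k unit columns -> T x k similarity
  crossprod(x, centroids)
}

unitize_cols <- function(m) {
  nrm <- sqrt(colSums(m^2))
  nrm[nrm == 0] <- 1
  sweep(m, 2L, nrm, "/")
}

spherical_kmeans_once <- function(x, k, max_iter, max_reseed = 5L) {
  T_ <- ncol(x)
  centroids <- x[, sample.int(T_, k), drop = FALSE]
  labels <- integer(T_)
  degenerate <- FALSE
  reseeds <- 0L
  for (it in seq_len(max_iter)) {
    sim <- cosine_sim(x, centroids)
    new_labels <- max.col(sim, ties.method = "first")
    empty <- setdiff(seq_len(k), unique(new_labels))
    if (length(empty)) {
      if (reseeds >= max_reseed) { degenerate <- TRUE; labels <- new_labels; break }
      reseeds <- reseeds + 1L
      centroids[, empty] <- x[, sample.int(T_, length(empty)), drop = FALSE]
      next
    }
    if (identical(new_labels, labels)) { labels <- new_labels; break }
    labels <- new_labels
    for (c in seq_len(k))
      centroids[, c] <- rowMeans(x[, labels == c, drop = FALSE])
    centroids <- unitize_cols(centroids)
  }
  sim <- cosine_sim(x, centroids)
  obj <- sum(1 - sim[cbind(seq_len(T_), labels)])  # total cosine dissimilarity
  list(centroids = centroids, labels = labels, objective = obj,
       degenerate = degenerate)
}

#' Mean silhouette under cosine distance
#'
#' @param x N x T matrix of unit columns.
#' @param labels cluster labels per column.
#' @param max_points subsample cap for the pairwise distance matrix
#'   (default 2000); subsampling is seeded by the caller.
#' @return mean silhouette width.
#' @export
cosine_silhouette <- function(x, labels, max_points = 2000L) {
  T_ <- ncol(x)
  idx <- seq_len(T_)
  if (T_ > max_points) idx <- sort(sample.int(T_, max_points))
  x <- x[, idx, drop = FALSE]
  labels <- labels[idx]
  if (length(unique(labels)) < 2L) return(NA_real_)
  d <- 1 - crossprod(x)                 # cosine distance
  n <- ncol(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sum(own) - 1L
    if (n_own == 0L) { s[i] <- 0; next }
    a <- sum(d[i, own]) / n_own         # excludes self (d[i,i] = 0)
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), 0))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Extract recurrent phase-locking modes by spherical k-means
#'
#' Clusters the leading eigenvectors of ONE dataset (never concatenate
#' groups or datasets: per-dataset clustering avoids leakage across cohorts)
#' with k-means under cosine distance, best of `reps` random restarts, for
#' each k in `k_range`. Centroids are unit-normalized, sign-conventioned,
#' and modes are reordered: the global mode (no strictly negative entries)
#' first when present, then by descending occupancy.
#'
#' @param eigs an [eigen_series()] or N x T matrix of unit eigenvectors
#'   (columns may be concatenated across subjects of the SAME dataset).
#' @param k_range integer vector of candidate k (default 2:10).
#' @param reps random restarts per k (default 300).
#' @param max_iter Lloyd iterations per restart (default 400).
#' @param seed integer seed.
#' @param silhouette_max_points subsample cap for silhouette (default 2000).
#' @return list of class `mode_set_list`: per k a `mode_set` with
#'   `centroids` (N x k), `labels`, `occupancy`, `communities` (minority-pole
#'   region indices; all regions for the global mode), `silhouette`,
#'   `degenerate`.
#' @export
extract_modes <- function(eigs, k_range = 2:10, reps = 300L, max_iter = 400L,
                          seed = 1L, silhouette_max_points = 2000L) {
  x <- if (inherits(eigs, "eigen_series")) eigs$vectors else as.matrix(eigs)
  x <- unitize_cols(x)
  if (any(k_range < 2L)) stop("k_range must be >= 2")
  if (ncol(x) < max(k_range))
    stop("need at least max(k_range) = ", max(k_range), " eigenvectors")
  set.seed(seed)
  out <- list()
  for (k in k_range) {
    best <- NULL
    for (r in seq_len(reps)) {
      fit <- spherical_kmeans_once(x, k, max_iter)
      if (fit$degenerate) next
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    if (is.null(best)) {
      # all replicates degenerate (e.g. identical input columns)
      fit <- spherical_kmeans_once(x, k, max_iter)
      fit$degenerate <- TRUE
      best <- fit
      warning("degenerate clustering for k = ", k,
              " (empty clusters in every replicate)")
    }
    out[[as.character(k)]] <- finalize_mode_set(x, best, k,
                                                silhouette_max_points)
  }
  structure(out, class = "mode_set_list")
}

finalize_mode_set <- function(x, fit, k, silhouette_max_points) {
  centroids <- unitize_cols(fit$centroids)
  for (c in seq_len(k)) centroids[, c] <- fix_eigvec_sign(centroids[, c])
  labels <- fit$labels
  occ <- tabulate(labels, nbins = k)
  is_global <- vapply(seq_len(k), function(c) all(centroids[, c] >= 0), TRUE)
  ord <- order(!is_global, -occ)        # global mode(s) first, then occupancy
  centroids <- centroids[, ord, drop = FALSE]
  relabel <- match(seq_len(k), ord)
  labels <- relabel[labels]
  occ <- occ[ord]
  communities <- lapply(seq_len(k), function(c) {
    neg <- which(centroids[, c] < 0)
    if (length(neg) == 0L) seq_len(nrow(centroids)) else neg
  })
  sil <- cosine_silhouette(x, labels, silhouette_max_points)
  structure(list(k = k, centroids = centroids, labels = labels,
                 occupancy = occ, communities = communities,
                 silhouette = sil, degenerate = fit$degenerate),
            class = "mode_set")
}

#' Choose k by mean silhouette
#'
#' @param mode_sets a `mode_set_list` from [extract_modes()].
#' @param k_override optional fixed k (the convention in the literature is
#'   k = 5, often preferred over the raw argmax for comparability).
#' @return list with `k` (chosen), `table` (k vs mean silhouette).
#' @export
select_k_silhouette <- function(mode_sets, k_override = NULL) {
  stopifnot(length(mode_sets) >= 2L || !is.null(k_override))
  tab <- data.frame(
    k = as.integer(names(mode_sets)),
    silhouette = vapply(mode_sets, function(m) m$silhouette, 0)
  )
  k <- if (!is.null(k_override)) as.integer(k_override)
       else tab$k[which.max(tab$silhouette)]
  list(k = k, table = tab)
}

#' Assign eigenvectors to modes by cosine distance
#'
#' label(t) = argmin_c (1 - cos(V1(t), Vc)); ties go to the lowest mode
#' index.
#'
#' @param eigs an [eigen_series()] or N x T matrix.
#' @param centroids N x k centroid matrix.
#' @return integer label vector.
#' @export
assign_modes <- function(eigs, centroids) {
  x <- if (inherits(eigs, "eigen_series")) eigs$vectors else as.matrix(eigs)
  x <- unitize_cols(x)
  centroids <- unitize_cols(as.matrix(centroids))
  sim <- cosine_sim(x, centroids)
  max.col(sim, ties.method = "first")
}

#' Half-switch label smoothing (hysteresis rule)
#'
#' Optional smoothing of the mode label series: a timepoint keeps the
#' previous label when its two closest centroids are nearly equidistant
#' (cosine-distance gap below `delta`). Disabled by default; the rule is a
#' package convention (the technique is named in the literature without a
#' formula). Smoothing never increases the number of label switches.
#'
#' @param eigs an [eigen_series()] or N x T matrix.
#' @param centroids N x k centroid matrix.
#' @param enabled logical (default FALSE: return raw assignment).
#' @param delta hysteresis width on cosine distance (default 0.05).
#' @return integer label vector.
#' @export
half_switch_smooth <- function(eigs, centroids, enabled = FALSE,
                               delta = 0.05) {
  x <- if (inherits(eigs, "eigen_series")) eigs$vectors else as.matrix(eigs)
  x <- unitize_cols(x)
  centroids <- unitize_cols(as.matrix(centroids))
  raw <- assign_modes(x, centroids)
  if (!enabled || delta <= 0 || ncol(centroids) < 2L) return(raw)
  d <- 1 - cosine_sim(x, centroids)     # T x k cosine distances
  out <- raw
  for (t in 2L:length(raw)) {
    ds <- sort(d[t, ])
    if (ds[2L] - ds[1L] < delta) out[t] <- out[t - 1L]
  }
  out
}

#' Mode functional-connectivity matrix
#'
#' Outer product Vc Vc' of a unit-norm centroid: the rank-1 phase-locking
#' pattern the mode represents (unit trace, entry signs given by the
#' centroid pole structure).
#'
#' @param centroid unit-norm centroid vector.
#' @return N x N symmetric rank-1 matrix.
#' @export
mode_fc <- function(centroid) {
  stopifnot(abs(sum(centroid^2) - 1) < 1e-6)
  tcrossprod(centroid)
}

#' Connectogram edge list of a mode
#'
#' Retains the regions in antiphase with the global pole (minority,
#' negative-sign regions of the sign-conventioned centroid) and returns the
#' edges among them whose mode-FC weight is positive (mutually in-phase
#' within the antiphase community). The global mode has no antiphase
#' connectivity, so its edge list is empty.
#'
#' @param centroid sign-conventioned unit centroid.
#' @param region_labels optional region names.
#' @return data.frame with columns `region_a`, `region_b`, `weight`.
#' @export
connectogram_edges <- function(centroid, region_labels = NULL) {
  centroid <- fix_eigvec_sign(centroid)
  if (is.null(region_labels))
    region_labels <- sprintf("R%03d", seq_along(centroid))
  fc <- tcrossprod(centroid)
  neg <- which(centroid < 0)
  if (length(neg) < 1L)
    return(data.frame(region_a = character(0), region_b = character(0),
                      weight = numeric(0)))
  pairs <- which(upper.tri(fc), arr.ind = TRUE)
  keep <- pairs[, 1L] %in% neg & pairs[, 2L] %in% neg &
    fc[pairs] > 0
  pairs <- pairs[keep, , drop = FALSE]
  data.frame(region_a = region_labels[pairs[, 1L]],
             region_b = region_labels[pairs[, 2L]],
             weight = fc[pairs])
}

#' Regional contribution to a mode
#'
#' Mean over the timepoints assigned to mode `mode` of the region's
#' phase-locking value. Default `method = "eigenvector"` averages the
#' region's leading-eigenvector element; `method = "ipl_row"` averages the
#' region's mean instantaneous phase-locking with all other regions
#' (requires `phases`).
#'
#' @param eigs an [eigen_series()].
#' @param labels mode label series.
#' @param region region index.
#' @param mode mode index.
#' @param method `"eigenvector"` (default) or `"ipl_row"`.
#' @param phases N x T phase matrix (needed for `"ipl_row"`).
#' @return list with `value` and `n_timepoints`.
#' @export
regional_contribution <- function(eigs, labels, region, mode,
                                  method = c("eigenvector", "ipl_row"),
                                  phases = NULL) {
  method <- match.arg(method)
  tt <- which(labels == mode)
  if (length(tt) == 0L)
    stop("mode ", mode, " occupies no timepoints")
  if (method == "eigenvector") {
    x <- if (inherits(eigs, "eigen_series")) eigs$vectors else as.matrix(eigs)
    val <- mean(x[region, tt])
  } else {
    stopifnot(!is.null(phases))
    other <- setdiff(seq_len(nrow(phases)), region)
    val <- mean(vapply(tt, function(t)
      mean(cos(phases[region, t] - phases[other, t])), 0))
  }
  list(value = val, n_timepoints = length(tt))
}
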