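#' Kuramoto order parameter of a community
#'
#' R(t) is the modulus of the mean unit phasor over the community members:
#' 1 at full synchrony, 0 for balanced phase dispersion.
#'
#' @param phases N x T phase matrix (radians).
#' @param community integer vector of member region indices (default all).
#' @return length-T numeric vector in \[0, 1\].
#' @export
kuramoto_order <- function(phases, community = seq_len(nrow(phases))) {
  stopifnot(length(community) >= 1L,
            all(community >= 1L), all(community <= nrow(phases)))
  z <- exp(1i * phases[community, , drop = FALSE])
  Mod(colMeans(z))
}

#' Phase-synchrony metastability (META)
#'
#' Standard deviation over time of the community Kuramoto order parameter
#' (sample sd, denominator T - 1).
#'
#' @param R Kuramoto order series (from [kuramoto_order()]).
#' @return scalar META >= 0.
#' @export
meta_metric <- function(R) {
  stopifnot(length(R) >= 2L)
  stats::sd(R)
}

#' Global metastability
#'
#' Unweighted mean of per-community META values.
#' @param metas numeric vector of community META values.
#' @return scalar.
#' @export
global_meta <- function(metas) mean(metas)

#' Chimerality series
#'
#' Instantaneous variance of the Kuramoto order parameter across
#' communities: an index of cluster (chimera-like) synchronization. Uses the
#' population variance across the k communities at each timepoint.
#'
#' @param R_matrix k x T matrix, one row of Kuramoto order per community.
#' @return length-T CHI series >= 0.
#' @export
chimerality <- function(R_matrix) {
  stopifnot(is.matrix(R_matrix), nrow(R_matrix) >= 2L)
  colMeans(R_matrix^2) - colMeans(R_matrix)^2
}

#' Phase-locking metastability (VAR)
#'
#' For every unordered pair of distinct regions in the community, take the
#' temporal sample variance of their instantaneous phase-locking
#' cos(theta_n - theta_p); VAR is the mean of those pairwise variances.
#' Unlike META it is sensitive to antiphase as well as in-phase variability.
#'
#' @param phases N x T phase matrix.
#' @param community member region indices (size >= 2).
#' @param by `"pair"` (default: mean over pairwise variances) or `"region"`
#'   (mean over regions of the variance of the region's mean phase-locking
#'   with the rest of the community).
#' @return scalar VAR >= 0.
#' @export
var_metric <- function(phases, community = seq_len(nrow(phases)),
                       by = c("pair", "region")) {
  by <- match.arg(by)
  m <- length(community)
  stopifnot(m >= 2L, ncol(phases) >= 2L)
  th <- phases[community, , drop = FALSE]
  if (by == "pair") {
    pr <- utils::combn(m, 2L)
    d <- th[pr[1L, ], , drop = FALSE] - th[pr[2L, ], , drop = FALSE]
    ipl <- cos(d)                       # n_pairs x T
    mean(apply(ipl, 1L, stats::var))
  } else {
    v <- vapply(seq_len(m), function(i) {
      other <- setdiff(seq_len(m), i)
      row <- colMeans(cos(sweep(th[other, , drop = FALSE], 2L, th[i, ])))
      stats::var(row)
    }, 0)
    mean(v)
  }
}

#' Global VAR
#'
#' Unweighted mean of per-community VAR values.
#' @param vars numeric vector of community VAR values.
#' @return scalar.
#' @export
global_var <- function(vars) mean(vars)

#' Time-averaged phase-locking matrix
#'
#' @param phases N x T phase matrix.
#' @return N x N symmetric matrix of mean iPL values.
#' @export
mean_ipl <- function(phases) {
  C <- cos(phases); S <- sin(phases)
  m <- (tcrossprod(C) + tcrossprod(S)) / ncol(phases)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

union_find_lcc <- function(adj) {
  # size of the largest connected component via weighted union-find
  n <- nrow(adj)
  parent <- seq_len(n)
  size <- rep(1L, n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1L]); b <- find(edges[e, 2L])
    if (a != b) {
      if (size[a] < size[b]) { tmp <- a; a <- b; b <- tmp }
      parent[b] <- a
      size[a] <- size[a] + size[b]
    }
  }
  max(size)
}

#' Global integration (GINT)
#'
#' Scans the time-averaged phase-locking matrix through binarization
#' thresholds tau = 0, 0.01, ..., 1; at each tau an edge exists when the
#' off-diagonal entry is >= tau, and the largest connected component size is
#' recorded as a fraction of N. GINT is the trapezoidal integral of that
#' curve over \[0, 1\], so GINT lies in \[0, 1\].
#'
#' @param mean_ipl_matrix symmetric matrix (e.g. from [mean_ipl()]).
#' @param step threshold grid step (default 0.01).
#' @return scalar GINT with attribute `curve` (data.frame tau, lcc_frac).
#' @export
integration_gint <- function(mean_ipl_matrix, step = 0.01) {
  m <- as.matrix(mean_ipl_matrix)
  stopifnot(nrow(m) == ncol(m), max(abs(m - t(m))) < 1e-8)
  n <- nrow(m)
  taus <- seq(0, 1, by = step)
  off <- m; diag(off) <- -Inf
  frac <- vapply(taus, function(tau) {
    adj <- off >= tau
    union_find_lcc(adj) / n
  }, 0)
  # trapezoid rule on the uniform grid
  gint <- sum((frac[-1L] + frac[-length(frac)]) / 2) * step
  attr(gint, "curve") <- data.frame(tau = taus, lcc_frac = frac)
  gint
}

#' Functional segregation (FSEG)
#'
#' Newman modularity Q of the time-averaged phase-locking matrix under the
#' best Louvain partition. Negative entries and the diagonal are removed
#' before building the weighted graph; the algorithm is stochastic, so the
#' best of `restarts` seeded runs is kept.
#'
#' @param mean_ipl_matrix symmetric matrix.
#' @param restarts Louvain restarts (default 20).
#' @param seed integer seed.
#' @return scalar Q with attribute `membership` (best partition).
#' @export
segregation_fseg <- function(mean_ipl_matrix, restarts = 20L, seed = 1L) {
  m <- as.matrix(mean_ipl_matrix)
  stopifnot(nrow(m) == ncol(m), max(abs(m - t(m))) < 1e-8)
  m[m < 0] <- 0
  diag(m) <- 0
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  best_q <- -Inf
  best_mem <- rep(1L, nrow(m))
  for (r in seq_len(restarts)) {
    cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
    q <- igraph::modularity(g, igraph::membership(cl),
                            weights = igraph::E(g)$weight)
    if (q > best_q) { best_q <- q; best_mem <- as.integer(igraph::membership(cl)) }
  }
  structure(best_q, membership = best_mem)
}

#' Newman modularity of a given partition (direct formula)
#'
#' Q = sum_c (e_c / m - (d_c / 2m)^2) over communities c, with e_c the
#' within-community weight, d_c the community degree sum, and m the total
#' weight. Used as the analytic oracle for [segregation_fseg()].
#'
#' @param w symmetric nonnegative weight matrix (zero diagonal).
#' @param membership community label per node.
#' @return scalar Q.
#' @export
modularity_direct <- function(w, membership) {
  w <- as.matrix(w)
  diag(w) <- 0
  m2 <- sum(w)                          # 2m
  stopifnot(m2 > 0)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    e_c <- sum(w[idx, idx])             # 2 * within weight
    d_c <- sum(w[idx, ])
    q <- q + e_c / m2 - (d_c / m2)^2
  }
  q
}

#' Metastability index K
#'
#' K = FSEG / GINT: the competitive tension between functional segregation
#' and global integration.
#'
#' @param fseg segregation value.
#' @param gint integration value (> 0).
#' @return scalar K.
#' @export
metastability_index <- function(fseg, gint) {
  if (gint <= 0) stop("GINT must be positive (got ", gint, ")")
  as.numeric(fseg) / as.numeric(gint)
}

#' Per-subject metrics from phases and communities
#'
#' Computes the full dynamical summary for one subject-run: per-community
#' META and VAR with their global means, mean and max chimerality,
#' magnetization summary, GINT, FSEG and K.
#'
#' @param phases N x T phase matrix.
#' @param communities list of integer vectors (region index sets), e.g. the
#'   `communities` of a `mode_set`.
#' @param louvain_restarts,seed passed to [segregation_fseg()].
#' @return one-row data.frame.
#' @export
subject_metrics <- function(phases, communities, louvain_restarts = 20L,
                            seed = 1L) {
  k <- length(communities)
  stopifnot(k >= 1L)
  Rm <- t(vapply(communities, function(cm) kuramoto_order(phases, cm),
                 numeric(ncol(phases))))
  metas <- apply(Rm, 1L, meta_metric)
  vars <- vapply(communities, function(cm)
    if (length(cm) >= 2L) var_metric(phases, cm) else NA_real_, 0)
  chi <- if (k >= 2L) chimerality(Rm) else rep(0, ncol(phases))
  mi <- mean_ipl(phases)
  gint <- integration_gint(mi)
  fseg <- segregation_fseg(mi, restarts = louvain_restarts, seed = seed)
  es <- eigen_series(phases)
  row <- data.frame(
    global_meta = global_meta(metas),
    global_var = global_var(vars[!is.na(vars)]),
    chi_mean = mean(chi), chi_max = max(chi),
    mag_mean = mean(es$magnetization),
    gint = as.numeric(gint), fseg = as.numeric(fseg),
    k_index = metastability_index(as.numeric(fseg), as.numeric(gint))
  )
  for (c in seq_len(k)) {
    row[[paste0("meta_c", c)]] <- metas[c]
    row[[paste0("var_c", c)]] <- vars[c]
  }
  row
}

#' Metrics table for a cohort
#'
#' Runs the preprocessing chain (band-pass, Hilbert phase) and
#' [subject_metrics()] for every subject-run of a dataset against a fixed
#' set of communities, producing the long table consumed by the statistics
#' and classification layers.
#'
#' @param dataset a `cohort_dataset` (see [generate_cohorts()] /
#'   [read_manifest()]).
#' @param communities list of region index sets.
#' @param f_lo,f_hi band edges in Hz.
#' @param louvain_restarts,seed passed through.
#' @return data.frame with identifier columns `subject`, `group`, `run` and
#'   one column per metric.
#' @export
metrics_table <- function(dataset, communities, f_lo = 0.01, f_hi = 0.08,
                          louvain_restarts = 20L, seed = 1L) {
  rows <- lapply(dataset$subjects, function(su) {
    filt <- bandpass_fft(su$series, f_lo, f_hi)
    ph <- analytic_signal(filt)$phase
    cbind(data.frame(subject = su$subject_id, group = su$group,
                     run = su$run),
          subject_metrics(ph, communities,
                          louvain_restarts = louvain_restarts, seed = seed))
  })
  do.call(rbind, rows)
}
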