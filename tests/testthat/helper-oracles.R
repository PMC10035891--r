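# Independent brute-force oracles used across the suite. These deliberately
# take the dumbest correct route (loops, full decompositions, BFS) so they
# share no code with the implementation they check.

# full-decomposition leading eigenpair
oracle_leading_eig <- function(m) {
  eg <- eigen(m, symmetric = TRUE)
  i <- which.max(abs(eg$values))
  list(vector = eg$vectors[, i], value = eg$values[i])
}

# VAR by explicit loops over pairs and frames
oracle_var_metric <- function(phases, community) {
  prs <- utils::combn(community, 2L)
  vals <- numeric(ncol(prs))
  for (j in seq_len(ncol(prs))) {
    series <- numeric(ncol(phases))
    for (t in seq_len(ncol(phases)))
      series[t] <- cos(phases[prs[1L, j], t] - phases[prs[2L, j], t])
    vals[j] <- stats::var(series)
  }
  mean(vals)
}

# largest connected component by breadth-first search
oracle_lcc_bfs <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  best <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; size <- 0L
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]; size <- size + 1L
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    best <- max(best, size)
  }
  best
}

# ICC(1,1) from an explicit one-way ANOVA fit
oracle_icc_anova <- function(x) {
  n <- nrow(x); k <- ncol(x)
  long <- data.frame(y = as.vector(x),
                     subject = factor(rep(seq_len(n), k)))
  a <- stats::anova(stats::lm(y ~ subject, data = long))
  bms <- a["subject", "Mean Sq"]
  wms <- a["Residuals", "Mean Sq"]
  (bms - wms) / (bms + (k - 1) * wms)
}

# circular concordance: mean resultant of the pointwise phase difference
# (1 iff the two phase series agree everywhere up to a fixed zero offset;
# robust for uniformly sweeping phases where Fisher-Lee correlation
# degenerates)
circ_concord <- function(a, b) {
  d <- a - b
  Mod(mean(exp(1i * d)))
}

# best label agreement over all permutations of k cluster indices
best_label_agreement <- function(labels, truth, k) {
  perms <- perms_of(seq_len(k))
  best <- 0
  for (i in seq_len(nrow(perms))) {
    mapped <- perms[i, ][labels]
    best <- max(best, mean(mapped == truth))
  }
  best
}
perms_of <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], perms_of(v[-i])))
  out
}

# small deterministic random phase matrix
rand_phases <- function(n, t, seed) {
  set.seed(seed)
  matrix(stats::runif(n * t, -pi, pi), n, t)
}
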