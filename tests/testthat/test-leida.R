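# leida_core: iPL, leading eigenvectors, magnetization, mode extraction

test_that("instantaneous phase-locking hits its boundary values", {
  th <- c(0.7, 0.7, 0.7 + pi, 0.7 + pi / 2)
  m <- ipl_at_time(th)
  expect_equal(m[1, 2], 1)                # in-phase
  expect_equal(m[1, 3], -1)               # antiphase
  expect_equal(m[1, 4], 0, tolerance = 1e-12)  # quadrature
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(1, 4))
  expect_true(all(m >= -1 - 1e-12 & m <= 1 + 1e-12))
})

test_that("leading eigenvector: closed-form cases", {
  ones <- matrix(1, 4, 4)
  le <- leading_eigenvector(ones)
  expect_equal(le$value, 4, tolerance = 1e-9)
  expect_equal(le$vector, rep(0.5, 4), tolerance = 1e-9)
  # two 2-region blocks in antiphase
  u <- c(1, 1, -1, -1)
  blk <- outer(u, u)
  le2 <- leading_eigenvector(blk)
  expect_equal(le2$value, 4, tolerance = 1e-9)
  expect_equal(abs(le2$vector), rep(0.5, 4), tolerance = 1e-9)
  expect_true(all(sign(le2$vector[1:2]) == sign(le2$vector[1])))
  expect_true(all(sign(le2$vector[3:4]) == -sign(le2$vector[1])))
})

test_that("leading eigenvector and eigen_series match the full-decomposition oracle", {
  for (s in 1:50) {
    n <- sample(4:30, 1)
    th <- rand_phases(n, 1, seed = 100 + s)[, 1]
    m <- ipl_at_time(th)
    le <- leading_eigenvector(m)
    or <- oracle_leading_eig(m)
    v_or <- fix_eigvec_sign(or$vector)
    expect_lt(max(abs(le$vector - v_or)), 1e-8)
    expect_lt(abs(le$value - or$value), 1e-9)
    es <- eigen_series(matrix(th, n, 1))
    expect_lt(max(abs(es$vectors[, 1] - v_or)), 1e-8)
    expect_lt(abs(es$values[1] - or$value), 1e-9)
  }
})

test_that("sign convention is idempotent and respects the tie rule", {
  v <- c(-0.8, 0.1, 0.1, 0.1)
  f1 <- fix_eigvec_sign(v)
  expect_identical(fix_eigvec_sign(f1), f1)
  expect_equal(f1, v)                     # strict majority already nonneg
  w <- c(-0.5, 0.5)                       # tie: region 1 decides
  expect_equal(fix_eigvec_sign(w), c(0.5, -0.5))
})

test_that("magnetization counts antiphase over in-phase regions", {
  expect_equal(magnetization(rep(0.2, 10)), 0)
  v <- c(rep(0.09, 58), rep(-0.09, 58))
  expect_equal(magnetization(v), 1)
  v2 <- c(rep(0.1, 87), rep(-0.1, 29))
  expect_equal(magnetization(v2), 29 / 87)
})

planted_eigs <- function(T_ = 120L, noise = 0.05, seed = 2L) {
  # two orthogonal unit patterns alternating in blocks
  set.seed(seed)
  p1 <- c(rep(1, 5), rep(0, 5)); p1 <- p1 / sqrt(sum(p1^2))
  p2 <- c(rep(0, 5), rep(1, 5)); p2 <- p2 / sqrt(sum(p2^2))
  truth <- rep(c(1L, 2L), each = T_ / 2)
  x <- sapply(truth, function(k) {
    v <- (if (k == 1L) p1 else p2) + rnorm(10, sd = noise)
    v / sqrt(sum(v^2))
  })
  list(x = x, truth = truth, patterns = cbind(p1, p2))
}

test_that("spherical k-means recovers planted clusters", {
  pl <- planted_eigs()
  ms <- extract_modes(pl$x, k_range = 2, reps = 20, max_iter = 100,
                      seed = 1L)[["2"]]
  sim <- abs(crossprod(ms$centroids, pl$patterns))
  # each pattern matched by one centroid
  expect_gt(max(sim[, 1]), 0.99)
  expect_gt(max(sim[, 2]), 0.99)
  acc <- best_label_agreement(ms$labels, pl$truth, 2L)
  expect_gt(acc, 0.99)
  expect_equal(sum(ms$occupancy), ncol(pl$x))
})

test_that("extract_modes contracts: k bounds and degenerate input", {
  pl <- planted_eigs()
  expect_error(extract_modes(pl$x, k_range = 1), "k_range")
  same <- matrix(rep(pl$x[, 1], 30), 10, 30)
  expect_warning(ms <- extract_modes(same, k_range = 2, reps = 3,
                                     max_iter = 20, seed = 1L),
                 "degenerate")
  expect_true(ms[["2"]]$degenerate)
})

test_that("silhouette selection prefers the true cluster count", {
  pl <- planted_eigs()
  ms <- extract_modes(pl$x, k_range = 2:4, reps = 15, max_iter = 100,
                      seed = 3L)
  sel <- select_k_silhouette(ms)
  expect_gt(ms[["2"]]$silhouette, ms[["3"]]$silhouette)
  expect_equal(sel$k, 2L)
  # a single blob: silhouette decreases from k = 2 onward
  set.seed(9)
  blob <- matrix(rnorm(8 * 100), 8, 100)
  blob <- sweep(blob, 2, sqrt(colSums(blob^2)), "/")
  msb <- extract_modes(blob, k_range = 2:4, reps = 10, max_iter = 50,
                       seed = 4L)
  expect_gt(msb[["2"]]$silhouette, msb[["4"]]$silhouette)
  # perfectly separated duplicate points: silhouette ~ 1
  dup <- cbind(matrix(pl$patterns[, 1], 10, 10),
               matrix(pl$patterns[, 2], 10, 10))
  msd <- suppressWarnings(extract_modes(dup, k_range = 2, reps = 10,
                                        max_iter = 50, seed = 5L))
  expect_gt(msd[["2"]]$silhouette, 0.999)
})

test_that("mode assignment matches the exhaustive-distance oracle", {
  set.seed(6)
  cent <- matrix(rnorm(8 * 3), 8, 3)
  cent <- sweep(cent, 2, sqrt(colSums(cent^2)), "/")
  x <- matrix(rnorm(8 * 40), 8, 40)
  x <- sweep(x, 2, sqrt(colSums(x^2)), "/")
  lab <- assign_modes(x, cent)
  oracle <- apply(x, 2, function(v) {
    d <- apply(cent, 2, function(c) 1 - sum(v * c))
    which.min(d)
  })
  expect_equal(lab, unname(oracle))
  # vector equal to a centroid gets that label
  expect_equal(assign_modes(cent[, 2, drop = FALSE], cent), 2L)
  # exact tie between modes 2 and 3 -> lowest index (2)
  c23 <- cbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tied <- matrix(c(0, 1, 1) / sqrt(2), 3, 1)
  expect_equal(assign_modes(tied, c23), 2L)
})

test_that("half-switch smoothing is a hysteresis that never adds switches", {
  set.seed(8)
  cent <- cbind(c(1, 0), c(0, 1))
  # alternating near-boundary vectors
  xb <- sapply(rep(c(0.78, 0.79), 10), function(a) c(cos(a), sin(a)))
  raw <- half_switch_smooth(xb, cent, enabled = FALSE)
  expect_gt(sum(diff(raw) != 0), 0)
  sm <- half_switch_smooth(xb, cent, enabled = TRUE, delta = 0.5)
  expect_equal(length(unique(sm)), 1L)    # large delta: single label
  expect_equal(half_switch_smooth(xb, cent, enabled = TRUE, delta = 0),
               raw)                       # delta = 0: identity
  x <- matrix(rnorm(2 * 200), 2, 200)
  x <- sweep(x, 2, sqrt(colSums(x^2)), "/")
  raw <- half_switch_smooth(x, cent, enabled = FALSE)
  sm <- half_switch_smooth(x, cent, enabled = TRUE, delta = 0.1)
  expect_lte(sum(diff(sm) != 0), sum(diff(raw) != 0))
})

test_that("mode FC is the rank-1 outer product", {
  vc <- rep(0.5, 4)
  fc <- mode_fc(vc)
  expect_true(all(fc == 0.25))
  expect_equal(sum(diag(fc)), 1)
  set.seed(10)
  v <- rnorm(6); v <- v / sqrt(sum(v^2))
  fc <- mode_fc(v)
  expect_equal(sign(fc), outer(sign(v), sign(v)))
  expect_equal(qr(fc)$rank, 1L)
})

test_that("connectogram edges cover exactly the antiphase community", {
  expect_equal(nrow(connectogram_edges(rep(0.5, 4))), 0L)
  v <- c(0.6, 0.5, 0.4, -0.3, -0.25, -0.2)
  v <- v / sqrt(sum(v^2))
  ed <- connectogram_edges(v)
  expect_equal(nrow(ed), 3L)              # complete graph on 3 negatives
  expect_true(all(ed$weight > 0))
  # brute-force filter oracle on a random centroid
  set.seed(11)
  w <- rnorm(9); w <- fix_eigvec_sign(w / sqrt(sum(w^2)))
  ed <- connectogram_edges(w)
  fc <- tcrossprod(w)
  neg <- which(w < 0)
  oracle <- list()
  for (a in neg) for (b in neg) if (a < b && fc[a, b] > 0)
    oracle[[length(oracle) + 1L]] <- c(a, b)
  lab <- sprintf("R%03d", seq_len(9))
  got <- paste(ed$region_a, ed$region_b)
  want <- vapply(oracle, function(p) paste(lab[p[1]], lab[p[2]]), "")
  expect_setequal(got, want)
})

test_that("regional contribution averages eigenvector elements over a mode", {
  x <- matrix(0.1, 4, 6)
  x[2, ] <- c(0.1, 0.2, 0.3, 0.5, 0.5, 0.5)
  labels <- c(1L, 1L, 1L, 2L, 2L, 2L)
  rc <- regional_contribution(x, labels, region = 2, mode = 1)
  expect_equal(rc$value, 0.2)
  expect_equal(rc$n_timepoints, 3L)
  expect_error(regional_contribution(x, labels, region = 2, mode = 3),
               "no timepoints")
  # constant value case
  rc2 <- regional_contribution(x, labels, region = 1, mode = 2)
  expect_equal(rc2$value, 0.1)
})

test_that("eigenvalue spectrum of iPL matrices is real and bounded below by rank-1 value", {
  th <- rand_phases(12, 1, seed = 33)[, 1]
  m <- ipl_at_time(th)
  ev <- eigen(m, symmetric = TRUE)$values
  expect_true(all(abs(Im(ev)) == 0))
  expect_gte(max(ev), mean(m) * nrow(m) - 1e-9)  # Rayleigh quotient at 1/sqrt(N)
})
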