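# synthetic_cohort: generalized-HKB oscillator simulator and cohort plumbing

zero_templates <- function(n) list(matrix(0, n, n))

test_that("uncoupled deterministic oscillator advances linearly", {
  n <- 4L
  cfg <- sim_config(n_regions = n, n_frames = 50L, tr = 2,
                    coupling_templates = zero_templates(n),
                    phase_noise_sd = 0, obs_noise_sd = 0, seed = 1L)
  th0 <- rep(0.3, n)
  ph <- simulate_oscillator_network(cfg, "control",
                                    natural_freqs = rep(0.02, n),
                                    init_phases = th0, seed = 2L)
  tt <- (seq_len(50L) - 1L) * 2
  expected <- outer(rep(1, n), 0.3 + 2 * pi * 0.02 * tt)
  expect_lt(max(abs(ph - expected)), 1e-9)
})

test_that("Kuramoto limit (B = 0) synchronizes under strong uniform coupling", {
  n <- 6L
  A <- matrix(2, n, n); diag(A) <- 0
  cfg <- sim_config(n_regions = n, n_frames = 100L, tr = 1,
                    coupling_templates = list(A), second_order_ratio = 0,
                    phase_noise_sd = 0, seed = 1L)
  set.seed(11)
  ph <- simulate_oscillator_network(cfg, "control",
                                    natural_freqs = rep(0.03, n),
                                    init_phases = runif(n, 0, 2 * pi))
  R_end <- kuramoto_order(ph)[ncol(ph)]
  expect_gt(R_end, 0.99)
})

test_that("with B = 0 the drift is exactly the Kuramoto drift (one-step check)", {
  n <- 5L
  set.seed(42)
  A <- matrix(runif(n * n), n, n); A <- (A + t(A)) / 2; diag(A) <- 0
  th0 <- runif(n, -pi, pi)
  f <- runif(n, 0.01, 0.08)
  cfg <- sim_config(n_regions = n, n_frames = 2L, tr = 0.5,
                    coupling_templates = list(A), second_order_ratio = 0,
                    phase_noise_sd = 0, seed = 1L)
  ph <- simulate_oscillator_network(cfg, "control", natural_freqs = f,
                                    init_phases = th0, substeps = 1L)
  drift <- vapply(seq_len(n), function(i)
    2 * pi * f[i] - sum(A[i, ] * sin(th0[i] - th0)), 0)
  expect_equal(ph[, 2L], th0 + 0.5 * drift, tolerance = 1e-12)
})

test_that("antiphase is stable under generalized HKB coupling (A = 2B = 1)", {
  n <- 4L
  A <- matrix(1, n, n); diag(A) <- 0
  cfg <- sim_config(n_regions = n, n_frames = 200L, tr = 1,
                    coupling_templates = list(A), second_order_ratio = 0.5,
                    phase_noise_sd = 0, seed = 1L)
  init <- c(0, 0, pi, pi) + c(0.05, -0.04, 0.03, -0.05)
  ph <- simulate_oscillator_network(cfg, "control",
                                    natural_freqs = rep(0.02, n),
                                    init_phases = init)
  rel <- abs(atan2(sin(ph[1, ] - ph[3, ]), cos(ph[1, ] - ph[3, ])))
  expect_true(all(abs(rel - pi) < 0.2))      # cross-population: antiphase
  rel12 <- abs(atan2(sin(ph[1, ] - ph[2, ]), cos(ph[1, ] - ph[2, ])))
  expect_true(all(rel12 < 0.2))              # within-population: in-phase
})

test_that("simulation is seed-deterministic and fails loudly on blow-up", {
  cfg <- sim_config(n_regions = 6L, n_frames = 30L, tr = 2, seed = 5L,
                    coupling_templates = default_coupling_templates(6L, 2L))
  p1 <- simulate_oscillator_network(cfg, "case", seed = 7L)
  p2 <- simulate_oscillator_network(cfg, "case", seed = 7L)
  expect_identical(p1, p2)
  bad <- sim_config(n_regions = 3L, n_frames = 10L, tr = 2,
                    coupling_templates = zero_templates(3L),
                    phase_noise_sd = 0, seed = 1L)
  expect_error(
    simulate_oscillator_network(bad, "control", seed = 1L,
                                natural_freqs = rep(1e308, 3L)),
    "non-finite")
})

test_that("observation model recovers the latent phase and is deterministic", {
  n <- 4L
  cfg <- sim_config(n_regions = n, n_frames = 400L, tr = 2,
                    coupling_templates = zero_templates(n),
                    phase_noise_sd = 0.05, obs_noise_sd = 0, seed = 1L)
  ph <- simulate_oscillator_network(cfg, "control",
                                    natural_freqs = c(0.02, 0.03, 0.05, 0.07),
                                    seed = 3L)
  ser <- apply_observation_model(ph, cfg)
  an <- analytic_signal(bandpass_fft(ser, 0.01, 0.08))
  interior <- 41:360                      # interior 80% of samples
  for (i in seq_len(n)) {
    cc <- circ_concord(an$phase[i, interior], ph[i, interior])
    expect_gt(cc, 0.99)
  }
  # constant zero phase maps to a constant-1 signal
  cfg0 <- sim_config(n_regions = 2L, n_frames = 10L, tr = 2,
                     coupling_templates = zero_templates(2L),
                     obs_noise_sd = 0, seed = 1L)
  s0 <- apply_observation_model(matrix(0, 2L, 10L), cfg0)
  expect_true(all(s0$values == 1))
  # same seed twice -> identical matrices
  cfgn <- sim_config(n_regions = 2L, n_frames = 10L, tr = 2,
                     coupling_templates = zero_templates(2L),
                     obs_noise_sd = 0.3, seed = 1L)
  a <- apply_observation_model(matrix(0, 2L, 10L), cfgn, seed = 9L)
  b <- apply_observation_model(matrix(0, 2L, 10L), cfgn, seed = 9L)
  expect_identical(a$values, b$values)
})

test_that("generate_cohorts shapes and per-subject determinism", {
  cfg <- sim_config(n_regions = 6L, n_subjects_per_group = 1L,
                    n_frames = 20L, tr = 2, seed = 2L,
                    coupling_templates = default_coupling_templates(6L, 2L))
  ds <- generate_cohorts(cfg)
  expect_length(ds$subjects, 2L)
  expect_setequal(vapply(ds$subjects, `[[`, "", "group"),
                  c("control", "case"))
  ds2 <- generate_cohorts(cfg)
  expect_identical(ds$subjects[[1L]]$series$values,
                   ds2$subjects[[1L]]$series$values)
})

test_that("exchangeable cohorts give uniform permutation p-values (null calibration)", {
  # scaled-down version of the null-calibration example (100 master seeds,
  # small networks) to stay inside the test budget
  n_rep <- 100L
  pvals <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_regions = 8L, n_subjects_per_group = 6L,
                      n_frames = 60L, tr = 2, case_coupling_scale = 1,
                      coupling_templates = default_coupling_templates(8L, 2L),
                      seed = 1000L + r)
    ds <- generate_cohorts(cfg)
    gv <- vapply(ds$subjects, function(su) {
      ph <- analytic_signal(bandpass_fft(su$series, 0.01, 0.08))$phase
      var_metric(ph)
    }, 0)
    grp <- vapply(ds$subjects, `[[`, "", "group")
    pvals[r] <- perm_welch_t(gv[grp == "control"], gv[grp == "case"],
                             n_perm = 199L, seed = r)$p
  }
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("stationary constant-template runs have stable community synchrony", {
  n <- 9L
  cfg <- sim_config(n_regions = n, n_frames = 300L, tr = 1,
                    coupling_templates = default_coupling_templates(n, 1L,
                                                                    n_blocks = 3L),
                    phase_noise_sd = 0.2, seed = 4L)
  ph <- simulate_oscillator_network(cfg, "control", seed = 21L)
  R <- kuramoto_order(ph, 1:3)            # the strengthened block
  half <- length(R) %/% 2
  expect_lt(abs(mean(R[1:half]) - mean(R[(half + 1):length(R)])), 0.1)
})
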