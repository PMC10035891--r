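#' Simulation configuration for two-cohort oscillator datasets
#'
#' Collects every knob of the generalized Haken-Kelso-Bunz (HKB) network
#' simulator used to emulate parcellated, band-limited resting-state signals.
#' Oscillator `i` obeys
#' \deqn{d\theta_i = [2\pi f_i - \sum_j (A_{ij}\sin(\theta_i-\theta_j)
#'   + 2B_{ij}\sin 2(\theta_i-\theta_j))]dt + \sigma dW}
#' with second-order coupling \eqn{B = b A}. With `second_order_ratio = 0`
#' the drift reduces exactly to the Kuramoto model.
#'
#' Defaults emulate an HCPEP-like acquisition: 116 regions, 410 frames at
#' TR 0.72 s, natural frequencies uniform in the 0.01-0.08 Hz band,
#' community-structured coupling templates with exponentially distributed
#' dwell times, and a "case" cohort whose coupling in a designated
#' subcortical block is scaled down.
#'
#' @param n_regions number of regions (default 116).
#' @param n_subjects_per_group subjects per cohort (default 20).
#' @param n_runs runs per subject (default 1; multi-run emulates HCPEP).
#' @param n_frames frames per run (default 410).
#' @param tr repetition time in seconds (default 0.72).
#' @param freq_range two frequencies (Hz) bounding the uniform draw of the
#'   per-region natural frequencies (default `c(0.01, 0.08)`).
#' @param coupling_templates list of symmetric nonnegative N x N first-order
#'   coupling matrices (rad/s) with zero diagonal; `NULL` builds
#'   [default_coupling_templates()].
#' @param second_order_ratio scalar `b` with `B = b * A` (default 0.5, i.e.
#'   `A = 2B`).
#' @param dwell_mean mean template dwell time in seconds (default 20).
#' @param phase_noise_sd phase-noise intensity in rad/sqrt(s) (default 0.2).
#' @param obs_noise_sd additive observation noise sd in signal units
#'   (default 0.05).
#' @param case_block region indices forming the perturbed "subcortical"
#'   block; default the first 8 regions.
#' @param case_coupling_scale multiplier in \[0, 1\] applied to the rows and
#'   columns of `case_block` for case subjects (default 0.5).
#' @param seed master integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_regions = 116L,
                       n_subjects_per_group = 20L,
                       n_runs = 1L,
                       n_frames = 410L,
                       tr = 0.72,
                       freq_range = c(0.01, 0.08),
                       coupling_templates = NULL,
                       second_order_ratio = 0.5,
                       dwell_mean = 20,
                       phase_noise_sd = 0.2,
                       obs_noise_sd = 0.05,
                       case_block = seq_len(min(8L, n_regions)),
                       case_coupling_scale = 0.5,
                       seed = 1L) {
  stopifnot(n_regions >= 2L, n_frames >= 2L, tr > 0,
            length(freq_range) == 2L, freq_range[1] < freq_range[2],
            second_order_ratio >= 0, dwell_mean > 0,
            phase_noise_sd >= 0, obs_noise_sd >= 0,
            case_coupling_scale >= 0, case_coupling_scale <= 1,
            all(case_block >= 1L), all(case_block <= n_regions))
  if (is.null(coupling_templates))
    coupling_templates <- default_coupling_templates(n_regions)
  for (A in coupling_templates) {
    if (!is.matrix(A) || nrow(A) != n_regions || ncol(A) != n_regions)
      stop("coupling template dimensions must be n_regions x n_regions")
    if (any(A < 0)) stop("coupling templates must be nonnegative")
    if (any(abs(A - t(A)) > 1e-12)) stop("coupling templates must be symmetric")
    if (any(diag(A) != 0)) stop("coupling templates must have zero diagonal")
  }
  structure(list(
    n_regions = as.integer(n_regions),
    n_subjects_per_group = as.integer(n_subjects_per_group),
    n_runs = as.integer(n_runs),
    n_frames = as.integer(n_frames),
    tr = tr,
    freq_range = freq_range,
    coupling_templates = coupling_templates,
    second_order_ratio = second_order_ratio,
    dwell_mean = dwell_mean,
    phase_noise_sd = phase_noise_sd,
    obs_noise_sd = obs_noise_sd,
    case_block = as.integer(case_block),
    case_coupling_scale = case_coupling_scale,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Community-structured coupling templates
#'
#' Builds `n_templates` symmetric coupling matrices over a fixed partition of
#' the regions into `n_blocks` contiguous blocks. Every template carries a
#' weak global coupling; template m strengthens the within-block coupling of
#' block m (cycled), so the synchronized community -- and hence the leading
#' phase-locking eigenvector -- switches with the active template.
#'
#' Couplings are per-capita normalized (Kuramoto convention): `within` and
#' `baseline` are the TOTAL pull in rad/s a region feels from its block /
#' from the rest of the network, divided across the contributing pairs.
#' This keeps the effective coupling -- and the Euler stability limit --
#' independent of network and block size. Defaults: within-block total
#' 2 rad/s (locks a block against the 0.01-0.08 Hz natural-frequency
#' spread), background total 0.1 rad/s (subcritical for that spread, so
#' weak global coherence only).
#'
#' @param n_regions number of regions.
#' @param n_templates number of templates (default 3).
#' @param n_blocks number of contiguous blocks (default `n_templates`).
#' @param within total within-block coupling in rad/s (default 2).
#' @param baseline total background coupling in rad/s (default 0.1).
#' @return list of N x N matrices.
#' @export
default_coupling_templates <- function(n_regions, n_templates = 3L,
                                       n_blocks = n_templates,
                                       within = 2, baseline = 0.1) {
  stopifnot(n_blocks >= 1L, n_blocks <= n_regions)
  block_of <- rep(seq_len(n_blocks), length.out = n_regions)
  block_of <- sort(block_of)  # contiguous blocks
  base_pp <- baseline / (n_regions - 1L)
  templates <- vector("list", n_templates)
  for (m in seq_len(n_templates)) {
    A <- matrix(base_pp, n_regions, n_regions)
    b <- ((m - 1L) %% n_blocks) + 1L
    idx <- which(block_of == b)
    if (length(idx) > 1L)
      A[idx, idx] <- within / (length(idx) - 1L)
    diag(A) <- 0
    templates[[m]] <- A
  }
  templates
}

#' Relative-phase potential of the generalized HKB pair
#'
#' \eqn{V(\phi) = -a\cos\phi - b\cos 2\phi}; its gradient is the pairwise
#' coupling drift \eqn{a\sin\phi + 2b\sin 2\phi}. With `a = 2 b` (for
#' example `a = 1, b = 0.5`) the landscape is 2pi-periodic with alternating
#' in-phase and antiphase minima separated by pi: the antiphase valleys are
#' shallower, which is why antiphase coordination is metastable.
#'
#' @param phi relative phase(s) in radians.
#' @param a first-order coupling strength.
#' @param b second-order coupling strength.
#' @return potential value(s).
#' @export
hkb_potential <- function(phi, a = 1, b = 0.5) {
  -a * cos(phi) - b * cos(2 * phi)
}

#' Draw a template switching schedule
#'
#' Dwell times are exponential with mean `dwell_mean` seconds; on each switch
#' a template different from the current one is drawn uniformly (a single
#' template simply persists). Returns the active template index per frame.
#'
#' @keywords internal
template_schedule <- function(n_templates, n_frames, tr, dwell_mean) {
  if (n_templates == 1L) return(rep(1L, n_frames))
  active <- integer(n_frames)
  cur <- sample.int(n_templates, 1L)
  t_switch <- stats::rexp(1L, rate = 1 / dwell_mean)
  for (f in seq_len(n_frames)) {
    tt <- (f - 1L) * tr
    while (tt >= t_switch) {
      cur <- sample(setdiff(seq_len(n_templates), cur), 1L)
      t_switch <- t_switch + stats::rexp(1L, rate = 1 / dwell_mean)
    }
    active[f] <- cur
  }
  active
}

#' Simulate one subject's oscillator network
#'
#' Euler-Maruyama integration of the generalized HKB phase network with the
#' active coupling template switching along an exponential dwell schedule.
#' The integrator sub-steps so that the step never exceeds `tr / substeps`
#' (default a tenth of the TR); phases are sampled every TR.
#'
#' @param config a [sim_config()].
#' @param group `"control"` or `"case"`; for cases the rows and columns of
#'   `config$case_block` in every template are multiplied by
#'   `case_coupling_scale`.
#' @param natural_freqs optional per-region frequencies (Hz); drawn uniformly
#'   from `config$freq_range` when `NULL`.
#' @param init_phases optional initial phases (radians); uniform on
#'   \[0, 2pi) when `NULL`.
#' @param substeps integration sub-steps per TR (default 10).
#' @param schedule optional explicit active-template index per frame
#'   (length `n_frames`); when `NULL` a random exponential-dwell schedule
#'   is drawn. Planting a schedule makes recovery tests exact.
#' @param seed integer seed for this subject's randomness.
#' @return N x T phase matrix (radians, unwrapped) with attributes
#'   `schedule` (active template per frame), `natural_freqs`, and `tr`.
#' @export
simulate_oscillator_network <- function(config, group = c("control", "case"),
                                        natural_freqs = NULL,
                                        init_phases = NULL,
                                        substeps = 10L, schedule = NULL,
                                        seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  group <- match.arg(group)
  if (!is.null(seed)) set.seed(seed)
  N <- config$n_regions
  T_ <- config$n_frames
  if (is.null(natural_freqs))
    natural_freqs <- stats::runif(N, config$freq_range[1], config$freq_range[2])
  stopifnot(length(natural_freqs) == N)
  if (is.null(init_phases)) init_phases <- stats::runif(N, 0, 2 * pi)
  stopifnot(length(init_phases) == N)

  templates <- config$coupling_templates
  if (group == "case" && config$case_coupling_scale != 1) {
    # multiply rows and columns of the designated block (symmetric scaling
    # D A D): block-block entries scale^2, block-outside entries scale
    d <- rep(1, N)
    d[config$case_block] <- config$case_coupling_scale
    templates <- lapply(templates, function(A) A * tcrossprod(d))
  }
  if (is.null(schedule)) {
    schedule <- template_schedule(length(templates), T_, config$tr,
                                  config$dwell_mean)
  } else {
    stopifnot(length(schedule) == T_,
              all(schedule >= 1L), all(schedule <= length(templates)))
    schedule <- as.integer(schedule)
  }

  dt <- config$tr / substeps
  omega <- 2 * pi * natural_freqs
  b <- config$second_order_ratio
  theta <- init_phases
  out <- matrix(NA_real_, N, T_)
  out[, 1L] <- theta
  noise_scale <- config$phase_noise_sd * sqrt(dt)
  for (f in 2L:T_) {
    A <- templates[[schedule[f - 1L]]]
    B2 <- 2 * b * A
    for (s in seq_len(substeps)) {
      D <- outer(theta, theta, "-")          # D[i, j] = theta_i - theta_j
      drift <- omega - rowSums(A * sin(D)) - rowSums(B2 * sin(2 * D))
      theta <- theta + drift * dt
      if (noise_scale > 0) theta <- theta + noise_scale * stats::rnorm(N)
      if (any(!is.finite(theta)))
        stop("non-finite phase during integration at step size ", dt,
             " s (frame ", f, "); reduce coupling or step size")
    }
    out[, f] <- theta
  }
  attr(out, "schedule") <- schedule
  attr(out, "natural_freqs") <- natural_freqs
  attr(out, "tr") <- config$tr
  out
}

#' Observation model: phases to BOLD-like signals
#'
#' Maps latent phases to real signals `x_i(t) = cos(theta_i(t)) + eps` with
#' white Gaussian observation noise, the simplest signal whose Hilbert phase
#' recovers the latent phase.
#'
#' @param phases N x T phase matrix.
#' @param config a [sim_config()] (supplies `obs_noise_sd` and `tr`).
#' @param region_labels optional region names.
#' @param seed integer seed for the observation noise.
#' @return a [region_ts()] object.
#' @export
apply_observation_model <- function(phases, config, region_labels = NULL,
                                    seed = NULL) {
  stopifnot(all(is.finite(phases)))
  if (!is.null(seed)) set.seed(seed)
  x <- cos(phases)
  if (config$obs_noise_sd > 0)
    x <- x + matrix(stats::rnorm(length(x), sd = config$obs_noise_sd),
                    nrow(x), ncol(x))
  if (is.null(region_labels))
    region_labels <- sprintf("R%03d", seq_len(nrow(x)))
  region_ts(x, tr = config$tr, region_labels = region_labels)
}

#' Generate a labelled two-cohort dataset
#'
#' Simulates `n_subjects_per_group` control and case subjects (each with
#' `n_runs` runs). Per-subject-run seeds are derived deterministically from
#' the master seed, so cohorts are reproducible and subjects independent.
#' With `case_coupling_scale = 1` the cohorts are statistically exchangeable.
#'
#' @param config a [sim_config()].
#' @return a `cohort_dataset`: list with `subjects` (each a list holding
#'   `subject_id`, `group`, `run`, `series`, `phases`), `region_labels`,
#'   `config`.
#' @export
generate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  region_labels <- sprintf("R%03d", seq_len(config$n_regions))
  subjects <- list()
  idx <- 0L
  for (grp in c("control", "case")) {
    for (s in seq_len(config$n_subjects_per_group)) {
      sid <- sprintf("%s%03d", if (grp == "control") "CON" else "CASE", s)
      for (r in seq_len(config$n_runs)) {
        idx <- idx + 1L
        sub_seed <- (config$seed * 7919L + idx * 104729L) %% 2147483629L
        set.seed(sub_seed)
        ph <- simulate_oscillator_network(config, group = grp)
        series <- apply_observation_model(ph, config,
                                          region_labels = region_labels)
        subjects[[idx]] <- list(subject_id = sid, group = grp, run = r,
                                series = series, phases = ph,
                                seed = sub_seed)
      }
    }
  }
  structure(list(subjects = subjects, region_labels = region_labels,
                 config = config),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("cohort_dataset:", length(x$subjects), "subject-runs,",
      length(x$region_labels), "regions,",
      x$config$n_frames, "frames @ TR", x$config$tr, "s\n")
  tab <- table(vapply(x$subjects, `[[`, "", "group"))
  cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
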