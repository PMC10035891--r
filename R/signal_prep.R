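#' Region-by-time series container
#'
#' The pipeline's raw input: an N x T real matrix of parcellated signals with
#' its repetition time and region labels.
#'
#' @param values N x T numeric matrix.
#' @param tr repetition time in seconds.
#' @param region_labels character vector of N names.
#' @return object of class `region_ts`.
#' @export
region_ts <- function(values, tr, region_labels = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(region_labels))
    region_labels <- sprintf("R%03d", seq_len(nrow(values)))
  stopifnot(is.numeric(values), all(is.finite(values)),
            nrow(values) >= 2, tr > 0,
            length(region_labels) == nrow(values))
  rownames(values) <- region_labels
  structure(list(values = values, tr = tr,
                 region_labels = as.character(region_labels)),
            class = "region_ts")
}

#' @export
print.region_ts <- function(x, ...) {
  cat("region_ts:", nrow(x$values), "regions x", ncol(x$values),
      "frames @ TR", x$tr, "s\n")
  invisible(x)
}

#' Parcellate a voxel matrix into region time courses
#'
#' Averages voxel time courses within each region of an anatomical
#' parcellation (AAL-style). Region order follows first appearance in
#' `region_of_voxel` unless `region_order` is supplied.
#'
#' @param voxel_matrix V x T matrix of voxel time courses.
#' @param region_of_voxel length-V vector of region labels.
#' @param tr repetition time in seconds.
#' @param region_order optional explicit region ordering; must contain every
#'   observed region.
#' @return a [region_ts()] with one row per region.
#' @export
parcellate <- function(voxel_matrix, region_of_voxel, tr,
                       region_order = NULL) {
  voxel_matrix <- as.matrix(voxel_matrix)
  region_of_voxel <- as.character(region_of_voxel)
  stopifnot(length(region_of_voxel) == nrow(voxel_matrix))
  regions <- unique(region_of_voxel)
  if (!is.null(region_order)) {
    missing <- setdiff(regions, region_order)
    if (length(missing))
      stop("region_order missing regions: ", paste(missing, collapse = ", "))
    empty <- setdiff(region_order, regions)
    if (length(empty))
      stop("region with no voxels: ", paste(empty, collapse = ", "))
    regions <- region_order
  }
  out <- matrix(NA_real_, length(regions), ncol(voxel_matrix))
  for (i in seq_along(regions)) {
    rows <- which(region_of_voxel == regions[i])
    out[i, ] <- colMeans(voxel_matrix[rows, , drop = FALSE])
  }
  region_ts(out, tr = tr, region_labels = regions)
}

fft_freqs <- function(T_, tr) {
  f <- (seq_len(T_) - 1L) / (T_ * tr)
  nyq <- 1 / (2 * tr)
  f[f > nyq + 1e-12] <- f[f > nyq + 1e-12] - 1 / tr  # negative frequencies
  f
}

#' Ideal (brick-wall) DFT band-pass filter
#'
#' Per region: remove the mean, forward FFT, zero every bin whose absolute
#' frequency lies outside the closed band `[f_lo, f_hi]`, inverse FFT, and
#' take the real part. The filter is linear, idempotent, and energy
#' preserving inside the passband (Parseval).
#'
#' @param series a [region_ts()].
#' @param f_lo,f_hi band edges in Hz (defaults 0.01 and 0.08, the standard
#'   resting-state band).
#' @return a filtered [region_ts()] (per-region mean approximately zero).
#' @export
bandpass_fft <- function(series, f_lo = 0.01, f_hi = 0.08) {
  stopifnot(inherits(series, "region_ts"), f_lo > 0, f_lo < f_hi)
  x <- series$values
  T_ <- ncol(x)
  if (T_ < 8) stop("need at least 8 frames for FFT filtering")
  nyq <- 1 / (2 * series$tr)
  if (f_hi >= nyq)
    stop("f_hi (", f_hi, " Hz) must be below the Nyquist frequency ",
         signif(nyq, 6), " Hz for TR ", series$tr, " s")
  f <- fft_freqs(T_, series$tr)
  keep <- abs(f) >= f_lo - 1e-12 & abs(f) <= f_hi + 1e-12
  if (!any(keep))
    stop("no FFT bin falls inside [", f_lo, ", ", f_hi,
         "] Hz; series too short (T = ", T_, ")")
  xf <- x - rowMeans(x)
  filt <- t(apply(xf, 1L, function(row) {
    X <- stats::fft(row)
    X[!keep] <- 0 + 0i
    Re(stats::fft(X, inverse = TRUE)) / T_
  }))
  out <- series
  out$values <- filt
  rownames(out$values) <- series$region_labels
  attr(out, "band") <- c(f_lo = f_lo, f_hi = f_hi)
  out
}

#' Analytic signal via the Hilbert transform
#'
#' Computes per-region amplitude (envelope) and instantaneous phase of the
#' analytic signal. Phases are wrapped to (-pi, pi]. An all-zero region gets
#' amplitude 0 and phase 0 by convention.
#'
#' @param series a band-passed [region_ts()].
#' @return list of class `analytic_series` with `amplitude`, `phase`
#'   (both N x T), `tr`, `region_labels`, and `band` if present on input.
#' @export
analytic_signal <- function(series) {
  stopifnot(inherits(series, "region_ts"))
  x <- series$values
  T_ <- ncol(x)
  h <- numeric(T_)
  if (T_ %% 2 == 0) {
    h[1L] <- 1; h[T_ / 2 + 1L] <- 1
    h[2L:(T_ / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((T_ + 1L) / 2)] <- 2
  }
  amp <- matrix(0, nrow(x), T_, dimnames = list(series$region_labels, NULL))
  ph <- amp
  for (i in seq_len(nrow(x))) {
    if (all(x[i, ] == 0)) next  # convention: amplitude 0, phase 0
    z <- stats::fft(stats::fft(x[i, ]) * h, inverse = TRUE) / T_
    amp[i, ] <- Mod(z)
    ph[i, ] <- Arg(z)
  }
  structure(list(amplitude = amp, phase = ph, tr = series$tr,
                 region_labels = series$region_labels,
                 band = attr(series, "band")),
            class = "analytic_series")
}

#' Carson / Bedrosian narrowband-validity report
#'
#' The Hilbert phase of a band-limited signal is physically meaningful only
#' when the amplitude envelope varies slowly relative to the carrier
#' (Bedrosian theorem). Per region this report computes the envelope's
#' dominant modulation frequency `f_mod`, the peak instantaneous-frequency
#' deviation `delta_f_peak`, the Carson bandwidth
#' `BW = 2 * (delta_f_peak + f_mod)`, and the fraction of envelope spectral
#' power at or above `f_lo`. A region passes when that overlap fraction does
#' not exceed `tolerance`.
#'
#' @param analytic an [analytic_signal()] result.
#' @param f_lo lower band edge in Hz (defaults to the recorded band, else
#'   0.01).
#' @param tolerance maximum admissible envelope power fraction above `f_lo`
#'   (default 0.05; the criterion itself is a package convention, no
#'   standard numeric threshold exists).
#' @return data.frame with columns `region`, `f_mod`, `delta_f_peak`,
#'   `carson_bw`, `overlap_fraction`, `pass`.
#' @export
bedrosian_report <- function(analytic, f_lo = NULL, tolerance = 0.05) {
  stopifnot(inherits(analytic, "analytic_series"))
  if (is.null(f_lo))
    f_lo <- if (!is.null(analytic$band)) analytic$band[["f_lo"]] else 0.01
  N <- nrow(analytic$amplitude)
  T_ <- ncol(analytic$amplitude)
  f <- abs(fft_freqs(T_, analytic$tr))
  out <- data.frame(region = analytic$region_labels,
                    f_mod = NA_real_, delta_f_peak = NA_real_,
                    carson_bw = NA_real_, overlap_fraction = NA_real_,
                    pass = NA)
  for (i in seq_len(N)) {
    a <- analytic$amplitude[i, ]
    pow <- Mod(stats::fft(a))^2
    total <- sum(pow)
    if (total == 0) {  # silent region: trivially narrowband
      out$f_mod[i] <- 0; out$delta_f_peak[i] <- 0
      out$carson_bw[i] <- 0; out$overlap_fraction[i] <- 0
      out$pass[i] <- TRUE
      next
    }
    nondc <- which(f > 1e-12)
    out$f_mod[i] <- f[nondc[which.max(pow[nondc])]]
    inst_f <- diff(unwrap_phase(analytic$phase[i, ])) / (2 * pi * analytic$tr)
    out$delta_f_peak[i] <- max(abs(inst_f - mean(inst_f)))
    out$carson_bw[i] <- 2 * (out$delta_f_peak[i] + out$f_mod[i])
    out$overlap_fraction[i] <- sum(pow[f >= f_lo - 1e-12]) / total
    out$pass[i] <- out$overlap_fraction[i] <= tolerance
  }
  attr(out, "f_lo") <- f_lo
  attr(out, "tolerance") <- tolerance
  out
}

#' Unwrap a phase series
#'
#' Removes 2pi jumps so consecutive differences lie in (-pi, pi].
#' @param p phase vector in radians.
#' @return unwrapped phases.
#' @export
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1L], d))
}
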