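# Parametric Gabor spectrotemporal receptive fields (STRFs) on the
# (time-lag x frequency-channel) grid of the stimulus spectrogram.

#' Gabor receptive-field parameters
#'
#' The seven generative parameters of a separable Gabor STRF,
#' `RF(t, f) = H(t) * G(f)` with
#' `H(t) = exp(-0.5 ((t - t0)/sigma_t)^2) * cos(2 pi omega_t (t - t0) + p_t)`
#' and
#' `G(f) = exp(-0.5 ((f - f0)/sigma_f)^2) * cos(2 pi omega_f (f - f0))`.
#'
#' @param t0 latency (s)
#' @param f0 peak frequency (Hz), within the analysis band \[0, 8000\]
#' @param sigma_t temporal bandwidth (s), positive
#' @param sigma_f spectral bandwidth (Hz), positive
#' @param omega_t temporal modulation frequency (Hz), non-negative
#' @param omega_f spectral modulation frequency (cycles/Hz)
#' @param p_t temporal phase (radians)
#' @return an object of class `rf_params`
#' @export
rf_params <- function(t0, f0, sigma_t, sigma_f, omega_t = 0, omega_f = 0,
                      p_t = 0) {
  if (sigma_t <= 0 || sigma_f <= 0)
    stop("bandwidths sigma_t and sigma_f must be positive")
  if (omega_t < 0) stop("omega_t must be non-negative")
  if (f0 < 0 || f0 > 8000)
    stop("f0 must lie within the spectrogram band [0, 8000] Hz")
  structure(list(t0 = t0, f0 = f0, sigma_t = sigma_t, sigma_f = sigma_f,
                 omega_t = omega_t, omega_f = omega_f, p_t = p_t),
            class = "rf_params")
}

# temporal and spectral 1-D profiles of the Gabor
rf_temporal_profile <- function(params, t) {
  exp(-0.5 * ((t - params$t0) / params$sigma_t)^2) *
    cos(2 * pi * params$omega_t * (t - params$t0) + params$p_t)
}

rf_spectral_profile <- function(params, f) {
  exp(-0.5 * ((f - params$f0) / params$sigma_f)^2) *
    cos(2 * pi * params$omega_f * (f - params$f0))
}

#' Default spectrogram channel centers
#'
#' Centers of `n` equal-width frequency bands spanning \[0, fmax\] Hz.
#'
#' @param n number of channels
#' @param fmax upper band edge (Hz)
#' @return numeric vector of band-center frequencies
#' @export
default_channels <- function(n = 50, fmax = 8000) {
  width <- fmax / n
  (seq_len(n) - 0.5) * width
}

#' Build a receptive field on the spectrogram grid
#'
#' Samples the separable Gabor on `n_lags` time lags (spaced `lag_step`
#' apart, lag 0 first) by the given frequency channels, then normalizes
#' the grid. The default normalization sets the filter energy (L2 norm)
#' to one, which keeps response amplitudes commensurate across an
#' ensemble of Gabors of different bandwidths and modulation frequencies.
#' An `"integral"` mode (algebraic sum normalized to one, with an L1
#' fallback when the sum of an oscillatory Gabor nearly vanishes) is
#' available; note that for strongly modulated filters the near-zero sum
#' makes the integral rule blow up the grid, which is why it is not the
#' default. The mode actually applied is recorded in the result.
#'
#' @param params an `rf_params` object
#' @param n_lags number of time lags (default 100, i.e. a 100 ms window at
#'   1 ms resolution)
#' @param lag_step lag spacing in seconds (equal to the spectrogram frame
#'   step)
#' @param channels channel center frequencies (Hz)
#' @param norm `"l2"` (default), `"l1"`, `"integral"` (sum rule with L1
#'   fallback), or `"none"`
#' @return object of class `receptive_field`: list with `grid`
#'   (n_lags x n_channels matrix), `params`, `lag_step`, `channel_centers`,
#'   `norm`, `norm_applied`, `norm_divisor`
#' @export
build_rf <- function(params, n_lags = 100, lag_step = 1e-3,
                     channels = default_channels(), norm = "l2") {
  stopifnot(inherits(params, "rf_params"))
  if (n_lags * lag_step < params$t0 + 3 * params$sigma_t)
    stop("lag window must cover t0 + 3 sigma_t")
  lags <- (seq_len(n_lags) - 1) * lag_step
  H <- rf_temporal_profile(params, lags)
  G <- rf_spectral_profile(params, channels)
  grid <- outer(H, G)

  l1 <- sum(abs(grid))
  if (l1 < 1e-300) stop("degenerate receptive field: grid is zero")
  applied <- norm
  divisor <- switch(norm,
    integral = {
      s <- sum(grid)
      if (abs(s) > 1e-6 * l1) s else { applied <- "l1"; l1 }
    },
    l1 = l1,
    l2 = sqrt(sum(grid^2)),
    none = 1,
    stop("unknown norm mode: ", norm))
  if (abs(divisor) < 1e-300) stop("degenerate receptive field normalization")
  grid <- grid / divisor
  if (norm %in% c("l1", "l2")) {
    # orient the filter as net excitatory (positive integral), matching
    # the integral-to-one convention; for a near-zero-sum Gabor the
    # dominant lobe decides
    s <- sum(grid)
    flip <- if (abs(s) > 1e-9 * sum(abs(grid))) s < 0
            else grid[which.max(abs(grid))] < 0
    if (flip) grid <- -grid
  }
  structure(list(grid = grid, params = params,
                 lag_step = lag_step, channel_centers = channels,
                 norm = norm, norm_applied = applied,
                 norm_divisor = divisor),
            class = "receptive_field")
}

#' Default parameter distributions for RF ensembles
#'
#' Ranges chosen so that the ensemble's joint modulation-frequency cloud
#' spans the spectrotemporal modulation content typical of zebra finch
#' song: temporal modulation 5-80 Hz (log-uniform), spectral modulation
#' 0-1.2 cycles/kHz. Each entry is `list(dist, lo, hi)` with `dist` one of
#' `"uniform"` or `"loguniform"`.
#'
#' @return named list of per-parameter sampling ranges
#' @export
default_rf_ranges <- function() {
  list(
    t0      = list(dist = "uniform",    lo = 0.005, hi = 0.030),   # s
    f0      = list(dist = "uniform",    lo = 1000,  hi = 7000),    # Hz
    sigma_t = list(dist = "uniform",    lo = 0.003, hi = 0.015),   # s
    sigma_f = list(dist = "uniform",    lo = 300,   hi = 1500),    # Hz
    omega_t = list(dist = "loguniform", lo = 5,     hi = 80),      # Hz
    omega_f = list(dist = "uniform",    lo = 0,     hi = 1.2e-3),  # cyc/Hz
    p_t     = list(dist = "uniform",    lo = 0,     hi = 2 * pi)
  )
}

draw_one <- function(range) {
  if (!is.list(range) || is.null(range$lo) || is.null(range$hi) ||
      range$hi < range$lo)
    stop("invalid range configuration")
  u <- runif(1)
  switch(range$dist,
    uniform = range$lo + u * (range$hi - range$lo),
    loguniform = {
      if (range$lo <= 0) stop("log-uniform range requires positive bounds")
      exp(log(range$lo) + u * (log(range$hi) - log(range$lo)))
    },
    stop("unknown distribution: ", range$dist))
}

#' Draw an ensemble of RF parameter sets
#'
#' Reproducibly samples `n` Gabor parameter sets from the configured
#' per-parameter distributions.
#'
#' @param n ensemble size
#' @param ranges named list of sampling ranges as in [default_rf_ranges()]
#' @param seed integer seed; the draw is fully reproducible
#' @return list of `rf_params`, with the seed attached as attribute `seed`
#' @export
sample_rf_ensemble <- function(n, ranges = default_rf_ranges(), seed = 1) {
  if (n < 1) stop("n must be at least 1")
  required <- c("t0", "f0", "sigma_t", "sigma_f", "omega_t", "omega_f",
                "p_t")
  if (!all(required %in% names(ranges)))
    stop("ranges must configure all seven RF parameters")
  out <- with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      vals <- lapply(ranges[required], draw_one)
      do.call(rf_params, vals)
    })
  })
  attr(out, "seed") <- seed
  out
}

#' Vary the temporal modulation frequency of a base RF
#'
#' Returns copies of `base` differing only in `omega_t`, for sweeps of
#' selectivity against temporal modulation.
#'
#' @param base an `rf_params` object
#' @param values temporal modulation frequencies (Hz)
#' @return list of `rf_params`
#' @export
rf_sweep_omega_t <- function(base, values) {
  stopifnot(inherits(base, "rf_params"))
  if (length(values) < 1) stop("values must be non-empty")
  lapply(values, function(om) {
    p <- base
    p$omega_t <- om
    p
  })
}

#' Tabulate an RF ensemble
#'
#' One row per RF with the seven generative parameters, suitable for
#' serialization and joining with per-model metric tables.
#'
#' @param rfs list of `rf_params` (e.g. from [sample_rf_ensemble()])
#' @return data.frame with one row per parameter set
#' @export
rf_ensemble_table <- function(rfs) {
  df <- do.call(rbind, lapply(rfs, function(p) as.data.frame(unclass(p))))
  df$rf <- seq_len(nrow(df))
  df[, c("rf", setdiff(names(df), "rf"))]
}

#' @export
print.rf_params <- function(x, ...) {
  cat(sprintf(paste0("<rf_params> t0=%.1f ms f0=%.0f Hz sigma_t=%.1f ms ",
                     "sigma_f=%.0f Hz omega_t=%.1f Hz omega_f=%.2f cyc/kHz ",
                     "p_t=%.2f rad\n"),
              x$t0 * 1000, x$f0, x$sigma_t * 1000, x$sigma_f, x$omega_t,
              x$omega_f * 1000, x$p_t))
  invisible(x)
}

#' @export
print.receptive_field <- function(x, ...) {
  cat(sprintf("<receptive_field> %d lags x %d channels, norm %s (%s)\n",
              nrow(x$grid), ncol(x$grid), x$norm, x$norm_applied))
  invisible(x)
}

# Evaluate an expression under a fixed RNG seed without disturbing the
# caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
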