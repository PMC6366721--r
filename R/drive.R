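# Driving currents: RF-spectrogram convolution (I_stim), 1/f^alpha noise
# currents at a controlled SNR (I_noise), and per-trial noise seeding that
# is shared between phasic/tonic partners.

#' Convolve a receptive field with a spectrogram
#'
#' Forms the stimulus-driven current
#' `I_stim[t] = gain * (1/sigma_f_kHz) * sum_{l,c} grid[l,c] * S[t-l,c]`,
#' causal in the lag (the RF looks into the stimulus past) and zero-padded
#' at the start. The division by the RF's spectral bandwidth (in kHz)
#' equalizes the drive between narrowband and broadband RFs. By default
#' the spectrogram is mean-centered first, so the drive fluctuates about
#' zero: quiet stretches hyperpolarize and acoustic energy in the RF's
#' passband depolarizes, rather than every filter receiving a standing
#' offset proportional to overall stimulus level.
#'
#' @param rf a `receptive_field`
#' @param spec a `spectrogram` with matching channels
#' @param gain scale factor converting convolution units to pA
#' @param center subtract the spectrogram mean before convolving
#' @return object of class `drive_current`: list with `i_stim` (pA, one
#'   sample per spectrogram frame), `dt` (s), `gain`, `rf_ref`, `stim_ref`
#' @export
convolve_drive <- function(rf, spec, gain = 1, center = TRUE) {
  if (ncol(rf$grid) != ncol(spec$matrix) ||
      max(abs(rf$channel_centers - spec$channel_centers)) > 1e-6)
    stop("RF and spectrogram channels do not match")
  if (abs(rf$lag_step - spec$frame_step) > 1e-12)
    stop("RF lag step must equal the spectrogram frame step")
  S <- spec$matrix
  if (center) S <- S - mean(S)
  n <- nrow(S)
  n_lags <- nrow(rf$grid)
  # M[t, l] = sum_c S[t, c] * grid[l, c]; then delay column l by l frames
  M <- S %*% t(rf$grid)
  out <- numeric(n)
  for (l in seq_len(n_lags)) {
    d <- l - 1
    if (d < n) out[(d + 1):n] <- out[(d + 1):n] + M[seq_len(n - d), l]
  }
  sigma_f_khz <- rf$params$sigma_f / 1000
  structure(list(i_stim = gain * out / sigma_f_khz, dt = spec$frame_step,
                 gain = gain, rf_ref = rf$params,
                 stim_ref = spec$label),
            class = "drive_current")
}

#' Calibrate the convolution gain
#'
#' The absolute current scale of the cascade is set by calibration: the
#' gain is chosen so that the standard deviation of the stimulus current
#' over a reference stimulus set equals `target_sd` (pA), a level at
#' which the tonic model fires in the 1-30 Hz range typical of auditory
#' cortical responses. In the default per-RF mode each RF receives its
#' own gain (its drive pooled over the stimulus set has SD `target_sd`),
#' which equalizes drive amplitudes between narrowband/broadband and
#' weakly/strongly modulated RFs; in shared mode one gain is computed
#' from the drives of the whole ensemble pooled together. Either way the
#' calibrated gains are frozen for every model and condition of an
#' experiment, so sweeps differ only in the swept variable and the
#' phasic/tonic partners of a pair always share the same drive.
#'
#' @param rfs list of `receptive_field`
#' @param specs list of `spectrogram`
#' @param target_sd target standard deviation of I_stim (pA)
#' @param per_rf calibrate each RF separately (default) or share one
#'   pooled gain
#' @return gain(s) in pA per convolution unit: a vector of
#'   `length(rfs)` when `per_rf`, otherwise a scalar
#' @export
calibrate_gain <- function(rfs, specs, target_sd = 200, per_rf = TRUE) {
  sds <- vapply(rfs, function(rf)
    sd(unlist(lapply(specs, function(sp)
      convolve_drive(rf, sp, gain = 1)$i_stim))), numeric(1))
  if (any(!is.finite(sds) | sds < 1e-12))
    stop("cannot calibrate gain: reference drives have zero variance")
  if (per_rf) target_sd / sds
  else {
    pooled <- unlist(lapply(rfs, function(rf)
      lapply(specs, function(sp) convolve_drive(rf, sp, gain = 1)$i_stim)))
    target_sd / sd(pooled)
  }
}

#' Noise-current specification
#'
#' @param alpha spectral exponent of the 1/f^alpha power spectrum
#'   (0 = white, 1 = pink, 2 = red)
#' @param snr signal-to-noise ratio; by default the RMS-amplitude ratio
#'   of I_stim to I_noise (convention `"amplitude"`), with a power-ratio
#'   mode available
#' @param seed base integer seed for the experiment's noise stream
#' @param convention `"amplitude"` or `"power"`
#' @return object of class `noise_spec`
#' @export
noise_spec <- function(alpha = 2, snr = 4, seed = 1,
                       convention = c("amplitude", "power")) {
  convention <- match.arg(convention)
  if (alpha < 0) stop("alpha must be non-negative")
  if (snr <= 0) stop("snr must be positive")
  structure(list(alpha = alpha, snr = snr, seed = as.integer(seed),
                 convention = convention),
            class = "noise_spec")
}

#' Synthesize a 1/f^alpha noise current
#'
#' Frequency-domain synthesis: a complex spectrum with amplitude
#' proportional to `f^(-alpha/2)`, independent random phases and a zeroed
#' DC bin is inverse-transformed, giving a zero-mean trace with an exact
#' target power spectrum. The trace is scaled so that
#' `signal_rms / noise_rms` equals the configured SNR (amplitude
#' convention; under the power convention the RMS ratio is `sqrt(snr)`).
#'
#' @param n number of samples (>= 2)
#' @param dt sample interval (s)
#' @param spec a `noise_spec`
#' @param signal_rms RMS of the paired stimulus current (pA)
#' @param seed seed for this trace; defaults to `spec$seed`
#' @return numeric noise current (pA)
#' @export
make_noise <- function(n, dt = 1e-3, spec = noise_spec(),
                       signal_rms = 1, seed = spec$seed) {
  if (n < 2) stop("n must be at least 2")
  target_rms <- if (spec$convention == "amplitude") signal_rms / spec$snr
                else signal_rms / sqrt(spec$snr)
  with_local_seed(seed, {
    nf <- n %/% 2
    freqs <- seq_len(nf) / (n * dt)
    amp <- freqs^(-spec$alpha / 2)
    phase <- runif(nf, 0, 2 * pi)
    pos <- amp * exp(1i * phase)
    if (n %% 2 == 0) pos[nf] <- amp[nf] * cos(phase[nf])  # real Nyquist
    spec_full <- c(0, pos, Conj(rev(pos[seq_len(nf - (1 - n %% 2))])))
    x <- Re(fft(spec_full, inverse = TRUE)) / n
    x <- x - mean(x)
    r <- sqrt(mean(x^2))
    if (r < 1e-300) stop("degenerate noise trace")
    x * (target_rms / r)
  })
}

#' Deterministic per-trial noise seed
#'
#' Derives the seed of a trial's noise current from the experiment base
#' seed, the RF identity, the stimulus identity and the trial index --
#' and deliberately not from the dynamics type, so the phasic and tonic
#' partners of a pair receive bit-identical noise currents.
#'
#' @param spec a `noise_spec` (its `seed` is the base seed)
#' @param rf_id integer RF index
#' @param stim_id integer stimulus index
#' @param trial_index trial number
#' @return an integer seed in \[1, 2^31 - 2\]
#' @export
pair_trial_noise <- function(spec, rf_id = 1, stim_id = 1,
                             trial_index = 1) {
  derive_seed(spec$seed, rf_id, stim_id, trial_index)
}

# Small deterministic integer hash; every argument perturbs the stream.
# Kept within doubles' exact-integer range (products < 2^53).
derive_seed <- function(...) {
  m <- 2147483647
  h <- 104729
  for (x in list(...)) {
    x <- if (is.character(x)) sum(utf8ToInt(x) * seq_along(utf8ToInt(x)))
         else as.numeric(x)
    h <- (h * 69069 + x + 1) %% m
  }
  as.integer(h + 1)
}

#' @export
print.drive_current <- function(x, ...) {
  cat(sprintf("<drive_current> '%s': %d samples at %g ms, sd %.1f pA\n",
              x$stim_ref, length(x$i_stim), x$dt * 1000, sd(x$i_stim)))
  invisible(x)
}
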