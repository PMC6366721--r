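# Experiment orchestration: paired phasic/tonic ensembles and the SNR,
# noise-color, gKLT and temporal-modulation sweeps, with deterministic
# seeding throughout and per-cell error capture.

#' Experiment configuration
#'
#' Bundles every knob of a cascade experiment. The default desk-scale
#' profile (20 RF pairs, 10 synthetic 1 s songs, 5 trials) keeps a full
#' paired ensemble within minutes on one CPU; the `"paper"` profile
#' selects the full-scale design (60 RFs, 30 songs of 2.025 s, 10
#' trials).
#'
#' @param n_rfs number of receptive fields in the ensemble
#' @param n_songs number of synthetic song stimuli
#' @param song_duration stimulus duration (s)
#' @param syllables_per_song syllables per synthetic song
#' @param n_trials trials per (model, stimulus)
#' @param alpha noise spectral exponent (2 = red)
#' @param snr signal-to-noise ratio (RMS-amplitude convention)
#' @param base_seed master seed; every random stream in the experiment is
#'   derived from it deterministically
#' @param gain_target target SD of the stimulus current (pA) for gain
#'   calibration
#' @param gain_mode `"per_rf"` (each RF's drive calibrated to
#'   `gain_target`, the default) or `"shared"` (one pooled gain)
#' @param n_bins rate-discretization bins for the entropy metrics
#' @param dynamics character vector of parameter-set names among
#'   `"phasic"`, `"tonic"`
#' @param rf_ranges RF parameter sampling ranges ([default_rf_ranges()])
#' @param stimuli optional list of `stimulus` objects to use instead of
#'   synthetic songs
#' @param profile `"desk"` or `"paper"`
#' @return object of class `experiment_config`
#' @export
experiment_config <- function(n_rfs = 20, n_songs = 10, song_duration = 1,
                              syllables_per_song = 5, n_trials = 5,
                              alpha = 2, snr = 4, base_seed = 1,
                              gain_target = 200, gain_mode = "per_rf",
                              n_bins = 15,
                              dynamics = c("phasic", "tonic"),
                              rf_ranges = default_rf_ranges(),
                              stimuli = NULL,
                              profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  if (profile == "paper") {
    n_rfs <- 60; n_songs <- 30; song_duration <- 2.025; n_trials <- 10
  }
  if (n_trials < 1) stop("n_trials must be at least 1")
  stopifnot(all(dynamics %in% c("phasic", "tonic")))
  if (!is.null(stimuli) &&
      any(vapply(stimuli, function(s) is.null(s$syllables), logical(1))))
    stop("every stimulus must carry a syllable segmentation")
  structure(list(n_rfs = n_rfs, n_songs = n_songs,
                 song_duration = song_duration,
                 syllables_per_song = syllables_per_song,
                 n_trials = n_trials, alpha = alpha, snr = snr,
                 base_seed = as.integer(base_seed),
                 gain_target = gain_target,
                 gain_mode = match.arg(gain_mode, c("per_rf", "shared")),
                 n_bins = n_bins,
                 dynamics = dynamics, rf_ranges = rf_ranges,
                 stimuli = stimuli, profile = profile),
            class = "experiment_config")
}

neuron_params_by_name <- function(name) {
  switch(name, phasic = phasic_params(), tonic = tonic_params(),
         stop("unknown dynamics type: ", name))
}

# Shared set-up of an experiment: stimuli, spectrograms, RF ensemble,
# unit-gain drives and the calibrated gain (frozen for all conditions).
prepare_experiment <- function(cfg, rf_list = NULL, gain_groups = NULL) {
  stims <- cfg$stimuli
  if (is.null(stims)) {
    stims <- lapply(seq_len(cfg$n_songs), function(i)
      generate_synthetic_song(seed = derive_seed(cfg$base_seed, "stim", i),
                              n_syllables = cfg$syllables_per_song,
                              duration = cfg$song_duration,
                              label = sprintf("song%02d", i)))
  }
  specs <- lapply(stims, compute_spectrogram)
  if (is.null(rf_list))
    rf_list <- sample_rf_ensemble(cfg$n_rfs, cfg$rf_ranges,
                                  seed = derive_seed(cfg$base_seed, "rf"))
  rfs <- lapply(rf_list, build_rf)
  if (is.null(gain_groups)) {
    gain <- calibrate_gain(rfs, specs, cfg$gain_target,
                           per_rf = cfg$gain_mode == "per_rf")
    gains <- rep_len(gain, length(rfs))
  } else {
    # one gain per group of related RFs (e.g. the temporal-modulation
    # variants of a base RF), computed from their pooled drives so the
    # variants keep their natural relative amplitudes
    gains <- numeric(length(rfs))
    for (g in unique(gain_groups)) {
      idx <- which(gain_groups == g)
      pooled <- unlist(lapply(idx, function(i)
        lapply(specs, function(sp)
          convolve_drive(rfs[[i]], sp, gain = 1)$i_stim)))
      gains[idx] <- cfg$gain_target / sd(pooled)
    }
    gain <- gains
  }
  # unit drives scaled once by the calibrated gain(s)
  drives <- lapply(seq_along(rfs), function(i)
    lapply(specs, function(sp) convolve_drive(rfs[[i]], sp,
                                              gain = gains[i])))
  segments <- do.call(rbind, lapply(stims, function(s)
    cbind(stim = s$label, s$syllables)))
  list(cfg = cfg, stimuli = stims, specs = specs, rf_list = rf_list,
       rfs = rfs, gain = gain, gains = gains, drives = drives,
       segments = segments)
}

# Run every (rf x params x stimulus x trial) cell for one noise condition.
# param_sets: named list of neuron_params (name = dynamics label).
# Noise seeds depend on (base seed, rf, stimulus, trial) but not on the
# dynamics label, so partners sharing an RF receive identical noise.
run_cells <- function(prep, param_sets, nspec,
                      rf_indices = seq_along(prep$rfs)) {
  cfg <- prep$cfg
  rest <- lapply(param_sets, rest_state)
  metrics <- list()
  rates <- list()
  audit <- list()
  failures <- list()
  for (i in rf_indices) {
    noise_cache <- list()
    for (dyn in names(param_sets)) {
      spikes <- list()
      for (s in seq_along(prep$stimuli)) {
        drv <- prep$drives[[i]][[s]]
        signal_rms <- sqrt(mean(drv$i_stim^2))
        for (j in seq_len(cfg$n_trials)) {
          seed_j <- pair_trial_noise(nspec, i, s, j)
          key <- sprintf("%d.%d", s, j)
          if (is.null(noise_cache[[key]]))
            noise_cache[[key]] <- make_noise(length(drv$i_stim), drv$dt,
                                             nspec, signal_rms,
                                             seed = seed_j)
          cell <- tryCatch({
            sim <- simulate_neuron(param_sets[[dyn]], drv$i_stim,
                                   noise_cache[[key]],
                                   init = rest[[dyn]])
            detect_spikes(sim$voltage, sim$dt)
          }, error = function(e) e)
          audit[[length(audit) + 1]] <- data.frame(
            rf = i, dynamics = dyn, stim = prep$stimuli[[s]]$label,
            trial = j, noise_seed = seed_j,
            ok = !inherits(cell, "error"))
          if (inherits(cell, "error")) {
            failures[[length(failures) + 1]] <- data.frame(
              rf = i, dynamics = dyn, stim = prep$stimuli[[s]]$label,
              trial = j, message = conditionMessage(cell))
            next
          }
          if (length(cell$times) > 0)
            spikes[[length(spikes) + 1]] <- data.frame(
              time = cell$times, stim = prep$stimuli[[s]]$label,
              trial = j)
        }
      }
      sp <- if (length(spikes)) do.call(rbind, spikes)
            else data.frame(time = numeric(0), stim = character(0),
                            trial = integer(0))
      tbl <- rate_table(sp, prep$segments, cfg$n_trials)
      m <- response_metrics(tbl, cfg$n_bins)
      m$rf <- i
      m$dynamics <- dyn
      metrics[[length(metrics) + 1]] <- m
      tbl$rf <- i
      tbl$dynamics <- dyn
      rates[[length(rates) + 1]] <- as.data.frame(tbl)
    }
  }
  list(metrics = do.call(rbind, metrics),
       rates = do.call(rbind, rates),
       audit = do.call(rbind, audit),
       failures = if (length(failures)) do.call(rbind, failures),
       gain = prep$gain, noise = nspec)
}

#' Run the paired phasic/tonic ensemble experiment
#'
#' For each RF of the ensemble, simulates the phasic and the tonic model
#' on every stimulus and trial with identical noise currents within a
#' pair, extracts spikes, and aggregates syllable-by-trial rate tables
#' and rate-coding metrics per model.
#'
#' @param cfg an [experiment_config()]
#' @return list of class `result_set`: `metrics` (one row per model),
#'   `rates` (one row per class x trial x model), `audit` (per-cell noise
#'   seeds and status), `failures` (per-cell errors, or NULL), `gain`,
#'   `noise`, `rf_table`, `config`
#' @export
run_paired_ensemble <- function(cfg = experiment_config()) {
  prep <- prepare_experiment(cfg)
  nspec <- noise_spec(alpha = cfg$alpha, snr = cfg$snr,
                      seed = derive_seed(cfg$base_seed, "noise"))
  res <- run_cells(prep, stats::setNames(
    lapply(cfg$dynamics, neuron_params_by_name), cfg$dynamics), nspec)
  res$rf_table <- rf_ensemble_table(prep$rf_list)
  res$config <- cfg
  class(res) <- "result_set"
  res
}

#' Sweep the signal-to-noise ratio
#'
#' Reruns the paired ensemble at each SNR value with the gain and all
#' other settings frozen, so conditions differ only in noise amplitude.
#'
#' @param cfg an [experiment_config()]
#' @param snr_values SNR values; the study's reference value is 4
#' @return `result_set` whose tables carry an `snr` column
#' @export
run_snr_sweep <- function(cfg = experiment_config(),
                          snr_values = c(1, 2, 4, 8)) {
  prep <- prepare_experiment(cfg)
  psets <- stats::setNames(lapply(cfg$dynamics, neuron_params_by_name),
                           cfg$dynamics)
  sub <- lapply(snr_values, function(snr) {
    nspec <- noise_spec(alpha = cfg$alpha, snr = snr,
                        seed = derive_seed(cfg$base_seed, "noise"))
    r <- run_cells(prep, psets, nspec)
    r$metrics$snr <- snr
    r$audit$snr <- snr
    r
  })
  res <- list(metrics = do.call(rbind, lapply(sub, `[[`, "metrics")),
              audit = do.call(rbind, lapply(sub, `[[`, "audit")),
              gain = prep$gain, snr_values = snr_values,
              reference_snr = 4,
              rf_table = rf_ensemble_table(prep$rf_list), config = cfg)
  class(res) <- "result_set"
  res
}

#' Sweep the spectral color of the noise current
#'
#' Runs the paired ensemble under white, pink and red noise at the
#' per-color SNR values used in the study (white at SNR 0.5, pink at 2,
#' red at 4), where the SNRs are matched to drive comparable response
#' variability.
#'
#' @param cfg an [experiment_config()]
#' @param colors data.frame with columns `alpha` and `snr`
#' @return `result_set` whose tables carry `alpha` and `snr` columns
#' @export
run_noise_color_sweep <- function(cfg = experiment_config(),
                                  colors = data.frame(
                                    alpha = c(0, 1, 2),
                                    snr = c(0.5, 2, 4))) {
  prep <- prepare_experiment(cfg)
  psets <- stats::setNames(lapply(cfg$dynamics, neuron_params_by_name),
                           cfg$dynamics)
  sub <- lapply(seq_len(nrow(colors)), function(k) {
    nspec <- noise_spec(alpha = colors$alpha[k], snr = colors$snr[k],
                        seed = derive_seed(cfg$base_seed, "noise"))
    r <- run_cells(prep, psets, nspec)
    r$metrics$alpha <- colors$alpha[k]
    r$metrics$snr <- colors$snr[k]
    r$audit$alpha <- colors$alpha[k]
    r$audit$snr <- colors$snr[k]
    r
  })
  res <- list(metrics = do.call(rbind, lapply(sub, `[[`, "metrics")),
              audit = do.call(rbind, lapply(sub, `[[`, "audit")),
              gain = prep$gain, colors = colors,
              rf_table = rf_ensemble_table(prep$rf_list), config = cfg)
  class(res) <- "result_set"
  res
}

#' Sweep the low-threshold potassium conductance
#'
#' Runs the ensemble with phasic-base parameter sets differing only in
#' g_KLT, from the tonic limit (0 nS) to the phasic reference (50 nS),
#' with identical noise across g_KLT values for each (RF, stimulus,
#' trial) cell.
#'
#' @param cfg an [experiment_config()]
#' @param gklt_values g_KLT values (nS)
#' @return `result_set` whose metrics carry a `g_KLT` column
#' @export
run_gklt_sweep <- function(cfg = experiment_config(),
                           gklt_values = seq(0, 50, by = 10)) {
  prep <- prepare_experiment(cfg)
  psets <- stats::setNames(gklt_sweep_params(gklt_values),
                           sprintf("gklt%02d", gklt_values))
  nspec <- noise_spec(alpha = cfg$alpha, snr = cfg$snr,
                      seed = derive_seed(cfg$base_seed, "noise"))
  res <- run_cells(prep, psets, nspec)
  res$metrics$g_KLT <- gklt_values[match(res$metrics$dynamics,
                                         names(psets))]
  res$gklt_values <- gklt_values
  res$rf_table <- rf_ensemble_table(prep$rf_list)
  res$config <- cfg
  class(res) <- "result_set"
  res
}

#' Sweep the temporal modulation frequency of the RF
#'
#' Draws `n_base_rfs` base RFs and, holding all other RF parameters
#' fixed, sets the temporal modulation frequency to each value in
#' `omega_t_values`; every variant is paired with phasic and tonic
#' dynamics. The resulting table supports the interaction test of
#' selectivity against dynamics x temporal modulation.
#'
#' @param cfg an [experiment_config()]; `n_rfs` is ignored here
#' @param omega_t_values temporal modulation frequencies (Hz)
#' @param n_base_rfs number of base RFs
#' @return `result_set` whose metrics carry `base_rf` and `omega_t`
#'   columns
#' @export
run_omega_t_sweep <- function(cfg = experiment_config(),
                              omega_t_values = seq(10, 80, by = 10),
                              n_base_rfs = 8) {
  bases <- sample_rf_ensemble(n_base_rfs, cfg$rf_ranges,
                              seed = derive_seed(cfg$base_seed, "rf"))
  variants <- list()
  map <- list()
  for (b in seq_along(bases)) {
    for (om in omega_t_values) {
      v <- rf_sweep_omega_t(bases[[b]], om)[[1]]
      variants[[length(variants) + 1]] <- v
      map[[length(map) + 1]] <- data.frame(base_rf = b, omega_t = om)
    }
  }
  map <- do.call(rbind, map)
  cfg$n_rfs <- length(variants)
  prep <- prepare_experiment(cfg, rf_list = variants,
                             gain_groups = map$base_rf)
  psets <- stats::setNames(lapply(cfg$dynamics, neuron_params_by_name),
                           cfg$dynamics)
  nspec <- noise_spec(alpha = cfg$alpha, snr = cfg$snr,
                      seed = derive_seed(cfg$base_seed, "noise"))
  res <- run_cells(prep, psets, nspec)
  res$metrics$base_rf <- map$base_rf[res$metrics$rf]
  res$metrics$omega_t <- map$omega_t[res$metrics$rf]
  res$rf_table <- rf_ensemble_table(prep$rf_list)
  res$config <- cfg
  class(res) <- "result_set"
  res
}

#' Paired phasic-tonic metric differences of a result set
#'
#' Joins the phasic and tonic rows of a `result_set` metric table by RF
#' and returns per-pair differences for each rate-coding metric.
#'
#' @param res a `result_set` with both dynamics present
#' @return data.frame with one row per RF pair: phasic and tonic values
#'   and `d_*` difference columns (phasic minus tonic)
#' @export
paired_metrics <- function(res) {
  m <- res$metrics
  ph <- m[m$dynamics == "phasic", ]
  to <- m[m$dynamics == "tonic", ]
  key <- intersect(ph$rf, to$rf)
  ph <- ph[match(key, ph$rf), ]
  to <- to[match(key, to$rf), ]
  out <- data.frame(rf = key)
  for (v in c("A", "H_T", "H_N", "MI", "efficiency", "mean_rate")) {
    out[[paste0(v, "_phasic")]] <- ph[[v]]
    out[[paste0(v, "_tonic")]] <- to[[v]]
    out[[paste0("d_", v)]] <- ph[[v]] - to[[v]]
  }
  out
}

#' @export
print.result_set <- function(x, ...) {
  cat(sprintf("<result_set> %d model rows\n", nrow(x$metrics)))
  invisible(x)
}
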