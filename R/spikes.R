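# Spike extraction from voltage traces and syllable-by-trial rate tables,
# the substrate of all rate-coding metrics.

#' Detect spikes in a voltage trace
#'
#' Window discriminator: a spike is recorded at the local voltage maximum
#' within `peak_window` after each upward crossing of `threshold`;
#' crossings within `min_isi` of the previous accepted spike are ignored.
#'
#' @param voltage membrane potential trace (mV), uniformly sampled
#' @param dt sample interval (s)
#' @param threshold detection threshold (mV); spikes in this model family
#'   overshoot 0 mV, so the default separates them from subthreshold
#'   fluctuations
#' @param min_isi refractory window (s)
#' @param peak_window search window for the spike peak after a crossing (s)
#' @return object of class `spike_train`: list with `times` (s, sorted),
#'   `threshold` and the detection settings
#' @export
detect_spikes <- function(voltage, dt, threshold = -20, min_isi = 2e-3,
                          peak_window = 2e-3) {
  v <- as.numeric(voltage)
  n <- length(v)
  crossings <- which(v[-1] >= threshold & v[-n] < threshold)
  wpk <- max(1L, round(peak_window / dt))
  times <- numeric(0)
  last <- -Inf
  for (i in crossings) {
    t_cross <- (i - 1) * dt
    if (t_cross - last < min_isi) next
    j <- i + which.max(v[(i + 1):min(n, i + wpk)])
    t_peak <- (j - 1) * dt
    times <- c(times, t_peak)
    last <- t_peak
  }
  structure(list(times = times, threshold = threshold, min_isi = min_isi,
                 n_samples = n, dt = dt),
            class = "spike_train")
}

#' Build a syllable-by-trial spike-rate table
#'
#' Assigns each spike to the syllable interval containing it (half-open
#' \[onset, offset): a spike exactly at an offset belongs to the next
#' interval or gap) and computes the rate `r_ij` for syllable class `i`
#' in trial `j` as spike count divided by duration. Repeated syllables
#' (same class label within a stimulus) are pooled: their counts and
#' durations are summed within each trial before dividing.
#'
#' @param spikes data.frame with one row per spike: columns `time` (s,
#'   relative to stimulus onset), `stim` (stimulus identifier) and
#'   `trial` (integer). Trials with zero spikes need no rows but must be
#'   covered by `n_trials`.
#' @param segments data.frame with one row per syllable occurrence:
#'   columns `stim`, `onset`, `offset`, `label`
#' @param n_trials total number of trials (so silent trials contribute
#'   zero rates)
#' @return data.frame of class `rate_table`: one row per (class, trial)
#'   with columns `class`, `trial`, `count`, `duration`, `rate` (Hz)
#' @export
rate_table <- function(spikes, segments, n_trials) {
  need <- c("stim", "onset", "offset", "label")
  if (!all(need %in% names(segments)))
    stop("segments must have columns stim, onset, offset, label")
  if (nrow(spikes) > 0) {
    if (!all(c("time", "stim", "trial") %in% names(spikes)))
      stop("spikes must have columns time, stim, trial")
    if (!all(spikes$stim %in% segments$stim))
      stop("spikes reference stimuli absent from the segmentation")
    if (any(spikes$trial > n_trials))
      stop("spike trial index exceeds n_trials")
  }
  segments$class <- paste(segments$stim, segments$label, sep = "/")
  classes <- unique(segments$class)
  # duration pooled over occurrences of a class (constant across trials)
  dur <- vapply(classes, function(cl) {
    s <- segments[segments$class == cl, ]
    sum(s$offset - s$onset)
  }, numeric(1))

  counts <- matrix(0, nrow = length(classes), ncol = n_trials,
                   dimnames = list(classes, NULL))
  if (nrow(spikes) > 0) {
    for (st in unique(segments$stim)) {
      seg_s <- segments[segments$stim == st, ]
      sp_s <- spikes[spikes$stim == st, ]
      if (nrow(sp_s) == 0) next
      # half-open [onset, offset): index of containing interval or 0
      idx <- findInterval(sp_s$time, seg_s$onset)
      inside <- idx > 0 & sp_s$time < seg_s$offset[pmax(idx, 1)]
      for (k in which(inside)) {
        cl <- seg_s$class[idx[k]]
        tr <- sp_s$trial[k]
        counts[cl, tr] <- counts[cl, tr] + 1
      }
    }
  }
  out <- data.frame(
    class = rep(classes, n_trials),
    trial = rep(seq_len(n_trials), each = length(classes)),
    count = as.vector(counts),
    duration = rep(dur, n_trials),
    stringsAsFactors = FALSE)
  out$rate <- out$count / out$duration
  class(out) <- c("rate_table", "data.frame")
  out
}

#' Tabulate spike trains as a tidy data.frame
#'
#' @param trains named or unnamed list of `spike_train` objects
#' @param meta optional data.frame with one row of metadata per train
#'   (recycled columns are bound to the spike rows)
#' @return data.frame with one row per spike (column `time` plus metadata)
#' @export
spike_table <- function(trains, meta = NULL) {
  rows <- lapply(seq_along(trains), function(i) {
    tt <- trains[[i]]$times
    if (length(tt) == 0) return(NULL)
    df <- data.frame(time = tt)
    if (!is.null(meta)) df <- cbind(df, meta[rep(i, length(tt)), ,
                                             drop = FALSE])
    df
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(time = numeric(0))
  rownames(out) <- NULL
  out
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.3f s\n", length(x$times),
              x$n_samples * x$dt))
  invisible(x)
}
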