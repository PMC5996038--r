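#' Centro-parietal channel set
#'
#' The nine channels over which decision-related activity is averaged in
#' the encoding analyses.
#'
#' @return character vector of channel labels.
#' @export
cp_channels <- function() {
  c("CP1", "CP2", "CPZ", "P1", "P2", "PZ", "PO1", "PO2", "POZ")
}

#' Temporal response kernel of the EEG forward model
#'
#' Zero before `onset`, half-cosine ramp to 1 at `peak`, half-cosine decay
#' back to zero over `decay` seconds. A short rise keeps the kernel's
#' half-maximum crossing close to the onset, so onset-latency estimators
#' are well-posed on this forward model.
#'
#' @param times numeric vector of times (s).
#' @param onset,peak kernel onset and peak times (s), onset < peak.
#' @param decay decay duration after the peak (s).
#' @return kernel values in [0, 1].
#' @export
response_kernel <- function(times, onset, peak, decay = 0.15) {
  if (!(onset < peak)) stop("kernel onset must precede its peak")
  k <- numeric(length(times))
  up <- times >= onset & times <= peak
  k[up] <- 0.5 * (1 - cos(pi * (times[up] - onset) / (peak - onset)))
  down <- times > peak & times <= peak + decay
  k[down] <- 0.5 * (1 + cos(pi * (times[down] - peak) / decay))
  k
}

#' EEG generator configuration
#'
#' Forward model for synthetic epochs: each encoding entry injects
#' `amplitude * kernel(t) * weight(channel) * covariate(trial)` into the
#' data, on top of white Gaussian noise. Defaults place a shared-association
#' component at 270 ms and an emotion-strength component at 390 ms on the
#' centro-parietal channels, the latency ordering the encoding analyses are
#' designed to resolve.
#'
#' @param entries list of encoding entries; each is a list with `covariate`
#'   (name of a per-trial covariate), `onset` and `peak` (s), `amplitude`,
#'   and `weights` (named channel weight vector).
#' @param noise_sd Gaussian noise standard deviation per sample (same
#'   arbitrary units as the amplitudes).
#' @param srate sampling rate (Hz).
#' @param window epoch time window (s relative to stimulus onset).
#' @param channels channel labels; defaults to the centro-parietal set plus
#'   three frontal channels that carry no signal.
#' @return list of class `eeg_gen_params`.
#' @export
eeg_gen_params <- function(entries = NULL, noise_sd = 2, srate = 100,
                           window = c(-0.1, 0.8), channels = NULL) {
  if (is.null(channels)) channels <- c(cp_channels(), "FZ", "F1", "F2")
  if (is.null(entries)) {
    cpw <- setNames(rep(1, length(cp_channels())), cp_channels())
    entries <- list(
      list(covariate = "shared", onset = 0.270, peak = 0.290,
           amplitude = 1, weights = cpw),
      list(covariate = "emotion", onset = 0.390, peak = 0.410,
           amplitude = 1, weights = cpw))
  }
  for (e in entries) {
    if (!(e$onset < e$peak)) stop("encoding entry onset must precede peak")
    if (!all(is.finite(e$amplitude))) stop("non-finite amplitude")
  }
  structure(list(entries = entries, noise_sd = noise_sd, srate = srate,
                 window = window, channels = channels),
            class = "eeg_gen_params")
}

#' Simulate one subject's EEG epochs
#'
#' @param trials trial table rows the epochs are time-locked to (their row
#'   order defines the trial axis).
#' @param covariates data.frame of per-trial covariate values, one row per
#'   trial row, columns named as referenced by the generator entries.
#' @param gen an [eeg_gen_params()].
#' @param seed integer seed.
#' @return list of class `eeg_epochs`: `data` (trial x channel x time
#'   array), `channels`, `times`, `srate`, `trial_index` (row indices into
#'   `trials`).
#' @export
simulate_eeg <- function(trials, covariates, gen = eeg_gen_params(),
                         seed = 1L) {
  set.seed(as.integer(seed))
  nt <- nrow(trials)
  if (nrow(covariates) != nt)
    stop("covariates must have one row per trial")
  times <- seq(gen$window[1], gen$window[2], by = 1 / gen$srate)
  nc <- length(gen$channels); ns <- length(times)
  data <- array(stats::rnorm(nt * nc * ns, 0, gen$noise_sd),
                dim = c(nt, nc, ns),
                dimnames = list(NULL, gen$channels, NULL))
  for (e in gen$entries) {
    if (is.null(covariates[[e$covariate]]))
      stop("covariate '", e$covariate, "' not found")
    v <- covariates[[e$covariate]]
    k <- e$amplitude * response_kernel(times, e$onset, e$peak)
    w <- setNames(numeric(nc), gen$channels)
    w[names(e$weights)] <- e$weights
    # outer product trial x channel x time, added channel by channel
    vk <- outer(v, k)                       # trial x time
    for (ci in which(w != 0))
      data[, ci, ] <- data[, ci, ] + w[ci] * vk
  }
  structure(list(data = data, channels = gen$channels, times = times,
                 srate = gen$srate, trial_index = seq_len(nt)),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat("EEG epochs:", dim(x$data)[1], "trials x", dim(x$data)[2],
      "channels x", dim(x$data)[3], "samples @", x$srate, "Hz\n")
  invisible(x)
}
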