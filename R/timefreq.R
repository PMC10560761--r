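## Morlet-wavelet time-frequency decomposition of total power.
##
## Each trial is convolved with complex Morlet wavelets (analytic,
## Gaussian-enveloped); per-trial squared magnitudes are averaged over
## trials (total power: evoked plus induced) and then over the channel
## subset. Convolution is FFT-based with zero padding sized to the
## longest wavelet. Samples near the epoch edges lose wavelet energy
## beyond the data support; power is divided by the analytically known
## in-support energy fraction, which makes the estimate unbiased for
## stationary signals, and samples with less than half of the energy in
## support are marked invalid (NA).

#' Time-frequency configuration
#'
#' @param freqs_hz Analysis frequencies, strictly increasing (default
#'   1-60 Hz in 1 Hz steps).
#' @param n_cycles Wavelet widths; default log-spaced from 4 cycles at
#'   1 Hz to 10 cycles at 60 Hz:
#'   `n_cycles(f) = 4 * (10/4)^(log(f/1)/log(60/1))`.
#' @param baseline_ms Baseline window for dB normalization, default
#'   `c(-850, -650)`.
#' @param channel_subset `"parieto_occipital"` (default) or `"all"`.
#' @return A `wm_tfr_config` list.
#' @export
tfr_config <- function(freqs_hz = 1:60, n_cycles = NULL,
                       baseline_ms = c(-850, -650),
                       channel_subset = c("parieto_occipital", "all")) {
  if (any(diff(freqs_hz) <= 0)) stop("freqs_hz must be strictly increasing")
  if (is.null(n_cycles))
    n_cycles <- 4 * (10 / 4)^(log(freqs_hz / 1) / log(60 / 1))
  stopifnot(length(n_cycles) == length(freqs_hz), all(n_cycles > 0))
  structure(list(freqs_hz = freqs_hz, n_cycles = n_cycles,
                 baseline_ms = baseline_ms,
                 channel_subset = match.arg(channel_subset)),
            class = "wm_tfr_config")
}

## energy fraction of a Gaussian wavelet (power envelope sd = sigma_t/sqrt(2))
## that overlaps the data support, per time sample
edge_energy_fraction <- function(n_t, fs, sigma_t) {
  s <- sigma_t / sqrt(2) * fs          # in samples
  t <- seq_len(n_t) - 1
  pnorm((t + 0.5) / s) + pnorm((n_t - 0.5 - t) / s) - 1
}

#' Morlet-wavelet total power
#'
#' @param epochs A `wm_epochs` object.
#' @param cfg A [tfr_config()].
#' @return A `wm_tfr` object with `power`: a list (one per condition) of
#'   frequency x time matrices of raw power (nominal microvolts squared),
#'   channel-averaged over the subset, cue sides pooled; invalid edge
#'   samples are NA.
#' @export
morlet_power <- function(epochs, cfg = tfr_config()) {
  tms <- epochs$time_ms
  n_t <- length(tms)
  fs <- epochs$schedule$fs_hz
  mon <- epochs$montage
  chans <- if (cfg$channel_subset == "parieto_occipital")
    which(mon$parieto_occipital) else seq_len(nrow(mon))
  if (length(chans) == 0) stop("empty channel subset")
  freqs <- cfg$freqs_hz
  sigma_t <- cfg$n_cycles / (2 * pi * freqs)
  max_support <- 2 * ceiling(3.5 * max(sigma_t) * fs)
  if (max_support >= n_t * 4)
    stop("epoch too short for the longest wavelet")
  nfft <- stats::nextn(n_t + max_support)
  fgrid <- (0:(nfft - 1)) / nfft * fs

  ## analytic Morlet in the frequency domain: Gaussian of sd f/n_cycles
  ## centred on the wavelet frequency, unit gain at centre, positive
  ## frequencies doubled so a unit-amplitude tone yields unit power
  wavelet_fft <- function(fi) {
    sf <- freqs[fi] / cfg$n_cycles[fi]
    w <- 2 * exp(-(fgrid - freqs[fi])^2 / (2 * sf^2))
    w[fgrid > fs / 2] <- 0
    w
  }
  wl <- lapply(seq_along(freqs), wavelet_fft)
  efrac <- lapply(seq_along(freqs), function(fi)
    edge_energy_fraction(n_t, fs, sigma_t[fi]))

  conds <- unique(epochs$cells$condition)
  power <- lapply(conds, function(cond) {
    cis <- which(epochs$cells$condition == cond)
    acc <- matrix(0, length(freqs), n_t)
    n_acc <- 0L
    for (ci in cis) for (ch in chans) {
      seg <- epochs$data[ci, ch, , , drop = TRUE]
      if (is.null(dim(seg))) seg <- matrix(seg, ncol = 1)
      Z <- ncol(seg)
      pad <- rbind(seg, matrix(0, nfft - n_t, Z))
      FT <- stats::mvfft(pad)
      for (fi in seq_along(freqs)) {
        conv <- stats::mvfft(FT * wl[[fi]], inverse = TRUE) / nfft
        acc[fi, ] <- acc[fi, ] +
          rowSums(Mod(conv[1:n_t, , drop = FALSE])^2) / efrac[[fi]]
      }
      n_acc <- n_acc + Z
    }
    acc / n_acc      # n_acc counts channel-trial pairs: joint mean
  })
  ## mark invalid edge zones (less than half the wavelet energy in support)
  for (k in seq_along(power)) {
    for (fi in seq_along(freqs)) {
      bad <- efrac[[fi]] < 0.5
      if (any(bad)) power[[k]][fi, bad] <- NA_real_
    }
  }
  names(power) <- conds
  structure(list(subject_id = epochs$subject_id, group = epochs$group,
                 power = power, freqs_hz = freqs, time_ms = tms,
                 scale = "raw", config = cfg),
            class = "wm_tfr")
}

#' Decibel baseline normalization
#'
#' Per frequency, `dB(t, f) = 10 log10(P(t, f) / mean P(baseline, f))`.
#'
#' @param tfr A raw-power `wm_tfr`.
#' @param baseline_ms Baseline window; defaults to the configuration's.
#' @return A dB-scaled `wm_tfr`.
#' @export
db_baseline <- function(tfr, baseline_ms = NULL) {
  if (tfr$scale != "raw") stop("tfr is already baseline-normalized")
  if (is.null(baseline_ms)) baseline_ms <- tfr$config$baseline_ms
  sel <- tfr$time_ms >= baseline_ms[1] & tfr$time_ms <= baseline_ms[2]
  if (!any(sel)) stop("baseline window outside epoch")
  tfr$power <- lapply(tfr$power, function(p) {
    b <- rowMeans(p[, sel, drop = FALSE], na.rm = TRUE)
    if (any(!is.finite(b)) || any(b <= 0))
      stop("baseline power must be positive")
    10 * log10(p / b)
  })
  tfr$scale <- "dB"
  tfr$baseline_ms <- baseline_ms
  tfr
}

#' Mean over a time-frequency region of interest
#'
#' Unweighted mean of the map values over the rectangle spanned by a
#' phase window (half-open in time) and a frequency band (edges
#' inclusive).
#'
#' @param map Frequency x time matrix.
#' @param freqs_hz,time_ms Axes of `map`.
#' @param band Two-element frequency band (Hz), edges inclusive.
#' @param window_ms Two-element time window, half-open `[t1, t2)`.
#' @return Scalar mean.
#' @export
roi_mean <- function(map, freqs_hz, time_ms, band, window_ms) {
  fsel <- freqs_hz >= band[1] & freqs_hz <= band[2]
  tsel <- time_ms >= window_ms[1] & time_ms < window_ms[2]
  if (!any(fsel) || !any(tsel)) stop("empty region of interest")
  mean(map[fsel, tsel])
}

#' Phase-by-band ROI table for one subject
#'
#' @param tfr A dB-scaled `wm_tfr`.
#' @param phases,bands Named window lists; defaults [phase_windows()],
#'   [frequency_bands()] restricted to bands inside the analyzed range.
#' @return Long data.frame: subject, group, condition, phase, band, db.
#' @export
tfr_roi_table <- function(tfr, phases = phase_windows(),
                          bands = frequency_bands()) {
  if (tfr$scale != "dB") stop("ROI statistics expect a dB-scaled map")
  bands <- Filter(function(b) b[1] >= min(tfr$freqs_hz) &&
                    b[2] <= max(tfr$freqs_hz), bands)
  if (length(bands) == 0) stop("no frequency band inside the analyzed range")
  out <- do.call(rbind, lapply(names(tfr$power), function(cond) {
    do.call(rbind, lapply(names(phases), function(ph) {
      do.call(rbind, lapply(names(bands), function(bd) {
        data.frame(subject = tfr$subject_id, group = tfr$group,
                   condition = cond, phase = ph, band = bd,
                   db = roi_mean(tfr$power[[cond]], tfr$freqs_hz,
                                 tfr$time_ms, bands[[bd]], phases[[ph]]),
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Group-difference time-frequency map
#'
#' Grand average over subjects and conditions per group, then patients
#' minus controls.
#'
#' @param tfrs List of `wm_tfr` objects on identical grids.
#' @return Frequency x time difference matrix.
#' @export
group_difference_map <- function(tfrs) {
  if (length(tfrs) == 0) stop("empty cohort")
  f0 <- tfrs[[1]]$freqs_hz; t0 <- tfrs[[1]]$time_ms
  for (tf in tfrs)
    if (!isTRUE(all.equal(tf$freqs_hz, f0)) ||
        !isTRUE(all.equal(tf$time_ms, t0)))
      stop("time-frequency grids differ between subjects")
  avg <- function(group) {
    sel <- Filter(function(tf) tf$group == group, tfrs)
    if (length(sel) == 0) stop("no subjects in group ", group)
    maps <- lapply(sel, function(tf) Reduce(`+`, tf$power) / length(tf$power))
    Reduce(`+`, maps) / length(maps)
  }
  avg("patient") - avg("control")
}
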