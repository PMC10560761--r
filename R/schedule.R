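#' Task schedule for the lateralized change-detection trial
#'
#' Timing of one trial of the visual working-memory task, expressed
#' relative to the onset of the memory array (time 0). An arrow cue
#' (200 ms) is followed by a fixation cross (400 ms), the memory array
#' (300 ms), a delay (1400 ms) and a test array (4000 ms). Epochs span
#' the half-open window [-1000, 4500) ms sampled at 500 Hz, which gives
#' exactly 2750 samples; the time stamp of a sample is the left edge of
#' its sampling interval.
#'
#' @param fs_hz Sampling rate in Hz.
#' @param epoch_window_ms Two-element numeric, half-open epoch window in
#'   ms relative to memory-array onset.
#' @return An object of class `wm_schedule`: a list with the event
#'   timing fields, the sampling rate, the epoch window, `n_samples`
#'   and `time_ms` (the time axis).
#' @export
task_schedule <- function(fs_hz = 500, epoch_window_ms = c(-1000, 4500)) {
  stopifnot(fs_hz > 0, length(epoch_window_ms) == 2,
            epoch_window_ms[1] < epoch_window_ms[2])
  step <- 1000 / fs_hz
  n <- (epoch_window_ms[2] - epoch_window_ms[1]) * fs_hz / 1000
  if (abs(n - round(n)) > 1e-9)
    stop("epoch window is not an integer number of samples at this sampling rate")
  n <- as.integer(round(n))
  sch <- list(
    cue_onset_ms     = -600,
    cue_dur_ms       = 200,
    fixation_dur_ms  = 400,
    memarray_dur_ms  = 300,
    delay_dur_ms     = 1400,
    testarray_dur_ms = 4000,
    fs_hz            = fs_hz,
    epoch_window_ms  = epoch_window_ms,
    n_samples        = n,
    time_ms          = seq(epoch_window_ms[1], by = step, length.out = n)
  )
  # cue + fixation lead exactly to memory-array onset at 0
  stopifnot(sch$cue_onset_ms + sch$cue_dur_ms + sch$fixation_dur_ms == 0)
  class(sch) <- "wm_schedule"
  sch
}

#' Electrode montage with left/right pairing
#'
#' A montage table for synthetic cohorts. Each channel is labelled with
#' its hemisphere (`L`, `R`, or `M` for midline), the label of its
#' mirror-symmetric partner, and whether it belongs to the
#' parieto-occipital subset used for the contralateral delay activity
#' and the time-frequency region-of-interest statistics.
#'
#' The default 32-channel layout follows a standard active-electrode
#' cap and contains four parieto-occipital pairs (P3/P4, P7/P8, O1/O2,
#' PO9/PO10). `n_channels = 8` gives a reduced posterior montage with
#' two parieto-occipital pairs, convenient for small simulations;
#' `n_channels = 128` tiles the 32-channel layout with interpolated
#' labels so that full-montage configurations can be exercised.
#'
#' @param n_channels One of 8, 32 (default) or 128.
#' @return A data.frame with columns `label`, `hemisphere`, `pair` and
#'   `parieto_occipital`.
#' @export
montage <- function(n_channels = 32) {
  base <- data.frame(
    label = c("Fp1","Fp2","F7","F3","Fz","F4","F8","FC5","FC1","FC2","FC6",
              "T7","C3","Cz","C4","T8","TP9","CP5","CP1","CP2","CP6","TP10",
              "P7","P3","Pz","P4","P8","PO9","O1","Oz","O2","PO10"),
    hemisphere = c("L","R","L","L","M","R","R","L","L","R","R",
                   "L","L","M","R","R","L","L","L","R","R","R",
                   "L","L","M","R","R","L","L","M","R","R"),
    pair = c("Fp2","Fp1","F8","F4",NA,"F3","F7","FC6","FC2","FC1","FC5",
             "T8","C4",NA,"C3","T7","TP10","CP6","CP2","CP1","CP5","TP9",
             "P8","P4",NA,"P3","P7","PO10","O2",NA,"O1","PO9"),
    parieto_occipital = FALSE,
    stringsAsFactors = FALSE)
  base$parieto_occipital <- base$label %in%
    c("P3","P4","P7","P8","O1","O2","PO9","PO10")
  if (n_channels == 32) return(base)
  if (n_channels == 8) {
    m <- base[base$label %in% c("P3","P4","O1","O2","Cz","Fz","C3","C4"), ]
    m$parieto_occipital <- m$label %in% c("P3","P4","O1","O2")
    rownames(m) <- NULL
    return(m)
  }
  if (n_channels == 128) {
    reps <- ceiling(128 / 32)
    m <- base[rep(seq_len(32), reps)[1:128], ]
    k <- rep(seq_len(reps), each = 32)[1:128]
    m$label <- ifelse(k == 1, m$label, paste0(m$label, "_", k))
    m$pair <- ifelse(is.na(m$pair) | k == 1, m$pair, paste0(m$pair, "_", k))
    # only the first replicate of the posterior ring is treated as the
    # analysis subset; duplicates act as additional generic channels
    m$parieto_occipital <- m$parieto_occipital & k == 1
    rownames(m) <- NULL
    return(m)
  }
  stop("n_channels must be one of 8, 32, 128")
}

#' Working-memory task phase windows
#'
#' Phase windows on the trial timeline (ms relative to memory-array
#' onset): preparation (-400 to 0), encoding (0 to 300), maintenance
#' (300 to 1700) and retrieval (1700 to 3060). The retrieval window end
#' corresponds to the slower group's mean reaction time plus one
#' standard deviation after test-array onset.
#'
#' @return Named list of two-element numeric windows.
#' @export
phase_windows <- function() {
  list(preparation = c(-400, 0), encoding = c(0, 300),
       maintenance = c(300, 1700), retrieval = c(1700, 3060))
}

#' Frequency bands of interest
#'
#' Theta (4-7 Hz), alpha (8-12 Hz), beta (13-29 Hz) and gamma
#' (30-60 Hz); band edges inclusive on the integer frequency grid, so
#' the bands are disjoint and cover 4-60 Hz.
#'
#' @return Named list of two-element numeric bands (Hz).
#' @export
frequency_bands <- function() {
  list(theta = c(4, 7), alpha = c(8, 12), beta = c(13, 29), gamma = c(30, 60))
}
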