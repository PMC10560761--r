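## Synthetic cohort generator.
##
## Signal model per subject, channel and trial (nominal microvolts):
##   x(t) = 1/f background noise
##        + alpha-band oscillation (posterior channels), amplitude-
##          modulated by the subject's planted suppression envelope and
##          partially phase-reset at cue / memory-array / test-array
##          onsets
##        + task-locked slow evoked deflections (identical for all
##          subjects)
##        + a sustained lateralized potential on parieto-occipital
##          channels contralateral to the cue (the CDA)
## Group effects are planted only through the alpha envelope; the
## baseline window is left untouched so baseline statistics are
## group-independent.

#' Cohort configuration
#'
#' Parameters of the synthetic cohort. Defaults reproduce the study
#' conditions: 15 patients and 15 controls, three interleaved
#' conditions (2, 2+2, 4) by two cue sides, 200 trials per condition,
#' 500 Hz sampling, epochs of 2750 samples, and group-by-phase alpha
#' suppression levels (dB change from a -850 to -650 ms baseline) taken
#' from the study's group summary statistics.
#'
#' @param n_patients,n_controls Group sizes.
#' @param n_channels Montage size (8, 32 or 128); see [montage()].
#' @param trials_per_condition Trials per condition (split equally over
#'   the two cue sides).
#' @param alpha_db Named list with `patient` and `control` entries, each
#'   a list of `mean` and `sd` length-4 vectors (preparation, encoding,
#'   maintenance, retrieval) of dB change from baseline.
#' @param alpha_phase_corr Correlation of a subject's suppression level
#'   across task phases (shared subject intercept).
#' @param alpha_rms_uv Baseline RMS amplitude of the posterior alpha
#'   oscillation.
#' @param alpha_subject_cv Between-subject coefficient of variation of
#'   the baseline alpha amplitude.
#' @param alpha_trial_cv Trial-to-trial amplitude jitter (lognormal CV).
#' @param phase_reset List with `itc` (peak inter-trial phase clustering
#'   after a stimulus event) and `tau_ms` (its exponential decay time).
#' @param noise List with `exponent` (power spectral density falls as
#'   1/f^exponent) and `broadband_rms_uv`.
#' @param cda_uv Named numeric, planted contralateral-minus-ipsilateral
#'   amplitude per condition over the 300-1700 ms window.
#' @param behavior Named list with `patient` and `control` entries, each
#'   containing `hit_rate` and `false_alarm_rate` (length 3, one per
#'   condition) and `rt_mean_ms`, `rt_sd_ms`.
#' @param seed Master seed; expands to one RNG stream per subject, so a
#'   subject's data do not depend on the cohort size.
#' @return A `wm_cohort_config` list.
#' @export
cohort_config <- function(n_patients = 15, n_controls = 15,
                          n_channels = 32, trials_per_condition = 200,
                          alpha_db = NULL,
                          alpha_phase_corr = 0.8,
                          alpha_rms_uv = 10,
                          alpha_subject_cv = 0.02,
                          alpha_trial_cv = 0.2,
                          phase_reset = list(itc = 0.65, tau_ms = 800),
                          noise = list(exponent = 1, broadband_rms_uv = 3.69),
                          cda_uv = c("2" = -0.5, "2+2" = -0.7, "4" = -1.0),
                          behavior = NULL,
                          seed = 1L) {
  if (is.null(alpha_db)) {
    alpha_db <- list(
      patient = list(mean = c(preparation = -1.09, encoding = -0.83,
                              maintenance = -1.11, retrieval = -1.13),
                     sd   = c(0.81, 1.00, 0.98, 1.13)),
      control = list(mean = c(preparation = -2.36, encoding = -2.17,
                              maintenance = -2.29, retrieval = -2.50),
                     sd   = c(1.81, 1.93, 1.95, 2.16)))
  }
  if (is.null(behavior)) {
    behavior <- list(
      patient = list(hit_rate = c("2" = 0.915, "2+2" = 0.894, "4" = 0.696),
                     false_alarm_rate = c("2" = 0.10, "2+2" = 0.12, "4" = 0.15),
                     rt_mean_ms = 1000, rt_sd_ms = 360),
      control = list(hit_rate = c("2" = 0.915, "2+2" = 0.894, "4" = 0.696),
                     false_alarm_rate = c("2" = 0.10, "2+2" = 0.12, "4" = 0.15),
                     rt_mean_ms = 900, rt_sd_ms = 300))
  }
  cfg <- list(n_patients = n_patients, n_controls = n_controls,
              n_channels = n_channels,
              trials_per_condition = trials_per_condition,
              conditions = c("2", "2+2", "4"),
              set_sizes = c("2" = 2, "2+2" = 2, "4" = 4),
              alpha_db = alpha_db, alpha_phase_corr = alpha_phase_corr,
              alpha_rms_uv = alpha_rms_uv,
              alpha_subject_cv = alpha_subject_cv,
              alpha_trial_cv = alpha_trial_cv,
              phase_reset = phase_reset, noise = noise, cda_uv = cda_uv,
              behavior = behavior, seed = as.integer(seed),
              schedule = task_schedule())
  validate_cohort_config(cfg)
  class(cfg) <- "wm_cohort_config"
  cfg
}

#' Null-effect cohort configuration
#'
#' Convenience wrapper: all planted group effects (alpha suppression,
#' CDA, behavioral differences) are removed, so the two groups are
#' exchangeable. Used for calibration checks.
#'
#' @param ... Passed to [cohort_config()].
#' @return A `wm_cohort_config` with zeroed effects.
#' @export
null_cohort_config <- function(...) {
  zero <- list(mean = rep(0, 4), sd = rep(0, 4))
  beh <- list(hit_rate = c("2" = 0.9, "2+2" = 0.9, "4" = 0.7),
              false_alarm_rate = c("2" = 0.1, "2+2" = 0.1, "4" = 0.15),
              rt_mean_ms = 950, rt_sd_ms = 320)
  cohort_config(alpha_db = list(patient = zero, control = zero),
                cda_uv = c("2" = 0, "2+2" = 0, "4" = 0),
                behavior = list(patient = beh, control = beh), ...)
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_patients < 1 || cfg$n_controls < 1)
    stop("group sizes must be positive")
  if (cfg$trials_per_condition < 2 || cfg$trials_per_condition %% 2 != 0)
    stop("trials_per_condition must be a positive even count")
  for (g in c("patient", "control")) {
    b <- cfg$behavior[[g]]
    if (any(b$hit_rate < 0 | b$hit_rate > 1) ||
        any(b$false_alarm_rate < 0 | b$false_alarm_rate > 1))
      stop("hit and false-alarm rates must lie in [0, 1]")
    if (any(cfg$alpha_db[[g]]$sd < 0)) stop("alpha dB SDs must be >= 0")
  }
  invisible(cfg)
}

## ---- spectral synthesis helpers ----

## unit-RMS band-limited Gaussian process (flat spectrum inside band)
synth_narrowband <- function(n, f1, f2, fs, nfft = stats::nextn(n)) {
  fr <- (0:(nfft - 1)) / nfft * fs
  amp <- as.numeric(fr >= f1 & fr <= f2)
  z <- complex(real = rnorm(nfft), imaginary = rnorm(nfft)) * amp
  x <- Re(stats::fft(z, inverse = TRUE))[1:n]
  x / stats::sd(x)
}

## unit-RMS 1/f^exponent noise, one column per trial/channel
synth_onef <- function(n, ncol, exponent, fs, nfft = stats::nextn(n)) {
  if (nfft %% 2 == 1) nfft <- nfft + 1
  fr <- (0:(nfft - 1)) / nfft * fs
  half <- nfft %/% 2
  amp <- c(0, 1 / fr[2:(half + 1)]^(exponent / 2))
  amp <- c(amp, rev(amp[2:half]))
  z <- matrix(complex(real = rnorm(nfft * ncol), imaginary = rnorm(nfft * ncol)),
              nfft, ncol) * amp
  x <- Re(stats::mvfft(z, inverse = TRUE))[1:n, , drop = FALSE]
  sds <- sqrt(colMeans(x^2) - colMeans(x)^2)
  sweep(x, 2, sds, "/")
}

## subject suppression envelope (amplitude scale, 1 = baseline level)
alpha_envelope <- function(db, time_ms) {
  lv <- 10^(db / 20)
  approx(x = c(-1000, -500, -400, -50, 50, 250, 350, 1650, 1750, 3060, 3460, 4500),
         y = c(1, 1, lv[1], lv[1], lv[2], lv[2], lv[3], lv[3], lv[4], lv[4], 1, 1),
         xout = time_ms, rule = 2)$y
}

## inter-trial phase-clustering profile: partial phase reset at cue,
## memory-array and test-array onsets, decaying exponentially
lock_profile <- function(time_ms, itc, tau_ms) {
  lam <- rep(0, length(time_ms))
  for (ev in c(-600, 0, 1700)) {
    d <- time_ms - ev
    lam <- pmax(lam, ifelse(d >= 0, itc * exp(-d / tau_ms), 0))
  }
  pmin(lam, 1)
}

## smooth plateau used for the planted CDA (300-1700 ms)
cda_shape <- function(time_ms) {
  approx(x = c(-1000, 275, 325, 1675, 1725, 4500),
         y = c(0, 0, 1, 1, 0, 0), xout = time_ms, rule = 2)$y
}

## task-locked slow evoked deflections, identical for all subjects
evoked_shape <- function(time_ms) {
  bump <- function(center, sigma, amp) amp * exp(-(time_ms - center)^2 / (2 * sigma^2))
  bump(-600, 50, 2) + bump(0, 80, 3) + bump(1700, 80, 3)
}

subject_seeds <- function(cfg) {
  n <- cfg$n_patients + cfg$n_controls
  set.seed(cfg$seed)
  # cohort-level draw order: locked-waveform seed first, then one seed
  # per subject, so adding subjects does not change existing ones
  wseed <- sample.int(.Machine$integer.max - 1, 1)
  sseeds <- sample.int(.Machine$integer.max - 1, n)
  list(waveform = wseed, subjects = sseeds)
}

#' Generate one synthetic subject
#'
#' @param config A [cohort_config()].
#' @param index Subject index in 1..(n_patients + n_controls); patients
#'   come first.
#' @return A `wm_epochs` object: list with `subject_id`, `group`, a
#'   `data` array of dimension cell x channel x time x trial (cells are
#'   condition by cue side), `cells`, `montage`, `time_ms`, `schedule`
#'   and the behavioral `log` (see [cohort_config()] for the planted
#'   parameters).
#' @export
generate_subject <- function(config, index) {
  cfg <- config
  n_sub <- cfg$n_patients + cfg$n_controls
  stopifnot(index >= 1, index <= n_sub)
  sch <- cfg$schedule
  tms <- sch$time_ms
  n_t <- sch$n_samples
  fs <- sch$fs_hz
  mon <- montage(cfg$n_channels)
  n_ch <- nrow(mon)
  Z <- cfg$trials_per_condition %/% 2L     # trials per cell (cond x side)
  cells <- expand.grid(condition = cfg$conditions, cue_side = c("left", "right"),
                       stringsAsFactors = FALSE)
  n_cell <- nrow(cells)
  group <- if (index <= cfg$n_patients) "patient" else "control"

  seeds <- subject_seeds(cfg)
  set.seed(seeds$waveform)
  ## stimulus-locked alpha trajectory shared by all subjects (phase
  ## reset aligns trial phases toward it); same narrowband family as
  ## the per-trial oscillation, so the reset mixing preserves measured
  ## band power
  w_locked <- synth_narrowband(n_t, 8, 12, fs)

  set.seed(seeds$subjects[index])
  ad <- cfg$alpha_db[[group]]
  rho <- cfg$alpha_phase_corr
  z0 <- rnorm(1)
  db <- ad$mean + ad$sd * (sqrt(rho) * z0 + sqrt(1 - rho) * rnorm(4))
  g_env <- alpha_envelope(db, tms)
  lam <- lock_profile(tms, cfg$phase_reset$itc, cfg$phase_reset$tau_ms)
  A_s <- cfg$alpha_rms_uv * exp(rnorm(1, 0, cfg$alpha_subject_cv))
  sdlog_tr <- sqrt(log(1 + cfg$alpha_trial_cv^2))

  ev <- evoked_shape(tms)
  ch_scale <- ifelse(mon$parieto_occipital, 1, 0.6)
  po <- mon$parieto_occipital
  cda_t <- cda_shape(tms)

  x <- array(0, dim = c(n_t, n_ch, Z, n_cell))
  mix_locked <- lam * w_locked
  mix_res <- sqrt(pmax(1 - lam^2, 0))
  ev_ch <- outer(ev, ch_scale)                 # n_t x n_ch
  po_idx <- which(po)
  for (ci in seq_len(n_cell)) {
    ## background noise for all channels and trials of this cell, plus
    ## the task-locked evoked deflections (recycled over trials)
    blk <- synth_onef(n_t, n_ch * Z, cfg$noise$exponent, fs, nfft = n_t) *
      cfg$noise$broadband_rms_uv
    dim(blk) <- c(n_t, n_ch, Z)
    blk <- blk + as.vector(ev_ch)
    ## posterior alpha: one realization per trial, shared across the
    ## parieto-occipital channels
    u <- vapply(seq_len(Z), function(z) synth_narrowband(n_t, 8, 12, fs, nfft = n_t),
                numeric(n_t))
    eta <- exp(rnorm(Z, -sdlog_tr^2 / 2, sdlog_tr))
    alpha_cell <- (matrix(mix_locked, n_t, Z) + u * mix_res) * (A_s * g_env)
    alpha_cell <- sweep(alpha_cell, 2, eta, "*")
    ## lateralized sustained potential, contralateral to the cue
    contra_hemi <- if (cells$cue_side[ci] == "left") "R" else "L"
    cda_amp <- cfg$cda_uv[[cells$condition[ci]]]
    for (ch in po_idx) {
      blk[, ch, ] <- blk[, ch, ] + alpha_cell
      if (mon$hemisphere[ch] == contra_hemi && cda_amp != 0)
        blk[, ch, ] <- blk[, ch, ] + cda_amp * cda_t
    }
    x[, , , ci] <- blk
  }
  x <- aperm(x, c(4, 2, 1, 3))                 # cell x channel x time x trial

  log <- generate_trial_log(cfg, group, cells, Z)

  structure(list(subject_id = sprintf("sub-%02d", index), group = group,
                 data = x, cells = cells, montage = mon, time_ms = tms,
                 schedule = sch, log = log),
            class = "wm_epochs")
}

generate_trial_log <- function(cfg, group, cells, Z) {
  b <- cfg$behavior[[group]]
  sdlog <- sqrt(log(1 + (b$rt_sd_ms / b$rt_mean_ms)^2))
  meanlog <- log(b$rt_mean_ms) - sdlog^2 / 2
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(ci) {
    cond <- cells$condition[ci]
    change <- sample(rep(c(TRUE, FALSE), each = Z / 2))
    if (length(change) < Z) change <- c(change, FALSE)
    p_diff <- ifelse(change, b$hit_rate[[cond]], b$false_alarm_rate[[cond]])
    resp <- ifelse(runif(Z) < p_diff, "different", "same")
    rt <- rlnorm(Z, meanlog, sdlog)
    over <- rt > 4000
    if (any(over)) rt[over] <- runif(sum(over), 0.5, 1) * 4000  # response window
    data.frame(condition = cond, cue_side = cells$cue_side[ci],
               set_size = cfg$set_sizes[[cond]], change = change,
               response = resp,
               correct = (resp == "different") == change,
               rt_ms = rt, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic cohort
#'
#' Materializes every subject in memory. For full-size cohorts (200
#' trials per condition) a subject's epoch array alone is ~0.8 GB, so
#' prefer [subject_map()] for reductions that only need one subject at
#' a time.
#'
#' @param config A [cohort_config()].
#' @return List of `wm_epochs` objects, patients first.
#' @export
generate_cohort <- function(config) {
  n <- config$n_patients + config$n_controls
  lapply(seq_len(n), function(i) generate_subject(config, i))
}

#' Apply a function to each subject of a cohort, one at a time
#'
#' Generates subject `i`, applies `fun`, discards the raw epochs, and
#' collects the results. Keeps peak memory at one subject regardless of
#' cohort size.
#'
#' @param config A [cohort_config()].
#' @param fun Function of one `wm_epochs` argument.
#' @return List of `fun` results, one per subject.
#' @export
subject_map <- function(config, fun) {
  n <- config$n_patients + config$n_controls
  lapply(seq_len(n), function(i) fun(generate_subject(config, i)))
}

#' @export
print.wm_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<wm_epochs> %s (%s): %d cells x %d channels x %d samples x %d trials\n",
              x$subject_id, x$group, d[1], d[2], d[3], d[4]))
  invisible(x)
}
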