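#' Threshold a group-difference map for display
#'
#' Masks (sets to NA) all values below `fraction` times the map
#' maximum. Idempotent at a fixed fraction.
#'
#' @param map Numeric matrix.
#' @param fraction Fraction of the maximum, in [0, 1] (default 0.30).
#' @return Matrix with sub-threshold values replaced by NA.
#' @export
threshold_map <- function(map, fraction = 0.30) {
  if (length(map) == 0) stop("empty map")
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  mx <- max(map, na.rm = TRUE)
  map[map < fraction * mx] <- NA_real_
  map
}

#' Locate the highest peaks of an attention trace
#'
#' Finds local maxima and returns the top `k`, enforcing a minimum
#' separation so that the reported peaks are distinct task events
#' rather than one broad bump. A constant trace has no peaks.
#'
#' @param a Attention values (or any non-negative trace).
#' @param time_ms Time axis of `a`.
#' @param k Number of peaks to report.
#' @param min_separation_ms Minimum distance between reported peaks.
#' @return Data.frame with `time_ms` and `value`, sorted by descending
#'   value; zero rows if the trace is flat.
#' @export
locate_peaks <- function(a, time_ms, k = 2, min_separation_ms = 200) {
  stopifnot(k >= 1, length(a) == length(time_ms))
  if (length(a) < 3 || diff(range(a)) == 0)
    return(data.frame(time_ms = numeric(0), value = numeric(0)))
  n <- length(a)
  is_peak <- c(FALSE, a[2:(n - 1)] >= a[1:(n - 2)] & a[2:(n - 1)] >= a[3:n], FALSE)
  ## plateaus: keep only the first sample of runs of equal values
  is_peak[is_peak & c(FALSE, diff(a) == 0)] <- FALSE
  cand <- order(a, decreasing = TRUE)
  cand <- cand[is_peak[cand]]
  picked <- integer(0)
  for (i in cand) {
    if (length(picked) >= k) break
    if (all(abs(time_ms[i] - time_ms[picked]) >= min_separation_ms))
      picked <- c(picked, i)
  }
  data.frame(time_ms = time_ms[picked], value = a[picked])
}

#' Overlay report: attention peaks versus task phases and ROI statistics
#'
#' Maps each attention peak to its task-phase window, computes the
#' fraction of total attention mass inside each phase window, and flags
#' whether each of the top peaks falls inside a phase whose
#' region-of-interest statistic shows a significant group difference.
#' Concordance is reported descriptively, not tested inferentially.
#'
#' @param attention A `wm_attention` object (or list with `attention`
#'   and `time_ms`).
#' @param roi_stats Optional data.frame with columns `phase` and `p`
#'   (or `p_adjusted`), e.g. per-phase group effects.
#' @param phases Phase windows, default [phase_windows()].
#' @param alpha Significance level for the concordance flags.
#' @param k,min_separation_ms Passed to [locate_peaks()].
#' @return A `wm_overlay` list: `peaks` (with phase and concordance
#'   columns), `phase_mass`, and the threshold settings used.
#' @export
phase_overlap <- function(attention, roi_stats = NULL,
                          phases = phase_windows(), alpha = 0.05,
                          k = 2, min_separation_ms = 200) {
  a <- attention$attention / sum(attention$attention)
  tms <- attention$time_ms
  peaks <- locate_peaks(a, tms, k = k, min_separation_ms = min_separation_ms)
  phase_of <- function(t) {
    for (ph in names(phases))
      if (t >= phases[[ph]][1] && t < phases[[ph]][2]) return(ph)
    NA_character_
  }
  peaks$phase <- vapply(peaks$time_ms, phase_of, character(1))
  mass <- vapply(phases, function(w) sum(a[tms >= w[1] & tms < w[2]]), numeric(1))
  sig_phases <- character(0)
  if (!is.null(roi_stats)) {
    pcol <- if ("p_adjusted" %in% names(roi_stats)) "p_adjusted" else "p"
    sig_phases <- unique(roi_stats$phase[roi_stats[[pcol]] < alpha])
    peaks$concordant <- !is.na(peaks$phase) & peaks$phase %in% sig_phases
  }
  structure(list(peaks = peaks, phase_mass = mass,
                 significant_phases = sig_phases, alpha = alpha),
            class = "wm_overlay")
}
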