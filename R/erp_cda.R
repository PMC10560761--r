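#' Contralateral delay activity
#'
#' For each condition, averages trials into ERPs, pools channels of the
#' parieto-occipital pairs into contralateral and ipsilateral sets
#' relative to the cued side (right-hemisphere channels on left-cue
#' trials together with left-hemisphere channels on right-cue trials,
#' and conversely), and returns the contralateral-minus-ipsilateral
#' difference waveform averaged over pairs, plus its mean amplitude in
#' the closed 500-900 ms measurement window.
#'
#' No separate pre-cue baseline is subtracted by default: the
#' contra-ipsi subtraction cancels non-lateralized offsets. Set
#' `baseline_ms` to enable a subtractive baseline.
#'
#' @param epochs A `wm_epochs` object.
#' @param window_ms Measurement window (closed interval), default
#'   `c(500, 900)`.
#' @param channels Optional character vector restricting the
#'   parieto-occipital subset.
#' @param baseline_ms Optional two-element window for ERP baseline
#'   subtraction before the contra-ipsi difference.
#' @return A `wm_cda` list: `subject_id`, `group`, `time_ms`,
#'   `waveforms` (time x condition matrix) and `amplitudes` (data.frame
#'   with `condition`, `mean_amplitude_uv`).
#' @export
compute_cda <- function(epochs, window_ms = c(500, 900), channels = NULL,
                        baseline_ms = NULL) {
  mon <- epochs$montage
  tms <- epochs$time_ms
  if (window_ms[1] < tms[1] || window_ms[2] > tms[length(tms)])
    stop("measurement window outside epoch")
  po <- mon[mon$parieto_occipital & mon$hemisphere %in% c("L", "R"), ]
  if (!is.null(channels)) po <- po[po$label %in% channels, ]
  if (nrow(po) == 0) stop("no lateral parieto-occipital channels")
  if (!all(po$pair %in% po$label))
    stop("montage error: unpaired parieto-occipital channel")
  conds <- unique(epochs$cells$condition)
  sel <- tms >= window_ms[1] & tms <= window_ms[2]

  erp <- function(ci, ch) {       # trial-average ERP of one cell/channel
    e <- rowMeans(epochs$data[ci, ch, , , drop = TRUE])
    if (!is.null(baseline_ms)) {
      bsel <- tms >= baseline_ms[1] & tms <= baseline_ms[2]
      e <- e - mean(e[bsel])
    }
    e
  }

  wf <- sapply(conds, function(cond) {
    diffs <- lapply(c("L", "R"), function(hemi) {
      chans <- which(mon$label %in% po$label[po$hemisphere == hemi])
      # contralateral cue side for this hemisphere
      contra_side <- if (hemi == "R") "left" else "right"
      ipsi_side <- setdiff(c("left", "right"), contra_side)
      ci_contra <- which(epochs$cells$condition == cond &
                           epochs$cells$cue_side == contra_side)
      ci_ipsi <- which(epochs$cells$condition == cond &
                         epochs$cells$cue_side == ipsi_side)
      if (length(ci_contra) == 0 || length(ci_ipsi) == 0)
        stop("missing cue side for condition ", cond)
      contra <- rowMeans(sapply(chans, function(ch) erp(ci_contra, ch)))
      ipsi <- rowMeans(sapply(chans, function(ch) erp(ci_ipsi, ch)))
      contra - ipsi
    })
    (diffs[[1]] + diffs[[2]]) / 2
  })
  amps <- data.frame(condition = conds,
                     mean_amplitude_uv = colMeans(wf[sel, , drop = FALSE]),
                     stringsAsFactors = FALSE)
  rownames(amps) <- NULL
  structure(list(subject_id = epochs$subject_id, group = epochs$group,
                 time_ms = tms, waveforms = wf, amplitudes = amps,
                 window_ms = window_ms),
            class = "wm_cda")
}
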