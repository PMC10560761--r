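#' Incremental stepwise averaging of an epoch tensor
#'
#' Reduces one subject's condition x channel x time x trial tensor to a
#' single time series: for every time point, the grand mean over the
#' six condition-by-cue-side cells, all channels and all trials,
#' \deqn{S_\gamma = \frac{1}{RNZ}\sum_\mu\sum_\nu\sum_\sigma
#'   M_{\mu\nu\gamma\sigma}.}
#' Temporal order is preserved; with the default schedule the output
#' has 2750 elements.
#'
#' @param epochs A `wm_epochs` object, or a bare 4-d array ordered
#'   cell x channel x time x trial.
#' @return Numeric vector of length equal to the number of time samples.
#' @export
incremental_stepwise_average <- function(epochs) {
  x <- if (inherits(epochs, "wm_epochs")) epochs$data else epochs
  if (length(dim(x)) != 4) stop("expected a 4-d epoch tensor")
  if (any(!is.finite(x))) stop("epoch tensor contains non-finite values")
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3], d[4])
  rowMeans(colMeans(x))              # mean over cells+channels, then trials
}

#' Build the subjects x time feature matrix
#'
#' Applies [incremental_stepwise_average()] to every subject and stacks
#' the results. All subjects must share the same schedule.
#'
#' @param cohort List of `wm_epochs`, or a `wm_cohort_config` (subjects
#'   are then generated one at a time and discarded).
#' @return A `wm_features` object: list with `X` (subjects x time),
#'   `y` (1 = patient, 0 = control), `groups`, `subject_ids`, `time_ms`.
#' @export
build_feature_matrix <- function(cohort) {
  reduce1 <- function(s) list(v = incremental_stepwise_average(s),
                              id = s$subject_id, group = s$group,
                              time_ms = s$time_ms)
  rows <- if (inherits(cohort, "wm_cohort_config"))
    subject_map(cohort, reduce1) else lapply(cohort, reduce1)
  if (length(rows) == 0) stop("empty cohort")
  t0 <- rows[[1]]$time_ms
  for (r in rows)
    if (!isTRUE(all.equal(r$time_ms, t0))) stop("schedule mismatch between subjects")
  X <- do.call(rbind, lapply(rows, `[[`, "v"))
  groups <- vapply(rows, `[[`, character(1), "group")
  structure(list(X = X, y = as.integer(groups == "patient"),
                 groups = groups,
                 subject_ids = vapply(rows, `[[`, character(1), "id"),
                 time_ms = t0),
            class = "wm_features")
}
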