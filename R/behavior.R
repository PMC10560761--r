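#' Pashler working-memory capacity K
#'
#' Capacity estimate for whole-display change detection,
#' \deqn{K = N (HR - FAR) / (1 - FAR),}
#' where `N` is the number of to-be-remembered items, `HR` the hit rate
#' and `FAR` the false-alarm rate. K may be negative when FAR exceeds
#' HR; the value is returned as-is with a warning.
#'
#' @param n_items Set size N (> 0).
#' @param hit_rate,false_alarm_rate Proportions in [0, 1]; FAR must be
#'   strictly below 1.
#' @return Capacity in items.
#' @export
compute_k <- function(n_items, hit_rate, false_alarm_rate) {
  if (any(n_items <= 0)) stop("n_items must be positive")
  if (any(hit_rate < 0 | hit_rate > 1) || any(false_alarm_rate < 0))
    stop("rates must lie in [0, 1]")
  if (any(false_alarm_rate >= 1)) stop("K is undefined for FAR = 1")
  k <- n_items * (hit_rate - false_alarm_rate) / (1 - false_alarm_rate)
  if (any(k < 0)) warning("negative K (false-alarm rate exceeds hit rate)")
  k
}

#' Coefficient of variation of reaction times
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param rts Reaction times in ms of responded trials; at least two,
#'   all positive.
#' @return Dimensionless coefficient of variation.
#' @export
compute_rt_cv <- function(rts) {
  rts <- rts[!is.na(rts)]
  if (length(rts) < 2) stop("need at least two responded trials")
  if (any(rts <= 0)) stop("reaction times must be positive")
  stats::sd(rts) / mean(rts)
}

#' Behavioral summary per condition
#'
#' Tabulates hit rate (P(respond "different" | change)), false-alarm
#' rate (P(respond "different" | no change)), capacity K and
#' reaction-time statistics for each condition of a trial log. In the
#' distractor condition (2+2) the set size is 2: only the target items
#' count. By default the RT coefficient of variation is computed over
#' correct trials only.
#'
#' @param log Trial log data.frame with columns `condition`,
#'   `set_size`, `change`, `response`, `correct`, `rt_ms`.
#' @param rt_correct_only Use only correct trials for the RT pool.
#' @return Data.frame with one row per condition: `condition`, `n_items`,
#'   `hit_rate`, `false_alarm_rate`, `k`, `rt_mean_ms`, `rt_sd_ms`, `rt_cv`.
#' @export
summarize_behavior <- function(log, rt_correct_only = TRUE) {
  conds <- unique(log$condition)
  out <- do.call(rbind, lapply(conds, function(cond) {
    d <- log[log$condition == cond & !is.na(log$response), ]
    if (sum(d$change) == 0 || sum(!d$change) == 0)
      stop("condition ", cond, " lacks change or no-change trials")
    hr <- mean(d$response[d$change] == "different")
    far <- mean(d$response[!d$change] == "different")
    n_items <- d$set_size[1]
    rts <- if (rt_correct_only) d$rt_ms[d$correct] else d$rt_ms
    data.frame(condition = cond, n_items = n_items, hit_rate = hr,
               false_alarm_rate = far,
               k = compute_k(n_items, hr, far),
               rt_mean_ms = mean(rts), rt_sd_ms = stats::sd(rts),
               rt_cv = compute_rt_cv(rts), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
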