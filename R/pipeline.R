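#' End-to-end analysis run on a synthetic cohort
#'
#' Chains the pipeline stages on one synthetic cohort: generation,
#' behavioral summaries, contralateral delay activity, time-frequency
#' ROI statistics and mixed ANOVAs, feature reduction, DAN evaluation
#' (optionally the full reference bank), and the attention overlay
#' report. Results are returned and, if `out_dir` is given, written as
#' TSV/JSON files together with a manifest recording seeds and stage
#' settings, so a run is reproducible from the manifest alone.
#'
#' Stage toggles allow skipping the expensive stages. The time-
#' frequency stage can be restricted to a frequency range to keep small
#' runs fast.
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional output directory.
#' @param tfr_cfg A [tfr_config()] for the time-frequency stage.
#' @param dan_cfg A [dan_config()].
#' @param repeats LOOCV repeats for model evaluation.
#' @param stages Character vector of stages to run; any of "behavior",
#'   "cda", "tfr", "stats", "dan", "bank", "overlay".
#' @param seed Seed for model evaluation (cohort generation uses
#'   `config$seed`).
#' @return A `wm_run` list with one entry per executed stage plus the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         tfr_cfg = tfr_config(),
                         dan_cfg = dan_config(), repeats = 10,
                         stages = c("behavior", "cda", "tfr", "stats",
                                    "dan", "overlay"),
                         seed = 1) {
  res <- list()
  manifest <- list(package_version = as.character(utils::packageVersion("wmdan")),
                   cohort_seed = config$seed, eval_seed = seed,
                   stages = stages, timestamp = format(Sys.time(), "%Y-%m-%d"))

  ## single pass over subjects: collect every per-subject reduction
  per_subject <- subject_map(config, function(s) {
    out <- list(id = s$subject_id, group = s$group, time_ms = s$time_ms)
    if ("behavior" %in% stages)
      out$behavior <- cbind(subject = s$subject_id, group = s$group,
                            summarize_behavior(s$log))
    if ("cda" %in% stages) {
      cda <- compute_cda(s)
      out$cda <- cbind(subject = s$subject_id, group = s$group,
                       cda$amplitudes)
    }
    if ("tfr" %in% stages) {
      tfr <- db_baseline(morlet_power(s, tfr_cfg))
      out$roi <- tfr_roi_table(tfr)
      out$tfr_mean_map <- Reduce(`+`, tfr$power) / length(tfr$power)
      out$tfr_axes <- list(freqs_hz = tfr$freqs_hz, time_ms = tfr$time_ms)
    }
    if (any(c("dan", "bank", "overlay") %in% stages))
      out$features <- incremental_stepwise_average(s)
    out
  })
  groups <- vapply(per_subject, `[[`, character(1), "group")

  if ("behavior" %in% stages)
    res$behavior <- do.call(rbind, lapply(per_subject, `[[`, "behavior"))
  if ("cda" %in% stages)
    res$cda <- do.call(rbind, lapply(per_subject, `[[`, "cda"))
  if ("tfr" %in% stages) {
    res$tfr_roi <- do.call(rbind, lapply(per_subject, `[[`, "roi"))
    maps <- lapply(per_subject, `[[`, "tfr_mean_map")
    pat <- Reduce(`+`, maps[groups == "patient"]) / sum(groups == "patient")
    ctl <- Reduce(`+`, maps[groups == "control"]) / sum(groups == "control")
    res$diff_map <- pat - ctl
    res$tfr_axes <- per_subject[[1]]$tfr_axes
  }

  if ("stats" %in% stages) {
    res$anova <- list()
    if (!is.null(res$behavior))
      res$anova$k <- mixed_anova(res$behavior, dv = "k", within = "condition",
                                 between = "group")
    if (!is.null(res$cda))
      res$anova$cda <- mixed_anova(res$cda, dv = "mean_amplitude_uv",
                                   within = "condition", between = "group")
    if (!is.null(res$tfr_roi)) {
      res$anova$tfr <- lapply(split(res$tfr_roi, res$tfr_roi$band),
                              function(d) mixed_anova(d, dv = "db",
                                                      within = c("condition", "phase"),
                                                      between = "group"))
      ## per-phase follow-up group effects (used by the overlay stage)
      alpha_roi <- res$tfr_roi[res$tfr_roi$band == "alpha", ]
      if (nrow(alpha_roi) > 0)
        res$alpha_phase_stats <- do.call(rbind, lapply(
          split(alpha_roi, alpha_roi$phase), function(d) {
            an <- mixed_anova(d, dv = "db", within = "condition",
                              between = "group")
            data.frame(phase = d$phase[1], p = an$p[an$effect == "group"])
          }))
    }
  }

  if (any(c("dan", "bank", "overlay") %in% stages)) {
    X <- do.call(rbind, lapply(per_subject, `[[`, "features"))
    y <- as.integer(groups == "patient")
    res$features <- list(X = X, y = y, time_ms = per_subject[[1]]$time_ms)
    if ("dan" %in% stages)
      res$dan <- loocv_evaluate(dan_cfg, X, y, repeats = repeats, seed = seed)
    if ("bank" %in% stages)
      res$bank <- run_baseline_bank(X, y, repeats = repeats, seed = seed)
    if ("overlay" %in% stages) {
      att <- extract_attention(X, y, config = dan_cfg, repeats = 1,
                               seed = seed, time_ms = res$features$time_ms)
      res$attention <- att
      res$overlay <- phase_overlap(att, roi_stats = res$alpha_phase_stats)
    }
  }

  res$manifest <- manifest
  class(res) <- "wm_run"
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) write.table(d, file.path(out_dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  if (!is.null(res$behavior)) wt(res$behavior, "behavior.tsv")
  if (!is.null(res$cda)) wt(res$cda, "cda.tsv")
  if (!is.null(res$tfr_roi)) wt(res$tfr_roi, "tfr_roi.tsv")
  if (!is.null(res$diff_map))
    wt(as.data.frame(res$diff_map), "diff_map.tsv")
  if (!is.null(res$anova))
    jsonlite::write_json(lapply(res$anova, function(a)
      if (is.data.frame(a)) a else lapply(a, as.data.frame)),
      file.path(out_dir, "anova.json"), dataframe = "rows", digits = NA)
  if (!is.null(res$dan)) wt(res$dan$summary, "dan.tsv")
  if (!is.null(res$bank)) wt(res$bank, "table_models.tsv")
  if (!is.null(res$attention))
    wt(data.frame(time_ms = res$attention$time_ms,
                  attention = res$attention$attention), "attention.tsv")
  if (!is.null(res$overlay))
    jsonlite::write_json(list(peaks = res$overlay$peaks,
                              phase_mass = as.list(res$overlay$phase_mass),
                              significant_phases = res$overlay$significant_phases),
                         file.path(out_dir, "overlay.json"),
                         dataframe = "rows", digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
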