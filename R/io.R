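## Cohort container: one directory per cohort. Per subject, the epoch
## array is stored as a raw little-endian double stream with a JSON
## sidecar holding dimensions, labels, timing and group metadata; the
## behavioral log is a TSV. Round trips are bit-exact.

#' Write a cohort to disk
#'
#' @param cohort List of `wm_epochs` (see [generate_cohort()]).
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(cohort, function(s) s$subject_id, character(1))
  jsonlite::write_json(list(container = "wmdan-cohort", version = 1L,
                            subjects = ids),
                       file.path(path, "cohort.json"), auto_unbox = TRUE)
  for (s in cohort) {
    base <- file.path(path, s$subject_id)
    con <- file(paste0(base, "_epochs.bin"), "wb")
    writeBin(as.vector(s$data), con, size = 8, endian = "little")
    close(con)
    meta <- list(subject_id = s$subject_id, group = s$group,
                 dim = dim(s$data),
                 cells = s$cells, montage = s$montage,
                 time_ms = s$time_ms,
                 fs_hz = s$schedule$fs_hz,
                 epoch_window_ms = s$schedule$epoch_window_ms)
    jsonlite::write_json(meta, paste0(base, "_meta.json"),
                         auto_unbox = TRUE, digits = NA)
    write.table(s$log, paste0(base, "_trials.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a cohort from disk
#'
#' @param path Directory written by [write_cohort()].
#' @return List of `wm_epochs`.
#' @export
read_cohort <- function(path) {
  idx_file <- file.path(path, "cohort.json")
  if (!file.exists(idx_file)) stop("not a cohort directory: ", path)
  idx <- jsonlite::read_json(idx_file, simplifyVector = TRUE)
  if (!identical(idx$container, "wmdan-cohort"))
    stop("malformed cohort container")
  lapply(idx$subjects, function(id) read_subject(path, id))
}

read_subject <- function(path, id) {
  base <- file.path(path, id)
  meta <- jsonlite::read_json(paste0(base, "_meta.json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(paste0(base, "_epochs.bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n, size = 8, endian = "little")
  if (length(vals) != n) stop("truncated epoch file for ", id)
  x <- array(vals, dim = meta$dim)
  log <- read.table(paste0(base, "_trials.tsv"), sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  sch <- task_schedule(fs_hz = meta$fs_hz, epoch_window_ms = meta$epoch_window_ms)
  structure(list(subject_id = meta$subject_id, group = meta$group,
                 data = x,
                 cells = as.data.frame(meta$cells, stringsAsFactors = FALSE),
                 montage = as.data.frame(meta$montage, stringsAsFactors = FALSE),
                 time_ms = meta$time_ms, schedule = sch, log = log),
            class = "wm_epochs")
}
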