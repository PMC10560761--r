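## small cohorts used across tests
tiny_config <- function(seed = 1, ...) {
  cohort_config(n_patients = 2, n_controls = 2, n_channels = 8,
                trials_per_condition = 4, seed = seed, ...)
}

## a hand-built epochs object with fully controlled content
manual_epochs <- function(fill, n_ch = 4, Z = 2, group = "patient") {
  sch <- task_schedule()
  mon <- montage(8)
  mon <- mon[mon$label %in% c("P3", "P4", "O1", "O2"), ]
  cells <- expand.grid(condition = c("2", "2+2", "4"),
                       cue_side = c("left", "right"), stringsAsFactors = FALSE)
  x <- array(fill, dim = c(nrow(cells), nrow(mon), sch$n_samples, Z))
  structure(list(subject_id = "sub-01", group = group, data = x,
                 cells = cells, montage = mon, time_ms = sch$time_ms,
                 schedule = sch, log = NULL),
            class = "wm_epochs")
}

## synthetic feature matrices with a localized informative bump: class
## means differ by `shift` on the `width` columns centred at j
planted_feature_matrix <- function(n_per_group = 15, D = 300, j = NULL,
                                   width = 21, shift = 3, noise = 1,
                                   seed = 1) {
  if (is.null(j)) j <- round(D / 2)
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_group * D, 0, noise), 2 * n_per_group, D)
  y <- rep(c(1L, 0L), each = n_per_group)
  cols <- max(1, j - width %/% 2):min(D, j + width %/% 2)
  X[y == 1, cols] <- X[y == 1, cols] + shift
  list(X = X, y = y, j = j, cols = cols)
}
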