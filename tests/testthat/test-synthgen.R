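test_that("cohorts are bit-identical under the same seed", {
  a <- generate_subject(tiny_config(3), 2)
  b <- generate_subject(tiny_config(3), 2)
  expect_identical(a$data, b$data)
  expect_identical(a$log, b$log)
  c <- generate_subject(tiny_config(4), 2)
  expect_false(identical(a$data, c$data))
})

test_that("cohort structure follows the configuration", {
  cfg <- tiny_config()
  co <- generate_cohort(cfg)
  expect_length(co, 4)
  expect_equal(vapply(co, function(s) s$group, character(1)),
               rep(c("patient", "control"), each = 2))
  d <- dim(co[[1]]$data)
  expect_equal(d, c(6, 8, 2750, 2))   # cells x channels x samples x trials/cell
  # 200-trials-per-condition default: check on the config level
  expect_equal(cohort_config()$trials_per_condition, 200)
  expect_equal(nrow(co[[1]]$log), 6 * 2)
  expect_true(all(table(co[[1]]$log$condition) == 4))
  # change flag balanced within each cell
  tab <- with(co[[1]]$log, table(condition, cue_side, change))
  expect_true(all(tab == 1))
})

test_that("a subject's data do not depend on cohort size", {
  big <- cohort_config(n_patients = 3, n_controls = 3, n_channels = 8,
                       trials_per_condition = 4, seed = 5)
  small <- cohort_config(n_patients = 2, n_controls = 4, n_channels = 8,
                         trials_per_condition = 4, seed = 5)
  expect_identical(generate_subject(big, 2)$data,
                   generate_subject(small, 2)$data)
})

test_that("baseline window alpha amplitude is group-independent", {
  ## strong planted suppression, no noise ambiguity: compare baseline
  ## RMS of patients vs controls across several subjects
  cfg <- cohort_config(n_patients = 4, n_controls = 4, n_channels = 8,
                       trials_per_condition = 8, seed = 11,
                       alpha_subject_cv = 0)
  rms_base <- subject_map(cfg, function(s) {
    sel <- s$time_ms >= -850 & s$time_ms <= -650
    po <- which(s$montage$parieto_occipital)
    sqrt(mean(s$data[, po, sel, ]^2))
  })
  rms <- unlist(rms_base)
  pat <- rms[1:4]; ctl <- rms[5:8]
  expect_lt(abs(mean(pat) - mean(ctl)) / mean(rms), 0.05)
})

test_that("planted effects modulate the task window, not the baseline", {
  cfg0 <- null_cohort_config(n_patients = 2, n_controls = 2, n_channels = 8,
                             trials_per_condition = 8, seed = 9)
  fixed <- list(mean = c(-2.36, -2.17, -2.29, -2.50), sd = rep(0, 4))
  cfg1 <- cohort_config(n_patients = 2, n_controls = 2, n_channels = 8,
                        trials_per_condition = 8, seed = 9,
                        alpha_db = list(patient = fixed, control = fixed))
  s0 <- generate_subject(cfg0, 3); s1 <- generate_subject(cfg1, 3)  # controls
  po <- which(s1$montage$parieto_occipital)
  task <- s1$time_ms >= 0 & s1$time_ms <= 1700
  base <- s1$time_ms >= -850 & s1$time_ms <= -650
  r1 <- sqrt(mean(s1$data[, po, task, ]^2)) / sqrt(mean(s1$data[, po, base, ]^2))
  r0 <- sqrt(mean(s0$data[, po, task, ]^2)) / sqrt(mean(s0$data[, po, base, ]^2))
  expect_lt(r1, r0)    # suppression reduces task-window amplitude
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_patients = 0), "positive")
  expect_error(cohort_config(trials_per_condition = 3), "even")
  bad <- cohort_config()
  bad$behavior$patient$hit_rate[1] <- 1.4
  expect_error(validate_cohort_config(bad), "\\[0, 1\\]")
})

test_that("cohort containers round-trip bit-exactly", {
  co <- generate_cohort(tiny_config(8))
  td <- withr::local_tempdir()
  write_cohort(co, td)
  co2 <- read_cohort(td)
  for (i in seq_along(co)) {
    expect_identical(co[[i]]$data, co2[[i]]$data)
    expect_equal(co[[i]]$log, co2[[i]]$log, ignore_attr = TRUE)
    expect_equal(co[[i]]$time_ms, co2[[i]]$time_ms)
    expect_equal(co[[i]]$montage$label, co2[[i]]$montage$label)
    expect_equal(co[[i]]$group, co2[[i]]$group)
  }
})

test_that("truncated or malformed containers raise format errors", {
  co <- generate_cohort(tiny_config(8))
  td <- withr::local_tempdir()
  write_cohort(co, td)
  f <- file.path(td, "sub-01_epochs.bin")
  sz <- file.size(f)
  raw <- readBin(f, "raw", n = sz)
  writeBin(raw[1:(sz / 2)], f)
  expect_error(read_cohort(td), "truncated")
  expect_error(read_cohort(withr::local_tempdir()), "not a cohort")
})
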