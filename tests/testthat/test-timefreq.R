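## helper: epochs whose every trial is a given time series
tone_epochs <- function(signal_fun) {
  e <- manual_epochs(0, Z = 2)
  tms <- e$time_ms / 1000
  sig <- signal_fun(tms)
  for (ci in 1:6) for (ch in 1:4) for (z in 1:2) e$data[ci, ch, , z] <- sig
  e
}

test_that("a pure tone peaks at its own frequency with quadratic scaling", {
  cfgf <- tfr_config(freqs_hz = 2:20)
  e1 <- tone_epochs(function(t) 2 * cos(2 * pi * 10 * t))
  p1 <- morlet_power(e1, cfgf)
  prof <- rowMeans(p1$power[["2"]], na.rm = TRUE)
  expect_equal(cfgf$freqs_hz[which.max(prof)], 10)
  ## interior samples of the tone measure its squared amplitude
  mid <- p1$time_ms > 0 & p1$time_ms < 2000
  expect_equal(mean(p1$power[["2"]][cfgf$freqs_hz == 10, mid]), 4,
               tolerance = 0.05)
  e2 <- tone_epochs(function(t) 4 * cos(2 * pi * 10 * t))
  p2 <- morlet_power(e2, cfgf)
  ratio <- p2$power[["2"]] / p1$power[["2"]]
  expect_equal(max(ratio, na.rm = TRUE), 4, tolerance = 1e-6)
  expect_equal(min(ratio, na.rm = TRUE), 4, tolerance = 1e-6)
})

test_that("a 6 + 40 Hz mixture shows two local spectral maxima", {
  e <- tone_epochs(function(t) cos(2 * pi * 6 * t) + cos(2 * pi * 40 * t))
  cfgf <- tfr_config(freqs_hz = 2:50)
  p <- morlet_power(e, cfgf)
  prof <- rowMeans(p$power[["4"]], na.rm = TRUE)
  f <- cfgf$freqs_hz
  locmax <- f[which(diff(sign(diff(prof))) == -2) + 1]
  expect_true(6 %in% locmax)
  expect_true(40 %in% locmax)
})

test_that("raw power is non-negative and finite on valid samples", {
  s <- generate_subject(tiny_config(41), 1)
  p <- morlet_power(s, tfr_config(freqs_hz = c(4, 10, 30)))
  for (m in p$power) {
    expect_true(all(m[is.finite(m)] >= 0))
    expect_false(any(is.nan(m)))
  }
})

test_that("dB baseline identities: 0, +10 and -20 dB", {
  s <- generate_subject(tiny_config(42), 1)
  p <- morlet_power(s, tfr_config(freqs_hz = 8:10))
  sel <- p$time_ms >= -850 & p$time_ms <= -650
  ## constant-in-time map -> 0 dB
  pc <- p
  pc$power <- lapply(p$power, function(m) matrix(5, nrow(m), ncol(m)))
  d0 <- db_baseline(pc)
  expect_equal(max(abs(d0$power[[1]])), 0)
  ## 10x baseline -> +10 dB; 0.01x -> -20 dB
  pc$power <- lapply(p$power, function(m) {
    m[] <- 3; m[, !sel] <- 30; m })
  d10 <- db_baseline(pc)
  expect_equal(unique(as.vector(d10$power[[1]][, !sel])), 10)
  pc$power <- lapply(p$power, function(m) {
    m[] <- 2; m[, !sel] <- 0.02; m })
  dm20 <- db_baseline(pc)
  expect_equal(unique(as.vector(dm20$power[[1]][, !sel])), -20)
})

test_that("dB maps are invariant to a global gain on the raw signal", {
  s <- generate_subject(tiny_config(43), 1)
  s2 <- s
  s2$data <- 3 * s$data
  cfgf <- tfr_config(freqs_hz = 8:12)
  d1 <- db_baseline(morlet_power(s, cfgf))
  d2 <- db_baseline(morlet_power(s2, cfgf))
  expect_equal(d1$power[["2"]], d2$power[["2"]], tolerance = 1e-10)
})

test_that("roi_mean equals a brute-force nested-loop mean", {
  set.seed(7)
  m <- matrix(rnorm(50 * 60), 50, 60)
  freqs <- 1:50
  tms <- seq(-1000, by = 50, length.out = 60)
  band <- c(8, 12); win <- c(-400, 0)
  brute <- 0; nb <- 0
  for (i in seq_along(freqs)) for (j in seq_along(tms)) {
    if (freqs[i] >= band[1] && freqs[i] <= band[2] &&
        tms[j] >= win[1] && tms[j] < win[2]) {
      brute <- brute + m[i, j]; nb <- nb + 1
    }
  }
  expect_equal(roi_mean(m, freqs, tms, band, win), brute / nb,
               tolerance = 1e-12)
  expect_equal(roi_mean(matrix(2.5, 50, 60), freqs, tms, band, win), 2.5)
  expect_error(roi_mean(m, freqs, tms, c(70, 80), win), "empty")
})

test_that("group difference maps: zero for identical groups, antisymmetric", {
  s1 <- generate_subject(tiny_config(44), 1)
  s2 <- s1; s2$group <- "control"; s2$subject_id <- "sub-99"
  cfgf <- tfr_config(freqs_hz = 8:10)
  t1 <- db_baseline(morlet_power(s1, cfgf))
  t2 <- db_baseline(morlet_power(s2, cfgf))
  expect_equal(max(abs(group_difference_map(list(t1, t2))), na.rm = TRUE), 0)
  s3 <- generate_subject(tiny_config(44), 4)   # a genuine control
  t3 <- db_baseline(morlet_power(s3, cfgf))
  d <- group_difference_map(list(t1, t3))
  t1b <- t1; t1b$group <- "control"
  t3b <- t3; t3b$group <- "patient"
  expect_equal(group_difference_map(list(t1b, t3b)), -d)
})

test_that("planted alpha suppression leaves positive patient-control alpha rows", {
  cfg <- cohort_config(n_patients = 3, n_controls = 3, n_channels = 8,
                       trials_per_condition = 8, seed = 46)
  cfgf <- tfr_config(freqs_hz = 8:12)
  tfrs <- subject_map(cfg, function(s) db_baseline(morlet_power(s, cfgf)))
  d <- group_difference_map(tfrs)
  task <- tfrs[[1]]$time_ms >= 0 & tfrs[[1]]$time_ms <= 3060
  expect_gt(mean(d[, task]), 0)    # patients suppress less
})

test_that("grid mismatches and bad baselines are rejected", {
  s <- generate_subject(tiny_config(45), 1)
  t1 <- morlet_power(s, tfr_config(freqs_hz = 8:10))
  t2 <- morlet_power(s, tfr_config(freqs_hz = 9:11))
  t2$group <- "control"
  expect_error(group_difference_map(list(t1, t2)), "grids differ")
  expect_error(db_baseline(t1, baseline_ms = c(9000, 9500)), "outside")
  expect_error(db_baseline(db_baseline(t1)), "already")
})
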