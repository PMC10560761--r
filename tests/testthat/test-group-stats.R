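make_long <- function(n_per_group = 6, conds = c("a", "b", "c"),
                      phases = NULL, seed = 1, effect = 0) {
  set.seed(seed)
  n <- 2 * n_per_group
  cells <- if (is.null(phases)) expand.grid(condition = conds) else
    expand.grid(condition = conds, phase = phases)
  d <- do.call(rbind, lapply(seq_len(n), function(s) {
    out <- cells
    out$subject <- sprintf("s%02d", s)
    out$group <- if (s <= n_per_group) "patient" else "control"
    out$value <- rnorm(nrow(cells)) + effect * (out$group == "patient")
    out
  }))
  d
}

test_that("degenerate all-identical tables give F = 0 for every effect", {
  d <- make_long()
  d$value <- 7
  a <- mixed_anova(d, dv = "value", within = "condition", between = "group")
  expect_true(all(a$F == 0))
})

test_that("between-group F equals the squared pooled t on subject means", {
  d <- make_long(n_per_group = 8, conds = c("a", "b"), seed = 3, effect = 0.8)
  a <- mixed_anova(d, dv = "value", within = "condition", between = "group")
  sm <- aggregate(value ~ subject + group, d, mean)
  tt <- t.test(value ~ group, sm, var.equal = TRUE)
  fg <- a$F[a$effect == "group"]
  expect_equal(fg, unname(tt$statistic)^2, tolerance = 1e-8)
  ## within-factor df bookkeeping
  expect_equal(a$df_num[a$effect == "condition"], 1)
  expect_equal(a$df_den[a$effect == "condition"], 14)
})

test_that("eta squared matches a brute-force sums-of-squares decomposition", {
  d <- make_long(n_per_group = 3, conds = c("a", "b", "c"), seed = 5,
                 effect = 0.5)
  a <- mixed_anova(d, dv = "value", within = "condition", between = "group")
  gm <- mean(d$value)
  ss_total <- sum((d$value - gm)^2)
  ## group effect SS by hand (balanced design)
  ss_group <- sum(tapply(d$value, d$group, function(v) length(v) * (mean(v) - gm)^2))
  ss_cond <- sum(tapply(d$value, d$condition, function(v) length(v) * (mean(v) - gm)^2))
  cellm <- aggregate(value ~ group + condition, d, mean)
  ncell <- nrow(d) / nrow(cellm)
  ss_cells <- sum(ncell * (cellm$value - gm)^2)
  ss_int <- ss_cells - ss_group - ss_cond
  expect_equal(a$eta_sq[a$effect == "group"], ss_group / ss_total,
               tolerance = 1e-10)
  expect_equal(a$eta_sq[a$effect == "condition"], ss_cond / ss_total,
               tolerance = 1e-10)
  expect_equal(a$eta_sq[a$effect == "group:condition"], ss_int / ss_total,
               tolerance = 1e-10)
})

test_that("two-within-factor designs report all seven effects with GG fields", {
  d <- make_long(n_per_group = 6, conds = c("a", "b", "c"),
                 phases = c("p1", "p2", "p3", "p4"), seed = 7, effect = 0.6)
  a <- mixed_anova(d, dv = "value", within = c("condition", "phase"),
                   between = "group")
  expect_setequal(a$effect,
                  c("group", "condition", "group:condition", "phase",
                    "group:phase", "condition:phase", "group:condition:phase"))
  expect_true(all(a$p >= 0 & a$p <= 1))
  expect_true(all(a$eta_sq >= 0 & a$eta_sq <= 1))
  within_fx <- a[a$effect != "group", ]
  expect_true(all(is.finite(within_fx$gg_epsilon)))
  expect_true(all(within_fx$gg_epsilon > 0 & within_fx$gg_epsilon <= 1.0001))
  ## when sphericity is violated the corrected dfs shrink
  v <- within_fx[within_fx$sphericity_violated, ]
  if (nrow(v) > 0) expect_true(all(v$df_num < 3.0001 * 2))
})

test_that("Welch t reproduces the printed group comparisons", {
  ## overall alpha suppression: patients -1.04 (0.89) vs controls -2.33 (1.84)
  w <- welch_t(-1.04, 0.89, 15, -2.33, 1.84, 15)
  expect_equal(w$t, 2.43, tolerance = 0.02)
  expect_equal(w$df, 20.24, tolerance = 0.15)
  expect_equal(w$cohens_d, 0.889, tolerance = 0.005)
  ## preparation phase: -1.09 (0.81) vs -2.36 (1.81)
  w2 <- welch_t(-1.09, 0.81, 15, -2.36, 1.81, 15)
  expect_equal(w2$t, 2.48, tolerance = 0.02)
  expect_equal(w2$df, 19.41, tolerance = 0.15)
  expect_equal(w2$cohens_d, 0.906, tolerance = 0.005)
  ## remaining phase effect sizes
  expect_equal(cohens_d(-0.83, 1.00, -2.17, 1.93), 0.874, tolerance = 0.005)
  expect_equal(cohens_d(-1.13, 1.13, -2.50, 2.16), 0.794, tolerance = 0.005)
})

test_that("Welch t behaves like Student's t with equal variances and n", {
  w <- welch_t(1.2, 1, 20, 0.4, 1, 20)
  tv <- (1.2 - 0.4) / (1 * sqrt(2 / 20))
  expect_equal(w$t, tv)
  expect_equal(w$df, 38)
  expect_equal(welch_t(0.5, 1, 10, 0.5, 2, 10)$t, 0)
  expect_error(welch_t(1, 0, 10, 2, 0, 10), "zero variance")
  expect_equal(welch_t(1, 1, 10, 0, 1, 10, bonferroni_m = 4)$p_adjusted,
               min(1, 4 * welch_t(1, 1, 10, 0, 1, 10)$p))
})

test_that("Cohen's d edge cases", {
  expect_equal(cohens_d(3, 1, 3, 2), 0)
  expect_error(cohens_d(1, 0, 2, 0), "zero spread")
  expect_equal(cohens_d(2, 1, 1, 1), 1)
})

test_that("paired post-hocs are Bonferroni-adjusted over the family", {
  d <- make_long(n_per_group = 8, conds = c("a", "b", "c"), seed = 11,
                 effect = 0)
  d$value[d$condition == "c"] <- d$value[d$condition == "c"] + 1
  ph <- paired_posthoc(d, dv = "value", factor_col = "condition")
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p_adjusted, pmin(1, 3 * ph$p))
  expect_true(all(abs(ph$cohens_d[grepl("c", ph$comparison)]) > 0.2))
})
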