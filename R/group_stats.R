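#' Mixed-design ANOVA with Greenhouse-Geisser correction
#'
#' Fits a mixed-design (split-plot) ANOVA with one between-subject
#' factor and one or two within-subject factors on a balanced
#' long-format table (one value per subject and cell). Sphericity of
#' each within-subject effect is assessed with Mauchly's test; when it
#' is rejected at `mauchly_alpha`, Greenhouse-Geisser corrected degrees
#' of freedom and p-values are reported for that effect. Effect sizes
#' are classical eta squared, `SS_effect / SS_total`, with `SS_total`
#' the sum of all effect and error sums of squares (intercept
#' excluded).
#'
#' The underlying multivariate fit and sphericity machinery come from
#' \pkg{car}; sums of squares for the eta-squared decomposition come
#' from the equivalent univariate `aov` fit.
#'
#' @param data Long-format data.frame.
#' @param dv Name of the value column.
#' @param within Character vector (length 1 or 2) of within-subject
#'   factor columns.
#' @param between Name of the between-subject factor column (2+ levels).
#' @param subject Name of the subject identifier column.
#' @param mauchly_alpha Significance level that triggers the
#'   Greenhouse-Geisser correction.
#' @return A `wm_anova` object: data.frame of effects with columns
#'   `effect`, `F`, `df_num`, `df_den`, `p`, `eta_sq`, `gg_epsilon`,
#'   `sphericity_violated`, `p_uncorrected`.
#' @export
mixed_anova <- function(data, dv, within, between, subject = "subject",
                        mauchly_alpha = 0.05) {
  stopifnot(length(within) %in% 1:2)
  for (v in c(dv, within, between, subject))
    if (!v %in% names(data)) stop("missing column: ", v)
  d <- data[, c(subject, between, within, dv)]
  names(d) <- c(".subject", ".between", paste0(".w", seq_along(within)), ".y")
  d$.subject <- factor(d$.subject)
  d$.between <- factor(d$.between)
  wcols <- paste0(".w", seq_along(within))
  for (w in wcols) d[[w]] <- factor(d[[w]])
  if (nlevels(d$.between) < 2) stop("between factor needs at least 2 levels")
  if (min(table(d$.between)) / prod(vapply(wcols, function(w) nlevels(d[[w]]), 1L)) < 2)
    stop("need at least two subjects per group")

  cells <- expand.grid(lapply(wcols, function(w) levels(d[[w]])),
                       stringsAsFactors = FALSE)
  names(cells) <- wcols
  subjects <- levels(d$.subject)
  M <- vapply(seq_len(nrow(cells)), function(i) {
    sel <- rep(TRUE, nrow(d))
    for (w in wcols) sel <- sel & d[[w]] == cells[[w]][i]
    x <- d[sel, ]
    if (nrow(x) != length(subjects) || anyDuplicated(x$.subject))
      stop("design must be balanced with one value per subject and cell")
    x$.y[match(subjects, x$.subject)]
  }, numeric(length(subjects)))
  grp <- d$.between[match(subjects, d$.subject)]

  idata <- cells
  for (w in wcols) idata[[w]] <- factor(idata[[w]])
  idesign <- stats::as.formula(paste("~", paste(wcols, collapse = "*")))
  mlm <- stats::lm(M ~ grp)
  A <- car::Anova(mlm, idata = idata, idesign = idesign, type = 3)
  s <- suppressWarnings(summary(A, multivariate = FALSE))
  ut <- s$univariate.tests
  sph <- s$sphericity.tests
  adj <- s$pval.adjustments

  ## eta squared from the univariate aov decomposition
  fml <- stats::as.formula(paste(
    ".y ~ .between *", paste(wcols, collapse = "*"),
    "+ Error(.subject/(", paste(wcols, collapse = "*"), "))"))
  av <- summary(stats::aov(fml, data = d))
  ss <- numeric(0)
  for (stratum in av) {
    tab <- stratum[[1]]
    ss <- c(ss, setNames(tab[["Sum Sq"]], trimws(rownames(tab))))
  }
  ss_total <- sum(ss)

  effects <- setdiff(rownames(ut), "(Intercept)")
  res <- do.call(rbind, lapply(effects, function(e) {
    Fv <- ut[e, "F value"]; p <- ut[e, "Pr(>F)"]
    df1 <- ut[e, "num Df"]; df2 <- ut[e, "den Df"]
    eps <- NA_real_; viol <- FALSE; p_unc <- p
    if (!is.null(sph) && e %in% rownames(sph)) {
      mau_p <- sph[e, "p-value"]
      eps <- adj[e, "GG eps"]
      viol <- is.finite(mau_p) && mau_p < mauchly_alpha
      if (viol) {
        p <- adj[e, "Pr(>F[GG])"]
        df1 <- df1 * eps; df2 <- df2 * eps
      }
    }
    ## translate car's effect naming back to user columns
    lab <- e
    lab <- gsub("grp", ".between", lab, fixed = TRUE)
    aov_key <- gsub(".between", ".between", lab, fixed = TRUE)
    ss_e <- ss[match_effect(aov_key, names(ss))]
    lab <- gsub(".between", between, lab, fixed = TRUE)
    for (i in seq_along(within)) lab <- gsub(wcols[i], within[i], lab, fixed = TRUE)
    ## degenerate strata (zero effect variance): F := 0
    if (abs(ss_e) < 1e-12 && (!is.finite(Fv) || ss_total < 1e-12)) {
      Fv <- 0; p <- 1; p_unc <- 1
    }
    data.frame(effect = lab, F = Fv, df_num = df1, df_den = df2, p = p,
               eta_sq = if (ss_total > 0) unname(ss_e) / ss_total else 0,
               gg_epsilon = eps,
               sphericity_violated = viol, p_uncorrected = p_unc,
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  class(res) <- c("wm_anova", "data.frame")
  res
}

## match "A:B" style effect names irrespective of term order
match_effect <- function(e, pool) {
  parts <- sort(strsplit(e, ":", fixed = TRUE)[[1]])
  hits <- which(vapply(pool, function(p)
    identical(sort(strsplit(p, ":", fixed = TRUE)[[1]]), parts), logical(1)))
  if (length(hits) != 1) stop("cannot locate effect ", e, " in aov table")
  hits
}

#' Welch's t-test from summary statistics
#'
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom; two-sided p-value, optionally Bonferroni
#' adjusted by the size of the comparison family.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries.
#' @param bonferroni_m Family size for the Bonferroni adjustment
#'   (default 1: no adjustment).
#' @param label Comparison label.
#' @return A one-row data.frame: `comparison`, `t`, `df`, `p`,
#'   `p_adjusted`, `cohens_d`.
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2, bonferroni_m = 1,
                    label = "group1 - group2") {
  stopifnot(n1 >= 2, n2 >= 2)
  if (sd1 == 0 && sd2 == 0) stop("both groups have zero variance")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  se2 <- v1 + v2
  tv <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tv), df)
  data.frame(comparison = label, t = tv, df = df, p = p,
             p_adjusted = min(1, bonferroni_m * p),
             cohens_d = cohens_d(mean1, sd1, mean2, sd2),
             stringsAsFactors = FALSE)
}

#' Cohen's d from summary statistics
#'
#' Standardized mean difference with the unweighted root-mean of the
#' two variances as the standardizer:
#' `d = (m1 - m2) / sqrt((s1^2 + s2^2)/2)`.
#'
#' @param mean1,sd1,mean2,sd2 Group summaries.
#' @return Effect size d (sign follows `mean1 - mean2`).
#' @export
cohens_d <- function(mean1, sd1, mean2, sd2) {
  if (sd1 == 0 && sd2 == 0) stop("both groups have zero spread")
  (mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)
}

#' Paired post-hoc comparisons with Bonferroni correction
#'
#' All pairwise paired t-tests between levels of a within-subject
#' factor, Bonferroni-adjusted over the family of comparisons.
#'
#' @param data Long-format data.frame.
#' @param dv,factor_col,subject Column names.
#' @return Data.frame of comparisons with `t`, `df`, `p`, `p_adjusted`,
#'   `cohens_d`.
#' @export
paired_posthoc <- function(data, dv, factor_col, subject = "subject") {
  levs <- unique(as.character(data[[factor_col]]))
  prs <- utils::combn(levs, 2, simplify = FALSE)
  m <- length(prs)
  out <- do.call(rbind, lapply(prs, function(pr) {
    a <- data[data[[factor_col]] == pr[1], ]
    b <- data[data[[factor_col]] == pr[2], ]
    a <- a[order(a[[subject]]), ]; b <- b[order(b[[subject]]), ]
    tt <- stats::t.test(a[[dv]], b[[dv]], paired = TRUE)
    data.frame(comparison = paste(pr[1], "-", pr[2]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, p_adjusted = min(1, m * tt$p.value),
               cohens_d = cohens_d(mean(a[[dv]]), stats::sd(a[[dv]]),
                                   mean(b[[dv]]), stats::sd(b[[dv]])),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
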