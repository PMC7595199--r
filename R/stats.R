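#' Per-severity cohort summary
#'
#' Recomputes the demographic summary table from participant rows: group
#' size, percent left-lateralized (strokes), mean days post-onset, mean
#' NIHSS, percent male and mean age.  Controls report size, gender and age
#' only.  Empty groups are omitted (with a note attribute).
#'
#' @param cohort A `qeeg_cohort`.
#' @return Data frame with one row per non-empty severity group and columns
#'   `severity`, `n`, `pct_left`, `mean_days_post_onset`, `mean_nihss`,
#'   `pct_male`, `mean_age`.
#' @export
summarize_cohort <- function(cohort) {
  rows <- lapply(severity_levels(), function(lv) {
    g <- cohort[cohort$severity == lv, , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    is_ctrl <- lv == "control"
    data.frame(
      severity = lv, n = nrow(g),
      pct_left = if (is_ctrl) NA_real_ else
        100 * mean(g$lateralization == "left"),
      mean_days_post_onset = if (is_ctrl) NA_real_ else
        mean(g$days_post_onset),
      mean_nihss = if (is_ctrl) NA_real_ else mean(g$nihss),
      pct_male = 100 * mean(g$gender == "M"),
      mean_age = mean(g$age),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  empty <- setdiff(severity_levels(), out$severity)
  if (length(empty)) attr(out, "note") <-
      sprintf("empty group(s) omitted: %s", paste(empty, collapse = ", "))
  out
}

#' Fixed-effects ANOVA with partial eta-squared
#'
#' One- or two-way fixed-effects ANOVA on a numeric outcome with
#' categorical factors, using Type III sums of squares (sum-to-zero
#' contrasts; each term's SS is the increase in residual SS when that term
#' alone is dropped from the full model), so unbalanced designs are handled
#' consistently.  Effect size is partial eta-squared,
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param values Numeric outcome vector.
#' @param f1 First factor (coerced).
#' @param f2 Optional second factor; when present the full model includes
#'   the interaction.
#' @return Data frame of class `anova_pes` with one row per term
#'   (`f1`, `f2`, `f1:f2`): `ss`, `df`, `F`, `p`, `partial_eta_sq`, plus
#'   the residual row.  A saturated, noise-free design (residual SS = 0)
#'   is flagged: `p = 0`, `partial_eta_sq = 1`, `F = Inf`.
#' @export
anova_pes <- function(values, f1, f2 = NULL) {
  f1 <- droplevels(as.factor(f1))
  if (nlevels(f1) < 2) abort_param("f1 needs at least 2 levels")
  dat <- data.frame(y = as.numeric(values), f1 = f1)
  form <- y ~ f1
  if (!is.null(f2)) {
    f2 <- droplevels(as.factor(f2))
    if (nlevels(f2) < 2) abort_param("f2 needs at least 2 levels")
    dat$f2 <- f2
    form <- y ~ f1 * f2
  }
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  full <- stats::lm(form, data = dat)
  rss <- sum(stats::residuals(full)^2)
  df_res <- full$df.residual
  if (df_res < 1) abort_param("zero residual degrees of freedom")

  mm <- stats::model.matrix(full)
  assign <- attr(mm, "assign")
  terms_lab <- attr(stats::terms(full), "term.labels")
  qr_y <- dat$y
  rows <- lapply(seq_along(terms_lab), function(ti) {
    keep <- assign != ti
    red <- stats::lm.fit(mm[, keep, drop = FALSE], qr_y)
    ss <- sum(red$residuals^2) - rss
    ss <- max(ss, 0)
    df_t <- sum(assign == ti)
    if (rss > 1e-12 * (ss + rss + 1e-300)) {
      Fv <- (ss / df_t) / (rss / df_res)
      pv <- stats::pf(Fv, df_t, df_res, lower.tail = FALSE)
      pes <- ss / (ss + rss)
    } else {                       # noise-free saturated fit
      Fv <- if (ss > 0) Inf else 0
      pv <- if (ss > 0) 0 else 1
      pes <- if (ss > 0) 1 else 0
    }
    data.frame(term = terms_lab[ti], ss = ss, df = df_t, F = Fv, p = pv,
               partial_eta_sq = pes, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(term = "residual", ss = rss, df = df_res,
                               F = NA, p = NA, partial_eta_sq = NA))
  class(out) <- c("anova_pes", "data.frame")
  out
}
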