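#' Partial eta squared from an F statistic
#'
#' `F * df1 / (F * df1 + df2)`, the effect-size measure reported alongside
#' every F test.
#'
#' @param f F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @export
partial_eta_squared <- function(f, df1, df2) {
  stopifnot(all(f >= 0, na.rm = TRUE), all(df1 >= 1, na.rm = TRUE),
            all(df2 >= 1, na.rm = TRUE))
  f * df1 / (f * df1 + df2)
}

#' Post-hoc observed power of an F test
#'
#' Power of the test at the observed effect size under the fixed-effects
#' convention: the noncentrality parameter is taken as `lambda = F * df1`
#' and power is the probability that a noncentral F variable exceeds the
#' alpha-level critical value.  At `F = 0` the power equals `alpha`.
#'
#' @param f Observed F statistic.
#' @param df1,df2 Degrees of freedom.
#' @param alpha Significance level.
#' @export
observed_power <- function(f, df1, df2, alpha = 0.05) {
  pf(qf(1 - alpha, df1, df2), df1, df2, ncp = f * df1, lower.tail = FALSE)
}

#' Session-level means of per-trial metrics
#'
#' Averages per-trial metric values within each (session, condition, unit,
#' measure) cell, the aggregation unit of the session-level ANOVAs.
#'
#' @param trial_metrics Tidy tibble with columns `session`, `condition`,
#'   `unit` (J1 / J2 / HYPER), `measure`, `value` and one row per trial.
#' @param design Optional session design joined onto the result (adds the
#'   `matched` flag and experience-based `skill` level).
#' @return Tibble with one row per cell: the mean `value` and `n_trials`.
#' @export
aggregate_session_means <- function(trial_metrics, design = NULL) {
  tm <- trial_metrics[!is.na(trial_metrics$value), , drop = FALSE]
  key <- interaction(tm$session, tm$condition, tm$unit, tm$measure,
                     drop = TRUE)
  agg <- do.call(rbind, lapply(split(tm, key), function(g)
    data.frame(session = g$session[1], condition = g$condition[1],
               unit = g$unit[1], measure = g$measure[1],
               value = mean(g$value), n_trials = nrow(g),
               stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  out <- tibble::as_tibble(agg)
  if (!is.null(design)) {
    d <- unique(design[, c("session", "matched")])
    out <- merge(out, d, by = "session", all.x = TRUE)
    # J1 is by convention the less experienced member
    out$skill <- ifelse(out$unit == "J1", "less",
                        ifelse(out$unit == "J2", "more", NA))
    out <- tibble::as_tibble(out)
  }
  out[order(out$session, out$condition, out$unit, out$measure), ]
}

# extract (effect, df1, df2, F, p) rows from a summary.aovlist
.tidy_aovlist <- function(s) {
  out <- list()
  for (stratum in s) {
    tab <- stratum[[1]]
    resid <- trimws(rownames(tab)) == "Residuals"
    df2 <- if (any(resid)) tab[resid, "Df"] else NA_real_
    for (r in which(!resid)) {
      eff <- trimws(rownames(tab)[r])
      f <- tab[r, "F value"]; p <- tab[r, "Pr(>F)"]
      if (!is.null(tab[r, "Sum Sq"]) && !is.na(tab[r, "Sum Sq"]) &&
          tab[r, "Sum Sq"] < 1e-12) { f <- 0; p <- 1 }
      out[[length(out) + 1L]] <- data.frame(
        effect = eff, df1 = tab[r, "Df"], df2 = df2,
        F = if (is.null(f) || is.na(f)) NA_real_ else f,
        p = if (is.null(p) || is.na(p)) NA_real_ else p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Mixed-design (split-plot) ANOVA on session-level metrics
#'
#' Runs the session-level analysis of variance with the session as the
#' random blocking unit: up to two 2-level within-session factors (e.g.
#' condition SOLO vs PAIRED and skill level less vs more experienced) and
#' an optional between-session factor (e.g. matched vs unmatched dyads).
#' All main effects and interactions are reported with partial eta squared
#' and post-hoc observed power.  Omitting `between` (or subsetting the
#' table to one group first) gives the two-factor variant.  With 2-level
#' within factors sphericity holds trivially and no correction is applied.
#'
#' @param table Session-level tibble (see [aggregate_session_means()])
#'   already filtered to one measure, or any tidy data frame.
#' @param dv Name of the dependent-variable column.
#' @param within Names of within-session factor columns (1 or 2).
#' @param between Name of the between-session factor column, or `NULL`.
#' @param subject Name of the session identifier column.
#' @return Tibble with one row per effect: `effect`, `df1`, `df2`, `F`,
#'   `p`, `partial_eta_sq`, `observed_power`.
#' @export
mixed_anova <- function(table, dv = "value", within = c("condition", "skill"),
                        between = "matched", subject = "session") {
  df <- as.data.frame(table)
  if (!is.numeric(df[[dv]])) stop("dependent variable must be numeric")
  for (v in c(within, between, subject)) df[[v]] <- factor(df[[v]])
  if (!is.null(between)) {
    sizes <- table(unique(df[, c(subject, between)])[[between]])
    if (any(sizes < 2))
      stop("each between-session group needs at least two sessions")
  }
  wterm <- paste(within, collapse = "*")
  fixed <- if (is.null(between)) wterm
  else paste(between, wterm, sep = "*")
  form <- stats::as.formula(sprintf("%s ~ %s + Error(%s/(%s))", dv, fixed,
                                    subject, wterm))
  fit <- aov(form, data = df)
  res <- .tidy_aovlist(summary(fit))
  res$partial_eta_sq <- partial_eta_squared(pmax(res$F, 0), res$df1,
                                            res$df2)
  res$observed_power <- ifelse(is.na(res$F), NA_real_,
                               observed_power(pmax(res$F, 0), res$df1,
                                              res$df2))
  tibble::as_tibble(res)
}

.cohen_d <- function(x, y, paired) {
  if (paired) {
    d <- x - y
    if (sd(d) == 0) return(0)
    mean(d) / sd(d)
  } else {
    sp <- sqrt(((length(x) - 1) * stats::var(x) +
                  (length(y) - 1) * stats::var(y)) /
                 (length(x) + length(y) - 2))
    if (sp == 0) return(0)
    (mean(x) - mean(y)) / sp
  }
}

#' Follow-up t tests with Bonferroni correction
#'
#' Runs each contrast as a (paired or independent two-sample) t test and
#' multiplies the p values by the number of contrasts, capped at 1.
#' Cohen's d uses the standard deviation of the paired differences for
#' paired contrasts and the pooled standard deviation otherwise.
#'
#' @param contrasts Named list; each element a list with numeric vectors
#'   `x` and `y` and optional `paired` (default `TRUE`).
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @return Tibble with `contrast`, `t`, `df`, `p`, `p_corrected`,
#'   `cohen_d`.
#' @export
followup_ttests <- function(contrasts, correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  k <- length(contrasts)
  rows <- lapply(names(contrasts), function(nm) {
    ct <- contrasts[[nm]]
    paired <- if (is.null(ct$paired)) TRUE else ct$paired
    if (paired && sd(ct$x - ct$y) == 0) {
      # identical paired samples: no evidence either way
      return(data.frame(contrast = nm, t = 0, df = length(ct$x) - 1,
                        p = 1, p_corrected = 1, cohen_d = 0,
                        stringsAsFactors = FALSE))
    }
    tt <- t.test(ct$x, ct$y, paired = paired, var.equal = TRUE)
    data.frame(contrast = nm, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               p_corrected = if (correction == "bonferroni")
                 min(tt$p.value * k, 1) else tt$p.value,
               cohen_d = .cohen_d(ct$x, ct$y, paired),
               stringsAsFactors = FALSE)
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Independent t tests on hyperbrain measures between dyad groups
#'
#' One equal-variance, two-sided independent t test per measure comparing
#' session-level hyperbrain metrics between the matched and unmatched
#' skill-level groups.  Degenerate zero-variance inputs are flagged: with
#' identical constant groups `t = 0, p = 1`; with differing constant
#' groups the difference is reported as infinitely large (`p = 0`).
#'
#' @param table Session-level tibble with columns `measure`, `value` and a
#'   two-level grouping column.
#' @param measures Measures to test.
#' @param group Name of the grouping column.
#' @return Tibble with one row per measure.
#' @export
hyperbrain_group_ttests <- function(table,
                                    measures = c("G", "C", "SWI", "D", "IIR"),
                                    group = "matched") {
  rows <- lapply(measures, function(m) {
    sub <- table[table$measure == m & !is.na(table$value), , drop = FALSE]
    g <- factor(sub[[group]])
    if (nlevels(g) != 2) stop("grouping column must have two levels")
    x <- sub$value[g == levels(g)[1]]
    y <- sub$value[g == levels(g)[2]]
    if (length(x) < 2 || length(y) < 2)
      stop("each group needs at least two sessions")
    if (sd(x) == 0 && sd(y) == 0) {
      degen <- mean(x) != mean(y)
      return(data.frame(measure = m, t = if (degen) Inf else 0,
                        df = length(x) + length(y) - 2,
                        p = if (degen) 0 else 1, cohen_d = if (degen) Inf
                        else 0, zero_variance = TRUE,
                        stringsAsFactors = FALSE))
    }
    tt <- t.test(x, y, var.equal = TRUE)
    data.frame(measure = m, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               cohen_d = .cohen_d(x, y, paired = FALSE),
               zero_variance = FALSE, stringsAsFactors = FALSE)
  })
  tibble::as_tibble(do.call(rbind, rows))
}
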