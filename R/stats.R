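#' Linear mixed-effects models for footwear contrasts
#'
#' Three model forms contrast the two shoe configurations on a per-stride
#' (or per-step, per-lap-section) outcome table:
#' * `intercept_only`:  `Outcome ~ Config + (1 | Subject)`
#' * `random_slope`:    `Outcome ~ Config + (Config | Subject)`
#' * `random_slope_with_speed`: `Outcome ~ Config + Speed + (Config | Subject)`
#'
#' Fits are REML via `lmerTest`; `Config` is coded with Lace as the
#' reference level, so the `Config` coefficient is the Wrap - Lace effect.
#' Inference on the `Config` coefficient uses the Satterthwaite
#' denominator-degrees-of-freedom t-test, which stays calibrated for small
#' cohorts. A singular random-slope fit falls back to the random-intercept
#' form with a warning.
#'
#' @param table Data frame with columns `Outcome`, `Config` (values
#'   `"Wrap"`/`"Lace"`), `Subject`, and optionally `Speed`.
#' @param form One of `"intercept_only"`, `"random_slope"`,
#'   `"random_slope_with_speed"`.
#' @param alpha Significance level recorded in the fit.
#' @return An object of class `lmm_fit`: fixed effects with SEs and
#'   Satterthwaite p-values, variance components, emmeans per config,
#'   contrast (difference, percent difference, p), convergence metadata.
#' @export
fit_lmm <- function(table,
                    form = c("random_slope", "intercept_only",
                             "random_slope_with_speed"),
                    alpha = 0.05) {
  form <- match.arg(form)
  stopifnot(all(c("Outcome", "Config", "Subject") %in% names(table)))
  if (any(is.na(table$Config)) || any(is.na(table$Subject)))
    stop("Config and Subject must be complete")
  table <- table[is.finite(table$Outcome), , drop = FALSE]
  table$Config <- stats::relevel(factor(table$Config,
                                        levels = c("Lace", "Wrap")),
                                 ref = "Lace")
  table$Subject <- factor(table$Subject)
  if (nlevels(table$Subject) < 2) stop("need at least 2 subjects")

  fml <- switch(form,
    intercept_only = Outcome ~ Config + (1 | Subject),
    random_slope = Outcome ~ Config + (Config | Subject),
    random_slope_with_speed = Outcome ~ Config + Speed + (Config | Subject))
  if (form == "random_slope_with_speed" && !("Speed" %in% names(table)))
    stop("Speed covariate missing")

  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = TRUE)
  fit <- suppressMessages(lmerTest::lmer(fml, data = table, REML = TRUE,
                                         control = ctrl))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  fallback <- FALSE
  if (singular && form != "intercept_only") {
    # a boundary estimate of the intercept-slope correlation is the common
    # cause; refit with uncorrelated random effects before giving up on the
    # slope variance entirely
    fml_u <- if (form == "random_slope_with_speed")
      Outcome ~ Config + Speed + (Config || Subject)
    else Outcome ~ Config + (Config || Subject)
    fit_u <- suppressMessages(lmerTest::lmer(fml_u, data = table,
                                             REML = TRUE, control = ctrl))
    if (!lme4::isSingular(fit_u, tol = 1e-4)) {
      fit <- fit_u
    } else {
      warning("singular random-slope fit; falling back to random intercepts")
      fml2 <- if (form == "random_slope_with_speed")
        Outcome ~ Config + Speed + (1 | Subject)
      else Outcome ~ Config + (1 | Subject)
      fit <- suppressMessages(lmerTest::lmer(fml2, data = table, REML = TRUE,
                                             control = ctrl))
      fallback <- TRUE
    }
  }

  co <- stats::coef(summary(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- list(
    model = fit, form = form, alpha = alpha,
    fallback_intercept_only = fallback, singular = singular,
    fixed = co,
    varcorr = vc,
    n_obs = nrow(table), n_subjects = nlevels(table$Subject)
  )
  class(out) <- "lmm_fit"
  out
}

#' Estimated-marginal-mean contrast of a fitted model
#'
#' Computes the model-predicted outcome per configuration at the average of
#' any covariates (estimated marginal means), their Wrap - Lace difference,
#' the percent difference relative to the Lace emmean, and the Satterthwaite
#' p-value of the contrast.
#'
#' @param fit An `lmm_fit`.
#' @return List: `emmeans` (named numeric, Lace and Wrap),
#'   `difference` (Wrap - Lace), `percent_difference`
#'   (100 x (Wrap - Lace) / Lace; negative when Wrap is lower), `p`,
#'   `se`.
#' @export
emm_contrast <- function(fit) {
  em <- emmeans::emmeans(fit$model, "Config", lmer.df = "satterthwaite")
  es <- as.data.frame(em)
  emm <- stats::setNames(es$emmean, as.character(es$Config))
  ct <- as.data.frame(emmeans::contrast(em, method = "revpairwise"))
  # revpairwise on (Lace, Wrap) gives Wrap - Lace
  diff <- ct$estimate[1]
  if (abs(emm[["Lace"]]) < 1e-12) {
    warning("Lace emmean is zero; percent difference undefined")
    pct <- NA_real_
  } else {
    pct <- 100 * diff / emm[["Lace"]]
  }
  list(emmeans = emm, difference = diff, percent_difference = pct,
       p = ct$p.value[1], se = ct$SE[1])
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s%s, %d obs / %d subjects\n", x$form,
              if (x$fallback_intercept_only) " (fell back to intercepts)"
              else "", x$n_obs, x$n_subjects))
  print(round(x$fixed, 4))
  invisible(x)
}

#' Analyze a processed study
#'
#' Fits the full statistical battery on pipeline outputs: for each of the
#' biomechanical outcomes (speed, peak acceleration, peak jerk, peak
#' eversion velocity, M/L range from the IMU; heel/toe contact area and peak
#' pressures from the insole) a random-slope model per trail section; for
#' average heart rate and each questionnaire item a random-intercept model.
#' Subjects failing lap-time QC are excluded first.
#'
#' @param processed A `processed_study` from [process_study()] or
#'   [run_pipeline()].
#' @param speed_covariate If `TRUE`, also fit the speed-adjusted form
#'   (`random_slope_with_speed`) for IMU outcomes as a sensitivity analysis.
#' @param alpha Significance level.
#' @return An object of class `trail_report`: `contrasts` (one row per
#'   outcome x section: emmeans, difference, percent difference, p),
#'   `summary_table` (mean +/- SD of subject means per condition per
#'   section), `heart_rate`, `questionnaire`, `qc` (retained / excluded
#'   subjects), and `fits`.
#' @export
analyze_study <- function(processed, speed_covariate = FALSE, alpha = 0.05) {
  strides <- processed$strides
  steps <- processed$steps
  hr <- processed$hr

  keep <- processed$qc$retained
  if (length(keep) < 2) stop("fewer than 2 subjects pass lap QC")
  strides <- strides[strides$Subject %in% keep, ]
  steps <- steps[steps$Subject %in% keep, ]
  hr <- hr[hr$Subject %in% keep, ]

  imu_metrics <- c("speed", "peak_acc", "peak_jerk", "eversion_vel",
                   "ml_range")
  press_metrics <- c("heel_area", "toe_area", "heel_peak", "toe_peak")
  sections <- c("uphill", "top", "downhill")

  fits <- list()
  rows <- list()
  one <- function(tab, metric, section, form) {
    sub <- tab[tab$Section == section & is.finite(tab[[metric]]), ]
    df <- data.frame(Outcome = sub[[metric]], Config = sub$Config,
                     Subject = sub$Subject,
                     Speed = if ("speed" %in% names(sub)) sub$speed
                             else NA_real_)
    fit <- fit_lmm(df, form, alpha = alpha)
    ct <- emm_contrast(fit)
    fits[[paste(metric, section, sep = ".")]] <<- fit
    data.frame(metric = metric, section = section,
               emm_wrap = ct$emmeans[["Wrap"]],
               emm_lace = ct$emmeans[["Lace"]],
               difference = ct$difference,
               percent_difference = ct$percent_difference,
               se = ct$se, p = ct$p,
               significant = ct$p < alpha,
               form = fit$form,
               fallback = fit$fallback_intercept_only,
               stringsAsFactors = FALSE)
  }
  for (m in imu_metrics) for (s in sections)
    rows[[paste(m, s)]] <- one(strides, m, s, "random_slope")
  for (m in press_metrics) for (s in sections)
    rows[[paste(m, s)]] <- one(steps, m, s, "random_slope")
  contrasts <- do.call(rbind, rows)
  rownames(contrasts) <- NULL

  speed_adjusted <- NULL
  if (speed_covariate) {
    srows <- list()
    for (m in setdiff(imu_metrics, "speed")) for (s in sections) {
      sub <- strides[strides$Section == s & is.finite(strides[[m]]) &
                       is.finite(strides$speed), ]
      df <- data.frame(Outcome = sub[[m]], Config = sub$Config,
                       Subject = sub$Subject, Speed = sub$speed)
      fit <- fit_lmm(df, "random_slope_with_speed", alpha = alpha)
      ct <- emm_contrast(fit)
      srows[[paste(m, s)]] <- data.frame(
        metric = m, section = s, difference = ct$difference,
        percent_difference = ct$percent_difference, p = ct$p,
        stringsAsFactors = FALSE)
    }
    speed_adjusted <- do.call(rbind, srows)
    rownames(speed_adjusted) <- NULL
  }

  # heart rate: random-intercept model per section on lap-section means
  hr_rows <- list()
  for (s in sections) {
    sub <- hr[hr$Section == s & is.finite(hr$hr), ]
    df <- data.frame(Outcome = sub$hr, Config = sub$Config,
                     Subject = sub$Subject)
    fit <- fit_lmm(df, "intercept_only", alpha = alpha)
    ct <- emm_contrast(fit)
    hr_rows[[s]] <- data.frame(
      metric = "heart_rate", section = s,
      emm_wrap = ct$emmeans[["Wrap"]], emm_lace = ct$emmeans[["Lace"]],
      difference = ct$difference, p = ct$p, stringsAsFactors = FALSE)
  }
  heart_rate <- do.call(rbind, hr_rows)
  rownames(heart_rate) <- NULL

  questionnaire <- NULL
  if (!is.null(processed$questionnaire) && nrow(processed$questionnaire)) {
    q <- processed$questionnaire
    q <- q[q$Subject %in% keep, ]
    q_rows <- lapply(unique(q$item), function(it) {
      sub <- q[q$item == it, ]
      df <- data.frame(Outcome = sub$response, Config = sub$config,
                       Subject = sub$Subject)
      fit <- fit_lmm(df, "intercept_only", alpha = alpha)
      ct <- emm_contrast(fit)
      data.frame(item = it, emm_wrap = ct$emmeans[["Wrap"]],
                 emm_lace = ct$emmeans[["Lace"]],
                 difference = ct$difference, p = ct$p,
                 stringsAsFactors = FALSE)
    })
    questionnaire <- do.call(rbind, q_rows)
    rownames(questionnaire) <- NULL
  }

  summary_table <- study_summary_table(strides, steps, hr)

  out <- list(contrasts = contrasts, summary_table = summary_table,
              heart_rate = heart_rate, questionnaire = questionnaire,
              speed_adjusted = speed_adjusted,
              qc = processed$qc, fits = fits, alpha = alpha)
  class(out) <- "trail_report"
  out
}

# Mean +/- SD of per-subject means, per metric x section x condition.
study_summary_table <- function(strides, steps, hr) {
  dt_s <- data.table::as.data.table(strides)
  dt_p <- data.table::as.data.table(steps)
  dt_h <- data.table::as.data.table(hr)
  long <- rbind(
    data.table::melt(dt_s, id.vars = c("Subject", "Config", "Section"),
                     measure.vars = c("speed", "peak_acc", "peak_jerk",
                                      "eversion_vel", "ml_range"),
                     variable.name = "metric", value.name = "value"),
    data.table::melt(dt_p, id.vars = c("Subject", "Config", "Section"),
                     measure.vars = c("heel_area", "toe_area", "heel_peak",
                                      "toe_peak"),
                     variable.name = "metric", value.name = "value"),
    data.table::melt(dt_h, id.vars = c("Subject", "Config", "Section"),
                     measure.vars = "hr", variable.name = "metric",
                     value.name = "value"))
  subj <- long[is.finite(value),
               .(m = mean(value)), by = .(metric, Section, Config, Subject)]
  tab <- subj[, .(mean = mean(m), sd = stats::sd(m), n_subjects = .N),
              by = .(metric, Section, Config)]
  as.data.frame(tab)
}

#' @export
print.trail_report <- function(x, ...) {
  cat("<trail_report>\n")
  cat(sprintf("  subjects retained: %d (excluded: %s)\n",
              length(x$qc$retained),
              if (length(x$qc$excluded)) paste(x$qc$excluded, collapse = ", ")
              else "none"))
  cat("  per-section Wrap vs Lace contrasts:\n")
  d <- x$contrasts
  d$percent_difference <- round(d$percent_difference, 2)
  d$difference <- signif(d$difference, 3)
  d$p <- signif(d$p, 2)
  print(d[, c("metric", "section", "difference", "percent_difference", "p",
              "significant")], row.names = FALSE)
  invisible(x)
}

# value used in tests: NULL-safe accessor
`%||%` <- function(a, b) if (is.null(a)) b else a
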