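#' Disaggregate a time-varying covariate into within- and between-person parts
#'
#' Person-mean centering around the grand mean: the between-person
#' component is each person's mean minus the grand mean (constant within
#' person); the within-person component is the day value minus the
#' person's own mean. The decomposition reconstructs the raw value
#' exactly: `x = grand_mean + between + within`.
#'
#' @param x Numeric day-level values (e.g. day-mean pain).
#' @param id Participant identifier, same length as `x`.
#' @param grand `"person"` (default): grand mean is the unweighted mean
#'   of person means, so persons with more observed days do not dominate
#'   the between-person centring; `"pooled"`: plain mean of all
#'   observations.
#' @return Tibble with `between`, `within`, `person_mean`, and attribute
#'   `grand_mean`.
#' @export
#' @examples
#' center_within_between(c(1, 2, 3, 3, 4, 5), rep(c("a", "b"), each = 3))
center_within_between <- function(x, id, grand = c("person", "pooled")) {
  grand <- match.arg(grand)
  stopifnot(length(x) == length(id))
  ok <- !is.na(x)
  if (length(unique(id[ok])) < 2) {
    abort("within/between disaggregation needs at least 2 participants with non-missing values")
  }
  pm <- tapply(x[ok], id[ok], mean)
  gm <- if (grand == "person") mean(pm) else mean(x[ok])
  person_mean <- as.vector(pm[as.character(id)])
  out <- tibble::tibble(between = person_mean - gm,
                        within = x - person_mean,
                        person_mean = person_mean)
  attr(out, "grand_mean") <- gm
  out
}

#' Fit the two-level model for one life-space feature
#'
#' Linear mixed model for daily observations nested in participants: the
#' daily feature value is regressed on within-person and between-person
#' pain (person-mean centring around the grand mean), adjusted for age,
#' gender, and living alone, with a participant random intercept and
#' independent within-participant residuals. Fit by REML via
#' [lme4::lmer()]. Inference uses the normal reference: `p = 2 * pnorm(-|z|)`
#' and 95% CI = estimate +/- 1.96 SE.
#'
#' @param panel Tibble with one row per participant-day: `participant_id`,
#'   the feature column, `mean_pain`, and the covariate columns. Rows with
#'   missing outcome, pain, or covariates are dropped.
#' @param feature Name of the outcome column.
#' @param covariates Character vector of adjustment covariates (default
#'   `age`, `female`, `lives_alone`; may be empty).
#' @param grand Grand-mean convention, see [center_within_between()].
#' @param reml Fit by REML (default) or ML.
#' @return An object of class `lifespace_fit`: coefficient table
#'   (`term`, `estimate`, `se`, `z`, `p`, `conf.low`, `conf.high`),
#'   variance components, sample sizes, convergence and singularity flags.
#' @export
fit_feature_model <- function(panel, feature,
                              covariates = c("age", "female", "lives_alone"),
                              grand = c("person", "pooled"), reml = TRUE) {
  grand <- match.arg(grand)
  need <- c("participant_id", "mean_pain", feature, covariates)
  if (!all(need %in% names(panel))) {
    abort(paste("panel is missing column(s):",
                paste(setdiff(need, names(panel)), collapse = ", ")))
  }
  d <- panel[stats::complete.cases(panel[need]), need]
  if (nrow(d) < 10) abort("fewer than 10 usable rows for model fitting")
  if (length(unique(d$participant_id)) < 2) {
    abort("model fitting needs at least 2 participants")
  }
  cen <- center_within_between(d$mean_pain, d$participant_id, grand = grand)
  d$pain_within <- cen$within
  d$pain_between <- cen$between
  # centring identities, asserted on every fit
  wm <- tapply(d$pain_within, d$participant_id, mean)
  stopifnot(all(abs(wm) < 1e-10),
            all(abs(attr(cen, "grand_mean") + d$pain_between + d$pain_within -
                      d$mean_pain) < 1e-10))

  rhs <- paste(c("pain_within", "pain_between", covariates,
                 "(1 | participant_id)"), collapse = " + ")
  fml <- stats::as.formula(paste0("`", feature, "` ~ ", rhs))

  warn_msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = d, REML = reml),
    warning = function(w) {
      warn_msgs <<- c(warn_msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  singular <- lme4::isSingular(fit)
  conv_code <- fit@optinfo$conv$opt
  lme4_issues <- unlist(fit@optinfo$conv$lme4$messages)
  converged <- conv_code == 0 &&
    !any(grepl("failed to converge", c(warn_msgs, lme4_issues), ignore.case = TRUE))

  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- b / se
  coefs <- tibble::tibble(
    term = names(b),
    estimate = unname(b),
    se = unname(se),
    z = unname(z),
    p = 2 * stats::pnorm(-abs(unname(z))),
    conf.low = unname(b - 1.96 * se),
    conf.high = unname(b + 1.96 * se))
  vc <- as.data.frame(lme4::VarCorr(fit))

  structure(
    list(feature = feature,
         coefficients = coefs,
         var_intercept = vc$vcov[vc$grp == "participant_id"][1],
         var_residual = vc$vcov[vc$grp == "Residual"][1],
         n_obs = nrow(d),
         n_participants = length(unique(d$participant_id)),
         grand_mean = attr(cen, "grand_mean"),
         converged = converged,
         singular = singular,
         messages = c(warn_msgs, lme4_issues),
         model = fit),
    class = "lifespace_fit")
}

#' @export
print.lifespace_fit <- function(x, ...) {
  cat(sprintf("Two-level random-intercept model for '%s' (%d days, %d participants)\n",
              x$feature, x$n_obs, x$n_participants))
  pw <- x$coefficients[x$coefficients$term %in% c("pain_within", "pain_between"), ]
  for (i in seq_len(nrow(pw))) {
    cat(sprintf("  %-13s %8.3f (SE %.3f), P>|z| %.3f, 95%% CI [%.3f, %.3f]\n",
                sub("pain_", "", pw$term[i]), pw$estimate[i], pw$se[i],
                pw$p[i], pw$conf.low[i], pw$conf.high[i]))
  }
  if (x$singular) cat("  note: singular fit (random-intercept variance ~ 0)\n")
  if (!x$converged) cat("  WARNING: fit did not converge cleanly\n")
  invisible(x)
}

#' Fit the two-level model for every life-space feature
#'
#' One model per feature; per-feature failures are isolated and recorded
#' rather than aborting the batch. No multiplicity adjustment is applied.
#'
#' @inheritParams fit_feature_model
#' @param features Outcome columns to model (default the ten features).
#' @return Tibble with one row per feature x effect (between/within):
#'   `feature`, `effect`, `estimate`, `se`, `p`, `conf.low`, `conf.high`,
#'   `n_obs`, `n_participants`, `converged`, `singular`, `error`. Full
#'   fit objects are attached as attribute `fits`.
#' @export
fit_all_features <- function(panel, features = lifespace_feature_names(),
                             covariates = c("age", "female", "lives_alone"),
                             grand = c("person", "pooled"), reml = TRUE) {
  grand <- match.arg(grand)
  fits <- lapply(features, function(f) {
    tryCatch(fit_feature_model(panel, f, covariates = covariates,
                               grand = grand, reml = reml),
             error = function(e) conditionMessage(e))
  })
  names(fits) <- features
  rows <- lapply(features, function(f) {
    ft <- fits[[f]]
    if (is.character(ft)) {
      return(tibble::tibble(feature = f, effect = c("between", "within"),
                            estimate = NA_real_, se = NA_real_, p = NA_real_,
                            conf.low = NA_real_, conf.high = NA_real_,
                            n_obs = NA_integer_, n_participants = NA_integer_,
                            converged = FALSE, singular = NA, error = ft))
    }
    cf <- ft$coefficients
    sel <- match(c("pain_between", "pain_within"), cf$term)
    tibble::tibble(feature = f, effect = c("between", "within"),
                   estimate = cf$estimate[sel], se = cf$se[sel], p = cf$p[sel],
                   conf.low = cf$conf.low[sel], conf.high = cf$conf.high[sel],
                   n_obs = ft$n_obs, n_participants = ft$n_participants,
                   converged = ft$converged, singular = ft$singular,
                   error = NA_character_)
  })
  out <- dplyr::bind_rows(rows)
  if (all(!is.na(out$error))) {
    abort(paste("no feature model could be fitted;", out$error[1]))
  }
  attr(out, "fits") <- fits
  out
}

#' Join features, pain days and demographics into a modelling panel
#'
#' Inner-joins daily features with daily pain and participant
#' demographics. Only feature-valid days with a non-missing pain mean
#' are retained.
#'
#' @param features Output of [extract_features()].
#' @param pain_days Output of [aggregate_daily_pain()].
#' @param demographics Tibble `participant_id`, `age`, `female`,
#'   `lives_alone`.
#' @return Panel tibble, one row per usable participant-day.
#' @export
build_panel <- function(features, pain_days, demographics) {
  panel <- features |>
    dplyr::inner_join(pain_days, by = c("participant_id", "local_date")) |>
    dplyr::inner_join(demographics, by = "participant_id") |>
    dplyr::filter(.data$valid, !is.na(.data$mean_pain))
  panel
}

#' Format model results as a human-readable table
#'
#' Renders the between/within coefficient table in the conventional
#' report layout (coefficient, SE, P>|z|, 95% CI per feature).
#'
#' @param results Tibble from [fit_all_features()].
#' @return Character vector of report lines.
#' @export
format_results_table <- function(results) {
  lines <- c(sprintf("%-22s %-8s %10s %8s %8s  %s",
                     "GPS feature", "Effect", "Coef.", "SE", "P>|z|", "95% CI"))
  for (f in unique(results$feature)) {
    sub <- results[results$feature == f, ]
    lines <- c(lines, f)
    for (i in seq_len(nrow(sub))) {
      lines <- c(lines, if (is.na(sub$estimate[i])) {
        sprintf("  %-20s %-8s   failed: %s", "", sub$effect[i], sub$error[i])
      } else {
        sprintf("  %-20s %-8s %10.3f %8.3f %8.3f  [%.2f, %.2f]",
                "", sub$effect[i], sub$estimate[i], sub$se[i], sub$p[i],
                sub$conf.low[i], sub$conf.high[i])
      })
    }
  }
  lines
}
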