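# Group-comparison models. All game metrics are modeled at the
# participant x level grain with random intercepts for participant and
# level; fixed effects are limb group, age group and (for the interaction
# test) their product; covariates are age in years and median motor
# reaction time, each centered within age group and given separate slopes
# for children and adults. Likelihood-ratio tests compare maximum-
# likelihood nested refits.

# rows: one per play, joined with participant profile and covariates.
model_frame <- function(d, metrics = NULL) {
  if (is.null(metrics)) metrics <- level_metrics(d)
  p <- d$participants
  idx <- match(metrics$participant_id, p$participant_id)
  mf <- cbind(metrics,
              age_group = factor(p$age_group[idx], levels = c("adult", "child")),
              limb_group = factor(p$limb_group[idx], levels = c("NLD", "LD")),
              age_years = p$age_years[idx])
  ms <- tryCatch(motor_summary(d), error = function(e) NULL)
  mf$median_rt <- if (is.null(ms)) 0 else
    ms$median_rt[match(mf$participant_id, ms$participant_id)]
  add_group_centered(mf)
}

# center age and median rt within age group (participant-wise means) and
# split each into separate child/adult slopes, orthogonal to the age_group
# indicator.
add_group_centered <- function(mf) {
  one <- !duplicated(mf$participant_id)
  for (v in c("age_years", "median_rt")) {
    mns <- tapply(mf[[v]][one], mf$age_group[one], mean)
    cen <- mf[[v]] - mns[as.character(mf$age_group)]
    nm <- if (v == "age_years") "age" else "rt"
    mf[[paste0(nm, "_child")]] <- cen * (mf$age_group == "child")
    mf[[paste0(nm, "_adult")]] <- cen * (mf$age_group == "adult")
  }
  mf
}

lrt_stat <- function(full, reduced) {
  stat <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                        as.numeric(stats::logLik(reduced))))
  c(chisq = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

coef_table_lmer <- function(m) {
  s <- summary(m)$coefficients
  est <- s[, "Estimate"]; se <- s[, "Std. Error"]
  data.frame(term = rownames(s), estimate = est, se = se,
             ci_lo = est - stats::qnorm(0.975) * se,
             ci_hi = est + stats::qnorm(0.975) * se, row.names = NULL)
}

# boundary (singular) fits are legitimate estimates (a variance component
# at 0), not optimizer failures; only real convergence warnings flag a fit
converged_ok <- function(m) {
  msgs <- m@optinfo$conv$lme4$messages
  msgs <- msgs[!grepl("boundary \\(singular\\)", msgs)]
  length(msgs) == 0L && m@optinfo$conv$opt == 0
}

COVARS <- "age_child + age_adult + rt_child + rt_adult"

fit_mixed_family <- function(mf, response, gaussian = TRUE,
                             covariates = TRUE) {
  cov_term <- if (covariates) paste0(COVARS, " + ") else ""
  rand <- "(1 | participant_id) + (1 | level_id)"
  forms <- list(
    interaction = sprintf("%s ~ limb_group * age_group + %s%s",
                          response, cov_term, rand),
    additive = sprintf("%s ~ limb_group + age_group + %s%s",
                       response, cov_term, rand),
    no_limb = sprintf("%s ~ age_group + %s%s", response, cov_term, rand),
    no_age = sprintf("%s ~ limb_group + %s%s", response, cov_term, rand))
  fit1 <- function(f) {
    if (gaussian) lme4::lmer(stats::as.formula(f), data = mf, REML = FALSE)
    else lme4::glmer(stats::as.formula(f), data = mf,
                     family = stats::binomial(),
                     control = lme4::glmerControl(optimizer = "bobyqa"))
  }
  ms <- suppressWarnings(suppressMessages(lapply(forms, fit1)))
  tests <- rbind(
    limb_group = lrt_stat(ms$additive, ms$no_limb),
    age_group = lrt_stat(ms$additive, ms$no_age),
    interaction = lrt_stat(ms$interaction, ms$additive))
  list(model = ms$additive, model_interaction = ms$interaction,
       coef = coef_table_lmer(ms$additive),
       tests = data.frame(term = rownames(tests), chisq = tests[, "chisq"],
                          df = 1L, p = tests[, "p"], row.names = NULL),
       converged = all(vapply(ms, converged_ok, logical(1))))
}

new_fit_result <- function(fit, response, n_obs, extra = list()) {
  structure(c(list(response = response, model = fit$model,
                   model_interaction = fit$model_interaction,
                   coef = fit$coef, tests = fit$tests, n_obs = n_obs,
                   converged = fit$converged), extra),
            class = "cogstyle_fit")
}

#' @export
print.cogstyle_fit <- function(x, ...) {
  cat(sprintf("<cogstyle_fit> response: %s (n = %d)%s\n", x$response,
              x$n_obs, if (x$converged) "" else "  [did not converge]"))
  print(x$coef, digits = 3)
  cat("tests:\n")
  print(x$tests, digits = 3)
  if (!is.null(x$ratio))
    cat(sprintf("limb effect as ratio: %.3f, 95%% CI [%.3f, %.3f]\n",
                x$ratio[1], x$ratio[2], x$ratio[3]))
  invisible(x)
}

#' Mixed model for a timing metric
#'
#' Gaussian mixed model of `time_to_first`, `mean_gap`, or
#' `time_to_solution` on limb group and age group with random intercepts
#' for participant and level and the group-centered covariates.
#' Likelihood-ratio chi-squares (1 df) test the limb effect, the age
#' effect, and their interaction. The `limb_groupLD` coefficient is the
#' additive LD offset in seconds.
#'
#' @param d a `cogstyle_dataset`.
#' @param response which timing metric to model.
#' @param solved_only condition on solved plays (default), mirroring the
#'   convention of analysing only successful levels.
#' @param covariates include the group-centered age and motor-RT
#'   covariates (default); set `FALSE` for the covariate-free robustness
#'   variant.
#' @return A `cogstyle_fit`.
#' @export
fit_timing_model <- function(d, response = c("time_to_first", "mean_gap",
                                             "time_to_solution"),
                             solved_only = TRUE, covariates = TRUE) {
  response <- match.arg(response)
  mf <- model_frame(d)
  if (solved_only) mf <- mf[mf$solved, , drop = FALSE]
  mf <- mf[!is.na(mf[[response]]), , drop = FALSE]
  check_cells(mf)
  fit <- fit_mixed_family(mf, response, gaussian = TRUE,
                          covariates = covariates)
  new_fit_result(fit, response, nrow(mf))
}

#' Mixed model for attempt counts
#'
#' Gaussian mixed model of `log(n_attempts)` (so group effects are
#' multiplicative); the limb effect is additionally reported as
#' `exp(coefficient)` with its CI — the LD/NLD attempt ratio. A Poisson
#' mixed model on the raw counts is available via `family = "poisson"`.
#'
#' @param d a `cogstyle_dataset`.
#' @param solved_only condition on solved plays (default).
#' @param family `"lognormal"` (default) or `"poisson"`.
#' @param covariates include the group-centered covariates (default).
#' @return A `cogstyle_fit` with an extra `ratio` field
#'   `c(estimate, ci_lo, ci_hi)`.
#' @export
fit_attempts_model <- function(d, solved_only = TRUE,
                               family = c("lognormal", "poisson"),
                               covariates = TRUE) {
  family <- match.arg(family)
  mf <- model_frame(d)
  if (solved_only) mf <- mf[mf$solved, , drop = FALSE]
  mf <- mf[mf$n_attempts >= 1, , drop = FALSE]
  check_cells(mf)
  if (family == "lognormal") {
    mf$log_attempts <- log(mf$n_attempts)
    fit <- fit_mixed_family(mf, "log_attempts", gaussian = TRUE,
                            covariates = covariates)
  } else {
    rand <- "(1 | participant_id) + (1 | level_id)"
    forms <- sprintf("n_attempts ~ %%s + %s%s",
                     if (covariates) paste0(COVARS, " + ") else "", rand)
    f <- function(fe) suppressWarnings(lme4::glmer(
      stats::as.formula(sprintf(forms, fe)), data = mf,
      family = stats::poisson()))
    ms <- list(interaction = f("limb_group * age_group"),
               additive = f("limb_group + age_group"),
               no_limb = f("age_group"), no_age = f("limb_group"))
    tests <- rbind(limb_group = lrt_stat(ms$additive, ms$no_limb),
                   age_group = lrt_stat(ms$additive, ms$no_age),
                   interaction = lrt_stat(ms$interaction, ms$additive))
    fit <- list(model = ms$additive, model_interaction = ms$interaction,
                coef = coef_table_lmer(ms$additive),
                tests = data.frame(term = rownames(tests),
                                   chisq = tests[, "chisq"], df = 1L,
                                   p = tests[, "p"], row.names = NULL),
                converged = all(vapply(ms, converged_ok, logical(1))))
  }
  ld <- fit$coef[fit$coef$term == "limb_groupLD", ]
  new_fit_result(fit, "n_attempts", nrow(mf),
                 extra = list(ratio = c(estimate = exp(ld$estimate),
                                        ci_lo = exp(ld$ci_lo),
                                        ci_hi = exp(ld$ci_hi))))
}

#' Logistic mixed model for level solving
#'
#' Models the solved/unsolved outcome of every play (no conditioning) with
#' the same fixed, covariate and random structure as the timing models,
#' on the logit scale.
#'
#' @param d a `cogstyle_dataset`.
#' @param covariates include the group-centered covariates (default).
#' @return A `cogstyle_fit`.
#' @export
fit_solution_model <- function(d, covariates = TRUE) {
  mf <- model_frame(d)
  check_cells(mf)
  mf$solved_num <- as.numeric(mf$solved)
  fit <- fit_mixed_family(mf, "solved_num", gaussian = FALSE,
                          covariates = covariates)
  new_fit_result(fit, "solved", nrow(mf))
}

check_cells <- function(mf) {
  one <- !duplicated(mf$participant_id)
  tab <- table(mf$age_group[one], mf$limb_group[one])
  if (any(tab < 2))
    stop("need at least 2 participants per age x limb cell", call. = FALSE)
  if (length(unique(mf$level_id)) < 2)
    stop("need at least 2 levels", call. = FALSE)
  invisible(mf)
}

#' Linear model for the motor pre-test
#'
#' Ordinary linear model of a participant's median reaction time or median
#' click error on age group and limb group, controlling for age in years
#' with separate slopes per age group. F tests (type-II style, nested
#' model comparisons) are reported for the limb and age-group terms; with
#' `interaction = TRUE` an age x limb term is added and tested against the
#' additive model.
#'
#' @param d a `cogstyle_dataset` with motor data.
#' @param response `"median_rt"` or `"median_error"`.
#' @param interaction also fit and test the age x limb interaction.
#' @return A `cogstyle_fit` whose `tests` hold F statistics
#'   (`df1`, `df2`).
#' @export
fit_motor_lm <- function(d, response = c("median_rt", "median_error"),
                         interaction = FALSE) {
  response <- match.arg(response)
  ms <- motor_summary(d)
  p <- d$participants
  idx <- match(ms$participant_id, p$participant_id)
  mf <- cbind(ms,
              age_group = factor(p$age_group[idx], levels = c("adult", "child")),
              limb_group = factor(p$limb_group[idx], levels = c("NLD", "LD")),
              age_years = p$age_years[idx])
  mf <- add_group_centered(mf)
  base_rhs <- "age_group + age_child + age_adult"
  m_add <- stats::lm(stats::as.formula(
    sprintf("%s ~ limb_group + %s", response, base_rhs)), data = mf)
  if (any(is.na(stats::coef(m_add))))
    stop("motor model is rank deficient", call. = FALSE)
  m_nolimb <- stats::update(m_add, . ~ . - limb_group)
  m_noage <- stats::lm(stats::as.formula(
    sprintf("%s ~ limb_group + age_child + age_adult", response)), data = mf)
  ftest <- function(reduced, full) {
    a <- stats::anova(reduced, full)
    c(F = a$F[2], df1 = a$Df[2], df2 = a$Res.Df[2], p = a$`Pr(>F)`[2])
  }
  tests <- rbind(limb_group = ftest(m_nolimb, m_add),
                 age_group = ftest(m_noage, m_add))
  model <- m_add
  if (interaction) {
    m_int <- stats::update(m_add, . ~ . + limb_group:age_group)
    tests <- rbind(tests, interaction = ftest(m_add, m_int))
    model <- m_int
  }
  s <- summary(m_add)$coefficients
  ci <- stats::confint(m_add)
  coef_tab <- data.frame(term = rownames(s), estimate = s[, "Estimate"],
                         se = s[, "Std. Error"],
                         ci_lo = ci[rownames(s), 1], ci_hi = ci[rownames(s), 2],
                         row.names = NULL)
  structure(list(response = response, model = model,
                 coef = coef_tab,
                 tests = data.frame(term = rownames(tests),
                                    F = tests[, "F"], df1 = tests[, "df1"],
                                    df2 = tests[, "df2"], p = tests[, "p"],
                                    row.names = NULL),
                 n_obs = nrow(mf), converged = TRUE),
            class = "cogstyle_fit")
}
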