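# End-to-end orchestration: simulate/load -> metrics -> cluster ->
# classify -> switch -> infer, with a machine-readable report.

fit_summary <- function(f) {
  out <- list(response = f$response, n_obs = f$n_obs,
              converged = f$converged,
              coef = f$coef, tests = f$tests)
  if (!is.null(f$ratio)) out$ratio <- as.list(f$ratio)
  out
}

classification_summary <- function(cl) {
  list(grouping = cl$grouping, mean_score = cl$mean_score,
       n_participants = nrow(cl$participants), t = cl$t, df = cl$df,
       p = cl$p, n_skipped = nrow(cl$skipped))
}

#' Run the full analysis pipeline
#'
#' Runs, in order: data acquisition (a generator configuration or a
#' directory of canonical CSV logs), per-play metrics, leave-one-out group
#' classification for the requested contrasts, attempt-type clustering and
#' the switch-rate comparison across age groups, and the mixed-model /
#' linear-model group comparisons. Writes `report.json` (full precision),
#' `report.md` (3-significant-figure summary) and `metrics.csv` to
#' `out_dir`. Reruns with identical inputs and seed write identical
#' reports.
#'
#' @param input a `cogstyle_config` (the study is simulated) or a path to
#'   a directory containing `attempts.csv` and `motor.csv`.
#' @param out_dir output directory.
#' @param seed integer seed for simulation and clustering.
#' @param contrasts character vector among `"limb_group"`, `"age_group"`:
#'   classification contrasts to run.
#' @param solved_only condition process metrics on solved plays.
#' @param cluster_group_by population scheme for the switch clustering
#'   (see [label_sequences()]).
#' @param n_sweeps,burn_in Gibbs budget per clustering model.
#' @param stages subset of `c("metrics", "classify", "switch", "infer")`.
#' @return The report, invisibly.
#' @export
run_pipeline <- function(input, out_dir, seed = 1,
                         contrasts = c("limb_group", "age_group"),
                         solved_only = TRUE,
                         cluster_group_by = c("age_group", "limb_group"),
                         n_sweeps = 200, burn_in = 100,
                         stages = c("metrics", "classify", "switch",
                                    "infer")) {
  t0 <- proc.time()[["elapsed"]]
  stage_msg <- function(s) message(sprintf("[cogstyle] %-8s (%.1f s)", s,
                                           proc.time()[["elapsed"]] - t0))
  run_stage <- function(name, expr) {
    stage_msg(name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  d <- run_stage("data", {
    if (inherits(input, "cogstyle_config")) generate_dataset(input, seed)
    else if (inherits(input, "cogstyle_dataset")) input
    else adapt_archive(input)
  })

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  report <- list(manifest = list(
    package = "cogstyle",
    version = as.character(utils::packageVersion("cogstyle")),
    seed = seed, solved_only = solved_only,
    n_participants = nrow(d$participants),
    n_levels = length(unique(d$plays$level_id))))

  metrics <- run_stage("metrics", level_metrics(d))
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  if ("metrics" %in% stages) {
    p <- d$participants
    cell <- paste(p$age_group, p$limb_group, sep = "_")
    agg <- aggregate_participant(metrics, solved_only = solved_only)
    agg_cell <- cell[match(agg$participant_id, p$participant_id)]
    by_cell <- lapply(split(agg, agg_cell), function(g)
      list(n = nrow(g),
           solution_rate = mean(g$solution_rate),
           n_attempts = mean(g$n_attempts, na.rm = TRUE),
           time_to_first = mean(g$time_to_first, na.rm = TRUE),
           time_to_solution = mean(g$time_to_solution, na.rm = TRUE),
           mean_gap = mean(g$mean_gap, na.rm = TRUE)))
    report$group_summaries <- by_cell
  }

  if ("classify" %in% stages) {
    report$classification <- run_stage("classify", {
      lapply(stats::setNames(contrasts, contrasts), function(ct)
        classification_summary(loo_classify(d, grouping = ct)))
    })
  }

  if ("switch" %in% stages) {
    report$switching <- run_stage("switch", {
      dl <- label_sequences(d, group_by = cluster_group_by,
                            n_sweeps = n_sweeps, burn_in = burn_in,
                            seed = seed)
      a <- dl$attempts
      ag <- d$participants$age_group[match(a$participant_id,
                                           d$participants$participant_id)]
      cmp <- compare_switch_rates(a[ag == "child", ], a[ag == "adult", ],
                                  labels = c("child", "adult"))
      list(rates = as.list(cmp$rates),
           n_transitions = as.list(cmp$n_transitions),
           chisq = cmp$chisq, df = cmp$df, p = cmp$p,
           note = if (is.null(cmp$note)) NA else cmp$note)
    })
  }

  if ("infer" %in% stages) {
    report$models <- run_stage("infer", {
      fits <- list(
        time_to_first = fit_timing_model(d, "time_to_first", solved_only),
        mean_gap = fit_timing_model(d, "mean_gap", solved_only),
        time_to_solution = fit_timing_model(d, "time_to_solution", TRUE),
        n_attempts = fit_attempts_model(d, solved_only),
        solved = fit_solution_model(d),
        motor_rt = fit_motor_lm(d, "median_rt"),
        motor_error = fit_motor_lm(d, "median_error"))
      lapply(fits, fit_summary)
    })
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(render_report_md(report), file.path(out_dir, "report.md"))
  stage_msg("done")
  invisible(report)
}

sig3 <- function(x) formatC(signif(x, 3), format = "fg", flag = "#")

render_report_md <- function(report) {
  lines <- c("# cogstyle pipeline report", "",
             sprintf("- participants: %d, levels: %d, seed: %d",
                     report$manifest$n_participants,
                     report$manifest$n_levels, report$manifest$seed), "")
  if (!is.null(report$group_summaries)) {
    lines <- c(lines, "## Group summaries", "",
               "| group | n | solution rate | attempts | time to first (s) | mean gap (s) |",
               "|---|---|---|---|---|---|")
    for (g in names(report$group_summaries)) {
      s <- report$group_summaries[[g]]
      lines <- c(lines, sprintf("| %s | %d | %s | %s | %s | %s |", g, s$n,
                                sig3(s$solution_rate), sig3(s$n_attempts),
                                sig3(s$time_to_first), sig3(s$mean_gap)))
    }
    lines <- c(lines, "")
  }
  if (!is.null(report$classification)) {
    lines <- c(lines, "## Leave-one-out classification", "")
    for (ct in names(report$classification)) {
      s <- report$classification[[ct]]
      lines <- c(lines, sprintf(
        "- %s: mean score %s (chance 0.5), t(%s) = %s, p = %s",
        ct, sig3(s$mean_score), format(s$df), sig3(s$t), sig3(s$p)))
    }
    lines <- c(lines, "")
  }
  if (!is.null(report$switching)) {
    s <- report$switching
    lines <- c(lines, "## Attempt-type switching", "",
               sprintf("- rates: %s",
                       paste(sprintf("%s %s", names(s$rates),
                                     sig3(unlist(s$rates))), collapse = ", ")),
               sprintf("- mixed logistic LRT: chisq(1) = %s, p = %s",
                       sig3(s$chisq), sig3(s$p)), "")
  }
  if (!is.null(report$models)) {
    lines <- c(lines, "## Group-comparison models", "")
    for (nm in names(report$models)) {
      f <- report$models[[nm]]
      ld <- f$coef[f$coef$term == "limb_groupLD", ]
      extra <- if (!is.null(f$ratio))
        sprintf(" (ratio %s [%s, %s])", sig3(f$ratio$estimate),
                sig3(f$ratio$ci_lo), sig3(f$ratio$ci_hi)) else ""
      if (nrow(ld) == 1 && !is.null(f$tests$chisq)) {
        t_l <- f$tests[f$tests$term == "limb_group", ]
        lines <- c(lines, sprintf(
          "- %s: LD effect %s [%s, %s]%s; limb chisq(1) = %s, p = %s",
          nm, sig3(ld$estimate), sig3(ld$ci_lo), sig3(ld$ci_hi), extra,
          sig3(t_l$chisq), sig3(t_l$p)))
      } else if (nrow(ld) == 1) {
        t_l <- f$tests[f$tests$term == "limb_group", ]
        lines <- c(lines, sprintf(
          "- %s: LD effect %s [%s, %s]; F(%d, %d) = %s, p = %s",
          nm, sig3(ld$estimate), sig3(ld$ci_lo), sig3(ld$ci_hi),
          t_l$df1, t_l$df2, sig3(t_l$F), sig3(t_l$p)))
      }
    }
  }
  lines
}

#' Adapt an external data directory to the canonical schema
#'
#' Best-effort adapter for logs laid out differently from the canonical
#' files: common column synonyms are renamed (e.g. `subject` ->
#' `participant_id`, `trial`/`level` -> `level_id`, `time`/`t` -> `t_s`),
#' millisecond time columns are converted, and extra columns are preserved
#' as a `sidecar` attribute. A layout that still lacks required columns
#' raises an error listing the columns that were found.
#'
#' @param path directory containing `attempts.csv` (and optionally
#'   `motor.csv`), or a single attempts CSV file.
#' @return A validated `cogstyle_dataset` with attribute `sidecar` (extra
#'   columns of the attempts file, if any).
#' @export
adapt_archive <- function(path) {
  attempts_path <- if (dir.exists(path)) file.path(path, "attempts.csv")
                   else path
  if (!file.exists(attempts_path))
    stop("no attempts.csv found at ", path, call. = FALSE)
  raw <- utils::read.csv(attempts_path, stringsAsFactors = FALSE)
  synonyms <- c(subject = "participant_id", subject_id = "participant_id",
                participant = "participant_id",
                level = "level_id", trial = "level_id",
                tool = "tool_id", attempt = "attempt_index",
                attempt_number = "attempt_index",
                time = "t_s", t = "t_s", age = "age_years",
                end_time = "end_t_s", success = "solved")
  for (nm in names(synonyms)) {
    if (nm %in% names(raw) && !(synonyms[[nm]] %in% names(raw)))
      names(raw)[names(raw) == nm] <- synonyms[[nm]]
  }
  if (!"t_s" %in% names(raw) && "t_ms" %in% names(raw)) {
    raw$t_s <- raw$t_ms / 1000; raw$t_ms <- NULL
  }
  if (!"end_t_s" %in% names(raw) && "end_t_ms" %in% names(raw)) {
    raw$end_t_s <- raw$end_t_ms / 1000; raw$end_t_ms <- NULL
  }
  canonical <- c("participant_id", "age_group", "limb_group", "age_years",
                 "level_id", "attempt_index", "tool_id", "x", "y", "t_s",
                 "solved", "end_t_s")
  missing <- setdiff(canonical, names(raw))
  if (length(missing))
    stop(sprintf(
      "unrecognized layout: missing %s; found columns: %s",
      paste(missing, collapse = ", "), paste(names(raw), collapse = ", ")),
      call. = FALSE)
  extra <- setdiff(names(raw), canonical)
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(raw[, canonical], tmp, row.names = FALSE)
  d <- read_attempt_log(tmp)
  motor_path <- if (dir.exists(path)) file.path(path, "motor.csv") else ""
  if (nzchar(motor_path) && file.exists(motor_path))
    d <- read_motor_log(motor_path, d)
  if (length(extra))
    attr(d, "sidecar") <- raw[, c("participant_id", "level_id",
                                  "attempt_index", extra), drop = FALSE]
  d
}
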