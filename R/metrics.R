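#' Per-play performance metrics
#'
#' For every (participant, level) play, computes the four performance
#' facets: whether the level was solved, the number of attempts, the time
#' to solution (timestamp of the solving attempt, i.e. the last attempt of
#' a solved play), and the thinking-time measures — time to the first
#' attempt and the mean gap between consecutive attempts. The mean gap is
#' the average of successive timestamp differences, equivalently
#' `(t_last - t_first) / (n_attempts - 1)`, and is `NA` for plays with
#' fewer than two attempts.
#'
#' @param d a `cogstyle_dataset`.
#' @return A data frame with one row per play: `participant_id`,
#'   `level_id`, `solved`, `n_attempts`, `time_to_first`,
#'   `time_to_solution` (NA when unsolved), `mean_gap`.
#' @export
level_metrics <- function(d) {
  stopifnot(inherits(d, "cogstyle_dataset"))
  a <- d$attempts
  akey <- paste(a$participant_id, a$level_id, sep = "\r")
  pl <- d$plays
  pkey <- paste(pl$participant_id, pl$level_id, sep = "\r")
  firsts <- tapply(a$t, akey, min)
  lasts <- tapply(a$t, akey, max)
  counts <- tapply(a$t, akey, length)
  idx <- match(pkey, names(firsts))
  n_att <- ifelse(is.na(idx), 0L, as.integer(counts[idx]))
  t_first <- ifelse(is.na(idx), NA_real_, as.numeric(firsts[idx]))
  t_last <- ifelse(is.na(idx), NA_real_, as.numeric(lasts[idx]))
  data.frame(
    participant_id = pl$participant_id,
    level_id = pl$level_id,
    solved = pl$solved,
    n_attempts = n_att,
    time_to_first = t_first,
    time_to_solution = ifelse(pl$solved, t_last, NA_real_),
    mean_gap = ifelse(n_att >= 2, (t_last - t_first) / pmax(n_att - 1, 1),
                      NA_real_))
}

#' Metrics for a single play
#'
#' Convenience wrapper around [level_metrics()] for one (participant,
#' level) pair.
#'
#' @param d a `cogstyle_dataset`.
#' @param participant_id,level_id the play to summarise.
#' @return One-row data frame as in [level_metrics()].
#' @export
compute_level_metrics <- function(d, participant_id, level_id) {
  m <- level_metrics(d)
  row <- m[m$participant_id == participant_id & m$level_id == level_id, ,
           drop = FALSE]
  if (nrow(row) == 0L)
    stop(sprintf("no play recorded for participant %s, level %s",
                 participant_id, level_id), call. = FALSE)
  if (row$n_attempts == 0L && row$solved)
    stop("solved play with empty attempt list", call. = FALSE)
  row
}

#' Per-participant aggregation of level metrics
#'
#' Solution rate is solved levels over levels played. The timing and
#' attempt-count metrics are averaged over solved levels only when
#' `solved_only = TRUE` (the default, matching the convention of
#' conditioning process measures on successful plays), over all plays
#' otherwise.
#'
#' @param metrics output of [level_metrics()].
#' @param solved_only restrict time/attempt averages to solved plays.
#' @return Data frame, one row per participant: `solution_rate`,
#'   `n_levels`, and means of `n_attempts`, `time_to_first`,
#'   `time_to_solution`, `mean_gap`.
#' @export
aggregate_participant <- function(metrics, solved_only = TRUE) {
  if (nrow(metrics) == 0L) stop("no level metrics to aggregate", call. = FALSE)
  split_m <- split(metrics, metrics$participant_id)
  out <- lapply(split_m, function(m) {
    use <- if (solved_only) m[m$solved, , drop = FALSE] else m
    data.frame(
      participant_id = m$participant_id[1],
      n_levels = nrow(m),
      solution_rate = mean(m$solved),
      n_attempts = if (nrow(use)) mean(use$n_attempts) else NA_real_,
      time_to_first = if (nrow(use)) mean(use$time_to_first, na.rm = TRUE)
                      else NA_real_,
      time_to_solution = if (nrow(use))
        mean(use$time_to_solution, na.rm = TRUE) else NA_real_,
      mean_gap = if (nrow(use)) mean(use$mean_gap, na.rm = TRUE)
                 else NA_real_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Motor pre-test summary
#'
#' Medians of reaction time and click error across each participant's ten
#' motor trials (medians are used to resist outlier trials).
#'
#' @param d a `cogstyle_dataset` with motor data.
#' @return Data frame: `participant_id`, `median_rt` (s), `median_error`
#'   (px).
#' @export
motor_summary <- function(d) {
  stopifnot(inherits(d, "cogstyle_dataset"))
  m <- d$motor
  if (nrow(m) == 0L) stop("dataset has no motor trials", call. = FALSE)
  counts <- table(m$participant_id)
  if (any(counts != 10L))
    stop(sprintf("motor: participant %s has %d trials, expected 10",
                 names(counts)[counts != 10][1], counts[counts != 10][1]),
         call. = FALSE)
  res <- data.frame(
    participant_id = names(counts),
    median_rt = as.numeric(tapply(m$rt, m$participant_id, stats::median)),
    median_error = as.numeric(tapply(m$click_error, m$participant_id,
                                     stats::median)))
  rownames(res) <- NULL
  res
}
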