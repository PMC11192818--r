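AGE_GROUPS  <- c("child", "adult")
LIMB_GROUPS <- c("LD", "NLD")
PLAY_AREA   <- c(0, 600)

#' Assemble a validated dataset of game and motor logs
#'
#' A dataset bundles four tables: participant profiles, attempt records,
#' per-play outcomes, and motor pre-test trials. All analysis functions in
#' the package take this object as input. Validation enforces the log
#' invariants: coordinates inside the 600x600 px play area, timestamps
#' non-negative and strictly increasing within a (participant, level) play,
#' attempt indices 1..n, constant group labels per participant, solved plays
#' non-empty, and exactly ten motor trials (five per distance) per
#' participant with motor data.
#'
#' @param participants data frame with columns `participant_id`,
#'   `age_group` ("child"/"adult"), `limb_group` ("LD"/"NLD"), `age_years`.
#' @param attempts data frame with columns `participant_id`, `level_id`,
#'   `attempt_index`, `tool_id`, `x`, `y`, `t` (seconds since level start).
#' @param plays data frame with columns `participant_id`, `level_id`,
#'   `solved` (logical), `end_t` (seconds). One row per played level.
#' @param motor data frame with columns `participant_id`, `trial_index`,
#'   `distance_px`, `rt`, `click_error`, or `NULL` for none.
#' @return An object of class `cogstyle_dataset`.
#' @seealso [read_attempt_log()], [read_motor_log()], [write_dataset()]
#' @export
dataset <- function(participants, attempts, plays, motor = NULL) {
  if (is.null(motor)) {
    motor <- data.frame(participant_id = character(), trial_index = integer(),
                        distance_px = numeric(), rt = numeric(),
                        click_error = numeric())
  }
  d <- structure(
    list(participants = as.data.frame(participants),
         attempts = as.data.frame(attempts),
         plays = as.data.frame(plays),
         motor = as.data.frame(motor)),
    class = "cogstyle_dataset")
  d <- sort_dataset(d)
  validate_dataset(d)
  d
}

sort_dataset <- function(d) {
  p <- d$participants
  d$participants <- p[order(p$participant_id), , drop = FALSE]
  a <- d$attempts
  d$attempts <- a[order(a$participant_id, a$level_id, a$attempt_index), ,
                  drop = FALSE]
  pl <- d$plays
  d$plays <- pl[order(pl$participant_id, pl$level_id), , drop = FALSE]
  m <- d$motor
  d$motor <- m[order(m$participant_id, m$trial_index), , drop = FALSE]
  for (nm in names(d)) rownames(d[[nm]]) <- NULL
  d
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stop(sprintf("%s: missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

#' Validate a dataset against the log invariants
#'
#' Called by [dataset()] and the readers; exported so externally assembled
#' objects can be checked. Errors name the offending participant/level.
#'
#' @param d a `cogstyle_dataset`.
#' @return `d`, invisibly, if valid; otherwise an error.
#' @export
validate_dataset <- function(d) {
  stopifnot(inherits(d, "cogstyle_dataset"))
  p <- d$participants; a <- d$attempts; pl <- d$plays; m <- d$motor
  require_columns(p, c("participant_id", "age_group", "limb_group", "age_years"),
                  "participants")
  require_columns(a, c("participant_id", "level_id", "attempt_index",
                       "tool_id", "x", "y", "t"), "attempts")
  require_columns(pl, c("participant_id", "level_id", "solved", "end_t"),
                  "plays")
  require_columns(m, c("participant_id", "trial_index", "distance_px", "rt",
                       "click_error"), "motor")

  if (anyDuplicated(p$participant_id))
    stop("participants: duplicated participant_id", call. = FALSE)
  if (!all(p$age_group %in% AGE_GROUPS))
    stop("participants: age_group must be one of: ",
         paste(AGE_GROUPS, collapse = ", "), call. = FALSE)
  if (!all(p$limb_group %in% LIMB_GROUPS))
    stop("participants: limb_group must be one of: ",
         paste(LIMB_GROUPS, collapse = ", "), call. = FALSE)
  if (nrow(p) && any(!is.finite(p$age_years) | p$age_years <= 0))
    stop("participants: age_years must be positive", call. = FALSE)

  known <- p$participant_id
  for (tab in list(c("attempts", "a"), c("plays", "pl"), c("motor", "m"))) {
    df <- get(tab[2])
    unknown <- setdiff(unique(df$participant_id), known)
    if (length(unknown))
      stop(sprintf("%s: unknown participant(s): %s", tab[1],
                   paste(unknown, collapse = ", ")), call. = FALSE)
  }

  if (nrow(a)) {
    bad <- !is.finite(a$x) | !is.finite(a$y) |
      a$x < PLAY_AREA[1] | a$x > PLAY_AREA[2] |
      a$y < PLAY_AREA[1] | a$y > PLAY_AREA[2]
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf(
        "attempts: coordinate outside %dx%d play area (participant %s, level %s)",
        PLAY_AREA[2], PLAY_AREA[2], a$participant_id[i], a$level_id[i]),
        call. = FALSE)
    }
    if (any(!is.finite(a$t) | a$t < 0)) {
      i <- which(!is.finite(a$t) | a$t < 0)[1]
      stop(sprintf("attempts: negative or non-finite t (participant %s, level %s)",
                   a$participant_id[i], a$level_id[i]), call. = FALSE)
    }
    key <- paste(a$participant_id, a$level_id, sep = "\r")
    for (k in unique(key)) {
      rows <- a[key == k, , drop = FALSE]
      rows <- rows[order(rows$attempt_index), , drop = FALSE]
      who <- sprintf("participant %s, level %s",
                     rows$participant_id[1], rows$level_id[1])
      if (!identical(as.integer(rows$attempt_index),
                     seq_len(nrow(rows))))
        stop(sprintf("attempts: attempt_index must be 1..n (%s)", who),
             call. = FALSE)
      if (nrow(rows) > 1 && any(diff(rows$t) <= 0))
        stop(sprintf("attempts: t not strictly increasing (%s)", who),
             call. = FALSE)
    }
    akey <- unique(key)
    pkey <- paste(pl$participant_id, pl$level_id, sep = "\r")
    orphans <- setdiff(akey, pkey)
    if (length(orphans))
      stop("attempts: attempt rows without a matching play record", call. = FALSE)
  }

  if (nrow(pl)) {
    if (anyDuplicated(paste(pl$participant_id, pl$level_id)))
      stop("plays: duplicated (participant, level)", call. = FALSE)
    pkey <- paste(pl$participant_id, pl$level_id, sep = "\r")
    akey <- paste(a$participant_id, a$level_id, sep = "\r")
    last_t <- vapply(pkey, function(k) {
      tt <- a$t[akey == k]
      if (length(tt)) max(tt) else NA_real_
    }, numeric(1))
    n_att <- vapply(pkey, function(k) sum(akey == k), numeric(1))
    bad <- pl$solved & n_att == 0
    if (any(bad))
      stop(sprintf("plays: solved play with no attempts (participant %s, level %s)",
                   pl$participant_id[which(bad)[1]], pl$level_id[which(bad)[1]]),
           call. = FALSE)
    bad <- !is.na(last_t) & pl$end_t < last_t - 1e-9
    if (any(bad))
      stop(sprintf("plays: end_t before last attempt (participant %s, level %s)",
                   pl$participant_id[which(bad)[1]], pl$level_id[which(bad)[1]]),
           call. = FALSE)
  }

  if (nrow(m)) {
    if (any(!is.finite(m$click_error) | m$click_error < 0))
      stop("motor: click_error must be >= 0", call. = FALSE)
    if (any(!is.finite(m$rt) | m$rt <= 0))
      stop("motor: rt must be positive", call. = FALSE)
    for (pid in unique(m$participant_id)) {
      rows <- m[m$participant_id == pid, , drop = FALSE]
      if (nrow(rows) != 10L)
        stop(sprintf("motor: participant %s has %d trials, expected 10",
                     pid, nrow(rows)), call. = FALSE)
      tab <- table(rows$distance_px)
      if (length(tab) != 2L || any(tab != 5L))
        stop(sprintf("motor: participant %s must have 5 trials per distance",
                     pid), call. = FALSE)
    }
  }
  invisible(d)
}

#' @export
print.cogstyle_dataset <- function(x, ...) {
  cat("<cogstyle_dataset>\n")
  cat(sprintf("  participants: %d (%s)\n", nrow(x$participants),
              paste(sprintf("%s-%s: %d",
                            rep(AGE_GROUPS, each = 2),
                            rep(LIMB_GROUPS, 2),
                            vapply(AGE_GROUPS, function(ag)
                              vapply(LIMB_GROUPS, function(lg)
                                sum(x$participants$age_group == ag &
                                      x$participants$limb_group == lg),
                                integer(1)), integer(2))),
                    collapse = ", ")))
  cat(sprintf("  plays: %d (%d solved), attempts: %d, levels: %d\n",
              nrow(x$plays), sum(x$plays$solved), nrow(x$attempts),
              length(unique(x$plays$level_id))))
  cat(sprintf("  motor trials: %d\n", nrow(x$motor)))
  invisible(x)
}

#' Read an attempt-level game log
#'
#' Reads a CSV with one row per tool placement and reassembles it into a
#' validated dataset (plays part). Columns: `participant_id`, `age_group`,
#' `limb_group`, `age_years`, `level_id`, `attempt_index`, `tool_id`, `x`,
#' `y`, `t_s`, `solved`, `end_t_s`. Millisecond columns `t_ms`/`end_t_ms`
#' are accepted in place of the `_s` ones and converted on read. Row order
#' never matters: records are re-sorted by participant, level, attempt
#' index.
#'
#' @param path path to the CSV file.
#' @return A `cogstyle_dataset` with empty motor table.
#' @export
read_attempt_log <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!"t_s" %in% names(raw) && "t_ms" %in% names(raw))
    raw$t_s <- raw$t_ms / 1000
  if (!"end_t_s" %in% names(raw) && "end_t_ms" %in% names(raw))
    raw$end_t_s <- raw$end_t_ms / 1000
  require_columns(raw, c("participant_id", "age_group", "limb_group",
                         "age_years", "level_id", "attempt_index", "tool_id",
                         "x", "y", "t_s", "solved", "end_t_s"),
                  basename(path))
  raw$participant_id <- as.character(raw$participant_id)
  raw$level_id <- as.character(raw$level_id)
  raw$solved <- as.logical(raw$solved)

  if (nrow(raw) == 0L) {
    empty_p <- data.frame(participant_id = character(),
                          age_group = character(), limb_group = character(),
                          age_years = numeric())
    empty_a <- data.frame(participant_id = character(), level_id = character(),
                          attempt_index = integer(), tool_id = character(),
                          x = numeric(), y = numeric(), t = numeric())
    empty_pl <- data.frame(participant_id = character(), level_id = character(),
                           solved = logical(), end_t = numeric())
    return(dataset(empty_p, empty_a, empty_pl))
  }

  participants <- unique(raw[, c("participant_id", "age_group", "limb_group",
                                 "age_years")])
  if (anyDuplicated(participants$participant_id)) {
    dup <- participants$participant_id[duplicated(participants$participant_id)][1]
    stop(sprintf("attempts: inconsistent group labels for participant %s", dup),
         call. = FALSE)
  }
  attempts <- data.frame(participant_id = raw$participant_id,
                         level_id = raw$level_id,
                         attempt_index = as.integer(raw$attempt_index),
                         tool_id = as.character(raw$tool_id),
                         x = raw$x, y = raw$y, t = raw$t_s)
  plays <- unique(raw[, c("participant_id", "level_id", "solved", "end_t_s")])
  names(plays)[4] <- "end_t"
  if (anyDuplicated(paste(plays$participant_id, plays$level_id)))
    stop("attempts: solved/end_t inconsistent within a play", call. = FALSE)
  dataset(participants, attempts, plays)
}

#' Read a motor pre-test log
#'
#' CSV columns: `participant_id`, `trial_index`, `distance_px`, `rt_s`,
#' `click_error_px`. Each participant must have exactly ten trials, five at
#' each of the two distances. Because the motor file carries no group
#' labels, a `participants` table (or a dataset to merge into) must be
#' supplied.
#'
#' @param path path to the CSV file.
#' @param participants participants data frame (see [dataset()]), or a
#'   `cogstyle_dataset` whose participants/plays are reused.
#' @return A `cogstyle_dataset` with the motor table filled in.
#' @export
read_motor_log <- function(path, participants) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  require_columns(raw, c("participant_id", "trial_index", "distance_px",
                         "rt_s", "click_error_px"), basename(path))
  motor <- data.frame(participant_id = as.character(raw$participant_id),
                      trial_index = as.integer(raw$trial_index),
                      distance_px = raw$distance_px,
                      rt = raw$rt_s, click_error = raw$click_error_px)
  if (inherits(participants, "cogstyle_dataset")) {
    d <- participants
    return(dataset(d$participants, d$attempts, d$plays, motor))
  }
  empty_a <- data.frame(participant_id = character(), level_id = character(),
                        attempt_index = integer(), tool_id = character(),
                        x = numeric(), y = numeric(), t = numeric())
  empty_pl <- data.frame(participant_id = character(), level_id = character(),
                         solved = logical(), end_t = numeric())
  dataset(participants, empty_a, empty_pl, motor)
}

#' Write a dataset to attempts.csv and motor.csv
#'
#' Inverse of the readers: `read_attempt_log()` / `read_motor_log()` applied
#' to the written files reconstruct the dataset field-for-field (numeric
#' values round-trip to ~15 significant digits).
#'
#' @param d a `cogstyle_dataset`.
#' @param dir output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(d, dir) {
  validate_dataset(d)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  a <- d$attempts
  key <- paste(a$participant_id, a$level_id, sep = "\r")
  pkey <- paste(d$plays$participant_id, d$plays$level_id, sep = "\r")
  pidx <- match(key, pkey)
  out <- data.frame(
    participant_id = a$participant_id,
    age_group = d$participants$age_group[match(a$participant_id,
                                               d$participants$participant_id)],
    limb_group = d$participants$limb_group[match(a$participant_id,
                                                 d$participants$participant_id)],
    age_years = d$participants$age_years[match(a$participant_id,
                                               d$participants$participant_id)],
    level_id = a$level_id, attempt_index = a$attempt_index,
    tool_id = a$tool_id, x = a$x, y = a$y, t_s = a$t,
    solved = d$plays$solved[pidx], end_t_s = d$plays$end_t[pidx])
  attempts_path <- file.path(dir, "attempts.csv")
  motor_path <- file.path(dir, "motor.csv")
  utils::write.csv(out, attempts_path, row.names = FALSE, quote = FALSE)
  m <- d$motor
  mout <- data.frame(participant_id = m$participant_id,
                     trial_index = m$trial_index, distance_px = m$distance_px,
                     rt_s = m$rt, click_error_px = m$click_error)
  utils::write.csv(mout, motor_path, row.names = FALSE, quote = FALSE)
  invisible(c(attempts = attempts_path, motor = motor_path))
}
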