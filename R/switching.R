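# Attempt-type switching: label every attempt with its DPMM cluster (fit
# per level within a participant-group population, on x/y positions only,
# ignoring tool identity), then count label changes between consecutive
# attempts of a play.

#' Cluster-label all attempt sequences
#'
#' Fits one Dirichlet-process Gaussian mixture per level and population
#' cell (the interaction of the `group_by` columns; use `character(0)` to
#' pool everyone) over the `(x, y)` positions of all attempts, and labels
#' every attempt with its highest-responsibility cluster from its own
#' cell's model.
#'
#' @param d a `cogstyle_dataset`.
#' @param group_by participant columns defining the model populations;
#'   default fits separate models per age x limb cell.
#' @param alpha,n_sweeps,burn_in,seed passed to [fit_dpmm()]; the sub-seed
#'   of each (level, cell) model is derived deterministically from `seed`.
#' @return `d` with a `cluster` integer column added to `d$attempts`
#'   (labels are only comparable within a (level, cell)); fitted models in
#'   `attr(, "dpmm_fits")`.
#' @export
label_sequences <- function(d, group_by = c("age_group", "limb_group"),
                            alpha = 1, n_sweeps = 500, burn_in = 250,
                            seed = 1) {
  stopifnot(inherits(d, "cogstyle_dataset"))
  a <- d$attempts
  pidx <- match(a$participant_id, d$participants$participant_id)
  cell <- if (length(group_by)) {
    do.call(paste, c(lapply(group_by, function(g) d$participants[[g]][pidx]),
                     sep = "."))
  } else rep("all", nrow(a))
  key <- paste(a$level_id, cell, sep = "\r")
  a$cluster <- NA_integer_
  fits <- list()
  for (k in sort(unique(key))) {
    idx <- which(key == k)
    fit <- fit_dpmm(cbind(a$x[idx], a$y[idx]), alpha = alpha,
                    n_sweeps = n_sweeps, burn_in = burn_in,
                    seed = mix_seed(seed, match(k, sort(unique(key)))))
    a$cluster[idx] <- map_labels(fit)
    fits[[k]] <- fit
  }
  d$attempts <- a
  attr(d, "dpmm_fits") <- fits
  d
}

#' Switch counts and rate from labeled attempts
#'
#' A switch occurs at attempt j > 1 of a play when its cluster label
#' differs from attempt j-1's. Plays with a single attempt contribute zero
#' transitions.
#'
#' @param attempts labeled attempts data frame: `participant_id`,
#'   `level_id`, `attempt_index`, `cluster`.
#' @return List with `per_participant` (`n_transitions`, `n_switches`),
#'   `transitions` (one row per transition with a logical `switch`), and
#'   `rate` (total switches over total transitions; `NaN` with no
#'   transitions).
#' @export
switch_rate <- function(attempts) {
  require_columns(attempts, c("participant_id", "level_id", "attempt_index",
                              "cluster"), "labeled attempts")
  a <- attempts[order(attempts$participant_id, attempts$level_id,
                      attempts$attempt_index), , drop = FALSE]
  key <- paste(a$participant_id, a$level_id, sep = "\r")
  prev_same_play <- c(FALSE, key[-1] == key[-nrow(a)])
  is_switch <- prev_same_play &
    c(NA, a$cluster[-1] != a$cluster[-nrow(a)])
  trans <- data.frame(participant_id = a$participant_id[prev_same_play],
                      level_id = a$level_id[prev_same_play],
                      switch = is_switch[prev_same_play])
  per_part <- if (nrow(trans)) {
    agg <- stats::aggregate(switch ~ participant_id, trans,
                            function(s) c(length(s), sum(s)))
    data.frame(participant_id = agg$participant_id,
               n_transitions = agg$switch[, 1],
               n_switches = agg$switch[, 2])
  } else data.frame(participant_id = character(), n_transitions = numeric(),
                    n_switches = numeric())
  list(per_participant = per_part, transitions = trans,
       rate = if (nrow(trans)) mean(trans$switch) else NaN)
}

#' Compare switch rates between two groups
#'
#' Pools the transition-level switch indicators of two labeled groups and
#' tests the group effect. The default is a mixed logistic regression of
#' switch events on group with random intercepts for participant and
#' level, tested by a 1-df likelihood-ratio chi-square; `method =
#' "pooled"` falls back to a 2x2 chi-square on the pooled counts.
#'
#' @param attempts_a,attempts_b labeled attempts (see [switch_rate()]) for
#'   the two groups; labels need only be consistent within each group's
#'   own models.
#' @param labels length-2 character names for the groups.
#' @param method `"mixed"` (default) or `"pooled"`.
#' @return An object of class `cogstyle_switch`: per-group `rates`,
#'   `n_transitions`, `chisq`, `df`, `p`, `method`, and `note` (set when
#'   the test is degenerate, e.g. all-0 or all-1 outcomes).
#' @export
compare_switch_rates <- function(attempts_a, attempts_b,
                                 labels = c("A", "B"),
                                 method = c("mixed", "pooled")) {
  method <- match.arg(method)
  sa <- switch_rate(attempts_a)
  sb <- switch_rate(attempts_b)
  trans <- rbind(cbind(sa$transitions, group = labels[1]),
                 cbind(sb$transitions, group = labels[2]))
  rates <- c(sa$rate, sb$rate)
  names(rates) <- labels
  n_trans <- c(nrow(sa$transitions), nrow(sb$transitions))
  names(n_trans) <- labels

  out <- list(rates = rates, n_transitions = n_trans, method = method,
              chisq = NA_real_, df = 1L, p = NA_real_, note = NULL)
  if (any(n_trans == 0)) {
    out$note <- "a group has no transitions; no test performed"
  } else if (all(trans$switch) || !any(trans$switch)) {
    out$note <- "complete separation (all outcomes identical); no test performed"
  } else if (method == "pooled") {
    tab <- table(trans$group, trans$switch)
    ct <- stats::chisq.test(tab, correct = FALSE)
    out$chisq <- unname(ct$statistic)
    out$p <- ct$p.value
  } else {
    trans$group <- factor(trans$group, levels = labels)
    ctrl <- lme4::glmerControl(optimizer = "bobyqa")
    full <- suppressMessages(lme4::glmer(
      switch ~ group + (1 | participant_id) + (1 | level_id),
      data = trans, family = stats::binomial(), control = ctrl))
    null <- suppressMessages(lme4::glmer(
      switch ~ 1 + (1 | participant_id) + (1 | level_id),
      data = trans, family = stats::binomial(), control = ctrl))
    lrt <- 2 * (as.numeric(stats::logLik(full)) -
                  as.numeric(stats::logLik(null)))
    out$chisq <- max(lrt, 0)
    out$p <- stats::pchisq(out$chisq, df = 1, lower.tail = FALSE)
    out$model <- full
  }
  class(out) <- "cogstyle_switch"
  out
}

#' @export
print.cogstyle_switch <- function(x, ...) {
  cat("<cogstyle_switch>\n")
  cat(sprintf("  switch rates: %s\n",
              paste(sprintf("%s %.1f%% (n=%d)", names(x$rates),
                            100 * x$rates, x$n_transitions),
                    collapse = ", ")))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  else cat(sprintf("  %s test: chisq(1) = %.2f, p = %.3g\n", x$method,
                   x$chisq, x$p))
  invisible(x)
}
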