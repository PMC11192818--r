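# Leave-one-out classification of first attempts by relative group
# likelihood. A group's distribution over attempts on a level factorizes
# into a Laplace-smoothed categorical over tool identities and a Gaussian
# product-kernel density over (x, y) placements.

#' Build a group's density over (tool, x, y) for one level
#'
#' Training data are first attempts on one level by members of one group.
#' The tool distribution is Laplace-smoothed over the level's tool set; the
#' spatial density is a product of per-dimension Gaussian kernels with
#' plug-in bandwidth `h_d = sd_d * m^(-1/6)` for `m` training points.
#'
#' @param attempts data frame of one group's first attempts on one level:
#'   columns `participant_id`, `tool_id`, `x`, `y`.
#' @param tools character vector of the level's tools (the categorical
#'   support for smoothing).
#' @param exclude participant id to leave out, or `NULL`.
#' @param smoothing Laplace pseudo-count for tool probabilities.
#' @return An object of class `group_density`.
#' @export
build_group_density <- function(attempts, tools, exclude = NULL,
                                smoothing = 1) {
  if (!is.null(exclude))
    attempts <- attempts[attempts$participant_id != exclude, , drop = FALSE]
  m <- nrow(attempts)
  if (length(unique(attempts$participant_id)) < 2L)
    stop("need at least 2 contributing participants", call. = FALSE)
  counts <- vapply(tools, function(tl) sum(attempts$tool_id == tl), numeric(1))
  tool_probs <- (counts + smoothing) / (m + smoothing * length(tools))
  h <- pmax(c(stats::sd(attempts$x), stats::sd(attempts$y)) * m^(-1 / 6),
            1e-3)
  structure(list(tools = tools, tool_probs = tool_probs,
                 train = cbind(attempts$x, attempts$y),
                 h = h, m = m, smoothing = smoothing),
            class = "group_density")
}

#' Evaluate a group density at an attempt
#'
#' Returns `P(tool) * f(x, y)` with the spatial kernel density floored at
#' 1e-12. A tool outside the density's support contributes probability 0
#' before flooring.
#'
#' @param gd a `group_density`.
#' @param tool_id tool identity of the attempt.
#' @param x,y placement coordinates (px).
#' @return Non-negative density value.
#' @export
eval_group_density <- function(gd, tool_id, x, y) {
  tp <- if (tool_id %in% gd$tools) gd$tool_probs[[tool_id]] else 0
  sp <- mean(stats::dnorm(x, gd$train[, 1], gd$h[1]) *
               stats::dnorm(y, gd$train[, 2], gd$h[2]))
  tp * max(sp, 1e-12)
}

#' Relative likelihood that an attempt belongs to its own group
#'
#' `s = p_own / (p_own + p_other)` where each `p` is the attempt's density
#' under the group's (tool x position) distribution; `s = 0.5` when both
#' densities vanish. Scores above 0.5 classify the attempt into its own
#' group; 0.5 is chance.
#'
#' @param attempt one-row data frame (or list) with `tool_id`, `x`, `y`.
#' @param own,other `group_density` objects for the same level.
#' @return A score in `[0, 1]`.
#' @export
relative_likelihood <- function(attempt, own, other) {
  p_own <- eval_group_density(own, attempt$tool_id, attempt$x, attempt$y)
  p_other <- eval_group_density(other, attempt$tool_id, attempt$x, attempt$y)
  if (p_own + p_other == 0) return(0.5)
  p_own / (p_own + p_other)
}

#' Leave-one-out group classification of first attempts
#'
#' For each participant and level, the participant's first attempt is
#' scored by its relative likelihood under their own group's density built
#' without them versus the other group's density (the participant is
#' excluded from both — a no-op for the other group, but it makes the two
#' directions of a contrast exactly complementary). Per-participant scores
#' (means over levels) are tested against chance (0.5) with a two-sided
#' one-sample t-test across participants. Levels with fewer than two
#' contributing participants in either density are skipped and recorded.
#'
#' @param d a `cogstyle_dataset`.
#' @param grouping `"limb_group"` or `"age_group"`: which pair of groups to
#'   contrast.
#' @param subset optional logical or participant-id filter applied to the
#'   participants table first (e.g. restrict a limb contrast to adults).
#' @param smoothing Laplace pseudo-count for tool probabilities.
#' @return An object of class `cogstyle_classification`: `scores` (one row
#'   per participant x level), `participants` (mean score per participant),
#'   `skipped`, `mean_score`, `t`, `df`, `p`, `grouping`.
#' @export
loo_classify <- function(d, grouping = c("limb_group", "age_group"),
                         subset = NULL, smoothing = 1) {
  stopifnot(inherits(d, "cogstyle_dataset"))
  grouping <- match.arg(grouping)
  p <- d$participants
  if (!is.null(subset)) {
    keep <- if (is.logical(subset)) subset else p$participant_id %in% subset
    p <- p[keep, , drop = FALSE]
  }
  groups <- if (grouping == "limb_group") LIMB_GROUPS else AGE_GROUPS
  member <- stats::setNames(p[[grouping]], p$participant_id)
  sizes <- table(factor(member, levels = groups))
  if (any(sizes < 3))
    stop(sprintf("group %s has %d participants; need at least 3",
                 names(sizes)[sizes < 3][1], min(sizes)), call. = FALSE)

  a <- d$attempts
  a <- a[a$attempt_index == 1L & a$participant_id %in% p$participant_id, ,
         drop = FALSE]
  a$group <- member[a$participant_id]

  score_rows <- list()
  skip_rows <- list()
  for (lev in sort(unique(a$level_id))) {
    al <- a[a$level_id == lev, , drop = FALSE]
    tools <- sort(unique(d$attempts$tool_id[d$attempts$level_id == lev]))
    by_group <- split(al, factor(al$group, levels = groups))
    for (i in seq_len(nrow(al))) {
      row <- al[i, ]
      own_g <- row$group
      other_g <- setdiff(groups, own_g)
      own_train <- by_group[[own_g]]
      other_train <- by_group[[other_g]]
      ok <- length(unique(own_train$participant_id[
        own_train$participant_id != row$participant_id])) >= 2 &&
        length(unique(other_train$participant_id)) >= 2
      if (!ok) {
        skip_rows[[length(skip_rows) + 1L]] <-
          data.frame(participant_id = row$participant_id, level_id = lev,
                     reason = "fewer than 2 contributors")
        next
      }
      # the participant is excluded from both densities; a no-op for the
      # other group (they are never a member), but it makes contrasting
      # (A, B) and (B, A) exactly complementary
      own <- build_group_density(own_train, tools,
                                 exclude = row$participant_id,
                                 smoothing = smoothing)
      other <- build_group_density(other_train, tools,
                                   exclude = row$participant_id,
                                   smoothing = smoothing)
      s <- relative_likelihood(row, own, other)
      score_rows[[length(score_rows) + 1L]] <-
        data.frame(participant_id = row$participant_id, level_id = lev,
                   group = own_g, score = s)
    }
  }
  scores <- if (length(score_rows)) do.call(rbind, score_rows) else
    data.frame(participant_id = character(), level_id = character(),
               group = character(), score = numeric())
  skipped <- if (length(skip_rows)) do.call(rbind, skip_rows) else
    data.frame(participant_id = character(), level_id = character(),
               reason = character())

  per_part <- if (nrow(scores)) {
    agg <- stats::aggregate(score ~ participant_id + group, scores, mean)
    nlev <- stats::aggregate(level_id ~ participant_id, scores, length)
    agg$n_levels <- nlev$level_id[match(agg$participant_id,
                                        nlev$participant_id)]
    agg[order(agg$participant_id), ]
  } else data.frame(participant_id = character(), group = character(),
                    score = numeric(), n_levels = integer())
  rownames(per_part) <- NULL

  n_sc <- nrow(per_part)
  if (n_sc >= 2 && stats::sd(per_part$score) > 0) {
    tt <- stats::t.test(per_part$score, mu = 0.5)
    t_stat <- unname(tt$statistic); t_df <- unname(tt$parameter)
    t_p <- tt$p.value
  } else {
    t_stat <- NA_real_; t_df <- if (n_sc >= 1) n_sc - 1 else NA_real_
    t_p <- NA_real_
  }

  structure(list(scores = scores, participants = per_part, skipped = skipped,
                 mean_score = if (n_sc) mean(per_part$score) else NA_real_,
                 t = t_stat, df = t_df, p = t_p, grouping = grouping),
            class = "cogstyle_classification")
}

#' @export
print.cogstyle_classification <- function(x, ...) {
  cat(sprintf("<cogstyle_classification> contrast: %s\n", x$grouping))
  cat(sprintf("  mean score %.3f over %d participants (chance = 0.5)\n",
              x$mean_score, nrow(x$participants)))
  if (!is.na(x$t))
    cat(sprintf("  t(%d) = %.2f, p = %.3g\n", x$df, x$t, x$p))
  if (nrow(x$skipped))
    cat(sprintf("  skipped %d participant-levels (too few contributors)\n",
                nrow(x$skipped)))
  invisible(x)
}
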