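GROUP_CELLS <- c("child_LD", "child_NLD", "adult_LD", "adult_NLD")

# Evaluate code under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed from a stream seed and indices; keeps every draw
# for a (participant, level) pair on its own substream so adding
# participants or levels never perturbs existing ones.
mix_seed <- function(seed, i, j = 0L) {
  s <- (as.numeric(seed) %% 2147483647)
  s <- (s * 48271 + as.numeric(i) * 16807 + as.numeric(j)) %% 2147483629
  as.integer(s + 1)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Construct a synthetic-study generator configuration
#'
#' The generator emulates a four-cell study (child/adult x limb-different
#' LD / no-limb-difference NLD) playing `n_levels` puzzle levels inside a
#' 600x600 px play area. Placements on a level follow a finite Gaussian
#' mixture over `clusters_per_level` attempt-type clusters; the attempt-type
#' sequence is a first-order Markov chain with per-age switch probability;
#' first-attempt and inter-attempt latencies are lognormal with additive LD
#' offsets and a per-participant intercept; each attempt solves the level
#' with a per-attempt probability (geometric process), scaled for LD so the
#' expected LD/NLD attempt ratio equals `ld_attempt_ratio`; plays truncate
#' at `time_bound` seconds. Motor pre-test trials are drawn around
#' per-participant medians with group means and the LD reaction-time offset.
#'
#' Cluster centers, per-cluster tool preferences and per-(age, level)
#' mixture weights are drawn deterministically from `structure_seed`; limb
#' groups share placement and tool distributions (group differences in
#' placement enter only through age), so LD-vs-NLD placement contrasts are
#' exchangeable by construction.
#'
#' @param n_per_group participants per age x limb cell: one integer, or a
#'   named vector over child_LD, child_NLD, adult_LD, adult_NLD.
#' @param n_levels number of levels.
#' @param clusters_per_level number of attempt-type clusters per level.
#' @param cluster_centers optional explicit centers: a list of length
#'   `n_levels`, each a `clusters_per_level` x 2 matrix (px); `NULL` draws
#'   them from `structure_seed`.
#' @param group_mixture_weights optional explicit attempt-type mixture
#'   weights: a list keyed by age group ("child", "adult") or by full cell
#'   ("child_LD", ...), each an `n_levels` x `clusters_per_level` matrix of
#'   rows on the simplex; `NULL` draws per-age weights (shared across limb
#'   groups) from `structure_seed`.
#' @param cluster_sd isotropic placement sd around a cluster center (px).
#' @param base_first_latency_mu,base_first_latency_sigma lognormal
#'   parameters (log-seconds) of the first-attempt latency.
#' @param ld_first_offset additive LD offset on first-attempt latency (s).
#' @param base_gap_mu,base_gap_sigma lognormal parameters of inter-attempt
#'   gaps.
#' @param ld_gap_offset additive LD offset on gaps (s).
#' @param participant_latency_sd sd of the per-participant additive latency
#'   intercept (s).
#' @param per_attempt_solve_p named per-age probability that an attempt
#'   solves the level (NLD scale).
#' @param ld_attempt_ratio target ratio of expected LD to NLD attempt
#'   counts; implemented as `p_LD = p / ld_attempt_ratio`.
#' @param switch_p named per-age probability that consecutive attempts come
#'   from different clusters.
#' @param motor_error_mean,motor_rt_mean named per-age medians of motor
#'   click error (px) and reaction time (s).
#' @param ld_motor_rt_offset additive LD offset on motor reaction time (s);
#'   negative means LD participants are faster.
#' @param motor_rt_participant_sd,motor_error_participant_sd between-
#'   participant sds of the motor medians.
#' @param age_ranges list of `c(lo, hi)` ages (years) per age group; ages
#'   drawn uniformly.
#' @param time_bound level time limit (s).
#' @param structure_seed seed for the structural draws (centers, weights,
#'   tool preferences).
#' @return An object of class `cogstyle_config` (a validated list).
#' @seealso [default_paper_config()], [generate_dataset()]
#' @export
generator_config <- function(n_per_group = 40,
                             n_levels = 14L,
                             clusters_per_level = 3L,
                             cluster_centers = NULL,
                             group_mixture_weights = NULL,
                             cluster_sd = 40,
                             base_first_latency_mu = 1.3,
                             base_first_latency_sigma = 0.5,
                             ld_first_offset = 3.79,
                             base_gap_mu = 2.0,
                             base_gap_sigma = 0.5,
                             ld_gap_offset = 2.80,
                             participant_latency_sd = 1,
                             per_attempt_solve_p = c(child = 0.185, adult = 0.235),
                             ld_attempt_ratio = 0.839,
                             switch_p = c(child = 0.39, adult = 0.33),
                             motor_error_mean = c(child = 7.65, adult = 2.92),
                             motor_rt_mean = c(child = 3.04, adult = 1.91),
                             ld_motor_rt_offset = -0.356,
                             motor_rt_participant_sd = 0.6,
                             motor_error_participant_sd = 2.0,
                             age_ranges = list(child = c(5, 10.7),
                                               adult = c(18, 76)),
                             time_bound = 60,
                             structure_seed = 1L) {
  if (length(n_per_group) == 1L && is.null(names(n_per_group))) {
    n_per_group <- stats::setNames(rep(as.integer(n_per_group), 4), GROUP_CELLS)
  }
  if (!all(GROUP_CELLS %in% names(n_per_group)))
    stop("n_per_group must be a single integer or named over: ",
         paste(GROUP_CELLS, collapse = ", "), call. = FALSE)
  cfg <- structure(list(
    n_per_group = n_per_group[GROUP_CELLS],
    n_levels = as.integer(n_levels),
    clusters_per_level = as.integer(clusters_per_level),
    cluster_centers = cluster_centers,
    group_mixture_weights = group_mixture_weights,
    cluster_sd = cluster_sd,
    base_first_latency_mu = base_first_latency_mu,
    base_first_latency_sigma = base_first_latency_sigma,
    ld_first_offset = ld_first_offset,
    base_gap_mu = base_gap_mu,
    base_gap_sigma = base_gap_sigma,
    ld_gap_offset = ld_gap_offset,
    participant_latency_sd = participant_latency_sd,
    per_attempt_solve_p = per_attempt_solve_p,
    ld_attempt_ratio = ld_attempt_ratio,
    switch_p = switch_p,
    motor_error_mean = motor_error_mean,
    motor_rt_mean = motor_rt_mean,
    ld_motor_rt_offset = ld_motor_rt_offset,
    motor_rt_participant_sd = motor_rt_participant_sd,
    motor_error_participant_sd = motor_error_participant_sd,
    age_ranges = age_ranges,
    time_bound = time_bound,
    structure_seed = as.integer(structure_seed)),
    class = "cogstyle_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "cogstyle_config"))
  with(cfg, {
    if (any(n_per_group < 0)) stop("n_per_group must be >= 0", call. = FALSE)
    if (n_levels < 1) stop("n_levels must be >= 1", call. = FALSE)
    if (clusters_per_level < 1) stop("clusters_per_level must be >= 1",
                                     call. = FALSE)
    if (cluster_sd <= 0 || base_first_latency_sigma <= 0 ||
        base_gap_sigma <= 0 || participant_latency_sd < 0)
      stop("all sds must be positive", call. = FALSE)
    for (p in list(per_attempt_solve_p, switch_p)) {
      if (!all(AGE_GROUPS %in% names(p)))
        stop("per-age parameters must be named over: ",
             paste(AGE_GROUPS, collapse = ", "), call. = FALSE)
      if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]",
                                   call. = FALSE)
    }
    if (ld_attempt_ratio <= 0) stop("ld_attempt_ratio must be > 0",
                                    call. = FALSE)
    if (time_bound <= 0) stop("time_bound must be > 0", call. = FALSE)
    if (!is.null(cluster_centers)) {
      ok <- length(cluster_centers) == n_levels &&
        all(vapply(cluster_centers, function(m)
          is.matrix(m) && nrow(m) == clusters_per_level && ncol(m) == 2 &&
            all(m >= PLAY_AREA[1] & m <= PLAY_AREA[2]), logical(1)))
      if (!ok) stop("cluster_centers must be a list of n_levels K x 2 ",
                    "matrices inside the play area", call. = FALSE)
    }
    if (!is.null(group_mixture_weights)) {
      keys <- names(group_mixture_weights)
      if (!(all(AGE_GROUPS %in% keys) || all(GROUP_CELLS %in% keys)))
        stop("group_mixture_weights must be keyed by age group or by cell",
             call. = FALSE)
      ok <- all(vapply(group_mixture_weights, function(m)
        is.matrix(m) && nrow(m) == n_levels &&
          ncol(m) == clusters_per_level && all(m >= 0) &&
          all(abs(rowSums(m) - 1) < 1e-8), logical(1)))
      if (!ok) stop("each weight matrix must be n_levels x K with rows ",
                    "summing to 1", call. = FALSE)
    }
  })
  invisible(cfg)
}

#' @export
print.cogstyle_config <- function(x, ...) {
  cat("<cogstyle_config>\n")
  cat(sprintf("  cells: %s\n",
              paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group),
                    collapse = ", ")))
  cat(sprintf("  levels: %d, clusters/level: %d, cluster sd: %g px\n",
              x$n_levels, x$clusters_per_level, x$cluster_sd))
  cat(sprintf("  LD offsets: first %+.2f s, gap %+.2f s, attempts x%.3f, motor RT %+.3f s\n",
              x$ld_first_offset, x$ld_gap_offset, x$ld_attempt_ratio,
              x$ld_motor_rt_offset))
  cat(sprintf("  switch_p: child %.2f, adult %.2f; time bound %g s\n",
              x$switch_p[["child"]], x$switch_p[["adult"]], x$time_bound))
  invisible(x)
}

#' Generator configuration mirroring the study's point estimates
#'
#' Returns the configuration whose group-effect defaults are the published
#' point estimates: LD first-attempt latency offset 3.79 s, LD gap offset
#' 2.80 s, LD/NLD attempt ratio 0.839, switch probabilities 0.39 (children)
#' and 0.33 (adults), motor click error 7.65/2.92 px and reaction time
#' 3.04/1.91 s (children/adults), LD motor reaction-time offset -0.356 s —
#' with the study's four unbalanced cell sizes (25 child-LD, 45 child-NLD,
#' 35 adult-LD, 40 adult-NLD).
#'
#' @param structure_seed seed for the deterministic structural draws.
#' @return A `cogstyle_config`.
#' @export
default_paper_config <- function(structure_seed = 1L) {
  generator_config(
    n_per_group = c(child_LD = 25, child_NLD = 45,
                    adult_LD = 35, adult_NLD = 40),
    structure_seed = structure_seed)
}

# Structural draws shared by every dataset generated from this config:
# cluster centers, per-(age, level) mixture weights, per-cluster tool
# preferences. Deterministic in cfg$structure_seed.
config_structure <- function(cfg) {
  K <- cfg$clusters_per_level
  st <- with_seed(cfg$structure_seed, {
    centers <- lapply(seq_len(cfg$n_levels), function(l)
      matrix(stats::runif(2 * K, 60, 540), ncol = 2))
    tool_probs <- lapply(seq_len(cfg$n_levels), function(l) {
      m <- t(vapply(seq_len(K), function(k) rdirichlet1(rep(1.5, 3)),
                    numeric(3)))
      colnames(m) <- paste0("tool", 1:3)
      m
    })
    weights <- lapply(stats::setNames(AGE_GROUPS, AGE_GROUPS), function(ag)
      matrix(t(vapply(seq_len(cfg$n_levels), function(l)
        rdirichlet1(rep(2, K)), numeric(K))), ncol = K))
    list(centers = centers, tool_probs = tool_probs, weights = weights)
  })
  if (!is.null(cfg$cluster_centers)) st$centers <- cfg$cluster_centers
  if (!is.null(cfg$group_mixture_weights))
    st$weights <- cfg$group_mixture_weights
  # resolve to one weight matrix per cell
  st$weights <- lapply(stats::setNames(GROUP_CELLS, GROUP_CELLS),
                       function(cell) {
    ag <- sub("_.*", "", cell)
    if (!is.null(st$weights[[cell]])) st$weights[[cell]]
    else st$weights[[ag]]
  })
  st
}

# Draw one placement: cluster center + isotropic noise, truncated to the
# play area by resampling (then clipping after 100 draws).
draw_placement <- function(center, sd) {
  for (i in 1:100) {
    p <- center + stats::rnorm(2, 0, sd)
    if (all(p >= PLAY_AREA[1] & p <= PLAY_AREA[2])) return(p)
  }
  pmin(pmax(p, PLAY_AREA[1]), PLAY_AREA[2])
}

#' Generate a synthetic study dataset
#'
#' Draws a full dataset (participants, level plays with attempt records,
#' motor pre-test trials) from a generator configuration. Fully reproducible
#' from `(config, seed)`; randomness is split hierarchically by
#' (participant, level) so enlarging the study leaves existing participants'
#' data unchanged. Every play contains at least one attempt: the
#' first-attempt latency is resampled if it would exceed the time bound.
#'
#' @param config a `cogstyle_config`.
#' @param seed integer seed for the participant-level randomness.
#' @return A `cogstyle_dataset`. The realized structural parameters are
#'   attached as `attr(, "ground_truth")` (cluster centers, mixture
#'   weights, tool preferences, true attempt-type labels are in the
#'   attempts table as column `true_cluster`).
#' @export
generate_dataset <- function(config, seed) {
  validate_config(config)
  st <- config_structure(config)
  K <- config$clusters_per_level
  cells <- rep(GROUP_CELLS, times = config$n_per_group[GROUP_CELLS])
  n <- length(cells)
  ids <- sprintf("P%03d", seq_len(n))

  participants <- data.frame(
    participant_id = ids,
    age_group = sub("_.*", "", cells),
    limb_group = sub(".*_", "", cells),
    age_years = NA_real_)

  att_list <- vector("list", n * config$n_levels)
  play_list <- vector("list", n * config$n_levels)
  motor_list <- vector("list", n)

  for (i in seq_len(n)) {
    ag <- participants$age_group[i]
    lg <- participants$limb_group[i]
    is_ld <- lg == "LD"
    rng_p <- with_seed(mix_seed(seed, i, 0L), {
      list(age = stats::runif(1, config$age_ranges[[ag]][1],
                              config$age_ranges[[ag]][2]),
           intercept = stats::rnorm(1, 0, config$participant_latency_sd),
           rt_center = max(0.3, config$motor_rt_mean[[ag]] +
                             (if (is_ld) config$ld_motor_rt_offset else 0) +
                             stats::rnorm(1, 0, config$motor_rt_participant_sd)),
           err_center = max(0.5, config$motor_error_mean[[ag]] +
                              stats::rnorm(1, 0, config$motor_error_participant_sd)))
    })
    participants$age_years[i] <- rng_p$age

    p_solve <- config$per_attempt_solve_p[[ag]]
    if (is_ld) p_solve <- min(0.999, p_solve / config$ld_attempt_ratio)
    sw <- config$switch_p[[ag]]

    for (l in seq_len(config$n_levels)) {
      lev <- sprintf("L%02d", l)
      w <- st$weights[[paste(ag, lg, sep = "_")]][l, ]
      res <- with_seed(mix_seed(seed, i, l), {
        state <- sample.int(K, 1, prob = w)
        t_first <- NA_real_
        for (r in 1:100) {
          t_first <- stats::rlnorm(1, config$base_first_latency_mu,
                                   config$base_first_latency_sigma) +
            (if (is_ld) config$ld_first_offset else 0) + rng_p$intercept
          t_first <- max(t_first, 0.05)
          if (t_first < config$time_bound) break
        }
        t_first <- min(t_first, config$time_bound - 1e-3)
        t_cur <- t_first
        xs <- ys <- ts <- numeric(0)
        tools <- character(0)
        states <- integer(0)
        solved <- FALSE
        repeat {
          p <- draw_placement(st$centers[[l]][state, ], config$cluster_sd)
          tool <- sample(colnames(st$tool_probs[[l]]), 1,
                         prob = st$tool_probs[[l]][state, ])
          xs <- c(xs, p[1]); ys <- c(ys, p[2]); ts <- c(ts, t_cur)
          tools <- c(tools, tool); states <- c(states, state)
          if (stats::runif(1) < p_solve) { solved <- TRUE; break }
          if (K > 1 && stats::runif(1) < sw) {
            wk <- w; wk[state] <- 0
            # a state whose alternatives all have zero weight cannot switch
            if (sum(wk) > 0) state <- sample.int(K, 1, prob = wk / sum(wk))
          }
          gap <- stats::rlnorm(1, config$base_gap_mu, config$base_gap_sigma) +
            (if (is_ld) config$ld_gap_offset else 0) + rng_p$intercept
          gap <- max(gap, 0.05)
          t_cur <- t_cur + gap
          if (t_cur >= config$time_bound) break
        }
        list(xs = xs, ys = ys, ts = ts, tools = tools, states = states,
             solved = solved,
             end_t = if (solved) ts[length(ts)] else config$time_bound)
      })
      idx <- (i - 1L) * config$n_levels + l
      att_list[[idx]] <- data.frame(
        participant_id = ids[i], level_id = lev,
        attempt_index = seq_along(res$ts), tool_id = res$tools,
        x = res$xs, y = res$ys, t = res$ts, true_cluster = res$states)
      play_list[[idx]] <- data.frame(
        participant_id = ids[i], level_id = lev,
        solved = res$solved, end_t = res$end_t)
    }

    motor_list[[i]] <- with_seed(mix_seed(seed, i, 100000L), {
      dist <- sample(rep(c(150, 250), 5))
      data.frame(participant_id = ids[i], trial_index = 1:10,
                 distance_px = dist,
                 rt = rng_p$rt_center * exp(stats::rnorm(10, 0, 0.25)),
                 click_error = rng_p$err_center * exp(stats::rnorm(10, 0, 0.4)))
    })
  }

  attempts <- do.call(rbind, att_list)
  d <- dataset(participants, attempts, do.call(rbind, play_list),
               do.call(rbind, motor_list))
  attr(d, "ground_truth") <- list(centers = st$centers,
                                  weights = st$weights,
                                  tool_probs = st$tool_probs,
                                  config = config, seed = seed)
  d
}
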