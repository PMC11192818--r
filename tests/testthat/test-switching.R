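test_that("switch counting follows the label-change definition exactly", {
  a <- labeled_plays(list(c(1, 1, 1, 1)))
  expect_equal(switch_rate(a)$rate, 0)
  a <- labeled_plays(list(c(1, 2, 1, 2)))
  expect_equal(switch_rate(a)$rate, 1)
  # mixed plays: (1,1,2) has 1 switch / 2 transitions; (3) has none
  a <- labeled_plays(list(c(1, 1, 2), 3))
  sr <- switch_rate(a)
  expect_equal(sr$rate, 0.5)
  expect_equal(sr$per_participant$n_transitions, 2)
  expect_equal(sr$per_participant$n_switches, 1)
})

test_that("switch rate is invariant to relabeling and 1-attempt plays", {
  a <- labeled_plays(list(c(1, 2, 2, 3), c(2, 2), 1, c(3, 1)))
  r1 <- switch_rate(a)$rate
  perm <- c(2L, 3L, 1L)
  a2 <- a; a2$cluster <- perm[a$cluster]
  expect_equal(switch_rate(a2)$rate, r1)
  a3 <- a[ave(a$attempt_index, a$participant_id, a$level_id,
              FUN = length) > 1, ]
  expect_equal(switch_rate(a3)$rate, r1)
  # doubling the data doubles transition counts exactly
  b <- a; b$participant_id <- "P2"
  expect_equal(nrow(switch_rate(rbind(a, b))$transitions),
               2 * nrow(switch_rate(a)$transitions))
})

test_that("cluster labeling recovers planted attempt types", {
  # two-blob fixture: labels must match the nearest-center oracle
  nl <- 2
  centers <- lapply(1:nl, function(l) rbind(c(120, 120), c(480, 480)))
  w <- matrix(0.5, nl, 2)
  cfg <- generator_config(n_per_group = 8, n_levels = nl,
                          clusters_per_level = 2, cluster_centers = centers,
                          group_mixture_weights = list(child = w, adult = w),
                          cluster_sd = 25, structure_seed = 5)
  d <- generate_dataset(cfg, seed = 3)
  dl <- label_sequences(d, group_by = character(0), n_sweeps = 150,
                        burn_in = 75, seed = 4)
  a <- dl$attempts
  oracle <- ifelse((a$x - 120)^2 + (a$y - 120)^2 <
                     (a$x - 480)^2 + (a$y - 480)^2, 1L, 2L)
  agree <- 0
  for (lev in unique(a$level_id)) {
    al <- a[a$level_id == lev, ]
    o <- oracle[a$level_id == lev]
    agree <- agree + max(sum(al$cluster == o), sum(al$cluster == 3L - o))
  }
  expect_equal(agree / nrow(a), 1)

  # deterministic given seed
  dl2 <- label_sequences(d, group_by = character(0), n_sweeps = 150,
                         burn_in = 75, seed = 4)
  expect_identical(dl$attempts$cluster, dl2$attempts$cluster)
})

test_that("switch-rate comparison detects the child-adult difference", {
  # power check on generator ground-truth labels at study-like size
  cfg <- default_paper_config()
  sig <- logical(5)
  rates <- matrix(NA_real_, 5, 2)
  for (r in seq_len(5)) {
    d <- generate_dataset(cfg, seed = 300 + r)
    a <- data.frame(d$attempts[, c("participant_id", "level_id",
                                   "attempt_index")],
                    cluster = d$attempts$true_cluster)
    ag <- d$participants$age_group[match(a$participant_id,
                                         d$participants$participant_id)]
    cmp <- compare_switch_rates(a[ag == "child", ], a[ag == "adult", ],
                                labels = c("child", "adult"))
    sig[r] <- cmp$p < 0.05
    rates[r, ] <- cmp$rates
  }
  expect_gte(sum(sig), 3)                       # majority of replicates
  expect_lt(abs(mean(rates[, 1]) - 0.39), 0.03) # child rate
  expect_lt(abs(mean(rates[, 2]) - 0.33), 0.03) # adult rate
})

test_that("null and degenerate comparisons behave correctly", {
  cfg <- tiny_config(n_per_group = 10, n_levels = 6,
                     switch_p = c(child = 0.35, adult = 0.35))
  d <- generate_dataset(cfg, seed = 77)
  a <- data.frame(d$attempts[, c("participant_id", "level_id",
                                 "attempt_index")],
                  cluster = d$attempts$true_cluster)
  ag <- d$participants$age_group[match(a$participant_id,
                                       d$participants$participant_id)]
  cmp <- compare_switch_rates(a[ag == "child", ], a[ag == "adult", ],
                              labels = c("child", "adult"))
  expect_gt(cmp$p, 0.001)   # no spurious strong signal under equality

  # pooled fallback agrees in direction
  cmp_pooled <- compare_switch_rates(a[ag == "child", ], a[ag == "adult", ],
                                     labels = c("child", "adult"),
                                     method = "pooled")
  expect_true(is.finite(cmp_pooled$chisq))

  # all-identical outcomes: separation note, no test
  a0 <- labeled_plays(list(c(1, 1, 1), c(1, 1)))
  b0 <- labeled_plays(list(c(2, 2, 2)), participant = "Q1")
  cmp0 <- compare_switch_rates(a0, b0)
  expect_true(is.na(cmp0$chisq))
  expect_match(cmp0$note, "separation")
})
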