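test_that("default paper configuration carries the published point estimates", {
  cfg <- default_paper_config()
  expect_equal(cfg$ld_first_offset, 3.79)
  expect_equal(cfg$ld_gap_offset, 2.80)
  expect_equal(cfg$ld_attempt_ratio, 0.839)
  expect_equal(unname(cfg$switch_p[c("child", "adult")]), c(0.39, 0.33))
  expect_equal(unname(cfg$motor_error_mean[c("child", "adult")]),
               c(7.65, 2.92))
  expect_equal(unname(cfg$motor_rt_mean[c("child", "adult")]), c(3.04, 1.91))
  expect_equal(cfg$ld_motor_rt_offset, -0.356)
  expect_equal(unname(cfg$n_per_group[c("adult_NLD", "adult_LD",
                                        "child_NLD", "child_LD")]),
               c(40, 35, 45, 25))
})

test_that("generation is deterministic and validates", {
  cfg <- tiny_config()
  d1 <- generate_dataset(cfg, seed = 11)
  d2 <- generate_dataset(cfg, seed = 11)
  attr(d1, "ground_truth") <- attr(d2, "ground_truth") <- NULL
  expect_identical(d1, d2)
  expect_silent(validate_dataset(d1))
  d3 <- generate_dataset(cfg, seed = 12)
  expect_false(identical(d1$attempts, d3$attempts))
})

test_that("adding participants never perturbs existing ones", {
  small <- generate_dataset(tiny_config(n_per_group = 4), seed = 5)
  # enlarging only the *last* cell leaves earlier participants untouched
  big <- generate_dataset(
    tiny_config(n_per_group = c(child_LD = 4, child_NLD = 4,
                                adult_LD = 4, adult_NLD = 8)), seed = 5)
  ids <- small$participants$participant_id
  expect_identical(small$attempts,
                   big$attempts[big$attempts$participant_id %in% ids, ])
})

test_that("degenerate switch configuration yields a single attempt type", {
  cfg <- tiny_config(clusters_per_level = 1,
                     switch_p = c(child = 0, adult = 0))
  d <- generate_dataset(cfg, seed = 3)
  expect_true(all(d$attempts$true_cluster == 1L))
  sr <- switch_rate(data.frame(d$attempts[, c("participant_id", "level_id",
                                              "attempt_index")],
                               cluster = d$attempts$true_cluster))
  expect_identical(sr$rate, 0)
})

test_that("LD first-attempt offset matches the generative expectation", {
  # oracle: additive offset on a lognormal leaves E[LD] - E[NLD] equal to
  # the offset; compare empirical group means at Monte-Carlo scale
  cfg <- tiny_config(n_per_group = 60, n_levels = 6)
  d <- generate_dataset(cfg, seed = 21)
  m <- level_metrics(d)
  lg <- d$participants$limb_group[match(m$participant_id,
                                        d$participants$participant_id)]
  diff_emp <- mean(m$time_to_first[lg == "LD"]) -
    mean(m$time_to_first[lg == "NLD"])
  expect_lt(abs(diff_emp - cfg$ld_first_offset), 0.45)
})

test_that("attempt-count ratio converges to the configured value", {
  cfg <- tiny_config(n_per_group = 100, n_levels = 8)
  d <- generate_dataset(cfg, seed = 31)
  m <- level_metrics(d)
  lg <- d$participants$limb_group[match(m$participant_id,
                                        d$participants$participant_id)]
  ratio <- mean(m$n_attempts[lg == "LD"]) / mean(m$n_attempts[lg == "NLD"])
  expect_lt(abs(ratio - cfg$ld_attempt_ratio), 0.05)
})

test_that("empirical switch frequency converges to switch_p per age group", {
  cfg <- tiny_config(n_per_group = 40, n_levels = 14)
  d <- generate_dataset(cfg, seed = 41)
  a <- data.frame(d$attempts[, c("participant_id", "level_id",
                                 "attempt_index")],
                  cluster = d$attempts$true_cluster)
  ag <- d$participants$age_group[match(a$participant_id,
                                       d$participants$participant_id)]
  for (g in c("child", "adult")) {
    sr <- switch_rate(a[ag == g, ])
    expect_gte(nrow(sr$transitions), 2000)
    expect_lt(abs(sr$rate - cfg$switch_p[[g]]), 0.03)
  }
})

test_that("placements honor the play area and configs validate", {
  d <- generate_dataset(tiny_config(cluster_sd = 200), seed = 2)
  expect_true(all(d$attempts$x >= 0 & d$attempts$x <= 600))
  expect_true(all(d$attempts$y >= 0 & d$attempts$y <= 600))
  expect_error(generator_config(cluster_sd = -1), "sds")
  expect_error(generator_config(switch_p = c(child = 1.2, adult = 0.3)),
               "probabilities")
  expect_error(generator_config(n_per_group = c(a = 3)), "named")
  w <- matrix(c(0.6, 0.6), 1, 2)  # rows must sum to 1
  expect_error(generator_config(n_levels = 1, clusters_per_level = 2,
                                group_mixture_weights = list(child = w,
                                                             adult = w)),
               "summing to 1")
})
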