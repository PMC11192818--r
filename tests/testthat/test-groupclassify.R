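train_df <- function(pid, tool, x, y) {
  data.frame(participant_id = pid, tool_id = tool, x = x, y = y)
}

test_that("tool probabilities follow Laplace smoothing arithmetic", {
  tr <- train_df(sprintf("P%d", 1:9), rep("A", 9),
                 seq(100, 500, length.out = 9), rep(300, 9))
  gd <- build_group_density(tr, tools = c("A", "B", "C"), smoothing = 1)
  expect_equal(unname(gd$tool_probs), c(10 / 12, 1 / 12, 1 / 12))
  # point-mass training set: density at the point is the kernel maximum
  tr2 <- train_df(c("P1", "P2", "P3"), "A", rep(250, 3), rep(250, 3))
  gd2 <- build_group_density(tr2, tools = "A")
  expect_equal(eval_group_density(gd2, "A", 250, 250),
               dnorm(0, sd = gd2$h[1]) * dnorm(0, sd = gd2$h[2]))
})

test_that("exclusion removes exactly the participant's rows", {
  set.seed(3)
  tr <- train_df(rep(sprintf("P%d", 1:6), each = 2), "A",
                 runif(12, 0, 600), runif(12, 0, 600))
  gd_excl <- build_group_density(tr, "A", exclude = "P3")
  gd_manual <- build_group_density(tr[tr$participant_id != "P3", ], "A")
  expect_equal(gd_excl, gd_manual)
  expect_error(build_group_density(tr[tr$participant_id == "P1", ], "A"),
               "2 contributing")
})

test_that("relative likelihood is symmetric and swap-antisymmetric", {
  set.seed(4)
  tr <- train_df(sprintf("P%d", 1:8), sample(c("A", "B"), 8, TRUE),
                 runif(8, 0, 600), runif(8, 0, 600))
  gd <- build_group_density(tr, c("A", "B"))
  q <- list(tool_id = "A", x = 300, y = 300)
  expect_equal(relative_likelihood(q, gd, gd), 0.5)

  tr2 <- train_df(sprintf("Q%d", 1:8), "B", runif(8, 0, 600),
                  runif(8, 0, 600))
  gd2 <- build_group_density(tr2, c("A", "B"))
  s <- relative_likelihood(q, gd, gd2)
  expect_equal(relative_likelihood(q, gd2, gd), 1 - s)
})

test_that("disjoint tool usage pushes the score toward the user's group", {
  xs <- c(100, 200, 300, 400, 500)
  own_tr <- train_df(sprintf("P%d", 1:5), "A", xs, xs)
  oth_tr <- train_df(sprintf("Q%d", 1:5), "B", xs, xs)
  q <- list(tool_id = "A", x = 300, y = 300)
  s1 <- relative_likelihood(q,
                            build_group_density(own_tr, c("A", "B"), smoothing = 1),
                            build_group_density(oth_tr, c("A", "B"), smoothing = 1))
  expect_gt(s1, 0.5)
  s_small <- relative_likelihood(q,
                                 build_group_density(own_tr, c("A", "B"),
                                                     smoothing = 1e-6),
                                 build_group_density(oth_tr, c("A", "B"),
                                                     smoothing = 1e-6))
  expect_gt(s_small, s1)
  expect_gt(s_small, 0.999)
})

test_that("LOO scores depend on group membership, not group names", {
  d <- generate_dataset(tiny_config(n_per_group = 5, n_levels = 3), seed = 6)
  cl <- loo_classify(d, "limb_group")
  # renaming the groups (swapping every label) leaves each participant's
  # own-group score unchanged: the score is referenced to the participant's
  # own group, whatever it is called
  d2 <- d
  d2$participants$limb_group <- ifelse(d$participants$limb_group == "LD",
                                       "NLD", "LD")
  cl2 <- loo_classify(d2, "limb_group")
  key <- function(x) paste(x$scores$participant_id, x$scores$level_id)
  expect_setequal(key(cl), key(cl2))
  m <- match(key(cl), key(cl2))
  expect_equal(cl2$scores$score[m], cl$scores$score)
  # orientation antisymmetry lives at the density level: scoring the same
  # attempt against (own, other) and (other, own) is exactly complementary
  lev <- cl$scores$level_id[1]
  al <- d$attempts[d$attempts$attempt_index == 1 &
                     d$attempts$level_id == lev, ]
  lg <- d$participants$limb_group[match(al$participant_id,
                                        d$participants$participant_id)]
  tools <- sort(unique(d$attempts$tool_id[d$attempts$level_id == lev]))
  q <- al[1, ]
  own <- build_group_density(al[lg == lg[1], ], tools,
                             exclude = q$participant_id)
  other <- build_group_density(al[lg != lg[1], ], tools,
                               exclude = q$participant_id)
  expect_equal(relative_likelihood(q, own, other),
               1 - relative_likelihood(q, other, own))
})

test_that("exchangeable groups score near chance; separated groups near 1", {
  # limb groups share placement and tool distributions by construction
  cfg <- generator_config(n_per_group = 20, n_levels = 8, structure_seed = 2)
  d <- generate_dataset(cfg, seed = 13)
  cl <- loo_classify(d, "limb_group",
                     subset = d$participants$age_group == "adult")
  expect_lt(abs(cl$mean_score - 0.5), 0.05)
  expect_equal(cl$df, nrow(cl$participants) - 1)

  # level-wise disjoint clusters 300 px apart between limb groups
  nl <- 6
  centers <- lapply(1:nl, function(l) rbind(c(150, 150), c(450, 450)))
  w_ld <- matrix(rep(c(1, 0), each = nl), ncol = 2)
  w_nld <- matrix(rep(c(0, 1), each = nl), ncol = 2)
  cfg2 <- generator_config(n_per_group = 15, n_levels = nl,
                           clusters_per_level = 2, cluster_centers = centers,
                           group_mixture_weights =
                             list(child_LD = w_ld, adult_LD = w_ld,
                                  child_NLD = w_nld, adult_NLD = w_nld),
                           cluster_sd = 40, structure_seed = 3)
  d2 <- generate_dataset(cfg2, seed = 14)
  cl2 <- loo_classify(d2, "limb_group")
  expect_gt(cl2$mean_score, 0.9)
  expect_gt(cl2$t, 0)
})

test_that("degenerate inputs are refused or flagged, never silently dropped", {
  d <- generate_dataset(tiny_config(n_per_group = 1), seed = 2)
  expect_error(loo_classify(d, "limb_group"), "at least 3")

  # minimal viable contrast still returns scores and a finite summary
  d3 <- generate_dataset(tiny_config(n_per_group = 3, n_levels = 2), seed = 4)
  res <- loo_classify(d3, "limb_group")
  expect_true(nrow(res$scores) > 0)
  expect_true(is.finite(res$mean_score))
  expect_true(all(res$scores$score >= 0 & res$scores$score <= 1))
})
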