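test_that("attempt log round-trips through CSV field-for-field", {
  d <- toy_dataset()
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  d2 <- read_attempt_log(file.path(dir, "attempts.csv"))
  d2 <- read_motor_log(file.path(dir, "motor.csv"), d2)
  expect_equal(d2$participants, d$participants, tolerance = 1e-12)
  expect_equal(d2$attempts, d$attempts, tolerance = 1e-12)
  expect_equal(d2$plays, d$plays, tolerance = 1e-12)
  expect_equal(d2$motor, d$motor, tolerance = 1e-12)

  # attempt counts preserved per play
  cnt <- function(x) table(paste(x$attempts$participant_id,
                                 x$attempts$level_id))
  expect_equal(cnt(d2), cnt(d))

  # generated dataset round-trips too (canonical columns)
  g <- generate_dataset(tiny_config(), seed = 7)
  write_dataset(g, dir)
  g2 <- read_attempt_log(file.path(dir, "attempts.csv"))
  cols <- c("participant_id", "level_id", "attempt_index", "tool_id",
            "x", "y", "t")
  expect_equal(g2$attempts[, cols], g$attempts[, cols], tolerance = 1e-9)
  expect_equal(g2$plays, g$plays, tolerance = 1e-9)
  expect_equal(g2$participants, g$participants, tolerance = 1e-9)
})

test_that("empty attempt log yields an empty dataset that round-trips", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "attempts.csv")
  writeLines(paste("participant_id,age_group,limb_group,age_years,level_id,",
                   "attempt_index,tool_id,x,y,t_s,solved,end_t_s", sep = ""),
             path)
  d <- read_attempt_log(path)
  expect_s3_class(d, "cogstyle_dataset")
  expect_equal(nrow(d$plays), 0L)
  expect_equal(nrow(d$attempts), 0L)
  out <- withr::local_tempdir()
  write_dataset(d, out)
  expect_equal(nrow(read_attempt_log(file.path(out, "attempts.csv"))$plays), 0L)
})

test_that("reader is permutation-invariant and re-sorts by time order", {
  d <- toy_dataset()
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  raw <- read.csv(file.path(dir, "attempts.csv"))
  set.seed(1)
  shuffled <- raw[sample(nrow(raw)), ]
  path2 <- file.path(dir, "shuffled.csv")
  write.csv(shuffled, path2, row.names = FALSE)
  d2 <- read_attempt_log(path2)
  d1 <- read_attempt_log(file.path(dir, "attempts.csv"))
  expect_identical(d2$attempts, d1$attempts)
  expect_identical(d2$plays, d1$plays)
  # sorted: t increasing within each play
  expect_equal(d2$attempts$t[d2$attempts$participant_id == "P1" &
                               d2$attempts$level_id == "L01"],
               c(5, 12, 20))
})

test_that("format and validation errors name the offending column or play", {
  dir <- withr::local_tempdir()
  d <- toy_dataset()
  write_dataset(d, dir)
  raw <- read.csv(file.path(dir, "attempts.csv"))

  # missing column named in the error
  bad <- raw[, setdiff(names(raw), "tool_id")]
  p <- file.path(dir, "bad.csv")
  write.csv(bad, p, row.names = FALSE)
  expect_error(read_attempt_log(p), "tool_id")

  # non-monotone timestamps name participant and level
  bad <- raw
  bad$t_s[bad$participant_id == "P1" & bad$level_id == "L01"] <- c(5, 4, 20)
  write.csv(bad, p, row.names = FALSE)
  expect_error(read_attempt_log(p), "P1.*L01|L01.*P1")

  # out-of-range coordinate
  bad <- raw
  bad$x[1] <- 700
  write.csv(bad, p, row.names = FALSE)
  expect_error(read_attempt_log(p), "play area")

  # millisecond columns accepted and converted
  ms <- raw
  ms$t_ms <- ms$t_s * 1000; ms$t_s <- NULL
  ms$end_t_ms <- ms$end_t_s * 1000; ms$end_t_s <- NULL
  write.csv(ms, p, row.names = FALSE)
  expect_equal(read_attempt_log(p)$attempts$t, d$attempts$t)
})

test_that("motor log validation enforces 10 trials, 5 per distance", {
  d <- toy_dataset()
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  raw <- read.csv(file.path(dir, "motor.csv"))
  p <- file.path(dir, "m.csv")

  write.csv(raw, p, row.names = FALSE)
  expect_s3_class(read_motor_log(p, d), "cogstyle_dataset")

  write.csv(raw[-1, ], p, row.names = FALSE)   # 9 trials for P1
  expect_error(read_motor_log(p, d), "9 trials")

  bad <- raw; bad$distance_px[bad$participant_id == "P1"] <- 150
  write.csv(bad, p, row.names = FALSE)
  expect_error(read_motor_log(p, d), "5 trials per distance")

  bad <- raw; bad$click_error_px[2] <- -1
  write.csv(bad, p, row.names = FALSE)
  expect_error(read_motor_log(p, d), "click_error")
})

test_that("dataset invariants reject inconsistent objects", {
  d <- toy_dataset()
  # solved play with no attempts
  pl <- rbind(d$plays, data.frame(participant_id = "P1", level_id = "L99",
                                  solved = TRUE, end_t = 10))
  expect_error(dataset(d$participants, d$attempts, pl, d$motor),
               "no attempts")
  # end_t before last attempt
  pl <- d$plays; pl$end_t[pl$participant_id == "P1" & pl$level_id == "L01"] <- 3
  expect_error(dataset(d$participants, d$attempts, pl, d$motor),
               "end_t before last attempt")
  # unknown participant
  a <- rbind(d$attempts, data.frame(participant_id = "PX", level_id = "L01",
                                    attempt_index = 1L, tool_id = "tool1",
                                    x = 1, y = 1, t = 1))
  expect_error(dataset(d$participants, a, d$plays, d$motor), "unknown")
})
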