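# Shared in-code fixtures: a tiny handcrafted dataset with known arithmetic,
# and small generator configs for property tests.

# Two participants, two levels. P1/L01: attempts at t = 5, 12, 20 s, solved
# on the third; P1/L02: one attempt at t = 8, solved; P2/L01: unsolved,
# attempts at 10, 30 s; P2/L02: unsolved with a single attempt.
toy_dataset <- function() {
  participants <- data.frame(
    participant_id = c("P1", "P2"),
    age_group = c("adult", "child"),
    limb_group = c("LD", "NLD"),
    age_years = c(30, 8))
  attempts <- data.frame(
    participant_id = c("P1", "P1", "P1", "P1", "P2", "P2", "P2"),
    level_id = c("L01", "L01", "L01", "L02", "L01", "L01", "L02"),
    attempt_index = c(1L, 2L, 3L, 1L, 1L, 2L, 1L),
    tool_id = c("tool1", "tool2", "tool1", "tool3", "tool1", "tool1", "tool2"),
    x = c(100, 200, 300, 150, 400, 420, 50),
    y = c(100, 250, 300, 350, 100, 120, 500),
    t = c(5, 12, 20, 8, 10, 30, 40))
  plays <- data.frame(
    participant_id = c("P1", "P1", "P2", "P2"),
    level_id = c("L01", "L02", "L01", "L02"),
    solved = c(TRUE, TRUE, FALSE, FALSE),
    end_t = c(20, 8, 60, 60))
  motor <- data.frame(
    participant_id = rep(c("P1", "P2"), each = 10),
    trial_index = rep(1:10, 2),
    distance_px = rep(rep(c(150, 250), 5), 2),
    rt = c(rep(c(1, 2), 5), rep(3, 10)),
    click_error = c(1:10, rep(3, 10)))
  dataset(participants, attempts, plays, motor)
}

# small fast generator config for property tests
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_per_group = 6, n_levels = 4, structure_seed = 1)
  do.call(generator_config, utils::modifyList(defaults, args))
}

# labeled-attempts frame from explicit label sequences (one play each)
labeled_plays <- function(label_list, participant = "P1") {
  do.call(rbind, lapply(seq_along(label_list), function(i)
    data.frame(participant_id = participant,
               level_id = sprintf("L%02d", i),
               attempt_index = seq_along(label_list[[i]]),
               cluster = label_list[[i]])))
}

canonical_partition <- function(z) paste(match(z, unique(z)), collapse = ".")
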