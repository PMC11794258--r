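# Shared helpers: fixture paths and small random dialogues built in code.

mc_path <- function() system.file("extdata", "monte_cristo.tsv",
                                  package = "dialtk")

responses_path <- function() system.file("extdata",
                                         "testasap_responses.tsv",
                                         package = "dialtk")

summaries_path <- function() system.file("extdata", "group_summaries.tsv",
                                         package = "dialtk")

# A minimal valid act table (no randomness).
tiny_acts <- function(n = 4) {
  data.frame(speaker = rep(c("A", "B"), length.out = n),
             epsilon = seq_len(n),
             content = paste0("utt-", seq_len(n)),
             act_type = rep(c("DMK", "MK"), length.out = n),
             x = 1L, y = seq_len(n),
             delta_task = 1L, delta_interlocutor = 1L, decisive = 1L,
             stringsAsFactors = FALSE)
}

# Transcript files persist the acts, the id and the speaker set; roster
# order and the free-text condition label are in-memory metadata. A
# round-tripped dialogue must agree on everything the format carries.
expect_dialogue_equal <- function(actual, expected) {
  expect_identical(actual$id, expected$id)
  expect_setequal(actual$participants, expected$participants)
  expect_identical(as.data.frame(actual)[names(as.data.frame(expected))],
                   as.data.frame(expected))
}

# A random generator config with modest sizes, for property-style loops.
random_config <- function(seed) {
  set.seed(seed)
  generator_config(
    n_concatenations = sample(1:5, 1),
    acts_per_concatenation = sort(sample(2:8, 2)),
    p_delta_task = runif(1),
    p_delta_interlocutor = runif(1),
    p_decisive_given_positive = runif(1),
    turn_persistence = runif(1, 0, 0.8),
    seed = seed)
}
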