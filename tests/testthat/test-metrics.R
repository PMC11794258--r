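test_that("whole-dialogue vergence and celerity reproduce the worked example", {
  mc <- read_transcript(mc_path())
  expect_identical(vergence(mc, "task"), 1)
  expect_identical(celerity(mc), 0.75)
  expect_identical((1 - celerity(mc)) * 100, 25)
})

test_that("vergence and celerity are plain proportions with clear errors", {
  acts <- tiny_acts(5)
  acts$delta_task <- c(1L, 1L, 1L, 0L, 0L)
  acts$decisive <- c(1L, 1L, 1L, 0L, 0L)
  d <- dialogue(acts, participants = c("A", "B"))
  expect_equal(vergence(d), 0.6)
  acts$delta_task <- 0L
  acts$decisive <- 0L
  expect_equal(vergence(dialogue(acts, participants = c("A", "B"))), 0)
  acts$decisive <- 1L
  expect_equal(celerity(acts), 1)
  empty <- acts[0, ]
  expect_error(vergence(empty), "empty act set")
  expect_error(celerity(empty), "empty act set")
  expect_error(vergence(tiny_acts(3), object = "nonexistent"),
               "no polarity annotation")
})

test_that("per-concatenation metrics give one point per theme in order", {
  mc <- read_transcript(mc_path())
  s <- per_concatenation_metrics(mc)
  expect_identical(nrow(s), 2L)
  expect_equal(s$vergence, c(1, 1))
  expect_identical(s$n_acts, c(6L, 2L))
  # an all-null-polarity theme gives a zero point
  acts <- tiny_acts(6)
  acts$x <- rep(1:2, each = 3L)
  acts$y <- rep(1:3, 2L)
  acts$delta_task[acts$x == 2] <- 0L
  acts$decisive[acts$x == 2] <- 0L
  s2 <- per_concatenation_metrics(dialogue(acts, participants = c("A", "B")))
  expect_equal(s2$vergence, c(1, 0))
})

test_that("running vergence matches a brute-force trailing-window recount", {
  brute <- function(flags, w) {
    vapply(seq_along(flags), function(i)
      mean(flags[max(1, i - w + 1):i]), numeric(1))
  }
  for (seed in 1:10) {
    set.seed(seed)
    flags <- rbinom(80, 1, runif(1))
    w <- sample(1:30, 1)
    expect_equal(running_prop(flags, w), brute(flags, w))
  }
  set.seed(3)
  flags <- rbinom(40, 1, 0.5)
  expect_equal(running_prop(flags, "cumulative"),
               cumsum(flags) / seq_along(flags))
})

test_that("running vergence limiting cases behave", {
  acts <- tiny_acts(10)
  d <- dialogue(acts, participants = c("A", "B"))
  s <- running_vergence(d, window = 4)
  expect_equal(s$vergence, rep(1, 10))          # constant positive stream
  acts$delta_task <- rep(c(1L, 0L), 5)
  acts$decisive <- pmin(acts$decisive, acts$delta_task)
  d2 <- dialogue(acts, participants = c("A", "B"))
  s2 <- running_vergence(d2, window = 2)
  expect_equal(s2$vergence[-1], rep(0.5, 9))    # alternating, window 2
  # window = dialogue length at the last act equals whole-dialogue vergence
  s3 <- running_vergence(d2, window = 10)
  expect_equal(s3$vergence[10], vergence(d2))
  expect_error(running_vergence(d2, window = 50, strict = TRUE), "exceeds")
  # speaker restriction only sees that speaker's acts
  sA <- running_vergence(d2, window = "cumulative", speaker = "A")
  expect_identical(nrow(sA), 5L)
  expect_equal(sA$vergence[5], mean(acts$delta_task[acts$speaker == "A"]))
  expect_error(running_vergence(d2, speaker = "Z"), "unknown speaker")
})

test_that("act-type profiles are proportions over the five types", {
  acts <- tiny_acts(8)
  acts$speaker <- c(rep("A", 4), rep("B", 4))
  acts$act_type <- c("MK", "MK", "DO", "DMK", "MK", "MK", "MK", "MK")
  d <- dialogue(acts, participants = c("A", "B"))
  pr <- act_type_profile(d, "A")
  expect_equal(as.numeric(pr[c("MK", "DO", "DMK", "DC", "DM")]),
               c(0.5, 0.25, 0.25, 0, 0))
  expect_equal(sum(pr), 1)
  expect_error(act_type_profile(d, "C"), "not in roster")
  d$participants <- c("A", "B", "C")
  expect_error(act_type_profile(d, "C"), "has no acts")
})

test_that("profile identities hold on random dialogues", {
  for (seed in 1:10) {
    d <- generate_dialogue(random_config(seed))
    for (s in d$participants) {
      if (!any(d$acts$speaker == s)) next
      pr <- act_type_profile(d, s)
      expect_equal(sum(pr), 1)
      # elaborative (MK + DO) share is the complement of the rest
      expect_equal(pr[["MK"]] + pr[["DO"]],
                   1 - (pr[["DMK"]] + pr[["DC"]] + pr[["DM"]]))
    }
  }
})

test_that("vergence-celerity correlation matches the covariance formula", {
  s <- metric_series(1:4, c(0.2, 0.4, 0.6, 0.8), c(0.8, 0.6, 0.4, 0.2), 5L)
  expect_equal(vc_correlation(s)$r, -1)
  s2 <- metric_series(1:4, c(0.2, 0.4, 0.6, 0.8), c(0.2, 0.4, 0.6, 0.8), 5L)
  expect_equal(vc_correlation(s2)$r, 1)
  set.seed(11)
  v <- runif(9); c_ <- pmin(v, runif(9))
  s3 <- metric_series(1:9, v, c_, 10L)
  ct <- vc_correlation(s3)
  # independent textbook computation
  r_manual <- sum((v - mean(v)) * (c_ - mean(c_))) /
    sqrt(sum((v - mean(v))^2) * sum((c_ - mean(c_))^2))
  t_manual <- r_manual * sqrt(7 / (1 - r_manual^2))
  p_manual <- 2 * pt(-abs(t_manual), 7)
  expect_equal(ct$r, r_manual, tolerance = 1e-12)
  expect_equal(ct$p, p_manual, tolerance = 1e-12)
  expect_equal(ct$df, 7)
})

test_that("degenerate correlations error rather than return NaN", {
  s <- metric_series(1:4, rep(0.5, 4), c(0.1, 0.2, 0.3, 0.4), 5L)
  expect_error(vc_correlation(s), "constant")
  expect_error(vc_correlation(metric_series(1:2, c(0, 1), c(0, 1), 5L)),
               "at least 3")
})

test_that("the primacy inequality holds on the worked example and fails only on invalid input", {
  mc <- read_transcript(mc_path())
  expect_true(primacy_check(mc)$ok)
  # hand-built invalid act set bypassing validation
  acts <- tiny_acts(4)
  acts$delta_task <- c(1L, 0L, 1L, 1L)
  acts$decisive <- c(1L, 1L, 1L, 1L)
  d <- dialogue(acts, validate = FALSE)
  pc <- primacy_check(d)
  expect_false(pc$ok)
  s <- metric_series(1:3, c(0.5, 0.9, 0.2), c(0.6, 0.9, 0.1), 10L)
  pcs <- primacy_check(s)
  expect_false(pcs$ok)
  expect_identical(pcs$violations, 1L)
})

test_that("0 <= C <= V <= 1 on every validated synthetic dialogue", {
  # property over many random dialogues, whole and per concatenation
  for (seed in 1:60) {
    d <- generate_dialogue(random_config(seed))
    expect_identical(nrow(validate_dialogue(d)), 0L)
    v <- vergence(d); c_ <- celerity(d)
    expect_true(c_ >= 0 && c_ <= v && v <= 1)
    s <- per_concatenation_metrics(d)
    expect_true(all(s$celerity <= s$vergence))
    expect_true(all(s$vergence >= 0 & s$vergence <= 1))
  }
})

test_that("vergence is invariant to act order", {
  set.seed(5)
  d <- generate_dialogue(random_config(5))
  acts <- as.data.frame(d)
  shuffled <- acts[sample(nrow(acts)), ]
  expect_equal(vergence(shuffled), vergence(d))
  expect_equal(celerity(shuffled), celerity(d))
})
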