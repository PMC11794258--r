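test_that("generator configs validate their probabilities", {
  expect_error(generator_config(p_delta_task = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(p_delta_task = c(0.9, 0.2)),
               "change_point")
  cfg <- generator_config(p_delta_task = c(0.9, 0.2), change_point = 10)
  expect_s3_class(cfg, "generator_config")
})

test_that("degenerate polarity probabilities pin the metrics", {
  d1 <- generate_dialogue(generator_config(n_concatenations = 2,
                                           acts_per_concatenation = 10,
                                           p_delta_task = 1, seed = 1))
  expect_identical(vergence(d1), 1)
  d0 <- generate_dialogue(generator_config(n_concatenations = 2,
                                           acts_per_concatenation = 10,
                                           p_delta_task = 0, seed = 2))
  expect_identical(vergence(d0), 0)
  expect_identical(celerity(d0), 0)  # d drawn only for task-polarized acts
})

test_that("every generated dialogue passes validation (primacy by construction)", {
  for (seed in 1:200) {
    d <- generate_dialogue(random_config(seed))
    expect_identical(nrow(validate_dialogue(d)), 0L)
  }
})

test_that("vergence recovers the generating probability at binomial accuracy", {
  p <- 0.6
  n <- 10000
  hits <- 0L
  seeds <- 1:50
  for (seed in seeds) {
    d <- generate_dialogue(generator_config(n_concatenations = 10,
                                            acts_per_concatenation = 1000,
                                            p_delta_task = p, seed = seed))
    if (abs(vergence(d) - p) <= 3 * sqrt(p * (1 - p) / n)) hits <- hits + 1L
  }
  expect_gte(hits, 49L)  # 3-sigma bound holds in >= 99% of seeds
})

test_that("empirical act-type frequencies converge to the configured distribution", {
  cfg <- generator_config(n_concatenations = 10,
                          acts_per_concatenation = 1000, seed = 31)
  d <- generate_dialogue(cfg)
  for (s in cfg$speakers) {
    pr <- act_type_profile(d, s)
    tv <- sum(abs(as.numeric(pr) - cfg$act_type_probs[s, ])) / 2
    expect_lt(tv, 0.05)
  }
})

test_that("a regime change depresses the windowed vergence after the change point", {
  for (seed in 1:20) {
    cfg <- generator_config(n_concatenations = 15,
                            acts_per_concatenation = 20,
                            p_delta_task = c(0.9, 0.2),
                            change_point = 150, seed = seed)
    s <- generate_regime_series(cfg, window = 20)
    pre <- mean(s$vergence[50:150])
    post <- mean(s$vergence[200:300])
    expect_lt(post, pre)
  }
})

test_that("without a change point the series is stationary", {
  p <- 0.7
  for (seed in 1:10) {
    cfg <- generator_config(n_concatenations = 15,
                            acts_per_concatenation = 20,
                            p_delta_task = p, seed = seed)
    s <- generate_regime_series(cfg, window = 20)
    delta <- attr(s, "delta")
    half <- length(delta) %/% 2
    m1 <- mean(delta[1:half]); m2 <- mean(delta[(half + 1):length(delta)])
    expect_lt(abs(m1 - m2), 3 * sqrt(2 * p * (1 - p) / half))
  }
})

test_that("constant positive polarity gives a flat series at 1", {
  cfg <- generator_config(n_concatenations = 3,
                          acts_per_concatenation = 20,
                          p_delta_task = 1, seed = 5)
  s <- generate_regime_series(cfg)
  expect_true(all(s$vergence == 1))
})

test_that("group response sampling is reproducible and honours the distribution", {
  r1 <- generate_group_responses(5, c(0.8, 0, 0, 0.2), seed = 7)
  r2 <- generate_group_responses(5, c(0.8, 0, 0, 0.2), seed = 7)
  expect_identical(r1, r2)
  all0 <- generate_group_responses(6, c(1, 0, 0, 0), seed = 8)
  expect_true(all(all0$level == 0))
  expect_error(generate_group_responses(5, c(0.5, 0.5, 0.5, 0)), "sum to 1")
})

test_that("expected failure occupancy matches exhaustive enumeration", {
  # with levels in {0, 3} and P(3) = 0.2, enumerate all 2^5 outcomes and
  # weight the occupancy at the failure terminal (4, 6)
  p3 <- 0.2
  n <- 5
  expected <- 0
  for (k in 0:n) {
    prob <- choose(n, k) * p3^k * (1 - p3)^(n - k)
    expected <- expected + prob * (k / n)
  }
  expect_equal(expected, p3)  # analytic identity the sampler must match
  sims <- vapply(1:400, function(seed) {
    resp <- generate_group_responses(n, c(0.8, 0, 0, 0.2), seed = seed)
    score_group(resp, subtask = "basket")$occupancy[6, 4]
  }, numeric(1))
  se <- sqrt(p3 * (1 - p3) / (n * length(sims)))
  expect_lt(abs(mean(sims) - expected), 4 * se)
})
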