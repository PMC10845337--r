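cfg <- study_config()

test_that("degenerate choice profiles behave deterministically", {
  set.seed(3)
  q <- build_question(contact(2, 5), cfg)
  always_right <- participant_profile(p_correct = 1, memory = 0)
  always_invert <- participant_profile(p_correct = 0,
                                       p_invert_given_error = 1, memory = 0)
  for (i in 1:20) {
    expect_equal(sample_choice(always_right, q), contact(2, 5))
    expect_equal(sample_choice(always_invert, q), contact(4, 7))
  }
  # on a self-symmetric contact the inverted reading is the correct answer
  q_sym <- build_question(contact(3, 6), cfg)
  for (i in 1:20)
    expect_equal(sample_choice(always_invert, q_sym), contact(3, 6))
})

test_that("perfect memory repeats the prior answer on duplicates", {
  set.seed(4)
  q <- build_question(contact(1, 6), cfg)
  prof <- participant_profile(p_correct = 1, memory = 1)
  prior <- contact(2, 6)
  for (i in 1:10)
    expect_equal(sample_choice(prof, q, prior_answer = prior), prior)
})

test_that("the uniform clicker picks each option at the analytic 1/5 rate", {
  set.seed(8)
  q <- build_question(contact(2, 6), cfg)
  prof <- random_clicker_profile()
  n <- 10000
  draws <- vapply(seq_len(n), function(i) {
    ch <- sample_choice(prof, q)
    paste0(ch$a, "-", ch$b)
  }, character(1))
  freq <- table(draws) / n
  expect_length(freq, 5L)
  se3 <- 3 * sqrt(0.2 * 0.8 / n)  # Monte Carlo tolerance
  expect_true(all(abs(freq - 0.2) < se3))
})

test_that("response times follow the decay-to-plateau closed form", {
  prof <- participant_profile(rt_plateau = 5, rt_amplitude = 10,
                              rt_decay = 0.3, rt_noise_sd = 0)
  expect_equal(sample_rt(prof, 1), 15)
  expect_equal(sample_rt(prof, 1e6), 5, tolerance = 1e-9)
  flat <- participant_profile(rt_plateau = 5, rt_amplitude = 10,
                              rt_decay = 0, rt_noise_sd = 0)
  expect_equal(sample_rt(flat, 1), sample_rt(flat, 40))
  # mean-one noise keeps expectations on the curve:
  # E[rt(1)] - E[rt(15)] = amplitude * (1 - exp(-14 * decay))
  noisy <- participant_profile(rt_plateau = 5, rt_amplitude = 10,
                               rt_decay = 0.3, rt_noise_sd = 0.5)
  set.seed(10)
  m1 <- mean(replicate(40000, sample_rt(noisy, 1)))
  m15 <- mean(replicate(40000, sample_rt(noisy, 15)))
  expect_equal(m1 - m15, 10 * (1 - exp(-14 * 0.3)), tolerance = 0.05)
  expect_true(all(replicate(100, sample_rt(noisy, 3)) > 0))
})

test_that("preset designs produce the documented record counts, reproducibly", {
  tab <- simulate_study("expert", cfg, seed = 2)
  expect_equal(nrow(tab), 900L)
  expect_equal(sort(unique(tab$layout)),
               c("circular", "half_matrix", "matrix"))
  expect_equal(length(unique(tab$participant_id)), 30L)
  tab2 <- simulate_study("expert", cfg, seed = 2)
  expect_identical(tab, tab2)
  expect_error(validate_responses(tab), NA)
  counts <- table(table(paste(tab$participant_id, tab$model_id)))
  expect_equal(names(counts), "2")  # every question answered exactly twice
})

test_that("the crowdsourced preset has the full 4500-record design", {
  tab <- simulate_study("mturk", cfg, seed = 3)
  expect_equal(nrow(tab), 4500L)
  expect_equal(sum(tab$is_repeat), 2250L)
})

test_that("response tables round trip through CSV", {
  tab <- simulate_study(list(cohort_spec("circular", 2,
                                         participant_profile())),
                        cfg, seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(tab, path)
  back <- read_responses(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
})

test_that("generated inversion shares are recovered by the metrics pipeline", {
  # cohort-level parameter recovery at the reference 50 x 30 scale
  for (target in c(0.845, 0.566, 0.605)) {
    prof <- participant_profile(
      p_correct = 0.8,
      p_invert_given_error = invert_rate_for_share(target),
      memory = 0)
    tab <- simulate_study(list(cohort_spec("circular", 50, prof)), cfg,
                          seed = round(1000 * target))
    bd <- error_breakdown(score_responses(tab))
    obs <- bd$class_fractions$inversion[1]
    n_err <- bd$class_fractions$n_errors[1]
    se <- sqrt(target * (1 - target) / n_err)
    expect_lt(abs(obs - target), 3 * se)
  }
})

test_that("separation bias skews erroneous choices toward closer segments", {
  prof <- participant_profile(p_correct = 0.3, p_invert_given_error = 0,
                              separation_bias = 1.2, proximity_bias = 0,
                              memory = 0)
  tab <- simulate_study(list(cohort_spec("matrix", 40, prof)), cfg, seed = 9)
  tab <- score_responses(tab)
  err <- tab[tab$error_class != "correct", ]
  expect_lt(median(err$intersegment_distance), 0)
})

test_that("perfect duplicate memory yields consistency exactly 1", {
  prof <- participant_profile(p_correct = 0.5, memory = 1, rt_noise_sd = 0)
  tab <- simulate_study(list(cohort_spec("circular", 5, prof)), cfg,
                        seed = 12)
  for (s in split(tab, tab$participant_id))
    expect_equal(consistency_score(s), 1)
})

test_that("an injected outlier is present and filterable", {
  tab <- simulate_study(list(cohort_spec("circular", 1,
                                         participant_profile())),
                        cfg, seed = 13)
  tab <- inject_rt_outlier(tab, row = 7)
  expect_gt(tab$rt_seconds[7], 5000)
  flt <- filter_responses(tab)
  expect_equal(nrow(flt$removed), 1L)
})
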