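all_pairs <- function() {
  ct <- reference_contacts()
  expand.grid(chosen = seq_len(nrow(ct)), correct = seq_len(nrow(ct)))
}

test_that("consistency is the fraction of identically answered duplicate pairs", {
  correct <- names(reference_inversions)
  tab_all <- make_participant_table(correct, correct, correct)
  expect_equal(consistency_score(tab_all), 1)
  # agree on the first 3 pairs only
  second <- correct
  second[4:15] <- c(correct[5:15], correct[1])  # shift -> all different
  tab_some <- make_participant_table(correct, second, correct)
  expect_equal(consistency_score(tab_some), 3 / 15)
  # unpaired duplicates are a schema error
  bad <- rbind(tab_all, tab_all[1, ])
  expect_error(consistency_score(bad), "schema")
})

test_that("error classification matches the taxonomy and partitions responses", {
  expect_equal(as.character(classify_error(contact(4, 7), contact(2, 5),
                                           contact(4, 7))), "inversion")
  expect_equal(as.character(classify_error(contact(1, 4), contact(3, 6))),
               "inverted_missing")
  expect_equal(as.character(classify_error(contact(1, 3, 8), contact(2, 5),
                                           contact(4, 7))), "other")
  expect_equal(as.character(classify_error(contact(2, 5), contact(2, 5),
                                           contact(4, 7))), "correct")
  # partition property on a simulated table: counts sum to the total
  tab <- score_responses(simulate_study("expert", study_config(), seed = 21))
  expect_equal(sum(table(tab$error_class)), nrow(tab))
  expect_false(any(is.na(tab$error_class)))
  # inversion is only possible when an inverted answer exists
  expect_equal(sum(tab$error_class == "inversion" & is.na(tab$inverted_a)), 0L)
})

test_that("inter-segment distance score matches the worked example and zero set", {
  expect_equal(intersegment_distance(contact(1, 3, 8), contact(2, 5)), -1L)
  expect_equal(intersegment_distance(contact(2, 5), contact(2, 5)), 0L)
  expect_equal(intersegment_distance(contact(5, 8), contact(1, 4)), 0L)
  # exhaustive: zero for the correct answer and for every inversion
  ct <- reference_contacts()
  pairs <- all_pairs()
  for (k in seq_len(nrow(pairs))) {
    chosen <- ct[pairs$chosen[k], , drop = FALSE]
    corr <- ct[pairs$correct[k], , drop = FALSE]
    inv <- invert_contact(corr, 8)
    d <- intersegment_distance(chosen, corr)
    if (identical(unname(unlist(chosen)), unname(unlist(corr))) ||
        (!is.null(inv) && identical(unname(unlist(chosen)),
                                    unname(unlist(inv))))) {
      expect_equal(d, 0L)
    }
  }
})

test_that("MinDistance matches the brute-force oracle on all contact pairs", {
  ct <- reference_contacts()
  pairs <- all_pairs()
  for (k in seq_len(nrow(pairs))) {
    chosen <- ct[pairs$chosen[k], , drop = FALSE]
    corr <- ct[pairs$correct[k], , drop = FALSE]
    md <- min_distance(chosen, corr, 8)
    expect_equal(md, oracle_min_distance(chosen, corr, 8))
    # zero exactly for the correct answer or its inversion
    inv <- invert_contact(corr, 8)
    is_zero_case <- identical(unname(unlist(chosen)), unname(unlist(corr))) ||
      (!is.null(inv) && identical(unname(unlist(chosen)),
                                  unname(unlist(inv))))
    expect_equal(md == 0L, is_zero_case)
  }
})

test_that("MinDistance worked example evaluates to 3", {
  expect_equal(min_distance(contact(1, 3, 8), contact(2, 5), 8), 3L)
  expect_equal(min_distance(contact(5, 8), contact(1, 4), 8), 0L)
  expect_equal(min_distance(contact(2, 5), contact(2, 5), 8), 0L)
})

test_that("scores vectorize over whole tables", {
  tab <- simulate_study("expert", study_config(), seed = 31)
  scored <- score_responses(tab)
  i <- c(1, 100, 500)
  for (k in i) {
    expect_equal(scored$min_distance[k],
                 min_distance(data.frame(a = tab$chosen_a[k],
                                         b = tab$chosen_b[k]),
                              data.frame(a = tab$correct_a[k],
                                         b = tab$correct_b[k]), 8))
  }
})

test_that("learning curves average duplicate pairs into 15 ranked points", {
  correct <- names(reference_inversions)
  rt <- c(rep(4, 15), rep(6, 15))
  tab <- make_participant_table(correct, correct, correct, rt = rt)
  lc <- learning_curve(tab)
  expect_equal(nrow(lc), 15L)
  expect_equal(lc$mean_rt, rep(5, 15))  # pair (4, 6) averages to 5
  expect_equal(lc$n, rep(1L, 15))
  # flat input -> flat curve
  flat <- make_participant_table(correct, correct, correct,
                                 rt = rep(7, 30))
  expect_equal(learning_curve(flat)$mean_rt, rep(7, 15))
})

test_that("learning-curve points follow the earlier presentation of each pair", {
  tab <- simulate_study(list(cohort_spec("circular", 6,
                                         participant_profile())),
                        study_config(), seed = 41)
  lc <- learning_curve(tab)
  expect_equal(nrow(lc), 15L)
  expect_equal(unique(lc$n), 6L)
})

test_that("the response-time filter removes only outliers and logs them", {
  tab <- simulate_study(list(cohort_spec("circular", 2,
                                         participant_profile())),
                        study_config(), seed = 51)
  tab$rt_seconds[10] <- 5001
  flt <- filter_responses(tab)
  expect_equal(nrow(flt$removed), 1L)
  expect_equal(nrow(flt$responses), nrow(tab) - 1L)
  expect_equal(flt$removed$rt_seconds, 5001)
  # infinite cutoff is the identity; the empty table passes through
  expect_equal(nrow(filter_responses(tab, Inf)$removed), 0L)
  empty <- tab[0, ]
  expect_equal(nrow(filter_responses(empty)$responses), 0L)
})

test_that("participant exclusion uses an inclusive 20% bound", {
  sm <- data.frame(participant_id = c("p1", "p2", "p3"),
                   layout = "circular",
                   consistency = c(0.20, 4 / 15, 0),
                   accuracy = 0.5, n_responses = 30L,
                   excluded = FALSE, exclusion_reason = NA_character_)
  out <- filter_participants(sm)
  expect_equal(out$excluded, c(TRUE, FALSE, TRUE))
  out0 <- filter_participants(sm, consistency_threshold = 0)
  expect_equal(out0$excluded, c(FALSE, FALSE, TRUE))
})

test_that("error breakdown handles edge compositions without dividing by zero", {
  correct <- names(reference_inversions)
  perfect <- make_participant_table(correct, correct, correct)
  bd <- error_breakdown(perfect)
  expect_equal(bd$class_fractions$n_errors, 0L)
  expect_true(is.na(bd$class_fractions$inversion))
  # all errors inversions -> fraction 1 (use only invertible questions)
  invertible <- names(reference_inversions)[reference_inversions != ""]
  inverted <- unname(reference_inversions[invertible])
  all_inv <- make_participant_table(inverted, inverted, invertible)
  bd2 <- error_breakdown(all_inv)
  expect_equal(bd2$class_fractions$inversion, 1)
  expect_equal(bd2$class_fractions$n_errors, 24L)
})

test_that("a uniform clicker's consistency converges to the 1/5 baseline", {
  cfg <- study_config()
  tab <- simulate_study(list(cohort_spec("circular", 300,
                                         random_clicker_profile())),
                        cfg, seed = 61)
  scores <- vapply(split(tab, tab$participant_id), consistency_score,
                   numeric(1))
  se <- sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores) - 0.2), 3 * se + 1e-12)
  # the dedicated baseline estimator agrees with the table-based route
  expect_lt(abs(random_consistency_baseline(300, cfg, seed = 62) - 0.2),
            0.02)
})
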