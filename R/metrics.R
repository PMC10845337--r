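# Participant- and answer-level scores: duplicate-question consistency,
# accuracy, the error taxonomy, the inter-segment distance score, the
# MinDistance score, learning curves, and the two standard filters.

#' Duplicate-question consistency score
#'
#' Fraction of duplicated questions that a participant answered identically
#' at both presentations. With five options, a participant choosing
#' uniformly at random agrees with themselves with probability 1/5, so 20%
#' is the threshold for complete randomness under the reference design.
#'
#' @param responses Response-table rows of a single participant.
#' @return Proportion in `[0, 1]`; `NaN` when no question is duplicated.
#' @export
consistency_score <- function(responses) {
  counts <- table(responses$model_id)
  dup <- names(counts)[counts == 2L]
  if (any(counts > 2L))
    stop("schema error: a model_id appears more than twice for a participant",
         call. = FALSE)
  if (length(dup) == 0L) return(NaN)
  agree <- vapply(dup, function(m) {
    rows <- responses[responses$model_id == m, ]
    rows$chosen_a[1] == rows$chosen_a[2] && rows$chosen_b[1] == rows$chosen_b[2]
  }, logical(1))
  mean(agree)
}

#' Classify one answer
#'
#' Partition of every answer into `correct`, `inversion` (the chosen contact
#' is the question's inverted answer), `inverted_missing` (an error on a
#' question whose self-symmetric contact has no inverted answer), or `other`.
#' All arguments are contact data frames of equal height; `inverted` rows may
#' be `NA` when the inverted answer is absent.
#'
#' @param chosen,correct Contact data frames (columns `a`, `b`).
#' @param inverted Contact data frame, `NA` rows where absent, or `NULL`.
#' @return Factor with levels `correct`, `inversion`, `inverted_missing`,
#'   `other`.
#' @export
classify_error <- function(chosen, correct, inverted = NULL) {
  n <- nrow(chosen)
  if (is.null(inverted))
    inverted <- data.frame(a = rep(NA_integer_, n), b = rep(NA_integer_, n))
  is_correct <- chosen$a == correct$a & chosen$b == correct$b
  has_inv <- !is.na(inverted$a)
  is_inv <- has_inv & !is_correct &
    chosen$a == inverted$a & chosen$b == inverted$b
  out <- rep("other", n)
  out[!is_correct & !has_inv] <- "inverted_missing"
  out[is_inv] <- "inversion"
  out[is_correct] <- "correct"
  factor(out, levels = c("correct", "inversion", "inverted_missing", "other"))
}

#' Inter-segment distance score
#'
#' Separation of the chosen contact minus separation of the correct contact:
#' `|a - b|` chosen minus `|a - b|` correct. Zero for correct answers and for
#' inversion errors; negative when the chosen segments are closer in
#' sequence than the truth.
#'
#' @param chosen,correct Contact data frames (columns `a`, `b`).
#' @return Integer vector of score values.
#' @export
intersegment_distance <- function(chosen, correct) {
  as.integer(abs(chosen$a - chosen$b) - abs(correct$a - correct$b))
}

#' MinDistance score
#'
#' Total segment-index displacement between the chosen and correct contacts,
#' minimized over the direct reading and the inverted reading of the chosen
#' answer: `min(|aC - aT| + |bC - bT|, |aC' - aT| + |bC' - bT|)` where
#' `(aC', bC')` is the chosen contact with every segment `i` replaced by
#' `n_segments + 1 - i` and re-sorted ascending. Zero exactly when the
#' chosen contact is the correct answer or its inversion, so inversion
#' errors are not penalized.
#'
#' @param chosen,correct Contact data frames (columns `a`, `b`).
#' @param n_segments Chain length.
#' @return Non-negative integer vector.
#' @export
min_distance <- function(chosen, correct, n_segments = 8L) {
  direct <- abs(chosen$a - correct$a) + abs(chosen$b - correct$b)
  inv_a <- n_segments + 1L - chosen$b   # re-sorted ascending
  inv_b <- n_segments + 1L - chosen$a
  inverted <- abs(inv_a - correct$a) + abs(inv_b - correct$b)
  as.integer(pmin(direct, inverted))
}

# contact-column views of a response table
.chosen_ct <- function(tab) data.frame(a = tab$chosen_a, b = tab$chosen_b)
.correct_ct <- function(tab) data.frame(a = tab$correct_a, b = tab$correct_b)
.inverted_ct <- function(tab) data.frame(a = tab$inverted_a, b = tab$inverted_b)

#' Annotate a response table with scores
#'
#' Adds `error_class`, `intersegment_distance` and `min_distance` columns.
#'
#' @param table A response table.
#' @param n_segments Chain length.
#' @return The annotated table.
#' @export
score_responses <- function(table, n_segments = 8L) {
  table$error_class <- classify_error(.chosen_ct(table), .correct_ct(table),
                                      .inverted_ct(table))
  table$intersegment_distance <- intersegment_distance(.chosen_ct(table),
                                                       .correct_ct(table))
  table$min_distance <- min_distance(.chosen_ct(table), .correct_ct(table),
                                     n_segments)
  table
}

#' Per-participant summaries
#'
#' Consistency and accuracy per participant, before any exclusion.
#'
#' @param table A response table.
#' @return Data frame with `participant_id`, `layout`, `consistency`,
#'   `accuracy`, `n_responses`, `excluded`, `exclusion_reason`.
#' @export
participant_summaries <- function(table) {
  ids <- unique(table$participant_id)
  rows <- lapply(ids, function(pid) {
    sub <- table[table$participant_id == pid, ]
    data.frame(participant_id = pid, layout = sub$layout[1],
               consistency = consistency_score(sub),
               accuracy = mean(sub$chosen_a == sub$correct_a &
                                 sub$chosen_b == sub$correct_b),
               n_responses = nrow(sub),
               excluded = FALSE, exclusion_reason = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Remove response-time outliers
#'
#' Drops responses slower than `rt_cutoff` (5000 s by default) and logs each
#' removal.
#'
#' @param table A response table.
#' @param rt_cutoff Cutoff in seconds; responses with `rt_seconds >
#'   rt_cutoff` are removed. `Inf` disables the filter.
#' @return List with `responses` (kept rows) and `removed` (dropped rows).
#' @export
filter_responses <- function(table, rt_cutoff = 5000) {
  drop <- table$rt_seconds > rt_cutoff
  drop[is.na(drop)] <- FALSE
  list(responses = table[!drop, , drop = FALSE],
       removed = table[drop, , drop = FALSE])
}

#' Exclude low-consistency participants
#'
#' Excludes every participant whose consistency score is at or below the
#' threshold (inclusive bound: a participant at exactly 20% is excluded).
#' Exclusion is by participant; all their responses are dropped downstream.
#'
#' @param summaries Output of [participant_summaries()].
#' @param consistency_threshold Exclusion bound (default 0.20).
#' @return The summaries with `excluded` and `exclusion_reason` filled in.
#' @export
filter_participants <- function(summaries, consistency_threshold = 0.20) {
  out <- !is.nan(summaries$consistency) &
    summaries$consistency <= consistency_threshold
  summaries$excluded <- out
  summaries$exclusion_reason[out] <-
    sprintf("consistency %.3f <= %.2f", summaries$consistency[out],
            consistency_threshold)
  summaries
}

#' Learning curve of a cohort
#'
#' For each participant the two response times of every duplicated question
#' are averaged into one pair value, and the pair is placed at the rank of
#' its earlier presentation index. The curve's k-th point is the mean (with
#' SD and n) of the k-th ranked pair value across the cohort, giving a
#' 15-point curve for a fully duplicated 15-question survey.
#'
#' @param responses Response-table rows of one cohort (one layout).
#' @return Data frame with `question_rank`, `mean_rt`, `sd_rt`, `n`.
#' @export
learning_curve <- function(responses) {
  ids <- unique(responses$participant_id)
  per_part <- lapply(ids, function(pid) {
    sub <- responses[responses$participant_id == pid, ]
    models <- unique(sub$model_id)
    vals <- vapply(models, function(m) {
      mean(sub$rt_seconds[sub$model_id == m])
    }, numeric(1))
    first_seen <- vapply(models, function(m) {
      min(sub$presentation_index[sub$model_id == m])
    }, numeric(1))
    vals[order(first_seen)]
  })
  n_q <- max(vapply(per_part, length, integer(1)))
  rows <- lapply(seq_len(n_q), function(k) {
    xs <- unlist(lapply(per_part, function(v) if (length(v) >= k) v[k]))
    data.frame(question_rank = k, mean_rt = mean(xs),
               sd_rt = stats::sd(xs), n = length(xs))
  })
  do.call(rbind, rows)
}

#' Per-layout error breakdown
#'
#' Among incorrect answers only: the fractions of inversion, inverted-missing
#' and other errors, and the inter-segment distance score distribution.
#' Across all answers: the MinDistance score distribution. Layouts with no
#' errors are reported with `n_errors = 0` and `NA` fractions.
#'
#' @param table A scored response table (see [score_responses()]); unscored
#'   tables are scored on the fly.
#' @param n_segments Chain length.
#' @return List with `class_fractions` (per-layout data frame),
#'   `intersegment` (per-incorrect-answer scores, long format) and
#'   `min_distance` (per-answer scores, long format).
#' @export
error_breakdown <- function(table, n_segments = 8L) {
  if (!"error_class" %in% names(table))
    table <- score_responses(table, n_segments)
  layouts <- unique(table$layout)
  frac <- lapply(layouts, function(ly) {
    sub <- table[table$layout == ly, ]
    err <- sub[sub$error_class != "correct", ]
    n_err <- nrow(err)
    if (n_err == 0L) {
      data.frame(layout = ly, inversion = NA_real_,
                 inverted_missing = NA_real_, other = NA_real_,
                 n_errors = 0L, n_answers = nrow(sub))
    } else {
      data.frame(layout = ly,
                 inversion = mean(err$error_class == "inversion"),
                 inverted_missing = mean(err$error_class == "inverted_missing"),
                 other = mean(err$error_class == "other"),
                 n_errors = n_err, n_answers = nrow(sub))
    }
  })
  errors <- table[table$error_class != "correct", ]
  list(class_fractions = do.call(rbind, frac),
       intersegment = data.frame(layout = errors$layout,
                                 score = errors$intersegment_distance),
       min_distance = data.frame(layout = table$layout,
                                 score = table$min_distance))
}
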