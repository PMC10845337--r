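# Synthetic participant simulator. The behavioral model mirrors what the
# analysis battery assumes: layout-dependent accuracy, a propensity to read
# the 3D model in the inverted direction, a bias of erroneous choices toward
# contacts closer in sequence than the truth, response times decaying to a
# plateau, and partial memory of one's earlier answer on duplicated questions.

#' Participant behavior profile
#'
#' @param p_correct Probability of reading the model correctly and choosing
#'   the correct option.
#' @param p_invert_given_error Given a misread, probability the misread is a
#'   direction inversion. On questions whose contact is self-symmetric the
#'   inverted reading coincides with the correct contact, so this branch then
#'   yields the correct answer; on other questions it selects the inverted
#'   option.
#' @param separation_bias Nonnegative `gamma`: erroneous distractor choices
#'   are weighted by `exp(-gamma * (separation(d) - separation(correct)))`,
#'   skewing errors toward contacts closer in sequence than the truth.
#' @param proximity_bias Nonnegative `beta`: distractor weight also includes
#'   `exp(-beta * MinDistance(d, correct))`, favoring near-miss contacts.
#' @param rt_plateau Asymptotic response time in seconds (> 0).
#' @param rt_amplitude Initial response-time excess over the plateau (>= 0).
#' @param rt_decay Per-presentation exponential decay rate (>= 0).
#' @param rt_noise_sd Log-scale standard deviation of the multiplicative
#'   mean-one lognormal response-time noise (>= 0).
#' @param memory Probability `rho` of repeating one's earlier answer verbatim
#'   when a question is presented the second time.
#' @param choice_model `"mixture"` for the behavioral model above, or
#'   `"uniform"` for a random clicker that picks uniformly among the
#'   presented options (the 20%-consistency baseline).
#' @return An object of class `participant_profile`.
#' @export
participant_profile <- function(p_correct = 0.9,
                                p_invert_given_error = 0.6,
                                separation_bias = 0.8,
                                proximity_bias = 0.6,
                                rt_plateau = 6,
                                rt_amplitude = 10,
                                rt_decay = 0.3,
                                rt_noise_sd = 0.45,
                                memory = 0.7,
                                choice_model = c("mixture", "uniform")) {
  choice_model <- match.arg(choice_model)
  probs <- c(p_correct, p_invert_given_error, memory)
  if (any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (rt_plateau <= 0) stop("rt_plateau must be > 0", call. = FALSE)
  if (rt_amplitude < 0 || rt_decay < 0 || rt_noise_sd < 0 ||
      separation_bias < 0 || proximity_bias < 0)
    stop("rate/sd/bias parameters must be >= 0", call. = FALSE)
  structure(list(p_correct = p_correct,
                 p_invert_given_error = p_invert_given_error,
                 separation_bias = separation_bias,
                 proximity_bias = proximity_bias,
                 rt_plateau = rt_plateau,
                 rt_amplitude = rt_amplitude,
                 rt_decay = rt_decay,
                 rt_noise_sd = rt_noise_sd,
                 memory = memory,
                 choice_model = choice_model),
            class = "participant_profile")
}

#' Random-clicker profile
#'
#' A participant who picks uniformly among the presented options with no
#' answer memory. With five options the expected duplicate-question
#' consistency of this profile is exactly 1/5, the randomness threshold used
#' to screen participants.
#'
#' @inheritParams participant_profile
#' @return A `participant_profile` with `choice_model = "uniform"`.
#' @export
random_clicker_profile <- function(rt_plateau = 6, rt_amplitude = 0,
                                   rt_decay = 0, rt_noise_sd = 0.45) {
  participant_profile(p_correct = 0, p_invert_given_error = 0,
                      separation_bias = 0, proximity_bias = 0,
                      rt_plateau = rt_plateau, rt_amplitude = rt_amplitude,
                      rt_decay = rt_decay, rt_noise_sd = rt_noise_sd,
                      memory = 0, choice_model = "uniform")
}

#' Inversion rate needed for a target inversion share of errors
#'
#' Under the behavioral model, a direction misread on a self-symmetric
#' question lands on the correct answer, so with `I` invertible and `S`
#' self-symmetric questions presented equally often, the expected share of
#' inversion errors among all errors is `I p / (I + S (1 - p))` with
#' `p = p_invert_given_error`. Inverting
#' that relation gives the rate to generate a target share:
#' `p = share (I + S) / (I + share S)`. For the reference design
#' (12 invertible, 3 symmetric) this is `5 share / (4 + share)`.
#'
#' @param share Target expected fraction of errors that are inversions.
#' @param n_invertible Number of questions with an inverted answer.
#' @param n_symmetric Number of self-symmetric questions.
#' @return The `p_invert_given_error` value generating that share.
#' @export
invert_rate_for_share <- function(share, n_invertible = 12L,
                                  n_symmetric = 3L) {
  stopifnot(share >= 0, share <= 1)
  p <- share * (n_invertible + n_symmetric) / (n_invertible + share * n_symmetric)
  if (p > 1)
    stop("target share not attainable for this question mix", call. = FALSE)
  p
}

#' Cohort specification
#'
#' @param layout Layout label the cohort answers.
#' @param n_participants Cohort size (>= 1).
#' @param profile A [participant_profile()] shared by the cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(layout, n_participants, profile) {
  stopifnot(n_participants >= 1, inherits(profile, "participant_profile"))
  structure(list(layout = layout,
                 n_participants = as.integer(n_participants),
                 profile = profile),
            class = "cohort_spec")
}

# Per-layout default profiles for the crowdsourced-cohort preset. Accuracy,
# inversion share, consistency and response-time levels are set so the three
# layouts differ the way the reference study found: circular most accurate,
# most consistent, fastest, with the largest share of pure inversion errors.
.mturk_profiles <- function() {
  list(
    circular = participant_profile(
      p_correct = 0.92,
      p_invert_given_error = invert_rate_for_share(0.845),
      separation_bias = 0.8, proximity_bias = 0.6,
      rt_plateau = 5.3, rt_amplitude = 10, rt_decay = 0.35,
      rt_noise_sd = 0.45, memory = 0.80),
    half_matrix = participant_profile(
      p_correct = 0.82,
      p_invert_given_error = invert_rate_for_share(0.566),
      separation_bias = 0.8, proximity_bias = 0.6,
      rt_plateau = 9.2, rt_amplitude = 14, rt_decay = 0.18,
      rt_noise_sd = 0.45, memory = 0.53),
    matrix = participant_profile(
      p_correct = 0.80,
      p_invert_given_error = invert_rate_for_share(0.605),
      separation_bias = 0.8, proximity_bias = 0.6,
      rt_plateau = 10.0, rt_amplitude = 14, rt_decay = 0.18,
      rt_noise_sd = 0.45, memory = 0.66))
}

# Expert preset: uniformly high consistency, accuracy circ ~ half > matrix,
# matrix fastest, half-matrix slowest to plateau.
.expert_profiles <- function() {
  list(
    circular = participant_profile(
      p_correct = 0.93,
      p_invert_given_error = invert_rate_for_share(0.80),
      separation_bias = 0.8, proximity_bias = 0.6,
      rt_plateau = 5.5, rt_amplitude = 8, rt_decay = 0.30,
      rt_noise_sd = 0.40, memory = 0.85),
    half_matrix = participant_profile(
      p_correct = 0.91,
      p_invert_given_error = invert_rate_for_share(0.55),
      separation_bias = 0.8, proximity_bias = 0.6,
      rt_plateau = 7.5, rt_amplitude = 12, rt_decay = 0.15,
      rt_noise_sd = 0.40, memory = 0.85),
    matrix = participant_profile(
      p_correct = 0.84,
      p_invert_given_error = invert_rate_for_share(0.55),
      separation_bias = 0.8, proximity_bias = 0.6,
      rt_plateau = 5.0, rt_amplitude = 8, rt_decay = 0.28,
      rt_noise_sd = 0.40, memory = 0.85))
}

#' Preset cohort designs
#'
#' `"mturk"` is the crowdsourced design (50 participants per layout, 4,500
#' responses in total); `"expert"` is the expert design (10 per layout, 900
#' responses). Both cover the three layouts with per-layout behavior
#' profiles.
#'
#' @param preset `"mturk"` or `"expert"`.
#' @return List of [cohort_spec()] objects.
#' @export
preset_cohorts <- function(preset = c("mturk", "expert")) {
  preset <- match.arg(preset)
  profiles <- if (preset == "mturk") .mturk_profiles() else .expert_profiles()
  n <- if (preset == "mturk") 50L else 10L
  mapply(function(layout, prof) cohort_spec(layout, n, prof),
         names(profiles), profiles, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Sample one answer
#'
#' Implements the choice model. On a duplicate presentation the participant
#' repeats their earlier answer with probability `memory`; otherwise a fresh
#' choice is drawn: correct with probability `p_correct`; on a misread, a
#' direction inversion with probability `p_invert_given_error` (which picks
#' the inverted option, or the correct one when the contact is
#' self-symmetric); any remaining error picks a distractor with weight
#' `exp(-beta * MinDistance(d, correct) - gamma * (sep(d) - sep(correct)))`.
#' Under `choice_model = "uniform"` every presented option is equally likely.
#'
#' @param profile A [participant_profile()].
#' @param question A `question` object.
#' @param prior_answer The contact chosen at the question's first
#'   presentation, or `NULL`.
#' @param n_segments Chain length (needed for the MinDistance weight).
#' @return A one-row contact data frame.
#' @export
sample_choice <- function(profile, question, prior_answer = NULL,
                          n_segments = 8L) {
  if (!is.null(prior_answer) && profile$memory > 0 &&
      stats::runif(1) < profile$memory) {
    return(prior_answer)
  }
  opts <- question$options
  if (profile$choice_model == "uniform") {
    return(opts[sample.int(nrow(opts), 1L), , drop = FALSE])
  }
  if (stats::runif(1) < profile$p_correct) return(question$correct)
  if (stats::runif(1) < profile$p_invert_given_error) {
    # inverted reading of the 3D model: on a self-symmetric contact this
    # coincides with the correct answer
    if (is.null(question$inverted)) return(question$correct)
    return(question$inverted)
  }
  keys <- contact_key(opts)
  excl <- contact_key(question$correct)
  if (!is.null(question$inverted))
    excl <- c(excl, contact_key(question$inverted))
  pool <- opts[!keys %in% excl, , drop = FALSE]
  if (nrow(pool) == 0L) return(question$correct)
  md <- vapply(seq_len(nrow(pool)), function(i) {
    min_distance(pool[i, , drop = FALSE], question$correct, n_segments)
  }, numeric(1))
  dsep <- contact_separation(pool) - contact_separation(question$correct)
  w <- exp(-profile$proximity_bias * md - profile$separation_bias * dsep)
  pool[sample.int(nrow(pool), 1L, prob = w), , drop = FALSE]
}

#' Sample one response time
#'
#' Decay-to-plateau response time with multiplicative mean-one lognormal
#' noise: `(rt_plateau + rt_amplitude * exp(-rt_decay * (k - 1))) *
#' exp(sigma * Z - sigma^2 / 2)`. The mean-one noise keeps the expected
#' response time on the deterministic decay curve for any noise level.
#'
#' @param profile A [participant_profile()].
#' @param k Presentation index (1-based).
#' @return Response time in seconds (strictly positive).
#' @export
sample_rt <- function(profile, k) {
  stopifnot(k >= 1)
  base <- profile$rt_plateau +
    profile$rt_amplitude * exp(-profile$rt_decay * (k - 1))
  s <- profile$rt_noise_sd
  noise <- if (s > 0) exp(stats::rnorm(length(k), 0, s) - s^2 / 2) else 1
  base * noise
}

.empty_response_table <- function() {
  data.frame(participant_id = character(0), layout = character(0),
             presentation_index = integer(0), model_id = character(0),
             is_repeat = logical(0),
             chosen_a = integer(0), chosen_b = integer(0),
             correct_a = integer(0), correct_b = integer(0),
             inverted_a = integer(0), inverted_b = integer(0),
             rt_seconds = numeric(0), stringsAsFactors = FALSE)
}

#' Simulate a full study
#'
#' Draws one independently randomized survey per participant (fresh question
#' order, option order and distractor sets), then one response per
#' presentation via [sample_choice()] and [sample_rt()]. The result is a
#' response table in the documented CSV schema, fully reproducible from the
#' seed.
#'
#' @param cohorts List of [cohort_spec()] objects (or a preset name for
#'   [preset_cohorts()]).
#' @param config A [study_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `response_table` data frame: one row per presentation with
#'   columns `participant_id`, `layout`, `presentation_index`, `model_id`,
#'   `is_repeat`, `chosen_a/b`, `correct_a/b`, `inverted_a/b` (`NA` when the
#'   contact is self-symmetric) and `rt_seconds`.
#' @examples
#' tab <- simulate_study(preset_cohorts("expert"), study_config(), seed = 1)
#' nrow(tab)  # 900
#' @export
simulate_study <- function(cohorts, config = study_config(), seed = NULL) {
  if (is.character(cohorts)) cohorts <- preset_cohorts(cohorts)
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", sum(vapply(cohorts, function(co) co$n_participants,
                                    integer(1))))
  ri <- 0L
  for (co in cohorts) {
    for (p in seq_len(co$n_participants)) {
      pid <- sprintf("%s_%02d", co$layout, p)
      bank <- build_question_bank(config)
      design <- build_survey(co$layout, bank, config)
      pres <- design$presentations
      n <- nrow(pres)
      chosen_a <- chosen_b <- correct_a <- correct_b <- integer(n)
      inverted_a <- inverted_b <- rep(NA_integer_, n)
      rt <- numeric(n)
      prior <- list()
      for (i in seq_len(n)) {
        q <- design$questions[[pres$model_id[i]]]
        prev <- prior[[pres$model_id[i]]]
        ch <- sample_choice(co$profile, q, prior_answer = prev,
                            n_segments = config$n_segments)
        prior[[pres$model_id[i]]] <- ch
        chosen_a[i] <- ch$a; chosen_b[i] <- ch$b
        correct_a[i] <- q$correct$a; correct_b[i] <- q$correct$b
        if (!is.null(q$inverted)) {
          inverted_a[i] <- q$inverted$a; inverted_b[i] <- q$inverted$b
        }
        rt[i] <- sample_rt(co$profile, i)
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(participant_id = pid, layout = co$layout,
                               presentation_index = pres$presentation_index,
                               model_id = pres$model_id,
                               is_repeat = pres$is_repeat,
                               chosen_a = chosen_a, chosen_b = chosen_b,
                               correct_a = correct_a, correct_b = correct_b,
                               inverted_a = inverted_a,
                               inverted_b = inverted_b,
                               rt_seconds = rt, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("response_table", "data.frame")
  out
}

#' Inject a response-time outlier
#'
#' Replaces the response time of one record (the first, by default) with a
#' value above the standard 5000 s cutoff, to exercise the outlier filter.
#'
#' @param table A response table.
#' @param row Row index to contaminate.
#' @param rt_seconds Outlying response time.
#' @return The modified table.
#' @export
inject_rt_outlier <- function(table, row = 1L, rt_seconds = 5400) {
  stopifnot(row >= 1L, row <= nrow(table))
  table$rt_seconds[row] <- rt_seconds
  table
}

.response_columns <- c("participant_id", "layout", "presentation_index",
                       "model_id", "is_repeat", "chosen_a", "chosen_b",
                       "correct_a", "correct_b", "inverted_a", "inverted_b",
                       "rt_seconds")

#' Validate a response table against the schema
#'
#' Checks column presence and types, that contacts are stored ascending,
#' that the chosen/correct segment indices are admissible, and that response
#' times are positive. Returns the table invisibly or stops with the name of
#' the offending column.
#'
#' @param table A data frame in the response schema.
#' @return The validated table (classed `response_table`), invisibly.
#' @export
validate_responses <- function(table) {
  missing <- setdiff(.response_columns, names(table))
  if (length(missing) > 0L)
    stop("response table schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(table) == 0L) {
    class(table) <- unique(c("response_table", class(table)))
    return(invisible(table))
  }
  for (col in c("chosen", "correct")) {
    a <- table[[paste0(col, "_a")]]; b <- table[[paste0(col, "_b")]]
    if (any(is.na(a)) || any(is.na(b)) || any(a >= b) || any(a < 1L))
      stop("response table schema error: column ", col,
           "_a/_b must hold ascending 1-based contacts", call. = FALSE)
  }
  inv_ok <- (is.na(table$inverted_a) & is.na(table$inverted_b)) |
    (!is.na(table$inverted_a) & !is.na(table$inverted_b) &
       table$inverted_a < table$inverted_b)
  if (!all(inv_ok))
    stop("response table schema error: column inverted_a/_b inconsistent",
         call. = FALSE)
  if (any(!is.finite(table$rt_seconds)) || any(table$rt_seconds <= 0))
    stop("response table schema error: column rt_seconds must be positive",
         call. = FALSE)
  class(table) <- unique(c("response_table", class(table)))
  invisible(table)
}

#' Write / read a response table as CSV
#'
#' Comma-separated, UTF-8, header row, RFC-4180 quoting; absent inverted
#' answers serialize as empty fields.
#'
#' @param table A response table.
#' @param path File path.
#' @return `path` (write) or the validated table (read).
#' @export
write_responses <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(participant_id = "character",
                                        layout = "character",
                                        model_id = "character"))
  tab$is_repeat <- as.logical(tab$is_repeat)
  for (col in c("presentation_index", "chosen_a", "chosen_b", "correct_a",
                "correct_b", "inverted_a", "inverted_b"))
    tab[[col]] <- as.integer(tab[[col]])
  validate_responses(tab)
  tab
}

#' Monte Carlo randomness baseline for the consistency score
#'
#' Expected duplicate-question consistency of a participant choosing
#' uniformly at random among the presented options, estimated by simulating
#' `n_participants` random clickers on the fully duplicated survey and
#' averaging their consistency scores. With five options the analytic value
#' is 1/5; this is the threshold used to screen out random clickers.
#'
#' @param n_participants Number of simulated random clickers.
#' @param config A [study_config()].
#' @param seed Integer seed, or `NULL`.
#' @return Mean consistency (proportion in `[0, 1]`).
#' @export
random_consistency_baseline <- function(n_participants = 10000L,
                                        config = study_config(),
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  profile <- random_clicker_profile()
  bank <- build_question_bank(config)
  mean(vapply(seq_len(n_participants), function(i) {
    agree <- vapply(bank, function(q) {
      first <- sample_choice(profile, q)
      second <- sample_choice(profile, q)
      first$a == second$a && first$b == second$b
    }, logical(1))
    mean(agree)
  }, numeric(1)))
}
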