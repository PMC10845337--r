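#' Study configuration
#'
#' Bundles the design constants of a layout-perception study: the number of
#' chain segments, the minimum sequence separation a contact must span, the
#' number of answer options per question, the fraction of questions duplicated
#' for consistency scoring, and the layouts under comparison.
#'
#' The defaults reproduce the reference design: an eight-segment chain, 15
#' admissible contacts (separation >= 3), five options per question, every
#' question repeated once (30 presentations per participant), and the three
#' layouts `circular`, `half_matrix` and `matrix`. The animation constants
#' (3 degree rocking amplitude, 136 frames over 3 s) describe how the 3D
#' stimuli were rendered; they are carried for provenance only and are not
#' used by any computation.
#'
#' @param n_segments Number of segments on the chain (>= 2).
#' @param min_separation Minimum `b - a` for an admissible contact
#'   (1 <= min_separation <= n_segments - 1).
#' @param n_options Number of answer options per question (>= 2).
#' @param repeat_fraction Fraction of questions duplicated, in `[0, 1]`.
#' @param layouts Character vector of layout labels.
#' @param rng_seed Integer seed recorded in the config (used by callers that
#'   take a config rather than an explicit seed).
#' @param animation List of rendering constants, kept for provenance.
#' @return An object of class `study_config`.
#' @examples
#' cfg <- study_config()
#' nrow(enumerate_contacts(cfg$n_segments, cfg$min_separation))
#' @export
study_config <- function(n_segments = 8L,
                         min_separation = 3L,
                         n_options = 5L,
                         repeat_fraction = 1.0,
                         layouts = c("circular", "half_matrix", "matrix"),
                         rng_seed = 1L,
                         animation = list(rocking_amplitude_deg = 3,
                                          n_frames = 136,
                                          cycle_seconds = 3)) {
  n_segments <- as.integer(n_segments)
  min_separation <- as.integer(min_separation)
  n_options <- as.integer(n_options)
  if (is.na(n_segments) || n_segments < 2L)
    stop("invalid config: n_segments must be >= 2", call. = FALSE)
  if (is.na(min_separation) || min_separation < 1L ||
      min_separation > n_segments - 1L)
    stop("invalid config: need 1 <= min_separation <= n_segments - 1",
         call. = FALSE)
  if (is.na(n_options) || n_options < 2L)
    stop("invalid config: n_options must be >= 2", call. = FALSE)
  if (!is.numeric(repeat_fraction) || repeat_fraction < 0 ||
      repeat_fraction > 1)
    stop("invalid config: repeat_fraction must be in [0, 1]", call. = FALSE)
  layouts <- as.character(layouts)
  if (length(layouts) < 1L)
    stop("invalid config: at least one layout label required", call. = FALSE)
  structure(list(n_segments = n_segments,
                 min_separation = min_separation,
                 n_options = n_options,
                 repeat_fraction = repeat_fraction,
                 layouts = layouts,
                 rng_seed = as.integer(rng_seed),
                 animation = animation),
            class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study configuration\n")
  cat(sprintf("  segments: %d, min separation: %d, options/question: %d\n",
              x$n_segments, x$min_separation, x$n_options))
  cat(sprintf("  repeat fraction: %.2f, layouts: %s\n",
              x$repeat_fraction, paste(x$layouts, collapse = ", ")))
  invisible(x)
}

#' Construct a contact
#'
#' A contact is an unordered pair of segment indices on the chain, stored in
#' ascending order. Contacts are represented as two-column data frames
#' (`a < b`, both 1-based), one row per contact, so that vectors of contacts
#' are ordinary tables.
#'
#' @param a,b Segment indices (any order; stored ascending).
#' @param n_segments Chain length used for validation.
#' @return A one-row data frame with integer columns `a` and `b`.
#' @export
contact <- function(a, b, n_segments = 8L) {
  a <- as.integer(a); b <- as.integer(b)
  if (any(is.na(a)) || any(is.na(b)))
    stop("contact: segment indices must be integers", call. = FALSE)
  lo <- pmin(a, b); hi <- pmax(a, b)
  if (any(lo < 1L) || any(hi > n_segments))
    stop("contact: segment indices out of range 1..n_segments", call. = FALSE)
  if (any(lo == hi))
    stop("contact: intrasegment contacts (a == b) are not admissible",
         call. = FALSE)
  data.frame(a = lo, b = hi)
}

#' Contact separation
#'
#' Sequence separation `b - a` of one or more contacts.
#'
#' @param ct Data frame with columns `a`, `b`.
#' @return Integer vector of separations.
#' @export
contact_separation <- function(ct) as.integer(ct$b - ct$a)

# "a-b" keys used for joining / equality of contacts
contact_key <- function(ct) paste0(ct$a, "-", ct$b)

#' Enumerate the admissible contact set
#'
#' All contacts on an `n_segments`-chain whose sequence separation `b - a` is
#' at least `min_separation`, sorted by (separation, a). With 8 segments and
#' a minimum separation of 3 this is the 15-contact stimulus family
#' 1-4, 2-5, 3-6, 4-7, 5-8, 1-5, ..., 1-8.
#'
#' @param n_segments Chain length (>= 2).
#' @param min_separation Minimum separation (>= 1). Values larger than
#'   `n_segments - 1` yield an empty set.
#' @return Data frame of contacts (`a`, `b`), possibly zero rows.
#' @export
enumerate_contacts <- function(n_segments, min_separation) {
  n_segments <- as.integer(n_segments)
  min_separation <- as.integer(min_separation)
  if (is.na(n_segments) || n_segments < 2L || is.na(min_separation) ||
      min_separation < 1L)
    stop("invalid config: counts must be positive (n_segments >= 2)",
         call. = FALSE)
  out <- list()
  seps <- seq.int(min_separation, length.out = max(0L, n_segments - min_separation))
  for (s in seps) {
    a <- seq_len(n_segments - s)
    out[[length(out) + 1L]] <- data.frame(a = a, b = a + s)
  }
  if (length(out) == 0L) return(data.frame(a = integer(0), b = integer(0)))
  do.call(rbind, out)
}

#' Inverted answer of a contact
#'
#' The contact obtained by reading the chain in the opposite direction:
#' segment `i` maps to `n_segments + 1 - i` and the pair is re-sorted
#' ascending. Self-symmetric contacts (those with `a + b = n_segments + 1`,
#' e.g. 3-6, 2-7 and 1-8 on eight segments) map to themselves and have no
#' inverted answer; `NULL` is returned for those.
#'
#' @param ct One-row contact data frame.
#' @param n_segments Chain length.
#' @return A one-row contact data frame, or `NULL` when the contact is
#'   self-symmetric.
#' @export
invert_contact <- function(ct, n_segments = 8L) {
  stopifnot(nrow(ct) == 1L)
  inv <- contact(n_segments + 1L - ct$b, n_segments + 1L - ct$a, n_segments)
  if (inv$a == ct$a && inv$b == ct$b) return(NULL)
  inv
}

#' Build one multiple-choice question
#'
#' A question presents `n_options` contacts: the correct answer, its inverted
#' answer when one exists, and distinct random distractors drawn without
#' replacement from the admissible contact set (minus the correct and
#' inverted answers). Using the admissible set as the distractor pool keeps
#' every option a plausible stimulus from the same family.
#'
#' @param correct One-row contact data frame; must belong to
#'   `enumerate_contacts(config$n_segments, config$min_separation)`.
#' @param config A [study_config()].
#' @param model_id Identifier for the underlying 3D model; defaults to the
#'   "a-b" key of the correct contact.
#' @return An object of class `question`: a list with `model_id`, `correct`,
#'   `inverted` (`NULL` when absent) and `options` (a data frame of
#'   `n_options` distinct contacts containing the correct answer).
#' @export
build_question <- function(correct, config, model_id = NULL) {
  pool <- enumerate_contacts(config$n_segments, config$min_separation)
  if (!contact_key(correct) %in% contact_key(pool))
    stop("correct answer is not in the admissible contact set", call. = FALSE)
  inv <- invert_contact(correct, config$n_segments)
  fixed <- if (is.null(inv)) correct else rbind(correct, inv)
  candidates <- pool[!contact_key(pool) %in% contact_key(fixed), , drop = FALSE]
  n_fill <- config$n_options - nrow(fixed)
  if (n_fill < 0L || nrow(candidates) < n_fill)
    stop("invalid config: distractor pool smaller than required option slots",
         call. = FALSE)
  picked <- candidates[sample.int(nrow(candidates), n_fill), , drop = FALSE]
  options <- rbind(fixed, picked)
  rownames(options) <- NULL
  structure(list(model_id = if (is.null(model_id)) contact_key(correct)
                            else as.character(model_id),
                 correct = correct,
                 inverted = inv,
                 options = options),
            class = "question")
}

#' Build the full question bank for a configuration
#'
#' One question per admissible contact, in the canonical enumeration order.
#'
#' @inheritParams build_question
#' @return List of [build_question()] results.
#' @export
build_question_bank <- function(config) {
  pool <- enumerate_contacts(config$n_segments, config$min_separation)
  lapply(seq_len(nrow(pool)),
         function(i) build_question(pool[i, , drop = FALSE], config))
}

#' Build a randomized survey for one participant
#'
#' Duplicates `ceiling(repeat_fraction * n)` of the questions (all of them at
#' the default repeat fraction of 1), shuffles the resulting presentation
#' list, and draws an independent permutation of the option slots for every
#' presentation. The second occurrence of a duplicated question in
#' presentation order carries `is_repeat = TRUE`. No spacing constraint is
#' imposed on where a duplicate lands.
#'
#' @param layout Layout label for this survey.
#' @param questions List of `question` objects (the question bank).
#' @param config A [study_config()].
#' @return An object of class `survey_design`: list with `layout`,
#'   `questions` (the bank, indexed by model_id) and `presentations`, a data
#'   frame with columns `presentation_index`, `model_id`, `is_repeat`, and a
#'   list-column `option_order` of slot permutations.
#' @export
build_survey <- function(layout, questions, config) {
  if (length(questions) == 0L) stop("questions must be non-empty", call. = FALSE)
  ids <- vapply(questions, function(q) q$model_id, character(1))
  n_rep <- ceiling(config$repeat_fraction * length(questions))
  repeated <- if (n_rep > 0L) sample(ids, n_rep) else character(0)
  deck <- c(ids, repeated)
  deck <- deck[sample.int(length(deck))]
  seen <- character(0)
  is_repeat <- logical(length(deck))
  for (i in seq_along(deck)) {
    is_repeat[i] <- deck[i] %in% seen
    seen <- c(seen, deck[i])
  }
  option_order <- replicate(length(deck),
                            sample.int(config$n_options), simplify = FALSE)
  pres <- data.frame(presentation_index = seq_along(deck),
                     model_id = deck,
                     is_repeat = is_repeat,
                     stringsAsFactors = FALSE)
  pres$option_order <- option_order
  names(questions) <- ids
  structure(list(layout = layout, questions = questions,
                 presentations = pres),
            class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat(sprintf("Survey design (%s): %d presentations, %d unique questions\n",
              x$layout, nrow(x$presentations),
              length(unique(x$presentations$model_id))))
  invisible(x)
}

#' Flatten a survey design to a table
#'
#' One row per presentation: layout, presentation index, model id, repeat
#' flag, the options in presented order as "a-b" keys, and the slot (1-based)
#' holding the correct answer. This is the serialization contract for survey
#' designs.
#'
#' @param design A `survey_design`.
#' @return A data frame.
#' @export
survey_table <- function(design) {
  pres <- design$presentations
  rows <- lapply(seq_len(nrow(pres)), function(i) {
    q <- design$questions[[pres$model_id[i]]]
    opts <- q$options[pres$option_order[[i]], , drop = FALSE]
    keys <- contact_key(opts)
    data.frame(layout = design$layout,
               presentation_index = pres$presentation_index[i],
               model_id = pres$model_id[i],
               is_repeat = pres$is_repeat[i],
               options = paste(keys, collapse = ";"),
               correct_slot = match(contact_key(q$correct), keys),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a survey design as CSV
#'
#' @param design A `survey_design`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(design, path) {
  utils::write.csv(survey_table(design), path, row.names = FALSE)
  invisible(path)
}
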