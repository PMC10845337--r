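# Independent oracles and small fixture builders shared across test files.

# Reference stimulus family and inversion pairs for the 8-segment design,
# written out by hand: contact key -> inverted key ("" = self-symmetric).
reference_inversions <- c(
  "1-4" = "5-8", "2-5" = "4-7", "3-6" = "",    "4-7" = "2-5", "5-8" = "1-4",
  "1-5" = "4-8", "2-6" = "3-7", "3-7" = "2-6", "4-8" = "1-5",
  "1-6" = "3-8", "2-7" = "",    "3-8" = "1-6",
  "1-7" = "2-8", "2-8" = "1-7", "1-8" = "")

# Brute-force MinDistance: minimize total index displacement over every
# endpoint pairing combined with optionally inverting the chosen contact.
oracle_min_distance <- function(chosen, correct, n_segments = 8L) {
  readings <- list(c(chosen$a, chosen$b),
                   c(n_segments + 1L - chosen$a, n_segments + 1L - chosen$b))
  best <- Inf
  for (r in readings) {
    for (perm in list(r, rev(r))) {
      best <- min(best, abs(perm[1] - correct$a) + abs(perm[2] - correct$b))
    }
  }
  best
}

# Minimal single-participant response table with full duplication, built
# from parallel vectors of chosen/correct keys ("a-b").
make_participant_table <- function(chosen_first, chosen_second, correct,
                                   rt = NULL, participant_id = "p1",
                                   layout = "circular", n_segments = 8L) {
  stopifnot(length(chosen_first) == length(correct),
            length(chosen_second) == length(correct))
  parse <- function(keys) {
    m <- do.call(rbind, strsplit(keys, "-"))
    data.frame(a = as.integer(m[, 1]), b = as.integer(m[, 2]))
  }
  nq <- length(correct)
  ct_corr <- parse(correct)
  ch <- parse(c(chosen_first, chosen_second))
  inv <- lapply(seq_len(nq), function(i) {
    invert_contact(ct_corr[i, , drop = FALSE], n_segments)
  })
  inv_a <- vapply(inv, function(x) if (is.null(x)) NA_integer_ else x$a,
                  integer(1))
  inv_b <- vapply(inv, function(x) if (is.null(x)) NA_integer_ else x$b,
                  integer(1))
  if (is.null(rt)) rt <- rep(5, 2 * nq)
  data.frame(participant_id = participant_id, layout = layout,
             presentation_index = seq_len(2 * nq),
             model_id = rep(correct, 2),
             is_repeat = rep(c(FALSE, TRUE), each = nq),
             chosen_a = ch$a, chosen_b = ch$b,
             correct_a = rep(ct_corr$a, 2), correct_b = rep(ct_corr$b, 2),
             inverted_a = rep(inv_a, 2), inverted_b = rep(inv_b, 2),
             rt_seconds = rt, stringsAsFactors = FALSE)
}

# All 15 admissible contacts of the reference design, as a data frame.
reference_contacts <- function() enumerate_contacts(8L, 3L)
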