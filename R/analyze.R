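#' Run the full study analysis
#'
#' The complete battery applied to a response table, in the order the design
#' prescribes: (1) remove response-time outliers; (2) compute per-participant
#' consistency and exclude participants at or below the randomness-derived
#' threshold; (3) on the retained responses compute accuracy, the error
#' taxonomy, the inter-segment distance and MinDistance scores and the
#' learning curves; (4) run the inferential battery — one-way ANOVA with
#' Tukey post hoc for consistency, response times and pair-averaged learning
#' times; pairwise Pearson chi-squared for accuracy and for the inversion
#' share of errors; Kruskal-Wallis with Dunn post hoc for the inter-segment
#' distance scores (incorrect answers only) and the MinDistance scores (all
#' answers) — with p-values adjusted by the configured method at the given
#' alpha.
#'
#' @param table A response table (see [simulate_study()] /
#'   [read_responses()]).
#' @param config The [study_config()] the table was collected under.
#' @param rt_cutoff Response-time outlier cutoff in seconds.
#' @param consistency_threshold Participant exclusion bound (inclusive).
#' @param alpha Significance level.
#' @param adjust_method Multiple-testing adjustment: `"bh"`, `"holm"` or
#'   `"bonferroni"`.
#' @return An object of class `layout_study`; see Details. Inspect with
#'   `print()`, `summary()` and `plot()`, or export with [write_report()].
#' @details The returned object bundles: `responses` (retained, scored),
#'   `summaries` (per participant, with exclusion flags), `filter_log`
#'   (removed responses and excluded participants), `learning_curves` (one
#'   per layout), `breakdown` (error taxonomy and score distributions), and
#'   the test families `consistency_test`, `accuracy_test`, `rt_test`,
#'   `learning_test`, `inversion_share_test`, `intersegment_test`,
#'   `min_distance_test`.
#' @examples
#' tab <- simulate_study(preset_cohorts("expert"), study_config(), seed = 1)
#' fit <- analyze_study(tab)
#' fit
#' @export
analyze_study <- function(table, config = study_config(), rt_cutoff = 5000,
                          consistency_threshold = 0.20, alpha = 0.05,
                          adjust_method = c("bh", "holm", "bonferroni")) {
  adjust_method <- match.arg(adjust_method)
  validate_responses(table)
  if (nrow(table) == 0L)
    stop("no data: the response table is empty", call. = FALSE)

  rt_filter <- filter_responses(table, rt_cutoff)
  tab <- rt_filter$responses
  if (nrow(tab) == 0L)
    stop("no data: every response was removed by the outlier filter",
         call. = FALSE)

  summaries <- filter_participants(participant_summaries(tab),
                                   consistency_threshold)
  kept_ids <- summaries$participant_id[!summaries$excluded]
  tab <- tab[tab$participant_id %in% kept_ids, , drop = FALSE]
  if (nrow(tab) == 0L)
    stop("no data: every participant was excluded by the consistency filter",
         call. = FALSE)
  tab <- score_responses(tab, config$n_segments)

  layouts <- intersect(config$layouts, unique(tab$layout))
  kept <- summaries[!summaries$excluded & summaries$layout %in% layouts, ]

  by_layout <- function(values, layout) split(values, factor(layout, layouts))

  consistency_test <- anova_tukey(by_layout(kept$consistency, kept$layout),
                                  alpha)
  acc_counts <- do.call(rbind, lapply(layouts, function(ly) {
    sub <- tab[tab$layout == ly, ]
    ok <- sub$error_class == "correct"
    data.frame(group = ly, success = sum(ok), failure = sum(!ok))
  }))
  accuracy_test <- pairwise_chi2(acc_counts, alpha, adjust_method)
  rt_test <- anova_tukey(by_layout(tab$rt_seconds, tab$layout), alpha)

  learning_curves <- lapply(stats::setNames(layouts, layouts), function(ly) {
    learning_curve(tab[tab$layout == ly, ])
  })
  pair_avgs <- lapply(stats::setNames(layouts, layouts), function(ly) {
    sub <- tab[tab$layout == ly, ]
    unlist(lapply(split(sub, sub$participant_id), function(s) {
      tapply(s$rt_seconds, s$model_id, mean)
    }), use.names = FALSE)
  })
  learning_test <- anova_tukey(pair_avgs, alpha)

  breakdown <- error_breakdown(tab, config$n_segments)
  errors <- tab[tab$error_class != "correct", ]
  inv_counts <- do.call(rbind, lapply(layouts, function(ly) {
    sub <- errors[errors$layout == ly, ]
    data.frame(group = ly,
               success = sum(sub$error_class == "inversion"),
               failure = sum(sub$error_class != "inversion"))
  }))
  inversion_share_test <- pairwise_chi2(inv_counts, alpha, adjust_method)
  intersegment_test <-
    if (length(unique(errors$layout)) >= 2L)
      kruskal_dunn(by_layout(errors$intersegment_distance, errors$layout),
                   alpha, adjust_method)
    else NULL
  min_distance_test <- kruskal_dunn(by_layout(tab$min_distance, tab$layout),
                                    alpha, adjust_method)

  structure(list(responses = tab,
                 summaries = summaries,
                 filter_log = list(removed_responses = rt_filter$removed,
                                   excluded_participants =
                                     summaries[summaries$excluded, ]),
                 learning_curves = learning_curves,
                 breakdown = breakdown,
                 consistency_test = consistency_test,
                 accuracy_test = accuracy_test,
                 rt_test = rt_test,
                 learning_test = learning_test,
                 inversion_share_test = inversion_share_test,
                 intersegment_test = intersegment_test,
                 min_distance_test = min_distance_test,
                 config = config,
                 params = list(rt_cutoff = rt_cutoff,
                               consistency_threshold = consistency_threshold,
                               alpha = alpha,
                               adjust_method = adjust_method)),
            class = "layout_study")
}

.layout_means <- function(x) {
  kept <- x$summaries[!x$summaries$excluded, ]
  layouts <- unique(kept$layout)
  do.call(rbind, lapply(layouts, function(ly) {
    sub <- x$responses[x$responses$layout == ly, ]
    data.frame(layout = ly,
               n_participants = sum(kept$layout == ly),
               consistency = mean(kept$consistency[kept$layout == ly]),
               accuracy = mean(sub$error_class == "correct"),
               mean_rt = mean(sub$rt_seconds))
  }))
}

#' @export
print.layout_study <- function(x, ...) {
  cat("Layout perception study analysis\n")
  cat(sprintf("  %d responses retained (%d removed as outliers, %d participants excluded)\n",
              nrow(x$responses), nrow(x$filter_log$removed_responses),
              nrow(x$filter_log$excluded_participants)))
  lm <- .layout_means(x)
  cat("  per-layout means:\n")
  for (i in seq_len(nrow(lm)))
    cat(sprintf("    %-12s n=%-3d consistency %.3f  accuracy %.3f  rt %.2fs\n",
                lm$layout[i], lm$n_participants[i], lm$consistency[i],
                lm$accuracy[i], lm$mean_rt[i]))
  sig <- function(tr) paste0(sum(tr$significant), "/", nrow(tr))
  cat(sprintf("  significant pairwise contrasts (alpha=%.2f): consistency %s, accuracy %s, rt %s\n",
              x$params$alpha, sig(x$consistency_test$pairwise),
              sig(x$accuracy_test), sig(x$rt_test$pairwise)))
  invisible(x)
}

#' @export
summary.layout_study <- function(object, ...) {
  x <- object
  print(x)
  cat("\nError breakdown (fractions of incorrect answers):\n")
  print(x$breakdown$class_fractions, row.names = FALSE)
  cat("\nConsistency ANOVA + Tukey:\n")
  print(rbind(x$consistency_test$omnibus, x$consistency_test$pairwise),
        row.names = FALSE)
  cat("\nAccuracy pairwise chi-squared:\n")
  print(x$accuracy_test, row.names = FALSE)
  cat("\nResponse-time ANOVA + Tukey:\n")
  print(rbind(x$rt_test$omnibus, x$rt_test$pairwise), row.names = FALSE)
  cat("\nInversion share pairwise chi-squared:\n")
  print(x$inversion_share_test, row.names = FALSE)
  if (!is.null(x$intersegment_test)) {
    cat("\nInter-segment distance Kruskal-Wallis + Dunn (errors only):\n")
    print(rbind(x$intersegment_test$omnibus, x$intersegment_test$pairwise),
          row.names = FALSE)
  }
  cat("\nMinDistance Kruskal-Wallis + Dunn (all answers):\n")
  print(rbind(x$min_distance_test$omnibus, x$min_distance_test$pairwise),
        row.names = FALSE)
  invisible(x)
}

#' Plot a study analysis
#'
#' Four panels: per-participant consistency by layout, accuracy by layout,
#' response times by layout on a log scale, and the per-layout learning
#' curves.
#'
#' @param x A `layout_study` object.
#' @param ... Passed to [graphics::boxplot()].
#' @return `x`, invisibly.
#' @export
plot.layout_study <- function(x, ...) {
  kept <- x$summaries[!x$summaries$excluded, ]
  lm <- .layout_means(x)
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::boxplot(consistency ~ layout, data = kept,
                    main = "Consistency", ylab = "consistency score", ...)
  graphics::barplot(stats::setNames(lm$accuracy, lm$layout),
                    main = "Accuracy", ylab = "fraction correct",
                    ylim = c(0, 1))
  graphics::boxplot(rt_seconds ~ layout, data = x$responses, log = "y",
                    main = "Response time", ylab = "seconds (log)", ...)
  curves <- x$learning_curves
  rng <- range(unlist(lapply(curves, function(cv) cv$mean_rt)))
  graphics::plot(NULL, xlim = c(1, max(vapply(curves, nrow, integer(1)))),
                 ylim = rng, xlab = "question", ylab = "mean rt (s)",
                 main = "Learning curves")
  for (i in seq_along(curves))
    graphics::lines(curves[[i]]$question_rank, curves[[i]]$mean_rt,
                    col = i, lwd = 2)
  graphics::legend("topright", legend = names(curves), col = seq_along(curves),
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(x)
}

#' Write the report bundle
#'
#' Exports the analysis as CSV tables (one per test family, plus participant
#' summaries, learning curves and the error breakdown), an SVG figure with
#' the four overview panels, and a plain-text summary. File names are stable.
#'
#' @param x A `layout_study` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "layout_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(dir, name)
  w <- function(df, name) utils::write.csv(df, out(name), row.names = FALSE)
  w(x$summaries, "participant_summaries.csv")
  w(x$breakdown$class_fractions, "error_breakdown.csv")
  w(rbind(x$consistency_test$omnibus, x$consistency_test$pairwise),
    "consistency_tests.csv")
  w(x$accuracy_test, "accuracy_tests.csv")
  w(rbind(x$rt_test$omnibus, x$rt_test$pairwise), "response_time_tests.csv")
  w(rbind(x$learning_test$omnibus, x$learning_test$pairwise),
    "learning_tests.csv")
  w(x$inversion_share_test, "inversion_share_tests.csv")
  if (!is.null(x$intersegment_test))
    w(rbind(x$intersegment_test$omnibus, x$intersegment_test$pairwise),
      "intersegment_tests.csv")
  w(rbind(x$min_distance_test$omnibus, x$min_distance_test$pairwise),
    "min_distance_tests.csv")
  curves <- do.call(rbind, lapply(names(x$learning_curves), function(ly) {
    cbind(layout = ly, x$learning_curves[[ly]])
  }))
  w(curves, "learning_curves.csv")
  grDevices::svg(out("overview.svg"), width = 9, height = 7)
  plot(x)
  grDevices::dev.off()
  con <- file(out("summary.txt"), open = "wt")
  sink(con)
  on.exit({ sink(); close(con) }, add = TRUE)
  summary(x)
  invisible(dir)
}
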