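# Inferential battery: one-way ANOVA with Tukey HSD, pairwise Pearson
# chi-squared tests of independence, Kruskal-Wallis with Dunn post hoc, and
# multiple-testing adjustment. Each test family returns rows in a common
# TestResult layout.

.test_result <- function(method, comparison, statistic, df, p_raw,
                         p_adjusted, alpha) {
  data.frame(method = method, comparison = comparison,
             statistic = statistic, df = df, p_raw = p_raw,
             p_adjusted = p_adjusted,
             significant = !is.na(p_adjusted) & p_adjusted < alpha,
             stringsAsFactors = FALSE)
}

#' Multiple-testing adjustment
#'
#' Thin wrapper over [stats::p.adjust()] restricted to the methods the
#' pipeline exposes; Benjamini-Hochberg step-up by default.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"bh"`, `"holm"` or `"bonferroni"`.
#' @return Adjusted p-values, never below the raw ones.
#' @export
adjust_pvalues <- function(p, method = c("bh", "holm", "bonferroni")) {
  method <- match.arg(method)
  ok <- is.na(p) | (p >= 0 & p <= 1)
  if (!all(ok))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = c(bh = "BH", holm = "holm",
                                bonferroni = "bonferroni")[[method]])
}

.group_list <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  lapply(groups, function(g) g[is.finite(g)])
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' Omnibus F test across the groups followed by all-pairs Tukey honest
#' significant difference comparisons; the pairwise rows carry the
#' Tukey-adjusted p-values (no further adjustment is applied on top). The
#' degenerate case of zero variance everywhere with equal means reports
#' F = 0, p = 1.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @param alpha Significance level for the `significant` flag.
#' @return List with `omnibus` and `pairwise` TestResult data frames and the
#'   fitted `aov` object.
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  groups <- .group_list(groups)
  stopifnot(all(vapply(groups, length, integer(1)) >= 2L))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  df1 <- nlevels(g) - 1L
  df2 <- length(values) - nlevels(g)
  pair_names <- utils::combn(names(groups), 2L,
                             function(x) paste(x[2], "-", x[1]))
  if (stats::var(values) == 0) {  # all values identical across all groups
    omni <- .test_result("anova", "omnibus", 0, paste(df1, df2, sep = ","),
                         1, 1, alpha)
    pw <- .test_result("tukey_hsd", pair_names, 0,
                       paste(df1, df2, sep = ","), 1, 1, alpha)
    return(list(omnibus = omni, pairwise = pw, fit = NULL))
  }
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1]]
  fstat <- an[["F value"]][1]
  p <- an[["Pr(>F)"]][1]
  if (is.na(fstat)) { fstat <- 0; p <- 1 }  # zero residual variance, equal means
  omni <- .test_result("anova", "omnibus", fstat,
                       paste(df1, df2, sep = ","), p, p, alpha)
  tk <- stats::TukeyHSD(fit)$g
  pw <- .test_result("tukey_hsd", rownames(tk), tk[, "diff"],
                     paste(df1, df2, sep = ","), NA_real_, tk[, "p adj"],
                     alpha)
  list(omnibus = omni, pairwise = pw, fit = fit)
}

#' Pairwise Pearson chi-squared tests of independence
#'
#' One 2x2 Pearson chi-squared test (no continuity correction) per pair of
#' groups on success/failure counts, with the p-values adjusted across the
#' pairs. Pairs with a zero margin are reported with `NA` statistics.
#'
#' @param counts Data frame or matrix with one row per group: columns
#'   `success` and `failure` (or the first two columns), rownames or a
#'   `group` column naming the groups.
#' @param alpha Significance level.
#' @param method Adjustment method for [adjust_pvalues()].
#' @return TestResult data frame, one row per group pair.
#' @export
pairwise_chi2 <- function(counts, alpha = 0.05, method = "bh") {
  if (is.data.frame(counts) && "group" %in% names(counts)) {
    rownames(counts) <- counts$group
    counts <- counts[, setdiff(names(counts), "group"), drop = FALSE]
  }
  m <- as.matrix(counts[, 1:2])
  if (is.null(rownames(m))) rownames(m) <- paste0("group", seq_len(nrow(m)))
  pairs <- utils::combn(rownames(m), 2L, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    tab <- m[pr, , drop = FALSE]
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      return(.test_result("pearson_chi2", paste(pr, collapse = " vs "),
                          NA_real_, NA_character_, NA_real_, NA_real_,
                          alpha))
    }
    # small expected counts are allowed; the Pearson statistic is reported
    # as-is, so the stock low-count warning is silenced deliberately
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    .test_result("pearson_chi2", paste(pr, collapse = " vs "),
                 unname(ct$statistic), as.character(unname(ct$parameter)),
                 ct$p.value, NA_real_, alpha)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- adjust_pvalues(out$p_raw, method)
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out
}

#' Dunn post hoc z tests
#'
#' Tie-corrected Dunn pairwise comparisons on the pooled ranks, the standard
#' post hoc companion of the Kruskal-Wallis test. For each pair of groups
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' with `T = sum(t^3 - t)` over tie groups; two-sided normal p-values.
#'
#' @param groups Named list of numeric vectors.
#' @param alpha Significance level.
#' @param method Adjustment method across the pairs.
#' @return TestResult data frame, one row per group pair.
#' @export
dunn_test <- function(groups, alpha = 0.05, method = "bh") {
  groups <- .group_list(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, integer(1)))
  n_tot <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_sum <- sum(ties^3 - ties)
  var_term <- n_tot * (n_tot + 1) / 12 - tie_sum / (12 * (n_tot - 1))
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  pairs <- utils::combn(names(groups), 2L, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    se <- sqrt(var_term * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    z <- if (se == 0) 0 else (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
    p <- if (se == 0) 1 else 2 * stats::pnorm(-abs(z))
    .test_result("dunn", paste(pr, collapse = " vs "), z, NA_character_,
                 p, NA_real_, alpha)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- adjust_pvalues(out$p_raw, method)
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out
}

#' Kruskal-Wallis omnibus with Dunn post hoc
#'
#' Tie-corrected Kruskal-Wallis rank test across the groups followed by
#' [dunn_test()] pairwise comparisons. When every value is identical the
#' omnibus reports H = 0, p = 1.
#'
#' @inheritParams dunn_test
#' @return List with `omnibus` and `pairwise` TestResult data frames.
#' @export
kruskal_dunn <- function(groups, alpha = 0.05, method = "bh") {
  groups <- .group_list(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))))
  df <- nlevels(g) - 1L
  if (length(unique(values)) == 1L) {
    omni <- .test_result("kruskal_wallis", "omnibus", 0, as.character(df),
                         1, 1, alpha)
    pw <- dunn_test(groups, alpha, method)
    return(list(omnibus = omni, pairwise = pw))
  }
  kt <- stats::kruskal.test(values, g)
  omni <- .test_result("kruskal_wallis", "omnibus", unname(kt$statistic),
                       as.character(unname(kt$parameter)), kt$p.value,
                       kt$p.value, alpha)
  list(omnibus = omni, pairwise = dunn_test(groups, alpha, method))
}
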