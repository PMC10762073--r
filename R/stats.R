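#' Build the ROI-level analysis frame
#'
#' Extracts the per-ROI outcome and design columns expected by the nested
#' and mixed-effects tests. ROIs with a missing outcome are dropped.
#'
#' @param summaries ROI summary data frame ([bind_summaries()], typically
#'   after [qc_filter()]).
#' @param outcome_col Name of the outcome column (e.g. `pct_fos_chat_only`).
#' @return Data frame with columns `roi`, `mouse`, `sex`, `treatment`,
#'   `dose`, `day`, `region` (those present) and `outcome`.
#' @export
stats_frame <- function(summaries, outcome_col = "pct_fos_chat_only") {
  if (is.null(summaries[[outcome_col]]))
    stop("no column ", outcome_col, " in summaries", call. = FALSE)
  keep <- intersect(c("roi", "mouse", "sex", "treatment", "dose", "day",
                      "region"), names(summaries))
  out <- summaries[, keep, drop = FALSE]
  out$outcome <- summaries[[outcome_col]]
  out <- out[is.finite(out$outcome), , drop = FALSE]
  if (!is.null(out$roi) && anyDuplicated(out$roi))
    stop("duplicate ROI identifiers", call. = FALSE)
  rownames(out) <- NULL
  out
}

# mouse-level means, group assignment and ROI counts
mouse_means <- function(data, factor_col, outcome_col = "outcome",
                        mouse_col = "mouse") {
  mm <- aggregate(data[[outcome_col]],
                  by = list(mouse = data[[mouse_col]],
                            group = as.character(data[[factor_col]])),
                  FUN = mean)
  names(mm)[3] <- "mean"
  cnt <- aggregate(data[[outcome_col]],
                   by = list(mouse = data[[mouse_col]]), FUN = length)
  mm$n_roi <- cnt$x[match(mm$mouse, cnt$mouse)]
  if (anyDuplicated(mm$mouse))
    stop("a mouse appears in more than one group", call. = FALSE)
  mm
}

#' Nested one-way ANOVA (ROIs nested in mice)
#'
#' Tests a group effect on an ROI-level outcome while treating ROIs as
#' non-independent replicates within mice: the error term is the
#' mouse-within-group mean square, with denominator degrees of freedom based
#' on the number of mice, not ROIs. On balanced data (equal ROIs per mouse
#' and mice per group) the F statistic is computed from expected mean
#' squares and equals the ordinary one-way ANOVA on mouse means; unbalanced
#' data fall back to a linear mixed model (random mouse intercept) with
#' Satterthwaite denominator degrees of freedom.
#'
#' @param data A [stats_frame()] restricted to one sex and region.
#' @param factor_col Grouping column (`"treatment"`, `"dose"`, `"day"`, ...).
#' @param outcome_col,mouse_col Column names.
#' @return Object of class `nested_anova`: `statistic` (F), `df` (num,
#'   den), `p.value`, `means` (per-group ROI-level mean +/- SEM),
#'   `mouse_means`, `ms_error` and `df_error` on the mouse-mean scale
#'   (used by [tukey_hsd()]), `method`.
#' @export
nested_oneway <- function(data, factor_col = "treatment",
                          outcome_col = "outcome", mouse_col = "mouse") {
  grp <- as.character(data[[factor_col]])
  levels_ <- unique(grp)
  k <- length(levels_)
  if (k < 2) stop("need >= 2 groups", call. = FALSE)
  mm <- mouse_means(data, factor_col, outcome_col, mouse_col)
  mice_per_group <- table(mm$group)
  if (any(mice_per_group < 2))
    stop("need >= 2 mice per group (mouse-level error term undefined)",
         call. = FALSE)
  M <- nrow(mm)

  y <- data[[outcome_col]]
  balanced <- length(unique(mm$n_roi)) == 1 &&
    length(unique(as.vector(mice_per_group))) == 1

  # error term on the mouse-mean scale (always available; drives Tukey HSD)
  gm <- tapply(mm$mean, mm$group, mean)
  ss_err_mm <- sum((mm$mean - gm[mm$group])^2)
  ms_error_mm <- ss_err_mm / (M - k)

  if (balanced) {
    ybar <- mean(y)
    g_of_roi <- grp
    ybar_g <- tapply(y, g_of_roi, mean)
    ybar_m <- tapply(y, data[[mouse_col]], mean)
    g_of_mouse <- mm$group[match(names(ybar_m), mm$mouse)]
    n_g <- table(g_of_roi)
    r_m <- table(data[[mouse_col]])
    ss_group <- sum(n_g * (ybar_g - ybar)^2)
    ss_mouse <- sum(r_m * (ybar_m - ybar_g[g_of_mouse])^2)
    df1 <- k - 1; df2 <- M - k
    if (ss_mouse == 0) {
      f <- if (ss_group == 0) 0 else Inf
    } else {
      f <- (ss_group / df1) / (ss_mouse / df2)
    }
    p <- if (is.infinite(f)) 0 else pf(f, df1, df2, lower.tail = FALSE)
    method <- "nested one-way ANOVA (expected mean squares, balanced)"
  } else {
    data$..g <- factor(grp)
    data$..m <- factor(data[[mouse_col]])
    fit <- lmerTest::lmer(stats::reformulate(c("..g", "(1 | ..m)"),
                                             response = outcome_col),
                          data = data)
    an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
    f <- an$`F value`[1]; df1 <- an$NumDF[1]; df2 <- an$DenDF[1]
    p <- an$`Pr(>F)`[1]
    method <- "nested one-way ANOVA (mixed model, Satterthwaite df)"
  }

  means <- data.frame(
    group = names(tapply(y, grp, mean)),
    mean = as.vector(tapply(y, grp, mean)),
    sem = as.vector(tapply(y, grp, function(v) sd(v) / sqrt(length(v)))),
    n_roi = as.vector(table(grp)),
    n_mice = as.vector(mice_per_group[names(tapply(y, grp, mean))]))
  structure(list(statistic = f, df = c(df1, df2), p.value = p,
                 means = means, mouse_means = mm,
                 ms_error = ms_error_mm, df_error = M - k,
                 factor = factor_col, method = method),
            class = "nested_anova")
}

#' @export
print.nested_anova <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("F(%g, %g) = %.4g, P = %.4g\n",
              x$df[1], x$df[2], x$statistic, x$p.value))
  print(x$means, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Nested t-test (two groups, ROIs nested in mice)
#'
#' The two-group special case of [nested_oneway()]: t is the signed square
#' root of the nested F (sign of the first-minus-second group mean
#' difference), with the mouse-level denominator degrees of freedom and a
#' two-sided p-value.
#'
#' @inheritParams nested_oneway
#' @param order Optional character(2) giving the group order for the sign of
#'   the difference (default: order of appearance).
#' @return Object of class `nested_ttest` with `statistic` (t), `df`,
#'   `p.value`, `estimate` (mean difference), `means`, `anova` (the
#'   underlying `nested_anova`).
#' @export
nested_ttest <- function(data, factor_col = "treatment",
                         outcome_col = "outcome", mouse_col = "mouse",
                         order = NULL) {
  levels_ <- unique(as.character(data[[factor_col]]))
  if (length(levels_) != 2) stop("nested t-test needs exactly 2 groups",
                                 call. = FALSE)
  if (!is.null(order)) {
    if (!setequal(order, levels_)) stop("`order` must name the two groups",
                                        call. = FALSE)
    levels_ <- order
  }
  an <- nested_oneway(data, factor_col, outcome_col, mouse_col)
  m <- setNames(an$means$mean, an$means$group)
  diff <- m[levels_[1]] - m[levels_[2]]
  t <- sign(diff) * sqrt(an$statistic)
  p <- 2 * pt(-abs(t), an$df[2])
  structure(list(statistic = unname(t), df = an$df[2], p.value = unname(p),
                 estimate = unname(diff), groups = levels_,
                 means = an$means, anova = an),
            class = "nested_ttest")
}

#' @export
print.nested_ttest <- function(x, ...) {
  cat(sprintf("nested t-test (%s vs %s): t(%g) = %.4g, P = %.4g\n",
              x$groups[1], x$groups[2], x$df, x$statistic, x$p.value))
  print(x$means, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tukey HSD post-hoc comparisons for a nested ANOVA
#'
#' All pairwise group comparisons using the studentized range distribution
#' with the nested (mouse-within-group) error term: comparisons are made on
#' mouse means, with the pooled within-group variance of mouse means as the
#' error mean square and mouse-level degrees of freedom. Unequal group sizes
#' use the Tukey-Kramer standard error.
#'
#' @param fit A `nested_anova` (with >= 3 groups; for 2 groups use
#'   [nested_ttest()]).
#' @return Data frame: `group1`, `group2`, `diff` (mouse-mean difference),
#'   `se`, `q` (studentized range statistic), `p.adj`.
#' @export
tukey_hsd <- function(fit) {
  stopifnot(inherits(fit, "nested_anova"))
  mm <- fit$mouse_means
  groups <- sort(unique(mm$group))
  k <- length(groups)
  if (k < 3)
    stop("omnibus has fewer than 3 levels; use nested_ttest()", call. = FALSE)
  gm <- tapply(mm$mean, mm$group, mean)
  n <- table(mm$group)
  cmb <- utils::combn(groups, 2)
  out <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ])
  out$diff <- gm[out$group1] - gm[out$group2]
  out$se <- sqrt(fit$ms_error / 2 * (1 / n[out$group1] + 1 / n[out$group2]))
  out$q <- abs(out$diff) / out$se
  out$p.adj <- ptukey(out$q, nmeans = k, df = fit$df_error,
                      lower.tail = FALSE)
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected pairwise t-tests on mouse means
#'
#' Planned pairwise comparisons with a pooled error: the pooled
#' within-group variance of mouse means across all groups (mouse-level
#' degrees of freedom), with p-values multiplied by the number of requested
#' pairs (capped at 1).
#'
#' @param data A [stats_frame()].
#' @param pairs List of character(2) group labels to compare.
#' @param factor_col,outcome_col,mouse_col Column names.
#' @return Data frame: `group1`, `group2`, `diff`, `t`, `df`, `p`, `p.adj`.
#' @export
pairwise_corrected_t <- function(data, pairs, factor_col = "treatment",
                                 outcome_col = "outcome",
                                 mouse_col = "mouse") {
  mm <- mouse_means(data, factor_col, outcome_col, mouse_col)
  groups <- unique(mm$group)
  k <- length(groups)
  bad <- setdiff(unlist(pairs), groups)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  gm <- tapply(mm$mean, mm$group, mean)
  n <- table(mm$group)
  dfe <- nrow(mm) - k
  mse <- sum((mm$mean - gm[mm$group])^2) / dfe
  out <- do.call(rbind, lapply(pairs, function(pr) {
    diff <- gm[pr[1]] - gm[pr[2]]
    se <- sqrt(mse * (1 / n[pr[1]] + 1 / n[pr[2]]))
    t <- if (se == 0) 0 else diff / se
    p <- 2 * pt(-abs(t), dfe)
    data.frame(group1 = pr[1], group2 = pr[2], diff = unname(diff),
               t = unname(t), df = dfe, p = unname(p))
  }))
  out$p.adj <- pmin(1, out$p * length(pairs))
  rownames(out) <- NULL
  out
}

#' Fixed-effects mixed model for sex x treatment with a random mouse effect
#'
#' Fits `outcome ~ sex * treatment + (1 | mouse)` with sum-to-zero contrasts
#' and reports Type III F tests with Satterthwaite denominator degrees of
#' freedom (fractional, mouse-informed). A qualitative sex difference is
#' flagged when the interaction is significant (p < 0.05) and the simple
#' treatment effects (last vs first treatment level, on mouse means) have
#' opposite signs in males and females — the condition under which
#' downstream analyses should be run separately by sex.
#'
#' @param data A [stats_frame()] containing both sexes and >= 2 treatments.
#' @param outcome_col,mouse_col Column names.
#' @param alpha Significance threshold for the interaction (default 0.05).
#' @return Object of class `mixed_model_result`: `table` (effect, F, df1,
#'   df2, p), `qualitative_sex_difference`, `simple_effects` (per-sex
#'   last-minus-first treatment differences), `singular`, `fit`.
#' @export
mixed_model_sex_treatment <- function(data, outcome_col = "outcome",
                                      mouse_col = "mouse", alpha = 0.05) {
  if (length(unique(data$sex)) < 2) stop("both sexes required", call. = FALSE)
  if (length(unique(data$treatment)) < 2)
    stop(">= 2 treatments required", call. = FALSE)
  d <- data
  d$sex <- factor(d$sex)
  d$treatment <- factor(d$treatment, levels = unique(as.character(d$treatment)))
  d$..m <- factor(d[[mouse_col]])
  d$..y <- d[[outcome_col]]

  trt_levels <- levels(d$treatment)
  eff <- vapply(levels(d$sex), function(s) {
    mm <- mouse_means(d[d$sex == s, ], "treatment", "..y", "..m")
    gm <- tapply(mm$mean, mm$group, mean)
    unname(gm[trt_levels[length(trt_levels)]] - gm[trt_levels[1]])
  }, numeric(1))

  if (var(d$..y) == 0) {
    tab <- data.frame(effect = c("sex", "treatment", "sex:treatment"),
                      F = 0, df1 = NA_real_, df2 = NA_real_, p = 1)
    return(structure(list(table = tab, qualitative_sex_difference = FALSE,
                          simple_effects = eff, singular = TRUE, fit = NULL),
                     class = "mixed_model_result"))
  }

  fit <- lmerTest::lmer(
    ..y ~ sex * treatment + (1 | ..m), data = d,
    contrasts = list(sex = "contr.sum", treatment = "contr.sum"))
  an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
  tab <- data.frame(effect = rownames(an), F = an$`F value`,
                    df1 = an$NumDF, df2 = an$DenDF, p = an$`Pr(>F)`)
  tab$effect <- sub("^sex:treatment$", "sex:treatment", tab$effect)
  p_int <- tab$p[tab$effect == "sex:treatment"]
  qualitative <- length(p_int) == 1 && is.finite(p_int) && p_int < alpha &&
    length(eff) == 2 && prod(eff) < 0
  structure(list(table = tab, qualitative_sex_difference = qualitative,
                 simple_effects = eff, singular = lme4::isSingular(fit),
                 fit = fit),
            class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat("mixed model: outcome ~ sex * treatment + (1 | mouse), Type III,",
      "Satterthwaite df\n")
  for (i in seq_len(nrow(x$table)))
    cat(sprintf("  F_%s(%g, %.1f) = %.4g, P = %.4g\n", x$table$effect[i],
                x$table$df1[i], x$table$df2[i], x$table$F[i], x$table$p[i]))
  if (isTRUE(x$singular)) cat("  note: singular fit (random-effect variance ~ 0)\n")
  cat("  qualitative sex difference:",
      if (isTRUE(x$qualitative_sex_difference)) "YES (analyze sexes separately)"
      else "no", "\n")
  invisible(x)
}

#' One-sample t-test
#'
#' Standard one-sample t-test of a mean against `mu0` (e.g. body-weight
#' change against zero).
#'
#' @param values Numeric vector (n >= 2, non-zero variance).
#' @param mu0 Null mean (default 0).
#' @return An object of class `htest` from [stats::t.test()].
#' @export
one_sample_t <- function(values, mu0 = 0) {
  if (length(values) < 2) stop("need n >= 2", call. = FALSE)
  if (sd(values) == 0) stop("zero variance", call. = FALSE)
  stats::t.test(values, mu = mu0)
}

#' Fold change between two group means
#'
#' @param mean_a,mean_b Group means; `mean_b` must be > 0.
#' @return The ratio `mean_a / mean_b` (report rounded to 1 decimal).
#' @examples
#' round(fold_change(38.9, 16.8), 1)  # 2.3
#' @export
fold_change <- function(mean_a, mean_b) {
  if (any(mean_b <= 0)) stop("denominator mean must be > 0", call. = FALSE)
  mean_a / mean_b
}
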