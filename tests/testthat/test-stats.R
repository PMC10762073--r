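test_that("nested one-way ANOVA equals ordinary ANOVA on mouse means", {
  # mouse means {10, 20} vs {30, 40}, no ROI noise:
  # group means 15, 35; SSb = 2*100 + 2*100 = 400 (df 1)
  # SSw on mouse means = 25*4 = 100 (df 2)  ->  F = 400 / 50 = 8
  d <- make_nested_data(c(0, 0), m = 2, r = 3,
                        mouse_means = list(c(10, 20), c(30, 40)))
  an <- nested_oneway(d)
  expect_equal(an$statistic, 8)
  expect_equal(an$df, c(1, 2))
  expect_equal(an$p.value, pf(8, 1, 2, lower.tail = FALSE))

  # with ROI noise the balanced EMS route still matches aov on mouse means
  set.seed(12)
  d2 <- make_nested_data(c(10, 14, 20), m = 4, r = 4, sd_mouse = 3, sd_roi = 5)
  an2 <- nested_oneway(d2)
  mm <- aggregate(outcome ~ mouse + treatment, d2, mean)
  fit <- anova(stats::lm(outcome ~ treatment, mm))
  expect_equal(an2$statistic, fit$`F value`[1], tolerance = 1e-9)
  expect_equal(an2$df, c(fit$Df[1], fit$Df[2]))
})

test_that("identical groups give F = 0 and p = 1", {
  d <- make_nested_data(c(0, 0), m = 3, r = 2,
                        mouse_means = list(c(5, 6, 7), c(5, 6, 7)))
  an <- nested_oneway(d)
  expect_equal(an$statistic, 0, tolerance = 1e-12)
  expect_equal(an$p.value, 1, tolerance = 1e-9)
})

test_that("one mouse per group is rejected", {
  d <- make_nested_data(c(1, 2), m = 1, r = 4, sd_roi = 1)
  expect_error(nested_oneway(d), "2 mice")
})

test_that("unbalanced data fall back to the mixed model", {
  set.seed(3)
  d <- make_nested_data(c(10, 18), m = 4, r = 3, sd_mouse = 2, sd_roi = 4)
  d <- d[-c(1, 14), ]  # drop ROIs to unbalance
  an <- nested_oneway(d)
  expect_match(an$method, "mixed model")
  expect_true(is.finite(an$statistic) && is.finite(an$p.value))
  expect_lt(an$df[2], nrow(d))  # denominator df near the mouse count, not ROI count
})

test_that("nested t equals the signed root of nested F", {
  set.seed(21)
  d <- make_nested_data(c(30, 20), m = 4, r = 4, sd_mouse = 3, sd_roi = 4)
  tt <- nested_ttest(d)
  an <- nested_oneway(d)
  expect_equal(tt$statistic^2, an$statistic, tolerance = 1e-9)
  expect_equal(tt$df, an$df[2])
  # sign follows the group order: g1 mean > g2 mean here
  expect_gt(tt$statistic, 0)
  expect_equal(nested_ttest(d, order = c("g2", "g1"))$statistic,
               -tt$statistic, tolerance = 1e-12)
  # equal group means -> t = 0
  d0 <- make_nested_data(c(0, 0), m = 2, r = 2,
                         mouse_means = list(c(4, 8), c(4, 8)))
  expect_equal(nested_ttest(d0)$statistic, 0)
  expect_error(nested_ttest(make_nested_data(c(1, 2, 3), m = 2, r = 2)),
               "exactly 2")
})

test_that("p-values are invariant to mouse relabeling and row order", {
  set.seed(8)
  d <- make_nested_data(c(10, 16), m = 4, r = 3, sd_mouse = 2, sd_roi = 3)
  p0 <- nested_ttest(d)$p.value
  perm <- d[sample(nrow(d)), ]
  expect_equal(nested_ttest(perm)$p.value, p0, tolerance = 1e-12)
  relab <- d
  relab$mouse <- paste0("zz_", relab$mouse)
  expect_equal(nested_ttest(relab)$p.value, p0, tolerance = 1e-12)
})

test_that("Tukey HSD uses the studentized range on the nested error term", {
  # mouse means: g1 {10,12}, g2 {20,22}, g3 {30,32}
  # group means 11, 21, 31; MSE = sum((+-1)^2)/3 = 2, df = 3
  # q(g1,g2) = 10 / sqrt(2/2 * (1/2 + 1/2)) = 10
  d <- make_nested_data(c(0, 0, 0), m = 2, r = 2,
                        mouse_means = list(c(10, 12), c(20, 22), c(30, 32)))
  an <- nested_oneway(d)
  expect_equal(an$ms_error, 2)
  expect_equal(an$df_error, 3)
  hsd <- tukey_hsd(an)
  expect_equal(nrow(hsd), 3)
  q12 <- hsd$q[hsd$group1 == "g1" & hsd$group2 == "g2"]
  expect_equal(q12, 10, tolerance = 1e-12)
  expect_equal(hsd$p.adj[hsd$group1 == "g1" & hsd$group2 == "g2"],
               ptukey(10, 3, 3, lower.tail = FALSE), tolerance = 1e-12)
  # adjusted p >= the unadjusted pairwise p for every pair
  pw <- pairwise_corrected_t(d, pairs = list(c("g1", "g2"), c("g1", "g3"),
                                             c("g2", "g3")))
  expect_true(all(hsd$p.adj >= pw$p - 1e-12))
  # identical groups -> all adjusted p ~ 1
  d0 <- make_nested_data(c(0, 0, 0), m = 2, r = 2,
                         mouse_means = list(c(5, 7), c(5, 7), c(5, 7)))
  expect_true(all(tukey_hsd(nested_oneway(d0))$p.adj >= 0.999))
  expect_error(tukey_hsd(nested_oneway(make_nested_data(c(1, 5), m = 2, r = 2,
    mouse_means = list(c(1, 2), c(5, 6))))), "nested_ttest")
})

test_that("pairwise corrected t matches a pooled-error oracle on a 2x3 toy", {
  d <- make_nested_data(c(0, 0, 0), m = 2, r = 2,
                        mouse_means = list(c(10, 12), c(20, 22), c(30, 32)))
  pw <- pairwise_corrected_t(d, pairs = list(c("g1", "g2"), c("g2", "g3")))
  # oracle: MSE = 2 (df 3), se = sqrt(2 * (1/2 + 1/2)) = sqrt(2)
  t_expect <- -10 / sqrt(2)
  expect_equal(pw$t, c(t_expect, t_expect), tolerance = 1e-12)
  p_raw <- 2 * pt(-abs(t_expect), 3)
  expect_equal(pw$p, rep(p_raw, 2), tolerance = 1e-12)
  expect_equal(pw$p.adj, pmin(1, rep(p_raw * 2, 2)), tolerance = 1e-12)
  # identical groups -> p = 1; correction caps at 1
  d0 <- make_nested_data(c(0, 0), m = 2, r = 2,
                         mouse_means = list(c(5, 7), c(5, 7)))
  pw0 <- pairwise_corrected_t(d0, pairs = list(c("g1", "g2")))
  expect_equal(pw0$p.adj, 1)
  expect_error(pairwise_corrected_t(d, pairs = list(c("g1", "nope"))),
               "unknown")
})

test_that("the sex x treatment mixed model matches two-way ANOVA when the mouse effect is nil", {
  # balanced 2x2, two ROIs per mouse, data generated with no mouse effect;
  # the seed is chosen so the variance estimate sits on the zero boundary,
  # where the Satterthwaite F must coincide with ordinary least squares
  set.seed(6)
  d <- expand.grid(rep = 1:2, m = 1:4, sex = c("M", "F"),
                   treatment = c("saline", "etoh"))
  d$mouse <- sprintf("m_%s_%s_%d", d$sex, d$treatment, d$m)
  d$roi <- sprintf("r%03d", seq_len(nrow(d)))
  d$outcome <- rnorm(nrow(d), 20, 4) +
    ifelse(d$sex == "M" & d$treatment == "etoh", 10, 0)
  res <- suppressMessages(mixed_model_sex_treatment(d))
  ref <- car::Anova(stats::lm(outcome ~ sex * treatment, data = d,
                              contrasts = list(sex = "contr.sum",
                                               treatment = "contr.sum")),
                    type = 3)
  for (eff in c("sex", "treatment", "sex:treatment")) {
    expect_equal(res$table$F[res$table$effect == eff],
                 ref[eff, "F value"], tolerance = 1e-6)
  }
  expect_true(res$singular)  # zero random-effect variance is reported
})

test_that("constant outcomes short-circuit to F = 0, p = 1", {
  d <- expand.grid(rep = 1:3, sex = c("M", "F"), treatment = c("a", "b"))
  d$mouse <- sprintf("m%02d", seq_len(nrow(d)))
  d$outcome <- 5
  res <- mixed_model_sex_treatment(d)
  expect_true(all(res$table$F == 0))
  expect_true(all(res$table$p == 1))
})

test_that("opposite-direction treatment effects are flagged as qualitative", {
  # males +20 points under treatment, females -15: the interaction should be
  # detected and the sign reversal recognised in nearly every replicate
  sim_once <- function(seed) {
    set.seed(seed)
    rows <- list()
    mi <- 0
    for (sex in c("M", "F")) for (trt in c("saline", "etoh"))
      for (j in 1:4) {
        mi <- mi + 1
        mu <- 20 + ifelse(trt == "etoh", ifelse(sex == "M", 20, -15), 0) +
          rnorm(1, 0, 3)
        for (r in 1:5) {
          rows[[length(rows) + 1]] <- data.frame(
            roi = sprintf("r%d_%d", mi, r), mouse = sprintf("m%02d", mi),
            sex = sex, treatment = trt, outcome = mu + rnorm(1, 0, 5))
        }
      }
    mixed_model_sex_treatment(do.call(rbind, rows))
  }
  hits <- vapply(1:60, function(s) {
    r <- sim_once(s)
    isTRUE(r$qualitative_sex_difference)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # simple effects carry the injected signs
  r <- sim_once(1)
  expect_gt(r$simple_effects[["M"]], 0)
  expect_lt(r$simple_effects[["F"]], 0)
})

test_that("one-sample t matches its closed form and flips with the sign", {
  v <- c(-2, -1, -1, 0)
  r <- one_sample_t(v, 0)
  expect_equal(unname(r$statistic), -sqrt(6), tolerance = 1e-12)
  r2 <- one_sample_t(-v, 0)
  expect_equal(unname(r2$statistic), sqrt(6), tolerance = 1e-12)
  expect_equal(r$p.value, r2$p.value)
  expect_error(one_sample_t(rep(3, 5), 3), "variance")
  expect_error(one_sample_t(1), "n >= 2")
})

test_that("fold changes reproduce ratio arithmetic", {
  expect_equal(fold_change(10, 10), 1)
  expect_equal(round(fold_change(34.5, 18.7), 1), 1.8)
  expect_error(fold_change(5, 0), "denominator")
})

test_that("stats_frame validates and extracts the outcome", {
  summ <- data.frame(roi = c("a", "b"), mouse = c("m1", "m2"), sex = "M",
                     treatment = c("s", "e"), region = "PPN", day = 1,
                     pct_fos_chat_only = c(40, NA))
  sf <- stats_frame(summ)
  expect_equal(nrow(sf), 1)  # NA outcome dropped
  expect_equal(sf$outcome, 40)
  expect_error(stats_frame(summ, "missing_col"), "no column")
})
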