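#' Quality-control configuration for ROI filtering
#'
#' Captures the two-stage ROI screen: (1) cell-count inclusion bounds —
#' ROIs with fewer than `min_cells` or more than `max_cells` cholinergic
#' cells are excluded (defaults: 20–250 for IHC, 20–300 for RNAscope; both
#' bounds read literally, so a count equal to a bound is retained); (2) a
#' conjunctive outlier rule applied within each comparison stratum — an ROI
#' metric is excluded only when it lies outside the 1.5 x IQR fences AND its
#' z-score (computed from the stratum mean and SD, candidate included)
#' exceeds 2.68 in absolute value.
#'
#' @param mode `"RNAscope"` or `"IHC"` (sets the default `max_cells`).
#' @param min_cells Lower cell-count bound (default 20).
#' @param max_cells Upper bound; defaults to 300 (RNAscope) or 250 (IHC).
#' @param iqr_multiplier IQR fence multiplier (default 1.5).
#' @param z_cutoff Absolute z-score cutoff (default 2.68).
#' @param grouping Metadata columns defining the outlier stratum (default
#'   `sex`, `treatment`, `region`, `day` — the comparison cell).
#' @param count_col Summary column holding the cholinergic count used by the
#'   count filter (default `n_chat_pos`, all Chat+ cells).
#' @param metric_col Summary column screened for outliers (default
#'   `pct_fos_chat_only`, the percent of activated cholinergic neurons).
#' @param leave_one_out If `TRUE`, z-scores use the stratum mean/SD with the
#'   candidate removed (variant; default `FALSE`).
#' @return Object of class `qc_config`.
#' @export
qc_config <- function(mode = c("RNAscope", "IHC"),
                      min_cells = 20,
                      max_cells = NULL,
                      iqr_multiplier = 1.5,
                      z_cutoff = 2.68,
                      grouping = c("sex", "treatment", "region", "day"),
                      count_col = "n_chat_pos",
                      metric_col = "pct_fos_chat_only",
                      leave_one_out = FALSE) {
  mode <- match.arg(mode)
  if (is.null(max_cells)) max_cells <- if (mode == "IHC") 250 else 300
  stopifnot(min_cells < max_cells, iqr_multiplier > 0, z_cutoff > 0)
  structure(list(mode = mode, min_cells = min_cells, max_cells = max_cells,
                 iqr_multiplier = iqr_multiplier, z_cutoff = z_cutoff,
                 grouping = grouping, count_col = count_col,
                 metric_col = metric_col, leave_one_out = leave_one_out),
            class = "qc_config")
}

#' Cell-count inclusion filter
#'
#' Retains ROIs whose cholinergic cell count lies within
#' `[min_cells, max_cells]` inclusive; boundary counts are retained because
#' the exclusion rule reads "fewer than" / "more than".
#'
#' @param summaries ROI summary data frame ([bind_summaries()]).
#' @param cfg A [qc_config()].
#' @return List with `included` (retained rows) and `excluded` (dropped rows
#'   with a `qc_reason` column).
#' @export
count_filter <- function(summaries, cfg) {
  stopifnot(inherits(cfg, "qc_config"))
  counts <- summaries[[cfg$count_col]]
  if (is.null(counts) || anyNA(counts))
    stop("missing cholinergic counts in column ", cfg$count_col, call. = FALSE)
  low <- counts < cfg$min_cells
  high <- counts > cfg$max_cells
  excluded <- summaries[low | high, , drop = FALSE]
  if (nrow(excluded))
    excluded$qc_reason <- ifelse(excluded[[cfg$count_col]] < cfg$min_cells,
                                 sprintf("count < %d", cfg$min_cells),
                                 sprintf("count > %d", cfg$max_cells))
  list(included = summaries[!(low | high), , drop = FALSE],
       excluded = excluded)
}

#' Conjunctive IQR and z-score outlier flags
#'
#' Flags values within one stratum that are BOTH outside the IQR fences
#' (below Q1 - m*IQR or above Q3 + m*IQR; quartiles by linear interpolation)
#' AND beyond the absolute z-score cutoff. The conjunction means either
#' criterion alone never excludes. Strata with fewer than 4 values (quartiles
#' undefined) or zero SD produce no exclusions.
#'
#' @param values Numeric vector of the per-ROI metric within one stratum.
#' @param cfg A [qc_config()].
#' @return Logical vector of exclusion flags with attribute `stats`
#'   (Q1, Q3, IQR, fences, mean, sd).
#' @examples
#' outlier_filter(c(10, 11, 12, 13), qc_config())  # no outliers
#' @export
outlier_filter <- function(values, cfg = qc_config()) {
  stopifnot(inherits(cfg, "qc_config"))
  n <- length(values)
  flags <- rep(FALSE, n)
  if (n < 4 || anyNA(values)) {
    attr(flags, "stats") <- NULL
    return(flags)
  }
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - cfg$iqr_multiplier * iqr
  hi <- q[2] + cfg$iqr_multiplier * iqr
  outside_fence <- values < lo | values > hi
  if (cfg$leave_one_out) {
    z <- vapply(seq_len(n), function(i) {
      s <- sd(values[-i])
      if (s == 0) 0 else (values[i] - mean(values[-i])) / s
    }, numeric(1))
  } else {
    s <- sd(values)
    z <- if (s == 0) rep(0, n) else (values - mean(values)) / s
  }
  flags <- outside_fence & abs(z) > cfg$z_cutoff
  attr(flags, "stats") <- c(q1 = q[1], q3 = q[2], iqr = iqr,
                            fence_low = lo, fence_high = hi,
                            mean = mean(values), sd = sd(values))
  flags
}

#' Apply the full two-stage ROI screen
#'
#' Runs [count_filter()] first, then [outlier_filter()] on the primary
#' metric within each stratum defined by `cfg$grouping`, restricted to the
#' count-surviving ROIs. The outlier stage runs exactly once (re-screening
#' after removal could flag new points; this pipeline deliberately does
#' not iterate).
#'
#' @param summaries ROI summary data frame.
#' @param cfg A [qc_config()].
#' @return List with `included`, `excluded` (with `qc_reason` and stratum
#'   statistics columns), and `log` (all exclusions, auditable).
#' @export
qc_filter <- function(summaries, cfg = qc_config()) {
  stage1 <- count_filter(summaries, cfg)
  kept <- stage1$included
  metric <- kept[[cfg$metric_col]]
  if (is.null(metric))
    stop("missing QC metric column ", cfg$metric_col, call. = FALSE)
  grouping <- intersect(cfg$grouping, names(kept))
  stratum <- if (length(grouping))
    interaction(kept[grouping], drop = TRUE) else factor(rep(1, nrow(kept)))
  flags <- rep(FALSE, nrow(kept))
  for (s in levels(stratum)) {
    idx <- which(stratum == s)
    flags[idx] <- outlier_filter(metric[idx], cfg)
  }
  out_excl <- kept[flags, , drop = FALSE]
  if (nrow(out_excl))
    out_excl$qc_reason <- sprintf("outlier (|z| > %.2f and outside %.1fxIQR fence)",
                                  cfg$z_cutoff, cfg$iqr_multiplier)
  log <- rbind(
    if (nrow(stage1$excluded)) stage1$excluded else NULL,
    if (nrow(out_excl)) out_excl else NULL)
  list(included = kept[!flags, , drop = FALSE],
       excluded = out_excl,
       log = log %||% kept[0, , drop = FALSE])
}
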