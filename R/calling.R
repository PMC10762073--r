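#' Exact binomial per-cell probe-positivity test
#'
#' Tests whether a cell's puncta-positive pixel volume exceeds what the
#' background would produce over an area that size. Under the null, each of
#' the cell's `cell_pixel_area` pixels is puncta-positive independently with
#' the per-pixel background rate, so the observed volume is
#' Binomial(area, rate) and the p-value is the exact upper tail
#' P(X >= observed). A cell is called positive when p < alpha / n_cells —
#' a per-ROI Bonferroni correction with the number of segmented cells in the
#' ROI as the divisor.
#'
#' All arguments are vectorized over cells.
#'
#' @param observed Observed puncta-positive pixels in the cell (or punctum
#'   count, when testing punctum objects against an object-rate null).
#' @param cell_pixel_area Cell area in pixels (n of the binomial), >= 1.
#' @param background_rate Per-pixel background puncta probability in \[0,1\].
#' @param alpha Per-ROI family-wise error target (default 0.01).
#' @param n_cells Number of cells in the ROI (Bonferroni divisor), >= 1.
#' @return Data frame with columns `p_value` and `positive`.
#' @examples
#' binomial_positive(8, 200, 0.005, alpha = 0.01, n_cells = 50)
#' @export
binomial_positive <- function(observed, cell_pixel_area, background_rate,
                              alpha = 0.01, n_cells = 1) {
  if (any(observed < 0)) stop("observed must be >= 0", call. = FALSE)
  if (any(cell_pixel_area < 1)) stop("cell_pixel_area must be >= 1", call. = FALSE)
  stop_if_not_prob(background_rate, "background_rate")
  stop_if_not_prob(alpha, "alpha")
  if (any(n_cells < 1)) stop("n_cells must be >= 1", call. = FALSE)
  # exact upper tail P(X >= obs); pbinom is exact summation, no approximation
  p <- pbinom(observed - 1, size = cell_pixel_area, prob = background_rate,
              lower.tail = FALSE)
  p[observed == 0] <- 1
  data.frame(p_value = p, positive = p < alpha / n_cells)
}

#' Classify a cell from its Chat and Vglut2 positivity flags
#'
#' Exhaustive four-way partition: `chat_only` (Chat+, Vglut2-), `vglut_only`
#' (Chat-, Vglut2+), `colabel` (Chat+, Vglut2+), `neither`.
#'
#' @param chat_pos,vglut_pos Logical vectors.
#' @return Factor with levels `chat_only`, `vglut_only`, `colabel`,
#'   `neither`.
#' @examples
#' classify_cell(c(TRUE, TRUE, FALSE), c(FALSE, TRUE, FALSE))
#' @export
classify_cell <- function(chat_pos, vglut_pos) {
  stopifnot(is.logical(chat_pos), is.logical(vglut_pos),
            length(chat_pos) == length(vglut_pos))
  out <- ifelse(chat_pos & vglut_pos, "colabel",
         ifelse(chat_pos, "chat_only",
         ifelse(vglut_pos, "vglut_only", "neither")))
  factor(out, levels = cell_types())
}

#' Percent Fos transcript of a cell
#'
#' The total *Fos* puncta pixel volume inside the cell divided by the cell's
#' pixel volume, times 100. Volumes are clipped to the cell mask upstream,
#' so the result lies in \[0, 100\].
#'
#' @param fos_pixel_volume Fos puncta-positive pixels inside the cell.
#' @param cell_pixel_volume Cell area in pixels (> 0).
#' @return Percent value(s).
#' @examples
#' fos_transcript_pct(12, 300)  # 4
#' @export
fos_transcript_pct <- function(fos_pixel_volume, cell_pixel_volume) {
  if (any(cell_pixel_volume <= 0))
    stop("cell_pixel_volume must be > 0", call. = FALSE)
  if (any(fos_pixel_volume < 0))
    stop("fos_pixel_volume must be >= 0", call. = FALSE)
  100 * pmin(fos_pixel_volume, cell_pixel_volume) / cell_pixel_volume
}

#' Call probe positivity and cell types for one ROI
#'
#' Runs the exact binomial test for every cell x probe pair of a puncta
#' table (Bonferroni divisor = number of cells in the ROI), classifies each
#' cell from its Chat/Vglut2 flags, flags activation from the *Fos* probe,
#' and computes the %Fos-transcript metric.
#'
#' @param tab A `puncta_table` (from [quantify_roi()] or
#'   [generate_puncta_table()]).
#' @param alpha Family-wise alpha per ROI (default 0.01).
#' @param statistic `"pixels"` tests puncta-positive pixel volumes against
#'   the per-pixel background rate (default); `"objects"` tests punctum
#'   counts against an object-rate null (background rate interpreted per
#'   pixel, scaled by area either way).
#' @return Object of class `cell_calls` (a data frame, one row per cell):
#'   positivity flags and p-values per probe, `cell_type`,
#'   `fos_transcript_pct`; attributes `n_cells`, `alpha`,
#'   `corrected_alpha`, `background_rate`.
#' @export
call_cells <- function(tab, alpha = 0.01, statistic = c("pixels", "objects")) {
  stopifnot(inherits(tab, "puncta_table"))
  statistic <- match.arg(statistic)
  bg <- attr(tab, "background_rate")
  cells <- sort(unique(tab$cell))
  n_cells <- length(cells)
  if (n_cells == 0) stop("empty puncta table", call. = FALSE)
  out <- data.frame(cell = cells)
  for (pr in intersect(probes(), unique(tab$probe))) {
    sub <- tab[tab$probe == pr, ]
    sub <- sub[match(cells, sub$cell), ]
    obs <- if (statistic == "pixels") sub$puncta_pixel_volume else sub$puncta_count
    res <- binomial_positive(obs, sub$cell_pixel_area, bg[[pr]],
                             alpha = alpha, n_cells = n_cells)
    out[[paste0(pr, "_p")]] <- res$p_value
    out[[paste0(pr, "_pos")]] <- res$positive
    if (pr == "fos") {
      fos_sub <- sub
      out$fos_transcript_pct <-
        fos_transcript_pct(fos_sub$puncta_pixel_volume, fos_sub$cell_pixel_area)
    }
    out$cell_pixel_area <- sub$cell_pixel_area
  }
  if (all(c("chat_pos", "vglut2_pos") %in% names(out)))
    out$cell_type <- classify_cell(out$chat_pos, out$vglut2_pos)
  structure(out, n_cells = n_cells, alpha = alpha,
            corrected_alpha = alpha / n_cells,
            background_rate = bg,
            class = c("cell_calls", "data.frame"))
}

#' Activation calls for the immunohistochemistry arm
#'
#' IHC images have a c-Fos stain rather than countable transcript puncta:
#' a ChAT+ cell is called activated when its mean c-Fos intensity exceeds a
#' configurable threshold.
#'
#' @param intensity Per-cell mean c-Fos stain intensity.
#' @param threshold Intensity cutoff (same scale as `intensity`).
#' @return Logical activation flags.
#' @export
ihc_activated <- function(intensity, threshold) {
  if (any(intensity < 0)) stop("intensity must be >= 0", call. = FALSE)
  intensity > threshold
}

#' Summarize cell calls of one ROI
#'
#' Builds the per-ROI record feeding QC and group statistics: cell counts
#' per type, the percent of Fos+ (activated) cells within each type, the
#' mean %Fos transcript over the activated cells of each type (or over all
#' cells of the type with `fos_pct_over = "all"`), and the co-label shares
#' of the cholinergic and glutamatergic populations. A type with zero cells
#' yields `NA` (not 0) for its percentages.
#'
#' @param calls A `cell_calls`.
#' @param metadata Named list of ROI metadata carried into the summary row
#'   (`roi`, `mouse`, `sex`, `treatment`, `dose`, `day`, `region`, ...).
#' @param fos_pct_over `"activated"` (default; mean %Fos transcript over
#'   Fos+ cells) or `"all"` (over all cells of the type).
#' @return One-row data frame of class `roi_summary`.
#' @export
summarize_roi <- function(calls, metadata = list(),
                          fos_pct_over = c("activated", "all")) {
  stopifnot(inherits(calls, "cell_calls"))
  if (!nrow(calls)) stop("empty cell calls", call. = FALSE)
  fos_pct_over <- match.arg(fos_pct_over)
  md <- metadata[intersect(c("roi", "mouse", "sex", "treatment", "dose",
                             "day", "region", "hemisphere"), names(metadata))]
  out <- as.data.frame(md, stringsAsFactors = FALSE)
  if (!nrow(out)) out <- data.frame(row.names = 1)
  out$n_cells <- nrow(calls)
  for (ty in cell_types())
    out[[paste0("n_", ty)]] <- sum(calls$cell_type == ty)
  out$n_chat_pos <- sum(calls$chat_pos)
  out$n_vglut2_pos <- sum(calls$vglut2_pos)
  for (ty in cell_types()) {
    in_ty <- calls$cell_type == ty
    n_ty <- sum(in_ty)
    out[[paste0("pct_fos_", ty)]] <-
      if (n_ty > 0) 100 * sum(calls$fos_pos[in_ty]) / n_ty else NA_real_
    sel <- if (fos_pct_over == "activated") in_ty & calls$fos_pos else in_ty
    out[[paste0("mean_fos_pct_", ty)]] <-
      if (any(sel)) mean(calls$fos_transcript_pct[sel]) else NA_real_
  }
  n_chat_only <- out$n_chat_only; n_vglut <- out$n_vglut_only
  n_co <- out$n_colabel
  out$colabel_share_chol <-
    if (n_co + n_chat_only > 0) 100 * n_co / (n_co + n_chat_only) else NA_real_
  out$colabel_share_glut <-
    if (n_co + n_vglut > 0) 100 * n_co / (n_co + n_vglut) else NA_real_
  class(out) <- c("roi_summary", "data.frame")
  out
}

#' Bind per-ROI summaries into a study-level table
#'
#' @param summaries List of `roi_summary` rows.
#' @return Data frame with one row per ROI.
#' @export
bind_summaries <- function(summaries) {
  out <- do.call(rbind, lapply(summaries, as.data.frame))
  rownames(out) <- NULL
  out
}
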