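#' Detect transcript puncta in a probe channel
#'
#' Thresholds the channel (Otsu by default, or a fixed threshold), labels
#' connected supra-threshold components, and discards components smaller
#' than `min_size` pixels. Each retained component is one punctum with a
#' centroid and a pixel volume.
#'
#' @param probe_channel 2-D intensity matrix (background-subtracted channel
#'   recommended).
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold Threshold value when `threshold_method = "fixed"`.
#' @param min_size Minimum punctum size in pixels (default 1).
#' @param connectivity 4 or 8 (default 8).
#' @return Object of class `puncta_set`: `label` (integer punctum label
#'   image), `puncta` (data frame: `punctum`, `volume`, `row`, `col`),
#'   `mask` (logical puncta-positive pixels), `threshold`.
#' @examples
#' ch <- matrix(0, 20, 20); ch[c(30, 200, 350)] <- 1
#' detect_puncta(ch, threshold_method = "fixed", threshold = 0.5)$puncta
#' @export
detect_puncta <- function(probe_channel,
                          threshold_method = c("otsu", "fixed"),
                          threshold = NULL, min_size = 1, connectivity = 8) {
  probe_channel <- as_intensity_matrix(probe_channel)
  threshold_method <- match.arg(threshold_method)
  thr <- if (threshold_method == "otsu") {
    if (diff(range(probe_channel)) == 0)
      stop("no threshold: channel is constant", call. = FALSE)
    otsu_threshold(probe_channel)
  } else {
    if (is.null(threshold)) stop("fixed method needs `threshold`", call. = FALSE)
    threshold
  }
  mask <- probe_channel > thr
  lab <- label_components(mask, connectivity)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(sizes > 0 & sizes < min_size)
    if (length(drop)) lab[lab %in% drop] <- 0L
    lab <- relabel_raster(lab)
  }
  k <- max(lab)
  if (k > 0) {
    nr <- nrow(lab)
    rows <- matrix(rep(seq_len(nr), ncol(lab)), nr)
    cols <- matrix(rep(seq_len(ncol(lab)), each = nr), nr)
    idx <- lab > 0
    puncta <- data.frame(
      punctum = seq_len(k),
      volume = tabulate(lab[idx], nbins = k),
      row = as.vector(tapply(rows[idx], lab[idx], mean)),
      col = as.vector(tapply(cols[idx], lab[idx], mean)))
  } else {
    puncta <- data.frame(punctum = integer(0), volume = integer(0),
                         row = numeric(0), col = numeric(0))
  }
  structure(list(label = lab, puncta = puncta, mask = lab > 0,
                 threshold = thr),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat("<puncta_set>", nrow(x$puncta), "puncta,",
      sum(x$puncta$volume), "px total,",
      sprintf("threshold %.4g\n", x$threshold))
  invisible(x)
}

#' Assign detected puncta to segmented cells
#'
#' Each punctum is assigned to the cell whose area contains its (rounded)
#' centroid — at most one cell per punctum, so counts are never duplicated.
#' Puncta whose centroid falls on background are tallied separately for
#' background-rate estimation. Per-cell pixel volumes are the puncta-positive
#' pixels lying inside the cell area (clipped at the cell boundary).
#'
#' @param seg A `segmented_roi`.
#' @param puncta A `puncta_set` from the same image geometry.
#' @return Data frame with one row per cell: `cell`, `puncta_count`,
#'   `puncta_pixel_volume`, `cell_pixel_area`; attributes
#'   `background_count` (puncta objects on background) and
#'   `background_volume` (puncta-positive background pixels).
#' @export
assign_puncta <- function(seg, puncta) {
  stopifnot(inherits(seg, "segmented_roi"), inherits(puncta, "puncta_set"))
  if (!identical(dim(seg$label), dim(puncta$label)))
    stop("segmentation and puncta geometries differ", call. = FALSE)
  k <- nrow(seg$cells)
  counts <- integer(k)
  bg_count <- 0L
  if (nrow(puncta$puncta)) {
    ri <- pmin(pmax(round(puncta$puncta$row), 1), nrow(seg$label))
    ci <- pmin(pmax(round(puncta$puncta$col), 1), ncol(seg$label))
    owner <- seg$label[cbind(ri, ci)]
    tab <- tabulate(owner[owner > 0], nbins = k)
    counts <- tab
    bg_count <- sum(owner == 0)
  }
  vol <- integer(k)
  inside <- puncta$mask & seg$label > 0
  if (any(inside)) {
    v <- tabulate(seg$label[inside], nbins = k)
    vol <- v
  }
  out <- data.frame(cell = seg$cells$cell, puncta_count = counts,
                    puncta_pixel_volume = vol,
                    cell_pixel_area = seg$cells$area)
  attr(out, "background_count") <- bg_count
  attr(out, "background_volume") <- sum(puncta$mask & seg$label == 0)
  out
}

#' Estimate the per-pixel background puncta rate
#'
#' The fraction of background pixels (label 0 in the segmentation) that are
#' puncta-positive — the Bernoulli rate entering the binomial positivity
#' test.
#'
#' @param puncta A `puncta_set` (or a logical puncta mask).
#' @param seg A `segmented_roi` on the same geometry.
#' @return Background rate in \[0, 1\].
#' @export
estimate_background <- function(puncta, seg) {
  stopifnot(inherits(seg, "segmented_roi"))
  mask <- if (inherits(puncta, "puncta_set")) puncta$mask else puncta
  if (!identical(dim(mask), dim(seg$label)))
    stop("puncta and segmentation geometries differ", call. = FALSE)
  bg <- seg$label == 0
  n_bg <- sum(bg)
  if (n_bg == 0) stop("zero background area", call. = FALSE)
  sum(mask & bg) / n_bg
}

new_puncta_table <- function(rows, background_rate) {
  stopifnot(all(c("cell", "probe", "puncta_count", "puncta_pixel_volume",
                  "cell_pixel_area") %in% names(rows)))
  if (any(rows$puncta_count < 0) || any(rows$puncta_pixel_volume < 0))
    stop("puncta counts and volumes must be >= 0", call. = FALSE)
  if (any(rows$cell_pixel_area <= 0))
    stop("cell_pixel_area must be > 0", call. = FALSE)
  stop_if_not_prob(background_rate, "background_rate")
  structure(rows, background_rate = background_rate,
            class = c("puncta_table", "data.frame"))
}

#' Quantify all probe channels of an ROI against a segmentation
#'
#' For each probe channel: subtract background, detect puncta, assign them
#' to cells, and estimate the background rate. Produces the tidy per-cell,
#' per-probe puncta table feeding the binomial positivity caller.
#'
#' @param image A `roi_image` with channels `dapi`, `chat`, `vglut2`, `fos`.
#' @param seg A `segmented_roi` of the DAPI channel.
#' @param bg_radius Background-subtraction disc radius (default 25; see
#'   [subtract_background()]).
#' @param min_size Minimum punctum size in pixels.
#' @param threshold_method,threshold Passed to [detect_puncta()].
#' @return A `puncta_table`: one row per cell x probe with `puncta_count`,
#'   `puncta_pixel_volume`, `cell_pixel_area`; per-probe background rates in
#'   `attr(, "background_rate")`.
#' @export
quantify_roi <- function(image, seg, bg_radius = 25, min_size = 1,
                         threshold_method = "otsu", threshold = NULL) {
  stopifnot(inherits(image, "roi_image"), inherits(seg, "segmented_roi"))
  prs <- intersect(probes(), image$channel_names)
  if (!length(prs)) stop("no probe channels found in image", call. = FALSE)
  bg_rate <- setNames(numeric(length(prs)), prs)
  rows <- vector("list", length(prs))
  for (i in seq_along(prs)) {
    ch <- subtract_background(image$channels[[prs[i]]], bg_radius)
    ps <- detect_puncta(ch, threshold_method = threshold_method,
                        threshold = threshold, min_size = min_size)
    per_cell <- assign_puncta(seg, ps)
    per_cell$probe <- prs[i]
    bg_rate[i] <- estimate_background(ps, seg)
    rows[[i]] <- per_cell
  }
  rows <- do.call(rbind, rows)
  rows <- rows[order(rows$cell, match(rows$probe, probes())),
               c("cell", "probe", "puncta_count", "puncta_pixel_volume",
                 "cell_pixel_area")]
  rownames(rows) <- NULL
  new_puncta_table(rows, background_rate = bg_rate)
}

#' Write a puncta table and its background rates
#'
#' @param tab A `puncta_table`.
#' @param csv_path CSV output (one row per cell x probe).
#' @param json_path Optional JSON sidecar with the per-probe background
#'   rates.
#' @return Invisibly, the paths written.
#' @export
write_puncta_table <- function(tab, csv_path, json_path = NULL) {
  stopifnot(inherits(tab, "puncta_table"))
  write.csv(as.data.frame(tab), csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(as.list(attr(tab, "background_rate")), json_path,
                         auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, json = json_path))
}
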