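#' Rolling-ball style background subtraction
#'
#' Removes smooth background by a morphological white top-hat (image minus
#' its grayscale opening with a disc structuring element). A constant or
#' slowly varying background maps to (near) zero while features narrower
#' than the disc are preserved.
#'
#' @param channel 2-D numeric intensity matrix, values >= 0.
#' @param radius Disc radius in pixels (default 50, sized for full-resolution
#'   micrographs; use a smaller radius for small synthetic frames).
#' @return Matrix of the same dimensions, non-negative.
#' @examples
#' m <- matrix(7, 32, 32); m[16, 16] <- 20
#' range(subtract_background(m, radius = 5))
#' @export
subtract_background <- function(channel, radius = 50) {
  channel <- as_intensity_matrix(channel)
  if (radius < 1) stop("radius must be >= 1", call. = FALSE)
  top <- max(channel)
  if (top == 0) return(channel)
  kern <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  # EBImage grayscale morphology expects intensities in [0, 1]
  out <- EBImage::imageData(EBImage::whiteTopHat(EBImage::Image(channel / top),
                                                 kern)) * top
  matrix(pmax(out, 0), nrow(channel), ncol(channel))
}

#' Convert an image to grayscale via the HSV value component
#'
#' A single-channel image passes through unchanged; a multi-channel (e.g.
#' RGB) image is reduced to the V component of HSV, i.e. the per-pixel
#' maximum over channels.
#'
#' @param img 2-D matrix, or 3-D array with channels in the third dimension,
#'   or a `roi_image` channel list element.
#' @return 2-D intensity matrix.
#' @examples
#' to_grayscale(array(c(30, 200, 100), c(1, 1, 3)))  # 200
#' @export
to_grayscale <- function(img) {
  if (is.matrix(img)) return(img)
  if (is.array(img) && length(dim(img)) == 3) {
    nch <- dim(img)[3]
    if (nch < 1 || nch > 4)
      stop("unsupported channel count: ", nch, call. = FALSE)
    out <- img[, , 1, drop = FALSE]
    for (i in seq_len(nch)[-1]) out <- pmax(out, img[, , i, drop = FALSE])
    return(matrix(out, dim(img)[1], dim(img)[2]))
  }
  stop("unsupported image type", call. = FALSE)
}

as_intensity_matrix <- function(x) {
  if (inherits(x, "Image")) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("expected a 2-D numeric intensity matrix", call. = FALSE)
  if (length(x) == 0) stop("empty image", call. = FALSE)
  if (any(x < 0)) stop("intensities must be >= 0", call. = FALSE)
  x
}

#' Otsu threshold of an intensity image
#'
#' Chooses the threshold maximizing between-class variance over a 256-level
#' histogram of the image. Errors on constant images, where the criterion is
#' undefined.
#'
#' @param x 2-D numeric matrix.
#' @param levels Number of histogram levels (default 256).
#' @return Threshold on the intensity scale of `x`; pixels strictly above it
#'   are foreground.
#' @export
otsu_threshold <- function(x, levels = 256) {
  x <- as_intensity_matrix(x)
  rng <- range(x)
  if (diff(rng) == 0)
    stop("no threshold: image is constant", call. = FALSE)
  # exhaustive search over all histogram cuts, cumulative-moment form;
  # classes are disjoint: {bins <= t} vs {bins > t}
  scaled <- (x - rng[1]) / diff(rng)
  h <- hist(scaled, breaks = seq(0, 1, length.out = levels + 1), plot = FALSE)
  counts <- as.double(h$counts); mids <- h$mids
  w0 <- cumsum(counts)
  w1 <- sum(counts) - w0
  m0 <- cumsum(counts * mids)
  m1 <- sum(counts * mids) - m0
  keep <- seq_len(levels - 1)
  vb <- w0[keep] * w1[keep] * (m1[keep] / w1[keep] - m0[keep] / w0[keep])^2
  t <- which.max(vb)  # first maximum on ties
  rng[1] + mids[t] * diff(rng)
}

# 4-connected labels from EBImage::bwlabel; for 8-connectivity, merge labels
# that touch diagonally (union-find over diagonal label adjacencies).
label_components <- function(mask, connectivity = 8) {
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask * 1)))
  storage.mode(lab) <- "integer"
  if (connectivity == 4 || max(lab) <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]   # \ diagonal pairs
  c_ <- lab[-nr, -1]; d <- lab[-1, -nc]  # / diagonal pairs
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c_), as.vector(d)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    parent <- seq_len(max(lab))
    find <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(max(lab)), find, integer(1))
    lab[lab > 0] <- root[lab[lab > 0]]
  }
  lab
}

# Relabel positive labels as consecutive 1..k in raster-scan (row-major)
# order of each component's first pixel.
relabel_raster <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) return(lab)
  nr <- nrow(lab)
  rows <- matrix(rep(seq_len(nr), ncol(lab)), nr)[lab > 0]
  cols <- matrix(rep(seq_len(ncol(lab)), each = nr), nr)[lab > 0]
  pos <- (rows - 1) * ncol(lab) + cols
  first <- tapply(pos, lab[lab > 0], min)
  new_id <- integer(max(ids))
  new_id[as.integer(names(first))[order(first)]] <- seq_along(first)
  lab[lab > 0] <- new_id[lab[lab > 0]]
  lab
}

#' Segment cell areas from a DAPI channel
#'
#' Thresholds the DAPI image by Otsu's criterion, labels connected
#' components, discards components below `min_area`, optionally dilates each
#' retained component by `dilation_radius` pixels to approximate the
#' cytoplasmic cell area, and relabels cells 1..k deterministically in
#' raster-scan order of each component's first pixel. Touching nuclei are not
#' split.
#'
#' @param dapi 2-D DAPI intensity matrix (non-constant).
#' @param min_area Minimum component area in pixels (default 20).
#' @param connectivity Pixel connectivity, 4 or 8 (default 8).
#' @param dilation_radius Dilation of each cell area in pixels (default 2; 0
#'   for raw nuclear masks).
#' @return Object of class `segmented_roi`: `label` (integer label image,
#'   0 = background), `cells` (data frame: `cell`, `area`, `row`, `col`
#'   centroids, 0-based coordinates available via `row - 1`, `col - 1`),
#'   `threshold`.
#' @examples
#' m <- matrix(0, 40, 40); m[5:10, 5:10] <- 0.9; m[25:30, 25:30] <- 0.9
#' seg <- segment_cells(m, dilation_radius = 0)
#' seg$cells
#' @export
segment_cells <- function(dapi, min_area = 20, connectivity = 8,
                          dilation_radius = 2) {
  dapi <- as_intensity_matrix(dapi)
  if (!connectivity %in% c(4, 8))
    stop("connectivity must be 4 or 8", call. = FALSE)
  thr <- otsu_threshold(dapi)
  mask <- dapi > thr
  lab <- label_components(mask, connectivity)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(sizes > 0 & sizes < min_area)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  if (dilation_radius > 0 && max(lab) > 0) {
    kern <- EBImage::makeBrush(2L * as.integer(dilation_radius) + 1L, "disc")
    # grayscale (max) dilation keeps distinct labels distinct
    lab <- as.matrix(EBImage::dilate(EBImage::Image(lab), kern))
    storage.mode(lab) <- "integer"
  }
  lab <- relabel_raster(lab)
  new_segmented_roi(lab, threshold = thr)
}

new_segmented_roi <- function(label, threshold = NA_real_) {
  k <- max(label)
  if (k > 0) {
    nr <- nrow(label)
    rows <- matrix(rep(seq_len(nr), ncol(label)), nr)
    cols <- matrix(rep(seq_len(ncol(label)), each = nr), nr)
    idx <- label > 0
    cells <- data.frame(
      cell = seq_len(k),
      area = tabulate(label[idx], nbins = k),
      row = as.vector(tapply(rows[idx], label[idx], mean)),
      col = as.vector(tapply(cols[idx], label[idx], mean)))
  } else {
    cells <- data.frame(cell = integer(0), area = integer(0),
                        row = numeric(0), col = numeric(0))
  }
  structure(list(label = label, cells = cells, threshold = threshold),
            class = "segmented_roi")
}

#' @export
print.segmented_roi <- function(x, ...) {
  cat("<segmented_roi>", nrow(x$cells), "cells over",
    paste(dim(x$label), collapse = " x "), "px")
  if (!is.na(x$threshold)) cat(sprintf(", Otsu threshold %.4g", x$threshold))
  cat("\n")
  invisible(x)
}

#' Write a label image as 16-bit TIFF and the cell table as CSV
#'
#' @param seg A `segmented_roi`.
#' @param image_path,table_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_segmentation <- function(seg, image_path = NULL, table_path = NULL) {
  stopifnot(inherits(seg, "segmented_roi"))
  if (!is.null(image_path))
    EBImage::writeImage(EBImage::Image(seg$label / 65535), image_path,
                        type = "tiff", bits.per.sample = 16L)
  if (!is.null(table_path)) {
    tab <- seg$cells
    tab$row0 <- tab$row - 1   # 0-based pixel coordinates, row-major
    tab$col0 <- tab$col - 1
    write.csv(tab, table_path, row.names = FALSE)
  }
  invisible(c(image = image_path, table = table_path))
}

#' Match segmented cells to ground-truth cells by centroid distance
#'
#' Greedy one-to-one matching by increasing centroid distance within a
#' gating radius. With well-separated nuclei (spacing comfortably above the
#' gate) each truth cell has at most one candidate and the greedy solution
#' coincides with the optimal assignment.
#'
#' @param truth Data frame with `row`, `col` centroids (ground truth).
#' @param seg A `segmented_roi` or data frame with `row`, `col`.
#' @param max_dist Gating radius in pixels (default 5).
#' @return Data frame `truth_cell`, `seg_cell`, `dist` of matched pairs;
#'   attribute `match_rate` = matched / n truth cells.
#' @export
match_cells <- function(truth, seg, max_dist = 5) {
  sc <- if (inherits(seg, "segmented_roi")) seg$cells else seg
  if (!nrow(truth) || !nrow(sc)) {
    out <- data.frame(truth_cell = integer(0), seg_cell = integer(0),
                      dist = numeric(0))
    attr(out, "match_rate") <- 0
    return(out)
  }
  d <- sqrt(outer(truth$row, sc$row, "-")^2 + outer(truth$col, sc$col, "-")^2)
  cand <- which(d <= max_dist, arr.ind = TRUE)
  cand <- cand[order(d[cand]), , drop = FALSE]
  used_t <- logical(nrow(truth)); used_s <- logical(nrow(sc))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ti <- cand[i, 1]; si <- cand[i, 2]
    if (!used_t[ti] && !used_s[si]) {
      used_t[ti] <- used_s[si] <- TRUE
      keep[i] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(truth_cell = truth$cell[cand[, 1]] %||% cand[, 1],
                    seg_cell = sc$cell[cand[, 2]] %||% cand[, 2],
                    dist = d[cand])
  attr(out, "match_rate") <- nrow(out) / nrow(truth)
  out
}
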