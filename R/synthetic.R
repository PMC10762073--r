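#' Cell-type mixture and signal model for synthetic ROIs
#'
#' Defines the latent composition of a simulated region of interest (ROI):
#' the four cell-type probabilities (cholinergic `chat_only`, glutamatergic
#' `vglut_only`, co-labeled `colabel`, and `neither`), the per-type,
#' per-treatment activation probabilities (probability that a cell expresses
#' *Fos*), the expected number of transcript puncta per positive cell for each
#' probe, and the per-pixel background puncta probability.
#'
#' The default type mixture is solved from two observed co-label shares:
#' co-labeled cells are ~27% of all *Chat*+ cells and ~11.5% of all *Vglut2*+
#' cells, giving (0.16, 0.46, 0.06, 0.32). Default activation probabilities
#' follow chronic-treatment group means for the PPN in males (e.g. cholinergic
#' 0.507 under saline vs 0.668 under ethanol; co-labeled cells constitutively
#' active at ~0.88). Signal rates and the background rate are free parameters
#' of the simulation: marker probes (*Chat*, *Vglut2*) default to 30 puncta
#' per positive cell, *Fos* to 12 — about 4% of the default ~250 px cell
#' area, placing the %Fos-transcript metric in the few-percent range typical
#' of activated cells, and far above the default background of 5e-4 per
#' pixel.
#'
#' @param p_chat_only,p_vglut_only,p_colabel,p_neither Type probabilities;
#'   must be in \[0, 1\] and sum to 1.
#' @param activation_prob Numeric matrix of activation probabilities with
#'   rows named by cell type and columns by treatment.
#' @param signal_rate Named numeric vector: expected puncta per latent-positive
#'   cell for probes `chat`, `vglut2`, `fos`.
#' @param background_rate Probability that any background pixel is
#'   puncta-positive, per probe channel.
#' @return An object of class `cell_type_mix`.
#' @examples
#' mix <- cell_type_mix()
#' mix$p["colabel"] / sum(mix$p[c("chat_only", "colabel")])  # ~0.27
#' @export
cell_type_mix <- function(p_chat_only = 0.16,
                          p_vglut_only = 0.46,
                          p_colabel = 0.06,
                          p_neither = 0.32,
                          activation_prob = default_activation_prob(),
                          signal_rate = c(chat = 30, vglut2 = 30, fos = 12),
                          background_rate = 5e-4) {
  p <- c(chat_only = p_chat_only, vglut_only = p_vglut_only,
         colabel = p_colabel, neither = p_neither)
  stop_if_not_prob(p, "type probabilities")
  if (abs(sum(p) - 1) > 1e-8)
    stop("cell-type probabilities must sum to 1", call. = FALSE)
  stop_if_not_prob(activation_prob, "activation_prob")
  stop_if_not_prob(background_rate, "background_rate")
  if (!all(cell_types() %in% rownames(activation_prob)))
    stop("activation_prob must have rows ", paste(cell_types(), collapse = ", "),
         call. = FALSE)
  if (is.null(names(signal_rate)) || !all(probes() %in% names(signal_rate)))
    stop("signal_rate must be named with probes ", paste(probes(), collapse = ", "),
         call. = FALSE)
  if (any(signal_rate < 0)) stop("signal_rate must be non-negative", call. = FALSE)
  structure(list(p = p, activation_prob = activation_prob,
                 signal_rate = signal_rate, background_rate = background_rate),
            class = "cell_type_mix")
}

#' @rdname cell_type_mix
#' @export
default_activation_prob <- function() {
  m <- rbind(chat_only  = c(0.507, 0.668),
             vglut_only = c(0.417, 0.631),
             colabel    = c(0.877, 0.883),
             neither    = c(0.300, 0.300))
  colnames(m) <- c("saline", "etoh")
  m
}

cell_types <- function() c("chat_only", "vglut_only", "colabel", "neither")
probes <- function() c("chat", "vglut2", "fos")

#' Study design for a simulated cohort
#'
#' Describes the experimental layout the generator reproduces: groups defined
#' by sex x treatment (with dose in g/kg and treatment duration in days), the
#' number of mice per group, the brain subregions imaged (PPN and/or LDT), and
#' the number of ROIs collected per mouse per subregion.
#'
#' @param n_mice_per_group Mice per group (>= 1).
#' @param groups Data frame with columns `sex` (`"M"`/`"F"`), `treatment`,
#'   `dose` (g/kg) and `days`.
#' @param rois_per_mouse_per_region ROIs per mouse in each region (>= 1).
#' @param regions Character vector, subset of `c("PPN", "LDT")`.
#' @param seed Integer master seed; the full study is reproduced bit-identically
#'   from it.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_mice_per_group = 4,
                         groups = data.frame(
                           sex = c("M", "M"),
                           treatment = c("saline", "etoh"),
                           dose = c(0, 2),
                           days = c(15, 15)),
                         rois_per_mouse_per_region = 4,
                         regions = "PPN",
                         seed = 1L) {
  stopifnot(n_mice_per_group >= 1, rois_per_mouse_per_region >= 1)
  if (!all(c("sex", "treatment", "dose", "days") %in% names(groups)))
    stop("groups must have columns sex, treatment, dose, days", call. = FALSE)
  if (!all(groups$sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'", call. = FALSE)
  if (!all(regions %in% c("PPN", "LDT")))
    stop("regions must be in {PPN, LDT}", call. = FALSE)
  structure(list(n_mice_per_group = as.integer(n_mice_per_group),
                 groups = groups,
                 rois_per_mouse_per_region = as.integer(rois_per_mouse_per_region),
                 regions = regions, seed = as.integer(seed)),
            class = "study_design")
}

# Draw latent per-cell state (type, activation, true puncta counts).
draw_latents <- function(mix, n_cells, treatment, logit_shift = 0) {
  type <- sample(cell_types(), n_cells, replace = TRUE, prob = mix$p)
  treatment <- match.arg(treatment, colnames(mix$activation_prob))
  p_act <- plogis(qlogis(mix$activation_prob[type, treatment]) + logit_shift)
  p_act[mix$activation_prob[type, treatment] %in% c(0, 1)] <-
    mix$activation_prob[type, treatment][mix$activation_prob[type, treatment] %in% c(0, 1)]
  activated <- runif(n_cells) < p_act
  chat_pos <- type %in% c("chat_only", "colabel")
  vglut_pos <- type %in% c("vglut_only", "colabel")
  data.frame(
    cell = seq_len(n_cells), type = type, activated = activated,
    true_chat = ifelse(chat_pos, rpois(n_cells, mix$signal_rate["chat"]), 0L),
    true_vglut2 = ifelse(vglut_pos, rpois(n_cells, mix$signal_rate["vglut2"]), 0L),
    true_fos = ifelse(activated, rpois(n_cells, mix$signal_rate["fos"]), 0L))
}

#' Generate one synthetic multi-channel ROI image with ground truth
#'
#' Renders a 4-channel fluorescence ROI (DAPI + *Chat* + *Vglut2* + *Fos*).
#' Nuclei are non-overlapping discs; the cell area is the nucleus dilated by
#' `dilation_radius` pixels. Each latent-positive cell receives a Poisson
#' number of single-pixel puncta placed uniformly inside its cell area;
#' every background pixel is independently puncta-positive with probability
#' `background_rate`. All latent state is returned as ground truth.
#'
#' @param mix A [cell_type_mix()].
#' @param n_cells Number of cells to place (>= 1).
#' @param seed Integer seed; output is bit-identical for identical seeds.
#' @param image_size Image dimensions `c(rows, cols)`.
#' @param nucleus_radius Range `c(min, max)` of nucleus radii in pixels.
#' @param dilation_radius Pixels added to the nucleus radius to form the
#'   cell area (default 2).
#' @param min_spacing Minimum centre-to-centre distance between nuclei.
#' @param treatment Treatment label selecting the activation column.
#' @param logit_shift Additive shift on the logit of the activation
#'   probability (mouse-level random effect).
#' @param noise_sd SD of Gaussian intensity noise added to each channel.
#' @param metadata Named list of ROI metadata (mouse, sex, region, ...).
#' @return A list of class `roi_sim` with elements `image` (class
#'   `roi_image`) and `truth` (class `roi_truth`).
#' @examples
#' sim <- generate_roi(cell_type_mix(), n_cells = 20, seed = 1)
#' table(sim$truth$cells$type)
#' @export
generate_roi <- function(mix, n_cells, seed,
                         image_size = c(256, 256),
                         nucleus_radius = c(6, 8),
                         dilation_radius = 2,
                         min_spacing = 22,
                         treatment = "saline",
                         logit_shift = 0,
                         noise_sd = 0.02,
                         metadata = list()) {
  stopifnot(n_cells >= 1, length(image_size) == 2)
  mean_area <- pi * (mean(nucleus_radius) + dilation_radius)^2
  if (n_cells * mean_area > 0.5 * prod(image_size))
    stop("impossible packing: n_cells x mean cell area exceeds half the image",
         call. = FALSE)
  with_seed(seed, {
    nr <- image_size[1]; nc <- image_size[2]
    rmax <- max(nucleus_radius) + dilation_radius

    # dart-throwing placement with a minimum spacing so nuclei never touch
    rows <- cols <- numeric(0)
    tries <- 0L
    while (length(rows) < n_cells) {
      tries <- tries + 1L
      if (tries > 500L * n_cells)
        stop("could not place ", n_cells, " cells with min_spacing ",
             min_spacing, call. = FALSE)
      y <- runif(1, rmax + 1, nr - rmax)
      x <- runif(1, rmax + 1, nc - rmax)
      if (!length(rows) || all((rows - y)^2 + (cols - x)^2 >= min_spacing^2)) {
        rows <- c(rows, y); cols <- c(cols, x)
      }
    }
    radius <- runif(n_cells, nucleus_radius[1], nucleus_radius[2])

    latents <- draw_latents(mix, n_cells, treatment, logit_shift)

    # label image of dilated cell areas (cells never overlap by construction)
    label <- matrix(0L, nr, nc)
    dapi <- matrix(0, nr, nc)
    px_row <- matrix(rep(seq_len(nr), nc), nr, nc)
    px_col <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    area <- integer(n_cells)
    for (i in seq_len(n_cells)) {
      d2 <- (px_row - rows[i])^2 + (px_col - cols[i])^2
      cellpx <- d2 <= (radius[i] + dilation_radius)^2
      label[cellpx] <- i
      area[i] <- sum(cellpx)
      dapi[d2 <= radius[i]^2] <- 0.85 + runif(1, -0.1, 0.1)
    }

    channels <- list(dapi = dapi)
    counts <- cbind(chat = latents$true_chat, vglut2 = latents$true_vglut2,
                    fos = latents$true_fos)
    for (pr in probes()) {
      ch <- matrix(0, nr, nc)
      for (i in seq_len(n_cells)) {
        k <- counts[i, pr]
        if (k > 0) {
          inside <- which(label == i)
          ch[sample(inside, k, replace = TRUE)] <- 1
        }
      }
      bg <- which(label == 0L)
      if (mix$background_rate > 0) {
        hit <- bg[runif(length(bg)) < mix$background_rate]
        ch[hit] <- 1
      }
      channels[[pr]] <- ch
    }
    if (noise_sd > 0)
      channels <- lapply(channels, function(ch)
        pmin(pmax(ch + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc), 0), 1))

    cells <- cbind(data.frame(cell = seq_len(n_cells), row = rows, col = cols,
                              radius = radius, area = area),
                   latents[, -1])
    image <- structure(list(channels = channels,
                            channel_names = names(channels),
                            dim = c(nr, nc), metadata = metadata),
                       class = "roi_image")
    truth <- structure(list(cells = cells, label = label, mix = mix,
                            params = list(dilation_radius = dilation_radius,
                                          treatment = treatment,
                                          logit_shift = logit_shift)),
                       class = "roi_truth")
    structure(list(image = image, truth = truth), class = "roi_sim")
  })
}

#' Generate a per-cell puncta table directly (no image rendering)
#'
#' Fast path for statistical validation: draws the same latent state as
#' [generate_roi()] and produces the observed per-cell, per-probe
#' puncta pixel volumes by the same signal model (each true punctum occupies
#' one pixel; background pixels inside the cell area are puncta-positive
#' independently with probability `background_rate`), skipping rendering,
#' segmentation and detection. The returned background rate is the model
#' rate, as would be estimated from a large background area.
#'
#' @inheritParams generate_roi
#' @param mean_cell_area,area_sd Mean and SD of simulated cell pixel areas.
#' @return List of class `roi_table_sim`: `puncta` (a tidy `puncta_table`),
#'   `truth` (per-cell latent data frame), `background_rate`.
#' @export
generate_puncta_table <- function(mix, n_cells, seed,
                                  mean_cell_area = 250, area_sd = 30,
                                  treatment = "saline", logit_shift = 0,
                                  metadata = list()) {
  stopifnot(n_cells >= 1, mean_cell_area > 1)
  with_seed(seed, {
    latents <- draw_latents(mix, n_cells, treatment, logit_shift)
    area <- pmax(20L, as.integer(round(rnorm(n_cells, mean_cell_area, area_sd))))
    counts <- cbind(chat = latents$true_chat, vglut2 = latents$true_vglut2,
                    fos = latents$true_fos)
    rows <- do.call(rbind, lapply(probes(), function(pr) {
      signal_px <- pmin(counts[, pr], area)  # 1 px per punctum, capped at area
      bg_px <- rbinom(n_cells, area - signal_px, mix$background_rate)
      data.frame(cell = latents$cell, probe = pr,
                 puncta_count = counts[, pr] + bg_px,
                 puncta_pixel_volume = signal_px + bg_px,
                 cell_pixel_area = area)
    }))
    rows <- rows[order(rows$cell, match(rows$probe, probes())), ]
    rownames(rows) <- NULL
    bg <- setNames(rep(mix$background_rate, 3), probes())
    puncta <- new_puncta_table(rows, background_rate = bg)
    latents$area <- area
    structure(list(puncta = puncta, truth = latents,
                   background_rate = bg, metadata = metadata),
              class = "roi_table_sim")
  })
}

#' Generate a full simulated study
#'
#' Produces one set of ROIs per mouse x region following a [study_design()].
#' Each mouse receives a random logit-scale shift of its activation
#' probability (`mouse_sd`), inducing the within-mouse correlation of ROI
#' outcomes that the nested statistics must handle.
#'
#' @param design A [study_design()].
#' @param mix A [cell_type_mix()].
#' @param output `"image"` for rendered ROIs ([generate_roi()]) or `"table"`
#'   for per-cell puncta tables ([generate_puncta_table()]).
#' @param mouse_sd SD of the mouse-level logit-normal activation shift
#'   (default 0.2, calibrated so nested-test statistics at 4-5 mice/group
#'   match the reported scale once within-mouse ROI sampling is added).
#' @param n_cells_range Range of per-ROI cell counts, sampled uniformly.
#' @param ... Passed to [generate_roi()] or [generate_puncta_table()].
#' @return List of class `study_sim`: one element per ROI, each carrying the
#'   simulated ROI and a `metadata` list (`roi`, `mouse`, `sex`, `treatment`,
#'   `dose`, `day`, `region`, `hemisphere`).
#' @examples
#' des <- study_design(n_mice_per_group = 2, rois_per_mouse_per_region = 2)
#' st <- generate_study(des, cell_type_mix(), output = "table",
#'                      n_cells_range = c(40, 60))
#' length(st)
#' @export
generate_study <- function(design, mix,
                           output = c("image", "table"),
                           mouse_sd = 0.2,
                           n_cells_range = c(30, 60), ...) {
  stopifnot(inherits(design, "study_design"), inherits(mix, "cell_type_mix"))
  output <- match.arg(output)
  n_groups <- nrow(design$groups)
  n_mice <- n_groups * design$n_mice_per_group
  n_roi_per_mouse <- design$rois_per_mouse_per_region * length(design$regions)
  n_roi <- n_mice * n_roi_per_mouse

  seeds <- child_seeds(design$seed, n_roi + n_mice + 1L)
  shift <- with_seed(seeds[n_roi + n_mice + 1L], rnorm(n_mice, 0, mouse_sd))

  out <- vector("list", n_roi)
  k <- 0L; m <- 0L
  for (g in seq_len(n_groups)) {
    grp <- design$groups[g, ]
    for (i in seq_len(design$n_mice_per_group)) {
      m <- m + 1L
      mouse_id <- sprintf("%s_%s_m%02d", grp$sex, grp$treatment, m)
      for (region in design$regions) {
        for (r in seq_len(design$rois_per_mouse_per_region)) {
          k <- k + 1L
          nrange <- seq(n_cells_range[1], n_cells_range[2])
          n_cells <- with_seed(seeds[n_roi + m],
            nrange[sample.int(length(nrange), n_roi_per_mouse,
                              replace = TRUE)])[(match(region, design$regions) - 1L) *
                                                  design$rois_per_mouse_per_region + r]
          md <- list(roi = sprintf("roi%04d", k), mouse = mouse_id,
                     sex = grp$sex, treatment = grp$treatment,
                     dose = grp$dose, day = grp$days, region = region,
                     hemisphere = if (r %% 2 == 1) "L" else "R")
          sim <- if (output == "image")
            generate_roi(mix, n_cells, seed = seeds[k],
                         treatment = grp$treatment, logit_shift = shift[m],
                         metadata = md, ...)
          else
            generate_puncta_table(mix, n_cells, seed = seeds[k],
                                  treatment = grp$treatment,
                                  logit_shift = shift[m], metadata = md, ...)
          sim$metadata <- md
          out[[k]] <- sim
        }
      }
    }
  }
  structure(out, class = "study_sim")
}

#' @export
print.roi_image <- function(x, ...) {
  cat("<roi_image>", paste(x$dim, collapse = " x "), "px,",
      length(x$channels), "channels:",
      paste(x$channel_names, collapse = ", "), "\n")
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.roi_truth <- function(x, ...) {
  cat("<roi_truth>", nrow(x$cells), "cells;",
      sum(x$cells$activated), "activated\n")
  print(table(x$cells$type))
  invisible(x)
}

#' Write a simulated ROI to disk
#'
#' Writes the image as a multi-page TIFF (one page per channel, order
#' DAPI, *Chat*, *Vglut2*, *Fos*), the ground-truth cell table as CSV, and a
#' JSON manifest holding channel names and metadata.
#'
#' @param sim A `roi_sim` from [generate_roi()].
#' @param dir Output directory (created if needed).
#' @param name Basename for the three files.
#' @return Invisibly, the paths written.
#' @export
write_roi <- function(sim, dir, name = sim$metadata$roi %||% "roi") {
  stopifnot(inherits(sim, "roi_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(dir, paste0(name, ".tiff"))
  arr <- simplify2array(sim$image$channels)
  EBImage::writeImage(EBImage::Image(arr), img_path, type = "tiff")
  truth_path <- file.path(dir, paste0(name, "_truth.csv"))
  write.csv(sim$truth$cells, truth_path, row.names = FALSE)
  man_path <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(list(channel_names = sim$image$channel_names,
                            metadata = sim$image$metadata),
                       man_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(image = img_path, truth = truth_path, manifest = man_path))
}

#' Read a multi-channel ROI image written by [write_roi()]
#'
#' @param path Path to the TIFF; the JSON manifest is looked up alongside.
#' @param metadata Optional metadata list overriding the manifest.
#' @return A `roi_image`.
#' @export
read_roi <- function(path, metadata = NULL) {
  arr <- as.array(EBImage::readImage(path))
  man_path <- sub("\\.tiff?$", ".json", path)
  man <- if (file.exists(man_path)) jsonlite::read_json(man_path, simplifyVector = TRUE)
  ch_names <- man$channel_names %||% c("dapi", probes())[seq_len(dim(arr)[3])]
  channels <- lapply(seq_len(dim(arr)[3]), function(i) arr[, , i])
  names(channels) <- ch_names
  structure(list(channels = channels, channel_names = ch_names,
                 dim = dim(arr)[1:2],
                 metadata = metadata %||% (man$metadata %||% list())),
            class = "roi_image")
}
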