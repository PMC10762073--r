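#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: the simulated study design,
#' cell-type mixture, QC settings, calling alpha, and image-analysis
#' parameters. In `analyze` mode the images and metadata are read from
#' `input_dir` instead of being simulated.
#'
#' @param mode `"full"` (simulate then analyze), `"simulate"` (write images
#'   and ground truth only) or `"analyze"` (read images from `input_dir`).
#' @param out_dir Run directory (created; overwritten files are replaced).
#' @param design A [study_design()] (simulate/full modes).
#' @param mix A [cell_type_mix()].
#' @param qc A [qc_config()].
#' @param alpha Per-ROI family-wise alpha for positivity calls.
#' @param input_dir Directory of TIFFs + `metadata.csv` (analyze mode).
#' @param image_size,n_cells_range,bg_radius,min_size Imaging/analysis
#'   parameters (see [generate_roi()], [quantify_roi()]).
#' @param mouse_sd Mouse random-effect SD (logit scale).
#' @param fos_pct_over Passed to [summarize_roi()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = c("full", "simulate", "analyze"),
                       out_dir,
                       design = study_design(),
                       mix = cell_type_mix(),
                       qc = qc_config(),
                       alpha = 0.01,
                       input_dir = NULL,
                       image_size = c(384, 384),
                       n_cells_range = c(100, 140),
                       bg_radius = 15,
                       min_size = 1,
                       mouse_sd = 0.2,
                       fos_pct_over = "activated") {
  mode <- match.arg(mode)
  if (mode == "analyze") {
    if (is.null(input_dir) || !dir.exists(input_dir))
      stop("analyze mode needs an existing `input_dir`", call. = FALSE)
  }
  stopifnot(inherits(design, "study_design"), inherits(mix, "cell_type_mix"),
            inherits(qc, "qc_config"))
  stop_if_not_prob(alpha, "alpha")
  structure(list(mode = mode, out_dir = out_dir, design = design, mix = mix,
                 qc = qc, alpha = alpha, input_dir = input_dir,
                 image_size = image_size, n_cells_range = n_cells_range,
                 bg_radius = bg_radius, min_size = min_size,
                 mouse_sd = mouse_sd, fos_pct_over = fos_pct_over),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; `design`, `mix` and
#' `qc` are nested maps passed to their constructors. Invalid field values
#' raise a validation error naming the field.
#'
#' @param path YAML file.
#' @param out_dir Optional override of the configured output directory.
#' @return A `run_config`.
#' @export
load_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  design <- if (!is.null(y$design)) {
    d <- y$design
    if (!is.null(d$groups)) d$groups <- as.data.frame(do.call(cbind.data.frame, d$groups))
    do.call(study_design, d)
  } else study_design()
  mix <- if (!is.null(y$mix)) {
    m <- y$mix
    if (!is.null(m$activation_prob)) {
      ap <- do.call(rbind, m$activation_prob)
      colnames(ap) <- m$treatments %||% c("saline", "etoh")
      m$activation_prob <- ap
      m$treatments <- NULL
    }
    if (!is.null(m$signal_rate)) m$signal_rate <- unlist(m$signal_rate)
    do.call(cell_type_mix, m)
  } else cell_type_mix()
  qc <- if (!is.null(y$qc)) do.call(qc_config, y$qc) else qc_config()
  args <- y[setdiff(names(y), c("design", "mix", "qc"))]
  args$design <- design; args$mix <- mix; args$qc <- qc
  if (!is.null(out_dir)) args$out_dir <- out_dir
  if (!is.null(args$image_size)) args$image_size <- unlist(args$image_size)
  if (!is.null(args$n_cells_range)) args$n_cells_range <- unlist(args$n_cells_range)
  do.call(run_config, args)
}

analyze_one_roi <- function(image, cfg) {
  seg <- segment_cells(image$channels$dapi)
  if (nrow(seg$cells) == 0) return(NULL)
  tab <- quantify_roi(image, seg, bg_radius = cfg$bg_radius,
                      min_size = cfg$min_size)
  calls <- call_cells(tab, alpha = cfg$alpha)
  summ <- summarize_roi(calls, metadata = image$metadata,
                        fos_pct_over = cfg$fos_pct_over)
  list(seg = seg, tab = tab, calls = calls, summary = summ)
}

run_stats_stage <- function(summaries, stats_dir, outcome_col = "pct_fos_chat_only") {
  dir.create(stats_dir, recursive = TRUE, showWarnings = FALSE)
  if (!nrow(summaries))
    stop("no ROIs survived QC; nothing to analyze", call. = FALSE)
  sf <- stats_frame(summaries, outcome_col)
  report <- c(sprintf("outcome: %s", outcome_col), "")
  results <- list()

  split_by_sex <- FALSE
  if (length(unique(sf$sex)) >= 2 && length(unique(sf$treatment)) >= 2) {
    mm <- try(mixed_model_sex_treatment(sf), silent = TRUE)
    if (!inherits(mm, "try-error")) {
      results$mixed_model <- mm$table
      write.csv(mm$table, file.path(stats_dir, "mixed_model.csv"),
                row.names = FALSE)
      report <- c(report, "fixed-effects mixed model (random mouse intercept):",
                  vapply(seq_len(nrow(mm$table)), function(i)
                    sprintf("  F_%s(%g, %.1f) = %.4g, P = %.4g",
                            mm$table$effect[i], mm$table$df1[i],
                            mm$table$df2[i], mm$table$F[i], mm$table$p[i]),
                    character(1)),
                  sprintf("  qualitative sex difference: %s",
                          mm$qualitative_sex_difference), "")
      split_by_sex <- isTRUE(mm$qualitative_sex_difference)
    }
  }

  strata <- unique(sf[, intersect(c("sex", "region"), names(sf)), drop = FALSE])
  nested <- list()
  for (i in seq_len(nrow(strata))) {
    sub <- sf
    lab <- character(0)
    for (cn in names(strata)) {
      sub <- sub[sub[[cn]] == strata[[cn]][i], , drop = FALSE]
      lab <- c(lab, paste0(cn, "=", strata[[cn]][i]))
    }
    lab <- paste(lab, collapse = ", ")
    k <- length(unique(sub$treatment))
    res <- try({
      if (k == 2) {
        tt <- nested_ttest(sub)
        report <- c(report, sprintf("%s: nested t(%g) = %.4g, P = %.4g",
                                    lab, tt$df, tt$statistic, tt$p.value))
        data.frame(stratum = lab, test = "nested_t", statistic = tt$statistic,
                   df1 = 1, df2 = tt$df, p = tt$p.value)
      } else if (k > 2) {
        an <- nested_oneway(sub)
        report <- c(report, sprintf("%s: nested F(%g, %g) = %.4g, P = %.4g",
                                    lab, an$df[1], an$df[2], an$statistic,
                                    an$p.value))
        hsd <- tukey_hsd(an)
        write.csv(hsd, file.path(stats_dir,
                                 sprintf("tukey_%s.csv", gsub("[^A-Za-z0-9]+", "_", lab))),
                  row.names = FALSE)
        data.frame(stratum = lab, test = "nested_anova", statistic = an$statistic,
                   df1 = an$df[1], df2 = an$df[2], p = an$p.value)
      } else NULL
    }, silent = TRUE)
    if (!inherits(res, "try-error") && !is.null(res)) nested[[length(nested) + 1]] <- res
  }
  if (length(nested)) {
    nested <- do.call(rbind, nested)
    results$nested <- nested
    write.csv(nested, file.path(stats_dir, "nested_tests.csv"), row.names = FALSE)
  }
  writeLines(report, file.path(stats_dir, "report.txt"))
  results
}

#' Run the end-to-end pipeline
#'
#' Executes simulate -> segment -> quantify -> call -> QC -> stats per the
#' configuration, writing a deterministic run directory: `images/` (simulate
#' and full modes), `cells.csv` (per-cell segmentation table), `calls.csv`
#' (per-cell calls), `roi_summary.csv`, `exclusions.csv`, `stats/` and
#' `manifest.json`. Re-running with an identical configuration reproduces
#' all CSVs bit-identically. On failure a `FAILED` marker naming the error
#' is left in the run directory and the error is re-thrown.
#'
#' @param cfg A [run_config()] (or a YAML path accepted by
#'   [load_run_config()]).
#' @return Invisibly, a list with `summaries`, `qc`, `stats` and the run
#'   directory path.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(cfg$out_dir, "FAILED")
  if (file.exists(marker)) unlink(marker)
  tryCatch(
    run_pipeline_impl(cfg),
    error = function(e) {
      writeLines(conditionMessage(e), marker)
      stop(e)
    })
}

run_pipeline_impl <- function(cfg) {
  out <- cfg$out_dir
  rois <- list()

  if (cfg$mode %in% c("full", "simulate")) {
    study <- generate_study(cfg$design, cfg$mix, output = "image",
                            mouse_sd = cfg$mouse_sd,
                            n_cells_range = cfg$n_cells_range,
                            image_size = cfg$image_size)
    img_dir <- file.path(out, "images")
    md <- lapply(study, function(s) {
      write_roi(s, img_dir)
      as.data.frame(s$metadata)
    })
    write.csv(do.call(rbind, md), file.path(img_dir, "metadata.csv"),
              row.names = FALSE)
    rois <- lapply(study, function(s) {
      img <- s$image
      img$metadata <- s$metadata
      img
    })
  } else {
    md <- read.csv(file.path(cfg$input_dir, "metadata.csv"),
                   stringsAsFactors = FALSE)
    if (!all(md$region %in% c("PPN", "LDT")))
      stop("validation error: field `region` must be 'PPN' or 'LDT'",
           call. = FALSE)
    rois <- lapply(seq_len(nrow(md)), function(i) {
      read_roi(file.path(cfg$input_dir, paste0(md$roi[i], ".tiff")),
               metadata = as.list(md[i, ]))
    })
  }

  if (cfg$mode == "simulate") {
    manifest <- build_manifest(cfg)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(list(dir = out)))
  }

  regions_seen <- unique(vapply(rois, function(r) r$metadata$region %||% "PPN",
                                character(1)))
  if (!all(regions_seen %in% c("PPN", "LDT")))
    stop("validation error: field `region` must be 'PPN' or 'LDT'",
         call. = FALSE)

  cells <- list(); calls <- list(); summaries <- list()
  for (img in rois) {
    res <- analyze_one_roi(img, cfg)
    if (is.null(res)) next
    roi_id <- img$metadata$roi %||% sprintf("roi%04d", length(summaries) + 1L)
    ct <- res$seg$cells; ct$roi <- roi_id
    cells[[length(cells) + 1]] <- ct
    cc <- as.data.frame(res$calls); cc$roi <- roi_id
    calls[[length(calls) + 1]] <- cc
    summaries[[length(summaries) + 1]] <- res$summary
  }
  if (!length(summaries)) stop("no ROIs produced any cells", call. = FALSE)
  write.csv(do.call(rbind, cells), file.path(out, "cells.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, calls), file.path(out, "calls.csv"),
            row.names = FALSE)
  summ <- bind_summaries(summaries)
  write.csv(summ, file.path(out, "roi_summary.csv"), row.names = FALSE)

  qcres <- qc_filter(summ, cfg$qc)
  write.csv(qcres$log, file.path(out, "exclusions.csv"), row.names = FALSE)

  stats_res <- run_stats_stage(qcres$included, file.path(out, "stats"))

  manifest <- build_manifest(cfg)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(dir = out, summaries = summ, qc = qcres, stats = stats_res))
}

build_manifest <- function(cfg) {
  list(
    mode = cfg$mode,
    seed = cfg$design$seed,
    design = list(n_mice_per_group = cfg$design$n_mice_per_group,
                  groups = cfg$design$groups,
                  rois_per_mouse_per_region = cfg$design$rois_per_mouse_per_region,
                  regions = cfg$design$regions),
    mix = list(p = as.list(cfg$mix$p),
               activation_prob = apply(cfg$mix$activation_prob, 1, as.list),
               signal_rate = as.list(cfg$mix$signal_rate),
               background_rate = cfg$mix$background_rate),
    qc = unclass(cfg$qc),
    alpha = cfg$alpha,
    image_size = cfg$image_size, n_cells_range = cfg$n_cells_range,
    bg_radius = cfg$bg_radius, min_size = cfg$min_size,
    mouse_sd = cfg$mouse_sd, fos_pct_over = cfg$fos_pct_over,
    versions = list(package = as.character(packageVersion("punctacall")),
                    R = paste(R.version$major, R.version$minor, sep = ".")))
}
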