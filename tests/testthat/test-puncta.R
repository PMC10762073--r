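make_seg <- function(nr = 30, nc = 30, boxes) {
  # boxes: list of c(r1, r2, c1, c2) rendered as bright blocks, then segmented
  m <- matrix(0, nr, nc)
  for (b in boxes) m[b[1]:b[2], b[3]:b[4]] <- 0.9
  segment_cells(m, min_area = 1, dilation_radius = 0)
}

test_that("puncta detection counts isolated spots and respects min_size", {
  z <- matrix(0, 20, 20)
  expect_equal(nrow(detect_puncta(z, "fixed", threshold = 0.5)$puncta), 0)
  expect_error(detect_puncta(z, "otsu"), "constant")

  ch <- matrix(0, 20, 20)
  ch[cbind(c(2, 5, 9, 14, 18), c(3, 7, 11, 2, 16))] <- 1
  ps <- detect_puncta(ch, "fixed", threshold = 0.5, min_size = 1)
  expect_equal(nrow(ps$puncta), 5)
  expect_equal(sum(ps$puncta$volume), 5)
  # min_size filters out single-pixel spots
  ch[2:3, 18:19] <- 1  # one 4-px punctum
  ps2 <- detect_puncta(ch, "fixed", threshold = 0.5, min_size = 2)
  expect_equal(nrow(ps2$puncta), 1)
  expect_equal(ps2$puncta$volume, 4)
})

test_that("detected components equal a flood-fill oracle on generator output", {
  mix <- cell_type_mix(background_rate = 1e-3)
  sim <- generate_roi(mix, n_cells = 12, seed = 21, noise_sd = 0)
  ch <- sim$image$channels$chat
  ps <- detect_puncta(ch, "fixed", threshold = 0.5)
  expect_equal(nrow(ps$puncta), flood_fill_count(ch > 0.5))
  expect_equal(sum(ps$puncta$volume), sum(ch > 0.5))
})

test_that("raising the detection threshold never increases the puncta signal", {
  # total puncta-positive volume is monotone for any image; component counts
  # are monotone once spots are isolated (a dense blob can split when the
  # threshold rises, which is why the test separates the two claims)
  set.seed(4)
  ch <- matrix(runif(900)^4, 30, 30)
  vols <- vapply(seq(0.1, 0.9, by = 0.1), function(th)
    sum(detect_puncta(ch, "fixed", threshold = th)$puncta$volume), numeric(1))
  expect_true(all(diff(vols) <= 0))
  sparse <- matrix(0, 30, 30)
  sparse[cbind(seq(2, 28, by = 4), seq(2, 28, by = 4))] <- runif(7, 0.2, 1)
  counts <- vapply(seq(0.1, 0.9, by = 0.1), function(th)
    nrow(detect_puncta(sparse, "fixed", threshold = th)$puncta), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("puncta are assigned by centroid containment, once each", {
  seg <- make_seg(boxes = list(c(3, 8, 3, 8), c(15, 20, 15, 20),
                               c(24, 28, 3, 7)))
  expect_equal(nrow(seg$cells), 3)
  ch <- matrix(0, 30, 30)
  ch[5, 5] <- 1        # inside cell 1
  ch[25, 5] <- 1       # inside cell 3
  ch[12, 12] <- 1      # background
  ps <- detect_puncta(ch, "fixed", threshold = 0.5)
  tab <- assign_puncta(seg, ps)
  expect_equal(tab$puncta_count, c(1, 0, 1))
  expect_equal(attr(tab, "background_count"), 1)
  # conservation: total = per-cell + background
  expect_equal(sum(tab$puncta_count) + attr(tab, "background_count"),
               nrow(ps$puncta))
  # geometry mismatch is rejected
  bad <- detect_puncta(matrix(0, 10, 10), "fixed", threshold = 0.5)
  expect_error(assign_puncta(seg, bad), "geometr")
})

test_that("per-cell counts equal ground truth when puncta lie inside masks", {
  ap <- default_activation_prob(); ap[] <- 0
  mix <- cell_type_mix(p_chat_only = 1, p_vglut_only = 0, p_colabel = 0,
                       p_neither = 0, activation_prob = ap,
                       background_rate = 0)
  sim <- generate_roi(mix, n_cells = 10, seed = 14, noise_sd = 0)
  seg <- new_seg_from_truth <- structure(
    list(label = sim$truth$label,
         cells = data.frame(cell = sim$truth$cells$cell,
                            area = sim$truth$cells$area,
                            row = sim$truth$cells$row,
                            col = sim$truth$cells$col),
         threshold = NA_real_), class = "segmented_roi")
  ps <- detect_puncta(sim$image$channels$chat, "fixed", threshold = 0.5)
  tab <- assign_puncta(seg, ps)
  # pixel volumes match the rendered truth exactly (puncta may merge, so
  # compare distinct puncta pixels per cell, not Poisson draws)
  for (i in sim$truth$cells$cell) {
    truth_px <- sum(sim$image$channels$chat[sim$truth$label == i] > 0.5)
    expect_equal(tab$puncta_pixel_volume[tab$cell == i], truth_px)
  }
  expect_equal(attr(tab, "background_count"), 0)
})

test_that("background rate is the puncta-positive fraction of background", {
  seg <- make_seg(nr = 100, nc = 100, boxes = list(c(40, 59, 40, 59)))
  n_bg <- 100 * 100 - seg$cells$area
  ch <- matrix(0, 100, 100)
  bg_px <- which(seg$label == 0)[seq(1, 9000, length.out = 10)]
  ch[bg_px] <- 1
  ps <- detect_puncta(ch, "fixed", threshold = 0.5)
  expect_equal(estimate_background(ps, seg), 10 / n_bg)
  # no background puncta -> 0
  expect_equal(estimate_background(detect_puncta(matrix(0, 100, 100), "fixed",
                                                 threshold = 0.5), seg), 0)
  # zero background area errors
  full <- structure(list(label = matrix(1L, 5, 5),
                         cells = data.frame(cell = 1, area = 25, row = 3, col = 3),
                         threshold = NA_real_), class = "segmented_roi")
  expect_error(estimate_background(matrix(FALSE, 5, 5), full), "background")
})

test_that("background-rate estimation is unbiased over repeated simulations", {
  mix <- cell_type_mix(background_rate = 5e-4)
  rates <- vapply(1:60, function(s) {
    sim <- generate_puncta_table(mix, n_cells = 1, seed = s)
    # image-free check is meaningless; render a small frame instead
    sim2 <- generate_roi(mix, n_cells = 4, seed = s, image_size = c(128, 128),
                         noise_sd = 0)
    seg <- structure(list(label = sim2$truth$label,
                          cells = data.frame(cell = sim2$truth$cells$cell,
                                             area = sim2$truth$cells$area,
                                             row = sim2$truth$cells$row,
                                             col = sim2$truth$cells$col),
                          threshold = NA_real_), class = "segmented_roi")
    ps <- detect_puncta(sim2$image$channels$chat, "fixed", threshold = 0.5)
    estimate_background(ps, seg)
  }, numeric(1))
  n_bg_approx <- 128^2 - 4 * pi * 81
  se <- sqrt(5e-4 * (1 - 5e-4) / (60 * n_bg_approx))
  expect_lt(abs(mean(rates) - 5e-4), 2 * se + 1e-6)
})

test_that("quantify_roi produces a tidy conserved table with background rates", {
  sim <- generate_roi(cell_type_mix(), n_cells = 15, seed = 6)
  seg <- segment_cells(sim$image$channels$dapi)
  tab <- quantify_roi(sim$image, seg, bg_radius = 15)
  expect_s3_class(tab, "puncta_table")
  expect_equal(nrow(tab), nrow(seg$cells) * 3)
  expect_setequal(unique(tab$probe), c("chat", "vglut2", "fos"))
  expect_true(all(tab$puncta_pixel_volume >= 0))
  expect_true(all(tab$cell_pixel_area > 0))
  bg <- attr(tab, "background_rate")
  expect_true(all(bg >= 0 & bg <= 1))
  # CSV + JSON sidecar round-trip
  dir <- withr::local_tempdir()
  write_puncta_table(tab, file.path(dir, "tab.csv"), file.path(dir, "bg.json"))
  back <- read.csv(file.path(dir, "tab.csv"))
  expect_equal(nrow(back), nrow(tab))
  bgj <- jsonlite::read_json(file.path(dir, "bg.json"))
  expect_equal(unlist(bgj), bg, tolerance = 1e-12)
})
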