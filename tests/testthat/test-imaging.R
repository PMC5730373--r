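make_disc_labels <- function(h = 64, w = 64, centers, r_px) {
  lab <- matrix(0L, h, w)
  for (i in seq_len(nrow(centers))) {
    for (x in seq_len(w)) {
      for (y in seq_len(h)) {
        if ((x - centers$cx[i])^2 + (y - centers$cy[i])^2 <= r_px^2) {
          lab[y, x] <- i
        }
      }
    }
  }
  array(lab, dim = c(h, w, 1))
}

test_that("background subtraction removes scalars and clips at zero", {
  arr <- array(110, dim = c(8, 8, 2))
  fs <- frame_set(list(YFP = arr), pixel_size = 0.5, background = 100)
  out <- subtract_background(fs)
  expect_equal(out$channels$YFP, array(10, dim = c(8, 8, 2)))
  fs0 <- frame_set(list(YFP = arr), pixel_size = 0.5, background = 0)
  expect_equal(subtract_background(fs0)$channels$YFP, arr)
  fs2 <- frame_set(list(YFP = array(90, dim = c(8, 8, 1))), 0.5,
                   background = 100)
  expect_true(all(subtract_background(fs2)$channels$YFP == 0))
  expect_error(subtract_background(fs, matrix(FALSE, 8, 8)), "empty")
})

test_that("background-region subtraction leaves cell-free residual near zero", {
  set.seed(4)
  arr <- array(100 + rnorm(16 * 16, 0, 2), dim = c(16, 16, 1))
  bgmask <- matrix(TRUE, 16, 16)
  bgmask[1:8, ] <- FALSE
  fs <- frame_set(list(CFP = arr), 0.5, background = bgmask)
  out <- subtract_background(fs)
  resid <- mean(out$channels$CFP[, , 1][bgmask])
  expect_lt(abs(resid), 2) # clipped-at-zero mean stays within noise sd
})

test_that("erosion depth follows pixel size and shrinks nuclei", {
  labs <- make_disc_labels(centers = data.frame(cx = 32, cy = 32), r_px = 10)
  ms <- derive_masks(labs, pixel_size = 0.5, erode_um = 1)
  orig_area <- sum(labs == 1)
  er_area <- sum(ms$eroded == 1)
  expect_lt(er_area, orig_area)
  # 1 um at 0.5 um/px = 2 px erosion; area ~ pi * (r - k)^2 by pixel counting
  r_eff <- 10 - 2
  expect_lt(abs(er_area - pi * r_eff^2) / (pi * r_eff^2), 0.15)
  # erosion annihilates a tiny nucleus -> flagged and dropped
  tiny <- make_disc_labels(centers = data.frame(cx = 10, cy = 10), r_px = 1)
  ms2 <- derive_masks(tiny, pixel_size = 0.5, erode_um = 1)
  expect_true(1 %in% ms2$dropped)
})

test_that("donuts avoid nuclei, stay disjoint and split contested pixels", {
  labs <- make_disc_labels(centers = data.frame(cx = c(20, 44), cy = c(32, 32)),
                           r_px = 8)
  ms <- derive_masks(labs, pixel_size = 0.5)
  don <- ms$donut[, , 1]
  lab <- labs[, , 1]
  expect_true(all(don[lab > 0] == 0))               # no nuclear pixels
  expect_true(all((don > 0) + (ms$eroded[, , 1] > 0) <= 1))
  # the eroded-perimeter inner-rim variant touches closer to the nucleus
  ms_alt <- derive_masks(labs, pixel_size = 0.5, inner = "eroded_perimeter")
  expect_gt(sum(ms_alt$donut > 0), sum(ms$donut > 0))
  # its donuts overlap at the midline; contested pixels go to the nearer
  # nucleus, splitting the shared band at the symmetry axis
  don2 <- ms_alt$donut[, , 1]
  expect_true(all(don2[, 1:32][don2[, 1:32] > 0] == 1))
  expect_true(all(don2[, 33:64][don2[, 33:64] > 0] == 2))
})

test_that("channel means recover uniform values and flag empty regions", {
  labs <- make_disc_labels(centers = data.frame(cx = 32, cy = 32), r_px = 10)
  arr <- array(7, dim = c(64, 64, 1))
  fs <- frame_set(list(YFP = arr), pixel_size = 0.5, background = 0)
  ms <- derive_masks(labs, pixel_size = 0.5)
  cm <- extract_channel_means(fs, ms)
  expect_equal(cm$nuclear_mean, 7)
  expect_equal(cm$cyto_mean, 7)
})

test_that("index formulas are the specified channel ratios", {
  means <- tibble::tibble(
    cell = 1, frame = 1, time_min = 0,
    channel = c("TSapphire", "YFP", "CFP", "RFP"),
    nuclear_mean = c(120, 120, 50, 80),
    cyto_mean = c(10, 100, 200, 80))
  expect_equal(compute_index(means, "NADH")$value, 1)
  expect_equal(compute_index(means, "Akt")$value, 1)
  expect_equal(compute_index(means, "AMPK_raw")$value, 2)
  # missing denominator -> NA
  means$cyto_mean[means$channel == "YFP"] <- 0
  expect_true(is.na(compute_index(means, "AMPK_raw")$value))
  expect_error(compute_index(means[means$channel != "RFP", ], "Akt"), "RFP")
})

test_that("AMPK offset inversion matches the forced example and is offset-invariant", {
  tr <- tibble::tibble(cell_id = "c1", time_min = c(0, 3, 6),
                       reporter = "AMPK_raw", value = c(2, 2.5, 3),
                       condition = "x", replicate = "R1",
                       treatment_time_min = 0)
  out <- normalize_ampk_offset(tr)
  expect_equal(out$value, c(1, 0.5, 0))
  expect_equal(unique(out$reporter), "AMPK")
  # monotone decreasing raw -> monotone increasing index
  expect_true(all(diff(out$value[order(tr$value, decreasing = TRUE)]) >= 0))
  tr2 <- tr
  tr2$value <- tr$value + 11
  expect_equal(normalize_ampk_offset(tr2)$value, out$value)
  expect_error(normalize_ampk_offset(dplyr::mutate(tr, reporter = "NADH")),
               "AMPK_raw")
})

test_that("rendered fixtures round-trip through the imaging pipeline exactly", {
  tr <- simulate_traces("dual_ia", n_cells = 2, seed = 1, duration = 30,
                        treatment_time = 0, noise_sd = 0, drift_sd = 0,
                        death_window = NULL, locked_fraction = 1)
  cells <- tibble::tibble(cell_id = c("cell_0001", "cell_0002"),
                          cx = c(24, 72), cy = c(24, 72),
                          nucleus_radius_um = 5, cyto_radius_um = 10)
  geo <- scene_geometry(width = 96, height = 96, pixel_size = 0.5,
                        cells = cells)
  r <- render_synthetic_frames(tr, geo)
  # ground-truth masks are pairwise disjoint label regions
  expect_equal(sort(unique(as.vector(r$masks))), c(0L, 1L, 2L))
  ext <- extract_indices(r$frames, r$masks,
                         reporters = c("NADH", "Akt", "AMPK_raw"),
                         condition = "dual_ia")
  ext <- normalize_ampk_offset(ext)
  truth <- as_tibble(tr)
  # AMPK is defined up to the per-experiment offset; align both to min 0
  for (rep_name in c("NADH", "Akt", "AMPK")) {
    got <- ext[ext$reporter == rep_name, c("cell_id", "time_min", "value")]
    want <- truth[truth$reporter == rep_name,
                  c("cell_id", "time_min", "value")]
    j <- dplyr::inner_join(got, want, by = c("cell_id", "time_min"))
    expect_gt(nrow(j), 0)
    if (rep_name == "AMPK") {
      j$value.x <- j$value.x - min(j$value.x)
      j$value.y <- j$value.y - min(j$value.y)
    }
    expect_lt(max(abs(j$value.x - j$value.y)), 1e-6)
  }
  # zero-cell scene renders background-only frames with empty masks
  geo0 <- scene_geometry(cells = cells[0, ], background = 50)
  r0 <- render_synthetic_frames(tr[0, ], geo0)
  expect_true(all(r0$masks == 0))
  expect_true(all(vapply(r0$frames$channels, function(a) all(a == 50),
                         logical(1))))
  # overlapping nuclei are rejected
  expect_error(scene_geometry(cells = dplyr::mutate(cells, cx = c(24, 26),
                                                    cy = 24)),
               "overlap")
})

test_that("scaling all channels by a common factor leaves indices unchanged", {
  tr <- simulate_traces("dual_ia", n_cells = 1, seed = 2, duration = 30,
                        treatment_time = 0, noise_sd = 0, drift_sd = 0,
                        death_window = NULL)
  cells <- tibble::tibble(cell_id = "cell_0001", cx = 32, cy = 32,
                          nucleus_radius_um = 5, cyto_radius_um = 12)
  geo <- scene_geometry(width = 64, height = 64, pixel_size = 0.5,
                        cells = cells, background = 0)
  r <- render_synthetic_frames(tr, geo)
  scaled <- r$frames
  for (ch in names(scaled$channels)) {
    scaled$channels[[ch]] <- scaled$channels[[ch]] * 2.5
  }
  a <- extract_indices(r$frames, r$masks, c("NADH", "Akt", "AMPK_raw"))
  b <- extract_indices(scaled, r$masks, c("NADH", "Akt", "AMPK_raw"))
  # AMPK_raw is a pure ratio too, so all three match before normalization
  expect_equal(b$value, a$value, tolerance = 1e-12)
})

test_that("frame stacks and masks survive the 16-bit TIFF round trip", {
  tr <- simulate_traces("ia_high", n_cells = 1, seed = 1, duration = 9,
                        treatment_time = 0, noise_sd = 0, drift_sd = 0,
                        death_window = NULL)
  cells <- tibble::tibble(cell_id = "cell_0001", cx = 16, cy = 16,
                          nucleus_radius_um = 3, cyto_radius_um = 7)
  geo <- scene_geometry(width = 32, height = 32, pixel_size = 0.5,
                        cells = cells)
  r <- render_synthetic_frames(tr, geo)
  dir <- withr::local_tempdir()
  write_frames_tiff(r$frames, dir)
  back <- read_stack_tiff(file.path(dir, "YFP.tif"))
  expect_equal(back, round(r$frames$channels$YFP))
  mp <- file.path(dir, "masks.tif")
  write_masks_tiff(r$masks, mp)
  expect_equal(read_stack_tiff(mp), r$masks + 0)
})
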