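test_that("red color intensity is 255 minus the Blue channel", {
  px <- array(255, dim = c(2, 2, 3))
  px[1, 1, ] <- c(200, 80, 255)
  px[1, 2, ] <- c(255, 255, 0)
  img <- stain_image(px, dpi = 300)
  m <- to_intensity(img)
  expect_equal(m$values[1, 1], 0)
  expect_equal(m$values[1, 2], 255)
  expect_equal(m$values[2, ], c(0, 0))  # all-white rows map to zero
  expect_equal(m$dpi, 300)
  expect_error(to_intensity(matrix(1, 2, 2)), "Blue channel")
})

test_that("radial profile averages pixels by distance bin", {
  uni <- intensity_map(matrix(37, 41, 41), dpi = 254)  # 10 px per mm
  prof <- compute_radial_profile(uni, c(21, 21), bin_width_mm = 0.5)
  expect_true(all(prof$mean_intensity == 37))
  expect_true(all(diff(prof$bin_center_mm) > 0))

  # perfect disk of intensity 80, radius 1.5 mm on zero background
  r <- sqrt(outer((1:41 - 21)^2, (1:41 - 21)^2, `+`)) / 10
  disk <- intensity_map(80 * (r <= 1.5), dpi = 254)
  prof <- compute_radial_profile(disk, c(21, 21), bin_width_mm = 0.5)
  expect_equal(prof$mean_intensity[prof$bin_center_mm < 1.4][1], 80)
  expect_error(compute_radial_profile(disk, c(100, 21), 0.5), "outside")
})

test_that("noise-free generator profile matches the closed-form model", {
  p <- generator_params(percent_hbs = 40, noise_sd = 0)
  st <- generate_stain(p)
  m <- to_intensity(st$image)
  ctr <- c(st$truth$center_x_px, st$truth$center_y_px)
  prof <- compute_radial_profile(m, ctr, bin_width_mm = 0.1, max_radius_mm = 9)
  model <- stain_model(prof$bin_center_mm, p)
  # bin means average the model over a 0.1 mm shell; agreement away from the
  # steep edges is tight, at the edges bounded by the within-bin variation
  steep <- abs(prof$bin_center_mm - 2.5) < 0.5 | abs(prof$bin_center_mm - 7.5) < 0.5
  expect_lt(max(abs(prof$mean_intensity[!steep] - model[!steep])), 0.5)
  expect_lt(max(abs(prof$mean_intensity - model)), 15)
})

test_that("geometry estimation recovers disk and stain radii", {
  r <- sqrt(outer((1:161 - 81)^2, (1:161 - 81)^2, `+`)) / 10
  disk <- intensity_map(100 * (r <= 2.5), dpi = 254)
  prof <- compute_radial_profile(disk, c(81, 81), bin_width_mm = 0.2)
  g <- estimate_geometry(prof, geometry_config(background = 0))
  # a bare disk has r_outer at the disk edge; r_center sits at the clamp
  # r_outer - margin just below it
  expect_lt(abs(g$r_outer - 2.5), 0.3)
  expect_lt(abs(g$r_center - (g$r_outer - 0.5)), 1e-9)

  # generator stain: r_outer within one bin of the nominal outer radius
  p <- generator_params(percent_hbs = 40, noise_sd = 0)
  ix <- index_stain(p)
  expect_lt(abs(ix$geom$r_outer - p$r_outer_mm), 0.3)
  expect_lt(abs(ix$geom$r_center - p$r_center_mm), 0.3)

  flat <- intensity_map(matrix(10, 61, 61), dpi = 254)
  prof_flat <- compute_radial_profile(flat, c(31, 31), 0.2)
  expect_error(estimate_geometry(prof_flat, geometry_config(background = 10)),
               "no stain")
})

test_that("S-index is the center/ring mean intensity quotient", {
  # constructed map: center mean 120, ring mean 60
  r <- sqrt(outer((1:161 - 81)^2, (1:161 - 81)^2, `+`)) / 10
  v <- 120 * (r <= 2.5) + 60 * (r > 2.5 & r <= 7.5)
  m <- intensity_map(v, dpi = 254)
  expect_equal(compute_s_index(m, c(81, 81), 2.5, 7.5), 2.0)
  uni <- intensity_map(matrix(42, 161, 161), dpi = 254)
  expect_equal(compute_s_index(uni, c(81, 81), 2.5, 7.5), 1.0)
  zero <- intensity_map(matrix(0, 161, 161), dpi = 254)
  expect_error(compute_s_index(zero, c(81, 81), 2.5, 7.5),
               class = "stainscore_undefined_index")
})

test_that("S-index is invariant under intensity scaling", {
  p <- generator_params(percent_hbs = 60, background = 0, noise_sd = 0)
  ix <- index_stain(p, geometry_config(background = 0))
  scaled <- intensity_map(ix$map$values * 3.7, ix$map$dpi)
  s2 <- compute_s_index(scaled, ix$center, ix$geom$r_center, ix$geom$r_outer)
  expect_lt(abs(s2 / ix$s - 1), 1e-9)
})

test_that("generator S-index increases across the AA/AS/SS %HbS levels", {
  s <- vapply(c(0, 40, 85), function(pct)
    index_stain(generator_params(percent_hbs = pct, noise_sd = 0))$s,
    numeric(1))
  expect_true(all(diff(s) > 0))
})

test_that("C-index is the center total times the 5 mm mean", {
  zero <- intensity_map(matrix(0, 161, 161), dpi = 254)
  expect_equal(compute_c_index(zero, c(81, 81), 2.5), 0)

  p <- generator_params(percent_hbs = 40, background = 0, noise_sd = 0)
  ix <- index_stain(p, geometry_config(background = 0))
  doubled <- intensity_map(ix$map$values * 2, ix$map$dpi)
  c2 <- compute_c_index(doubled, ix$center, ix$geom$r_center)
  expect_equal(c2, 4 * ix$c, tolerance = 1e-12)

  # matches independent evaluation of the closed-form model on the grid
  H <- nrow(ix$map$values); W <- ncol(ix$map$values)
  r <- px_to_mm(sqrt(outer((seq_len(H) - ix$center[2])^2,
                           (seq_len(W) - ix$center[1])^2, `+`)), p$dpi)
  model <- stain_model(r, p)
  oracle <- sum(model[r <= ix$geom$r_center]) *
    mean(model[abs(r - 5) <= 0.25])
  expect_lt(abs(ix$c / oracle - 1), 1e-6)

  # annulus outside the image is a domain error
  small <- intensity_map(matrix(50, 41, 41), dpi = 254)
  expect_error(compute_c_index(small, c(21, 21), 1), "outside")
})

test_that("C-index grows with hemoglobin concentration at fixed %HbS", {
  cc <- vapply(c(8, 11, 14, 17), function(hb)
    index_stain(generator_params(percent_hbs = 40, hb_conc = hb,
                                 noise_sd = 0))$c, numeric(1))
  expect_true(all(diff(cc) > 0))
})

test_that("detection recovers planted stains and ignores blank sheets", {
  layout <- sheet_layout(nrow = 2, ncol = 4, pitch_mm = 22, margin_mm = 10)
  samples <- lapply(rep(c(0, 40, 85, 40), 2), function(pct)
    generator_params(percent_hbs = pct, noise_sd = 0))
  sh <- generate_sheet(samples, layout, seed = 8)
  det <- detect_stains(to_intensity(sh$image))
  expect_equal(nrow(det), 8)
  m <- match_detections(
    data.frame(center_x_px = det$center_x, center_y_px = det$center_y),
    sh$truth)
  expect_equal(nrow(m), 8)
  expect_lt(max(m$center_error_px), 2)

  blank <- generate_sheet(list(), layout, seed = 1)
  expect_equal(nrow(detect_stains(to_intensity(blank$image))), 0)
})

test_that("detection stays within 3 px of truth under pixel noise", {
  p <- generator_params(percent_hbs = 85, hb_conc = 9, noise_sd = 3, seed = 2)
  sh <- generate_sheet(list(p), sheet_layout(1, 1, pitch_mm = 25,
                                             margin_mm = 12), seed = 21)
  det <- detect_stains(to_intensity(sh$image))
  expect_equal(nrow(det), 1)
  err <- sqrt((det$center_x - sh$truth$center_x_px)^2 +
              (det$center_y - sh$truth$center_y_px)^2)
  expect_lt(err, 3)
})

test_that("index computations are pure", {
  p <- generator_params(percent_hbs = 40, noise_sd = 3, seed = 4)
  ix1 <- index_stain(p)
  ix2 <- index_stain(p)
  expect_identical(ix1$s, ix2$s)
  expect_identical(ix1$c, ix2$c)
})
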