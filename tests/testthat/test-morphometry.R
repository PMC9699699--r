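test_that("N/C ratio and classification behave at and around the cutoff", {
  img <- matrix(100, 20, 20)
  nuc <- matrix(FALSE, 20, 20); nuc[8:12, 8:12] <- TRUE
  cyt <- matrix(FALSE, 20, 20); cyt[2:6, 2:6] <- TRUE
  r <- nc_ratio_and_class(img, nuc, cyt)
  expect_equal(r$nc_ratio, 1.0)
  expect_equal(r$nuclear_class, "nucleus_filled")
  img2 <- img; img2[nuc] <- 40
  r2 <- nc_ratio_and_class(img2, nuc, cyt)
  expect_equal(r2$nc_ratio, 0.4)
  expect_equal(r2$nuclear_class, "nucleus_excluded")
  img3 <- img; img3[nuc] <- 80               # exactly the cutoff: excluded
  expect_equal(nc_ratio_and_class(img3, nuc, cyt)$nuclear_class,
               "nucleus_excluded")
  # scale invariance
  expect_equal(nc_ratio_and_class(5 * img2, nuc, cyt)$nc_ratio, 0.4)
  expect_error(nc_ratio_and_class(img, nuc, nuc), "overlap")
  expect_error(nc_ratio_and_class(img, matrix(FALSE, 20, 20), cyt), "empty")
})

test_that("rendered images recover the preset N/C ratio and class", {
  mp <- build_morph_presets()
  img <- render_neuron_image(get_preset(mp, "DIV28", "toxic"), seed = 2)
  r <- nc_ratio_and_class(img$pixels, img$masks$nucleus, img$masks$cytosol)
  expect_lt(abs(r$nc_ratio - img$truth_nc_ratio) / img$truth_nc_ratio, 0.05)
  imgs <- lapply(1:8, function(s) {
    render_neuron_image(get_preset(mp, "DIV28", "toxic"), seed = 100 + s)
  })
  classes <- vapply(imgs, function(im) {
    nc_ratio_and_class(im$pixels, im$masks$nucleus, im$masks$cytosol)$nuclear_class
  }, character(1))
  expect_gt(mean(classes == "nucleus_filled"), 0.5)   # N/C 1.1 +/- 0.15
})

test_that("soma area is pixel count times pixel size squared", {
  m <- matrix(FALSE, 30, 30); m[1:10, 1:10] <- TRUE
  expect_equal(soma_area(m, 1), 100)
  expect_equal(soma_area(m, 0.5), 25)
  expect_error(soma_area(matrix(FALSE, 5, 5), 1), "empty")
  # rasterized disk of radius 9.77 um ~ 300 um^2
  r <- 9.772
  xg <- matrix(rep(1:100, each = 100), 100)
  yg <- matrix(rep(1:100, times = 100), 100)
  disk <- (xg - 50)^2 + (yg - 50)^2 <= r^2
  expect_lt(abs(soma_area(disk, 1) - pi * r^2) / (pi * r^2), 0.05)
  expect_lt(abs(soma_area(disk, 1) - 300) / 300, 0.05)
})

test_that("skeleton length weights axial and diagonal steps correctly", {
  m <- matrix(FALSE, 120, 120)
  m[60, 10:110] <- TRUE                      # spans 100 px -> 100 steps
  expect_equal(total_neurite_length(m, 1), 100)
  expect_equal(total_neurite_length(m, 0.5), 50)
  d <- matrix(FALSE, 120, 120)
  for (i in 0:100) d[10 + i, 10 + i] <- TRUE # 100 diagonal steps
  expect_equal(total_neurite_length(d, 1), 100 * sqrt(2))
  # additivity over disjoint components
  both <- m | d
  expect_equal(total_neurite_length(both, 1),
               total_neurite_length(m, 1) + total_neurite_length(d, 1),
               tolerance = 0.03)
  expect_warning(z <- total_neurite_length(matrix(FALSE, 5, 5), 1), "empty")
  expect_equal(z, 0)
})

test_that("thick strokes thin to the same centerline length", {
  m <- matrix(FALSE, 60, 120)
  m[29:31, 10:110] <- TRUE                   # 3-px-thick horizontal bar
  len <- total_neurite_length(m, 1)
  expect_lt(abs(len - 100) / 100, 0.05)
})

test_that("generator trees recover truth length within tolerance", {
  mp <- build_morph_presets()
  errs <- vapply(1:10, function(s) {
    img <- render_neuron_image(get_preset(mp, "DIV28", "healthy"), seed = s)
    (total_neurite_length(img$masks$neurites, img$pixel_size) -
       img$truth_length) / img$truth_length
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.05)
  expect_true(all(abs(errs) < 0.12))
})

test_that("Sholl profiles count crossings of straight and branched neurites", {
  sk <- matrix(FALSE, 200, 200)
  sk[100, 100:180] <- TRUE                   # single straight 80 um neurite
  prof <- sholl_profile(sk, c(100, 100), step = 10, max_radius = 100,
                        pixel_size = 1)
  expect_equal(prof$intersections[1:8], rep(1L, 8))
  expect_equal(prof$intersections[9:10], c(0L, 0L))
  # Y-branch: trunk to 30 um, two arms to ~70 um
  y <- matrix(FALSE, 200, 200)
  y[100, 100:130] <- TRUE
  for (i in 0:40) { y[100 - i, 130 + i] <- TRUE; y[100 + i, 130 + i] <- TRUE }
  profy <- sholl_profile(y, c(100, 100), step = 10, max_radius = 90,
                         pixel_size = 1)
  expect_equal(profy$intersections[1:3], rep(1L, 3))
  expect_true(all(profy$intersections[4:7] == 2L))
  expect_error(sholl_profile(sk, c(500, 500), 10, 50), "outside")
})

test_that("generator-tree Sholl matches the exact circle-crossing oracle", {
  mp <- build_morph_presets()
  img <- render_neuron_image(get_preset(mp, "DIV21", "healthy"), seed = 6)
  sk <- skeletonize(img$masks$neurites)
  prof <- sholl_profile(sk, img$soma_center, step = 15, max_radius = 90,
                        pixel_size = img$pixel_size)
  soma_r_px <- sqrt(img$truth_soma_area / pi) / img$pixel_size
  for (i in seq_len(nrow(prof))) {
    r_px <- prof$radius[i] / img$pixel_size
    if (r_px <= soma_r_px + 2) next          # inside/near soma: no neurites
    pts <- oracle_circle_crossing_points(img$polylines, img$soma_center, r_px)
    if (nrow(pts) > 1 && min(dist(pts)) < 4) next  # coincident crossings
                                                   # merge into one pixel run
    expect_lte(abs(prof$intersections[i] - nrow(pts)), 1)
  }
})

test_that("image contrast follows 1 - 2/(F/Fbg + 1)", {
  expect_equal(image_contrast(100, 100), 0)
  expect_equal(image_contrast(300, 100), 0.5)
  expect_lt(abs(image_contrast(1e6 * 100, 100) - 1), 1e-4)
  expect_error(image_contrast(100, 0), "positive")
  # strictly increasing, bounded
  f <- c(0.01, 0.1, 1, 10, 1000)
  v <- image_contrast(f, 1)
  expect_true(all(diff(v) > 0))
  expect_true(all(v > -1 & v < 1))
})
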