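test_that("five-line distance data points are means with audit trail", {
  segs <- cbind(0, (1:5) * 10, 184, (1:5) * 10)
  dp <- distance_datapoint(line_set(segs, "between_braids"))
  expect_equal(dp$value, 184)
  expect_equal(dp$component_values, rep(184, 5))
  expect_equal(dp$kind, "spacing")
  # arithmetic mean of unequal lines
  segs2 <- cbind(0, (1:5) * 10, c(180, 182, 184, 186, 188), (1:5) * 10)
  expect_equal(distance_datapoint(line_set(segs2, "between_braids"))$value, 184)
  # permutation invariance
  perm <- segs2[c(4, 1, 5, 2, 3), ]
  expect_equal(distance_datapoint(line_set(perm, "between_braids"))$value, 184)
  # the protocol is exactly five lines
  expect_error(line_set(segs2[1:4, ], "between_braids"), "five")
  expect_error(line_set(rbind(segs2, segs2[1, ]), "between_braids"), "five")
})

test_that("trace length sums segment lengths", {
  expect_equal(trace_length(polyline(rbind(c(0, 0), c(500, 0)))), 500)
  sq <- polyline(rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100)))
  expect_equal(trace_length(sq), 300)  # open square, 4 vertices
  set.seed(6)
  v <- matrix(runif(20, 0, 1000), ncol = 2)
  oracle <- sum(sqrt(rowSums((v[-1, ] - v[-nrow(v), ])^2)))
  expect_equal(trace_length(polyline(v)), oracle)
})

test_that("FWHM width measurement is analytic on a noiseless Gaussian ridge", {
  ps <- 1
  sdw <- 5
  xc <- (0:511) * ps
  img <- rendered_image(matrix(exp(-(xc - 250)^2 / (2 * sdw^2)),
                               64, 512, byrow = TRUE), ps)
  w <- width_profile(img, c(200, 30, 300, 30))
  expect_equal(w, 2 * sqrt(2 * log(2)) * sdw, tolerance = (ps / 2) / 11)
  # flat cut: no ridge above background
  flat <- rendered_image(matrix(1, 32, 128), ps)
  expect_error(width_profile(flat, c(10, 16, 100, 16)), "no ridge")
})

test_that("synthetic coated filament measures in the expected replica width range", {
  p <- braid_scene_params(filament_diameter = 7, coating_thickness = 2,
                          braid_gap = 60, pixel_size = 1,
                          image_size = c(64, 1024), noise_sd = 0, seed = 4)
  b <- make_braid_image(p)
  x_fil <- b$truth$braid_centers[2] - 30
  w <- width_profile(b$image, c(x_fil - 25, 32, x_fil + 25, 32))
  expect_gte(w, 9)
  expect_lte(w, 11 + p$pixel_size / 2)
})

test_that("width is stable to oblique cuts after obliquity correction", {
  ps <- 1
  sdw <- 8 / (2 * sqrt(2 * log(2)))  # true FWHM 8 nm, vertical ridge at x = 250
  xc <- (0:511) * ps
  img <- rendered_image(matrix(exp(-(xc - 250)^2 / (2 * sdw^2)),
                               256, 512, byrow = TRUE), ps)
  w0 <- width_profile(img, c(220, 128, 280, 128))
  for (ang in c(-20, -10, 10, 20) * pi / 180) {
    cut <- c(250 - 40 * cos(ang), 128 - 40 * sin(ang),
             250 + 40 * cos(ang), 128 + 40 * sin(ang))
    wc <- width_profile(img, cut, obliquity_correction = TRUE)
    expect_equal(wc, w0, tolerance = ps / 8)
  }
})

test_that("five-line spacing on synthetic braid scenes is unbiased within a pixel", {
  errs <- vapply(1:10, function(s) {
    b <- make_braid_image(braid_scene_params(spacing = 184, noise_sd = 10,
                                             pixel_size = 2, seed = s))
    prof <- colMeans(b$image$pixels)
    xs <- (seq_along(prof) - 1) * b$image$pixel_size
    # detect ridge peaks independently of ground truth
    pk <- which(diff(sign(diff(prof))) == -2) + 1L
    pk <- pk[prof[pk] > max(prof) / 2]
    ys <- seq(40, 360, length.out = 5)
    dps <- vapply(seq_len(length(pk) - 1L), function(i) {
      segs <- cbind(xs[pk[i]], ys, xs[pk[i + 1L]], ys)
      distance_datapoint(line_set(segs, "between_braids"))$value
    }, numeric(1))
    mean(dps) - 184
  }, numeric(1))
  expect_lt(abs(mean(errs)), 2)          # bias below one 2 nm pixel
  expect_lt(max(abs(errs)), 4)
})

test_that("braid width shows filament overlap: braid < 2 x split", {
  mk <- function(gap) {
    make_braid_image(braid_scene_params(braid_gap = gap, pixel_size = 1,
                                        image_size = c(64, 1024),
                                        noise_sd = 0, seed = 3))
  }
  braided <- mk(8)    # intertwined: centers a few nm apart, merged ridge
  split <- mk(60)     # fully separated filaments
  cb <- braided$truth$braid_centers[2]
  w_braid <- width_profile(braided$image, c(cb - 30, 32, cb + 30, 32))
  cs <- split$truth$braid_centers[2] + split$truth$filament_offsets[2]
  w_split <- width_profile(split$image, c(cs - 25, 32, cs + 25, 32))
  expect_gt(w_braid, w_split)
  expect_lt(w_braid, 2 * w_split)
  expect_equal(w_split, 11, tolerance = 0.1)
})

test_that("morphometry summaries report mean, SEM and n", {
  s <- summarize_morpho(c(10, 12, 14))
  expect_equal(s$mean, 12)
  expect_equal(s$sem, sd(c(10, 12, 14)) / sqrt(3))
  expect_equal(s$n, 3L)
  expect_warning(s1 <- summarize_morpho(42), "single")
  expect_equal(s1$sem, 0)
  pts <- list(distance_datapoint(line_set(cbind(0, 1:5, 184, 1:5), "between_braids")),
              distance_datapoint(line_set(cbind(0, 1:5, 190, 1:5), "between_braids")),
              distance_datapoint(line_set(cbind(0, 1:5, 0, 1:5 + 18), "across_braid")))
  sp <- summarize_morpho(pts, kind = "spacing")
  expect_equal(sp$n, 2L)
  expect_equal(sp$mean, 187)
  expect_error(summarize_morpho(list(), kind = "length"), "no data")
})

test_that("annotation files round-trip: polylines, transforms, control points", {
  tr <- polyline(rbind(c(10.5, 20), c(300, 400.25), c(500, 100)),
                 band_width = 96)
  f <- withr::local_tempfile(fileext = ".json")
  write_polylines_json(tr, f)
  back <- read_polylines_json(f)
  expect_length(back, 1L)
  expect_equal(back[[1]]$vertices, tr$vertices)
  expect_equal(back[[1]]$band_width, 96)
  write_polylines_json(list(tr, tr), f)
  expect_length(read_polylines_json(f), 2L)

  t0 <- affine2d(matrix(c(1.1, 0.2, -0.1, 0.9), 2, 2), c(12.5, -8))
  ft <- withr::local_tempfile(fileext = ".json")
  write_affine_json(t0, ft)
  t1 <- read_affine_json(ft)
  expect_equal(t1$linear, t0$linear)
  expect_equal(t1$translation, t0$translation)

  cp <- data.frame(x_src = c(0, 10, 5), y_src = c(0, 2, 9),
                   x_dst = c(1, 11, 6), y_dst = c(2, 4, 11))
  fc <- withr::local_tempfile(fileext = ".csv")
  write_control_points(cp, fc)
  expect_equal(read_control_points(fc), cp)
})
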