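test_that("FFT autocorrelation matches the O(N^2) definition", {
  set.seed(42)
  for (n in c(24, 100, 257, 1024)) {
    pr <- make_profile(rnorm(n) + sin(seq_len(n) / 5))
    ac <- autocorrelate(pr)
    expect_equal(ac$values[1], 1)
    expect_true(all(abs(ac$values) <= 1 + 1e-12))
    expect_equal(ac$values, brute_force_ac(pr$values), tolerance = 1e-12)
    expect_equal(ac$lags, (0:(n - 1)) * 16)
  }
  expect_error(autocorrelate(make_profile(rep(3, 100))), "zero-variance")
  expect_error(autocorrelate(make_profile(rnorm(10))), "24")
})

test_that("a pure cosine gives the analytic peak, valley, and amplitude", {
  pr <- cosine_profile(192, n_periods = 20)
  ac <- autocorrelate(pr)
  # first non-zero peak on the grid at one period
  fit <- fit_spacing(ac)
  expect_equal(fit$spacing_nm, 192, tolerance = 2 / 192)
  expect_lt(ac$values[ac$lags == 96], 0)   # half-period anticorrelation
  amp <- ac_amplitude(ac)
  expect_gte(amp, 1.5)
  expect_lte(amp, 2)
})

test_that("white noise shows no stable periodicity (Monte-Carlo null)", {
  n <- 512
  exceed <- 0; checked <- 0; amps <- numeric(20)
  for (s in 1:20) {
    set.seed(1000 + s)
    ac <- autocorrelate(make_profile(rnorm(n)))
    exceed <- exceed + sum(abs(ac$values[-1]) > 3 / sqrt(n))
    checked <- checked + n - 1
    amps[s] <- ac_amplitude(ac)
  }
  expect_lt(exceed / checked, 0.02)          # ~3 sigma exceedances are rare
  expect_lt(abs(mean(amps)), 3 / sqrt(n))    # amplitude is a null statistic
})

test_that("curve averaging is a pointwise mean with bookkeeping", {
  set.seed(3)
  curves <- lapply(1:4, function(i) autocorrelate(make_profile(rnorm(64))))
  avg <- average_curves(curves)
  mat <- sapply(curves, function(cu) cu$values)
  expect_equal(avg$values, rowMeans(mat))
  expect_equal(avg$n, 4L)
  expect_equal(average_curves(curves[1])$values, curves[[1]]$values)
  expect_equal(average_curves(curves[c(1, 1)])$values, curves[[1]]$values)
  bad <- curves[[1]]; bad$lags <- bad$lags * 2
  expect_error(average_curves(list(curves[[2]], bad)), "lag grid")
})

test_that("spacing fit refines the grid peak and flags aperiodic curves", {
  # off-grid period: grid peak at 192, fitted center pulled to 185
  fit185 <- fit_spacing(autocorrelate(cosine_profile(185, 25)))
  expect_equal(fit185$spacing_nm, 185, tolerance = 2 / 185)
  expect_true(fit185$spacing_error_nm >= 0)
  # gaussian and quadratic peak models agree on smooth curves
  fitq <- fit_spacing(autocorrelate(cosine_profile(185, 25)), model = "quadratic")
  expect_equal(fitq$spacing_nm, fit185$spacing_nm, tolerance = 2 / 185)
  # monotone decaying curve has no interior peak: the swinholide-like case
  decay <- structure(list(lags = (0:63) * 16, values = exp(-(0:63) / 10), n = 1L),
                     class = "autocorr_curve")
  expect_error(fit_spacing(decay), class = "mpscope_no_peak")
  # tie-break toward the smaller lag (first-peak semantics)
  v <- rep(0, 40); v[c(13, 25)] <- 1   # equal maxima at 192 and 384 nm
  tie <- structure(list(lags = (0:39) * 16, values = v, n = 1L),
                   class = "autocorr_curve")
  expect_equal(fit_spacing(tie, window = c(100, 600))$peak_lag_nm, 192)
})

test_that("amplitude uses fixed 192/96 nm lags with interpolation off-grid", {
  ac <- autocorrelate(cosine_profile(192, 20))
  # on the 16 nm grid both lags are exact grid points
  expect_equal(ac_amplitude(ac),
               ac$values[ac$lags == 192] - ac$values[ac$lags == 96])
  # off-grid: linear interpolation between neighbors
  ac10 <- autocorrelate(cosine_profile(192, 20, step = 10))
  v <- approx(ac10$lags, ac10$values, xout = c(192, 96))$y
  expect_equal(ac_amplitude(ac10), v[1] - v[2])
  short <- structure(list(lags = (0:5) * 16, values = c(1, rep(0, 5)), n = 1L),
                     class = "autocorr_curve")
  expect_error(ac_amplitude(short), "192")
})

test_that("profile extraction reproduces stripe patterns and is rotation-equivariant", {
  # vertical stripes: value depends only on x
  nx <- 128; ny <- 64; ps <- 16
  stripe <- matrix(rep(sin(2 * pi * (0:(nx - 1)) * ps / 192), each = ny), ny, nx)
  img <- rendered_image(stripe + 2, ps, c(0, 0))
  tr <- polyline(rbind(c(ps, ny / 2 * ps), c((nx - 2) * ps, ny / 2 * ps)),
                 band_width = 160)
  pr <- extract_profile(img, tr)
  expected <- sin(2 * pi * (pr$positions + ps) / 192) + 2
  expect_equal(pr$values, expected, tolerance = 1e-10)
  # constant image: constant profile regardless of band width
  flat <- rendered_image(matrix(7, 64, 64), ps)
  prf <- extract_profile(flat, polyline(rbind(c(100, 300), c(800, 600)),
                                        band_width = 96))
  expect_true(all(abs(prf$values - 7) < 1e-12))
  # 45-degree stripes sampled along a 45-degree trace match the axis-aligned case
  n <- 256
  xc <- (0:(n - 1)) * ps
  gx <- matrix(xc, n, n, byrow = TRUE); gy <- matrix(xc, n, n)
  u <- (gx + gy) / sqrt(2)      # coordinate along the rotated axis
  img45 <- rendered_image(sin(2 * pi * u / 192) + 2, ps, c(0, 0))
  p0 <- c(40 * ps, 40 * ps); p1 <- p0 + 1500 / sqrt(2)
  pr45 <- extract_profile(img45, polyline(rbind(p0, p1), band_width = 64))
  expected45 <- sin(2 * pi * ((p0[1] + p0[2]) / sqrt(2) + pr45$positions) / 192) + 2
  expect_lt(max(abs(pr45$values - expected45)), 0.05)
  # a trace leaving the image names where it failed
  expect_error(extract_profile(flat, polyline(rbind(c(100, 100), c(5000, 100)))),
               "leaves the image")
})

test_that("background-corrected intensity matches pixel-set oracles", {
  ps <- 16
  img <- rendered_image(matrix(5, 64, 64), ps)
  tr <- polyline(rbind(c(100, 200), c(800, 200)), band_width = 64)
  bg <- polyline(rbind(c(100, 800), c(800, 800)), band_width = 64)
  expect_equal(measure_intensity(img, tr, bg), 0)
  # stripe of value 9 on a zero background
  m <- matrix(0, 64, 64); m[10:14, ] <- 9
  img2 <- rendered_image(m, ps)
  stripe_tr <- polyline(rbind(c(100, 12 * ps), c(800, 12 * ps)), band_width = 0)
  expect_equal(measure_intensity(img2, stripe_tr, bg), 9)
  expect_warning(measure_intensity(img, tr,
                                   polyline(rbind(c(100, 210), c(800, 210)),
                                            band_width = 64)),
                 "overlap")
})

test_that("group comparisons follow the published testing scheme", {
  # identical groups: maximal p, not significant
  same <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5))
  cs <- compare_groups(same)
  expect_equal(cs$p_omnibus, 1, tolerance = 1e-6)
  expect_equal(cs$pairwise$code, "ns")
  # complete separation
  sep <- compare_groups(list(a = as.numeric(1:10), b = as.numeric(101:110)))
  expect_lt(sep$p_omnibus, 0.001)
  expect_equal(sep$pairwise$code, "***")
  # Mann-Whitney U equals the exhaustive pairwise-win count (5 x 5)
  set.seed(9)
  x <- rnorm(5); y <- rnorm(5, 1)
  cmp <- compare_groups(list(x = x, y = y))
  expect_equal(unname(cmp$pairwise$statistic), brute_force_u(x, y))
  # summary block: SEM = sd / sqrt(n)
  expect_equal(cmp$summary$sem[1], sd(x) / sqrt(5))
  # multi-group route: omnibus + Holm-adjusted pairwise
  g <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8, 5))
  cm <- compare_groups(g)
  expect_lt(cm$p_omnibus, 0.01)
  expect_equal(nrow(cm$pairwise), 3L)
  expect_true(all(cm$pairwise$p >= 0 & cm$pairwise$p <= 1))
  sig <- cm$pairwise[cm$pairwise$group2 == "c" | cm$pairwise$group1 == "c", ]
  expect_true(all(sig$p < 0.05))
  # parametric alternative remains available
  cmt <- compare_groups(g, posthoc = "anova_tukey")
  expect_equal(nrow(cmt$pairwise), 3L)
  expect_error(compare_groups(list(a = 1:2, b = 1:5)), "n >= 3")
})
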