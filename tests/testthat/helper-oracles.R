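# Independent oracles and small builders shared across tests.

# Direct O(N^2) normalized biased autocorrelation (the definition).
brute_force_ac <- function(v) {
  n <- length(v)
  v <- v - mean(v)
  denom <- sum(v^2)
  vapply(0:(n - 1L), function(k) {
    sum(v[seq_len(n - k)] * v[seq_len(n - k) + k]) / denom
  }, numeric(1))
}

# Intensity profile object without going through an image.
make_profile <- function(values, step = 16) {
  structure(list(positions = (seq_along(values) - 1) * step,
                 values = values, step = step),
            class = "intensity_profile")
}

cosine_profile <- function(period, n_periods = 20, step = 16, phase = 0) {
  n <- ceiling(n_periods * period / step)
  make_profile(cos(2 * pi * (0:(n - 1)) * step / period + phase), step)
}

# Mann-Whitney U by exhaustive pair enumeration (ties count 1/2).
brute_force_u <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Horizontal full-width trace through the middle of an image.
mid_trace <- function(img, band_width = 0, inset = 1) {
  ext <- mpscope:::image_extent(img)
  ps <- img$pixel_size
  y <- img$origin[2] + (nrow(img$pixels) - 1) / 2 * ps
  polyline(rbind(c(img$origin[1] + inset * ps, y),
                 c(img$origin[1] + (ncol(img$pixels) - 1 - inset) * ps, y)),
           band_width = band_width)
}

# Straight-line axis trace for an MPS scene generated at axis_angle = 0.
scene_axis_trace <- function(scene, img, band_width = 300) {
  ext <- mpscope:::image_extent(img)
  y <- mean(ext$ylim)
  polyline(rbind(c(ext$xlim[1] + 2 * img$pixel_size, y),
                 c(ext$xlim[2] - 2 * img$pixel_size, y)),
           band_width = band_width)
}
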