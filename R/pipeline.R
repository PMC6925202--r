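#' Periodicity analysis of traced axons
#'
#' Runs the standard quantification on one reconstructed image: extracts a
#' band-averaged intensity profile along each tracing, autocorrelates each
#' profile, averages the curves, fits the spacing on the averaged curve and
#' reports the per-tracing periodicity amplitudes (amplitude statistics are
#' computed per tracing, which is what group comparisons operate on).
#'
#' @param image a [rendered_image()].
#' @param traces a [polyline()] or list of them.
#' @param window spacing search window in nm, default `c(100, 300)`.
#' @return A list of class `periodicity_result`: `spacing_nm`,
#'   `spacing_error_nm`, `amplitudes` (one per tracing), `n_tracings`,
#'   `curve` (the averaged `autocorr_curve`), and `curves` (per tracing).
#' @export
measure_periodicity <- function(image, traces, window = c(100, 300)) {
  if (inherits(traces, "polyline")) traces <- list(traces)
  curves <- lapply(traces, function(tr) autocorrelate(extract_profile(image, tr)))
  avg <- average_curves(curves)
  fit <- fit_spacing(avg, window = window)
  amps <- vapply(curves, ac_amplitude, numeric(1))
  structure(list(spacing_nm = fit$spacing_nm,
                 spacing_error_nm = fit$spacing_error_nm,
                 amplitudes = amps,
                 n_tracings = length(curves),
                 curve = avg, curves = curves,
                 model = fit$model),
            class = "periodicity_result")
}

#' @export
print.periodicity_result <- function(x, ...) {
  cat(sprintf("periodicity: spacing s = %.1f +/- %.1f nm (%d tracings)\n",
              x$spacing_nm, x$spacing_error_nm, x$n_tracings))
  cat(sprintf("  amplitude = %.3f +/- %.3f (per-tracing mean +/- SEM)\n",
              mean(x$amplitudes),
              stats::sd(x$amplitudes) / sqrt(max(1, length(x$amplitudes)))))
  invisible(x)
}

#' Recompute summary statistics from the deposited study data
#'
#' Applies the package's operators to a local copy of the study's deposited
#' data (the FigShare archive / Source Data file with per-measurement graph
#' data and SMLM localization files). For every `*.csv` whose first numeric
#' column holds per-measurement values in nm (braid spacings, lengths,
#' widths), reports mean +/- SEM via [summarize_morpho()]; for every
#' localization table (`*_locs.csv`, ThunderSTORM dialect), reconstructs at
#' 16 nm/px, autocorrelates along the long axis and reports the fitted
#' spacing. The deposit is not bundled with the package and must be
#' downloaded and extracted by the user.
#'
#' @param source_dir directory containing the extracted deposit.
#' @param pixel_size reconstruction pixel size, nm.
#' @return Data frame with one row per recomputed quantity: `name`,
#'   `statistic` (`"mean"` or `"spacing"`), `value`, `sem_or_error`, `n`.
#' @export
recompute_deposited_stats <- function(source_dir, pixel_size = 16) {
  if (!dir.exists(source_dir)) {
    stop("recompute_deposited_stats: deposit directory not found: ", source_dir)
  }
  rows <- list()
  loc_files <- list.files(source_dir, pattern = "_locs\\.csv$", full.names = TRUE)
  for (f in loc_files) {
    locs <- read_localizations(f, "thunderstorm_csv")
    img <- reconstruct(locs, pixel_size = pixel_size)
    ext <- image_extent(img)
    mid_y <- mean(ext$ylim)
    tr <- polyline(rbind(c(ext$xlim[1] + pixel_size, mid_y),
                         c(ext$xlim[2] - pixel_size, mid_y)),
                   band_width = diff(ext$ylim) - 4 * pixel_size)
    fit <- fit_spacing(autocorrelate(extract_profile(img, tr)))
    rows[[length(rows) + 1L]] <- data.frame(
      name = basename(f), statistic = "spacing", value = fit$spacing_nm,
      sem_or_error = fit$spacing_error_nm, n = 1L)
  }
  val_files <- setdiff(list.files(source_dir, pattern = "\\.csv$", full.names = TRUE),
                       loc_files)
  for (f in val_files) {
    df <- utils::read.csv(f)
    num <- df[[which(vapply(df, is.numeric, logical(1)))[1]]]
    s <- summarize_morpho(num)
    rows[[length(rows) + 1L]] <- data.frame(
      name = basename(f), statistic = "mean", value = s$mean,
      sem_or_error = s$sem, n = s$n)
  }
  if (length(rows) == 0L) {
    stop("recompute_deposited_stats: no recognized data files in ", source_dir)
  }
  do.call(rbind, rows)
}
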