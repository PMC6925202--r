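#' Localization table
#'
#' Per-emitter records from single-molecule localization microscopy. Stored
#' as a `data.frame` with canonical columns `frame`, `x`, `y` (nm),
#' `photons`, `uncertainty` (nm), `channel`; any extra columns read from a
#' file are carried along unchanged.
#'
#' @param frame acquisition frame index (integer-valued).
#' @param x,y coordinates in nm.
#' @param photons photon count per localization (>= 0).
#' @param uncertainty lateral localization precision, nm.
#' @param channel channel label.
#' @return A `data.frame` with class `localization_table`.
#' @export
localization_table <- function(frame = integer(), x = numeric(),
                               y = numeric(), photons = numeric(),
                               uncertainty = rep(NA_real_, length(x)),
                               channel = rep("ch1", length(x))) {
  df <- data.frame(frame = as.numeric(frame), x = as.numeric(x),
                   y = as.numeric(y), photons = as.numeric(photons),
                   uncertainty = as.numeric(uncertainty),
                   channel = as.character(channel),
                   stringsAsFactors = FALSE)
  validate_localization_table(df)
  class(df) <- c("localization_table", "data.frame")
  df
}

validate_localization_table <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(!is.finite(df$x)) || any(!is.finite(df$y))) {
    stop("localization_table: x and y must be finite")
  }
  if (any(df$photons < 0, na.rm = TRUE)) {
    stop("localization_table: photon counts must be >= 0")
  }
  invisible(df)
}

# Dialect definitions. Both dialects store x/y in nm. `cols` maps canonical
# field -> file column name.
loc_dialects <- list(
  thunderstorm_csv = list(
    sep = ",",
    cols = c(frame = "frame", x = "x [nm]", y = "y [nm]",
             photons = "intensity [photon]", uncertainty = "uncertainty [nm]")
  ),
  nstorm_txt = list(
    sep = "\t",
    cols = c(channel = "Channel Name", x = "Xc", y = "Yc",
             photons = "Photons", frame = "Frame",
             uncertainty = "Lateral Localization Accuracy")
  )
)

#' Read a localization table
#'
#' Parses delimited-text localization exports in either the ThunderSTORM CSV
#' dialect (comma-separated, headers `frame,x [nm],y [nm],intensity
#' [photon],uncertainty [nm]`) or the N-STORM tab-separated vendor dialect
#' (`Channel Name`, `Xc`, `Yc`, `Photons`, `Frame`, ...). Coordinates are nm
#' in both. Columns beyond the canonical set are preserved verbatim.
#'
#' @param path path to the file.
#' @param dialect `"thunderstorm_csv"` or `"nstorm_txt"`.
#' @return A [localization_table()]. An empty file yields an empty table.
#' @export
read_localizations <- function(path,
                               dialect = c("thunderstorm_csv", "nstorm_txt")) {
  dialect <- match.arg(dialect)
  spec <- loc_dialects[[dialect]]
  if (!file.exists(path)) stop("read_localizations: file not found: ", path)
  if (file.size(path) == 0L) return(localization_table())
  raw <- utils::read.table(path, sep = spec$sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  missing <- setdiff(unname(spec$cols), names(raw))
  if (length(missing) > 0L) {
    stop("read_localizations: missing column(s) for dialect ", dialect, ": ",
         paste(missing, collapse = ", "))
  }
  numeric_fields <- setdiff(names(spec$cols), "channel")
  out <- list()
  for (field in names(spec$cols)) {
    col <- raw[[spec$cols[[field]]]]
    if (field %in% numeric_fields) {
      val <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(val) & !(is.na(col) | col == "" | toupper(col) == "NA"))
      if (length(bad) > 0L) {
        stop("read_localizations: malformed numeric value '", col[bad[1]],
             "' in column '", spec$cols[[field]], "' at data row ", bad[1])
      }
      out[[field]] <- val
    } else {
      out[[field]] <- col
    }
  }
  if (is.null(out$channel)) out$channel <- rep("ch1", nrow(raw))
  if (is.null(out$uncertainty)) out$uncertainty <- rep(NA_real_, nrow(raw))
  tb <- localization_table(frame = out$frame, x = out$x, y = out$y,
                           photons = out$photons,
                           uncertainty = out$uncertainty,
                           channel = out$channel)
  extras <- setdiff(names(raw), unname(spec$cols))
  for (e in extras) {
    v <- suppressWarnings(as.numeric(raw[[e]]))
    tb[[e]] <- if (all(is.na(v) == is.na(raw[[e]]))) v else raw[[e]]
  }
  message("read_localizations: ", nrow(tb), " localizations from ", path)
  tb
}

#' Write a localization table
#'
#' Writes a [localization_table()] in either dialect; the result re-parses
#' with [read_localizations()] with all shared fields intact (numbers are
#' written with full double precision). Extra columns are appended after the
#' dialect's canonical columns.
#'
#' @param table a [localization_table()].
#' @param path output path.
#' @param dialect `"thunderstorm_csv"` or `"nstorm_txt"`.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path,
                                dialect = c("thunderstorm_csv", "nstorm_txt")) {
  dialect <- match.arg(dialect)
  spec <- loc_dialects[[dialect]]
  stopifnot(inherits(table, "localization_table"))
  canonical <- c("frame", "x", "y", "photons", "uncertainty", "channel")
  fmt <- function(v) {
    if (is.numeric(v)) {
      out <- sprintf("%.17g", v)
      out[is.na(v)] <- "NA"
      int <- is.finite(v) & v == round(v) & abs(v) < 2^53
      out[int] <- sprintf("%.0f", v[int])
      out
    } else as.character(v)
  }
  cols <- list()
  for (field in names(spec$cols)) cols[[spec$cols[[field]]]] <- fmt(table[[field]])
  for (e in setdiff(names(table), canonical)) cols[[e]] <- fmt(table[[e]])
  df <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = spec$sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Filter localizations by photon count
#'
#' Keeps records whose photon count lies in the closed interval
#' `[min_photons, max_photons]`, the standard rejection of too-dim and
#' too-bright (multi-emitter) localizations before reconstruction.
#'
#' @param table a [localization_table()].
#' @param min_photons,max_photons inclusive bounds; `min_photons <= max_photons`.
#' @return The filtered table, original row order preserved.
#' @export
filter_photons <- function(table, min_photons = 0, max_photons = Inf) {
  stopifnot(inherits(table, "localization_table"))
  if (min_photons > max_photons) {
    stop("filter_photons: min_photons must be <= max_photons")
  }
  keep <- table$photons >= min_photons & table$photons <= max_photons
  keep[is.na(keep)] <- FALSE
  message("filter_photons: rejected ", sum(!keep), " of ", nrow(table),
          " localizations")
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("localization_table", "data.frame")
  out
}
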