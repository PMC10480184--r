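# File interchange: trajectory CSVs (native and TrackMate-style export),
# intensity traces and ACF curves.

#' Read a trajectory CSV
#'
#' The native dialect has columns `track_id`, `frame`, `x`, `y` (and
#' optionally `t`, `truth_label`), positions in micrometres, rows sorted by
#' (track_id, frame).  The TrackMate-style dialect maps `TRACK_ID`,
#' `FRAME`, `POSITION_X`, `POSITION_Y`; non-numeric sub-header rows (unit
#' rows of some exports) are skipped and rows are sorted by
#' (track, frame) before validation.
#'
#' @param path CSV path.
#' @param dialect `"native"` or `"trackmate"`.
#' @param frame_interval Frame interval in seconds attached to the result.
#' @param unit Position unit: `"um"` (default) or `"pixel"`.
#' @param pixel_size Pixel size in um used when `unit = "pixel"`
#'   (default 0.065 um).
#'
#' @return Track tibble (`track_id`, `frame`, `t`, `x`, `y`,
#'   `truth_label`) with a `frame_interval` attribute.  Missing columns,
#'   non-finite positions, duplicated or non-increasing frames within a
#'   track raise errors naming the offending row.
#' @export
read_tracks <- function(path, dialect = c("native", "trackmate"),
                        frame_interval = 0.01,
                        unit = c("um", "pixel"), pixel_size = 0.065) {
  dialect <- match.arg(dialect)
  unit <- match.arg(unit)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (dialect == "trackmate") {
    need <- c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y")
    if (!all(need %in% names(raw))) {
      stop_domain("TrackMate export must have columns ",
                  paste(need, collapse = ", "))
    }
    numeric_rows <- !is.na(suppressWarnings(as.numeric(raw$FRAME)))
    raw <- raw[numeric_rows, , drop = FALSE]
    out <- tibble::tibble(
      track_id = as.integer(as.numeric(raw$TRACK_ID)),
      frame = as.integer(as.numeric(raw$FRAME)),
      x = as.numeric(raw$POSITION_X),
      y = as.numeric(raw$POSITION_Y),
      truth_label = NA_character_
    )
    out <- out[order(out$track_id, out$frame), , drop = FALSE]
  } else {
    need <- c("track_id", "frame", "x", "y")
    if (!all(need %in% names(raw))) {
      stop_domain("native trajectory CSV must have columns ",
                  paste(need, collapse = ", "))
    }
    out <- tibble::tibble(
      track_id = as.integer(as.numeric(raw$track_id)),
      frame = as.integer(as.numeric(raw$frame)),
      x = as.numeric(raw$x),
      y = as.numeric(raw$y),
      truth_label = if ("truth_label" %in% names(raw)) raw$truth_label
                    else NA_character_
    )
  }
  if (unit == "pixel") {
    out$x <- out$x * pixel_size
    out$y <- out$y * pixel_size
  }
  bad <- which(!is.finite(out$x) | !is.finite(out$y))
  if (length(bad)) {
    stop_domain("non-finite position at row ", bad[1])
  }
  # frames must strictly increase within each track
  same <- c(FALSE, out$track_id[-1] == out$track_id[-nrow(out)])
  nonmono <- which(same & c(TRUE, diff(out$frame) <= 0))
  if (length(nonmono)) {
    stop_domain("frame indices not strictly increasing within track ",
                out$track_id[nonmono[1]], " at row ", nonmono[1])
  }
  out$t <- out$frame * frame_interval
  out <- out[, c("track_id", "frame", "t", "x", "y", "truth_label")]
  attr(out, "frame_interval") <- frame_interval
  out
}

#' Write a trajectory CSV in the native dialect
#'
#' @param tracks Track tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  cols <- intersect(c("track_id", "frame", "t", "x", "y", "truth_label"),
                    names(tracks))
  readr::write_csv(tracks[, cols], path)
  invisible(path)
}

#' Read / write an intensity trace CSV (`t`, `counts`)
#'
#' @param path CSV path.
#' @return Tibble `t`, `counts` with a `bin_width` attribute inferred from
#'   the time column.
#' @export
read_intensity_trace <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(t = readr::col_double(),
                                                 counts = readr::col_double()))
  if (nrow(out) >= 2) attr(out, "bin_width") <- out$t[2] - out$t[1]
  attr(out, "duration") <- nrow(out) * (attr(out, "bin_width") %||% NA_real_)
  out$counts <- as.integer(out$counts)
  out
}

#' @rdname read_intensity_trace
#' @param trace Trace tibble.
#' @export
write_intensity_trace <- function(trace, path) {
  readr::write_csv(trace[, c("t", "counts")], path)
  invisible(path)
}

#' Read a precomputed ACF curve CSV
#'
#' Expected columns `lag_s`, `g` and optionally `sigma` (per-lag standard
#' error).
#'
#' @param path CSV path.
#' @return ACF tibble (`lag`, `g`, `g_se`) compatible with the fitters.
#' @export
read_acf_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("lag_s", "g") %in% names(raw))) {
    stop_domain("ACF CSV must have columns lag_s, g")
  }
  tibble::tibble(
    lag = as.numeric(raw$lag_s),
    g = as.numeric(raw$g),
    g_se = if ("sigma" %in% names(raw)) as.numeric(raw$sigma) else NA_real_
  )
}
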