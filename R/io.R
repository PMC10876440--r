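#' Write a movie stack to multi-page TIFF
#'
#' Frames are written as 16-bit greyscale pages (TYX order). Calibration
#' (frame interval, pixel size) goes into a JSON sidecar next to the TIFF
#' (`<path>.json`), because baseline TIFF tags cannot carry it losslessly.
#' Integer data in 0..65535 round-trips exactly.
#'
#' @param stack A [movie_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(stack, path) {
  stopifnot(inherits(stack, "movie_stack"))
  d <- dim(stack$data)
  if (max(stack$data) > 65535) stop("intensities exceed 16-bit range")
  frames <- lapply(seq_len(d[1]), function(f) {
    round(stack$data[f, , ]) / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  jsonlite::write_json(
    list(frame_interval_s = stack$frame_interval_s,
         pixel_size_um = stack$pixel_size_um,
         axes = "TYX"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a movie stack from multi-page TIFF
#'
#' Calibration is taken from the JSON sidecar written by [write_movie()];
#' explicit arguments override the sidecar. With neither sidecar nor
#' overrides, reading fails.
#'
#' @param path TIFF path.
#' @param frame_interval_s,pixel_size_um Calibration overrides.
#' @return A [movie_stack()] with integer intensities.
#' @export
read_movie <- function(path, frame_interval_s = NULL, pixel_size_um = NULL) {
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) stop("not a readable TIFF file: ", path,
                             " (", conditionMessage(e), ")")
  )
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  fi <- frame_interval_s %||% meta$frame_interval_s
  px <- pixel_size_um %||% meta$pixel_size_um
  if (is.null(fi) || is.null(px)) {
    stop("missing calibration: no sidecar metadata and no override given")
  }
  d <- dim(pages[[1]])
  data <- array(0, dim = c(length(pages), d[1], d[2]))
  for (f in seq_along(pages)) data[f, , ] <- pages[[f]]
  movie_stack(data, frame_interval_s = fi, pixel_size_um = px)
}

#' Write / read a mechanical trace as two-column CSV
#'
#' Columns are `time_s` and the value column, whose name declares the kind
#' (`displacement_m` or `velocity_m_s`).
#'
#' @param trace A [mech_trace()].
#' @param path CSV path.
#' @return `path` invisibly (write); a `mech_trace` (read).
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "mech_trace"))
  n <- length(trace$values)
  df <- data.frame(time_s = (seq_len(n) - 1) / trace$sample_rate_hz,
                   value = trace$values)
  names(df)[2] <- trace$kind
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param temperature_K Temperature to attach on read (default 298).
#' @export
read_trace <- function(path, temperature_K = 298) {
  df <- utils::read.csv(path)
  kind <- setdiff(names(df), "time_s")[1]
  if (!kind %in% c("displacement_m", "velocity_m_s")) {
    stop("trace CSV must have a displacement_m or velocity_m_s column")
  }
  dt <- stats::median(diff(df$time_s))
  mech_trace(df[[kind]], sample_rate_hz = 1 / dt, kind = kind,
             temperature_K = temperature_K)
}

#' Write / read a stimulus-response table as CSV
#'
#' Columns `spv_m_s`, `displacement_m`, `f_eigen_hz` (constant).
#'
#' @param responses A `stimulus_response` object.
#' @param path CSV path.
#' @export
write_responses <- function(responses, path) {
  df <- as.data.frame(responses)
  df$f_eigen_hz <- attr(responses, "f_eigen_hz")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path)
  out <- df[c("spv_m_s", "displacement_m")]
  attr(out, "f_eigen_hz") <- df$f_eigen_hz[1]
  class(out) <- c("stimulus_response", "data.frame")
  out
}

#' Write / read ground truth as JSON
#'
#' @param truth Ground truth list from a generator.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  empty_proto <- list(
    tracks = data.frame(id = integer(), direction = character(),
                        entry_frame = integer(), speed_um_s = numeric(),
                        length_nm = numeric(), visible = logical()),
    encounters = data.frame(retro_id = integer(), antero_id = integer(),
                            frame = integer(), arc_um = numeric(),
                            outcome = character(),
                            pause_duration_s = numeric()),
    pauses = data.frame(track_id = integer(), start_frame = integer(),
                        end_frame = integer(), duration_s = numeric())
  )
  as_df <- function(x, proto = NULL) {
    if (is.data.frame(x)) return(x)
    if (!length(x) && !is.null(proto)) return(proto)
    as.data.frame(x)
  }
  if (!is.null(truth$trajectories)) {
    truth$trajectories <- lapply(
      truth$trajectories, as_df,
      proto = data.frame(frame = integer(), arc_um = numeric()))
  }
  for (nm in names(empty_proto)) {
    if (!is.null(truth[[nm]])) {
      truth[[nm]] <- as_df(truth[[nm]], empty_proto[[nm]])
    }
  }
  truth
}
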