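`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a time-lapse stack as a multi-page TIFF with a JSON sidecar
#'
#' Pages are emitted in TZYX order (all z-sections of frame 1, then frame 2,
#' ...). The stack shape, voxel size, frame interval and intensity scale are
#' recorded in a JSON sidecar (\code{<path>.json}) so the stack can be
#' reshaped and rescaled exactly on read.
#'
#' @param stack a [timelapse_stack()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "timelapse_stack"))
  d <- dim(stack$data)
  mx <- max(stack$data, 1e-12)
  pages <- vector("list", d[1] * d[2])
  i <- 0L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
    i <- i + 1L
    pages[[i]] <- stack$data[t, z, , ] / mx
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16, reduce = FALSE)
  jsonlite::write_json(
    list(axes = "TZYX", frames = d[1], slices = d[2],
         spacing_um = stack$voxel_um[1], pixel_um = stack$voxel_um[2:3],
         frame_interval_s = stack$frame_interval_s, intensity_scale = mx),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_stack_tiff()]
#'
#' @param path TIFF file path; the \code{<path>.json} sidecar is read when
#'   present, otherwise single-frame defaults are assumed.
#' @return A [timelapse_stack()].
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE) else
      list()
  n_frames <- meta$frames %||% 1
  n_slices <- meta$slices %||% length(pages)
  spacing <- meta$spacing_um %||% 1
  finterval <- meta$frame_interval_s %||% 30
  pixel_um <- (meta$pixel_um %||% 1)[1]
  scale <- meta$intensity_scale %||% 1
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  data <- array(0, c(n_frames, n_slices, ny, nx))
  i <- 0L
  for (t in seq_len(n_frames)) for (z in seq_len(n_slices)) {
    i <- i + 1L
    data[t, z, , ] <- pages[[i]] * scale
  }
  timelapse_stack(data, voxel_um = c(spacing, pixel_um, pixel_um),
                  frame_interval_s = finterval)
}

#' Write an EEG trace as CSV (time_s, amplitude_uV)
#'
#' @param trace an [eeg_trace()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_eeg_csv <- function(trace, path) {
  stopifnot(inherits(trace, "eeg_trace"))
  utils::write.csv(
    data.frame(time_s = (seq_along(trace$samples) - 1) / trace$fs_hz,
               amplitude_uV = trace$samples),
    path, row.names = FALSE)
  invisible(path)
}

#' Read an EEG trace from CSV (time_s, amplitude_uV)
#'
#' The sampling rate is recovered from the median time step.
#'
#' @param path CSV path with columns time_s and amplitude_uV.
#' @return An [eeg_trace()].
#' @export
read_eeg_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "amplitude_uV") %in% names(df)))
  fs <- 1 / stats::median(diff(df$time_s))
  eeg_trace(df$amplitude_uV, fs_hz = round(fs))
}
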