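#' Write / read a neural trace
#'
#' The trace samples are stored as a flat binary array of doubles
#' (`<prefix>.bin`) with a structured JSON sidecar (`<prefix>.json`)
#' holding the sampling rate, stimulus epochs and ground truth.
#'
#' @param trace A `neural_trace`.
#' @param prefix File path prefix (without extension).
#' @return `write_neural_trace()` returns the prefix invisibly;
#'   `read_neural_trace()` returns a `neural_trace`.
#' @export
write_neural_trace <- function(trace, prefix) {
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(trace$samples, con, size = 8, endian = "little")
  meta <- list(
    sampling_rate = trace$sampling_rate,
    duration = trace$duration,
    n_samples = length(trace$samples),
    epochs = as.data.frame(trace$epochs),
    truth = list(
      spike_times = trace$truth$spike_times,
      after_discharge_duration = trace$truth$after_discharge_duration,
      template = as.numeric(trace$truth$template),
      amplitude = trace$truth$amplitude
    )
  )
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_neural_trace
#' @export
read_neural_trace <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  samples <- readBin(con, "double", n = meta$n_samples, size = 8,
                     endian = "little")
  epochs <- as_tibble(meta$epochs)
  structure(
    list(samples = samples, sampling_rate = meta$sampling_rate,
         duration = meta$duration, epochs = epochs,
         truth = list(
           spike_times = as.numeric(meta$truth$spike_times %||% numeric(0)),
           after_discharge_duration = meta$truth$after_discharge_duration,
           template = as.numeric(meta$truth$template),
           amplitude = meta$truth$amplitude),
         spec = NULL, noise_sd = NA_real_, seed = NA_integer_),
    class = "neural_trace"
  )
}

#' Write / read an OCT M-mode trial
#'
#' The intensity matrix is stored as a 32-bit float TIFF plus a JSON
#' sidecar with the acquisition metadata and ground truth.
#'
#' @param trial An `oct_mmode`.
#' @param prefix File path prefix.
#' @return The prefix (write) or an `oct_mmode` (read).
#' @export
write_oct_mmode <- function(trial, prefix) {
  img <- pmin(pmax(trial$intensity, 0), 1)
  tiff::writeTIFF(img, paste0(prefix, ".tif"), bits.per.sample = 32)
  meta <- list(
    aline_rate = trial$aline_rate,
    depth_resolution = trial$depth_resolution,
    condition = trial$condition,
    location = trial$location,
    replicate = trial$replicate,
    truth = list(displacement = trial$truth$displacement,
                 event_time = trial$truth$event_time,
                 artefact = trial$truth$artefact)
  )
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_oct_mmode
#' @export
read_oct_mmode <- function(prefix) {
  img <- tiff::readTIFF(paste0(prefix, ".tif"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  structure(
    list(intensity = img, aline_rate = meta$aline_rate,
         depth_resolution = meta$depth_resolution,
         condition = meta$condition,
         location = as.integer(meta$location),
         replicate = as.integer(meta$replicate),
         truth = list(displacement = meta$truth$displacement,
                      event_time = meta$truth$event_time,
                      surface = NULL,
                      artefact = meta$truth$artefact %||% "none"),
         seed = NA_integer_),
    class = "oct_mmode"
  )
}

#' Write / read a frame stack
#'
#' Frames are stored as a multi-page grayscale TIFF plus a JSON sidecar
#' (fps, calibration, ground-truth trajectory if present).
#'
#' @param stack A `frame_stack`.
#' @param prefix File path prefix.
#' @return The prefix (write) or a `frame_stack` (read).
#' @export
write_frame_stack <- function(stack, prefix) {
  imgs <- lapply(stack$frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(imgs, paste0(prefix, ".tif"), bits.per.sample = 16)
  meta <- list(fps = stack$fps, calibration = stack$calibration,
               truth = if (!is.null(stack$truth)) as.data.frame(stack$truth))
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(prefix) {
  imgs <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  structure(
    list(frames = imgs, fps = meta$fps, calibration = meta$calibration,
         truth = if (!is.null(meta$truth)) as_tibble(meta$truth),
         seed = NA_integer_),
    class = "frame_stack"
  )
}

#' Write a tibble as tab-separated values
#'
#' Thin wrapper standardising the table export used across the pipeline
#' (displacement tables, unit tables, trajectory exports).
#'
#' @param x A data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
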