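#' @importFrom utils read.csv write.csv
NULL

# Sidecar path convention: <file>.json next to <file>.
.sidecarPath <- function(path) paste0(path, ".json")

#' Read and write raw captures
#'
#' Captures are stored as CSV with one row per digitized point and columns
#' \code{swimmer_id, frame, time, point_index, x, y} (micrometres, seconds),
#' plus a JSON sidecar (\code{<file>.csv.json}) recording units and optional
#' acquisition metadata. Reading validates the schema and reports the
#' offending frame or field on failure.
#'
#' @param path CSV file path.
#' @param capture a [RawCapture-class].
#' @param metadata named list merged into the JSON sidecar on write.
#' @return \code{readCapture} returns a [RawCapture-class].
#' @export
readCapture <- function(path) {
  df <- read.csv(path)
  need <- c("swimmer_id", "frame", "time", "point_index", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("capture schema violation in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  ids <- unique(df$swimmer_id)
  if (length(ids) != 1L)
    stop("capture file must hold one swimmer; found: ", paste(ids, collapse = ", "))
  df <- df[order(df$frame, df$point_index), ]
  frames <- split(df, factor(df$frame, levels = unique(df$frame)))
  ts <- vapply(frames, function(fr) fr$time[1L], numeric(1))
  if (any(diff(ts) <= 0)) {
    bad <- names(frames)[which(diff(ts) <= 0)[1L] + 1L]
    stop("non-monotone timestamps in ", path, " at frame ", bad)
  }
  RawCapture(lapply(frames, function(fr) cbind(fr$x, fr$y)),
             ts - ts[1L], as.character(ids))
}

#' @rdname readCapture
#' @export
writeCapture <- function(capture, path, metadata = list()) {
  stopifnot(is(capture, "RawCapture"))
  rows <- lapply(seq_along(capture@frames), function(m) {
    f <- capture@frames[[m]]
    data.frame(swimmer_id = capture@swimmerID, frame = m - 1L,
               time = capture@timestamps[m],
               point_index = seq_len(nrow(f)) - 1L, x = f[, 1L], y = f[, 2L])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  meta <- c(list(schema_version = 1L, units = list(x = "um", y = "um", time = "s")),
            metadata)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read and write normalized beats
#'
#' A normalized beat is stored as a long CSV with columns
#' \code{s_index, t_index, x, y, theta} (grid indices are 0-based) and a JSON
#' sidecar holding the scalar metadata \code{L} (micrometres), \code{T}
#' (seconds), \code{beat_offset}, the grid sizes and the swimmer label.
#' The round trip is lossless: values are written in full precision.
#'
#' @param beat a [NormalizedBeat-class].
#' @param path CSV file path.
#' @return \code{readBeat} returns a [NormalizedBeat-class].
#' @export
writeBeat <- function(beat, path) {
  stopifnot(is(beat, "NormalizedBeat"))
  w <- beat@waveform
  th <- thetaMatrix(beat)
  nS <- nrow(w@x); nT <- ncol(w@x)
  df <- data.frame(s_index = rep(0:(nS - 1L), times = nT),
                   t_index = rep(0:(nT - 1L), each = nS),
                   x = sprintf("%.17g", as.numeric(w@x)),
                   y = sprintf("%.17g", as.numeric(w@y)),
                   theta = sprintf("%.17g", as.numeric(th)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(schema_version = 1L, swimmer_id = beat@swimmerID,
               L_um = beat@L, T_s = beat@T, beat_offset = beat@beatOffset,
               captured_fraction = beat@capturedFraction,
               n_arclength = nS, n_timepoints = nT)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname writeBeat
#' @export
readBeat <- function(path) {
  df <- read.csv(path)
  need <- c("s_index", "t_index", "x", "y", "theta")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("beat schema violation in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  meta <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  nS <- meta$n_arclength; nT <- meta$n_timepoints
  if (nrow(df) != nS * nT)
    stop("beat file ", path, " has ", nrow(df), " rows; expected ", nS * nT)
  df <- df[order(df$t_index, df$s_index), ]
  new("NormalizedBeat",
      waveform = CartesianWaveform(matrix(df$x, nS, nT), matrix(df$y, nS, nT)),
      L = as.numeric(meta$L_um), T = as.numeric(meta$T_s),
      beatOffset = as.numeric(meta$beat_offset),
      swimmerID = as.character(meta$swimmer_id),
      capturedFraction = if (is.null(meta$captured_fraction)) NA_real_
                         else as.numeric(meta$captured_fraction))
}

#' Read a directory of beats as one dataset
#'
#' Loads every \code{*.beat.csv} in a directory, checks that all beats share
#' one common grid (listing every offending file otherwise), and returns the
#' beats together with an assembled [EmpiricalDataset-class].
#'
#' @param dir directory containing beat files written by [writeBeat()].
#' @return list with \code{beats} (list of [NormalizedBeat-class]) and
#'   \code{dataset} (an [EmpiricalDataset-class]).
#' @export
readBeatDataset <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.beat\\.csv$", full.names = TRUE))
  if (length(files) == 0L) stop("no .beat.csv files found in ", dir)
  beats <- lapply(files, readBeat)
  dims <- vapply(beats, function(b) dim(xCoords(b)), integer(2))
  ok <- dims[1L, ] == dims[1L, 1L] & dims[2L, ] == dims[2L, 1L]
  if (!all(ok))
    stop("beats on mismatched grids: ", paste(basename(files)[!ok], collapse = ", "))
  names(beats) <- vapply(beats, function(b) b@swimmerID, character(1))
  list(beats = beats, dataset = EmpiricalDataset(beats))
}

#' Write an analysis report as JSON
#'
#' Serializes a named list of results (test outcomes, fitted parameters,
#' summary statistics) to JSON with a versioned schema tag.
#'
#' @param results named list.
#' @param path output JSON path.
#' @export
writeReport <- function(results, path) {
  jsonlite::write_json(c(list(schema_version = 1L), results), path,
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}
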