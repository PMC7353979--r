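#' Accessors for waveform and model objects
#'
#' Small generic accessors: \code{sGrid} and \code{tGrid} return the
#' normalized arclength and time grids; \code{xCoords}, \code{yCoords} and
#' \code{thetaMatrix} return the coordinate fields (arclength by time);
#' \code{flagellumLength} and \code{beatPeriod} return the physical scales in
#' micrometres and seconds; \code{pcaModes}, \code{pcaWeights},
#' \code{modeCoefficients} and \code{meanShape} expose the parts of a
#' [PopulationModes-class] fit.
#'
#' @param object an object of one of the package's classes.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("sGrid", function(object) standardGeneric("sGrid"))

#' @rdname accessors
#' @export
setGeneric("tGrid", function(object) standardGeneric("tGrid"))

#' @rdname accessors
#' @export
setGeneric("xCoords", function(object) standardGeneric("xCoords"))

#' @rdname accessors
#' @export
setGeneric("yCoords", function(object) standardGeneric("yCoords"))

#' @rdname accessors
#' @export
setGeneric("thetaMatrix", function(object) standardGeneric("thetaMatrix"))

#' @rdname accessors
#' @export
setGeneric("flagellumLength", function(object) standardGeneric("flagellumLength"))

#' @rdname accessors
#' @export
setGeneric("beatPeriod", function(object) standardGeneric("beatPeriod"))

#' @rdname accessors
#' @export
setGeneric("pcaModes", function(object) standardGeneric("pcaModes"))

#' @rdname accessors
#' @export
setGeneric("pcaWeights", function(object) standardGeneric("pcaWeights"))

#' @rdname accessors
#' @export
setGeneric("modeCoefficients", function(object) standardGeneric("modeCoefficients"))

#' @rdname accessors
#' @export
setGeneric("meanShape", function(object) standardGeneric("meanShape"))

setMethod("sGrid", "CartesianWaveform", function(object) object@sGrid)
setMethod("sGrid", "AngleWaveform", function(object) object@sGrid)
setMethod("sGrid", "NormalizedBeat", function(object) object@waveform@sGrid)
setMethod("tGrid", "CartesianWaveform", function(object) object@tGrid)
setMethod("tGrid", "AngleWaveform", function(object) object@tGrid)
setMethod("tGrid", "NormalizedBeat", function(object) object@waveform@tGrid)
setMethod("xCoords", "CartesianWaveform", function(object) object@x)
setMethod("yCoords", "CartesianWaveform", function(object) object@y)
setMethod("xCoords", "NormalizedBeat", function(object) object@waveform@x)
setMethod("yCoords", "NormalizedBeat", function(object) object@waveform@y)
setMethod("thetaMatrix", "AngleWaveform", function(object) object@theta)
setMethod("thetaMatrix", "NormalizedBeat",
          function(object) thetaMatrix(cartesianToAngle(object@waveform)))
setMethod("thetaMatrix", "CartesianWaveform",
          function(object) thetaMatrix(cartesianToAngle(object)))
setMethod("flagellumLength", "NormalizedBeat", function(object) object@L)
setMethod("beatPeriod", "NormalizedBeat", function(object) object@T)
setMethod("flagellumLength", "SyntheticBeat", function(object) object@L)
setMethod("beatPeriod", "SyntheticBeat", function(object) object@T)
setMethod("pcaModes", "PopulationModes", function(object) object@modes)
setMethod("pcaWeights", "PopulationModes", function(object) object@weights)
setMethod("modeCoefficients", "PopulationModes", function(object) object@coefficients)
setMethod("meanShape", "PopulationModes", function(object) object@mean)

setMethod("show", "CartesianWaveform", function(object) {
  cat(sprintf("CartesianWaveform: %d arclength points x %d timepoints (normalized units)\n",
              nrow(object@x), ncol(object@x)))
})

setMethod("show", "AngleWaveform", function(object) {
  cat(sprintf("AngleWaveform: %d arclength points x %d timepoints, theta in [%.3f, %.3f] rad\n",
              nrow(object@theta), ncol(object@theta),
              min(object@theta), max(object@theta)))
})

setMethod("show", "RawCapture", function(object) {
  cat(sprintf("RawCapture '%s': %d frames over %.4g s, %d-%d points per frame\n",
              object@swimmerID, length(object@frames),
              if (length(object@timestamps)) max(object@timestamps) else 0,
              min(vapply(object@frames, NROW, integer(1))),
              max(vapply(object@frames, NROW, integer(1)))))
})

setMethod("show", "NormalizedBeat", function(object) {
  cat(sprintf(paste0("NormalizedBeat '%s': %d x %d grid, L = %.3g um, T = %.4g s,",
                     " beat offset %.3f\n"),
              object@swimmerID, nrow(object@waveform@x), ncol(object@waveform@x),
              object@L, object@T, object@beatOffset))
})

setMethod("show", "PopulationModes", function(object) {
  k <- min(3L, length(object@weights))
  cat(sprintf("PopulationModes (%s): %d swimmers, %d modes\n",
              object@representation, dim(object@coefficients)[1L],
              length(object@weights)))
  cat(sprintf("  leading weights: %s\n",
              paste(sprintf("%.1f%%", 100 * object@weights[seq_len(k)]), collapse = ", ")))
})

setMethod("show", "SinusoidFit", function(object) {
  cat(sprintf("SinusoidFit of c%d: k = %.4f, phi = %.4f; %d swimmers\n",
              object@mode, object@k, object@phi, nrow(object@perSwimmer)))
})

setMethod("show", "EmpiricalDataset", function(object) {
  cat(sprintf("EmpiricalDataset: %d angle waveforms on a %d x %d grid\n",
              dim(object@theta)[3L], dim(object@theta)[1L], dim(object@theta)[2L]))
})

setMethod("show", "SyntheticBeat", function(object) {
  cat(sprintf("SyntheticBeat from %d source waveforms: L = %.3g um, T = %.4g s\n",
              length(object@sourceIndices), object@L, object@T))
})
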