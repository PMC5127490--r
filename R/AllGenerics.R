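# Generics and shared accessors.

#' @rdname Structure-class
#' @param x a pullscope object
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname Structure-class
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname Trajectory-class
#' @param x a pullscope object
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname NativeContactMap-class
#' @param x a pullscope object
#' @export
setGeneric("contactPairs", function(x) standardGeneric("contactPairs"))

#' @rdname NativeContactMap-class
#' @export
setGeneric("totalWeight", function(x) standardGeneric("totalWeight"))

#' @rdname TwoStateFit-class
#' @param x a pullscope object
#' @export
setGeneric("foldingTemperature", function(x) standardGeneric("foldingTemperature"))

setMethod("coords", "Structure", function(x)
  as.matrix(x@atoms[, c("x", "y", "z")]))
setMethod("nResidues", "Structure", function(x) length(unique(x@atoms$resno)))

setMethod("coords", "Trajectory", function(x) x@coords)
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])

setMethod("contactPairs", "NativeContactMap", function(x) x@pairs)
setMethod("totalWeight", "NativeContactMap", function(x) x@totalWeight)

setMethod("foldingTemperature", "TwoStateFit", function(x) x@Tf)

setMethod("show", "Structure", function(object) {
  cat(sprintf("Structure: %d moieties, %d residues, resolution %s\n",
              nrow(object@atoms), nResidues(object), object@resolution))
})

setMethod("show", "NativeContactMap", function(object) {
  cat(sprintf("NativeContactMap (%s): %d pairs, total weight %g, R0 = %.3f nm\n",
              object@resolution, nrow(object@pairs), object@totalWeight,
              object@cdef@R0))
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat(sprintf("Trajectory '%s': %d frames x %d moieties", object@runId, d[3], d[1]))
  if (any(is.finite(object@extension)))
    cat(sprintf(", extension %.2f..%.2f nm",
                min(object@extension, na.rm = TRUE),
                max(object@extension, na.rm = TRUE)))
  cat("\n")
})

setMethod("show", "TwoStateFit", function(object) {
  cat(sprintf(
    "TwoStateFit: qf = %.3f, qu = %.3f, dH = %.4g, dS = %.4g, Tf = %.4g\n",
    object@qf, object@qu, object@dH, object@dS, object@Tf))
})

setMethod("show", "MeltingCurve", function(object) {
  cat(sprintf("MeltingCurve: %d temperatures in [%g, %g]\n",
              length(object@temperatures), min(object@temperatures),
              max(object@temperatures)))
})

setMethod("show", "PathwayGraph", function(object) {
  cat(sprintf("PathwayGraph: %d nodes over %d Q levels, %d edges, %d trajectories\n",
              nrow(object@nodes), length(unique(object@nodes$level)),
              nrow(object@edges), object@nTrajectories))
})
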