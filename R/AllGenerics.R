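#' Extract the numeric matrix held by a container
#'
#' @param x a \linkS4class{CouplingMatrix}, \linkS4class{MultiTS} or
#'   \linkS4class{CausalityMatrix}.
#' @return the underlying numeric matrix.
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname values
setMethod("values", "CouplingMatrix", function(x) x@values)
#' @rdname values
setMethod("values", "MultiTS", function(x) x@values)
#' @rdname values
setMethod("values", "CausalityMatrix", function(x) x@values)

#' Channel / node labels
#' @param x a container with labelled channels or nodes.
#' @return character vector of labels.
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname channelLabels
setMethod("channelLabels", "MultiTS", function(x) colnames(x@values))
#' @rdname channelLabels
setMethod("channelLabels", "CouplingMatrix", function(x) colnames(x@values))
#' @rdname channelLabels
setMethod("channelLabels", "LeadField", function(x) x@electrodes$label)

#' Topology class of a coupling network
#' @param x a \linkS4class{CouplingMatrix}.
#' @return \code{"RAND"}, \code{"SW"} or \code{"SCF"}.
#' @export
setGeneric("topologyType", function(x) standardGeneric("topologyType"))
#' @rdname topologyType
setMethod("topologyType", "CouplingMatrix", function(x) x@topology)

#' Space tag of a time-series set
#' @param x a \linkS4class{MultiTS}.
#' @return \code{"sensor"} or \code{"source"}.
#' @export
setGeneric("spaceTag", function(x) standardGeneric("spaceTag"))
#' @rdname spaceTag
setMethod("spaceTag", "MultiTS", function(x) x@space)

#' Sampling interval of a time-series set
#' @param x a \linkS4class{MultiTS}.
#' @return positive scalar.
#' @export
setGeneric("samplingInterval", function(x) standardGeneric("samplingInterval"))
#' @rdname samplingInterval
setMethod("samplingInterval", "MultiTS", function(x) x@samplingInterval)

#' Causality measure tag
#' @param x a \linkS4class{CausalityMatrix}.
#' @return \code{"RCGCI"} or \code{"PMIME"}.
#' @export
setGeneric("measureTag", function(x) standardGeneric("measureTag"))
#' @rdname measureTag
setMethod("measureTag", "CausalityMatrix", function(x) x@measure)

#' Gain matrix of a lead field
#' @param x a \linkS4class{LeadField}.
#' @return c x 3v numeric matrix.
#' @export
setGeneric("gainMatrix", function(x) standardGeneric("gainMatrix"))
#' @rdname gainMatrix
setMethod("gainMatrix", "LeadField", function(x) x@gain)

#' Voxel positions of a lead field
#' @param x a \linkS4class{LeadField}.
#' @return v x 3 matrix.
#' @export
setGeneric("voxelPositions", function(x) standardGeneric("voxelPositions"))
#' @rdname voxelPositions
setMethod("voxelPositions", "LeadField", function(x) x@voxels)

#' ROI labels of a voxel partition
#' @param x a \linkS4class{RoiPartition}.
#' @return factor of length v.
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))
#' @rdname roiLabels
setMethod("roiLabels", "RoiPartition", function(x) x@roi)

#' Number of nodes / channels
#' @param x a matrix-backed container.
#' @return integer count.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))
#' @rdname nNodes
setMethod("nNodes", "CouplingMatrix", function(x) nrow(x@values))
#' @rdname nNodes
setMethod("nNodes", "CausalityMatrix", function(x) nrow(x@values))
#' @rdname nNodes
setMethod("nNodes", "MultiTS", function(x) ncol(x@values))

setMethod("show", "CouplingMatrix", function(object) {
  v <- object@values
  cat(sprintf("CouplingMatrix: %d nodes, %d directed edges, topology %s\n",
              nrow(v), sum(v > 0) - sum(diag(v) > 0), object@topology))
  s <- unique(v[v > 0 & row(v) != col(v)])
  if (length(s) == 1) cat(sprintf("  uniform coupling strength %g\n", s))
  else if (length(s) == 0) cat("  empty (no off-diagonal couplings)\n")
  else cat("  binary/unset or heterogeneous strengths\n")
})

setMethod("show", "MultiTS", function(object) {
  cat(sprintf("MultiTS: %d time points x %d channels (%s space), dt = %g\n",
              nrow(object@values), ncol(object@values), object@space,
              object@samplingInterval))
})

setMethod("show", "VarProcess", function(object) {
  sr <- max(abs(eigen(object@A, only.values = TRUE)$values))
  cat(sprintf("VarProcess(1): K = %d, %d non-zero coefficients, spectral radius %.3f\n",
              nrow(object@A), sum(object@A != 0), sr))
})

setMethod("show", "LeadField", function(object) {
  cat(sprintf("LeadField: %d electrodes x %d voxels (3 dipole components), source radius %g\n",
              nrow(object@gain), nrow(object@voxels), object@radius))
})

setMethod("show", "SloretaTransform", function(object) {
  cat(sprintf("SloretaTransform: %d voxels <- %d electrodes\n",
              nrow(object@Tmat) / 3, ncol(object@Tmat)))
})

setMethod("show", "CausalityMatrix", function(object) {
  v <- object@values
  cat(sprintf("CausalityMatrix (%s): %d nodes, %d positive entries\n",
              object@measure, nrow(v), sum(v > 0)))
})

setMethod("show", "EdEpoch", function(object) {
  dur <- nrow(object@signal@values) * object@signal@samplingInterval
  cat(sprintf("EdEpoch: %.2f s, %d channels, ED %.2f-%.2f s\n",
              dur, ncol(object@signal@values), object@edStart, object@edEnd))
})

setMethod("show", "WindowSet", function(object) {
  cat(sprintf("WindowSet: %d windows of %g s, step %g s (%s)\n",
              nrow(object@windows), object@width, object@step,
              paste(sprintf("%s: %d", names(table(object@windows$label)),
                            table(object@windows$label)), collapse = ", ")))
})
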