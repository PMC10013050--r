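#' @import methods
#' @importFrom stats sd cor rnorm runif rbinom t.test lm anova pnorm quantile
#'   fivenum aov
#' @importFrom utils head write.table read.table
#' @useDynLib causalspace, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.TOPOLOGIES <- c("RAND", "SW", "SCF")
.SPACES <- c("sensor", "source")
.MEASURES <- c("RCGCI", "PMIME")

#' Directed coupling network
#'
#' A square non-negative matrix of directed coupling strengths; entry
#' \code{[i, j]} is the strength with which node \code{i} drives node
#' \code{j}. The diagonal is left zero by generation; simulators add their
#' own self-term conventions.
#'
#' @slot values square numeric matrix of non-negative couplings, zero diagonal.
#' @slot topology one of \code{"RAND"}, \code{"SW"}, \code{"SCF"}.
#' @slot params generation parameters used.
#' @slot seed integer seed the network was drawn under (\code{NA} if none).
#' @exportClass CouplingMatrix
setClass("CouplingMatrix",
  slots = c(values = "matrix", topology = "character", params = "list",
            seed = "integer"),
  prototype = prototype(topology = "RAND", params = list(), seed = NA_integer_)
)

setValidity("CouplingMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v) || nrow(v) != ncol(v)) return("values must be a square numeric matrix")
  if (nrow(v) < 2) return("at least 2 nodes required")
  if (any(!is.finite(v))) return("couplings must be finite")
  if (any(v < 0)) return("couplings must be non-negative")
  if (!object@topology %in% .TOPOLOGIES)
    return(sprintf("topology must be one of %s", paste(.TOPOLOGIES, collapse = ", ")))
  TRUE
})

#' Multivariate time series
#'
#' An N x K matrix of sampled signals with a sampling interval, channel
#' labels (column names) and a space tag marking whether the signals live in
#' the sensor space (recorded channels) or the source space (ROI-averaged
#' standardized current-density power).
#'
#' @slot values N x K numeric matrix (rows are time points).
#' @slot samplingInterval time between consecutive rows, in the system's
#'   time units (seconds for synthetic EEG).
#' @slot space \code{"sensor"} or \code{"source"}.
#' @exportClass MultiTS
setClass("MultiTS",
  slots = c(values = "matrix", samplingInterval = "numeric", space = "character"),
  prototype = prototype(samplingInterval = 1, space = "sensor")
)

setValidity("MultiTS", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (nrow(v) < 2) return("need at least 2 time points")
  if (any(!is.finite(v))) return("values contain NaN/Inf")
  if (length(object@samplingInterval) != 1 || object@samplingInterval <= 0)
    return("samplingInterval must be a positive scalar")
  if (!object@space %in% .SPACES)
    return(sprintf("space must be one of %s", paste(.SPACES, collapse = ", ")))
  TRUE
})

#' First-order vector autoregressive process
#'
#' @slot A K x K coefficient matrix of \code{x_t = A x_{t-1} + e_t}.
#' @slot noiseCov K x K innovation covariance (identity by default).
#' @slot order model order (fixed at 1).
#' @exportClass VarProcess
setClass("VarProcess",
  slots = c(A = "matrix", noiseCov = "matrix", order = "integer"),
  prototype = prototype(order = 1L)
)

setValidity("VarProcess", function(object) {
  if (nrow(object@A) != ncol(object@A)) return("A must be square")
  if (any(!is.finite(object@A))) return("A must be finite")
  if (!identical(dim(object@A), dim(object@noiseCov)))
    return("noiseCov must match the dimension of A")
  TRUE
})

#' Linear transform of a VAR process
#'
#' Records an invertible mixing matrix H applied to the state of a VAR(1)
#' process, the induced coefficient matrix \code{B = H A H^-1} (similar to A,
#' hence with identical eigenvalues) and the eigenvector matrix of A.
#'
#' @slot H invertible K x K mixing matrix.
#' @slot B induced coefficient matrix \code{H A H^-1}.
#' @slot QA eigenvector matrix of A (columns are eigenvectors; complex if
#'   A has complex eigenvalues).
#' @exportClass LinearTransform
setClass("LinearTransform", slots = c(H = "matrix", B = "matrix", QA = "ANY"))

#' Lead field of a synthetic spherical head model
#'
#' Gain matrix of the forward model \code{m = G d} for c electrodes on the
#' unit sphere and v voxels on a regular grid inside a concentric sphere,
#' three dipole components per voxel (columns ordered voxel-major: x, y, z of
#' voxel 1, then voxel 2, ...).
#'
#' @slot gain c x 3v gain matrix.
#' @slot electrodes data.frame with columns label, x, y, z (unit sphere).
#' @slot voxels v x 3 matrix of voxel centre positions.
#' @slot spacing grid spacing of the voxel lattice.
#' @slot radius radius of the source sphere (electrodes sit at radius 1).
#' @exportClass LeadField
setClass("LeadField",
  slots = c(gain = "matrix", electrodes = "data.frame", voxels = "matrix",
            spacing = "numeric", radius = "numeric")
)

setValidity("LeadField", function(object) {
  c_ <- nrow(object@gain); v <- nrow(object@voxels)
  if (ncol(object@gain) != 3 * v) return("gain must have 3 columns per voxel")
  if (nrow(object@electrodes) != c_) return("electrode table must match gain rows")
  if (any(!is.finite(object@gain))) return("gain must be finite")
  cn <- sqrt(colSums(object@gain^2))
  if (any(cn == 0)) return("lead field has a zero column (invisible dipole component)")
  TRUE
})

#' Standardized weighted-Laplacian minimum-norm inverse operator
#'
#' The inverse operator T of the weighted minimum-norm problem
#' \code{min ||L W d||} subject to \code{m = G d}, together with the
#' per-voxel 3 x 3 inverse covariance blocks used for the standardized
#' power (the quadratic form \code{di . Sii^-1 . di}).
#'
#' @slot Tmat 3v x c inverse operator.
#' @slot W diagonal column-norm weights (length 3v).
#' @slot Sinv 3 x 3 x v array of inverted model-covariance blocks.
#' @slot electrodeLabels channel labels the operator expects, in order.
#' @exportClass SloretaTransform
setClass("SloretaTransform",
  slots = c(Tmat = "matrix", W = "numeric", Sinv = "array",
            electrodeLabels = "character")
)

#' Voxel-to-ROI partition
#'
#' Assignment of every voxel to the nearest electrode; ROI labels coincide
#' with electrode labels, cells are disjoint and jointly exhaustive.
#'
#' @slot roi factor of length v with one level per electrode label.
#' @exportClass RoiPartition
setClass("RoiPartition", slots = c(roi = "factor"))

setValidity("RoiPartition", function(object) {
  if (anyNA(object@roi)) return("every voxel must be assigned to a ROI")
  TRUE
})

#' Estimated directed causality matrix
#'
#' K x K non-negative matrix of estimated directed causal strengths with a
#' zero diagonal; entry \code{[i, j]} is the estimated strength of the
#' driving i -> j. A zero entry means no driving was detected. PMIME values
#' lie in [0, 1].
#'
#' @slot values K x K non-negative matrix, zero diagonal.
#' @slot measure \code{"RCGCI"} or \code{"PMIME"}.
#' @slot params estimation parameters used.
#' @exportClass CausalityMatrix
setClass("CausalityMatrix",
  slots = c(values = "matrix", measure = "character", params = "list"),
  prototype = prototype(params = list())
)

setValidity("CausalityMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (any(!is.finite(v))) return("values must be finite")
  if (any(v < 0)) return("causality values must be non-negative")
  if (any(diag(v) != 0)) return("diagonal must be zero")
  if (!object@measure %in% .MEASURES)
    return(sprintf("measure must be one of %s", paste(.MEASURES, collapse = ", ")))
  if (object@measure == "PMIME" && any(v > 1)) return("PMIME values must lie in [0, 1]")
  TRUE
})

#' Synthetic epileptiform-discharge epoch
#'
#' A multichannel epoch with a pre-ED period, an ED period of configurable
#' duration and a post-ED period, together with the ground-truth generating
#' networks of the background and ED segments.
#'
#' @slot signal \linkS4class{MultiTS} at the configured sampling rate.
#' @slot edStart,edEnd ED boundaries in seconds from epoch start.
#' @slot background,edNetwork generating \linkS4class{CouplingMatrix} objects.
#' @exportClass EdEpoch
setClass("EdEpoch",
  slots = c(signal = "MultiTS", edStart = "numeric", edEnd = "numeric",
            background = "CouplingMatrix", edNetwork = "CouplingMatrix")
)

setValidity("EdEpoch", function(object) {
  if (object@edStart <= 0 || object@edEnd <= object@edStart) return("invalid ED boundaries")
  dur <- nrow(object@signal@values) * object@signal@samplingInterval
  if (object@edEnd >= dur) return("ED must end before the epoch does")
  TRUE
})

#' Sliding-window set over an epoch
#'
#' @slot windows data.frame with columns start, end (seconds) and label
#'   (one of preED, ED, postED).
#' @slot width,step window width and sliding step in seconds.
#' @exportClass WindowSet
setClass("WindowSet",
  slots = c(windows = "data.frame", width = "numeric", step = "numeric")
)

setValidity("WindowSet", function(object) {
  if (object@width <= object@step || object@step <= 0)
    return("need width > step > 0")
  w <- object@windows
  if (!all(c("start", "end", "label") %in% names(w))) return("missing window columns")
  if (is.unsorted(w$start)) return("windows must be ordered")
  TRUE
})
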