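#' @import methods
NULL

SS3_STATES <- c("H", "E", "C")
SS8_STATES <- c("H", "G", "I", "E", "B", "T", "S", "C")

#' SSDataset: a collection of protein chains with secondary structure
#'
#' Holds an ordered set of protein chains, each with an amino-acid
#' sequence, an 8-state DSSP secondary structure string (alphabet
#' H, G, I, E, B, T, S with C standing for blank/irregular) and,
#' optionally after reduction, a 3-state string over H/E/C.
#'
#' @slot chainId character vector of unique chain identifiers.
#' @slot sequence character vector of amino-acid sequences (one-letter
#'   codes, \code{X} allowed for unknown residues).
#' @slot ss8 character vector of 8-state structure strings, same
#'   lengths as \code{sequence}.
#' @slot ss3 character vector of 3-state structure strings over
#'   \code{H,E,C}, or \code{NA} where the reduction has not been applied.
#' @slot name single string naming the dataset.
#'
#' @seealso [SSDataset()], [reduceToSS3()], [trimTermini()]
#' @export
setClass("SSDataset",
  representation(
    chainId = "character",
    sequence = "character",
    ss8 = "character",
    ss3 = "character",
    name = "character"
  ),
  prototype(name = "")
)

setValidity("SSDataset", function(object) {
  n <- length(object@chainId)
  msgs <- character()
  if (length(object@sequence) != n || length(object@ss8) != n ||
      length(object@ss3) != n) {
    return("chainId, sequence, ss8 and ss3 must have equal length")
  }
  if (anyDuplicated(object@chainId)) {
    msgs <- c(msgs, "chain identifiers must be unique")
  }
  if (any(nchar(object@sequence) != nchar(object@ss8))) {
    bad <- object@chainId[nchar(object@sequence) != nchar(object@ss8)]
    msgs <- c(msgs, paste0("sequence/ss8 length mismatch for chain(s): ",
                           paste(bad, collapse = ", ")))
  }
  has3 <- !is.na(object@ss3)
  if (any(nchar(object@ss3[has3]) != nchar(object@sequence[has3]))) {
    bad <- object@chainId[has3][nchar(object@ss3[has3]) !=
                                  nchar(object@sequence[has3])]
    msgs <- c(msgs, paste0("sequence/ss3 length mismatch for chain(s): ",
                           paste(bad, collapse = ", ")))
  }
  if (any(grepl("[^HEC]", object@ss3[has3]))) {
    msgs <- c(msgs, "ss3 strings may contain only H, E, C")
  }
  if (length(msgs)) msgs else TRUE
})

#' FeatureSet: per-residue 27-dimensional probability features
#'
#' One row per scored residue.  The 27 raw features are ordered as nine
#' P(H) values, nine P(E) values and nine P(C) values, each block
#' covering window positions t-4..t+4 around the target residue t.
#' Normalized ([-1,1]) and complex (unit-circle) forms are filled in by
#' [normalizeFeatures()] and [circularTransform()].
#'
#' @slot raw numeric matrix (residues x 27) of probabilities in [0,1].
#' @slot normalized numeric matrix (residues x 27) in [-1,1], or a
#'   0-row matrix before normalization.
#' @slot complexForm complex matrix (residues x 27) with unit-modulus
#'   entries, or a 0-row matrix before the circular transform.
#' @slot labels character vector of true 3-state labels (H/E/C).
#' @slot chainId character vector mapping rows to chains.
#' @slot resIdx integer vector of 1-based residue positions within each
#'   chain.
#' @slot normExtrema numeric 2 x 27 matrix (rows \code{min}, \code{max})
#'   of the extrema used at normalization time; NA before normalization.
#' @slot alpha circular-transform angle in radians (NA before the
#'   transform).
#' @export
setClass("FeatureSet",
  representation(
    raw = "matrix",
    normalized = "matrix",
    complexForm = "matrix",
    labels = "character",
    chainId = "character",
    resIdx = "integer",
    normExtrema = "matrix",
    alpha = "numeric"
  ),
  prototype(
    normalized = matrix(numeric(), 0, 27),
    complexForm = matrix(complex(), 0, 27),
    normExtrema = matrix(NA_real_, 2, 27,
                         dimnames = list(c("min", "max"), NULL)),
    alpha = NA_real_
  )
)

setValidity("FeatureSet", function(object) {
  n <- nrow(object@raw)
  msgs <- character()
  if (ncol(object@raw) != 27) msgs <- c(msgs, "raw must have 27 columns")
  if (length(object@labels) != n || length(object@chainId) != n ||
      length(object@resIdx) != n) {
    msgs <- c(msgs, "labels, chainId, resIdx must match the row count")
  }
  if (any(!object@labels %in% SS3_STATES)) {
    msgs <- c(msgs, "labels must be H, E or C")
  }
  if (nrow(object@normalized) > 0 && nrow(object@normalized) != n) {
    msgs <- c(msgs, "normalized must be empty or match the row count")
  }
  if (nrow(object@complexForm) > 0 && nrow(object@complexForm) != n) {
    msgs <- c(msgs, "complexForm must be empty or match the row count")
  }
  if (length(msgs)) msgs else TRUE
})

#' FCRNModel: a trained fully complex-valued relaxation network
#'
#' Single-hidden-layer complex network: input layer of \code{m} neurons
#' holding the circularly transformed features, \code{K} hidden neurons
#' with hyperbolic-secant activation, and \code{n} output neurons with
#' exponential activation.  Hidden parameters are random seeded
#' projections; output weights are obtained analytically by a
#' regularized complex least-squares solve against log-coded labels.
#'
#' @slot m input dimensionality (27).
#' @slot n number of classes (3).
#' @slot K hidden-neuron count.
#' @slot V complex K x m matrix of hidden projection vectors.
#' @slot b complex length-K vector of hidden biases.
#' @slot W complex n x K output weight matrix.
#' @slot classCodes complex length-2 vector \code{c(true=, false=)} of
#'   coded label values.
#' @slot classes character class order used on the output layer
#'   (\code{H, E, C}).
#' @slot alpha circular-transform angle carried for inference.
#' @slot normExtrema 2 x 27 reference extrema carried for inference.
#' @slot ridge ridge parameter used in the output-weight solve.
#' @slot seed integer seed the hidden parameters were drawn from.
#' @export
setClass("FCRNModel",
  representation(
    m = "integer", n = "integer", K = "integer",
    V = "matrix", b = "complex", W = "matrix",
    classCodes = "complex", classes = "character",
    alpha = "numeric", normExtrema = "matrix",
    ridge = "numeric", seed = "integer"
  )
)

setValidity("FCRNModel", function(object) {
  msgs <- character()
  if (object@K < 1L) msgs <- c(msgs, "K must be >= 1")
  if (!all(is.finite(Re(object@W))) || !all(is.finite(Im(object@W)))) {
    msgs <- c(msgs, "output weights must be finite")
  }
  if (anyDuplicated(object@classCodes)) {
    msgs <- c(msgs, "class codes must be pairwise distinct")
  }
  if (length(msgs)) msgs else TRUE
})

#' CandidateSet: a candidate compact training set
#'
#' Either a chain-level selection (named chains from the development
#' dataset) or a residue-level selection (specific residues, used by the
#' class-balanced heuristic).
#'
#' @slot name candidate label, e.g. \code{sampled}, \code{balanced},
#'   \code{spread} or \code{curve_derived}.
#' @slot level \code{"chain"} or \code{"residue"}.
#' @slot chains character vector of member chain ids (chain level).
#' @slot residues data.frame with columns \code{chainId}, \code{resIdx}
#'   (residue level); 0-row otherwise.
#' @slot seed provenance seed used to draw the set.
#' @export
setClass("CandidateSet",
  representation(
    name = "character", level = "character",
    chains = "character", residues = "data.frame",
    seed = "integer"
  ),
  prototype(residues = data.frame(chainId = character(),
                                  resIdx = integer()))
)

setValidity("CandidateSet", function(object) {
  if (!object@level %in% c("chain", "residue")) {
    return("level must be 'chain' or 'residue'")
  }
  TRUE
})

#' MetricsReport: the full evaluation summary for a prediction
#'
#' @slot confusion 3 x 3 integer matrix, rows observed H/E/C, columns
#'   predicted H/E/C.
#' @slot q3 overall residue accuracy, percent.
#' @slot qClass named per-class accuracies (percent); NA for classes
#'   absent from the observed strings.
#' @slot mcc named per-class Matthews correlation coefficients.
#' @slot qHEError percentage of residues confused between helix and
#'   sheet.
#' @slot sov named segment-overlap scores: \code{all}, \code{H},
#'   \code{E}, \code{C}.
#' @slot nResidues total residues scored.
#' @export
setClass("MetricsReport",
  representation(
    confusion = "matrix",
    q3 = "numeric",
    qClass = "numeric",
    mcc = "numeric",
    qHEError = "numeric",
    sov = "numeric",
    nResidues = "integer"
  )
)
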