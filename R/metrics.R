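#' Build a 3 x 3 confusion matrix from observed/predicted strings
#'
#' @param observed,predicted 3-state structure strings (or character
#'   vectors of single states) of equal length over H/E/C.
#' @return Integer 3 x 3 matrix, rows observed H/E/C, columns predicted
#'   H/E/C.
#' @examples
#' confusionMatrix3("HHEE", "HEEC")
#' @export
confusionMatrix3 <- function(observed, predicted) {
  o <- if (length(observed) == 1L) ssChars(observed) else observed
  p <- if (length(predicted) == 1L) ssChars(predicted) else predicted
  if (length(o) != length(p)) {
    stopf("observed (%d) and predicted (%d) lengths differ",
          length(o), length(p))
  }
  if (any(!o %in% SS3_STATES) || any(!p %in% SS3_STATES)) {
    stopf("states must be H, E or C")
  }
  cm <- table(factor(o, SS3_STATES), factor(p, SS3_STATES))
  m <- matrix(as.integer(cm), 3, 3,
              dimnames = list(observed = SS3_STATES,
                              predicted = SS3_STATES))
  m
}

checkCM <- function(cm) {
  if (!is.matrix(cm) || !all(dim(cm) == c(3, 3)) || any(cm < 0)) {
    stopf("expected a 3 x 3 non-negative confusion matrix")
  }
  cm
}

#' Residue-level accuracy scores from a confusion matrix
#'
#' `q3` is the overall three-state accuracy (correctly predicted
#' residues over all residues, percent).  `qClass` is the per-class
#' accuracy: correctly predicted residues of state j over all observed
#' residues of state j.  `qHEError` is the helix/sheet confusion rate:
#' residues observed H but predicted E plus observed E predicted H, over
#' all residues.
#'
#' @param cm a 3 x 3 confusion matrix (rows observed, columns
#'   predicted, order H/E/C), e.g. from [confusionMatrix3()].
#' @return Percentages at full precision (round only for display).
#' @export
q3 <- function(cm) {
  cm <- checkCM(cm)
  tot <- sum(cm)
  if (tot == 0) stopf("empty confusion matrix")
  100 * sum(diag(cm)) / tot
}

#' @rdname q3
#' @param j state: \code{"H"}, \code{"E"} or \code{"C"}.
#' @return `qClass` returns NA (undefined, not 0) when no residue of
#'   state j was observed.
#' @export
qClass <- function(cm, j) {
  cm <- checkCM(cm)
  i <- match(match.arg(j, SS3_STATES), SS3_STATES)
  rs <- sum(cm[i, ])
  if (rs == 0) return(NA_real_)
  100 * cm[i, i] / rs
}

#' @rdname q3
#' @export
qHEError <- function(cm) {
  cm <- checkCM(cm)
  tot <- sum(cm)
  if (tot == 0) stopf("empty confusion matrix")
  100 * (cm[1, 2] + cm[2, 1]) / tot
}

#' Per-class Matthews correlation coefficient
#'
#' One-vs-rest MCC for state j:
#' \deqn{MCC_j = \frac{TP \cdot TN - FP \cdot FN}{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' with TP/FP/TN/FN tallied from the confusion matrix treating state j
#' as positive.  Returns 0 when any factor of the denominator is 0 (the
#' standard degenerate convention).
#'
#' @param cm a 3 x 3 confusion matrix.
#' @param j state: \code{"H"}, \code{"E"} or \code{"C"}.
#' @return A value in [-1, 1].
#' @export
mccClass <- function(cm, j) {
  cm <- checkCM(cm)
  i <- match(match.arg(j, SS3_STATES), SS3_STATES)
  # double precision: one-vs-rest products overflow integer range
  tp <- as.numeric(cm[i, i])
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Score predictions over one or more chains
#'
#' Pools residues across chains for the confusion-matrix statistics
#' (Q3, per-class Q, MCC, helix/sheet confusion) and computes the
#' segment-overlap scores with hard segment breaks between chains (a
#' segment never spans two chains).
#'
#' @param observed,predicted character vectors of 3-state strings, one
#'   element per chain, equal lengths pairwise.
#' @param chainIds optional chain names used in error messages.
#' @return A [MetricsReport-class].
#' @export
scoreChains <- function(observed, predicted, chainIds = NULL) {
  if (length(observed) != length(predicted) || !length(observed)) {
    stopf("need >= 1 observed/predicted pair, in equal numbers")
  }
  if (is.null(chainIds)) chainIds <- as.character(seq_along(observed))
  bad <- nchar(observed) != nchar(predicted)
  if (any(bad)) {
    stopf("observed/predicted length mismatch for chain(s): %s",
          paste(chainIds[bad], collapse = ", "))
  }
  cm <- confusionMatrix3(paste(observed, collapse = ""),
                         paste(predicted, collapse = ""))
  qc <- vapply(SS3_STATES, function(j) qClass(cm, j), numeric(1))
  mcc <- vapply(SS3_STATES, function(j) mccClass(cm, j), numeric(1))
  sovAll <- sovScore(observed, predicted)
  sovJ <- vapply(SS3_STATES,
                 function(j) sovScore(observed, predicted, states = j),
                 numeric(1))
  new("MetricsReport", confusion = cm, q3 = q3(cm), qClass = qc,
      mcc = mcc, qHEError = qHEError(cm),
      sov = c(all = sovAll, sovJ), nResidues = sum(cm))
}

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport on %d residues\n", object@nResidues))
  cat(sprintf("  Q3 %.2f%%   SOV %.2f%%   Q_HEerror %.2f%%\n",
              object@q3, object@sov[["all"]], object@qHEError))
  for (j in SS3_STATES) {
    cat(sprintf("  %s: Q %6.2f%%  SOV %6.2f%%  MCC %5.2f\n", j,
                object@qClass[[j]], object@sov[[j]], object@mcc[[j]]))
  }
  cat("  confusion (rows observed, cols predicted):\n")
  print(object@confusion)
})

#' Accessors for MetricsReport
#'
#' @param x a [MetricsReport-class].
#' @return `metricsTable` returns a one-row data.frame of all scores;
#'   `confusion` the pooled 3 x 3 matrix.
#' @export
metricsTable <- function(x) {
  data.frame(q3 = x@q3, qH = x@qClass[["H"]], qE = x@qClass[["E"]],
             qC = x@qClass[["C"]], sov = x@sov[["all"]],
             sovH = x@sov[["H"]], sovE = x@sov[["E"]],
             sovC = x@sov[["C"]], mccH = x@mcc[["H"]],
             mccE = x@mcc[["E"]], mccC = x@mcc[["C"]],
             qHEError = x@qHEError, nResidues = x@nResidues,
             row.names = NULL)
}

#' @rdname metricsTable
#' @export
confusion <- function(x) x@confusion
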