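#' Construct a FeatureSet from raw components
#'
#' Mostly used internally and by [readFeatureSet()]; end users normally
#' obtain feature sets from [generateFeatures()].
#'
#' @param raw numeric matrix (residues x 27) of probabilities.
#' @param labels character vector of 3-state labels.
#' @param chainId character vector of chain ids per row.
#' @param resIdx integer vector of residue positions per row.
#' @return A [FeatureSet-class].
#' @export
FeatureSet <- function(raw, labels, chainId, resIdx) {
  new("FeatureSet", raw = as.matrix(raw), labels = as.character(labels),
      chainId = as.character(chainId), resIdx = as.integer(resIdx))
}

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf(paste0("FeatureSet: %d residues x 27 features ",
                     "(%d chains)\n  normalized: %s   complex form: %s\n"),
              nrow(object@raw), length(unique(object@chainId)),
              if (nrow(object@normalized)) "yes" else "no",
              if (nrow(object@complexForm)) "yes" else "no"))
})

#' @describeIn FeatureSet number of residues (rows)
#' @param x a FeatureSet
#' @export
setMethod("nrow", "FeatureSet", function(x) nrow(x@raw))

#' Accessors for FeatureSet contents
#'
#' @param x a [FeatureSet-class].
#' @return `featureMatrix` the raw 27-column matrix; `featureLabels`
#'   the true labels; `normalizedMatrix` / `complexMatrix` the derived
#'   forms (error if not yet computed); `normExtrema` the stored
#'   per-feature min/max.
#' @export
featureMatrix <- function(x) x@raw

#' @rdname featureMatrix
#' @export
featureLabels <- function(x) x@labels

#' @rdname featureMatrix
#' @export
normalizedMatrix <- function(x) {
  if (!nrow(x@normalized)) stopf("features not normalized yet")
  x@normalized
}

#' @rdname featureMatrix
#' @export
complexMatrix <- function(x) {
  if (!nrow(x@complexForm)) stopf("circular transform not applied yet")
  x@complexForm
}

#' @rdname featureMatrix
#' @export
normExtrema <- function(x) x@normExtrema

# row subset preserving derived forms
subsetFeatures <- function(x, i) {
  new("FeatureSet",
      raw = x@raw[i, , drop = FALSE],
      normalized = if (nrow(x@normalized)) x@normalized[i, , drop = FALSE]
                   else x@normalized,
      complexForm = if (nrow(x@complexForm)) x@complexForm[i, , drop = FALSE]
                    else x@complexForm,
      labels = x@labels[i], chainId = x@chainId[i], resIdx = x@resIdx[i],
      normExtrema = x@normExtrema, alpha = x@alpha)
}

#' @export
setMethod("[", "FeatureSet", function(x, i, j, ..., drop = TRUE) {
  subsetFeatures(x, i)
})

#' Generate synthetic residue probability features
#'
#' Emulates the statistical structure of energy-potential-derived
#' residue features: for each residue a probability triplet over
#' (H, E, C) is drawn from a Dirichlet law whose concentration vector is
#' \code{kappa} on the true state plus a small uniform smoothing mass
#' (0.05 per state).  As \code{kappa} grows the triplet concentrates on
#' the true state; as \code{kappa} approaches 0 the mean triplet tends
#' to (1/3, 1/3, 1/3).  Each residue's triplet is drawn once and shared
#' by every nine-residue window containing it, so neighbouring feature
#' vectors are correlated exactly as a sliding-window encoder's would
#' be.  Feature vectors are emitted only for residues with four
#' neighbours on both sides, i.e. \code{length - 8} rows per chain.
#'
#' @param chains an [SSDataset-class] with \code{ss3} present.
#' @param kappa concentration parameter (> 0) controlling how
#'   informative the triplets are about the true state.
#' @param seed integer seed; identical (chains, kappa, seed) reproduce
#'   identical output.
#' @param smoothing uniform smoothing mass added to each concentration
#'   component (default 0.05).
#' @return A [FeatureSet-class] with raw probabilities filled.
#' @export
generateFeatures <- function(chains, kappa, seed, smoothing = 0.05) {
  if (!is.numeric(kappa) || kappa <= 0) stopf("kappa must be > 0")
  if (any(is.na(chains@ss3))) stopf("chains must carry ss3")
  withSeed(seed, {
    rows <- list(); labs <- list(); cids <- list(); idxs <- list()
    for (i in seq_along(chains@chainId)) {
      s3 <- ssChars(chains@ss3[i])
      L <- length(s3)
      conc <- matrix(smoothing, L, 3)
      conc[cbind(seq_len(L), match(s3, SS3_STATES))] <-
        kappa + smoothing
      g <- matrix(stats::rgamma(L * 3L, shape = conc), L, 3)
      rs <- rowSums(g)
      zero <- rs == 0
      if (any(zero)) { g[zero, ] <- 1; rs[zero] <- 3 }
      trip <- g / rs
      if (L >= 9L) {
        centre <- 5:(L - 4L)
        off <- -4:4
        win <- outer(centre, off, `+`)
        # block order: 9 x P(H), 9 x P(E), 9 x P(C)
        feat <- cbind(matrix(trip[win, 1], length(centre), 9),
                      matrix(trip[win, 2], length(centre), 9),
                      matrix(trip[win, 3], length(centre), 9))
        rows[[i]] <- feat
        labs[[i]] <- s3[centre]
        cids[[i]] <- rep(chains@chainId[i], length(centre))
        idxs[[i]] <- centre
      }
    }
    FeatureSet(do.call(rbind, rows), unlist(labs), unlist(cids),
               unlist(idxs))
  })
}

#' Normalize features to [-1, 1]
#'
#' Applies the linear map \eqn{2 (x - min)/(max - min) - 1}.  By default
#' the per-feature extrema of the data themselves are used (dataset
#' level, one min/max per feature column) and recorded on the returned
#' object; a stored reference (e.g. the training set's extrema, for
#' blind-test data) can be supplied instead, in which case values
#' falling outside the reference range are clipped to +-1.  A per-vector
#' mode (extrema taken within each 27-vector) is also available.
#'
#' @param fs a [FeatureSet-class].
#' @param refExtrema optional 2 x 27 matrix (rows min, max), e.g.
#'   [normExtrema()] of the training features.
#' @param mode \code{"feature"} (default: per-feature, dataset-level
#'   extrema) or \code{"vector"} (per-27-vector extrema).
#' @return The feature set with \code{normalized} filled and the
#'   extrema used recorded (feature mode).
#' @export
normalizeFeatures <- function(fs, refExtrema = NULL,
                              mode = c("feature", "vector")) {
  mode <- match.arg(mode)
  x <- fs@raw
  if (mode == "vector") {
    mn <- apply(x, 1, min); mx <- apply(x, 1, max)
    if (any(mx == mn)) {
      stopf("degenerate scale (max == min) for row(s): %s",
            paste(which(mx == mn), collapse = ", "))
    }
    fs@normalized <- 2 * (x - mn) / (mx - mn) - 1
    return(fs)
  }
  if (is.null(refExtrema)) {
    mn <- apply(x, 2, min); mx <- apply(x, 2, max)
  } else {
    if (!is.matrix(refExtrema) || ncol(refExtrema) != 27 ||
        nrow(refExtrema) != 2) {
      stopf("refExtrema must be a 2 x 27 matrix (rows min, max)")
    }
    mn <- refExtrema[1, ]; mx <- refExtrema[2, ]
  }
  degen <- mx == mn
  if (any(degen)) {
    stopf("degenerate scale (max == min) for feature(s): %s",
          paste(which(degen), collapse = ", "))
  }
  z <- sweep(sweep(x, 2, mn), 2, (mx - mn) / 2, `/`) - 1
  z[z > 1] <- 1; z[z < -1] <- -1   # clip outside a reference range
  fs@normalized <- z
  fs@normExtrema <- rbind(min = mn, max = mx)
  fs
}

#' Map normalized features onto the unit circle
#'
#' The circular transformation \eqn{z_j = \exp(i \alpha x_j)} carries
#' each normalized real feature in [-1, 1] to a unit-modulus complex
#' number; it is injective on [-1, 1] whenever \eqn{\alpha < \pi}.
#'
#' @param fs a [FeatureSet-class] with normalized values present.
#' @param alpha transform angle in radians, default \eqn{\pi/2}.
#' @return The feature set with \code{complexForm} filled and
#'   \code{alpha} recorded.
#' @export
circularTransform <- function(fs, alpha = pi / 2) {
  if (!nrow(fs@normalized)) stopf("normalize features before transforming")
  if (alpha >= pi) stopf("alpha must be < pi to keep the map injective")
  if (alpha <= 0) stopf("alpha must be > 0")
  fs@complexForm <- exp(1i * alpha * fs@normalized)
  fs@alpha <- alpha
  fs
}

#' Read and write FeatureSet TSV files
#'
#' Plain tab-separated serialization, one row per residue with fixed
#' header \code{chain_id}, \code{residue_index}, \code{label},
#' \code{f01}..\code{f27} (the raw probabilities; derived forms are
#' recomputable).
#'
#' @param fs a [FeatureSet-class].
#' @param path output path.
#' @export
writeFeatureSet <- function(fs, path) {
  df <- data.frame(chain_id = fs@chainId, residue_index = fs@resIdx,
                   label = fs@labels, fs@raw)
  names(df)[-(1:3)] <- sprintf("f%02d", 1:27)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureSet
#' @export
readFeatureSet <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer",
                                         "character", rep("numeric", 27)))
  expected <- c("chain_id", "residue_index", "label",
                sprintf("f%02d", 1:27))
  if (!identical(names(df), expected)) {
    stopf("unexpected FeatureSet header in %s", path)
  }
  FeatureSet(as.matrix(df[, -(1:3)]), df$label, df$chain_id,
             df$residue_index)
}
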