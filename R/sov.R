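# maximal runs of `state` in a state-character vector: data.frame(start, end, len)
ssSegments <- function(chars, state) {
  r <- rle(chars == state)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  keep <- r$values
  data.frame(start = start[keep], end = end[keep],
             len = r$lengths[keep])
}

# SOV numerator/denominator contributions for one chain and one state
sovAccumulate <- function(obsChars, predChars, state) {
  s1 <- ssSegments(obsChars, state)
  s2 <- ssSegments(predChars, state)
  num <- 0; den <- 0
  if (!nrow(s1)) return(c(num = 0, den = 0))
  for (a in seq_len(nrow(s1))) {
    o1 <- s1$start[a]:s1$end[a]
    overlapped <- FALSE
    if (nrow(s2)) {
      for (b in seq_len(nrow(s2))) {
        lo <- max(s1$start[a], s2$start[b])
        hi <- min(s1$end[a], s2$end[b])
        if (lo > hi) next
        overlapped <- TRUE
        minov <- hi - lo + 1L
        maxov <- max(s1$end[a], s2$end[b]) -
          min(s1$start[a], s2$start[b]) + 1L
        delta <- min(maxov - minov, minov,
                     s1$len[a] %/% 2L, s2$len[b] %/% 2L)
        num <- num + s1$len[a] * (minov + delta) / maxov
        den <- den + s1$len[a]
      }
    }
    if (!overlapped) den <- den + s1$len[a]
  }
  c(num = num, den = den)
}

#' Segment overlap score (SOV, 1999 revision)
#'
#' Segment-level agreement between observed and predicted secondary
#' structure.  Segments are maximal runs of one state.  Every pair of
#' overlapping observed/predicted segments (s1, s2) of the same state
#' contributes \eqn{len(s1)(minov + \delta)/maxov} to the numerator
#' and \eqn{len(s1)} to the normalizer, where minov and maxov are the
#' lengths of the intersection and the union of the two segments'
#' position ranges and the tolerance is
#' \eqn{\delta = \min(maxov - minov,\; minov,\; \lfloor len(s1)/2
#' \rfloor,\; \lfloor len(s2)/2 \rfloor)}.  Observed segments with no
#' overlapping partner contribute \eqn{len(s1)} to the normalizer only.
#' Per-state scores restrict to one state; the overall score pools
#' numerators and normalizers over H, E and C.  Chains are treated
#' independently: segments never merge across chain boundaries.
#'
#' @param observed,predicted 3-state strings or character vectors of
#'   strings (one per chain).
#' @param states which states to pool over (default all of H, E, C).
#' @return The score as a percentage; 100 when every observed state has
#'   no segments (empty numerator and normalizer).
#' @export
sovScore <- function(observed, predicted, states = SS3_STATES) {
  if (length(observed) != length(predicted)) {
    stopf("observed and predicted chain counts differ")
  }
  if (any(nchar(observed) != nchar(predicted))) {
    stopf("observed/predicted length mismatch")
  }
  states <- match.arg(states, SS3_STATES, several.ok = TRUE)
  num <- 0; den <- 0
  for (i in seq_along(observed)) {
    o <- ssChars(observed[i]); p <- ssChars(predicted[i])
    if (any(!o %in% SS3_STATES) || any(!p %in% SS3_STATES)) {
      stopf("states must be H, E or C")
    }
    for (st in states) {
      acc <- sovAccumulate(o, p, st)
      num <- num + acc[["num"]]
      den <- den + acc[["den"]]
    }
  }
  if (den == 0) return(100)
  100 * num / den
}
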