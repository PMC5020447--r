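# Train on the rows of `features` selected by `trainIdx`, predict the
# rows in `testIdx`, and return predictions + Q3.  Normalization extrema
# come from the training rows only; test features are clipped to them.
trainEvalRows <- function(features, trainIdx, testIdx, K = NULL,
                          kMax = 100L, ridge = 1e-8, seed = 1L,
                          alpha = pi / 2) {
  tr <- subsetFeatures(features, trainIdx)
  tr <- circularTransform(normalizeFeatures(tr), alpha = alpha)
  if (is.null(K)) K <- min(kMax, nrow(tr@raw))
  model <- trainFCRN(tr, K = K, ridge = ridge, seed = seed, kMax = kMax)
  te <- subsetFeatures(features, testIdx)
  pred <- predict(model, te)
  cm <- confusionMatrix3(te@labels, pred)
  list(model = model, predicted = pred, observed = te@labels,
       chainId = te@chainId, q3 = q3(cm))
}

rowsForChains <- function(features, chains) {
  which(features@chainId %in% chains)
}

# fold per-residue predictions back into per-chain strings
chainStrings <- function(labels, chainId) {
  vapply(split(labels, factor(chainId, unique(chainId))),
         paste, character(1), collapse = "")
}

#' Stage 1: estimate the training-set size by a randomized curve
#'
#' Chains are added to the training set \code{step} at a time by seeded
#' uniform sampling without replacement; at each size an FCRN is
#' trained on the accumulated chains and Q3 is recorded on all
#' remaining chains.  The estimated training size P is the size of
#' maximal Q3 (first occurrence on ties).
#'
#' @param dataset an [SSDataset-class] with \code{ss3}.
#' @param features a [FeatureSet-class] for the dataset (e.g. from
#'   [generateFeatures()]); generated internally when \code{NULL}.
#' @param step chains added per trial (default 5).
#' @param kMax hidden-neuron cap (default 100).
#' @param kappa concentration for internally generated features.
#' @param seed integer seed driving the chain order, feature generation
#'   and hidden parameters.
#' @param ridge,alpha classifier settings, see [trainFCRN()].
#' @return A list of class \code{ssTrainingCurve}: \code{curve} (a
#'   data.frame of \code{size}, \code{q3}), \code{P}, \code{order} (the
#'   sampled chain order) and \code{seed}.
#' @export
stage1TrainingCurve <- function(dataset, features = NULL, step = 5L,
                                kMax = 100L, kappa = 100, seed = 1L,
                                ridge = 1e-8, alpha = pi / 2) {
  step <- as.integer(step)
  n <- length(dataset)
  if (n < 2L * step) stopf("need at least %d chains", 2L * step)
  if (is.null(features)) {
    features <- generateFeatures(dataset, kappa = kappa,
                                 seed = childSeed(seed, 1L))
  }
  order <- withSeed(childSeed(seed, 2L), sample(dataset@chainId))
  sizes <- seq(step, n - step, by = step)
  q3s <- numeric(length(sizes))
  for (i in seq_along(sizes)) {
    trainChains <- order[seq_len(sizes[i])]
    testChains <- order[-seq_len(sizes[i])]
    fit <- trainEvalRows(features,
                         rowsForChains(features, trainChains),
                         rowsForChains(features, testChains),
                         kMax = kMax, ridge = ridge,
                         seed = childSeed(seed, 100L + i),
                         alpha = alpha)
    q3s[i] <- fit$q3
  }
  structure(list(curve = data.frame(size = sizes, q3 = q3s),
                 P = sizes[which.max(q3s)], order = order,
                 seed = as.integer(seed)),
            class = "ssTrainingCurve")
}

#' @export
print.ssTrainingCurve <- function(x, ...) {
  cat(sprintf("Training curve: %d points, estimated P = %d chains\n",
              nrow(x$curve), x$P))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Stage 2 heuristics: candidate compact training sets
#'
#' `candidateSampled` draws P chains uniformly without replacement
#' (optionally disjoint from an exclusion list, e.g. the stage-1
#' chains).  `candidateBalanced` draws a residue-level set with exactly
#' \code{nPerClass} residues from each of H, E and C.
#' `candidateSpread` picks chains spread over the secondary-structure
#' composition simplex by greedy farthest-point sampling on
#' (fH, fE, fC): it starts from the chain nearest the dataset centroid,
#' then repeatedly adds the chain maximizing its minimum Euclidean
#' distance to the already-chosen compositions (ties broken by chain
#' order).
#'
#' @param dataset an [SSDataset-class] with \code{ss3}.
#' @param P number of chains to select.
#' @param seed integer seed.
#' @param exclude chain ids that must not be selected.
#' @param name candidate name.
#' @return A [CandidateSet-class].
#' @export
candidateSampled <- function(dataset, P, seed = 1L,
                             exclude = character(0),
                             name = "sampled") {
  pool <- setdiff(dataset@chainId, exclude)
  if (length(pool) < P) {
    stopf("only %d chains available after exclusions (need %d)",
          length(pool), P)
  }
  chains <- withSeed(seed, sample(pool, P))
  new("CandidateSet", name = name, level = "chain", chains = chains,
      seed = as.integer(seed))
}

#' @rdname candidateSampled
#' @param nPerClass residues to draw from each class.
#' @export
candidateBalanced <- function(dataset, nPerClass, seed = 1L,
                              name = "balanced") {
  if (any(is.na(dataset@ss3))) stopf("ss3 absent")
  # residues eligible for features: interior positions only
  res <- do.call(rbind, lapply(seq_along(dataset@chainId), function(i) {
    s3 <- ssChars(dataset@ss3[i])
    L <- length(s3)
    if (L < 9L) return(NULL)
    pos <- 5:(L - 4L)
    data.frame(chainId = dataset@chainId[i], resIdx = pos,
               state = s3[pos])
  }))
  picks <- withSeed(seed, {
    lapply(SS3_STATES, function(st) {
      avail <- which(res$state == st)
      if (length(avail) < nPerClass) {
        stopf("class %s has only %d eligible residues (need %d)",
              st, length(avail), nPerClass)
      }
      sample(avail, nPerClass)
    })
  })
  sel <- res[sort(unlist(picks)), c("chainId", "resIdx")]
  rownames(sel) <- NULL
  new("CandidateSet", name = name, level = "residue",
      chains = unique(sel$chainId), residues = sel,
      seed = as.integer(seed))
}

#' @rdname candidateSampled
#' @export
candidateSpread <- function(dataset, P, seed = 1L, name = "spread") {
  comp <- ssComposition(dataset)
  n <- nrow(comp)
  if (n < P) stopf("only %d chains available (need %d)", n, P)
  X <- as.matrix(comp[, c("fH", "fE", "fC")])
  centroid <- colMeans(X)
  d0 <- sqrt(rowSums(sweep(X, 2, centroid)^2))
  chosen <- which.min(d0)              # first index on ties
  minDist <- sqrt(rowSums(sweep(X, 2, X[chosen, ])^2))
  while (length(chosen) < P) {
    minDist[chosen] <- -Inf
    nxt <- which.max(minDist)
    chosen <- c(chosen, nxt)
    d <- sqrt(rowSums(sweep(X, 2, X[nxt, ])^2))
    minDist <- pmin(minDist, d)
  }
  new("CandidateSet", name = name, level = "chain",
      chains = comp$chainId[chosen], seed = as.integer(seed))
}

setMethod("show", "CandidateSet", function(object) {
  cat(sprintf("CandidateSet '%s' (%s level): %s\n", object@name,
              object@level,
              if (object@level == "chain")
                sprintf("%d chains", length(object@chains))
              else sprintf("%d residues over %d chains",
                           nrow(object@residues),
                           length(object@chains))))
})

candidateRows <- function(features, cand) {
  if (cand@level == "chain") {
    rowsForChains(features, cand@chains)
  } else {
    key <- paste(features@chainId, features@resIdx)
    which(key %in% paste(cand@residues$chainId, cand@residues$resIdx))
  }
}

#' Stage 3: rank candidate sets on a blind dataset
#'
#' Trains one FCRN per candidate on the development dataset's features,
#' scores every model on the blind set, and returns the candidates
#' sorted by blind Q3 (descending).  The top candidate is the compact
#' model.  Candidates must be disjoint from the blind set.
#'
#' @param candidates list of [CandidateSet-class] objects.
#' @param features a [FeatureSet-class] covering every candidate's
#'   residues (the development dataset's features).
#' @param blindFeatures a [FeatureSet-class] for the blind dataset.
#' @param kMax hidden-neuron cap.
#' @param seed integer seed for hidden parameters.
#' @param ridge,alpha classifier settings.
#' @return A list of class \code{blindRanking}: \code{ranking} (a
#'   data.frame of \code{name}, \code{q3}, sorted), \code{winner},
#'   \code{model} (the winning FCRN), and \code{reports} (a per-
#'   candidate list of [MetricsReport-class] objects).
#' @export
stage3BlindRank <- function(candidates, features, blindFeatures,
                            kMax = 100L, seed = 1L, ridge = 1e-8,
                            alpha = pi / 2) {
  if (!length(candidates)) stopf("need >= 1 candidate")
  blindChains <- unique(blindFeatures@chainId)
  nms <- vapply(candidates, function(cc) cc@name, character(1))
  if (anyDuplicated(nms)) stopf("candidate names must be unique")
  q3s <- numeric(length(candidates))
  models <- vector("list", length(candidates))
  reports <- vector("list", length(candidates))
  names(reports) <- nms
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]
    overlap <- intersect(cand@chains, blindChains)
    if (length(overlap)) {
      stopf("candidate '%s' overlaps the blind set: %s", cand@name,
            paste(overlap, collapse = ", "))
    }
    idx <- candidateRows(features, cand)
    if (!length(idx)) stopf("candidate '%s' selects no residues",
                            cand@name)
    tr <- subsetFeatures(features, idx)
    tr <- circularTransform(normalizeFeatures(tr), alpha = alpha)
    model <- trainFCRN(tr, K = min(kMax, nrow(tr@raw)), ridge = ridge,
                       seed = childSeed(seed, i), kMax = kMax)
    pred <- predict(model, blindFeatures)
    obs <- chainStrings(blindFeatures@labels, blindFeatures@chainId)
    prd <- chainStrings(pred, blindFeatures@chainId)
    rep_i <- scoreChains(obs, prd, names(obs))
    q3s[i] <- rep_i@q3
    models[[i]] <- model
    reports[[i]] <- rep_i
  }
  ord <- order(-q3s)
  structure(list(ranking = data.frame(name = nms[ord], q3 = q3s[ord],
                                      row.names = NULL),
                 winner = nms[ord[1]], model = models[[ord[1]]],
                 reports = reports, seed = as.integer(seed)),
            class = "blindRanking")
}

#' @export
print.blindRanking <- function(x, ...) {
  cat(sprintf("Blind ranking (winner: %s)\n", x$winner))
  print(x$ranking, row.names = FALSE)
  invisible(x)
}
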