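#' Default complex class codes
#'
#' Coded class labels live on the unit circle: the true-class code is
#' \eqn{e^{i\pi/4}} and the false-class code the antipodal
#' \eqn{e^{i5\pi/4}}.  Both have well-defined principal logarithms, so
#' the log-domain targets are phase-separated and the analytic
#' output-weight solve sees both magnitude and phase of the error.
#'
#' @return A named complex vector \code{c(true=, false=)}.
#' @export
fcrnClassCodes <- function() {
  c(true = exp(1i * pi / 4), false = exp(1i * 5 * pi / 4))
}

#' Encode 3-state labels as complex coded outputs
#'
#' @param labels character vector over H/E/C.
#' @param classCodes named complex vector \code{c(true=, false=)}.
#' @param classes class order on the output layer.
#' @return Complex n x T matrix; column t carries the true-class code in
#'   the row of the t-th label's class and the false-class code
#'   elsewhere.
#' @export
encodeLabels <- function(labels, classCodes = fcrnClassCodes(),
                         classes = SS3_STATES) {
  idx <- match(labels, classes)
  if (anyNA(idx)) {
    stopf("unknown label symbol(s): %s",
          paste(unique(labels[is.na(idx)]), collapse = ", "))
  }
  Y <- matrix(classCodes[["false"]], length(classes), length(labels))
  Y[cbind(idx, seq_along(labels))] <- classCodes[["true"]]
  rownames(Y) <- classes
  Y
}

#' @rdname encodeLabels
#' @param Y a complex n x T coded-label matrix.
#' @return `decodeLabels` returns the character labels whose row is
#'   nearest the true-class code in each column.
#' @export
decodeLabels <- function(Y, classCodes = fcrnClassCodes(),
                         classes = SS3_STATES) {
  d <- abs(Y - classCodes[["true"]])
  classes[apply(d, 2, which.min)]
}

# numerically stable complex hyperbolic secant: 2/(e^u + e^-u),
# rearranged so no exponential ever exceeds modulus 1
csech <- function(u) {
  s <- ifelse(Re(u) >= 0, 1 + 0i, -1 + 0i)
  e <- exp(-s * u)
  2 * e / (1 + e * e)
}

#' Hidden-layer response of an FCRN
#'
#' Each hidden neuron k computes \eqn{h_k = sech(v_k \cdot z + b_k)}
#' with the complex hyperbolic secant \eqn{sech(u) = 2/(e^u + e^{-u})},
#' evaluated in a numerically stable form.
#'
#' @param model a trained [FCRNModel-class].
#' @param Z complex matrix (samples x m) of unit-modulus inputs (a
#'   single 27-vector is also accepted).
#' @return Complex matrix (samples x K) of hidden responses.
#' @export
hiddenResponse <- function(model, Z) {
  if (is.null(dim(Z))) Z <- matrix(Z, 1)
  U <- Z %*% t(model@V) + matrix(model@b, nrow(Z), model@K, byrow = TRUE)
  H <- csech(U)
  if (any(!is.finite(Re(H)) | !is.finite(Im(H)))) {
    stopf("non-finite hidden response")
  }
  H
}

#' Network outputs of an FCRN
#'
#' The exponential output layer:
#' \eqn{\hat y_l = \exp(\sum_{k=1}^K w_{lk} h_k)}.
#'
#' @param model a trained [FCRNModel-class].
#' @param Z complex input matrix (samples x m) or a single 27-vector.
#' @return Complex matrix (samples x n) of predicted outputs.
#' @export
predictOutputs <- function(model, Z) {
  H <- hiddenResponse(model, Z)
  exp(H %*% t(model@W))
}

#' Decode network outputs to class symbols
#'
#' Returns for each sample the class l minimizing the distance
#' \eqn{|\hat y_l - code_{true}|}; ties break by the fixed class order
#' H, E, C.
#'
#' @param model a trained [FCRNModel-class].
#' @param Yhat complex matrix (samples x n) of outputs, or one n-vector.
#' @return Character vector of 3-state symbols.
#' @export
decodeClass <- function(model, Yhat) {
  if (is.null(dim(Yhat))) Yhat <- matrix(Yhat, 1)
  d <- abs(Yhat - model@classCodes[["true"]])
  model@classes[apply(d, 1, which.min)]
}

#' Train a fully complex-valued relaxation network
#'
#' Hidden parameters are drawn reproducibly from \code{seed}: projection
#' entries from a complex standard normal scaled by
#' \eqn{hiddenScale/\sqrt m}, biases uniform on the unit circle.  The
#' default \code{hiddenScale} of 0.25 keeps the hidden activations in
#' the gently nonlinear regime of sech, where a modest number of random
#' projections spans the input's affine dual and the analytic solve can
#' recover near-linear decision functions exactly; larger values give
#' more strongly nonlinear hidden features at the cost of needing more
#' neurons.  Output weights are then obtained
#' in a single analytic step (no iterative epochs) as the minimizer of
#' the regularized complex least-squares objective
#' \deqn{\sum_t \|W h^t - \log y^t\|^2 + ridge\,\|W\|^2,}
#' where \eqn{\log y^t} is the entrywise principal logarithm of the
#' coded labels, so the real part of the target carries the label
#' magnitude and the imaginary part its phase.  Because the output layer
#' is exponential, this projection solve linearizes the network exactly.
#'
#' @param train a [FeatureSet-class] with the complex form present (see
#'   [circularTransform()]).
#' @param K number of hidden neurons (1 <= K <= kMax and K <= samples).
#' @param classCodes complex coded label values, see [fcrnClassCodes()].
#' @param ridge ridge regularization, default 1e-8; must be > 0 unless
#'   the normal equations are known to be well posed.
#' @param seed integer seed for the hidden parameters.
#' @param kMax hidden-neuron cap (default 100).
#' @param hiddenScale standard deviation multiplier of the hidden
#'   projections (default 0.25).
#' @return A trained [FCRNModel-class] carrying the normalization
#'   extrema and transform angle of \code{train} for inference.
#' @export
trainFCRN <- function(train, K, classCodes = fcrnClassCodes(),
                      ridge = 1e-8, seed = 1L, kMax = 100L,
                      hiddenScale = 0.25) {
  K <- as.integer(K)
  Z <- complexMatrix(train)
  Tn <- nrow(Z); m <- ncol(Z)
  if (K < 1L || K > kMax) stopf("K must be in 1..%d", kMax)
  if (K > Tn) stopf("K (%d) exceeds the sample count (%d)", K, Tn)
  if (ridge < 0) stopf("ridge must be >= 0")
  hp <- withSeed(seed, {
    V <- matrix(complex(real = stats::rnorm(K * m),
                        imaginary = stats::rnorm(K * m)) *
                  (hiddenScale / sqrt(2 * m)), K, m)
    b <- exp(1i * stats::runif(K, 0, 2 * pi))
    list(V = V, b = b)
  })
  model <- new("FCRNModel", m = m, n = length(SS3_STATES), K = K,
               V = hp$V, b = hp$b,
               W = matrix(0i, length(SS3_STATES), K),
               classCodes = classCodes, classes = SS3_STATES,
               alpha = train@alpha, normExtrema = train@normExtrema,
               ridge = ridge, seed = as.integer(seed))
  H <- hiddenResponse(model, Z)                  # T x K
  L <- log(encodeLabels(train@labels, classCodes))  # n x T, principal log
  A <- crossprod(Conj(H), H) + diag(ridge, K)    # H^H H + ridge I
  B <- crossprod(Conj(H), t(L))                  # H^H L^T  (K x n)
  Wt <- tryCatch(solve(A, B), error = function(e) {
    stopf(paste0("normal equations are singular; ",
                 "use ridge > 0 (got ridge = %g)"), ridge)
  })
  model@W <- t(Wt)
  validObject(model)
  model
}

# regularized training objective, used by optimality tests
fcrnObjective <- function(W, H, L, ridge) {
  R <- t(W %*% t(H)) - t(L)      # T x n residuals
  sum(Mod(R)^2) + ridge * sum(Mod(W)^2)
}

#' Predict secondary structure with a trained FCRN
#'
#' Applies the model's stored normalization extrema (with clipping) and
#' circular transform to raw features, evaluates the network, and
#' decodes class symbols.
#'
#' @param object a trained [FCRNModel-class].
#' @param newdata a [FeatureSet-class]; raw features suffice.
#' @param type \code{"class"} (default) for 3-state symbols,
#'   \code{"output"} for the complex output matrix.
#' @return Character vector of predicted H/E/C states, or the complex
#'   output matrix.
#' @export
setMethod("predict", "FCRNModel", function(object, newdata,
                                           type = c("class", "output")) {
  type <- match.arg(type)
  if (anyNA(object@normExtrema)) {
    stopf("model carries no normalization extrema")
  }
  fs <- normalizeFeatures(newdata, refExtrema = object@normExtrema)
  fs <- circularTransform(fs, alpha = object@alpha)
  Yhat <- predictOutputs(object, complexMatrix(fs))
  if (type == "output") Yhat else decodeClass(object, Yhat)
})

setMethod("show", "FCRNModel", function(object) {
  cat(sprintf(paste0("FCRNModel: %d -> %d -> %d (sech hidden, exp ",
                     "output)\n  ridge %g, alpha %.4f, seed %d\n"),
              object@m, object@K, object@n, object@ridge, object@alpha,
              object@seed))
})

#' Save and load FCRN models
#'
#' Self-describing JSON archive; complex arrays are stored as real and
#' imaginary parts.  A reloaded model reproduces training-time
#' predictions exactly.
#'
#' @param model a trained [FCRNModel-class].
#' @param path file path (.json).
#' @export
saveFCRN <- function(model, path) {
  cplx <- function(z) list(re = Re(z), im = Im(z))
  obj <- list(
    format = "compactSSP-fcrn", version = 1L,
    m = model@m, n = model@n, K = model@K,
    V = cplx(model@V), b = cplx(model@b), W = cplx(model@W),
    classCodes = cplx(model@classCodes), classes = model@classes,
    alpha = model@alpha,
    normMin = model@normExtrema[1, ], normMax = model@normExtrema[2, ],
    ridge = model@ridge, seed = model@seed
  )
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname saveFCRN
#' @export
readFCRN <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path))
  if (!identical(obj$format, "compactSSP-fcrn")) {
    stopf("%s is not an FCRN model archive", path)
  }
  uncplx <- function(x, nr = NULL) {
    z <- complex(real = unlist(x$re), imaginary = unlist(x$im))
    if (!is.null(nr)) z <- matrix(z, nr)
    z
  }
  codes <- uncplx(obj$classCodes)
  names(codes) <- c("true", "false")
  new("FCRNModel", m = as.integer(obj$m), n = as.integer(obj$n),
      K = as.integer(obj$K),
      V = uncplx(obj$V, as.integer(obj$K)),
      b = uncplx(obj$b),
      W = uncplx(obj$W, as.integer(obj$n)),
      classCodes = codes, classes = obj$classes,
      alpha = obj$alpha,
      normExtrema = rbind(min = obj$normMin, max = obj$normMax),
      ridge = obj$ridge, seed = as.integer(obj$seed))
}
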