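# small trained model on separable data, shared across blocks
fcrnToy <- local({
  d <- simulateChains(16, 40, seed = 51)
  fs <- generateFeatures(d, kappa = 1e4, seed = 52)
  fsc <- circularTransform(normalizeFeatures(fs))
  list(fs = fs, fsc = fsc,
       model = trainFCRN(fsc, K = 30, seed = 53))
})

test_that("label coding places the true-class code and round-trips", {
  codes <- fcrnClassCodes()
  Y <- encodeLabels(c("H", "E", "C"))
  expect_equal(Y[, 1], c(H = codes[["true"]], E = codes[["false"]],
                         C = codes[["false"]]))
  expect_equal(Y["C", 3], codes[["true"]], ignore_attr = TRUE)
  expect_equal(Y["H", 3], codes[["false"]], ignore_attr = TRUE)
  set.seed(54)
  labs <- sample(c("H", "E", "C"), 200, replace = TRUE)
  expect_identical(decodeLabels(encodeLabels(labs)), labs)
  expect_error(encodeLabels(c("H", "Q")), "Q")
})

test_that("hidden response equals the complex sech of the projection", {
  m <- fcrnToy$model
  # v = 0, b = 0  =>  sech(0) = 1
  m0 <- m; m0@V <- matrix(0i, m@K, m@m); m0@b <- rep(0i, m@K)
  z <- complexMatrix(fcrnToy$fsc)[1, ]
  expect_equal(as.vector(hiddenResponse(m0, z)), rep(1 + 0i, m@K))
  # sech(i pi/3) = 1/cos(pi/3) = 2
  m1 <- m0; m1@b <- rep(1i * pi / 3, m@K)
  expect_equal(as.vector(hiddenResponse(m1, z)),
               rep(2 + 0i, m@K), tolerance = 1e-12)
  # random projections against the direct 2/(e^u + e^-u) formula
  set.seed(55)
  Z <- complexMatrix(fcrnToy$fsc)[1:50, ]
  U <- Z %*% t(m@V) + matrix(m@b, 50, m@K, byrow = TRUE)
  expect_equal(hiddenResponse(m, Z), 2 / (exp(U) + exp(-U)),
               tolerance = 1e-12)
  # stability: huge real parts do not overflow
  mbig <- m0; mbig@b <- rep(800 + 2i, m@K)
  h <- hiddenResponse(mbig, z)
  expect_true(all(is.finite(Re(h)) & is.finite(Im(h))))
})

test_that("network output is the exponential of the weighted hidden sum", {
  m <- fcrnToy$model
  z <- complexMatrix(fcrnToy$fsc)[3, ]
  # all-zero weights give exp(0) = 1 on every output
  m0 <- m; m0@W <- matrix(0i, m@n, m@K)
  expect_equal(as.vector(predictOutputs(m0, z)), rep(1 + 0i, m@n))
  # Euler: K = 1, w = i pi, h = 1  =>  exp(i pi) = -1
  m1 <- m
  m1@K <- 1L; m1@V <- matrix(0i, 1, m@m); m1@b <- 0i
  m1@W <- matrix(rep(1i * pi, 3), 3, 1)
  expect_equal(as.vector(predictOutputs(m1, z)), rep(-1 + 0i, 3),
               tolerance = 1e-12)
  # term-by-term oracle for the trained model
  H <- hiddenResponse(m, complexMatrix(fcrnToy$fsc)[1:20, ])
  Yhat <- predictOutputs(m, complexMatrix(fcrnToy$fsc)[1:20, ])
  for (t in 1:20) {
    for (l in 1:3) {
      acc <- 0i
      for (k in seq_len(m@K)) acc <- acc + m@W[l, k] * H[t, k]
      expect_equal(Yhat[t, l], exp(acc), tolerance = 1e-10)
    }
  }
})

test_that("class decoding minimizes distance to the true code with H,E,C ties", {
  m <- fcrnToy$model
  codes <- m@classCodes
  exact <- encodeLabels("E")[, 1]
  expect_identical(decodeClass(m, exact), "E")
  # equidistant outputs fall back to the first class in order
  expect_identical(decodeClass(m, c(0i, 0i, 0i)), "H")
  set.seed(56)
  Yh <- matrix(complex(real = rnorm(300), imaginary = rnorm(300)),
               100, 3)
  got <- decodeClass(m, Yh)
  oracle <- apply(abs(Yh - codes[["true"]]), 1, function(r) {
    c("H", "E", "C")[which(r == min(r))[1]]
  })
  expect_identical(got, oracle)
})

test_that("training is single-shot, deterministic and recovers separable data", {
  m1 <- trainFCRN(fcrnToy$fsc, K = 30, seed = 53)
  expect_identical(m1@W, fcrnToy$model@W)
  expect_identical(m1@V, fcrnToy$model@V)
  pred <- decodeClass(m1, predictOutputs(m1, complexMatrix(fcrnToy$fsc)))
  cm <- confusionMatrix3(featureLabels(fcrnToy$fsc), pred)
  expect_gte(q3(cm), 99)
  expect_error(trainFCRN(fcrnToy$fsc, K = 0), "K must be")
  expect_error(trainFCRN(fcrnToy$fsc, K = 101), "K must be")
  expect_error(trainFCRN(fcrnToy$fsc[1:10], K = 20), "sample count")
})

test_that("the closed-form weights minimize the regularized objective", {
  d <- simulateChains(3, 20, seed = 57)
  fs <- circularTransform(normalizeFeatures(
    generateFeatures(d, kappa = 20, seed = 58)))
  ridge <- 1e-4
  model <- trainFCRN(fs, K = 5, ridge = ridge, seed = 59)
  H <- hiddenResponse(model, complexMatrix(fs))
  L <- log(encodeLabels(featureLabels(fs)))
  obj <- compactSSP:::fcrnObjective
  f0 <- obj(model@W, H, L, ridge)
  # any single-weight perturbation strictly increases the objective
  set.seed(60)
  for (rep in 1:25) {
    W2 <- model@W
    l <- sample(3, 1); k <- sample(5, 1)
    eps <- complex(real = rnorm(1), imaginary = rnorm(1)) * 1e-3
    W2[l, k] <- W2[l, k] + eps
    expect_gt(obj(W2, H, L, ridge), f0)
  }
  # iterative minimizer over the real parametrization agrees
  par0 <- c(Re(model@W), Im(model@W)) * 0
  fn <- function(par) {
    W <- matrix(complex(real = par[1:15], imaginary = par[16:30]), 3, 5)
    obj(W, H, L, ridge)
  }
  it <- stats::optim(par0, fn, method = "BFGS",
                     control = list(maxit = 2000, reltol = 1e-15))
  expect_lt(abs(it$value - f0) / f0, 1e-6)
  expect_error(trainFCRN(fs, K = 5, ridge = -1, seed = 59), "ridge")
})

test_that("held-out prediction and the full pipeline are reproducible", {
  run <- function() {
    tr <- simulateChains(10, 40, seed = 61)
    te <- simulateChains(10, 40, seed = 62, prefix = "t")
    ftr <- circularTransform(normalizeFeatures(
      generateFeatures(tr, kappa = 100, seed = 63)))
    fte <- generateFeatures(te, kappa = 100, seed = 64)
    model <- trainFCRN(ftr, K = 30, seed = 65)
    predict(model, fte)
  }
  expect_identical(run(), run())
})

test_that("test accuracy does not degrade as features get more informative", {
  # mean held-out Q3 over seeds is non-decreasing across kappa levels
  kappas <- c(0.5, 5, 1000)
  means <- sapply(kappas, function(kp) {
    mean(sapply(1:5, function(s) {
      tr <- simulateChains(8, 40, seed = 700 + s)
      te <- simulateChains(8, 40, seed = 800 + s, prefix = "t")
      ftr <- circularTransform(normalizeFeatures(
        generateFeatures(tr, kappa = kp, seed = 900 + s)))
      fte <- generateFeatures(te, kappa = kp, seed = 950 + s)
      model <- trainFCRN(ftr, K = 30, seed = s)
      q3(confusionMatrix3(featureLabels(fte), predict(model, fte)))
    }))
  })
  expect_true(all(diff(means) >= 0))
})

test_that("a saved model reloads and reproduces predictions exactly", {
  f <- withr::local_tempfile(fileext = ".json")
  saveFCRN(fcrnToy$model, f)
  m2 <- readFCRN(f)
  expect_equal(m2@W, fcrnToy$model@W)
  expect_equal(m2@V, fcrnToy$model@V)
  expect_equal(m2@normExtrema, fcrnToy$model@normExtrema,
               ignore_attr = TRUE)
  p1 <- predict(fcrnToy$model, fcrnToy$fs)
  p2 <- predict(m2, fcrnToy$fs)
  expect_identical(p1, p2)
  fbad <- withr::local_tempfile(fileext = ".json")
  writeLines("{\"format\": \"something-else\"}", fbad)
  expect_error(readFCRN(fbad), "not an FCRN")
})
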