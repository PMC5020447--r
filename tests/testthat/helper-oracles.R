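# Independent brute-force oracles.  Deliberately naive, loop-based and
# structured differently from the package implementations.

oracleReduce8to3 <- function(ss8) {
  lut <- c(H = "H", G = "H", I = "H", E = "E", B = "E",
           T = "C", S = "C", C = "C", " " = "C", "-" = "C")
  chs <- strsplit(ss8, "")[[1]]
  out <- character(length(chs))
  for (i in seq_along(chs)) out[i] <- lut[[chs[i]]]
  paste(out, collapse = "")
}

oracleConfusion <- function(obs, pred) {
  o <- strsplit(obs, "")[[1]]; p <- strsplit(pred, "")[[1]]
  st <- c("H", "E", "C")
  m <- matrix(0L, 3, 3, dimnames = list(observed = st, predicted = st))
  for (k in seq_along(o)) {
    m[o[k], p[k]] <- m[o[k], p[k]] + 1L
  }
  m
}

oracleQ3 <- function(obs, pred) {
  o <- strsplit(obs, "")[[1]]; p <- strsplit(pred, "")[[1]]
  100 * sum(o == p) / length(o)
}

oracleQClass <- function(obs, pred, j) {
  o <- strsplit(obs, "")[[1]]; p <- strsplit(pred, "")[[1]]
  n <- sum(o == j)
  if (n == 0) return(NA_real_)
  100 * sum(o == j & p == j) / n
}

oracleMCC <- function(obs, pred, j) {
  o <- strsplit(obs, "")[[1]]; p <- strsplit(pred, "")[[1]]
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (k in seq_along(o)) {
    if (o[k] == j && p[k] == j) tp <- tp + 1
    else if (o[k] == j && p[k] != j) fn <- fn + 1
    else if (o[k] != j && p[k] == j) fp <- fp + 1
    else tn <- tn + 1
  }
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

# segments as explicit position sets
oracleSegments <- function(chars, state) {
  segs <- list(); i <- 1L; n <- length(chars)
  while (i <= n) {
    if (chars[i] == state) {
      j <- i
      while (j < n && chars[j + 1L] == state) j <- j + 1L
      segs[[length(segs) + 1L]] <- i:j
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  segs
}

oracleSOV <- function(obs, pred, states = c("H", "E", "C")) {
  num <- 0; den <- 0
  for (k in seq_along(obs)) {
    o <- strsplit(obs[k], "")[[1]]; p <- strsplit(pred[k], "")[[1]]
    for (st in states) {
      s1list <- oracleSegments(o, st)
      s2list <- oracleSegments(p, st)
      for (s1 in s1list) {
        partners <- Filter(function(s2) length(intersect(s1, s2)) > 0,
                           s2list)
        if (!length(partners)) {
          den <- den + length(s1)
          next
        }
        for (s2 in partners) {
          minov <- length(intersect(s1, s2))
          maxov <- length(union(s1, s2))
          delta <- min(maxov - minov, minov,
                       length(s1) %/% 2, length(s2) %/% 2)
          num <- num + length(s1) * (minov + delta) / maxov
          den <- den + length(s1)
        }
      }
    }
  }
  if (den == 0) 100 else 100 * num / den
}

# all-pairs contact detection with independently coded rules
oracleContacts <- function(atoms, cutoff = 3.6) {
  waters <- c("HOH", "WAT", "DOD")
  classOf <- function(r) {
    if (atoms$resid[r] %in% waters && atoms$element[r] == "O") return("H")
    if (atoms$hetero[r] || atoms$resid[r] %in% waters) return("X")
    if (atoms$elety[r] %in% c("N", "O", "OXT")) return("M")
    "S"
  }
  catOf <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "")
    switch(key, MM = "MM", HM = "MH", MS = "MS", SS = "SS",
           HS = "SH", "other")
  }
  res <- NULL
  n <- nrow(atoms)
  for (i in seq_len(n - 1)) {
    if (!atoms$element[i] %in% c("N", "O")) next
    for (j in (i + 1):n) {
      if (!atoms$element[j] %in% c("N", "O")) next
      d <- sqrt((atoms$x[i] - atoms$x[j])^2 +
                  (atoms$y[i] - atoms$y[j])^2 +
                  (atoms$z[i] - atoms$z[j])^2)
      if (d > cutoff) next
      same <- atoms$chain[i] == atoms$chain[j] &&
        atoms$resno[i] == atoms$resno[j] &&
        atoms$resid[i] == atoms$resid[j]
      if (same) next
      pept <- FALSE
      if (atoms$chain[i] == atoms$chain[j] && !atoms$hetero[i] &&
          !atoms$hetero[j]) {
        if (atoms$elety[i] == "O" && atoms$elety[j] == "N" &&
            atoms$resno[j] - atoms$resno[i] == 1) pept <- TRUE
        if (atoms$elety[j] == "O" && atoms$elety[i] == "N" &&
            atoms$resno[i] - atoms$resno[j] == 1) pept <- TRUE
      }
      if (pept) next
      res <- rbind(res, data.frame(i = i, j = j, distance = d,
                                   category = catOf(classOf(i),
                                                    classOf(j))))
    }
  }
  if (is.null(res)) {
    data.frame(i = integer(), j = integer(), distance = numeric(),
               category = character())
  } else res
}

randomSS3 <- function(len) {
  paste(sample(c("H", "E", "C"), len, replace = TRUE,
               prob = c(0.35, 0.23, 0.42)), collapse = "")
}

# random synthetic structure: a short pseudo-chain plus scattered waters
randomStructure <- function(nres = 12, nwat = 6, box = 10) {
  rows <- list()
  for (r in seq_len(nres)) {
    base <- runif(3, 0, box)
    rows[[length(rows) + 1L]] <- data.frame(
      chain = "A", resno = r, resid = "ALA",
      elety = c("N", "CA", "O", "OG"),
      element = c("N", "C", "O", "O"),
      x = base[1] + runif(4, -1, 1), y = base[2] + runif(4, -1, 1),
      z = base[3] + runif(4, -1, 1), occ = 1, hetero = FALSE)
  }
  for (w in seq_len(nwat)) {
    pos <- runif(3, 0, box)
    rows[[length(rows) + 1L]] <- data.frame(
      chain = "A", resno = 1000L + w, resid = "HOH", elety = "O",
      element = "O", x = pos[1], y = pos[2], z = pos[3], occ = 1,
      hetero = TRUE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
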