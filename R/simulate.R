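#' Simulate protein chains with secondary structure
#'
#' Generates chains whose 3-state structure strings are built from
#' alternating segments: segment states are drawn with the given
#' composition weights (consecutive segments never repeat a state) and
#' segment lengths are geometric around field-typical means (helices
#' longer than strands, strands than irregular coil stretches).  An
#' 8-state string consistent with the reduction is drawn per residue
#' (H from \{H,G,I\}, E from \{E,B\}, C from \{C,T,S\}) so the datasets
#' exercise the full reduction path, and sequences are uniform random
#' amino-acid letters (structure strings drive everything downstream).
#'
#' @param n number of chains.
#' @param len chain length in residues (single value or per chain).
#' @param composition named weights for H, E, C segment states; the
#'   default mirrors a typical globular benchmark mix (35/23/42).
#' @param meanSegLen named mean segment lengths per state.
#' @param seed integer seed.
#' @param name dataset name.
#' @param prefix chain-id prefix.
#' @return An [SSDataset-class] with \code{ss3} present.
#' @export
simulateChains <- function(n, len = 56L,
                           composition = c(H = 0.35, E = 0.23, C = 0.42),
                           meanSegLen = c(H = 9, E = 5, C = 5),
                           seed = 1L, name = "simulated",
                           prefix = "sim") {
  stopifnot(n >= 1, all(len >= 1), all(composition >= 0),
            sum(composition) > 0, all(meanSegLen >= 1))
  len <- rep_len(as.integer(len), n)
  comp <- composition[SS3_STATES] / sum(composition[SS3_STATES])
  withSeed(seed, {
    ss3v <- character(n); ss8v <- character(n); seqv <- character(n)
    sub8 <- list(H = c("H", "G", "I"), E = c("E", "B"),
                 C = c("C", "T", "S"))
    p8 <- list(H = c(0.8, 0.15, 0.05), E = c(0.85, 0.15),
               C = c(0.5, 0.3, 0.2))
    aa <- setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z"))
    for (i in seq_len(n)) {
      states <- character(0); prev <- ""
      left <- len[i]
      s3 <- character(0)
      while (left > 0) {
        w <- comp
        if (nzchar(prev)) w[prev] <- 0
        st <- sample(SS3_STATES, 1, prob = w / sum(w))
        sl <- min(left, 1L + stats::rgeom(1, 1 / meanSegLen[[st]]))
        s3 <- c(s3, rep(st, sl))
        left <- left - sl
        prev <- st
      }
      ss3v[i] <- paste(s3, collapse = "")
      s8 <- vapply(s3, function(st) {
        sample(sub8[[st]], 1, prob = p8[[st]])
      }, character(1))
      ss8v[i] <- paste(s8, collapse = "")
      seqv[i] <- paste(sample(aa, len[i], replace = TRUE),
                       collapse = "")
    }
    SSDataset(sprintf("%s%03d", prefix, seq_len(n)), seqv, ss8v, ss3v,
              name = name)
  })
}
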