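#' Construct an SSDataset
#'
#' @param chainId character vector of unique chain identifiers.
#' @param sequence character vector of amino-acid sequences.
#' @param ss8 character vector of 8-state DSSP structure strings; any of
#'   \code{' '}, \code{'-'} or \code{'C'} is accepted as the
#'   blank/irregular symbol and stored as \code{'C'}.
#' @param ss3 optional character vector of 3-state strings; defaults to
#'   \code{NA} (call [reduceToSS3()] to fill it from \code{ss8}).
#' @param name dataset name.
#' @return An [SSDataset-class] object.
#' @examples
#' d <- SSDataset("ch1", "ARNDARNDA", "CHHHHHHTC")
#' ss3(reduceToSS3(d))
#' @export
SSDataset <- function(chainId, sequence, ss8,
                      ss3 = rep(NA_character_, length(chainId)),
                      name = "") {
  ss8 <- vapply(ss8, canonicalSS8, character(1), USE.NAMES = FALSE)
  new("SSDataset", chainId = as.character(chainId),
      sequence = toupper(as.character(sequence)),
      ss8 = ss8, ss3 = as.character(ss3), name = name)
}

# normalise blank/dash irregular symbols to 'C' and validate the alphabet
canonicalSS8 <- function(ss8) {
  ss8 <- chartr(" -", "CC", toupper(ss8))
  bad <- regexpr("[^HGIEBTSC]", ss8)
  if (bad > 0) {
    stopf("unknown 8-state symbol '%s' at position %d",
          substr(ss8, bad, bad), bad)
  }
  ss8
}

#' @describeIn SSDataset number of chains
#' @param x an SSDataset
#' @export
setMethod("length", "SSDataset", function(x) length(x@chainId))

#' Accessors for SSDataset slots
#'
#' @param x an [SSDataset-class].
#' @return `chainIds`, `sequences`, `ss8`, `ss3` return character
#'   vectors named by chain id.
#' @export
chainIds <- function(x) x@chainId

#' @rdname chainIds
#' @export
sequences <- function(x) stats::setNames(x@sequence, x@chainId)

#' @rdname chainIds
#' @export
ss8 <- function(x) stats::setNames(x@ss8, x@chainId)

#' @rdname chainIds
#' @export
ss3 <- function(x) stats::setNames(x@ss3, x@chainId)

#' @export
setMethod("[", "SSDataset", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@chainId)
  new("SSDataset", chainId = x@chainId[i], sequence = x@sequence[i],
      ss8 = x@ss8[i], ss3 = x@ss3[i], name = x@name)
})

setMethod("show", "SSDataset", function(object) {
  cat(sprintf("SSDataset%s with %d chain(s), %d residues\n",
              if (nzchar(object@name)) paste0(" '", object@name, "'") else "",
              length(object), sum(nchar(object@sequence))))
  if (length(object)) {
    k <- min(length(object), 5L)
    for (i in seq_len(k)) {
      cat(sprintf("  %s  (%d aa)  ss3: %s\n", object@chainId[i],
                  nchar(object@sequence[i]),
                  if (is.na(object@ss3[i])) "absent" else "present"))
    }
    if (length(object) > k) cat("  ...\n")
  }
})

#' Reduce an 8-state DSSP string to 3 states
#'
#' Applies the standard reduction: the helical states H, G, I (alpha,
#' 3-10 and pi helices) map to H; the extended states E and B
#' (beta-strand and isolated beta-bridge) map to E; T, S and
#' blank/irregular (represented as C) map to C.
#'
#' @param ss8 an 8-state string; \code{' '} and \code{'-'} are accepted
#'   for the irregular state.
#' @return The 3-state string over \code{H,E,C}, same length.
#' @examples
#' reduceSS8("GHIEBTS ")   # "HHHEECCC"
#' @export
reduceSS8 <- function(ss8) {
  chartr("GIBTS", "HHECC", canonicalSS8(ss8))
}

#' Fill the 3-state strings of a dataset from its 8-state strings
#'
#' @param x an [SSDataset-class].
#' @return The dataset with \code{ss3} populated.
#' @export
reduceToSS3 <- function(x) {
  x@ss3 <- vapply(x@ss8, reduceSS8, character(1), USE.NAMES = FALSE)
  validObject(x)
  x
}

#' Trim chain termini
#'
#' Removes the first and last \code{nTrim} residues of every chain
#' (sequence and structure strings consistently).  Terminal residues
#' lack the full nine-residue feature window and are excluded from
#' compact-model development; for blind-test evaluation that keeps the
#' termini, use \code{nTrim = 0}.
#'
#' @param x an [SSDataset-class].
#' @param nTrim residues to drop at each end (default 4).
#' @return The trimmed dataset.
#' @export
trimTermini <- function(x, nTrim = 4L) {
  nTrim <- as.integer(nTrim)
  if (nTrim < 0L) stopf("nTrim must be >= 0")
  if (nTrim == 0L) return(x)
  len <- nchar(x@sequence)
  short <- len <= 2L * nTrim
  if (any(short)) {
    stopf("chain(s) too short to trim (need length > %d): %s",
          2L * nTrim, paste(x@chainId[short], collapse = ", "))
  }
  cut <- function(s) substr(s, nTrim + 1L, nchar(s) - nTrim)
  x@sequence <- vapply(x@sequence, cut, character(1), USE.NAMES = FALSE)
  x@ss8 <- vapply(x@ss8, cut, character(1), USE.NAMES = FALSE)
  has3 <- !is.na(x@ss3)
  x@ss3[has3] <- vapply(x@ss3[has3], cut, character(1), USE.NAMES = FALSE)
  validObject(x)
  x
}

#' Secondary-structure composition of chains
#'
#' Fractions of helix, sheet and coil residues per chain, i.e. the
#' coordinates used to spread chains over the composition simplex when
#' selecting representative training proteins.
#'
#' @param x an [SSDataset-class] with \code{ss3} present.
#' @return A data.frame with columns \code{chainId}, \code{fH},
#'   \code{fE}, \code{fC}; rows sum to 1.
#' @export
ssComposition <- function(x) {
  if (any(is.na(x@ss3))) {
    stopf("ss3 absent for chain(s): %s",
          paste(x@chainId[is.na(x@ss3)], collapse = ", "))
  }
  counts <- t(vapply(x@ss3, function(s) {
    ch <- ssChars(s)
    c(sum(ch == "H"), sum(ch == "E"), sum(ch == "C"))
  }, numeric(3), USE.NAMES = FALSE))
  frac <- counts / nchar(x@ss3)
  data.frame(chainId = x@chainId, fH = frac[, 1], fE = frac[, 2],
             fC = frac[, 3], row.names = NULL)
}

#' Read and write chain files
#'
#' The chain file dialect is FASTA-like: a header line
#' \code{>chain_id}, then the amino-acid sequence on one line, then the
#' structure string on the next.  The structure alphabet is
#' auto-detected: strings containing any of \code{G,I,B,T,S} (or
#' blank/dash) are treated as 8-state, pure \code{H/E/C} strings as
#' already-reduced 3-state.
#'
#' @param path file path.
#' @param name dataset name recorded on read.
#' @return `readChainFile` returns an [SSDataset-class]; for 3-state
#'   records both \code{ss8} and \code{ss3} hold the reduced string.
#' @export
readChainFile <- function(path, name = basename(path)) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) | grepl("^>", lines)]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stopf("no records found in %s", path)
  if (any(diff(c(hdr, length(lines) + 1L)) != 3L)) {
    stopf("malformed chain file %s: each record needs a header plus 2 lines",
          path)
  }
  ids <- sub("^>\\s*", "", lines[hdr])
  seqs <- toupper(lines[hdr + 1L])
  structs <- toupper(lines[hdr + 2L])
  bad <- nchar(seqs) != nchar(structs)
  if (any(bad)) {
    stopf("sequence/structure length mismatch in record(s): %s",
          paste(ids[bad], collapse = ", "))
  }
  is3 <- !grepl("[GIBTS -]", structs)
  ss8v <- vapply(structs, canonicalSS8, character(1), USE.NAMES = FALSE)
  ss3v <- ifelse(is3, ss8v, NA_character_)
  SSDataset(ids, seqs, ss8v, ss3v, name = name)
}

#' @rdname readChainFile
#' @param x an [SSDataset-class] to write.
#' @param what which structure string to write: \code{"ss8"} or
#'   \code{"ss3"}.
#' @export
writeChainFile <- function(x, path, what = c("ss8", "ss3")) {
  what <- match.arg(what)
  struct <- if (what == "ss8") x@ss8 else x@ss3
  if (any(is.na(struct))) stopf("%s absent; cannot write", what)
  out <- character(3L * length(x))
  out[seq(1, by = 3, length.out = length(x))] <- paste0(">", x@chainId)
  out[seq(2, by = 3, length.out = length(x))] <- x@sequence
  out[seq(3, by = 3, length.out = length(x))] <- struct
  writeLines(out, path)
  invisible(path)
}

#' Parse the per-residue structure column of DSSP text output
#'
#' Reads standard DSSP output (the block following the
#' \code{'  #  RESIDUE'} header), taking the one-letter amino-acid code
#' and the structure-summary column; chains are split on chain-break
#' records (\code{'!'} in the amino-acid column) and on changes of the
#' chain identifier column.
#'
#' @param path path to a DSSP output file.
#' @param name dataset name.
#' @return An [SSDataset-class] with chain ids
#'   \code{<name>_<chain letter>}.
#' @export
readDSSP <- function(path, name = basename(path)) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  start <- grep("^  #  RESIDUE", lines)
  if (!length(start)) stopf("not DSSP output (no residue header): %s", path)
  body <- lines[(start[1] + 1L):length(lines)]
  body <- body[nchar(trimws(body)) >= 1]
  body <- sprintf("%-17s", body)   # pad short break records
  aa <- substr(body, 14, 14)
  ch <- substr(body, 12, 12)
  st <- substr(body, 17, 17)
  brk <- aa == "!"
  grp <- cumsum(brk)
  keep <- !brk
  ids <- character(); seqs <- character(); ss <- character()
  for (g in unique(grp[keep])) {
    sel <- keep & grp == g
    if (!any(sel)) next
    ids <- c(ids, paste0(name, "_", ch[sel][1], if (g > 0) g else ""))
    seqs <- c(seqs, paste(aa[sel], collapse = ""))
    ss <- c(ss, paste(ifelse(st[sel] == " ", "C", st[sel]), collapse = ""))
  }
  SSDataset(ids, seqs, ss, name = name)
}
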