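WATER_RESIDUES <- c("HOH", "WAT", "DOD")
MAINCHAIN_ATOMS <- c("N", "O", "OXT")

#' Read atoms from a PDB file
#'
#' Parses ATOM and HETATM records (via the bio3d reader) into a flat
#' atom table.  Alternate locations are resolved to the highest
#' occupancy (first record on ties).  The element is taken from the
#' element-symbol column when present, otherwise derived from the atom
#' name.
#'
#' @param path path to a PDB-format text file.
#' @return A data.frame with columns \code{chain}, \code{resno},
#'   \code{resid}, \code{elety} (atom name), \code{element},
#'   \code{x,y,z} (Angstrom), \code{occ}, \code{hetero} (logical).
#' @export
readPDBAtoms <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) {
                    stopf("cannot parse PDB file %s: %s", path,
                          conditionMessage(e))
                  })
  a <- pdb$atom
  df <- data.frame(
    chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    resno = as.integer(a$resno),
    resid = toupper(a$resid),
    elety = toupper(a$elety),
    element = toupper(ifelse(is.na(a$elesy) | !nzchar(trimws(a$elesy)),
                             substr(gsub("[^A-Za-z]", "", a$elety), 1, 1),
                             trimws(a$elesy))),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    alt = ifelse(is.na(a$alt), "", a$alt),
    hetero = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))) {
    stopf("non-finite coordinates in %s", path)
  }
  # resolve altlocs: keep the highest-occupancy copy of each atom
  key <- paste(df$chain, df$resno, df$resid, df$elety)
  if (anyDuplicated(key)) {
    ord <- order(key, -df$occ, seq_len(nrow(df)))
    df <- df[ord, ][!duplicated(key[ord]), ]
    df <- df[order(as.integer(rownames(df))), ]
  }
  rownames(df) <- NULL
  df$alt <- NULL
  df
}

#' Write an atom table back to PDB format
#'
#' @param atoms a data.frame as returned by [readPDBAtoms()].
#' @param path output path.
#' @export
writePDBAtoms <- function(atoms, path) {
  bio3d::write.pdb(file = path,
                   type = ifelse(atoms$hetero, "HETATM", "ATOM"),
                   eleno = seq_len(nrow(atoms)),
                   elety = atoms$elety, resid = atoms$resid,
                   chain = atoms$chain, resno = atoms$resno,
                   xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                   o = atoms$occ, b = rep(0, nrow(atoms)),
                   elesy = atoms$element)
  invisible(path)
}

# classify a polar atom: M main-chain, S side-chain polar, H water
# oxygen, X other polar hetero-atom
atomClass <- function(atoms) {
  cls <- rep("X", nrow(atoms))
  water <- atoms$resid %in% WATER_RESIDUES & atoms$element == "O"
  std <- !atoms$hetero & !atoms$resid %in% WATER_RESIDUES
  cls[std & atoms$elety %in% MAINCHAIN_ATOMS] <- "M"
  cls[std & !atoms$elety %in% MAINCHAIN_ATOMS] <- "S"
  cls[water] <- "H"
  cls
}

pairCategory <- function(c1, c2) {
  key <- paste0(pmin(c1, c2), pmax(c1, c2))   # alphabetical pair key
  map <- c(MM = "MM", HM = "MH", MS = "MS", SS = "SS", HS = "SH")
  out <- unname(map[key])
  out[is.na(out)] <- "other"
  out
}

#' Detect putative hydrogen-bond contacts by donor-acceptor distance
#'
#' All unordered pairs of polar atoms (N or O element, including water
#' oxygens) whose centres lie within \code{cutoff} are reported,
#' excluding pairs within one residue and the backbone O(i)-N(i+1) pair
#' of sequential peptide-bond partners.  Donor/acceptor roles are
#' ignored.  Each contact is categorized by its two atom classes:
#' M (main-chain N/O/OXT of a standard residue), S (polar side-chain
#' atom), H (water oxygen); MM, MH, MS, SS, SH, or \code{other}.
#' Detection uses spatial grid binning with cell width \code{cutoff};
#' results are identical to the all-pairs computation.
#'
#' @param atoms atom table from [readPDBAtoms()].
#' @param cutoff maximum donor-acceptor distance in Angstrom
#'   (default 3.6).
#' @return A data.frame with one row per contact: indices \code{i},
#'   \code{j} into \code{atoms} (i < j), per-atom identity columns,
#'   \code{distance} and \code{category}.
#' @export
findHBonds <- function(atoms, cutoff = 3.6) {
  if (!nrow(atoms)) stopf("empty structure")
  polar <- which(atoms$element %in% c("N", "O"))
  empty <- data.frame(i = integer(), j = integer(),
                      distance = numeric(), category = character())
  if (length(polar) < 2) return(empty)
  P <- atoms[polar, ]
  xyz <- as.matrix(P[, c("x", "y", "z")])
  cell <- floor(xyz / cutoff)
  keyOf <- function(cc) paste(cc[, 1], cc[, 2], cc[, 3])
  cellKey <- keyOf(cell)
  bins <- split(seq_len(nrow(P)), cellKey)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ii <- integer(0); jj <- integer(0)
  for (b in names(bins)) {
    here <- bins[[b]]
    base <- cell[here[1], ]
    neigh <- unlist(bins[keyOf(sweep(offs, 2, base, `+`))],
                    use.names = FALSE)
    for (a in here) {
      cand <- neigh[neigh > a]
      if (length(cand)) {
        ii <- c(ii, rep.int(a, length(cand)))
        jj <- c(jj, cand)
      }
    }
  }
  if (!length(ii)) return(empty)
  d <- sqrt(rowSums((xyz[ii, , drop = FALSE] -
                       xyz[jj, , drop = FALSE])^2))
  keep <- d <= cutoff
  ii <- ii[keep]; jj <- jj[keep]; d <- d[keep]
  if (!length(ii)) return(empty)
  sameRes <- P$chain[ii] == P$chain[jj] &
    P$resno[ii] == P$resno[jj] & P$resid[ii] == P$resid[jj]
  # backbone O(i)-N(i+1) across the peptide bond
  pept <- P$chain[ii] == P$chain[jj] & !P$hetero[ii] & !P$hetero[jj] &
    ((P$elety[ii] == "O" & P$elety[jj] == "N" &
        P$resno[jj] - P$resno[ii] == 1L) |
       (P$elety[jj] == "O" & P$elety[ii] == "N" &
          P$resno[ii] - P$resno[jj] == 1L))
  keep <- !sameRes & !pept
  ii <- ii[keep]; jj <- jj[keep]; d <- d[keep]
  cls <- atomClass(P)
  out <- data.frame(
    i = polar[ii], j = polar[jj],
    chain1 = P$chain[ii], resno1 = P$resno[ii], resid1 = P$resid[ii],
    elety1 = P$elety[ii], class1 = cls[ii],
    chain2 = P$chain[jj], resno2 = P$resno[jj], resid2 = P$resid[jj],
    elety2 = P$elety[jj], class2 = cls[jj],
    distance = d, category = pairCategory(cls[ii], cls[jj]),
    stringsAsFactors = FALSE
  )
  out[order(out$i, out$j), , drop = FALSE]
}

#' Fraction of main-chain contacts that are main-chain/main-chain
#'
#' The fraction arithmetic used on MM/MH tallies:
#' \code{100 * mm / (mm + mh)} and its complement.
#'
#' @param mm,mh counts of main-chain/main-chain and main-chain/water
#'   contacts.
#' @return A data.frame with \code{fracMM} and \code{fracMH} percent
#'   columns (rows sum to 100).
#' @export
contactFractions <- function(mm, mh) {
  tot <- mm + mh
  data.frame(fracMM = 100 * mm / tot, fracMH = 100 * mh / tot)
}

#' Tally hydrogen-bond contacts by prediction outcome
#'
#' Each scored residue whose observed state is Coil or Sheet is assigned
#' its outcome category R_ij (observed i, predicted j; i, j in C, E).
#' Within each category the tally counts, per residue endpoint, the
#' contacts in which one of the residue's main-chain atoms partners
#' another main-chain atom (MM) or a water oxygen (MH), plus all
#' hydrogen bonds involving any of the residue's atoms (\code{allBonds}).
#' The MM and MH fractions are percentages of MM + MH.  Residues are
#' counted when they carry at least one tallied contact.
#'
#' @param contacts contact table from [findHBonds()].
#' @param atoms atom table from [readPDBAtoms()].
#' @param observed,predicted 3-state strings for the scored residues.
#' @param residueMap data.frame with columns \code{chain}, \code{resno},
#'   \code{pos} mapping structure residues to string positions.
#' @return A data.frame with rows R_CC, R_CE, R_EC, R_EE and columns
#'   \code{mm}, \code{mh}, \code{mmPlusMh}, \code{fracMM},
#'   \code{fracMH}, \code{allBonds}, \code{nResidues}.
#' @export
tallyByOutcome <- function(contacts, atoms, observed, predicted,
                           residueMap) {
  o <- ssChars(observed); p <- ssChars(predicted)
  if (length(o) != length(p)) stopf("observed/predicted length mismatch")
  if (!all(c("chain", "resno", "pos") %in% names(residueMap))) {
    stopf("residueMap needs columns chain, resno, pos")
  }
  bad <- residueMap$pos < 1 | residueMap$pos > length(o)
  if (any(bad)) {
    stopf("unmappable residue(s): %s",
          paste(paste0(residueMap$chain[bad], residueMap$resno[bad]),
                collapse = ", "))
  }
  resKey <- function(chain, resno) paste(chain, resno)
  mapKey <- resKey(residueMap$chain, residueMap$resno)
  cats <- c("R_CC", "R_CE", "R_EC", "R_EE")
  zero <- stats::setNames(numeric(length(mapKey)), mapKey)
  mmC <- zero; mhC <- zero; allC <- zero
  countEnd <- function(keyEnd, clsEnd, clsOther) {
    sel <- keyEnd %in% mapKey
    addTo <- function(vec, which) {
      t <- table(keyEnd[which])
      vec[names(t)] <- vec[names(t)] + as.numeric(t)
      vec
    }
    mmC <<- addTo(mmC, sel & clsEnd == "M" & clsOther == "M")
    mhC <<- addTo(mhC, sel & clsEnd == "M" & clsOther == "H")
    allC <<- addTo(allC, sel)
  }
  if (nrow(contacts)) {
    k1 <- resKey(contacts$chain1, contacts$resno1)
    k2 <- resKey(contacts$chain2, contacts$resno2)
    countEnd(k1, contacts$class1, contacts$class2)
    countEnd(k2, contacts$class2, contacts$class1)
  }
  obsState <- o[residueMap$pos]
  predState <- p[residueMap$pos]
  out <- data.frame(mm = numeric(4), mh = numeric(4),
                    mmPlusMh = numeric(4), fracMM = numeric(4),
                    fracMH = numeric(4), allBonds = numeric(4),
                    nResidues = integer(4), row.names = cats)
  for (ci in cats) {
    i <- substr(ci, 3, 3); j <- substr(ci, 4, 4)
    sel <- obsState == i & predState == j
    mm <- sum(mmC[sel]); mh <- sum(mhC[sel]); ab <- sum(allC[sel])
    fr <- if (mm + mh > 0) contactFractions(mm, mh)
          else data.frame(fracMM = NA_real_, fracMH = NA_real_)
    out[ci, ] <- list(mm, mh, mm + mh, fr$fracMM, fr$fracMH, ab,
                      sum(sel & allC > 0))
  }
  out
}
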