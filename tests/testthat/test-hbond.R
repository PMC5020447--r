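# write a small PDB text file from an atom table (fixed columns)
writeToyPDB <- function(atoms, path) {
  lines <- sprintf(
    "%-6s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(atoms$hetero, "HETATM", "ATOM"), seq_len(nrow(atoms)),
    ifelse(nchar(atoms$elety) < 4, paste0(" ", atoms$elety),
           atoms$elety),
    atoms$resid, atoms$chain, atoms$resno, atoms$x, atoms$y, atoms$z,
    atoms$occ, 0, atoms$element)
  writeLines(c(lines, "END"), path)
}

toyAtoms <- function() {
  data.frame(
    chain = "A",
    resno = c(1L, 1L, 2L, 2L, 3L, 3L, 1001L),
    resid = c("ALA", "ALA", "GLY", "GLY", "SER", "SER", "HOH"),
    elety = c("N", "O", "N", "O", "N", "OG", "O"),
    element = c("N", "O", "N", "O", "N", "O", "O"),
    x = c(0, 1.5, 3, 4.5, 6, 7.5, 9),
    y = 0, z = 0, occ = 1,
    hetero = c(rep(FALSE, 6), TRUE),
    stringsAsFactors = FALSE)
}

test_that("PDB atom reading resolves altlocs and flags waters", {
  a <- toyAtoms()
  f <- withr::local_tempfile(fileext = ".pdb")
  writeToyPDB(a, f)
  got <- readPDBAtoms(f)
  expect_equal(nrow(got), 7)
  expect_true(got$hetero[got$resid == "HOH"])
  expect_false(any(got$hetero[got$resid != "HOH"]))
  expect_equal(got$x, a$x, tolerance = 1e-6)
  # round trip through the writer preserves coordinates to 3 decimals
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writePDBAtoms(got, f2)
  back <- readPDBAtoms(f2)
  expect_equal(back$x, got$x, tolerance = 5e-4)
  expect_equal(back$y, got$y, tolerance = 5e-4)
  expect_equal(back$z, got$z, tolerance = 5e-4)
  expect_identical(back$elety, got$elety)
  expect_error(readPDBAtoms(withr::local_tempfile(fileext = ".pdb")),
               "cannot parse|No input")
})

test_that("altloc copies collapse to the highest occupancy", {
  a <- toyAtoms()[c(1, 1, 2), ]
  a$occ <- c(0.4, 0.6, 1)
  a$x <- c(0, 10, 1.5)
  f <- withr::local_tempfile(fileext = ".pdb")
  # emulate altloc column by writing both copies
  lines <- sprintf(
    "ATOM  %5d  N  %sALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           N",
    1:2, c("A", "B"), 1L, a$x[1:2], 0, 0, a$occ[1:2], 0)
  lines <- c(lines, sprintf(
    "ATOM  %5d  O   ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           O",
    3L, 1L, 1.5, 0, 0, 1, 0))
  writeLines(c(lines, "END"), f)
  got <- readPDBAtoms(f)
  expect_equal(nrow(got), 2)
  expect_equal(got$x[got$elety == "N"], 10)   # occupancy 0.6 copy wins
})

test_that("contact detection applies the distance cutoff and exclusions", {
  mk <- function(x2) {
    data.frame(chain = "A", resno = c(1L, 5L), resid = "ALA",
               elety = c("O", "N"), element = c("O", "N"),
               x = c(0, x2), y = 0, z = 0, occ = 1, hetero = FALSE,
               stringsAsFactors = FALSE)
  }
  inside <- findHBonds(mk(3.5))
  expect_equal(nrow(inside), 1)
  expect_equal(inside$category, "MM")
  expect_equal(inside$distance, 3.5)
  expect_equal(nrow(findHBonds(mk(3.7))), 0)
  # the cutoff is inclusive
  expect_equal(nrow(findHBonds(mk(3.6) , cutoff = 3.6)), 1)
  # sequential peptide-bond partners O(i)-N(i+1) are excluded ...
  pept <- mk(3.0); pept$resno <- c(1L, 2L)
  expect_equal(nrow(findHBonds(pept)), 0)
  # ... but N(i)-O(i+1) across the same step is kept
  rev <- pept; rev$elety <- c("N", "O"); rev$element <- c("N", "O")
  expect_equal(nrow(findHBonds(rev)), 1)
  # same-residue pairs never count
  same <- mk(3.0); same$resno <- c(1L, 1L)
  expect_equal(nrow(findHBonds(same)), 0)
  # main-chain to water is MH; side-chain to water is SH
  wat <- mk(3.0)
  wat$resno[2] <- 2001L; wat$resid[2] <- "HOH"
  wat$elety[2] <- "O"; wat$element[2] <- "O"; wat$hetero[2] <- TRUE
  expect_equal(findHBonds(wat)$category, "MH")
  sc <- wat; sc$elety[1] <- "OG"
  expect_equal(findHBonds(sc)$category, "SH")
})

test_that("contact detection is symmetric and matches the all-pairs oracle", {
  set.seed(111)
  for (rep in 1:12) {
    atoms <- randomStructure(nres = sample(8:20, 1),
                             nwat = sample(3:10, 1))
    got <- findHBonds(atoms)
    want <- oracleContacts(atoms)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      key <- function(df) sort(paste(pmin(df$i, df$j),
                                     pmax(df$i, df$j), df$category))
      expect_identical(key(got), key(want))
      expect_equal(sort(got$distance), sort(want$distance),
                   tolerance = 1e-12)
    }
    # atom order must not matter
    perm <- sample(nrow(atoms))
    shuf <- atoms[perm, ]
    rownames(shuf) <- NULL
    got2 <- findHBonds(shuf)
    expect_equal(nrow(got2), nrow(got))
    origIdx <- function(df) sort(paste(pmin(perm[df$i], perm[df$j]),
                                       pmax(perm[df$i], perm[df$j])))
    expect_identical(origIdx(got2),
                     sort(paste(pmin(got$i, got$j),
                                pmax(got$i, got$j))))
  }
})

test_that("outcome tallies count MM/MH per residue endpoint", {
  # residues 1..4 in a row; O(1)-N(3) contact, O(3)-water, N(4)-water
  atoms <- data.frame(
    chain = "A",
    resno = c(1L, 3L, 3L, 4L, 2001L, 2002L),
    resid = c("ALA", "ALA", "ALA", "ALA", "HOH", "HOH"),
    elety = c("O", "N", "O", "N", "O", "O"),
    element = c("O", "N", "O", "N", "O", "O"),
    x = c(0, 3, 10, 20, 12, 22),
    y = 0, z = 0, occ = 1,
    hetero = c(rep(FALSE, 4), TRUE, TRUE),
    stringsAsFactors = FALSE)
  contacts <- findHBonds(atoms)
  expect_setequal(contacts$category, c("MM", "MH"))
  map <- data.frame(chain = "A", resno = 1:4, pos = 1:4)
  # observed CCEE, predicted CEEC:
  #   res1 R_CC (MM 1), res2 R_CE (none), res3 R_EE (MM 1 + MH 1),
  #   res4 R_EC (MH 1)
  tal <- tallyByOutcome(contacts, atoms, "CCEE", "CEEC", map)
  expect_equal(tal["R_CC", "mm"], 1)
  expect_equal(tal["R_CC", "mh"], 0)
  expect_equal(tal["R_CC", "fracMM"], 100)
  expect_equal(tal["R_CE", "mmPlusMh"], 0)
  expect_equal(tal["R_EE", "mm"], 1)
  expect_equal(tal["R_EE", "mh"], 1)
  expect_equal(tal["R_EE", "fracMM"], 50)
  expect_equal(tal["R_EC", "mh"], 1)
  expect_equal(tal["R_EC", "fracMH"], 100)
  expect_equal(sum(tal$nResidues), 3)   # residues 1, 3, 4 carry bonds
  expect_error(tallyByOutcome(contacts, atoms, "CCEE", "CEEC",
                              data.frame(chain = "A", resno = 9,
                                         pos = 9)),
               "unmappable")
})

test_that("the published MM/MH fractions follow from their counts", {
  fx <- loadTableFixtures()
  fr <- contactFractions(fx$hbond$mm, fx$hbond$mh)
  expect_equal(round(fr$fracMM, 1), c(41.3, 47.0, 63.3, 72.5))
  expect_equal(fr$fracMM + fr$fracMH, rep(100, 4))
  expect_equal(fx$hbond$mm + fx$hbond$mh, fx$hbond$mm_mh)
})

test_that("adding waters near the backbone cannot raise the MM fraction", {
  base <- data.frame(
    chain = "A", resno = c(1L, 4L), resid = "ALA",
    elety = c("O", "N"), element = c("O", "N"),
    x = c(0, 3), y = 0, z = 0, occ = 1, hetero = FALSE,
    stringsAsFactors = FALSE)
  map <- data.frame(chain = "A", resno = c(1L, 4L), pos = 1:2)
  fracs <- sapply(0:4, function(nw) {
    atoms <- base
    if (nw > 0) {
      atoms <- rbind(atoms, data.frame(
        chain = "A", resno = 3000L + seq_len(nw), resid = "HOH",
        elety = "O", element = "O",
        x = 0 + 0.5 * seq_len(nw), y = 2.5, z = 0, occ = 1,
        hetero = TRUE))
    }
    tal <- tallyByOutcome(findHBonds(atoms), atoms, "CC", "CC", map)
    tal["R_CC", "fracMM"]
  })
  expect_true(all(diff(fracs) <= 0))
})
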