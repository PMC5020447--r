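fixturePath <- function(file) {
  p <- system.file("extdata", file, package = "compactSSP")
  if (!nzchar(p)) stopf("bundled fixture %s not found", file)
  p
}

#' Load the bundled benchmark-table fixtures
#'
#' Machine-readable transcriptions of published benchmark tables: the
#' CB513 and GSW25 confusion matrices with their printed scores, the
#' two inhibitor observed/predicted structure strings, the MM/MH
#' hydrogen-bond count table, and the printed helix/sheet confusion
#' rates.  Fixture integrity is verified against a bundled MD5 manifest
#' before parsing.
#'
#' @param verify check fixture checksums (default TRUE).
#' @return A list with elements \code{cb513}, \code{gsw25} (data.frames
#'   of confusion rows and printed scores), \code{inhibitors},
#'   \code{hbond}, \code{qhe}.
#' @export
loadTableFixtures <- function(verify = TRUE) {
  if (verify) verifyFixtures()
  rd <- function(f) utils::read.table(fixturePath(f), sep = "\t",
                                      header = TRUE,
                                      stringsAsFactors = FALSE)
  list(cb513 = rd("table1_cb513.tsv"),
       gsw25 = rd("table2_gsw25.tsv"),
       inhibitors = rd("table5_inhibitors.tsv"),
       hbond = rd("table6_hbond_counts.tsv"),
       qhe = rd("qhe_gsw25.tsv"))
}

#' @rdname loadTableFixtures
#' @export
verifyFixtures <- function() {
  man <- utils::read.table(fixturePath("checksums.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  sums <- tools::md5sum(vapply(man$file, fixturePath, character(1)))
  bad <- man$file[unname(sums) != man$md5]
  if (length(bad)) {
    stopf("fixture checksum failure: %s", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

# confusion matrix for one model out of a fixture table
fixtureCM <- function(df, model) {
  rows <- df[df$model == model, ]
  rows <- rows[match(SS3_STATES, rows$observed), ]
  m <- as.matrix(rows[, c("pred_H", "pred_E", "pred_C")])
  dimnames(m) <- list(observed = SS3_STATES, predicted = SS3_STATES)
  m
}

#' Recompute every derived benchmark-table figure from the fixtures
#'
#' Runs the metrics and contact-fraction code on the fixture inputs
#' (confusion-matrix counts, inhibitor structure strings, MM/MH counts)
#' and compares each computed value against the printed one.  The
#' comparison tolerance is half an ulp of the printed precision plus
#' 0.01, because several published values are internally inconsistent
#' with their own matrices at the last printed digit.
#'
#' @return A data.frame with columns \code{quantity}, \code{computed},
#'   \code{printed}, \code{tolerance}, \code{pass}.
#' @export
reproduceTables <- function() {
  fx <- loadTableFixtures()
  rows <- list()
  add <- function(quantity, computed, printed) {
    dec <- nchar(sub("^[^.]*\\.?", "", format(printed, trim = TRUE)))
    tol <- 0.5 * 10^(-dec) + 0.01
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, computed = computed, printed = printed,
      tolerance = tol, pass = abs(computed - printed) <= tol)
  }
  for (tab in c("cb513", "gsw25")) {
    df <- fx[[tab]]
    for (model in unique(df$model)) {
      cm <- fixtureCM(df, model)
      pr <- df[df$model == model, ]
      add(paste(tab, model, "q3", sep = "_"), q3(cm), pr$q3[1])
      for (j in SS3_STATES) {
        add(paste(tab, model, "q", j, sep = "_"), qClass(cm, j),
            pr$q_j[pr$observed == j])
        add(paste(tab, model, "mcc", j, sep = "_"), mccClass(cm, j),
            pr$mcc_j[pr$observed == j])
      }
    }
  }
  for (model in fx$qhe$model) {
    cm <- fixtureCM(fx$gsw25, model)
    add(paste("gsw25", model, "qhe", sep = "_"), qHEError(cm),
        fx$qhe$q_he_error_printed[fx$qhe$model == model])
  }
  for (i in seq_len(nrow(fx$inhibitors))) {
    cm <- confusionMatrix3(fx$inhibitors$observed[i],
                           fx$inhibitors$predicted[i])
    add(paste0("inhibitor_qC_", sub("_.*", "", fx$inhibitors$chain[i])),
        qClass(cm, "C"), fx$inhibitors$q_c_printed[i])
  }
  for (i in seq_len(nrow(fx$hbond))) {
    fr <- contactFractions(fx$hbond$mm[i], fx$hbond$mh[i])
    add(paste0("hbond_fracMM_", fx$hbond$category[i]), fr$fracMM,
        fx$hbond$frac_mm_printed[i])
    add(paste0("hbond_fracMH_", fx$hbond$category[i]), fr$fracMH,
        fx$hbond$frac_mh_printed[i])
  }
  do.call(rbind, rows)
}
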