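#' Reference benchmark statistics and results
#'
#' Small reference tables from the drug-target interaction prediction
#' literature, shipped so that the package's arithmetic utilities
#' ([summarizeCounts()], [errorRate()], [errorReduction()], report
#' averaging) can be exercised on the published numbers without
#' downloading the benchmark distributions.
#'
#' `benchmarkStatistics()` gives the drug/target/known-interaction counts
#' of the four Yamanishi_08 gold-standard datasets (nuclear receptors,
#' GPCRs, ion channels, enzymes) and the FDA_DrugBank dataset.
#'
#' `referenceAUPR()` gives the published random-setting tenfold-CV AUPR
#' of the embedding-plus-boosting method this package implements, per
#' dataset, classifier and fusion function, together with the best
#' per-dataset AUPRs and the hold-out AUPRs of all compared methods on
#' FDA_DrugBank.
#'
#' @return `benchmarkStatistics()`: data.frame with columns `dataset`,
#'   `drugs`, `targets`, `known`. `referenceAUPR()`: list of data.frames
#'   `byFusion` (per classifier/fusion AUPR per dataset), `best`
#'   (best AUPR and second-best method AUPR per dataset) and `holdout`
#'   (FDA_DrugBank hold-out AUPRs).
#' @examples
#' s <- benchmarkStatistics()
#' with(s[s$dataset == "NR", ], summarizeCounts(drugs, targets, known))
#' @export
benchmarkStatistics <- function() {
  data.frame(
    dataset = c("NR", "GPCR", "IC", "Enzyme", "FDA_DrugBank"),
    drugs = c(54L, 223L, 210L, 445L, 1482L),
    targets = c(26L, 95L, 204L, 664L, 1408L),
    known = c(90L, 635L, 1476L, 2926L, 9881L),
    stringsAsFactors = FALSE)
}

#' @rdname benchmarkStatistics
#' @export
referenceAUPR <- function() {
  byFusion <- rbind(
    data.frame(classifier = "adaboost",
      fusion = c("concatenate", "hadamard", "average", "weighted_l1",
        "weighted_l2"),
      NR = c(0.74, 0.85, 0.64, 0.92, 0.92),
      GPCR = c(0.83, 0.89, 0.78, 0.84, 0.84),
      IC = c(0.97, 0.93, 0.90, 0.93, 0.94),
      Enzyme = c(0.97, 0.96, 0.92, 0.96, 0.96),
      FDA_DrugBank = c(0.77, 0.82, 0.75, 0.82, 0.82)),
    data.frame(classifier = "xgboost",
      fusion = c("concatenate", "hadamard", "average", "weighted_l1",
        "weighted_l2"),
      NR = c(0.72, 0.81, 0.68, 0.88, 0.89),
      GPCR = c(0.87, 0.90, 0.81, 0.84, 0.84),
      IC = c(0.98, 0.93, 0.91, 0.94, 0.94),
      Enzyme = c(0.98, 0.97, 0.95, 0.97, 0.97),
      FDA_DrugBank = c(0.82, 0.88, 0.78, 0.87, 0.87)))
  best <- data.frame(
    dataset = c("NR", "GPCR", "IC", "Enzyme", "FDA_DrugBank"),
    best_aupr = c(0.92, 0.90, 0.98, 0.98, 0.88),
    stringsAsFactors = FALSE)
  holdout <- data.frame(
    method = c("NRLMF", "DNILMF", "DDR", "TriModel", "DTiGEMS+", "best"),
    aupr = c(0.34, 0.31, 0.63, 0.66, 0.62, 0.82),
    stringsAsFactors = FALSE)
  list(byFusion = byFusion, best = best, holdout = holdout)
}
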