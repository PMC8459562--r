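#' Read a binary drug-target interaction matrix
#'
#' Parses the tab-separated matrix dialect used by the Yamanishi_08
#' gold-standard distribution: a header row of column identifiers (the
#' first header cell may be empty) followed by one row per row-identifier.
#' Files in that distribution place targets in rows and drugs in columns;
#' the returned network is always oriented drugs-in-rows internally.
#'
#' @param path file path.
#' @param orientation `"targets_in_rows"` (the distribution default) or
#'   `"drugs_in_rows"`.
#' @return A [DrugTargetNetwork-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("\td1\td2", "t1\t1\t0", "t2\t0\t1"), f)
#' net <- readInteractionMatrix(f)
#' dim(net)  # 2 drugs x 2 targets
#' @export
readInteractionMatrix <- function(path,
    orientation = c("targets_in_rows", "drugs_in_rows")) {
  orientation <- match.arg(orientation)
  parsed <- readMatrixFile(path)
  y <- parsed$values
  bad <- which(!(y == 0 | y == 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-binary interaction value %s at row '%s', column '%s' in %s",
      format(y[bad[1, 1], bad[1, 2]]), parsed$rowIds[bad[1, 1]],
      parsed$colIds[bad[1, 2]], path))
  }
  if (orientation == "targets_in_rows") {
    DrugTargetNetwork(t(y), drugIds = parsed$colIds, targetIds = parsed$rowIds)
  } else {
    DrugTargetNetwork(y, drugIds = parsed$rowIds, targetIds = parsed$colIds)
  }
}

#' Read a square similarity matrix
#'
#' Same tab-separated dialect as [readInteractionMatrix()]. Row and column
#' identifier sets must match. Asymmetries up to `1e-6` (rounding noise in
#' distributed files) are repaired by averaging with the transpose; larger
#' asymmetry is an error, as is any value outside \[0, 1\].
#'
#' @param path file path.
#' @return A [SimilarityMatrix-class].
#' @export
readSimilarityMatrix <- function(path) {
  parsed <- readMatrixFile(path)
  if (!identical(parsed$rowIds, parsed$colIds)) {
    if (!setequal(parsed$rowIds, parsed$colIds))
      stop(sprintf("row/column identifier mismatch in %s", path))
    parsed$values <- parsed$values[, parsed$rowIds, drop = FALSE]
    parsed$colIds <- parsed$rowIds
  }
  s <- parsed$values
  if (any(s < 0 | s > 1)) {
    bad <- which(s < 0 | s > 1, arr.ind = TRUE)[1, ]
    stop(sprintf("similarity value %s outside [0, 1] at ('%s', '%s') in %s",
      format(s[bad[1], bad[2]]), parsed$rowIds[bad[1]], parsed$colIds[bad[2]], path))
  }
  SimilarityMatrix(s, ids = parsed$rowIds)
}

# Shared tab-separated matrix reader: header of column ids (leading cell
# optional), then rowid + numeric cells. Errors on ragged or duplicate rows.
readMatrixFile <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop(sprintf("matrix file %s has no data rows", path))
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!nzchar(header[1L])) header <- header[-1L]
  colIds <- header
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  widths <- lengths(body)
  if (any(widths != length(colIds) + 1L))
    stop(sprintf("ragged row %d in %s: %d cells, expected %d",
      which(widths != length(colIds) + 1L)[1L] + 1L, path,
      widths[widths != length(colIds) + 1L][1L], length(colIds) + 1L))
  rowIds <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(rowIds))
    stop(sprintf("duplicate row identifier '%s' in %s",
      rowIds[duplicated(rowIds)][1L], path))
  if (anyDuplicated(colIds))
    stop(sprintf("duplicate column identifier '%s' in %s",
      colIds[duplicated(colIds)][1L], path))
  cells <- vapply(body, function(r) as.numeric(r[-1L]), numeric(length(colIds)))
  values <- if (is.matrix(cells)) t(cells) else matrix(cells, ncol = length(colIds))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("unparseable numeric cell at row '%s', column '%s' in %s",
      rowIds[bad[1]], colIds[bad[2]], path))
  }
  dimnames(values) <- list(rowIds, colIds)
  list(rowIds = rowIds, colIds = colIds, values = values)
}

#' Write matrices in the distribution dialect
#'
#' `writeInteractionMatrix()` writes targets in rows (the Yamanishi_08
#' convention) unless told otherwise; `writeSimilarityMatrix()` writes the
#' square matrix at full precision so that reading it back round-trips.
#'
#' @param net a [DrugTargetNetwork-class].
#' @param sim a [SimilarityMatrix-class].
#' @param path output file path.
#' @param orientation row family for the written file.
#' @param digits significant digits for similarity values.
#' @return The path, invisibly.
#' @export
writeInteractionMatrix <- function(net, path,
    orientation = c("targets_in_rows", "drugs_in_rows")) {
  orientation <- match.arg(orientation)
  y <- interactionMatrix(net)
  if (orientation == "targets_in_rows") y <- t(y)
  writeMatrixFile(y, path, format_fun = function(v) format(as.integer(v)))
  invisible(path)
}

#' @rdname writeInteractionMatrix
#' @export
writeSimilarityMatrix <- function(sim, path, digits = 17) {
  writeMatrixFile(similarityValues(sim), path,
    format_fun = function(v) format(v, digits = digits, scientific = FALSE,
      trim = TRUE))
  invisible(path)
}

writeMatrixFile <- function(m, path, format_fun) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], format_fun(m[i, ])), collapse = "\t"), con)
  }
}

#' Cross-check a dataset's interaction and similarity components
#'
#' Report-only validation: lists identifier mismatches between the network
#' and each similarity matrix, and any drug or target with zero known
#' interactions (such nodes violate the random cross-validation setting,
#' which assumes every drug and target is seen interacting in training).
#'
#' @param net a [DrugTargetNetwork-class].
#' @param drugSim,targetSim [SimilarityMatrix-class] objects for the drug
#'   and target families.
#' @return A list with character vectors `drug_id_mismatches`,
#'   `target_id_mismatches`, `drugs_without_interactions`,
#'   `targets_without_interactions`, and logical `ok`.
#' @export
validateDataset <- function(net, drugSim, targetSim) {
  y <- interactionMatrix(net)
  report <- list(
    drug_id_mismatches = sort(unique(c(
      setdiff(drugIds(net), nodeIds(drugSim)),
      setdiff(nodeIds(drugSim), drugIds(net))))),
    target_id_mismatches = sort(unique(c(
      setdiff(targetIds(net), nodeIds(targetSim)),
      setdiff(nodeIds(targetSim), targetIds(net))))),
    drugs_without_interactions = drugIds(net)[rowSums(y) == 0],
    targets_without_interactions = targetIds(net)[colSums(y) == 0]
  )
  report$ok <- all(lengths(report[1:4]) == 0L)
  report
}

#' Write ranked predictions
#'
#' Tab-separated columns: rank, drug_id, target_id, score.
#'
#' @param predictions data.frame with columns `drug`, `target`, `score`
#'   (as returned by [rankNovel()]).
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writePredictions <- function(predictions, path) {
  out <- data.frame(
    rank = seq_len(nrow(predictions)),
    drug_id = predictions$drug,
    target_id = predictions$target,
    score = format(predictions$score, digits = 10, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Enumerate pairs of a network
#'
#' `interactionPairs()` lists the known (label 1) pairs;
#' `pairUniverse()` lists all m x n drug-target pairs with their labels,
#' the sample universe of the link-prediction task (unknown pairs are the
#' negative class).
#'
#' @param net a [DrugTargetNetwork-class].
#' @return A data.frame with columns `drug`, `target` (and `label` for
#'   `pairUniverse()`), ordered target-major to match the flattened
#'   interaction matrix.
#' @export
interactionPairs <- function(net) {
  idx <- which(interactionMatrix(net) == 1, arr.ind = TRUE)
  out <- data.frame(
    drug = drugIds(net)[idx[, 1]],
    target = targetIds(net)[idx[, 2]],
    stringsAsFactors = FALSE)
  out[order(idx[, 2], idx[, 1]), , drop = FALSE]
}

#' @rdname interactionPairs
#' @export
pairUniverse <- function(net) {
  y <- interactionMatrix(net)
  data.frame(
    drug = rep(drugIds(net), times = ncol(y)),
    target = rep(targetIds(net), each = nrow(y)),
    label = as.numeric(y),
    stringsAsFactors = FALSE)
}
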