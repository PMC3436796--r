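#' Read a signed network from a SIF file
#'
#' Three whitespace-separated columns: source, relation (1 or -1),
#' target. Lines starting with \code{#} and blank lines are ignored.
#'
#' @param path file path.
#' @param stimulated,inhibited,measured optional role annotations.
#' @return A [SignedNetwork-class].
#' @export
readSIF <- function(path, stimulated = character(), inhibited = character(),
                    measured = character()) {
  if (!file.exists(path)) .inputError("SIF file not found: %s", path)
  lines <- readLines(path)
  edges <- NULL
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(ln))) next
    f <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    if (length(f) != 3L)
      .inputError("line %d of %s: expected 3 fields, got %d",
                  i, path, length(f))
    s <- suppressWarnings(as.integer(f[2L]))
    if (is.na(s) || !(s %in% c(-1L, 1L)))
      .inputError("line %d of %s: relation must be 1 or -1 (got '%s')",
                  i, path, f[2L])
    edges <- rbind(edges, data.frame(from = f[1L], to = f[3L], sign = s,
                                     stringsAsFactors = FALSE))
  }
  signedNetwork(edges, stimulated = stimulated, inhibited = inhibited,
                measured = measured)
}

#' Write a signed network to a SIF file
#'
#' Edges are written sorted (source, target, sign) so output is
#' deterministic and diffs cleanly.
#'
#' @param net a [SignedNetwork-class].
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeSIF <- function(net, path) {
  ed <- net@edges
  ed <- ed[order(ed$from, ed$to, ed$sign), , drop = FALSE]
  writeLines(sprintf("%s %d %s", ed$from, ed$sign, ed$to), path)
  invisible(path)
}

#' Read a perturbation dataset from a MIDAS CSV file
#'
#' Dialect: columns \code{TR:<name>} in 0/1 for stimuli,
#' \code{TR:<name>i} for inhibitors, \code{DA:<readout>} for acquisition
#' times and \code{DV:<readout>} for values; one row per condition and
#' time.
#'
#' @param path file path.
#' @return A [PerturbationData-class].
#' @export
readMIDAS <- function(path) {
  if (!file.exists(path)) .inputError("MIDAS file not found: %s", path)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cn <- colnames(tab)
  trCols <- grep("^TR:", cn, value = TRUE)
  daCols <- grep("^DA:", cn, value = TRUE)
  dvCols <- grep("^DV:", cn, value = TRUE)
  dvNames <- sub("^DV:", "", dvCols)
  daNames <- sub("^DA:", "", daCols)
  if (!setequal(dvNames, daNames))
    .inputError("%s: DV column without matching DA (or vice versa): %s",
                path, paste(c(setdiff(dvNames, daNames),
                              setdiff(daNames, dvNames)), collapse = ", "))
  readouts <- sort(dvNames)
  inhCols <- grep("i$", trCols, value = TRUE)
  stimCols <- setdiff(trCols, inhCols)
  stimuli <- sort(sub("^TR:", "", stimCols))
  inhibitors <- sort(sub("i$", "", sub("^TR:", "", inhCols)))
  for (cc in c(trCols, daCols, dvCols)) {
    bad <- which(!is.na(tab[[cc]]) & is.na(suppressWarnings(
      as.numeric(tab[[cc]]))))
    if (length(bad))
      .inputError("%s: non-numeric value at row %d, column %s",
                  path, bad[1L], cc)
  }
  cueOf <- function(nm, inh = FALSE)
    paste0("TR:", nm, if (inh) "i" else "")
  cueMat <- sapply(c(stimuli, inhibitors), function(nm)
    as.integer(tab[[cueOf(nm, nm %in% inhibitors)]]))
  cueMat <- matrix(cueMat, nrow = nrow(tab),
                   dimnames = list(NULL, c(stimuli, inhibitors)))
  rowTime <- apply(tab[, paste0("DA:", readouts), drop = FALSE], 1L,
                   function(x) {
                     u <- unique(stats::na.omit(as.numeric(x)))
                     if (length(u) != 1L)
                       .inputError("%s: mixed acquisition times in a row",
                                   path)
                     u
                   })
  key <- apply(cueMat, 1L, paste, collapse = "")
  condKeys <- unique(key)
  timepoints <- sort(unique(rowTime))
  vals <- array(NA_real_, dim = c(length(condKeys), length(readouts),
                                  length(timepoints)),
                dimnames = list(NULL, readouts, timepoints))
  for (r in seq_len(nrow(tab))) {
    ci <- match(key[r], condKeys)
    ti <- match(rowTime[r], timepoints)
    vals[ci, , ti] <- as.numeric(tab[r, paste0("DV:", readouts)])
  }
  design <- cueMat[match(condKeys, key), , drop = FALSE]
  perturbationData(design, vals, stimuli = stimuli,
                   inhibitors = inhibitors, readouts = readouts,
                   timepoints = timepoints)
}

#' Write a perturbation dataset to a MIDAS CSV file
#'
#' One row per condition and timepoint, deterministic order (conditions
#' as stored, timepoints ascending).
#'
#' @param ds a [PerturbationData-class].
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeMIDAS <- function(ds, path) {
  d <- ds@design
  ro <- ds@readouts
  rows <- list()
  for (ci in seq_len(nrow(d))) for (ti in seq_along(ds@timepoints)) {
    tr <- as.list(d[ci, ])
    names(tr) <- paste0("TR:", colnames(d),
                        ifelse(colnames(d) %in% ds@inhibitors, "i", ""))
    da <- as.list(rep(ds@timepoints[ti], length(ro)))
    names(da) <- paste0("DA:", ro)
    dv <- as.list(ds@values[ci, , ti])
    names(dv) <- paste0("DV:", ro)
    rows[[length(rows) + 1L]] <- c(tr, da, dv)
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a protein-protein interaction network from a TSV file
#'
#' Three tab- or whitespace-separated columns: proteinA, proteinB,
#' evidence count. Identifiers must share the prior network's
#' namespace. Self-interactions are dropped; parallel evidences merged.
#'
#' @param path file path.
#' @return An [InteractionNetwork-class].
#' @export
readPIN <- function(path) {
  if (!file.exists(path)) .inputError("PIN file not found: %s", path)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#",
                           col.names = c("a", "b", "evidence"))
  if (any(is.na(suppressWarnings(as.integer(tab$evidence)))))
    .inputError("%s: non-integer evidence count", path)
  nSelf <- sum(tab$a == tab$b)
  if (nSelf) warning(sprintf("%s: dropped %d self-interaction(s)",
                             path, nSelf))
  interactionNetwork(tab)
}

#' Write a protein-protein interaction network to a TSV file
#'
#' @param pin an [InteractionNetwork-class].
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writePIN <- function(pin, path) {
  ed <- pin@edges[order(pin@edges$a, pin@edges$b), , drop = FALSE]
  utils::write.table(ed, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
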