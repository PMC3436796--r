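#' Mutual information matrix of readouts and cues
#'
#' Plug-in (maximum-likelihood) mutual information between all pairs of
#' variables, after equal-width discretization of each variable into
#' \code{nBins} bins over [0, 1] (the scale of normalized activation
#' levels); cues enter as binary variables. Natural logarithms are used.
#'
#' @param dataset a normalized [PerturbationData-class] with at least 4
#'   conditions.
#' @param nBins number of equal-width bins (default 3).
#' @return Symmetric non-negative matrix with zero diagonal; rows and
#'   columns named by readouts then cues. Constant variables yield zero
#'   rows/columns.
#' @export
mutualInfoMatrix <- function(dataset, nBins = 3L) {
  obs <- trainingValues(dataset)
  d <- dataset@design
  if (nrow(d) < 4L) .inputError("mutual information needs >= 4 conditions")
  vars <- cbind(obs, d[, , drop = FALSE])
  colnames(vars) <- c(readoutNames(dataset), colnames(d))
  breaks <- seq(0, 1, length.out = nBins + 1L)
  disc <- apply(vars, 2L, function(x) {
    x <- pmin(pmax(x, 0), 1)
    b <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    b
  })
  p <- ncol(disc)
  mi <- matrix(0, p, p, dimnames = list(colnames(vars), colnames(vars)))
  for (i in seq_len(p - 1L)) for (j in seq((i + 1L), p)) {
    ok <- !is.na(disc[, i]) & !is.na(disc[, j])
    if (!sum(ok)) next
    tab <- table(disc[ok, i], disc[ok, j]) / sum(ok)
    px <- rowSums(tab); py <- colSums(tab)
    nz <- tab > 0
    val <- sum(tab[nz] * log(tab[nz] / outer(px, py)[nz]))
    mi[i, j] <- mi[j, i] <- max(0, val)
  }
  mi
}

#' ARACNe network from a mutual information matrix
#'
#' Starts from all pairs with positive mutual information and applies
#' the data processing inequality: in every triangle (a, b, c) the edge
#' (a, c) is deleted if
#' mi(a, c) < min(mi(a, b), mi(b, c)) * (1 - dpiTolerance).
#' Mutual information carries no directionality, so the result is
#' undirected with unset signs; direction (and sign) is assigned later
#' by comparison with the prior network during integration.
#'
#' @param mi symmetric mutual information matrix
#'   (from [mutualInfoMatrix()]).
#' @param dpiTolerance DPI tolerance in [0, 1); 0 is the strict rule.
#' @param stimulated,inhibited,measured optional role annotations carried
#'   onto the result.
#' @return An undirected [SignedNetwork-class] with \code{sign = NA} and
#'   provenance \code{"ddn"}.
#' @export
aracneNetwork <- function(mi, dpiTolerance = 0, stimulated = character(),
                          inhibited = character(), measured = character()) {
  v <- colnames(mi)
  keep <- mi > 0
  removed <- matrix(FALSE, nrow(mi), ncol(mi))
  p <- ncol(mi)
  for (a in seq_len(p)) for (b in seq_len(p)) for (cc in seq_len(p)) {
    if (a >= cc || b == a || b == cc) next
    if (keep[a, b] && keep[b, cc] && keep[a, cc] &&
        mi[a, cc] < min(mi[a, b], mi[b, cc]) * (1 - dpiTolerance))
      removed[a, cc] <- removed[cc, a] <- TRUE
  }
  keep <- keep & !removed
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  edges <- if (nrow(idx))
    data.frame(from = v[idx[, 1L]], to = v[idx[, 2L]], sign = NA_integer_,
               provenance = "ddn", stringsAsFactors = FALSE) else NULL
  signedNetwork(edges, nodes = v, stimulated = stimulated,
                inhibited = inhibited, measured = measured,
                directed = FALSE)
}

#' CLR network from a mutual information matrix
#'
#' Context likelihood of relatedness: each mutual information value is
#' converted to a z-score against the background of its row
#' (z = (mi - mean) / sd, with z = 0 for degenerate sd = 0 rows), the
#' pair score is sqrt(max(0, z_i)^2 + max(0, z_j)^2), and edges with
#' score above \code{zThreshold} are kept. Undirected, signs unset.
#'
#' @inheritParams aracneNetwork
#' @param zThreshold score threshold (default 2).
#' @return An undirected [SignedNetwork-class].
#' @export
clrNetwork <- function(mi, zThreshold = 2, stimulated = character(),
                       inhibited = character(), measured = character()) {
  v <- colnames(mi)
  p <- ncol(mi)
  z <- matrix(0, p, p)
  for (i in seq_len(p)) {
    row <- mi[i, -i]
    s <- stats::sd(row)
    if (!is.na(s) && s > 0) z[i, -i] <- (mi[i, -i] - mean(row)) / s
  }
  zp <- pmax(z, 0)
  score <- sqrt(zp^2 + t(zp)^2)
  idx <- which(score > zThreshold & upper.tri(score), arr.ind = TRUE)
  edges <- if (nrow(idx))
    data.frame(from = v[idx[, 1L]], to = v[idx[, 2L]], sign = NA_integer_,
               provenance = "ddn", stringsAsFactors = FALSE) else NULL
  signedNetwork(edges, nodes = v, stimulated = stimulated,
                inhibited = inhibited, measured = measured,
                directed = FALSE)
}

#' Infer a data-driven network from a perturbation dataset
#'
#' Umbrella over the available reverse-engineering methods. External
#' inference engines (e.g. Bayesian-network structure learning) plug in
#' as adapters: pass a function taking the dataset and returning a
#' [SignedNetwork-class].
#'
#' @param dataset a normalized [PerturbationData-class].
#' @param method \code{"feed"}, \code{"aracne"}, \code{"clr"}, or a
#'   function \code{dataset -> SignedNetwork}.
#' @param epsilon,kSigma FEED parameters (see [feedEffectTables()]).
#' @param dpiTolerance ARACNe parameter (see [aracneNetwork()]).
#' @param zThreshold CLR parameter (see [clrNetwork()]).
#' @param nBins discretization for the mutual-information methods.
#' @return A [SignedNetwork-class] (the DDN).
#' @export
inferDDN <- function(dataset, method = c("feed", "aracne", "clr"),
                     epsilon = 0.1, kSigma = 2, dpiTolerance = 0,
                     zThreshold = 2, nBins = 3L) {
  if (is.function(method)) return(method(dataset))
  method <- match.arg(method)
  if (method == "feed")
    return(inferFEED(dataset, epsilon = epsilon, kSigma = kSigma))
  mi <- mutualInfoMatrix(dataset, nBins = nBins)
  args <- list(mi, stimulated = dataset@stimuli,
               inhibited = dataset@inhibitors,
               measured = readoutNames(dataset))
  if (method == "aracne")
    do.call(aracneNetwork, c(args, dpiTolerance = dpiTolerance))
  else
    do.call(clrNetwork, c(args, zThreshold = zThreshold))
}
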