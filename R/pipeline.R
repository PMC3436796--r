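#' Read a pipeline run configuration
#'
#' YAML configuration with file paths (\code{pkn}, \code{midas},
#' optional \code{pin}), role annotations (\code{stimulated},
#' \code{inhibited}, \code{measured}; inferred from the MIDAS file when
#' omitted), method selection and parameters, and a \code{seed}.
#' Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A named list of configuration values.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) .inputError("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  known <- c("pkn", "midas", "pin", "outputDir", "method", "epsilon",
             "kSigma", "dpiTolerance", "zThreshold", "nBins",
             "maxAndArity", "alpha", "beta", "naFac", "ga", "seed",
             "optimizer")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    .inputError("unknown config keys: %s", paste(unknown, collapse = ", "))
  for (p in c("pkn", "midas", "pin"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      .inputError("config path does not exist: %s", cfg[[p]])
  cfg
}

#' Run the full inference-to-training pipeline
#'
#' Executes infer -> compress -> integrate -> weigh -> train: a
#' data-driven network is inferred from the perturbation data, the
#' prior network is compressed to its identifiable core, DDN links
#' missing from it are integrated and weighted by evidence-weighted
#' shortest paths in the interaction network, the result is expanded
#' into the AND/OR superstructure and trained against the data. Each
#' stage logs its sizes; all randomness derives from \code{seed}.
#'
#' @param pkn a [SignedNetwork-class] or SIF path; role annotations are
#'   taken from the MIDAS design if absent.
#' @param midas a [PerturbationData-class] or MIDAS CSV path.
#' @param pin an [InteractionNetwork-class], PIN TSV path, or
#'   \code{NULL}: without a PIN all integrated links get penalty
#'   weight 1.
#' @param method DDN inference method (see [inferDDN()]).
#' @param epsilon,kSigma,dpiTolerance,zThreshold,nBins inference
#'   parameters.
#' @param maxAndArity AND-gate arity cap for the superstructure.
#' @param params an [objectiveParams()] list (alpha, beta, naFac).
#' @param ga a [gaParams()] list; its seed is overridden by \code{seed}.
#' @param optimizer \code{"ga"} (default) or \code{"exhaustive"}.
#' @param seed master seed for the run.
#' @param verbose log stage summaries via \code{message()}.
#' @return A list of class \code{"pipelineRun"}: \code{ddn},
#'   \code{compressed}, \code{compressionMap}, \code{integrated},
#'   \code{records}, \code{model}, \code{family}, \code{decomposition}
#'   (objective components of the best model) and \code{sizes}.
#' @export
runPipeline <- function(pkn, midas, pin = NULL,
                        method = "feed", epsilon = 0.1, kSigma = 2,
                        dpiTolerance = 0, zThreshold = 2, nBins = 3L,
                        maxAndArity = 2L,
                        params = objectiveParams(), ga = gaParams(),
                        optimizer = c("ga", "exhaustive"),
                        seed = 1L, verbose = TRUE) {
  optimizer <- match.arg(optimizer)
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  if (is.character(midas)) midas <- readMIDAS(midas)
  if (is.character(pkn))
    pkn <- readSIF(pkn, stimulated = midas@stimuli,
                   inhibited = midas@inhibitors,
                   measured = readoutNames(midas))
  if (!length(.cueNodes(pkn)) || !length(pkn@roles$measured))
    pkn <- signedNetwork(pkn@edges, nodes = pkn@nodes,
                         stimulated = midas@stimuli,
                         inhibited = midas@inhibitors,
                         measured = readoutNames(midas))
  if (is.character(pin)) pin <- readPIN(pin)

  ddn <- inferDDN(midas, method = method, epsilon = epsilon,
                  kSigma = kSigma, dpiTolerance = dpiTolerance,
                  zThreshold = zThreshold, nBins = nBins)
  say("[infer] DDN: %d nodes, %d edges (method %s)",
      length(ddn@nodes), nrow(ddn@edges),
      if (is.function(method)) "custom" else method)

  comp <- compressNetwork(pkn)
  say("[compress] %d -> %d nodes, %d -> %d edges",
      length(pkn@nodes), length(comp$network@nodes),
      nrow(pkn@edges), nrow(comp$network@edges))

  intg <- integrateLinks(comp$network, ddn, pkn)
  say("[integrate] %d link(s) integrated", length(intg$records))

  if (!is.null(pin) && length(intg$records)) {
    intg$records <- penaltyWeights(intg$records, pin)
    say("[weigh] reliabilities %s",
        paste(sprintf("%.3g", vapply(intg$records,
                                     function(r) r$reliability, 0)),
              collapse = " "))
  } else if (length(intg$records)) {
    say("[weigh] no PIN supplied: all penalty weights set to 1")
  }

  model <- expandNetwork(intg$network, maxAndArity = maxAndArity)
  say("[expand] superstructure with %d hyperedges over %d species",
      nHyperedges(model), length(model@species))

  ga$seed <- as.integer(seed)
  family <- if (optimizer == "exhaustive") {
    es <- exhaustiveSearch(model, midas, params, intg$records)
    structure(list(best = es, members = list(list(P = es$P,
                                                  score = es$score)),
                   traces = list(), nEvaluated = 2^nHyperedges(model)),
              class = "modelFamily")
  } else gaOptimize(model, midas, params, ga, intg$records)
  dec <- objectiveScore(family$best$P, model, midas, params,
                        intg$records, decompose = TRUE)
  say(paste0("[train] best theta %.6g = fit %.6g + alpha*%.4g ",
             "+ beta*%.4g (%d hyperedges)"),
      dec$theta, dec$thetaF, dec$sizePrior, dec$sizeIntegrated,
      sum(family$best$P))
  structure(list(ddn = ddn, compressed = comp$network,
                 compressionMap = comp$map, integrated = intg$network,
                 records = intg$records, model = model, family = family,
                 decomposition = dec,
                 sizes = list(pknNodes = length(pkn@nodes),
                              pknEdges = nrow(pkn@edges),
                              ddnEdges = nrow(ddn@edges),
                              compressedNodes = length(comp$network@nodes),
                              integratedLinks = length(intg$records),
                              hyperedges = nHyperedges(model))),
            class = "pipelineRun")
}

#' Serialize integrated-link records to JSON
#'
#' @param records integrated-link records.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeRecords <- function(records, path) {
  out <- lapply(records, function(r)
    list(from = r$from, to = r$to, sign = r$sign,
         candidates = r$candidates, novel = r$novel,
         reliability = if (is.finite(r$reliability)) r$reliability
           else if (is.na(r$reliability)) NULL else "Inf",
         weight = r$weight))
  jsonlite::write_json(list(schema = "boolsignet-records/1", records = out),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.pipelineRun <- function(x, ...) {
  s <- x$sizes
  cat(sprintf(paste0("pipelineRun: PKN %d nodes/%d edges; DDN %d edges; ",
                     "%d integrated; %d hyperedges\n"),
              s$pknNodes, s$pknEdges, s$ddnEdges, s$integratedLinks,
              s$hyperedges))
  cat(sprintf("  best theta %.6g (fit %.6g), %d hyperedges selected\n",
              x$decomposition$theta, x$decomposition$thetaF,
              sum(x$family$best$P)))
  invisible(x)
}
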