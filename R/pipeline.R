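#' Run the ancestral-OGT pipeline
#'
#' End-to-end orchestration: (optionally) root the gene tree by minimal
#' ancestor deviation, (optionally) fit the gamma shape and re-estimate
#' branch lengths, reconstruct marginal ancestral profiles, compute each
#' node's CvP bias — both from the MAP ancestral sequence and
#' posterior-weighted — and predict node OGTs through the active
#' calibration. Identical inputs, configuration and seed give byte-identical
#' outputs.
#'
#' @param alignment a [ProteinAlignment-class] of the (gapped) marker
#'   sequences.
#' @param tree \code{ape::phylo}; unrooted when \code{rooting = "mad"}.
#' @param ogtTable optional OGT table ([readOgtTable()] format) used to fit
#'   the calibration when \code{calibration} is NULL. Leaves without a
#'   tabled OGT are allowed.
#' @param calibration a [CalibrationModel-class], the name of a built-in
#'   calibration (e.g. "hua2019"), or NULL to fit from \code{ogtTable}.
#' @param rooting "mad" or "pre-rooted".
#' @param model substitution model name, "LG" (default) or "WAG".
#' @param frequencies "empirical" (+F, default), "model", or numeric(20).
#' @param alpha gamma shape; the string "estimate" requests ML fitting.
#' @param k number of rate categories (default 10).
#' @param optimizeLengths re-estimate branch lengths by ML (default FALSE;
#'   input lengths are kept fixed).
#' @param collapse OGT collapse rule passed to [buildCalibrationPoints()].
#' @param excludePsychrophiles passed to [buildCalibrationPoints()].
#' @param maskGappyColumns drop columns with >= 50 percent gaps from the
#'   ancestral CvP (default FALSE: all columns are used, gap columns being
#'   reconstructed as missing-data posteriors).
#' @param seed integer recorded in output headers (the pipeline itself is
#'   deterministic given its inputs).
#' @param outDir optional output directory; when given, writes the
#'   annotation TSV, annotated Newick, calibration TSV, a JSON run manifest
#'   and a plain-text log.
#' @return An [OgtPipelineResult-class].
#' @seealso [summarizeCladeOgt()], [madRoot()], [marginalAncestralProfiles()]
#' @export
runPipeline <- function(alignment, tree, ogtTable = NULL,
                        calibration = "hua2019",
                        rooting = c("mad", "pre-rooted"),
                        model = c("LG", "WAG"),
                        frequencies = "empirical",
                        alpha = 1, k = 10L,
                        optimizeLengths = FALSE,
                        collapse = 37, excludePsychrophiles = TRUE,
                        maskGappyColumns = FALSE,
                        seed = 0L, outDir = NULL) {
  rooting <- match.arg(rooting)
  model <- match.arg(model)
  logLines <- character()
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...))
    logLines <<- c(logLines, line)
  }
  stopifnot(methods::is(alignment, "ProteinAlignment"))
  validatePhyloTree(tree)
  note("inputs: %d sequences x %d columns, %d leaves; alignment digest %s",
       length(alignmentIds(alignment)), nColumns(alignment),
       ape::Ntip(tree), .digest(sequenceStrings(alignment)))
  note("config: rooting=%s model=%s alpha=%s k=%d optimizeLengths=%s seed=%d",
       rooting, model, paste(alpha, collapse = ""), as.integer(k),
       optimizeLengths, as.integer(seed))

  ## stage: rooting
  ambiguity <- NA_real_
  if (rooting == "mad") {
    mr <- madRoot(tree)
    tree <- mr$tree
    ambiguity <- mr$ambiguity
    note("MAD rooting: best branch %d, x=%.6g, score=%.6g, ambiguity=%.4f",
         mr$candidates$branch[1L], mr$candidates$x[1L],
         mr$candidates$score[1L], ambiguity)
  } else {
    validatePhyloTree(tree, requireRooted = TRUE)
    note("rooting: input tree used as-is (pre-rooted)")
  }

  ## stage: calibration
  points <- NULL
  if (is.character(calibration)) {
    calib <- defaultCalibration(calibration)
    note("calibration: built-in '%s' (slope %.4f, intercept %.4f)",
         calibration, modelSlope(calib), modelIntercept(calib))
  } else if (methods::is(calibration, "CalibrationModel")) {
    calib <- calibration
    note("calibration: user-supplied model")
  } else if (is.null(calibration)) {
    if (is.null(ogtTable))
      stop("either a calibration model or an OGT table is required")
    ogtTable <- validateOgtRecords(ogtTable)
    leafCvp <- cvpBias(alignment)
    seqId <- ifelse(ogtTable$copy_id == "1", ogtTable$taxon,
                    paste(ogtTable$taxon, ogtTable$copy_id, sep = "|"))
    hit <- seqId %in% names(leafCvp)
    if (!any(hit)) stop("no OGT-table taxon matches an alignment id")
    cvps <- data.frame(taxon = ogtTable$taxon[hit],
                       copy_id = ogtTable$copy_id[hit],
                       cvp = unname(leafCvp[seqId[hit]]))
    points <- buildCalibrationPoints(ogtTable[hit, , drop = FALSE], cvps,
                                     collapse = collapse,
                                     excludePsychrophiles = excludePsychrophiles)
    calib <- fitCalibration(points)
    note("calibration: fitted to %d points, slope %.4f, intercept %.4f, R^2 %.4f",
         nPoints(calib), modelSlope(calib), modelIntercept(calib),
         rSquared(calib))
  } else stop("unrecognised calibration argument")

  ## stage: substitution model (+ optional alpha / branch-length fitting)
  freqs <- if (identical(frequencies, "empirical")) alignment
           else if (identical(frequencies, "model")) NULL
           else frequencies
  estAlpha <- identical(alpha, "estimate")
  subModel <- substitutionModel(model, frequencies = freqs,
                                alpha = if (estAlpha) 1 else alpha, k = k)
  if (estAlpha) {
    fit <- estimateAlpha(tree, alignment, subModel)
    subModel <- fit$model
    note("alpha estimated: %.4f (logL %.4f)", fit$alpha, fit$logLik)
  }
  if (optimizeLengths) {
    ob <- optimizeBranchLengths(tree, alignment, subModel)
    tree <- ob$tree
    note("branch lengths re-estimated in %d sweeps (logL %.4f)",
         ob$sweeps, ob$logLik)
  }

  ## stage: ancestral reconstruction
  prof <- marginalAncestralProfiles(tree, alignment, subModel)
  note("marginal reconstruction: %d internal nodes, logL %.4f",
       length(nodeIds(prof)), logLikelihood(prof))

  ## stage: per-node CvP and OGT
  keepCols <- rep(TRUE, nColumns(alignment))
  if (maskGappyColumns) {
    gapFrac <- colMeans(alignmentMatrix(alignment) == "-")
    keepCols <- gapFrac < 0.5
    note("column mask: %d / %d columns kept (<50%% gaps)",
         sum(keepCols), length(keepCols))
  }
  ids <- treeNodeIds(tree)
  n <- ape::Ntip(tree)
  leafCvp <- vapply(tree$tip.label, function(tip) {
    ch <- alignmentMatrix(alignment)[match(tip, alignmentIds(alignment)),
                                     keepCols]
    .cvpChars(ch)
  }, numeric(1L))
  mapCvp <- vapply(nodeIds(prof), function(nd) {
    ch <- strsplit(mapSequences(prof)[[nd]], "")[[1L]][keepCols]
    .cvpChars(ch)
  }, numeric(1L))
  expCvp <- vapply(nodeIds(prof), function(nd)
    expectedCvp(profiles(prof)[[nd]][keepCols, , drop = FALSE]), numeric(1L))
  obsOgt <- rep(NA_real_, n)
  if (!is.null(ogtTable)) {
    ogtTable <- validateOgtRecords(ogtTable)
    seqId <- ifelse(ogtTable$copy_id == "1", ogtTable$taxon,
                    paste(ogtTable$taxon, ogtTable$copy_id, sep = "|"))
    m <- match(tree$tip.label, seqId)
    obsOgt <- ogtTable$ogt_celsius[m]
  }
  ann <- rbind(
    data.frame(node = tree$tip.label, is_leaf = TRUE,
               cvp_map = unname(leafCvp), cvp_expected = unname(leafCvp),
               observed_ogt = obsOgt, stringsAsFactors = FALSE),
    data.frame(node = nodeIds(prof), is_leaf = FALSE,
               cvp_map = unname(mapCvp), cvp_expected = unname(expCvp),
               observed_ogt = NA_real_, stringsAsFactors = FALSE))
  ann$ogt_map <- predictOgt(calib, ann$cvp_map)
  ann$ogt_expected <- predictOgt(calib, ann$cvp_expected)
  ann <- ann[order(match(ann$node, ids[.preorderNodes(tree)])), ,
             drop = FALSE]
  rownames(ann) <- NULL
  note("annotated %d nodes (%d leaves); internal MAP OGT range %.2f-%.2f degC",
       nrow(ann), n, min(ann$ogt_map[!ann$is_leaf]),
       max(ann$ogt_map[!ann$is_leaf]))

  config <- list(rooting = rooting, model = model,
                 frequencies = if (is.numeric(frequencies)) "custom"
                               else frequencies,
                 alpha = if (estAlpha) subModel@alpha else alpha,
                 alphaMode = if (estAlpha) "estimate" else "fixed",
                 k = as.integer(k), optimizeLengths = optimizeLengths,
                 collapse = collapse,
                 excludePsychrophiles = excludePsychrophiles,
                 maskGappyColumns = maskGappyColumns,
                 madAmbiguity = ambiguity, seed = as.integer(seed))
  res <- methods::new("OgtPipelineResult", tree = tree, annotations = ann,
                      calibration = calib, profiles = prof, config = config,
                      log = logLines)
  if (!is.null(outDir)) .writePipelineOutputs(res, points, outDir)
  res
}

## Deterministic short digest of character content (no external deps).
.digest <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

.writePipelineOutputs <- function(res, points, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("seed=%d", res@config$seed)
  num <- vapply(res@annotations, is.numeric, logical(1L))
  ann <- res@annotations
  ann[num] <- lapply(ann[num], function(x) sprintf("%.6f", x))
  writeNodeAnnotations(res@tree, cbind(ann),
                       file.path(outDir, "annotations.tsv"),
                       newickPath = file.path(outDir, "annotated.nwk"),
                       header = hdr)
  writeCalibration(res@calibration, points,
                   file.path(outDir, "calibration.tsv"))
  manifest <- list(package = "thermoasr",
                   version = as.character(utils::packageVersion("thermoasr")),
                   seed = res@config$seed,
                   config = res@config[setdiff(names(res@config), "seed")],
                   n_nodes = nrow(res@annotations),
                   log_digest = .digest(res@log))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(res@log, file.path(outDir, "run.log"))
  invisible(outDir)
}

#' OGT annotation of a clade's most recent common ancestor
#'
#' @param result an [OgtPipelineResult-class].
#' @param leaves character vector of leaf labels selecting the clade.
#' @return one-row data.frame: the MRCA's annotation plus a
#'   \code{spans_root} flag (TRUE when the selector's MRCA is the root).
#' @export
summarizeCladeOgt <- function(result, leaves) {
  stopifnot(methods::is(result, "OgtPipelineResult"))
  if (length(leaves) == 0L) stop("empty clade selector")
  tree <- result@tree
  missing <- setdiff(leaves, tree$tip.label)
  if (length(missing)) stop("selector leaf not in tree: ", missing[1L])
  mrca <- if (length(leaves) == 1L)
    match(leaves, tree$tip.label)
  else ape::getMRCA(tree, leaves)
  id <- treeNodeIds(tree)[mrca]
  out <- result@annotations[result@annotations$node == id, , drop = FALSE]
  out$spans_root <- mrca == ape::Ntip(tree) + 1L
  rownames(out) <- NULL
  out
}
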