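#' Construct a calibration model from coefficients
#'
#' @param slope degC per CvP percentage point.
#' @param intercept degC.
#' @param rSquared squared Pearson correlation of the fit (NA if unknown).
#' @param nPoints number of calibration points (0 if unknown).
#' @param pValue slope p-value diagnostic (NA if unknown).
#' @param note provenance note.
#' @return A [CalibrationModel-class].
#' @export
calibrationModel <- function(slope, intercept, rSquared = NA_real_,
                             nPoints = 0L, pValue = NA_real_,
                             note = "user-supplied") {
  methods::new("CalibrationModel", slope = as.numeric(slope),
               intercept = as.numeric(intercept),
               rSquared = as.numeric(rSquared),
               nPoints = as.integer(nPoints),
               pValue = as.numeric(pValue), note = note)
}

#' Built-in named calibration models
#'
#' \code{"hua2019"} is the published McrABG calibration
#' OGT = 6.7548 * CvP + 13.858 (R^2 = 0.7288), fitted to extant methanogen
#' genomes with known growth optima; its underlying point set is not shipped,
#' so \code{nPoints} is recorded as 0.
#'
#' @param name calibration name; currently only "hua2019".
#' @return A [CalibrationModel-class].
#' @examples
#' predictOgt(defaultCalibration(), 0)   # 13.858
#' @export
defaultCalibration <- function(name = "hua2019") {
  switch(match.arg(name, "hua2019"),
         hua2019 = calibrationModel(6.7548, 13.858, rSquared = 0.7288,
                                    nPoints = 0L,
                                    note = "built-in McrABG calibration (hua2019)"))
}

#' Assemble calibration points from OGT records and CvP values
#'
#' Applies the corrections used when calibrating CvP against known OGTs:
#' psychrophiles are excluded (they adapt by a different mechanism), every
#' (taxon, gene copy) contributes its own provisional point (species with
#' two gene copies enter twice with the same OGT), and the over-represented
#' group at the collapse temperature (default 37 degC, the mesophile pile-up)
#' is replaced by a single point at its mean CvP.
#'
#' @param records data.frame of OGT records ([readOgtTable()] format).
#' @param cvps data.frame with columns taxon, copy_id (optional, default
#'   "1") and cvp, or a named numeric vector (names = taxon, copies implied
#'   "1").
#' @param collapse numeric vector of OGT values whose groups are collapsed
#'   to one averaged point (default 37), or \code{"duplicates"} to collapse
#'   every OGT value shared by more than one provisional point, or
#'   \code{NULL} for no collapsing.
#' @param excludePsychrophiles drop records flagged as psychrophiles
#'   (default TRUE).
#' @return data.frame of points with columns cvp, ogt, n_sources, sources,
#'   sorted by ogt then cvp.
#' @seealso [fitCalibration()]
#' @export
buildCalibrationPoints <- function(records, cvps, collapse = 37,
                                   excludePsychrophiles = TRUE) {
  records <- validateOgtRecords(records)
  if (is.numeric(cvps) && !is.null(names(cvps)))
    cvps <- data.frame(taxon = names(cvps), copy_id = "1", cvp = unname(cvps),
                       stringsAsFactors = FALSE)
  if (!all(c("taxon", "cvp") %in% names(cvps)))
    stop("cvps must provide taxon and cvp")
  if (is.null(cvps$copy_id)) cvps$copy_id <- "1"
  if (any(abs(cvps$cvp) > 100)) stop("CvP outside [-100, 100]")
  if (excludePsychrophiles)
    records <- records[!records$psychrophile, , drop = FALSE]
  key <- function(t, c) paste(t, c, sep = "\r")
  idx <- match(key(records$taxon, records$copy_id),
               key(cvps$taxon, cvps$copy_id))
  if (anyNA(idx))
    stop("no CvP value for (taxon, copy_id): ",
         records$taxon[which(is.na(idx))[1L]])
  pts <- data.frame(cvp = cvps$cvp[idx], ogt = records$ogt_celsius,
                    n_sources = 1L,
                    sources = paste(records$taxon, records$copy_id, sep = ":"),
                    stringsAsFactors = FALSE)
  if (nrow(pts) == 0L) stop("no calibration points remain")
  collapseSet <- if (is.null(collapse)) numeric() else if (
    identical(collapse, "duplicates")) {
    as.numeric(names(which(table(pts$ogt) > 1L)))
  } else as.numeric(collapse)
  for (tv in collapseSet) {
    grp <- pts$ogt == tv
    if (sum(grp) > 1L) {
      merged <- data.frame(cvp = mean(pts$cvp[grp]), ogt = tv,
                           n_sources = sum(grp),
                           sources = paste(sort(pts$sources[grp]),
                                           collapse = ";"),
                           stringsAsFactors = FALSE)
      pts <- rbind(pts[!grp, , drop = FALSE], merged)
    }
  }
  pts <- pts[order(pts$ogt, pts$cvp, pts$sources), , drop = FALSE]
  rownames(pts) <- NULL
  pts
}

#' Fit the linear CvP-to-OGT calibration
#'
#' Ordinary least squares of OGT (degC) on CvP bias (percentage points).
#' R^2 is the squared Pearson correlation; the slope's two-sided t-test
#' p-value is kept as a diagnostic.
#'
#' @param points data.frame with columns cvp and ogt
#'   (see [buildCalibrationPoints()]).
#' @return A [CalibrationModel-class].
#' @export
fitCalibration <- function(points) {
  if (!all(c("cvp", "ogt") %in% names(points)))
    stop("points must have columns cvp and ogt")
  if (nrow(points) < 3L)
    stop("insufficient data: at least 3 calibration points required")
  if (length(unique(points$cvp)) < 2L)
    stop("singular fit: all CvP values identical")
  fit <- stats::lm(ogt ~ cvp, data = points)
  sm <- suppressWarnings(summary(fit))  # perfect fits trip summary.lm
  r2 <- stats::cor(points$cvp, points$ogt)^2
  calibrationModel(stats::coef(fit)[["cvp"]], stats::coef(fit)[["(Intercept)"]],
                   rSquared = r2, nPoints = nrow(points),
                   pValue = sm$coefficients["cvp", "Pr(>|t|)"],
                   note = sprintf("OLS fit to %d points", nrow(points)))
}

#' Predict optimal growth temperature from CvP bias
#'
#' @param model a [CalibrationModel-class].
#' @param cvp CvP bias in percentage points (vectorised).
#' @return Predicted OGT in degC.
#' @examples
#' predictOgt(defaultCalibration(), 10)  # 81.406
#' @export
predictOgt <- function(model, cvp) {
  stopifnot(methods::is(model, "CalibrationModel"))
  if (any(!is.finite(cvp))) stop("non-finite CvP value")
  model@slope * cvp + model@intercept
}

#' Export calibration points and coefficients as TSV
#'
#' @param model a [CalibrationModel-class].
#' @param points the point set the model was fitted to (may be NULL).
#' @param path output TSV.
#' @return Invisibly, \code{path}.
#' @export
writeCalibration <- function(model, points, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# slope\t%.10g", model@slope), con)
  writeLines(sprintf("# intercept\t%.10g", model@intercept), con)
  writeLines(sprintf("# r_squared\t%.10g", model@rSquared), con)
  writeLines(sprintf("# n_points\t%d", model@nPoints), con)
  writeLines(sprintf("# note\t%s", model@note), con)
  if (!is.null(points))
    utils::write.table(points, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
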