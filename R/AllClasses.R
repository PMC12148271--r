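#' @import methods
#' @import stats
#' @importFrom utils capture.output head read.delim tail write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
NULL

#' Scan-level imaging data container
#'
#' `ScanSet` wraps a [SummarizedExperiment::SummarizedExperiment] holding one
#' assay, `volumes` (ROIs in rows, imaging visits in columns, mm^3), with
#' per-visit phenotypes (`pid`, `study`, `scanner`, `visit`, `age`, `sex`,
#' `hand`, `group`) in `colData`. Volumes must be strictly positive and the
#' group label one of `HC`, `SUD` or `excluded` (substance-specific labels
#' such as `SUD:alcohol` are also accepted).
#'
#' @slot se-inherited see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("ScanSet", contains = "SummarizedExperiment")

.scanCols <- c("pid", "study", "scanner", "visit", "age", "sex", "hand", "group")

setValidity("ScanSet", function(object) {
  msg <- character()
  if (!"volumes" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'volumes' is required")
  else if (any(SummarizedExperiment::assay(object, "volumes") <= 0, na.rm = TRUE))
    msg <- c(msg, "ROI volumes must be strictly positive")
  miss <- setdiff(.scanCols, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste("missing colData columns:", paste(miss, collapse = ", ")))
  if ("group" %in% colnames(SummarizedExperiment::colData(object))) {
    g <- as.character(object$group)
    ok <- g %in% c("HC", "excluded") | startsWith(g, "SUD")
    if (!all(ok)) msg <- c(msg, "group must be 'HC', 'SUD[:substance]' or 'excluded'")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted generalized-gamma normative model for one ROI
#'
#' Location is modeled on the log scale as a fractional polynomial of age plus
#' sex, handedness and optional per-study offsets; log dispersion is a
#' fractional polynomial of age; the power-shape parameter nu is constant.
#'
#' @slot roi ROI name.
#' @slot powersMu,powersSigma fractional-polynomial power multisets (from
#'   \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}) for the location and dispersion bases.
#' @slot coefMu,coefSigma named numeric coefficient vectors.
#' @slot nu numeric(1), constant power-shape.
#' @slot hasStudyOffsets logical(1).
#' @slot studyLevels character, study factor levels seen in training.
#' @slot logLik,bic,nTrain fit summaries; BIC = -2 logLik + k log(nTrain).
#' @slot converged logical(1) optimizer status.
#' @slot ageRange numeric(2), training age span (years); scoring outside it is
#'   flagged as extrapolated.
#' @slot searchLog data.frame, one row per candidate model in the BIC search.
#' @export
setClass("GGNormativeModel", representation(
  roi = "character", powersMu = "numeric", powersSigma = "numeric",
  coefMu = "numeric", coefSigma = "numeric", nu = "numeric",
  hasStudyOffsets = "logical", studyLevels = "character",
  logLik = "numeric", bic = "numeric", nTrain = "integer",
  converged = "logical", ageRange = "numeric", searchLog = "data.frame"))

setValidity("GGNormativeModel", function(object) {
  msg <- character()
  if (length(object@nu) != 1L || !is.finite(object@nu))
    msg <- c(msg, "nu must be a single finite number")
  kk <- length(object@coefMu) + length(object@coefSigma) + 1L
  if (abs(object@bic - (-2 * object@logLik + kk * log(object@nTrain))) > 1e-6)
    msg <- c(msg, "BIC inconsistent with logLik, parameter count and nTrain")
  if (nrow(object@searchLog) && object@bic > min(object@searchLog$bic) + 1e-8)
    msg <- c(msg, "selected BIC exceeds the best candidate in the search log")
  if (length(msg)) msg else TRUE
})

#' Age-grid divergence between SUD and HC trajectories for one ROI
#'
#' Holds pointwise group means and standard errors on the 8--70y grid
#' (step 0.05y, 1241 points), the two-sided z statistic
#' z(a) = (m_SUD - m_HC) / sqrt(se_SUD^2 + se_HC^2), its p-value, the
#' Benjamini-Hochberg q-value computed across grid points within the ROI, and
#' the maximal significant age windows (q < alpha).
#'
#' @slot roi ROI name.
#' @slot ages numeric grid of ages (years).
#' @slot mHC,seHC,mSUD,seSUD pointwise trajectory means / standard errors.
#' @slot z,p,q pointwise statistics.
#' @slot valid logical; FALSE where either trajectory is extrapolated
#'   (excluded from window calling).
#' @slot windows data.frame with columns `lo`, `hi` (years), disjoint.
#' @slot alpha significance level used for window calling.
#' @export
setClass("DivergenceGrid", representation(
  roi = "character", ages = "numeric", mHC = "numeric", seHC = "numeric",
  mSUD = "numeric", seSUD = "numeric", z = "numeric", p = "numeric",
  q = "numeric", valid = "logical", windows = "data.frame", alpha = "numeric"))

setValidity("DivergenceGrid", function(object) {
  msg <- character()
  n <- length(object@ages)
  for (s in c("mHC", "seHC", "mSUD", "seSUD", "z", "p", "q", "valid"))
    if (length(slot(object, s)) != n)
      msg <- c(msg, paste0("slot '", s, "' must match the age grid length"))
  ok <- object@valid & is.finite(object@q)
  if (any(object@q[ok] + 1e-12 < object@p[ok]))
    msg <- c(msg, "q-values must be >= p-values")
  w <- object@windows
  if (nrow(w) > 1 && any(w$lo[-1] <= w$hi[-nrow(w)]))
    msg <- c(msg, "significant windows must be disjoint and ordered")
  if (length(msg)) msg else TRUE
})

#' Varimax factor decomposition of a term-by-parcel atlas
#'
#' @slot loadings terms x factors matrix after varimax rotation.
#' @slot maps parcels x factors matrix of factor-level brain maps (regression
#'   scores computed from the retained loadings).
#' @slot varFrac fraction of total variance explained by each retained factor
#'   (each > the retention threshold).
#' @slot mask logical terms x factors matrix; TRUE where the term passes both
#'   loading filters (|loading| > 0.2 and >= the factor-wise median).
#' @slot rotation varimax rotation matrix (orthogonal).
#' @slot threshold variance-fraction retention threshold.
#' @export
setClass("AtlasFactorSet", representation(
  loadings = "matrix", maps = "matrix", varFrac = "numeric",
  mask = "matrix", rotation = "matrix", threshold = "numeric"))

setValidity("AtlasFactorSet", function(object) {
  msg <- character()
  if (ncol(object@loadings) != length(object@varFrac))
    msg <- c(msg, "one variance fraction per factor required")
  if (any(object@varFrac <= object@threshold))
    msg <- c(msg, "retained factors must exceed the variance threshold")
  R <- object@rotation
  if (nrow(R) && max(abs(crossprod(R) - diag(ncol(R)))) > 1e-6)
    msg <- c(msg, "rotation matrix must be orthogonal")
  if (length(msg)) msg else TRUE
})
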