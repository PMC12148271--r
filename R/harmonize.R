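#' Exclude gross volumetric outliers
#'
#' Drops any scan whose volume in ANY ROI falls outside
#' \[Q1 - k IQR, Q3 + k IQR\] (default k = 4) computed over the retained
#' population, and reports per-ROI exclusion counts.
#'
#' @param scans scan table or `ScanSet`.
#' @param k IQR multiplier.
#' @return the filtered scan table, with attribute `qc` (per-ROI counts).
#' @export
qcExcludeOutliers <- function(scans, k = 4) {
  df <- .scanFrame(scans)
  roiCols <- .roiCols(df)
  if (nrow(df) < 8) stop("need at least 8 records to form quartiles")
  drop <- rep(FALSE, nrow(df))
  counts <- setNames(integer(length(roiCols)), roiCols)
  for (rc in roiCols) {
    v <- df[[rc]]
    qs <- quantile(v, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    iqr <- qs[2] - qs[1]
    bad <- v < qs[1] - k * iqr | v > qs[2] + k * iqr
    counts[rc] <- sum(bad, na.rm = TRUE)
    drop <- drop | (bad & !is.na(bad))
  }
  if (all(drop)) stop("outlier rule would exclude every scan")
  out <- df[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc") <- data.frame(roi = roiCols, excluded = as.integer(counts))
  out
}

#' Empirical-Bayes scanner harmonization
#'
#' Location/scale batch adjustment of ROI volumes via ComBat: volumes are
#' standardized on a covariate fit, per-batch means and variances are shrunk
#' toward pooled priors and removed, and the data are back-transformed;
#' covariate-associated variation is preserved. A single batch is returned
#' unchanged; a batch with (near) zero residual variance triggers a
#' mean-only adjustment with a warning.
#'
#' @param volumes numeric matrix, scans x ROIs (strictly positive).
#' @param batch batch (scanner) label per scan.
#' @param covariates optional data.frame of biological covariates to protect
#'   (e.g. age, sex).
#' @return adjusted matrix of the same shape.
#' @export
combatAdjust <- function(volumes, batch, covariates = NULL) {
  volumes <- as.matrix(volumes)
  batch <- as.factor(batch)
  if (any(table(batch) < 2)) stop("every batch needs at least 2 records")
  if (nlevels(batch) < 2) return(volumes)
  mod <- NULL
  if (!is.null(covariates))
    mod <- model.matrix(~ ., data = as.data.frame(covariates))
  meanOnly <- FALSE
  resVar <- vapply(levels(batch), function(b) {
    v <- volumes[batch == b, , drop = FALSE]
    min(apply(v, 2, var))
  }, numeric(1))
  if (any(resVar < 1e-12)) {
    warning("batch with zero variance: falling back to mean-only adjustment")
    meanOnly <- TRUE
  }
  out <- suppressMessages(
    sva::ComBat(dat = t(volumes), batch = batch, mod = mod,
                par.prior = TRUE, mean.only = meanOnly))
  t(out)
}

#' One cross-sectional visit per participant, frequency-weighted
#'
#' For participants with several visits, samples one visit with probability
#' proportional to the reciprocal of the frequency of that visit's age bin in
#' the pooled distribution (normalized per participant), so over-represented
#' ages are down-weighted. Deterministic under `seed`.
#'
#' @param scans scan table or `ScanSet` (possibly longitudinal).
#' @param seed RNG seed.
#' @param binWidth age bin width in years.
#' @return cross-sectional scan table (one row per `pid`).
#' @export
sampleOneVisit <- function(scans, seed = 1L, binWidth = 1) {
  df <- .scanFrame(scans)
  set.seed(seed)
  bins <- floor(df$age / binWidth)
  freq <- table(bins)
  w <- as.numeric(1 / freq[as.character(bins)])
  if (any(!is.finite(w))) {
    warning("empty age bin: uniform fallback for affected visits")
    w[!is.finite(w)] <- 1
  }
  keep <- unlist(lapply(split(seq_len(nrow(df)), df$pid), function(idx) {
    if (length(idx) == 1L) return(idx)
    p <- w[idx] / sum(w[idx])
    idx[sample.int(length(idx), 1L, prob = p)]
  }), use.names = FALSE)
  out <- df[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
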