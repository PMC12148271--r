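#' Longitudinal change-rate comparison between groups
#'
#' Computes each participant's per-year volume change between first and last
#' visit (optionally as percent of the baseline volume) and regresses it on
#' group, baseline age and sex; the coefficient on group estimates the extra
#' annual change in SUD relative to HC.
#'
#' @param scans longitudinal scan table or `ScanSet` (>= 2 visits for
#'   included participants).
#' @param roi ROI column.
#' @param percent express change as percent of baseline volume per year.
#' @return list with `estimate`, `se`, `p`, `n`.
#' @export
longitudinalChangeRate <- function(scans, roi, percent = TRUE) {
  df <- .scanFrame(scans)
  df <- df[order(df$pid, df$visit), ]
  multi <- names(which(table(df$pid) >= 2))
  if (!length(multi)) stop("no participants with follow-up visits")
  df <- df[df$pid %in% multi, ]
  firstIdx <- !duplicated(df$pid)
  lastIdx <- !duplicated(df$pid, fromLast = TRUE)
  b <- df[firstIdx, ]; f <- df[lastIdx, ]
  dt <- f$age - b$age
  rate <- (f[[roi]] - b[[roi]]) / dt
  if (percent) rate <- 100 * rate / b[[roi]]
  grp <- as.integer(startsWith(b$group, "SUD"))
  fit <- lm(rate ~ grp + age + sex, data = data.frame(
    rate = rate, grp = grp, age = b$age, sex = b$sex))
  sm <- summary(fit)$coefficients["grp", ]
  list(estimate = unname(sm[1]), se = unname(sm[2]), p = unname(sm[4]),
       n = length(rate))
}

#' Inverse-variance weighted meta-analysis
#'
#' Pooled estimate sum(w m)/sum(w) with w = 1/se^2 and pooled
#' SE = 1/sqrt(sum(w)).
#'
#' @param estimates,ses numeric vectors of matching length, `ses > 0`.
#' @return list with `estimate` and `se`.
#' @examples
#' ivwMeta(c(1, 3), c(1, 1))   # 2.0, 0.7071
#' @export
ivwMeta <- function(estimates, ses) {
  if (length(estimates) != length(ses)) stop("length mismatch")
  if (any(ses <= 0)) stop("standard errors must be > 0")
  w <- 1 / ses^2
  list(estimate = sum(w * estimates) / sum(w), se = 1 / sqrt(sum(w)))
}

#' Spearman consistency of discovery and validation z-curves
#'
#' Rank correlation of the two differential z-statistics over the
#' overlapping age span; fewer than 3 overlapping points gives NA.
#'
#' @param zDiscovery,zValidation numeric z-curves.
#' @param ages common age grid for both curves.
#' @param overlap optional age range (lo, hi) restricting the comparison.
#' @return Spearman correlation (NA when undefined).
#' @export
consistencyCorrelation <- function(zDiscovery, zValidation, ages = NULL,
                                   overlap = NULL) {
  ok <- is.finite(zDiscovery) & is.finite(zValidation)
  if (!is.null(overlap) && !is.null(ages))
    ok <- ok & ages >= overlap[1] & ages <= overlap[2]
  if (sum(ok) < 3) return(NA_real_)
  cor(zDiscovery[ok], zValidation[ok], method = "spearman")
}

#' Hierarchical clustering of ROI centile patterns
#'
#' Agglomerative clustering of ROIs with correlation distance (1 - r) and
#' average linkage; constant ROI columns (undefined distance) are dropped
#' with a warning.
#'
#' @param centiles scans x ROIs matrix (e.g. from [centileMatrix()]).
#' @param k optional number of clusters for the cut.
#' @param h optional cut height (used when `k` is missing).
#' @return list with the `hclust` tree, `labels` (if cut) and `dropped` ROI
#'   names.
#' @export
clusterCentilePatterns <- function(centiles, k = NULL, h = NULL) {
  centiles <- as.matrix(centiles)
  if (ncol(centiles) == 1L)
    return(list(tree = NULL,
                labels = setNames(1L, colnames(centiles)),
                dropped = character(0)))
  sds <- apply(centiles, 2, sd, na.rm = TRUE)
  dropped <- colnames(centiles)[sds < 1e-12 | is.na(sds)]
  if (length(dropped)) {
    warning("constant ROI column(s) dropped: ",
            paste(dropped, collapse = ", "))
    centiles <- centiles[, !(colnames(centiles) %in% dropped), drop = FALSE]
  }
  d <- as.dist(1 - cor(centiles, use = "pairwise.complete.obs"))
  tree <- hclust(d, method = "average")
  labels <- NULL
  if (!is.null(k)) labels <- cutree(tree, k = k)
  else if (!is.null(h)) labels <- cutree(tree, h = h)
  list(tree = tree, labels = labels, dropped = dropped)
}
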