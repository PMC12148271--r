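#' Remove confounder effects from volumes
#'
#' Linear adjustment for sex, handedness and study, fitted pooled across
#' groups (confounder effects are assumed independent of substance-use
#' status); returns residuals plus the grand mean, so the location of the
#' data is preserved. Aliased columns in a rank-deficient design are dropped
#' with a warning.
#'
#' @param values numeric vector (one ROI's volumes).
#' @param covariates data.frame of confounders (e.g. sex, hand, study).
#' @return adjusted numeric vector.
#' @export
adjustCovariates <- function(values, covariates) {
  covariates <- as.data.frame(covariates)
  if (anyNA(covariates)) stop("covariates must be complete")
  constant <- vapply(covariates, function(v) length(unique(v)) < 2, logical(1))
  covariates <- covariates[!constant]
  if (!ncol(covariates)) return(values)
  X <- model.matrix(~ ., data = covariates)
  fit <- lm.fit(X, values)
  if (any(is.na(fit$coefficients))) {
    warning("rank-deficient covariate design; aliased column(s) dropped")
    keep <- !is.na(fit$coefficients)
    fit <- lm.fit(X[, keep, drop = FALSE], values)
  }
  fit$residuals + mean(values)
}

#' Fit a group-level age trajectory on a natural cubic spline basis
#'
#' Least-squares fit with K interior knots placed at equally spaced age
#' quantiles of the group (default K = 3: quartile knots). The pointwise
#' standard error comes from the coefficient covariance,
#' se(a) = sqrt(x(a)' V x(a)).
#'
#' @param values covariate-adjusted volumes.
#' @param ages ages in years.
#' @param group group label stored with the fit.
#' @param K number of interior knots.
#' @return object of class `groupTrajectory`: evaluable via [predict()] at
#'   any age, returning `mean` and `se`.
#' @export
fitGroupTrajectory <- function(values, ages, group = "HC", K = 3L) {
  if (length(values) < 30) stop("need at least 30 records per group")
  if (diff(range(ages)) == 0) stop("all ages identical; trajectory undefined")
  probs <- seq(0, 1, length.out = K + 2L)[2:(K + 1L)]
  knots <- unique(quantile(ages, probs, names = FALSE))
  bound <- range(ages)
  X <- cbind(1, splines::ns(ages, knots = knots, Boundary.knots = bound))
  fit <- lm.fit(X, values)
  rss <- sum(fit$residuals^2)
  dfres <- length(values) - ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  V <- XtXinv * rss / dfres
  structure(list(coef = fit$coefficients, vcov = V, knots = knots,
                 boundary = bound, group = group,
                 ageRange = range(ages), n = length(values)),
            class = "groupTrajectory")
}

#' @rdname fitGroupTrajectory
#' @param object a `groupTrajectory`.
#' @param ages ages at which to evaluate.
#' @param ... unused.
#' @export
predict.groupTrajectory <- function(object, ages, ...) {
  X <- cbind(1, splines::ns(ages, knots = object$knots,
                            Boundary.knots = object$boundary))
  m <- drop(X %*% object$coef)
  se <- sqrt(rowSums((X %*% object$vcov) * X))
  data.frame(age = ages, mean = m, se = se,
             extrapolated = ages < object$ageRange[1] |
               ages > object$ageRange[2])
}

#' Age-grid divergence between SUD and HC trajectories
#'
#' Evaluates both trajectories on the 8-70y grid (step 0.05y, 1241 points),
#' forms z(a) = (m_SUD - m_HC)/sqrt(se_SUD^2 + se_HC^2) with a two-sided
#' normal p-value, applies Benjamini-Hochberg FDR across the grid points
#' within the ROI, and reports maximal runs of q < alpha as significant age
#' windows. Grid points where either trajectory is extrapolated beyond its
#' group's observed age span are flagged invalid and excluded from window
#' calling.
#'
#' @param trajSUD,trajHC `groupTrajectory` fits for the two groups.
#' @param roi ROI name.
#' @param ages evaluation grid.
#' @param alpha window-calling threshold on q.
#' @return a [DivergenceGrid-class] object.
#' @export
divergenceGrid <- function(trajSUD, trajHC, roi = "roi",
                           ages = seq(8, 70, by = 0.05), alpha = 0.05) {
  if (missing(trajSUD) || missing(trajHC) || is.null(trajSUD) ||
      is.null(trajHC)) stop("both group trajectories are required")
  pS <- predict(trajSUD, ages)
  pH <- predict(trajHC, ages)
  z <- (pS$mean - pH$mean) / sqrt(pS$se^2 + pH$se^2)
  p <- 2 * pnorm(-abs(z))
  valid <- !(pS$extrapolated | pH$extrapolated)
  q <- rep(NA_real_, length(p))
  q[valid] <- bhFdr(p[valid])
  sig <- valid & !is.na(q) & q < alpha
  windows <- .runsToWindows(ages, sig)
  new("DivergenceGrid", roi = roi, ages = ages,
      mHC = pH$mean, seHC = pH$se, mSUD = pS$mean, seSUD = pS$se,
      z = z, p = p, q = q, valid = valid, windows = windows, alpha = alpha)
}

.runsToWindows <- function(ages, sig) {
  if (!any(sig)) return(data.frame(lo = numeric(0), hi = numeric(0)))
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(lo = ages[starts[keep]], hi = ages[ends[keep]])
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p p-values in \[0, 1\] (NA passed through).
#' @return q-values of the same length; empty input gives empty output.
#' @export
bhFdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Smoothed signed significance trajectory
#'
#' Fits a cubic smoothing spline to the signed significance curve
#' `-log10(q(a)) * sign(z(a))` of a divergence grid and reports the ages at
#' which the smooth crosses the `-log10(alpha)` level (window edges).
#'
#' @param grid a [DivergenceGrid-class].
#' @param df effective degrees of freedom of the smoother.
#' @return list with `ages`, `raw`, `smooth` and `crossings` (years).
#' @export
significanceTrajectory <- function(grid, df = 20) {
  a <- grid@ages[grid@valid]
  y <- -log10(pmax(grid@q[grid@valid], 1e-300)) * sign(grid@z[grid@valid])
  if (all(abs(y) < 1e-12)) {
    return(list(ages = a, raw = y, smooth = rep(0, length(y)),
                crossings = numeric(0)))
  }
  fit <- smooth.spline(a, y, df = min(df, length(a) - 1))
  s <- predict(fit, a)$y
  lev <- -log10(grid@alpha)
  above <- abs(s) > lev
  cross <- which(diff(above) != 0)
  crossings <- (a[cross] + a[cross + 1L]) / 2
  list(ages = a, raw = y, smooth = s, crossings = crossings)
}

#' One-call SUD-vs-HC divergence for one ROI
#'
#' Convenience wrapper: adjusts the ROI volumes for sex, handedness and
#' study, fits per-group natural-spline trajectories and returns the
#' [DivergenceGrid-class]. Group labels starting with `"SUD"` count as SUD;
#' with `subgroup` given, only `SUD:<subgroup>` rows enter the SUD arm
#' (substance-specific reruns share this code path).
#'
#' @param scans scan table or `ScanSet`.
#' @param roi ROI column.
#' @param subgroup optional substance label.
#' @param K interior knots for the trajectories.
#' @param ages evaluation grid.
#' @param alpha window threshold.
#' @return a [DivergenceGrid-class].
#' @export
roiDivergence <- function(scans, roi, subgroup = NULL, K = 3L,
                          ages = seq(8, 70, by = 0.05), alpha = 0.05) {
  df <- .scanFrame(scans)
  isSud <- if (is.null(subgroup)) startsWith(df$group, "SUD")
           else df$group == paste0("SUD:", subgroup)
  isHc <- df$group == "HC"
  use <- isSud | isHc
  df <- df[use, , drop = FALSE]
  isSud <- isSud[use]
  adj <- adjustCovariates(df[[roi]],
                          df[c("sex", "hand", "study")])
  tS <- fitGroupTrajectory(adj[isSud], df$age[isSud], "SUD", K = K)
  tH <- fitGroupTrajectory(adj[!isSud], df$age[!isSud], "HC", K = K)
  divergenceGrid(tS, tH, roi = roi, ages = ages, alpha = alpha)
}

#' @rdname DivergenceGrid-class
#' @param x,object a `DivergenceGrid`.
#' @export
setMethod("gridAges", "DivergenceGrid", function(x) x@ages)

#' @rdname DivergenceGrid-class
#' @export
setMethod("zStat", "DivergenceGrid", function(x) x@z)

#' @rdname DivergenceGrid-class
#' @export
setMethod("qValue", "DivergenceGrid", function(x) x@q)

#' @rdname DivergenceGrid-class
#' @export
setMethod("sigWindows", "DivergenceGrid", function(x) x@windows)

#' @rdname DivergenceGrid-class
#' @export
setMethod("show", "DivergenceGrid", function(object) {
  cat("DivergenceGrid for", object@roi, ":",
      length(object@ages), "grid ages\n")
  cat("  max |z| =", round(max(abs(object@z[object@valid])), 2),
      " min q =", signif(suppressWarnings(
        min(object@q[object@valid], na.rm = TRUE)), 3), "\n")
  w <- object@windows
  if (nrow(w))
    cat("  significant windows:",
        paste(sprintf("[%.2f, %.2f]", w$lo, w$hi), collapse = " "), "\n")
  else cat("  no significant windows\n")
})

#' Export a divergence grid as a tidy table
#'
#' @param grid a [DivergenceGrid-class].
#' @return data.frame with columns roi, age, m_hc, se_hc, m_sud, se_sud,
#'   z, p, q.
#' @export
divergenceTable <- function(grid) {
  data.frame(roi = grid@roi, age = grid@ages, m_hc = grid@mHC,
             se_hc = grid@seHC, m_sud = grid@mSUD, se_sud = grid@seSUD,
             z = grid@z, p = grid@p, q = grid@q)
}
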