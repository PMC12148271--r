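#' Covariate-adjusted group comparison of behavioral scores
#'
#' For each score column: linear model `score ~ group + covariates`;
#' Cohen's d = adjusted group difference / residual SD, two-sided p, and
#' Benjamini-Hochberg q across the scores. With `downsample = TRUE`
#' (for severe class imbalance) the HC group is subsampled to the SUD size
#' `R` times and the median d/p reported.
#'
#' @param scores data.frame (or matrix) of score columns; NAs allowed.
#' @param groups group labels (`HC` / `SUD*`).
#' @param covariates data.frame of covariates (e.g. age, sex, hand).
#' @param downsample logical.
#' @param R downsampling repeats.
#' @param seed RNG seed used when downsampling.
#' @return data.frame: `score`, `d`, `se`, `p`, `q`, `n`.
#' @export
groupCompare <- function(scores, groups, covariates = NULL,
                         downsample = FALSE, R = 1000L, seed = 1L) {
  scores <- as.data.frame(scores)
  isSud <- startsWith(as.character(groups), "SUD")
  if (!any(isSud) || all(isSud)) stop("both groups must be non-empty")
  one <- function(y, keep) {
    ok <- keep & !is.na(y)
    g <- as.integer(isSud[ok])
    X <- cbind(1, g)
    if (!is.null(covariates))
      X <- cbind(X, model.matrix(~ . - 1, data =
                                   as.data.frame(covariates)[ok, , drop = FALSE]))
    fit <- lm.fit(X, y[ok])
    rdf <- sum(ok) - qr(X)$rank
    sdRes <- sqrt(sum(fit$residuals^2) / rdf)
    if (sdRes < 1e-12) return(c(NA, NA, NA, sum(ok)))
    XtXinv <- tryCatch(chol2inv(chol(crossprod(X))), error = function(e) NULL)
    if (is.null(XtXinv)) return(c(NA, NA, NA, sum(ok)))
    beta <- fit$coefficients[2]
    seB <- sdRes * sqrt(XtXinv[2, 2])
    p <- 2 * pt(-abs(beta / seB), rdf)
    c(beta / sdRes, seB / sdRes, p, sum(ok))
  }
  res <- lapply(names(scores), function(sc) {
    y <- scores[[sc]]
    if (!downsample) {
      v <- one(y, rep(TRUE, length(y)))
    } else {
      set.seed(seed)
      hcIdx <- which(!isSud & !is.na(y))
      nS <- sum(isSud & !is.na(y))
      reps <- vapply(seq_len(R), function(r) {
        keep <- isSud
        keep[sample(hcIdx, min(nS, length(hcIdx)))] <- TRUE
        one(y, keep)
      }, numeric(4))
      v <- c(apply(reps[1:3, , drop = FALSE], 1, median), reps[4, 1])
    }
    data.frame(score = sc, d = v[1], se = v[2], p = v[3], n = v[4])
  })
  out <- do.call(rbind, res)
  out$q <- bhFdr(out$p)
  rownames(out) <- NULL
  out
}

#' Age-by-group interaction model for a behavioral score
#'
#' `score ~ age + group + age:group + sex + hand`; returns the interaction
#' coefficient (per year), its model-based SE and p-value.
#'
#' @param score numeric vector.
#' @param groups group labels.
#' @param age ages in years.
#' @param sex,hand optional covariates.
#' @return list with `coef`, `se`, `p`.
#' @export
interactionModel <- function(score, groups, age, sex = NULL, hand = NULL) {
  if (diff(range(age)) == 0) stop("age spread is zero")
  g <- as.integer(startsWith(as.character(groups), "SUD"))
  dat <- data.frame(score = score, age = age, g = g)
  form <- score ~ age * g
  if (!is.null(sex)) { dat$sex <- sex; form <- update(form, . ~ . + sex) }
  if (!is.null(hand)) { dat$hand <- hand; form <- update(form, . ~ . + hand) }
  X <- model.matrix(form, dat)
  kap <- kappa(X, exact = TRUE)
  if (kap > 1e10)
    stop("collinear design (condition number ", format(kap, digits = 3), ")")
  fit <- lm(form, data = dat)
  sm <- summary(fit)$coefficients["age:g", ]
  list(coef = unname(sm[1]), se = unname(sm[2]), p = unname(sm[4]))
}

#' Extract common behavioral factors
#'
#' Principal-axis factor analysis of the instrument correlation matrix:
#' the number of retained factors equals the number of eigenvalues of the
#' correlation matrix above 1, loadings are varimax-rotated, and scores are
#' computed by the regression method (standardized, sign-fixed so the
#' maximum-loading instrument loads positively). Factors are labeled by the
#' construct of their maximum-loading instrument when an
#' instrument-to-construct map is given.
#'
#' @param block data.frame/matrix of instrument scores (one study block).
#' @param labels optional named character vector mapping instrument column
#'   names to construct labels (e.g. `"rule_breaking"`, `"impulsivity"`).
#' @param maxIter,tol principal-axis iteration controls.
#' @return list: `scores` (n x factors, unit variance), `loadings`,
#'   `eigenvalues`, `nFactors`. Zero retained factors gives empty scores.
#' @export
extractCommonFactors <- function(block, labels = NULL, maxIter = 100L,
                                 tol = 1e-6) {
  X <- as.matrix(block)
  if (ncol(X) < 2) stop("need at least 2 instruments")
  R <- cor(X, use = "pairwise.complete.obs")
  if (anyNA(R)) stop("pairwise-complete correlations not estimable")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    warning("correlation matrix not positive definite; ridge-regularized")
    R <- R + diag(1e-6 - min(ev, 0), ncol(R))
    R <- cov2cor(R)
  }
  # strict eigenvalue-1 rule, with a machine-precision guard so an exactly
  # identity correlation matrix retains nothing
  nf <- sum(eigen(R, symmetric = TRUE, only.values = TRUE)$values > 1 + 1e-8)
  if (nf == 0)
    return(list(scores = matrix(numeric(0), nrow(X), 0),
                loadings = matrix(numeric(0), ncol(X), 0),
                eigenvalues = ev, nFactors = 0L))
  L <- .principalAxis(R, nf, maxIter, tol)
  if (nf > 1) {
    vm <- varimax(L, normalize = TRUE)
    L <- L %*% vm$rotmat
  }
  ## sign convention: maximum-|loading| instrument positive per factor
  for (f in seq_len(nf)) {
    top <- which.max(abs(L[, f]))
    if (L[top, f] < 0) L[, f] <- -L[, f]
  }
  fNames <- vapply(seq_len(nf), function(f) {
    top <- colnames(X)[which.max(abs(L[, f]))]
    if (!is.null(labels) && top %in% names(labels)) labels[[top]]
    else paste0("factor", f)
  }, character(1))
  if (anyDuplicated(fNames)) fNames <- make.unique(fNames)
  dimnames(L) <- list(colnames(X), fNames)
  ## regression-method scores on standardized data (mean imputation for NA)
  Z <- scale(X)
  Z[is.na(Z)] <- 0
  W <- solve(R, L)
  S <- Z %*% W
  S <- scale(S)
  colnames(S) <- fNames
  list(scores = S, loadings = L, eigenvalues = ev, nFactors = nf)
}

## iterated principal-axis extraction (internal)
.principalAxis <- function(R, nf, maxIter, tol) {
  h <- 1 - 1 / diag(solve(R))       # squared multiple correlations
  for (it in seq_len(maxIter)) {
    Rh <- R
    diag(Rh) <- h
    e <- eigen(Rh, symmetric = TRUE)
    lam <- pmax(e$values[seq_len(nf)], 0)
    L <- e$vectors[, seq_len(nf), drop = FALSE] %*% diag(sqrt(lam), nf)
    hNew <- pmin(rowSums(L^2), 0.999)
    if (max(abs(hNew - h)) < tol) { h <- hNew; break }
    h <- hNew
  }
  L
}

#' Brain-behavior correlation across ROIs
#'
#' Pearson correlation between a factor score and each ROI centile, with an
#' optional partial adjustment for a conditioning score (e.g. adjust the
#' impulsivity-GMV correlation for rule-breaking); two-sided p and
#' Benjamini-Hochberg q across ROIs.
#'
#' @param factorScore numeric vector, one value per scan row.
#' @param centiles scans x ROIs matrix aligned with `factorScore`.
#' @param partial optional conditioning score.
#' @return data.frame: `roi`, `r`, `p`, `q`, `n`.
#' @export
brainBehaviorCorr <- function(factorScore, centiles, partial = NULL) {
  centiles <- as.matrix(centiles)
  ok0 <- !is.na(factorScore)
  if (!is.null(partial)) ok0 <- ok0 & !is.na(partial)
  res <- lapply(colnames(centiles), function(rc) {
    y <- centiles[, rc]
    ok <- ok0 & !is.na(y)
    n <- sum(ok)
    if (n < 10) stop("fewer than 10 complete pairs for ", rc)
    x <- factorScore[ok]; yy <- y[ok]
    if (is.null(partial)) {
      r <- cor(x, yy)
      dfree <- n - 2
    } else {
      z <- partial[ok]
      if (abs(cor(z, x)) > 1 - 1e-10) {
        # conditioning score identical (up to sign/scale) to the score itself
        return(data.frame(roi = rc, r = 0, p = NA_real_, n = n,
                          degenerate = TRUE))
      }
      rx <- residuals(lm(x ~ z))
      ry <- residuals(lm(yy ~ z))
      r <- cor(rx, ry)
      dfree <- n - 3
    }
    tt <- r * sqrt(dfree / max(1 - r^2, 1e-12))
    data.frame(roi = rc, r = r, p = 2 * pt(-abs(tt), dfree), n = n,
               degenerate = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bhFdr(out$p)
  rownames(out) <- NULL
  out
}

#' Fisher-z meta-analysis of correlations across studies
#'
#' Correlations are Fisher-z transformed, pooled with inverse-variance
#' weights w = n - 3, and back-transformed. Studies with n <= 3 are excluded
#' with a warning.
#'
#' @param rs per-study correlations.
#' @param ns per-study sample sizes.
#' @return list: `r` (pooled), `se` (on the z scale), `p`.
#' @examples
#' metaEffects(c(0.1, 0.3), c(103, 103))$r   # ~0.2013
#' @export
metaEffects <- function(rs, ns) {
  if (length(rs) != length(ns)) stop("length mismatch")
  if (length(rs) < 2) stop("need at least 2 studies")
  keep <- ns > 3
  if (!all(keep)) {
    warning(sum(!keep), " study(ies) with n <= 3 excluded")
    rs <- rs[keep]; ns <- ns[keep]
  }
  z <- atanh(rs)
  w <- ns - 3
  zbar <- sum(w * z) / sum(w)
  se <- 1 / sqrt(sum(w))
  list(r = tanh(zbar), se = se, p = 2 * pnorm(-abs(zbar / se)))
}
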