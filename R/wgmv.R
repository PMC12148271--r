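#' Weighted grey-matter-volume (wGMV) brain score
#'
#' Per-participant score `sum_roi w_roi * centile_roi`, interpretable as a
#' brain-based SUD propensity score when the weights are the ROI-level
#' SUD-HC differential z-statistics (see [wgmvWeights()]). Participants with
#' a missing centile are skipped with a warning.
#'
#' @param centiles scans x ROIs centile matrix (see [centileMatrix()]).
#' @param weights named numeric vector covering every ROI column.
#' @return named numeric vector of scores.
#' @examples
#' m <- rbind(a = c(r1 = 0.2, r2 = 0.8))
#' computeWgmv(m, c(r1 = 1, r2 = -1))   # -0.6
#' @export
computeWgmv <- function(centiles, weights) {
  centiles <- as.matrix(centiles)
  miss <- setdiff(colnames(centiles), names(weights))
  if (length(miss)) stop("weights missing for ROI(s): ",
                         paste(miss, collapse = ", "))
  w <- weights[colnames(centiles)]
  bad <- rowSums(is.na(centiles)) > 0
  if (any(bad)) {
    warning(sum(bad), " participant(s) with missing centiles skipped")
    centiles <- centiles[!bad, , drop = FALSE]
  }
  drop(centiles %*% w)
}

#' Differential-z wGMV weights at a reference age
#'
#' Default weight source: the SUD-HC differential z of each ROI taken from
#' its divergence grid at the reference age (e.g. the study's mean age).
#' GWAS-derived z weights can be supplied to [computeWgmv()] directly
#' instead.
#'
#' @param grids named list of [DivergenceGrid-class] objects.
#' @param age reference age in years.
#' @return named numeric vector of weights.
#' @export
wgmvWeights <- function(grids, age) {
  suppressMessages(differentialMapAtAge(grids, age))
}

#' Greedy windowed LD pruning
#'
#' Plink-style `--indep-pairwise`: within every window of `windowKb`
#' kilobases (advanced by `step` variants), one of any variant pair with
#' dosage r^2 above `r2` is removed — the variant with the lower MAF, or the
#' later position on a tie. A final sweep guarantees that no retained pair
#' within a window violates the threshold. Deterministic.
#'
#' @param dosages n x m dosage matrix (columns named by variant id).
#' @param map variant map with `chrom`, `pos`, `id`, `maf` (positions sorted
#'   within chromosome).
#' @param windowKb window size in kb.
#' @param step variants to slide between windows.
#' @param r2 squared-correlation threshold.
#' @return character vector of retained variant ids.
#' @export
ldPrune <- function(dosages, map, windowKb = 50, step = 5L, r2 = 0.1) {
  D <- as.matrix(dosages)
  m <- ncol(D)
  stopifnot(nrow(map) == m)
  if (is.unsorted(order(map$chrom, map$pos)) ||
      any(unlist(tapply(map$pos, map$chrom, function(p) diff(p) <= 0))))
    stop("variant map must be sorted by position within chromosome")
  maf <- if ("maf" %in% names(map)) map$maf else {
    af <- colMeans(D, na.rm = TRUE) / 2
    pmin(af, 1 - af)
  }
  win <- windowKb * 1000
  keep <- rep(TRUE, m)
  dropPair <- function(i, j) {
    # drop lower MAF; tie -> later position
    if (maf[i] < maf[j]) i
    else if (maf[j] < maf[i]) j
    else if (map$pos[i] > map$pos[j]) i else j
  }
  pruneSet <- function(idx) {
    idx <- idx[keep[idx]]
    if (length(idx) < 2) return(invisible())
    repeat {
      idx <- idx[keep[idx]]
      if (length(idx) < 2) break
      cc <- suppressWarnings(cor(D[, idx, drop = FALSE]))^2
      cc[!is.finite(cc)] <- 0
      diag(cc) <- 0
      mx <- which.max(cc)
      if (cc[mx] <= r2) break
      ij <- arrayInd(mx, dim(cc))
      keep[dropPair(idx[ij[1]], idx[ij[2]])] <<- FALSE
    }
  }
  start <- 1L
  while (start <= m) {
    inWin <- which(map$chrom == map$chrom[start] &
                     map$pos >= map$pos[start] &
                     map$pos <= map$pos[start] + win)
    pruneSet(inWin)
    start <- start + step
  }
  ## final sweep: exhaustive within-window check
  repeat {
    idx <- which(keep)
    violated <- FALSE
    for (a in seq_along(idx)) {
      i <- idx[a]
      for (b in seq_along(idx)) {
        j <- idx[b]
        if (j <= i) next
        if (map$chrom[j] != map$chrom[i]) break
        if (map$pos[j] - map$pos[i] > win) break
        cc <- suppressWarnings(cor(D[, i], D[, j]))^2
        if (is.finite(cc) && cc > r2) {
          keep[dropPair(i, j)] <- FALSE
          violated <- TRUE
        }
      }
      if (violated) break
    }
    if (!violated) break
  }
  map$id[keep]
}

#' Polygenic score from summary statistics
#'
#' PGS = sum over the pruned variant set of dosage x beta, with the effect
#' allele aligned to `a1` of the weights table (a1/a2 swap flips the dosage;
#' an unresolvable allele pair drops the variant with a count). Missing
#' dosages are mean-imputed per variant.
#'
#' @param dosages n x m dosage matrix, columns named by variant id.
#' @param map variant map for the dosages (`id`, `a1`, `a2`).
#' @param weights GWAS table supplying `id`, `a1`, `a2`, `beta`.
#' @param keep optional character vector of variant ids (e.g. from
#'   [ldPrune()]).
#' @return named numeric vector of scores, with attribute `dropped` (number
#'   of allele-mismatched variants).
#' @export
pgsScore <- function(dosages, map, weights, keep = NULL) {
  D <- as.matrix(dosages)
  ids <- if (is.null(keep)) intersect(colnames(D), weights$id)
         else intersect(keep, intersect(colnames(D), weights$id))
  wIdx <- match(ids, weights$id)
  mIdx <- match(ids, map$id)
  same <- weights$a1[wIdx] == map$a1[mIdx] & weights$a2[wIdx] == map$a2[mIdx]
  swap <- weights$a1[wIdx] == map$a2[mIdx] & weights$a2[wIdx] == map$a1[mIdx]
  bad <- !(same | swap)
  if (any(bad)) ids <- ids[!bad]
  same <- same[!bad]; wIdx <- wIdx[!bad]
  X <- D[, ids, drop = FALSE]
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
  }
  X[, !same] <- 2 - X[, !same]
  b <- weights$beta[wIdx]
  b[is.na(b)] <- 0
  s <- drop(X %*% b)
  attr(s, "dropped") <- sum(bad)
  s
}

#' Genetic correlation via cross-trait polygenic score
#'
#' Regression of the target phenotype on the standardized PGS plus
#' covariates; returns the standardized slope, the incremental R^2 over the
#' covariate-only model, and the p-value. The estimate is NOT corrected for
#' PGS measurement error (`uncorrected = TRUE` in the result).
#'
#' @param pgs polygenic score.
#' @param target phenotype vector (n >= 100).
#' @param covariates optional data.frame.
#' @return list: `slope` (standardized), `se`, `r2`, `p`,
#'   `uncorrected = TRUE`.
#' @export
pgsGeneticCorrelation <- function(pgs, target, covariates = NULL) {
  if (length(pgs) < 100) stop("need n >= 100")
  if (sd(pgs) < 1e-12) stop("constant PGS")
  dat <- data.frame(y = as.vector(scale(target)),
                    pgs = as.vector(scale(pgs)))
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  full <- lm(y ~ ., data = dat)
  base <- lm(y ~ . - pgs, data = dat)
  sm <- summary(full)$coefficients["pgs", ]
  list(slope = unname(sm[1]), se = unname(sm[2]),
       r2 = summary(full)$r.squared - summary(base)$r.squared,
       p = unname(sm[4]), uncorrected = TRUE)
}

#' Compare gene-expression polygenic scores between groups
#'
#' Two-sided t-test of a PGS between SUD and HC with Cohen's d.
#'
#' @param pgs polygenic score vector.
#' @param groups group labels (`HC` / `SUD*`), >= 10 per group.
#' @return list: `d`, `p`, `nSud`, `nHc`.
#' @export
genePgsCompare <- function(pgs, groups) {
  isSud <- startsWith(as.character(groups), "SUD")
  if (sum(isSud) < 10 || sum(!isSud) < 10)
    stop("need at least 10 participants per group")
  a <- pgs[isSud]; b <- pgs[!isSud]
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  list(d = (mean(a) - mean(b)) / sp,
       p = t.test(a, b)$p.value,
       nSud = length(a), nHc = length(b))
}
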