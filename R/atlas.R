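#' Varimax factor analysis of a term-by-parcel atlas
#'
#' Principal factoring of the term correlation matrix (terms as variables,
#' parcels as observations) with varimax rotation. Factors explaining more
#' than `threshold` of the total variance are retained; within each factor,
#' terms are kept only if their |loading| exceeds 0.2 AND reaches the
#' factor-wise median |loading| (the top 50th percentile); a factor whose
#' retained-term mask is empty is dropped with a warning. Factor-level brain
#' maps are regression scores over parcels computed from the retained
#' loadings.
#'
#' @param terms terms x parcels matrix (>= 2 terms, >= 24 parcels).
#' @param threshold variance-fraction retention threshold (default 1\%).
#' @param loadingCut absolute-loading filter.
#' @return an [AtlasFactorSet-class].
#' @export
atlasFactorAnalysis <- function(terms, threshold = 0.01, loadingCut = 0.2) {
  terms <- as.matrix(terms)
  if (nrow(terms) < 2) stop("need at least 2 terms")
  if (ncol(terms) < 24) stop("need at least 24 parcels")
  Z <- t(scale(t(terms)))                  # standardize each term over parcels
  R <- cor(t(terms))
  e <- eigen(R, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  frac <- ev / sum(ev)
  nf <- sum(frac > threshold)
  if (nf < 1) {
    warning("degenerate term matrix; keeping a single factor")
    nf <- 1L
  }
  L <- e$vectors[, seq_len(nf), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(nf)]), nf)
  rot <- diag(nf)
  if (nf > 1) {
    vm <- varimax(L, normalize = TRUE)
    L <- L %*% vm$rotmat
    rot <- vm$rotmat
  }
  for (f in seq_len(nf)) if (L[which.max(abs(L[, f])), f] < 0)
    L[, f] <- -L[, f]
  varFrac <- colSums(L^2) / sum(ev)
  mask <- matrix(FALSE, nrow(terms), nf)
  for (f in seq_len(nf)) {
    al <- abs(L[, f])
    mask[, f] <- al > loadingCut & al >= median(al)
  }
  keep <- colSums(mask) > 0 & varFrac > threshold
  if (!all(keep)) {
    warning(sum(!keep), " factor(s) dropped (empty retained-term mask or ",
            "below the variance threshold after rotation)")
    L <- L[, keep, drop = FALSE]
    mask <- mask[, keep, drop = FALSE]
    varFrac <- varFrac[keep]
    rot <- rot[, keep, drop = FALSE]
    nf <- sum(keep)
  }
  if (nf == 0L)
    return(new("AtlasFactorSet",
               loadings = matrix(numeric(0), nrow(terms), 0),
               maps = matrix(numeric(0), ncol(terms), 0),
               varFrac = numeric(0),
               mask = matrix(logical(0), nrow(terms), 0),
               rotation = matrix(numeric(0), 0, 0), threshold = threshold))
  ## regression scores per parcel from the retained loadings
  maps <- matrix(0, ncol(terms), nf)
  Rridge <- R + diag(1e-8, ncol(R))
  for (f in seq_len(nf)) {
    m <- mask[, f]
    W <- solve(Rridge[m, m, drop = FALSE], L[m, f])
    maps[, f] <- drop(t(Z[m, , drop = FALSE]) %*% W)
  }
  fn <- paste0("factor", seq_len(nf))
  dimnames(L) <- list(rownames(terms), fn)
  dimnames(mask) <- dimnames(L)
  dimnames(maps) <- list(colnames(terms), fn)
  names(varFrac) <- fn
  new("AtlasFactorSet", loadings = L, maps = maps, varFrac = varFrac,
      mask = mask, rotation = rot, threshold = threshold)
}

#' @rdname AtlasFactorSet-class
#' @param x,object an `AtlasFactorSet`.
#' @export
setMethod("factorMaps", "AtlasFactorSet", function(x) x@maps)

#' @rdname AtlasFactorSet-class
#' @export
setMethod("varianceFraction", "AtlasFactorSet", function(x) x@varFrac)

#' @rdname AtlasFactorSet-class
#' @export
setMethod("show", "AtlasFactorSet", function(object) {
  cat("AtlasFactorSet:", ncol(object@loadings), "factors,",
      nrow(object@loadings), "terms,", nrow(object@maps), "parcels\n")
  cat("  variance fractions:",
      paste(sprintf("%.1f%%", 100 * object@varFrac), collapse = ", "), "\n")
})

#' Differential z-map at one age
#'
#' Extracts z(a) per ROI from a list of divergence grids at the requested
#' age; an off-grid age snaps to the nearest 0.05y grid point with a note.
#'
#' @param grids named list of [DivergenceGrid-class] objects (one per ROI).
#' @param age target age in years (8-70).
#' @return named numeric vector of z-statistics.
#' @export
differentialMapAtAge <- function(grids, age) {
  if (age < 8 || age > 70) stop("age must lie in [8, 70]")
  g1 <- grids[[1]]
  i <- which.min(abs(g1@ages - age))
  if (abs(g1@ages[i] - age) > 1e-9)
    message("age ", age, " snapped to grid age ", g1@ages[i])
  vapply(grids, function(g) g@z[i], numeric(1))
}

#' Uniform random 3D rotation matrices
#'
#' Orthogonalized Gaussian triples (QR) with the determinant fixed to +1.
#'
#' @param n number of rotations.
#' @return list of 3 x 3 rotation matrices.
#' @export
randomRotations <- function(n) {
  lapply(seq_len(n), function(i) {
    qrd <- qr(matrix(rnorm(9), 3, 3))
    Q <- qr.Q(qrd)
    Q <- Q %*% diag(sign(diag(qr.R(qrd))))
    if (det(Q) < 0) Q[, 3] <- -Q[, 3]
    Q
  })
}

#' Precompute spin-permutation parcel reassignments
#'
#' Each spin rotates the parcel centroids by a uniform random rotation and
#' reassigns every parcel to its nearest original centroid (duplicates
#' allowed, the standard spin behavior). The resulting index matrix can be
#' reused across ages and factors so all tests share one spatial null.
#'
#' @param centroids parcels x 3 matrix of unit-norm coordinates.
#' @param nSpins number of spins.
#' @param seed RNG seed.
#' @return parcels x nSpins integer matrix of source indices.
#' @export
spinNullAssignments <- function(centroids, nSpins = 1000L, seed = 1L) {
  centroids <- as.matrix(centroids)
  if (any(abs(sqrt(rowSums(centroids^2)) - 1) > 1e-6))
    stop("centroids must lie on the unit sphere")
  if (nSpins < 100) warning("fewer than 100 spins gives a coarse null")
  set.seed(seed)
  rot <- randomRotations(nSpins)
  out <- matrix(NA_integer_, nrow(centroids), nSpins)
  for (s in seq_len(nSpins)) {
    rc <- centroids %*% t(rot[[s]])
    ## nearest original centroid for each rotated position
    out[, s] <- max.col(tcrossprod(rc, centroids), ties.method = "first")
  }
  out
}

#' Spin-permutation test of a factor-map / z-map association
#'
#' Observed R^2 from univariate regression of the z map on the factor map;
#' the null distribution spins the factor map over random sphere rotations
#' with nearest-centroid reassignment. One-sided p with the +1 correction:
#' p = (1 + #\{null >= observed\}) / (1 + nSpins).
#'
#' @param factorMap,zMap numeric vectors over parcels.
#' @param centroids parcels x 3 unit-sphere coordinates (ignored when
#'   `nullAssign` is supplied).
#' @param nSpins number of spins.
#' @param seed RNG seed.
#' @param nullAssign optional precomputed matrix from
#'   [spinNullAssignments()].
#' @return list: `r2`, `nullR2`, `p`.
#' @export
spinCorrelation <- function(factorMap, zMap, centroids = NULL,
                            nSpins = 1000L, seed = 1L, nullAssign = NULL) {
  if (is.null(nullAssign)) {
    if (is.null(centroids)) stop("need centroids or a precomputed null")
    nullAssign <- spinNullAssignments(centroids, nSpins, seed)
  }
  nSpins <- ncol(nullAssign)
  obs <- cor(factorMap, zMap)^2
  spun <- matrix(factorMap[nullAssign], nrow = length(factorMap))
  nullR2 <- drop(cor(zMap, spun))^2
  p <- (1 + sum(nullR2 >= obs)) / (1 + nSpins)
  list(r2 = obs, nullR2 = nullR2, p = p)
}

#' Age-resolved factor-map association profile
#'
#' For every factor and every age on the 0.5y grid: R^2 between the factor
#' map and the SUD-HC differential z map, spin p-value (one shared spatial
#' null across ages), and Benjamini-Hochberg q across ages within factor;
#' plus a peak-age summary.
#'
#' @param factors an [AtlasFactorSet-class] whose parcels correspond to the
#'   ROIs of `grids` (same order).
#' @param grids named list of [DivergenceGrid-class] objects.
#' @param centroids parcels x 3 unit-sphere coordinates.
#' @param ages age grid (default 8..70 step 0.5, 125 ages).
#' @param nSpins spins shared across cells.
#' @param seed RNG seed.
#' @return list: `profile` (long data.frame factor/age/r2/p/q),
#'   `peak` (per factor: age of maximal R^2).
#' @export
ageProfile <- function(factors, grids, centroids,
                       ages = seq(8, 70, by = 0.5), nSpins = 1000L,
                       seed = 1L) {
  maps <- factorMaps(factors)
  stopifnot(nrow(maps) == length(grids))
  nullAssign <- spinNullAssignments(centroids, nSpins, seed)
  rows <- list()
  for (f in colnames(maps)) {
    r2 <- p <- numeric(length(ages))
    for (i in seq_along(ages)) {
      zmap <- differentialMapAtAge(grids, ages[i])
      sc <- spinCorrelation(maps[, f], zmap, nullAssign = nullAssign)
      r2[i] <- sc$r2; p[i] <- sc$p
    }
    rows[[f]] <- data.frame(factor = f, age = ages, r2 = r2, p = p,
                            q = bhFdr(p))
  }
  profile <- do.call(rbind, rows)
  rownames(profile) <- NULL
  peak <- aggregate(r2 ~ factor, profile, max)
  peak$age <- profile$age[match(paste(peak$factor, peak$r2),
                                paste(profile$factor, profile$r2))]
  list(profile = profile, peak = peak)
}
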