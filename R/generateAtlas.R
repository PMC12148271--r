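#' Generate a spatially autocorrelated term-by-parcel atlas on the sphere
#'
#' Parcel centroids are placed deterministically by a Fibonacci lattice on
#' the unit sphere. `n_factors` latent spatial patterns are built by
#' geodesic-Gaussian smoothing of white noise (kernel bandwidth in radians);
#' each cognitive term loads primarily on one factor, and term maps are
#' loadings times patterns plus smoothed residual noise.
#'
#' @param config a [simConfig()] with an `atlas_truth` block.
#' @param seed RNG seed (defaults to `config$seed`).
#' @return list: `terms` (terms x parcels matrix), `centroids`
#'   (parcels x 3, unit norm), `truth` (true loadings and spatial patterns).
#' @export
generateAtlas <- function(config, seed = config$seed) {
  at <- config$atlas_truth
  if (is.null(at)) stop("config has no atlas_truth block")
  if (at$bandwidth <= 0) stop("smoothing bandwidth must be > 0")
  if (at$n_parcels < 24) stop("need at least 24 parcels")
  set.seed(seed)
  C <- fibonacciSphere(at$n_parcels)
  K <- .geodesicKernel(C, at$bandwidth)
  smooth <- function(v) {
    s <- drop(K %*% v)
    (s - mean(s)) / sd(s)
  }
  P <- t(vapply(seq_len(at$n_factors), function(f) smooth(rnorm(at$n_parcels)),
                numeric(at$n_parcels)))          # factors x parcels
  ## orthogonalize the spatial patterns (linear combinations of smooth maps
  ## stay smooth) so factor recovery is identified up to rotation
  P <- t(qr.Q(qr(t(P)))) * sqrt(at$n_parcels)
  primary <- rep_len(seq_len(at$n_factors), at$n_terms)
  L <- matrix(rnorm(at$n_terms * at$n_factors, 0, 0.08),
              at$n_terms, at$n_factors)
  L[cbind(seq_len(at$n_terms), primary)] <-
    0.8 + runif(at$n_terms, -0.05, 0.05)
  terms <- L %*% P
  if (at$noise > 0)
    terms <- terms + at$noise *
      t(vapply(seq_len(at$n_terms), function(i) smooth(rnorm(at$n_parcels)),
               numeric(at$n_parcels)))
  rownames(terms) <- sprintf("term_%02d", seq_len(at$n_terms))
  colnames(terms) <- sprintf("parcel_%02d", seq_len(at$n_parcels))
  rownames(C) <- colnames(terms)
  list(terms = terms, centroids = C,
       truth = list(loadings = L, patterns = P))
}

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Fibonacci (golden-angle) lattice; all rows have unit norm.
#'
#' @param n number of points.
#' @return n x 3 matrix of coordinates.
#' @export
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

## row-normalized geodesic Gaussian smoothing kernel
.geodesicKernel <- function(centroids, bandwidth) {
  cosd <- pmin(pmax(tcrossprod(centroids), -1), 1)
  d <- acos(cosd)
  K <- exp(-(d / bandwidth)^2 / 2)
  K / rowSums(K)
}

## Moran's I spatial autocorrelation on a k-nearest-neighbor graph (internal,
## used to verify that the smoothing bandwidth controls spatial structure)
.moranI <- function(values, centroids, k = 5L) {
  n <- length(values)
  d <- acos(pmin(pmax(tcrossprod(centroids), -1), 1))
  diag(d) <- Inf
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, order(d[i, ])[seq_len(k)]] <- 1
  z <- values - mean(values)
  (n / sum(W)) * sum(W * tcrossprod(z)) / sum(z^2)
}

#' Write the synthetic atlas as TSV files
#'
#' @param atlas list from [generateAtlas()].
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
writeAtlas <- function(atlas, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tpath <- file.path(dir, "atlas_terms.tsv")
  cpath <- file.path(dir, "centroids.tsv")
  write.table(data.frame(term = rownames(atlas$terms), atlas$terms,
                         check.names = FALSE),
              tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(parcel = rownames(atlas$centroids),
                         atlas$centroids),
              cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(tpath, cpath))
}
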