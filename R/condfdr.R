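#' Empirical conditional FDR
#'
#' Pointwise empirical estimator evaluated at each variant's own p-value
#' pair:
#' `cFDR(p1 | p2) = p1 * #\{P2 <= p2\} / #\{P1 <= p1 AND P2 <= p2\}`,
#' capped at 1. The test statistic of the primary trait is thereby re-ranked
#' by its associational strength with the conditioning trait. An empty
#' conditioning subset gives cFDR = 1. No kernel smoothing or binning grid
#' is applied.
#'
#' @param p1 primary-trait p-values in (0, 1\].
#' @param p2 conditioning-trait p-values, matched variant order.
#' @return numeric vector of conditional FDR values (always >= `p1`).
#' @export
condFdr <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("variant lists must match")
  if (any(p1 <= 0 | p1 > 1 | p2 <= 0 | p2 > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  m <- length(p1)
  out <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    if (is.na(p1[i]) || is.na(p2[i])) next
    cond <- !is.na(p2) & p2 <= p2[i]
    num <- sum(cond)
    den <- sum(cond & !is.na(p1) & p1 <= p1[i])
    out[i] <- if (den == 0) 1 else min(1, p1[i] * num / den)
  }
  out
}

#' Conjunctional FDR and shared-locus calling
#'
#' conjFDR = elementwise maximum of the two conditional FDR vectors.
#' Variants with conjFDR below `alpha` are clumped into loci: significant
#' variants within `windowKb` on the same chromosome form one locus, led by
#' the variant with the smallest conjFDR.
#'
#' @param cfdr12 cFDR of trait 1 given trait 2.
#' @param cfdr21 cFDR of trait 2 given trait 1 (matched order).
#' @param map optional variant map (`id`, `chrom`, `pos`) for locus calling.
#' @param alpha significance threshold.
#' @param windowKb clumping distance in kb.
#' @return list: `conjfdr` (vector), `loci` (data.frame of lead variants,
#'   empty without a map or hits).
#' @export
conjFdr <- function(cfdr12, cfdr21, map = NULL, alpha = 0.05,
                    windowKb = 50) {
  if (length(cfdr12) != length(cfdr21)) stop("vectors must match")
  cj <- pmax(cfdr12, cfdr21)
  loci <- data.frame(id = character(0), chrom = integer(0),
                     pos = integer(0), conjfdr = numeric(0))
  if (!is.null(map)) {
    sig <- which(!is.na(cj) & cj < alpha)
    if (length(sig)) {
      o <- sig[order(map$chrom[sig], map$pos[sig])]
      gap <- c(TRUE, diff(map$pos[o]) > windowKb * 1000 |
                 diff(map$chrom[o]) != 0)
      locus <- cumsum(gap)
      lead <- vapply(split(o, locus), function(ix) ix[which.min(cj[ix])],
                     integer(1))
      loci <- data.frame(id = map$id[lead], chrom = map$chrom[lead],
                         pos = map$pos[lead], conjfdr = cj[lead])
      rownames(loci) <- NULL
    }
  }
  list(conjfdr = cj, loci = loci)
}
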