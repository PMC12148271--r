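#' Fractional-polynomial design columns of age
#'
#' Royston-Altman convention on the rescaled age x = age/10: power 0 maps to
#' log(x); a repeated power p contributes x^p * log(x) (a further repeat
#' multiplies by log(x) again). Powers must come from
#' \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}.
#'
#' @param age positive ages in years.
#' @param powers numeric multiset of fractional-polynomial powers.
#' @return matrix with one column per power (sorted).
#' @examples
#' fpBasis(20, 1)            # 2.0
#' fpBasis(40, c(-0.5, 2))   # 0.5, 16
#' @export
fpBasis <- function(age, powers) {
  x <- age / 10
  if (any(x <= 0)) stop("ages must be positive")
  if (!all(powers %in% .fpPowerSet))
    stop("powers must be drawn from {", paste(.fpPowerSet, collapse = ", "), "}")
  powers <- sort(powers)
  H <- matrix(0, length(x), length(powers))
  lx <- log(x)
  for (j in seq_along(powers)) {
    p <- powers[j]
    if (j > 1L && powers[j] == powers[j - 1L]) {
      H[, j] <- H[, j - 1L] * lx
    } else {
      H[, j] <- if (p == 0) lx else x^p
    }
  }
  colnames(H) <- paste0("fp", seq_along(powers), "(", powers, ")")
  H
}

.fpPowerSet <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

## all power multisets of a given degree (combinations with repetition)
.fpCombos <- function(degree) {
  if (degree == 1L) return(lapply(.fpPowerSet, identity))
  combos <- list()
  rec <- function(prefix, startIdx) {
    if (length(prefix) == degree) {
      combos[[length(combos) + 1L]] <<- prefix
      return()
    }
    for (i in startIdx:length(.fpPowerSet))
      rec(c(prefix, .fpPowerSet[i]), i)
  }
  rec(numeric(0), 1L)
  combos
}

## least-squares screen: top-k power multisets of each degree for response ~
## fp(age) + extra covariate columns, ranked by residual sum of squares
.fpScreen <- function(response, age, extra = NULL, maxDegree = 3L, k = 1L) {
  lapply(seq_len(maxDegree), function(d) {
    combos <- .fpCombos(d)
    rss <- vapply(combos, function(pw) {
      X <- cbind(1, fpBasis(age, pw), extra)
      sum(lm.fit(X, response)$residuals^2)
    }, numeric(1))
    combos[order(rss)][seq_len(min(k, length(combos)))]
  })
}
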