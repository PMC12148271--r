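#' Genotype and sample quality control
#'
#' Drops samples with more than `missSample` missing dosages, then variants
#' with call rate below `callRate`, minor allele frequency below `maf`, or a
#' 1-df Hardy-Weinberg chi-square p-value (on genotype counts, allowing the
#' 0/1/2 dosage coding) below `hwe`.
#'
#' @param dosages n x m matrix of dosages in \{0, 1, 2, NA\}.
#' @param map variant map aligned with the columns.
#' @param missSample,callRate,maf,hwe thresholds.
#' @return list: `dosages`, `map` (filtered), `report` (counts per rule).
#' @export
qcFilter <- function(dosages, map, missSample = 0.10, callRate = 0.95,
                     maf = 0.01, hwe = 1e-10) {
  dosages <- as.matrix(dosages)
  stopifnot(nrow(map) == ncol(dosages))
  sampMiss <- rowMeans(is.na(dosages))
  keepS <- sampMiss <= missSample
  D <- dosages[keepS, , drop = FALSE]
  call <- colMeans(!is.na(D))
  af <- colMeans(D, na.rm = TRUE) / 2
  mafv <- pmin(af, 1 - af)
  hweP <- vapply(seq_len(ncol(D)), function(j) .hweChisqP(D[, j]), numeric(1))
  keepV <- call >= callRate & mafv >= maf & hweP >= hwe
  if (!any(keepS) || !any(keepV)) stop("quality control removed everything")
  report <- data.frame(
    rule = c("sample_missing", "call_rate", "maf", "hwe"),
    removed = c(sum(!keepS), sum(call < callRate),
                sum(call >= callRate & mafv < maf),
                sum(call >= callRate & mafv >= maf & hweP < hwe)))
  list(dosages = D[, keepV, drop = FALSE],
       map = map[keepV, , drop = FALSE], report = report)
}

## Hardy-Weinberg equilibrium chi-square (1 df) p-value on genotype counts
.hweChisqP <- function(g) {
  g <- g[!is.na(g)]
  n <- length(g)
  if (n < 5) return(1)
  obs <- c(sum(g == 0), sum(g == 1), sum(g == 2))
  p <- (obs[2] + 2 * obs[3]) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  x2 <- sum((obs - expd)^2 / expd)
  pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Collapse longitudinal group labels to a binary case/control phenotype
#'
#' A participant is a case iff labeled SUD at strictly more than half of
#' their visits; otherwise a control.
#'
#' @param pid participant id per visit.
#' @param group group label per visit (`HC` / `SUD*`).
#' @return named integer vector (1 = case, 0 = control), one per
#'   participant.
#' @export
collapseCaseControl <- function(pid, group) {
  isSud <- startsWith(as.character(group), "SUD")
  tab <- tapply(isSud, pid, function(v) as.integer(sum(v) > length(v) / 2))
  setNames(as.integer(tab), names(tab))
}

#' Per-variant association scan
#'
#' Covariate-adjusted Wald association per variant: logistic regression for
#' a binary phenotype, or a vectorized linear regression (covariates
#' residualized out once) for a continuous one. Variants with (near)
#' constant dosage, or with separation in the logistic fit, are flagged with
#' missing statistics.
#'
#' @param dosages n x m dosage matrix (QC'd; NAs mean-imputed per variant).
#' @param phenotype binary (0/1) or continuous vector.
#' @param covariates optional data.frame.
#' @param map optional variant map contributing `chrom`/`pos`/`a1`/`a2`.
#' @return GWAS table: `id`, `chrom`, `pos`, `a1`, `a2`, `beta`, `se`, `z`,
#'   `p`, `n` (positions sorted within chromosome as supplied).
#' @export
snpAssociation <- function(dosages, phenotype, covariates = NULL,
                           map = NULL) {
  D <- as.matrix(dosages)
  n <- nrow(D)
  for (j in seq_len(ncol(D))) {
    nas <- is.na(D[, j])
    if (any(nas)) D[nas, j] <- mean(D[, j], na.rm = TRUE)
  }
  binary <- all(phenotype %in% c(0, 1))
  Xc <- if (is.null(covariates)) matrix(1, n, 1)
        else model.matrix(~ ., data = as.data.frame(covariates))
  m <- ncol(D)
  beta <- se <- rep(NA_real_, m)
  if (binary) {
    for (j in seq_len(m)) {
      x <- D[, j]
      if (sd(x) < 1e-8) next
      fit <- tryCatch(
        suppressWarnings(glm.fit(cbind(x, Xc), phenotype,
                                 family = binomial())),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) next
      w <- fit$weights
      XtWX <- crossprod(cbind(x, Xc) * sqrt(w))
      Vd <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
      if (is.null(Vd)) next
      b <- fit$coefficients[1]
      s <- sqrt(Vd[1, 1])
      if (!is.finite(b) || !is.finite(s) || abs(b) > 15) next  # separation
      beta[j] <- b; se[j] <- s
    }
  } else {
    Q <- qr.Q(qr(Xc))
    ry <- phenotype - Q %*% crossprod(Q, phenotype)
    RD <- D - Q %*% crossprod(Q, D)
    sx2 <- colSums(RD^2)
    mono <- sx2 < 1e-10
    bj <- colSums(RD * drop(ry)) / pmax(sx2, 1e-300)
    dfres <- n - ncol(Xc) - 1
    rss <- sum(ry^2) - bj^2 * sx2
    sj <- sqrt(pmax(rss, 0) / dfres / pmax(sx2, 1e-300))
    beta <- ifelse(mono, NA_real_, bj)
    se <- ifelse(mono, NA_real_, sj)
  }
  z <- beta / se
  p <- pmax(2 * pnorm(-abs(z)), 1e-300)  # keep p in (0, 1] after underflow
  out <- data.frame(
    id = colnames(D) %||% sprintf("v%d", seq_len(m)),
    chrom = if (!is.null(map)) map$chrom else 1L,
    pos = if (!is.null(map)) map$pos else seq_len(m),
    a1 = if (!is.null(map)) map$a1 else "A",
    a2 = if (!is.null(map)) map$a2 else "G",
    beta = beta, se = se, z = z, p = p, n = n)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write GWAS summary statistics
#'
#' Tab-separated with header columns ID, CHR, BP, A1, A2, BETA, SE, P, N.
#' @param path file path.
#' @param gwas GWAS table as from [snpAssociation()].
#' @return `readGwasTable` returns the table in internal column naming.
#' @export
writeGwasTable <- function(gwas, path) {
  out <- data.frame(ID = gwas$id, CHR = gwas$chrom, BP = gwas$pos,
                    A1 = gwas$a1, A2 = gwas$a2, BETA = gwas$beta,
                    SE = gwas$se, P = gwas$p, N = gwas$n)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGwasTable
#' @export
readGwasTable <- function(path) {
  x <- read.delim(path)
  need <- c("ID", "CHR", "BP", "A1", "A2", "BETA", "SE", "P", "N")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("summary statistics lack column(s): ",
                         paste(miss, collapse = ", "))
  data.frame(id = x$ID, chrom = x$CHR, pos = x$BP, a1 = x$A1, a2 = x$A2,
             beta = x$BETA, se = x$SE, z = x$BETA / x$SE, p = x$P, n = x$N)
}
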