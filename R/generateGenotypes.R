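#' Generate LD-blocked genotype dosages with causal effects on SUD liability
#' and ROI volumes
#'
#' Two independent latent Gaussian "haplotype" vectors are drawn per
#' participant from AR(1) blocks of `block` variants with correlation `rho`,
#' and thresholded at the variant's minor-allele frequency; the dosage is the
#' number of haplotypes past the threshold, giving Hardy-Weinberg genotypes
#' with tunable within-block LD. Causal variants (sampled one per block where
#' possible) contribute additively to the standardized SUD genetic burden and
#' to the standardized brain genetic shift; `n_shared` variants belong to
#' both causal sets, linking the SUD and brain-volume arms.
#'
#' @param config a [simConfig()] with non-NULL `geno_truth`.
#' @param n number of participants.
#' @param seed RNG seed (defaults to `config$seed`). Ignored (stream
#'   continues) when called internally from [generateCohort()].
#' @return list: `dosages` (n x m matrix, values 0/1/2, variant ids as
#'   column names), `map` (data.frame `chrom`, `pos`, `id`, `a1`, `a2`,
#'   `maf`; positions strictly increasing within chromosome), `causal`
#'   (id, beta_sud, beta_brain, shared), `burden` and `brainShift`
#'   (standardized per-participant genetic scores).
#' @export
generateGenotypes <- function(config, n = 2000L, seed = config$seed) {
  if (is.null(config$geno_truth)) stop("config has no geno_truth block")
  .validateConfig(config)
  set.seed(seed)
  .genGenotypes(config, n, ids = sprintf("id_%05d", seq_len(n)))
}

.genGenotypes <- function(config, n, ids) {
  gt <- config$geno_truth
  m <- gt$m
  nBlocks <- ceiling(m / gt$block)
  blockOf <- rep(seq_len(nBlocks), each = gt$block)[seq_len(m)]
  maf <- runif(m, gt$maf[1], gt$maf[2])
  thr <- qnorm(1 - maf)

  latent <- function() {
    Z <- matrix(NA_real_, n, m)
    for (b in seq_len(nBlocks)) {
      idx <- which(blockOf == b)
      Z[, idx[1]] <- rnorm(n)
      for (j in idx[-1])
        Z[, j] <- gt$rho * Z[, j - 1] + sqrt(1 - gt$rho^2) * rnorm(n)
    }
    Z
  }
  D <- (latent() > rep(thr, each = n)) + (latent() > rep(thr, each = n))
  storage.mode(D) <- "integer"

  ## variant map: ~10 blocks per chromosome, blocks > 50kb apart so that the
  ## pruning window never straddles two blocks
  blocksPerChrom <- 10L
  chromOfBlock <- ceiling(seq_len(nBlocks) / blocksPerChrom)
  chrom <- chromOfBlock[blockOf]
  pos <- integer(m)
  cur <- 0L
  for (j in seq_len(m)) {
    newChrom <- j == 1L || chrom[j] != chrom[j - 1L]
    newBlock <- j == 1L || blockOf[j] != blockOf[j - 1L]
    gap <- if (newChrom) sample(100000:200000, 1L)
           else if (newBlock) sample(60000:120000, 1L)
           else sample(500:3000, 1L)
    cur <- if (newChrom) gap else cur + gap
    pos[j] <- cur
  }
  ids_v <- sprintf("rs%d_%d", chrom, pos)
  map <- data.frame(chrom = chrom, pos = pos, id = ids_v,
                    a1 = "A", a2 = "G", maf = maf)
  colnames(D) <- ids_v
  rownames(D) <- ids

  ## causal sets: prefer common variants, at most one per block
  pool <- which(maf > 0.1)
  lead <- pool[!duplicated(blockOf[pool])]
  nSud <- gt$n_causal_sud; nBrain <- gt$n_causal_brain; nShared <- gt$n_shared
  need <- nSud + nBrain - nShared
  if (length(lead) < need) lead <- seq_len(m)[!duplicated(blockOf)]
  pick <- sample(lead, need)
  sudIdx <- pick[seq_len(nSud)]
  brainIdx <- c(pick[seq_len(nShared)],
                pick[nSud + seq_len(nBrain - nShared)])
  betaSud <- setNames(rnorm(nSud, 0, gt$beta_sd) +
                        sign(rnorm(nSud)) * 0.5, ids_v[sudIdx])
  betaBrain <- setNames(rnorm(nBrain, 0, gt$beta_sd) +
                          sign(rnorm(nBrain)) * 0.5, ids_v[brainIdx])
  scoreOf <- function(idx, beta) {
    s <- drop(D[, idx, drop = FALSE] %*% beta)
    if (sd(s) < 1e-12) rep(0, n) else as.vector(scale(s))
  }
  burden <- scoreOf(sudIdx, betaSud)
  brainShift <- scoreOf(brainIdx, betaBrain)

  causal <- data.frame(
    id = ids_v[union(sudIdx, brainIdx)],
    beta_sud = ifelse(ids_v[union(sudIdx, brainIdx)] %in% names(betaSud),
                      betaSud[ids_v[union(sudIdx, brainIdx)]], 0),
    beta_brain = ifelse(ids_v[union(sudIdx, brainIdx)] %in% names(betaBrain),
                        betaBrain[ids_v[union(sudIdx, brainIdx)]], 0))
  causal$shared <- causal$beta_sud != 0 & causal$beta_brain != 0
  rownames(causal) <- NULL
  list(dosages = D, map = map, causal = causal,
       burden = burden, brainShift = brainShift)
}

#' Write synthetic genotypes as dosage TSV plus variant map, or VCFv4.2
#'
#' The VCF writer emits hard-call genotypes (`0/0`, `0/1`, `1/1`) from the
#' dosage matrix, one sample column per participant.
#'
#' @param geno list from [generateGenotypes()].
#' @param dir output directory for `writeGenotypes`.
#' @param path output file for `writeGenotypesVcf`.
#' @return invisibly, the written path(s).
#' @export
writeGenotypes <- function(geno, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gpath <- file.path(dir, "geno.tsv")
  vpath <- file.path(dir, "variants.tsv")
  gtab <- data.frame(pid = rownames(geno$dosages), geno$dosages,
                     check.names = FALSE)
  write.table(gtab, gpath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(geno$map, vpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(gpath, vpath))
}

#' @rdname writeGenotypes
#' @export
writeGenotypesVcf <- function(geno, path) {
  map <- geno$map
  gtCode <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=lifespanSUD synthetic genotype generator",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(geno$dosages)),
                     collapse = "\t")), con)
  for (j in seq_len(nrow(map))) {
    gt <- gtCode[geno$dosages[, j] + 1L]
    gt[is.na(geno$dosages[, j])] <- "./."
    writeLines(paste(c(map$chrom[j], map$pos[j], map$id[j], map$a2[j],
                       map$a1[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}
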