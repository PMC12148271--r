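test_that("quality control applies the call-rate, MAF and HWE rules", {
  set.seed(71)
  n <- 5000
  maf <- 0.3
  filler <- matrix(rbinom(n * 20, 2, maf), n, 20,
                   dimnames = list(NULL, sprintf("f%02d", 1:20)))
  hwOk <- rbinom(n, 2, maf)                 # HWE-conforming
  noHet <- sample(rep(c(0L, 2L), round(c((1 - maf) * n, maf * n))))[1:n]
  rare <- rbinom(n, 2, 0.002)               # MAF below 1%
  lowCall <- hwOk
  lowCall[sample(n, round(0.06 * n))] <- NA # call rate 94%, samples stay
  D <- cbind(filler, ok = hwOk, nohet = noHet, rare = rare,
             lowcall = lowCall)
  map <- data.frame(chrom = 1L, pos = seq(1e5, by = 1e5,
                                          length.out = ncol(D)),
                    id = colnames(D), a1 = "A", a2 = "G")
  qc <- qcFilter(D, map)
  expect_true("ok" %in% qc$map$id)
  expect_false("nohet" %in% qc$map$id)       # HWE p << 1e-10
  expect_false("rare" %in% qc$map$id)
  expect_false("lowcall" %in% qc$map$id)
  # a sample with 15% missing dosages is dropped
  D3 <- matrix(rbinom(n * 20, 2, 0.3), n, 20,
               dimnames = list(NULL, sprintf("s%02d", 1:20)))
  D3[7, 1:3] <- NA                           # 15% missing
  qc3 <- qcFilter(D3, data.frame(chrom = 1L, pos = seq(1e5, by = 1e5,
                                                       length.out = 20),
                                 id = colnames(D3), a1 = "A", a2 = "G"))
  expect_equal(nrow(qc3$dosages), n - 1)
})

test_that("case/control collapsing uses a strict majority of visits", {
  expect_equal(unname(collapseCaseControl(rep("p", 3),
                                          c("SUD:alcohol", "SUD:drug", "HC"))),
               1L)
  expect_equal(unname(collapseCaseControl(rep("p", 2), c("HC", "HC"))), 0L)
  expect_equal(unname(collapseCaseControl(rep("p", 2), c("SUD", "HC"))), 0L)
  out <- collapseCaseControl(c("a", "a", "b"), c("SUD", "SUD", "HC"))
  expect_equal(out, c(a = 1L, b = 0L))
})

test_that("association tests cover planted effects and flag degeneracy", {
  set.seed(72)
  n <- 1200
  x <- rbinom(n, 2, 0.3)
  covs <- data.frame(age = runif(n, 10, 70))
  # 95% CI coverage for a continuous phenotype over replicates
  hits <- vapply(1:80, function(i) {
    y <- 0.25 * x + 0.01 * covs$age + rnorm(n)
    g <- snpAssociation(cbind(v = x), y, covs)
    abs(g$beta - 0.25) < 1.96 * g$se
  }, logical(1))
  expect_gt(mean(hits), 0.88)
  # binary phenotype: direction and significance
  set.seed(73)
  lp <- -1 + 0.5 * x
  yb <- rbinom(n, 1, plogis(lp))
  gb <- snpAssociation(cbind(v = x), yb, covs)
  expect_gt(gb$z, 2)
  expect_equal(gb$z, gb$beta / gb$se, tolerance = 1e-6)
  # constant dosage flagged missing for both paths
  const <- cbind(v = rep(1L, n))
  expect_true(is.na(snpAssociation(const, yb, covs)$p))
  expect_true(is.na(snpAssociation(const, rnorm(n), covs)$p))
})

test_that("the wGMV score is a weighted centile sum", {
  m <- rbind(a = c(r1 = 0.2, r2 = 0.8), b = c(r1 = 0.5, r2 = 0.5))
  expect_equal(unname(computeWgmv(m, c(r1 = 1, r2 = -1))), c(-0.6, 0))
  expect_equal(unname(computeWgmv(m, c(r1 = 0, r2 = 0))), c(0, 0))
  expect_equal(unname(computeWgmv(m, c(r1 = 0, r2 = 1))), unname(m[, "r2"]))
  expect_error(computeWgmv(m, c(r1 = 1)), "missing")
  m2 <- m; m2["b", "r1"] <- NA
  expect_warning(s <- computeWgmv(m2, c(r1 = 1, r2 = -1)), "skipped")
  expect_equal(length(s), 1L)
})

test_that("LD pruning removes correlated pairs deterministically", {
  set.seed(74)
  n <- 800
  base <- rbinom(n, 2, 0.4)
  # duplicate variants 1kb apart: exactly one survives
  D <- cbind(v1 = base, v2 = base)
  mp <- data.frame(chrom = 1L, pos = c(1000, 2000), id = c("v1", "v2"),
                   maf = c(0.4, 0.4))
  expect_equal(ldPrune(D, mp), "v1")      # tie -> later position dropped
  # independent variants all retained
  Di <- sapply(1:10, function(i) rbinom(n, 2, 0.3))
  colnames(Di) <- sprintf("i%02d", 1:10)
  mpi <- data.frame(chrom = 1L, pos = seq(1000, by = 4000, length.out = 10),
                    id = colnames(Di), maf = 0.3)
  expect_equal(length(ldPrune(Di, mpi)), 10L)
  # chain A-B-C with r2(A,B), r2(B,C) ~ 0.5 and r2(A,C) ~ 0: exhaustive
  # post-check finds no violating pair among the retained set
  mk <- function(src, flipP) ifelse(runif(n) < flipP, rbinom(n, 2, 0.4), src)
  A <- rbinom(n, 2, 0.4); B <- mk(A, 0.25); C <- mk(B, 0.25)
  Dc <- cbind(A = A, B = B, C = C)
  mpc <- data.frame(chrom = 1L, pos = c(1000, 2000, 3000),
                    id = c("A", "B", "C"),
                    maf = pmin(colMeans(Dc) / 2, 1 - colMeans(Dc) / 2))
  kept <- ldPrune(Dc, mpc, r2 = 0.1)
  ki <- match(kept, mpc$id)
  if (length(ki) > 1) {
    for (a in seq_along(ki)) for (b in seq_along(ki)) if (b > a)
      expect_lte(cor(Dc[, ki[a]], Dc[, ki[b]])^2, 0.1)
  }
  # determinism and sortedness guard
  expect_identical(ldPrune(Dc, mpc), ldPrune(Dc, mpc))
  bad <- mpc; bad$pos <- rev(bad$pos)
  expect_error(ldPrune(Dc, bad), "sorted")
})

test_that("retained variants pass an exhaustive pairwise r2 post-check", {
  g <- generateGenotypes(simConfig(seed = 75), n = 1200)
  kept <- ldPrune(g$dosages, g$map)
  ki <- match(kept, g$map$id)
  for (a in seq_along(ki)) {
    for (b in seq_along(ki)) {
      if (b <= a) next
      i <- ki[a]; j <- ki[b]
      if (g$map$chrom[j] != g$map$chrom[i]) next
      if (abs(g$map$pos[j] - g$map$pos[i]) > 50000) next
      expect_lte(cor(g$dosages[, i], g$dosages[, j])^2, 0.1)
    }
  }
})

test_that("polygenic scores align alleles and recover liability", {
  set.seed(76)
  n <- 300
  D <- cbind(v1 = rbinom(n, 2, 0.3), v2 = rbinom(n, 2, 0.4))
  map <- data.frame(chrom = 1, pos = c(1, 2) * 1e5, id = c("v1", "v2"),
                    a1 = c("A", "A"), a2 = c("G", "G"))
  w0 <- data.frame(id = c("v1", "v2"), a1 = c("A", "A"), a2 = c("G", "G"),
                   beta = c(0, 0))
  expect_equal(as.numeric(pgsScore(D, map, w0)), rep(0, n))
  w1 <- data.frame(id = "v1", a1 = "A", a2 = "G", beta = 1)
  expect_equal(as.numeric(pgsScore(D, map, w1)), as.numeric(D[, "v1"]))
  # swapped alleles flip the dosage
  wS <- data.frame(id = "v1", a1 = "G", a2 = "A", beta = 1)
  expect_equal(as.numeric(pgsScore(D, map, wS)), as.numeric(2 - D[, "v1"]))
  # unresolvable alleles are dropped and counted
  wB <- data.frame(id = c("v1", "v2"), a1 = c("T", "A"), a2 = c("C", "G"),
                   beta = c(5, 1))
  sB <- pgsScore(D, map, wB)
  expect_equal(attr(sB, "dropped"), 1L)
  expect_equal(as.numeric(sB), as.numeric(D[, "v2"]))
  # true causal betas recover the latent liability
  cfg <- oneStudyConfig(77, 2000)
  sim <- generateCohort(cfg)
  w <- data.frame(id = sim$geno$causal$id, a1 = "A", a2 = "G",
                  beta = sim$geno$causal$beta_sud)
  pgs <- pgsScore(sim$geno$dosages, sim$geno$map, w)
  expect_gt(cor(pgs, sim$manifest$participants$liability), 0.3)
})

test_that("PGS genetic correlation is calibrated and scale-invariant", {
  set.seed(78)
  n <- 800
  pgs <- rnorm(n)
  y0 <- rnorm(n)
  covs <- data.frame(age = runif(n, 10, 70))
  g0 <- pgsGeneticCorrelation(pgs, y0, covs)
  expect_lt(abs(g0$slope), 3 * g0$se)
  expect_true(g0$uncorrected)
  y1 <- 0.3 * pgs + rnorm(n)
  g1 <- pgsGeneticCorrelation(pgs, y1, covs)
  g1s <- pgsGeneticCorrelation(pgs * 17 + 3, y1, covs)
  expect_equal(g1$r2, g1s$r2, tolerance = 1e-10)
  expect_lt(g1$p, 0.001)
  expect_error(pgsGeneticCorrelation(rep(1, n), y1), "constant")
  expect_error(pgsGeneticCorrelation(pgs[1:50], y1[1:50]), "100")
})

test_that("conditional FDR matches brute-force counting exactly", {
  # uninformative conditioning trait
  p1 <- seq(0.01, 0.10, by = 0.01)
  p2 <- rep(1, 10)
  cf <- condFdr(p1, p2)
  expect_equal(cf[1], 0.01 * 10 / 1)
  expect_equal(cf, bruteCondFdr(p1, p2))
  # perfect pleiotropy
  u <- (1:50) / 50
  expect_equal(condFdr(u, u), bruteCondFdr(u, u))
  # random inputs, exact agreement, and the cfdr >= p1 bound
  set.seed(79)
  for (i in 1:3) {
    a <- runif(400); b <- runif(400)
    cf <- condFdr(a, b)
    expect_identical(cf, bruteCondFdr(a, b))
    expect_true(all(cf >= a))
  }
  expect_error(condFdr(c(0, 0.5), c(0.5, 0.5)), "0, 1")
  expect_error(condFdr(0.5, c(0.5, 0.5)), "match")
})

test_that("conjunctional FDR is the elementwise maximum with locus calling", {
  cj <- conjFdr(c(0.01, 0.2), c(0.03, 0.1))
  expect_equal(cj$conjfdr, c(0.03, 0.2))
  a <- runif(50); b <- runif(50)
  cj2 <- conjFdr(a, b)$conjfdr
  expect_true(all(cj2 >= a & cj2 >= b))
  # clumping: two significant variants 10kb apart form one locus
  map <- data.frame(id = c("x", "y", "z"), chrom = 1L,
                    pos = c(1e5, 1.1e5, 9e5))
  cj3 <- conjFdr(c(0.01, 0.02, 0.5), c(0.02, 0.03, 0.6), map = map)
  expect_equal(nrow(cj3$loci), 1L)
  expect_equal(cj3$loci$id, "x")
})

test_that("gene-PGS group comparison has symmetric effect signs", {
  set.seed(80)
  pgs <- rnorm(400)
  grp <- rep(c("HC", "SUD"), 200)
  g0 <- genePgsCompare(pgs, grp)
  expect_lt(abs(g0$d), 0.3)
  shift <- pgs + 0.5 * (grp == "SUD")
  g1 <- genePgsCompare(shift, grp)
  g2 <- genePgsCompare(shift, ifelse(grp == "SUD", "HC", "SUD"))
  expect_equal(g1$d, -g2$d, tolerance = 1e-10)
  expect_lt(g1$p, 0.01)
  expect_error(genePgsCompare(pgs[1:15], grp[1:15]), "at least 10")
})

test_that("GWAS summary statistics round-trip through the TSV format", {
  g <- generateGenotypes(simConfig(seed = 81), n = 300)
  set.seed(82)
  gw <- snpAssociation(g$dosages[, 1:20], rnorm(300), map = g$map[1:20, ])
  path <- withr::local_tempfile(fileext = ".tsv")
  writeGwasTable(gw, path)
  rt <- readGwasTable(path)
  expect_equal(rt$beta, gw$beta)
  expect_equal(rt$z, gw$z, tolerance = 1e-6)
  expect_error(readGwasTable(withr::local_tempfile(lines = "A\tB")), "lack")
})
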