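test_that("covariate adjustment removes planted confounder effects", {
  set.seed(14)
  n <- 2000
  sex <- rbinom(n, 1, 0.5)
  study <- sample(c("a", "b"), n, TRUE)
  base <- rnorm(n, 5000, 300)
  v <- base + 100 * sex + 50 * (study == "b")
  adj <- adjustCovariates(v, data.frame(sex = sex, hand = 1, study = study))
  expect_lt(abs(mean(adj[sex == 1]) - mean(adj[sex == 0])), 5)
  # no covariate effect: adjusted stays close to raw
  adj0 <- adjustCovariates(base, data.frame(sex = sex, study = study))
  expect_gt(cor(adj0, base), 0.999)
  # location equivariance
  expect_equal(adjustCovariates(v + 123, data.frame(sex = sex)),
               adjustCovariates(v, data.frame(sex = sex)) + 123,
               tolerance = 1e-8)
  expect_error(adjustCovariates(v, data.frame(sex = c(NA, sex[-1]))),
               "complete")
})

test_that("spline trajectories nest straight lines and scale their SEs", {
  set.seed(15)
  ages <- runif(300, 8, 70)
  line <- 100 + 3 * ages
  tr <- fitGroupTrajectory(line, ages)
  grid <- seq(8, 70, by = 0.05)
  expect_lt(max(abs(predict(tr, grid)$mean - (100 + 3 * grid))), 1e-6)
  # duplicating every row shrinks se(a) by ~1/sqrt(2)
  noisy <- line + rnorm(300, 0, 40)
  t1 <- fitGroupTrajectory(noisy, ages)
  t2 <- fitGroupTrajectory(rep(noisy, 2), rep(ages, 2))
  ratio <- predict(t2, grid)$se / predict(t1, grid)$se
  expect_equal(mean(ratio), 1 / sqrt(2), tolerance = 0.02)
  # quadratic truth recovered
  quad <- 5000 + 20 * ages - 0.3 * ages^2 + rnorm(300, 0, 30)
  tq <- fitGroupTrajectory(quad, ages)
  mid <- seq(15, 63, by = 1)
  expect_lt(max(abs(predict(tq, mid)$mean - (5000 + 20 * mid - 0.3 * mid^2))),
            40)
  expect_error(fitGroupTrajectory(noisy, rep(20, 300)), "identical")
  expect_error(fitGroupTrajectory(noisy[1:10], ages[1:10]), "at least 30")
})

test_that("identical groups give zero divergence; label swap negates z", {
  set.seed(16)
  ages <- runif(400, 8, 70)
  v <- 4000 + 10 * ages + rnorm(400, 0, 200)
  tA <- fitGroupTrajectory(v, ages, "SUD")
  tB <- fitGroupTrajectory(v, ages, "HC")
  g <- divergenceGrid(tA, tB)
  expect_true(all(abs(zStat(g)) < 1e-10))
  expect_equal(nrow(sigWindows(g)), 0L)
  # antisymmetry under group swap
  v2 <- v + 30 * (ages > 40)
  tS <- fitGroupTrajectory(v2[1:200], ages[1:200], "SUD")
  tH <- fitGroupTrajectory(v[201:400], ages[201:400], "HC")
  g1 <- divergenceGrid(tS, tH)
  g2 <- divergenceGrid(tH, tS)
  expect_equal(zStat(g1), -zStat(g2), tolerance = 1e-12)
  expect_error(divergenceGrid(tS, NULL), "required")
})

test_that("the grid matches a brute-force pointwise recomputation", {
  sim <- generateCohort(oneStudyConfig(44, 1500, geno_truth = NULL,
                                       rois = miniRois()))
  df <- sim$scans
  isSud <- startsWith(df$group, "SUD")
  adj <- adjustCovariates(df$L_insula, df[c("sex", "hand", "study")])
  tS <- fitGroupTrajectory(adj[isSud], df$age[isSud], "SUD")
  tH <- fitGroupTrajectory(adj[!isSud], df$age[!isSud], "HC")
  g <- divergenceGrid(tS, tH)
  sub <- seq(10, 67, by = 3)
  idx <- match(round(sub, 2), round(gridAges(g), 2))
  for (k in seq_along(sub)) {
    a <- sub[k]
    bf <- function(tr) {
      X <- cbind(1, splines::ns(a, knots = tr$knots,
                                Boundary.knots = tr$boundary))
      c(drop(X %*% tr$coef), sqrt(drop(X %*% tr$vcov %*% t(X))))
    }
    s <- bf(tS); h <- bf(tH)
    zExp <- (s[1] - h[1]) / sqrt(s[2]^2 + h[2]^2)
    expect_equal(zStat(g)[idx[k]], zExp, tolerance = 1e-10)
  }
})

test_that("Benjamini-Hochberg q-values match a brute-force step-up", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.037), 0.037)
  expect_equal(bhFdr(rep(1, 6)), rep(1, 6))
  expect_identical(bhFdr(numeric(0)), numeric(0))
  set.seed(17)
  for (i in 1:5) {
    p <- round(runif(200), 3)
    expect_equal(bhFdr(p), bruteBH(p), tolerance = 1e-12)
  }
  expect_error(bhFdr(c(0.5, 1.2)), "0, 1")
})

test_that("significance trajectory is flat under the null, crosses twice
           around one significant block", {
  ages <- seq(8, 70, by = 0.05)
  n <- length(ages)
  flat <- new("DivergenceGrid", roi = "r", ages = ages,
              mHC = numeric(n), seHC = rep(1, n), mSUD = numeric(n),
              seSUD = rep(1, n), z = numeric(n), p = rep(1, n),
              q = rep(1, n), valid = rep(TRUE, n),
              windows = data.frame(lo = numeric(0), hi = numeric(0)),
              alpha = 0.05)
  st <- significanceTrajectory(flat)
  expect_true(all(st$smooth == 0))
  expect_length(st$crossings, 0)
  # one strong contiguous block: exactly two level crossings
  z <- 6 * exp(-(ages - 40)^2 / 20)
  p <- 2 * pnorm(-abs(z))
  blk <- new("DivergenceGrid", roi = "r", ages = ages,
             mHC = numeric(n), seHC = rep(1, n), mSUD = z, seSUD = rep(1, n),
             z = z, p = p, q = bhFdr(p), valid = rep(TRUE, n),
             windows = data.frame(lo = numeric(0), hi = numeric(0)),
             alpha = 0.05)
  stb <- significanceTrajectory(blk)
  expect_length(stb$crossings, 2)
  expect_true(all(stb$crossings > 30 & stb$crossings < 50))
})

test_that("inverse-variance meta-analysis follows the closed form", {
  m <- ivwMeta(c(1, 3), c(1, 1))
  expect_equal(m$estimate, 2)
  expect_equal(m$se, sqrt(0.5), tolerance = 1e-10)
  one <- ivwMeta(2.5, 0.3)
  expect_equal(one$estimate, 2.5)
  expect_equal(one$se, 0.3)
  # a vanishing SE dominates the pool
  lim <- ivwMeta(c(1, 5), c(1e-8, 1))
  expect_equal(lim$estimate, 1, tolerance = 1e-10)
  expect_error(ivwMeta(c(1, 2), 1), "length")
  expect_error(ivwMeta(1, 0), "> 0")
})

test_that("consistency correlation behaves at its extremes", {
  z <- sin(seq(0, 3, length.out = 50))
  expect_equal(consistencyCorrelation(z, z), 1)
  expect_equal(consistencyCorrelation(z, -z), -1)
  expect_true(is.na(consistencyCorrelation(z[1:2], z[1:2])))
  # noisier validation curves have lower but positive mean correlation
  set.seed(18)
  rNoise <- vapply(c(0.5, 2), function(s) {
    mean(replicate(20, consistencyCorrelation(z, z + rnorm(50, 0, s))))
  }, numeric(1))
  expect_true(all(rNoise > 0 & rNoise < 1))
  expect_gt(rNoise[1], rNoise[2])
})

test_that("centile-pattern clustering recovers planted ROI blocks", {
  set.seed(19)
  n <- 400
  f1 <- rnorm(n); f2 <- rnorm(n)
  mk <- function(f) sqrt(0.8) * f + sqrt(0.2) * rnorm(n)
  M <- cbind(a1 = mk(f1), a2 = mk(f1), a3 = mk(f1),
             b1 = mk(f2), b2 = mk(f2), b3 = mk(f2))
  cl <- clusterCentilePatterns(M, k = 2)
  expect_equal(length(unique(cl$labels[1:3])), 1L)
  expect_equal(length(unique(cl$labels[4:6])), 1L)
  expect_false(cl$labels[1] == cl$labels[4])
  # input order invariance (same partition of ROI names)
  perm <- c(4, 1, 5, 2, 6, 3)
  cl2 <- clusterCentilePatterns(M[, perm], k = 2)
  part <- function(lab) sort(vapply(split(names(lab), lab),
                                    function(g) paste(sort(g), collapse = "+"),
                                    character(1)))
  expect_equal(unname(part(cl$labels)), unname(part(cl2$labels)))
  # single ROI: one cluster, constant column dropped with warning
  expect_equal(unname(clusterCentilePatterns(M[, 1, drop = FALSE])$labels),
               1L)
  M2 <- cbind(M, const = rep(0.5, n))
  expect_warning(cl3 <- clusterCentilePatterns(M2, k = 2), "constant")
  expect_equal(cl3$dropped, "const")
})

test_that("substance-subgroup rerun reuses the full-group code path", {
  cfg <- oneStudyConfig(55, 1200, geno_truth = NULL, rois = miniRois(),
                        substances = "alcohol")
  sim <- generateCohort(cfg)
  full <- roiDivergence(sim$scans, "L_insula")
  sub <- roiDivergence(sim$scans, "L_insula", subgroup = "alcohol")
  expect_equal(zStat(sub), zStat(full), tolerance = 1e-12)
  expect_equal(sigWindows(sub), sigWindows(full))
})
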