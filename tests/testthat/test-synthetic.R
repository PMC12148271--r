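test_that("cohort generation is bit-for-bit deterministic under a seed", {
  cfg <- oneStudyConfig(5, 150)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(a$scans, b$scans)
  expect_identical(a$behavior, b$behavior)
  expect_identical(a$geno$dosages, b$geno$dosages)
  expect_identical(a$manifest$participants, b$manifest$participants)
})

test_that("invalid configurations are rejected with a message", {
  expect_error(oneStudyConfig(1, -5), "positive")
  expect_error(oneStudyConfig(1, 10, ageLow = 50, ageHigh = 20), "age_low")
  r <- defaultRois(); r$category[1] <- "weird"
  expect_error(oneStudyConfig(1, 10, rois = r), "unknown ROI category")
  expect_error(oneStudyConfig(1, 10, geno_truth = list(
    m = 100L, block = 4L, rho = 1.2, maf = c(0.05, 0.5), n_causal_sud = 2L,
    n_causal_brain = 2L, n_shared = 1L, beta_sd = 1, roi_effect = 0)),
    "rho")
})

test_that("zero SUD amplitude leaves no group difference beyond chance", {
  sim <- generateCohort(nullConfig(3, 4000))
  isSud <- startsWith(sim$scans$group, "SUD")
  for (rc in miniRois()$name) {
    v <- sim$scans[[rc]]
    d <- mean(v[isSud]) - mean(v[!isSud])
    se <- sqrt(var(v[isSud]) / sum(isSud) + var(v[!isSud]) / sum(!isSud))
    expect_lt(abs(d), 3 * se)
  }
})

test_that("a 0.5-SD mid-life offset reproduces the configured Cohen's d", {
  r <- defaultRois()
  cfg <- oneStudyConfig(17, 8000, ageLow = 38, ageHigh = 52,
                        rois = r[r$name == "L_insula", ],
                        sud_effects = list(early = 0, late = 0,
                                           mid = function(a) 0.5),
                        prevalence = list(base = 0, peak = 25, width = 12,
                                          amplitude = 0),
                        liability = list(geno = 0, impulsivity = 0),
                        geno_truth = NULL,
                        batch_effects = list(shift_sd = 0, scale_sd = 0))
  sim <- generateCohort(cfg)
  s <- sim$scans[sim$scans$age >= 40 & sim$scans$age <= 50, ]
  isSud <- startsWith(s$group, "SUD")
  v <- log(s$L_insula)
  v <- v - fitted(lm(v ~ poly(s$age, 2)))   # strip the age trend
  sp <- sqrt(((sum(isSud) - 1) * var(v[isSud]) +
                (sum(!isSud) - 1) * var(v[!isSud])) / (length(v) - 2))
  d <- (mean(v[isSud]) - mean(v[!isSud])) / sp
  expect_lt(abs(d - 0.5), 0.1)
})

test_that("SUD prevalence follows the configured age curve", {
  cfg <- oneStudyConfig(23, 6000, geno_truth = NULL)
  sim <- generateCohort(cfg)
  isSud <- startsWith(sim$scans$group, "SUD")
  for (win in list(c(8, 20), c(20, 35), c(35, 55), c(55, 70))) {
    inw <- sim$scans$age >= win[1] & sim$scans$age < win[2]
    pHat <- mean(isSud[inw])
    pTrue <- mean(truePrevalence(cfg, sim$scans$age[inw]))
    se <- sqrt(pTrue * (1 - pTrue) / sum(inw))
    expect_lt(abs(pHat - pTrue), 4 * se)
  }
})

test_that("healthy-control volumes are uniform centiles under the truth", {
  cfg <- oneStudyConfig(31, 3000, batch_effects = list(shift_sd = 0,
                                                       scale_sd = 0),
                        geno_truth = NULL, rois = miniRois())
  sim <- generateCohort(cfg)
  hc <- sim$scans[sim$scans$group == "HC", ][1:2000, ]
  tm <- trueNormativeModel(cfg, "L_insula")
  ct <- scoreCentiles(list(L_insula = tm), hc)
  expect_gt(ks.test(ct$centile, "punif")$p.value, 0.01)
})

test_that("uncorrelated genotype blocks have near-zero dosage correlation", {
  cfg <- simConfig(seed = 12, geno_truth = list(
    m = 120L, block = 4L, rho = 0, maf = c(0.05, 0.5), n_causal_sud = 2L,
    n_causal_brain = 2L, n_shared = 1L, beta_sd = 1, roi_effect = 0))
  g <- generateGenotypes(cfg, n = 2000)
  cc <- cor(g$dosages)
  expect_lt(median(abs(cc[upper.tri(cc)])), 0.05)
})

test_that("variant map positions increase within chromosome", {
  g <- generateGenotypes(simConfig(seed = 9), n = 100)
  byChr <- split(g$map$pos, g$map$chrom)
  expect_true(all(vapply(byChr, function(p) all(diff(p) > 0), logical(1))))
})

test_that("block length 1 leaves nothing for LD pruning to remove", {
  cfg <- simConfig(seed = 13, geno_truth = list(
    m = 150L, block = 1L, rho = 0, maf = c(0.1, 0.5), n_causal_sud = 2L,
    n_causal_brain = 2L, n_shared = 1L, beta_sd = 1, roi_effect = 0))
  g <- generateGenotypes(cfg, n = 2000)
  keep <- ldPrune(g$dosages, g$map)
  expect_gte(length(keep), ncol(g$dosages) - 2)
})

test_that("atlas centroids sit on the unit sphere", {
  atl <- generateAtlas(simConfig(seed = 2))
  expect_lt(max(abs(sqrt(rowSums(atl$centroids^2)) - 1)), 1e-12)
  C <- fibonacciSphere(500)
  expect_lt(max(abs(sqrt(rowSums(C^2)) - 1)), 1e-12)
})

test_that("noise-free term maps recover the true loading pattern", {
  cfg <- simConfig(seed = 6, atlas_truth = list(
    n_terms = 40L, n_parcels = 48L, n_factors = 4L, bandwidth = 0.5,
    noise = 0))
  atl <- generateAtlas(cfg)
  fs <- atlasFactorAnalysis(atl$terms)
  expect_gte(ncol(fs@loadings), 4)
  # recovery is defined up to sign/rotation: Procrustes-align first
  Lhat <- fs@loadings[, 1:4]
  sv <- svd(crossprod(Lhat, atl$truth$loadings))
  aligned <- Lhat %*% (sv$u %*% t(sv$v))
  cg <- vapply(1:4, function(f)
    abs(sum(aligned[, f] * atl$truth$loadings[, f])) /
      sqrt(sum(aligned[, f]^2) * sum(atl$truth$loadings[, f]^2)),
    numeric(1))
  expect_true(all(cg > 0.95))
})

test_that("spatial autocorrelation increases with the smoothing bandwidth", {
  mi <- vapply(c(0.2, 0.5, 1.0), function(bw) {
    atl <- generateAtlas(simConfig(seed = 4, atlas_truth = list(
      n_terms = 30L, n_parcels = 48L, n_factors = 4L, bandwidth = bw,
      noise = 0.2)))
    mean(apply(atl$terms, 1, lifespanSUD:::.moranI,
               centroids = atl$centroids))
  }, numeric(1))
  expect_true(all(diff(mi) > 0))
  expect_error(generateAtlas(simConfig(seed = 4, atlas_truth = list(
    n_terms = 30L, n_parcels = 48L, n_factors = 4L, bandwidth = -1,
    noise = 0.2))), "bandwidth")
})

test_that("follow-up generation respects probability, interval and truth", {
  cfg <- nullConfig(7, 400)
  sim <- generateCohort(cfg)
  cfg0 <- cfg; cfg0$followup$prob <- 0
  expect_identical(generateFollowup(sim$scans, cfg0), sim$scans)
  cfgNeg <- cfg; cfgNeg$followup$interval <- -1
  expect_error(generateFollowup(sim$scans, cfgNeg), "interval")
  lf <- generateFollowup(sim$scans, cfg)
  f2 <- lf[lf$visit == 2, ]
  b <- lf[lf$visit == 1 & lf$pid %in% f2$pid, ]
  expect_equal(f2$age, b[match(f2$pid, b$pid), "age"] + cfg$followup$interval)
  expect_gt(cor(b[match(f2$pid, b$pid), "L_insula"], f2$L_insula), 0)
})

test_that("longitudinal change-rate regression recovers the planted slope", {
  # zero slope difference: group coefficient within 3 SEs of 0
  cfg0 <- nullConfig(19, 1500)
  cfg0$followup <- list(prob = 1, interval = 2, sud_decline = 0,
                        noise = 0.015)
  lf0 <- generateFollowup(generateCohort(cfg0)$scans, cfg0)
  r0 <- longitudinalChangeRate(lf0, "L_insula")
  expect_lt(abs(r0$estimate), 3 * r0$se)
  # -0.5 %/yr planted: recovered within 0.15 %/yr
  cfg1 <- nullConfig(20, 3000)
  cfg1$followup <- list(prob = 1, interval = 2, sud_decline = -0.005,
                        noise = 0.015)
  lf1 <- generateFollowup(generateCohort(cfg1)$scans, cfg1)
  r1 <- longitudinalChangeRate(lf1, "L_insula")
  expect_lt(abs(r1$estimate - (-0.5)), 0.15)
  # group-coding flip changes the sign
  flip <- lf1
  flip$group <- ifelse(startsWith(flip$group, "SUD"), "HC", "SUD")
  expect_equal(longitudinalChangeRate(flip, "L_insula")$estimate,
               -r1$estimate, tolerance = 1e-8)
})

test_that("ScanSet round-trips a scan table and validates it", {
  sim <- generateCohort(oneStudyConfig(2, 60, geno_truth = NULL))
  ss <- ScanSet(sim$scans)
  expect_s4_class(ss, "ScanSet")
  expect_equal(sort(rois(ss)), sort(defaultRois()$name))
  back <- lifespanSUD:::.scanFrame(ss)
  expect_equal(back$age, sim$scans$age)
  expect_equal(back$L_insula, sim$scans$L_insula)
  bad <- sim$scans
  bad$L_insula[1] <- -5
  expect_error(ScanSet(bad), "positive")
  bad2 <- sim$scans
  bad2$group[2] <- "sick"
  expect_error(ScanSet(bad2), "group")
})

test_that("manifest and table writers produce readable plain-text files", {
  sim <- generateCohort(oneStudyConfig(2, 40))
  d <- withr::local_tempdir()
  writeManifest(sim$manifest, d)
  expect_true(file.exists(file.path(d, "manifest.tsv")))
  side <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(side$seed, 2)
  writeScans(sim$scans, file.path(d, "scans.tsv"))
  rt <- readScans(file.path(d, "scans.tsv"))
  expect_equal(rt$L_insula, sim$scans$L_insula)
  writeGenotypes(sim$geno, d)
  writeGenotypesVcf(sim$geno, file.path(d, "geno.vcf"))
  first <- readLines(file.path(d, "geno.vcf"), n = 1)
  expect_match(first, "VCFv4.2")
})
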