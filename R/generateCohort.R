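#' Generate a synthetic multi-cohort lifespan dataset with known ground truth
#'
#' Draws participants per study with cohort-specific age windows, assigns SUD
#' labels through a logistic liability combining genetic burden, the latent
#' impulsivity factor and an age-dependent prevalence offset, and samples ROI
#' volumes from the configured generalized-gamma normative truth with
#' per-category SUD offsets and per-scanner batch effects. Behavioral
#' instrument scores are generated from the latent rule-breaking and
#' impulsivity factors per study block. Every sampled latent quantity is
#' recorded in the ground-truth manifest.
#'
#' @param config a [simConfig()].
#' @param seed RNG seed (defaults to `config$seed`); identical config and
#'   seed reproduce all tables bit-for-bit.
#' @return list with elements `scans` (one row per baseline visit: `pid`,
#'   `study`, `scanner`, `visit`, `age`, `sex`, `hand`, `group`, one column
#'   per ROI), `behavior` (instrument scores per study block), `geno`
#'   (dosage matrix, variant map and causal table, or `NULL`), and `manifest`
#'   (participant-level truth, ROI truth, scanner effects, causal variants).
#' @examples
#' cfg <- simConfig(seed = 7, studies = data.frame(
#'   name = "demo", age_low = 10, age_high = 60, n = 80,
#'   sex_ratio = 0.5, n_scanners = 2), geno_truth = NULL)
#' sim <- generateCohort(cfg)
#' head(sim$scans[, 1:10])
#' @export
generateCohort <- function(config, seed = config$seed) {
  .validateConfig(config)
  set.seed(seed)
  st <- config$studies
  parts <- do.call(rbind, lapply(seq_len(nrow(st)), function(i) {
    n <- st$n[i]
    data.frame(
      pid = sprintf("%s_%05d", st$name[i], seq_len(n)),
      study = st$name[i],
      scanner = paste0(st$name[i], "_sc",
                       sample.int(st$n_scanners[i], n, replace = TRUE)),
      visit = 1L,
      age = runif(n, st$age_low[i], st$age_high[i]),
      sex = rbinom(n, 1L, st$sex_ratio[min(i, length(st$sex_ratio))]),
      hand = rbinom(n, 1L, 0.9))
  }))
  n <- nrow(parts)

  ## genetic burden and brain genetic shift
  geno <- NULL
  if (!is.null(config$geno_truth)) {
    geno <- .genGenotypes(config, n, ids = parts$pid)
    burden <- geno$burden
    brainShift <- geno$brainShift
    roiEffect <- config$geno_truth$roi_effect
  } else {
    burden <- rnorm(n)
    brainShift <- numeric(n)
    roiEffect <- 0
  }

  ## latent behavioral factors
  bt <- config$behavior_truth
  fImp <- rnorm(n)
  fRb <- bt$factor_cor * fImp + sqrt(1 - bt$factor_cor^2) * rnorm(n)

  ## liability and group label
  liab <- config$liability$geno * burden +
    config$liability$impulsivity * fImp + .prevOffset(config, parts$age)
  sud <- (liab + rlogis(n)) > 0
  substance <- sample(config$substances, n, replace = TRUE)
  parts$group <- ifelse(sud, paste0("SUD:", substance), "HC")

  ## scanner batch effects (log-scale shift and scale)
  scanners <- sort(unique(parts$scanner))
  be <- data.frame(
    scanner = scanners,
    shift = rnorm(length(scanners), 0, config$batch_effects$shift_sd),
    scale = rnorm(length(scanners), 0, config$batch_effects$scale_sd))
  sidx <- match(parts$scanner, be$scanner)

  ## per-study log-location offsets
  ft <- config$fp_truth
  studyOff <- setNames(rnorm(nrow(st), 0, ft$study_sd), st$name)
  studyOff <- studyOff - studyOff[1]     # first study is the reference

  ## ROI volumes
  x <- fpBasis(parts$age, ft$powers_mu)
  ageTrend <- drop(x %*% ft$beta_age)
  sigma <- ft$sigma0 * exp(ft$sigma_slope * parts$age / 10)
  fRbShifted <- fRb + bt$rb_shift * sud
  vol <- matrix(NA_real_, n, nrow(config$rois),
                dimnames = list(NULL, config$rois$name))
  for (r in seq_len(nrow(config$rois))) {
    roi <- config$rois[r, ]
    off <- .sudOffsetFun(config, roi$category)(parts$age) * sud
    logmu <- log(roi$base_mm3) + ageTrend + ft$sex_effect * parts$sex +
      ft$hand_effect * parts$hand + studyOff[parts$study] +
      (off + roiEffect * brainShift) * sigma
    raw <- ggRandom(n, exp(logmu), sigma, ft$nu)
    vol[, r] <- exp(logmu + (log(raw) - logmu) * (1 + be$scale[sidx]) +
                      be$shift[sidx])
  }
  scans <- cbind(parts, as.data.frame(vol))
  rownames(scans) <- NULL

  ## behavioral instrument scores, one block per study
  behavior <- .genBehavior(config, parts, fRbShifted, fImp)

  manifest <- list(
    participants = data.frame(
      pid = parts$pid, study = parts$study, age = parts$age,
      sex = parts$sex, hand = parts$hand, group = parts$group,
      substance = ifelse(sud, substance, ""),
      burden = burden, brain_shift = brainShift,
      f_impulsivity = fImp, f_rule_breaking = fRbShifted,
      liability = liab),
    rois = config$rois,
    fp_truth = ft,
    study_offsets = studyOff,
    scanner_effects = be,
    causal = if (is.null(geno)) NULL else geno$causal,
    seed = seed)
  list(scans = scans, behavior = behavior,
       geno = if (is.null(geno)) NULL else
         geno[c("dosages", "map", "causal", "burden", "brainShift")],
       manifest = manifest)
}

.genBehavior <- function(config, parts, fRb, fImp) {
  bt <- config$behavior_truth
  k <- bt$n_per_factor
  out <- parts[c("pid", "study", "age", "sex", "hand", "group")]
  for (s in unique(parts$study)) {
    i <- parts$study == s
    ni <- sum(i)
    for (j in seq_len(k)) {
      rb <- bt$loading * fRb[i] + bt$cross * fImp[i] + rnorm(ni, 0, bt$noise)
      im <- bt$loading * fImp[i] + bt$cross * fRb[i] + rnorm(ni, 0, bt$noise)
      out[i, paste0(s, "_rb", j)] <- rb
      out[i, paste0(s, "_imp", j)] <- im
    }
  }
  out
}

#' Write the ground-truth manifest
#'
#' Participant-level truth goes to a flat TSV; the remaining truth (ROI model,
#' study offsets, scanner effects, causal variants, seed) to a JSON sidecar.
#'
#' @param manifest manifest element of [generateCohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
writeManifest <- function(manifest, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "manifest.tsv")
  json <- file.path(dir, "manifest.json")
  write.table(manifest$participants, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  side <- manifest[setdiff(names(manifest), "participants")]
  jsonlite::write_json(side, json, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(tsv, json))
}
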