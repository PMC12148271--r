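#' Default addiction-circuit ROI set
#'
#' Twenty-four regions (12 bilateral structures) spanning striatum, amygdala,
#' hippocampus, insula, anterior cingulate and prefrontal subregions, each
#' assigned to one temporal class of SUD-HC divergence: `early` (group
#' differences largest in adolescence, decaying by ~25y), `mid` (a bump
#' centred in the mid-40s) or `late` (monotone increase after 45y).
#' `base_mm3` is the location of the volume distribution at the trajectory
#' reference, in mm^3 per hemisphere.
#'
#' @return data.frame with columns `name`, `structure`, `category`,
#'   `hemisphere`, `base_mm3`.
#' @export
defaultRois <- function() {
  s <- data.frame(
    structure = c("accumbens", "caudate", "putamen", "frontal_pole",
                  "superior_frontal", "insula", "rostral_acc", "lateral_ofc",
                  "amygdala", "hippocampus", "medial_ofc", "caudal_acc"),
    category = c("early", "early", "early", "early",
                 "early", "mid", "mid", "mid",
                 "late", "late", "late", "late"),
    base_mm3 = c(550, 3600, 5000, 4000,
                 22000, 7000, 2500, 7500,
                 1600, 4200, 5500, 2000))
  out <- rbind(transform(s, hemisphere = "L"), transform(s, hemisphere = "R"))
  out$name <- paste(out$hemisphere, out$structure, sep = "_")
  out[order(out$structure, out$hemisphere),
      c("name", "structure", "category", "hemisphere", "base_mm3")]
}

#' Simulation configuration for the synthetic multi-cohort generator
#'
#' Bundles every ground-truth quantity of the generative model: cohort age
#' windows and sizes, the fractional-polynomial age trend and generalized
#' gamma noise of each ROI, scanner batch effects, the three temporal classes
#' of SUD-HC volume offsets, the latent rule-breaking/impulsivity behavioral
#' factors, the LD-blocked genotype architecture linking genetic burden to
#' both SUD liability and ROI volumes, the spatially autocorrelated
#' term-by-parcel atlas, and longitudinal follow-up. Defaults are the study
#' conditions used throughout the test-suite simulations.
#'
#' @param seed integer RNG seed; regenerating with the same configuration and
#'   seed reproduces every table bit-for-bit.
#' @param studies data.frame: `name`, `age_low`, `age_high` (years), `n`,
#'   `sex_ratio` (proportion coded 1), `n_scanners`.
#' @param rois data.frame as returned by [defaultRois()].
#' @param fp_truth true normative model: `powers_mu` (fractional-polynomial
#'   powers of the location trend), `beta_age` (their coefficients on the log
#'   scale), `sigma0` and `sigma_slope` (log-dispersion intercept/trend in
#'   x = age/10), `nu` (power shape), `sex_effect`, `hand_effect` and
#'   `study_sd` (SD of per-study log-location offsets).
#' @param batch_effects per-scanner multiplicative shift (`shift_sd`) and
#'   scale (`scale_sd`) perturbations on the log volume.
#' @param sud_effects per-category SUD-HC offsets in units of sigma(age):
#'   either an amplitude (value of the canonical shape at its reference age)
#'   or a function of age. Canonical shapes: `early` decays as
#'   exp(-(a-8)/6) (negligible past 25y), `mid` is a Gaussian bump centred at
#'   45y (SD 8y), `late` rises linearly after 45y reaching the amplitude at
#'   70y.
#' @param prevalence age-dependent SUD prevalence offset on the logit scale:
#'   `base + amplitude * exp(-(age-peak)^2 / (2 width^2))`.
#' @param liability coefficients of the latent liability
#'   `geno * burden + impulsivity * f_imp + prevalence(age)` to which
#'   standard-logistic noise is added; SUD label = liability above 0.
#' @param behavior_truth instrument loading structure per study block:
#'   `loading` (primary), `cross` (secondary), `noise` SD,
#'   `n_per_factor` instruments per factor, `rb_shift` added to the latent
#'   rule-breaking factor of SUD participants, `factor_cor` between the two
#'   latent factors.
#' @param geno_truth genotype architecture: `m` variants in AR(1) latent
#'   blocks of `block` variants with correlation `rho`, MAF uniform on `maf`,
#'   `n_causal_sud` / `n_causal_brain` causal variants (`n_shared` in both
#'   sets), and `roi_effect` (SD units of log-volume shift per SD of brain
#'   genetic burden). Set to `NULL` to skip genotype generation.
#' @param atlas_truth term-map atlas: `n_terms`, `n_parcels`, `n_factors`
#'   spatial factors, geodesic smoothing `bandwidth` (radians) and residual
#'   `noise` SD.
#' @param followup revisit probability `prob`, `interval` (years),
#'   `sud_decline` (extra fractional volume change per year in SUD, e.g.
#'   -0.005 = -0.5\%/yr) and residual `noise` SD on the log change.
#' @param substances substance labels assigned to SUD participants.
#' @return a validated list of class `simConfig`.
#' @export
simConfig <- function(seed = 1L,
    studies = data.frame(
      name = c("devcohort", "adolcohort", "youngadult", "aging"),
      age_low = c(9, 14, 22, 45), age_high = c(11, 23, 37, 70),
      n = c(1200, 700, 600, 1500), sex_ratio = 0.5,
      n_scanners = c(3L, 4L, 2L, 3L)),
    rois = defaultRois(),
    fp_truth = list(powers_mu = c(1, 2), beta_age = c(0.12, -0.022),
                    sigma0 = 0.12, sigma_slope = -0.02, nu = 0.6,
                    sex_effect = 0.08, hand_effect = 0, study_sd = 0.02),
    batch_effects = list(shift_sd = 0.03, scale_sd = 0.05),
    sud_effects = list(early = -0.35, mid = 0.30, late = -0.45),
    prevalence = list(base = -2.2, peak = 25, width = 12, amplitude = 1),
    liability = list(geno = 0.6, impulsivity = 0.8),
    behavior_truth = list(loading = 0.75, cross = 0.1, noise = 0.65,
                          n_per_factor = 3L, rb_shift = 0.4,
                          factor_cor = 0.2),
    geno_truth = list(m = 400L, block = 8L, rho = 0.6, maf = c(0.05, 0.5),
                      n_causal_sud = 8L, n_causal_brain = 8L, n_shared = 4L,
                      beta_sd = 1, roi_effect = 0.6),
    atlas_truth = list(n_terms = 40L, n_parcels = 24L, n_factors = 4L,
                       bandwidth = 0.5, noise = 0.2),
    followup = list(prob = 0.5, interval = 2, sud_decline = -0.005,
                    noise = 0.015),
    substances = c("alcohol", "tobacco", "marijuana", "drug")) {
  cfg <- list(seed = as.integer(seed), studies = studies, rois = rois,
              fp_truth = fp_truth, batch_effects = batch_effects,
              sud_effects = sud_effects, prevalence = prevalence,
              liability = liability, behavior_truth = behavior_truth,
              geno_truth = geno_truth, atlas_truth = atlas_truth,
              followup = followup, substances = substances)
  class(cfg) <- "simConfig"
  .validateConfig(cfg)
  cfg
}

.validateConfig <- function(cfg) {
  st <- cfg$studies
  if (any(st$n <= 0)) stop("study sample sizes must be positive")
  if (any(st$age_low >= st$age_high)) stop("age_low must be below age_high")
  if (any(st$age_low <= 0)) stop("study ages must be positive")
  bad <- setdiff(unique(cfg$rois$category), c("early", "mid", "late"))
  if (length(bad)) stop("unknown ROI category: ", paste(bad, collapse = ", "))
  if (!is.null(cfg$geno_truth)) {
    gt <- cfg$geno_truth
    if (abs(gt$rho) >= 1) stop("genotype block correlation rho must satisfy |rho| < 1")
    if (gt$maf[1] <= 0 || gt$maf[2] > 0.5 || gt$maf[1] > gt$maf[2])
      stop("MAF range must lie in (0, 0.5]")
    if (gt$m < 2 * gt$block) stop("need at least two genotype blocks (m >= 2*block)")
    if (gt$n_shared > min(gt$n_causal_sud, gt$n_causal_brain))
      stop("n_shared cannot exceed either causal set")
  }
  ages <- seq(8, 70, by = 0.5)
  for (cat in c("early", "mid", "late")) {
    v <- .sudOffsetFun(cfg, cat)(ages)
    if (any(!is.finite(v))) stop("SUD offset for '", cat,
                                 "' is not finite on [8, 70]")
  }
  if (!is.null(cfg$atlas_truth) && cfg$atlas_truth$bandwidth <= 0)
    stop("atlas smoothing bandwidth must be > 0")
  if (!is.null(cfg$followup) && cfg$followup$interval < 0)
    stop("follow-up interval must be non-negative")
  invisible(cfg)
}

## per-category SUD-HC offset (units of sigma(age)) as a function of age
.sudOffsetFun <- function(cfg, category) {
  off <- cfg$sud_effects[[category]]
  if (is.null(off)) stop("unknown ROI category: ", category)
  if (is.function(off)) return(off)
  amp <- off
  switch(category,
    early = function(a) amp * exp(-(a - 8) / 6),
    mid   = function(a) amp * exp(-(a - 45)^2 / (2 * 8^2)),
    late  = function(a) amp * pmax(0, a - 45) / 25)
}

## logit-scale age prevalence offset
.prevOffset <- function(cfg, age) {
  p <- cfg$prevalence
  p$base + p$amplitude * exp(-(age - p$peak)^2 / (2 * p$width^2))
}

#' Marginal SUD prevalence implied by a configuration
#'
#' Integrates the liability model over the latent genetic burden and
#' impulsivity factor (jointly standard normal) by Gauss-Legendre quadrature.
#'
#' @param config a [simConfig()].
#' @param ages ages in years.
#' @return numeric vector of P(SUD | age).
#' @export
truePrevalence <- function(config, ages) {
  s <- sqrt(config$liability$geno^2 + config$liability$impulsivity^2)
  t <- seq(-6, 6, length.out = 201)
  w <- exp(-t^2 / 2) / sqrt(2 * pi)
  w <- w / sum(w)
  off <- .prevOffset(config, ages)
  vapply(off, function(o) sum(w * plogis(o + s * t)), numeric(1))
}
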