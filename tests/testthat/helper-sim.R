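## shared fixture builders: small single-study configurations used across
## the suite (full defaults are exercised in the synthetic-cohort tests)

oneStudyConfig <- function(seed, n, ageLow = 8, ageHigh = 70, ...) {
  simConfig(seed = seed,
            studies = data.frame(name = "one", age_low = ageLow,
                                 age_high = ageHigh, n = n,
                                 sex_ratio = 0.5, n_scanners = 2L),
            ...)
}

## one ROI per temporal category keeps per-replicate simulation cheap
miniRois <- function() {
  r <- defaultRois()
  r[r$name %in% c("L_insula", "L_accumbens", "L_hippocampus"), ]
}

## balanced-null config: no SUD offsets, labels independent of everything,
## P(SUD) = 0.5
nullConfig <- function(seed, n, rois = miniRois()) {
  oneStudyConfig(seed, n, rois = rois,
                 sud_effects = list(early = 0, mid = 0, late = 0),
                 prevalence = list(base = 0, peak = 25, width = 12,
                                   amplitude = 0),
                 liability = list(geno = 0, impulsivity = 0),
                 geno_truth = NULL)
}

## rectangular 0.5-SD deficit at ages 40-50 on a single mid-class ROI
windowedEffectConfig <- function(seed, n) {
  r <- defaultRois()
  oneStudyConfig(seed, n, rois = r[r$name == "L_insula", ],
                 sud_effects = list(early = 0, late = 0,
                                    mid = function(a) -0.5 * (a >= 40 & a <= 50)),
                 prevalence = list(base = 0, peak = 25, width = 12,
                                   amplitude = 0),
                 liability = list(geno = 0, impulsivity = 0),
                 geno_truth = NULL)
}

## brute-force Benjamini-Hochberg step-up, written independently of bhFdr
bruteBH <- function(p) {
  m <- length(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- sapply(seq_len(m), function(j) {
      if (p[j] >= p[i]) m * p[j] / rank(p, ties.method = "max")[j] else Inf
    })
    q[i] <- min(1, min(vals))
  }
  q
}

## brute-force pointwise empirical conditional FDR by direct counting
bruteCondFdr <- function(p1, p2) {
  m <- length(p1)
  out <- numeric(m)
  for (i in seq_len(m)) {
    num <- 0; den <- 0
    for (j in seq_len(m)) {
      if (p2[j] <= p2[i]) {
        num <- num + 1
        if (p1[j] <= p1[i]) den <- den + 1
      }
    }
    out[i] <- if (den == 0) 1 else min(1, p1[i] * num / den)
  }
  out
}
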