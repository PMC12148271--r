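#' Fit a generalized-gamma normative model for one ROI
#'
#' Maximum likelihood fit of the location-scale-shape generalized gamma to
#' healthy-control volumes:
#' `log mu = FP(age) beta + sex + handedness [+ study offsets]`,
#' `log sigma = FP(age) gamma`, `nu` constant. Fractional-polynomial power
#' multisets are pre-screened per degree by least squares on the log volumes
#' (location) and log absolute residuals (dispersion); the generalized-gamma
#' likelihood is then maximized over a staged candidate set — dispersion
#' degree 1..`maxDegree` and study-offset inclusion first, then location
#' degree 1..`maxDegree` carrying the top screened power sets per degree so
#' the degree comparison is not hostage to a noisy single power pick — and
#' the minimum-BIC model is returned. Optimization uses BFGS on the
#' unconstrained parameterization with jittered restarts on non-convergence.
#'
#' @param scans scan table or `ScanSet`; rows with group other than `HC` are
#'   dropped, and the training set must be cross-sectional (one visit per
#'   participant; see [sampleOneVisit()]).
#' @param roi ROI column name to fit.
#' @param maxDegree maximum fractional-polynomial degree searched (1-3).
#' @param restarts maximum jittered restarts per candidate on
#'   non-convergence.
#' @return a [GGNormativeModel-class] object; its `searchLog` records every
#'   candidate's BIC.
#' @export
fitNormative <- function(scans, roi, maxDegree = 3L, restarts = 2L) {
  df <- .scanFrame(scans)
  df <- df[df$group == "HC", , drop = FALSE]
  if (anyDuplicated(df$pid))
    stop("training set must be cross-sectional; see sampleOneVisit()")
  if (nrow(df) < 50) stop("need at least 50 healthy-control records")
  if (!roi %in% names(df)) stop("ROI '", roi, "' not found")
  y <- df[[roi]]
  logy <- log(y)
  studyLevels <- sort(unique(as.character(df$study)))
  nStud <- length(studyLevels)
  S <- if (nStud > 1)
    outer(df$study, studyLevels[-1], "==") + 0 else NULL
  extra <- cbind(sex = df$sex, hand = df$hand, S)

  muPw <- .fpScreen(logy, df$age, extra, maxDegree, k = 3L)
  base0 <- lm.fit(cbind(1, fpBasis(df$age, muPw[[maxDegree]][[1]]), extra),
                  logy)
  sigPw <- .fpScreen(log(abs(base0$residuals) + 1e-8), df$age, NULL,
                     maxDegree)

  ## staged BIC search. Stage A: dispersion degree and study-offset
  ## inclusion, with the location basis held at the best max-degree screen
  ## pick. Stage B: location degree, trying the top screened power sets per
  ## degree so degree comparison is not hostage to a noisy power pick.
  log_ <- data.frame()
  fits <- list()
  addFit <- function(pwMu, pwSig, offs) {
    f <- .fitGGCandidate(y, df, pwMu, pwSig, if (offs) S else NULL, restarts)
    fits[[length(fits) + 1L]] <<- c(f, list(pwMu = pwMu, pwSig = pwSig,
                                            offs = offs))
    log_ <<- rbind(log_, data.frame(
      powers_mu = paste(sort(pwMu), collapse = ","),
      powers_sigma = paste(sort(pwSig), collapse = ","),
      study_offsets = offs, logLik = f$logLik, bic = f$bic,
      converged = f$converged))
    f
  }
  candA <- expand.grid(dsig = seq_len(maxDegree),
                       offsets = if (nStud > 1) c(FALSE, TRUE) else FALSE)
  for (i in seq_len(nrow(candA)))
    addFit(muPw[[maxDegree]][[1]], sigPw[[candA$dsig[i]]][[1]],
           candA$offsets[i])
  okA <- which(log_$converged)
  if (!length(okA))
    stop("no candidate model converged; attempted:\n",
         paste(utils::capture.output(print(log_)), collapse = "\n"))
  bestA <- okA[which.min(log_$bic[okA])]
  pwSig <- fits[[bestA]]$pwSig
  offs <- fits[[bestA]]$offs
  for (d in seq_len(maxDegree))
    for (pw in muPw[[d]])
      if (d < maxDegree || !identical(sort(pw), sort(fits[[bestA]]$pwMu)))
        addFit(pw, pwSig, offs)
  ok <- which(log_$converged)
  best <- ok[which.min(log_$bic[ok])]
  f <- fits[[best]]
  new("GGNormativeModel",
      roi = roi, powersMu = sort(f$pwMu), powersSigma = sort(f$pwSig),
      coefMu = f$coefMu, coefSigma = f$coefSigma, nu = f$nu,
      hasStudyOffsets = f$offs, studyLevels = studyLevels,
      logLik = f$logLik, bic = f$bic, nTrain = nrow(df),
      converged = f$converged, ageRange = range(df$age), searchLog = log_)
}

## single-candidate generalized-gamma MLE (internal)
.fitGGCandidate <- function(y, df, powersMu, powersSigma, S, restarts) {
  Xmu <- cbind(`(Intercept)` = 1, fpBasis(df$age, powersMu),
               sex = df$sex, hand = df$hand, S)
  if (!is.null(S))
    colnames(Xmu)[(ncol(Xmu) - ncol(S) + 1):ncol(Xmu)] <-
      paste0("study:", colnames(S))
  Xsig <- cbind(`(Intercept)` = 1, fpBasis(df$age, powersSigma))
  pMu <- ncol(Xmu); pSig <- ncol(Xsig)
  logy <- log(y)
  negll <- function(par) {
    beta <- par[seq_len(pMu)]
    gamma <- par[pMu + seq_len(pSig)]
    nu <- par[pMu + pSig + 1L]
    logmu <- drop(Xmu %*% beta)
    logsig <- drop(Xsig %*% gamma)
    if (any(!is.finite(logmu)) || any(abs(logsig) > 20)) return(1e10)
    ll <- sum(ggLogLik(y, exp(logmu), exp(logsig), nu))
    if (!is.finite(ll)) 1e10 else -ll
  }
  init <- local({
    b <- lm.fit(Xmu, logy)
    r <- b$residuals
    g <- lm.fit(Xsig, log(abs(r) + 1e-8))
    c(b$coefficients, g$coefficients, 0.5)
  })
  best <- NULL
  par0 <- init
  for (tryi in 0:restarts) {
    fit <- tryCatch(
      optim(par0, negll, method = "BFGS",
            control = list(maxit = 300, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    if (!is.null(best) && best$convergence == 0) break
    par0 <- init + rnorm(length(init), 0, 0.05)
  }
  if (is.null(best))
    return(list(logLik = -Inf, bic = Inf, converged = FALSE,
                coefMu = setNames(rep(NA_real_, pMu), colnames(Xmu)),
                coefSigma = setNames(rep(NA_real_, pSig), colnames(Xsig)),
                nu = NA_real_))
  k <- length(best$par)
  list(coefMu = setNames(best$par[seq_len(pMu)], colnames(Xmu)),
       coefSigma = setNames(best$par[pMu + seq_len(pSig)], colnames(Xsig)),
       nu = best$par[k],
       logLik = -best$value,
       bic = 2 * best$value + k * log(length(y)),
       converged = best$convergence == 0)
}

## evaluate fitted mu/sigma for new scans (internal)
.predictGG <- function(model, df) {
  Xmu <- cbind(1, fpBasis(df$age, model@powersMu), df$sex, df$hand)
  beta <- model@coefMu
  nFix <- 3 + length(model@powersMu)
  logmu <- drop(Xmu %*% beta[seq_len(nFix)])
  if (model@hasStudyOffsets && length(beta) > nFix) {
    offs <- beta[-seq_len(nFix)]
    idx <- match(paste0("study:", df$study), names(offs))
    logmu <- logmu + ifelse(is.na(idx), 0, offs[idx])
  }
  Xsig <- cbind(1, fpBasis(df$age, model@powersSigma))
  logsig <- drop(Xsig %*% model@coefSigma)
  list(mu = exp(logmu), sigma = exp(logsig),
       extrapolated = df$age < model@ageRange[1] | df$age > model@ageRange[2])
}

#' Score scans against a set of normative models
#'
#' Each volume is converted into a centile F_GG(volume; mu(covariates),
#' sigma(age), nu) under the ROI's fitted model, clipped to
#' \[1e-7, 1 - 1e-7\], with its probit z-equivalent. Scans outside the
#' training age range are scored but flagged `extrapolated`.
#'
#' @param models named list of [GGNormativeModel-class] objects covering
#'   every ROI to score (names = ROI columns).
#' @param scans scan table or `ScanSet`.
#' @return long data.frame: `pid`, `visit`, `roi`, `centile`, `z`,
#'   `extrapolated`.
#' @export
scoreCentiles <- function(models, scans) {
  df <- .scanFrame(scans)
  miss <- setdiff(names(models), names(df))
  if (length(miss)) stop("scan table lacks ROI column(s): ",
                         paste(miss, collapse = ", "))
  out <- lapply(names(models), function(rc) {
    pr <- .predictGG(models[[rc]], df)
    cent <- ggCdf(df[[rc]], pr$mu, pr$sigma, models[[rc]]@nu)
    cent <- pmin(pmax(cent, 1e-7), 1 - 1e-7)
    data.frame(pid = df$pid, visit = df$visit, roi = rc,
               centile = cent, z = qnorm(cent),
               extrapolated = pr$extrapolated)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Reshape a centile table to a scans-by-ROIs matrix
#'
#' @param centiles long table from [scoreCentiles()].
#' @param value which column to spread (`"centile"` or `"z"`).
#' @return matrix with `pid.visit` rows and ROI columns.
#' @export
centileMatrix <- function(centiles, value = c("centile", "z")) {
  value <- match.arg(value)
  key <- paste(centiles$pid, centiles$visit, sep = ".")
  roiLv <- unique(centiles$roi)
  keyLv <- unique(key)
  M <- matrix(NA_real_, length(keyLv), length(roiLv),
              dimnames = list(keyLv, roiLv))
  M[cbind(match(key, keyLv), match(centiles$roi, roiLv))] <-
    centiles[[value]]
  M
}

#' Ground-truth normative model from a simulation configuration
#'
#' Builds the [GGNormativeModel-class] that the synthetic generator actually
#' sampled from for one ROI (no scanner effects, reference study), so
#' centiles of simulated healthy controls scored against it are exactly
#' Uniform(0, 1).
#'
#' @param config a [simConfig()].
#' @param roi ROI name from `config$rois`.
#' @return a [GGNormativeModel-class] object.
#' @export
trueNormativeModel <- function(config, roi) {
  ft <- config$fp_truth
  r <- config$rois[config$rois$name == roi, ]
  if (!nrow(r)) stop("unknown ROI: ", roi)
  coefMu <- c(log(r$base_mm3), ft$beta_age, ft$sex_effect, ft$hand_effect)
  names(coefMu) <- c("(Intercept)",
                     paste0("fp", seq_along(ft$powers_mu)), "sex", "hand")
  coefSigma <- c(`(Intercept)` = log(ft$sigma0), fp1 = ft$sigma_slope)
  new("GGNormativeModel",
      roi = roi, powersMu = sort(ft$powers_mu), powersSigma = 1,
      coefMu = coefMu, coefSigma = coefSigma, nu = ft$nu,
      hasStudyOffsets = FALSE, studyLevels = character(0),
      logLik = 0, bic = (length(coefMu) + length(coefSigma) + 1) *
        log(1L), nTrain = 1L, converged = TRUE,
      ageRange = c(8, 70), searchLog = data.frame())
}

#' @rdname GGNormativeModel-class
#' @param x,object a `GGNormativeModel`.
#' @export
setMethod("bic", "GGNormativeModel", function(x) x@bic)

#' @rdname GGNormativeModel-class
#' @export
setMethod("fpPowers", "GGNormativeModel", function(x)
  list(mu = x@powersMu, sigma = x@powersSigma))

#' @rdname GGNormativeModel-class
#' @export
setMethod("show", "GGNormativeModel", function(object) {
  cat("GGNormativeModel for", object@roi, "\n")
  cat("  FP powers: mu (", paste(object@powersMu, collapse = ", "),
      "), sigma (", paste(object@powersSigma, collapse = ", "), ")\n", sep = "")
  cat("  study offsets:", object@hasStudyOffsets,
      " nu:", signif(object@nu, 4), "\n")
  cat("  n =", object@nTrain, " logLik =", round(object@logLik, 2),
      " BIC =", round(object@bic, 2), "\n")
  if (!object@converged) cat("  WARNING: optimizer did not converge\n")
})

#' Write a set of fitted normative models to JSON
#'
#' @param models named list of [GGNormativeModel-class] objects.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeModels <- function(models, path) {
  obj <- lapply(models, function(m) list(
    roi = m@roi, powers_mu = m@powersMu, powers_sigma = m@powersSigma,
    coef_mu = as.list(m@coefMu), coef_sigma = as.list(m@coefSigma),
    nu = m@nu, study_offsets = m@hasStudyOffsets,
    study_levels = m@studyLevels, loglik = m@logLik, bic = m@bic,
    n_train = m@nTrain, converged = m@converged, age_range = m@ageRange,
    bic_trace = m@searchLog))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
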