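#' Add longitudinal follow-up visits to a baseline scan table
#'
#' Each baseline participant revisits with probability `followup$prob` after
#' `followup$interval` years. The follow-up volume is the baseline volume
#' scaled by the true normative age trend between the two ages, times an
#' extra `exp(sud_decline * interval)` annual decline for SUD participants,
#' times lognormal measurement noise; within-person volumes are therefore
#' positively correlated by construction.
#'
#' @param scans baseline scan table (or `ScanSet`) from [generateCohort()].
#' @param config the [simConfig()] that generated it.
#' @param seed RNG seed (defaults to `config$seed + 1`).
#' @return scan table with the follow-up rows (visit = 2) appended; equals
#'   the input when the revisit probability is 0.
#' @export
generateFollowup <- function(scans, config, seed = config$seed + 1L) {
  fu <- config$followup
  if (is.null(fu)) stop("config has no followup block")
  if (fu$interval < 0) stop("follow-up interval must be non-negative")
  scans <- .scanFrame(scans)
  set.seed(seed)
  base <- scans[scans$visit == 1L, , drop = FALSE]
  take <- runif(nrow(base)) < fu$prob
  if (!any(take)) return(scans)
  f <- base[take, , drop = FALSE]
  a1 <- f$age
  a2 <- a1 + fu$interval
  ft <- config$fp_truth
  trend <- drop((fpBasis(a2, ft$powers_mu) - fpBasis(a1, ft$powers_mu)) %*%
                  ft$beta_age)
  isSud <- startsWith(f$group, "SUD")
  extra <- fu$sud_decline * fu$interval * isSud
  roiCols <- .roiCols(scans)
  for (rc in roiCols) {
    eps <- rnorm(nrow(f), 0, fu$noise)
    f[[rc]] <- f[[rc]] * exp(trend + extra + eps)
  }
  f$age <- a2
  f$visit <- 2L
  out <- rbind(scans, f)
  rownames(out) <- NULL
  out
}
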