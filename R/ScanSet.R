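#' Build a ScanSet from a scan table
#'
#' @param scans data.frame with columns `pid`, `study`, `scanner`, `visit`,
#'   `age`, `sex`, `hand`, `group` plus one strictly positive column per ROI
#'   (any column not in the phenotype set is treated as an ROI volume in mm^3).
#' @return a [ScanSet-class] object.
#' @examples
#' cfg <- simConfig(seed = 1, studies = data.frame(
#'   name = "demo", age_low = 10, age_high = 60, n = 50,
#'   sex_ratio = 0.5, n_scanners = 2))
#' sim <- generateCohort(cfg)
#' ss <- ScanSet(sim$scans)
#' ss
#' @export
ScanSet <- function(scans) {
  stopifnot(is.data.frame(scans))
  miss <- setdiff(.scanCols, names(scans))
  if (length(miss))
    stop("scan table lacks column(s): ", paste(miss, collapse = ", "))
  roiCols <- setdiff(names(scans), .scanCols)
  if (!length(roiCols)) stop("scan table has no ROI volume columns")
  vol <- t(as.matrix(scans[roiCols]))
  colnames(vol) <- paste(scans$pid, scans$visit, sep = ".")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(volumes = vol),
    colData = S4Vectors::DataFrame(scans[.scanCols]))
  new("ScanSet", se)
}

#' @rdname ScanSet
#' @export
setMethod("volumes", "ScanSet", function(x)
  SummarizedExperiment::assay(x, "volumes"))

#' @rdname ScanSet
#' @export
setMethod("scanInfo", "ScanSet", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname ScanSet
#' @export
setMethod("rois", "ScanSet", function(x) rownames(x))

#' @rdname ScanSet
#' @export
setMethod("show", "ScanSet", function(object) {
  info <- scanInfo(object)
  cat("ScanSet:", ncol(object), "scans,", nrow(object), "ROIs\n")
  cat("  studies:", paste(unique(info$study), collapse = ", "), "\n")
  cat("  ages:", sprintf("%.1f-%.1f y", min(info$age), max(info$age)), "\n")
  g <- table(sub(":.*", "", info$group))
  cat("  groups:", paste(names(g), g, sep = "=", collapse = ", "), "\n")
})

## internal: accept a ScanSet or a plain scan table, return the data.frame form
.scanFrame <- function(x) {
  if (is(x, "ScanSet")) {
    df <- scanInfo(x)
    df <- cbind(df, as.data.frame(t(volumes(x))))
    rownames(df) <- NULL
    df
  } else {
    stopifnot(is.data.frame(x))
    x
  }
}

## internal: ROI column names of a scan table
.roiCols <- function(scans) setdiff(names(scans), .scanCols)

#' Read / write a scan table
#'
#' Plain TSV with a header; columns as in [ScanSet()].
#' @param path file path.
#' @param scans scan table or `ScanSet`.
#' @return `readScans` returns a data.frame.
#' @export
readScans <- function(path) read.delim(path, check.names = FALSE)

#' @rdname readScans
#' @export
writeScans <- function(scans, path) {
  write.table(.scanFrame(scans), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
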