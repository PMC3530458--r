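#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
NULL

## Known vineyard labels used throughout; free labels are also accepted.
.VINEYARDS <- c("BD", "CONV", "IPW")

# ---------------------------------------------------------------------------
# BinScheme
# ---------------------------------------------------------------------------

#' Adaptive fragment-length binning scheme
#'
#' Describes how ARISA fragment lengths are grouped into OTU bins: a length
#' window, a breakpoint, and two bin widths (narrow bins below the
#' breakpoint where capillary sizing is more accurate, wider bins above).
#' Bins are half-open intervals \code{[edge, edge + width)} anchored at
#' \code{windowMin}; the final bin is closed at \code{windowMax}. With the
#' defaults the 3-bp edges are 300, 303, ..., 697 covering [300, 700) and
#' the 5-bp edges are 700, 705, ..., 995 covering [700, 1000].
#'
#' @slot windowMin lower length bound in bp (default 300)
#' @slot windowMax upper length bound in bp (default 1000)
#' @slot breakpoint bp at which the bin width changes (default 700); the
#'   breakpoint itself belongs to the wide-bin regime
#' @slot widthBelow bin width in bp below the breakpoint (default 3)
#' @slot widthAbove bin width in bp at and above the breakpoint (default 5)
#' @export
setClass("BinScheme",
  representation(
    windowMin = "numeric", windowMax = "numeric", breakpoint = "numeric",
    widthBelow = "numeric", widthAbove = "numeric"
  ),
  prototype(
    windowMin = 300, windowMax = 1000, breakpoint = 700,
    widthBelow = 3, widthAbove = 5
  )
)

setValidity("BinScheme", function(object) {
  msg <- character()
  if (!(object@windowMin < object@breakpoint &&
        object@breakpoint < object@windowMax))
    msg <- c(msg, "must have windowMin < breakpoint < windowMax")
  if (object@widthBelow <= 0 || object@widthAbove <= 0)
    msg <- c(msg, "bin widths must be positive")
  if (length(msg)) msg else TRUE
})

#' @param windowMin,windowMax,breakpoint,widthBelow,widthAbove see slots
#' @return \code{BinScheme()} returns a \code{BinScheme} object.
#' @examples
#' BinScheme()
#' BinScheme(widthBelow = 2, widthAbove = 4)
#' @rdname BinScheme-class
#' @export
BinScheme <- function(windowMin = 300, windowMax = 1000, breakpoint = 700,
                      widthBelow = 3, widthAbove = 5) {
  new("BinScheme",
    windowMin = as.numeric(windowMin), windowMax = as.numeric(windowMax),
    breakpoint = as.numeric(breakpoint),
    widthBelow = as.numeric(widthBelow), widthAbove = as.numeric(widthAbove)
  )
}

setMethod("show", "BinScheme", function(object) {
  cat(sprintf(
    "BinScheme: [%g, %g] bp; %g-bp bins below %g bp, %g-bp bins above\n",
    object@windowMin, object@windowMax, object@widthBelow,
    object@breakpoint, object@widthAbove
  ))
})

# ---------------------------------------------------------------------------
# PeakSet
# ---------------------------------------------------------------------------

#' Electropherogram peak tables for a collection of samples
#'
#' Holds the discrete peaks (fragment length in bp, fluorescence in RFU)
#' called from each sample's ARISA electropherogram, in long format, plus
#' per-sample metadata (vineyard, row, panel). One \code{PeakSet} typically
#' holds every sampling point of a study; single-sample sets are valid.
#'
#' @slot peaks data.frame with columns \code{sample}, \code{length_bp},
#'   \code{fluorescence} (peak area preferred over height, since areas carry
#'   the relative proportions of the fragments)
#' @slot sampleData data.frame keyed by \code{sample} with optional columns
#'   \code{vineyard}, \code{row}, \code{panel}; one row per distinct sample,
#'   in input order. Samples with zero peaks are legal.
#' @export
setClass("PeakSet",
  representation(peaks = "data.frame", sampleData = "data.frame")
)

setValidity("PeakSet", function(object) {
  p <- object@peaks
  msg <- character()
  need <- c("sample", "length_bp", "fluorescence")
  if (!all(need %in% names(p)))
    msg <- c(msg, paste("peaks must have columns", paste(need, collapse = ", ")))
  else {
    if (nrow(p) && any(p$length_bp <= 0))
      msg <- c(msg, "fragment lengths must be positive")
    if (nrow(p) && any(p$fluorescence < 0))
      msg <- c(msg, "fluorescence must be non-negative")
    if (!all(p$sample %in% object@sampleData$sample))
      msg <- c(msg, "every peak's sample must appear in sampleData")
  }
  if (anyDuplicated(object@sampleData$sample))
    msg <- c(msg, "sample ids must be unique")
  if (length(msg)) msg else TRUE
})

#' @param peaks,sampleData see slots; if \code{sampleData} is \code{NULL} it
#'   is derived from the distinct samples of \code{peaks} (input order kept)
#' @return \code{PeakSet()} returns a \code{PeakSet} object.
#' @rdname PeakSet-class
#' @export
PeakSet <- function(peaks, sampleData = NULL) {
  peaks$sample <- as.character(peaks$sample)
  if (is.null(sampleData)) {
    meta <- c("vineyard", "row", "panel")
    keep <- intersect(c("sample", meta), names(peaks))
    sampleData <- unique(peaks[keep])
    rownames(sampleData) <- NULL
    peaks <- peaks[setdiff(names(peaks), meta)]
  } else {
    sampleData$sample <- as.character(sampleData$sample)
  }
  new("PeakSet",
    peaks = peaks[c("sample", "length_bp", "fluorescence")],
    sampleData = sampleData
  )
}

#' @param x,object a \code{PeakSet}
#' @rdname PeakSet-class
#' @export
peakData <- function(x) x@peaks

#' @rdname PeakSet-class
#' @export
sampleInfo <- function(x) x@sampleData

#' @rdname PeakSet-class
#' @export
sampleIDs <- function(x) x@sampleData$sample

setMethod("show", "PeakSet", function(object) {
  cat(sprintf(
    "PeakSet: %d peaks across %d sample(s)\n",
    nrow(object@peaks), nrow(object@sampleData)
  ))
  if ("vineyard" %in% names(object@sampleData)) {
    tab <- table(object@sampleData$vineyard)
    cat("  vineyards:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
})

# ---------------------------------------------------------------------------
# OTUMatrix
# ---------------------------------------------------------------------------

#' Sample-by-OTU fluorescence matrix
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"fluorescence"}
#' stores binned ARISA fluorescence with OTU bins as rows and samples as
#' columns; \code{colData} carries vineyard/row/panel. Row names are the bin
#' lower edges in bp (e.g. \code{"518"}), so a peak named "518 bp" maps to
#' bin label 518. Construction removes nothing itself: use
#' \code{\link{buildOTUMatrix}} which drops bins unoccupied in every sample.
#' All-zero samples are retained but flagged with a warning; correlation
#' operations reject them explicitly.
#'
#' @export
setClass("OTUMatrix", contains = "SummarizedExperiment")

setValidity("OTUMatrix", function(object) {
  m <- assay(object)
  msg <- character()
  if (any(m < 0)) msg <- c(msg, "fluorescence values must be non-negative")
  if (nrow(m) && any(rowSums(m) == 0))
    msg <- c(msg, "contains OTU bins with zero fluorescence in every sample")
  if (length(msg)) msg else TRUE
})

#' @param values samples-by-OTU numeric matrix (rows = samples, columns =
#'   bin labels), the user-facing orientation
#' @param sampleData data.frame of per-sample metadata, one row per sample
#' @return \code{OTUMatrix()} returns an \code{OTUMatrix}.
#' @rdname OTUMatrix-class
#' @export
OTUMatrix <- function(values, sampleData = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- as.character(seq_len(ncol(values)))
  if (is.null(sampleData))
    sampleData <- data.frame(row.names = rownames(values))
  obj <- new("OTUMatrix", SummarizedExperiment(
    assays = list(fluorescence = t(values)),
    colData = DataFrame(sampleData, row.names = rownames(values))
  ))
  zero <- rownames(values)[rowSums(values) == 0]
  if (length(zero))
    warning("all-zero sample(s) retained but flagged: ",
            paste(zero, collapse = ", "))
  obj
}

#' @param x an \code{OTUMatrix}
#' @return \code{otuAbundance()} returns the samples-by-OTU matrix.
#' @rdname OTUMatrix-class
#' @export
otuAbundance <- function(x) t(assay(x, "fluorescence"))

#' @rdname OTUMatrix-class
#' @export
binLabels <- function(x) rownames(x)

#' @return \code{sampleData()} returns per-sample metadata as a data.frame.
#' @rdname OTUMatrix-class
#' @export
sampleData <- function(x) as.data.frame(colData(x))

setMethod("show", "OTUMatrix", function(object) {
  cat(sprintf("OTUMatrix: %d sample(s) x %d OTU bin(s)\n",
              ncol(object), nrow(object)))
  if ("vineyard" %in% names(colData(object))) {
    tab <- table(colData(object)$vineyard)
    cat("  vineyards:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  if (nrow(object))
    cat("  bins:", rownames(object)[1], "...",
        rownames(object)[nrow(object)], "bp\n")
})

# ---------------------------------------------------------------------------
# ProbabilityMatrix
# ---------------------------------------------------------------------------

#' Row-stochastic OTU occurrence probabilities
#'
#' Same shape and labels as the source \linkS4class{OTUMatrix}, but each
#' sample vector is divided by its total so every entry is the probability
#' of that sample containing that OTU; each sample's probabilities sum to 1.
#'
#' @export
setClass("ProbabilityMatrix", contains = "OTUMatrix")

setValidity("ProbabilityMatrix", function(object) {
  m <- otuAbundance(object)
  if (nrow(m) && any(abs(rowSums(m) - 1) > 1e-9))
    return("every sample's probabilities must sum to 1 (tolerance 1e-9)")
  TRUE
})

# ---------------------------------------------------------------------------
# VineyardLayout
# ---------------------------------------------------------------------------

#' Vineyard block as a two-dimensional sampling lot
#'
#' Describes which rows and panels of a vineyard block are sampled and the
#' physical spacing between them. A panel is a trellis segment of six vines;
#' together with the row number it identifies a sampling location. Metric
#' coordinates use the printed row/panel numbers times the widths
#' (x = row x rowWidth, y = panel x panelWidth), which preserves the
#' non-consecutive row spacing of real designs.
#'
#' @slot name vineyard label, e.g. \code{"CONV"}
#' @slot rowNumbers strictly increasing integer row numbers
#' @slot panelNumbers strictly increasing integer panel numbers
#' @slot rowWidth row spacing in meters (default 2.5)
#' @slot panelWidth panel length in meters (default 9)
#' @export
setClass("VineyardLayout",
  representation(
    name = "character", rowNumbers = "integer", panelNumbers = "integer",
    rowWidth = "numeric", panelWidth = "numeric"
  )
)

setValidity("VineyardLayout", function(object) {
  msg <- character()
  if (!length(object@rowNumbers) || !length(object@panelNumbers))
    msg <- c(msg, "rowNumbers and panelNumbers must be non-empty")
  if (is.unsorted(object@rowNumbers, strictly = TRUE) ||
      is.unsorted(object@panelNumbers, strictly = TRUE))
    msg <- c(msg, "row and panel numbers must be strictly increasing")
  if (object@rowWidth <= 0 || object@panelWidth <= 0)
    msg <- c(msg, "widths must be positive")
  if (length(msg)) msg else TRUE
})

#' @param name,rowNumbers,panelNumbers,rowWidth,panelWidth see slots
#' @return \code{VineyardLayout()} returns a \code{VineyardLayout}.
#' @examples
#' VineyardLayout("CONV", c(9, 11, 13, 15, 17, 19), c(3, 7, 11))
#' @rdname VineyardLayout-class
#' @export
VineyardLayout <- function(name, rowNumbers, panelNumbers,
                           rowWidth = 2.5, panelWidth = 9) {
  new("VineyardLayout",
    name = as.character(name),
    rowNumbers = as.integer(rowNumbers),
    panelNumbers = as.integer(panelNumbers),
    rowWidth = as.numeric(rowWidth), panelWidth = as.numeric(panelWidth)
  )
}

setMethod("show", "VineyardLayout", function(object) {
  cat(sprintf(
    "VineyardLayout '%s': %d rows x %d panels (%d points); row width %g m, panel width %g m\n",
    object@name, length(object@rowNumbers), length(object@panelNumbers),
    length(object@rowNumbers) * length(object@panelNumbers),
    object@rowWidth, object@panelWidth
  ))
})

# ---------------------------------------------------------------------------
# IsolateTable
# ---------------------------------------------------------------------------

#' Species-by-vineyard isolate abundance table
#'
#' Culture-based abundances of yeast species per vineyard, either raw
#' isolate counts (\code{mode = "counts"}) or percentage distributions
#' (\code{mode = "percent"}, columns summing to 100 within a 0.5 rounding
#' slack). Zero/absent entries are stored as 0.
#'
#' @slot abundance species-by-vineyard non-negative matrix with species as
#'   row names and vineyard labels as column names
#' @slot mode \code{"counts"} or \code{"percent"}
#' @export
setClass("IsolateTable",
  representation(abundance = "matrix", mode = "character")
)

setValidity("IsolateTable", function(object) {
  msg <- character()
  if (!object@mode %in% c("counts", "percent"))
    msg <- c(msg, "mode must be 'counts' or 'percent'")
  if (any(object@abundance < 0))
    msg <- c(msg, "abundances must be non-negative")
  if (object@mode == "percent") {
    s <- colSums(object@abundance)
    bad <- abs(s - 100) > 0.5
    if (any(bad))
      msg <- c(msg, paste0(
        "percent columns must sum to 100 +/- 0.5; offending: ",
        paste(colnames(object@abundance)[bad], round(s[bad], 2),
              sep = "=", collapse = ", ")
      ))
  }
  if (length(msg)) msg else TRUE
})

#' @param abundance,mode see slots
#' @return \code{IsolateTable()} returns an \code{IsolateTable}.
#' @rdname IsolateTable-class
#' @export
IsolateTable <- function(abundance, mode = c("counts", "percent")) {
  new("IsolateTable", abundance = as.matrix(abundance),
      mode = match.arg(mode))
}

#' @param x,object an \code{IsolateTable}
#' @rdname IsolateTable-class
#' @export
isolateAbundance <- function(x) x@abundance

#' @rdname IsolateTable-class
#' @export
abundanceMode <- function(x) x@mode

setMethod("show", "IsolateTable", function(object) {
  cat(sprintf("IsolateTable (%s): %d species x %d vineyard(s)\n",
              object@mode, nrow(object@abundance), ncol(object@abundance)))
  cat("  vineyards:", paste(colnames(object@abundance), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# PseudoreplicationResult
# ---------------------------------------------------------------------------

#' Result of the distance-decay pseudoreplication test
#'
#' For every unordered pair of sampling points in one vineyard, the
#' Euclidean distance and the Pearson correlation of the two samples' OTU
#' vectors; plus the summary of the ordinary least squares fit of community
#' correlation on distance.
#'
#' @slot pairs data.frame with columns \code{sample_i}, \code{sample_j},
#'   \code{distance_m}, \code{pearson_r} (the scatter table for plotting)
#' @slot rDistance Pearson correlation between distance and community r
#' @slot rSquared coefficient of determination of the linear fit, in [0, 1]
#' @slot signedR2 sign(slope) x rSquared, the signed convention some
#'   studies print as "R2"
#' @slot slope,intercept OLS coefficients of community-r on distance
#' @export
setClass("PseudoreplicationResult",
  representation(
    pairs = "data.frame", rDistance = "numeric", rSquared = "numeric",
    signedR2 = "numeric", slope = "numeric", intercept = "numeric"
  )
)

setMethod("show", "PseudoreplicationResult", function(object) {
  cat(sprintf(
    "PseudoreplicationResult: %d pairs; r = %.4f, R2 = %.4f, signed R2 = %.4f, slope = %.3g per m\n",
    nrow(object@pairs), object@rDistance, object@rSquared,
    object@signedR2, object@slope
  ))
})
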