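# ARISA electropherogram processing: read exported peak tables, filter
# background/out-of-window/minor peaks, bin fragment lengths adaptively and
# assemble the sample x OTU fluorescence matrix.

#' Read a genotyping-software peak-table export
#'
#' Ingests delimited text with one row per called peak. Required columns:
#' \code{sample}, \code{length_bp}, \code{fluorescence}; optional
#' \code{vineyard}, \code{row}, \code{panel} are carried into the sample
#' metadata. The delimiter is auto-detected from the header (comma or tab)
#' unless given.
#'
#' @param path path to the delimited file
#' @param delim field delimiter; \code{NULL} (default) auto-detects
#' @return a \linkS4class{PeakSet} with one peak table per distinct sample
#'   id, in file order; a header-only file yields an empty \code{PeakSet}
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("sample,length_bp,fluorescence", "S1,518.2,5000"), f)
#' peakData(readPeakTable(f))
#' @export
readPeakTable <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) {
    header <- readLines(path, n = 1)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("sample", "length_bp", "fluorescence")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  for (col in c("length_bp", "fluorescence")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric %s in data row(s): %s", col,
                   paste(bad, collapse = ", ")))
    df[[col]] <- v
  }
  PeakSet(df)
}

#' Filter electropherogram peaks
#'
#' Applies the three peak-retention rules in a fixed order, independently
#' within each sample: (1) drop background fluorescence below
#' \code{rfuThreshold}; (2) keep only fragments inside the analysis window
#' \code{[windowMin, windowMax]}; (3) drop peaks whose fluorescence is not
#' strictly larger than \code{relFloor} of the sample's total fluorescence.
#' By default the relative-floor total is computed over the peaks surviving
#' steps 1-2 (\code{relTotal = "window"}), which makes the floor insensitive
#' to out-of-window noise; \code{relTotal = "all"} instead uses the total
#' over all above-threshold peaks.
#'
#' A sample whose peaks are all removed stays in the set with an empty peak
#' table and is flagged with a message. The input is not modified.
#'
#' @param x a \linkS4class{PeakSet}
#' @param rfuThreshold background-exclusion threshold in RFU (default 50)
#' @param scheme a \linkS4class{BinScheme}, supplying the length window
#' @param relFloor relative fluorescence floor as a fraction (default 0.005,
#'   i.e. 0.5 percent of the sample total)
#' @param relTotal which total the relative floor refers to (see above)
#' @return a filtered \code{PeakSet}
#' @export
filterPeaks <- function(x, rfuThreshold = 50, scheme = BinScheme(),
                        relFloor = 0.005, relTotal = c("window", "all")) {
  stopifnot(is(x, "PeakSet"), rfuThreshold >= 0, relFloor >= 0)
  relTotal <- match.arg(relTotal)
  p <- peakData(x)
  keep <- logical(nrow(p))
  for (s in sampleIDs(x)) {
    i <- which(p$sample == s)
    if (!length(i)) next
    s1 <- p$fluorescence[i] >= rfuThreshold
    s2 <- p$length_bp[i] >= scheme@windowMin &
          p$length_bp[i] <= scheme@windowMax
    total <- if (relTotal == "window") sum(p$fluorescence[i][s1 & s2])
             else sum(p$fluorescence[i][s1])
    keep[i] <- s1 & s2 & (p$fluorescence[i] > relFloor * total)
    if (!any(keep[i]))
      message("sample '", s, "' has no peaks surviving the filters")
  }
  PeakSet(p[keep, , drop = FALSE], sampleInfo(x))
}

## lower bin edge for each fragment length under a scheme; lengths must
## already lie inside the window (the final bin is closed at windowMax)
.binEdge <- function(len, scheme) {
  below <- len < scheme@breakpoint
  edge <- ifelse(below,
    scheme@windowMin +
      floor((len - scheme@windowMin) / scheme@widthBelow) * scheme@widthBelow,
    scheme@breakpoint +
      floor((len - scheme@breakpoint) / scheme@widthAbove) * scheme@widthAbove)
  lastEdge <- scheme@breakpoint + floor(
    (scheme@windowMax - scheme@breakpoint - 1e-9) / scheme@widthAbove
  ) * scheme@widthAbove
  pmin(edge, lastEdge)
}

#' Bin fragment lengths and sum co-binned fluorescence
#'
#' Assigns every peak to its half-open bin \code{[edge, edge + width)} under
#' \code{scheme} (the final bin is closed at the window maximum) and sums
#' the fluorescence of peaks falling in the same bin of the same sample.
#' Total fluorescence per sample is conserved. Peaks must already lie
#' inside the analysis window: run \code{\link{filterPeaks}} first.
#'
#' @param x a filtered \linkS4class{PeakSet}
#' @param scheme a \linkS4class{BinScheme}
#' @return data.frame with columns \code{sample}, \code{bin} (integer lower
#'   edge in bp) and \code{fluorescence}, ordered by sample (input order)
#'   then ascending bin
#' @export
binFragments <- function(x, scheme = BinScheme()) {
  stopifnot(is(x, "PeakSet"))
  p <- peakData(x)
  if (nrow(p) && (any(p$length_bp < scheme@windowMin) ||
                  any(p$length_bp > scheme@windowMax)))
    stop("peaks outside [", scheme@windowMin, ", ", scheme@windowMax,
         "] bp: run filterPeaks() before binning")
  if (!nrow(p))
    return(data.frame(sample = character(), bin = numeric(),
                      fluorescence = numeric()))
  p$bin <- .binEdge(p$length_bp, scheme)
  agg <- stats::aggregate(fluorescence ~ sample + bin, data = p, FUN = sum)
  agg$sample <- factor(agg$sample, levels = sampleIDs(x))
  agg <- agg[order(agg$sample, agg$bin), c("sample", "bin", "fluorescence")]
  agg$sample <- as.character(agg$sample)
  rownames(agg) <- NULL
  agg
}

#' Assemble the sample x OTU matrix from binned peaks
#'
#' Columns are the union of bins occupied in at least one sample; bins with
#' zero fluorescence in every sample never enter the matrix (elution points
#' without a peak in any sample are removed). Row order follows the input
#' sample order; column order is ascending bin edge. Samples that lost all
#' their peaks in filtering are kept as all-zero rows (flagged).
#'
#' @param x the filtered \linkS4class{PeakSet} the binned peaks came from
#'   (supplies sample order and metadata)
#' @param scheme a \linkS4class{BinScheme} used to bin \code{x}
#' @return an \linkS4class{OTUMatrix}
#' @examples
#' ps <- PeakSet(data.frame(sample = c("A", "B", "B"),
#'                          length_bp = c(518, 518.9, 545.2),
#'                          fluorescence = c(100, 200, 300)))
#' otuAbundance(buildOTUMatrix(ps))
#' @export
buildOTUMatrix <- function(x, scheme = BinScheme()) {
  stopifnot(is(x, "PeakSet"))
  ids <- sampleIDs(x)
  if (!length(ids)) stop("empty input: no samples")
  if (anyDuplicated(ids))
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  binned <- binFragments(x, scheme)
  bins <- sort(unique(binned$bin))
  m <- matrix(0, nrow = length(ids), ncol = length(bins),
              dimnames = list(ids, as.character(bins)))
  if (nrow(binned))
    m[cbind(match(binned$sample, ids), match(binned$bin, bins))] <-
      binned$fluorescence
  meta <- sampleInfo(x)
  rownames(meta) <- meta$sample
  OTUMatrix(m, meta[ids, setdiff(names(meta), "sample"), drop = FALSE])
}

#' Write / read an OTU matrix as CSV
#'
#' \code{writeOTUMatrix} writes the samples-by-bins matrix (first column
#' \code{sample}, remaining columns bin labels) and, alongside it, a
#' \code{*_metadata.csv} sidecar with the per-sample metadata.
#' \code{readOTUMatrix} reads the pair back.
#'
#' @param x an \linkS4class{OTUMatrix}
#' @param path output CSV path
#' @return \code{readOTUMatrix} returns an \linkS4class{OTUMatrix};
#'   \code{writeOTUMatrix} returns \code{path} invisibly.
#' @export
writeOTUMatrix <- function(x, path) {
  m <- otuAbundance(x)
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- sampleData(x)
  metaPath <- sub("\\.csv$", "_metadata.csv", path)
  utils::write.csv(data.frame(sample = rownames(m), meta,
                              check.names = FALSE),
                   metaPath, row.names = FALSE)
  invisible(path)
}

#' @rdname writeOTUMatrix
#' @export
readOTUMatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample
  metaPath <- sub("\\.csv$", "_metadata.csv", path)
  meta <- NULL
  if (file.exists(metaPath)) {
    meta <- utils::read.csv(metaPath, check.names = FALSE)
    rownames(meta) <- meta$sample
    meta <- meta[rownames(m), setdiff(names(meta), "sample"), drop = FALSE]
  }
  OTUMatrix(m, meta)
}
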