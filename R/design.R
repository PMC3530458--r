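# Theory-of-Sampling vineyard design: treat a vineyard block as a
# two-dimensional lot, unfold ("linearize") it into a one-dimensional
# sequence of sampling points, and test for pseudoreplication by regressing
# community correlation on inter-point distance.

#' The three reference vineyard layouts
#'
#' Conventional (CONV): rows 9, 11, 13, 15, 17, 19 sampled at panels
#' 3, 7, 11 (18 points). Biodynamic (BD): rows 1, 4, 7, 10, 13, 16, 19 at
#' panels 3, 7, 11 (21 points). Integrated production (IPW): rows 115, 117,
#' 119 at panels 1, 3, 5, 7, 9, 11 (18 points). Row width 2.5 m, panel
#' width 9 m throughout.
#'
#' @return named list of \linkS4class{VineyardLayout} objects
#'   (\code{CONV}, \code{BD}, \code{IPW})
#' @examples
#' vapply(defaultLayouts(), function(l) nrow(linearizeLayout(l)), 0L)
#' @export
defaultLayouts <- function() {
  list(
    CONV = VineyardLayout("CONV", c(9, 11, 13, 15, 17, 19), c(3, 7, 11)),
    BD   = VineyardLayout("BD", c(1, 4, 7, 10, 13, 16, 19), c(3, 7, 11)),
    IPW  = VineyardLayout("IPW", c(115, 117, 119), c(1, 3, 5, 7, 9, 11))
  )
}

#' Read a vineyard layout from a YAML config
#'
#' Expects keys \code{rows}, \code{panels} and optionally \code{name},
#' \code{row_width} (default 2.5) and \code{panel_width} (default 9).
#'
#' @param path YAML file path
#' @param name layout label, overriding any \code{name} key
#' @return a \linkS4class{VineyardLayout}
#' @export
readLayout <- function(path, name = NULL) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$rows) || is.null(cfg$panels))
    stop("layout config must define 'rows' and 'panels'")
  VineyardLayout(
    name = name %||% cfg$name %||% "vineyard",
    rowNumbers = cfg$rows, panelNumbers = cfg$panels,
    rowWidth = cfg$row_width %||% 2.5,
    panelWidth = cfg$panel_width %||% 9
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Linearize a vineyard lot into sampling points
#'
#' Unfolds the two-dimensional lot into an elongated one-dimensional lot:
#' one sampling point per (row, panel) combination, ordered serpentine
#' (row-major, panel order reversed on alternate rows, the path a sampler
#' walking the unfolded lot takes). Metric coordinates are
#' x = row x rowWidth and y = panel x panelWidth; \code{linear_index} is
#' the position along the unfolded lot and affects only bookkeeping, never
#' distances.
#'
#' @param layout a \linkS4class{VineyardLayout}
#' @return data.frame with columns \code{sample}, \code{vineyard},
#'   \code{row}, \code{panel}, \code{x}, \code{y}, \code{linear_index};
#'   sample ids follow the \code{<vineyard>_r<row>_p<panel>} convention
#' @examples
#' head(linearizeLayout(defaultLayouts()$CONV))
#' @export
linearizeLayout <- function(layout) {
  stopifnot(is(layout, "VineyardLayout"))
  pts <- do.call(rbind, lapply(seq_along(layout@rowNumbers), function(i) {
    panels <- layout@panelNumbers
    if (i %% 2 == 0) panels <- rev(panels)  # serpentine
    data.frame(row = layout@rowNumbers[i], panel = panels)
  }))
  data.frame(
    sample = sprintf("%s_r%d_p%d", layout@name, pts$row, pts$panel),
    vineyard = layout@name,
    row = pts$row, panel = pts$panel,
    x = pts$row * layout@rowWidth,
    y = pts$panel * layout@panelWidth,
    linear_index = seq_len(nrow(pts))
  )
}

#' Euclidean distance between two sampling points
#'
#' \code{sqrt(dx^2 + dy^2)} where dx and dy are the differences of the
#' metric x and y coordinates. Both points must belong to the same
#' vineyard; cross-vineyard distances are outside the procedure.
#'
#' @param a,b single rows of a \code{\link{linearizeLayout}} table
#' @return distance in meters
#' @examples
#' pts <- linearizeLayout(defaultLayouts()$CONV)
#' pairwiseDistance(pts[1, ], pts[2, ])
#' @export
pairwiseDistance <- function(a, b) {
  if (a$vineyard != b$vineyard)
    stop("points belong to different vineyards ('", a$vineyard, "' vs '",
         b$vineyard, "')")
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
}

#' Distance-decay test for pseudoreplication
#'
#' For every unordered pair of sampling points within one vineyard,
#' computes the Euclidean distance and the Pearson correlation between the
#' two samples' OTU fluorescence vectors, then fits ordinary least squares
#' of community correlation (dependent) on distance (independent). A strong
#' negative relationship would indicate that location, not treatment,
#' drives community composition (pseudoreplication); a flat fit supports
#' treating the points as replicates.
#'
#' Samples are matched to points by sample id when the ids follow the
#' \code{\link{linearizeLayout}} convention, otherwise by the (row, panel)
#' metadata of the \linkS4class{OTUMatrix}.
#'
#' @param x an \linkS4class{OTUMatrix} containing the vineyard's samples
#' @param points the \code{\link{linearizeLayout}} table of one vineyard
#' @return a \linkS4class{PseudoreplicationResult}
#' @export
pseudoreplicationTest <- function(x, points) {
  stopifnot(is(x, "OTUMatrix"))
  if (length(unique(points$vineyard)) != 1)
    stop("points must come from a single vineyard")
  if (nrow(points) < 3)
    stop("need at least 3 sampling points, got ", nrow(points))
  m <- otuAbundance(x)
  idx <- match(points$sample, rownames(m))
  if (anyNA(idx)) {
    meta <- sampleData(x)
    if (!all(c("row", "panel") %in% names(meta)))
      stop("cannot match points to samples: sample(s) ",
           paste(points$sample[is.na(idx)], collapse = ", "),
           " absent and no row/panel metadata to fall back on")
    key <- paste(meta$row, meta$panel)
    idx <- match(paste(points$row, points$panel), key)
    if (anyNA(idx))
      stop("no sample for point(s): ",
           paste(points$sample[is.na(idx)], collapse = ", "))
  }
  m <- m[idx, , drop = FALSE]
  sdv <- apply(m, 1, stats::sd)
  if (any(sdv == 0))
    stop("zero-variance sample vector(s): ",
         paste(rownames(m)[sdv == 0], collapse = ", "))

  pair <- utils::combn(nrow(points), 2)
  d <- sqrt((points$x[pair[1, ]] - points$x[pair[2, ]])^2 +
            (points$y[pair[1, ]] - points$y[pair[2, ]])^2)
  r <- vapply(seq_len(ncol(pair)), function(k)
    stats::cor(m[pair[1, k], ], m[pair[2, k], ]), 0)
  pairs <- data.frame(
    sample_i = points$sample[pair[1, ]],
    sample_j = points$sample[pair[2, ]],
    distance_m = d, pearson_r = r
  )
  fit <- stats::lm(pearson_r ~ distance_m, data = pairs)
  rDist <- stats::cor(pairs$distance_m, pairs$pearson_r)
  slope <- unname(stats::coef(fit)[2])
  new("PseudoreplicationResult",
    pairs = pairs, rDistance = rDist, rSquared = rDist^2,
    signedR2 = sign(slope) * rDist^2,
    slope = slope, intercept = unname(stats::coef(fit)[1])
  )
}

#' @param x a \linkS4class{PseudoreplicationResult}
#' @return \code{pseudoreplicationPairs()} returns the per-pair scatter
#'   table (distance vs community correlation).
#' @rdname pseudoreplicationTest
#' @export
pseudoreplicationPairs <- function(x) x@pairs

#' @return \code{pseudoreplicationSummary()} returns a one-row data.frame
#'   with \code{n_pairs}, \code{r_distance}, \code{r_squared},
#'   \code{signed_r2}, \code{slope} and \code{intercept}.
#' @rdname pseudoreplicationTest
#' @export
pseudoreplicationSummary <- function(x) {
  data.frame(
    n_pairs = nrow(x@pairs), r_distance = x@rDistance,
    r_squared = x@rSquared, signed_r2 = x@signedR2,
    slope = x@slope, intercept = x@intercept
  )
}
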