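# Culture-based alpha diversity: relative abundance, Shannon diversity
# (natural log), Menhinick richness and Pielou evenness per vineyard, from
# species x vineyard isolate tables.

#' Read a species-by-vineyard isolate table
#'
#' CSV with the species label in the first column and one column of
#' abundances per vineyard. Dashes, empty cells and NA are read as 0
#' (absent). In percent mode each vineyard column must sum to 100 within a
#' 0.5 rounding slack.
#'
#' @param path CSV path
#' @param mode \code{"counts"} or \code{"percent"}
#' @return an \linkS4class{IsolateTable}
#' @export
readIsolateTable <- function(path, mode = c("counts", "percent")) {
  mode <- match.arg(mode)
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  m[m %in% c("-", "–", "")] <- "0"
  m <- apply(m, 2, function(col) {
    v <- suppressWarnings(as.numeric(col))
    v[is.na(v)] <- 0
    v
  })
  rownames(m) <- df[[1]]
  IsolateTable(m, mode)
}

#' Relative abundance of species
#'
#' Proportion of each species in a sample: each entry divided by the
#' column total. Zeros are preserved; the result sums to 1.
#'
#' @param counts non-negative abundance vector with at least one positive
#'   entry
#' @return proportions vector of the same length
#' @examples
#' relativeAbundance(c(7, 2, 1))
#' @export
relativeAbundance <- function(counts) {
  if (any(counts < 0)) stop("abundances must be non-negative")
  tot <- sum(counts)
  if (tot == 0) stop("all-zero abundance vector: proportions undefined")
  counts / tot
}

#' Shannon diversity index (natural log)
#'
#' H = -sum(p_i * ln p_i) over the nonzero proportions. Natural logarithm
#' throughout (nats); no base option is offered, to avoid silent base
#' mismatches between studies.
#'
#' @param p proportions summing to 1 (tolerance \code{tol}); zero entries
#'   are skipped
#' @param tol allowed deviation of \code{sum(p)} from 1 (default 1e-6; a
#'   rounded percentage table divided by 100 needs a looser 0.005)
#' @return H in nats; 0 for a single-species community
#' @examples
#' shannonIndex(c(0.5, 0.5))  # ln 2
#' @export
shannonIndex <- function(p, tol = 1e-6) {
  if (any(p < 0)) stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > tol)
    stop("proportions must sum to 1 (got ", format(sum(p)), ")")
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Menhinick's richness index
#'
#' D = S / sqrt(N): species count standardized by the square root of the
#' number of individuals. Requires true individual counts; it is never
#' estimated from percentages.
#'
#' @param S species richness (count, >= 1)
#' @param N number of individuals (>= S)
#' @return D
#' @examples
#' menhinickIndex(4, 16)  # 1
#' @export
menhinickIndex <- function(S, N) {
  if (S < 1) stop("need at least one species")
  if (N < S) stop("individuals (N) cannot be fewer than species (S)")
  S / sqrt(N)
}

#' Pielou's evenness index
#'
#' J = H / ln S, the observed Shannon diversity relative to its maximum
#' for S species. Undefined for a single species.
#'
#' @param H Shannon diversity in nats
#' @param S species richness (>= 2)
#' @return J in [0, 1]
#' @examples
#' pielouIndex(log(5), 5)  # uniform community: 1
#' @export
pielouIndex <- function(H, S) {
  if (S < 2) stop("evenness is undefined for a single species")
  H / log(S)
}

#' Per-vineyard diversity report
#'
#' For each vineyard column of an \linkS4class{IsolateTable}: species
#' richness S (species with positive abundance), Shannon H from the
#' relative abundances, Pielou J = H/ln S (NA when S = 1), and, in counts
#' mode only, the individual total N and Menhinick D = S/sqrt(N). In
#' percent mode the percentages divided by 100 are used directly as the
#' proportions (no renormalization; a 0.1-point rounding residual in the
#' column sum is tolerated), and N and D are reported as NA (undefined
#' without true counts).
#'
#' @param table an \linkS4class{IsolateTable}
#' @return data.frame with one row per vineyard and columns
#'   \code{vineyard}, \code{S}, \code{N}, \code{H}, \code{D}, \code{J}
#' @examples
#' tbl <- IsolateTable(cbind(V1 = c(6, 3, 1)), mode = "counts")
#' diversityReport(tbl)
#' @export
diversityReport <- function(table) {
  stopifnot(is(table, "IsolateTable"))
  ab <- isolateAbundance(table)
  counts <- abundanceMode(table) == "counts"
  rows <- lapply(colnames(ab), function(v) {
    col <- ab[, v]
    S <- sum(col > 0)
    p <- if (counts) relativeAbundance(col) else col / 100
    H <- shannonIndex(p, tol = if (counts) 1e-6 else 0.005)
    data.frame(
      vineyard = v, S = S,
      N = if (counts) sum(col) else NA_real_,
      H = H,
      D = if (counts) menhinickIndex(S, sum(col)) else NA_real_,
      J = if (S > 1) pielouIndex(H, S) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
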