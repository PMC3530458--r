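# Synthetic data with the statistical structure the analysis assumes:
# per-sampling-point electropherograms (shared dominant 500-600 bp bands,
# vineyard-private minor OTUs, sub-threshold noise) and culture-isolate
# tables, so the whole pipeline is testable without any deposited data.

## draw fragment lengths uniformly from the window minus an excluded band
.drawMinorLengths <- function(n, lower, upper, excl) {
  left <- c(lower, excl[1])
  right <- c(excl[2], upper)
  wl <- left[2] - left[1]
  wr <- right[2] - right[1]
  u <- stats::runif(n, 0, wl + wr)
  ifelse(u < wl, left[1] + u, right[1] + (u - wl))
}

#' Simulate per-sampling-point ARISA electropherograms
#'
#' Generates one peak table per sampling point of every layout. Each
#' sample's peaks comprise: (i) shared dominant OTUs whose fragment lengths
#' are drawn once from \code{dominantBand} and which carry, log-normally
#' dispersed, \code{dominantFraction} of the sample's total fluorescence;
#' (ii) vineyard-private minor OTUs, each present at a given point with
#' probability \code{occupancy} (independent Bernoulli, creating
#' intra-vineyard heterogeneity) and following a geometric rank-abundance
#' profile; and (iii) \code{noisePeaks} background peaks below the 50-RFU
#' threshold whose lengths may fall outside the 300-1000 bp window (in
#' [100, 1050]), so the length filter is exercised.
#'
#' With \code{spatialKernel = TRUE}, each private OTU is given a random
#' focus inside its vineyard and its occupancy decays with a Gaussian
#' kernel of range \code{kernelRange} around that focus (rescaled so the
#' vineyard-average occupancy stays at \code{occupancy}). Nearby points
#' then share minor OTUs more often, producing a distance-decay community
#' — the positive control for \code{\link{pseudoreplicationTest}}.
#'
#' Fully reproducible from \code{seed}; no other random state is consulted.
#'
#' @param layouts list of \linkS4class{VineyardLayout} (default the three
#'   reference layouts, 57 points in all)
#' @param nSharedOtus dominant OTUs shared by all vineyards (default 6)
#' @param nPrivateOtus minor OTUs private to each vineyard (default 12)
#' @param dominantFraction expected fraction of total fluorescence carried
#'   by the shared dominant OTUs (default 0.6)
#' @param dominantBand bp interval the dominant fragments fall in
#'   (default c(500, 600))
#' @param occupancy probability a private OTU appears at a sampling point
#'   (default 0.6)
#' @param noisePeaks sub-threshold background peaks per sample (default 5)
#' @param fluorescenceScale typical total sample fluorescence in RFU
#'   (default 5e4)
#' @param decay geometric rank-abundance decay of OTU base weights
#'   (default 0.65)
#' @param spatialKernel,kernelRange see above; range in meters (default 20)
#' @param seed integer seed
#' @return a \linkS4class{PeakSet} with vineyard/row/panel metadata
#' @examples
#' ps <- simulateProfiles(layouts = defaultLayouts()["CONV"], seed = 1)
#' ps
#' @export
simulateProfiles <- function(layouts = defaultLayouts(),
                             nSharedOtus = 6, nPrivateOtus = 12,
                             dominantFraction = 0.6,
                             dominantBand = c(500, 600),
                             occupancy = 0.6, noisePeaks = 5,
                             fluorescenceScale = 5e4, decay = 0.65,
                             spatialKernel = FALSE, kernelRange = 20,
                             seed = 1) {
  stopifnot(dominantFraction >= 0, dominantFraction <= 1,
            occupancy >= 0, occupancy <= 1,
            dominantBand[1] >= 300, dominantBand[2] <= 1000)
  set.seed(seed)
  sharedLen <- stats::runif(nSharedOtus, dominantBand[1], dominantBand[2])
  sharedBase <- decay^(seq_len(nSharedOtus) - 1)

  out <- lapply(layouts, function(layout) {
    pts <- linearizeLayout(layout)
    privLen <- .drawMinorLengths(nPrivateOtus, 310, 990, dominantBand)
    privBase <- decay^(seq_len(nPrivateOtus) - 1)
    if (spatialKernel && nPrivateOtus > 0) {
      fx <- stats::runif(nPrivateOtus, min(pts$x), max(pts$x))
      fy <- stats::runif(nPrivateOtus, min(pts$y), max(pts$y))
      K <- outer(seq_len(nrow(pts)), seq_len(nPrivateOtus), function(i, j)
        exp(-0.5 * ((pts$x[i] - fx[j])^2 + (pts$y[i] - fy[j])^2) /
              kernelRange^2))
      # rescale so each OTU keeps a vineyard-average occupancy of `occupancy`
      P <- sweep(K, 2, colMeans(K), "/") * occupancy
      P[P > 1] <- 1
    } else {
      P <- matrix(occupancy, nrow(pts), max(nPrivateOtus, 1))
    }
    peaks <- lapply(seq_len(nrow(pts)), function(i) {
      total <- fluorescenceScale * exp(stats::rnorm(1, 0, 0.2))
      sharedTot <- dominantFraction * total * exp(stats::rnorm(1, 0, 0.15))
      minorTot <- (1 - dominantFraction) * total *
        exp(stats::rnorm(1, 0, 0.15))
      sw <- sharedBase * exp(stats::rnorm(nSharedOtus, 0, 0.3))
      lens <- sharedLen
      fluo <- sharedTot * sw / sum(sw)
      present <- if (nPrivateOtus > 0)
        which(stats::runif(nPrivateOtus) < P[i, ]) else integer()
      if (length(present)) {
        mw <- privBase[present] * exp(stats::rnorm(length(present), 0, 0.4))
        lens <- c(lens, privLen[present])
        fluo <- c(fluo, minorTot * mw / sum(mw))
      }
      if (noisePeaks > 0) {
        lens <- c(lens, stats::runif(noisePeaks, 100, 1050))
        fluo <- c(fluo, stats::runif(noisePeaks, 5, 49.9))
      }
      data.frame(sample = pts$sample[i], vineyard = pts$vineyard[i],
                 row = pts$row[i], panel = pts$panel[i],
                 length_bp = lens, fluorescence = fluo)
    })
    do.call(rbind, peaks)
  })
  PeakSet(do.call(rbind, c(out, list(make.row.names = FALSE))))
}

#' Simulate a culture-isolate abundance table
#'
#' Per-vineyard multinomial draws over a geometric-decay rank-abundance
#' profile led by a shared dominant species (the role the black yeast-like
#' fungus plays on real grape berries, carrying roughly 50-70 percent of
#' isolates). A core of \code{sharedCore} species occurs in every vineyard;
#' the remaining species are vineyard-private. Every configured species
#' receives at least one isolate, so the realized per-vineyard richness
#' equals \code{speciesPerVineyard} exactly, and the grand total equals
#' \code{totalIsolates} exactly (split across vineyards proportionally to
#' their sampling-point counts by largest remainder).
#'
#' @param speciesPerVineyard named integer vector of per-vineyard species
#'   richness (defaults to the reference study: CONV 11, IPW 9, BD 17)
#' @param totalIsolates grand total number of isolates (default 628)
#' @param dominantShare expected share of the leading species (default 0.6)
#' @param decay geometric decay of the remaining species' expected shares
#'   (default 0.65)
#' @param sharedCore number of species common to all vineyards (default 4)
#' @param pointWeights per-vineyard weights for splitting the total
#'   (defaults to the reference sampling-point counts 18/18/21)
#' @param seed integer seed
#' @return a counts-mode \linkS4class{IsolateTable}
#' @examples
#' tbl <- simulateIsolates(seed = 1)
#' colSums(isolateAbundance(tbl) > 0)  # realized richness
#' @export
simulateIsolates <- function(speciesPerVineyard = c(CONV = 11, IPW = 9,
                                                    BD = 17),
                             totalIsolates = 628, dominantShare = 0.6,
                             decay = 0.65, sharedCore = 4,
                             pointWeights = c(CONV = 18, IPW = 18, BD = 21),
                             seed = 1) {
  vineyards <- names(speciesPerVineyard)
  sharedCore <- min(sharedCore, min(speciesPerVineyard))
  # largest-remainder split of the grand total
  raw <- totalIsolates * pointWeights[vineyards] / sum(pointWeights[vineyards])
  nv <- floor(raw)
  left <- totalIsolates - sum(nv)
  if (left > 0) {
    up <- order(raw - nv, decreasing = TRUE)[seq_len(left)]
    nv[up] <- nv[up] + 1
  }
  bad <- speciesPerVineyard > nv
  if (any(bad))
    stop("infeasible config: richness exceeds isolate total for ",
         paste(vineyards[bad], collapse = ", "))
  set.seed(seed)
  coreNames <- sprintf("core_species_%02d", seq_len(sharedCore))
  cols <- lapply(vineyards, function(v) {
    S <- speciesPerVineyard[[v]]
    species <- c(coreNames,
                 if (S > sharedCore)
                   sprintf("%s_species_%02d", v, seq_len(S - sharedCore)))
    p <- c(dominantShare,
           (1 - dominantShare) * decay^(seq_len(S - 1) - 1) /
             sum(decay^(seq_len(S - 1) - 1)))
    counts <- rep(1L, S) +
      as.integer(stats::rmultinom(1, nv[[v]] - S, prob = p))
    stats::setNames(counts, species)
  })
  species <- unique(unlist(lapply(cols, names)))
  m <- matrix(0L, length(species), length(vineyards),
              dimnames = list(species, vineyards))
  for (k in seq_along(vineyards))
    m[names(cols[[k]]), k] <- cols[[k]]
  IsolateTable(m, mode = "counts")
}
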