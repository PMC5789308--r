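#' Scan-sampled lying observations for one pen
#'
#' Container for one pen-week of instantaneous scan samples: which animals
#' were lying at each scan and which unordered pairs were lying together.
#' Co-lying is stored pairwise, never as lying groups, so transitivity is
#' not implied: pairs (A,B) and (B,C) do not entail (A,C).
#'
#' @slot penId pen identifier.
#' @slot week age of the animals in weeks at observation.
#' @slot roster ordered animal ids (length n).
#' @slot lying n x S logical matrix; \code{lying[a, s]} is TRUE when animal
#'   a was recorded lying at scan s.
#' @slot colying list of length S; element s is a 2-column character matrix
#'   of unordered co-lying pairs at scan s, each row sorted so column 1 is
#'   the lexicographically smaller id, rows sorted and unique.
#'
#' @examples
#' cfg <- simulationConfig(nAnimals = 4, nScans = 10, seed = 1)
#' obs <- simulatePen(cfg)
#' roster(obs)
#' nScans(obs)
#' @export
setClass("PenObservations",
  representation(penId = "character", week = "integer",
                 roster = "character", lying = "matrix",
                 colying = "list"))

setValidity("PenObservations", function(object) {
  r <- object@roster
  if (length(r) < 1L || anyDuplicated(r) || any(!nzchar(r)))
    return("roster must be non-empty, unique, non-blank ids")
  L <- object@lying
  if (!is.logical(L) || nrow(L) != length(r) ||
      !identical(rownames(L), r))
    return("lying must be a logical matrix with one row per roster animal")
  S <- ncol(L)
  if (S < 1L) return("at least one scan is required (S >= 1)")
  if (length(object@colying) != S)
    return("colying must have one element per scan")
  for (s in seq_len(S)) {
    p <- object@colying[[s]]
    if (!is.matrix(p) || ncol(p) != 2L || !is.character(p))
      return(sprintf("colying[[%d]] must be a 2-column character matrix", s))
    if (nrow(p) == 0L) next
    if (!all(p %in% r))
      return(sprintf("scan %d: co-lying pair references unknown animal", s))
    if (any(p[, 1L] == p[, 2L]))
      return(sprintf("scan %d: self-pair in co-lying records", s))
    if (any(p[, 1L] >= p[, 2L]))
      return(sprintf("scan %d: pairs must be stored (smaller id, larger id)", s))
    keys <- paste(p[, 1L], p[, 2L], sep = "\r")
    if (anyDuplicated(keys))
      return(sprintf("scan %d: duplicate co-lying pair", s))
    lyingHere <- r[L[, s]]
    badRow <- !(p[, 1L] %in% lyingHere) | !(p[, 2L] %in% lyingHere)
    if (any(badRow)) {
      i <- which(badRow)[1L]
      return(sprintf(
        "scan %d: co-lying pair (%s, %s) includes an animal not recorded lying",
        s, p[i, 1L], p[i, 2L]))
    }
  }
  TRUE
})

#' Construct a PenObservations object
#'
#' @param penId pen identifier.
#' @param week integer age in weeks.
#' @param roster ordered character vector of animal ids.
#' @param lying n x S logical (or 0/1) matrix, rows in roster order.
#' @param colying list of length S of 2-column character matrices of
#'   co-lying pairs (any row order / within-pair order; canonicalized).
#' @return A validated \linkS4class{PenObservations}.
#' @export
PenObservations <- function(penId, week, roster, lying, colying) {
  roster <- as.character(roster)
  checkIds(roster)
  lying <- as.matrix(lying)
  storage.mode(lying) <- "logical"
  rownames(lying) <- roster
  colnames(lying) <- as.character(seq_len(ncol(lying)))
  colying <- lapply(colying, canonicalPairs)
  new("PenObservations", penId = as.character(penId),
      week = as.integer(week), roster = roster,
      lying = lying, colying = colying)
}

# sort within pair, then sort rows, drop duplicates
canonicalPairs <- function(p) {
  if (is.null(p) || length(p) == 0L)
    return(matrix(character(0), ncol = 2L))
  p <- matrix(as.character(p), ncol = 2L)
  swap <- p[, 1L] > p[, 2L]
  p[swap, ] <- p[swap, c(2L, 1L)]
  p <- unique(p)
  p[order(p[, 1L], p[, 2L]), , drop = FALSE]
}

#' @rdname roster
#' @export
setMethod("roster", "PenObservations", function(x) x@roster)
#' @rdname nScans
#' @export
setMethod("nScans", "PenObservations", function(x) ncol(x@lying))
#' @rdname penId
#' @export
setMethod("penId", "PenObservations", function(x) x@penId)
#' @rdname week
#' @export
setMethod("week", "PenObservations", function(x) x@week)

setMethod("show", "PenObservations", function(object) {
  nPairs <- sum(vapply(object@colying, nrow, 1L))
  cat(sprintf(
    "PenObservations: pen %s, week %d\n  %d animals, %d scans, %d co-lying pair records\n",
    object@penId, object@week, length(object@roster),
    ncol(object@lying), nPairs))
})

#' Pairwise co-lying frequency matrix for one pen
#'
#' @slot roster ordered animal ids.
#' @slot pairCounts symmetric integer matrix x_ab: scans in which the pair
#'   lay together; zero diagonal.
#' @slot lyingCounts named integer vector n_a: scans each animal spent lying.
#' @slot totalScans total number of scans S.
#' @export
setClass("FrequencyMatrix",
  representation(roster = "character", pairCounts = "matrix",
                 lyingCounts = "integer", totalScans = "integer"))

setValidity("FrequencyMatrix", function(object) {
  r <- object@roster
  x <- object@pairCounts
  n <- object@lyingCounts
  S <- object@totalScans
  if (nrow(x) != length(r) || ncol(x) != length(r))
    return("pairCounts must be square over the roster")
  if (!identical(x, t(x))) return("pairCounts must be symmetric")
  if (any(diag(x) != 0L)) return("pairCounts diagonal must be zero")
  if (length(n) != length(r)) return("one lying count per animal required")
  if (any(n < 0L) || any(n > S)) return("lying counts must lie in [0, S]")
  lim <- outer(n, n, pmin); diag(lim) <- 0L
  if (any(x > lim))
    return("pairCounts exceed min(n_a, n_b) for some pair")
  if (any(x < 0L)) return("pairCounts must be nonnegative")
  TRUE
})

#' @rdname roster
#' @export
setMethod("roster", "FrequencyMatrix", function(x) x@roster)
#' @rdname nScans
#' @export
setMethod("nScans", "FrequencyMatrix", function(x) x@totalScans)
#' @rdname pairCounts
#' @export
setMethod("pairCounts", "FrequencyMatrix", function(x) x@pairCounts)
#' @rdname lyingCounts
#' @export
setMethod("lyingCounts", "FrequencyMatrix", function(x) x@lyingCounts)

setMethod("show", "FrequencyMatrix", function(object) {
  cat(sprintf(
    "FrequencyMatrix: %d animals, %d scans\n  pair counts %d..%d, lying counts %d..%d\n",
    length(object@roster), object@totalScans,
    min(upperTriVals(object@pairCounts)), max(upperTriVals(object@pairCounts)),
    min(object@lyingCounts), max(object@lyingCounts)))
})

#' Half-weight association index matrix
#'
#' Symmetric weighted association matrix with values in [0, 1] and zero
#' diagonal; the undirected, valued network over which all pen-level and
#' animal-level measures are computed.
#'
#' @slot roster ordered animal ids.
#' @slot weights symmetric numeric matrix of HWI values.
#' @export
setClass("HWIMatrix",
  representation(roster = "character", weights = "matrix"))

setValidity("HWIMatrix", function(object) {
  w <- object@weights
  r <- object@roster
  if (nrow(w) != length(r) || ncol(w) != length(r))
    return("weights must be square over the roster")
  if (max(abs(w - t(w))) > 1e-12) return("weights must be symmetric")
  if (any(diag(w) != 0)) return("diagonal must be zero")
  if (any(w < 0) || any(w > 1 + 1e-12)) return("weights must lie in [0, 1]")
  TRUE
})

#' Construct an HWIMatrix from a weight matrix
#'
#' @param weights symmetric numeric matrix in [0, 1], zero diagonal;
#'   dimnames supply the roster unless \code{roster} is given.
#' @param roster optional character vector of animal ids.
#' @return A validated \linkS4class{HWIMatrix}.
#' @export
HWIMatrix <- function(weights, roster = NULL) {
  checkSquareNamed(weights, "weights")
  if (is.null(roster)) roster <- rownames(weights)
  if (is.null(roster)) roster <- as.character(seq_len(nrow(weights)))
  checkIds(roster)
  dimnames(weights) <- list(roster, roster)
  new("HWIMatrix", roster = as.character(roster), weights = weights)
}

#' @rdname roster
#' @export
setMethod("roster", "HWIMatrix", function(x) x@roster)
#' @rdname weightMatrix
#' @export
setMethod("weightMatrix", "HWIMatrix", function(x) x@weights)

setMethod("show", "HWIMatrix", function(object) {
  w <- upperTriVals(object@weights)
  cat(sprintf(
    "HWIMatrix: %d animals, %d pairs\n  HWI mean %.3f, range [%.3f, %.3f]\n",
    length(object@roster), length(w), mean(w), min(w), max(w)))
})

#' Simulation parameters for a synthetic pen
#'
#' Generative model of the scan-sampling observation process: each animal
#' lies according to a two-state chain with stationary probability
#' \code{lieProb} and carry-over probability \code{boutPersistence}; each
#' pair with both members lying co-lies independently with probability
#' \code{preference[a, b]}.
#'
#' @slot nAnimals group size n.
#' @slot nScans number of scans S.
#' @slot lieProb per-animal stationary lying probability.
#' @slot boutPersistence probability in [0, 1) that the lying state carries
#'   over to the next scan; 0 gives independent scans.
#' @slot preference symmetric matrix of pairwise co-lying probabilities
#'   given both members lying; zero diagonal.
#' @slot seed RNG seed (NA for "use current stream").
#' @export
setClass("SimulationConfig",
  representation(nAnimals = "integer", nScans = "integer",
                 lieProb = "numeric", boutPersistence = "numeric",
                 preference = "matrix", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  n <- object@nAnimals
  if (n < 2L) return("at least two animals required")
  if (object@nScans < 1L) return("at least one scan required")
  p <- object@lieProb
  if (length(p) != n || any(p < 0) || any(p > 1))
    return("lieProb must be one probability per animal")
  rho <- object@boutPersistence
  if (length(rho) != 1L || rho < 0 || rho >= 1)
    return("boutPersistence must lie in [0, 1)")
  w <- object@preference
  if (nrow(w) != n || ncol(w) != n) return("preference must be n x n")
  if (max(abs(w - t(w))) > 1e-12) return("preference must be symmetric")
  if (any(diag(w) != 0)) return("preference diagonal must be zero")
  if (any(w < 0) || any(w > 1)) return("preference must lie in [0, 1]")
  TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d animals x %d scans\n  lieProb %.2f..%.2f, persistence %.2f, mean preference %.3f, seed %s\n",
    object@nAnimals, object@nScans, min(object@lieProb), max(object@lieProb),
    object@boutPersistence, mean(upperTriVals(object@preference)),
    ifelse(is.na(object@seed), "<none>", object@seed)))
})
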