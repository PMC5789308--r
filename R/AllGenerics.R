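#' @import methods
NULL

#' Animal roster of an observation or matrix object
#'
#' Returns the ordered vector of animal ids carried by a
#' \linkS4class{PenObservations}, \linkS4class{FrequencyMatrix} or
#' \linkS4class{HWIMatrix} object.
#'
#' @param x an object with a roster.
#' @return Character vector of animal ids, in roster order.
#' @export
setGeneric("roster", function(x) standardGeneric("roster"))

#' Number of scan samples
#'
#' @param x a \linkS4class{PenObservations} or \linkS4class{FrequencyMatrix}.
#' @return Integer count of scans.
#' @export
setGeneric("nScans", function(x) standardGeneric("nScans"))

#' Pen identifier
#' @param x a \linkS4class{PenObservations}.
#' @return Character pen id.
#' @export
setGeneric("penId", function(x) standardGeneric("penId"))

#' Observation week (age of the animals in weeks)
#' @param x a \linkS4class{PenObservations}.
#' @return Integer week.
#' @export
setGeneric("week", function(x) standardGeneric("week"))

#' Per-scan binary co-lying matrices
#'
#' One symmetric 0/1 matrix per scan with zero diagonal; entry (a, b) is 1
#' exactly when the pair was recorded lying together at that scan. Summing
#' the list reproduces the pairwise counts of
#' \code{\link{frequencyMatrix}}.
#'
#' @param obs a \linkS4class{PenObservations}.
#' @return List of S integer matrices, each n x n.
#' @export
setGeneric("binaryMatrices", function(obs) standardGeneric("binaryMatrices"))

#' Pairwise co-lying frequency matrix
#'
#' Aggregates the per-scan binary matrices: pairwise counts x_ab of scans in
#' which a pair lay together, per-animal counts n_a of scans spent lying,
#' and the total number of scans S.
#'
#' @param obs a \linkS4class{PenObservations}.
#' @return A \linkS4class{FrequencyMatrix}.
#' @export
setGeneric("frequencyMatrix", function(obs) standardGeneric("frequencyMatrix"))

#' Half-weight association index matrix
#'
#' HWI(a, b) = x_ab / ((n_a + n_b) / 2): the number of scans a pair spent
#' lying together relative to their average number of lying scans. Pairs
#' with n_a + n_b = 0 get 0, so an animal never observed lying has HWI 0
#' with every pen-mate.
#'
#' @param x a \linkS4class{FrequencyMatrix}, or a
#'   \linkS4class{PenObservations} (aggregated first).
#' @return An \linkS4class{HWIMatrix} with values in [0, 1], zero diagonal.
#' @export
setGeneric("hwi", function(x) standardGeneric("hwi"))

#' Pairwise count accessor
#' @param x a \linkS4class{FrequencyMatrix}.
#' @return Symmetric integer matrix of co-lying counts.
#' @export
setGeneric("pairCounts", function(x) standardGeneric("pairCounts"))

#' Per-animal lying count accessor
#' @param x a \linkS4class{FrequencyMatrix}.
#' @return Named integer vector, scans spent lying per animal.
#' @export
setGeneric("lyingCounts", function(x) standardGeneric("lyingCounts"))

#' Association weight accessor
#' @param x an \linkS4class{HWIMatrix}.
#' @return Symmetric numeric matrix of association weights.
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))
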