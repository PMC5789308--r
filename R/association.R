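#' @rdname frequencyMatrix
#' @export
setMethod("frequencyMatrix", "PenObservations", function(obs) {
  r <- obs@roster
  n <- length(r)
  x <- matrix(0L, n, n, dimnames = list(r, r))
  for (p in obs@colying) {
    if (nrow(p) == 0L) next
    i <- match(p[, 1L], r); j <- match(p[, 2L], r)
    x[cbind(i, j)] <- x[cbind(i, j)] + 1L
    x[cbind(j, i)] <- x[cbind(j, i)] + 1L
  }
  counts <- as.integer(rowSums(obs@lying))
  names(counts) <- r
  new("FrequencyMatrix", roster = r, pairCounts = x,
      lyingCounts = counts, totalScans = nScans(obs))
})

#' @rdname hwi
#' @export
setMethod("hwi", "FrequencyMatrix", function(x) {
  n_a <- x@lyingCounts
  denom <- outer(n_a, n_a, "+") / 2
  w <- ifelse(denom > 0, x@pairCounts / denom, 0)
  diag(w) <- 0
  dimnames(w) <- list(x@roster, x@roster)
  HWIMatrix(w, x@roster)
})

#' @rdname hwi
#' @export
setMethod("hwi", "PenObservations", function(x) hwi(frequencyMatrix(x)))
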