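#' @importFrom stats rbinom runif sd cor pnorm rnorm
#' @importFrom utils read.csv write.csv
NULL

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL means "use the current stream".
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derived from a master seed and a stage label,
# kept inside 32-bit integer range.
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# Upper-triangle (i < j) values of a square matrix, in column-major order.
upperTriVals <- function(m) m[upper.tri(m)]

# All unordered pairs over a roster, canonical order: (1,2),(1,3),...,(n-1,n).
rosterPairs <- function(roster) {
  n <- length(roster)
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(a = roster[idx[, 1L]], b = roster[idx[, 2L]],
             stringsAsFactors = FALSE)
}

checkSquareNamed <- function(m, what) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be a square matrix", call. = FALSE)
  invisible(m)
}

# ids appear unquoted in CSV output, so separators are forbidden in them
checkIds <- function(ids) {
  bad <- grepl('[,"\n\r]', ids)
  if (any(bad))
    stop("animal ids must not contain commas, quotes or newlines: ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  invisible(ids)
}
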