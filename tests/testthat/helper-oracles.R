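# Independent oracles and small fixture builders used across the suite.
# Each oracle recomputes a quantity by a different route than the package
# (naive loops, full enumeration, power iteration) so agreement is evidence,
# not tautology.

# Hand-built observation set: lying is an n x S 0/1 matrix (rows named by
# roster), pairs a list of per-scan 2-column matrices.
makeObs <- function(roster, lying, pairs = NULL, penId = "t1", week = 6L) {
  S <- ncol(lying)
  if (is.null(pairs)) pairs <- rep(list(matrix(character(0), ncol = 2)), S)
  PenObservations(penId, week, roster, lying, pairs)
}

# Brute-force HWI: per-pair scan-by-scan counting on the raw records,
# scalar arithmetic only.
bruteHWI <- function(obs) {
  r <- roster(obs)
  n <- length(r)
  S <- nScans(obs)
  budget <- lyingTimeBudget(obs)
  nLying <- structure(budget$lyingCount, names = budget$animal)
  w <- matrix(0, n, n, dimnames = list(r, r))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    x <- 0L
    for (s in seq_len(S)) {
      p <- obs@colying[[s]]
      if (nrow(p) == 0L) next
      hit <- (p[, 1] == r[i] & p[, 2] == r[j]) |
             (p[, 1] == r[j] & p[, 2] == r[i])
      x <- x + sum(hit)
    }
    denom <- (nLying[[r[i]]] + nLying[[r[j]]]) / 2
    w[i, j] <- w[j, i] <- if (denom > 0) x / denom else 0
  }
  w
}

# Power-iteration principal eigenvector, unit Euclidean norm.
powerIterationEV <- function(w, tol = 1e-13, maxit = 10000L) {
  v <- rep(1, nrow(w)) / sqrt(nrow(w))
  for (i in seq_len(maxit)) {
    v2 <- as.vector(w %*% v)
    v2 <- v2 / sqrt(sum(v2^2))
    if (max(abs(v2 - v)) < tol) return(v2)
    v <- v2
  }
  v
}

# All permutations of 1..n (n small), one per row.
allPerms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- allPerms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Exhaustive QAP p-value: fraction of all n! relabelings of m2 whose
# |r| >= |r_obs| (identity included).
exactQAP <- function(w1, w2) {
  v1 <- w1[upper.tri(w1)]
  rObs <- cor(v1, w2[upper.tri(w2)])
  perms <- allPerms(nrow(w1))
  rs <- apply(perms, 1, function(pm) {
    wp <- w2[pm, pm]
    cor(v1, wp[upper.tri(wp)])
  })
  list(r = rObs, p = mean(abs(rs) >= abs(rObs) - 1e-12))
}

# Random symmetric nonnegative association matrix with zero diagonal.
randomHWIMatrix <- function(n, seed) {
  set.seed(seed)
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- runif(choose(n, 2))
  w <- w + t(w)
  HWIMatrix(w, sprintf("A%02d", seq_len(n)))
}
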