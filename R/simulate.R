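#' Build a simulation configuration
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' pens of 8 animals scanned 36 times, per-animal lying probabilities drawn
#' uniformly in [0.60, 0.89] (the observed range of lying time budgets),
#' and a uniform pairwise co-lying preference of 0.20, which at the mean
#' lying probability of ~0.745 yields expected pairwise HWI near 0.15, the
#' study-wide mean.
#'
#' @param nAnimals group size (default 8).
#' @param nScans number of scans (default 36).
#' @param lieProb per-animal lying probability; a scalar is recycled;
#'   NULL draws one value per animal uniformly in [0.60, 0.89].
#' @param boutPersistence probability in [0, 1) that the lying state
#'   carries over to the next scan (default 0: independent scans).
#' @param preference symmetric n x n matrix of co-lying probabilities
#'   given both members lying; a scalar fills all pairs; default 0.20.
#' @param seed RNG seed stored in the config and used both for drawing
#'   default lying probabilities and for simulation.
#' @return A validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nAnimals = 8L, nScans = 36L, lieProb = NULL,
                             boutPersistence = 0, preference = 0.20,
                             seed = NULL) {
  n <- as.integer(nAnimals)
  if (is.null(lieProb)) {
    lieProb <- withSeed(if (is.null(seed)) NULL else deriveSeed(seed, "lieprob"),
                        runif(n, 0.60, 0.89))
  } else if (length(lieProb) == 1L) {
    lieProb <- rep(lieProb, n)
  }
  if (length(preference) == 1L) {
    preference <- matrix(preference, n, n)
    diag(preference) <- 0
  }
  new("SimulationConfig", nAnimals = n, nScans = as.integer(nScans),
      lieProb = as.numeric(lieProb), boutPersistence = boutPersistence,
      preference = preference,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Simulate one pen of scan-sampling observations
#'
#' Each animal's lying state follows a two-state chain: at each scan it
#' keeps its previous state with probability \code{boutPersistence} and
#' otherwise draws fresh from Bernoulli(\code{lieProb}), so the stationary
#' lying probability equals \code{lieProb} regardless of persistence. Given
#' both members of a pair lying at a scan, a co-lying event occurs
#' independently with probability \code{preference[a, b]}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param penId pen label for the output (default "sim1").
#' @param week week label (default 6).
#' @return A \linkS4class{PenObservations}; identical for identical
#'   (config, penId, week).
#' @export
simulatePen <- function(config, penId = "sim1", week = 6L) {
  stopifnot(is(config, "SimulationConfig"))
  n <- config@nAnimals
  S <- config@nScans
  p <- config@lieProb
  rho <- config@boutPersistence
  w <- config@preference
  roster <- sprintf("P%02d", seq_len(n))
  sd0 <- if (is.na(config@seed)) NULL else deriveSeed(config@seed, "simulate")
  withSeed(sd0, {
    lying <- matrix(FALSE, n, S)
    lying[, 1L] <- runif(n) < p
    if (S > 1L) for (s in 2L:S) {
      keep <- runif(n) < rho
      fresh <- runif(n) < p
      lying[, s] <- ifelse(keep, lying[, s - 1L], fresh)
    }
    ij <- which(upper.tri(diag(n)), arr.ind = TRUE)
    colying <- lapply(seq_len(S), function(s) {
      both <- lying[ij[, 1L], s] & lying[ij[, 2L], s]
      if (!any(both)) return(matrix(character(0), ncol = 2L))
      cand <- ij[both, , drop = FALSE]
      hit <- runif(nrow(cand)) < w[cand]
      if (!any(hit)) return(matrix(character(0), ncol = 2L))
      cbind(roster[cand[hit, 1L]], roster[cand[hit, 2L]])
    })
    rownames(lying) <- roster
    PenObservations(penId, week, roster, lying, colying)
  })
}

#' Recover pairwise co-lying preferences from observations
#'
#' Moment estimator of the generative preference: for each pair,
#' co-lying scans divided by scans in which both animals lay. Pairs with
#' no joint lying scans carry estimate 0 and are flagged in the
#' \code{"lowInformation"} attribute.
#'
#' @param obs a \linkS4class{PenObservations} in which every animal lies at
#'   least once.
#' @return Symmetric numeric matrix of estimates in [0, 1] with a logical
#'   \code{"lowInformation"} attribute marking pairs never jointly lying.
#' @export
recoverPreferences <- function(obs) {
  stopifnot(is(obs, "PenObservations"))
  if (any(rowSums(obs@lying) == 0L))
    stop("every animal must be observed lying at least once", call. = FALSE)
  freq <- frequencyMatrix(obs)
  L <- obs@lying * 1L
  joint <- L %*% t(L)          # scans where both members lie
  diag(joint) <- 0
  est <- ifelse(joint > 0, freq@pairCounts / joint, 0)
  diag(est) <- 0
  low <- joint == 0
  diag(low) <- FALSE
  dimnames(est) <- dimnames(low) <- list(obs@roster, obs@roster)
  attr(est, "lowInformation") <- low
  est
}

#' Preset simulation scenarios
#'
#' Parameter bundles calibrated to the contrast the pipeline is meant to
#' detect, with expected pen density (over many simulated pens) of about
#' 0.17 for \code{non_littermate_like}, about 0.12 for
#' \code{littermate_like}, and an exactly uniform preference for
#' \code{null_uniform} (expected pairwise HWI near 0.15, no structure).
#' The structured presets use a block preference: two high-preference
#' pairs (strong-tie candidates), a medium block, and a low block, so all
#' three tie classes are populated.
#'
#' @param name one of \code{"littermate_like"}, \code{"non_littermate_like"},
#'   \code{"null_uniform"}.
#' @param seed RNG seed stored in the config.
#' @param nScans number of scans (default 36).
#' @return A \linkS4class{SimulationConfig}; identical for identical
#'   (name, seed, nScans).
#' @export
makePreset <- function(name, seed = NULL, nScans = 36L) {
  n <- 8L
  block <- function(wStrong, nMed, wMed, wLow) {
    w <- matrix(wLow, n, n)
    ij <- which(upper.tri(w), arr.ind = TRUE)
    ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
    setPair <- function(i, j, v) { w[i, j] <<- v; w[j, i] <<- v }
    setPair(1L, 2L, wStrong); setPair(3L, 4L, wStrong)
    rest <- ij[!(ij[, 1L] == 1L & ij[, 2L] == 2L) &
               !(ij[, 1L] == 3L & ij[, 2L] == 4L), , drop = FALSE]
    for (k in seq_len(nMed)) setPair(rest[k, 1L], rest[k, 2L], wMed)
    diag(w) <- 0
    w
  }
  drawProbs <- function(lo, hi) {
    withSeed(if (is.null(seed)) NULL else deriveSeed(seed, "presetprob"),
             runif(n, lo, hi))
  }
  cfg <- switch(name,
    non_littermate_like = simulationConfig(
      n, nScans, lieProb = drawProbs(0.64, 0.72),
      preference = block(0.62, 14L, 0.33, 0.12), seed = seed),
    littermate_like = simulationConfig(
      n, nScans, lieProb = drawProbs(0.56, 0.64),
      preference = block(0.667, 6L, 0.367, 0.10), seed = seed),
    null_uniform = simulationConfig(
      n, nScans, lieProb = 0.65, preference = 0.23, seed = seed),
    stop("unknown preset: ", name, call. = FALSE))
  cfg
}
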