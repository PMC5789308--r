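#' Read scan-sampling observations from CSV
#'
#' Long-format scan CSV with header \code{pen,week,scan,animal,lying,partner}.
#' Posture rows (one per animal per scan) leave \code{partner} empty;
#' co-lying rows repeat the scan with \code{lying = 1} and \code{partner}
#' set, the lexicographically smaller id in the \code{animal} column, one
#' row per unordered pair. A file may hold several pens/weeks; the
#' (pen, week) pairs partition the records.
#'
#' Validation is strict: every animal must have a posture row at every scan
#' (absent rows are an error, not "not lying"), and every co-lying pair
#' must reference two animals recorded lying at that scan.
#'
#' @param path CSV file path.
#' @return A \linkS4class{PenObservations} when the file holds exactly one
#'   (pen, week) group; otherwise a named list of them
#'   (names \code{"<pen>:<week>"}).
#' @export
readScanCSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("pen", "week", "scan", "animal", "lying", "partner")
  if (!identical(names(df), need))
    stop("scan CSV must have header exactly: ", paste(need, collapse = ","),
         call. = FALSE)
  lineNo <- seq_len(nrow(df)) + 1L  # header is line 1
  badWeek <- is.na(suppressWarnings(as.integer(df$week)))
  badScan <- is.na(suppressWarnings(as.integer(df$scan)))
  badLying <- !(df$lying %in% c("0", "1"))
  bad <- badWeek | badScan | badLying | !nzchar(df$animal) | !nzchar(df$pen)
  if (any(bad))
    stop("malformed scan CSV row at line ", lineNo[which(bad)[1L]],
         call. = FALSE)
  df$week <- as.integer(df$week)
  df$scan <- as.integer(df$scan)
  df$lying <- as.integer(df$lying)

  keys <- paste(df$pen, df$week, sep = ":")
  out <- lapply(split(seq_len(nrow(df)), factor(keys, unique(keys))),
                function(i) parsePenGroup(df[i, , drop = FALSE], lineNo[i]))
  if (length(out) == 1L) out[[1L]] else out
}

parsePenGroup <- function(g, lines) {
  posture <- !nzchar(g$partner)
  pr <- g[posture, , drop = FALSE]
  cr <- g[!posture, , drop = FALSE]
  roster <- unique(pr$animal)
  S <- max(g$scan)
  if (!setequal(unique(g$scan), seq_len(S)))
    stop(sprintf("pen %s week %d: scan indices must be 1..S without gaps",
                 g$pen[1L], g$week[1L]), call. = FALSE)
  key <- paste(pr$animal, pr$scan, sep = ":")
  if (anyDuplicated(key))
    stop(sprintf("pen %s week %d: duplicate posture row at line %d",
                 g$pen[1L], g$week[1L],
                 lines[posture][anyDuplicated(key)]), call. = FALSE)
  if (length(key) != length(roster) * S)
    stop(sprintf(
      "pen %s week %d: incomplete posture records (%d rows, expected %d); absent rows are not imputed",
      g$pen[1L], g$week[1L], length(key), length(roster) * S), call. = FALSE)
  lying <- matrix(FALSE, length(roster), S,
                  dimnames = list(roster, as.character(seq_len(S))))
  lying[cbind(match(pr$animal, roster), pr$scan)] <- pr$lying == 1L

  colying <- rep(list(matrix(character(0), ncol = 2L)), S)
  if (nrow(cr) > 0L) {
    if (any(cr$lying != 1L))
      stop(sprintf("pen %s week %d: co-lying row with lying = 0 at line %d",
                   g$pen[1L], g$week[1L], lines[!posture][which(cr$lying != 1L)[1L]]),
           call. = FALSE)
    if (any(cr$animal >= cr$partner))
      stop(sprintf(
        "pen %s week %d: co-lying rows must list the smaller id first (line %d)",
        g$pen[1L], g$week[1L],
        lines[!posture][which(cr$animal >= cr$partner)[1L]]), call. = FALSE)
    unknown <- !(cr$partner %in% roster) | !(cr$animal %in% roster)
    if (any(unknown))
      stop(sprintf("pen %s week %d: co-lying row references unknown animal (line %d)",
                   g$pen[1L], g$week[1L], lines[!posture][which(unknown)[1L]]),
           call. = FALSE)
    for (s in unique(cr$scan)) {
      rows <- cr[cr$scan == s, , drop = FALSE]
      pairs <- cbind(rows$animal, rows$partner)
      lyingHere <- roster[lying[, s]]
      ok <- pairs[, 1L] %in% lyingHere & pairs[, 2L] %in% lyingHere
      if (!all(ok)) {
        i <- which(!ok)[1L]
        stop(sprintf(
          "pen %s week %d scan %d: co-lying pair (%s, %s) references an animal not recorded lying",
          g$pen[1L], g$week[1L], s, pairs[i, 1L], pairs[i, 2L]), call. = FALSE)
      }
      if (anyDuplicated(paste(pairs[, 1L], pairs[, 2L])))
        stop(sprintf("pen %s week %d scan %d: duplicate co-lying pair",
                     g$pen[1L], g$week[1L], s), call. = FALSE)
      colying[[s]] <- pairs
    }
  }
  PenObservations(g$pen[1L], g$week[1L], roster, lying, colying)
}

#' Write scan-sampling observations to CSV
#'
#' Canonical serialization of the format read by \code{\link{readScanCSV}}:
#' for each scan, posture rows in roster order followed by co-lying rows in
#' sorted pair order. Writing, reading and writing again is byte-identical.
#'
#' @param obs a \linkS4class{PenObservations}, or a list of them (written
#'   consecutively to one file).
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeScanCSV <- function(obs, path) {
  if (is(obs, "PenObservations")) obs <- list(obs)
  stopifnot(all(vapply(obs, is, TRUE, "PenObservations")))
  rows <- do.call(rbind, lapply(obs, scanRows))
  con <- file(path, open = "wt")
  on.exit(close(con))
  write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

scanRows <- function(o) {
  r <- o@roster
  S <- nScans(o)
  out <- vector("list", S)
  for (s in seq_len(S)) {
    posture <- data.frame(pen = o@penId, week = o@week, scan = s,
                          animal = r, lying = as.integer(o@lying[, s]),
                          partner = "", stringsAsFactors = FALSE)
    p <- o@colying[[s]]
    if (nrow(p) > 0L) {
      co <- data.frame(pen = o@penId, week = o@week, scan = s,
                       animal = p[, 1L], lying = 1L, partner = p[, 2L],
                       stringsAsFactors = FALSE)
      out[[s]] <- rbind(posture, co)
    } else out[[s]] <- posture
  }
  do.call(rbind, out)
}

#' Read a square association matrix from CSV
#'
#' First row and first column carry the animal ids; cells are numeric
#' weights. Values round-trip at full double precision.
#'
#' @param path CSV file path.
#' @return An \linkS4class{HWIMatrix}.
#' @export
readAssociationCSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (!identical(colnames(m), ids))
    stop("matrix CSV row and column ids disagree", call. = FALSE)
  dimnames(m) <- list(ids, ids)
  HWIMatrix(m, ids)
}

#' Write a square association matrix to CSV
#'
#' @param x an \linkS4class{HWIMatrix} (or square named numeric matrix).
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeAssociationCSV <- function(x, path) {
  m <- if (is(x, "HWIMatrix")) x@weights else x
  ids <- rownames(m)
  cells <- matrix(sprintf("%.17g", m), nrow(m))
  lines <- c(paste(c("id", ids), collapse = ","),
             vapply(seq_len(nrow(m)),
                    function(i) paste(c(ids[i], cells[i, ]), collapse = ","),
                    ""))
  writeLines(lines, path)
  invisible(path)
}
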