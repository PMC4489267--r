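## stats_reporting: empirical P-value calibration, CSV hit tables,
## sequence-logo frequency matrices.

#' Calibrate an empirical BC-score null distribution
#'
#' Draws `nSamples` pairs of length-`length` windows uniformly (with
#' replacement) from *distinct* structures of the bank and records their BC
#' scores. The resulting empirical distribution stands in for the score
#' distribution of unrelated conformations (whose BC scores concentrate
#' near 0) and backs [bcPValue()]. With `flankGap = L` the sampled windows
#' have length `8 + L` and are scored on their two 4-residue flanks,
#' matching the [loopSearch()] statistic.
#'
#' @param bank a [FragmentBank-class] with windows of the requested length
#'   in at least 2 distinct structures.
#' @param length window length, residues.
#' @param nSamples number of null pairs, default 10000.
#' @param seed RNG seed, default 1; identical inputs give identical models.
#' @param flankGap optional gap length for the loop-search flank statistic.
#' @return A [NullModel-class].
#' @examples
#' b <- syntheticBank(lapply(1:4, function(i)
#'   generatorSpec("random_walk", 30, seed = i)))
#' nm <- calibrateNull(b$bank, 9, nSamples = 500, seed = 7)
#' mean(nm@scores)   # near 0 for unrelated conformations
#' @export
calibrateNull <- function(bank, length, nSamples = 10000L, seed = 1L,
                          flankGap = NA_integer_) {
  length <- as.integer(length)
  winLen <- if (is.na(flankGap)) length else 8L + as.integer(flankGap)
  if (!is.na(flankGap) && length != 8L)
    .bcError("bc_usage_error", "flank statistic implies length = 8")
  wins <- .enumWindows(bank, winLen)
  flankIdx <- if (is.na(flankGap)) seq_len(winLen) else
    c(1:4, (as.integer(flankGap) + 5L):winLen)
  preps <- lapply(wins, function(w)
    .prepWindow(w$coords[flankIdx, , drop = FALSE]))
  ok <- !vapply(preps, is.null, logical(1))
  wins <- wins[ok]
  preps <- preps[ok]
  sids <- vapply(wins, `[[`, character(1), "sid")
  if (length(wins) < 2L || length(unique(sids)) < 2L)
    .bcError("bc_calibration_error", sprintf(
      "need windows of length %d in >= 2 distinct structures", winLen))
  scores <- .withSeed(seed, {
    i <- sample.int(length(wins), nSamples, replace = TRUE)
    j <- vapply(i, function(a) {
      cand <- which(sids != sids[a])
      cand[sample.int(length(cand), 1L)]
    }, integer(1))
    vapply(seq_len(nSamples), function(k) {
      A <- preps[[i[k]]]
      B <- preps[[j[k]]]
      bc <- .det3(crossprod(A$coords, B$coords)) / sqrt(A$det * B$det)
      max(-1, min(1, bc))
    }, numeric(1))
  })
  new("NullModel", scores = sort(scores), nSamples = as.integer(nSamples),
      fragmentLength = length, flankGap = as.integer(flankGap),
      seed = as.integer(seed),
      bankId = sprintf("%d structures / %d windows",
                       length(unique(sids)), length(wins)))
}

#' Empirical tail P-value of a BC score
#'
#' One-sided empirical P-value with add-one smoothing:
#' `(1 + #\{null >= bc\}) / (n + 1)` for the similarity (upper) tail, and
#' symmetrically `(1 + #\{null <= bc\}) / (n + 1)` for mirror hits (lower
#' tail). Always in `(0, 1]`; a score beyond every null sample gets
#' `1 / (n + 1)`.
#'
#' @param bc numeric vector of BC scores.
#' @param nullModel a [NullModel-class].
#' @param tail `"upper"` (fragment search) or `"lower"` (mirror search).
#' @return numeric vector of P-values.
#' @export
bcPValue <- function(bc, nullModel, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  s <- nullModel@scores
  n <- length(s)
  vapply(bc, function(b) {
    k <- if (tail == "upper") sum(s >= b) else sum(s <= b)
    (1 + k) / (n + 1)
  }, numeric(1))
}

.fmt4 <- function(x) ifelse(is.na(x), "NA", formatC(x, format = "f",
                                                    digits = 4))

#' Write a hit table to CSV
#'
#' One row per hit with columns `query`, `hit`, `q_start`, `q_end`,
#' `h_start`, `h_end`, `bc_score`, `rigidity`, `p_value`, `rmsd`,
#' `sequence`, `is_self`; numeric fields printed with 4 decimals. The table
#' is truncated to the best `params@maxHits` hits (the head of the total
#' order, 1000 by default). Null-model provenance is recorded as `#`
#' comment lines before the header.
#'
#' @param hits hit data.frame from [fragSearch()], [mirrorSearch()] or
#'   [loopSearch()].
#' @param path output file path.
#' @param params a [SearchParams-class] (supplies `maxHits`).
#' @param nullModel optional [NullModel-class] for the header comments;
#'   defaults to the hit table's `nullModel` attribute.
#' @return Invisibly, the number of rows written.
#' @export
writeHitsCsv <- function(hits, path, params = searchParams(),
                         nullModel = attr(hits, "nullModel")) {
  if (nrow(hits) > params@maxHits)
    hits <- hits[seq_len(params@maxHits), , drop = FALSE]
  con <- tryCatch(file(path, "w"),
                  error = function(e)
                    .bcError("bc_io_error",
                             paste("cannot write", path)))
  on.exit(close(con))
  if (!is.null(nullModel))
    writeLines(sprintf(
      "# null: %s; fragment_length=%d; n_samples=%d; seed=%d",
      nullModel@bankId, nullModel@fragmentLength, nullModel@nSamples,
      nullModel@seed), con)
  out <- hits
  for (col in c("bc_score", "rigidity", "p_value", "rmsd"))
    out[[col]] <- .fmt4(out[[col]])
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(nrow(hits))
}

#' Position frequency matrix of hit sequences
#'
#' Builds the per-position amino-acid frequency matrix underlying the
#' sequence logo that depicts sequence variability among hits: entry
#' `[j, a]` is the fraction of hit sequences carrying residue `a` at
#' position `j` (20 standard residues plus `X` for nonstandard). Every row
#' sums to 1 (or is all zero when there are no sequences).
#'
#' @param hits a hit data.frame (column `sequence` is used) or a character
#'   vector of equal-length sequences.
#' @return Numeric matrix, positions x 21 residues, with attribute
#'   `nSequences`.
#' @examples
#' logoMatrix(c("AC", "AG"))
#' @export
logoMatrix <- function(hits) {
  seqs <- if (is.data.frame(hits)) hits$sequence else hits
  if (length(seqs) == 0L) {
    out <- matrix(0, nrow = 0L, ncol = length(.AA21),
                  dimnames = list(NULL, .AA21))
    attr(out, "nSequences") <- 0L
    return(out)
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    .shapeError("hit sequences must all have the same length")
  n <- lens[1L]
  m <- matrix(0, nrow = n, ncol = length(.AA21),
              dimnames = list(seq_len(n), .AA21))
  letters <- do.call(rbind, strsplit(seqs, ""))
  for (j in seq_len(n)) {
    tab <- table(factor(letters[, j], levels = .AA21))
    m[j, ] <- as.numeric(tab) / length(seqs)
  }
  attr(m, "nSequences") <- length(seqs)
  m
}

#' Write a logo frequency matrix as TSV
#'
#' @param m matrix from [logoMatrix()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeLogoTsv <- function(m, path) {
  df <- data.frame(position = seq_len(nrow(m)), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
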