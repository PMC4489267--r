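## search: exhaustive fragment search, mirror search, gaped loop search
## with clash pruning, and specificity profiling.

## enumerate all length-n windows of a bank (stride 1, never crossing a
## segment boundary), with provenance
.enumWindows <- function(bank, n) {
  n <- as.integer(n)
  out <- list()
  for (si in seq_along(bank@segments)) {
    seg <- bank@segments[[si]]
    len <- nrow(seg@coords)
    if (len < n) next
    aa <- strsplit(seg@sequence, "")[[1L]]
    for (off in seq_len(len - n + 1L)) {
      idx <- off:(off + n - 1L)
      out[[length(out) + 1L]] <- list(
        segIdx = si, off = off, sid = seg@structureId, chain = seg@chainId,
        resno = seg@resno[idx], icode = seg@icode[idx],
        seq = paste(aa[idx], collapse = ""),
        coords = seg@coords[idx, , drop = FALSE])
    }
  }
  out
}

## centered coords + Gram determinant for a window; NULL when degenerate
.prepWindow <- function(m) {
  cc <- centerCoords(m)
  g <- .gramInfo(cc)
  if (g$degenerate) return(NULL)
  list(coords = cc, det = g$det)
}

.emptyHits <- function() {
  data.frame(query = character(), hit = character(),
             q_start = character(), q_end = character(),
             h_start = character(), h_end = character(),
             bc_score = numeric(), rigidity = numeric(),
             p_value = numeric(), rmsd = numeric(),
             sequence = character(), is_self = logical(),
             stringsAsFactors = FALSE)
}

## total order: bc (desc for frag, asc for mirror), rigidity asc, hit id,
## then window start (residue number, insertion code)
.orderHits <- function(df, resno, icode, mirror = FALSE) {
  ord <- order(if (mirror) df$bc_score else -df$bc_score,
               df$rigidity, df$hit, resno, icode, method = "radix")
  df[ord, , drop = FALSE]
}

.rigidityCentered <- function(X, Y) {
  n <- nrow(X)
  term <- sqrt(sum((X[n, ] - X[1, ])^2)) - sqrt(sum((Y[n, ] - Y[1, ])^2))
  max(max(abs(sqrt(rowSums(X^2)) - sqrt(rowSums(Y^2)))), abs(term))
}

.scanBank <- function(query, bank, params, mirror = FALSE,
                      nullModel = NULL, nullSamples = 10000L,
                      nullSeed = 1L) {
  qco <- .asCoords(query)
  n <- nrow(qco)
  if (n < 4L) .shapeError("query must have >= 4 residues")
  qc <- centerCoords(qco)
  qg <- .gramInfo(qc)
  if (qg$degenerate)
    .degeneracyError("degenerate query fragment")
  qIsFrag <- is(query, "CaFragment")
  qid <- if (qIsFrag) query@sourceId else "query"
  qlab <- if (qIsFrag) residueLabels(query) else as.character(seq_len(n))
  mq <- qc
  mq[, 3] <- -mq[, 3]          # mirrored query, for mirror-search RMSD
  wins <- .enumWindows(bank, n)
  if (length(wins) == 0L) {
    warning(sprintf("window length %d exceeds every bank segment", n))
    return(.emptyHits())
  }
  if (is.null(nullModel)) {
    nullModel <- tryCatch(
      calibrateNull(bank, n, nSamples = nullSamples, seed = nullSeed),
      bcmine_error = function(e) {
        .bcLog("warn", "P-value calibration unavailable: %s",
               conditionMessage(e))
        NULL
      })
  }
  nDegen <- 0L
  rows <- list()
  resno <- integer()
  icode <- character()
  for (w in wins) {
    pw <- .prepWindow(w$coords)
    if (is.null(pw)) {
      nDegen <- nDegen + 1L
      next
    }
    bc <- .det3(crossprod(qc, pw$coords)) / sqrt(qg$det * pw$det)
    bc <- max(-1, min(1, bc))
    pass <- if (mirror) bc <= -params@bcCutoff else bc >= params@bcCutoff
    if (!pass) next
    rg <- .rigidityCentered(qc, pw$coords)
    if (rg > params@rigidityCutoff) next
    ref <- if (mirror) mq else qc
    rmsd <- kabschSuperpose(pw$coords, ref)$rmsd
    pv <- if (is.null(nullModel)) NA_real_ else
      bcPValue(bc, nullModel, tail = if (mirror) "lower" else "upper")
    isSelf <- qIsFrag && w$sid == query@sourceId &&
      w$chain == query@chainId &&
      identical(w$resno, query@resno) && identical(w$icode, query@icode)
    rows[[length(rows) + 1L]] <- data.frame(
      query = qid, hit = w$sid,
      q_start = qlab[1L], q_end = qlab[n],
      h_start = .labels(w$resno[1L], w$icode[1L]),
      h_end = .labels(w$resno[n], w$icode[n]),
      bc_score = bc, rigidity = rg, p_value = pv, rmsd = rmsd,
      sequence = w$seq, is_self = isSelf, stringsAsFactors = FALSE)
    resno <- c(resno, w$resno[1L])
    icode <- c(icode, w$icode[1L])
  }
  .bcLog("info", "%s: %d windows scanned, %d degenerate skipped, %d hits",
         if (mirror) "mirrorSearch" else "fragSearch",
         length(wins), nDegen, length(rows))
  if (length(rows) == 0L) {
    out <- .emptyHits()
  } else {
    out <- .orderHits(do.call(rbind, rows), resno, icode, mirror = mirror)
    rownames(out) <- NULL
  }
  attr(out, "nWindows") <- length(wins)
  attr(out, "nDegenerate") <- nDegen
  attr(out, "nullModel") <- nullModel
  out
}

#' Exhaustive fragment search
#'
#' Scores the query against every window of its length in every segment of
#' the bank. A window is a hit iff its BC score is at least `bcCutoff` and
#' its rigidity score at most `rigidityCutoff`. Hits are returned in a
#' deterministic total order: BC score descending, then rigidity ascending,
#' then hit id, then window start. Each hit carries the optimal-superposition
#' RMSD to the query and an empirical P-value; a window identical in
#' provenance to the query fragment is flagged `is_self` (kept, not
#' removed). Degenerate bank windows are skipped and counted (attribute
#' `nDegenerate`); a degenerate query is an error.
#'
#' @param query a [CaFragment-class] (>= 4 residues, non-degenerate).
#' @param bank a [FragmentBank-class].
#' @param params a [SearchParams-class]; defaults are the published ones
#'   (0.95 / 1.0).
#' @param nullModel optional pre-calibrated [NullModel-class]; when `NULL`
#'   one is calibrated from the bank (seed `nullSeed`). P-values are `NA`
#'   when the bank cannot support calibration.
#' @param nullSamples,nullSeed calibration size and seed when `nullModel`
#'   is `NULL`.
#' @return data.frame of hits with columns `query`, `hit`, `q_start`,
#'   `q_end`, `h_start`, `h_end`, `bc_score`, `rigidity`, `p_value`,
#'   `rmsd`, `sequence`, `is_self`; attributes `nWindows`, `nDegenerate`
#'   and `nullModel`.
#' @examples
#' q <- randomWalkFragment(9, seed = 11)
#' sb <- syntheticBank(lapply(1:3, function(i)
#'   generatorSpec("random_walk", 25, seed = i)), planted = list(
#'   fragment = q, structure = 2, offset = 6, seed = 99))
#' hits <- fragSearch(q, sb$bank)
#' hits[1, c("hit", "h_start", "bc_score", "rigidity")]
#' @seealso [mirrorSearch()], [loopSearch()], [specificitySearch()]
#' @export
fragSearch <- function(query, bank, params = searchParams(),
                       nullModel = NULL, nullSamples = 10000L,
                       nullSeed = 1L)
  .scanBank(query, bank, params, mirror = FALSE, nullModel = nullModel,
            nullSamples = nullSamples, nullSeed = nullSeed)

#' Exhaustive mirror-conformation search
#'
#' Finds windows anti-similar to the query: hits satisfy
#' `bc <= -bcCutoff` and `rigidity <= rigidityCutoff` (the rigidity score is
#' reflection-invariant and is computed directly). Hits are ordered by BC
#' score ascending (most anti-similar first); the reported RMSD is between
#' the window and the mirrored query, and P-values use the lower tail of
#' the null. Left-handed helices, for example, are mirror hits of a
#' right-handed helical query.
#'
#' @inheritParams fragSearch
#' @return data.frame of hits; see [fragSearch()].
#' @export
mirrorSearch <- function(query, bank, params = searchParams(),
                         nullModel = NULL, nullSamples = 10000L,
                         nullSeed = 1L)
  .scanBank(query, bank, params, mirror = TRUE, nullModel = nullModel,
            nullSamples = nullSamples, nullSeed = nullSeed)

#' Steric clash check for a grafted loop candidate
#'
#' A candidate fails if any of its loop Calpha lies closer than
#' `clashCutoff` (3 Angstrom by default) to a template Calpha at least
#' `minSeqSep` (default 3) positions away along the repaired chain.
#' Template residues within `minSeqSep` of the loop (the flanks and their
#' immediate neighbours) are exempt; residues on other chains are always
#' checked.
#'
#' @param loopCoords L x 3 matrix of candidate loop Calpha, already in the
#'   template frame.
#' @param loopQuery the [LoopQuery-class] supplying the template.
#' @param params a [SearchParams-class].
#' @return `TRUE` (pass) or `FALSE` (clash).
#' @export
clashCheck <- function(loopCoords, loopQuery, params = searchParams()) {
  loopPos <- loopQuery@gapStart + seq_len(nrow(loopCoords)) - 1L
  tc <- loopQuery@templateCoords
  sep <- outer(loopQuery@templatePos, loopPos,
               function(a, b) abs(a - b))        # NA for other chains
  sep[is.na(sep)] <- .Machine$integer.max
  for (j in seq_len(nrow(loopCoords))) {
    check <- sep[, j] >= params@minSeqSep
    if (!any(check)) next
    d2 <- (tc[check, 1] - loopCoords[j, 1])^2 +
          (tc[check, 2] - loopCoords[j, 2])^2 +
          (tc[check, 3] - loopCoords[j, 3])^2
    if (any(d2 < params@clashCutoff^2)) return(FALSE)
  }
  TRUE
}

#' Graft a hit window's loop into the template frame
#'
#' Kabsch-superposes the hit's 8 flank Calpha (window positions 1-4 and
#' L+5..L+8) onto the query's 8 flank Calpha in the template frame and
#' applies the same rigid transform to the hit's L loop Calpha.
#'
#' @param hitWindow a [CaFragment-class] or (8+L) x 3 matrix: the full
#'   bank window, flanks plus loop.
#' @param loopQuery the [LoopQuery-class].
#' @return L x 3 matrix of grafted loop coordinates with attribute
#'   `flankRmsd` (the superposition RMSD over the 8 flank atoms).
#' @export
graftLoop <- function(hitWindow, loopQuery) {
  w <- .asCoords(hitWindow)
  L <- loopQuery@gapLength
  if (nrow(w) != 8L + L)
    .shapeError(sprintf("window must have %d residues (4 + %d + 4)",
                        8L + L, L))
  qf <- rbind(coords(loopQuery@nFlank), coords(loopQuery@cFlank))
  flankIdx <- c(1:4, (L + 5L):(L + 8L))
  sup <- kabschSuperpose(w[flankIdx, , drop = FALSE], qf)
  loop <- w[5:(L + 4L), , drop = FALSE]
  out <- loop %*% sup$rotation +
    matrix(sup$translation, nrow = L, ncol = 3L, byrow = TRUE)
  attr(out, "flankRmsd") <- sup$rmsd
  out
}

#' Knowledge-based loop candidate search
#'
#' For a sequence gap of length L anchored by four-residue flanks, every
#' bank window of length 4 + L + 4 is scored: the window's two flanks
#' (jointly centered, preserving inter-flank geometry) against the query's
#' jointly centered 8 flank Calpha, by BC and rigidity. Passing windows are
#' grafted into the template frame by Kabsch superposition of the 8 flank
#' atoms and discarded if the grafted loop clashes with the template
#' ([clashCheck()]). The search is purely geometric; hit sequences are not
#' constrained. Reported RMSD and P-value are flank-based.
#'
#' @param loopQuery a [LoopQuery-class] (see [makeLoopQuery()]).
#' @param bank a [FragmentBank-class].
#' @inheritParams fragSearch
#' @return data.frame of hits as in [fragSearch()] (`rmsd` = flank RMSD
#'   after grafting); attribute `grafts` is a list of grafted L x 3 loop
#'   coordinate matrices, parallel to the rows; attributes `nWindows`,
#'   `nDegenerate`, `nClash`, `nullModel`.
#' @export
loopSearch <- function(loopQuery, bank, params = searchParams(),
                       nullModel = NULL, nullSamples = 10000L,
                       nullSeed = 1L) {
  L <- loopQuery@gapLength
  n <- 8L + L
  qf <- rbind(coords(loopQuery@nFlank), coords(loopQuery@cFlank))
  qc <- centerCoords(qf)
  qg <- .gramInfo(qc)
  if (qg$degenerate)
    .degeneracyError("degenerate flanks: joint 8-point set near-coplanar")
  flankIdx <- c(1:4, (L + 5L):n)
  wins <- .enumWindows(bank, n)
  if (length(wins) == 0L) {
    warning(sprintf("window length %d exceeds every bank segment", n))
    out <- .emptyHits()
    attr(out, "grafts") <- list()
    return(out)
  }
  if (is.null(nullModel)) {
    nullModel <- tryCatch(
      calibrateNull(bank, 8L, nSamples = nullSamples, seed = nullSeed,
                    flankGap = L),
      bcmine_error = function(e) {
        .bcLog("warn", "P-value calibration unavailable: %s",
               conditionMessage(e))
        NULL
      })
  }
  qlab <- c(residueLabels(loopQuery@nFlank), residueLabels(loopQuery@cFlank))
  nDegen <- 0L
  nClash <- 0L
  rows <- list()
  grafts <- list()
  resno <- integer()
  icode <- character()
  for (w in wins) {
    pw <- .prepWindow(w$coords[flankIdx, , drop = FALSE])
    if (is.null(pw)) {
      nDegen <- nDegen + 1L
      next
    }
    bc <- .det3(crossprod(qc, pw$coords)) / sqrt(qg$det * pw$det)
    bc <- max(-1, min(1, bc))
    if (bc < params@bcCutoff) next
    rg <- .rigidityCentered(qc, pw$coords)
    if (rg > params@rigidityCutoff) next
    loop <- graftLoop(w$coords, loopQuery)
    if (!clashCheck(loop, loopQuery, params)) {
      nClash <- nClash + 1L
      next
    }
    pv <- if (is.null(nullModel)) NA_real_ else
      bcPValue(bc, nullModel, tail = "upper")
    isSelf <- w$sid == loopQuery@queryId
    rows[[length(rows) + 1L]] <- data.frame(
      query = loopQuery@queryId, hit = w$sid,
      q_start = qlab[1L], q_end = qlab[8L],
      h_start = .labels(w$resno[1L], w$icode[1L]),
      h_end = .labels(w$resno[n], w$icode[n]),
      bc_score = bc, rigidity = rg, p_value = pv,
      rmsd = attr(loop, "flankRmsd"),
      sequence = w$seq, is_self = isSelf, stringsAsFactors = FALSE)
    grafts[[length(grafts) + 1L]] <- loop
    resno <- c(resno, w$resno[1L])
    icode <- c(icode, w$icode[1L])
  }
  .bcLog("info",
         "loopSearch: %d windows, %d degenerate, %d clash-pruned, %d hits",
         length(wins), nDegen, nClash, length(rows))
  if (length(rows) == 0L) {
    out <- .emptyHits()
    grafts <- list()
  } else {
    df <- do.call(rbind, rows)
    ord <- order(-df$bc_score, df$rigidity, df$hit, resno, icode,
                 method = "radix")
    out <- df[ord, , drop = FALSE]
    rownames(out) <- NULL
    grafts <- grafts[ord]
  }
  attr(out, "grafts") <- grafts
  attr(out, "nWindows") <- length(wins)
  attr(out, "nDegenerate") <- nDegen
  attr(out, "nClash") <- nClash
  attr(out, "nullModel") <- nullModel
  out
}

#' Conformational specificity profiling of a whole structure
#'
#' Slides a window of `windowSize` residues over the query structure and,
#' for each window, counts the bank proteins containing at least one
#' similar window (same cutoffs as [fragSearch()]; one protein counts once
#' however many of its windows match). The specificity score is
#' `sp = 1 - N_hits / N_total`: near 1 marks conformations rarely found in
#' the bank. The bank can be restricted by classification-code prefixes,
#' e.g. include class `"b"` while excluding fold `"b.47"`. Degenerate query
#' windows get `sp = NA`. The per-residue score is the maximum `sp` over
#' the windows covering the residue.
#'
#' @param query a [CaStructure-class].
#' @param bank a [FragmentBank-class].
#' @param params a [SearchParams-class] (`windowSize` sets the fragment
#'   size, default 9).
#' @param include,exclude optional classification-code prefixes
#'   (see [filterBankBySccs()]).
#' @return A [SpecificityProfile-class].
#' @export
specificitySearch <- function(query, bank, params = searchParams(),
                              include = NULL, exclude = NULL) {
  if (!is.null(include) || !is.null(exclude))
    bank <- filterBankBySccs(bank, include = include, exclude = exclude)
  ids <- bankStructureIds(bank)
  nTotal <- length(ids)
  if (nTotal == 0L)
    .bcError("bc_empty_error", "empty filtered bank")
  w <- params@windowSize
  wins <- .enumWindows(bank, w)
  preps <- lapply(wins, function(x) .prepWindow(x$coords))
  sids <- vapply(wins, `[[`, character(1), "sid")
  segs <- contiguousSegments(query)
  rows <- list()
  for (seg in segs) {
    len <- nrow(seg@coords)
    if (len < w) next
    for (off in seq_len(len - w + 1L)) {
      idx <- off:(off + w - 1L)
      qc <- centerCoords(seg@coords[idx, , drop = FALSE])
      qg <- .gramInfo(qc)
      if (qg$degenerate) {
        nh <- NA_integer_
        sp <- NA_real_
      } else {
        hitSid <- character()
        for (k in seq_along(wins)) {
          if (sids[k] %in% hitSid) next     # one protein, one count
          pw <- preps[[k]]
          if (is.null(pw)) next
          bc <- .det3(crossprod(qc, pw$coords)) / sqrt(qg$det * pw$det)
          if (bc < params@bcCutoff) next
          if (.rigidityCentered(qc, pw$coords) > params@rigidityCutoff) next
          hitSid <- c(hitSid, sids[k])
        }
        nh <- length(hitSid)
        sp <- 1 - nh / nTotal
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chain = seg@chainId, resno = seg@resno[off], icode = seg@icode[off],
        n_hits = nh, sp = sp, stringsAsFactors = FALSE)
    }
  }
  winScores <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain = character(), resno = integer(), icode = character(),
               n_hits = integer(), sp = numeric(), stringsAsFactors = FALSE)
  ## residue score: max sp over covering windows
  resRows <- list()
  for (seg in segs) {
    len <- nrow(seg@coords)
    for (i in seq_len(len)) {
      starts <- max(1L, i - w + 1L):i
      starts <- starts[starts <= len - w + 1L]
      if (length(starts) == 0L) next
      vals <- winScores$sp[match(paste(seg@chainId, seg@resno[starts],
                                       seg@icode[starts]),
                                 paste(winScores$chain, winScores$resno,
                                       winScores$icode))]
      sp <- if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
      resRows[[length(resRows) + 1L]] <- data.frame(
        chain = seg@chainId, resno = seg@resno[i], icode = seg@icode[i],
        sp = sp, stringsAsFactors = FALSE)
    }
  }
  resScores <- if (length(resRows)) do.call(rbind, resRows) else
    data.frame(chain = character(), resno = integer(), icode = character(),
               sp = numeric(), stringsAsFactors = FALSE)
  new("SpecificityProfile", windowScores = winScores,
      residueScores = resScores, nTotal = nTotal, windowSize = w)
}
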