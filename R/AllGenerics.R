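#' Extract Calpha coordinates
#'
#' @param x a [CaFragment-class], [CaSegment-class] or [CaStructure-class].
#' @return Numeric N x 3 matrix of coordinates (Angstrom).
#' @examples
#' coords(idealHelix(6))
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "CaFragment", function(x) x@coords)

#' @rdname coords
#' @export
setMethod("coords", "CaSegment", function(x) x@coords)

#' @rdname coords
#' @export
setMethod("coords", "CaStructure",
          function(x) unname(as.matrix(x@atoms[, c("x", "y", "z")])))

#' One-letter amino-acid sequence of an object
#'
#' @param x a [CaFragment-class] or [CaSegment-class].
#' @return character(1), one-letter codes, `"X"` for nonstandard residues.
#' @examples
#' fragmentSequence(idealHelix(6))
#' @export
setGeneric("fragmentSequence", function(x) standardGeneric("fragmentSequence"))

#' @rdname fragmentSequence
#' @export
setMethod("fragmentSequence", "CaFragment", function(x) x@sequence)

#' @rdname fragmentSequence
#' @export
setMethod("fragmentSequence", "CaSegment", function(x) x@sequence)

#' Number of Calpha positions in an object
#'
#' @param x a [CaFragment-class], [CaSegment-class], [CaStructure-class] or
#'   [FragmentBank-class] (for a bank, the number of segments).
#' @return integer(1).
#' @export
setMethod("length", "CaFragment", function(x) nrow(x@coords))

#' @rdname length-CaFragment-method
#' @export
setMethod("length", "CaSegment", function(x) nrow(x@coords))

#' Residue labels (number + insertion code) of an object
#'
#' @param x a [CaFragment-class] or [CaSegment-class].
#' @return character vector like `"15"` or `"52A"`.
#' @export
setGeneric("residueLabels", function(x) standardGeneric("residueLabels"))

.labels <- function(resno, icode) paste0(resno, ifelse(icode == "", "", icode))

#' @rdname residueLabels
#' @export
setMethod("residueLabels", "CaFragment", function(x) .labels(x@resno, x@icode))

#' @rdname residueLabels
#' @export
setMethod("residueLabels", "CaSegment", function(x) .labels(x@resno, x@icode))

setMethod("show", "CaFragment", function(object) {
  n <- nrow(object@coords)
  lab <- residueLabels(object)
  cat(sprintf("CaFragment: %d residues, %s chain %s [%s..%s]\n  %s\n",
              n, object@sourceId, object@chainId,
              if (n) lab[1] else "-", if (n) lab[n] else "-",
              object@sequence))
})

setMethod("show", "CaStructure", function(object) {
  ch <- table(object@atoms$chain)
  cat(sprintf("CaStructure %s: %d residues in %d chain(s) (%s)\n",
              object@structureId, nrow(object@atoms), length(ch),
              paste(names(ch), ch, sep = ":", collapse = ", ")))
})

setMethod("show", "CaSegment", function(object) {
  lab <- .labels(object@resno, object@icode)
  cat(sprintf("CaSegment: %s chain %s residues %s..%s (%d)\n",
              object@structureId, object@chainId, lab[1],
              lab[length(lab)], length(lab)))
})

setMethod("show", "FragmentBank", function(object) {
  ns <- length(unique(vapply(object@segments, slot, character(1),
                             "structureId")))
  cat(sprintf(
    "FragmentBank: %d segments from %d structure(s); %d with sccs codes\n",
    length(object@segments), ns, length(object@sccs)))
})

setMethod("show", "SearchParams", function(object) {
  cat(sprintf(paste0("SearchParams: bc >= %g, rigidity <= %g A, ",
                     "maxHits %d, clash %g A (sep >= %d), window %d\n"),
              object@bcCutoff, object@rigidityCutoff, object@maxHits,
              object@clashCutoff, object@minSeqSep, object@windowSize))
})

setMethod("show", "NullModel", function(object) {
  cat(sprintf(
    "NullModel: %d BC scores, window length %d%s, seed %d (%s)\n",
    object@nSamples, object@fragmentLength,
    if (is.na(object@flankGap)) "" else
      sprintf(" (flank statistic, gap %d)", object@flankGap),
    object@seed, object@bankId))
})

setMethod("show", "LoopQuery", function(object) {
  cat(sprintf(
    "LoopQuery %s chain %s: gap of %d residue(s) at position %d, flanks %s / %s\n",
    object@queryId, object@chainId, object@gapLength, object@gapStart,
    paste(residueLabels(object@nFlank), collapse = ","),
    paste(residueLabels(object@cFlank), collapse = ",")))
})

setMethod("show", "SpecificityProfile", function(object) {
  sp <- object@windowScores$sp
  cat(sprintf(paste0("SpecificityProfile: %d windows (size %d) over a bank ",
                     "of %d proteins; sp range [%.3f, %.3f], %d undefined\n"),
              nrow(object@windowScores), object@windowSize, object@nTotal,
              suppressWarnings(min(sp, na.rm = TRUE)),
              suppressWarnings(max(sp, na.rm = TRUE)), sum(is.na(sp))))
})
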