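#' @import methods
NULL

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.AA21 <- c(.AA20, "X")

.checkCoords <- function(m) {
  if (!is.matrix(m) || !is.numeric(m) || ncol(m) != 3L)
    return("coords must be a numeric N x 3 matrix")
  if (any(!is.finite(m)))
    return("coords must be finite")
  NULL
}

#' CaFragment: a contiguous run of Calpha positions
#'
#' A `CaFragment` holds the ordered Calpha coordinates of one contiguous
#' stretch of a protein chain together with its provenance: the source
#' structure identifier, chain, residue labels and one-letter sequence
#' (`"X"` for nonstandard residues).
#'
#' @slot coords numeric N x 3 matrix of Calpha coordinates (Angstrom).
#' @slot sourceId character(1), identifier of the source structure.
#' @slot chainId character(1), chain identifier.
#' @slot resno integer vector of residue numbers (length N).
#' @slot icode character vector of insertion codes (length N, `""` if none).
#' @slot sequence character(1) of N one-letter residue codes.
#'
#' @examples
#' frag <- idealHelix(8)
#' frag
#' coords(frag)[1:2, ]
#' @seealso [bcScore()], [rigidityScore()], [idealHelix()]
#' @export
setClass("CaFragment",
  slots = c(coords = "matrix", sourceId = "character", chainId = "character",
            resno = "integer", icode = "character", sequence = "character"),
  prototype = prototype(sourceId = "frag", chainId = "A", sequence = ""))

setValidity("CaFragment", function(object) {
  msg <- .checkCoords(object@coords)
  if (!is.null(msg)) return(msg)
  n <- nrow(object@coords)
  if (nchar(object@sequence) != n)
    return("sequence length must equal the number of Calpha positions")
  if (length(object@resno) != n || length(object@icode) != n)
    return("resno and icode must have one entry per Calpha")
  TRUE
})

#' Constructor for [CaFragment-class] objects
#'
#' @param coords numeric N x 3 matrix of Calpha coordinates (Angstrom).
#' @param sourceId,chainId provenance identifiers.
#' @param resno residue numbers; defaults to `1:N`.
#' @param icode insertion codes; defaults to `""`.
#' @param sequence one-letter sequence string; defaults to poly-alanine.
#' @return A [CaFragment-class] object.
#' @examples
#' CaFragment(matrix(rnorm(15), ncol = 3), sourceId = "toy")
#' @export
CaFragment <- function(coords, sourceId = "frag", chainId = "A",
                       resno = seq_len(nrow(coords)),
                       icode = rep("", nrow(coords)),
                       sequence = strrep("A", nrow(coords))) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  new("CaFragment", coords = coords, sourceId = sourceId, chainId = chainId,
      resno = as.integer(resno), icode = as.character(icode),
      sequence = sequence)
}

#' CaStructure: Calpha trace of a parsed structure
#'
#' One row per kept residue (first model, altlocs resolved, one Calpha per
#' residue), in file order.
#'
#' @slot structureId character(1).
#' @slot atoms data.frame with columns `chain`, `resno`, `icode`, `aa`
#'   (one-letter), `x`, `y`, `z`.
#' @seealso [readCaStructure()], [contiguousSegments()]
#' @export
setClass("CaStructure",
  slots = c(structureId = "character", atoms = "data.frame"))

setValidity("CaStructure", function(object) {
  need <- c("chain", "resno", "icode", "aa", "x", "y", "z")
  if (!all(need %in% names(object@atoms)))
    return(paste("atoms must have columns", paste(need, collapse = ", ")))
  key <- paste(object@atoms$chain, object@atoms$resno, object@atoms$icode)
  if (anyDuplicated(key))
    return("residue labels must be unique within a chain")
  TRUE
})

#' CaSegment: a maximal contiguous chain segment
#'
#' Windows for fragment search are enumerated inside segments only, so no
#' window ever spans a chain break. Consecutive Calpha-Calpha distances
#' within a segment lie in the virtual-bond gate `[2.5, 4.5]` Angstrom.
#'
#' @slot structureId,chainId provenance.
#' @slot resno,icode residue labels.
#' @slot sequence one-letter sequence string.
#' @slot coords numeric N x 3 matrix.
#' @export
setClass("CaSegment",
  slots = c(structureId = "character", chainId = "character",
            resno = "integer", icode = "character",
            sequence = "character", coords = "matrix"))

#' FragmentBank: a searchable collection of chain segments
#'
#' The bank stores every contiguous segment of every readable structure in a
#' collection, with optional SCOP-style classification codes
#' (`class.fold.superfamily.family`) attached from a manifest. All length-N
#' windows over the segments constitute the search space.
#'
#' @slot segments list of [CaSegment-class] objects.
#' @slot sccs named character vector mapping structureId to classification
#'   code (may be empty).
#' @seealso [buildFragmentBank()], [fragSearch()]
#' @export
setClass("FragmentBank",
  slots = c(segments = "list", sccs = "character"))

setValidity("FragmentBank", function(object) {
  if (!all(vapply(object@segments, is, logical(1), "CaSegment")))
    return("segments must all be CaSegment objects")
  TRUE
})

#' SearchParams: cutoffs and sizes for the mining services
#'
#' Defaults follow the published service: BC-score cutoff 0.95, rigidity
#' cutoff 1.0 Angstrom, reports truncated to the best 1000 hits, steric
#' clash cutoff 3.0 Angstrom applied at sequence separation >= 3, and a
#' 9-residue window for specificity profiling.
#'
#' @slot bcCutoff numeric(1) in (0, 1].
#' @slot rigidityCutoff numeric(1) >= 0, Angstrom.
#' @slot maxHits integer(1) >= 1.
#' @slot clashCutoff numeric(1), Angstrom.
#' @slot minSeqSep integer(1), residues.
#' @slot windowSize integer(1), residues (specificity profiling).
#' @export
setClass("SearchParams",
  slots = c(bcCutoff = "numeric", rigidityCutoff = "numeric",
            maxHits = "integer", clashCutoff = "numeric",
            minSeqSep = "integer", windowSize = "integer"))

setValidity("SearchParams", function(object) {
  if (object@bcCutoff <= 0 || object@bcCutoff > 1)
    return("bcCutoff must lie in (0, 1]")
  if (object@rigidityCutoff < 0) return("rigidityCutoff must be >= 0")
  if (object@maxHits < 1L) return("maxHits must be >= 1")
  if (object@clashCutoff < 0) return("clashCutoff must be >= 0")
  if (object@windowSize < 4L) return("windowSize must be >= 4")
  TRUE
})

#' Constructor for [SearchParams-class]
#'
#' @param bcCutoff BC-score cutoff, default 0.95.
#' @param rigidityCutoff rigidity cutoff in Angstrom, default 1.0.
#' @param maxHits report truncation, default 1000.
#' @param clashCutoff loop clash distance cutoff in Angstrom, default 3.0.
#' @param minSeqSep minimum sequence separation for the clash rule, default 3.
#' @param windowSize specificity window size, default 9.
#' @return A [SearchParams-class] object.
#' @examples
#' searchParams()
#' searchParams(bcCutoff = 0.99)
#' @export
searchParams <- function(bcCutoff = 0.95, rigidityCutoff = 1.0,
                         maxHits = 1000L, clashCutoff = 3.0,
                         minSeqSep = 3L, windowSize = 9L) {
  new("SearchParams", bcCutoff = bcCutoff, rigidityCutoff = rigidityCutoff,
      maxHits = as.integer(maxHits), clashCutoff = clashCutoff,
      minSeqSep = as.integer(minSeqSep), windowSize = as.integer(windowSize))
}

#' LoopQuery: flank anchors for gaped-structure loop search
#'
#' Holds the two four-residue flank fragments of a sequence gap, in the
#' template's coordinate frame, plus everything the clash filter needs: all
#' template Calpha with their positions along the repaired (full-sequence)
#' chain.
#'
#' @slot queryId character(1).
#' @slot chainId chain carrying the gap.
#' @slot nFlank,cFlank [CaFragment-class] of exactly 4 residues each,
#'   immediately preceding / following the gap.
#' @slot gapStart integer(1), full-sequence position of the first missing
#'   residue.
#' @slot gapLength integer(1) >= 1.
#' @slot templateCoords numeric matrix of all template Calpha.
#' @slot templateChain,templatePos chain and full-sequence position of each
#'   template Calpha (position `NA` for chains other than `chainId`).
#' @slot fullSequence character(1), the complete chain sequence.
#' @seealso [makeLoopQuery()], [loopSearch()]
#' @export
setClass("LoopQuery",
  slots = c(queryId = "character", chainId = "character",
            nFlank = "CaFragment", cFlank = "CaFragment",
            gapStart = "integer", gapLength = "integer",
            templateCoords = "matrix", templateChain = "character",
            templatePos = "integer", fullSequence = "character"))

setValidity("LoopQuery", function(object) {
  if (nrow(object@nFlank@coords) != 4L || nrow(object@cFlank@coords) != 4L)
    return("flanks must be exactly 4 residues each")
  if (object@gapLength < 1L) return("gapLength must be >= 1")
  if (nrow(object@templateCoords) != length(object@templatePos))
    return("templatePos must match templateCoords")
  TRUE
})

#' NullModel: empirical BC-score null distribution
#'
#' BC scores of randomly paired, unrelated bank windows, used to convert a
#' hit's BC score into an empirical tail P-value with add-one smoothing.
#'
#' @slot scores sorted numeric vector of null BC scores, in `[-1, 1]`.
#' @slot nSamples integer(1).
#' @slot fragmentLength integer(1), window length used.
#' @slot flankGap integer(1), `NA` for plain windows; when set, the null is
#'   over the 8 flank Calpha of windows of length `8 + flankGap` (loop
#'   search statistic).
#' @slot seed integer(1) RNG seed used for calibration.
#' @slot bankId character(1), free-text description of the null bank.
#' @seealso [calibrateNull()], [bcPValue()]
#' @export
setClass("NullModel",
  slots = c(scores = "numeric", nSamples = "integer",
            fragmentLength = "integer", flankGap = "integer",
            seed = "integer", bankId = "character"))

setValidity("NullModel", function(object) {
  if (is.unsorted(object@scores)) return("scores must be sorted ascending")
  if (length(object@scores) &&
      (min(object@scores) < -1 - 1e-9 || max(object@scores) > 1 + 1e-9))
    return("scores must lie in [-1, 1]")
  TRUE
})

#' SpecificityProfile: per-window and per-residue specificity scores
#'
#' For each query window, `sp = 1 - N_hits / N_total` where `N_hits` counts
#' the distinct bank proteins containing at least one similar window and
#' `N_total` is the number of proteins in the (filtered) bank; `sp` near 1
#' marks a conformation rarely found in the bank. The residue score is the
#' maximum `sp` over the windows covering the residue.
#'
#' @slot windowScores data.frame: `chain`, `resno`, `icode` (window start),
#'   `n_hits`, `sp` (`NA` for degenerate windows).
#' @slot residueScores data.frame: `chain`, `resno`, `icode`, `sp`.
#' @slot nTotal integer(1), proteins in the filtered bank.
#' @slot windowSize integer(1).
#' @seealso [specificitySearch()]
#' @export
setClass("SpecificityProfile",
  slots = c(windowScores = "data.frame", residueScores = "data.frame",
            nTotal = "integer", windowSize = "integer"))

#' GeneratorSpec: recipe for one synthetic structure
#'
#' @slot kind one of `"helix"`, `"strand"`, `"random_walk"`,
#'   `"perturbed_copy"`, `"mirrored_copy"`.
#' @slot length integer(1) >= 4, residues.
#' @slot noiseSigma numeric(1) >= 0, Angstrom of isotropic Gaussian noise.
#' @slot seed integer(1).
#' @slot plantedSequence character(1) or `NA`; fixture sequences default to
#'   poly-alanine.
#' @slot base optional [CaFragment-class] required by the `*_copy` kinds.
#' @slot sccs character(1) classification code or `NA`.
#' @seealso [generatorSpec()], [syntheticBank()]
#' @export
setClass("GeneratorSpec",
  slots = c(kind = "character", length = "integer", noiseSigma = "numeric",
            seed = "integer", plantedSequence = "character",
            base = "ANY", sccs = "character"))

setValidity("GeneratorSpec", function(object) {
  kinds <- c("helix", "strand", "random_walk", "perturbed_copy",
             "mirrored_copy")
  if (!object@kind %in% kinds)
    return(paste("kind must be one of", paste(kinds, collapse = ", ")))
  if (object@length < 4L) return("length must be >= 4")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (object@kind %in% c("perturbed_copy", "mirrored_copy") &&
      !is(object@base, "CaFragment"))
    return("perturbed_copy/mirrored_copy require a base CaFragment")
  TRUE
})

#' Constructor for [GeneratorSpec-class]
#'
#' @param kind generator kind; see [GeneratorSpec-class].
#' @param length fragment length in residues.
#' @param noiseSigma Gaussian noise level, Angstrom.
#' @param seed RNG seed for this structure.
#' @param plantedSequence optional sequence to stamp on the fixture.
#' @param base base fragment for the copy kinds.
#' @param sccs optional classification code for the manifest.
#' @return A [GeneratorSpec-class] object.
#' @examples
#' generatorSpec("random_walk", 30, seed = 7)
#' @export
generatorSpec <- function(kind, length, noiseSigma = 0, seed = 1L,
                          plantedSequence = NA_character_, base = NULL,
                          sccs = NA_character_) {
  new("GeneratorSpec", kind = kind, length = as.integer(length),
      noiseSigma = noiseSigma, seed = as.integer(seed),
      plantedSequence = plantedSequence, base = base, sccs = sccs)
}
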