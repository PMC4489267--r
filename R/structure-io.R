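## structure_io: PDB -> Calpha chains, contiguous segments, fragment bank,
## query selection and sequence-gap detection.

## virtual-bond gate: consecutive Calpha closer/farther than this is a break
.BOND_MIN <- 2.5
.BOND_MAX <- 4.5

.STD_AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
              "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
              "THR", "TRP", "TYR", "VAL", "MSE")

.aa1 <- function(aa3) {
  out <- suppressWarnings(bio3d::aa321(aa3))
  out[is.na(out)] <- "X"
  out
}

#' Read a PDB file into a Calpha structure
#'
#' Keeps the first MODEL only, resolves alternate locations to a single
#' Calpha per residue (highest occupancy, ties broken toward altloc `"A"`),
#' skips residues lacking a Calpha, and skips HETATM residues unless they
#' are standard amino acids (selenomethionine MSE is kept and mapped to
#' `M`).
#'
#' @param path path to a PDB-formatted file.
#' @param structureId identifier to record; defaults to the file base name.
#' @return A [CaStructure-class].
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeCaPdb(idealHelix(8), pdb)
#' readCaStructure(pdb)
#' @export
readCaStructure <- function(path, structureId = NULL) {
  if (!file.exists(path))
    .bcError("bc_io_error", paste("file not found:", path))
  if (is.null(structureId))
    structureId <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e)
      .bcError("bc_parse_error",
               sprintf("cannot parse PDB %s: %s", path, conditionMessage(e))))
  at <- pdb$atom
  at <- at[at$elety == "CA" & at$resid %in% .STD_AA3, , drop = FALSE]
  if (nrow(at) == 0L)
    .bcError("bc_empty_error", paste("no Calpha atoms in", path))
  at$chain[is.na(at$chain)] <- " "
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  ## altloc resolution per residue: keep highest occupancy, ties -> 'A'
  key <- paste(at$chain, at$resno, at$insert, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(at)), factor(key, unique(key))),
                        function(idx) {
    if (length(idx) == 1L) return(idx)
    o <- at$o[idx]
    best <- idx[o == max(o)]
    if (length(best) > 1L) {
      pref <- best[at$alt[best] %in% c("A", "")]
      if (length(pref)) best <- pref
    }
    best[1L]
  }), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]
  atoms <- data.frame(chain = at$chain, resno = as.integer(at$resno),
                      icode = at$insert, aa = .aa1(at$resid),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  new("CaStructure", structureId = structureId, atoms = atoms)
}

#' Split a structure into maximal contiguous segments
#'
#' A chain is split wherever residue numbering jumps (insertion codes count
#' as continuity within the same number) or the consecutive Calpha-Calpha
#' distance falls outside the virtual-bond gate `[2.5, 4.5]` Angstrom.
#' Segments shorter than 4 residues are dropped (no window fits them).
#'
#' @param structure a [CaStructure-class].
#' @param minLength drop segments shorter than this; default 4.
#' @return A list of [CaSegment-class] objects in chain order.
#' @export
contiguousSegments <- function(structure, minLength = 4L) {
  at <- structure@atoms
  segs <- list()
  for (ch in unique(at$chain)) {
    a <- at[at$chain == ch, , drop = FALSE]
    n <- nrow(a)
    if (n == 0L) next
    brk <- logical(n)        # brk[i]: break between residue i-1 and i
    if (n > 1L) for (i in 2:n) {
      dn <- a$resno[i] - a$resno[i - 1L]
      numOk <- (dn == 1L) || (dn == 0L && a$icode[i] != a$icode[i - 1L])
      d <- sqrt((a$x[i] - a$x[i - 1L])^2 + (a$y[i] - a$y[i - 1L])^2 +
                (a$z[i] - a$z[i - 1L])^2)
      brk[i] <- !numOk || d < .BOND_MIN || d > .BOND_MAX
    }
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      b <- a[grp == g, , drop = FALSE]
      if (nrow(b) < minLength) next
      segs[[length(segs) + 1L]] <- new("CaSegment",
        structureId = structure@structureId, chainId = ch,
        resno = b$resno, icode = b$icode,
        sequence = paste(b$aa, collapse = ""),
        coords = unname(as.matrix(b[, c("x", "y", "z")])))
    }
  }
  segs
}

#' Build a fragment bank from a collection of PDB files
#'
#' Registers every contiguous segment of every readable structure.
#' Unreadable files are logged and skipped, never fatal. An optional
#' manifest (TSV with columns `file_path`, `domain_id`, `sccs_code`)
#' attaches SCOP-style `class.fold.superfamily.family` codes and overrides
#' structure identifiers with domain identifiers.
#'
#' @param paths character vector of PDB file paths.
#' @param manifest optional path to the manifest TSV.
#' @return A [FragmentBank-class].
#' @examples
#' b <- syntheticBank(list(generatorSpec("random_walk", 30, seed = 1),
#'                         generatorSpec("helix", 20)))
#' b$bank
#' @export
buildFragmentBank <- function(paths, manifest = NULL) {
  man <- NULL
  if (!is.null(manifest)) {
    man <- utils::read.delim(manifest, stringsAsFactors = FALSE)
    need <- c("file_path", "domain_id", "sccs_code")
    if (!all(need %in% names(man)))
      .bcError("bc_parse_error",
               paste("manifest must have columns", paste(need, collapse = ", ")))
  }
  segs <- list()
  sccs <- character()
  nRead <- 0L
  for (p in paths) {
    sid <- NULL
    code <- NA_character_
    if (!is.null(man)) {
      row <- match(basename(p), basename(man$file_path))
      if (!is.na(row)) {
        sid <- man$domain_id[row]
        code <- man$sccs_code[row]
      }
    }
    st <- tryCatch(readCaStructure(p, structureId = sid),
                   error = function(e) {
                     .bcLog("warn", "skipping unreadable %s: %s", p,
                            conditionMessage(e))
                     NULL
                   })
    if (is.null(st)) next
    nRead <- nRead + 1L
    segs <- c(segs, contiguousSegments(st))
    if (!is.na(code)) sccs[st@structureId] <- code
  }
  if (nRead == 0L)
    .bcError("bc_empty_error", "no readable structures: empty bank")
  new("FragmentBank", segments = segs, sccs = sccs)
}

#' Number of length-n windows a bank exposes
#'
#' Equals the closed form `sum over segments of max(0, len - n + 1)`.
#'
#' @param bank a [FragmentBank-class].
#' @param n window length, residues.
#' @return integer(1).
#' @export
windowCount <- function(bank, n) {
  sum(vapply(bank@segments,
             function(s) max(0L, nrow(s@coords) - as.integer(n) + 1L),
             integer(1)))
}

#' Structure identifiers present in a bank
#'
#' @param bank a [FragmentBank-class].
#' @return character vector of unique structure ids.
#' @export
bankStructureIds <- function(bank)
  unique(vapply(bank@segments, slot, character(1), "structureId"))

.sccsMatches <- function(code, prefix) {
  !is.na(code) &
    (code == prefix | startsWith(code, paste0(prefix, ".")))
}

#' Filter a bank by classification-code prefix
#'
#' Prefix matching respects code-component boundaries: `"g.37"` matches
#' `g.37.1` but not `g.370`. Structures without a code never match an
#' include prefix and are retained under an exclude prefix.
#'
#' @param bank a [FragmentBank-class].
#' @param include keep only structures whose code matches this prefix
#'   (`NULL` = keep all).
#' @param exclude drop structures whose code matches this prefix.
#' @return A filtered [FragmentBank-class].
#' @export
filterBankBySccs <- function(bank, include = NULL, exclude = NULL) {
  keep <- vapply(bank@segments, function(s) {
    code <- if (s@structureId %in% names(bank@sccs))
      bank@sccs[[s@structureId]] else NA_character_
    ok <- TRUE
    if (!is.null(include)) ok <- .sccsMatches(code, include)
    if (ok && !is.null(exclude)) ok <- !.sccsMatches(code, exclude)
    ok
  }, logical(1))
  segs <- bank@segments[keep]
  ids <- unique(vapply(segs, slot, character(1), "structureId"))
  new("FragmentBank", segments = segs,
      sccs = bank@sccs[names(bank@sccs) %in% ids])
}

## parse "A:15-37" / "15-37" selections
.parseRange <- function(sel) {
  m <- regmatches(sel, regexec(
    "^(?:([A-Za-z0-9 ]):)?(-?[0-9]+)([A-Za-z]?)[-:](-?[0-9]+)([A-Za-z]?)$",
    sel))[[1]]
  if (length(m) == 0L) return(NULL)
  list(chain = if (m[2] == "") NULL else m[2],
       from = as.integer(m[3]), fromIns = m[4],
       to = as.integer(m[5]), toIns = m[6])
}

.segToFragment <- function(seg, idx) {
  CaFragment(seg@coords[idx, , drop = FALSE], sourceId = seg@structureId,
             chainId = seg@chainId, resno = seg@resno[idx],
             icode = seg@icode[idx],
             sequence = paste(strsplit(seg@sequence, "")[[1]][idx],
                              collapse = ""))
}

#' Extract the query fragment from a structure
#'
#' The selection is either a residue range like `"A:15-37"` (chain
#' optional when unambiguous) or a sequence substring, which must occur
#' exactly once among the structure's contiguous segments. Either way the
#' selection must resolve to one contiguous run of at least 4 residues.
#'
#' @param structure a [CaStructure-class].
#' @param selection character(1): residue range or sequence substring.
#' @return A [CaFragment-class] with provenance.
#' @export
extractQueryFragment <- function(structure, selection) {
  segs <- contiguousSegments(structure)
  if (length(segs) == 0L)
    .bcError("bc_empty_error", "structure has no segment of length >= 4")
  rng <- .parseRange(selection)
  if (!is.null(rng)) {
    hits <- list()
    for (seg in segs) {
      if (!is.null(rng$chain) && seg@chainId != rng$chain) next
      lab <- .labels(seg@resno, seg@icode)
      i1 <- match(paste0(rng$from, rng$fromIns), lab)
      i2 <- match(paste0(rng$to, rng$toIns), lab)
      if (is.na(i1) || is.na(i2) || i2 < i1) next
      hits[[length(hits) + 1L]] <- .segToFragment(seg, i1:i2)
    }
    if (length(hits) == 0L)
      .bcError("bc_notfound_error",
               sprintf("selection '%s' matches no contiguous run", selection))
    if (length(hits) > 1L)
      .bcError("bc_ambiguity_error",
               sprintf("selection '%s' is ambiguous (%d matches)",
                       selection, length(hits)))
    frag <- hits[[1L]]
  } else {
    pos <- list()
    for (seg in segs) {
      starts <- gregexpr(selection, seg@sequence, fixed = TRUE)[[1L]]
      if (starts[1L] == -1L) next
      for (s in starts)
        pos[[length(pos) + 1L]] <- list(seg = seg, at = s)
    }
    if (length(pos) == 0L)
      .bcError("bc_notfound_error",
               sprintf("sequence '%s' not found in any contiguous segment",
                       selection))
    if (length(pos) > 1L)
      .bcError("bc_ambiguity_error", sprintf(
        "sequence '%s' is ambiguous: matches at %s",
        selection,
        paste(vapply(pos, function(p)
          sprintf("%s:%s", p$seg@chainId,
                  .labels(p$seg@resno, p$seg@icode)[p$at]),
          character(1)), collapse = ", ")))
    seg <- pos[[1L]]$seg
    frag <- .segToFragment(seg, pos[[1L]]$at:(pos[[1L]]$at +
                                              nchar(selection) - 1L))
  }
  if (nrow(frag@coords) < 4L)
    .bcError("bc_shape_error", "query fragment must have >= 4 residues")
  frag
}

## place the observed blocks of one chain into the full sequence.
## Numbering-anchored placement is tried first (residue number = position);
## otherwise each block is matched leftmost as an exact substring after the
## previous block.
.placeBlocks <- function(blocks, fullSequence) {
  ok <- all(vapply(blocks, function(b) {
    p <- b$resno[1L]
    p >= 1L && (p + length(b$resno) - 1L) <= nchar(fullSequence) &&
      substr(fullSequence, p, p + length(b$resno) - 1L) == b$seq
  }, logical(1)))
  if (ok) return(lapply(blocks, function(b) b$resno[1L]))
  at <- integer(length(blocks))
  cursor <- 1L
  for (i in seq_along(blocks)) {
    hit <- regexpr(blocks[[i]]$seq, substr(fullSequence, cursor,
                                           nchar(fullSequence)),
                   fixed = TRUE)
    if (hit == -1L) {
      bad <- blocks[[i]]
      .bcError("bc_mismatch_error", sprintf(
        paste0("observed residues are not a subsequence of the full ",
               "sequence: block starting at residue %s%s ('%s...') has no ",
               "match at or after position %d"),
        bad$resno[1L], bad$icode[1L],
        substr(bad$seq, 1L, 8L), cursor))
    }
    at[i] <- cursor + as.integer(hit) - 1L
    cursor <- at[i] + length(blocks[[i]]$resno)
  }
  as.list(at)
}

#' Detect sequence gaps in a structure
#'
#' Compares the complete chain sequence with the residues observed in the
#' structure; each maximal run of residues present in the sequence but
#' absent from the structure yields one gap record with its length and the
#' four observed residues on each side. Gaps with fewer than 4 observed
#' residues on either side are reported with `searchable = FALSE`.
#'
#' @param fullSequence character(1): the complete amino-acid sequence of
#'   the chain(s), or a named vector (names = chain ids) for multi-chain
#'   structures.
#' @param structure a [CaStructure-class].
#' @return A data.frame with columns `chain`, `gap_start` (full-sequence
#'   position of the first missing residue), `gap_length`,
#'   `n_flank`, `c_flank` (comma-separated residue labels, `NA` at termini)
#'   and `searchable`.
#' @export
detectGaps <- function(fullSequence, structure) {
  at <- structure@atoms
  chains <- unique(at$chain)
  if (is.null(names(fullSequence))) {
    if (length(chains) > 1L && length(fullSequence) == 1L)
      .bcError("bc_usage_error",
               "multi-chain structure: name fullSequence by chain id")
    names(fullSequence) <- chains[seq_along(fullSequence)]
  }
  out <- list()
  for (ch in intersect(chains, names(fullSequence))) {
    full <- fullSequence[[ch]]
    a <- at[at$chain == ch, , drop = FALSE]
    if (nchar(full) < nrow(a))
      .bcError("bc_mismatch_error",
               sprintf("full sequence of chain %s shorter than the structure",
                       ch))
    ## split observed residues into contiguously-numbered blocks
    brk <- c(FALSE, diff(a$resno) != 1L)
    grp <- cumsum(brk)
    blocks <- lapply(split(seq_len(nrow(a)), grp), function(idx)
      list(resno = a$resno[idx], icode = a$icode[idx],
           seq = paste(a$aa[idx], collapse = ""), rows = idx))
    pos <- .placeBlocks(blocks, full)
    ## occupancy of full-sequence positions
    covered <- rep(FALSE, nchar(full))
    for (i in seq_along(blocks))
      covered[pos[[i]] + seq_along(blocks[[i]]$resno) - 1L] <- TRUE
    runs <- rle(covered)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    labAll <- .labels(a$resno, a$icode)
    posOfRow <- integer(nrow(a))
    for (i in seq_along(blocks))
      posOfRow[blocks[[i]]$rows] <- pos[[i]] + seq_along(blocks[[i]]$rows) - 1L
    for (r in which(!runs$values)) {
      gs <- starts[r]
      gl <- runs$lengths[r]
      before <- which(posOfRow < gs)
      after <- which(posOfRow > gs + gl - 1L)
      nf <- if (length(before) >= 4L)
        paste(labAll[utils::tail(before, 4L)], collapse = ",") else NA_character_
      cf <- if (length(after) >= 4L)
        paste(labAll[utils::head(after, 4L)], collapse = ",") else NA_character_
      out[[length(out) + 1L]] <- data.frame(
        chain = ch, gap_start = gs, gap_length = gl,
        n_flank = nf, c_flank = cf,
        searchable = !is.na(nf) && !is.na(cf),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(chain = character(), gap_start = integer(),
                      gap_length = integer(), n_flank = character(),
                      c_flank = character(), searchable = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Build a loop query from a gaped structure
#'
#' Packages the two four-residue flanks of one detected gap together with
#' the full template Calpha set required by the clash filter.
#'
#' @param structure a [CaStructure-class] (the gaped template).
#' @param fullSequence complete chain sequence (see [detectGaps()]).
#' @param gap which searchable gap to use (index into the searchable rows
#'   of [detectGaps()]), default the first.
#' @return A [LoopQuery-class].
#' @export
makeLoopQuery <- function(structure, fullSequence, gap = 1L) {
  gaps <- detectGaps(fullSequence, structure)
  gaps <- gaps[gaps$searchable, , drop = FALSE]
  if (nrow(gaps) == 0L)
    .bcError("bc_notfound_error", "no searchable gap (4 observed residues needed on each side)")
  if (gap > nrow(gaps))
    .bcError("bc_usage_error",
             sprintf("gap index %d out of range (%d searchable gaps)",
                     gap, nrow(gaps)))
  g <- gaps[gap, ]
  ch <- g$chain
  at <- structure@atoms
  a <- at[at$chain == ch, , drop = FALSE]
  lab <- .labels(a$resno, a$icode)
  nLab <- strsplit(g$n_flank, ",")[[1L]]
  cLab <- strsplit(g$c_flank, ",")[[1L]]
  pick <- function(labels) {
    idx <- match(labels, lab)
    CaFragment(unname(as.matrix(a[idx, c("x", "y", "z")])),
               sourceId = structure@structureId, chainId = ch,
               resno = a$resno[idx], icode = a$icode[idx],
               sequence = paste(a$aa[idx], collapse = ""))
  }
  if (is.null(names(fullSequence)))
    names(fullSequence) <- ch
  full <- fullSequence[[ch]]
  ## full-sequence position of each template residue, all chains
  tmplPos <- rep(NA_integer_, nrow(at))
  brk <- c(FALSE, diff(a$resno) != 1L)
  blocks <- lapply(split(seq_len(nrow(a)), cumsum(brk)), function(idx)
    list(resno = a$resno[idx], icode = a$icode[idx],
         seq = paste(a$aa[idx], collapse = ""), rows = idx))
  pos <- .placeBlocks(blocks, full)
  rowsInChain <- which(at$chain == ch)
  for (i in seq_along(blocks))
    tmplPos[rowsInChain[blocks[[i]]$rows]] <-
      pos[[i]] + seq_along(blocks[[i]]$rows) - 1L
  new("LoopQuery", queryId = structure@structureId, chainId = ch,
      nFlank = pick(nLab), cFlank = pick(cLab),
      gapStart = as.integer(g$gap_start), gapLength = as.integer(g$gap_length),
      templateCoords = unname(as.matrix(at[, c("x", "y", "z")])),
      templateChain = at$chain, templatePos = tmplPos,
      fullSequence = full)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper used by the loop-search CLI; returns a named character
#' vector of sequences.
#'
#' @param path FASTA file path.
#' @return Named character vector.
#' @export
readFastaSequences <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
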