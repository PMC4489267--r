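## fixtures: deterministic synthetic Calpha structures so every service is
## testable without downloading real structures.

.CA_STEP <- 3.8     # virtual Calpha-Calpha bond, Angstrom

#' Ideal alpha-helix Calpha trace
#'
#' Canonical right-handed helix: 1.5 Angstrom rise per residue, 2.3
#' Angstrom radius, 100 degrees of turn per residue; consecutive Calpha
#' distances come out at ~3.83 Angstrom. Its mirror image is a left-handed
#' helix.
#'
#' @param n number of residues, >= 4.
#' @param sequence optional sequence; defaults to poly-alanine.
#' @return A [CaFragment-class].
#' @examples
#' h <- idealHelix(12)
#' range(sqrt(rowSums(diff(coords(h))^2)))
#' @export
idealHelix <- function(n, sequence = strrep("A", n)) {
  if (n < 4L) .bcError("bc_shape_error", "need n >= 4")
  i <- seq_len(n) - 1L
  th <- i * 100 * pi / 180
  CaFragment(cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * i),
             sourceId = "helix", sequence = sequence)
}

#' Ideal beta-strand Calpha trace
#'
#' Near-straight zig-zag with a 3.3 Angstrom rise and lateral alternation
#' chosen so consecutive Calpha distances are 3.8 Angstrom.
#'
#' @inheritParams idealHelix
#' @return A [CaFragment-class].
#' @export
idealStrand <- function(n, sequence = strrep("A", n)) {
  if (n < 4L) .bcError("bc_shape_error", "need n >= 4")
  i <- seq_len(n) - 1L
  lat <- sqrt(.CA_STEP^2 - 3.3^2) / 2
  CaFragment(cbind(lat * (-1)^i, rep(0, n), 3.3 * i),
             sourceId = "strand", sequence = sequence)
}

## NeRF placement: new point at distance r from c, bond angle theta at c
## (b-c-new) and dihedral phi (a-b-c-new)
.nerf <- function(a, b, c, r, theta, phi) {
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- .cross3(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d <- c(-r * cos(theta), r * sin(theta) * cos(phi),
         r * sin(theta) * sin(phi))
  c + cbind(bc, m, n) %*% d
}

#' Random-walk Calpha decoy fragment
#'
#' A walk with exact 3.8 Angstrom steps, pseudo-bond angles uniform in
#' [80, 150] degrees (protein-like) and uniform dihedrals; deterministic
#' per seed. Used as unrelated-conformation decoys: two independent walks
#' have BC scores concentrated near 0.
#'
#' @param n number of residues, >= 4.
#' @param seed RNG seed.
#' @param sequence optional sequence; defaults to poly-alanine.
#' @return A [CaFragment-class].
#' @export
randomWalkFragment <- function(n, seed = 1L, sequence = strrep("A", n)) {
  if (n < 4L) .bcError("bc_shape_error", "need n >= 4")
  co <- .withSeed(seed, {
    m <- matrix(0, nrow = n, ncol = 3L)
    m[2L, ] <- c(.CA_STEP, 0, 0)
    th <- runif(1L, 80, 150) * pi / 180
    m[3L, ] <- m[2L, ] + .CA_STEP * c(cos(pi - th), sin(pi - th), 0)
    if (n >= 4L) for (i in 4:n) {
      th <- runif(1L, 80, 150) * pi / 180
      ph <- runif(1L, -pi, pi)
      m[i, ] <- .nerf(m[i - 3L, ], m[i - 2L, ], m[i - 1L, ], .CA_STEP,
                      th, ph)
    }
    m
  })
  CaFragment(co, sourceId = sprintf("walk%d", seed), sequence = sequence)
}

#' Add isotropic Gaussian coordinate noise
#'
#' @param frag a [CaFragment-class].
#' @param sigma standard deviation per coordinate, Angstrom (`0` returns
#'   the input unchanged).
#' @param seed RNG seed.
#' @return A [CaFragment-class] with perturbed coordinates.
#' @export
perturbFragment <- function(frag, sigma, seed = 1L) {
  if (sigma < 0) .bcError("bc_usage_error", "sigma must be >= 0")
  if (sigma == 0) return(frag)
  n <- nrow(frag@coords)
  out <- frag
  out@coords <- frag@coords +
    .withSeed(seed, matrix(stats::rnorm(3L * n, 0, sigma), ncol = 3L))
  out
}

## uniform random proper rotation (quaternion method)
.randomRotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3L, byrow = TRUE)
}

#' Write a minimal Calpha-only PDB file
#'
#' Single model, single altloc, ATOM + TER + END; one CA record per
#' residue. Output is deterministic: identical inputs give byte-identical
#' files.
#'
#' @param x a [CaFragment-class] or [CaStructure-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeCaPdb <- function(x, path) {
  if (is(x, "CaFragment")) {
    df <- data.frame(chain = x@chainId, resno = x@resno, icode = x@icode,
                     aa = strsplit(x@sequence, "")[[1L]],
                     x = x@coords[, 1L], y = x@coords[, 2L],
                     z = x@coords[, 3L], stringsAsFactors = FALSE)
  } else if (is(x, "CaStructure")) {
    df <- x@atoms
  } else .bcError("bc_usage_error", "expected a CaFragment or CaStructure")
  aa3 <- vapply(df$aa, function(a) {
    out <- suppressWarnings(bio3d::aa123(a))
    if (is.na(out) || a == "X") "UNK" else out
  }, character(1))
  lines <- character()
  eleno <- 0L
  for (ch in unique(df$chain)) {
    d <- df[df$chain == ch, , drop = FALSE]
    a3 <- aa3[df$chain == ch]
    for (i in seq_len(nrow(d))) {
      eleno <- eleno + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
        eleno, a3[i], ch, d$resno[i],
        if (d$icode[i] == "") " " else d$icode[i],
        d$x[i], d$y[i], d$z[i]))
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

## realize one GeneratorSpec as a CaFragment
.generateFragment <- function(spec) {
  frag <- switch(spec@kind,
    helix = idealHelix(spec@length),
    strand = idealStrand(spec@length),
    random_walk = randomWalkFragment(spec@length, seed = spec@seed),
    perturbed_copy = perturbFragment(spec@base, spec@noiseSigma,
                                     seed = spec@seed),
    mirrored_copy = mirrorFragment(spec@base))
  if (spec@kind %in% c("helix", "strand", "random_walk") &&
      spec@noiseSigma > 0)
    frag <- perturbFragment(frag, spec@noiseSigma, seed = spec@seed + 1L)
  if (!is.na(spec@plantedSequence)) {
    if (nchar(spec@plantedSequence) != nrow(frag@coords))
      .bcError("bc_usage_error", "plantedSequence length mismatch")
    frag@sequence <- spec@plantedSequence
  }
  frag
}

## rigidly place `frag` so its first atom continues the chain ending at
## `tail3` (>= 1 previous points), with a random orientation
.placeAfter <- function(prev, frag) {
  co <- centerCoords(frag@coords)
  co <- sweep(co, 2L, co[1L, ])          # first atom at origin
  R <- .randomRotation()
  co <- co %*% R
  np <- nrow(prev)
  dir <- if (np >= 2L) prev[np, ] - prev[np - 1L, ] else c(1, 0, 0)
  dir <- dir / sqrt(sum(dir^2))
  sweep(co, 2L, prev[np, ] + .CA_STEP * dir, "+")
}

#' Build a synthetic fragment bank with known ground truth
#'
#' Realizes each [GeneratorSpec-class] as one single-chain structure,
#' writes valid PDB fixture files, builds a [FragmentBank-class] through
#' the real PDB-reading path, and (optionally) plants a given fragment as
#' a rigid, randomly oriented copy at a known offset of one structure so
#' searches can be asserted against ground truth. When any spec carries an
#' `sccs` code a manifest TSV is written and attached.
#'
#' @param specs list of [GeneratorSpec-class] objects.
#' @param planted optional list with elements `fragment` (a
#'   [CaFragment-class]), `structure` (index into `specs`), `offset`
#'   (1-based window start) and `seed` (orientation RNG). The host
#'   structure is a random walk into which the fragment is spliced with
#'   exact virtual bonds at the joints.
#' @param dir directory for the fixture files; created if needed.
#' @return A list: `bank` ([FragmentBank-class]), `dir`, `files`, and
#'   `truth` (`NULL` or list with `structureId`, `chain`, `offset`,
#'   `resno` range and the placed `coords`).
#' @examples
#' sb <- syntheticBank(list(generatorSpec("random_walk", 24, seed = 3),
#'                          generatorSpec("helix", 16)))
#' windowCount(sb$bank, 9)
#' @export
syntheticBank <- function(specs, planted = NULL,
                          dir = tempfile("bcbank")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(specs))
  sccs <- character()
  truth <- NULL
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    sid <- sprintf("S%02d", i)
    if (!is.null(planted) && planted$structure == i) {
      pf <- planted$fragment
      npl <- nrow(pf@coords)
      off <- as.integer(planted$offset)
      total <- max(spec@length, off + npl - 1L + 4L)
      host <- .withSeed(if (is.null(planted$seed)) spec@seed else
                        planted$seed, {
        prev <- coords(randomWalkFragment(max(off - 1L, 4L),
                                          seed = spec@seed))[
          seq_len(max(off - 1L, 1L)), , drop = FALSE]
        if (off == 1L) {
          placed <- centerCoords(pf@coords)
          attr(placed, "originOffset") <- NULL
        } else {
          placed <- .placeAfter(prev, pf)
        }
        nTail <- total - (off - 1L) - npl
        tail <- matrix(numeric(0), ncol = 3L)
        if (nTail > 0L) {
          cur <- if (off == 1L) placed else rbind(prev, placed)
          for (k in seq_len(nTail)) {
            nc <- nrow(cur)
            th <- runif(1L, 80, 150) * pi / 180
            ph <- runif(1L, -pi, pi)
            nxt <- as.numeric(.nerf(cur[nc - 2L, ], cur[nc - 1L, ],
                                    cur[nc, ], .CA_STEP, th, ph))
            cur <- rbind(cur, nxt)
            tail <- rbind(tail, nxt)
          }
        }
        list(coords = if (off == 1L) rbind(placed, tail) else
               rbind(prev, placed, tail), placed = placed)
      })
      n <- nrow(host$coords)
      seqs <- strsplit(strrep("A", n), "")[[1L]]
      seqs[off:(off + npl - 1L)] <- strsplit(pf@sequence, "")[[1L]]
      frag <- CaFragment(host$coords, sourceId = sid,
                         sequence = paste(seqs, collapse = ""))
      truth <- list(structureId = sid, chain = "A", offset = off,
                    resno = off:(off + npl - 1L), coords = host$placed)
    } else {
      frag <- .generateFragment(spec)
      frag@sourceId <- sid
    }
    frag@chainId <- "A"
    frag@resno <- seq_len(nrow(frag@coords))
    frag@icode <- rep("", nrow(frag@coords))
    files[i] <- file.path(dir, paste0(sid, ".pdb"))
    writeCaPdb(frag, files[i])
    if (!is.na(spec@sccs)) sccs[sid] <- spec@sccs
  }
  manifest <- NULL
  if (length(sccs)) {
    manifest <- file.path(dir, "manifest.tsv")
    ids <- sprintf("S%02d", seq_along(specs))
    utils::write.table(
      data.frame(file_path = files, domain_id = ids,
                 sccs_code = ifelse(ids %in% names(sccs),
                                    sccs[ids], NA_character_),
                 stringsAsFactors = FALSE),
      manifest, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  bank <- buildFragmentBank(files, manifest = manifest)
  list(bank = bank, dir = dir, files = files, truth = truth)
}
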