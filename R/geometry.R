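## geometry_core: centering, BC score, rigidity score, reflection,
## Kabsch superposition and RMSD on Calpha coordinate matrices.

#' Center coordinates at the origin
#'
#' Subtracts the centroid so the component-wise mean is zero. The subtracted
#' centroid is attached as attribute `"originOffset"`, making the map
#' invertible.
#'
#' @param x a [CaFragment-class] or numeric N x 3 matrix.
#' @return A centered N x 3 matrix with attribute `originOffset`.
#' @examples
#' m <- centerCoords(idealHelix(6))
#' colMeans(m)                  # ~ c(0, 0, 0)
#' attr(m, "originOffset")
#' @export
centerCoords <- function(x) {
  m <- .asCoords(x)
  if (nrow(m) < 1L) .bcError("bc_coord_error", "need at least one point")
  if (any(!is.finite(m)))
    .bcError("bc_coord_error", "non-finite coordinates")
  ctr <- colMeans(m)
  out <- sweep(m, 2L, ctr)
  attr(out, "originOffset") <- ctr
  out
}

## relative degeneracy criterion: det(X'X) < 1e-6 * (tr(X'X)/3)^3.
## A near-zero Gram determinant means the centered points are
## (near-)coplanar or collinear and the BC denominator is meaningless.
.DEGEN_REL <- 1e-6

.gramInfo <- function(centered) {
  g <- crossprod(centered)
  d <- .det3(g)
  floor <- .DEGEN_REL * (sum(diag(g)) / 3)^3
  list(gram = g, det = d, degenerate = (d < floor))
}

.checkPair <- function(x, y, minN = 4L, what = "BC score") {
  X <- centerCoords(x)
  Y <- centerCoords(y)
  if (nrow(X) != nrow(Y))
    .shapeError(sprintf("fragment lengths differ (%d vs %d)",
                        nrow(X), nrow(Y)))
  if (nrow(X) < minN)
    .shapeError(sprintf("%s needs at least %d points, got %d",
                        what, minN, nrow(X)))
  list(X = X, Y = Y)
}

#' Binet-Cauchy score between two Calpha fragments
#'
#' The BC score is the cosine between the Grassmann representations of the
#' two centered coordinate sets,
#' \deqn{BC(X, Y) = \det(X^\top Y) / \sqrt{\det(X^\top X)\,\det(Y^\top Y)},}
#' a geometric correlation: 1 for identical shapes, near 0 for unrelated
#' conformations, -1 for mirror images. It is invariant to rotation and
#' translation of either argument (inputs are centered internally) and
#' symmetric. Degenerate (collinear or coplanar) fragments have no score and
#' raise an error of class `bc_degeneracy_error`.
#'
#' @param x,y [CaFragment-class] objects or N x 3 matrices of equal length
#'   N >= 4.
#' @return numeric(1) in `[-1, 1]` (clamped against rounding; a warning is
#'   emitted if the pre-clamp excursion exceeds 1e-6).
#' @examples
#' h <- idealHelix(12)
#' bcScore(h, h)                    # 1
#' bcScore(h, mirrorFragment(h))    # -1
#' @seealso [rigidityScore()], [mirrorFragment()]
#' @references Guyon & Tuffery, on the Binet-Cauchy kernel for protein
#'   fragment comparison.
#' @export
bcScore <- function(x, y) {
  p <- .checkPair(x, y)
  gx <- .gramInfo(p$X)
  gy <- .gramInfo(p$Y)
  if (gx$degenerate || gy$degenerate)
    .degeneracyError("degenerate (collinear/coplanar) fragment: BC score undefined")
  ## canonical argument order makes the score bitwise symmetric
  ## (det(X'Y) and det(Y'X) agree only up to rounding otherwise)
  A <- p$X
  B <- p$Y
  d <- as.vector(A) - as.vector(B)
  k <- which(d != 0)[1L]
  if (!is.na(k) && d[k] > 0) {
    A <- p$Y
    B <- p$X
  }
  raw <- .det3(crossprod(A, B)) / sqrt(gx$det * gy$det)
  if (abs(raw) > 1 + 1e-6)
    warning(sprintf("BC score %.3g outside [-1, 1] beyond rounding; clamped",
                    raw))
  max(-1, min(1, raw))
}

#' Rigidity score between two Calpha fragments
#'
#' The maximum variation of intra-distances: the largest absolute difference
#' of residue-to-centroid distances over positions, or of the terminal
#' Calpha-Calpha distances, whichever is greater:
#' \deqn{R(X,Y) = \max\{\max_i \big|\;\lVert X_i\rVert - \lVert Y_i\rVert\;\big|,\;
#'   \big|\,\lVert X_N - X_1\rVert - \lVert Y_N - Y_1\rVert\,\big|\}.}
#' The BC score is deliberately flexible (it can equal 1 for fragments that
#' differ by an anisotropic scaling); the rigidity score caps that
#' flexibility. Zero for rigid copies and for mirror images; invariant to
#' rotations and reflections of either argument.
#'
#' @param x,y [CaFragment-class] objects or N x 3 matrices of equal length
#'   N >= 2. Centered internally.
#' @return numeric(1) >= 0, Angstrom.
#' @examples
#' h <- idealHelix(9)
#' rigidityScore(h, h)                        # 0
#' rigidityScore(h, coords(h) * 2)            # > 0: catches scaling
#' @export
rigidityScore <- function(x, y) {
  p <- .checkPair(x, y, minN = 2L, what = "rigidity score")
  nx <- sqrt(rowSums(p$X^2))
  ny <- sqrt(rowSums(p$Y^2))
  n <- nrow(p$X)
  term <- sqrt(sum((p$X[n, ] - p$X[1, ])^2)) -
          sqrt(sum((p$Y[n, ] - p$Y[1, ])^2))
  max(max(abs(nx - ny)), abs(term))
}

#' Mirror image of a fragment
#'
#' Reflects the centered coordinates through the xy-plane (z negated),
#' inverting chirality while preserving all pairwise distances. Any fixed
#' reflection is equivalent up to rotation and the BC score is
#' rotation-invariant, so one convention suffices;
#' `bcScore(x, mirrorFragment(x))` is -1 for any non-degenerate fragment.
#'
#' @param x a [CaFragment-class] or N x 3 matrix.
#' @return An object of the same kind with reflected, centered coordinates.
#' @examples
#' h <- idealHelix(12)          # right-handed helix
#' m <- mirrorFragment(h)       # its left-handed image
#' bcScore(h, m)                # -1
#' @export
mirrorFragment <- function(x) {
  m <- centerCoords(x)
  m[, 3] <- -m[, 3]
  attr(m, "originOffset") <- NULL
  if (is(x, "CaFragment")) {
    out <- x
    out@coords <- m
    out
  } else m
}

#' Kabsch superposition of two fragments
#'
#' Least-squares optimal proper rotation aligning `x` onto `y` after
#' centering both. Built on the singular value decomposition of the 3 x 3
#' cross-covariance; when the raw optimum is a reflection, the singular
#' direction with the smallest singular value is flipped so the returned
#' rotation always has determinant +1.
#'
#' @param x,y [CaFragment-class] objects or N x 3 matrices, equal length
#'   N >= 3.
#' @return A list with components `rotation` (3 x 3, det +1; rows of the
#'   centered `x` are mapped by `X %*% rotation`), `translation` (applied
#'   after rotation so that raw `x` maps into the frame of raw `y`) and
#'   `rmsd` (minimized Calpha RMSD, Angstrom).
#' @examples
#' h <- idealHelix(8)
#' kabschSuperpose(h, h)$rmsd   # 0
#' @export
kabschSuperpose <- function(x, y) {
  rawX <- .asCoords(x)
  p <- .checkPair(x, y, minN = 3L, what = "superposition")
  H <- crossprod(p$X, p$Y)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- p$X %*% R
  rmsd <- sqrt(mean(rowSums((fitted - p$Y)^2)))
  ctrX <- colMeans(rawX)
  ctrY <- attr(p$Y, "originOffset")
  list(rotation = R, translation = as.numeric(ctrY - ctrX %*% R),
       rmsd = rmsd)
}

#' Optimal-superposition RMSD between two fragments
#'
#' Root-mean-square Calpha deviation after centering and Kabsch
#' superposition. Proper rotations only: the RMSD between a chiral fragment
#' and its mirror image is strictly positive.
#'
#' @param x,y [CaFragment-class] objects or N x 3 matrices of equal length.
#' @return numeric(1) >= 0, Angstrom.
#' @examples
#' h <- idealHelix(10)
#' fragRMSD(h, coords(h) + 5)   # 0: translation removed
#' @export
fragRMSD <- function(x, y) kabschSuperpose(x, y)$rmsd
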