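## condition helpers: every package error carries a subclass so callers and
## the CLI can react without string-matching messages

.bcError <- function(class, msg, call = sys.call(-1)) {
  stop(structure(class = c(class, "bcmine_error", "error", "condition"),
                 list(message = msg, call = call)))
}

.shapeError <- function(msg) .bcError("bc_shape_error", msg)
.degeneracyError <- function(msg) .bcError("bc_degeneracy_error", msg)

## run expr with a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

.asCoords <- function(x) {
  if (is(x, "CaFragment") || is(x, "CaSegment")) return(coords(x))
  if (is.matrix(x)) {
    m <- x
    storage.mode(m) <- "double"
    return(m)
  }
  .bcError("bc_coord_error", "expected a CaFragment or an N x 3 matrix")
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## determinant of a 3x3 matrix, explicit cofactor-free arithmetic
.det3 <- function(m) {
  m[1, 1] * (m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2]) -
  m[1, 2] * (m[2, 1] * m[3, 3] - m[2, 3] * m[3, 1]) +
  m[1, 3] * (m[2, 1] * m[3, 2] - m[2, 2] * m[3, 1])
}

.logLevels <- c(debug = 10L, info = 20L, warn = 30L, error = 40L)

.bcLog <- function(level, fmt, ...) {
  threshold <- getOption("bcmine.log.level", "info")
  if (.logLevels[[level]] >= .logLevels[[threshold]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  invisible(NULL)
}
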