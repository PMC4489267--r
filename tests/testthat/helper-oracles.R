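# Independent naive implementations used as oracles. They share no code
# with the package: determinants by explicit cofactor expansion, explicit
# loops over score terms, window enumeration written from the definitions.

o_det3 <- function(m) {
  # cofactor expansion along the first row
  m[1, 1] * (m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2]) -
    m[1, 2] * (m[2, 1] * m[3, 3] - m[2, 3] * m[3, 1]) +
    m[1, 3] * (m[2, 1] * m[3, 2] - m[2, 2] * m[3, 1])
}

o_center <- function(m) {
  ctr <- c(mean(m[, 1]), mean(m[, 2]), mean(m[, 3]))
  cbind(m[, 1] - ctr[1], m[, 2] - ctr[2], m[, 3] - ctr[3])
}

o_degenerate <- function(cm) {
  g <- t(cm) %*% cm
  o_det3(g) < 1e-6 * ((g[1, 1] + g[2, 2] + g[3, 3]) / 3)^3
}

o_bc <- function(x, y) {
  X <- o_center(x)
  Y <- o_center(y)
  v <- o_det3(t(X) %*% Y) / sqrt(o_det3(t(X) %*% X) * o_det3(t(Y) %*% Y))
  max(-1, min(1, v))
}

o_rigidity <- function(x, y) {
  X <- o_center(x)
  Y <- o_center(y)
  n <- nrow(X)
  best <- 0
  for (i in seq_len(n)) {
    d <- abs(sqrt(sum(X[i, ]^2)) - sqrt(sum(Y[i, ]^2)))
    if (d > best) best <- d
  }
  term <- abs(sqrt(sum((X[n, ] - X[1, ])^2)) - sqrt(sum((Y[n, ] - Y[1, ])^2)))
  max(best, term)
}

# random proper rotation via axis-angle (Rodrigues), independent of the
# package's quaternion construction
o_rotation <- function() {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# enumerate all length-n windows from the bank's segments, from the
# definition: every start offset inside every segment
o_windows <- function(bank, n) {
  out <- list()
  for (seg in bank@segments) {
    len <- nrow(seg@coords)
    if (len < n) next
    aa <- strsplit(seg@sequence, "")[[1]]
    for (off in seq_len(len - n + 1)) {
      idx <- off:(off + n - 1)
      out[[length(out) + 1]] <- list(
        sid = seg@structureId, chain = seg@chainId,
        resno = seg@resno[idx], icode = seg@icode[idx],
        seq = paste(aa[idx], collapse = ""),
        coords = seg@coords[idx, , drop = FALSE])
    }
  }
  out
}

# naive fragment / mirror search: hit iff bc >= cut (or <= -cut) and
# rigidity <= rcut; ordering bc desc (asc for mirror), rigidity asc,
# hit id, start residue number
o_search <- function(qcoords, bank, bc_cut = 0.95, rg_cut = 1.0,
                     mirror = FALSE) {
  wins <- o_windows(bank, nrow(qcoords))
  rows <- list()
  for (w in wins) {
    if (o_degenerate(o_center(w$coords))) next
    bc <- o_bc(qcoords, w$coords)
    ok <- if (mirror) bc <= -bc_cut else bc >= bc_cut
    if (!ok) next
    rg <- o_rigidity(qcoords, w$coords)
    if (rg > rg_cut) next
    rows[[length(rows) + 1]] <- data.frame(
      hit = w$sid, h_start = paste0(w$resno[1],
                                    ifelse(w$icode[1] == "", "", w$icode[1])),
      start_resno = w$resno[1], start_icode = w$icode[1],
      bc_score = bc, rigidity = rg, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(hit = character(), h_start = character(),
                      bc_score = numeric(), rigidity = numeric()))
  df <- do.call(rbind, rows)
  key <- if (mirror) df$bc_score else -df$bc_score
  df[order(key, df$rigidity, df$hit, df$start_resno, df$start_icode,
           method = "radix"), , drop = FALSE]
}

# naive loop search: flank scoring, grafting with bio3d's superposition
# (independent of the package's Kabsch), explicit clash scan
o_loop_search <- function(lq, bank, bc_cut = 0.95, rg_cut = 1.0,
                          clash = 3.0, sep_min = 3) {
  L <- lq@gapLength
  n <- 8 + L
  fl <- c(1:4, (L + 5):n)
  qf <- rbind(lq@nFlank@coords, lq@cFlank@coords)
  wins <- o_windows(bank, n)
  loopPos <- lq@gapStart + seq_len(L) - 1
  rows <- list()
  for (w in wins) {
    wf <- w$coords[fl, , drop = FALSE]
    if (o_degenerate(o_center(wf))) next
    bc <- o_bc(qf, wf)
    if (bc < bc_cut) next
    rg <- o_rigidity(qf, wf)
    if (rg > rg_cut) next
    fitted <- bio3d::fit.xyz(fixed = as.numeric(t(qf)),
                             mobile = as.numeric(t(w$coords)),
                             fixed.inds = bio3d::atom2xyz(1:8),
                             mobile.inds = bio3d::atom2xyz(fl))
    all3 <- matrix(fitted, ncol = 3, byrow = TRUE)
    loop <- all3[5:(L + 4), , drop = FALSE]
    clashed <- FALSE
    for (j in seq_len(L)) {
      for (t in seq_len(nrow(lq@templateCoords))) {
        sep <- if (is.na(lq@templatePos[t])) Inf else
          abs(lq@templatePos[t] - loopPos[j])
        if (sep < sep_min) next
        if (sqrt(sum((lq@templateCoords[t, ] - loop[j, ])^2)) < clash) {
          clashed <- TRUE
          break
        }
      }
      if (clashed) break
    }
    if (clashed) next
    rows[[length(rows) + 1]] <- data.frame(
      hit = w$sid, h_start = paste0(w$resno[1],
                                    ifelse(w$icode[1] == "", "", w$icode[1])),
      start_resno = w$resno[1], start_icode = w$icode[1],
      bc_score = bc, rigidity = rg, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(hit = character(), h_start = character(),
                      bc_score = numeric(), rigidity = numeric()))
  df <- do.call(rbind, rows)
  df[order(-df$bc_score, df$rigidity, df$hit, df$start_resno,
           df$start_icode, method = "radix"), , drop = FALSE]
}

# naive specificity: for every window of the query structure, count
# distinct bank structure ids with >= 1 similar window
o_specificity <- function(query, bank, w = 9, bc_cut = 0.95, rg_cut = 1.0) {
  segs <- contiguousSegments(query)
  ids <- unique(vapply(bank@segments, function(s) s@structureId,
                       character(1)))
  out <- list()
  for (seg in segs) {
    len <- nrow(seg@coords)
    if (len < w) next
    for (off in seq_len(len - w + 1)) {
      win <- seg@coords[off:(off + w - 1), , drop = FALSE]
      if (o_degenerate(o_center(win))) {
        sp <- NA_real_
      } else {
        res <- o_search(win, bank, bc_cut, rg_cut)
        sp <- 1 - length(unique(res$hit)) / length(ids)
      }
      out[[length(out) + 1]] <- data.frame(
        chain = seg@chainId, resno = seg@resno[off], sp = sp,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
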