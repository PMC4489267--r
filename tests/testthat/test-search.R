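# Shared planted-bank fixture: random-walk decoys plus an exact copy of the
# query spliced into structure 2 at offset 6.
planted_setup <- local({
  q <- randomWalkFragment(9, seed = 11, sequence = "ACDEFGHIK")
  sb <- syntheticBank(
    lapply(1:10, function(i) generatorSpec("random_walk", 30, seed = i)),
    planted = list(fragment = q, structure = 2, offset = 6, seed = 99))
  list(q = q, sb = sb)
})

test_that("fragment search recovers a planted identical window", {
  q <- planted_setup$q
  sb <- planted_setup$sb
  hits <- fragSearch(q, sb$bank, nullSamples = 300)
  expect_gte(nrow(hits), 1)
  top <- hits[1, ]
  expect_equal(top$hit, sb$truth$structureId)
  expect_equal(top$h_start, as.character(sb$truth$offset))
  expect_equal(top$bc_score, 1, tolerance = 1e-3)
  expect_lt(top$rigidity, 0.01)      # PDB 3-decimal quantisation only
  expect_lt(top$rmsd, 0.01)
  expect_equal(top$sequence, "ACDEFGHIK")   # planted sequence round-trips
  # the planted window survives cutoffs far harsher than the defaults
  # (bounded by the 3-decimal coordinate quantisation of the PDB fixture)
  hits2 <- fragSearch(q, sb$bank, searchParams(bcCutoff = 0.9999,
                                               rigidityCutoff = 0.01),
                      nullSamples = 100)
  expect_true(any(hits2$hit == sb$truth$structureId &
                  hits2$h_start == as.character(sb$truth$offset)))
})

test_that("mirror search finds a planted mirrored window", {
  q <- planted_setup$q
  sb <- planted_setup$sb
  mh <- mirrorSearch(mirrorFragment(q), sb$bank, nullSamples = 300)
  expect_gte(nrow(mh), 1)
  expect_equal(mh$bc_score[1], -1, tolerance = 1e-3)
  expect_lt(mh$rigidity[1], 0.01)
  expect_lt(mh$rmsd[1], 0.01)        # rmsd vs the mirrored query
  expect_equal(mh$hit[1], sb$truth$structureId)
})

test_that("hit sets and orderings equal the naive oracle", {
  # decoys + noisy copies of the query so default cutoffs yield a
  # non-trivial hit set
  q <- randomWalkFragment(9, seed = 50)
  specs <- c(
    lapply(1:6, function(i) generatorSpec("random_walk", 45, seed = 60 + i)),
    lapply(1:4, function(i) generatorSpec("perturbed_copy", 9,
                                          noiseSigma = 0.12 * i,
                                          seed = 70 + i, base = q)),
    list(generatorSpec("mirrored_copy", 9, base = q)))
  sb <- syntheticBank(specs,
                      planted = list(fragment = q, structure = 3,
                                     offset = 10, seed = 5))
  hits <- fragSearch(q, sb$bank, nullSamples = 100)
  orc <- o_search(coords(q), sb$bank)
  expect_gt(nrow(orc), 1)
  expect_equal(hits$hit, orc$hit)
  expect_equal(hits$h_start, orc$h_start)
  expect_equal(hits$bc_score, orc$bc_score, tolerance = 1e-12)
  expect_equal(hits$rigidity, orc$rigidity, tolerance = 1e-12)
  mh <- mirrorSearch(q, sb$bank, nullSamples = 100)
  morc <- o_search(coords(q), sb$bank, mirror = TRUE)
  expect_gte(nrow(morc), 1)
  expect_equal(mh$hit, morc$hit)
  expect_equal(mh$h_start, morc$h_start)
  expect_equal(mh$bc_score, morc$bc_score, tolerance = 1e-12)
})

test_that("mirror search duals with fragment search of the mirrored query", {
  q <- planted_setup$q
  sb <- planted_setup$sb
  p <- searchParams(bcCutoff = 0.7)    # widen so both sets are non-trivial
  a <- mirrorSearch(q, sb$bank, p, nullSamples = 100)
  b <- fragSearch(mirrorFragment(q), sb$bank, p, nullSamples = 100)
  expect_setequal(paste(a$hit, a$h_start), paste(b$hit, b$h_start))
  expect_equal(a$rigidity[order(paste(a$hit, a$h_start))],
               b$rigidity[order(paste(b$hit, b$h_start))],
               tolerance = 1e-9)
})

test_that("thresholds are monotone and the floor cutoff keeps all windows", {
  q <- randomWalkFragment(8, seed = 33)
  sb <- syntheticBank(lapply(1:5, function(i)
    generatorSpec("random_walk", 25, seed = 40 + i)))
  loose <- fragSearch(q, sb$bank, searchParams(bcCutoff = 1e-12,
                                               rigidityCutoff = 1e6),
                      nullSamples = 100)
  # bc > 0 half of the time only; hit count at the floor equals the count
  # of windows with non-negative bc... the true no-filter count equals all
  # non-degenerate windows when rigidity is unbounded and bc cutoff ~ 0+
  # only for windows with bc >= ~0; so compare against the oracle instead
  orc <- o_search(coords(q), sb$bank, bc_cut = 1e-12, rg_cut = 1e6)
  expect_equal(nrow(loose), nrow(orc))
  key <- function(df) paste(df$hit, df$h_start)
  for (cuts in list(c(0.3, 2), c(0.6, 1), c(0.9, 0.5))) {
    tight <- fragSearch(q, sb$bank, searchParams(bcCutoff = cuts[1],
                                                 rigidityCutoff = cuts[2]),
                        nullSamples = 100)
    expect_true(all(key(tight) %in% key(loose)))
    expect_true(all(tight$bc_score >= cuts[1]))
    expect_true(all(tight$rigidity <= cuts[2]))
  }
})

test_that("a bank containing the query structure flags the self window", {
  w <- randomWalkFragment(20, seed = 91)
  dir <- tempfile()
  dir.create(dir)
  writeCaPdb(w, file.path(dir, "self.pdb"))
  writeCaPdb(randomWalkFragment(20, seed = 92), file.path(dir, "other.pdb"))
  bank <- buildFragmentBank(sort(list.files(dir, full.names = TRUE)))
  st <- readCaStructure(file.path(dir, "self.pdb"))
  q <- extractQueryFragment(st, "A:5-13")
  hits <- fragSearch(q, bank, nullSamples = 100)
  expect_true(any(hits$is_self))
  self <- hits[hits$is_self, ]
  expect_equal(self$hit, "self")
  expect_equal(self$h_start, "5")
  expect_equal(self$bc_score, 1, tolerance = 1e-9)
})

test_that("degenerate queries error; oversized windows warn empty", {
  sb <- syntheticBank(list(generatorSpec("random_walk", 12, seed = 2)))
  line <- CaFragment(cbind(seq(0, 30, length.out = 9), 0, 0))
  expect_error(fragSearch(line, sb$bank, nullSamples = 10),
               class = "bc_degeneracy_error")
  big <- randomWalkFragment(15, seed = 3)
  expect_warning(hits <- fragSearch(big, sb$bank, nullSamples = 10),
                 "exceeds every bank segment")
  expect_equal(nrow(hits), 0)
})

test_that("loop search recovers the native loop of a gaped template", {
  fx <- make_loop_fixture()
  hits <- loopSearch(fx$lq, fx$bank, nullSamples = 200)
  expect_gte(nrow(hits), 1)
  expect_equal(hits$hit[1], "T")
  expect_equal(hits$bc_score[1], 1, tolerance = 1e-3)
  expect_lt(hits$rmsd[1], 0.01)
  g <- attr(hits, "grafts")[[1]]
  expect_equal(nrow(g), fx$lq@gapLength)
  expect_lt(sqrt(mean(rowSums((g - fx$native_loop)^2))), 0.01)
})

test_that("grafting is rigid and reproduces the flank superposition", {
  fx <- make_loop_fixture()
  L <- fx$lq@gapLength
  win <- coords(fx$template)[9:21, ]           # native 4+L+4 window
  set.seed(1)
  R <- o_rotation()
  moved <- win %*% R + matrix(c(5, -3, 8), 13, 3, byrow = TRUE)
  g <- graftLoop(moved, fx$lq)
  # intra-loop distances preserved (rigid transform)
  expect_equal(as.numeric(dist(g)), as.numeric(dist(moved[5:(L + 4), ])),
               tolerance = 1e-9)
  # flank rmsd attribute equals an explicit recomputation from output
  qf <- rbind(coords(fx$lq@nFlank), coords(fx$lq@cFlank))
  sup <- kabschSuperpose(moved[c(1:4, (L + 5):(L + 8)), ], qf)
  expect_equal(attr(g, "flankRmsd"), sup$rmsd, tolerance = 1e-12)
  # native window grafted back lands on the excised loop
  g0 <- graftLoop(win, fx$lq)
  expect_lt(max(abs(g0 - fx$native_loop)), 0.01)
  expect_error(graftLoop(win[1:10, ], fx$lq), class = "bc_shape_error")
})

test_that("clash filter discards candidates near the template core", {
  fx <- make_loop_fixture()
  # far-from-everything loop passes
  far <- matrix(500 + rnorm(15), ncol = 3)
  expect_true(clashCheck(far, fx$lq))
  # 2.9 A from a template residue 10+ positions away fails
  bad <- far
  distant_row <- which(fx$lq@templatePos == 27)
  bad[3, ] <- fx$lq@templateCoords[distant_row, ] + c(2.9, 0, 0)
  expect_false(clashCheck(bad, fx$lq))
  # 2.9 A from the immediately flanking residue (separation < 3) is exempt
  near <- far
  flank_row <- which(fx$lq@templatePos == 12)   # adjacent to gap at 13
  near[1, ] <- fx$lq@templateCoords[flank_row, ] + c(2.9, 0, 0)
  expect_true(clashCheck(near, fx$lq))
  # cutoff boundary: exactly at the cutoff is not a clash (strict <)
  border <- far
  border[3, ] <- fx$lq@templateCoords[distant_row, ] + c(3.0, 0, 0)
  expect_true(clashCheck(border, fx$lq))
})

test_that("an engineered template prunes the native candidate as a clash", {
  fx <- make_loop_fixture(move_clasher = TRUE)
  hits <- loopSearch(fx$lq, fx$bank, nullSamples = 100)
  expect_false(any(hits$hit == "T"))
  expect_gte(attr(hits, "nClash"), 1)
})

test_that("loop search equals its naive oracle, clash rule included", {
  q <- make_loop_fixture(seed = 5, extra_seeds = c(8, 9))
  # add noisy copies of the native window as extra bank structures so the
  # hit set is non-trivial
  native <- CaFragment(coords(q$template)[9:21, ])
  for (i in 1:3)
    writeCaPdb(perturbFragment(native, 0.1 * i, seed = 200 + i),
               file.path(q$dir, sprintf("P%d.pdb", i)))
  paths <- sort(list.files(q$dir, full.names = TRUE))
  paths <- paths[!grepl("gaped_template", paths)]
  bank <- buildFragmentBank(paths)
  hits <- loopSearch(q$lq, bank, nullSamples = 100)
  orc <- o_loop_search(q$lq, bank)
  expect_gt(nrow(orc), 1)
  expect_equal(hits$hit, orc$hit)
  expect_equal(hits$h_start, orc$h_start)
  expect_equal(hits$bc_score, orc$bc_score, tolerance = 1e-12)
})

test_that("specificity follows sp = 1 - N_hits/N_total exactly", {
  q <- randomWalkFragment(9, seed = 5)
  qf <- tempfile(fileext = ".pdb")
  writeCaPdb(q, qf)
  st <- readCaStructure(qf)
  # window planted in 1 of 4 proteins -> sp = 0.75
  sb1 <- syntheticBank(lapply(1:4, function(i)
    generatorSpec("random_walk", 28, seed = 20 + i)),
    planted = list(fragment = q, structure = 3, offset = 8, seed = 1))
  p1 <- specificitySearch(st, sb1$bank)
  expect_equal(p1@windowScores$sp, 0.75)
  expect_equal(p1@windowScores$n_hits, 1L)
  expect_equal(p1@nTotal, 4L)
  # zero hits -> sp = 1
  sb0 <- syntheticBank(lapply(1:4, function(i)
    generatorSpec("random_walk", 28, seed = 30 + i)))
  p0 <- specificitySearch(st, sb0$bank)
  expect_equal(p0@windowScores$sp, 1)
  # every protein hits -> sp = 0 (bank of noiseless copies)
  sbA <- syntheticBank(lapply(1:3, function(i)
    generatorSpec("perturbed_copy", 9, noiseSigma = 0, seed = i, base = q)))
  pA <- specificitySearch(st, sbA$bank)
  expect_equal(pA@windowScores$sp, 0)
  # adding a matching protein strictly decreases sp
  expect_lt(p1@windowScores$sp[1], p0@windowScores$sp[1])
  # residue scores are the max over covering windows, here the single window
  expect_equal(unique(p1@residueScores$sp), 0.75)
})

test_that("specificity profile equals the naive per-window oracle", {
  q <- randomWalkFragment(16, seed = 81)
  qf <- tempfile(fileext = ".pdb")
  writeCaPdb(q, qf)
  st <- readCaStructure(qf)
  win1 <- CaFragment(coords(q)[1:9, ])
  sb <- syntheticBank(c(
    lapply(1:3, function(i) generatorSpec("random_walk", 30, seed = 85 + i)),
    list(generatorSpec("perturbed_copy", 9, noiseSigma = 0.05, seed = 9,
                       base = win1))))
  prof <- specificitySearch(st, sb$bank)
  orc <- o_specificity(st, sb$bank)
  expect_equal(prof@windowScores$sp, orc$sp)
  expect_true(all(prof@windowScores$sp >= 0 & prof@windowScores$sp <= 1,
                  na.rm = TRUE))
})

test_that("specificity respects include/exclude classification filters", {
  q <- randomWalkFragment(9, seed = 5)
  qf <- tempfile(fileext = ".pdb")
  writeCaPdb(q, qf)
  st <- readCaStructure(qf)
  specs <- lapply(1:4, function(i)
    generatorSpec("random_walk", 28, seed = 20 + i,
                  sccs = c("b.1.1.1", "b.47.1.1", "b.47.2.1", "g.3.1.1")[i]))
  sb <- syntheticBank(specs,
                      planted = list(fragment = q, structure = 1,
                                     offset = 5, seed = 2))
  # bank restricted to class b minus fold b.47: N_total = 1 (S01), 1 hit
  p <- specificitySearch(st, sb$bank, include = "b", exclude = "b.47")
  expect_equal(p@nTotal, 1L)
  expect_equal(p@windowScores$sp, 0)
  # excluding the planted carrier leaves no hits
  p2 <- specificitySearch(st, sb$bank, include = "b", exclude = "b.1")
  expect_equal(p2@nTotal, 2L)
  expect_equal(p2@windowScores$sp, 1)
  expect_error(specificitySearch(st, sb$bank, include = "zz"),
               class = "bc_empty_error")
})

test_that("searches are deterministic across repeated runs", {
  q <- planted_setup$q
  sb <- planted_setup$sb
  p <- searchParams(bcCutoff = 0.5)
  h1 <- fragSearch(q, sb$bank, p, nullSamples = 200, nullSeed = 4)
  h2 <- fragSearch(q, sb$bank, p, nullSamples = 200, nullSeed = 4)
  expect_identical(h1, h2)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  writeHitsCsv(h1, f1, p)
  writeHitsCsv(h2, f2, p)
  expect_identical(readLines(f1), readLines(f2))
})
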