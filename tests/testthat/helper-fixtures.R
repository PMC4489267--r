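# Shared fixture builders (all generated in code, nothing stored on disk).

quiet_opts <- function() options(bcmine.log.level = "error")
quiet_opts()

# a gaped-template loop-search setup with the intact template in the bank:
# returns the loop query, the bank, and the native loop coordinates
make_loop_fixture <- function(seed = 42, n = 30, gap = 13:17,
                              extra_seeds = 7, move_clasher = FALSE) {
  tmpl <- randomWalkFragment(n, seed = seed)
  dir <- tempfile("loopfix")
  dir.create(dir)
  writeCaPdb(tmpl, file.path(dir, "T.pdb"))
  for (s in extra_seeds)
    writeCaPdb(randomWalkFragment(40, seed = s),
               file.path(dir, sprintf("E%d.pdb", s)))
  bank <- buildFragmentBank(sort(list.files(dir, full.names = TRUE)))
  keep <- setdiff(seq_len(n), gap)
  co <- coords(tmpl)[keep, , drop = FALSE]
  if (move_clasher) {
    # relocate a residue far from the gap in sequence right onto the
    # native loop path, so the native graft must be clash-pruned
    target <- which(keep == 27)
    co[target, ] <- coords(tmpl)[gap[3], ] + c(1.0, 0.5, 0)
  }
  gaped <- CaFragment(co, sourceId = "gaped", resno = keep,
                      sequence = paste(strsplit(fragmentSequence(tmpl),
                                                "")[[1]][keep],
                                       collapse = ""))
  gf <- file.path(dir, "gaped_template.pdb")   # not part of the bank dir scan
  writeCaPdb(gaped, gf)
  st <- readCaStructure(gf)
  lq <- makeLoopQuery(st, fragmentSequence(tmpl))
  list(lq = lq, bank = bank, native_loop = coords(tmpl)[gap, , drop = FALSE],
       template = tmpl, gaped = st, dir = dir)
}

# minimal hand-written PDB text fixtures for parser tests
pdb_line <- function(eleno, elety, alt, resid, chain, resno, icode,
                     x, y, z, o = 1, type = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f  0.00           C",
          type, eleno, paste0(" ", elety), alt, resid, chain, resno, icode,
          x, y, z, o)
}

write_text_pdb <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}
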