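test_that("synthetic models survive a PDB write/load round trip", {
  m <- fixture("hairpin", stem = 3, loop = "GAAA")
  path <- tempfile(fileext = ".pdb")
  write_structure_pdb(m, path)
  m2 <- load_structure(path, format = "pdb")
  expect_equal(m2$nucleotides$resid, m$nucleotides$resid)
  expect_equal(m2$nucleotides$base, m$nucleotides$base)
  expect_equal(
    as.matrix(m2$atoms[, c("x", "y", "z")]),
    as.matrix(m$atoms[, c("x", "y", "z")]),
    tolerance = 1e-3, ignore_attr = TRUE
  )
})

test_that("mmCIF atom_site parsing agrees with the PDB reader", {
  m <- fixture("triple")
  cif <- tempfile(fileext = ".cif")
  res <- m$nucleotides[match(m$atoms$resid, m$nucleotides$resid), ]
  rows <- sprintf(
    "ATOM %s \"%s\" . %s %s %d ? %.3f %.3f %.3f 1.00 1",
    m$atoms$element, m$atoms$atom, res$raw_name, res$chain, res$number,
    m$atoms$x, m$atoms$y, m$atoms$z
  )
  writeLines(c(
    "data_synthetic", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.type_symbol",
    "_atom_site.auth_atom_id", "_atom_site.label_alt_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id", "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.pdbx_PDB_model_num",
    rows, "#"
  ), cif)
  mc <- load_structure(cif, format = "mmcif")
  expect_equal(mc$nucleotides$resid, m$nucleotides$resid)
  expect_equal(
    as.matrix(mc$atoms[, c("x", "y", "z")]),
    as.matrix(m$atoms[, c("x", "y", "z")]),
    tolerance = 1e-3, ignore_attr = TRUE
  )
})

test_that("waters-only input gives an empty-model error, bad files a parse error", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A 101      10.000  10.000  10.000  1.00  0.00           O",
    "END"
  ), path)
  expect_error(load_structure(path), "empty model")
  bad <- tempfile(fileext = ".pdb")
  writeLines("ATOM      1  N9    G A   1      xx.xxx   0.000   0.000", bad)
  expect_error(load_structure(bad), "parse error")
  expect_error(load_structure(tempfile()), "not found")
})

test_that("alternate locations resolve to the highest-occupancy copy", {
  path <- tempfile(fileext = ".pdb")
  g <- ideal_base("G")
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s%2s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(g)), ifelse(nchar(g$atom) < 4, paste0(" ", g$atom), g$atom),
    "G", "A", 1, g$x, g$y, g$z, 1, 0, g$element
  )
  # N9 in two altlocs: B has higher occupancy and a shifted position
  n9 <- g[g$atom == "N9", ]
  alt <- c(
    sprintf("ATOM  %5d  N9 AG  A   1    %8.3f%8.3f%8.3f%6.2f%6.2f           N",
      100L, n9$x, n9$y, n9$z, 0.4, 0),
    sprintf("ATOM  %5d  N9 BG  A   1    %8.3f%8.3f%8.3f%6.2f%6.2f           N",
      101L, n9$x + 1, n9$y, n9$z, 0.6, 0)
  )
  writeLines(c(lines[g$atom != "N9"], alt, "END"), path)
  m <- load_structure(path)
  got <- m$atoms[m$atoms$atom == "N9", ]
  expect_equal(nrow(got), 1)
  expect_equal(got$x, n9$x + 1, tolerance = 1e-3)
})

test_that("residue names standardise to parent bases", {
  expect_equal(standardize_base(c("G", "a", "PSU", "5MC", "XYZ")),
    c("G", "A", "U", "C", "UNKNOWN"))
})

test_that("modified residues keep numbering and appear as parent base in sequences", {
  u <- ideal_base("U")
  path <- tempfile(fileext = ".pdb")
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s%2s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(u)), ifelse(nchar(u$atom) < 4, paste0(" ", u$atom), u$atom),
    "PSU", "A", 5, u$x, u$y, u$z, 1, 0, u$element
  )
  writeLines(c(lines, "END"), path)
  m <- load_structure(path)
  expect_equal(m$nucleotides$base, "U")
  expect_true(m$nucleotides$is_modified)
  es <- extract_sequence(m)
  expect_equal(es$sequence, "U")
  expect_true(es$map$is_modified)
})

test_that("base frames are planar, ring-winding oriented, and equivariant", {
  m <- fixture("triple")
  f <- compute_base_frame(m, "A:1")
  expect_lt(f$rms, 0.01)
  expect_equal(sum(f$normal^2), 1, tolerance = 1e-9)
  expect_equal(sum(f$normal * f$x_axis), 0, tolerance = 1e-6)
  expect_equal(sum(f$normal * f$y_axis), 0, tolerance = 1e-6)

  set.seed(11)
  tr <- ribomotifs:::.random_rigid()
  m2 <- transform_structure(m, tr$R, tr$t)
  f2 <- compute_base_frame(m2, "A:1")
  rn <- as.numeric(tr$R %*% f$normal)
  expect_lt(min(
    sqrt(sum((f2$normal - rn)^2)), sqrt(sum((f2$normal + rn)^2))
  ), 1e-6)
})

test_that("frames in an A-form-like helix strand agree in hemisphere", {
  m <- fixture("helix", n_pairs = 4)
  fr <- base_frames(m)
  n1 <- fr[["A:1"]]$normal
  for (r in c("A:2", "A:3", "A:4")) {
    expect_gt(sum(n1 * fr[[r]]$normal), 0)
  }
})

test_that("too few ring atoms yields a frame-unavailable error", {
  g <- ideal_base("G")
  keep <- g[g$atom %in% c("N9", "C8", "N7", "C1'", "C2'", "O2'", "C4'"), ]
  m <- ribomotifs:::.assemble_model(list(
    list(chain = "A", number = 1, base = "G", atoms = keep)
  ))
  expect_error(compute_base_frame(m, "A:1"), "frame unavailable")
  fr <- base_frames(m)
  expect_equal(attr(fr, "unavailable"), "A:1")
})

test_that("sequence extraction maps residues in order and handles chain selection", {
  m <- fixture("hairpin", stem = 4, loop = "GAAA")
  es <- extract_sequence(m)
  expect_equal(nchar(es$sequence), nrow(m$nucleotides))
  expect_equal(nrow(es$map), nrow(m$nucleotides))
  expect_equal(es$map$resid, m$nucleotides$resid)
  expect_equal(extract_sequence(m, "")$sequence, es$sequence)
  expect_error(extract_sequence(m, "Z"), "chain not found")
})

test_that("sequence extraction is stable under atom-order permutation", {
  m <- fixture("hairpin", stem = 3, loop = "GAAA")
  path <- tempfile(fileext = ".pdb")
  write_structure_pdb(m, path)
  lines <- readLines(path)
  atom <- grepl("^ATOM", lines)
  set.seed(42)
  shuffled <- c(sample(lines[atom]), lines[!atom])
  path2 <- tempfile(fileext = ".pdb")
  writeLines(shuffled, path2)
  m2 <- load_structure(path2)
  expect_equal(extract_sequence(m2)$sequence, extract_sequence(m)$sequence)
  expect_equal(m2$nucleotides$resid, m$nucleotides$resid)
})
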