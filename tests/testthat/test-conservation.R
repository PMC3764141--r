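toy_stockholm <- function(path, rows = NULL, gc = NULL) {
  if (is.null(rows)) {
    rows <- c("seq1  AUGC-A", "seq2  AUGCCA", "seq3  auGctA")
  }
  writeLines(c("# STOCKHOLM 1.0", rows, gc, "//"), path)
  path
}

test_that("Stockholm parsing normalises the alphabet and keeps GC lines", {
  p <- toy_stockholm(tempfile(), gc = "#=GC SS_cons  <<..>>")
  a <- read_stockholm(p)
  expect_equal(length(a$ids), 3)
  expect_equal(a$ncols, 6)
  expect_equal(a$seqs[3], "AUGCUA") # case folded, T -> U
  expect_equal(a$gc$SS_cons, "<<..>>")
})

test_that("malformed Stockholm input fails with a line-level parse error", {
  p <- toy_stockholm(tempfile(), rows = c("seq1  AUGC", "seq2  AUG"))
  expect_error(read_stockholm(p), "columns")
  p2 <- tempfile()
  writeLines(c("seq1 AUGC"), p2)
  expect_error(read_stockholm(p2), "STOCKHOLM")
})

test_that("Stockholm files round-trip through the writer", {
  a <- make_alignment(8, 12, c(1, 0.75), seed = 4)
  a$gc$SS_cons <- paste(rep(".", 12), collapse = "")
  p <- tempfile()
  write_stockholm(a, p)
  b <- read_stockholm(p)
  expect_equal(b$seqs, a$seqs)
  expect_equal(b$ids, a$ids)
  expect_equal(b$gc$SS_cons, a$gc$SS_cons)
})

test_that("column profiles implement the strict more-than-95% rule", {
  a <- make_alignment(20, 3, c(1, 0.95, 0.6), seed = 2)
  pr <- column_profiles(a)
  expect_true(pr$conserved[1])
  expect_equal(pr$modal_fraction[2], 0.95)
  expect_false(pr$conserved[2]) # 19 of 20 is NOT more than 95%
  expect_false(pr$conserved[3])
})

test_that("planted conservation vectors are recovered for arbitrary seeds", {
  for (seed in c(1, 17, 4242)) {
    fr <- c(1, 0.9, 0.75, 1, 0.55, 0.8, 1, 0.65)
    a <- make_alignment(20, length(fr), fr, seed = seed)
    pr <- column_profiles(a)
    expect_equal(pr$modal_fraction, fr, info = paste("seed", seed))
    expect_equal(sum(pr$conserved), sum(fr > 0.95))
  }
})

test_that("profiles are invariant under row permutation", {
  a <- make_alignment(15, 6, c(1, 0.8, 0.6), seed = 9)
  set.seed(1)
  perm <- sample(length(a$ids))
  b <- a
  b$ids <- a$ids[perm]
  b$seqs <- a$seqs[perm]
  expect_equal(column_profiles(b), column_profiles(a))
})

test_that("gap-denominator choice changes what can be conserved", {
  a <- structure(list(
    ids = paste0("s", 1:4),
    seqs = c("A-", "A-", "A-", "-U"), ncols = 2, gc = list(),
    insert = c(FALSE, FALSE)
  ), class = "stockholm_alignment")
  with_gaps <- column_profiles(a, threshold = 0.95)
  without <- column_profiles(a, threshold = 0.95, gap_denominator = FALSE)
  expect_false(with_gaps$conserved[1])
  expect_true(without$conserved[1]) # 3/3 of non-gap rows
})

test_that("inserting an existing sequence copies its gap pattern exactly", {
  a <- make_alignment(6, 15, c(1, 0.7), seed = 12)
  # introduce a gap column pattern by hand
  a$seqs[2] <- paste0(substr(a$seqs[2], 1, 6), "---",
    substr(a$seqs[2], 10, 15))
  s <- gsub("-", "", a$seqs[2])
  ins <- insert_sequence(a, s, id = "copy")
  expect_equal(ins$alignment$ncols, a$ncols)
  expect_equal(sum(ins$map$insert), 0)
  expect_equal(ins$alignment$seqs[ins$row], a$seqs[2])
  # idempotent: inserting again changes nothing about the layout
  ins2 <- insert_sequence(ins$alignment, s, id = "copy2")
  expect_equal(ins2$alignment$ncols, a$ncols)
})

test_that("an extra residue creates exactly one flagged insert column", {
  a <- make_alignment(5, 10, 1, seed = 3)
  s <- gsub("-", "", a$seqs[1])
  s2 <- paste0(substr(s, 1, 4), "A", substr(s, 5, 10))
  ins <- insert_sequence(a, s2)
  expect_equal(ins$alignment$ncols, 11)
  expect_equal(sum(ins$alignment$insert), 1)
  expect_equal(which(ins$alignment$insert), 5)
  expect_equal(ins$map$column, 1:11)
  expect_equal(ins$map$insert, seq_len(11) == 5)
  # all other rows are gapped in the insert column
  expect_true(all(substr(ins$alignment$seqs[1:5], 5, 5) == "-"))
})

test_that("inserting into an empty alignment or empty sequence errors", {
  a <- structure(list(ids = character(0), seqs = character(0), ncols = 0,
    gc = list(), insert = logical(0)), class = "stockholm_alignment")
  expect_error(insert_sequence(a, "ACGU"), "empty alignment")
  b <- make_alignment(4, 6, 1, seed = 1)
  expect_error(insert_sequence(b, ""), "empty sequence")
})

test_that("motif conservation classes follow the fully/highly/variable rules", {
  resmap <- data.frame(
    resid = c("A:1", "A:2", "A:3"), column = 1:3,
    insert = FALSE, base = c("A", "G", "C"), stringsAsFactors = FALSE
  )
  prof <- function(frac, modal = c("A", "G", "C")) {
    data.frame(column = 1:3, modal_base = modal, modal_fraction = frac,
      stringsAsFactors = FALSE)
  }
  expect_equal(motif_conservation(c("A:1", "A:2", "A:3"), resmap,
    prof(c(1, 1, 1)))$class, "fully_conserved")
  expect_equal(motif_conservation(c("A:1", "A:2", "A:3"), resmap,
    prof(c(1, 0.96, 1)))$class, "highly_conserved")
  expect_equal(motif_conservation(c("A:1", "A:2", "A:3"), resmap,
    prof(c(1, 0.6, 1)))$class, "variable")
  # 100% columns whose modal base differs from the structure are not "fully"
  expect_equal(motif_conservation(c("A:1", "A:2", "A:3"), resmap,
    prof(c(1, 1, 1), modal = c("A", "G", "U")))$class, "highly_conserved")
  expect_warning(
    out <- motif_conservation("A:9", resmap, prof(c(1, 1, 1))),
    "unmapped"
  )
  expect_equal(out$class, "unassessed")
})

test_that("structure residues map onto the planted alignment columns", {
  m <- fixture("hairpin", stem = 3, loop = "GAAA")
  s <- extract_sequence(m)$sequence
  # alignment whose first row is the structure sequence itself
  a <- make_alignment(10, nchar(s), 1, seed = 6)
  chars <- strsplit(s, "")[[1]]
  a$seqs <- vapply(a$seqs, function(x) s, character(1), USE.NAMES = FALSE)
  mp <- map_structure_to_alignment(m, a)
  expect_equal(nrow(mp$map), nrow(m$nucleotides))
  expect_equal(mp$map$column, seq_along(chars))
  expect_false(any(mp$map$insert))
  pr <- column_profiles(mp$alignment)
  mc <- motif_conservation(c("A:1", "A:2"), mp$map, pr)
  expect_equal(mc$class, "fully_conserved")
})

test_that("alignments with planted fractions are infeasible when not strictly modal", {
  expect_error(make_alignment(8, 2, c(1, 0.25), seed = 1), "infeasible")
})
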