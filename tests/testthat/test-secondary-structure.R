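test_that("already nested pairs are kept whole; crossing pairs are split", {
  m <- toy_model(16)
  p <- toy_pairs(c(1, 2, 3), c(10, 9, 8))
  r <- nested_skeleton(p, m)
  expect_equal(nrow(r$skeleton), 3)
  expect_equal(nrow(r$remainder), 0)

  p <- toy_pairs(c(2, 6), c(11, 16))
  r <- nested_skeleton(p, m)
  expect_equal(nrow(r$skeleton), 1)
  expect_equal(nrow(r$remainder), 1)
  # equal hydrogen-bond counts: the 5'-earlier pair wins
  expect_equal(r$skeleton$res_a, "A:2")
  # more bonds win over lexicographic order
  p$n_hbonds <- c(2, 3)
  r <- nested_skeleton(p, m)
  expect_equal(r$skeleton$res_a, "A:6")
})

test_that("skeleton DP cardinality matches exhaustive search on random pair sets", {
  noncrossing_ok <- function(lo, hi) {
    n <- length(lo)
    if (n <= 1) return(TRUE)
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        if (lo[a] < lo[b] && lo[b] < hi[a] && hi[a] < hi[b]) return(FALSE)
        if (lo[b] < lo[a] && lo[a] < hi[b] && hi[b] < hi[a]) return(FALSE)
      }
    }
    TRUE
  }
  set.seed(202)
  for (trial in 1:8) {
    npairs <- sample(6:11, 1)
    lo <- hi <- integer(npairs)
    for (k in seq_len(npairs)) {
      ij <- sort(sample(1:14, 2))
      lo[k] <- ij[1]; hi[k] <- ij[2]
    }
    m <- toy_model(14)
    p <- toy_pairs(lo, hi)
    got <- nrow(nested_skeleton(p, m)$skeleton)
    best <- 0
    for (mask in 0:(2^npairs - 1)) {
      sel <- which(bitwAnd(mask, 2^(seq_len(npairs) - 1)) > 0)
      if (length(sel) <= best) next
      used <- c(lo[sel], hi[sel])
      if (anyDuplicated(used)) next
      if (noncrossing_ok(lo[sel], hi[sel])) best <- length(sel)
    }
    expect_equal(got, best, info = paste("trial", trial))
  }
})

test_that("a single hairpin labels as P1 + L1 with no junctions", {
  a <- annotated("hairpin", stem = 4, loop = "GAAA")
  ss <- a$ss
  expect_equal(ss$stems$label, "P1")
  expect_equal(sum(vapply(ss$loops, function(l) l$kind == "hairpin",
    logical(1))), 1)
  expect_equal(length(ss$junctions), 0)
  expect_equal(unname(ss$element_of[c("A:5", "A:6")]), c("L1", "L1"))
})

test_that("cloverleaf topology labels three stems and wraparound junctions", {
  # closing stem (1,40)..(3,38), children (6,15)..(8,13) and (20,29)..(22,27)
  m <- toy_model(40)
  p <- toy_pairs(
    c(1, 2, 3, 6, 7, 8, 20, 21, 22),
    c(40, 39, 38, 15, 14, 13, 29, 28, 27)
  )
  sk <- nested_skeleton(p, m)$skeleton
  ss <- build_elements(sk, m)
  expect_setequal(ss$stems$label, c("P1", "P2", "P3"))
  labs <- vapply(ss$junctions, function(j) j$label, character(1))
  expect_setequal(labs, c("J1-2", "J2-3", "J3-1"))
  expect_equal(unname(ss$element_of["A:4"]), "J1-2")
  expect_equal(unname(ss$element_of["A:17"]), "J2-3")
  expect_equal(unname(ss$element_of["A:31"]), "J3-1")
  # hairpin loops take their stem group number
  expect_equal(unname(ss$element_of["A:10"]), "L2")
  expect_equal(unname(ss$element_of["A:24"]), "L3")
})

test_that("sub-stems separated by internal loops share a number with letters", {
  # P1a (1..2 / 19..20), internal loop, P1b (5..6 / 15..16), hairpin
  m <- toy_model(20)
  p <- toy_pairs(c(1, 2, 5, 6), c(20, 19, 16, 15))
  ss <- build_elements(nested_skeleton(p, m)$skeleton, m)
  expect_setequal(ss$stems$label, c("P1a", "P1b"))
  expect_equal(unname(ss$element_of["A:3"]), "IL1")
  expect_equal(unname(ss$kind_of["A:3"]), "internal")
})

test_that("every residue maps to exactly one element", {
  for (a in list(annotated("hairpin", stem = 3, loop = "GAAA"),
    annotated("kissing"), annotated("pseudoknot"))) {
    eo <- a$ss$element_of
    expect_setequal(names(eo), a$model$nucleotides$resid)
    expect_false(any(is.na(eo)))
  }
})

test_that("stem naming is invariant to pair-list input order", {
  m <- toy_model(40)
  p <- toy_pairs(
    c(1, 2, 3, 6, 7, 8, 20, 21, 22),
    c(40, 39, 38, 15, 14, 13, 29, 28, 27)
  )
  ss1 <- build_elements(nested_skeleton(p, m)$skeleton, m)
  set.seed(5)
  p2 <- p[sample(nrow(p)), ]
  ss2 <- build_elements(nested_skeleton(p2, m)$skeleton, m)
  expect_equal(ss1$element_of, ss2$element_of)
})

test_that("context strings render the element kinds the published way", {
  m <- toy_model(40)
  p <- toy_pairs(
    c(1, 2, 3, 6, 7, 8, 20, 21, 22),
    c(40, 39, 38, 15, 14, 13, 29, 28, 27)
  )
  ss <- build_elements(nested_skeleton(p, m)$skeleton, m)
  expect_equal(classify_context(c("A:4", "A:17"), ss),
    "Interaction between junctions (J1-2 & J2-3)")
  expect_equal(classify_context(c("A:4", "A:5"), ss),
    "Interaction within junction (J1-2)")
  expect_equal(classify_context(c("A:6", "A:17"), ss),
    "Helix - junction interaction (P2 & J2-3)")
  expect_equal(classify_context(c("A:7", "A:10"), ss),
    "Helix - hairpin loop interaction (P2 & L2)")
  expect_equal(classify_context(c("A:10", "A:24"), ss),
    "Hairpin loop - hairpin loop interaction (L2 & L3)")
  expect_equal(classify_context(c("A:6", "A:7"), ss),
    "Helix - helix interaction (P2)")
  expect_equal(classify_context(c("A:6", "A:21"), ss),
    "Helix - helix interaction (P2 & P3)")
  expect_warning(out <- classify_context("A:99", ss), "unmapped")
  expect_equal(out, "unassigned")
})

test_that("bulged-out residues render with their host helix", {
  # stem with a one-residue bulge: P1a/P1b with a bulge at 4
  m <- toy_model(20)
  p <- toy_pairs(c(1, 2, 3, 5, 6), c(20, 19, 18, 17, 16))
  ss <- build_elements(nested_skeleton(p, m)$skeleton, m)
  expect_equal(unname(ss$kind_of["A:4"]), "bulge")
  expect_equal(classify_context(c("A:4", "A:5"), ss),
    "Bulged-out residue - helix interaction (P1)")
})

test_that("dot-bracket layers nested and crossing pairs", {
  a <- annotated("pseudoknot")
  db <- dot_bracket(a$model, a$skeleton, a$remainder)
  expect_equal(nchar(db), nrow(a$model$nucleotides))
  expect_true(grepl("\\[", db))
  counts <- table(strsplit(db, "")[[1]])
  expect_equal(unname(counts["("]), unname(counts[")"]))
  expect_equal(unname(counts["["]), unname(counts["]"]))
})
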