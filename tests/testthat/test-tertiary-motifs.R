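test_that("a planar docked AGC triple is detected once, tilted not at all", {
  a <- annotated("triple")
  tr <- detect_triples(a$model, a$pairs, a$frames, cfg, a$ss)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$composition, "ACG")
  expect_equal(tr$display_composition, "AGC")
  expect_true(tr$contains_wc)
  expect_lt(tr$planarity, cfg$triple_planarity_max)

  b <- annotated("triple", tilt = 60)
  expect_equal(nrow(detect_triples(b$model, b$pairs, b$frames, cfg)), 0)
})

test_that("every emitted triple re-passes both filter clauses independently", {
  a <- annotated("triple")
  tr <- a$triples
  hb <- a$hbonds
  for (i in seq_len(nrow(tr))) {
    trio <- c(tr$res1[i], tr$res2[i], tr$res3[i])
    # planarity clause
    for (pair in list(trio[1:2], trio[2:3], trio[c(1, 3)])) {
      n1 <- a$frames[[pair[1]]]$normal
      n2 <- a$frames[[pair[2]]]$normal
      ang <- acos(min(1, abs(sum(n1 * n2)))) * 180 / pi
      expect_lte(ang, cfg$triple_planarity_max)
    }
    # two-bonds-per-pairing clause, recounted straight from the bond table
    pairings <- strsplit(tr$pairings[i], ";")[[1]]
    expect_gte(length(pairings), 2)
    for (pk in pairings) {
      rr <- strsplit(pk, " ")[[1]]
      nb <- sum(
        (hb$res_i == rr[1] & hb$res_j == rr[2]) &
          hb$donor_moiety == "base" & hb$acceptor_moiety == "base"
      )
      expect_gte(nb, 2)
    }
  }
})

test_that("triples equal brute-force enumeration over all residue triples", {
  for (kind in list(list("triple"), list("helix", n_pairs = 4),
    list("kinkturn"))) {
    a <- do.call(annotated, kind)
    got <- if (nrow(a$triples) == 0) character(0) else
      paste(a$triples$res1, a$triples$res2, a$triples$res3)
    pairs_key <- paste(pmin(a$pairs$res_a, a$pairs$res_b),
      pmax(a$pairs$res_a, a$pairs$res_b))
    resids <- a$model$nucleotides$resid
    want <- character(0)
    if (length(resids) >= 3) {
      cmb <- utils::combn(resids, 3)
      for (q in seq_len(ncol(cmb))) {
        trio <- cmb[, q]
        pk <- utils::combn(trio, 2)
        present <- paste(pmin(pk[1, ], pk[2, ]), pmax(pk[1, ], pk[2, ])) %in%
          pairs_key
        if (sum(present) < 2) next
        # one residue must pair with both others
        deg <- vapply(trio, function(r) {
          sum(present & apply(pk, 2, function(x) r %in% x))
        }, numeric(1))
        if (max(deg) < 2) next
        fr <- a$frames[trio]
        if (any(vapply(fr, is.null, logical(1)))) next
        angs <- utils::combn(3, 2, function(ij) {
          n1 <- fr[[ij[1]]]$normal; n2 <- fr[[ij[2]]]$normal
          ang <- acos(min(1, abs(sum(n1 * n2)))) * 180 / pi
          ang
        })
        if (max(angs) > cfg$triple_planarity_max) next
        want <- c(want, paste(trio, collapse = " "))
      }
    }
    expect_setequal(got, want)
  }
})

test_that("triples sharing a pairing merge into a quadruple; disjoint ones do not", {
  tri <- data.frame(
    res1 = c("A:1", "A:1"), res2 = c("A:2", "A:2"), res3 = c("A:3", "A:4"),
    stringsAsFactors = FALSE
  )
  pairs <- toy_pairs(c(1, 1, 1), c(2, 3, 4))
  q <- detect_quadruples(tri, pairs)
  expect_equal(nrow(q), 1)
  expect_setequal(unlist(q[1, c("res1", "res2", "res3", "res4")]),
    c("A:1", "A:2", "A:3", "A:4"))

  tri2 <- data.frame(
    res1 = c("A:1", "A:5"), res2 = c("A:2", "A:6"), res3 = c("A:3", "A:7"),
    stringsAsFactors = FALSE
  )
  expect_equal(nrow(detect_quadruples(tri2, pairs)), 0)
})

test_that("A-minor types and variants recover their planted fixtures", {
  for (ty in c("I", "II", "0")) {
    a <- annotated("aminor", type = ty)
    am <- detect_a_minor(a$model, a$pairs, a$hbonds, cfg)
    expect_equal(nrow(am), 1, info = paste("type", ty))
    expect_equal(am$type, ty)
    expect_equal(am$donor, "A:10")
    expect_equal(am$receptor_label, "GC")
    expect_equal(am$variant, "A-minor")
  }
  g <- annotated("aminor", type = "I", donor_base = "G")
  am <- detect_a_minor(g$model, g$pairs, g$hbonds, cfg)
  expect_equal(am$variant, "G-minor")
  expect_equal(am$donor_base, "G")
})

test_that("ribose zipper classes recover and a single bond is rejected", {
  for (zc in c("canonical", "pseudo-cis")) {
    a <- annotated("zipper", zclass = zc)
    z <- detect_ribose_zipper(a$model, a$hbonds, cfg, a$pairs)
    expect_equal(nrow(z), 1, info = zc)
    expect_equal(z$zclass, zc)
    expect_setequal(
      unlist(z[1, c("strand1_a", "strand1_b", "strand2_a", "strand2_b")]),
      c("A:1", "A:2", "A:10", "A:11")
    )
  }
  a1 <- annotated("zipper", n_bonds = 1)
  expect_equal(nrow(detect_ribose_zipper(a1$model, a1$hbonds, cfg, a1$pairs)), 0)
  # a plain helix zips nothing
  h <- annotated("helix", n_pairs = 4)
  expect_equal(nrow(detect_ribose_zipper(h$model, h$hbonds, cfg, h$pairs)), 0)
})

test_that("pseudoknots come from the crossing remainder with the H-type flag", {
  a <- annotated("pseudoknot")
  pk <- detect_pseudoknots(a$model, a$skeleton, a$remainder, a$ss)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$n_pairs, 2)
  expect_true(pk$htype)
  # nested-only input: empty
  h <- annotated("hairpin", stem = 3, loop = "GAAA")
  expect_equal(nrow(detect_pseudoknots(h$model, h$skeleton, h$remainder,
    h$ss)), 0)
})

test_that("pair crossing test agrees with the brute-force index scan", {
  set.seed(77)
  for (trial in 1:20) {
    ij <- sort(sample(1:30, 2)); kl <- sort(sample(1:30, 2))
    got <- ribomotifs:::.crossing(ij[1], ij[2], kl[1], kl[2])
    want <- (ij[1] < kl[1] && kl[1] < ij[2] && ij[2] < kl[2]) ||
      (kl[1] < ij[1] && ij[1] < kl[2] && kl[2] < ij[2])
    expect_equal(got, want)
  }
})

test_that("kissing loops need two inter-loop pairs between distinct hairpins", {
  a <- annotated("kissing")
  ki <- detect_kissing_loops(a$model, a$pairs, a$ss, cfg)
  expect_equal(nrow(ki), 1)
  expect_setequal(c(ki$loop_a, ki$loop_b), c("L1", "L2"))
  expect_equal(ki$n_pairs, 3)
  one <- annotated("kissing", n_kiss = 1)
  expect_equal(nrow(detect_kissing_loops(one$model, one$pairs, one$ss, cfg)), 0)
})

test_that("the kink-turn pattern requires sheared G-A pairs, a bulge and a bend", {
  a <- annotated("kinkturn")
  kt <- detect_kink_turn(a$model, a$pairs, a$ss, cfg, a$a_minors)
  expect_equal(nrow(kt), 1)
  expect_equal(kt$c_stem, "P1")
  expect_equal(sort(strsplit(kt$bulge, ";")[[1]]), c("A:4", "A:5", "A:6"))
  expect_lt(kt$axis_angle, cfg$kink_axis_angle_max)
  h <- annotated("helix", n_pairs = 5)
  expect_equal(nrow(detect_kink_turn(h$model, h$pairs, h$ss, cfg)), 0)
})

test_that("loop-receptor interactions require an A-minor from a short loop", {
  a <- annotated("loop_receptor")
  lr <- detect_loop_receptor(a$model, a$ss, a$a_minors, a$zippers, cfg)
  expect_equal(nrow(lr), 1)
  expect_equal(lr$loop, "L1")
  expect_equal(lr$loop_size, 4)
  expect_equal(lr$receptor_stem, "P2")
  expect_true(nzchar(lr$zipper))
  b <- annotated("loop_receptor", with_aminor = FALSE)
  expect_equal(nrow(detect_loop_receptor(b$model, b$ss, b$a_minors,
    b$zippers, cfg)), 0)
  # ... even though the zipper itself is still there
  expect_gte(nrow(b$zippers), 1)
})

test_that("motif lists are duplicate-free and invariant to model reversal", {
  a <- annotated("kinkturn")
  tr <- a$triples
  key <- apply(tr[, c("res1", "res2", "res3")], 1, function(r) {
    paste(sort(r), collapse = "|")
  })
  expect_false(any(duplicated(key)))
  am_key <- paste(a$a_minors$donor, a$a_minors$receptor_a, a$a_minors$receptor_b)
  expect_false(any(duplicated(am_key)))
})
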