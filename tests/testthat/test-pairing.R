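test_that("ideal Watson-Crick pairs give the textbook hydrogen bonds", {
  pr <- place_pair("G", "C", "WC")
  m <- ribomotifs:::.assemble_model(list(
    list(chain = "A", number = 1, base = "G", atoms = pr$res1),
    list(chain = "A", number = 2, base = "C", atoms = pr$res2)
  ))
  hb <- detect_hbonds(m, cfg)
  bb <- hb[hb$donor_moiety == "base" & hb$acceptor_moiety == "base", ]
  got <- sort(paste(bb$donor_atom, bb$acceptor_atom))
  expect_equal(got, sort(c("N4 O6", "N1 N3", "N2 O2")))
  expect_true(all(bb$distance >= 2.8 & bb$distance <= 3.0))

  pr <- place_pair("A", "U", "WC")
  m <- ribomotifs:::.assemble_model(list(
    list(chain = "A", number = 1, base = "A", atoms = pr$res1),
    list(chain = "A", number = 2, base = "U", atoms = pr$res2)
  ))
  hb <- detect_hbonds(m, cfg)
  bb <- hb[hb$donor_moiety == "base" & hb$acceptor_moiety == "base", ]
  expect_equal(sort(paste(bb$donor_atom, bb$acceptor_atom)),
    sort(c("N6 O4", "N3 N1")))
})

test_that("distant bases give no hydrogen bonds", {
  g <- ideal_base("G")
  c20 <- ribomotifs:::.df_translate(ideal_base("C"), c(20, 0, 0))
  m <- ribomotifs:::.assemble_model(list(
    list(chain = "A", number = 1, base = "G", atoms = g),
    list(chain = "A", number = 2, base = "C", atoms = c20)
  ))
  expect_equal(nrow(detect_hbonds(m, cfg)), 0)
})

test_that("pair classification assigns edges, orientation and flags", {
  a <- annotated("triple")
  p <- a$pairs
  gc <- p[p$res_a == "A:1" & p$res_b == "A:2", ]
  expect_equal(gc$edge_a, "WatsonCrick")
  expect_equal(gc$edge_b, "WatsonCrick")
  expect_equal(gc$orientation, "cis")
  expect_true(gc$canonical)
  expect_false(gc$wobble)
  expect_equal(gc$n_hbonds, 3)

  ga <- p[p$res_a == "A:1" & p$res_b == "A:3", ]
  expect_equal(ga$edge_a, "Sugar")
  expect_equal(ga$edge_b, "Hoogsteen")
  expect_false(ga$canonical)
})

test_that("wobble pairs are flagged and excluded from canonical", {
  pr <- place_pair("G", "U", "GU_wobble")
  m <- ribomotifs:::.assemble_model(list(
    list(chain = "A", number = 1, base = "G", atoms = pr$res1),
    list(chain = "A", number = 2, base = "U", atoms = pr$res2)
  ))
  p <- detect_base_pairs(m, cfg)
  expect_true(p$wobble)
  expect_false(p$canonical)
})

test_that("a single hydrogen bond is not a pair", {
  # pull the third base of the triple fixture but strip one of its two
  # bonded atoms so only one bond remains
  m <- fixture("triple")
  m$atoms <- m$atoms[!(m$atoms$resid == "A:3" & m$atoms$atom == "N7"), ]
  hb <- detect_hbonds(m, cfg)
  expect_null(classify_pair(m, "A:1", "A:3", hb, cfg))
})

test_that("a synthetic 4-bp helix yields exactly 4 canonical pairs", {
  a <- annotated("helix", n_pairs = 4)
  expect_equal(nrow(a$pairs), 4)
  expect_true(all(a$pairs$canonical))
})

test_that("the triple fixture has two pairs sharing the central base", {
  a <- annotated("triple")
  expect_equal(nrow(a$pairs), 2)
  expect_equal(sum(c(a$pairs$res_a, a$pairs$res_b) == "A:1"), 2)
})

test_that("detected pairs equal a brute-force all-pairs classify_pair scan", {
  for (kind in list(list("triple"), list("helix", n_pairs = 4),
    list("aminor", type = "I"))) {
    m <- do.call(fixture, kind)
    frames <- base_frames(m)
    hb <- detect_hbonds(m, cfg, frames)
    p <- detect_base_pairs(m, cfg, hb, frames)
    got <- paste(p$res_a, p$res_b)
    resids <- m$nucleotides$resid
    want <- character(0)
    for (i in seq_along(resids)) {
      for (j in seq_along(resids)) {
        if (i >= j) next
        r <- classify_pair(m, resids[i], resids[j], hb, cfg, frames)
        if (!is.null(r)) want <- c(want, paste(r$res_a, r$res_b))
      }
    }
    expect_setequal(got, want)
  }
})

test_that("pairs are invariant under rigid transforms of the model", {
  m <- fixture("triple")
  p0 <- detect_base_pairs(m, cfg)
  set.seed(99)
  for (rep in 1:3) {
    tr <- ribomotifs:::.random_rigid()
    m2 <- transform_structure(m, tr$R, tr$t)
    p2 <- detect_base_pairs(m2, cfg)
    expect_equal(p2[, names(p2) != "planarity"], p0[, names(p0) != "planarity"],
      tolerance = 1e-6)
    expect_equal(p2$planarity, p0$planarity, tolerance = 1e-3)
  }
})

test_that("pair detection is invariant to residue-order reversal of the input", {
  m <- fixture("triple")
  m2 <- m
  ord <- rev(seq_len(nrow(m2$nucleotides)))
  m2$nucleotides <- m2$nucleotides[ord, ]
  rownames(m2$nucleotides) <- NULL
  m2$atoms <- m2$atoms[order(match(m2$atoms$resid, m2$nucleotides$resid)), ]
  p1 <- detect_base_pairs(m, cfg)
  p2 <- detect_base_pairs(m2, cfg)
  key <- function(p) sort(paste(pmin(p$res_a, p$res_b), pmax(p$res_a, p$res_b)))
  expect_equal(key(p1), key(p2))
})
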