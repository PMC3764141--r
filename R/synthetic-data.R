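# Synthetic geometry and alignment generator.  Builds idealised
# nucleotides, base pairs placed to standard hydrogen-bond distances,
# A-form-like helices and planted tertiary motifs with known ground
# truth, so that every detector can be exercised (and falsified) without
# downloading structures.  Fixtures are written as minimal PDB files and
# re-loaded, so the structure parser is part of every closure test.

.template_oriented <- local({
  cache <- new.env(parent = emptyenv())
  function(base) {
    if (!is.null(cache[[base]])) return(cache[[base]])
    if (!base %in% names(.base_templates)) stop("unknown base: ", base)
    df <- .base_templates[[base]]
    xyz <- as.matrix(df[, c("x", "y", "z")])
    ring <- match(.ring_atoms[[base]], df$atom)
    fit <- .fit_plane(xyz[ring, ])
    n <- fit$normal
    w <- .cross3(xyz[ring[1], ] - fit$centroid, xyz[ring[2], ] - fit$centroid)
    if (sum(n * w) < 0) n <- -n
    gly <- xyz[match(.glycosidic_atom[[base]], df$atom), ]
    vx <- gly - fit$centroid
    vx <- .unit(vx - sum(vx * n) * n)
    R <- rbind(vx, .cross3(n, vx), n) # rows: new x, y, z axes
    xyz2 <- sweep(xyz, 2, fit$centroid) %*% t(R)
    out <- df
    out[, c("x", "y", "z")] <- xyz2
    cache[[base]] <- out
    out
  }
})

#' Idealised heavy-atom template of a standard base
#'
#' Planar heavy-atom template with standard bond geometry including the
#' ribose and phosphate atoms, oriented with the base-ring centroid at
#' the origin and the base plane in z = 0.
#'
#' @param base one of `"A"`, `"C"`, `"G"`, `"U"`.
#' @return data frame with columns `atom`, `element`, `x`, `y`, `z`.
#' @export
ideal_base <- function(base) {
  if (!is.character(base) || length(base) != 1 ||
    !base %in% names(.base_templates)) {
    stop("unknown base: ", paste(base, collapse = ","))
  }
  .template_oriented(base)
}

.df_coords <- function(df) as.matrix(df[, c("x", "y", "z")])

.df_set_coords <- function(df, xyz) {
  df[, c("x", "y", "z")] <- xyz
  df
}

.df_transform <- function(df, R, t = c(0, 0, 0)) {
  .df_set_coords(df, .transform_coords(.df_coords(df), R, t))
}

.df_translate <- function(df, t) {
  .df_set_coords(df, sweep(.df_coords(df), 2, -t))
}

# Rigid placement of a moving atom set against fixed atoms so that named
# atom-atom distances hit their targets while avoiding steric clashes.
# `targets` is a data frame with columns fixed_row, moving_row, dist
# (target distance) and optionally tol (per-target acceptance band,
# default `tol`), fixed_ant / moving_ant (antecedent atom rows: when
# given, the approach angle antecedent-atom-partner at that end is
# softly kept above ~100 degrees so hydrogen-bond geometry stays sane).
# Deterministic multi-start Nelder-Mead.
.place_rigid <- function(fixed, moving, targets, planar = FALSE,
                         clash_dist = 2.6, tol = 0.25) {
  if (is.null(targets$tol)) targets$tol <- tol
  if (is.null(targets$fixed_ant)) targets$fixed_ant <- NA_integer_
  if (is.null(targets$moving_ant)) targets$moving_ant <- NA_integer_
  fx <- .df_coords(fixed)
  mv0 <- .df_coords(moving)
  tgt_f <- fx[targets$fixed_row, , drop = FALSE]
  tgt_m_rows <- targets$moving_row
  tgt_d <- targets$dist
  ang3 <- function(v1, v2) {
    acos(pmin(1, pmax(-1, sum(v1 * v2) / (.vnorm(v1) * .vnorm(v2))))) * 180 / pi
  }

  apply_params <- function(p, flip, xyz) {
    R <- if (planar) {
      .rot_z(p[1])
    } else {
      .rot_z(p[1]) %*% .rot_y(p[2]) %*% .rot_x(p[3])
    }
    if (flip) R <- R %*% .rot_x(pi)
    t <- if (planar) c(p[2], p[3], 0) else p[4:6]
    .transform_coords(xyz, R, t)
  }
  objective <- function(p, flip) {
    xyz <- apply_params(p, flip, mv0)
    d <- sqrt(rowSums((xyz[tgt_m_rows, , drop = FALSE] - tgt_f)^2))
    obj <- sum((d - tgt_d)^2)
    dd2 <- outer(rowSums(fx^2), rowSums(xyz^2), "+") - 2 * fx %*% t(xyz)
    dd2[cbind(targets$fixed_row, targets$moving_row)] <- Inf
    close <- dd2 < clash_dist^2
    if (any(close)) {
      obj <- obj + sum((clash_dist - sqrt(pmax(dd2[close], 0)))^2) * 4
    }
    for (k in seq_len(nrow(targets))) {
      pf <- tgt_f[k, ]; pm <- xyz[tgt_m_rows[k], ]
      if (!is.na(targets$fixed_ant[k])) {
        a <- ang3(fx[targets$fixed_ant[k], ] - pf, pm - pf)
        if (a < 100) obj <- obj + ((100 - a) / 40)^2
      }
      if (!is.na(targets$moving_ant[k])) {
        a <- ang3(xyz[targets$moving_ant[k], ] - pm, pf - pm)
        if (a < 100) obj <- obj + ((100 - a) / 40)^2
      }
    }
    obj
  }

  best <- NULL
  fctr <- colMeans(fx)
  flips <- if (planar) c(FALSE, TRUE) else FALSE
  angles <- seq(0, 2 * pi, length.out = 9)[-9]
  for (flip in flips) {
    for (th in angles) {
      for (ph in if (planar) 0 else c(0, pi / 2, pi, 3 * pi / 2)) {
        R0 <- if (planar) .rot_z(th) else .rot_z(th) %*% .rot_y(ph)
        if (flip) R0 <- R0 %*% .rot_x(pi)
        m1 <- mv0[tgt_m_rows[1], ] %*% t(R0)
        dir <- tgt_f[1, ] - fctr
        dir <- if (.vnorm(dir) < 1e-6) c(1, 0, 0) else .unit(dir)
        t0 <- tgt_f[1, ] + dir * tgt_d[1] - as.numeric(m1)
        p0 <- if (planar) c(th, t0[1], t0[2]) else c(th, ph, 0, t0)
        fit <- stats::optim(p0, objective, flip = flip,
          method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-12))
        if (is.null(best) || fit$value < best$value) {
          best <- list(value = fit$value, par = fit$par, flip = flip)
        }
      }
    }
  }
  xyz <- apply_params(best$par, best$flip, mv0)
  d <- sqrt(rowSums((xyz[tgt_m_rows, , drop = FALSE] - tgt_f)^2))
  if (any(abs(d - tgt_d) > targets$tol)) {
    stop(
      "rigid placement failed to satisfy distance targets (",
      paste(sprintf("%.2f", d), collapse = ", "), " vs ",
      paste(sprintf("%.2f", tgt_d), collapse = ", "), ")"
    )
  }
  .df_set_coords(moving, xyz)
}

.pair_target_table <- function(b1, b2, geometry) {
  key <- paste(b1, b2, sep = "")
  tt <- switch(geometry,
    WC = switch(key,
      GC = list(c("O6", "N4"), c("N1", "N3"), c("N2", "O2")),
      CG = list(c("N4", "O6"), c("N3", "N1"), c("O2", "N2")),
      AU = list(c("N6", "O4"), c("N1", "N3")),
      UA = list(c("O4", "N6"), c("N3", "N1")),
      NULL
    ),
    GU_wobble = switch(key,
      GU = list(c("O6", "N3"), c("N1", "O2")),
      UG = list(c("N3", "O6"), c("O2", "N1")),
      NULL
    ),
    sheared_GA = switch(key,
      GA = list(c("N3", "N6"), c("N2", "N7")),
      AG = list(c("N6", "N3"), c("N7", "N2")),
      NULL
    ),
    NULL
  )
  if (is.null(tt)) {
    stop("geometry '", geometry, "' not defined for bases ", b1, "-", b2)
  }
  tt
}

.pair_cache <- new.env(parent = emptyenv())

#' Place two idealised bases as a hydrogen-bonded pair
#'
#' Positions the second base coplanar with the first so that the named
#' hydrogen-bond donor-acceptor distances of the requested geometry come
#' out near 2.9 Angstrom without steric clashes.
#'
#' @param b1,b2 base codes of the two residues.
#' @param geometry `"WC"` (canonical Watson-Crick), `"GU_wobble"`, or
#'   `"sheared_GA"`.
#' @return list of two atom data frames (`res1`, `res2`), base 1 at the
#'   template origin.
#' @export
place_pair <- function(b1, b2, geometry = c("WC", "GU_wobble", "sheared_GA")) {
  geometry <- match.arg(geometry)
  key <- paste(b1, b2, geometry, sep = "_")
  if (!is.null(.pair_cache[[key]])) return(.pair_cache[[key]])
  # optimise only one canonical base order per geometry; the reversed
  # combination reuses the same placement with the roles swapped, so
  # mirror-image poses cannot arise
  canon <- c(GC = "", CG = "GC", AU = "", UA = "AU", GU = "", UG = "GU",
    GA = "", AG = "GA")
  kk <- paste0(b1, b2)
  if (!is.na(canon[kk]) && nzchar(canon[kk])) {
    sw <- place_pair(substr(canon[kk], 1, 1), substr(canon[kk], 2, 2), geometry)
    out <- list(res1 = sw$res2, res2 = sw$res1)
    .pair_cache[[key]] <- out
    return(out)
  }
  tt <- .pair_target_table(b1, b2, geometry)
  r1 <- ideal_base(b1)
  r2 <- ideal_base(b2)
  targets <- data.frame(
    fixed_row = match(vapply(tt, `[`, "", 1), r1$atom),
    moving_row = match(vapply(tt, `[`, "", 2), r2$atom),
    dist = 2.9
  )
  r2p <- .place_rigid(r1, r2, targets, planar = TRUE)
  out <- list(res1 = r1, res2 = r2p)
  .pair_cache[[key]] <- out
  out
}

# ---- model assembly -------------------------------------------------------

# residues: list of list(chain, number, base, atoms); writes a minimal PDB
# and re-loads it so fixtures go through the parser.
.assemble_model <- function(residues, id = "synthetic") {
  res <- do.call(rbind, lapply(residues, function(r) {
    data.frame(
      resid = .make_resid(r$chain, r$number, ""), chain = r$chain,
      number = r$number, icode = "", raw_name = r$base, base = r$base,
      is_modified = FALSE, stringsAsFactors = FALSE
    )
  }))
  atoms <- do.call(rbind, lapply(residues, function(r) {
    data.frame(
      resid = .make_resid(r$chain, r$number, ""), atom = r$atoms$atom,
      element = r$atoms$element, x = r$atoms$x, y = r$atoms$y, z = r$atoms$z,
      stringsAsFactors = FALSE
    )
  }))
  ord <- order(res$chain, res$number)
  res <- res[ord, , drop = FALSE]
  atoms <- atoms[order(match(atoms$resid, res$resid)), , drop = FALSE]
  rownames(res) <- rownames(atoms) <- NULL
  structure(
    list(id = id, source_format = "pdb", nucleotides = res, atoms = atoms,
      hetero = atoms[0, c("resid", "atom", "element", "x", "y", "z")]),
    class = "rna_structure"
  )
}

.res_entry <- function(chain, number, base, atoms) {
  list(chain = chain, number = number, base = base, atoms = atoms)
}

# a residue parked far from the action (for unpaired loop/junction filler)
.spaced_residue <- function(chain, number, base, slot) {
  at <- ideal_base(base)
  .res_entry(chain, number, base,
    .df_translate(at, c(40 + 12 * (slot %% 8), 60 + 12 * (slot %/% 8), 0)))
}

# helix of WC pairs: pair k joins numbers s1[k] and s2[k]; each pair is
# centred so its C1'-C1' midpoint sits on the helical axis, making the
# stack of pair midpoints exactly colinear
.helix_residues <- function(types, s1, s2, chain = "A", twist = 33 * pi / 180,
                            rise = 3.4, origin = c(0, 0, 0), R0 = diag(3)) {
  out <- list()
  for (k in seq_along(types)) {
    ty <- strsplit(types[k], "")[[1]]
    geom <- if (all(sort(ty) == c("G", "U"))) "GU_wobble" else "WC"
    pr <- place_pair(ty[1], ty[2], geom)
    c1 <- .df_coords(pr$res1)[match("C1'", pr$res1$atom), ]
    c2 <- .df_coords(pr$res2)[match("C1'", pr$res2$atom), ]
    ctr <- c((c1 + c2) / 2)[1:2]
    r1 <- .df_translate(pr$res1, -c(ctr, 0))
    r2 <- .df_translate(pr$res2, -c(ctr, 0))
    Rk <- R0 %*% .rot_z((k - 1) * twist)
    tk <- origin + as.numeric(R0 %*% c(0, 0, (k - 1) * rise))
    out[[length(out) + 1]] <- .res_entry(chain, s1[k], ty[1],
      .df_transform(r1, Rk, tk))
    out[[length(out) + 1]] <- .res_entry(chain, s2[k], ty[2],
      .df_transform(r2, Rk, tk))
  }
  out
}

#' Specification of a synthetic motif fixture
#'
#' @param kind one of `"helix"`, `"hairpin"`, `"triple"`, `"aminor"`,
#'   `"zipper"`, `"pseudoknot"`, `"kissing"`, `"kinkturn"`,
#'   `"loop_receptor"`.
#' @param seed integer recorded in the spec (generation is fully
#'   deterministic; the seed participates in file naming only).
#' @param ... kind-specific parameters, see [build_motif()].
#' @return list of class `geometry_spec`.
#' @export
motif_spec <- function(kind, seed = 1L, ...) {
  kinds <- c("helix", "hairpin", "triple", "aminor", "zipper", "pseudoknot",
    "kissing", "kinkturn", "loop_receptor")
  if (!kind %in% kinds) {
    stop("invalid spec: unknown kind '", kind, "' (expected one of ",
      paste(kinds, collapse = ", "), ")")
  }
  structure(list(kind = kind, seed = as.integer(seed), args = list(...)),
    class = "geometry_spec")
}

.build_helix <- function(n_pairs = 4, types = NULL) {
  if (is.null(types)) types <- rep(c("GC", "CG", "AU", "UA"), length.out = n_pairs)
  .helix_residues(types, seq_len(n_pairs), 2 * n_pairs + 1 - seq_len(n_pairs))
}

.build_hairpin <- function(stem = 3, loop = "GAAA", offset = 0, chain = "A",
                           origin = c(0, 0, 0)) {
  nl <- nchar(loop)
  n <- 2 * stem + nl
  out <- .helix_residues(rep(c("GC", "CG"), length.out = stem),
    offset + seq_len(stem), offset + n + 1 - seq_len(stem),
    chain = chain, origin = origin)
  lb <- strsplit(loop, "")[[1]]
  for (i in seq_len(nl)) {
    th <- 2 * pi * (i - 1) / nl
    pos <- origin + c(10 * cos(th), 10 * sin(th), stem * 3.4 + 8)
    out[[length(out) + 1]] <- .res_entry(chain, offset + stem + i, lb[i],
      .df_translate(ideal_base(lb[i]), pos))
  }
  out
}

.build_triple <- function(tilt = 0) {
  pr <- place_pair("G", "C", "WC")
  fixed <- rbind(pr$res1, pr$res2)
  a <- ideal_base("A")
  targets <- data.frame(
    fixed_row = match(c("N3", "N2"), pr$res1$atom),
    moving_row = match(c("N6", "N7"), a$atom),
    dist = 2.9
  )
  a <- .place_rigid(fixed, a, targets, planar = TRUE)
  if (tilt != 0) {
    # tilt the third base about its bonded-atom axis: hydrogen-bond
    # distances survive but the base plane leaves the pair plane
    p1 <- as.numeric(a[match("N6", a$atom), c("x", "y", "z")])
    p2 <- as.numeric(a[match("N7", a$atom), c("x", "y", "z")])
    ax <- .unit(p2 - p1)
    th <- tilt * pi / 180
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
      byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    xyz <- sweep(.df_coords(a), 2, p1)
    a <- .df_set_coords(a, sweep(xyz %*% t(R), 2, -p1))
  }
  list(
    .res_entry("A", 1, "G", pr$res1),
    .res_entry("A", 2, "C", pr$res2),
    .res_entry("A", 3, "A", a)
  )
}

.build_aminor <- function(type = "I", donor_base = "A", receptor = c("G", "C")) {
  pr <- place_pair(receptor[1], receptor[2], "WC")
  fixed <- rbind(pr$res1, pr$res2)
  n1 <- nrow(pr$res1)
  d <- ideal_base(donor_base)
  row_f <- function(res_no, atom) {
    (if (res_no == 1) 0 else n1) +
      match(atom, (if (res_no == 1) pr$res1 else pr$res2)$atom)
  }
  targets <- switch(type,
    I = data.frame(
      fixed_row = c(row_f(1, "O2'"), row_f(2, "O2")),
      moving_row = match(c("N3", "O2'"), d$atom), dist = c(2.9, 2.9)
    ),
    II = data.frame(
      # docked against one receptor residue only: 2'-OH to 2'-OH plus the
      # receptor G amino group donating into the docking base's N3; the
      # loose C2 guide keeps the N2-H...N3 geometry roughly linear
      fixed_row = c(row_f(1, "O2'"), row_f(1, "N2"), row_f(1, "C2")),
      moving_row = match(c("O2'", "N3", "N3"), d$atom),
      dist = c(2.9, 2.9, 3.8), tol = c(0.25, 0.25, 0.6)
    ),
    `0` = data.frame(
      fixed_row = c(row_f(1, "N3"), row_f(1, "O2'")),
      moving_row = match(c("O2'", "O2'"), d$atom), dist = c(3.1, 3.1)
    ),
    stop("invalid spec: A-minor type must be I, II or 0")
  )
  d <- .place_rigid(fixed, d, targets, planar = FALSE)
  list(
    .res_entry("A", 1, receptor[1], pr$res1),
    .res_entry("A", 2, receptor[2], pr$res2),
    .res_entry("A", 10, donor_base, d)
  )
}

# two stacked residues (a dinucleotide backbone segment)
.stacked_segment <- function(bases, rise = 3.4) {
  lapply(seq_along(bases), function(i) {
    .df_translate(ideal_base(bases[i]), c(0, 0, (i - 1) * rise))
  })
}

.build_zipper <- function(zclass = "canonical", n_bonds = NULL) {
  sA <- .stacked_segment(c("A", "A"))
  sB <- .stacked_segment(c("G", "G"))
  fixed <- rbind(sA[[1]], sA[[2]])
  nA <- nrow(sA[[1]])
  moving <- rbind(sB[[1]], sB[[2]])
  nB <- nrow(sB[[1]])
  rA <- function(res_no, atom) (res_no - 1) * nA + match(atom, sA[[1]]$atom)
  rB <- function(res_no, atom) (res_no - 1) * nB + match(atom, sB[[1]]$atom)
  targets <- if (!is.null(n_bonds) && n_bonds == 1) {
    data.frame(fixed_row = rA(1, "O2'"), moving_row = rB(2, "O2'"), dist = 2.9)
  } else if (zclass == "canonical") {
    # antiparallel register: i <-> j+1, i+1 <-> j, plus a 2'-OH-to-base
    # bond; hydroxyl approach angles kept sane via the C2' antecedents
    data.frame(
      fixed_row = c(rA(1, "O2'"), rA(2, "O2'"), rA(1, "O2'")),
      moving_row = c(rB(2, "O2'"), rB(1, "O2'"), rB(2, "N3")),
      dist = c(2.9, 2.9, 3.3), tol = c(0.25, 0.25, 0.35),
      fixed_ant = c(rA(1, "C2'"), rA(2, "C2'"), rA(1, "C2'")),
      moving_ant = c(rB(2, "C2'"), rB(1, "C2'"), NA)
    )
  } else {
    # parallel (pseudo-cis) register: i <-> j, i+1 <-> j+1
    data.frame(
      fixed_row = c(rA(1, "O2'"), rA(2, "O2'")),
      moving_row = c(rB(1, "O2'"), rB(2, "O2'")),
      dist = c(2.9, 2.9),
      fixed_ant = c(rA(1, "C2'"), rA(2, "C2'")),
      moving_ant = c(rB(1, "C2'"), rB(2, "C2'"))
    )
  }
  moving <- .place_rigid(fixed, moving, targets, planar = FALSE, tol = 0.35)
  b1 <- moving[seq_len(nB), , drop = FALSE]
  b2 <- moving[nB + seq_len(nB), , drop = FALSE]
  list(
    .res_entry("A", 1, "A", sA[[1]]),
    .res_entry("A", 2, "A", sA[[2]]),
    .res_entry("A", 10, "G", b1),
    .res_entry("A", 11, "G", b2)
  )
}

.build_pseudoknot <- function() {
  out <- .helix_residues(c("GC", "CG", "GC"), c(1, 2, 3), c(10, 9, 8))
  out <- c(out, .helix_residues(c("GC", "CG"), c(5, 6), c(15, 14),
    origin = c(45, 0, 0)))
  slot <- 0
  for (n in c(4, 7, 11, 12, 13)) {
    out[[length(out) + 1]] <- .spaced_residue("A", n, "A", slot)
    slot <- slot + 1
  }
  out
}

.build_kissing <- function(n_kiss = 3) {
  out <- c(
    .build_hairpin(stem = 3, loop = "AAAAAA", offset = 0),
    lapply(.build_hairpin(stem = 3, loop = "AAAAAA", offset = 20,
      origin = c(45, 0, 0)), identity)
  )
  # loop residues 4..9 and 24..29 were parked by the hairpin builder;
  # re-place the kissing participants as an inter-loop helix
  kiss_types <- c("GC", "CG", "GC")[seq_len(n_kiss)]
  s1 <- c(5, 6, 7)[seq_len(n_kiss)]
  s2 <- c(26, 25, 24)[seq_len(n_kiss)]
  kiss <- .helix_residues(kiss_types, s1, s2, origin = c(90, 0, 0))
  drop <- vapply(out, function(r) r$number %in% c(s1, s2), logical(1))
  c(out[!drop], kiss)
}

.build_kinkturn <- function(bulge = 3) {
  # canonical stem: pairs (1,13) (2,12) (3,11), propagation +z
  out <- .helix_residues(c("GC", "CG", "GC"), c(1, 2, 3), c(13, 12, 11))
  # non-canonical stem: tandem sheared G-A pairs (7,10) and (8,9),
  # rotated so its axis bends away from the canonical stem axis
  ga <- place_pair("G", "A", "sheared_GA")
  c1 <- .df_coords(ga$res1)[match("C1'", ga$res1$atom), ]
  c2 <- .df_coords(ga$res2)[match("C1'", ga$res2$atom), ]
  ctr <- c((c1 + c2) / 2)[1:2]
  ga1 <- .df_translate(ga$res1, -c(ctr, 0))
  ga2 <- .df_translate(ga$res2, -c(ctr, 0))
  R <- .rot_y(120 * pi / 180)
  org <- c(11, 0, 3 * 3.4 + 5)
  nc <- list(
    .res_entry("A", 7, "G", .df_transform(ga1, R, org)),
    .res_entry("A", 10, "A", .df_transform(ga2, R, org)),
    .res_entry("A", 8, "G",
      .df_transform(ga1, R, org + as.numeric(R %*% c(0, 0, 3.4)))),
    .res_entry("A", 9, "A",
      .df_transform(ga2, R, org + as.numeric(R %*% c(0, 0, 3.4))))
  )
  out <- c(out, nc)
  for (i in seq_len(bulge)) {
    out[[length(out) + 1]] <- .spaced_residue("A", 3 + i, "U", i - 1)
  }
  out
}

.build_loop_receptor <- function(loop_size = 4, with_aminor = TRUE) {
  # docking hairpin: stem (1,12)..(4,9), loop 5..8 (tetraloop)
  stem_n <- (12 - loop_size) / 2
  hp <- .build_hairpin(stem = stem_n, loop = paste(rep("A", loop_size),
    collapse = ""), offset = 0)
  # receptor helix placed far away: pairs (21,31) (22,30) (23,29); the
  # A-minor-free variant uses wobble pairs, which cannot receive A-minors
  rec_types <- if (with_aminor) c("GC", "GC", "GC") else c("GU", "GU", "GU")
  rec <- .helix_residues(rec_types, c(21, 22, 23), c(31, 30, 29),
    origin = c(60, 0, 0))
  rec_atoms <- do.call(rbind, lapply(rec, function(r) r$atoms))
  find_rec <- function(number, atom) {
    off <- 0
    for (r in rec) {
      i <- match(atom, r$atoms$atom)
      if (r$number == number) return(off + i)
      off <- off + nrow(r$atoms)
    }
    stop("atom not found")
  }
  placed <- list()
  fixed <- rec_atoms
  if (with_aminor) {
    # loop residue 6 docks type-I into the open terminal pair (21,31)
    d <- ideal_base("A")
    targets <- data.frame(
      fixed_row = c(find_rec(21, "O2'"), find_rec(31, "O2")),
      moving_row = match(c("N3", "O2'"), d$atom), dist = c(2.9, 2.9)
    )
    d <- .place_rigid(fixed, d, targets, planar = FALSE)
    placed[[length(placed) + 1]] <- .res_entry("A", 6, "A", d)
    fixed <- rbind(fixed, d)
  }
  # loop residues 7,8 form a ribose zipper with receptor strand 22,23
  seg <- .stacked_segment(c("A", "A"))
  mv <- rbind(seg[[1]], seg[[2]])
  nseg <- nrow(seg[[1]])
  targets <- data.frame(
    fixed_row = c(find_rec(23, "O2'"), find_rec(22, "O2'"), find_rec(23, "N3")),
    moving_row = c(match("O2'", seg[[1]]$atom), nseg + match("O2'", seg[[2]]$atom),
      match("O2'", seg[[1]]$atom)),
    dist = c(2.9, 2.9, 3.3)
  )
  mv <- .place_rigid(fixed, mv, targets, planar = FALSE, tol = 0.35)
  placed[[length(placed) + 1]] <- .res_entry("A", 7, "A", mv[seq_len(nseg), ])
  placed[[length(placed) + 1]] <- .res_entry("A", 8, "A",
    mv[nseg + seq_len(nseg), ])
  replaced <- vapply(placed, function(r) r$number, numeric(1))
  keep <- vapply(hp, function(r) !(r$number %in% replaced), logical(1))
  c(hp[keep], rec, placed)
}

#' Build a synthetic structure model from a motif specification
#'
#' Renders the spec to idealised coordinates, writes them as a minimal
#' PDB file and re-loads that file, so the returned model has passed
#' through the structure parser exactly as a deposited entry would.
#' Generation is deterministic: identical specs give byte-identical
#' files.
#'
#' Kinds and their parameters:
#' * `helix`: `n_pairs` (default 4), `types`.
#' * `hairpin`: `stem` (pairs), `loop` (loop sequence).
#' * `triple`: `tilt` (degrees the third base is tilted out of plane;
#'   0 gives a planar AGC triple docked on a G-C pair).
#' * `aminor`: `type` (`"I"`, `"II"`, `"0"`), `donor_base` (`"A"`/`"G"`).
#' * `zipper`: `zclass` (`"canonical"`/`"pseudo-cis"`), `n_bonds`.
#' * `pseudoknot`, `kissing` (`n_kiss`), `kinkturn` (`bulge`),
#'   `loop_receptor` (`loop_size`, `with_aminor`).
#'
#' @param spec a [motif_spec()].
#' @param path optional path for the PDB file (default: tempfile).
#' @return an `rna_structure` (with the source path in attribute
#'   `"path"`).
#' @export
build_motif <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "geometry_spec"))
  residues <- do.call(switch(spec$kind,
    helix = .build_helix, hairpin = .build_hairpin, triple = .build_triple,
    aminor = .build_aminor, zipper = .build_zipper,
    pseudoknot = .build_pseudoknot, kissing = .build_kissing,
    kinkturn = .build_kinkturn, loop_receptor = .build_loop_receptor
  ), spec$args)
  m <- .assemble_model(residues, id = paste0("synthetic_", spec$kind))
  if (is.null(path)) {
    path <- tempfile(paste0("synthetic_", spec$kind, "_"), fileext = ".pdb")
  }
  write_structure_pdb(m, path)
  out <- load_structure(path, format = "pdb", id = m$id)
  attr(out, "path") <- path
  out
}

# ---- synthetic alignments -------------------------------------------------

#' Generate an alignment with planted per-column conservation
#'
#' For each column the requested modal fraction is realised exactly:
#' `round(fraction * nrows)` rows carry the modal base and the remaining
#' rows are filled with the other three bases as evenly as possible (so
#' the modal base is strictly modal).  The planted fractions are the
#' ground truth recovered by [column_profiles()].
#'
#' @param nrows number of sequences.
#' @param ncols number of columns.
#' @param fractions per-column modal fraction in `[0, 1]`, recycled.
#' @param seed RNG seed (modal bases and row assignment).
#' @return a `stockholm_alignment` (see [read_stockholm()]) with the
#'   planted modal counts in attribute `"planted"`.
#' @export
make_alignment <- function(nrows, ncols, fractions, seed = 1L) {
  fractions <- rep_len(fractions, ncols)
  if (any(fractions < 0 | fractions > 1)) {
    stop("fractions must lie in [0, 1]")
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  bases <- c("A", "C", "G", "U")
  mat <- matrix("", nrows, ncols)
  planted <- integer(ncols)
  for (j in seq_len(ncols)) {
    k <- as.integer(floor(fractions[j] * nrows + 0.5))
    rest <- nrows - k
    max_other <- ceiling(rest / 3)
    if (k < 1 || (rest > 0 && max_other >= k)) {
      stop(
        "infeasible counts in column ", j, ": ", k, " modal rows of ",
        nrows, " cannot be strictly modal"
      )
    }
    modal <- sample(bases, 1)
    others <- rep_len(sample(setdiff(bases, modal)), rest)
    col <- c(rep(modal, k), others)
    mat[, j] <- col[sample.int(nrows)]
    planted[j] <- k
  }
  seqs <- apply(mat, 1, paste, collapse = "")
  aln <- structure(
    list(
      ids = sprintf("seq%0*d", nchar(nrows), seq_len(nrows)),
      seqs = seqs, ncols = ncols, gc = list(), insert = rep(FALSE, ncols)
    ),
    class = "stockholm_alignment"
  )
  attr(aln, "planted") <- planted
  aln
}

# ---- packaged census fixture ---------------------------------------------

#' The packaged base-triple census fixture
#'
#' Nineteen published base-triple records for the eleven reference
#' riboswitch structures, with residue identities, the structural-context
#' string, the riboswitch class, and which two residues form a canonical
#' Watson-Crick pair (none for fully non-canonical triples).
#'
#' @return data frame of class `triple_census` with columns `pdb_id`,
#'   `res1`..`res3`, `triple` (display string), `bases`, `composition`
#'   (sorted A<C<G<U), `display_composition` (purine-first),
#'   `contains_wc`, `wc_members`, `context`, `riboswitch_class`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_census.tsv", package = "ribomotifs",
    mustWork = TRUE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
    colClasses = "character")
  parse_base <- function(x) substr(x, 1, 1)
  bases <- cbind(parse_base(df$res1), parse_base(df$res2), parse_base(df$res3))
  df$triple <- paste(df$res1, df$res2, df$res3, sep = "-")
  df$bases <- apply(bases, 1, paste, collapse = "")
  df$composition <- apply(bases, 1, function(b) paste(sort(b), collapse = ""))
  df$display_composition <- apply(bases, 1, function(b) {
    paste(b[order(match(b, .composition_display_order))], collapse = "")
  })
  df$contains_wc <- df$wc_members != ""
  out <- df[, c("pdb_id", "res1", "res2", "res3", "triple", "bases",
    "composition", "display_composition", "contains_wc", "wc_members",
    "context", "riboswitch_class")]
  class(out) <- c("triple_census", "data.frame")
  out
}
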