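# Hydrogen-bond detection and base-pair classification.  All criteria are
# heavy-atom criteria (no hydrogens are placed): a donor-acceptor contact
# within the distance cutoff whose angle at the donor, measured via the
# donor's covalent antecedent, is compatible with a roughly linear bond.
# A pair is accepted when at least two base-to-base hydrogen bonds join
# the residues and their base planes are not close to perpendicular; the
# interacting edge of each base is then assigned by a vote over which
# edge its bonded atoms belong to.

#' Configuration for the geometric detectors
#'
#' Every geometric threshold used by the pipeline, exposed in one place.
#' Distances are in Angstrom, angles in degrees.
#'
#' @param hbond_dist_max heavy-atom donor-acceptor distance cutoff.
#' @param hbond_dist_min minimum donor-acceptor distance (closer contacts
#'   are clashes or covalent geometry, not hydrogen bonds).
#' @param donor_angle_min minimum antecedent-donor-acceptor angle.
#' @param donor_angle_min_hydroxyl the same floor for 2'-OH donors, looser
#'   because the hydroxyl proton is rotatable (only the covalent
#'   direction is excluded).
#' @param pair_min_hbonds minimum base-base hydrogen bonds per accepted pair.
#' @param pair_planarity_max maximum base-plane angle for a pair (loose:
#'   pairing tolerates propeller/buckle).
#' @param pair_bond_scope which bonds count towards the pair minimum:
#'   `"base-base"` (both atoms base atoms, the default) or `"base-any"`
#'   (at least one base atom).
#' @param triple_planarity_max maximum pairwise base-plane angle within a
#'   base triple (strict: triples must be planar interactions).
#' @param aminor_min_hbonds minimum minor-groove bonds for an A-minor.
#' @param zipper_min_hbonds minimum cross-segment 2'-OH bonds for a
#'   ribose zipper.
#' @param zipper_min_seq_sep minimum residue separation between zipper
#'   segments.
#' @param kissing_min_pairs minimum inter-loop Watson-Crick pairs for a
#'   kissing loop.
#' @param kink_bulge_range allowed bulge length (nt) in a kink-turn.
#' @param kink_axis_angle_max maximum inter-stem axis angle of a
#'   kink-turn (axes oriented away from the bulge junction, so coaxial
#'   stems measure close to 180 degrees and kinked stems much less).
#' @param loop_receptor_sizes hairpin-loop sizes eligible as docking
#'   loops (tetraloop and pentaloop).
#' @param align_match,align_mismatch,align_gap_open,align_gap_extend
#'   pairwise-alignment scores used for alignment insertion and residue
#'   matching.
#' @param superpose_prune_cutoff residue deviation (Angstrom) above which
#'   matched pairs are discarded during iterative superposition pruning.
#' @param conserve_threshold strict conservation threshold (a column is
#'   conserved when its modal fraction exceeds this).
#' @param conserve_gap_denominator whether gaps count in the conservation
#'   denominator.
#' @return a list of class `motif_config`.
#' @export
motif_config <- function(hbond_dist_max = 3.5,
                         hbond_dist_min = 2.4,
                         donor_angle_min = 110,
                         donor_angle_min_hydroxyl = 80,
                         pair_min_hbonds = 2,
                         pair_planarity_max = 65,
                         pair_bond_scope = c("base-base", "base-any"),
                         triple_planarity_max = 30,
                         aminor_min_hbonds = 2,
                         zipper_min_hbonds = 2,
                         zipper_min_seq_sep = 4,
                         kissing_min_pairs = 2,
                         kink_bulge_range = c(2, 4),
                         kink_axis_angle_max = 120,
                         loop_receptor_sizes = c(4, 5),
                         align_match = 2,
                         align_mismatch = -1,
                         align_gap_open = 5,
                         align_gap_extend = 1,
                         superpose_prune_cutoff = 2,
                         conserve_threshold = 0.95,
                         conserve_gap_denominator = TRUE) {
  structure(list(
    hbond_dist_max = hbond_dist_max,
    hbond_dist_min = hbond_dist_min,
    donor_angle_min = donor_angle_min,
    donor_angle_min_hydroxyl = donor_angle_min_hydroxyl,
    pair_min_hbonds = pair_min_hbonds,
    pair_planarity_max = pair_planarity_max,
    pair_bond_scope = match.arg(pair_bond_scope),
    triple_planarity_max = triple_planarity_max,
    aminor_min_hbonds = aminor_min_hbonds,
    zipper_min_hbonds = zipper_min_hbonds,
    zipper_min_seq_sep = zipper_min_seq_sep,
    kissing_min_pairs = kissing_min_pairs,
    kink_bulge_range = kink_bulge_range,
    kink_axis_angle_max = kink_axis_angle_max,
    loop_receptor_sizes = loop_receptor_sizes,
    align_match = align_match,
    align_mismatch = align_mismatch,
    align_gap_open = align_gap_open,
    align_gap_extend = align_gap_extend,
    superpose_prune_cutoff = superpose_prune_cutoff,
    conserve_threshold = conserve_threshold,
    conserve_gap_denominator = conserve_gap_denominator
  ), class = "motif_config")
}

.atom_moiety <- function(atom) {
  ifelse(atom %in% .phosphate_atoms, "phosphate",
    ifelse(atom %in% .sugar_atoms, "sugar", "base")
  )
}

#' Detect hydrogen bonds in a structure
#'
#' All donor-acceptor heavy-atom pairs between distinct residues with
#' distance at most `hbond_dist_max` and antecedent-donor-acceptor angle
#' at least `donor_angle_min` (the angle criterion rejects stacking
#' contacts, whose acceptors sit perpendicular to the donor's base
#' plane).  Base-base, base-sugar (2'-OH) and base-phosphate contacts are
#' all reported and tagged by moiety.  Backbone-backbone contacts between
#' sequence-adjacent residues are suppressed as covalent-neighbour noise.
#'
#' @param model an `rna_structure`.
#' @param config a [motif_config()].
#' @param frames optional precomputed [base_frames()].
#' @return data frame, one row per bond, sorted by residue and atom:
#'   `res_i`/`res_j` (model order), donor and acceptor residue and atom,
#'   `distance`, `donor_angle`, moieties and `planarity_angle` (base-plane
#'   angle, `NA` when a frame is unavailable).
#' @export
detect_hbonds <- function(model, config = motif_config(), frames = NULL) {
  if (is.null(frames)) frames <- base_frames(model)
  res <- model$nucleotides
  a <- model$atoms
  a$moiety <- .atom_moiety(a$atom)
  idx <- stats::setNames(seq_len(nrow(res)), res$resid)
  coord_key <- paste(a$resid, a$atom)
  coords <- as.matrix(a[, c("x", "y", "z")])
  rownames(coords) <- coord_key

  empty <- data.frame(
    res_i = character(), res_j = character(), donor_res = character(),
    donor_atom = character(), acceptor_res = character(),
    acceptor_atom = character(), distance = numeric(),
    donor_angle = numeric(), donor_moiety = character(),
    acceptor_moiety = character(), planarity_angle = numeric(),
    stringsAsFactors = FALSE
  )

  donors <- do.call(rbind, lapply(seq_len(nrow(res)), function(i) {
    b <- res$base[i]
    tab <- if (b %in% names(.hbond_donors)) {
      rbind(.hbond_donors[[b]], .sugar_donor)
    } else {
      .sugar_donor
    }
    ra <- a[a$resid == res$resid[i], , drop = FALSE]
    ant_ok <- vapply(strsplit(tab$antecedent, ","), function(s) all(s %in% ra$atom),
      logical(1))
    tab <- tab[tab$atom %in% ra$atom & ant_ok, , drop = FALSE]
    if (nrow(tab) == 0) return(NULL)
    data.frame(resid = res$resid[i], atom = tab$atom,
      antecedent = tab$antecedent, stringsAsFactors = FALSE)
  }))
  acceptors <- do.call(rbind, lapply(seq_len(nrow(res)), function(i) {
    b <- res$base[i]
    acc <- c(if (b %in% names(.hbond_acceptors)) .hbond_acceptors[[b]],
      .backbone_acceptors)
    ra <- a[a$resid == res$resid[i], , drop = FALSE]
    acc <- acc[acc %in% ra$atom]
    if (length(acc) == 0) return(NULL)
    data.frame(resid = res$resid[i], atom = acc, stringsAsFactors = FALSE)
  }))
  if (is.null(donors) || is.null(acceptors)) return(empty)

  dxyz <- coords[paste(donors$resid, donors$atom), , drop = FALSE]
  axyz <- coords[paste(acceptors$resid, acceptors$atom), , drop = FALSE]
  # antecedent position: midpoint of the listed neighbour atoms
  antxyz <- t(vapply(seq_len(nrow(donors)), function(k) {
    nb <- strsplit(donors$antecedent[k], ",")[[1]]
    colMeans(coords[paste(donors$resid[k], nb), , drop = FALSE])
  }, numeric(3)))

  d2 <- outer(rowSums(dxyz^2), rowSums(axyz^2), "+") - 2 * dxyz %*% t(axyz)
  cand <- which(d2 <= config$hbond_dist_max^2 + 1e-9 &
    d2 >= config$hbond_dist_min^2, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  di <- cand[, 1]; ai <- cand[, 2]
  keep <- donors$resid[di] != acceptors$resid[ai]
  di <- di[keep]; ai <- ai[keep]
  if (length(di) == 0) return(empty)

  v1 <- antxyz[di, , drop = FALSE] - dxyz[di, , drop = FALSE]
  v2 <- axyz[ai, , drop = FALSE] - dxyz[di, , drop = FALSE]
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  amin <- ifelse(donors$atom[di] == "O2'", config$donor_angle_min_hydroxyl,
    config$donor_angle_min)
  keep <- ang >= amin
  di <- di[keep]; ai <- ai[keep]; ang <- ang[keep]
  if (length(di) == 0) return(empty)

  dres <- donors$resid[di]; ares <- acceptors$resid[ai]
  datom <- donors$atom[di]; aatom <- acceptors$atom[ai]
  dmo <- .atom_moiety(datom); amo <- .atom_moiety(aatom)
  adjacent <- abs(res$number[idx[dres]] - res$number[idx[ares]]) <= 1 &
    res$chain[idx[dres]] == res$chain[idx[ares]]
  keep <- !(adjacent & dmo != "base" & amo != "base")
  di <- di[keep]; ai <- ai[keep]; ang <- ang[keep]
  dres <- dres[keep]; ares <- ares[keep]
  datom <- datom[keep]; aatom <- aatom[keep]
  dmo <- dmo[keep]; amo <- amo[keep]
  if (length(di) == 0) return(empty)

  dist <- sqrt(rowSums((dxyz[di, , drop = FALSE] - axyz[ai, , drop = FALSE])^2))
  first <- ifelse(idx[dres] <= idx[ares], dres, ares)
  second <- ifelse(idx[dres] <= idx[ares], ares, dres)
  plan <- vapply(seq_along(di), function(k) {
    fa <- frames[[dres[k]]]; fb <- frames[[ares[k]]]
    if (is.null(fa) || is.null(fb)) return(NA_real_)
    .plane_angle(fa$normal, fb$normal)
  }, numeric(1))

  out <- data.frame(
    res_i = first, res_j = second, donor_res = dres, donor_atom = datom,
    acceptor_res = ares, acceptor_atom = aatom, distance = dist,
    donor_angle = ang, donor_moiety = dmo, acceptor_moiety = amo,
    planarity_angle = plan, stringsAsFactors = FALSE
  )
  # an O2'-O2' contact qualifies in both donor directions: report it once
  upair <- paste(
    pmin(paste(out$donor_res, out$donor_atom), paste(out$acceptor_res, out$acceptor_atom)),
    pmax(paste(out$donor_res, out$donor_atom), paste(out$acceptor_res, out$acceptor_atom))
  )
  ord <- order(idx[out$res_i], idx[out$res_j], out$donor_atom, out$acceptor_atom)
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(upair[ord]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# bonds between one residue pair that count towards pair acceptance
.pair_scope_bonds <- function(bonds, config) {
  if (config$pair_bond_scope == "base-base") {
    bonds[bonds$donor_moiety == "base" & bonds$acceptor_moiety == "base", ,
      drop = FALSE]
  } else {
    bonds[bonds$donor_moiety == "base" | bonds$acceptor_moiety == "base", ,
      drop = FALSE]
  }
}

.edge_vote <- function(base, atoms) {
  if (!base %in% names(.edge_atoms)) return(NA_character_)
  tab <- .edge_atoms[[base]]
  score <- c(WatsonCrick = 0, Hoogsteen = 0, Sugar = 0)
  for (at in atoms) {
    member <- names(tab)[vapply(tab, function(s) at %in% s, logical(1))]
    if (length(member) > 0) score[member] <- score[member] + 1 / length(member)
  }
  if (all(score == 0)) return(NA_character_)
  # deterministic tie-break: Watson-Crick, then Hoogsteen, then Sugar
  names(score)[which.max(score)]
}

.classify_pair_impl <- function(model, frames, res_a, res_b, bonds, config) {
  scoped <- .pair_scope_bonds(bonds, config)
  if (nrow(scoped) < config$pair_min_hbonds) return(NULL)
  fa <- frames[[res_a]]; fb <- frames[[res_b]]
  if (is.null(fa) || is.null(fb)) return(NULL)
  plan <- .plane_angle(fa$normal, fb$normal)
  if (plan > config$pair_planarity_max) return(NULL)

  res <- model$nucleotides
  base_a <- res$base[res$resid == res_a]
  base_b <- res$base[res$resid == res_b]
  atoms_of <- function(r) {
    c(
      scoped$donor_atom[scoped$donor_res == r],
      scoped$acceptor_atom[scoped$acceptor_res == r]
    )
  }
  edge_a <- .edge_vote(base_a, atoms_of(res_a))
  edge_b <- .edge_vote(base_b, atoms_of(res_b))
  if (is.na(edge_a) || is.na(edge_b)) return(NULL)

  ga <- .residue_coord(model, res_a, .glycosidic_atom[[base_a]])
  gb <- .residue_coord(model, res_b, .glycosidic_atom[[base_b]])
  c1a <- .residue_coord(model, res_a, "C1'")
  c1b <- .residue_coord(model, res_b, "C1'")
  orientation <- "cis"
  if (!is.null(ga) && !is.null(gb) && !is.null(c1a) && !is.null(c1b)) {
    axis <- gb - ga
    sa <- sum(fa$normal * .cross3(axis, c1a - ga))
    sb <- sum(fa$normal * .cross3(axis, c1b - gb))
    orientation <- if (sa * sb >= 0) "cis" else "trans"
  }
  bases <- sort(c(base_a, base_b))
  wcwc <- identical(edge_a, "WatsonCrick") && identical(edge_b, "WatsonCrick")
  canonical <- orientation == "cis" && wcwc &&
    (identical(bases, c("C", "G")) || identical(bases, c("A", "U")))
  wobble <- orientation == "cis" && wcwc && identical(bases, c("G", "U"))
  data.frame(
    res_a = res_a, res_b = res_b, base_a = base_a, base_b = base_b,
    edge_a = edge_a, edge_b = edge_b, orientation = orientation,
    canonical = canonical, wobble = wobble,
    n_hbonds = nrow(scoped), n_hbonds_all = nrow(bonds),
    planarity = plan, stringsAsFactors = FALSE
  )
}

#' Classify one residue pair from its hydrogen bonds
#'
#' Applies the pair acceptance filter (at least two base-base bonds and a
#' tolerable base-plane angle), assigns the interacting edge of each base
#' by a majority vote over the packaged atom-to-edge table, determines
#' cis/trans glycosidic orientation, and flags canonical (cis
#' Watson-Crick G-C / A-U) and wobble (cis G-U) pairs.
#'
#' @param model an `rna_structure`.
#' @param res_a,res_b residue identifiers.
#' @param hbonds output of [detect_hbonds()] (subset automatically).
#' @param config a [motif_config()].
#' @param frames optional precomputed frames.
#' @return a one-row data frame, or `NULL` when the contact fails the
#'   pair criteria.
#' @export
classify_pair <- function(model, res_a, res_b, hbonds, config = motif_config(),
                          frames = NULL) {
  if (is.null(frames)) frames <- base_frames(model)
  b <- hbonds[(hbonds$res_i == res_a & hbonds$res_j == res_b) |
    (hbonds$res_i == res_b & hbonds$res_j == res_a), , drop = FALSE]
  if (nrow(b) == 0) return(NULL)
  idx <- match(c(res_a, res_b), model$nucleotides$resid)
  if (idx[1] > idx[2]) {
    tmp <- res_a; res_a <- res_b; res_b <- tmp
  }
  .classify_pair_impl(model, frames, res_a, res_b, b, config)
}

#' Detect all base pairs of a structure
#'
#' Runs [detect_hbonds()] and classifies every residue pair joined by
#' hydrogen bonds.  A residue may participate in several pairs (base
#' triples depend on this).  Output order is deterministic (model order
#' of the first, then second residue).
#'
#' @param model an `rna_structure`.
#' @param config a [motif_config()].
#' @param hbonds,frames optional precomputed inputs.
#' @return data frame of class `rna_pairs`, one row per accepted pair,
#'   with the hydrogen-bond table attached as attribute `"hbonds"`.
#' @export
detect_base_pairs <- function(model, config = motif_config(), hbonds = NULL,
                              frames = NULL) {
  if (is.null(frames)) frames <- base_frames(model)
  if (is.null(hbonds)) hbonds <- detect_hbonds(model, config, frames)
  empty <- data.frame(
    res_a = character(), res_b = character(), base_a = character(),
    base_b = character(), edge_a = character(), edge_b = character(),
    orientation = character(), canonical = logical(), wobble = logical(),
    n_hbonds = integer(), n_hbonds_all = integer(), planarity = numeric(),
    stringsAsFactors = FALSE
  )
  if (nrow(hbonds) == 0) {
    attr(empty, "hbonds") <- hbonds
    class(empty) <- c("rna_pairs", "data.frame")
    return(empty)
  }
  key <- paste(hbonds$res_i, hbonds$res_j, sep = "\r")
  groups <- split(seq_len(nrow(hbonds)), key)
  rows <- lapply(groups, function(ii) {
    b <- hbonds[ii, , drop = FALSE]
    .classify_pair_impl(model, frames, b$res_i[1], b$res_j[1], b, config)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) == 0) empty else do.call(rbind, rows)
  idx <- match(out$res_a, model$nucleotides$resid)
  jdx <- match(out$res_b, model$nucleotides$resid)
  out <- out[order(idx, jdx), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "hbonds") <- hbonds
  class(out) <- c("rna_pairs", "data.frame")
  out
}

#' Write a base-pair table to TSV
#'
#' @param pairs output of [detect_base_pairs()].
#' @param path output file.
#' @param structure_id label written in the first column.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path, structure_id = "") {
  df <- data.frame(
    structure = structure_id, pairs[, c(
      "res_a", "res_b", "base_a", "base_b", "edge_a", "edge_b",
      "orientation", "canonical", "wobble", "n_hbonds"
    )],
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
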