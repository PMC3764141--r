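# Detectors for the seven tertiary motif classes of the survey: base
# triples (and the quadruples they merge into), A-minor/G-minor
# interactions, ribose zippers, pseudoknots, kissing loops, kink-turns
# and loop-receptor interactions.  All detectors are pure functions of
# the hydrogen-bond table, the classified pairs, the base frames and the
# secondary-structure elements; their acceptance rules are the explicit
# criteria stated in the documentation (no visual inspection step).

.sorted_set_key <- function(resids) paste(sort(resids), collapse = "|")

.model_index <- function(model) {
  stats::setNames(seq_len(nrow(model$nucleotides)), model$nucleotides$resid)
}

.base_of <- function(model) {
  stats::setNames(model$nucleotides$base, model$nucleotides$resid)
}

.number_of <- function(model) {
  stats::setNames(model$nucleotides$number, model$nucleotides$resid)
}

#' Detect base triples
#'
#' A base triple is three distinct residues in which one residue is
#' base-paired to both others (or all three pairwise), every
#' constituent pairing carries at least two base-base hydrogen bonds
#' (already enforced by pair acceptance), and all pairwise base-plane
#' angles stay within the triple planarity cutoff: only planar
#' interactions with at least two hydrogen bonds per base pair qualify.
#'
#' @param model an `rna_structure`.
#' @param pairs [detect_base_pairs()] output.
#' @param frames [base_frames()] output.
#' @param config a [motif_config()].
#' @param ss optional `rna_secondary` for context strings.
#' @return data frame: residues, `pairings` (semicolon list), `bases`,
#'   `composition` (sorted A<C<G<U), `display_composition`,
#'   `contains_wc`, `planarity` (max pairwise plane angle), `context`.
#' @export
detect_triples <- function(model, pairs, frames, config = motif_config(),
                           ss = NULL) {
  empty <- data.frame(
    res1 = character(), res2 = character(), res3 = character(),
    pairings = character(), bases = character(), composition = character(),
    display_composition = character(), contains_wc = logical(),
    planarity = numeric(), context = character(), stringsAsFactors = FALSE
  )
  if (nrow(pairs) < 2) return(empty)
  idx <- .model_index(model)
  base <- .base_of(model)
  partners <- split(
    c(pairs$res_b, pairs$res_a),
    c(pairs$res_a, pairs$res_b)
  )
  pair_key <- paste(pmin(pairs$res_a, pairs$res_b), pmax(pairs$res_a, pairs$res_b))
  canon <- stats::setNames(pairs$canonical, pair_key)
  seen <- character(0)
  rows <- list()
  for (ctr in names(partners)) {
    ps <- unique(partners[[ctr]])
    if (length(ps) < 2) next
    cmb <- utils::combn(ps, 2)
    for (q in seq_len(ncol(cmb))) {
      trio <- c(cmb[1, q], ctr, cmb[2, q])
      key <- .sorted_set_key(trio)
      if (key %in% seen) next
      fr <- frames[trio]
      if (any(vapply(fr, is.null, logical(1)))) next
      angs <- c(
        .plane_angle(fr[[1]]$normal, fr[[2]]$normal),
        .plane_angle(fr[[2]]$normal, fr[[3]]$normal),
        .plane_angle(fr[[1]]$normal, fr[[3]]$normal)
      )
      if (max(angs) > config$triple_planarity_max) next
      seen <- c(seen, key)
      trio <- trio[order(idx[trio])]
      pk <- utils::combn(trio, 2)
      pkey <- paste(pmin(pk[1, ], pk[2, ]), pmax(pk[1, ], pk[2, ]))
      present <- pkey %in% pair_key
      bases3 <- base[trio]
      rows[[length(rows) + 1]] <- data.frame(
        res1 = trio[1], res2 = trio[2], res3 = trio[3],
        pairings = paste(pkey[present], collapse = ";"),
        bases = paste(bases3, collapse = ""),
        composition = paste(sort(bases3), collapse = ""),
        display_composition = paste(
          bases3[order(match(bases3, .composition_display_order))],
          collapse = ""),
        contains_wc = any(canon[pkey[present]]),
        planarity = max(angs),
        context = if (is.null(ss)) NA_character_ else
          classify_context(trio, ss),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(idx[out$res1], idx[out$res2], idx[out$res3]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge base triples into base quadruples
#'
#' Two triples that share a constituent pairing and extend each other to
#' four residues merge into a quadruple.  The constituent triples remain
#' reported (the census counts triples).
#'
#' @param triples [detect_triples()] output.
#' @param pairs [detect_base_pairs()] output.
#' @return data frame with `res1`..`res4` and `members` (the merged
#'   triple keys).
#' @export
detect_quadruples <- function(triples, pairs) {
  empty <- data.frame(
    res1 = character(), res2 = character(), res3 = character(),
    res4 = character(), members = character(), stringsAsFactors = FALSE
  )
  if (nrow(triples) < 2) return(empty)
  pair_key <- paste(pmin(pairs$res_a, pairs$res_b), pmax(pairs$res_a, pairs$res_b))
  tri_sets <- lapply(seq_len(nrow(triples)), function(i) {
    c(triples$res1[i], triples$res2[i], triples$res3[i])
  })
  seen <- character(0)
  rows <- list()
  for (i in seq_len(nrow(triples) - 1)) {
    for (j in (i + 1):nrow(triples)) {
      u <- union(tri_sets[[i]], tri_sets[[j]])
      if (length(u) != 4) next
      shared <- intersect(tri_sets[[i]], tri_sets[[j]])
      if (length(shared) != 2) next
      sk <- paste(min(shared), max(shared))
      if (!sk %in% pair_key) next
      key <- .sorted_set_key(u)
      if (key %in% seen) next
      seen <- c(seen, key)
      u <- sort(u)
      rows[[length(rows) + 1]] <- data.frame(
        res1 = u[1], res2 = u[2], res3 = u[3], res4 = u[4],
        members = paste(i, j, sep = ";"), stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect A-minor (and G-minor) interactions
#'
#' A docking adenosine (or guanosine, for the G-minor variant) that is
#' not itself Watson-Crick paired to the receptor inserts its sugar
#' edge/minor-groove atoms (N3, C2/N2, 2'-OH) into the minor groove of a
#' canonical receptor pair; at least two such hydrogen bonds are
#' required.  Types follow the docking register: type I when both the
#' donor N3 and 2'-OH are bonded and the contacts reach both receptor
#' residues; type 0 when only the donor 2'-OH is involved (the kink-turn
#' internal interaction); type II otherwise.
#'
#' @param model an `rna_structure`.
#' @param pairs [detect_base_pairs()] output.
#' @param hbonds [detect_hbonds()] output.
#' @param config a [motif_config()].
#' @return data frame: `donor`, `donor_base`, `variant`, `receptor_a`,
#'   `receptor_b`, `receptor_label` (receptor bases in 5'-order),
#'   `type`, `n_hbonds`.
#' @export
detect_a_minor <- function(model, pairs, hbonds, config = motif_config()) {
  empty <- data.frame(
    donor = character(), donor_base = character(), variant = character(),
    receptor_a = character(), receptor_b = character(),
    receptor_label = character(), type = character(), n_hbonds = integer(),
    stringsAsFactors = FALSE
  )
  cp <- pairs[pairs$canonical, , drop = FALSE]
  if (nrow(cp) == 0 || nrow(hbonds) == 0) return(empty)
  idx <- .model_index(model)
  base <- .base_of(model)
  wc_partner <- c(
    stats::setNames(cp$res_b, cp$res_a),
    stats::setNames(cp$res_a, cp$res_b)
  )
  donors <- names(base)[base %in% c("A", "G")]
  rows <- list()
  for (k in seq_len(nrow(cp))) {
    p <- cp$res_a[k]; q <- cp$res_b[k]
    rec_minor <- function(r) .minor_groove_atoms[[base[r]]]
    for (r in donors) {
      if (r == p || r == q) next
      if (identical(unname(wc_partner[r]), p) ||
        identical(unname(wc_partner[r]), q)) next
      b <- hbonds[(hbonds$res_i == r & hbonds$res_j %in% c(p, q)) |
        (hbonds$res_j == r & hbonds$res_i %in% c(p, q)), , drop = FALSE]
      if (nrow(b) < config$aminor_min_hbonds) next
      r_atom <- ifelse(b$donor_res == r, b$donor_atom, b$acceptor_atom)
      o_res <- ifelse(b$donor_res == r, b$acceptor_res, b$donor_res)
      o_atom <- ifelse(b$donor_res == r, b$acceptor_atom, b$donor_atom)
      qual <- r_atom %in% .minor_groove_atoms[[base[r]]] &
        mapply(function(rr, aa) aa %in% rec_minor(rr), o_res, o_atom)
      if (sum(qual) < config$aminor_min_hbonds) next
      ra <- r_atom[qual]; ro <- o_res[qual]
      type <- if (all(ra == "O2'")) {
        "0"
      } else if (all(c("N3", "O2'") %in% ra) && length(unique(ro)) == 2) {
        "I"
      } else {
        "II"
      }
      rows[[length(rows) + 1]] <- data.frame(
        donor = r, donor_base = base[r],
        variant = if (base[r] == "G") "G-minor" else "A-minor",
        receptor_a = p, receptor_b = q,
        receptor_label = paste0(base[p], base[q]),
        type = type, n_hbonds = sum(qual), stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(idx[out$donor], idx[out$receptor_a]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect ribose zippers
#'
#' Two sequence-distant dinucleotide backbone segments joined by at
#' least two cross-segment hydrogen bonds that each involve a 2'-OH.
#' The bond signature classifies the zipper: `canonical` when the two
#' 2'-OH-to-2'-OH bonds run in antiparallel register (i with j+1, i+1
#' with j) alongside a 2'-OH-to-base contact; `pseudo-cis` when the
#' 2'-OH pairing runs parallel; `other-variant` otherwise.
#'
#' @param model an `rna_structure`.
#' @param hbonds [detect_hbonds()] output.
#' @param config a [motif_config()].
#' @param pairs optional [detect_base_pairs()] output: segments joined by
#'   a canonical or wobble pair are not zippers (a helix zips its own
#'   strands trivially; the motif is backbone packing between strands
#'   that are not paired to each other).
#' @return data frame: `strand1_a`, `strand1_b`, `strand2_a`,
#'   `strand2_b`, `n_hbonds`, `zclass`.
#' @export
detect_ribose_zipper <- function(model, hbonds, config = motif_config(),
                                 pairs = NULL) {
  paired_key <- if (!is.null(pairs) && nrow(pairs) > 0) {
    cw <- pairs[pairs$canonical | pairs$wobble, , drop = FALSE]
    paste(pmin(cw$res_a, cw$res_b), pmax(cw$res_a, cw$res_b))
  } else {
    character(0)
  }
  empty <- data.frame(
    strand1_a = character(), strand1_b = character(), strand2_a = character(),
    strand2_b = character(), n_hbonds = integer(), zclass = character(),
    stringsAsFactors = FALSE
  )
  res <- model$nucleotides
  idx <- .model_index(model)
  num <- .number_of(model)
  chain <- stats::setNames(res$chain, res$resid)
  oz <- hbonds[hbonds$donor_atom == "O2'" | hbonds$acceptor_atom == "O2'", ,
    drop = FALSE]
  if (nrow(oz) == 0) return(empty)
  next_res <- function(r) {
    i <- idx[r]
    if (i < nrow(res) && chain[res$resid[i + 1]] == chain[r] &&
      num[res$resid[i + 1]] == num[r] + 1) res$resid[i + 1] else NA_character_
  }
  prev_res <- function(r) {
    i <- idx[r]
    if (i > 1 && chain[res$resid[i - 1]] == chain[r] &&
      num[res$resid[i - 1]] == num[r] - 1) res$resid[i - 1] else NA_character_
  }
  cand <- unique(do.call(rbind, lapply(seq_len(nrow(oz)), function(k) {
    u <- oz$res_i[k]; v <- oz$res_j[k]
    expand.grid(i = c(prev_res(u), u), j = c(prev_res(v), v),
      stringsAsFactors = FALSE)
  })))
  cand <- cand[!is.na(cand$i) & !is.na(cand$j), , drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    i1 <- cand$i[k]; j1 <- cand$j[k]
    i2 <- next_res(i1); j2 <- next_res(j1)
    if (is.na(i2) || is.na(j2)) next
    if (chain[i1] == chain[j1] &&
      abs(num[i1] - num[j1]) < config$zipper_min_seq_sep) next
    if (idx[i1] >= idx[j1]) next
    seg1 <- c(i1, i2); seg2 <- c(j1, j2)
    cross <- expand.grid(seg1, seg2, stringsAsFactors = FALSE)
    if (any(paste(pmin(cross[, 1], cross[, 2]),
      pmax(cross[, 1], cross[, 2])) %in% paired_key)) next
    b <- oz[(oz$res_i %in% seg1 & oz$res_j %in% seg2) |
      (oz$res_i %in% seg2 & oz$res_j %in% seg1), , drop = FALSE]
    if (nrow(b) < config$zipper_min_hbonds) next
    oo <- b[b$donor_atom == "O2'" & b$acceptor_atom == "O2'", , drop = FALSE]
    oo_key <- paste(pmin(oo$donor_res, oo$acceptor_res),
      pmax(oo$donor_res, oo$acceptor_res))
    antip <- all(c(paste(min(i1, j2), max(i1, j2)),
      paste(min(i2, j1), max(i2, j1))) %in% oo_key)
    parallel <- all(c(paste(min(i1, j1), max(i1, j1)),
      paste(min(i2, j2), max(i2, j2))) %in% oo_key)
    has_base <- any((b$donor_atom == "O2'" & b$acceptor_moiety == "base") |
      (b$acceptor_atom == "O2'" & b$donor_moiety == "base"))
    zclass <- if (antip && has_base) {
      "canonical"
    } else if (parallel) {
      "pseudo-cis"
    } else {
      "other-variant"
    }
    rows[[length(rows) + 1]] <- data.frame(
      strand1_a = i1, strand1_b = i2, strand2_a = j1, strand2_b = j2,
      n_hbonds = nrow(b), zclass = zclass, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) return(empty)
  out <- unique(do.call(rbind, rows))
  # suppress register-shifted duplicates of the same contact patch
  out <- out[order(-out$n_hbonds, idx[out$strand1_a], idx[out$strand2_a]), ,
    drop = FALSE]
  kept <- list()
  keep <- logical(nrow(out))
  for (k in seq_len(nrow(out))) {
    set <- c(out$strand1_a[k], out$strand1_b[k], out$strand2_a[k], out$strand2_b[k])
    dup <- any(vapply(kept, function(s) length(intersect(s, set)) >= 3, logical(1)))
    if (!dup) {
      keep[k] <- TRUE
      kept[[length(kept) + 1]] <- set
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(idx[out$strand1_a], idx[out$strand2_a]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# do two pairs (as index pairs) cross?  i < k < j < l
.crossing <- function(lo1, hi1, lo2, hi2) {
  (lo1 < lo2 & lo2 < hi1 & hi1 < hi2) | (lo2 < lo1 & lo1 < hi2 & hi2 < hi1)
}

#' Detect pseudoknots
#'
#' Canonical pairs excluded from the nested skeleton are grouped into
#' stems; each such crossing stem, together with the skeleton pairs it
#' crosses, forms one pseudoknot record.  `htype` is set when one side
#' of the crossing stem lies in a hairpin loop of the skeleton (the
#' H-type loop-to-downstream topology).
#'
#' @param model an `rna_structure`.
#' @param skeleton,remainder from [nested_skeleton()] (canonical pairs).
#' @param ss optional `rna_secondary` for the `htype` flag.
#' @return data frame: `group1` (crossing pairs, semicolon list),
#'   `group2` (skeleton pairs crossed), `n_pairs`, `htype`.
#' @export
detect_pseudoknots <- function(model, skeleton, remainder, ss = NULL) {
  empty <- data.frame(
    group1 = character(), group2 = character(), n_pairs = integer(),
    htype = logical(), stringsAsFactors = FALSE
  )
  if (nrow(remainder) == 0) return(empty)
  idx <- .model_index(model)
  rlo <- pmin(idx[remainder$res_a], idx[remainder$res_b])
  rhi <- pmax(idx[remainder$res_a], idx[remainder$res_b])
  slo <- pmin(idx[skeleton$res_a], idx[skeleton$res_b])
  shi <- pmax(idx[skeleton$res_a], idx[skeleton$res_b])
  ord <- order(rlo)
  # group remainder pairs into stems (consecutive stacked pairs)
  groups <- list()
  cur <- integer(0)
  for (k in ord) {
    if (length(cur) > 0) {
      last <- cur[length(cur)]
      if (rlo[k] == rlo[last] + 1 && rhi[k] == rhi[last] - 1) {
        cur <- c(cur, k)
        next
      }
      groups[[length(groups) + 1]] <- cur
    }
    cur <- k
  }
  if (length(cur) > 0) groups[[length(groups) + 1]] <- cur
  rows <- list()
  for (g in groups) {
    crossed <- which(vapply(seq_along(slo), function(s) {
      any(.crossing(rlo[g], rhi[g], slo[s], shi[s]))
    }, logical(1)))
    if (length(crossed) == 0) next
    htype <- FALSE
    if (!is.null(ss)) {
      sides <- c(remainder$res_a[g], remainder$res_b[g])
      htype <- any(ss$kind_of[sides] == "hairpin", na.rm = TRUE)
    }
    fmt <- function(a, b) paste(paste(a, b, sep = "-"), collapse = ";")
    rows[[length(rows) + 1]] <- data.frame(
      group1 = fmt(remainder$res_a[g], remainder$res_b[g]),
      group2 = fmt(skeleton$res_a[crossed], skeleton$res_b[crossed]),
      n_pairs = length(g), htype = htype, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect kissing loops
#'
#' Watson-Crick pairing between the hairpin loops of two distinct stems:
#' at least `kissing_min_pairs` canonical pairs whose residues both lie
#' in (different) hairpin-loop elements.
#'
#' @param model an `rna_structure`.
#' @param pairs [detect_base_pairs()] output (all pairs; canonical used).
#' @param ss an `rna_secondary`.
#' @param config a [motif_config()].
#' @return data frame: `loop_a`, `loop_b`, `pairs` (semicolon list),
#'   `n_pairs`.
#' @export
detect_kissing_loops <- function(model, pairs, ss, config = motif_config()) {
  empty <- data.frame(
    loop_a = character(), loop_b = character(), pairs = character(),
    n_pairs = integer(), stringsAsFactors = FALSE
  )
  cp <- pairs[pairs$canonical, , drop = FALSE]
  if (nrow(cp) == 0) return(empty)
  ka <- ss$kind_of[cp$res_a]; kb <- ss$kind_of[cp$res_b]
  la <- ss$element_of[cp$res_a]; lb <- ss$element_of[cp$res_b]
  sel <- !is.na(ka) & !is.na(kb) & ka == "hairpin" & kb == "hairpin" & la != lb
  cp <- cp[sel, , drop = FALSE]
  if (nrow(cp) == 0) return(empty)
  key <- paste(pmin(la[sel], lb[sel]), pmax(la[sel], lb[sel]), sep = "~")
  rows <- lapply(split(seq_len(nrow(cp)), key), function(ii) {
    if (length(ii) < config$kissing_min_pairs) return(NULL)
    data.frame(
      loop_a = min(la[sel][ii[1]], lb[sel][ii[1]]),
      loop_b = max(la[sel][ii[1]], lb[sel][ii[1]]),
      pairs = paste(paste(cp$res_a[ii], cp$res_b[ii], sep = "-"), collapse = ";"),
      n_pairs = length(ii), stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# helical axis of a stem: the line through the C1'-C1' midpoints of its
# pairs, oriented from the `from` pair towards the `to` pair (so the
# across-pair spread does not masquerade as the axis)
.stem_axis <- function(model, pair_list, from_pair, to_pair) {
  mid <- function(pr) {
    a <- .residue_coord(model, pr[1], "C1'")
    b <- .residue_coord(model, pr[2], "C1'")
    if (is.null(a) || is.null(b)) return(NULL)
    (a + b) / 2
  }
  mids <- lapply(pair_list, mid)
  if (any(vapply(mids, is.null, logical(1))) || length(mids) < 2) return(NULL)
  mids <- do.call(rbind, mids)
  d <- if (nrow(mids) == 2) mids[2, ] - mids[1, ] else .fit_line(mids)$direction
  cf <- mid(from_pair); ct <- mid(to_pair)
  if (is.null(cf) || is.null(ct)) return(NULL)
  if (sum(d * (ct - cf)) < 0) d <- -d
  .unit(d)
}

#' Detect kink-turns
#'
#' Helix-bulge-helix pattern: a canonical stem (C-stem), a short bulge
#' (2-4 nt by default) on one strand, then a non-canonical stem opened
#' by tandem sheared G-A pairs (Sugar/Hoogsteen edges).  The sharp kink
#' is required geometrically: the two stem axes, each oriented away from
#' the bulge junction, must make an angle of at most
#' `kink_axis_angle_max` (coaxial stems measure close to 180 degrees).
#' An A-minor into the C-stem, when present, is attached as the internal
#' interaction.
#'
#' @param model an `rna_structure`.
#' @param pairs [detect_base_pairs()] output.
#' @param ss an `rna_secondary`.
#' @param config a [motif_config()].
#' @param a_minors optional [detect_a_minor()] output for the internal
#'   interaction.
#' @return data frame: `c_stem` (label), `nc_pairs`, `bulge` (residues),
#'   `ga_pairs`, `axis_angle`, `internal_a_minor`.
#' @export
detect_kink_turn <- function(model, pairs, ss, config = motif_config(),
                             a_minors = NULL) {
  empty <- data.frame(
    c_stem = character(), nc_pairs = character(), bulge = character(),
    ga_pairs = character(), axis_angle = numeric(),
    internal_a_minor = character(), stringsAsFactors = FALSE
  )
  idx <- .model_index(model)
  num <- .number_of(model)
  nc <- pairs[!pairs$canonical & !pairs$wobble, , drop = FALSE]
  is_ga <- (nc$base_a == "G" & nc$base_b == "A" &
    nc$edge_a == "Sugar" & nc$edge_b == "Hoogsteen") |
    (nc$base_a == "A" & nc$base_b == "G" &
      nc$edge_a == "Hoogsteen" & nc$edge_b == "Sugar")
  ga <- nc[is_ga, , drop = FALSE]
  if (nrow(ga) < 2) return(empty)
  glo <- pmin(idx[ga$res_a], idx[ga$res_b])
  ghi <- pmax(idx[ga$res_a], idx[ga$res_b])
  rows <- list()
  stems <- ss$stems
  for (i in seq_len(nrow(ga) - 1)) {
    for (j in (i + 1):nrow(ga)) {
      # tandem: adjacent on both strands, antiparallel stack
      if (!(abs(glo[i] - glo[j]) == 1 && abs(ghi[i] - ghi[j]) == 1 &&
        (glo[i] - glo[j]) * (ghi[i] - ghi[j]) < 0)) next
      nc_lo <- min(glo[i], glo[j]); nc_hi <- max(ghi[i], ghi[j])
      nc_res_near5 <- model$nucleotides$resid[max(glo[i], glo[j])]
      for (s in seq_len(nrow(stems))) {
        st <- stems[s, ]
        p <- ss$per[[st$chain]]
        # bulge on the 5' strand between the stem and the NC stem
        gap5 <- nc_lo - idx[p$resid[st$i2]] - 1
        gap3 <- idx[p$resid[st$j2]] - nc_hi - 1
        ok <- FALSE
        if (gap5 >= config$kink_bulge_range[1] &&
          gap5 <= config$kink_bulge_range[2] && abs(gap3) <= 1 && gap3 >= 0) {
          bulge_idx <- (idx[p$resid[st$i2]] + 1):(nc_lo - 1)
          bulge_side <- "5"
          ok <- TRUE
        } else if (gap3 >= config$kink_bulge_range[1] &&
          gap3 <= config$kink_bulge_range[2] && gap5 >= 0 && gap5 <= 1) {
          bulge_idx <- (nc_hi + 1):(idx[p$resid[st$j2]] - 1)
          bulge_side <- "3"
          ok <- TRUE
        }
        if (!ok) next
        bulge_res <- model$nucleotides$resid[bulge_idx]
        # unpaired bulge only
        if (any(!is.na(p$partner[match(bulge_res, p$resid)]))) next
        c_res <- p$resid[c(st$i1:st$i2, st$j2:st$j1)]
        nc_res <- unique(c(ga$res_a[c(i, j)], ga$res_b[c(i, j)]))
        c_pairs <- lapply(0:(st$n_pairs - 1), function(q) {
          p$resid[c(st$i1 + q, st$j1 - q)]
        })
        ax_c <- .stem_axis(model, c_pairs,
          from_pair = c_pairs[[length(c_pairs)]], to_pair = c_pairs[[1]])
        # the NC pair adjacent to the bulge junction: outermost on the
        # bulged strand
        near_k <- if (bulge_side == "5") {
          if (glo[i] < glo[j]) i else j
        } else {
          if (ghi[i] > ghi[j]) i else j
        }
        far_k <- if (near_k == i) j else i
        nc_pairs_l <- list(c(ga$res_a[near_k], ga$res_b[near_k]),
          c(ga$res_a[far_k], ga$res_b[far_k]))
        ax_nc <- .stem_axis(model, nc_pairs_l,
          from_pair = nc_pairs_l[[1]], to_pair = nc_pairs_l[[2]])
        if (is.null(ax_c) || is.null(ax_nc)) next
        angle <- .vangle(ax_c, ax_nc)
        if (angle > config$kink_axis_angle_max) next
        internal <- NA_character_
        if (!is.null(a_minors) && nrow(a_minors) > 0) {
          hit <- which(a_minors$donor %in% nc_res &
            a_minors$receptor_a %in% c_res & a_minors$receptor_b %in% c_res)
          if (length(hit) > 0) {
            internal <- paste0(a_minors$donor[hit[1]], ">",
              a_minors$receptor_a[hit[1]], "-", a_minors$receptor_b[hit[1]])
          }
        }
        rows[[length(rows) + 1]] <- data.frame(
          c_stem = st$label,
          nc_pairs = paste(paste(ga$res_a[c(i, j)], ga$res_b[c(i, j)],
            sep = "-"), collapse = ";"),
          bulge = paste(bulge_res, collapse = ";"),
          ga_pairs = paste(paste(ga$res_a[c(i, j)], ga$res_b[c(i, j)],
            sep = "-"), collapse = ";"),
          axis_angle = angle, internal_a_minor = internal,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Detect loop-receptor interactions
#'
#' A short hairpin loop (tetraloop or pentaloop) docking into a distal
#' stem: at least one of its residues forms an A-minor into a pair of a
#' stem belonging to a different helix group.  A ribose zipper whose
#' loop-side strand lies in the same loop is attached when present.
#'
#' @param model an `rna_structure`.
#' @param ss an `rna_secondary`.
#' @param a_minors [detect_a_minor()] output.
#' @param zippers [detect_ribose_zipper()] output.
#' @param config a [motif_config()].
#' @return data frame: `loop`, `loop_size`, `receptor_stem`, `a_minors`,
#'   `zipper`.
#' @export
detect_loop_receptor <- function(model, ss, a_minors, zippers,
                                 config = motif_config()) {
  empty <- data.frame(
    loop = character(), loop_size = integer(), receptor_stem = character(),
    a_minors = character(), zipper = character(), stringsAsFactors = FALSE
  )
  if (length(ss$loops) == 0 || nrow(a_minors) == 0) return(empty)
  hairpins <- Filter(function(l) l$kind == "hairpin" &&
    length(l$resids) %in% config$loop_receptor_sizes, ss$loops)
  if (length(hairpins) == 0) return(empty)
  rows <- list()
  for (l in hairpins) {
    am <- a_minors[a_minors$donor %in% l$resids, , drop = FALSE]
    if (nrow(am) == 0) next
    rec_elem <- ss$element_of[am$receptor_a]
    rec_stem <- rec_elem[ss$kind_of[am$receptor_a] == "stem"]
    # receptor must sit in a different helix group than the loop's own stem
    own <- paste0("P", l$stem_group)
    rec_stem <- rec_stem[!is.na(rec_stem) &
      sub("[a-z]$", "", rec_stem) != own]
    if (length(rec_stem) == 0) next
    zip <- ""
    if (nrow(zippers) > 0) {
      zi <- which(
        (zippers$strand1_a %in% l$resids & zippers$strand1_b %in% l$resids) |
          (zippers$strand2_a %in% l$resids & zippers$strand2_b %in% l$resids)
      )
      if (length(zi) > 0) {
        zip <- paste(zippers$strand1_a[zi[1]], zippers$strand1_b[zi[1]],
          zippers$strand2_a[zi[1]], zippers$strand2_b[zi[1]], sep = ";")
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      loop = l$label, loop_size = length(l$resids),
      receptor_stem = rec_stem[1],
      a_minors = paste(am$donor, collapse = ";"), zipper = zip,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
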