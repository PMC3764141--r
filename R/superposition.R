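# Sequence-guided rigid superposition: residues of two structures are
# matched by global sequence alignment, then a closed-form least-squares
# rotation (proper rotation enforced) fits matched backbone/glycosidic
# atoms, optionally with iterative pruning of badly fitting residue
# pairs, emulating the pruned-core behaviour of interactive matchers.

.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = R, translation = as.numeric(cq - R %*% cp))
}

#' Match residues of two structures by sequence alignment
#'
#' Global affine-gap alignment of the extracted chain sequences; aligned
#' non-gap positions whose residues both carry the selected atoms
#' (C4', C1' and the glycosidic nitrogen; P added when present on both
#' sides) become correspondences.
#'
#' @param a,b `rna_structure` models.
#' @param chain_a,chain_b chain ids (default: the single chain).
#' @param config a [motif_config()].
#' @return object of class `correspondence_set`: `pairs` (data frame
#'   `res_a`, `res_b`), `atoms` (list of per-pair atom-name pairs),
#'   `selection` description.
#' @export
match_residues <- function(a, b, chain_a = NULL, chain_b = NULL,
                           config = motif_config()) {
  ea <- extract_sequence(a, chain_a)
  eb <- extract_sequence(b, chain_b)
  pa <- .pairwise_align(ea$sequence, eb$sequence, config)
  sa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ia <- 0; ib <- 0
  pairs <- list(); atom_sel <- list()
  core <- c("C4'", "C1'")
  for (k in seq_along(sa)) {
    if (sa[k] != "-") ia <- ia + 1
    if (sb[k] != "-") ib <- ib + 1
    if (sa[k] == "-" || sb[k] == "-") next
    ra <- ea$map$resid[ia]; rb <- eb$map$resid[ib]
    ba <- ea$map$base[ia]; bb <- eb$map$base[ib]
    if (!ba %in% names(.glycosidic_atom) || !bb %in% names(.glycosidic_atom)) next
    sel_a <- c(core, .glycosidic_atom[[ba]])
    sel_b <- c(core, .glycosidic_atom[[bb]])
    at_a <- .residue_atoms(a, ra)$atom
    at_b <- .residue_atoms(b, rb)$atom
    if (!all(sel_a %in% at_a) || !all(sel_b %in% at_b)) next
    if ("P" %in% at_a && "P" %in% at_b) {
      sel_a <- c("P", sel_a); sel_b <- c("P", sel_b)
    }
    pairs[[length(pairs) + 1]] <- c(ra, rb)
    atom_sel[[length(atom_sel) + 1]] <- list(a = sel_a, b = sel_b)
  }
  if (length(pairs) == 0) stop("no alignable residues between models")
  pm <- do.call(rbind, pairs)
  structure(
    list(
      pairs = data.frame(res_a = pm[, 1], res_b = pm[, 2],
        stringsAsFactors = FALSE),
      atoms = atom_sel,
      selection = "P (when present), C4', C1', glycosidic N"
    ),
    class = "correspondence_set"
  )
}

#' Least-squares rigid superposition with optional pruning
#'
#' Closed-form optimal rotation/translation (proper rotation enforced;
#' reflections are never returned) mapping the first structure onto the
#' second over the matched atoms.  With a prune cutoff, the fit is
#' iterated: residue pairs whose RMS deviation exceeds the cutoff are
#' discarded and the remaining pairs refitted until stable.  Pruning and
#' refitting can only lower the reported RMSD.
#'
#' @param corr a `correspondence_set` from [match_residues()].
#' @param a,b the two `rna_structure` models.
#' @param prune_cutoff residue deviation cutoff in Angstrom, or `NULL`
#'   to disable pruning.
#' @return object of class `superposition`: `rotation` (3x3, det +1),
#'   `translation`, `rmsd` (over retained pairs), `n_matched`, `pruned`
#'   (discarded residue pairs), `retained`.
#' @export
superpose <- function(corr, a, b, prune_cutoff = 2) {
  n <- nrow(corr$pairs)
  if (n < 3) stop("need at least 3 correspondences, got ", n)
  coords <- function(model, resid, atoms) {
    do.call(rbind, lapply(atoms, function(at) .residue_coord(model, resid, at)))
  }
  X <- list(); Y <- list()
  for (k in seq_len(n)) {
    X[[k]] <- coords(a, corr$pairs$res_a[k], corr$atoms[[k]]$a)
    Y[[k]] <- coords(b, corr$pairs$res_b[k], corr$atoms[[k]]$b)
  }
  active <- seq_len(n)
  repeat {
    P <- do.call(rbind, X[active])
    Q <- do.call(rbind, Y[active])
    fit <- .kabsch(P, Q)
    dev <- vapply(active, function(k) {
      T <- sweep(X[[k]] %*% t(fit$rotation), 2, -fit$translation)
      sqrt(mean(rowSums((T - Y[[k]])^2)))
    }, numeric(1))
    if (is.null(prune_cutoff) || all(dev <= prune_cutoff)) break
    # discard the single worst pair, then refit: one gross outlier must
    # not drag well-fitting residues over the cutoff
    if (length(active) - 1 < 3) {
      stop("fewer than 3 correspondences remain after pruning")
    }
    active <- active[-which.max(dev)]
  }
  P <- do.call(rbind, X[active])
  Q <- do.call(rbind, Y[active])
  T <- sweep(P %*% t(fit$rotation), 2, -fit$translation)
  rmsd <- sqrt(mean(rowSums((T - Q)^2)))
  structure(
    list(
      rotation = fit$rotation, translation = fit$translation, rmsd = rmsd,
      n_matched = length(active),
      pruned = corr$pairs[setdiff(seq_len(n), active), , drop = FALSE],
      retained = corr$pairs[active, , drop = FALSE]
    ),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(
    "<superposition> rmsd", sprintf("%.3f", x$rmsd), "A over", x$n_matched,
    "residues (", nrow(x$pruned), "pruned )\n"
  )
  invisible(x)
}

#' Superpose two structures in one call
#'
#' [match_residues()] followed by [superpose()].
#'
#' @inheritParams match_residues
#' @param prune_cutoff see [superpose()]; `NULL` disables pruning.
#' @return a `superposition`.
#' @export
superpose_structures <- function(a, b, chain_a = NULL, chain_b = NULL,
                                 prune_cutoff = 2, config = motif_config()) {
  corr <- match_residues(a, b, chain_a, chain_b, config)
  superpose(corr, a, b, prune_cutoff)
}

#' Apply a rigid transform to a structure
#'
#' @param model an `rna_structure`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector.
#' @return the transformed `rna_structure`.
#' @export
transform_structure <- function(model, rotation, translation = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(rotation), 2, -translation)
  model$atoms[, c("x", "y", "z")] <- xyz
  if (nrow(model$hetero) > 0) {
    hz <- as.matrix(model$hetero[, c("x", "y", "z")])
    model$hetero[, c("x", "y", "z")] <- sweep(hz %*% t(rotation), 2, -translation)
  }
  model
}
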