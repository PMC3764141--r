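# Nested secondary structure from canonical pairs.  A maximum-cardinality
# non-crossing one-pairing-per-residue skeleton is selected by dynamic
# programming; stacked runs become stems labelled P1, P2, ... (sub-stems
# separated by internal loops get letter suffixes, P2a/P2b), hairpin
# loops are L(k), unpaired runs at multiloops are junctions Ji-j.  These
# element labels render the structural-context strings used to report
# where a tertiary motif sits.

#' Select the maximum nested (non-crossing) subset of pairs
#'
#' Dynamic programming over residue intervals: among the given pairs, a
#' maximum-cardinality subset is chosen such that no residue pairs twice
#' and no two pairs cross.  Ties are broken towards pairs with more
#' hydrogen bonds, then towards 5'-earlier pairs.  Pairs left out (the
#' crossing remainder: pseudoknots, kissing loops, inter-chain pairs)
#' are returned separately.
#'
#' @param pairs a pair data frame (normally the canonical + wobble subset
#'   of [detect_base_pairs()]).
#' @param model the `rna_structure` the pairs refer to (for residue order).
#' @return list with elements `skeleton` and `remainder`, both subsets of
#'   `pairs`.
#' @export
nested_skeleton <- function(pairs, model) {
  res_order <- model$nucleotides$resid
  chain_of <- stats::setNames(model$nucleotides$chain, res_order)
  if (nrow(pairs) == 0) {
    return(list(skeleton = pairs, remainder = pairs))
  }
  ia <- match(pairs$res_a, res_order)
  ib <- match(pairs$res_b, res_order)
  intra <- chain_of[pairs$res_a] == chain_of[pairs$res_b]
  cand <- which(intra)
  if (length(cand) == 0) {
    return(list(skeleton = pairs[0, , drop = FALSE], remainder = pairs))
  }
  pos <- sort(unique(c(ia[cand], ib[cand])))
  m <- length(pos)
  ci <- match(ia[cand], pos)
  cj <- match(ib[cand], pos)
  lo <- pmin(ci, cj); hi <- pmax(ci, cj)
  nh <- if ("n_hbonds" %in% names(pairs)) pairs$n_hbonds[cand] else rep(2, length(cand))
  # cardinality dominates; small biases break ties deterministically
  w <- 1 + 1e-6 * nh + 1e-9 * (m - lo) / m
  W <- matrix(NA_real_, m, m)
  ID <- matrix(NA_integer_, m, m)
  for (k in seq_along(cand)) {
    if (is.na(W[lo[k], hi[k]]) || w[k] > W[lo[k], hi[k]]) {
      W[lo[k], hi[k]] <- w[k]
      ID[lo[k], hi[k]] <- cand[k]
    }
  }
  best <- matrix(0, m + 1, m + 1) # best[i, j+1], 1-based guards
  for (span in 1:m) {
    for (i in seq_len(m - span + 1)) {
      j <- i + span - 1
      b <- best[i + 1, j + 1]
      ks <- which(!is.na(W[i, seq_len(m)])) # partners of i
      ks <- ks[ks <= j]
      for (k in ks) {
        v <- W[i, k] + (if (k - 1 >= i + 1) best[i + 1, k] else 0) +
          (if (k + 1 <= j) best[k + 1, j + 1] else 0)
        if (v > b + 1e-12) b <- v
      }
      best[i, j + 1] <- b
    }
  }
  chosen <- integer(0)
  stack <- list(c(1, m))
  while (length(stack) > 0) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    if (i > j) next
    if (abs(best[i, j + 1] - best[i + 1, j + 1]) < 1e-12) {
      stack[[length(stack) + 1]] <- c(i + 1, j)
      next
    }
    ks <- which(!is.na(W[i, seq_len(m)]))
    ks <- ks[ks <= j]
    for (k in ks) {
      v <- W[i, k] + (if (k - 1 >= i + 1) best[i + 1, k] else 0) +
        (if (k + 1 <= j) best[k + 1, j + 1] else 0)
      if (abs(best[i, j + 1] - v) < 1e-12) {
        chosen <- c(chosen, ID[i, k])
        stack[[length(stack) + 1]] <- c(i + 1, k - 1)
        stack[[length(stack) + 1]] <- c(k + 1, j)
        break
      }
    }
  }
  keep <- sort(chosen)
  list(
    skeleton = pairs[keep, , drop = FALSE],
    remainder = pairs[setdiff(seq_len(nrow(pairs)), keep), , drop = FALSE]
  )
}

.elements_one_chain <- function(skeleton, model, chain) {
  res <- model$nucleotides[model$nucleotides$chain == chain, , drop = FALSE]
  n <- nrow(res)
  resid <- res$resid
  partner <- rep(NA_integer_, n)
  if (nrow(skeleton) > 0) {
    sa <- match(skeleton$res_a, resid)
    sb <- match(skeleton$res_b, resid)
    ok <- !is.na(sa) & !is.na(sb)
    partner[sa[ok]] <- sb[ok]
    partner[sb[ok]] <- sa[ok]
  }

  # stems: maximal stacked runs
  stems <- list()
  i <- 1
  while (i <= n) {
    j <- partner[i]
    if (!is.na(j) && j > i) {
      len <- 1
      while (i + len <= n && !is.na(partner[i + len]) &&
        partner[i + len] == j - len && j - len > i + len) {
        len <- len + 1
      }
      stems[[length(stems) + 1]] <- list(
        i1 = i, i2 = i + len - 1, j2 = j - len + 1, j1 = j, n_pairs = len
      )
      i <- i + len
    } else {
      i <- i + 1
    }
  }
  ns <- length(stems)
  elem <- rep(NA_character_, n)
  kind <- rep(NA_character_, n)
  stem_df <- data.frame(
    label = character(), group = integer(), i1 = integer(), i2 = integer(),
    j2 = integer(), j1 = integer(), n_pairs = integer(),
    stringsAsFactors = FALSE
  )
  loops <- list(); juncs <- list()
  if (ns > 0) {
    # nesting: parent = smallest enclosing stem
    parent <- rep(0L, ns)
    for (a in seq_len(ns)) {
      enc <- which(vapply(seq_len(ns), function(b) {
        b != a && stems[[b]]$i2 < stems[[a]]$i1 && stems[[a]]$j1 < stems[[b]]$j2
      }, logical(1)))
      if (length(enc) > 0) {
        spans <- vapply(enc, function(b) stems[[b]]$j1 - stems[[b]]$i1, numeric(1))
        parent[a] <- enc[which.min(spans)]
      }
    }
    children <- lapply(seq_len(ns), function(s) which(parent == s))
    # helix groups: chains through single-child links
    group <- rep(NA_integer_, ns)
    letter <- rep("", ns)
    heads <- which(vapply(seq_len(ns), function(s) {
      p <- parent[s]
      p == 0 || length(children[[p]]) != 1
    }, logical(1)))
    heads <- heads[order(vapply(heads, function(s) stems[[s]]$i1, numeric(1)))]
    gmember <- list()
    for (g in seq_along(heads)) {
      s <- heads[g]
      members <- s
      while (length(children[[s]]) == 1) {
        s <- children[[s]]
        members <- c(members, s)
      }
      group[members] <- g
      gmember[[g]] <- members
      if (length(members) > 1) letter[members] <- letters[seq_along(members)]
    }
    stem_label <- paste0("P", group, letter)
    for (s in seq_len(ns)) {
      st <- stems[[s]]
      ii <- c(st$i1:st$i2, st$j2:st$j1)
      elem[ii] <- stem_label[s]
      kind[ii] <- "stem"
    }
    stem_df <- data.frame(
      label = stem_label, group = group,
      i1 = vapply(stems, function(s) as.integer(s$i1), integer(1)),
      i2 = vapply(stems, function(s) as.integer(s$i2), integer(1)),
      j2 = vapply(stems, function(s) as.integer(s$j2), integer(1)),
      j1 = vapply(stems, function(s) as.integer(s$j1), integer(1)),
      n_pairs = vapply(stems, function(s) as.integer(s$n_pairs), integer(1)),
      stringsAsFactors = FALSE
    )
    mark <- function(ii, label, k) {
      if (length(ii) == 0) return(invisible(NULL))
      elem[ii] <<- label
      kind[ii] <<- k
    }
    # hairpin loops and internal loops / bulges
    for (g in seq_along(gmember)) {
      members <- gmember[[g]]
      for (t in seq_along(members)) {
        s <- members[t]
        st <- stems[[s]]
        if (length(children[[s]]) == 0) {
          ii <- if (st$i2 + 1 <= st$j2 - 1) (st$i2 + 1):(st$j2 - 1) else integer(0)
          ii <- ii[is.na(elem[ii])]
          if (length(ii) > 0) {
            mark(ii, paste0("L", g), "hairpin")
            loops[[length(loops) + 1]] <- list(
              label = paste0("L", g), kind = "hairpin", idx = ii, stem_group = g
            )
          }
        } else if (t < length(members)) {
          cs <- stems[[members[t + 1]]]
          side5 <- if (st$i2 + 1 <= cs$i1 - 1) (st$i2 + 1):(cs$i1 - 1) else integer(0)
          side3 <- if (cs$j1 + 1 <= st$j2 - 1) (cs$j1 + 1):(st$j2 - 1) else integer(0)
          k <- if (length(side5) > 0 && length(side3) > 0) "internal" else "bulge"
          lab <- paste0(if (k == "internal") "IL" else "B", g,
            if (t > 1) paste0(".", t) else "")
          mark(c(side5, side3), lab, k)
          if (length(c(side5, side3)) > 0) {
            loops[[length(loops) + 1]] <- list(
              label = lab, kind = k, idx = c(side5, side3), stem_group = g
            )
          }
        }
      }
    }
    # junctions at multiloops (stems with >=2 children) and at the root
    add_junction <- function(ii, g5, g3) {
      ii <- ii[is.na(elem[ii])]
      if (length(ii) == 0) return(invisible(NULL))
      lab <- paste0("J", g5, "-", g3)
      mark(ii, lab, "junction")
      juncs[[length(juncs) + 1]] <<- list(label = lab, idx = ii,
        flank5 = g5, flank3 = g3)
    }
    mltabs <- which(vapply(seq_len(ns), function(s) length(children[[s]]) >= 2,
      logical(1)))
    for (s in mltabs) {
      st <- stems[[s]]
      kids <- children[[s]][order(vapply(children[[s]],
        function(c) stems[[c]]$i1, numeric(1)))]
      g0 <- group[s]
      segs_from <- c(st$i2, vapply(kids, function(c) as.integer(stems[[c]]$j1), integer(1)))
      segs_to <- c(vapply(kids, function(c) as.integer(stems[[c]]$i1), integer(1)), st$j2)
      gs <- c(g0, group[kids]); ge <- c(group[kids], g0)
      for (q in seq_along(segs_from)) {
        lo <- segs_from[q] + 1; hi <- segs_to[q] - 1
        if (lo <= hi) add_junction(lo:hi, gs[q], ge[q])
      }
    }
    # root-level segments between top-level stems
    tops <- which(parent == 0)
    tops <- tops[order(vapply(tops, function(s) stems[[s]]$i1, numeric(1)))]
    if (length(tops) >= 2) {
      for (q in seq_len(length(tops) - 1)) {
        lo <- stems[[tops[q]]]$j1 + 1
        hi <- stems[[tops[q + 1]]]$i1 - 1
        if (lo <= hi) add_junction(lo:hi, group[tops[q]], group[tops[q + 1]])
      }
    }
  }
  ext <- which(is.na(elem))
  if (length(ext) > 0) {
    elem[ext] <- "E"
    kind[ext] <- "exterior"
  }
  list(
    stems = stem_df, loops = loops, junctions = juncs,
    element_of = stats::setNames(elem, resid),
    kind_of = stats::setNames(kind, resid),
    resid = resid, partner = partner
  )
}

#' Build labelled secondary-structure elements from a nested skeleton
#'
#' @param skeleton_pairs the `skeleton` component of [nested_skeleton()].
#' @param model an `rna_structure`.
#' @return object of class `rna_secondary`: `stems` (data frame with
#'   labels and residue ranges), `loops` and `junctions` (lists),
#'   `element_of` / `kind_of` (named vectors over all residues), and
#'   `dotbracket`.
#' @export
build_elements <- function(skeleton_pairs, model) {
  chains <- unique(model$nucleotides$chain)
  per <- lapply(chains, function(ch) .elements_one_chain(skeleton_pairs, model, ch))
  names(per) <- chains
  prefix <- length(chains) > 1
  element_of <- character(0); kind_of <- character(0)
  stems <- list(); loops <- list(); junctions <- list()
  for (ch in chains) {
    p <- per[[ch]]
    lab <- p$element_of
    if (prefix) lab <- paste0(ch, ":", lab)
    element_of <- c(element_of, stats::setNames(lab, names(p$element_of)))
    kind_of <- c(kind_of, p$kind_of)
    st <- p$stems
    if (nrow(st) > 0) {
      st$chain <- ch
      if (prefix) st$label <- paste0(ch, ":", st$label)
      st$res_i1 <- p$resid[st$i1]; st$res_j1 <- p$resid[st$j1]
      stems[[length(stems) + 1]] <- st
    }
    loops <- c(loops, lapply(p$loops, function(l) {
      l$resids <- p$resid[l$idx]
      l$chain <- ch
      if (prefix) l$label <- paste0(ch, ":", l$label)
      l
    }))
    junctions <- c(junctions, lapply(p$junctions, function(j) {
      j$resids <- p$resid[j$idx]
      j$chain <- ch
      if (prefix) j$label <- paste0(ch, ":", j$label)
      j
    }))
  }
  stems <- if (length(stems) > 0) do.call(rbind, stems) else
    data.frame(label = character(), group = integer(), n_pairs = integer())
  structure(
    list(
      stems = stems, loops = loops, junctions = junctions,
      element_of = element_of, kind_of = kind_of, chains = chains, per = per
    ),
    class = "rna_secondary"
  )
}

#' Dot-bracket string of a structure
#'
#' Skeleton pairs render as `()`; crossing-remainder pairs are layered
#' into `[]`, `{}`, `<>` brackets.
#'
#' @param model an `rna_structure`.
#' @param skeleton,remainder pair subsets from [nested_skeleton()].
#' @return a character string, one symbol per nucleotide in model order.
#' @export
dot_bracket <- function(model, skeleton, remainder = NULL) {
  res <- model$nucleotides$resid
  n <- length(res)
  s <- rep(".", n)
  open <- c("(", "[", "{", "<"); close <- c(")", "]", "}", ">")
  layer_pairs <- list()
  place <- function(pairs_df, layer) {
    ia <- match(pairs_df$res_a, res); ib <- match(pairs_df$res_b, res)
    lo <- pmin(ia, ib); hi <- pmax(ia, ib)
    s[lo] <<- open[layer]; s[hi] <<- close[layer]
    layer_pairs[[layer]] <<- rbind(layer_pairs[[layer]], cbind(lo, hi))
  }
  crosses_layer <- function(lo, hi, layer) {
    lp <- layer_pairs[[layer]]
    if (is.null(lp) || nrow(lp) == 0) return(FALSE)
    any((lp[, 1] < lo & lo < lp[, 2] & lp[, 2] < hi) |
      (lo < lp[, 1] & lp[, 1] < hi & hi < lp[, 2]))
  }
  layer_pairs <- vector("list", 4)
  if (nrow(skeleton) > 0) place(skeleton, 1)
  if (!is.null(remainder) && nrow(remainder) > 0) {
    ia <- match(remainder$res_a, res); ib <- match(remainder$res_b, res)
    for (k in order(pmin(ia, ib))) {
      lo <- min(ia[k], ib[k]); hi <- max(ia[k], ib[k])
      for (layer in 2:4) {
        if (!crosses_layer(lo, hi, layer)) {
          s[lo] <- open[layer]; s[hi] <- close[layer]
          layer_pairs[[layer]] <- rbind(layer_pairs[[layer]], cbind(lo, hi))
          break
        }
      }
    }
  }
  paste(s, collapse = "")
}

#' Structural-context string of a motif
#'
#' Renders the multiset of secondary-structure element kinds touched by
#' the motif residues in the style used to report motif locations:
#' "Helix - junction interaction (P2b & J3-4)", "Interaction between
#' junctions (J1-2 & J2-3)", "Bulged-out residue - helix interaction
#' (P2 & P5)", and so on.
#'
#' @param resids motif residue identifiers.
#' @param ss an `rna_secondary`.
#' @return a context string; `"unassigned"` (with a warning) when a
#'   residue is not mapped.
#' @export
classify_context <- function(resids, ss) {
  lab <- ss$element_of[resids]
  knd <- ss$kind_of[resids]
  if (any(is.na(lab))) {
    warning("unmapped residues in context: ",
      paste(resids[is.na(lab)], collapse = ", "))
    return("unassigned")
  }
  host_stem <- function(i) {
    # the stem a bulged/internal-loop residue hangs off (same group)
    l <- ss$loops[[which(vapply(ss$loops, function(x) resids[i] %in% x$resids,
      logical(1)))[1]]]
    paste0("P", l$stem_group)
  }
  ord <- seq_along(resids)
  if (any(knd == "bulge")) {
    stem_labels <- unique(c(
      vapply(which(knd == "bulge"), host_stem, character(1)),
      lab[knd == "stem"]
    ))
    # strip sub-stem letters for the bulge-host rendering
    stem_labels <- unique(sub("^(P[0-9]+)[a-z]$", "\\1", stem_labels))
    return(paste0(
      "Bulged-out residue - helix interaction (",
      paste(stem_labels, collapse = " & "), ")"
    ))
  }
  if (all(knd == "junction")) {
    labs <- unique(lab)
    if (length(labs) == 1) {
      return(paste0("Interaction within junction (", labs, ")"))
    }
    return(paste0(
      "Interaction between junctions (", paste(labs, collapse = " & "), ")"
    ))
  }
  word <- c(
    stem = "helix", hairpin = "hairpin loop", junction = "junction",
    internal = "internal loop", bulge = "bulged-out residue",
    exterior = "exterior"
  )
  first_at <- ord[!duplicated(knd)]
  kinds_u <- knd[first_at]
  labs <- unique(lab)
  words <- word[kinds_u]
  if (length(words) == 1) words <- c(words, words)
  words[1] <- paste0(toupper(substr(words[1], 1, 1)), substr(words[1], 2, nchar(words[1])))
  sep <- if (length(labs) >= 3) ", " else " & "
  paste0(
    paste(words, collapse = " - "), " interaction (",
    paste(labs, collapse = sep), ")"
  )
}

#' Write element labels to TSV
#'
#' @param ss an `rna_secondary`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_elements_tsv <- function(ss, path) {
  df <- data.frame(
    resid = names(ss$element_of), element = unname(ss$element_of),
    kind = unname(ss$kind_of[names(ss$element_of)]), stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
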