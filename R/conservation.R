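# Alignment conservation: Stockholm parsing, per-column base frequency
# profiles with the strict "more than 95%" conservation rule, pairwise
# insertion of a structure-derived sequence into an existing alignment,
# and per-motif conservation classification.

#' Read a Stockholm 1.0 alignment
#'
#' Parses sequence rows (wrapped blocks are concatenated) and retains
#' `#=GC` annotation lines (consensus structure and friends).  The RNA
#' alphabet is normalised: upper case, `T` to `U`; gap symbols `-`, `.`
#' and `~` become `-`; other symbols are kept as ambiguity codes (they
#' count in the denominator but are never modal).
#'
#' @param path file path.
#' @return object of class `stockholm_alignment`: `ids`, `seqs` (gapped,
#'   normalised), `ncols`, `gc` (named list of `#=GC` lines), `insert`
#'   (logical per column; all `FALSE` on reading).
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^# STOCKHOLM", lines[1])) {
    stop("parse error in '", path, "' line 1: missing '# STOCKHOLM' header")
  }
  ids <- character(0)
  seqs <- list()
  gc <- list()
  for (i in seq_along(lines)[-1]) {
    ln <- lines[i]
    if (ln == "" || grepl("^//", ln)) next
    if (grepl("^#=GC[[:space:]]", ln)) {
      f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      if (length(f) < 3) stop("parse error in '", path, "' line ", i)
      gc[[f[2]]] <- paste0(if (is.null(gc[[f[2]]])) "" else gc[[f[2]]], f[3])
      next
    }
    if (grepl("^#", ln)) next
    f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(f) != 2) {
      stop("parse error in '", path, "' line ", i, ": expected 'id sequence'")
    }
    if (!f[1] %in% ids) {
      ids <- c(ids, f[1])
      seqs[[f[1]]] <- f[2]
    } else {
      seqs[[f[1]]] <- paste0(seqs[[f[1]]], f[2])
    }
  }
  if (length(ids) == 0) stop("parse error in '", path, "': no sequence rows")
  norm <- function(s) {
    s <- chartr("tT", "uU", s)
    s <- toupper(s)
    gsub("[.~]", "-", s)
  }
  seqs <- vapply(ids, function(id) norm(seqs[[id]]), character(1))
  ncols <- unique(nchar(seqs))
  if (length(ncols) != 1) {
    bad <- ids[which(nchar(seqs) != nchar(seqs)[1])[1]]
    stop(
      "parse error in '", path, "': row '", bad, "' has ",
      nchar(seqs[bad]), " columns (first row has ", nchar(seqs)[1], ")"
    )
  }
  gc <- lapply(gc, function(g) {
    if (nchar(g) != ncols) {
      stop("parse error in '", path, "': #=GC line length mismatch")
    }
    g
  })
  structure(
    list(ids = ids, seqs = unname(seqs), ncols = ncols, gc = gc,
      insert = rep(FALSE, ncols)),
    class = "stockholm_alignment"
  )
}

#' Write a Stockholm 1.0 alignment
#'
#' @param aln a `stockholm_alignment`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stockholm <- function(aln, path) {
  w <- max(nchar(aln$ids), nchar(paste0("#=GC ", names(aln$gc))), 10) + 2
  rows <- sprintf(paste0("%-", w, "s%s"), aln$ids, aln$seqs)
  gcl <- if (length(aln$gc) > 0) {
    sprintf(paste0("%-", w, "s%s"), paste("#=GC", names(aln$gc)), unlist(aln$gc))
  } else {
    character(0)
  }
  writeLines(c("# STOCKHOLM 1.0", rows, gcl, "//"), path)
  invisible(path)
}

#' @export
print.stockholm_alignment <- function(x, ...) {
  cat("<stockholm_alignment>", length(x$ids), "rows x", x$ncols, "columns\n")
  invisible(x)
}

.aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$seqs, ""))
}

#' Per-column conservation profiles
#'
#' Counts `A`/`C`/`G`/`U` and gaps per column; the modal base and its
#' fraction define the conserved flag with a strict inequality: a column
#' is conserved only when the modal fraction exceeds the threshold
#' ("more than 95%"), so 19 of 20 is not conserved.  By default gaps
#' count in the denominator; set `gap_denominator = FALSE` to use the
#' non-gap row count instead.
#'
#' @param aln a `stockholm_alignment` with at least 2 rows.
#' @param threshold conservation threshold (default 0.95).
#' @param gap_denominator whether gaps count in the denominator.
#' @return data frame, one row per column: `column` (1-based), counts,
#'   `modal_base`, `modal_fraction`, `conserved`, `insert`.
#' @export
column_profiles <- function(aln, threshold = 0.95, gap_denominator = TRUE) {
  if (length(aln$ids) < 2) stop("need at least 2 alignment rows")
  m <- .aln_matrix(aln)
  bases <- c("A", "C", "G", "U")
  counts <- vapply(bases, function(b) colSums(m == b), numeric(ncol(m)))
  if (aln$ncols == 1) counts <- matrix(counts, nrow = 1, dimnames = list(NULL, bases))
  gaps <- colSums(m == "-")
  denom <- if (gap_denominator) nrow(m) else pmax(nrow(m) - gaps, 1L)
  modal_i <- apply(counts, 1, which.max)
  modal_n <- counts[cbind(seq_len(nrow(counts)), modal_i)]
  frac <- modal_n / denom
  data.frame(
    column = seq_len(aln$ncols),
    n_A = counts[, "A"], n_C = counts[, "C"], n_G = counts[, "G"],
    n_U = counts[, "U"], n_gap = gaps,
    modal_base = bases[modal_i],
    modal_fraction = frac,
    conserved = frac > threshold,
    insert = aln$insert,
    stringsAsFactors = FALSE
  )
}

.ungap <- function(s) gsub("-", "", s)

.pairwise_align <- function(seq_a, seq_b, config) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = config$align_match, mismatch = config$align_mismatch,
    baseOnly = FALSE
  )
  Biostrings::pairwiseAlignment(
    chartr("U", "T", seq_a), chartr("U", "T", seq_b),
    type = "global", substitutionMatrix = sm,
    gapOpening = config$align_gap_open, gapExtension = config$align_gap_extend
  )
}

#' Insert an ungapped sequence into an alignment
#'
#' The sequence is aligned (affine-gap global alignment) against the
#' closest existing row (highest per cent identity) and that row's gap
#' pattern is transferred to place it into the alignment.  Positions
#' where the new sequence needs columns of its own are added as insert
#' columns (gap-filled in all other rows and flagged `insert`, mirroring
#' the treatment of non-match columns in seed alignments: they are
#' excluded from conservation reporting).
#'
#' @param aln a `stockholm_alignment`.
#' @param seq ungapped RNA sequence (character string).
#' @param id row identifier for the inserted sequence.
#' @param config a [motif_config()] (alignment scores).
#' @return list with `alignment` (the extended `stockholm_alignment`),
#'   `row` (index of the new row), and `map` (data frame `seq_index`,
#'   `column` (1-based in the new alignment), `insert`).
#' @export
insert_sequence <- function(aln, seq, id = "query", config = motif_config()) {
  if (length(aln$ids) == 0) stop("empty alignment")
  if (!nzchar(seq)) stop("empty sequence")
  seq <- toupper(chartr("tT", "uU", seq))
  ungapped <- vapply(aln$seqs, .ungap, character(1))
  pids <- vapply(ungapped, function(u) {
    Biostrings::pid(.pairwise_align(seq, u, config))
  }, numeric(1))
  best <- which.max(pids)
  pa <- .pairwise_align(seq, ungapped[best], config)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ap <- chartr("T", "U", ap)

  # original column of each ungapped position of the best row
  row_chars <- strsplit(aln$seqs[best], "")[[1]]
  col_of_pos <- which(row_chars != "-")

  # walk the pairwise alignment: emit (column spec) for every seq residue
  new_row <- rep("-", aln$ncols) # content in original columns
  inserts <- list() # after_col -> characters
  map_col <- integer(0)
  map_ins <- logical(0)
  pos_sub <- 0 # position in ungapped subject
  last_col <- 0
  for (k in seq_along(ap)) {
    if (as[k] != "-") {
      pos_sub <- pos_sub + 1
      last_col <- col_of_pos[pos_sub]
      if (ap[k] != "-") {
        new_row[last_col] <- ap[k]
        map_col <- c(map_col, last_col)
        map_ins <- c(map_ins, FALSE)
      }
    } else if (ap[k] != "-") {
      key <- as.character(last_col)
      inserts[[key]] <- c(inserts[[key]], ap[k])
      map_col <- c(map_col, NA_integer_) # fixed up below
      map_ins <- c(map_ins, TRUE)
    }
  }

  # assemble new column layout: original columns with insert blocks
  ins_after <- sort(as.integer(names(inserts)))
  n_new <- aln$ncols + sum(lengths(inserts))
  # offset of each original column in the new alignment: an insert block
  # after column a shifts columns a+1 .. ncols
  shift <- integer(aln$ncols)
  for (a in ins_after) {
    if (a < aln$ncols) {
      shift[(a + 1):aln$ncols] <- shift[(a + 1):aln$ncols] +
        length(inserts[[as.character(a)]])
    }
  }
  new_col_of <- seq_len(aln$ncols) + shift

  expand <- function(chars, fill) {
    out <- rep(fill, n_new)
    out[new_col_of] <- chars
    for (a in ins_after) {
      block <- inserts[[as.character(a)]]
      start <- (if (a == 0) 0 else new_col_of[a]) + seq_along(block)
      out[start] <- fill
    }
    out
  }
  seqs2 <- vapply(aln$seqs, function(s) {
    paste(expand(strsplit(s, "")[[1]], "-"), collapse = "")
  }, character(1))
  gc2 <- lapply(aln$gc, function(g) {
    paste(expand(strsplit(g, "")[[1]], "."), collapse = "")
  })
  insert2 <- expand(aln$insert, TRUE)
  qrow <- expand(new_row, "-")
  for (a in ins_after) {
    block <- inserts[[as.character(a)]]
    start <- (if (a == 0) 0 else new_col_of[a]) + seq_along(block)
    qrow[start] <- block
  }

  # fix up the map: walk seq residues again assigning new column indices
  ins_ptr <- stats::setNames(rep(0L, length(ins_after)), as.character(ins_after))
  new_map <- integer(length(map_col))
  for (k in seq_along(map_col)) {
    if (!map_ins[k]) {
      new_map[k] <- new_col_of[map_col[k]]
    }
  }
  # insert columns in order of appearance per block
  pos_in_block <- list()
  ki <- which(map_ins)
  # reconstruct block membership in encounter order
  pos_sub <- 0; last_col <- 0
  bcount <- list()
  ii <- 0
  for (k in seq_along(ap)) {
    if (as[k] != "-") {
      pos_sub <- pos_sub + 1
      last_col <- col_of_pos[pos_sub]
      if (ap[k] != "-") ii <- ii + 1
    } else if (ap[k] != "-") {
      ii <- ii + 1
      key <- as.character(last_col)
      bcount[[key]] <- (if (is.null(bcount[[key]])) 0 else bcount[[key]]) + 1
      base_col <- if (last_col == 0) 0 else new_col_of[last_col]
      new_map[ii] <- base_col + bcount[[key]]
    }
  }

  aln2 <- structure(
    list(
      ids = c(aln$ids, id), seqs = unname(c(seqs2, paste(qrow, collapse = ""))),
      ncols = n_new, gc = gc2, insert = insert2
    ),
    class = "stockholm_alignment"
  )
  list(
    alignment = aln2, row = length(aln2$ids),
    map = data.frame(seq_index = seq_along(new_map), column = new_map,
      insert = map_ins)
  )
}

#' Map structure residues of a chain onto alignment columns
#'
#' Extracts the chain sequence, inserts it into the alignment and
#' returns the residue-to-column map alongside the extended alignment.
#'
#' @param model an `rna_structure`.
#' @param aln a `stockholm_alignment`.
#' @param chain chain id (default: the single chain).
#' @param config a [motif_config()].
#' @return list with `alignment`, `map` (data frame `resid`, `column`,
#'   `insert`, `base`), and `row`.
#' @export
map_structure_to_alignment <- function(model, aln, chain = NULL,
                                       config = motif_config()) {
  es <- extract_sequence(model, chain)
  ins <- insert_sequence(aln, es$sequence, id = model$id, config = config)
  map <- data.frame(
    resid = es$map$resid, column = ins$map$column, insert = ins$map$insert,
    base = es$map$base, stringsAsFactors = FALSE
  )
  list(alignment = ins$alignment, map = map, row = ins$row)
}

#' Classify the sequence conservation of a motif
#'
#' `fully_conserved`: every motif column has modal fraction 1 and its
#' modal base equals the structure's base.  `highly_conserved`: every
#' column exceeds the conservation threshold.  Otherwise `variable`.
#' Residues that fall on insert columns or are unmapped give
#' `unassessed` with a warning.
#'
#' @param resids motif residue identifiers.
#' @param resmap residue-to-column map from
#'   [map_structure_to_alignment()].
#' @param profiles [column_profiles()] of the *original* (pre-insertion)
#'   alignment columns, or of the extended alignment.
#' @param threshold conservation threshold.
#' @return list with `class`, and `per_residue` data frame (`resid`,
#'   `column`, `modal_base`, `modal_fraction`).
#' @export
motif_conservation <- function(resids, resmap, profiles, threshold = 0.95) {
  i <- match(resids, resmap$resid)
  if (any(is.na(i)) || any(resmap$insert[i])) {
    warning("motif residues unmapped or on insert columns: ",
      paste(resids[is.na(i) | resmap$insert[i]], collapse = ", "))
    return(list(class = "unassessed", per_residue = NULL))
  }
  cols <- resmap$column[i]
  j <- match(cols, profiles$column)
  if (any(is.na(j))) {
    warning("columns missing from profiles")
    return(list(class = "unassessed", per_residue = NULL))
  }
  pr <- profiles[j, , drop = FALSE]
  per <- data.frame(
    resid = resids, column = cols, modal_base = pr$modal_base,
    modal_fraction = pr$modal_fraction, stringsAsFactors = FALSE
  )
  cls <- if (all(pr$modal_fraction >= 1) &&
    all(pr$modal_base == resmap$base[i])) {
    "fully_conserved"
  } else if (all(pr$modal_fraction > threshold)) {
    "highly_conserved"
  } else {
    "variable"
  }
  list(class = cls, per_residue = per)
}

#' Write a conservation report TSV
#'
#' @param profiles [column_profiles()] output.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_conservation_tsv <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}

#' Write an alignment annotated with a conservation mask
#'
#' Adds a `#=GC conserved` line (`x` for conserved columns, `.`
#' otherwise) and writes Stockholm.
#'
#' @param aln a `stockholm_alignment`.
#' @param profiles matching [column_profiles()] output.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotated_stockholm <- function(aln, profiles, path) {
  mask <- ifelse(profiles$conserved, "x", ".")
  aln$gc[["conserved"]] <- paste(mask, collapse = "")
  write_stockholm(aln, path)
}
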