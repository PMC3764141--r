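# Structure parsing: PDB / mmCIF atom records in, a uniform nucleotide
# model out.  Residue identity throughout the package is the author
# numbering "chain:number[icode]", because published motif descriptions
# cite author numbers (e.g. the purine riboswitch triple A23-G46-C53).

.make_resid <- function(chain, number, icode) {
  paste0(chain, ":", number, ifelse(icode == "" | is.na(icode), "", icode))
}

#' Standardise a residue name to a parent base code
#'
#' Maps standard ribonucleotide names to `A`/`C`/`G`/`U` and modified
#' residues (pseudouridine `PSU`, methylated bases, deoxy residues, ...)
#' to their parent base via a packaged lookup derived from the PDB
#' chemical component dictionary.  Unmapped names give `"UNKNOWN"`.
#' Total function: never errors.
#'
#' @param raw_name character vector of deposited residue names.
#' @return character vector in `{A, C, G, U, UNKNOWN}`.
#' @examples
#' standardize_base(c("G", "PSU", "XYZ"))
#' @export
standardize_base <- function(raw_name) {
  raw <- toupper(trimws(raw_name))
  out <- ifelse(raw %in% c("A", "C", "G", "U"), raw,
    ifelse(raw %in% names(.modified_parent),
      unname(.modified_parent[raw]), "UNKNOWN"
    )
  )
  unname(out)
}

.is_modified_name <- function(raw_name) {
  raw <- toupper(trimws(raw_name))
  !(raw %in% c("A", "C", "G", "U"))
}

.parse_pdb_atoms <- function(lines, path) {
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl) > 0) lines <- lines[seq_len(endmdl[1] - 1)]
  sel <- grepl("^(ATOM  |HETATM)", lines)
  lines <- lines[sel]
  if (length(lines) == 0) {
    stop("parse error in '", path, "': no ATOM/HETATM records found")
  }
  sub_fw <- function(start, stop) trimws(substr(lines, start, stop))
  xyz <- suppressWarnings(cbind(
    as.numeric(sub_fw(31, 38)), as.numeric(sub_fw(39, 46)),
    as.numeric(sub_fw(47, 54))
  ))
  bad <- which(!stats::complete.cases(xyz))
  if (length(bad) > 0) {
    stop(
      "parse error in '", path, "': unreadable coordinates in record: ",
      lines[bad[1]]
    )
  }
  occ <- suppressWarnings(as.numeric(sub_fw(55, 60)))
  occ[is.na(occ)] <- 1
  data.frame(
    record = sub_fw(1, 6),
    atom = gsub("\\*", "'", sub_fw(13, 16)),
    altloc = sub_fw(17, 17),
    resname = sub_fw(18, 20),
    chain = sub_fw(22, 22),
    number = suppressWarnings(as.integer(sub_fw(23, 26))),
    icode = sub_fw(27, 27),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = occ,
    element = sub_fw(77, 78),
    stringsAsFactors = FALSE
  )
}

.parse_mmcif_atoms <- function(lines, path) {
  field_idx <- grep("^_atom_site\\.", lines)
  if (length(field_idx) == 0) {
    stop("parse error in '", path, "': no _atom_site category found")
  }
  fields <- sub("^_atom_site\\.", "", trimws(lines[field_idx]))
  start <- max(field_idx) + 1
  rows <- character()
  for (i in start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^(#|loop_|_|data_)", ln)) break
    rows <- c(rows, ln)
  }
  if (length(rows) == 0) {
    stop("parse error in '", path, "': empty _atom_site loop")
  }
  toks <- strsplit(rows, "[[:space:]]+")
  nf <- length(fields)
  ok <- vapply(toks, length, integer(1)) == nf
  if (any(!ok)) {
    stop(
      "parse error in '", path, "': _atom_site row with ",
      length(toks[[which(!ok)[1]]]), " fields (expected ", nf, "): ",
      rows[which(!ok)[1]]
    )
  }
  m <- matrix(unlist(toks), ncol = nf, byrow = TRUE)
  colnames(m) <- fields
  pick <- function(nm, alt = NULL, default = NA_character_) {
    if (nm %in% fields) return(m[, nm])
    if (!is.null(alt) && alt %in% fields) return(m[, alt])
    rep(default, nrow(m))
  }
  strip <- function(x) gsub("^\"|\"$", "", x)
  model_num <- pick("pdbx_PDB_model_num", default = "1")
  keep <- model_num == model_num[1]
  icode <- pick("pdbx_PDB_ins_code", default = "?")
  icode[icode %in% c("?", ".")] <- ""
  altloc <- pick("label_alt_id", default = ".")
  altloc[altloc %in% c("?", ".")] <- ""
  occ <- suppressWarnings(as.numeric(pick("occupancy", default = "1")))
  occ[is.na(occ)] <- 1
  df <- data.frame(
    record = pick("group_PDB", default = "ATOM"),
    atom = gsub("\\*", "'", strip(pick("auth_atom_id", "label_atom_id"))),
    altloc = altloc,
    resname = strip(pick("auth_comp_id", "label_comp_id")),
    chain = strip(pick("auth_asym_id", "label_asym_id")),
    number = suppressWarnings(as.integer(pick("auth_seq_id", "label_seq_id"))),
    icode = icode,
    x = suppressWarnings(as.numeric(pick("Cartn_x"))),
    y = suppressWarnings(as.numeric(pick("Cartn_y"))),
    z = suppressWarnings(as.numeric(pick("Cartn_z"))),
    occupancy = occ,
    element = pick("type_symbol", default = ""),
    stringsAsFactors = FALSE
  )
  df <- df[keep, , drop = FALSE]
  bad <- which(!stats::complete.cases(df[, c("x", "y", "z")]))
  if (length(bad) > 0) {
    stop("parse error in '", path, "': unreadable coordinates in _atom_site row ", bad[1])
  }
  df
}

#' Load an RNA 3D structure into a nucleotide model
#'
#' Parses a PDB or mmCIF file, keeps the first model only, resolves
#' alternate locations to the highest-occupancy copy, and classifies
#' residues: nucleic-acid residues (standard or modified, plus unmapped
#' residues that carry a full ribose, a glycosidic nitrogen and a
#' phosphate) become the ordered `nucleotides` of the model; waters are
#' dropped; amino acids are dropped; remaining heteroatoms (ligands,
#' ions) are kept in a `hetero` side table.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param id structure label; defaults to the file base name.
#' @return an object of class `rna_structure` with elements `id`,
#'   `source_format`, `nucleotides` (one row per residue: `resid`,
#'   `chain`, `number`, `icode`, `raw_name`, `base`, `is_modified`),
#'   `atoms` (one row per heavy atom of those residues) and `hetero`.
#' @export
load_structure <- function(path, format = c("auto", "pdb", "mmcif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)(\\.gz)?$", path, ignore.case = TRUE)) {
      "mmcif"
    } else {
      "pdb"
    }
  }
  lines <- readLines(path, warn = FALSE)
  atoms <- switch(format,
    pdb = .parse_pdb_atoms(lines, path),
    mmcif = .parse_mmcif_atoms(lines, path)
  )
  atoms <- atoms[atoms$element != "H" & !grepl("^H", atoms$atom), , drop = FALSE]

  # highest-occupancy altloc per atom, deterministic tie-break on altloc id
  ord <- order(atoms$chain, atoms$number, atoms$icode, atoms$atom,
    -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  key <- paste(atoms$chain, atoms$number, atoms$icode, atoms$resname, atoms$atom)
  atoms <- atoms[!duplicated(key), , drop = FALSE]

  atoms$resid <- .make_resid(atoms$chain, atoms$number, atoms$icode)
  base <- standardize_base(atoms$resname)
  rn <- toupper(atoms$resname)
  is_water <- rn %in% .water_names
  is_amino <- rn %in% .amino_names

  # unmapped residues still count as nucleotides when they carry the full
  # nucleotide scaffold (ribose + glycosidic N + phosphate); ligands with
  # nucleoside moieties but no polymer phosphate (e.g. SAM) do not
  unk <- unique(atoms$resid[base == "UNKNOWN" & !is_water & !is_amino])
  scaffold_ok <- vapply(unk, function(r) {
    nm <- atoms$atom[atoms$resid == r]
    all(c("C1'", "C2'", "C4'", "O4'", "P") %in% nm) && any(c("N1", "N9") %in% nm)
  }, logical(1))
  is_nuc <- base != "UNKNOWN" | atoms$resid %in% unk[scaffold_ok]
  is_nuc <- is_nuc & !is_water & !is_amino

  nuc_atoms <- atoms[is_nuc, , drop = FALSE]
  het_atoms <- atoms[!is_nuc & !is_water & !is_amino, , drop = FALSE]
  if (nrow(nuc_atoms) == 0) {
    stop("empty model: no nucleic-acid residues in '", path, "'")
  }

  res <- nuc_atoms[!duplicated(nuc_atoms$resid),
    c("resid", "chain", "number", "icode", "resname")]
  names(res)[names(res) == "resname"] <- "raw_name"
  res$base <- standardize_base(res$raw_name)
  res$is_modified <- .is_modified_name(res$raw_name)
  res <- res[order(res$chain, res$number, res$icode), , drop = FALSE]
  rownames(res) <- NULL

  nuc_atoms <- nuc_atoms[order(match(nuc_atoms$resid, res$resid)), , drop = FALSE]
  structure(
    list(
      id = if (is.null(id)) sub("\\.[^.]*(\\.gz)?$", "", basename(path)) else id,
      source_format = format,
      nucleotides = res,
      atoms = nuc_atoms[, c("resid", "atom", "element", "x", "y", "z")],
      hetero = het_atoms[, c("resid", "resname", "atom", "element", "x", "y", "z")]
    ),
    class = "rna_structure"
  )
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(
    "<rna_structure>", x$id, "-", nrow(x$nucleotides), "nucleotides,",
    nrow(x$atoms), "atoms,", length(unique(x$nucleotides$chain)), "chain(s)\n"
  )
  invisible(x)
}

.residue_atoms <- function(model, resid) {
  model$atoms[model$atoms$resid == resid, , drop = FALSE]
}

.residue_coord <- function(model, resid, atom) {
  a <- model$atoms
  i <- which(a$resid == resid & a$atom == atom)
  if (length(i) == 0) return(NULL)
  c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
}

#' Write a nucleotide model to a minimal PDB file
#'
#' Writes ATOM records (3-decimal coordinates) for all nucleotides in
#' model order.  Used by the synthetic-geometry generator so fixtures
#' exercise the parser end to end.
#'
#' @param model an `rna_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  a <- model$atoms
  res <- model$nucleotides
  i <- match(a$resid, res$resid)
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s%2s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)),
    ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom),
    res$raw_name[i], res$chain[i], res$number[i],
    ifelse(res$icode[i] == "", " ", res$icode[i]),
    a$x, a$y, a$z, 1, 0, a$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Compute the base reference frame of a nucleotide
#'
#' Least-squares plane fit through the base ring atoms (purines
#' N9,C8,N7,C5,C6,N1,C2,N3,C4; pyrimidines N1..C6).  The frame origin is
#' the ring centroid; the normal is the plane normal with its sign fixed
#' by the winding of the ring atoms, so frames of sequential residues on
#' one helix strand fall in the same hemisphere; the x axis points from
#' the origin towards the glycosidic nitrogen projected into the plane.
#'
#' @param model an `rna_structure`.
#' @param resid residue identifier (`"chain:number"`).
#' @return list with `origin`, `normal`, `x_axis`, `y_axis` (orthonormal),
#'   and `rms` (plane-fit residual, Angstrom).
#' @export
compute_base_frame <- function(model, resid) {
  res <- model$nucleotides[model$nucleotides$resid == resid, , drop = FALSE]
  if (nrow(res) == 0) stop("residue not found: ", resid)
  base <- res$base[1]
  if (!base %in% names(.ring_atoms)) {
    stop("frame unavailable for ", resid, ": base ", base)
  }
  ring <- .ring_atoms[[base]]
  ra <- .residue_atoms(model, resid)
  present <- ring[ring %in% ra$atom]
  if (length(present) < 5) {
    stop(
      "frame unavailable for ", resid, ": only ", length(present),
      " of ", length(ring), " ring atoms present"
    )
  }
  xyz <- as.matrix(ra[match(present, ra$atom), c("x", "y", "z")])
  fit <- .fit_plane(xyz)
  normal <- fit$normal
  # fix sign by ring winding: normal agrees with (a1 - o) x (a2 - o)
  w <- .cross3(xyz[1, ] - fit$centroid, xyz[2, ] - fit$centroid)
  if (sum(normal * w) < 0) normal <- -normal
  gly <- .residue_coord(model, resid, .glycosidic_atom[[base]])
  if (is.null(gly)) gly <- xyz[1, ]
  vx <- gly - fit$centroid
  vx <- vx - sum(vx * normal) * normal
  x_axis <- if (.vnorm(vx) < 1e-9) {
    .unit(xyz[2, ] - fit$centroid - sum((xyz[2, ] - fit$centroid) * normal) * normal)
  } else {
    .unit(vx)
  }
  dev <- sweep(xyz, 2, fit$centroid) %*% normal
  list(
    origin = fit$centroid, normal = .unit(normal), x_axis = x_axis,
    y_axis = .cross3(.unit(normal), x_axis),
    rms = sqrt(mean(dev^2))
  )
}

#' Base frames for all nucleotides of a model
#'
#' Residues whose frame cannot be computed (unknown base or fewer than
#' five ring atoms) are skipped; their ids are recorded in the
#' `"unavailable"` attribute and they are excluded from all
#' planarity-dependent detectors.
#'
#' @param model an `rna_structure`.
#' @return named list of frames (see [compute_base_frame()]).
#' @export
base_frames <- function(model) {
  out <- list()
  missing <- character()
  for (r in model$nucleotides$resid) {
    f <- tryCatch(compute_base_frame(model, r), error = function(e) NULL)
    if (is.null(f)) missing <- c(missing, r) else out[[r]] <- f
  }
  attr(out, "unavailable") <- missing
  out
}

#' Extract the one-letter sequence of a chain
#'
#' @param model an `rna_structure`.
#' @param chain chain identifier; `NULL` (or `""`) selects the only chain
#'   of a single-chain model.
#' @return list with `sequence` (one-letter string, `N` for unknown
#'   bases) and `map` (data frame: `index`, `resid`, `chain`, `number`,
#'   `icode`, `base`, `is_modified`).
#' @export
extract_sequence <- function(model, chain = NULL) {
  chains <- unique(model$nucleotides$chain)
  if (is.null(chain) || identical(chain, "")) {
    if (length(chains) > 1) {
      stop("model has ", length(chains), " chains; specify one of: ",
        paste(chains, collapse = ", "))
    }
    chain <- chains[1]
  }
  if (!chain %in% chains) stop("chain not found: ", chain)
  res <- model$nucleotides[model$nucleotides$chain == chain, , drop = FALSE]
  letters <- ifelse(res$base == "UNKNOWN", "N", res$base)
  map <- data.frame(
    index = seq_len(nrow(res)), resid = res$resid, chain = res$chain,
    number = res$number, icode = res$icode, base = res$base,
    is_modified = res$is_modified, stringsAsFactors = FALSE
  )
  list(sequence = paste(letters, collapse = ""), map = map)
}
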