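# The census pipeline: structures in, per-structure motif annotation and
# summary statistics out, with optional per-class alignment conservation.

#' Annotate one structure with all motif classes
#'
#' Runs the full chain: frames, hydrogen bonds, base pairs, nested
#' skeleton, secondary-structure elements, then every tertiary-motif
#' detector, attaching structural-context strings.
#'
#' @param model an `rna_structure`.
#' @param config a [motif_config()].
#' @return list of class `structure_annotation` with `model`, `frames`,
#'   `hbonds`, `pairs`, `skeleton`, `remainder`, `ss`, and the motif
#'   tables `triples`, `quadruples`, `a_minors`, `zippers`,
#'   `pseudoknots`, `kissing_loops`, `kink_turns`, `loop_receptors`.
#' @export
annotate_structure <- function(model, config = motif_config()) {
  frames <- base_frames(model)
  hbonds <- detect_hbonds(model, config, frames)
  pairs <- detect_base_pairs(model, config, hbonds, frames)
  nest <- nested_skeleton(pairs[pairs$canonical | pairs$wobble, , drop = FALSE],
    model)
  ss <- build_elements(nest$skeleton, model)
  triples <- detect_triples(model, pairs, frames, config, ss)
  quadruples <- detect_quadruples(triples, pairs)
  a_minors <- detect_a_minor(model, pairs, hbonds, config)
  zippers <- detect_ribose_zipper(model, hbonds, config, pairs)
  pseudoknots <- detect_pseudoknots(model, nest$skeleton, nest$remainder, ss)
  kissing <- detect_kissing_loops(model, pairs, ss, config)
  kinks <- detect_kink_turn(model, pairs, ss, config, a_minors)
  loops <- detect_loop_receptor(model, ss, a_minors, zippers, config)
  structure(
    list(
      model = model, frames = frames, hbonds = hbonds, pairs = pairs,
      skeleton = nest$skeleton, remainder = nest$remainder, ss = ss,
      triples = triples, quadruples = quadruples, a_minors = a_minors,
      zippers = zippers, pseudoknots = pseudoknots, kissing_loops = kissing,
      kink_turns = kinks, loop_receptors = loops
    ),
    class = "structure_annotation"
  )
}

# most-specific-first order used to de-duplicate motifs that report the
# same residue set
.class_specificity <- c(
  "kink_turn", "loop_receptor", "kissing_loop", "pseudoknot",
  "ribose_zipper", "a_minor", "quadruple", "triple"
)

.split_resids <- function(s) unique(unlist(strsplit(s, "[;,]")))

.motif_rows <- function(ann) {
  id <- ann$model$id
  rows <- list()
  add <- function(class, residues, detail = "") {
    rows[[length(rows) + 1]] <<- data.frame(
      structure = id, class = class, residues = residues, detail = detail,
      stringsAsFactors = FALSE
    )
  }
  tr <- ann$triples
  for (i in seq_len(nrow(tr))) {
    add("triple", paste(tr$res1[i], tr$res2[i], tr$res3[i], sep = ";"),
      paste0("composition=", tr$display_composition[i],
        ";contains_wc=", tr$contains_wc[i], ";context=", tr$context[i]))
  }
  qd <- ann$quadruples
  for (i in seq_len(nrow(qd))) {
    add("quadruple",
      paste(qd$res1[i], qd$res2[i], qd$res3[i], qd$res4[i], sep = ";"))
  }
  am <- ann$a_minors
  for (i in seq_len(nrow(am))) {
    add("a_minor",
      paste(am$donor[i], am$receptor_a[i], am$receptor_b[i], sep = ";"),
      paste0("type=", am$type[i], ";variant=", am$variant[i],
        ";receptor=", am$receptor_label[i]))
  }
  zp <- ann$zippers
  for (i in seq_len(nrow(zp))) {
    add("ribose_zipper",
      paste(zp$strand1_a[i], zp$strand1_b[i], zp$strand2_a[i],
        zp$strand2_b[i], sep = ";"),
      paste0("zclass=", zp$zclass[i]))
  }
  pk <- ann$pseudoknots
  for (i in seq_len(nrow(pk))) {
    add("pseudoknot", paste(.split_resids(gsub("-", ";", pk$group1[i])),
      collapse = ";"), paste0("htype=", pk$htype[i]))
  }
  ki <- ann$kissing_loops
  for (i in seq_len(nrow(ki))) {
    add("kissing_loop", paste(.split_resids(gsub("-", ";", ki$pairs[i])),
      collapse = ";"), paste0("loops=", ki$loop_a[i], "~", ki$loop_b[i]))
  }
  kt <- ann$kink_turns
  for (i in seq_len(nrow(kt))) {
    add("kink_turn", paste(unique(c(
      .split_resids(gsub("-", ";", kt$nc_pairs[i])),
      .split_resids(kt$bulge[i])
    )), collapse = ";"), paste0("c_stem=", kt$c_stem[i]))
  }
  lr <- ann$loop_receptors
  for (i in seq_len(nrow(lr))) {
    add("loop_receptor", paste(.split_resids(lr$a_minors[i]), collapse = ";"),
      paste0("loop=", lr$loop[i], ";receptor=", lr$receptor_stem[i],
        ";loop_size=", lr$loop_size[i]))
  }
  if (length(rows) == 0) {
    return(data.frame(structure = character(), class = character(),
      residues = character(), detail = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# flag duplicate rows (same structure + residue set) keeping the most
# specific class
.dedup_motifs <- function(motifs) {
  if (nrow(motifs) == 0) {
    motifs$unique <- logical(0)
    return(motifs)
  }
  key <- paste(motifs$structure,
    vapply(strsplit(motifs$residues, ";"), function(r) {
      paste(sort(unique(r)), collapse = "|")
    }, character(1)))
  rank <- match(motifs$class, .class_specificity)
  ord <- order(key, rank)
  first <- !duplicated(key[ord])
  uniq <- logical(nrow(motifs))
  uniq[ord] <- first
  motifs$unique <- uniq
  motifs
}

#' Run the motif census over a set of structures
#'
#' For every structure: load (unless already a model), annotate all
#' motif classes, and collect one census row per motif.  When an
#' alignment is supplied for a structure, its chain sequence is inserted
#' into the alignment, residues are mapped to columns, and each motif
#' receives a conservation class.  Failures of individual structures
#' are logged and skipped (the report is then flagged partial).
#'
#' @param structures character vector of file paths and/or a list of
#'   `rna_structure` models.
#' @param alignments optional named list/vector: structure id ->
#'   Stockholm file path (or `stockholm_alignment`).
#' @param config a [motif_config()].
#' @param quiet suppress per-structure log lines.
#' @return object of class `census_report`: `annotations` (per
#'   structure), `motifs` (one row per motif, with `unique` flags after
#'   most-specific-class de-duplication), `conservation` (per-motif
#'   classes), `summary` (see [summarize_census()]), `failures`.
#' @export
run_census <- function(structures, alignments = NULL, config = motif_config(),
                       quiet = FALSE) {
  if (length(structures) == 0) stop("no structures given")
  if (!is.list(structures)) structures <- as.list(structures)
  annotations <- list()
  failures <- character(0)
  motif_tabs <- list()
  conservation <- list()
  for (s in structures) {
    id <- NULL
    ann <- tryCatch({
      model <- if (inherits(s, "rna_structure")) s else load_structure(s)
      id <- model$id
      annotate_structure(model, config)
    }, error = function(e) {
      failures <<- c(failures, paste0(if (is.null(id)) as.character(s) else id,
        ": ", conditionMessage(e)))
      NULL
    })
    if (is.null(ann)) next
    annotations[[ann$model$id]] <- ann
    rows <- .motif_rows(ann)
    motif_tabs[[ann$model$id]] <- rows
    if (!quiet) {
      message(
        ann$model$id, ": ", nrow(ann$pairs), " pairs, ",
        nrow(ann$triples), " triples, ", nrow(ann$a_minors), " A-minors, ",
        nrow(ann$zippers), " zippers, ", nrow(ann$pseudoknots),
        " pseudoknots, ", nrow(ann$kissing_loops), " kissing, ",
        nrow(ann$kink_turns), " kink-turns, ", nrow(ann$loop_receptors),
        " loop-receptors"
      )
    }
    aln_in <- if (!is.null(alignments)) alignments[[ann$model$id]] else NULL
    if (!is.null(aln_in)) {
      aln <- if (inherits(aln_in, "stockholm_alignment")) aln_in else
        read_stockholm(aln_in)
      profiles <- column_profiles(aln, config$conserve_threshold,
        config$conserve_gap_denominator)
      mp <- map_structure_to_alignment(ann$model, aln, config = config)
      # profile columns renumbered into the extended alignment layout
      prof2 <- column_profiles(mp$alignment, config$conserve_threshold,
        config$conserve_gap_denominator)
      rows_c <- rows
      rows_c$conservation <- vapply(seq_len(nrow(rows)), function(i) {
        resids <- strsplit(rows$residues[i], ";")[[1]]
        suppressWarnings(
          motif_conservation(resids, mp$map, prof2,
            config$conserve_threshold)$class
        )
      }, character(1))
      conservation[[ann$model$id]] <- rows_c[,
        c("structure", "class", "residues", "conservation")]
    }
  }
  if (length(annotations) == 0) {
    stop("census failed for all structures: ",
      paste(failures, collapse = " | "))
  }
  motifs <- .dedup_motifs(do.call(rbind, c(motif_tabs,
    list(make.row.names = FALSE))))
  cons <- if (length(conservation) > 0) {
    do.call(rbind, c(conservation, list(make.row.names = FALSE)))
  } else {
    NULL
  }
  rep <- structure(
    list(
      annotations = annotations, motifs = motifs, conservation = cons,
      failures = failures, partial = length(failures) > 0
    ),
    class = "census_report"
  )
  rep$summary <- summarize_census(rep)
  rep
}

.round_half_up <- function(x) floor(x + 0.5)

.summarize_triples <- function(n, wc, compositions) {
  comp_tab <- sort(table(compositions), decreasing = TRUE)
  list(
    n_triples = as.integer(n),
    n_triples_with_wc = as.integer(wc),
    composition_counts = comp_tab,
    modal_composition = if (length(comp_tab) > 0) names(comp_tab)[1] else NA,
    modal_composition_count = if (length(comp_tab) > 0)
      as.integer(comp_tab[1]) else 0L
  )
}

#' Summarise a census
#'
#' Computes the survey statistics from the motif lists: counts by motif
#' class, the base-triple composition histogram and how many triples
#' contain a canonical Watson-Crick pair, A-minor type and receptor
#' shares (percentages rounded to the nearest integer, ties up), the
#' ribose-zipper count and the total number of unique interactions
#' (duplicate residue sets count once, attributed to the most specific
#' class).  Accepts either a `census_report` or a `triple_census`
#' fixture table.
#'
#' @param x a `census_report` or `triple_census`.
#' @return a list of summary statistics.
#' @export
summarize_census <- function(x) {
  if (inherits(x, "triple_census")) {
    tri <- .summarize_triples(nrow(x), sum(x$contains_wc),
      x$display_composition)
    return(c(list(n_records = nrow(x)), tri))
  }
  stopifnot(inherits(x, "census_report"))
  m <- x$motifs
  mu <- m[m$unique, , drop = FALSE]
  class_counts <- table(factor(mu$class, levels = .class_specificity))
  tr <- do.call(rbind, lapply(x$annotations, function(a) a$triples))
  if (is.null(tr)) tr <- data.frame(contains_wc = logical(),
    display_composition = character())
  tri <- .summarize_triples(nrow(tr), sum(tr$contains_wc),
    tr$display_composition)
  am <- do.call(rbind, lapply(x$annotations, function(a) a$a_minors))
  if (is.null(am)) am <- data.frame(type = character(),
    receptor_label = character())
  shares <- function(v) {
    if (length(v) == 0) return(integer(0))
    tt <- table(v)
    stats::setNames(as.integer(.round_half_up(100 * as.numeric(tt) /
      length(v))), names(tt))
  }
  zp <- do.call(rbind, lapply(x$annotations, function(a) a$zippers))
  cons_classes <- if (!is.null(x$conservation)) {
    table(x$conservation$conservation)
  } else {
    NULL
  }
  c(
    list(
      n_structures = length(x$annotations),
      n_motifs = nrow(m),
      n_unique_interactions = nrow(mu),
      n_non_triple_unique = nrow(mu) - sum(mu$class == "triple"),
      class_counts = class_counts
    ),
    tri,
    list(
      n_a_minor = nrow(am),
      a_minor_type_shares = shares(am$type),
      a_minor_receptor_shares = shares(am$receptor_label),
      n_ribose_zippers = if (is.null(zp)) 0L else nrow(zp),
      conservation_classes = cons_classes
    )
  )
}

#' Write census outputs
#'
#' Writes `census.tsv` (one motif per row), `summary.json`,
#' `conservation.tsv` (when conservation was computed) and a
#' `<id>.dbn` dot-bracket file per structure.  Re-runs on identical
#' inputs produce byte-identical files.
#'
#' @param report a `census_report`.
#' @param outdir output directory (created if missing).
#' @param formats subset of `c("tsv", "json")`.
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(report, outdir, formats = c("tsv", "json")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if ("tsv" %in% formats) {
    p <- file.path(outdir, "census.tsv")
    utils::write.table(report$motifs, p, sep = "\t", quote = FALSE,
      row.names = FALSE)
    written <- c(written, p)
    if (!is.null(report$conservation)) {
      p <- file.path(outdir, "conservation.tsv")
      utils::write.table(report$conservation, p, sep = "\t", quote = FALSE,
        row.names = FALSE)
      written <- c(written, p)
    }
    for (id in names(report$annotations)) {
      ann <- report$annotations[[id]]
      p <- file.path(outdir, paste0(id, ".dbn"))
      writeLines(c(
        paste0("># ", id),
        extract_sequence(ann$model,
          ann$model$nucleotides$chain[1])$sequence,
        dot_bracket(ann$model, ann$skeleton, ann$remainder)
      ), p)
      written <- c(written, p)
    }
  }
  if ("json" %in% formats) {
    p <- file.path(outdir, "summary.json")
    s <- report$summary
    s$class_counts <- as.list(stats::setNames(as.integer(s$class_counts),
      names(s$class_counts)))
    s$composition_counts <- as.list(stats::setNames(
      as.integer(s$composition_counts), names(s$composition_counts)))
    s$a_minor_type_shares <- as.list(s$a_minor_type_shares)
    s$a_minor_receptor_shares <- as.list(s$a_minor_receptor_shares)
    s$conservation_classes <- if (is.null(s$conservation_classes)) NULL else
      as.list(stats::setNames(as.integer(s$conservation_classes),
        names(s$conservation_classes)))
    jsonlite::write_json(s, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, p)
  }
  invisible(written)
}

#' @export
print.census_report <- function(x, ...) {
  s <- x$summary
  cat("<census_report>", s$n_structures, "structures,", s$n_motifs,
    "motifs (", s$n_unique_interactions, "unique )\n")
  print(s$class_counts)
  invisible(x)
}
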