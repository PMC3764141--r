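# Shared fixture builders.  Geometric fixtures are deterministic, so they
# are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(kind, ...) {
  key <- paste(kind, paste(deparse(list(...)), collapse = ""), sep = "#")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- build_motif(motif_spec(kind, ...))
  }
  .fixture_cache[[key]]
}

annotated <- function(kind, ...) {
  key <- paste("ann", kind, paste(deparse(list(...)), collapse = ""), sep = "#")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- annotate_structure(fixture(kind, ...))
  }
  .fixture_cache[[key]]
}

cfg <- motif_config()

# minimal structure stand-in for topology-only operations (skeleton DP,
# element labelling): n residues on one chain, no atoms needed
toy_model <- function(n, chain = "A") {
  res <- data.frame(
    resid = paste0(chain, ":", seq_len(n)), chain = chain,
    number = seq_len(n), icode = "", raw_name = "A", base = "A",
    is_modified = FALSE, stringsAsFactors = FALSE
  )
  structure(list(id = "toy", source_format = "pdb", nucleotides = res,
    atoms = res[0, ], hetero = res[0, ]), class = "rna_structure")
}

toy_pairs <- function(i, j, n_hbonds = 3, canonical = TRUE, chain = "A") {
  data.frame(
    res_a = paste0(chain, ":", i), res_b = paste0(chain, ":", j),
    base_a = "G", base_b = "C", edge_a = "WatsonCrick",
    edge_b = "WatsonCrick", orientation = "cis", canonical = canonical,
    wobble = FALSE, n_hbonds = n_hbonds, n_hbonds_all = n_hbonds,
    planarity = 0, stringsAsFactors = FALSE
  )
}
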