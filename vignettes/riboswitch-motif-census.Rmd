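---
title: "Annotating tertiary motifs and their conservation in riboswitch structures"
author: "ribomotifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating tertiary motifs and their conservation in riboswitch structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribomotifs)
```

## The problem

Riboswitches are metabolite-sensing regulatory RNAs whose aptamer domains
fold into compact tertiary structures.  That compaction is held together
by a small vocabulary of recurring tertiary motifs — base triples,
A-minor interactions, ribose zippers, pseudoknots, kissing loops,
kink-turns and loop-receptor docks — and the nucleotides that form these
motifs tend to be strongly conserved across the sequence family even
when the rest of the aptamer drifts.  `ribomotifs` implements the whole
survey chain needed to study this agreement between structure and
sequence: geometric motif annotation from 3D coordinates, labelling of
each motif's secondary-structure context, mapping of structure residues
onto family-alignment columns, and per-motif conservation classes.

## From coordinates to hydrogen bonds and pairs

Structures are parsed from PDB or mmCIF into a uniform nucleotide model
(`load_structure()`).  Only the first model of multi-model files is
used and alternate locations resolve to the highest-occupancy copy;
modified residues are mapped to their parent base through a packaged
lookup derived from the chemical component dictionary, so pseudouridine
or methylated bases still participate in pairs under their author
numbering.  Residue identity everywhere is the author numbering
(`chain:number`), because that is how published motif descriptions cite
residues.

Hydrogen bonds are detected with conventional heavy-atom criteria: a
donor-acceptor distance between 2.4 and 3.5 Å and an approach angle at
the donor of at least 110°, measured through the donor's covalent
antecedent(s).  Two details matter in practice:

* ring N–H donors (G N1, U N3) use the midpoint of both ring neighbours
  as the antecedent, since the proton sits on the exterior bisector;
* 2'-OH donors get a much looser angle floor (80°), because the hydroxyl
  proton is rotatable and only the covalent direction genuinely excludes
  a bond.

The angle criterion is what rejects stacking: a stacked acceptor sits
perpendicular to the donor's base plane, giving angles near 90° for base
donors.

A **base pair** requires at least two base-to-base hydrogen bonds and a
base-plane angle below 65° (pairing tolerates propeller and buckle; the
65° value only excludes edge-on contacts).  Each base's interacting edge
(Watson-Crick, Hoogsteen or Sugar) is assigned by a fractional vote of
its bonded atoms over a packaged atom-to-edge table; atoms on an edge
boundary (A N6, G O6/N2, pyrimidine O2) contribute half a vote to each
edge.  Glycosidic orientation (cis/trans) comes from the side each
glycosidic bond takes relative to the axis joining the glycosidic
nitrogens.  *Canonical* means cis Watson-Crick/Watson-Crick G-C or A-U;
G-U wobble is flagged separately and is deliberately **not** counted as
a Watson-Crick pair in census statistics, matching the convention that
bold-faces only G-C/A-U pairs in published triple tables.

## Secondary structure and context strings

Canonical plus wobble pairs feed a maximum-cardinality non-crossing
one-pairing-per-residue skeleton (interval dynamic programming;
ties break towards pairs with more hydrogen bonds, then 5'-earlier
pairs).  Stacked runs become stems named `P1…Pn` in 5' order, with
sub-stems separated by internal loops sharing a number and taking
letters (`P2a`, `P2b`); hairpin loops take their stem's number (`L2`);
unpaired runs at multiloops become junctions `Ji-j` between the flanking
stems, including the wraparound segment back to the closing stem
(`J3-1`).  The pairs excluded from the skeleton — pseudoknots, kissing
interactions, inter-chain pairs — form the *crossing remainder*.

`classify_context()` renders the element kinds a motif touches the way
riboswitch papers phrase them: "Helix - junction interaction (P2b &
J3-4)", "Interaction between junctions (J1-2 & J2-3)", "Bulged-out
residue - helix interaction (P2 & P5)".  Labels are ASCII throughout.

## The seven motif detectors

**Base triples** are residue trios where one base pairs with both
others, each pairing carrying ≥ 2 base-base bonds, and all three base
planes mutually within 30°.  The 30° planarity cutoff is the
operational reading of "planar interaction": in trial geometry it
separates genuinely coplanar triples from stacked contacts, which sit
near 0° between *parallel* planes but fail the hydrogen-bonding clause,
and from perpendicular docks at 60–90°.  Triples are counted per
unordered residue set; compositions sort A<C<G<U internally and render
purine-first (`AGC`) for reporting.  Triples sharing a pairing merge
into **base quadruples**, without suppressing the constituent triples.

**A-minor interactions** are adenosines (or guanosines: the G-minor
variant) docking their sugar-edge atoms (N3, C2/N2, 2'-OH) into the
minor groove of a canonical receptor pair with ≥ 2 such bonds, excluding
residues Watson-Crick-paired to the receptor.  Typing is an operational
restatement of the standard taxonomy: type I needs both N3 and 2'-OH
bonded with contacts reaching both receptor residues; type 0 uses only
the 2'-OH (the kink-turn internal interaction); everything else is
type II.  Type III (no 2'-OH, shallow dock) is not assigned — the
survey context this package serves observed none.  The receptor label
is the receptor bases in 5' element order; because the orientation
convention behind published `GC`/`CG` splits is not stated anywhere,
both orders are trivially recoverable by flipping the label.

**Ribose zippers** are two sequence-distant dinucleotide segments with
≥ 2 cross-segment bonds each involving a 2'-OH.  Canonical zippers show
the antiparallel 2'-OH/2'-OH register (i with j+1, i+1 with j) plus a
2'-OH-to-base contact; a parallel register classifies as pseudo-cis;
other signatures are reported as variants.  Segments joined by a
canonical or wobble pair are excluded — a helix trivially "zips" its own
strands, but the motif means backbone packing between strands that are
not paired to each other.

**Pseudoknots** are crossing stems from the skeleton remainder, with an
H-type flag when the crossing pairs emanate from a hairpin loop.
**Kissing loops** are ≥ 2 canonical pairs joining two distinct hairpin
loops.  **Kink-turns** are found as a canonical stem, a 2–4 nt bulge on
one strand, then tandem sheared G·A pairs (Sugar/Hoogsteen edges)
opening the non-canonical stem, with a genuine geometric bend required:
stem axes are lines through the C1'-C1' pair midpoints, oriented away
from the bulge junction, and must meet at ≤ 120° (coaxial stems measure
≈ 180°).  **Loop-receptor interactions** are tetra- or pentaloops whose
residues dock at least one A-minor into a stem of a different helix
group, with a ribose zipper attached when its loop-side strand lies in
the same loop.

## Conservation

Stockholm alignments are profiled per column; a column is *conserved*
when its modal base fraction strictly exceeds 0.95 ("more than 95%"):
19 of 20 is exactly 0.95 and does not count.  Gaps count in the
denominator by default — a heavily gapped column cannot be conserved —
with a non-gap denominator available, since it is not knowable which
convention a given published count used.

Structure sequences enter the alignment by affine-gap global alignment
(match +2, mismatch −1, open −5, extend −1) against the closest existing
row, transferring that row's gap pattern; residues needing columns of
their own create flagged insert columns that are excluded from
conservation reporting, mirroring the match-column convention of seed
alignments.  This pairwise insertion **replaces** covariance-model
alignment deliberately: it needs no model building and is exactly
reproducible, at the cost of being less robust for remote homologs.
Consequences: family-wide conserved-position totals depend on the
alignment version and the alignment method, so the package treats them
as descriptive output, not as reproduction targets, and the conservation
module is validated against synthetic alignments with planted per-column
fractions instead.

Motif conservation classes: *fully_conserved* — every motif column at
100% with the modal base equal to the structure's base;
*highly_conserved* — every column above the threshold; otherwise
*variable*.  "Fully conserved" operationalises "conserved in all
sequences analysed"; no formula for it exists in the survey literature,
so the strictest reading was chosen.

## Superposition

Structure comparisons use sequence-guided correspondences (C4', C1',
glycosidic N, plus P where present on both sides) and a closed-form
least-squares fit with the reflection branch suppressed.  With a prune
cutoff (default 2 Å) the fit iterates, discarding the single
worst-deviating residue pair per round — one gross outlier must not
drag well-fitting residues over the cutoff — which emulates the
pruned-core behaviour of interactive structure matchers.  Pruning then
refitting can only lower the reported RMSD.

## The synthetic-geometry generator

Every detector is testable without downloads because the generator
builds idealised fixtures whose ground truth is known by construction:

* heavy-atom base templates (exactly planar, standard bond geometry);
* pairs placed by deterministic multi-start optimisation so the named
  donor-acceptor distances land at 2.9 Å without steric clashes, with
  soft approach-angle guides keeping hydrogen-bond geometry sane;
* helices stacking centred pairs (rise 3.4 Å, twist 33°), hairpins,
  and assembled motifs for every class — including deliberately broken
  variants (a 60°-tilted third base, a single-bond "zipper", a kissing
  contact with only one pair) that detectors must reject.

Fixtures are written as minimal PDB files and re-loaded, so the parser
sits inside every closure test.  What the fixtures do **not** emulate:
continuous backbone geometry between placed fragments, crystallographic
noise, modified residues in context, and crowded multi-motif
neighbourhoods.  Passing closures therefore demonstrates that the
detectors implement their stated criteria exactly; it does not by itself
calibrate the criteria against deposited coordinates, for which the
pipeline accepts any directory of PDB/mmCIF files.

Synthetic alignments plant per-column modal fractions realised exactly
(`round(fraction * nrows)` modal rows, remaining rows spread evenly over
the other bases so the modal base stays strictly modal), making the
planted vector the oracle for the profiler.

## Scale of the shipped validation

The test suite and the acceptance script run entirely at desk scale:
fixtures of 3–34 nucleotides, alignments of up to 40 rows, exhaustive
oracles up to 2^12 subsets, and a 10,000-rotation Monte-Carlo check for
the superposition fit — a few minutes end to end.  The full census over
deposited riboswitch structures runs from the same entry points
(`run_census()` over a directory of coordinate files) in about the same
time per structure as the fixtures.

## Worked example

```{r census}
dirp <- tempfile()
dir.create(dirp)
build_motif(motif_spec("triple"), file.path(dirp, "triple.pdb"))
build_motif(motif_spec("helix", n_pairs = 4), file.path(dirp, "helix.pdb"))
rep <- run_census(list.files(dirp, full.names = TRUE), quiet = TRUE)
rep$summary$class_counts
```

```{r table1}
fx <- table1_fixture()
s <- summarize_census(fx)
c(records = s$n_records, with_wc = s$n_triples_with_wc,
  modal = s$modal_composition_count)
```

## Known limitations

* Detector thresholds are conventional values, not fits to deposited
  data; on real structures the exposed `motif_config()` values are the
  knobs a user should expect to revisit.
* Sub-stem lettering follows deterministic 5'-order; where a published
  label differs (historic numbering of a family), context strings will
  differ in the label while agreeing in kind.
* T-loops and stacked tetrads are not detected automatically; published
  surveys found them by visual inspection, and no explicit geometric
  criterion is adopted here.
* Ligand contacts are not annotated; ligand heteroatoms are retained in
  the model's `hetero` table for downstream use only.
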