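# Chemical reference tables used by every geometric detector: idealised
# heavy-atom nucleotide templates, ring-atom definitions, hydrogen-bond
# donor/acceptor assignments, the atom-to-edge table behind the
# Watson-Crick / Hoogsteen / Sugar edge vote, and the modified-residue
# parent lookup.

# Idealised heavy-atom coordinates (Angstrom) for the four standard
# ribonucleotides, transcribed from the PDB chemical component dictionary
# ideal coordinate set.  Bases are exactly planar in these templates.
.template_coords <- list(
  A = c(
    "P",    1.024, -0.137, -4.723,  "OP1",  1.633,  1.190, -4.488,
    "OP2", -0.183,  0.005, -5.778,  "O5'",  0.456, -0.720, -3.334,
    "C5'", -0.520,  0.209, -2.863,  "C4'", -1.101, -0.287, -1.538,
    "O4'", -0.064, -0.383, -0.538,  "C3'", -2.105,  0.739, -0.969,
    "O3'", -3.445,  0.360, -1.287,  "C2'", -1.874,  0.684,  0.558,
    "O2'", -3.065,  0.271,  1.231,  "C1'", -0.755, -0.367,  0.729,
    "N9",   0.158,  0.029,  1.803,  "C8",   1.265,  0.813,  1.672,
    "N7",   1.843,  0.963,  2.828,  "C5",   1.143,  0.292,  3.773,
    "C6",   1.290,  0.091,  5.156,  "N6",   2.344,  0.664,  5.846,
    "N1",   0.391, -0.656,  5.787,  "C2",  -0.617, -1.206,  5.136,
    "N3",  -0.792, -1.051,  3.841,  "C4",   0.056, -0.320,  3.126),
  C = c(
    "P",    1.049, -0.039, -4.028,  "OP1",  1.692,  1.237, -3.646,
    "OP2", -0.116,  0.246, -5.102,  "O5'",  0.415, -0.733, -2.721,
    "C5'", -0.546,  0.181, -2.193,  "C4'", -1.189, -0.419, -0.942,
    "O4'", -0.190, -0.648,  0.076,  "C3'", -2.178,  0.583, -0.307,
    "O3'", -3.518,  0.283, -0.703,  "C2'", -2.001,  0.373,  1.215,
    "O2'", -3.228, -0.059,  1.806,  "C1'", -0.924, -0.729,  1.317,
    "N1",  -0.036, -0.470,  2.453,  "C2",   0.652,  0.683,  2.514,
    "O2",   0.529,  1.504,  1.620,  "N3",   1.467,  0.945,  3.535,
    "C4",   1.620,  0.070,  4.520,  "N4",   2.464,  0.350,  5.569,
    "C5",   0.916, -1.151,  4.483,  "C6",   0.087, -1.399,  3.442),
  G = c(
    "P",   -0.911, -0.277,  5.008,  "OP1", -1.598,  1.022,  4.844,
    "OP2",  0.325, -0.105,  6.025,  "O5'", -0.365, -0.780,  3.580,
    "C5'",  0.542,  0.217,  3.109,  "C4'",  1.100, -0.200,  1.748,
    "O4'",  0.033, -0.318,  0.782,  "C3'",  2.025,  0.898,  1.182,
    "O3'",  3.395,  0.582,  1.439,  "C2'",  1.741,  0.884, -0.338,
    "O2'",  2.927,  0.560, -1.066,  "C1'",  0.675, -0.220, -0.507,
    "N9",  -0.297,  0.162, -1.534,  "C8",  -1.440,  0.880, -1.334,
    "N7",  -2.066,  1.037, -2.464,  "C5",  -1.364,  0.431, -3.453,
    "C6",  -1.556,  0.279, -4.846,  "O6",  -2.534,  0.755, -5.397,
    "N1",  -0.626, -0.401, -5.551,  "C2",   0.459, -0.934, -4.923,
    "N2",   1.384, -1.626, -5.664,  "N3",   0.649, -0.800, -3.630,
    "C4",  -0.226, -0.134, -2.868),
  U = c(
    "P",   -1.030,  0.047, -4.037,  "OP1", -1.679, -1.228, -3.660,
    "OP2",  0.138, -0.241, -5.107,  "O5'", -0.399,  0.736, -2.726,
    "C5'",  0.557, -0.182, -2.196,  "C4'",  1.197,  0.415, -0.942,
    "O4'",  0.194,  0.645,  0.074,  "C3'",  2.181, -0.588, -0.301,
    "O3'",  3.524, -0.288, -0.686,  "C2'",  1.995, -0.383,  1.218,
    "O2'",  3.219,  0.046,  1.819,  "C1'",  0.922,  0.723,  1.319,
    "N1",   0.028,  0.464,  2.451,  "C2",  -0.690, -0.671,  2.486,
    "O2",  -0.587, -1.474,  1.580,  "N3",  -1.515, -0.936,  3.517,
    "C4",  -1.641, -0.055,  4.530,  "O4",  -2.391, -0.292,  5.460,
    "C5",  -0.894,  1.146,  4.502,  "C6",  -0.070,  1.384,  3.459)
)

.parse_template <- function(v) {
  m <- matrix(v, ncol = 4, byrow = TRUE)
  data.frame(
    atom = m[, 1],
    element = sub("[0-9'].*$", "", m[, 1]),
    x = as.numeric(m[, 2]), y = as.numeric(m[, 3]), z = as.numeric(m[, 4]),
    stringsAsFactors = FALSE
  )
}

.base_templates <- lapply(.template_coords, .parse_template)

# Base-plane (ring) atoms: the standard definition used to fit base planes.
.ring_atoms <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  U = c("N1", "C2", "N3", "C4", "C5", "C6")
)

.glycosidic_atom <- c(A = "N9", G = "N9", C = "N1", U = "N1")

# All base (non-sugar, non-phosphate) atom names per base.
.base_moiety_atoms <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
  C = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
  U = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6")
)

.sugar_atoms <- c("C1'", "C2'", "O2'", "C3'", "O3'", "C4'", "O4'", "C5'")
.phosphate_atoms <- c("P", "OP1", "OP2", "O5'")

# Heavy-atom hydrogen-bond donors with their covalent antecedent(s), used
# for the angle criterion at the donor (no hydrogens are placed).  Ring
# N-H donors list both ring neighbours: the proton sits on the exterior
# bisector, so the angle is measured against the neighbour midpoint.
.hbond_donors <- list(
  A = data.frame(atom = "N6", antecedent = "C6"),
  C = data.frame(atom = "N4", antecedent = "C4"),
  G = data.frame(atom = c("N1", "N2"), antecedent = c("C2,C6", "C2")),
  U = data.frame(atom = "N3", antecedent = "C2,C4")
)
.sugar_donor <- data.frame(atom = "O2'", antecedent = "C2'")

.hbond_acceptors <- list(
  A = c("N1", "N3", "N7"),
  C = c("O2", "N3"),
  G = c("O6", "N3", "N7"),
  U = c("O2", "O4")
)
.backbone_acceptors <- c("O2'", "O4'", "O3'", "OP1", "OP2", "O5'")

# Atom-to-edge membership behind the edge vote.  Atoms sitting at an edge
# boundary (e.g. A N6, G O6/N2, pyrimidine O2) belong to two edges and
# contribute half a vote to each.
.edge_atoms <- list(
  A = list(WatsonCrick = c("N1", "C2", "N6"),
           Hoogsteen   = c("N6", "N7", "C8"),
           Sugar       = c("N3", "C2", "O2'")),
  G = list(WatsonCrick = c("N1", "N2", "O6"),
           Hoogsteen   = c("O6", "N7", "C8"),
           Sugar       = c("N2", "N3", "O2'")),
  C = list(WatsonCrick = c("N3", "N4", "O2"),
           Hoogsteen   = c("N4", "C5", "C6"),
           Sugar       = c("O2", "O2'")),
  U = list(WatsonCrick = c("N3", "O4", "O2"),
           Hoogsteen   = c("O4", "C5", "C6"),
           Sugar       = c("O2", "O2'"))
)

# Minor-groove (sugar-edge side) atoms used by the A-minor detector.
.minor_groove_atoms <- list(
  A = c("N3", "C2", "O2'"),
  G = c("N3", "C2", "N2", "O2'"),
  C = c("O2", "O2'"),
  U = c("O2", "O2'")
)

# Modified residue name -> parent standard base.  Parent assignments follow
# the PDB chemical component dictionary; deoxy residues map to the
# corresponding ribo base (T to U).
.modified_parent <- c(
  PSU = "U", "5MU" = "U", H2U = "U", "4SU" = "U", OMU = "U", UR3 = "U",
  "5BU" = "U", DHU = "U", "3MU" = "U", "70U" = "U", "125" = "U",
  OMC = "C", "5MC" = "C", "4OC" = "C", CBV = "C", "1MC" = "C", M5C = "C",
  OMG = "G", "1MG" = "G", "2MG" = "G", M2G = "G", "7MG" = "G", G7M = "G",
  YG = "G", QUO = "G", I = "G", IG = "G", GTP = "G", GDP = "G", GMP = "G",
  "1MA" = "A", MA6 = "A", A2M = "A", "2MA" = "A", "6MA" = "A", RIA = "A",
  ATP = "A", ADP = "A", AMP = "A",
  DA = "A", DC = "C", DG = "G", DT = "U", DU = "U", T = "U"
)

.water_names <- c("HOH", "H2O", "WAT", "DOD")
.amino_names <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "SEC", "PYL"
)

# Display ordering for triple compositions (purines first, as the
# composition classes are conventionally written, e.g. "AGC").
.composition_display_order <- c("A", "G", "C", "U")
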