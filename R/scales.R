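# Reference tables used across the package: amino-acid alphabets, the
# Kyte-Doolittle hydropathy scale, the Bjellqvist pK set, and Bondi van der
# Waals radii. All are data of record for the cited methods, hard-coded so
# results are independent of any external resource.

# 20 standard residues; X/B/Z are ambiguity codes, U is selenocysteine.
AA_STANDARD <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)
AA_AMBIGUOUS <- c("X", "B", "Z")
AA_ALLOWED <- c(AA_STANDARD, AA_AMBIGUOUS, "U")

# Kyte & Doolittle (1982) hydropathy values; bounds are [-4.5, 4.5].
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# Bjellqvist pK set. Side chains plus termini; the N-terminal pK depends on
# the identity of the first residue, the C-terminal pK on the last.
BJELLQVIST_PK <- list(
  positive = c(K = 10.0, R = 12.0, H = 5.98),
  negative = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0),
  nterm_default = 7.5,
  nterm = c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44, E = 7.7),
  cterm_default = 3.55,
  cterm = c(D = 4.55, E = 4.75)
)

# Bondi (1964) van der Waals radii (Angstrom) by element; fallback 1.7.
BONDI_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
  P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  SE = 1.90
)
BONDI_DEFAULT_RADIUS <- 1.70

# Three-letter -> one-letter residue codes for coordinate files.
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M", SEC = "U"
)

# Canonical hydrophobin disulfide topology on cysteine ordinals.
CANONICAL_DISULFIDES <- list(c(1L, 6L), c(2L, 5L), c(3L, 4L), c(7L, 8L))
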