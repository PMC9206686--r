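# Reference constant tables for protein physicochemical indices.
# Average (isotope-weighted) residue masses and the water mass follow the
# Expasy ProtParam conventions; hydropathy values are the Kyte-Doolittle
# scale; the dipeptide instability weights (DIWV) are the published
# Guruprasad values; the pKa set is the Bjellqvist set used by Expasy's
# Compute pI.

.aa_letters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.aa_mass <- c(
  A = 71.0788,  C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519,  H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167,  Q = 128.1307, R = 156.1875,
  S = 87.0782,  T = 101.1051, V = 99.1326,  W = 186.2132, Y = 163.1760)

.water_mass <- 18.01524

.kyte_doolittle <- c(
  A = 1.8,  C = 2.5,  D = -3.5, E = -3.5, F = 2.8,
  G = -0.4, H = -3.2, I = 4.5,  K = -3.9, L = 3.8,
  M = 1.9,  N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V = 4.2,  W = -0.9, Y = -1.3)

# DIWV[i, j]: weight of the dipeptide formed by residue i followed by j.
.diwv <- matrix(c(
  1.0,44.94,-7.49,1.0,1.0,1.0,-7.49,1.0,1.0,1.0,1.0,1.0,20.26,1.0,1.0,1.0,1.0,1.0,1.0,1.0,
  1.0,1.0,20.26,1.0,1.0,1.0,33.6,1.0,1.0,20.26,33.6,1.0,20.26,-6.54,1.0,1.0,33.6,-6.54,24.68,1.0,
  1.0,1.0,1.0,1.0,-6.54,1.0,1.0,1.0,-7.49,1.0,1.0,1.0,1.0,1.0,-6.54,20.26,-14.03,1.0,1.0,1.0,
  1.0,44.94,20.26,33.6,1.0,1.0,-6.54,20.26,1.0,1.0,1.0,1.0,20.26,20.26,1.0,20.26,1.0,1.0,-14.03,1.0,
  1.0,1.0,13.34,1.0,1.0,1.0,1.0,1.0,-14.03,1.0,1.0,1.0,20.26,1.0,1.0,1.0,1.0,1.0,1.0,33.601,
  -7.49,1.0,1.0,-6.54,1.0,13.34,1.0,-7.49,-7.49,1.0,1.0,-7.49,1.0,1.0,1.0,1.0,-7.49,1.0,13.34,-7.49,
  1.0,1.0,1.0,1.0,-9.37,-9.37,1.0,44.94,24.68,1.0,1.0,24.68,-1.88,1.0,1.0,1.0,-6.54,1.0,-1.88,44.94,
  1.0,1.0,1.0,44.94,1.0,1.0,13.34,1.0,-7.49,20.26,1.0,1.0,-1.88,1.0,1.0,1.0,1.0,-7.49,1.0,1.0,
  1.0,1.0,1.0,1.0,1.0,-7.49,1.0,-7.49,1.0,-7.49,33.6,1.0,-6.54,24.64,33.6,1.0,1.0,-7.49,1.0,1.0,
  1.0,1.0,1.0,1.0,1.0,1.0,1.0,1.0,-7.49,1.0,1.0,1.0,20.26,33.6,20.26,1.0,1.0,1.0,24.68,1.0,
  13.34,1.0,1.0,1.0,1.0,1.0,58.28,1.0,1.0,1.0,-1.88,1.0,44.94,-6.54,-6.54,44.94,-1.88,1.0,1.0,24.68,
  1.0,-1.88,1.0,1.0,-14.03,-14.03,1.0,44.94,24.68,1.0,1.0,1.0,-1.88,-6.54,1.0,1.0,-7.49,1.0,-9.37,1.0,
  20.26,-6.54,-6.54,18.38,20.26,1.0,1.0,1.0,1.0,1.0,-6.54,1.0,20.26,20.26,-6.54,20.26,1.0,20.26,-1.88,1.0,
  1.0,-6.54,20.26,20.26,-6.54,1.0,1.0,1.0,1.0,1.0,1.0,1.0,20.26,20.26,1.0,44.94,1.0,-6.54,1.0,-6.54,
  1.0,1.0,1.0,1.0,1.0,-7.49,20.26,1.0,1.0,1.0,1.0,13.34,20.26,20.26,58.28,44.94,1.0,1.0,58.28,-6.54,
  1.0,33.6,1.0,20.26,1.0,1.0,1.0,1.0,1.0,1.0,1.0,1.0,44.94,20.26,20.26,20.26,1.0,1.0,1.0,1.0,
  1.0,1.0,1.0,20.26,13.34,-7.49,1.0,1.0,1.0,1.0,1.0,-14.03,1.0,-6.54,1.0,1.0,1.0,1.0,-14.03,1.0,
  1.0,1.0,-14.03,1.0,1.0,-7.49,1.0,1.0,-1.88,1.0,1.0,1.0,20.26,1.0,1.0,1.0,-7.49,1.0,1.0,-6.54,
  -14.03,1.0,1.0,1.0,1.0,-9.37,24.68,1.0,1.0,13.34,24.68,13.34,1.0,1.0,1.0,1.0,-14.03,-7.49,1.0,1.0,
  24.68,1.0,24.68,-6.54,1.0,-7.49,13.34,1.0,1.0,1.0,44.94,1.0,13.34,1.0,-15.91,1.0,-7.49,1.0,-9.37,13.34),
  nrow = 20, byrow = TRUE,
  dimnames = list(.aa_letters, .aa_letters))

# Bjellqvist pKa set (Expasy Compute pI).  Side chains plus termini;
# the N-terminal pKa depends on the first residue, and D/E have special
# values when C-terminal.
.pka <- list(
  positive = c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98),
  negative = c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0),
  nterm_by_residue = c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82,
                       V = 7.44, E = 7.7),
  cterm_by_residue = c(D = 4.55, E = 4.75))
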