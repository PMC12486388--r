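# Shared fixtures: a tiny hand-written PDB chain (with altlocs and
# hydrogens), random rotations, and a compact labelled graph builder.

write_fixture_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "HEADER    FIXTURE",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 12.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00 11.00           C",
    "ATOM      4  O   ALA A   1       1.500   2.400   0.500  1.00 11.00           O",
    "ATOM      5  CB AALA A   1       2.000   1.000   1.500  0.70 13.00           C",
    "ATOM      6  CB BALA A   1       2.200   1.100   1.600  0.30 13.00           C",
    "ATOM      7  HB1 ALA A   1       2.500   1.500   2.000  1.00 13.00           H",
    "ATOM      8  N   GLY A   2       3.300   1.500  -0.500  1.00 14.00           N",
    "ATOM      9  CA  GLY A   2       4.200   2.600  -0.800  1.00 15.00           C",
    "ATOM     10  C   GLY A   2       5.600   2.100  -1.100  1.00 15.00           C",
    "ATOM     11  O   GLY A   2       5.900   0.900  -1.000  1.00 15.00           O",
    "ATOM     12  N   SER A   3       6.500   3.000  -1.500  1.00 16.00           N",
    "ATOM     13  CA  SER A   3       7.900   2.700  -1.800  1.00 17.00           C",
    "ATOM     14  C   SER A   3       8.700   3.900  -2.300  1.00 17.00           C",
    "ATOM     15  O   SER A   3       8.200   5.000  -2.400  1.00 17.00           O",
    "ATOM     16  CB  SER A   3       8.000   1.600  -2.900  1.00 18.00           C",
    "ATOM     17  OG  SER A   3       9.300   1.200  -3.100  1.00 18.00           O",
    "ATOM     18  HG  SER A   3       9.600   0.500  -3.600  1.00 18.00           H",
    "TER",
    "END"
  ), path)
  path
}

random_rotation <- function() {
  qr_res <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Small labelled graph with random (valid-range) features, for model tests.
random_graph <- function(n = 12, seed = 1, cutoff = 14) {
  set.seed(seed)
  st <- synth_structure(n, seed = seed)
  feats <- matrix(runif(n * 62), n, 62)
  labels <- as.integer(runif(n) < 0.3)
  if (sum(labels) == 0) labels[1] <- 1L
  g <- build_protein_graph(st, feats, cutoff = cutoff, labels = labels)
  g$id <- sprintf("toy%06d_n%d", seed, n)
  g
}

# Finite-difference gradient of f (matrix -> scalar tensor value) at x0.
fd_gradient <- function(f, x0, h = 1e-6) {
  g <- matrix(0, nrow(x0), ncol(x0))
  for (i in seq_along(x0)) {
    xp <- x0; xp[i] <- xp[i] + h
    xm <- x0; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}
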