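# In-code text fixtures for the parser tests.

toy_pdb_lines <- function() {
  c(
    "TITLE     toy single residue",
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.000   2.000   3.000  1.00  0.00           C",
    "ATOM      3  CB  ALA A   1       3.000   2.500   3.000  1.00  0.00           C",
    "TER       4      ALA A   1",
    "END"
  )
}

two_model_pdb_lines <- function() {
  c(
    "MODEL        1",
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  GLY A   1       0.000   0.000   1.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   1.000  1.00  0.00           C",
    "ENDMDL",
    "END"
  )
}

altloc_pdb_lines <- function() {
  c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB  ALA A   1       1.000   1.000   0.000  1.00  0.00           C",
    "HETATM    4  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O",
    "END"
  )
}

write_lines_tmp <- function(lines, ext = ".pdb") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Five collinear residues: CA spacing 0.38 nm along x, single far-away
# side-chain atom each, so only the unconditional (i, i+3) pairs qualify
# at a 0.5 nm cutoff.
collinear_structure <- function(n = 5, spacing = 0.38) {
  tibble::tibble(
    chain = "A",
    resid = rep(seq_len(n), each = 2),
    ins = "",
    resname = "GLY",
    atom = rep(c("CA", "CB"), n),
    element = "C",
    x = rep((seq_len(n) - 1) * spacing, each = 2),
    y = as.numeric(t(cbind(rep(0, n), 5 + 3 * seq_len(n)))),
    z = 0
  )
}

# Collinear bead table with arbitrary spacing, for elastic-bond bound checks.
collinear_beads <- function(n, spacing) {
  tibble::tibble(
    index = seq_len(n), chain = "A", resid = seq_len(n), ins = "",
    resname = "GLY", x = (seq_len(n) - 1) * spacing, y = 0, z = 0,
    bead = "BB"
  )
}

# Static ensemble repeating one frame.
constant_ensemble <- function(xyz, n_frames = 5) {
  atoms <- tibble::tibble(chain = "A", resid = seq_len(nrow(xyz)), ins = "",
                          resname = "ALA", atom = "CA", element = "C")
  ensemble(replicate(n_frames, xyz, simplify = FALSE), atoms)
}

dssp_file_lines <- function() {
  c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    "    1    1 A M  H          0   0  200",
    "    2    2 A K  H          0   0  150",
    "    3    3 A V  E          0   0   20",
    "    4        !              0   0    0",
    "    5    5 A G  T          0   0   30",
    "    6    6 A L             0   0   40"
  )
}
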