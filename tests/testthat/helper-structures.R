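# In-code fixtures: tiny molecules and an independent pair-count oracle.

writeTempFile <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

methanolSdf <- function() writeTempFile(c(
  "methanol", "  test            3D", "",
  "  6  5  0  0  0  0  0  0  0  0999 V2000",
  "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    1.4300    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
  "   -0.3600    1.0280    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "   -0.3600   -0.5140    0.8900 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "   -0.3600   -0.5140   -0.8900 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "    1.7500    0.8900    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "  1  2  1  0", "  1  3  1  0", "  1  4  1  0", "  1  5  1  0",
  "  2  6  1  0", "M  END", "$$$$"), ".sdf")

# implicit hydrogens only; kekulized ring; slight pucker so coordinates
# are genuinely 3D
benzeneSdf <- function() writeTempFile(c(
  "benzene", "  test            3D", "",
  "  6  6  0  0  0  0  0  0  0  0999 V2000",
  "    1.3900    0.0000    0.0100 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    0.6950    1.2037   -0.0100 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "   -0.6950    1.2037    0.0100 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "   -1.3900    0.0000   -0.0100 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "   -0.6950   -1.2037    0.0100 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    0.6950   -1.2037   -0.0100 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "  1  2  2  0", "  2  3  1  0", "  3  4  2  0", "  4  5  1  0",
  "  5  6  2  0", "  6  1  1  0", "M  END", "$$$$"), ".sdf")

sdf2D <- function() writeTempFile(c(
  "flat", "  test            2D", "",
  "  2  1  0  0  0  0  0  0  0  0999 V2000",
  "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    1.5400    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "  1  2  1  0", "M  END", "$$$$"), ".sdf")

ethanolSdf <- function() writeTempFile(c(
  "ethanol", "  test            3D", "",
  "  3  2  0  0  0  0  0  0  0  0999 V2000",
  "    0.0000    0.0000    0.0100 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    1.5400    0.0000   -0.0100 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    2.1000    1.3300    0.0100 O   0  0  0  0  0  0  0  0  0  0  0  0",
  "  1  2  1  0", "  2  3  1  0", "M  END", "$$$$"), ".sdf")

# a full histidine residue (10 heavy atoms) plus hydrogens
histidinePdb <- function() writeTempFile(c(
  "ATOM      1  N   HIS A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  HIS A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   HIS A   1       2.009   1.420   0.000  1.00  0.00           C",
  "ATOM      4  O   HIS A   1       1.251   2.390   0.000  1.00  0.00           O",
  "ATOM      5  CB  HIS A   1       2.000  -0.760   1.220  1.00  0.00           C",
  "ATOM      6  CG  HIS A   1       3.480  -0.870   1.280  1.00  0.00           C",
  "ATOM      7  ND1 HIS A   1       4.170  -1.980   0.870  1.00  0.00           N",
  "ATOM      8  CD2 HIS A   1       4.420   0.010   1.740  1.00  0.00           C",
  "ATOM      9  CE1 HIS A   1       5.470  -1.790   1.050  1.00  0.00           C",
  "ATOM     10  NE2 HIS A   1       5.640  -0.580   1.580  1.00  0.00           N",
  "ATOM     11  H   HIS A   1       -0.40   0.800   0.000  1.00  0.00           H",
  "ATOM     12  HA  HIS A   1       1.800  -0.520  -0.890  1.00  0.00           H",
  "END"), ".pdb")

watersOnlyPdb <- function() writeTempFile(c(
  "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
  "HETATM    2  O   HOH A   2       3.000   0.000   0.000  1.00  0.00           O",
  "END"), ".pdb")

# Independent O(n^2) oracle: count typed pairs within a threshold from the
# loaded atom tables, without using enumeratePairs/feature code.
bruteForceCounts <- function(proteinAtoms, ligandAtoms, threshold,
                             variant = "five_element") {
  counts <- list()
  lt <- typeLigandAtom(ligandAtoms, variant)
  keepL <- lt %in% ligandTypes(buildVocabulary(variant))
  for (i in seq_len(nrow(proteinAtoms))) {
    pt <- typeProteinAtom(proteinAtoms$residue[i],
                          proteinAtoms$atom_name[i], variant)
    if (is.na(pt)) next
    for (j in seq_len(nrow(ligandAtoms))) {
      if (!keepL[j]) next
      d <- sqrt((proteinAtoms$x[i] - ligandAtoms$x[j])^2 +
                (proteinAtoms$y[i] - ligandAtoms$y[j])^2 +
                (proteinAtoms$z[i] - ligandAtoms$z[j])^2)
      if (d <= threshold) {
        key <- paste0(pt, "-", lt[j])
        counts[[key]] <- (counts[[key]] %||% 0) + 1
      }
    }
  }
  unlist(counts) %||% numeric(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random toy-complex specs over realizable types, fully seeded
randomSpecs <- function(nPairs, seed) {
  set.seed(seed)
  data.frame(
    protein_type = sample(realizableProteinTypes(), nPairs, replace = TRUE),
    ligand_type = sample(realizableLigandTypes(), nPairs, replace = TRUE),
    distance = round(stats::runif(nPairs, 2.1, 9.9), 3),
    stringsAsFactors = FALSE)
}
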