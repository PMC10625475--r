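workedExamplePairs <- function() {
  data.frame(protein_type = "N;3;2;1;0", ligand_type = "O;2;1;1;0",
             distance = c(2, 3, 4), stringsAsFactors = FALSE)
}

test_that("pair enumeration is inclusive at the threshold boundary", {
  prot <- data.frame(residue = "ALA", atom_name = "N", element = "N",
                     x = 0, y = 0, z = 0)
  lig <- data.frame(element = "O", explicit_valence = 2L,
                    n_heavy_neighbors = 1L, n_attached_hydrogens = 1L,
                    is_aromatic = FALSE, in_ring = FALSE,
                    x = 6, y = 0, z = 0)
  expect_identical(nrow(enumeratePairs(prot, lig, threshold = 6)), 1L)
  expect_equal(enumeratePairs(prot, lig, threshold = 6)$distance, 6)
  expect_identical(nrow(enumeratePairs(prot, lig, threshold = 5.9)), 0L)
})

test_that("enumeration recovers the worked-example geometry from files", {
  toy <- makeToyComplex(workedExamplePairs())
  pairs <- enumeratePairs(loadProtein(toy$pdb), loadLigand(toy$sdf),
                          threshold = 6)
  ours <- pairs[pairs$ligand_type == "O;2;1;1;0", ]
  expect_identical(nrow(ours), 3L)
  expect_equal(sort(ours$distance), c(2, 3, 4), tolerance = 1e-3)
})

test_that("untypeable atoms are skipped, unknown ligand types warn", {
  prot <- data.frame(residue = c("ALA", "XYZ"), atom_name = c("N", "ZZ1"),
                     element = c("N", "FE"), x = c(0, 1), y = 0, z = 0)
  lig <- data.frame(element = c("O", "U"),
                    explicit_valence = c(2L, 6L),
                    n_heavy_neighbors = c(1L, 0L),
                    n_attached_hydrogens = c(1L, 0L),
                    is_aromatic = FALSE, in_ring = FALSE,
                    x = c(3, 3.5), y = 0, z = 0)
  expect_warning(pairs <- enumeratePairs(prot, lig, threshold = 6),
                 "outside the packaged vocabulary")
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$protein_type, "N;3;2;1;0")
})

test_that("shell schemes follow the constant-step capped-terminal rule", {
  expect_equal(shellBounds(shellScheme(6, 2)), c(2.5, 4.5, 6.0))
  expect_equal(shellBounds(shellScheme(10, 2)), c(2.5, 4.5, 6.5, 8.5, 10))
  expect_equal(shellBounds(shellScheme(2.5001, 2)), c(2.5, 2.5001))
  expect_error(shellScheme(2.5, 2, minShell = 2.5), "smaller than")
  expect_error(shellScheme(6, -1), "step")
})

test_that("multi-shelled counts reproduce the worked example 1/2/0", {
  vocab <- buildVocabulary()
  ms <- multiShellFeatures(workedExamplePairs(), shellScheme(6, 2), vocab)
  expect_length(ms, 1540L * 3L)
  expect_identical(unname(ms["N;3;2;1;0-O;2;1;1;0-2.5"]), 1)
  expect_identical(unname(ms["N;3;2;1;0-O;2;1;1;0-4.5"]), 2)
  expect_identical(unname(ms["N;3;2;1;0-O;2;1;1;0-6.0"]), 0)
  expect_identical(sum(ms), 3)
})

test_that("shells partition pairs with (lower, upper] boundaries", {
  vocab <- buildVocabulary()
  onAndOff <- data.frame(protein_type = "N;3;2;1;0",
                         ligand_type = "O;2;1;1;0",
                         distance = c(2.5, 2.5000001, 4.5, 6.0))
  ms <- multiShellFeatures(onAndOff, shellScheme(6, 2), vocab)
  expect_identical(unname(ms["N;3;2;1;0-O;2;1;1;0-2.5"]), 1)  # 2.5 -> shell 1
  expect_identical(unname(ms["N;3;2;1;0-O;2;1;1;0-4.5"]), 2)
  expect_identical(unname(ms["N;3;2;1;0-O;2;1;1;0-6.0"]), 1)
  expect_identical(sum(ms), 4)  # every pair in exactly one shell
})

test_that("weighted features match the printed inverse-square example", {
  vocab <- buildVocabulary()
  w2 <- weightedFeatures(workedExamplePairs(), squared = TRUE, vocab)
  expect_length(w2, 1540L)
  expect_equal(unname(w2["N;3;2;1;0-O;2;1;1;0"]), 1/4 + 1/9 + 1/16,
               tolerance = 1e-12)
  expect_equal(round(unname(w2["N;3;2;1;0-O;2;1;1;0"]), 4), 0.4236)
  w1 <- weightedFeatures(workedExamplePairs(), squared = FALSE, vocab)
  expect_equal(unname(w1["N;3;2;1;0-O;2;1;1;0"]), 1/2 + 1/3 + 1/4,
               tolerance = 1e-12)
  expect_identical(sum(w2 > 0), 1L)
  bad <- workedExamplePairs(); bad$distance[1] <- 0
  expect_error(weightedFeatures(bad, TRUE, vocab), "impossible")
})

test_that("empty pair lists give all-zero vectors of the right length", {
  vocab <- buildVocabulary()
  none <- data.frame(protein_type = character(0),
                     ligand_type = character(0), distance = numeric(0))
  expect_identical(sum(multiShellFeatures(none, shellScheme(10, 2),
                                          vocab)), 0)
  expect_length(multiShellFeatures(none, shellScheme(10, 2), vocab),
                1540L * 5L)
  expect_identical(sum(weightedFeatures(none, TRUE, vocab)), 0)
  expect_identical(sum(ecifCounts(none, vocab)), 0)
})

test_that("shell sums conserve the single-threshold counts (property)", {
  vocab <- buildVocabulary()
  scheme <- shellScheme(10, 2)
  for (seed in 1:5) {
    set.seed(seed)
    n <- 60
    pairs <- data.frame(
      protein_type = sample(proteinTypes(vocab), n, replace = TRUE),
      ligand_type = sample(ligandTypes(vocab), n, replace = TRUE),
      distance = runif(n, 0.5, 10))
    ms <- multiShellFeatures(pairs, scheme, vocab)
    counts <- ecifCounts(pairs, vocab)
    sums <- rowsum(ms, rep(pairNames(vocab),
                           each = length(shellBounds(scheme))))
    expect_equal(sums[pairNames(vocab), 1], unname(counts),
                 ignore_attr = TRUE)
  }
})

test_that("features are invariant to atom input order", {
  toy <- makeToyComplex(randomSpecs(6, seed = 42))
  prot <- loadProtein(toy$pdb); lig <- loadLigand(toy$sdf)
  vocab <- buildVocabulary()
  p1 <- enumeratePairs(prot, lig, 10)
  set.seed(1)
  p2 <- enumeratePairs(prot[sample.int(nrow(prot)), ],
                       lig[sample.int(nrow(lig)), ], 10)
  scheme <- shellScheme(10, 2)
  expect_identical(multiShellFeatures(p1, scheme, vocab),
                   multiShellFeatures(p2, scheme, vocab))
  expect_equal(weightedFeatures(p1, TRUE, vocab),
               weightedFeatures(p2, TRUE, vocab), tolerance = 1e-12)
})

test_that("weighted features increase when any distance shrinks", {
  vocab <- buildVocabulary()
  base <- workedExamplePairs()
  for (squared in c(TRUE, FALSE)) {
    w0 <- weightedFeatures(base, squared, vocab)["N;3;2;1;0-O;2;1;1;0"]
    closer <- base; closer$distance[2] <- 2.5
    w1 <- weightedFeatures(closer, squared,
                           vocab)["N;3;2;1;0-O;2;1;1;0"]
    expect_gt(w1, w0)
  }
})

test_that("enlarging the threshold never decreases any count", {
  toy <- makeToyComplex(randomSpecs(8, seed = 7))
  prot <- loadProtein(toy$pdb); lig <- loadLigand(toy$sdf)
  vocab <- buildVocabulary()
  c6 <- ecifCounts(enumeratePairs(prot, lig, 6), vocab)
  c10 <- ecifCounts(enumeratePairs(prot, lig, 10), vocab)
  expect_true(all(c10 >= c6))
})

test_that("featurizeComplex wires files to features with tuned defaults", {
  toy <- makeToyComplex(workedExamplePairs())
  w <- featurizeComplex(toy$pdb, toy$sdf, method = "weighted")
  expect_length(w, 1540L)
  expect_equal(unname(w["N;3;2;1;0-O;2;1;1;0"]), 1/4 + 1/9 + 1/16,
               tolerance = 1e-3)
  ms <- featurizeComplex(toy$pdb, toy$sdf, method = "multishell",
                         threshold = 6)
  expect_identical(unname(ms["N;3;2;1;0-O;2;1;1;0-2.5"]), 1)
  ec <- featurizeComplex(toy$pdb, toy$sdf, method = "ecif")
  expect_identical(unname(ec["N;3;2;1;0-O;2;1;1;0"]), 3)
})
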