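test_that("parsing recovers atom counts, charges and implicit hydrogens", {
  asp <- parse_molecule("CC(=O)Oc1ccccc1C(=O)O")
  expect_s3_class(asp, "molecule")
  expect_equal(n_heavy_atoms(asp), 13L)

  expect_equal(n_heavy_atoms(parse_molecule("C")), 1L)
  expect_equal(parse_molecule("C")$atoms$nH, 4L)

  # aromatic H conventions: benzene CH, pyridine N, pyrrole written [nH]
  benz <- parse_molecule("c1ccccc1")
  expect_true(all(benz$atoms$nH == 1L))
  pyr <- parse_molecule("c1ccncc1")
  expect_equal(pyr$atoms$nH[pyr$atoms$element == "N"], 0L)
  pyrrole <- parse_molecule("c1cc[nH]c1")
  expect_equal(pyrrole$atoms$nH[pyrrole$atoms$element == "N"], 1L)

  # bracket atoms: explicit H and charge
  ammonium <- parse_molecule("[NH4+]")
  expect_equal(ammonium$atoms$nH, 4L)
  expect_equal(ammonium$atoms$charge, 1L)
  carboxylate <- parse_molecule("CC(=O)[O-]")
  expect_equal(carboxylate$atoms$charge[4], -1L)

  # multivalent sulfur / phosphorus default valences
  expect_equal(parse_molecule("CS(=O)(=O)C")$atoms$nH[2], 0L)
  expect_equal(parse_molecule("CP(C)C")$atoms$nH[2], 0L)
})

test_that("invalid SMILES produce named parse errors", {
  expect_error(parse_molecule("C1CC"), "unclosed ring")
  expect_error(parse_molecule("C(C"), "unmatched")
  expect_error(parse_molecule(""), "non-empty")
  expect_error(parse_molecule("C$C"), "unexpected character")
  expect_error(parse_molecule("[Xx]"), "unsupported element|cannot parse")
})

test_that("canonical form is independent of input spelling", {
  pairs <- list(
    c("CCO", "OCC"),
    c("CC(=O)Oc1ccccc1C(=O)O", "OC(=O)c1ccccc1OC(C)=O"),
    c("c1ccccc1", "C1=CC=CC=C1"),          # Kekule benzene aromatizes
    c("c1ccncc1", "C1=CC=NC=C1"),
    c("CC(C)CO", "OCC(C)C"),
    c("N[C@@H](C)C(=O)O", "C[C@H](N)C(=O)O") # stereo respelling
  )
  for (p in pairs) {
    expect_identical(canonical_smiles(p[1]), canonical_smiles(p[2]))
  }
})

test_that("parse/write round-trips are stable across the fixture corpus", {
  fx <- seed7_fixture()
  smis <- c(fx$building_blocks_tbl$smiles, fx$queries_tbl$smiles)
  for (s in smis) {
    can <- canonical_smiles(s)
    expect_identical(canonical_smiles(can), can)
  }
})

test_that("tetrahedral stereo survives canonicalization with correct parity", {
  l_ala <- canonical_smiles("C[C@H](N)C(=O)O")
  d_ala <- canonical_smiles("C[C@@H](N)C(=O)O")
  expect_false(identical(l_ala, d_ala))
  # idempotent and convergent from a reordered spelling
  expect_identical(canonical_smiles(l_ala), l_ala)
  expect_identical(canonical_smiles("N[C@@H](C)C(=O)O"), l_ala)
  # stereo flags are what the complexity term counts
  expect_equal(complexity_penalty("C[C@H](N)C(=O)O")$n_chiral, 1L)
  expect_equal(complexity_penalty("CC(N)C(=O)O")$n_chiral, 0L)
})

test_that("atom indices follow token order and maps are preserved", {
  m <- parse_molecule("[CH3:1][C:2](=[O:3])[OH:4]")
  expect_equal(m$atoms$map, 1:4)
  expect_equal(m$atoms$element, c("C", "C", "O", "O"))
  # writing with maps keeps them attached to the same atoms
  rt <- parse_molecule(write_smiles(m, with_maps = TRUE))
  expect_setequal(
    paste(rt$atoms$element, rt$atoms$map),
    paste(m$atoms$element, m$atoms$map)
  )
})
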