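ESTERIFICATION <- "[CH3:1][C:2](=[O:3])[OH:4].[OH:5][CH3:6]>>[CH3:1][C:2](=[O:3])[O:5][CH3:6]"

test_that("mapped reactions validate their atom-map contract", {
  rxn <- parse_mapped_reaction(ESTERIFICATION)
  expect_s3_class(rxn, "mapped_reaction")
  expect_length(rxn$reactants, 2L)
  expect_length(rxn$products, 1L)

  expect_s3_class(parse_mapped_reaction("[CH4:1]>>[CH4:1]"), "mapped_reaction")

  expect_error(parse_mapped_reaction("CC>>CC"), "without atom-map")
  expect_error(
    parse_mapped_reaction("[CH3:1][CH3:1]>>[CH3:1][CH3:1]"),
    "duplicate atom-map"
  )
  expect_error(
    parse_mapped_reaction("[CH4:1]>>[CH4:2]"),
    "no reactant counterpart"
  )
  expect_error(parse_mapped_reaction("[CH4:1]"), "separator")
})

test_that("reaction centre is the map-diffed changed-atom set", {
  ctr <- detect_reaction_center(parse_mapped_reaction(ESTERIFICATION))
  expect_setequal(ctr$map, c(2L, 5L))  # carbonyl C and ester O

  expect_equal(nrow(detect_reaction_center(parse_mapped_reaction("[CH4:1]>>[CH4:1]"))), 0L)

  # amide coupling: centre = carbonyl C and N
  amide <- build_mapped_reaction("amidation", "CC", "CC")
  ctr2 <- detect_reaction_center(parse_mapped_reaction(amide$text))
  prod <- parse_mapped_reaction(amide$text)$products[[1]]
  elems <- prod$atoms$element[match(ctr2$map, prod$atoms$map)]
  expect_setequal(elems, c("C", "N"))
  expect_equal(nrow(ctr2), 2L)
})

test_that("centre detection matches the brute-force adjacency-diff oracle", {
  fx <- seed7_fixture()
  for (txt in fx$reactions_tbl$reaction) {
    rxn <- parse_mapped_reaction(txt)
    ctr <- detect_reaction_center(rxn)
    expect_identical(sort(ctr$map), oracle_reaction_center(rxn))
  }
})

test_that("centre detection is invariant to reactant order and map renumbering", {
  flipped <- "[OH:5][CH3:6].[CH3:1][C:2](=[O:3])[OH:4]>>[CH3:1][C:2](=[O:3])[O:5][CH3:6]"
  renum <- "[CH3:11][C:12](=[O:13])[OH:14].[OH:15][CH3:16]>>[CH3:11][C:12](=[O:13])[O:15][CH3:16]"
  base <- detect_reaction_center(parse_mapped_reaction(ESTERIFICATION))
  expect_setequal(
    detect_reaction_center(parse_mapped_reaction(flipped))$map, base$map
  )
  expect_setequal(
    detect_reaction_center(parse_mapped_reaction(renum))$map, base$map + 10L
  )
})

test_that("RFrag weights follow 2^-d within the two-hop window", {
  rxn <- parse_mapped_reaction(ESTERIFICATION)
  fc <- extract_rfrags(rxn)
  # centre atoms at weight 1, one-hop neighbours at 0.5; N_R is the
  # weighted total
  expect_setequal(unname(fc$counts), c(1, 1, 0.5, 0.5, 0.5))
  expect_equal(fc$total, 3.5)

  # a long ester: atoms more than two bonds from the centre contribute
  # nothing
  long <- build_mapped_reaction("esterification", "CCCCC", "CCCC")
  rxn2 <- parse_mapped_reaction(long$text)
  fc2 <- extract_rfrags(rxn2)
  prod <- rxn2$products[[1]]
  ctr <- detect_reaction_center(rxn2)
  d <- mol_distances(prod)
  dmin <- apply(d[, ctr$atom, drop = FALSE], 1, min)
  expect_equal(sum(fc2$counts), sum(2^(-dmin[dmin <= 2])))
  expect_true(sum(dmin > 2) > 0)  # the fixture really has distant atoms
  expect_true(all(unlist(fc2$counts) %in% c(0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75, 2)))

  # identity reaction: empty centre, zero fragments, with a warning
  expect_warning(
    fc3 <- extract_rfrags(parse_mapped_reaction("[CH4:1]>>[CH4:1]")),
    "empty centre"
  )
  expect_length(fc3$counts, 0L)
})

test_that("all fixture RFrag per-atom weights lie in {1, 1/2, 1/4}", {
  fx <- seed7_fixture()
  for (txt in fx$reactions_tbl$reaction) {
    rxn <- parse_mapped_reaction(txt)
    ctr <- detect_reaction_center(rxn)
    for (j in seq_along(rxn$products)) {
      catoms <- ctr$atom[ctr$product == j]
      if (length(catoms) == 0L) next
      d <- mol_distances(rxn$products[[j]])
      dmin <- apply(d[, catoms, drop = FALSE], 1, min)
      w <- 2^(-dmin[dmin <= 2])
      expect_true(all(w %in% c(1, 0.5, 0.25)))
    }
  }
})
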