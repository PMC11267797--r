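test_that("building-block counts are normalized per molecule", {
  # OCCO: 4 retained fragments, two distinct environments each occurring
  # twice -> each gets 2/4 = 0.5, and N_B counts the 4 raw occurrences
  fc <- index_building_blocks("OCCO")
  expect_length(fc$counts, 2L)
  expect_equal(unname(sort(fc$counts)), c(0.5, 0.5))
  expect_equal(fc$total, 4)

  # per-molecule contributions always sum to 1
  fx <- seed7_fixture()
  for (s in fx$building_blocks_tbl$smiles[1:10]) {
    one <- index_building_blocks(s)
    expect_equal(sum(one$counts), 1)
  }
})

test_that("corpus indexing is additive and streaming-safe", {
  fx <- seed7_fixture()
  smis <- fx$building_blocks_tbl$smiles
  whole <- index_building_blocks(smis)
  doubled <- index_building_blocks(c(smis, smis))
  expect_equal(doubled$total, 2 * whole$total)
  expect_equal(
    doubled$counts[names(whole$counts)],
    2 * whole$counts
  )

  # reactions: concatenating two corpora sums their counts
  rx <- fx$reactions_tbl$reaction
  a <- index_reactions(rx[1:5])
  b <- index_reactions(rx[6:10])
  both <- index_reactions(rx[1:10])
  m <- merge_fragment_counts(a, b)
  expect_equal(m$total, both$total)
  expect_equal(
    sort(unlist(m$counts)),
    sort(unlist(both$counts))
  )
})

test_that("dirty corpora are skipped with a count, empty corpora error", {
  expect_error(index_building_blocks(character(0)), "empty")
  expect_error(index_reactions(character(0)), "empty")

  expect_warning(
    fc <- index_building_blocks(c("CCO", "C1CC", "not a molecule")),
    "skipped 2"
  )
  expect_equal(fc$n_records, 1L)
  expect_equal(fc$n_skipped, 2L)

  expect_warning(
    rc <- index_reactions(c(seed7_fixture()$reactions_tbl$reaction[1], "CC>>CC")),
    "skipped 1"
  )
  expect_equal(rc$n_skipped, 1L)
})

test_that("fragment counts survive a JSON round-trip", {
  fx <- seed7_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_fragment_counts(fx$bcounts, path)
  back <- read_fragment_counts(path)
  expect_equal(back$total, fx$bcounts$total)
  expect_equal(back$source, "building_blocks")
  expect_equal(
    back$counts[sort(names(back$counts))],
    fx$bcounts$counts[sort(names(fx$bcounts$counts))]
  )
})

test_that(".smi and .rsmi readers handle names and blank lines", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO\tethanol", "", "c1ccccc1"), path)
  tbl <- read_smi(path)
  expect_equal(tbl$smiles, c("CCO", "c1ccccc1"))
  expect_equal(tbl$name, c("ethanol", NA))
})
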