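test_that("fragment score averages negative terms over all n fragments", {
  mol <- parse_molecule("CCCO")  # 4 retained fragments
  ids <- retained_fragments(mol)$id

  # all fragments known and non-negative -> 0
  tab_pos <- make_test_table(ids, rep(1.5, 4))
  expect_equal(br_fragment_score(mol, tab_pos)$score, 0)

  # every fragment unknown -> all Score_i = -6 -> average -6
  tab_empty <- make_test_table(numeric(0), numeric(0))
  expect_equal(br_fragment_score(mol, tab_empty)$score, -6)

  # mixed scores {1.2, -2, -4, 0}: only negative terms sum, denominator n
  tab_mixed <- make_test_table(ids, c(1.2, -2, -4, 0))
  expect_equal(br_fragment_score(mol, tab_mixed)$score, (-2 - 4) / 4)

  # a fragment-free molecule scores 0 with a warning
  expect_warning(out <- br_fragment_score(parse_molecule("C"), tab_empty), "no retained")
  expect_equal(out$score, 0)
})

test_that("normalization maps the raw score onto [1, 10] with the stated anchors", {
  tab_empty <- make_test_table(numeric(0), numeric(0))
  mol <- parse_molecule("CCCO")
  ids <- retained_fragments(mol)$id
  tab_pos <- make_test_table(ids, rep(2, 4))

  # best case: no rare fragments, acyclic achiral small molecule
  res_best <- suppressWarnings(br_sascore("C", tab_pos))
  expect_identical(res_best$normalized, 1)

  # worst case: all fragments unknown and complexity >= penalty buffer
  hard <- "C[C@H]1CCCCCCCCC[C@@H](O)CC[C@H]1O"  # stereo-rich macrocycle: penalty > 1
  res_worst <- br_sascore(hard, tab_empty)
  expect_gte(res_worst$complexity$total, 1)
  expect_identical(res_worst$normalized, 10)

  # interior point: raw = -3.5 with PB = 1 gives 10 - 9*(3.5/7) = 5.5
  cfg <- scorer_config(penalty_buffer = 1)
  raw <- -3.5
  expect_equal(10 - 9 * (raw - cfg$raw_worst) / (0 - cfg$raw_worst), 5.5)

  expect_error(scorer_config(-0.1), "non-negative")
})

test_that("per-atom contributions are the negative fragment parts", {
  mol <- parse_molecule("CCCO")
  ids <- retained_fragments(mol)$id
  tab <- make_test_table(ids[-2], c(1, 1, 1))  # atom 2's fragment unknown
  res <- br_sascore(mol, tab)
  contrib <- atom_contributions(res)
  expect_equal(contrib$contribution[2], -6)
  expect_equal(contrib$contribution[-2], rep(0, 3))
  # algebraic identity: contributions sum to n * fragment score
  expect_equal(sum(contrib$contribution), nrow(res$fragments) * res$br_fragment_score)

  tab_pos <- make_test_table(ids, rep(0.5, 4))
  expect_true(all(atom_contributions(br_sascore(mol, tab_pos))$contribution == 0))
})

test_that("normalized scores stay in [1, 10] over the fixture queries", {
  fx <- seed7_fixture()
  sc <- suppressWarnings(score_molecules(fx$queries_tbl, fx$table))
  expect_true(all(sc$score >= 1 & sc$score <= 10))
  expect_true(all(sc$br_fragment_score <= 0))
  expect_equal(sc$raw, sc$br_fragment_score - sc$complexity)
})

test_that("lowering one fragment's score never lowers the normalized score", {
  mol <- parse_molecule("CCCO")
  ids <- retained_fragments(mol)$id
  base <- br_sascore(mol, make_test_table(ids, c(1, -1, 0.5, 0)))$normalized
  worse <- br_sascore(mol, make_test_table(ids, c(1, -2.5, 0.5, 0)))$normalized
  expect_gte(worse, base)
})

test_that("scoring is deterministic and independent of input spelling", {
  fx <- seed7_fixture()
  a <- br_sascore("CCOC(=O)c1ccccc1", fx$table)
  b <- br_sascore("c1ccccc1C(=O)OCC", fx$table)
  expect_equal(a$normalized, b$normalized)
  expect_equal(a$br_fragment_score, b$br_fragment_score)
  expect_equal(sort(a$fragments$score), sort(b$fragments$score))
})

test_that("score_molecules returns a tidy row per input and flags bad SMILES", {
  fx <- seed7_fixture()
  dat <- tibble::tibble(smiles = c("CCO", "C1CC", "c1ccccc1"))
  expect_warning(sc <- score_molecules(dat, fx$table), "skipped 1")
  expect_equal(nrow(sc), 3L)
  expect_true(is.na(sc$score[2]))
  expect_false(anyNA(sc$score[c(1, 3)]))
  expect_true(all(c("canonical_smiles", "raw", "score", "complexity") %in% names(sc)))

  # broom-style accessors
  res <- br_sascore("CCO", fx$table)
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(nrow(tidy(res)), 3L)
  expect_equal(nrow(glance(res)), 1L)
  expect_s3_class(tidy(fx$table), "tbl_df")
  expect_equal(nrow(glance(fx$table)), 1L)
})

test_that("autoplot builds a contribution chart without evaluation", {
  fx <- seed7_fixture()
  p <- ggplot2::autoplot(br_sascore("CCOC(=O)c1ccccc1", fx$table))
  expect_s3_class(p, "ggplot")
})
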