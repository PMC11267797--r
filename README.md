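# sabr — building-block- and reaction-aware synthetic accessibility scoring

`sabr` estimates how difficult a small molecule is to synthesize, on the
familiar 1 (easy) to 10 (hard) synthetic-accessibility scale, for
chemists and cheminformaticians triaging virtually designed molecules.
Instead of scoring fragment popularity against a generic corpus of known
molecules, it scores each fragment against the **synthesis knowledge a
planner actually has**: a catalog of purchasable building blocks and a
dataset of recorded, atom-mapped reactions. This is the BR-SAScore
approach: fragments a planner can buy (BFrags) or make (RFrags) score
well; everything else is flagged as hard, atom by atom.

## The score

Every heavy atom contributes one circular fragment — its ECFP4-style
environment identifier at radius 2 (radius-0/1 environments are excluded
as uninformative; for atoms whose radius-2 ball exceeds the molecule, the
largest realizable environment fills the slot). Two corpora are indexed:

* **BFrags** — fragments occurring in building blocks; each occurrence in
  a block with *m* fragments counts 1/*m* (fragments of large blocks are
  less versatile), and `N_B` is the total number of extracted occurrences.
* **RFrags** — fragments centred on, or within two bonds of, the reaction
  centre on the product side of each mapped reaction (the centre is the
  set of product atoms whose bonding, hydrogen count or charge changed
  through the atom map), weighted `2^-d` by the distance *d* to the
  nearest centre atom.

Counts ≤ 1 are discarded as unreliably rare, the rest become

```
BScore_i = ln(count_i / (0.001 N_B)),   RScore_i = ln(count_i / (0.001 N_R)),
```

each table min–max rescaled onto [−3, 3]. A fragment's score is
`Score_i = max(BScore_i, RScore_i)`, or **−6** if it appears in neither
table. The molecule-level fragment score averages the negative terms over
all *n* fragments, a four-term complexity penalty is subtracted

```
penalty = (n_atoms^1.005 − n_atoms) + log10(n_chiral + 1)
        + log10(n_bridgehead + 1) + log10(n_spiro + 1) + log10(n_macrocycle + 1)
```

and the raw score is mapped onto [1, 10] with anchors 0 (best) and
−6 − PenaltyBuffer (worst; PenaltyBuffer defaults to 1). Because every
atom owns exactly one fragment, the negative part of its `Score_i` is a
per-atom attribution — the darker-is-harder highlighting.

## Worked example

Build a score table from the bundled deterministic fixture generator (a
desk-scale stand-in for a reagent catalog and a reaction dataset), then
score a molecule:

```r
library(sabr)

fx  <- generate_fixture_corpus(fixture_spec(seed = 7), tempdir())
tab <- build_score_table(
  index_building_blocks(fx$building_blocks),
  index_reactions(fx$reactions)
)
tab
#> <score_table> 12 BScores, 34 RScores (N_B=411, N_R=153), missing fragments score -6

res <- br_sascore("c1ccccc1CNCCC", tab)   # N-propyl benzylamine
res
#> <sa_score> CCCNCc1ccccc1
#>   fragment score: -0.8095  complexity: 0.1327  raw: -0.9422  score (1-10): 2.21
```

The score of 2.21 says "easy": this is a reductive-amination product of
corpus reagents, so its junction fragments are known RFrags and most of
its interior matches building-block fragments. `tidy(res)` shows the
per-fragment decomposition (here 4 of 11 fragments are rare, the benzylic
fragment scoring −6 dominates the fragment score of −0.81), and
`autoplot(res)` draws the per-atom attribution chart. Scoring a whole
table and checking how well the score separates easy (ES) from hard (HS)
labels:

```r
sc <- score_molecules(read_queries(fx$queries), tab)
evaluate_scores(sc)
#> # A tibble: 1 × 4
#>   pr_auc roc_auc n_pos n_neg
#>    <dbl>   <dbl> <int> <int>
#> 1      1       1    20    20
```

The same pipeline is scriptable: `exec/sabr make-fixtures --seed 7
--out-dir d`, then `sabr build`, `sabr score` (with `--penalty-buffer`),
`sabr explain` for one molecule's per-atom JSON, and `sabr eval` for the
AUC report.

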