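---
title: "Scoring synthetic accessibility from building blocks and reactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring synthetic accessibility from building blocks and reactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`sabr` implements a likeness-style synthetic-accessibility score in the
SAScore family, with the fragment-popularity term replaced by scores
derived from the two knowledge sources a retrosynthesis planner actually
uses: purchasable building blocks and recorded reactions. The working
assumption is that a molecule is easy to make when every one of its
fragments is either *inherent in an available building block* (it can be
bought) or *formed at the centre of a known reaction* (it can be made).
Fragments matching neither source are penalized hard, and because every
fragment is anchored on one atom, the penalty localizes onto atoms — the
score explains itself.

The pipeline is:

1. **Fragments.** Every heavy atom contributes one circular fragment: the
   canonical identifier of its atom-centred environment computed by
   iterative neighbourhood hashing, exactly as in extended-connectivity
   fingerprint generation, but kept as unfolded full-width integers so
   that distinct environments essentially never collide. The radius-2
   slot (ECFP4) is retained; radius-0 and radius-1 environments are
   excluded so that ubiquitous one- and two-bond motifs cannot drown the
   tables.
2. **BFrags.** Building blocks are fragmented the same way. A block with
   *m* retained fragments contributes 1/*m* per occurrence — fragments
   locked inside large reagents are less versatile starting material than
   the same fragment in a small one — while the corpus total `N_B`
   accumulates raw occurrence counts.
3. **RFrags.** For each atom-mapped reaction the product atoms whose
   bond set, hydrogen count or charge changed relative to their mapped
   reactant counterpart form the reaction centre. Product atoms at
   shortest bond distance d ∈ {0, 1, 2} from the centre contribute their
   fragment with weight 2^−d; `N_R` accumulates the weighted total.
4. **Scores.** Counts ≤ 1 are excluded as unreliably rare. The rest are
   scored `ln(count / (0.001 × N))` against their corpus total and each
   table is independently min–max rescaled onto [−3, 3]. Lookup merges
   the tables by `Score_i = max(BScore_i, RScore_i)`, with −6 for a
   fragment found in neither — twice as bad as the worst known fragment.
5. **Molecule score.** The fragment score is the sum of negative
   `Score_i` divided by the total fragment count *n*; the structural
   complexity penalty (below) is subtracted; the result is linearly
   mapped onto [1, 10] between the anchors 0 (best) and
   −6 − PenaltyBuffer (worst) and clipped.

## Complexity penalty

Four additive terms capture global structure not visible to radius-2
fragments: size `n_atoms^1.005 − n_atoms`; stereo `log10(n_chiral + 1)`
counting **assigned** tetrahedral centres only (the drawn structure is
what gets scored; unassigned potential centres and double-bond stereo are
not counted); ring `log10(n_bridgehead + 1) + log10(n_spiro + 1)` from
pairwise SSSR ring overlap (two rings sharing one atom make it spiro; two
rings sharing two or more bonds make their junction atoms bridgeheads;
plain fusion contributes nothing); macrocycle `log10(n_macrocycle + 1)`
counting SSSR rings of more than 8 atoms. Base-10 logarithms follow the
SAScore lineage this decomposition comes from.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `max_radius` | 2 | environment radius of the retained fragment slot (ECFP4) |
| rare-count threshold | 1 | aggregated (fractional/weighted) counts ≤ 1 are excluded |
| score band | [−3, 3] | min–max range of each scaled table |
| `missing_score` | −6 | floor for fragments absent from both tables |
| `penalty_buffer` | 1 | slack in the normalization denominator; with all-unknown fragments, complexity differences up to this amount still separate scores before clipping |

The log base in the count-to-score transform is natural; any base change
is absorbed by the min–max rescaling, so the choice is recorded in the
table metadata purely for reproducibility.

## Numerical and design choices

* **Averaging denominator.** The fragment score divides the sum of
  negative terms by the *total* fragment count *n*, not by the number of
  negative terms: one rare fragment in a large, otherwise-known molecule
  should hurt less than the same fragment in a tiny one. With this
  choice, per-atom contributions sum exactly to *n* × fragment score.
* **Small molecules.** Retained fragment radius is min(2, eccentricity of
  the atom): an atom whose radius-2 ball exceeds the molecule keeps the
  largest environment it can realize. An isolated atom realizes only a
  radius-0 environment, which the radius-0/1 exclusion removes, so
  methane has no retained fragments and scores on complexity alone.
* **Scaling.** "Between −3 and 3" is implemented as per-table linear
  min–max (B and R independently); a degenerate constant table maps to 0.
  A one-ulp guard clamps floating-point overshoot at the band edges.
* **Raw scores below the worst anchor** (possible when the complexity
  penalty is large) clip to 10; raw scores above 0 cannot occur.
* **Identifier hashing** uses a polynomial rolling hash modulo 2^31 − 1
  over the environment invariant stream (element, heavy degree, implicit
  H, charge, aromaticity, ring membership, then per-iteration sorted
  (bond order, neighbour id) pairs). All intermediates stay below 2^52,
  so double arithmetic is exact and identifiers are platform-stable.
* **Dirty corpora** never abort an index run: unparsable records are
  skipped and counted, matching how large real catalogs behave.
* **Serialization** (count tables, score tables) is versioned JSON with
  17-significant-digit numbers and identifier-sorted entries, so
  identical corpora give byte-identical files and exact lookup
  round-trips.

## Chemistry layer and its limits

Molecules are parsed from SMILES into a heavy-atom graph with implicit
hydrogens (Daylight default valences; aromatic-atom conventions),
charges, atom maps and assigned tetrahedral stereo; canonical writing
uses Morgan-style invariant refinement with parity-corrected stereo
symbols. The test suite cross-checks canonicalization, environment
identity and ring-system descriptors against RDKit on the full fixture
set, including RDKit-generated random respellings.

Known limitations, deliberate at this scope: aromaticity perception for
Kekulé input covers six-membered C/N rings with alternating double bonds
(benzene, pyridine and their substituted forms); five-membered
heteroaromatics must be written in aromatic (lowercase) form. Double-bond
stereo is parsed but ignored. Tautomers are not canonicalized, and there
is no InChI or depiction support.

## The fixture generator

`generate_fixture_corpus()` emulates, at desk scale, the inputs a
planner-derived deployment would use: a purchasable-reagent catalog
(default 60 blocks: carboxylic acids, alcohols, amines, alkyl halides and
aldehydes over shared alkyl/aryl substituent pools, padded with
homologous series the way real catalogs carry them) and an atom-mapped
reaction dataset (default 40 reactions: esterification, amide coupling,
SN2 substitution, reductive amination, with maps constructed alongside
the product so every record validates by construction). The labeled query
set pairs products of those families (ES) against exotic structures —
spiro/bridged cages, macrocycles, cumulated systems, dense halogenation,
stereocentre clusters — absent from the corpora (HS). Everything is
byte-deterministic given the seed; seed 7 with the default sizes is the
corpus used throughout the tests, chosen small enough that the whole
suite indexes it many times within seconds.

What the fixture does *not* emulate: corpus scale (a real catalog has
10^8 blocks, so BFrag counts survive the rare-count filter far more
often; here only the most shared environments do, which pushes easy-query
scores upward), reaction diversity and noise (real atom maps are
imperfect; fixture maps are exact), and planner-derived labels (ES/HS
labels here are by construction, not by running a synthesis planner).
Passing tests therefore demonstrate the correctness of the machinery and
the direction and separability of the score at toy scale — not the
published-scale discrimination numbers, which depend on corpora and
labels this package deliberately does not ship.

## What the checks compute

The acceptance script rebuilds the seed-7 corpus and table from scratch
and verifies at run time the two normalization extremes (a
single-heavy-atom molecule: fragment score 0, penalty 0, score exactly 1;
a stereocentre-rich macrocyclic diol foreign to both corpora: all
fragments at −6, penalty ≥ 1, score exactly 10) and the maximum stored
scaled score (exactly 3 under min–max scaling). The test suite adds the
brute-force oracles: full map-keyed adjacency diff for reaction centres,
pairwise-comparison ROC-AUC and first-principles PR-AUC, RDKit
agreement for the chemistry layer, and byte-level determinism of the full
pipeline.
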