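---
title: "Mining and evaluating biotransformation rules: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and evaluating biotransformation rules: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models and algorithms behind `ruleminer`, the
parameters that matter, the numerical and design choices made where the
problem left room, and what the synthetic test corpora do and do not
demonstrate.

## Scope and input model

The package mines transformation rules from *decomposition* reactions: one
connected substrate yielding one or more products, as reaction SMILES
`substrate>>product1.product2`. Heavy atoms only are modeled; hydrogens
are tracked as per-atom counts and inferred by standard valence rules when
not written explicitly. Stereochemistry, isotopes and multi-substrate
(condensation) reactions are out of scope.

An atom-atom mapping (AAM) — a bijection between substrate heavy atoms and
mapped product heavy atoms that preserves elements — is the contract every
downstream step relies on. Pre-mapped input is the first-class path.
`map_atoms()` provides an internal mapper for unmapped reactions: an exact
branch-and-bound search over element-respecting injections minimizing the
number of changed bonds (formed + cleaved + order-changed, counting bonds
to unmatched product atoms). It is verified against a brute-force
enumeration oracle in the tests and is intended for small molecules; its
default budget of 15 substrate heavy atoms keeps the exact search fast,
and larger inputs are rejected with advice to supply pre-mapped SMILES.
Production-scale mapping should come from a dedicated mapping tool.

**Implicit cosubstrates.** Biotransformation databases typically write
`CC(=O)OC>>CC(=O)O.CO` without the water that donates the acid's hydroxyl
oxygen. Product atoms without a map are therefore tolerated for a
configurable element list (default: oxygen) and tagged *incoming*; they
participate in formed-bond descriptors and in product construction. This
is a deliberate interpretation choice, surfaced as the `incoming_elems`
argument rather than hidden.

**Canonical identity.** One canonical SMILES writer (partition refinement
with exhaustive tie-breaking, i.e. a minimum-certificate canonical graph
ordering) is used everywhere a compound is compared: pathway nodes,
observed-reaction lookup, compound universes, product sets. Aromaticity is
perceived before comparison by a Hückel-style test on rings of size 5–6
(benzene, pyridine, pyrrole/furan/thiophene chemotypes and fusions
thereof); Kekulé and aromatic input of the same molecule yield the same
string. Exotic aromatic systems (7-membered rings, charged rings) are not
perceived and should be written in aromatic form if needed.

## Reaction centers and fingerprints

The reaction center contains: endpoints of every formed, cleaved or
order-changed bond; atoms whose hydrogen count or formal charge changes;
and — when any of those atoms intersects a match of a configured
functional group — the entire matched group. The shipped group list
(`inst/extdata/functional_groups.yaml`, ~22 groups) is configuration, not
algorithm, and fully user-replaceable.

Fingerprints are three part-tagged *descriptor multisets* rather than
hashed bit vectors:

* formation/cleavage part — one descriptor per formed or cleaved bond
  (sorted endpoint element/aromaticity tokens, ring flag, orders);
* bond-change part — descriptors of order-changed bonds;
* center part — radius-1 atom environments *restricted to the
  center-induced subgraph* on each side.

The restriction of center environments to the center subgraph is what
makes, say, primary and secondary alcohol oxidations cluster together
(their centers are the same C–O/C–H chemistry) while aromatic and
aliphatic dehalogenation stay apart (the carbon token differs in its
aromaticity flag). Since clustering only ever uses the threshold
"Tanimoto exactly 1.0", exact string multisets are strictly better than
hashed fingerprints: similarity 1.0 is multiset equality, collision-free
by construction, and the Tanimoto value for any pair is the multiset
Jaccard index over the part-tagged union. The equivalence-at-1.0 makes
the partition well defined and input-order invariant.

## Rule generalization

Per group, the aligned center (plus incoming atoms and the bond edits) is
the backbone; a canonical ordering of the labeled center graph aligns all
members, and a certificate mismatch is treated as an internal error. For a
diameter $d \ge 1$, all atoms within $d$ bonds of the backbone are
included; connected substituent components become *leaves* keyed by their
attachment positions. Atoms at distance exactly $d$ are frontier atoms and
are generalized to element + aromaticity only; interior atoms carry their
full local structure. The most specific state on the ladder uses the
largest member eccentricity + 1, at which no frontier atoms remain and the
rule matches exactly the member substrates.

**Graph combination.** Without combination, a group of $n$ reactions
yields $n$ simple rules. Members are merged greedily (largest identical
groups first, deterministic tie-break by signature) under one guard: a
merge is legal only if every pair of substituent choices at *adjacent*
attachment keys (sharing or bonding backbone positions) co-occurs in at
least one source reaction. Choices at non-adjacent keys combine freely —
which means a rule can inherently trigger on unobserved cross-combinations
of distant substituents; this is exactly the residual over-generalization
the evaluation layer is designed to penalize, and the noisy test corpus
exploits it deliberately. Exact minimization of the number of simple rules
is set-cover-like; the greedy order is checked against a brute-force
partition enumeration for groups of up to six reactions in the tests.

**Explicit hydrogens.** After the diameter saturates, specificity can be
increased further by constraining per-atom hydrogen counts, applied to
changed backbone positions first and then the remaining backbone in
canonical order. The allowed hydrogen counts at each constrained position
are those observed among the simple rule's source reactions, treated
independently per position (co-occurrence of hydrogen counts across
positions is not tracked — a documented simplification; substituent
co-occurrence, where over-generalization actually bites, is tracked).

**Application semantics.** A rule triggers on a compound if the backbone
embeds as an induced subgraph (element, aromaticity, charge and bond
orders exact), every atom losing hydrogens actually carries them, and, for
$d \ge 1$, the compound's leaf configuration at every attachment key is
one of the simple rule's options (no substituent allowed where no member
had one). Products are built by replaying the group's bond edits, hydrogen
and charge deltas through the embedding, splitting components, and
canonicalizing. Trigger sets are monotonically non-increasing along both
the diameter and the explicit-hydrogen axes, which the tests assert over a
200-compound universe.

SMIRKS strings are a *serialization* of this structured object, emitted
with atom maps, `$()` recursive environments for substituent options,
degree constraints for no-substituent positions and `H` alternatives for
hydrogen constraints. Portable SMARTS cannot express multiset-exact leaf
options or substituents bridging two backbone positions, so the textual
form can be slightly more permissive than the structured rule; emitted
rules are verified in the tests to reproduce every source reaction when
re-parsed and applied as text. External SMARTS rule files are supported
through the same text path (`read_rule_file()`, `apply_smirks()`), within
the package's SMARTS subset.

## Genericity and its tuning

Genericity is NS/PS over a compound universe: NS counts compounds where
the rule triggers with no predicted product set matching any observed
reaction of that compound, PS counts those with a match. PS = 0 with
NS > 0 gives `Inf`; a rule that never triggers gives `NaN`. During tuning
both sentinels are treated as "never the closest state": the walk from the
most generic state (diameter 0) to the most specific state keeps the state
whose genericity is closest to the target, ties resolved toward the more
generic state, and falls back to the most generic state if every state is
degenerate. Tuning can never lose coverage — every state's options are
derived from the member substrates themselves — and this invariant is
re-asserted after every tuning and update step.

The default target follows the scan protocol below rather than a fixed
constant; the genericity level grid {0, 1, 5, 10, 20, 50} is the
conventional scan range.

## Learning and evaluation

* **Features**: 166 MACCS structural keys (computed through Open Babel via
  ChemmineOB) concatenated with one trigger bit per rule. The key width is
  a parameter (`key_width`), and key blocks are zero-padded to fixed
  width.
* **Labels**: per rule, positive/negative as above, missing where the rule
  does not trigger; missing labels are excluded from that label's loss.
* **Classifier**: an ensemble of classifier chains (default 10 chains;
  fixture-scale analyses in this package use 5). Each chain permutes the
  labels with its own seeded RNG stream; each label's classifier is an
  L2-regularized logistic regression (ridge penalty λ = 0.01, glmnet)
  seeing the features plus the earlier labels in the chain — ground truth
  while training, predicted probabilities at prediction time. Labels with
  fewer than two observations in either class fall back to a constant
  equal to the empirical positive rate. Given the master seed, training
  and prediction are bit-reproducible.
* **Single-gen**: per threshold in an evenly spaced 101-point grid on
  [0, 1], predicted products of all rules with probability ≥ t are pooled
  per test substrate and compared as canonical product multisets against
  the documented ones. Precision at zero predictions is defined as 1.0 (a
  logged convention avoiding NaN in curve aggregation). AUC is the
  trapezoidal area under the precision–recall curve, anchored at recall 0
  with the precision of the strictest point; FN counts only documented
  products that were not predicted.
* **Multi-gen**: breadth-first prediction from the pathway roots, expanding
  any predicted compound whose rule probability meets the threshold, down
  to the deepest observed generation (an explicit cap that prevents
  unbounded expansion). A node at generation g carries weight
  `gen_weight^(g-1)` (default 0.5, a flag rather than a constant — the
  simplest monotone discount). Two false-positive exemptions, both
  individually switchable: unobserved intermediates whose predicted
  descendants include a correct product, and unobserved co-products formed
  by a reaction application that also formed a correct product. With
  weight 1, depth-1 pathways and both exemptions disabled, multi-gen
  reproduces single-gen exactly (a test).
* **Splits**: train/test splits are by compound, so all reactions of a
  compound stay on one side; repetitions are seeded (`seed + rep`).
* **Genericity scan**: per repetition and level, rules are regenerated
  from the training reactions at that target, a model is trained, and each
  held-out reaction contributes the probability its model assigns to the
  rule(s) that actually reproduce it — zero when no rule does. The level
  with the highest mean probability wins. Overly specific levels lose by
  failing to trigger on held-out substrates; overly generic levels lose
  because their negative samples swamp the classifier.

## What the synthetic corpora show — and what they cannot

All tests run on generated data; the generators are first-class, tested
code. `fixture_corpus()` builds seven eligible reaction families (ester
and amide hydrolysis, benzylic hydroxylation, benzylic alcohol oxidation,
aromatic and aliphatic dechlorination, nitro reduction) plus one singleton
group, each substrate carrying exactly one reactive site, and atom maps
correct by construction. In its noise-free form the corpus is engineered
to be *perfectly learnable*: no substrate triggers a foreign rule at the
tuned specificity, so the full pipeline must reach a precision–recall AUC
of exactly 1.0 — any defect anywhere in the chain breaks that. The noisy
form adds (i) chlorinated esters whose observed reaction belongs to one
family while another family's rule inherently triggers through an
unavoidable non-adjacent substituent cross-combination, and (ii)
negative-sample compounds with no reactions; both strictly degrade the
AUC. The engineered tuning universe forces genericities of exactly 8, 4
and 1 at diameters 0, 1 and 2, and the scan fixture makes genericity 5 the
only level whose triggered positives and negatives are structurally
separable.

These corpora exercise every code path, but they are small, clean and
single-site by design. They say nothing about real-database issues:
mapping errors from external AAM tools, multi-site substrates with
ambiguous embeddings, tautomers and protonation states, reaction
duplicates across pathways, or the actual genericity optimum of a real
rule base — problem sizes here (tens of reactions, ≤ 100-compound
universes, 5–10 repetitions) were chosen as the smallest that make the
properties sharp.

## Numerical and degenerate-input conventions

* Tanimoto of two empty fingerprints is 1.0 (the identity reaction is
  identical to itself); the identity reaction has an empty center.
* Genericity sentinels: `Inf` (PS = 0, NS > 0), `NaN` (never triggers).
* Precision at TP = FP = 0 is 1.0; recall at TP = FN = 0 is 0.
* Cyclic pathway graphs are rejected; node generation is the shortest edge
  distance from a root.
* Product sets are multisets of canonical forms (two waters from a nitro
  reduction both count).
* Greedy merge order, canonical tie-breaking, candidate ordering in the
  mapper, and chain permutations are all deterministic given seeds; every
  randomized function takes an explicit seed.

## Known limitations

* The SMILES/SMARTS dialect is the subset the pipeline needs (organic
  subset + brackets with charge/H/maps; H, D, X primitives, `$()`
  recursion, alternation). No stereo, no isotopes, no `!`-negation.
* Aromatic ring cleavage in products would leave the aromatic flags of the
  residual fragment to re-perception; the bundled families avoid edits
  that break aromatic rings.
* Backbone automorphisms (e.g. the two nitro oxygens) are handled
  correctly at match time by enumerating embeddings, but symmetric
  substituent options may be bookkept conservatively during combination,
  which can only make rules less general, never wrong.
* The internal atom mapper is exact but exponential; it is a convenience
  for fixture-scale molecules, not a replacement for a production AAM
  tool.
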