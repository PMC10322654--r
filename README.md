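# ruleminer

Automatic extraction, generalization and updating of biotransformation
reaction rules, plus the machinery to evaluate how well the resulting
rules predict transformation products.

## The problem

Microbial transformation of organic contaminants produces transformation
products (TPs) that can be as hazardous as their parents, and identifying
TPs analytically is slow. Rule-based prediction systems encode known
enzymatic reaction chemistry as SMIRKS/SMARTS transformation rules and
apply them to a query compound to enumerate plausible TPs. Curating those
rules by hand does not scale as new reactions are reported, and the central
difficulty for automatic extraction is **genericity**: a rule written too
narrowly misses reactions it should cover, while a rule written too broadly
fires on everything and floods predictions with false positives.

`ruleminer` implements an end-to-end pipeline for mining rules from
atom-mapped reactions of the form `substrate >> product1.product2` (single
substrate, one or more products):

1. **Reaction clustering.** Each mapped reaction is reduced to its reaction
   center — the formed, cleaved and order-changed bonds, the atoms with
   hydrogen or charge changes, and any predefined functional group touching
   a changed atom. The center is encoded into a three-part descriptor
   multiset (bond formation/cleavage, bond-order changes, center atom
   environments), and reactions are grouped when the Tanimoto coefficient
   of these fingerprints is exactly 1.0. Only groups with at least two
   reactions proceed to rule generation.
2. **Rule generation.** Per group, the shared center backbone is expanded
   outwards by breadth-first search to an adjustable diameter *d*;
   substituents become leaves attached to backbone positions. Member
   substrate graphs are then combined greedily, but two graphs merge only
   when no substituent co-occurrence is created that was never observed in
   a source reaction — the guard against over-generalization. A group's
   composite rule is the resulting set of one or more simple rules, each
   serializable as SMIRKS.
3. **Genericity tuning.** A rule's genericity is the ratio of negative to
   positive samples over a compound universe,

   `genericity = NS / PS`,

   where a compound is a positive sample (PS) if the rule triggers and a
   predicted product set is observed, and a negative sample (NS) if it
   triggers without an observed match. The generator walks a specificity
   ladder (diameter 0, 1, 2, …, then explicit-hydrogen constraints) and
   keeps the state whose genericity is as close as possible to a target
   value, without ever losing coverage of the group's reactions.
4. **Incremental updates.** A persisted rule set stores all group
   fingerprints (singletons included). New reactions join the matching
   group at Tanimoto 1.0 or found new groups; only touched groups have
   their rules regenerated.
5. **Evaluation.** Pathway prediction is cast as multi-label
   classification: each composite rule is a label, compounds are featurized
   as MACCS structural keys plus rule-trigger bits, and an ensemble of
   classifier chains (ECC) assigns each rule a trigger probability.
   Reaction-level ("single-gen") evaluation sweeps a probability threshold
   and reports precision = TP/(TP+FP) and recall = TP/(TP+FN) over
   predicted vs. documented products, with the area under the
   precision-recall curve (AUC) as summary. Pathway-level ("multi-gen")
   evaluation predicts breadth-first from the root compound, discounts
   generation *g* by `w^(g-1)`, and does not punish unobserved
   intermediates that lead to correct downstream products, nor unobserved
   co-products of correct products. A genericity scan trains models at
   target levels {0, 1, 5, 10, 20, 50} and selects the level whose model
   assigns the highest mean probability to held-out observed reactions.

Everything is testable offline: the package ships a synthetic-data module
(`fixture_corpus()`, `make_reaction_family()`, `fixture_pathways()`, …)
that builds mapped reaction families and degradation cascades by graph
surgery, so no external database or atom-mapping tool is required.
Pre-mapped reaction SMILES are the first-class input; an internal
minimal-edit atom mapper (`map_atoms()`) handles small unmapped molecules.

## Worked example

```r
library(ruleminer)

rxns <- c(
  make_reaction_family("ester_hydrolysis",
    list(c("C", ""), c("CC", ""), c("CCC", "")), 3, seed = 1, prefix = "est"),
  make_reaction_family("nitro_reduction",
    list("c1ccccc1", "c1ccc(F)cc1"), 2, seed = 1, prefix = "nit"))

groups <- cluster_reactions(rxns)
#> <reaction groups> 5 reactions in 2 groups (2 eligible)

universe <- c(vapply(rxns, function(r) mol_signature(r$substrate), character(1)),
              "CCOC(C)=O", "COC(=O)c1ccccc1", "CC(C)C(=O)OC")
rs <- generate_ruleset(groups, target = 1, universe, rxns)
#> <rule set> 2 composite rules over 2 groups (5 reactions), target genericity 1

rs$rules[[1]]
#> <composite rule g001> 1 simple rule(s), diameter 0, explicit-H 0, genericity 1
attr(rs$rules[[1]], "trace")
#>   d h ps ns genericity
#> 1 0 0  3  3  1.0000000
#> 2 1 0  3  1  0.3333333
#> 3 2 0  3  0  0.0000000
#> ...
```

The trace shows the specificity ladder: at diameter 0 the bare ester
center fires on all six esters in the universe (3 observed, 3 negative,
genericity 1.0 — exactly the target, so that state is kept); widening the
diameter would push genericity to 0. The rule serializes as SMIRKS and
applies to unseen substrates:

```r
emit_smirks(rs$rules[[1]], groups)
#> [1] "[C:1](=[O:3])-[O:4]-[C:2]>>[C:1](=[O:3])-[O:5].[C:2]-[O:4]"
apply_rule(rs$rules[[1]], "CCCCC(=O)OC")
#> [[1]]
#> [1] "C(CCCC)(=O)O" "CO"
coverage(rs, rxns)
#> $covered: "est_01" "est_02" "est_03" "nit_01" "nit_02"
```

Methyl pentanoate is hydrolyzed to pentanoic acid and methanol, and every
source reaction is reproduced by its group's rule — an invariant the
package enforces after generation, tuning and every update.

The same workflow is scriptable from a shell through the installed
`exec/ruleminer` dispatcher (`cluster`, `generate`, `add`, `apply`,
`coverage`, `eval`, `scan-genericity`, `export`).

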