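---
title: "Methods: from gene cluster to ranked metabolite scaffolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from gene cluster to ranked metabolite scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette explains the models and procedures implemented in
`bgcscaffold`, the assumptions behind them, the tunable parameters and the
design choices made where the method left room for choice. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. Domain detection

Biosynthetic domains are detected with profile hidden Markov models, one
per domain family, built with `hmmbuild` from a MAFFT alignment of the
labelled training sequences and scanned with `hmmsearch`. Detection is
thresholded on the **per-domain bit score** (HMMER's domT semantics), not
on e-values: bit scores are independent of database size, which makes a
fixed calibrated threshold transferable across inputs.

**Threshold calibration.** The threshold of a profile is the minimum bit
score the profile attains on its own true-label sequences. This guarantees
recall 1 on the calibration set (tested by rescanning) and is the most
permissive threshold with that property; sequences the profile misses
entirely are excluded from the minimum with a warning. A packaged table of
thresholds for the 20 core domains ships as
`extdata/domain_thresholds.tsv`; the KSQ profile, which marks
decarboxylating PKS loading modules and is usually imported rather than
trained, reuses the KS threshold by convention (`add_ksq_profile()`).

**Overlap resolution.** The method does not specify how overlapping
above-threshold hits from different profiles are resolved. We keep the
higher-scoring hit whenever two hits on one protein overlap by more than
50% of the shorter hit, breaking ties alphabetically by domain label. This
is a package choice; it exists because module parsing needs a linear,
non-overlapping domain string.

**Carrier equivalence.** ACP, PCP and bACP all tether the growing chain;
profile confusion between ACP and bACP is known and harmless downstream,
so all three labels fill the same carrier role during module parsing while
keeping their original names.

**Cross-validation.** `crossvalidate_profiles()` rebuilds profiles per
stratified fold and assigns each held-out sequence the label of the
best-scoring profile (no thresholds, so that confusability is measured
rather than hidden). Metrics come from the pooled confusion matrix and are
property-tested against an independent tally.

## 2. Module architecture

A module is the domain set that incorporates and co-modifies one building
block. Since observed arrangements virtually always end in a carrier
domain optionally followed by epimerization or release domains, the
segmentation rule is: **cut after the carrier plus any trailing E/TE/TD**.
Trailing domains without a carrier form a dangling module; when a dangling
module at a gene end can merge with the first module of the next adjacent
same-strand gene into an arrangement that classifies as *normal*, the two
are merged (split modules across genes are common in real clusters; the
merge criterion "results in a normal module" is our operationalization of
"matches a known pattern"). Minus-strand gene runs are traversed in
translation order.

Classification is two-layered: the packaged pattern table
(`extdata/module_patterns.tsv`, the 20 most common arrangements) has
first-match priority, and everything else falls through to generic rules
(normal needs a substrate domain plus carrier and a derivable modification
profile; trans-AT and incomplete/unusual-reduction arrangements are
special; modules without any substrate-like domain are non-functional).
The table-first design matters because a few printed classifications (for
example the trans-AT arrangement KS-tAT_d-ACP with an Alkyl state, where
reduction happens in trans) cannot be derived from the module's own
domains.

Reduction states: {} → ketone, {KR} → hydroxyl, {DH,KR} → enoyl,
{DH,ER,KR} → alkyl; DH and/or ER without KR cannot act (reduction starts
at the ketone) and yields the flagged `ketone_star` state, which builds a
ketone block. {KR,ER} without DH is treated as hydroxyl (the ER cannot act
without the dehydration step). The dehydratase variants DH2/DHt count as
DH. Methyltransferase placement: cMT inside/before the reductive domains
or between AT and the carrier is cis α-methylation; cMT *after* the
reductive domains marks the trans-AT arrangement and, when no cis AT is
present, flags the module as trans-AT; oMT methylates only the plain
KR-derived hydroxyl (β-methoxy); nMT between A and the carrier methylates
the peptide nitrogen; a cMT in a pure NRPS module assigns nothing (too
case-specific for a general rule).

## 3. Module order

Blocks are maximal runs of genomically adjacent same-strand modules, split
after internal terminal modules. Order inference scores every ordered
block pair: the concatenated domain string is aligned locally
(Smith–Waterman with affine gaps; match +1, mismatch −1, gap open −2, gap
extend −1, a gap of length L costing open + L·extend) against every entry
of a reference database of single-block clusters, and the pair takes the
maximum. Pairs that would bury a loading block or a terminal block
mid-chain are excluded, and two terminal blocks never merge. The
best-scoring admissible pair is merged and the matrix recomputed
(greedy-iterative; the method only states that best pairs are combined).
Ties prefer the pair preserving genomic order, then lower block indices,
for determinism. Carrier-label equivalence is *not* applied here because
reference strings keep their original labels.

The implementation is a plain Gotoh dynamic program over the domain-label
alphabet; tests verify it against `Biostrings::pairwiseAlignment` on a
mapped single-character alphabet, and a parameter-recovery test plants a
shuffled k-block cluster (k ≤ 4) whose true concatenation is the only
reference entry.

## 4. Substrate specificity

AT- and A-domain substrates are predicted by random forests over one-hot
encoded alignment columns. The gap symbol is a first-class category: every
row then has exactly L set bits, the encoding is invertible, and gap
presence is informative. At predict time a new sequence is aligned into
the stored training alignment with `mafft --add --keeplength`, so columns
inserted by the new sequence are dropped and the feature space is
unchanged; symbols unseen in training leave their column block all zero.

Shipped defaults are the best grid-search configurations (A-domains:
depth 100, 1000 trees, min samples split 10, no bootstrap, gini, min
samples leaf 1; AT-domains: depth 50, 100 trees, split 1, leaf 2). The
grid (4 depths × 5 feature settings × 3 forest sizes × 3 split minima × 2
bootstrap settings × 2 criteria × 3 leaf minima = 2160 configurations) is
enumerated exactly; configurations are compared by mean micro-F1 over
stratified, seeded 10-fold cross-validation, ties keeping grid order. No
class weighting is applied, matching the reported micro/macro gap
behaviour.

The forests are trained with `ranger`. Two sklearn-style parameters have
no exact ranger equivalent: `min_samples_split` maps to `min.node.size`
(same "minimal node size to split" semantics) and `min_samples_leaf` is
honoured through `min.node.size = max(split, 2·leaf)`; the `entropy`
criterion is accepted in the grid but trained as gini (ranger implements
gini for classification). Training rows are sorted by id internally, so
prediction is invariant to training-row order for a fixed seed.

## 5. Scaffold assembly

Every chain extension contributes an α-carbon (substrate substituent,
possible α-methyls) and a carbonyl carbon; NRP blocks additionally
contribute the peptide nitrogen (their β-position). Because the carbonyl
installed by block i becomes the β-carbon of block i+1, the statement
"reductive domains act on the previous building block" becomes an index
shift: module i+1's reduction state is written onto block i's carbonyl.
The terminal block's carbonyl is set by the release chemistry (TE →
carboxyl, TD → hydroxyl; without either the chain ends as the bare
carbonyl). Loading blocks have no upstream carbonyl to modify — that is
the sense in which they "lack the β atom".

Assembly emits SMILES left to right (loading → terminal): amide bonds form
automatically where the next block starts with nitrogen, C–C bonds where
it starts with the α-carbon, and an enoyl state writes the double bond
between the carbonyl and the following α-carbon. The result is
canonicalized with OpenBabel, making assembly deterministic and
round-trip-stable.

Chemistry choices: L = (S) via `[C@@H]` in the backbone context, D by
descriptor flip; proline/pipecolate use full ring templates;
doubly-α-methylated blocks (methylmalonyl + cMT) cannot take enoyl/alkyl
states and fall back to hydroxyl when a KR is present; trans-AT and other
special modules without a substrate prediction insert the generic
malonyl-like block (the most common trans-AT substrate); `ketone_star`
modules emit a ketone block. TE release is always the linear carboxyl
form — macrolactonization and other ring-forming release chemistry is out
of scope, as are β-branching and glycoside attachment regiochemistry.

## 6. PSM prediction

The seven postsynthetic-modification patterns (glycoside, halogen,
spiroketal, disulfide, nitro, 6-ring, 5-ring) ship as SMARTS in
`extdata/psm_patterns.tsv` and are counted with OpenBabel's matcher using
unique (symmetry-deduplicated) matches, verified against a naive
subgraph-matching oracle for the plain patterns. Per-PSM predictors are
**ordinary linear least squares** on curated domain-count features,
evaluated by pooled out-of-fold R² over 5 folds against the
zero-prediction baseline R² = 1 − Σy²/Σ(y−ȳ)² (≤ 0 for nonnegative
targets with any positive value); a model is retained only when it beats
the baseline. Linear least squares is chosen over a logistic (classification)
model because the target is a count and the evaluation metric is R² — a
regression criterion. Predictions are rounded to the nearest integer and
clipped at zero. Only the number of glycosides is predicted,
never the sugar identity.

## 7. Screening

Libraries are deduplicated by canonical SMILES. Fingerprints are circular
Morgan-style, radius 3, 2048 bits, computed by iterative neighbourhood
hashing on the heavy-atom graph (initial invariant: element, degree,
summed bond orders); no installed R package provides Morgan fingerprints,
so the hashing is implemented here and tested for canonical-form
invariance and determinism.

The multi-fragment MCS score sorts query fragments by heavy-atom count,
enumerates up to 20 maximum common connected substructures of the current
fragment in the remaining target (atoms matched by element, bonds by
order, induced-subgraph semantics), deletes each match and recurses with
the next fragment; the best branch wins. The final score is the mean of
the query-side and target-side fractions of matched atoms + bonds (the
query-only normalization is a config switch). Tests verify equivalence
with an independent maximum-clique (modular product) oracle on small
molecules.

The Bray–Curtis **similarity** of PSM vectors is 1 − Σ|uᵢ−vᵢ|/Σ(uᵢ+vᵢ):
identical vectors score 1; two all-zero vectors are defined as identical.
The mixed score is the weighted sum a·similarity + b·MCS + c·PSM with
per-cluster-type defaults (`extdata/screening_weights.tsv`; all-type
default 0.3/0.4/0.1). The weight grid search varies each weight over
0–1 in steps of 0.1 (step size configurable) and selects the
lexicographically smallest configuration maximizing the Top-10 fraction.
Ranks are 1-based with ties sharing the best rank.

## 8. The fixture generator

`generate_fixtures()` defines the study conditions for every test: four
planted domain motif families (C 70, A 80, PCP 60, TE 70 residues; 16
training sequences per family at 10% point-mutation rate), three
A-domain substrate classes separated by six fixed code positions (12
sequences per class at 6% mutation outside the code), a toy annotated
genome with the three-module cluster A-PCP | C-A-PCP | C-A-PCP-TE
(substrates Gly/Ala/Val, genes 200 bp apart, one domain-free background
gene 60 kb away), a 25-compound library holding the true Gly-Ala-Val
product plus tripeptide and assorted decoys, and a 200-row domain-count/
PSM table with planted slope β = 2 and Gaussian noise (σ = 0.5). Genome
instances mutate at 2% — deliberately inside the training spread, since
the calibrated thresholds are the *minimum* training self-scores and
fresh instances must clear them. Everything derives from the single seed;
the same seed yields a byte-identical bundle.

What the fixtures do **not** emulate: real domain families are far more
diverse than point-mutated motifs, real A-domain specificity is not
encoded in six clean columns, real clusters carry tailoring genes,
split/nested clusters and trans-AT systems, and real libraries are 10²–10⁵
times larger. Passing the fixture tests therefore demonstrates that the
machinery is correct and internally consistent, not that field
performance on real genomes matches the toy numbers.

## 9. Problem sizes and numerical notes

Test and acceptance runs use the sizes above (16-sequence families,
36-row substrate sets, 25-compound library, 200-row regression table,
2–4 block order fixtures, MCS molecules ≤ ~20 atoms) — small enough for a
single CPU while still exercising every code path. The MCS search carries
a node budget (2·10⁵ states per pair) as a safety valve; at fixture scale
it is never reached. Bit-score comparisons use a 10⁻⁹ tolerance where
floating-point text round-trips are involved; fingerprint hashing is
integer-exact (double arithmetic below 2⁵³). Full-scale benchmark figures
(corpus-wide mean Tanimoto and Top-10 rates, and the reference AT/A
classifier scores) require the original training corpora and screening
libraries and are reproducible only through the provided harnesses once
those datasets are supplied; `reproduce_substrate_benchmark()` implements
the complete classifier protocol against user-supplied labelled FASTA
files.

## 10. Known limitations

- Gene calling is delegated to prodigal; GenBank input must carry
  `/translation` qualifiers (the GenBank reader supports the minimal
  LOCUS/CDS/ORIGIN subset).
- Aromatic systems are kekulized by OpenBabel before graph extraction, so
  MCS bond-order matching can distinguish resonance forms of the same
  aromatic ring.
- Docking-domain-based ordering is not implemented; order inference relies
  entirely on the reference-database alignment.
- The 212-arrangement full pattern catalogue is not shipped; the packaged
  table covers the 20 most common arrangements and the generic rules
  handle the rest.
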