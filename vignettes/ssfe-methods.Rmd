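---
title: "Methods: mining an enzyme family with ssfe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining an enzyme family with ssfe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ssfe` turns a reference enzyme with an annotated active pocket plus a pool
of candidate homolog sequences into: a phylogeny, per-homolog pocket
fingerprints in reference numbering, activity predictions, pocket-type
clusters, a diversity-maximizing representative panel, and pocket-transplant
mutation proposals. This vignette explains the models and the choices behind
each stage, what the synthetic-family generator does and does not emulate,
and the package's known limitations.

## The reference profile

Everything is anchored to a *reference annotation*: catalytic positions with
their expected residues, an ordered list of pocket positions with functional
roles (A-ring, B-ring, catalytic), and domain spans, all in 1-based
reference numbering. The bundled profile describes a bacterial chalcone
isomerase pocket of 21 residues with the His33 catalytic base and Tyr48
carbonyl stabilization. Position 47 is flagged *provisional*: it is
implicated through mutagenesis (D47E improves meta-hydroxylated substrates
together with K87R) rather than through the ligand-contact set, and users
can drop or replace it via the YAML config.

Two bundled-profile choices deserve a note:

* The bundled reference **sequence** is a synthetic stand-in (210 residues)
  that carries the annotated residues at the annotated positions — the true
  reference sequence is database-derived and is not redistributed. All
  identity-level checks (e.g. the HYETQ sub-fingerprint over positions
  33/48/69/71/101) depend only on the annotation, not on the filler
  residues.
* The domain layout places all pocket positions inside the catalytic domain
  (1–140) and leaves the solvent-exposed domain (141–210) free of pocket
  positions. That mirrors the biology being emulated — substrate binding in
  the catalytic domain, loop insertions characterizing the solvent-exposed
  domain — and it also keeps insertion-driven alignment ambiguity (see
  *Limitations*) away from the positions the fingerprints depend on.

## Alignment

Pairwise alignment is global Needleman-Wunsch-Gotoh with affine gaps: a gap
of length $L$ costs $g_o + (L-1)\,g_e$, terminal gaps are charged in full,
and the defaults are BLOSUM62 with $g_o = 11$, $g_e = 1$ — the
community-standard protein defaults; no attempt is made to reconstruct any
particular study's alignment parameters. The bundled BLOSUM62 covers the 20
standard residues plus `X`, scored $-1$ against everything (so unknown
residues neither reward nor dominate alignment decisions, and the diagonal
dominance property $s(a,a)+s(b,b) \ge 2\,s(a,b)$ holds for the whole
alphabet).

The multiple alignment is classic progressive alignment: indel-aware
pairwise distances (fraction of non-identical alignment columns) feed a
neighbor-joining guide tree, which is midpoint-rooted; profiles are merged
from the leaves to the root with the same gap model. Column scores between
profiles are average-of-pairs substitution scores, with one adjustment:
a residue paired against a gap character already present in the other
profile costs $g_e$ per pair. Without this term, residues can drift into
gap-dominated columns for free, which fragments long insertions across the
alignment and breaks both position mapping and insertion-length statistics.
Indel-aware guide distances matter for the same reason: under a plain
p-distance (which ignores indel columns) insertion-bearing members join the
guide tree early and freeze misalignments into the profiles.

Determinism is part of the contract: traceback ties resolve diagonal > up >
left, guide-tree children merge in canonical order (lexicographically
smallest descendant label), so the same inputs always give the same
alignment byte for byte.

## Phylogeny

Distances between aligned rows are mismatch fractions over columns where
both rows carry residues, optionally Poisson-corrected
($d = -\ln(1-p)$); a saturated pair ($p = 1$) is an error rather than an
arbitrary large number. Trees are built by standard neighbor joining. This
is a deliberate substitution for likelihood methods: downstream stages
consume only clade structure, which NJ recovers exactly on additive
distances (a property the tests verify on random trees), and NJ is
deterministic and fast at desk scale. Three numerical choices:

* Q-matrix ties break on the lexicographically smallest label pair (an
  agglomerated node carries its smallest descendant leaf label).
* Negative NJ branch lengths are clamped to zero with the deficit moved to
  the sibling, preserving the pair's total; depth-based clade cutting
  requires non-negative lengths.
* Midpoint rooting ties break on the smallest leaf pair, and an all-zero
  tree roots next to the smallest leaf, so rooting is total and
  deterministic.

Bootstrap supports resample alignment columns with replacement, rebuild the
NJ tree per replicate, and annotate each internal edge with the percentage
of replicates containing the same leaf bipartition; 100 replicates by
default, fully determined by the seed.

Clades are extracted by cutting all edges that cross a fixed fraction
(default 0.5) of the maximum root-to-leaf depth. The family's true
sub-branch structure has no published numeric criterion, so the fraction is
exposed as a parameter rather than hard-coded; on near-star families (see
*Limitations*) small fractions group and large fractions shatter, and the
default is a neutral middle.

## Pocket fingerprints and disruption

A homolog's fingerprint is read directly off the alignment: for each
annotated pocket position, the residue in the homolog row of that column,
or `-` if the homolog has a gap there. Fingerprint distance is
$\sum_\text{slots} [s(a,a)+s(b,b)]/2 - s(a,b)$, a symmetric premetric that
is zero exactly on identical symbols; a residue-versus-gap slot costs a
flat penalty (default 8, about the cost of losing a well-conserved match),
and a both-gap slot costs nothing — absence of evidence should not count as
divergence twice.

Disruption screening measures, per domain span: the longest run of homolog
residues inserted between consecutive mapped reference positions, and the
number of unaligned (deleted) reference positions. A member is disrupted
when any span exceeds `max_insert` (default 10 residues — comfortably above
alignment jitter, clearly below a restructured loop) or `max_unaligned`
(default 25% of the span). When a structure with a bound ligand is
available, the pocket can be defined geometrically instead: residues with a
heavy atom within 4.5 Å (inclusive) of any ligand heavy atom — a standard
contact cutoff; the count the annotation is based on is published but its
criterion is not, so the cutoff is a documented default, not a
reconstruction.

## Activity, pocket types, substrates

Activity prediction is categorical by design: `likely_active` iff every
catalytic position carries its expected residue and no domain is disrupted.
The underlying inference — catalytic-base conservation as the indication of
activity, domain restructuring as its veto — is rule-like in the source
biology, and a probabilistic dressing would suggest precision the evidence
does not carry.

Pocket types are single-linkage clusters under fingerprint distance.
Single linkage (connectivity) is chosen over compactness criteria because
family branches are connectivity-defined; the threshold (default 0:
exact-identity grouping) is exposed. Cluster representatives minimize the
summed within-cluster distance.

Substrate verdicts come from an editable YAML rule table; each substrate
carries alternative condition groups with weights and a threshold, plus
disallowed symbols. The bundled table encodes three B-ring pocket hints:
small residues (P/I) at 79 — or the E79+G125 combination — open the pocket
to para-methoxylated chalcones while D79 sterically excludes them, and
K/R87 with D/E47 supports hydroxylated B-rings. The weights and thresholds
are engineering choices (the source biology is qualitative), which is why
they live in config rather than code.

## Representative selection and transplants

The panel is greedy maximin: seed with the member whose fingerprint is
closest to the reference, then repeatedly add the member maximizing its
minimum distance to the panel, never taking a second member from a
pocket-type cluster until all clusters are covered; distance ties prefer
unrepresented clades, then the smallest id. Maximin is a stated substitute
for expert judgment — the original panel of representative pockets was
picked by hand, and no selection algorithm is published. The default panel
size is the number of pocket-type clusters. Only `likely_active` members
with gap-free fingerprints are eligible: a transplant proposed from an
unresolved pocket would be unverifiable.

Transplant proposals are position-wise: one substitution per slot where
scaffold and target differ, named in reference numbering (`D79P`) even when
the scaffold is not the reference, matching the field's convention of
numbering mutants in reference coordinates. Slots where the target is `-`
are skipped and reported as unresolvable; applying a proposal back onto the
scaffold reproduces the target on all resolvable slots, and the proposal
size equals the restricted Hamming distance — both are tested properties.

## The synthetic-family generator

`simulate_family()` emulates exactly the structure the pipeline presumes: a
reference; clades that are star-shaped around clade-specific pocket
variants (clade 1 keeps the reference pocket; later clades receive fixed
substitutions at non-catalytic pocket positions echoing naturally observed
pocket types: P79; E79+G125; R87+E47; then further B-ring swaps); i.i.d.
background substitutions at non-pocket sites (default rate 0.02 per site —
high enough that members are distinguishable, low enough that a family of
~95% identity remains trivially alignable, as real within-branch CHI
neighborhoods are); and an out-group whose members carry a contiguous
random insertion (default 15 residues) at a random site inside the
solvent-exposed domain, mimicking domain restructuring by flexible loops.
Background noise never touches pocket or catalytic positions unless
`noise_at_pocket` is set, separating partition-recovery tests from
robustness tests; with the option set, catalytic positions are still
spared so activity ground truth stays well-defined. Insertions only (no
deletions) are generated by default, because extra residues forming loops
are the phenomenon being modelled.

What the generator does *not* emulate: substitution-model realism (WAG/LG
rate matrices), within-clade tree structure (members are conditionally
i.i.d. around the clade centroid), indel length distributions, and
correlated evolution of pocket positions. Passing planted-truth tests
therefore shows the machinery is correct on families with clean clade
structure and high identity; it does not certify performance on deep,
twilight-zone homology, where alignment quality — not the downstream
logic — is the binding constraint.

## Problem sizes and reproducibility

The standard synthetic family used by the tests and the acceptance script
is 4 clades x 15 members + 5 out-group members + the reference (66
sequences of ~210 residues), which exercises every stage in tens of
seconds; property tests use 50 random peptide pairs (alignment oracle), 100
random 5–8-leaf trees (NJ additivity), and 200 random fingerprint pairs
(transplant round trip). Every stochastic component (bootstrap, generator,
property tests) is seed-parameterized, and `run_ssfe` with identical config
and seed produces byte-identical artifacts, bootstrap supports included —
newick output is canonicalized (children ordered by smallest descendant
label, branch lengths at 6 decimals) precisely so that regression tests can
compare bytes.

## Limitations

* **Progressive alignment near insertions.** When two members carry long
  insertions at nearby sites, their pairwise optimal alignment can absorb
  one insertion into the other ("zero-gap" alignments), shifting a few
  backbone residues; progressive merging then freezes the shift. Iterative
  refinement, which would repair this, is deliberately out of scope. The
  package mitigates (indel-aware guide distances; the residue-versus-gap
  column penalty) and the bundled profile keeps pocket positions away from
  the insertion-bearing domain, but fingerprints of heavily
  insertion-bearing members near their insertion sites should be treated
  with care.
* **Near-star trees.** High-identity families put most branch length on
  terminal edges, so depth-fraction clade cutting at the default 0.5 can
  yield many singleton clades; clade extraction is most informative when
  between-clade divergence clearly exceeds within-clade divergence.
* **Rule tables are hypotheses.** Substrate verdicts rank candidates for
  screening; they are not activity predictions in units, and stereochemical
  outcomes are entirely out of scope.
* **The structure path is minimal.** The PDB reader is fixed-column,
  first-model, first-altloc, and element inference from atom names
  misclassifies exotic heteroatoms; it is sufficient for ligand-contact
  pocket definition, not a general structure parser.
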