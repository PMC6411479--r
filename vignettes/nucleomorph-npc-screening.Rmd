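---
title: "Screening nucleomorph-containing algae for nuclear pore proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening nucleomorph-containing algae for nuclear pore proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egtscreen)
```

## The question and the inference chain

Nucleomorphs are the relict nuclei of algal endosymbionts retained inside
chlorarachniophyte and cryptophycean cells. Whether such a reduced nucleus
still builds its own nuclear pore complex (NPC) cannot be read off a genome
directly: nucleoporins are too divergent for plain BLAST, endosymbiotic gene
transfer (EGT) moves endosymbiont genes into the host nucleus, and
transcriptome-derived proteomes are riddled with truncated models and
paralogs. `egtscreen` implements the full inference chain that turns this
into a decidable question:

1. **Profile-HMM screening.** A profile hidden Markov model is built from a
   curated reference alignment of each nucleoporin family and used to scan
   query proteomes; hits are kept at an E-value of at most `1e-5`, and at
   most the best 200 per family.
2. **Paralog purging.** Hits are folded back into the reference alignment,
   a bootstrap-supported distance tree is built, and clades that confidently
   group with a different family are removed; the clean–realign–rebuild
   cycle repeats up to three times.
3. **Provenance classification.** On the final midpoint-rooted tree, each
   accepted query protein is labelled `host_related` or `algal_related`
   according to the role composition of its sister clade, and only when
   the supporting bootstrap value is strictly greater than 70.
4. **Targeting evidence.** Signal-peptide heuristics, N-terminus
   completeness, and FG-repeat density say whether a protein *could* be
   trafficked to the nucleomorph.
5. **Inventory.** Everything is summarised as a family-by-taxon matrix of
   copy counts, affinities, and targeting flags, with a per-taxon
   completeness proxy, corroborated absences, and a subcomplex summary.

A synthetic-data generator produces ground-truth scenarios with exactly the
statistical structure this chain assumes, so every stage is testable at
desk scale.

## The profile HMM

Each reference alignment column whose gap fraction is below 0.5 becomes a
match state (the common heuristic; the threshold is an argument). Match
emissions are observed residue counts plus a background-proportional
pseudocount of total weight 1, normalised; the background is the
Robinson–Robinson frequency vector, which also serves as the insert
emission and the decoy-generation distribution. Transitions are counted
from the gap structure of the alignment rows and Laplace-smoothed (+1 on
every allowed move). The state graph is the full Durbin-style profile
topology — match, insert, and delete states with all
{M,I,D} → {next-M, own-I, next-D} moves, including I→D and D→I, which real
gap structures do produce.

Scoring is in bits against the background. `glocal` mode forces a
begin-to-end traversal. `local` mode — the search default, because
transcriptome fragments are routinely truncated — is *uni-local*: the path
may enter any match state (uniform entry probability `1/M`), exit any match
state freely, and flanking residues are scored at background odds. Residue
`X` emits at background in both match and insert states (log-odds 0).
Viterbi and forward are exact dynamic programs; on every instance small
enough to enumerate (`M <= 4`, sequence length `<= 5`) both agree with
brute-force path enumeration to 1e-9 in log space, and on an insert-free
model the glocal forward probabilities of the complete sequence space sum
to 1 to the same tolerance. When no legal path exists the score is the
`-Inf` sentinel rather than an error.

E-values come from self-calibration rather than an external tool: 200
i.i.d. background decoys (length of the median search target) are scored
with local Viterbi and a Gumbel distribution is fitted to the decoy bits by
maximum likelihood; `evalue()` is the database size times the fitted upper
tail. Local Viterbi is the score that extreme-value theory actually covers,
which is why calibration is not done on forward scores. A factor-of-two
tail accuracy is ample against a `1e-5` threshold; on fresh decoys the
number with E at or below 100 out of 1000 sits inside the central 99%
binomial interval when the fit uses 1000 decoys (the default 200 is
noticeably noisier, which only matters for calibration diagnostics, not for
screening).

## Search, triage, and family assignment

Every (profile, protein) pair is scored; retention requires E ≤ `1e-5`,
then the best 200 hits per family are kept *pooled across taxa* (a
per-taxon cap is available — the original procedure is ambiguous on this
point, and on clean data the cap never binds either way). Ties break by
bit score, then id. Each hit protein is also assigned its best family: the
profile with the highest *forward* bit score, with the margin to the
runner-up recorded. This assignment replaces database-annotation lookups;
a margin of at least 2 bits is treated as confident downstream. The
pipeline's batch assigner shortlists profiles by Viterbi score before
forward-scoring the top two; `assign_family()` itself always scores every
profile.

## Trees

Maximum-likelihood inference is deliberately out of scope; the
classification consumes only a topology with supports, and externally
computed Newick trees can be dropped in per family (`external_trees`).
Internally: pairwise distances use pairwise deletion (gaps and `X`
dropped per pair) and a Kimura-style protein correction
`d = -ln(1 - p - p^2/5)` by default; a pair at `p >= 0.85` is saturated and
set to the ceiling distance 10 with a warning, and a pair with zero
comparable columns is an error naming the pair. Neighbor joining is the
classic Q-criterion algorithm; negative branch lengths are clamped to zero
with the deficit moved onto a sibling edge so inter-subtree path lengths
through the parent are preserved. Supports are nonparametric bootstrap
percentages over column resamples (default 100 replicates — scaled down
from the 1000 ultrafast replicates that a likelihood tool would use, and
configurable back up); each internal edge of the point tree gets the
percentage of replicates containing its bipartition. Midpoint rooting
places the root halfway along the longest leaf-to-leaf path and re-attaches
support labels to the same bipartitions; on random trees the two farthest
leaves are equidistant from the root to 1e-9. `flag_long_branches()` flags
leaves whose pendant edge exceeds 5 times the median — an explicit,
optional stand-in for the by-eye removal of long-branching reference taxa,
whose original criterion is not recorded.

## Paralog purging and provenance calls

Per cycle, the augmented alignment (reference rows plus surviving hits)
becomes a midpoint-rooted bootstrap tree. An internal clade qualifies for
removal when its support is strictly greater than 70 **and** more than half
of its annotated query leaves are assigned to a different family; maximal
qualifying clades have all their query leaves removed. Requiring support
means a paralog call is made only on confident structure, never on noise.
Survivors are re-inserted through `align_to_profile()` and the cycle
repeats until nothing is removed or the hard cap of three cycles is
reached; the report records per-cycle removals and whether the run
converged.

Acceptance of survivors is a disjunction: a query leaf is kept if the
sister context of its query-only clade contains at least one reference
leaf (in a single-family tree every reference row qualifies), *or* its
best-profile assignment matches the family with a margin of at least
2 bits. Classification then collapses each maximal clade of query leaves
into a unit and reads the role composition of the reference leaves on the
other side of the joining node: `host_related` if at least 80% of them are
host-outgroup taxa, `algal_related` if at least 80% are
endosymbiont-algal, otherwise `ambiguous`. The purity tolerance exists so a
single stray reference leaf does not void an otherwise clean call; it is an
argument. The decision support is the bootstrap value of the clade that
joins the unit to its sister — that clade is precisely the hypothesis
"these query proteins branch with these references". When the joining node
is the tree root, that clade is trivial and the support of the equivalent
unit-versus-rest bipartition is used instead. A host/algal label is demoted
to `ambiguous` whenever the decision support is 70 or less — strictly
greater than 70 is required, never "at least".

## Targeting evidence

The signal-peptide call is a documented heuristic, *not* a reimplementation
of a neural-network predictor, and external predictor output can be
imported per protein (`import_sp_predictions()`, last row wins on
duplicates). Over the first 40 residues, a positive call needs (a) a
non-negative net charge across residues 2–6 (K/R = +1, D/E = −1), (b) an
8-residue window inside positions 4–21 with mean Kyte–Doolittle hydropathy
of at least 1.6, and (c) a cleavage motif: a first mature residue at
1-based position 15–34 whose −1 and −3 positions hold a small residue
(A, G, S, C, T). The score is the best window hydropathy and the cleavage
position is the smallest qualifying one. Sequences shorter than 25
residues are inconclusive (`NA`), and — because predictors misfire on
incomplete N-terminal ends — the pipeline refuses an SP verdict outright on
any record whose N-terminus is not complete.

N-terminus completeness itself takes upstream ORF-caller metadata when
present; otherwise a record is complete when it starts with methionine and
its first residue sits no more than 15 alignment columns past the modal
reference start column. The 15-column tolerance is intentionally below the
smallest truncation the generator produces (10% of a 200-residue protein),
so the two bases of evidence agree by construction.

FG-repeat scanning counts overlapping `FG` dimers in the densest window of
at most 200 residues; the flag needs at least 5 dimers and a density of at
least 1.5 per 100 residues. Those thresholds separate FG-nucleoporin
density from background composition (a shuffled FG-rich sequence flags in
fewer than 5% of 1000 shuffles); `FXFG` and `GLFG` counts are reported
separately.

## Inventory

The matrix has exactly one cell per (registry family, query taxon); each
retained protein contributes a copy carrying its affinity label and
targeting flags. Ordering is deterministic (registry order, then taxon
name), so re-running a pipeline writes byte-identical tables. The per-taxon
completeness proxy replaces an external universal-single-copy-ortholog
scan: it is the fraction of control families (by default, families whose
reference alignment covers at least 80% of the reference taxa) with at
least one retained hit in that taxon; precomputed values can be supplied
instead. An absence is *corroborated* when at least 3 same-role taxa, each
with completeness of at least 0.5, all lack the family — the number 3 is a
choice, the source procedure only says "multiple taxa". The subcomplex
summary reports two groups: the host lineage (all retained copies) and the
pseudo-nucleomorph group (algal-related copies only), a subcomplex being
present as soon as one of its families has one copy in one taxon.

## The synthetic generator

The generator emits exactly the structure the analysis assumes, with a
truth table as the oracle. The fixed species tree has 20 taxa — six query
(host) taxa, four host outgroups on the same side of the root, six algal
taxa (the donor lineage), and four distant other-reference taxa — with
branch lengths giving roughly 70% within-host and 50% cross-clade identity
at the default rate of 0.6 substitutions per site per unit length. Family
lengths are uniform on [200, 600]; the default scenario has 12 families
spanning all six subcomplexes, two of which (the Nup98 and Rae1 analogs)
are transferred.

Sequence evolution is a background-frequency jump process: along a branch
of length *t* each site substitutes with probability `1 - exp(-rate * t)`
(optionally scaled by gamma site rates), the replacement drawn from the
background excluding the current residue. There is no closed-form identity
formula for this process across multiple branches; the test oracle instead
multiplies the exact per-branch transition matrices and checks observed
divergence within three standard errors. Site 1 is an invariant initiator
methionine. Two selection-like constraints keep the truth table honest:
root N-termini are resampled, and branch outcomes redrawn, whenever the
first 40 residues would read as a signal peptide under the generator's own
SP model — vertical copies are SP-free *by definition* in the truth table,
and nucleoporins are nucleoplasmic proteins under purifying selection
against spurious secretory targeting. Only the first 40 positions are
affected; all divergence statistics beyond them are untouched.

EGT is modelled as a single event: the donor tip's sequence diverges along
a stem of length 0.1 and then descends vertically along the query subtree,
so the transferred copies form a supported clade sister to the donor —
which is what a real transfer leaves behind. When `sp_on_egt` is on, each
transferred copy gains a prefix of Met, two basic residues, 8–10
hydrophobics from {L,V,A,F,I}, and an A-x-A cleavage motif; the prefix and
the heuristic are co-designed and make no claim of biological realism.
Decoy paralog families are evolved from a family root along an extra stem
of 0.4 and down the same species tree, with their own reference alignments
and registry entries; 0.4 keeps every decoy above the search threshold
(at 0.8 they fall out of the search entirely and the purge has nothing to
do) while remaining a clearly separated, wrongly-assigned clade. Losses,
within-taxon duplications, and N-terminal truncation (a uniform 10–50%
slice, with `nterm=incomplete` metadata) are all off by default — the
default scenario is the clean two-copy headline case — and are switched on
per test. Because the generator knows site homology and evolves no indels,
reference alignments are exact and ungapped; alignment inference is not
the system under test.

What passing on this generator does **not** show: robustness to indels and
alignment error, to long-branch attraction (the classifier reports
supports and leaves such artifacts to the user), to compositional
heterogeneity, or to the divergence depths where NJ is inferior to
likelihood methods. Those caveats are inherited by any claim about real
data.

## Determinism, seeds, and problem sizes

Every stochastic step (calibration decoys, bootstrap resampling, the
generator) runs under an explicit seed; the pipeline fans a single master
seed out to per-stage seeds through a stage-name hash, so toggling one
stage never shifts another's random stream, and identical configurations
produce byte-identical output files. The test suite exercises the
default-condition scenario across 25 seeds for provenance recovery, six
pure-host seeds for the false-positive rate, decoy scenarios for the
purge, and 50-tree batches for the distance machinery; the vignette-scale
examples and unit tests use a four-family mini scenario with lengths
150–250. These sizes are the package's chosen desk-scale study conditions;
all thresholds above (E-value `1e-5`, top 200, support > 70, three purge
cycles, purity 0.8, margin 2 bits) are the screening procedure's own
parameters, exposed in `run_config()`.

## A worked mini example

```{r example, eval = FALSE}
bundle <- generate_scenario(scenario_config(seed = 1))
res <- run_all(run_config(seed = 1, bundle = bundle))
copy_counts(res$inventory)
subset(res$subcomplex, group == "nucleomorph_derived" & present)
```

On the default scenario this prints a 12 x 6 count matrix with every
non-transferred family single-copy, the two transferred families two-copy,
and a pseudo-nucleomorph group containing only the central channel and the
cytoplasmic complex — the machine-readable form of the finding that a
transferred Nup98/Rae1 pair is not enough to build a canonical pore.
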