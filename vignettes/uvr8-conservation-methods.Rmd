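---
title: "Scanning UVR8-like proteins for functional-site conservation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning UVR8-like proteins for functional-site conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvr8scan)
```

## The biological question

UVR8 is the plant UV-B photoreceptor. Unlike every other photoreceptor it
carries no prosthetic chromophore: UV-B is perceived directly by tryptophan
residues, held in place by a Gly-Trp-Arg-His-Thr (GWRHT) pentapeptide
repeated in blades 5, 6 and 7 of its seven-bladed beta-propeller. In
Arabidopsis those motifs put the chromophore tryptophans at positions 233,
285 and 337; W285 is the main sensor, W233 contributes to perception and
exciton coupling, and W337 is auxiliary. In darkness UVR8 is a homodimer
held by salt bridges — R286 (blade 6) and R338 (blade 7) of one monomer
against D96/D107 (blade 2) and E43/D44 (blade 1) of the other — and
mutating either arginine yields a constitutive monomer. Downstream
signalling runs through a Val-Pro ("VP") dipeptide inside the C-terminal
27-residue region (C27, reference residues 397–423) that binds COP1 and the
RUP repressors.

Whether a candidate protein from another species is a *functional* UVR8
therefore reduces to a concrete, position-level question: after aligning it
to the Arabidopsis reference, does it retain the GWRHT motifs, the
tryptophan triad, the six dimer-interface residues and the VP core?
`uvr8scan` operationalises that question as a reproducible pipeline and
ships a simulator that generates UVR8-like families with known ground
truth, so every stage can be validated end to end without any database
download.

## The scanning model

Each candidate is globally aligned to the reference by Needleman–Wunsch
with affine gaps (BLOSUM62; gap open 10, extension 0.5; a gap of length
$L$ costs $10 + 0.5(L-1)$; terminal gaps are penalised). These are
ordinary protein-alignment defaults, and all are configurable. The
alignment engine is `Biostrings::pairwiseAlignment`; the test suite pins
its scores to an independent exhaustive-enumeration oracle over all global
alignments of short random pairs, so the scoring convention above is
checked, not assumed.

The alignment induces a *coordinate map*: the strictly increasing partial
map pairing reference and query positions at residue–residue columns.
Percent identity is defined over those aligned residue–residue columns
(the denominator is stated because conventions differ). Every annotated
site is then projected through the map:

* **Motifs.** The anchor interval (e.g. 284–288 for blade 6) is projected
  and widened by a slack of 5 residues on each side — enough to absorb
  small indels near the site without letting the scanner wander. Every
  placement of the pattern in the window is scored; the best placement
  (fewest non-conservative mismatches, then fewest total mismatches, then
  leftmost) determines the call:
  * `EXACT` — canonical pattern;
  * `CONSERVATIVE` — deviations only at non-invariant positions, inside
    that position's conservative set. For GWRHT these sets are exactly the
    substitutions observed in real homologs: R↔K at position 3 and T↔S at
    position 5. The W at position 2 is *invariant*: it is the chromophore,
    so no substitution there can ever be conservative;
  * `DEGRADED` — at most 2 non-conservative mismatches **and** strictly
    fewer than half the pattern positions. For the 5-mer this is the 1–2
    band that keeps the oomycete-style GWSHT and diatom-style GWSHS forms
    visible as degraded motifs rather than absences. For the VP dipeptide
    the rule means any mismatch is already `ABSENT`: a "degraded"
    half-matched dipeptide carries no signal, and without this guard a
    deleted VP is almost always rescued by a chance one-mismatch placement
    in the 27-residue window;
  * `ABSENT` — worse at every placement;
  * `UNALIGNED` — the anchor does not project at all, e.g. a C-terminally
    truncated model lacking the C27 region. This is deliberately distinct
    from `ABSENT`, because truncated gene models are an annotation
    artefact, not evidence the motif was lost.
* **Residues.** Single positions are projected and compared by identity.
  The definitions carry conservative sets (D↔E, R↔K) but these are only
  honoured under an opt-in flag: presence/absence tallies of the interface
  residues are identity-based by default.
* **Census.** The tryptophan census reports the total W count of the query
  and how many of the reference's 14 W positions project onto a W.

An `X` (unknown residue) never satisfies any check — conservative calling
in the face of incomplete sequence.

## Classification tiers

The tier rule uses blade 6 (the motif containing W285) and the VP core:

| tier | condition |
|---|---|
| `STRICT_HOMOLOG` | blade-6 GWRHT exact/conservative **and** VP exact |
| `PUTATIVE_HOMOLOG` | blade-6 present, VP not exact |
| `REMOTE_RCC1_LIKE` | blade-6 not present, identity < 40% |
| `NON_HOMOLOG` | otherwise |

The strict/putative split exists because the two lines of evidence can
genuinely disagree: several green-algal UVR8s lack the VP core yet are
clearly UVR8, so a single "homolog" verdict would either overclaim or
discard them. Both tallies are always reported with explicit denominators.

The remote tier was designed to be *monotone*: improving any single site
call can never demote a sequence. An alternative formulation ("remote only
if no blade motif is better than degraded") breaks monotonicity — a
low-identity sequence would be demoted from remote to non-homolog by
*improving* its blade-5 motif — so the rule here conditions only on blade-6
presence and identity. Low-identity beta-propellers without an intact
blade 6 are exactly the RCC1-like background the tier is named for.

Photoreception competence requires W233 and W285 exact (W337 is not
required); dimer competence requires all six interface residues present,
and a missing arginine or acidic partner predicts a constitutive monomer.

## Conservation summaries

Site tallies count `EXACT`/`CONSERVATIVE` calls as present by default,
since conservatively substituted motifs are counted among conserved
homologs; a strict `EXACT`-only mode is a flag. Percentages are rounded
half-up to integers — the convention is unconstrained by the worked
examples the package reproduces (97/102 → 95, 101/102 → 99, etc., all
below .5 fractions), so it is simply fixed and documented. Copy-number
summaries count homolog-tier sequences per species and report the share of
multi-copy species and the copy-count distribution among them, always with
denominators.

## The phylogeny stage

The tree stage is a deliberately simple, exactly testable stand-in for a
full MSA + model-based workflow (MAFFT/BMGE/PhyML-style), and makes no
claim of equivalence to any of those tools:

1. **Pseudo-MSA** — pairwise alignments are stacked on reference
   coordinates; insertions relative to the reference are dropped. This
   gives a rectangular matrix whose columns are reference positions, at
   the cost of ignoring query-specific insertions (acceptable here, since
   the reference defines the coordinate system of interest).
2. **Column filter** — a column is kept if its gap fraction is ≤ 0.5 and
   its normalized Shannon entropy (natural log over residue frequencies,
   gaps excluded, divided by log 20) is ≤ 0.5. Gaps count toward the gap
   fraction but not the entropy.
3. **p-distances** — mismatch fraction over mutually ungapped kept
   columns; a pair with no comparable columns is an error naming the pair,
   not a silent zero.
4. **Neighbor joining** — canonical NJ (`ape::nj`), which exactly recovers
   topology *and* branch lengths for additive distances; that exactness is
   what the test suite leans on (50 random additive matrices per run).
   Negative branch-length estimates on non-additive input are clamped to
   zero with a warning, the standard practice. NJ replaces
   maximum-likelihood inference on purpose: the trees here are sanity
   instruments over synthetic families, and NJ's additive-case exactness
   makes it testable where ML is not.
5. **Bootstrap** — kept columns are resampled with replacement; each
   internal bipartition of the full-data tree is labelled with the percent
   of replicate NJ trees containing it. Deterministic given a seed.

## The synthetic-data generator

The simulator is the package's source of ground truth. The scaffold is a
440-residue protein (long enough for the C27 region ending at 423 plus a
short tail) carrying the three GWRHT motifs at 232–236/284–288/336–340,
E43/D44/D96/D107, a VP at 410–411 (any position inside 397–423 would be
consistent; one was fixed for determinism) and 11 further tryptophans at
fixed positions, for the canonical total of 14. Background positions are
drawn from a uniform distribution over the 19 non-W residues — W is
excluded so the census is exactly 14 by construction. The scaffold
validates under the same annotation code as any user-supplied reference.

Families evolve root-to-leaf along a random (or supplied) binary tree.
On each branch every eligible site substitutes with a fixed probability
(default 0.02, the low-divergence regime in which site calls should be
perfectly recoverable; 0.05 is used for topology-recovery experiments),
drawing uniformly from the 19 alternative residues. Indel events are
Poisson per branch with geometric lengths. With invariant-site protection
on (the default), annotated positions receive no background substitutions
and indels avoid them, so the ground truth equals the knockout directive
list exactly; protection can be switched off for realism experiments.
Knockouts (`delete`, `to_alanine`, `conservative_swap`) are applied at
named leaves and recorded in a truth table.

What the generator does *not* emulate: site-heterogeneous rates, codon
structure, matrix-conditioned substitution preferences, alignment-hostile
repeat regions, and database-scale paralogy. Passing the recovery tests
therefore shows the pipeline is correct *given* clean alignments and
low-to-moderate divergence; it does not certify behaviour on remote,
gappy real retrievals, where the identity screen and the
`UNALIGNED`/`ABSENT` distinction do the heavy lifting.

A subtlety the knockout tests must respect: annotated sites physically
overlap (W233 sits inside the blade-5 motif; W285 and R286 inside blade 6;
W337 and R338 inside blade 7). A knockout editing a shared position
necessarily flags every overlapping site, so "detected at exactly the
targeted pair" is scored against the set of sites whose reference
positions intersect the edited positions. With that definition, detection
precision and recall are 100% across all 13 annotated sites at background
substitution probability 0.02.

## Problem sizes and determinism

The shipped validation uses deliberately small instances — families of
4–12 leaves on a 440-residue scaffold, 20 topology-recovery replicates, 50
additive matrices, 200 oracle alignment pairs — chosen so the whole suite
re-runs in well under a minute while still exercising every code path at
its documented operating point. Every stochastic step (scaffold
background, family evolution, bootstrap, simulations in the validation
script) takes an explicit integer seed, and every pipeline stage writes a
JSON manifest of its inputs, parameters and seeds; identical configuration
yields byte-identical outputs.

## Known limitations

* Pairwise reference anchoring, not a true progressive MSA: positional
  calls are only as good as each pairwise alignment, and insertions
  relative to the reference are invisible to the tree stage.
* The identity screen's 40% threshold is inherited from practice, and
  identity is computed over aligned columns only; sequences aligning over
  a short fragment can show inflated identity.
* The column filter is a two-parameter heuristic, not a trimming tool with
  smoothing windows.
* NJ trees are instruments for recovery testing, not publishable
  phylogenies; no model selection, no rate heterogeneity.
* De-duplication of isoforms is out of scope; copy-number summaries count
  sequences as given.

```{r example, eval = FALSE}
# end-to-end on a simulated family
cfg <- list(
  scaffold = list(length = 440, seed = 1),
  evolution = list(subst_prob = 0.02, seed = 7),
  species_design = list(
    list(species = "Physcomitrella patens", copies = 2, clade = "bryophyte"),
    list(species = "Arabidopsis thaliana", copies = 1, clade = "dicot")))
ds <- run_simulate(cfg, "demo_out")
res <- run_pipeline(ds$paths$fasta, "demo_out",
                    metadata_tsv = ds$paths$metadata, seed = 1)
res$classification
```
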