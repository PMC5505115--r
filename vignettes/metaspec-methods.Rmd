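---
title: "Assembling de novo protein sequence from multi-protease, multi-dissociation spectra"
author: "metaspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling de novo protein sequence from multi-protease, multi-dissociation spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaspec)
```

## The problem

Venoms and other proteomes from organisms without a sequenced genome
cannot be analysed by ordinary peptide-spectrum matching: there is no
database to match against, and single-spectrum de novo sequencing rarely
yields more than a short, error-prone tag. `metaspec` implements the
alternative strategy of *assembling* sequence from many spectra at once.
The experimental design it targets digests each sample with several
proteases (including a deliberately partial digest), so that peptides
overlap, and fragments every selected precursor with three dissociation
chemistries — CID, HCD, and ETD — so that every peptide bond is probed by
complementary ion series. The analysis then proceeds in five stages:

1. **PRM conversion.** Each MS/MS spectrum becomes a *prefix residue
   mass* (PRM) spectrum: a list of hypothesised cumulative N-terminal
   residue masses with log-odds scores. A b ion at cut site $k$ and the
   y ion at the complementary site corroborate the same PRM mass
   $p_k = \sum_{i \le k} m_i$; c and z ions do likewise with their own
   offsets.
2. **Triple merging.** The CID, HCD and ETD PRM spectra of one precursor
   are merged by adding the scores of matching masses, concentrating
   evidence that no single chemistry provides.
3. **Spectral network.** Merged PRM spectra of *different* peptides are
   aligned by a mass shift; a shift $\Delta$ with many matched masses
   means the peptides overlap, offset by a prefix of mass $\Delta$.
   Spectra and significant alignments form a graph whose connected
   components group peptides from one protein region.
4. **A-Bruijn assembly.** Matched peaks across a component are glued
   into vertices; the heaviest path through the resulting DAG is the
   contig, and its consensus masses with summed scores form the
   *meta-contig* — a consensus PRM spectrum that can span far more
   residues than any single peptide.
5. **Readout and mapping.** Adjacent consensus-mass differences are
   called as residue letters when exactly one residue mass fits, and as
   bracketed gap masses (e.g. `[227.31]`) otherwise; the gapped strings
   are placed on homologous database proteins with a mass-tolerant
   aligner, and a greedy maximum-parsimony step reports the smallest
   protein set explaining all meta-contigs.

A worked miniature: two ideal peptides overlapping by three residues
assemble into their union.

```{r worked}
a <- ideal_prm("GASP"); b <- ideal_prm("ASPK")
al <- align_pair(a, b, min_matches = 2)
al$shift                       # the mass of "G": b is offset by one glycine
mc <- to_meta_contig(consensus_path(glue(list(a, b), list(al)), "demo"))
format_denovo_string(sequence_consensus(mc))
```

## The scoring model

The original likelihood models for PRM scoring are not published in a
reusable form, so the package declares its own monotone
intensity-likelihood model (`scoring_model()`): a peak of intensity rank
$r$ read through ion series $s$ scores
$\log(\mathrm{LR}(r)\,\pi_s / \lambda_0)$, with rank tiers top-10 /
top-25 / top-50 / rest at likelihood ratios 8/4/2/1, series priors
CID $b=y=0.4$, HCD $b=y=0.35,\ a=0.1$, ETD $c=z^\bullet=0.45$, and noise
likelihood $\lambda_0 = 1$. Every value is a config-overridable default,
not a fitted quantity; all that downstream stages rely on is that the
score is a log-odds-like quantity, increasing in intensity, additive
under corroboration, and occasionally negative for weak evidence.

Both the N- and the C-terminal interpretation of every peak are always
generated. This is deliberate: a lone b ion cannot reveal which terminus
it extends, and the ambiguity is resolved by corroboration — across the
triple, across the network — rather than by a premature choice.

## Mirror images and cross-chemistry corroboration

Generating both interpretations creates a systematic artifact: the b/y
pair that corroborates the true mass $p_k$ also places a *mirror* mass
at $M - p_k$ (b read as y, y read as b). In CID and HCD the mirror falls
at exactly the same spurious position, so within those two chemistries
it is indistinguishable from signal. ETD breaks the symmetry: c and z
offsets place the corresponding artifact at $M - p_k - 15.035$ Da, never
at the CID/HCD mirror position. True prefix masses are therefore the
only masses corroborated by all three chemistries, and
`sparsify_prm(min_modes = 3)` — applied by the pipeline between merging
and network construction — retains essentially the pure prefix ladder on
clean data. This filter is the package's formalisation of why the
triple-dissociation design enables assembly at all. On noisy real data a
user may prefer `min_modes = 2` at the cost of more mirror clutter.

## Alignment: search, significance, and chimera control

`align_pair()` enumerates candidate shifts from all pairwise mass
differences (with virtual boundary masses 0 and $M$), and evaluates each
candidate with an exact monotone-matching dynamic program that maximises
the summed score of matched pairs. A greedy left-to-right matcher was
considered and rejected: it is not guaranteed optimal when several peaks
fall inside one tolerance window, and the package's own test suite
checks `align_pair()` against exhaustive enumeration on small instances,
which only an exact matcher passes. After the best candidate is chosen,
the reported shift is re-centred on the median of its matched-pair
differences, so a single displaced peak cannot bias the coordinate
frames propagated during assembly.

Residue-mass ladders are heavily quantised, and sums of residues collide
— exactly (GG = N, and any transposition) or nearly (K vs Q at
0.0364 Da, Q vs GA at $10^{-5}$ Da). Chance alignments between unrelated
peptides are therefore far more common than continuous-mass intuition
suggests, and they are the principal failure mode of assembly: a single
false edge welds two unrelated regions into a chimeric contig. Three
declared thresholds control this:

* `min_matches` — `align_pair()` defaults to 5; the pipeline requires 7.
  In all-vs-all comparison of hundreds of spectra, six-boundary
  coincidences (five-residue isobaric runs such as `NIGTW` ≡ `NLGTW`)
  occur at an appreciable rate; seven matched boundaries push the
  expected count of chance edges per run below one.
* `min_frac = 0.8` — a true overlap explains its window: inside the
  overlapping mass range, essentially every peak of either spectrum
  should belong to a matched pair. Coincidental alignments match only
  scattered peaks (at most about two-thirds of the in-window score in
  our calibrations on the synthetic design), while genuine noiseless
  overlaps sit at 1.0; the default separates the two populations.
* `min_score` — decoy-calibrated by default: `decoy_min_score()` aligns
  shuffled-mass versions of sampled spectrum pairs and returns twice the
  mean best decoy score.

`allow_offset = TRUE` additionally searches alignments with one internal
offset change (two shifts), the signature of a single unanticipated
modification mass; such edges are annotated for inspection but never
used by assembly.

## Assembly details

Within a component, coordinate frames are propagated from an anchor (the
highest-total-score spectrum) along a maximum-score spanning tree;
non-tree edges whose shift disagrees with the propagated frames by more
than `frame_tol` (0.35 Da) are dropped as inconsistent cycles. Gluing is
a union-find over matched peak pairs that refuses to place two peaks of
one spectrum in one vertex; vertices whose member frame masses spread
beyond `frame_tol` are split. Unmatched peaks stay as singleton vertices
— they may carry true ladder masses that only one digest sampled. The
contig is the heaviest path (by summed vertex score) through the DAG
whose edges connect vertices holding consecutive peaks of some member
spectrum; ties prefer more member peaks, then lower mass. Contig
coordinates are translated so the leftmost member peptide starts at 0,
which makes both contig boundaries true residue boundaries and lets the
readout call the terminal residues.

Two places need a robust average instead of a plain score-weighted mean.
First, log-odds scores can be negative, so weights are floored at a
small positive value. Second, a single-linkage merge cluster can chain a
near-collision candidate (e.g. at the K/Q offset of 0.0364 Da) onto a
corroborated mass; averaging over all members would drag the consensus
past the residue-calling tolerance and turn one correct call into two
gaps. `merge_triple()` therefore re-clusters each merge cluster at
`fine_tol` (0.02 Da, the high-resolution readout precision) and takes
the score-weighted mean of the *strongest coherent sub-population*,
while the cluster's full score is retained so that score conservation
(checked to $10^{-9}$ in the tests) is exact.

## Readout and mapping

`sequence_consensus()` calls a residue when exactly one entry of the
calling table lies within `call_tol` of an adjacent mass difference.
The default of 0.02 Da is deliberately tighter than any single ion-trap
spectrum would justify: consensus masses average many corroborating
observations. At 0.02 Da lysine (128.09496) and glutamine (128.05858)
are distinguishable; at looser user-set tolerances such differences
become bracketed gaps, which is why published gapped strings often show
masses like `[128.106]` where a residue seems obvious. I and L are
isobaric and always reported as `I`; the equivalence is restored during
database mapping. Gap masses print with three decimals, trailing zeros
trimmed, and the parser preserves printed digits verbatim so that
`format(parse(s))` is the identity on any published string.

`align_denovo_to_protein()` permits no insertions or deletions: residue
elements must match exactly (I ≡ L) and each gap element must consume
1–6 protein residues whose mass sum lies within `gap_tol` (0.05 Da) of
the gap. Scoring is the count of matched residue elements with
`min_matched = 6`; the study-style report ("homologous sequences" =
sequences with a qualifying match; "proteins" = greedy-parsimony
selection) follows.

## What the synthetic generator emulates — and what it does not

`generate_proteome()` draws sequences i.i.d. uniform over the 20
residues; `fractionate()` splits at 10 kDa by residue-mass sum; the four
digests are trypsin 4 h (each susceptible site cut with probability
0.5), trypsin 18 h, chymotrypsin 18 h, and pepsin 18 h (probability
0.9) — the only stated difference between the two trypsin digests is
incubation time, and partial digestion is precisely what produces the
overlapping peptides assembly needs. Products of 6–30 residues whose
precursor falls inside the m/z 350–1800 survey window at charge 2–3
yield one CID/HCD/ETD triple each (optionally via a top-3 DDA simulation
with Gaussian elution and 60 s dynamic exclusion). Cysteine always
carries carbamidomethyl (+57.02146 Da). The digestion-completeness
probabilities and DDA depth are declared stand-ins: the emulated study
does not quantify either.

The generator does **not** emulate isotope envelopes, fragment charges
above 1+, retention-time structure beyond Gaussian profiles, variable
modifications, non-uniform residue usage, or homologous protein
families. Passing the recovery tests therefore shows that the assembly
machinery is correct under its stated model, not that real venom data
would reach the same accuracy; on real data the scoring model, the
`min_modes` filter, and the alignment thresholds all face conditions the
simulation deliberately idealises. Paralogous toxin isoforms — abundant
in real venoms — are the known hard case: their genuinely shared
subsequences produce valid cross-isoform alignments that no local
significance test can reject, and contigs are then reported as assembled
(possibly chimeric across isoforms), as any assembly method would.

## Problem sizes and reproducibility

The bundled test suite and the acceptance script run the full design at
10 proteins of 60–200 residues (about 250 triples across the two mass
fractions), a size at which the all-vs-all network stage completes in
seconds on one core; the same code scales to a few thousand spectra
within minutes. Every stochastic step — proteome, digestion, acquisition,
decoy calibration — derives from the single config seed, and reruns are
bit-identical (checked file-by-file in the tests). The frozen
configuration is written as YAML into each run directory.

```{r summary}
res <- run_pipeline(pipeline_config(seed = 1,
                                    out_dir = file.path(tempdir(), "vig")))
res$summary
ground_truth_recovery(res)[c("n_meta_contigs", "frac_mapped_to_source",
                             "residue_accuracy", "parsimony_equals_truth")]
```

## Known limitations

* Fragment charge is fixed at 1+ in PRM conversion; 2+ fragments of
  3+ precursors are misplaced (they typically fail corroboration and are
  filtered, costing sensitivity rather than accuracy).
* Neutral-loss series are not modelled.
* The PTM-offset alignment mode annotates a single internal mass offset
  and does not localise it.
* Greedy set-cover parsimony is the standard approximation, not an
  exact minimum cover (the tests bound its gap on small instances).
* Table-style counts from any specific published study depend on its
  raw data and acquisition depth and are not reproduced by the synthetic
  design; the pipeline reproduces the count *categories* and the
  method's behaviour under ground truth.
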